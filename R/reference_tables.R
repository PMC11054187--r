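#' Literature-reported MM-GBSA components for inhibitor-bromodomain binding
#'
#' Published component means and standard deviations (kcal/mol) for three
#' inhibitors (H1B, JQ1, TVU) bound to the BRD4 and BRD9 bromodomains:
#' gas-phase electrostatics (dEele), van der Waals (dEvdw),
#' generalized-Born polar solvation (dGgb), nonpolar surface term
#' (dGsurf) and the entropy contribution (-TdS), together with the
#' polar-sum and total binding free energies as printed
#' (`dGpol_printed`, `dGbind_printed`) and the experimental estimate
#' `dGexp` from IC50 where available. Shipped as a plain TSV under
#' `extdata`; used to exercise the aggregation and cross-system
#' comparison arithmetic on real-scale numbers.
#'
#' Note: the printed dGpol of the H1B-BRD9 complex (3.62) is internally
#' inconsistent with its own components (dEele + dGgb = 8.53); the
#' component columns are the authoritative inputs.
#'
#' @return data.frame, one row per complex.
#' @export
reference_energy_components <- function() {
  path <- system.file("extdata", "brd_gbsa_reference.tsv",
                      package = "bindscape", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Binding free energy of one reference complex
#'
#' Feeds the tabulated component means of a complex into
#' [aggregate_binding_free_energy()] with its tabulated entropy term.
#'
#' @param system "BRD4" or "BRD9".
#' @param inhibitor "H1B", "JQ1" or "TVU".
#' @return a `binding_free_energy`.
#' @export
reference_binding_free_energy <- function(system, inhibitor) {
  tab <- reference_energy_components()
  row <- tab[tab$system == system & tab$inhibitor == inhibitor, ]
  if (nrow(row) != 1) stopf("unknown complex %s-%s", inhibitor, system)
  aggregate_binding_free_energy(
    c(dEele = row$dEele, dEvdw = row$dEvdw, dGgb = row$dGgb,
      dGsurf = row$dGsurf),
    neg_TdS = row$neg_TdS, neg_TdS_method = "supplied")
}
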