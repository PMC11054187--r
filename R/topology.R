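#' Build a molecular topology
#'
#' A topology is the static description of a system: one row per atom
#' (name, element, 1-based residue index, residue name, chain), plus an
#' optional per-atom parameter table used by the energetics module
#' (partial charge in e, Lennard-Jones sigma in Angstrom, epsilon in
#' kcal/mol, intrinsic Born radius in Angstrom, mass in amu).
#'
#' Residue indices must be non-decreasing along the atom list and every
#' residue must own at least one atom. All analysis code treats residue
#' numbering as 1-based, matching PDB convention.
#'
#' @param atom_name character vector of atom names (e.g. "CA").
#' @param element character vector of element symbols.
#' @param res_index integer vector, 1-based residue sequence numbers.
#' @param res_name character vector of residue names.
#' @param chain optional chain identifiers (read but ignored by analysis).
#' @param params optional data.frame with columns `charge`, `sigma`,
#'   `epsilon`, `born_radius`, `mass`, one row per atom.
#' @return An object of class `topology`.
#' @export
topology <- function(atom_name, element, res_index, res_name,
                     chain = NULL, params = NULL) {
  n <- length(atom_name)
  if (n == 0L) stopf("topology must contain at least one atom")
  if (length(element) != n || length(res_index) != n || length(res_name) != n) {
    stopf("atom_name, element, res_index and res_name must have equal length")
  }
  res_index <- as.integer(res_index)
  if (any(diff(res_index) < 0L)) {
    stopf("atom residue indices must be non-decreasing")
  }
  if (is.null(chain)) chain <- rep(NA_character_, n)
  atoms <- data.frame(
    name = as.character(atom_name),
    element = as.character(element),
    res_index = res_index,
    res_name = as.character(res_name),
    chain = as.character(chain),
    stringsAsFactors = FALSE
  )
  if (!is.null(params)) {
    params <- validate_atom_params(params, n)
  }
  idx <- unique(res_index)
  spans <- lapply(idx, function(r) range(which(res_index == r)))
  residues <- data.frame(
    res_index = idx,
    res_name = atoms$res_name[vapply(spans, `[`, 1L, 1L)],
    first_atom = vapply(spans, `[`, 1L, 1L),
    last_atom = vapply(spans, `[`, 1L, 2L),
    stringsAsFactors = FALSE
  )
  structure(list(atoms = atoms, residues = residues, params = params),
            class = "topology")
}

validate_atom_params <- function(params, n_atoms) {
  need <- c("charge", "sigma", "epsilon", "born_radius", "mass")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols) > 0) {
    stopf("parameter table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(params) != n_atoms) {
    stopf("parameter table has %d rows but topology has %d atoms",
          nrow(params), n_atoms)
  }
  as.data.frame(params[, need], stringsAsFactors = FALSE)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues%s\n",
              n_atoms(x), n_residues(x),
              if (is.null(x$params)) "" else ", parameterized"))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a `topology`.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Number of residues in a topology
#' @param top a `topology`.
#' @export
n_residues <- function(top) nrow(top$residues)

#' Indices of atoms selected by name
#'
#' @param top a `topology`.
#' @param selection one of `"calpha"` (atoms named CA), `"backbone"`
#'   (N, CA, C, O), `"heavy"` (element != H) or `"all"`; alternatively an
#'   integer vector of atom indices, passed through unchanged.
#' @return integer atom indices.
#' @export
select_atoms <- function(top, selection = "all") {
  if (is.numeric(selection)) return(as.integer(selection))
  sel <- match.arg(selection, c("calpha", "backbone", "heavy", "all"))
  switch(sel,
    calpha = which(top$atoms$name == "CA"),
    backbone = which(top$atoms$name %in% c("N", "CA", "C", "O")),
    heavy = which(toupper(top$atoms$element) != "H"),
    all = seq_len(n_atoms(top))
  )
}

# index of the selected atom for each residue (used by contact maps);
# errors naming the residue when the atom is absent.
residue_atom_indices <- function(top, atom = "CA") {
  idx <- vapply(seq_len(n_residues(top)), function(i) {
    span <- top$residues$first_atom[i]:top$residues$last_atom[i]
    hit <- span[top$atoms$name[span] == atom]
    if (length(hit) == 0) {
      stopf("residue %d (%s) has no %s atom", top$residues$res_index[i],
            top$residues$res_name[i], atom)
    }
    hit[1]
  }, integer(1))
  idx
}

topologies_identical <- function(a, b) {
  isTRUE(all.equal(a$atoms[c("name", "element", "res_index", "res_name")],
                   b$atoms[c("name", "element", "res_index", "res_name")],
                   check.attributes = FALSE))
}

# first differing atom between two topologies (for error messages)
first_topology_difference <- function(a, b) {
  if (n_atoms(a) != n_atoms(b)) return(min(n_atoms(a), n_atoms(b)) + 1L)
  cols <- c("name", "element", "res_index", "res_name")
  for (i in seq_len(n_atoms(a))) {
    for (cl in cols) {
      if (!identical(a$atoms[[cl]][i], b$atoms[[cl]][i])) return(i)
    }
  }
  0L
}

#' Read a per-atom parameter table
#'
#' Reads a whitespace/tab separated table keyed by atom serial with
#' columns `serial`, `charge`, `sigma`, `epsilon`, `born_radius`, `mass`,
#' `residue`, `name`, and attaches the parameters to a topology in atom
#' order.
#'
#' @param path path to the TSV file.
#' @param top the `topology` the parameters describe.
#' @return `top` with the `params` slot filled.
#' @export
read_atom_params <- function(path, top) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("serial", "charge", "sigma", "epsilon", "born_radius", "mass")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stopf("parameter file lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) != n_atoms(top)) {
    stopf("parameter file has %d rows but topology has %d atoms",
          nrow(tab), n_atoms(top))
  }
  tab <- tab[order(tab$serial), ]
  top$params <- validate_atom_params(tab, n_atoms(top))
  top
}

#' Write a per-atom parameter table
#'
#' @param top a parameterized `topology`.
#' @param path output path.
#' @export
write_atom_params <- function(top, path) {
  if (is.null(top$params)) stopf("topology carries no parameters")
  tab <- cbind(serial = seq_len(n_atoms(top)), top$params,
               residue = top$atoms$res_index, name = top$atoms$name)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a structural-domain annotation
#'
#' Domains are named, 1-based inclusive residue ranges (for bromodomains:
#' the alphaZ/alphaA/alphaB/alphaC helices and the ZA/BC loops). The file
#' is a 3-column table `name start end`, tab or whitespace separated,
#' without header.
#'
#' @param path path to the annotation table.
#' @param top optional `topology`; when given, ranges are validated
#'   against its residue numbering.
#' @return a `domain_annotation` data.frame with columns `name`, `start`,
#'   `end`.
#' @export
read_domain_annotation <- function(path, top = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("name", "start", "end"))
  domain_annotation(tab$name, tab$start, tab$end, top = top)
}

#' Construct a domain annotation
#'
#' @param name domain names.
#' @param start,end 1-based inclusive residue ranges.
#' @param top optional `topology` for range validation.
#' @export
domain_annotation <- function(name, start, end, top = NULL) {
  d <- data.frame(name = as.character(name), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  if (any(d$end < d$start)) {
    bad <- which(d$end < d$start)[1]
    stopf("domain '%s' has end < start", d$name[bad])
  }
  covered <- integer(0)
  for (i in seq_len(nrow(d))) {
    rng <- d$start[i]:d$end[i]
    if (any(rng %in% covered)) {
      stopf("domain '%s' overlaps a previous domain", d$name[i])
    }
    covered <- c(covered, rng)
  }
  if (!is.null(top)) {
    lo <- min(top$residues$res_index); hi <- max(top$residues$res_index)
    if (any(d$start < lo) || any(d$end > hi)) {
      stopf("domain annotation extends outside topology residues [%d, %d]",
            lo, hi)
    }
  }
  class(d) <- c("domain_annotation", "data.frame")
  d
}

# map residue index -> domain name ("unassigned" when uncovered)
domain_of_residue <- function(domains, res_index) {
  out <- rep("unassigned", length(res_index))
  for (i in seq_len(nrow(domains))) {
    hit <- res_index >= domains$start[i] & res_index <= domains$end[i]
    out[hit] <- domains$name[i]
  }
  out
}
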