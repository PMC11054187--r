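#' Build and validate a pipeline configuration
#'
#' The configuration is the single source of truth of a run: synthetic
#' generation parameters, stage toggles and every stage parameter, with
#' defaults matching the analysis conventions of the package (contact
#' cutoff 4.5 Angstrom, 80/20 split, 30 epochs, 100 x 100 landscape bins
#' at 300 K, gamma = 0.0072, beta = 0). It may be given as a named list
#' or as a path to a YAML/JSON file.
#'
#' @param config named list, or path to a YAML or JSON config file.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  defaults <- list(
    seed = 1L,
    n_residues = 40L,
    n_classes = 3L,
    frames_per_class = 300L,
    sigma = 0.3,
    contact_cutoff = 4.5,
    atom_rule = "calpha",
    split_fraction = 0.8,
    epochs = 30L,
    batch_size = 64L,
    lr = 1e-3,
    fel_bins = 100L,
    temperature = 300,
    basin_threshold = 0.5,
    gamma = 0.0072,
    beta = 0,
    eps_in = 1,
    eps_solv = 78.5,
    gbsa_frames = 100L,
    stages = c("simulate", "featurize", "train", "attribute", "metrics",
               "pca", "gbsa", "report")
  )
  cfg <- utils::modifyList(defaults, config)
  if (cfg$gamma < 0) stopf("invalid config: gamma must be non-negative")
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1) {
    stopf("invalid config: split_fraction must be in (0, 1)")
  }
  if (cfg$sigma <= 0) stopf("invalid config: sigma must be > 0")
  if (cfg$seed != round(cfg$seed)) stopf("invalid config: seed must be integer")
  unknown <- setdiff(cfg$stages,
                     c("simulate", "featurize", "train", "attribute",
                       "metrics", "pca", "gbsa", "report"))
  if (length(unknown) > 0) {
    stopf("invalid config: unknown stage '%s'", unknown[1])
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

default_domain_layout <- function(n_residues) {
  # six contiguous blocks named after the bromodomain fold elements
  edges <- round(seq(0, n_residues, length.out = 7))
  domain_annotation(
    name = c("alphaZ", "ZA-loop", "alphaA", "alphaB", "BC-loop", "alphaC"),
    start = edges[1:6] + 1, end = edges[2:7])
}

default_planted_classes <- function(domains, n_classes) {
  # one planted inter-domain contact per class, each in a different block
  picks <- list(c(1, 4), c(2, 6), c(3, 5), c(1, 6), c(2, 5), c(3, 6))
  lapply(seq_len(n_classes), function(k) {
    p <- picks[[(k - 1) %% length(picks) + 1]]
    mid <- function(d) (domains$start[d] + domains$end[d]) %/% 2
    matrix(c(mid(p[1]), mid(p[2])), ncol = 2)
  })
}

stage_log <- function(run_log, stage, t0, files) {
  message(sprintf("[%s] done in %.1fs (%d files)", stage,
                  as.numeric(Sys.time() - t0, units = "secs"), length(files)))
  c(run_log, stats::setNames(list(files), stage))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes the configured stages in dependency order: `simulate`
#' (generate the K-class ensembles and the toy ligand complex),
#' `featurize` (contact maps and images), `train` (CNN classification),
#' `attribute` (representative-cluster saliency, masked and aggregated
#' to domain pairs), `metrics` (RMSD/RMSF/RG/SASA summaries), `pca`
#' (eigenvalues, projections, free-energy landscape, basins), `gbsa`
#' (binding free-energy components, entropy, per-residue decomposition)
#' and `report` (summary document). All outputs are plain-text tables
#' under `output_dir`, and a run manifest (effective config, seeds,
#' per-stage files with checksums) is written last.
#'
#' @param config a `pipeline_config` (or anything accepted by
#'   [pipeline_config()]).
#' @param output_dir output directory (created if needed).
#' @param resume skip stages whose outputs already exist in a manifest.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), output_dir, resume = FALSE) {
  cfg <- pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(output_dir, "manifest.json")
  prev <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL
  stage_done <- function(stage) {
    !is.null(prev) && stage %in% names(prev$stages) &&
      all(file.exists(file.path(output_dir, unlist(prev$stages[[stage]]))))
  }
  run_log <- list()
  state <- new.env(parent = emptyenv())

  want <- function(stage) stage %in% cfg$stages && !stage_done(stage)
  need_sim <- any(vapply(c("simulate", "featurize", "train", "attribute",
                           "metrics", "pca"), want, logical(1)))

  domains <- default_domain_layout(cfg$n_residues)
  spec <- synthetic_spec(
    n_residues = cfg$n_residues,
    classes = default_planted_classes(domains, cfg$n_classes),
    domains = domains, sigma = cfg$sigma,
    frames_per_class = cfg$frames_per_class, seed = cfg$seed)

  if (need_sim) {
    state$gen <- generate_class_ensembles(spec)
  }

  if (want("simulate")) {
    t0 <- Sys.time(); files <- character(0)
    for (k in seq_along(state$gen$class_ensembles)) {
      f <- sprintf("class%d.pdb", k)
      write_multimodel_pdb(subset_frames(state$gen$class_ensembles[[k]],
                                         seq_len(min(20, cfg$frames_per_class))),
                           file.path(output_dir, f))
      files <- c(files, f)
    }
    gt <- state$gen$ground_truth
    jsonlite::write_json(
      list(classes = lapply(gt$classes, function(m) unclass(m)),
           n_residues = gt$n_residues, seed = gt$seed),
      file.path(output_dir, "ground_truth.json"), auto_unbox = TRUE)
    files <- c(files, "ground_truth.json")
    utils::write.table(as.data.frame(domains)[c("name", "start", "end")],
                       file.path(output_dir, "domains.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    files <- c(files, "domains.tsv")
    run_log <- stage_log(run_log, "simulate", t0, files)
  }

  if (any(vapply(c("featurize", "train", "attribute"), want, logical(1)))) {
    stacks <- lapply(state$gen$class_ensembles, contact_map_stack,
                     cutoff = cfg$contact_cutoff, atom_rule = cfg$atom_rule)
    ds <- join_image_datasets(lapply(seq_along(stacks), function(k) {
      set_labels(maps_to_images(stacks[[k]]),
                 rep(k, nrow(stacks[[k]]$maps)))
    }))
    ds <- split_train_val(ds, cfg$split_fraction, seed = cfg$seed)
    state$ds <- ds
  }

  if (want("featurize")) {
    t0 <- Sys.time()
    utils::write.csv(data.frame(image = seq_along(state$ds$labels),
                                label = state$ds$labels,
                                split = state$ds$split),
                     file.path(output_dir, "image_index.csv"),
                     row.names = FALSE)
    run_log <- stage_log(run_log, "featurize", t0, "image_index.csv")
  }

  if (any(vapply(c("train", "attribute"), want, logical(1)))) {
    model <- build_model(cnn_spec(cfg$n_residues, cfg$n_classes,
                                  epochs = cfg$epochs,
                                  batch_size = cfg$batch_size, lr = cfg$lr,
                                  seed = cfg$seed))
    state$fit <- train_classifier(model, state$ds)
  }

  if (want("train")) {
    t0 <- Sys.time()
    utils::write.csv(state$fit$history,
                     file.path(output_dir, "training_history.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(state$fit$confusion),
                     file.path(output_dir, "confusion_matrix.csv"),
                     row.names = FALSE)
    run_log <- stage_log(run_log, "train", t0,
                         c("training_history.csv", "confusion_matrix.csv"))
  }

  if (want("attribute")) {
    t0 <- Sys.time(); files <- character(0)
    for (k in seq_along(state$gen$class_ensembles)) {
      rep_k <- most_populated_representative(
        state$gen$class_ensembles[[k]], contact_cutoff = cfg$contact_cutoff,
        atom_rule = cfg$atom_rule)
      sal <- vanilla_gradient_saliency(state$fit$model,
                                       rep_k$contact_map, class = k)
      sal <- mask_and_aggregate(sal, rep_k$contact_map, domains)
      f <- sprintf("saliency_domains_class%d.tsv", k)
      utils::write.table(sal$domain_table, file.path(output_dir, f),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      files <- c(files, f)
    }
    run_log <- stage_log(run_log, "attribute", t0, files)
  }

  if (want("metrics")) {
    t0 <- Sys.time()
    ens <- state$gen$ensemble
    rs <- rmsd_series(ens, selection = "calpha")
    utils::write.csv(data.frame(frame = seq_along(rs$values),
                                rmsd = rs$values),
                     file.path(output_dir, "rmsd.csv"), row.names = FALSE)
    rf <- rmsf(ens)
    utils::write.csv(data.frame(residue = as.integer(names(rf)), rmsf = rf),
                     file.path(output_dir, "rmsf.csv"), row.names = FALSE)
    rg <- radius_of_gyration(ens)
    utils::write.csv(data.frame(frame = seq_along(rg), rg = rg),
                     file.path(output_dir, "rg.csv"), row.names = FALSE)
    run_log <- stage_log(run_log, "metrics", t0,
                         c("rmsd.csv", "rmsf.csv", "rg.csv"))
  }

  if (want("pca")) {
    t0 <- Sys.time()
    ens <- state$gen$ensemble
    model <- build_pca(ens)
    utils::write.csv(variance_fractions(model,
                                        k = min(6, length(model$eigenvalues))),
                     file.path(output_dir, "pca_eigenvalues.csv"),
                     row.names = FALSE)
    proj <- project_ensemble(ens, model)
    utils::write.csv(data.frame(frame = seq_len(nrow(proj)),
                                pc1 = proj[, 1], pc2 = proj[, 2]),
                     file.path(output_dir, "pca_projections.csv"),
                     row.names = FALSE)
    fel <- free_energy_landscape(proj, bins = cfg$fel_bins,
                                 temperature = cfg$temperature)
    utils::write.table(fel$free_energy,
                       file.path(output_dir, "fel_grid.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    basins <- find_basins(fel, cfg$basin_threshold, proj = proj)
    jsonlite::write_json(as.data.frame(basins),
                         file.path(output_dir, "basins.json"),
                         auto_unbox = TRUE, digits = NA)
    run_log <- stage_log(run_log, "pca", t0,
                         c("pca_eigenvalues.csv", "pca_projections.csv",
                           "fel_grid.tsv", "basins.json"))
  }

  if (want("gbsa")) {
    t0 <- Sys.time()
    sys <- generate_ligand_system(seed = cfg$seed, n_frames = cfg$gbsa_frames,
                                  salt_bridge = TRUE)
    settings <- gbsa_settings(cfg$eps_in, cfg$eps_solv, cfg$gamma, cfg$beta)
    comp <- ensemble_components(sys$ensemble, sys$receptor_atoms,
                                sys$ligand_atoms, settings,
                                n_frames = cfg$gbsa_frames)
    utils::write.csv(comp, file.path(output_dir, "gbsa_components.csv"),
                     row.names = FALSE)
    tds <- quasiharmonic_entropy(sys$ensemble,
                                 temperature = cfg$temperature)
    bfe <- aggregate_binding_free_energy(comp, as.numeric(tds),
                                         attr(tds, "method"))
    summ <- data.frame(
      term = c("dEele", "dEvdw", "dGgb", "dGsurf", "dGpol", "neg_TdS",
               "dGbind"),
      mean = c(bfe$mean, bfe$dGpol, bfe$neg_TdS, bfe$dGbind),
      sd = c(bfe$sd, NA, NA, NA))
    utils::write.table(summ, file.path(output_dir, "gbsa_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dec <- per_residue_decomposition(sys$ensemble, sys$receptor_atoms,
                                     sys$ligand_atoms, settings,
                                     n_frames = min(20, cfg$gbsa_frames))
    utils::write.table(dec, file.path(output_dir, "residue_decomposition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$bfe <- bfe
    run_log <- stage_log(run_log, "gbsa", t0,
                         c("gbsa_components.csv", "gbsa_summary.tsv",
                           "residue_decomposition.tsv"))
  }

  if (want("report")) {
    t0 <- Sys.time()
    lines <- c("# Pipeline report", "",
               sprintf("seed: %d", cfg$seed),
               sprintf("residues: %d, classes: %d, frames/class: %d",
                       cfg$n_residues, cfg$n_classes, cfg$frames_per_class))
    if (!is.null(state$fit)) {
      lines <- c(lines, "",
                 sprintf("validation accuracy: %.2f%%", state$fit$accuracy),
                 "confusion matrix (rows = true):",
                 utils::capture.output(print(state$fit$confusion)))
    }
    if (!is.null(state$bfe)) {
      lines <- c(lines, "", "binding free energy (kcal/mol):",
                 utils::capture.output(print(state$bfe)))
    }
    writeLines(lines, file.path(output_dir, "report.md"))
    run_log <- stage_log(run_log, "report", t0, "report.md")
  }

  # merge stages kept from a resumed manifest
  stages_out <- run_log
  if (!is.null(prev)) {
    for (st in names(prev$stages)) {
      if (!st %in% names(stages_out) && stage_done(st)) {
        stages_out[[st]] <- unlist(prev$stages[[st]])
      }
    }
  }
  all_files <- unique(unlist(stages_out))
  manifest <- list(
    package = "bindscape",
    version = as.character(utils::packageVersion("bindscape")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(cfg),
    stages = stages_out,
    files = lapply(stats::setNames(all_files, all_files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(output_dir, f))))
    })
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
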