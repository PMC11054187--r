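#' Residue contact map of a single frame
#'
#' Binary N x N residue adjacency: M[i, j] = 1 iff the selected-atom
#' distance between residues i and j is at or below the cutoff
#' (inclusive). The default rule measures Calpha-Calpha distances at
#' 4.5 Angstrom; `"closest-heavy"` measures the minimum distance over
#' heavy-atom pairs instead.
#'
#' @param coords A x 3 coordinate matrix of one frame.
#' @param top the `topology`.
#' @param cutoff Angstrom, inclusive (default 4.5).
#' @param atom_rule `"calpha"` or `"closest-heavy"`.
#' @return N x N binary (0/1) symmetric matrix with unit diagonal.
#' @export
contact_map <- function(coords, top, cutoff = 4.5,
                        atom_rule = c("calpha", "closest-heavy")) {
  atom_rule <- match.arg(atom_rule)
  n <- n_residues(top)
  if (atom_rule == "calpha") {
    idx <- residue_atom_indices(top, "CA")
    D <- as.matrix(stats::dist(coords[idx, , drop = FALSE]))
  } else {
    heavy <- select_atoms(top, "heavy")
    if (length(heavy) == 0) stopf("no heavy atoms in topology")
    res_of <- top$atoms$res_index[heavy]
    missing_res <- setdiff(top$residues$res_index, unique(res_of))
    if (length(missing_res) > 0) {
      stopf("residue %d has no heavy atom", missing_res[1])
    }
    Da <- as.matrix(stats::dist(coords[heavy, , drop = FALSE]))
    grp <- match(res_of, top$residues$res_index)
    D <- matrix(Inf, n, n)
    for (i in seq_len(n)) {
      rows <- grp == i
      D[i, ] <- tapply(apply(Da[rows, , drop = FALSE], 2, min), grp, min)
    }
    diag(D) <- 0
  }
  M <- (D <= cutoff) * 1L
  dimnames(M) <- NULL
  M
}

#' Contact maps for every frame of an ensemble
#'
#' @param ens a `conformational_ensemble`.
#' @param cutoff Angstrom, inclusive.
#' @param atom_rule see [contact_map()].
#' @return object of class `contact_map_stack`: `maps` is an F x N^2
#'   matrix (row = frame, column-major pixels), `n` the residue count.
#' @export
contact_map_stack <- function(ens, cutoff = 4.5,
                              atom_rule = c("calpha", "closest-heavy")) {
  atom_rule <- match.arg(atom_rule)
  n <- n_residues(ens$topology)
  maps <- t(vapply(seq_len(n_frames(ens)), function(f) {
    as.vector(contact_map(frame_coords(ens, f), ens$topology, cutoff,
                          atom_rule))
  }, numeric(n * n)))
  structure(list(maps = maps, n = n, cutoff = cutoff, atom_rule = atom_rule),
            class = "contact_map_stack")
}

#' @export
print.contact_map_stack <- function(x, ...) {
  cat(sprintf("<contact_map_stack> %d frames, %d x %d, cutoff %.2f A (%s)\n",
              nrow(x$maps), x$n, x$n, x$cutoff, x$atom_rule))
  invisible(x)
}

# recover the N x N matrix of one frame
stack_map <- function(stack, frame) matrix(stack$maps[frame, ], stack$n, stack$n)

#' Convert contact maps to a grayscale image dataset
#'
#' Pixel = 1.0 (white) where residues are in contact, 0.0 otherwise;
#' image f corresponds to frame f. Thresholding an image at 0.5
#' reproduces the original binary map.
#'
#' @param stack a `contact_map_stack`.
#' @return object of class `image_dataset` with `pixels` (F x N^2 in
#'   [0, 1]), `n`, and empty `labels` / `split`.
#' @export
maps_to_images <- function(stack) {
  structure(list(pixels = stack$maps * 1.0, n = stack$n,
                 labels = NULL, split = NULL),
            class = "image_dataset")
}

#' Attach class labels to an image dataset
#' @param ds an `image_dataset`.
#' @param labels integer class id per image (1-based).
#' @export
set_labels <- function(ds, labels) {
  if (length(labels) != nrow(ds$pixels)) {
    stopf("need one label per image")
  }
  ds$labels <- as.integer(labels)
  ds
}

#' Merge image datasets (frames concatenated, labels preserved)
#' @param datasets list of `image_dataset` objects of equal image size.
#' @export
join_image_datasets <- function(datasets) {
  n <- unique(vapply(datasets, function(d) d$n, numeric(1)))
  if (length(n) != 1) stopf("image sizes differ")
  structure(list(pixels = do.call(rbind, lapply(datasets, `[[`, "pixels")),
                 n = n,
                 labels = unlist(lapply(datasets, `[[`, "labels")),
                 split = NULL),
            class = "image_dataset")
}

#' Stratified train/validation split
#'
#' Randomly assigns `fraction` of each class to training and the rest to
#' validation, deterministically under the seed.
#'
#' @param ds a labelled `image_dataset`.
#' @param fraction training fraction (default 0.8).
#' @param seed integer seed.
#' @return the dataset with `split` filled ("train"/"val" per image).
#' @export
split_train_val <- function(ds, fraction = 0.8, seed = 1) {
  if (is.null(ds$labels)) stopf("dataset has no labels")
  if (fraction <= 0 || fraction >= 1) {
    stopf("training fraction must be in (0, 1)")
  }
  split <- rep(NA_character_, nrow(ds$pixels))
  with_seed(seed, {
    for (k in sort(unique(ds$labels))) {
      idx <- which(ds$labels == k)
      if (length(idx) < 2) stopf("class %d has fewer than 2 images", k)
      n_tr <- round(fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      tr <- sample(idx, n_tr)
      split[tr] <- "train"
      split[setdiff(idx, tr)] <- "val"
    }
  })
  ds$split <- split
  ds
}
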