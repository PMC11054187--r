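#' Representative frame of the most populated structural cluster
#'
#' Frames are clustered by average-linkage hierarchical clustering on
#' pairwise best-fit Calpha RMSD, the tree is cut at `cutoff` Angstrom,
#' and the medoid (frame minimizing summed RMSD within the largest
#' cluster) is returned together with its contact map — the map used to
#' mask saliency attributions. Ties in cluster size, and ties in the
#' medoid criterion, are broken toward the lower frame index.
#'
#' @param ens a `conformational_ensemble`.
#' @param cutoff tree cut height in Angstrom (default 2.0).
#' @param max_frames cap on frames entering the O(F^2) RMSD matrix;
#'   larger ensembles are evenly strided down to this size before
#'   clustering (default 200).
#' @param contact_cutoff,atom_rule passed to [contact_map()].
#' @return list with `frame` (index into `ens`), `contact_map`,
#'   `cluster_sizes`.
#' @export
most_populated_representative <- function(ens, cutoff = 2.0,
                                          max_frames = 200,
                                          contact_cutoff = 4.5,
                                          atom_rule = "calpha") {
  sel <- select_atoms(ens$topology, "calpha")
  frames <- unique(round(seq(1, n_frames(ens),
                             length.out = min(max_frames, n_frames(ens)))))
  nf <- length(frames)
  if (nf == 1) {
    return(list(frame = frames[1],
                contact_map = contact_map(frame_coords(ens, frames[1]),
                                          ens$topology, contact_cutoff,
                                          atom_rule),
                cluster_sizes = 1L))
  }
  # precenter the selected coordinates once
  mats <- lapply(frames, function(f) {
    m <- frame_coords(ens, f)[sel, , drop = FALSE]
    sweep(m, 2, colMeans(m))
  })
  sq <- vapply(mats, function(m) sum(m^2), numeric(1))
  na <- nrow(mats[[1]])
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    for (j in seq(i + 1, nf)) {
      H <- crossprod(mats[[i]], mats[[j]])
      sv <- svd(H)
      d <- sign(det(sv$v %*% t(sv$u)))
      tr <- sum(sv$d * c(1, 1, d))
      msd <- max((sq[i] + sq[j] - 2 * tr) / na, 0)
      D[i, j] <- D[j, i] <- sqrt(msd)
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  cl <- stats::cutree(hc, h = cutoff)
  sizes <- table(cl)
  best_size <- max(sizes)
  cands <- as.integer(names(sizes)[sizes == best_size])
  # lower-index tie-break: the candidate cluster containing the earliest frame
  first_member <- vapply(cands, function(k) min(which(cl == k)), integer(1))
  big <- cands[which.min(first_member)]
  members <- which(cl == big)
  sums <- vapply(members, function(i) sum(D[i, members]), numeric(1))
  medoid <- members[which.min(sums)]
  rep_frame <- frames[medoid]
  list(frame = rep_frame,
       contact_map = contact_map(frame_coords(ens, rep_frame),
                                 ens$topology, contact_cutoff, atom_rule),
       cluster_sizes = as.integer(sizes))
}

#' Mask a saliency map and aggregate it over domain pairs
#'
#' The raw gradient map is multiplied elementwise by the representative
#' contact map (attributions off real contacts are zeroed), then summed
#' over structural-domain blocks: entry (a, b) of the table is the total
#' masked |attribution| of residue pairs (i in a, j in b, i <= j).
#' Residues not covered by the annotation are reported under
#' "unassigned". When the domains tile the sequence, the table total
#' equals the total masked attribution of the upper triangle.
#'
#' @param sal a `saliency_result` from [vanilla_gradient_saliency()].
#' @param representative_map N x N binary contact map of the most
#'   populated cluster's representative.
#' @param domains a `domain_annotation`.
#' @return the `saliency_result` with `masked` and `domain_table`
#'   (data.frame `domain_a`, `domain_b`, `attribution`, sorted
#'   decreasing) filled in.
#' @export
mask_and_aggregate <- function(sal, representative_map, domains) {
  n <- nrow(sal$raw)
  if (!all(dim(representative_map) == c(n, n))) {
    stopf("saliency map and contact map shapes disagree")
  }
  masked <- sal$raw * representative_map
  dom <- domain_of_residue(domains, seq_len(n))
  dom_names <- unique(c(domains$name, if (any(dom == "unassigned")) "unassigned"))
  pairs <- expand.grid(a = seq_along(dom_names), b = seq_along(dom_names))
  pairs <- pairs[pairs$a <= pairs$b, ]
  attribution <- vapply(seq_len(nrow(pairs)), function(r) {
    ia <- which(dom == dom_names[pairs$a[r]])
    ib <- which(dom == dom_names[pairs$b[r]])
    block <- masked[ia, ib, drop = FALSE]
    # count each unordered residue pair once (upper triangle incl. diagonal)
    keep <- outer(ia, ib, "<=")
    if (pairs$a[r] != pairs$b[r]) {
      block2 <- masked[ib, ia, drop = FALSE]
      keep2 <- outer(ib, ia, "<=")
      sum(block * keep) + sum(block2 * keep2)
    } else {
      sum(block * keep)
    }
  }, numeric(1))
  tab <- data.frame(domain_a = dom_names[pairs$a],
                    domain_b = dom_names[pairs$b],
                    attribution = attribution,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$attribution), ]
  rownames(tab) <- NULL
  sal$masked <- masked
  sal$domain_table <- tab
  sal
}
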