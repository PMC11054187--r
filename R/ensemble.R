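#' Construct a conformational ensemble
#'
#' An ensemble couples a topology with an F x 3A coordinate matrix
#' (one row per frame, xyz interleaved per atom, Angstrom) and a frame
#' provenance table recording which run each frame came from. This is the
#' universal input of every analysis stage; independent runs merged into
#' one ensemble play the role of a single merged trajectory.
#'
#' @param top a `topology`.
#' @param xyz numeric matrix F x 3A (or a single frame as a length-3A
#'   vector / A x 3 matrix).
#' @param provenance optional data.frame with columns `run`, `frame`.
#' @return an object of class `conformational_ensemble`.
#' @export
conformational_ensemble <- function(top, xyz, provenance = NULL) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) == 3 && nrow(xyz) == n_atoms(top) && n_atoms(top) != 3) {
    xyz <- matrix(mat_to_xyz(xyz), nrow = 1)
  }
  if (ncol(xyz) != 3L * n_atoms(top)) {
    stopf("coordinate matrix has %d columns; expected 3 x %d atoms",
          ncol(xyz), n_atoms(top))
  }
  if (nrow(xyz) < 1L) stopf("ensemble must contain at least one frame")
  if (!all(is.finite(xyz))) stopf("coordinates must be finite")
  if (is.null(provenance)) {
    provenance <- data.frame(run = "run1", frame = seq_len(nrow(xyz)) - 1L,
                             stringsAsFactors = FALSE)
  }
  if (nrow(provenance) != nrow(xyz)) {
    stopf("provenance must have one row per frame")
  }
  structure(list(topology = top, xyz = unname(as.matrix(xyz)),
                 provenance = provenance),
            class = "conformational_ensemble")
}

#' @export
print.conformational_ensemble <- function(x, ...) {
  cat(sprintf("<conformational_ensemble> %d frames, %d atoms, %d residues\n",
              n_frames(x), n_atoms(x$topology), n_residues(x$topology)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens a `conformational_ensemble`.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Coordinates of one frame as an A x 3 matrix
#' @param ens a `conformational_ensemble`.
#' @param frame 1-based frame index.
#' @export
frame_coords <- function(ens, frame = 1L) {
  if (frame < 1L || frame > n_frames(ens)) stopf("frame %d out of range", frame)
  xyz_to_mat(ens$xyz[frame, ])
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each MODEL becomes one frame; a file without MODEL records yields a
#' single-frame ensemble. Atom order must be identical across models: a
#' model with a differing atom count is a hard error naming the model.
#' Residue indices are taken from the PDB residue sequence numbers.
#'
#' @param path path to a PDB file.
#' @return a `conformational_ensemble`.
#' @export
read_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (!any(is_atom)) stopf("no ATOM records found in '%s'", path)
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    counts <- vapply(seq_along(model_starts), function(k) {
      hi <- if (k <= length(model_ends)) model_ends[k] else length(lines)
      sum(is_atom[model_starts[k]:hi])
    }, integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stopf("MODEL %d has %d atoms; expected %d", bad, counts[bad], counts[1])
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  elem <- atom$elesy
  if (is.null(elem) || all(is.na(elem))) {
    elem <- substr(trimws(atom$elety), 1, 1)
  }
  top <- topology(
    atom_name = trimws(atom$elety),
    element = ifelse(is.na(elem) | elem == "",
                     substr(trimws(atom$elety), 1, 1), trimws(elem)),
    res_index = atom$resno,
    res_name = trimws(atom$resid),
    chain = atom$chain
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  conformational_ensemble(top, xyz)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates round-trip through the fixed-width PDB format to three
#' decimals; values outside the representable range of the 8.3 coordinate
#' field are rejected.
#'
#' @param ens a `conformational_ensemble`.
#' @param path output path.
#' @export
write_multimodel_pdb <- function(ens, path) {
  if (n_frames(ens) < 1) stopf("ensemble has no frames")
  if (any(ens$xyz > 9999.999) || any(ens$xyz < -999.999)) {
    stopf("coordinates overflow the fixed-width PDB coordinate field")
  }
  top <- ens$topology
  chain <- top$atoms$chain
  chain[is.na(chain)] <- " "
  bio3d::write.pdb(
    file = path,
    xyz = ens$xyz,
    resno = top$atoms$res_index,
    resid = top$atoms$res_name,
    elety = top$atoms$name,
    chain = chain
  )
  invisible(path)
}

#' Join independent ensembles into a single merged ensemble
#'
#' Concatenates frames of runs that share a topology, preserving run
#' provenance — the merged-trajectory convention under which all
#' downstream analyses operate.
#'
#' @param ensembles a list of `conformational_ensemble` objects.
#' @return a single `conformational_ensemble`.
#' @export
join_ensembles <- function(ensembles) {
  if (inherits(ensembles, "conformational_ensemble")) return(ensembles)
  if (length(ensembles) == 0) stopf("no ensembles to join")
  ref <- ensembles[[1]]
  for (k in seq_along(ensembles)[-1]) {
    if (!topologies_identical(ref$topology, ensembles[[k]]$topology)) {
      i <- first_topology_difference(ref$topology, ensembles[[k]]$topology)
      stopf("topology mismatch in ensemble %d at atom %d", k, i)
    }
  }
  xyz <- do.call(rbind, lapply(ensembles, function(e) e$xyz))
  prov <- do.call(rbind, lapply(seq_along(ensembles), function(k) {
    p <- ensembles[[k]]$provenance
    if (length(unique(p$run)) == 1 && p$run[1] == "run1" && length(ensembles) > 1) {
      p$run <- sprintf("run%d", k)
    }
    p
  }))
  conformational_ensemble(ref$topology, xyz, prov)
}

#' Read a plain per-frame coordinate table as an ensemble
#'
#' Dialect for synthetic data: a whitespace-separated table with columns
#' `frame atom x y z` (1-based indices, Angstrom), no header required.
#'
#' @param path path to the table.
#' @param top the `topology` the coordinates belong to.
#' @return a `conformational_ensemble`.
#' @export
read_coord_table <- function(path, top) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("frame", "atom", "x", "y", "z"))
  frames <- sort(unique(tab$frame))
  a <- n_atoms(top)
  xyz <- matrix(NA_real_, length(frames), 3 * a)
  for (k in seq_along(frames)) {
    sub <- tab[tab$frame == frames[k], ]
    sub <- sub[order(sub$atom), ]
    if (nrow(sub) != a) {
      stopf("frame %s has %d atoms; expected %d", frames[k], nrow(sub), a)
    }
    xyz[k, ] <- mat_to_xyz(as.matrix(sub[, c("x", "y", "z")]))
  }
  conformational_ensemble(top, xyz)
}

#' Write an ensemble as a plain coordinate table
#' @param ens a `conformational_ensemble`.
#' @param path output path.
#' @export
write_coord_table <- function(ens, path) {
  a <- n_atoms(ens$topology)
  tab <- do.call(rbind, lapply(seq_len(n_frames(ens)), function(f) {
    m <- frame_coords(ens, f)
    data.frame(frame = f, atom = seq_len(a),
               x = m[, 1], y = m[, 2], z = m[, 3])
  }))
  utils::write.table(tab, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a subset of frames
#' @param ens a `conformational_ensemble`.
#' @param frames integer frame indices (1-based).
#' @export
subset_frames <- function(ens, frames) {
  frames <- as.integer(frames)
  if (any(frames < 1L) || any(frames > n_frames(ens))) {
    stopf("frame index out of range")
  }
  conformational_ensemble(ens$topology, ens$xyz[frames, , drop = FALSE],
                          ens$provenance[frames, , drop = FALSE])
}
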