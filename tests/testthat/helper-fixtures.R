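# Shared fixtures: everything is generated in code at test time.

# n Calpha beads with unit-ish parameters
bead_top <- function(n, mass = 12.011, charge = 0, sigma = 3.4,
                     epsilon = 0.1, born = 1.7) {
  topology(
    atom_name = rep("CA", n), element = rep("C", n),
    res_index = seq_len(n), res_name = rep("ALA", n),
    chain = rep("A", n),
    params = data.frame(charge = charge, sigma = sigma, epsilon = epsilon,
                        born_radius = born, mass = mass)[rep(1, n), ]
  )
}

# ensemble with given per-frame A x 3 coordinate list
ens_from_frames <- function(top, frames) {
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  conformational_ensemble(top, xyz)
}

random_ensemble <- function(n_atoms = 5, n_frames = 3, seed = 1) {
  set.seed(seed)
  top <- bead_top(n_atoms)
  xyz <- matrix(round(runif(n_frames * 3 * n_atoms, -50, 50), 3),
                nrow = n_frames)
  conformational_ensemble(top, xyz)
}

rot_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# the standard 3-class planted-contact spec used across CNN tests
planted_spec <- function(n_res = 40, frames = 300, sigma = 0.3, seed = 7) {
  synthetic_spec(n_res, list(c(4, 28), c(12, 37), c(20, 33)),
                 domains = six_domain_layout(n_res),
                 sigma = sigma, frames_per_class = frames, seed = seed)
}

six_domain_layout <- function(n_res = 40) {
  edges <- round(seq(0, n_res, length.out = 7))
  domain_annotation(
    c("alphaZ", "ZA-loop", "alphaA", "alphaB", "BC-loop", "alphaC"),
    edges[1:6] + 1, edges[2:7])
}

# labelled, split image dataset from a planted-contact spec
planted_dataset <- function(spec) {
  gen <- generate_class_ensembles(spec)
  stacks <- lapply(gen$class_ensembles, contact_map_stack)
  ds <- join_image_datasets(lapply(seq_along(stacks), function(k) {
    set_labels(maps_to_images(stacks[[k]]), rep(k, nrow(stacks[[k]]$maps)))
  }))
  list(ds = split_train_val(ds, 0.8, seed = spec$seed), gen = gen)
}
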