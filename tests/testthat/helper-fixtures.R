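# Shared fixture builders for the test suite. All fixtures are generated
# in code; nothing is read from disk except files the tests write.

# small rigid helper: rotation matrix about z then x
rotation_matrix <- function(theta = 0.7, phi = 0.3) {
  rz <- matrix(c(cos(theta), -sin(theta), 0,
                 sin(theta),  cos(theta), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0,
                 0, cos(phi), -sin(phi),
                 0, sin(phi),  cos(phi)), 3, 3, byrow = TRUE)
  rz %*% rx
}

# apply a rigid motion (rotation + translation) to every configuration
transform_dataset <- function(ds, rot = diag(3), shift = c(0, 0, 0)) {
  coords <- ds$coords
  for (i in seq_len(dim(coords)[1])) {
    coords[i, , ] <- sweep(coords[i, , ] %*% rot, 2, -shift)
  }
  landmark_dataset(coords, ds$labels,
                   specimen_id = ds$info$specimen_id,
                   genotype = ds$info$genotype,
                   age = ds$info$age,
                   trial = ds$info$trial,
                   group_label = ds$group_label)
}

# scale every coordinate of a dataset by a constant
scale_dataset <- function(ds, c) {
  landmark_dataset(ds$coords * c, ds$labels,
                   specimen_id = ds$info$specimen_id,
                   genotype = ds$info$genotype,
                   age = ds$info$age,
                   trial = ds$info$trial,
                   group_label = ds$group_label)
}

# random K-landmark dataset of n specimens, mm scale
random_dataset <- function(n = 5, k = 7, seed = 1, sd = 0.05,
                           genotype = "unaffected") {
  set.seed(seed)
  base <- matrix(runif(k * 3, 0, 8), k, 3)
  coords <- array(NA_real_, dim = c(n, k, 3))
  for (i in seq_len(n)) coords[i, , ] <- base + rnorm(k * 3, sd = sd)
  landmark_dataset(coords, sprintf("lm%02d", seq_len(k)),
                   specimen_id = sprintf("s%02d", seq_len(n)),
                   genotype = genotype, age = "E15.5")
}

# a tiny 7-landmark synthetic spec on the chondrocranial MI labels
small_spec <- function(n = 10, seed = 1, noise_sd = NULL, ...) {
  mf <- default_mean_form()[1:7, ]
  synthetic_spec(mean_form = mf, noise_sd = noise_sd,
                 module_map = default_module_map()[rownames(mf)],
                 n_per_group = n, seed = seed, ...)
}

# matched two-module panels for both genotypes from one spec
matched_panels <- function(spec) {
  sim <- simulate_two_genotypes(spec)
  regions <- cranio_regions()
  lapply(sim[c("affected", "unaffected")], function(ds) {
    build_distance_panel(select_region(ds, regions$chondro_MI),
                         select_region(ds, regions$dermato_MI))
  })
}
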