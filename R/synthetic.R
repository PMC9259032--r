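#' Default synthetic mean form
#'
#' A 14-landmark configuration combining the 7 chondrocranial and 7
#' dermatocranial morphological-integration landmark labels, placed at
#' plausible millimetre-scale positions for a late-embryonic mouse skull
#' (x: anteroposterior, y: mediolateral, z: dorsoventral). This is a
#' documented synthetic fixture, not measured anatomy.
#'
#' @return a 14 x 3 numeric matrix with landmark rownames, mm.
#' @export
default_mean_form <- function() {
  m <- rbind(
    # chondrocranium (lateral wall/roof + posterior septum)
    psep   = c(2.5,  0.0, 1.0),
    lncse  = c(2.8, -0.9, 1.6),
    rncse  = c(2.8,  0.9, 1.6),
    laottr = c(4.0, -1.5, 2.2),
    raottr = c(4.0,  1.5, 2.2),
    lttr   = c(4.6, -1.7, 2.8),
    rttr   = c(4.6,  1.7, 2.8),
    # dermatocranium (frontal/parietal dermal bone)
    laif   = c(3.4, -1.3, 1.8),
    raif   = c(3.4,  1.3, 1.8),
    lalf   = c(3.6, -0.6, 2.4),
    lpfl   = c(5.2, -1.9, 2.6),
    rpfl   = c(5.2,  1.9, 2.6),
    lpto   = c(6.3, -1.0, 3.0),
    rpto   = c(6.3,  1.0, 3.0)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

#' Default module map for the synthetic mean form
#' @return named character vector: landmark -> module.
#' @export
default_module_map <- function() {
  c(psep = "chondro", lncse = "chondro", rncse = "chondro",
    laottr = "chondro", raottr = "chondro", lttr = "chondro",
    rttr = "chondro",
    laif = "dermato", raif = "dermato", lalf = "dermato",
    lpfl = "dermato", rpfl = "dermato", lpto = "dermato",
    rpto = "dermato")
}

#' Specify a synthetic landmark-data generating model
#'
#' The generator draws each specimen by scaling the mean form about each
#' module's centroid with a specimen-specific random scale and adding
#' isotropic Gaussian landmark noise:
#' \deqn{X_{ik} = c_m + s_i^{(m)} (M_k - c_m) + E_{ik}}
#' with \eqn{s_i^{(m)} = 1 + \gamma_m u_i + \delta_m v_i^{(m)}}, where
#' \eqn{u_i \sim N(0,1)} is shared across modules (driving
#' between-module integration), \eqn{v_i^{(m)} \sim N(0,1)} is
#' module-specific (driving within-module integration), and
#' \eqn{E_{ik} \sim N(0, \sigma^2 I_3)} is landmark noise. For the
#' affected group, each `group_scaling` entry first scales its landmark
#' subset about the subset centroid by its factor, so within-subset
#' distances carry an exact multiplicative group effect.
#'
#' @param mean_form K x 3 coordinate matrix with landmark rownames (mm);
#'   default [default_mean_form()].
#' @param noise_sd isotropic landmark noise sd in mm; default 2% of the
#'   mean inter-landmark distance of `mean_form`.
#' @param module_map named character vector landmark -> module; landmarks
#'   not listed form a module of their own with zero loadings.
#' @param gamma named numeric: per-module loading on the shared factor
#'   (between-module integration); default 0.
#' @param delta named numeric: per-module loading on the module factor
#'   (within-module integration); default 0.
#' @param group_scaling list of entries `list(labels =, factor =)`
#'   applied to the affected group's mean form; default none.
#' @param n_per_group specimens per group; default 10.
#' @param seed integer master seed; per-group substreams are derived
#'   deterministically from it.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mean_form = default_mean_form(),
                           noise_sd = NULL,
                           module_map = default_module_map(),
                           gamma = NULL, delta = NULL,
                           group_scaling = list(),
                           n_per_group = 10L, seed = 1L) {
  mean_form <- as.matrix(mean_form)
  if (is.null(rownames(mean_form))) {
    stop("mean_form must have landmark rownames")
  }
  if (ncol(mean_form) != 3L) stop("mean_form must be K x 3")
  if (any(stats::dist(mean_form) == 0)) {
    stop("mean_form is degenerate: coincident landmarks")
  }
  if (is.null(noise_sd)) noise_sd <- 0.02 * mean(stats::dist(mean_form))
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (n_per_group < 1L) stop("n_per_group must be at least 1")
  labels <- rownames(mean_form)
  module_map <- module_map[names(module_map) %in% labels]
  modules <- unique(c(module_map, "other"))
  fill <- function(x) {
    out <- stats::setNames(rep(0, length(modules)), modules)
    if (!is.null(x)) out[names(x)] <- x
    out
  }
  if (length(group_scaling) && !is.null(group_scaling$labels)) {
    group_scaling <- list(group_scaling)  # single entry given bare
  }
  for (gs in group_scaling) {
    if (is.null(gs$labels) || is.null(gs$factor)) {
      stop("each group_scaling entry needs 'labels' and 'factor'")
    }
    if (gs$factor <= 0) stop("scale factors must be positive")
    unknown <- setdiff(gs$labels, labels)
    if (length(unknown)) {
      stop("group_scaling refers to unknown landmark(s): ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(list(mean_form = mean_form, noise_sd = noise_sd,
                 module_map = module_map,
                 gamma = fill(gamma), delta = fill(delta),
                 group_scaling = group_scaling,
                 n_per_group = as.integer(n_per_group),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# module assignment per landmark, "other" for unmapped
spec_modules <- function(spec) {
  labels <- rownames(spec$mean_form)
  mods <- spec$module_map[labels]
  mods[is.na(mods)] <- "other"
  stats::setNames(mods, labels)
}

# group mean form after subset scaling (affected only)
group_mean_form <- function(spec, group) {
  m <- spec$mean_form
  if (group == "affected") {
    for (gs in spec$group_scaling) {
      idx <- match(gs$labels, rownames(m))
      ctr <- colMeans(m[idx, , drop = FALSE])
      dev <- sweep(m[idx, , drop = FALSE], 2, ctr)
      m[idx, ] <- sweep(gs$factor * dev, 2, ctr, `+`)
    }
  }
  m
}

#' Simulate one group of landmark configurations
#'
#' Draws `n_per_group` specimens from the generating model of a
#' [synthetic_spec()] for one genotype group. The affected group's mean
#' form carries the spec's subset scalings. Output is deterministic
#' under the spec's seed: the group substream seed is `seed + 1`
#' (affected) or `seed + 2` (unaffected).
#'
#' @param spec a [synthetic_spec()].
#' @param group `"affected"` or `"unaffected"`.
#' @param age age metadata to stamp on the specimens (default E15.5).
#' @return a [landmark_dataset()].
#' @export
simulate_dataset <- function(spec, group = c("unaffected", "affected"),
                             age = "E15.5") {
  stopifnot(inherits(spec, "synthetic_spec"))
  group <- match.arg(group)
  m <- group_mean_form(spec, group)
  labels <- rownames(m)
  k <- nrow(m)
  n <- spec$n_per_group
  mods <- spec_modules(spec)
  mod_levels <- unique(mods)
  centroids <- lapply(stats::setNames(mod_levels, mod_levels), function(md)
    colMeans(m[mods == md, , drop = FALSE]))
  sub_seed <- spec$seed + if (group == "affected") 1L else 2L
  coords <- with_seed(sub_seed, {
    out <- array(NA_real_, dim = c(n, k, 3L))
    for (i in seq_len(n)) {
      u <- stats::rnorm(1)
      v <- stats::setNames(stats::rnorm(length(mod_levels)), mod_levels)
      for (md in mod_levels) {
        s_im <- 1 + spec$gamma[md] * u + spec$delta[md] * v[md]
        idx <- which(mods == md)
        ctr <- centroids[[md]]
        dev <- sweep(m[idx, , drop = FALSE], 2, ctr)
        out[i, idx, ] <- sweep(s_im * dev, 2, ctr, `+`)
      }
      if (spec$noise_sd > 0) {
        out[i, , ] <- out[i, , ] +
          matrix(stats::rnorm(3 * k, sd = spec$noise_sd), k, 3)
      }
    }
    out
  })
  prefix <- if (group == "affected") "aff" else "una"
  landmark_dataset(coords, labels,
                   specimen_id = sprintf("%s%03d", prefix, seq_len(n)),
                   genotype = group, age = age, trial = 1L,
                   group_label = group)
}

#' Simulate matched affected and unaffected groups with a truth report
#'
#' Wraps [simulate_dataset()] for both genotypes of a
#' [synthetic_spec()]. The truth report records, per inter-landmark
#' distance, the expected affected/unaffected mean-distance ratio:
#' the subset scale factor for distances with both endpoints inside one
#' scaled subset, 1 for distances touching no scaled landmark, and `NA`
#' for mixed distances (one endpoint scaled), whose expected ratio is
#' geometry-dependent.
#'
#' @param spec a [synthetic_spec()].
#' @param age age metadata (default E15.5).
#' @return list with `affected`, `unaffected` (landmark datasets) and
#'   `truth` (list: `pairs`, `expected_ratio`, `is_true_effect`, `seed`,
#'   `spec`).
#' @export
simulate_two_genotypes <- function(spec, age = "E15.5") {
  stopifnot(inherits(spec, "synthetic_spec"))
  affected <- simulate_dataset(spec, "affected", age = age)
  unaffected <- simulate_dataset(spec, "unaffected", age = age)
  labels <- rownames(spec$mean_form)
  pairs <- landmark_pairs(labels)
  expected <- rep(1, nrow(pairs))
  scaled_any <- character(0)
  for (gs in spec$group_scaling) {
    both_in <- pairs$a %in% gs$labels & pairs$b %in% gs$labels
    expected[both_in] <- expected[both_in] * gs$factor
    scaled_any <- union(scaled_any, gs$labels)
  }
  mixed <- xor(pairs$a %in% scaled_any, pairs$b %in% scaled_any)
  expected[mixed] <- NA_real_
  truth <- list(pairs = pairs, expected_ratio = expected,
                is_true_effect = !is.na(expected) & expected != 1,
                seed = spec$seed, spec = spec)
  list(affected = affected, unaffected = unaffected, truth = truth)
}

#' Simulate a two-group lognormal measurement table
#'
#' Generates a long-format measurement table (one variable) with
#' lognormal values and a multiplicative group effect on the affected
#' group, as a fixture for [mann_whitney()] / [compare_measurements()].
#'
#' @param n_a,n_b group sizes (affected, unaffected).
#' @param effect multiplicative effect on the affected group (1 = null).
#' @param seed integer seed.
#' @param sdlog lognormal shape parameter (default 0.5).
#' @param variable variable name (default "measurement").
#' @return data.frame: specimen_id, genotype, variable, value.
#' @export
simulate_measurement_table <- function(n_a, n_b, effect = 1, seed = 1L,
                                       sdlog = 0.5,
                                       variable = "measurement") {
  if (n_a < 1L || n_b < 1L) stop("both groups need at least 1 observation")
  if (effect <= 0) stop("effect must be positive")
  vals <- with_seed(seed, {
    c(effect * stats::rlnorm(n_a, meanlog = 0, sdlog = sdlog),
      stats::rlnorm(n_b, meanlog = 0, sdlog = sdlog))
  })
  data.frame(
    specimen_id = c(sprintf("aff%03d", seq_len(n_a)),
                    sprintf("una%03d", seq_len(n_b))),
    genotype = c(rep("affected", n_a), rep("unaffected", n_b)),
    variable = variable,
    value = vals,
    stringsAsFactors = FALSE
  )
}

#' Write / read a synthetic spec as YAML
#'
#' Serializes the generating model so simulated datasets can be
#' regenerated bit-identically from a text file.
#'
#' @param spec a [synthetic_spec()].
#' @param path file path.
#' @return `path` invisibly (write); a `synthetic_spec` (read).
#' @export
write_synthetic_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synthetic_spec"))
  obj <- list(
    labels = rownames(spec$mean_form),
    mean_form = apply(spec$mean_form, 1, as.numeric, simplify = FALSE),
    noise_sd = spec$noise_sd,
    module_map = as.list(spec$module_map),
    gamma = as.list(spec$gamma),
    delta = as.list(spec$delta),
    group_scaling = lapply(spec$group_scaling, function(gs)
      list(labels = gs$labels, factor = gs$factor)),
    n_per_group = spec$n_per_group,
    seed = spec$seed
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_synthetic_spec
#' @export
read_synthetic_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  m <- do.call(rbind, obj$mean_form)
  rownames(m) <- obj$labels
  colnames(m) <- c("x", "y", "z")
  synthetic_spec(mean_form = m, noise_sd = obj$noise_sd,
                 module_map = unlist(obj$module_map),
                 gamma = unlist(obj$gamma), delta = unlist(obj$delta),
                 group_scaling = obj$group_scaling,
                 n_per_group = obj$n_per_group, seed = obj$seed)
}
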