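#' Canonical unique landmark pairs
#'
#' All distance vectors in the package follow this ordering: column-major
#' `utils::combn` order over the canonical label order.
#'
#' @param labels character vector of landmark labels (length >= 2).
#' @return data.frame with columns `a`, `b`, one row per unique pair.
#' @export
landmark_pairs <- function(labels) {
  if (length(labels) < 2L) stop("at least 2 landmarks required")
  cmb <- utils::combn(labels, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}

#' Per-specimen inter-landmark distance matrix
#'
#' @param ds a [landmark_dataset()].
#' @return `n x C(K,2)` matrix of inter-landmark distances (mm), columns
#'   in canonical [landmark_pairs()] order.
#' @export
distance_rows <- function(ds) {
  stopifnot(inherits(ds, "landmark_dataset"))
  n <- n_configurations(ds)
  p <- choose(length(ds$labels), 2)
  out <- matrix(NA_real_, n, p)
  for (i in seq_len(n)) {
    out[i, ] <- as.vector(stats::dist(ds$coords[i, , ]))
  }
  out
}

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Form matrix of a single landmark configuration
#'
#' Converts one 3D landmark configuration into the vector of all
#' C(K,2) unique inter-landmark Euclidean distances ("form matrix").
#' Form matrices are invariant to translation, rotation and reflection of
#' the configuration, so no superimposition is ever applied.
#'
#' @param ds a [landmark_dataset()] with exactly one configuration, or a
#'   `K x 3` coordinate matrix with rownames as labels.
#' @return object of class `form_matrix`: list with `labels`, `pairs`
#'   (data.frame `a`, `b` in canonical order) and `distances` (mm).
#' @export
form_matrix <- function(ds) {
  if (is.matrix(ds)) {
    labels <- rownames(ds)
    if (is.null(labels)) labels <- sprintf("lm%02d", seq_len(nrow(ds)))
    ds <- landmark_dataset(ds, labels, specimen_id = "single")
  }
  stopifnot(inherits(ds, "landmark_dataset"))
  if (n_configurations(ds) != 1L) {
    stop("form_matrix expects a single configuration; got ",
         n_configurations(ds))
  }
  pairs <- landmark_pairs(ds$labels)
  d <- as.vector(stats::dist(ds$coords[1, , ]))
  zero <- which(d == 0)
  if (length(zero)) {
    stop("coincident landmarks (zero distance): ",
         paste(paste(pairs$a[zero], pairs$b[zero], sep = "-"),
               collapse = ", "))
  }
  structure(list(labels = ds$labels, pairs = pairs, distances = d),
            class = "form_matrix")
}

#' Mean form of a sample of configurations
#'
#' Estimates the sample mean form as a vector of mean inter-landmark
#' distances over specimens. Two estimators are provided: `"arithmetic"`,
#' the per-pair arithmetic mean of observed distances (default), and
#' `"moment"`, the variance-corrected estimator
#' `sqrt(max(mean(d^2) - var(d), eps))` familiar from the EDMA
#' literature, which corrects the upward bias of squared distances under
#' landmark noise (sample variance; zero when n = 1).
#'
#' @param ds a [landmark_dataset()] with `n >= 1` configurations.
#' @param estimator `"arithmetic"` or `"moment"`.
#' @return object of class `mean_form`: list with `labels`, `pairs`,
#'   `mean_distances`, `estimator` and `n`.
#' @export
mean_form <- function(ds, estimator = c("arithmetic", "moment")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(ds, "landmark_dataset"))
  n <- n_configurations(ds)
  if (n < 1L) stop("mean_form requires at least one configuration")
  d <- distance_rows(ds)
  m <- mean_form_from_rows(d, estimator)
  structure(list(labels = ds$labels, pairs = landmark_pairs(ds$labels),
                 mean_distances = m, estimator = estimator, n = n),
            class = "mean_form")
}

# column-wise mean form on a precomputed distance-row matrix
mean_form_from_rows <- function(d, estimator) {
  if (estimator == "arithmetic") {
    colMeans(d)
  } else {
    m2 <- colMeans(d^2)
    v <- if (nrow(d) > 1L) apply(d, 2, stats::var) else 0
    sqrt(pmax(m2 - v, 1e-12))
  }
}

#' Form-difference matrix (point ratios)
#'
#' Per-pair ratios of two samples' mean-form distances,
#' numerator-group over denominator-group. Ratios above 1 mark linear
#' distances that are larger in the numerator group. By convention the
#' affected genotype is placed in the numerator so that "larger in
#' affected" corresponds to ratio > 1.
#'
#' @param num,den [landmark_dataset()]s with identical label sets.
#' @param estimator mean-form estimator, see [mean_form()].
#' @param numerator_group,denominator_group optional display names.
#' @return object of class `form_difference`: list with `pairs`, `ratio`,
#'   and group names (no confidence intervals; see [bootstrap_fdm_ci()]).
#' @export
form_difference_matrix <- function(num, den,
                                   estimator = c("arithmetic", "moment"),
                                   numerator_group = "affected",
                                   denominator_group = "unaffected") {
  estimator <- match.arg(estimator)
  check_same_labels(num, den)
  mf_num <- mean_form(num, estimator)
  mf_den <- mean_form(den, estimator)
  check_positive_denominator(mf_den)
  structure(list(labels = num$labels, pairs = mf_num$pairs,
                 ratio = mf_num$mean_distances / mf_den$mean_distances,
                 estimator = estimator,
                 numerator_group = numerator_group,
                 denominator_group = denominator_group),
            class = "form_difference")
}

check_same_labels <- function(num, den) {
  stopifnot(inherits(num, "landmark_dataset"),
            inherits(den, "landmark_dataset"))
  if (!identical(num$labels, den$labels)) {
    stop("numerator and denominator datasets must share an identical ",
         "ordered label set")
  }
}

check_positive_denominator <- function(mf) {
  zero <- which(mf$mean_distances <= 0)
  if (length(zero)) {
    stop("zero mean distance in denominator group for pair(s): ",
         paste(paste(mf$pairs$a[zero], mf$pairs$b[zero], sep = "-"),
               collapse = ", "))
  }
}

#' Bootstrap confidence intervals for a form-difference matrix
#'
#' Nonparametric ("model independent") bootstrap for per-pair
#' mean-distance ratios: specimens are resampled with replacement
#' independently within each group, the mean-form ratio is recomputed for
#' every replicate, and percentile confidence intervals at levels
#' (alpha/2, 1 - alpha/2) are taken per pair (inverse-ECDF quantiles,
#' `type = 1`). A pair is flagged significant when its interval excludes
#' 1; `direction` is `"larger"`/`"smaller"` in the numerator group, or
#' `"ns"`.
#'
#' With `method = "exhaustive"` the full resampling distribution is
#' enumerated instead of sampled: every ordered with-replacement resample
#' of each group is generated (feasible only for very small groups) and
#' the interval is the exact percentile interval of the complete
#' ratio distribution. `n_boot` and `seed` are ignored in that case.
#'
#' @param num,den [landmark_dataset()]s, `n >= 2` each, identical labels.
#' @param alpha two-sided miscoverage level, default 0.10 (90% CIs).
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed integer seed; the caller's RNG state is restored on exit.
#' @param estimator mean-form estimator, see [mean_form()].
#' @param method `"montecarlo"` (default) or `"exhaustive"`.
#' @param numerator_group,denominator_group display names.
#' @return object of class `form_difference` with additional fields
#'   `ci_lo`, `ci_hi`, `significant`, `direction`, `alpha`, `n_boot`,
#'   `seed`.
#' @export
bootstrap_fdm_ci <- function(num, den, alpha = 0.10, n_boot = 10000L,
                             seed = NULL,
                             estimator = c("arithmetic", "moment"),
                             method = c("montecarlo", "exhaustive"),
                             numerator_group = "affected",
                             denominator_group = "unaffected") {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  check_same_labels(num, den)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  n1 <- n_configurations(num)
  n2 <- n_configurations(den)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 specimens")
  d1 <- distance_rows(num)
  d2 <- distance_rows(den)
  point <- mean_form_from_rows(d1, estimator) /
    mean_form_from_rows(d2, estimator)
  probs <- c(alpha / 2, 1 - alpha / 2)
  p <- ncol(d1)

  if (method == "exhaustive") {
    if (n1^n1 * n2^n2 > 2e6) {
      stop("exhaustive enumeration is only feasible for very small groups")
    }
    m1 <- resample_mean_forms(d1, estimator)  # n1^n1 x p
    m2 <- resample_mean_forms(d2, estimator)
    ci <- matrix(NA_real_, p, 2)
    for (j in seq_len(p)) {
      r <- as.vector(outer(m1[, j], 1 / m2[, j]))
      ci[j, ] <- stats::quantile(r, probs, type = 1, names = FALSE)
    }
    n_boot <- nrow(m1) * nrow(m2)
  } else {
    if (n_boot < 1L) stop("n_boot must be at least 1")
    boot <- with_seed(seed, {
      out <- matrix(NA_real_, n_boot, p)
      for (b in seq_len(n_boot)) {
        i1 <- sample.int(n1, n1, replace = TRUE)
        i2 <- sample.int(n2, n2, replace = TRUE)
        out[b, ] <- mean_form_from_rows(d1[i1, , drop = FALSE], estimator) /
          mean_form_from_rows(d2[i2, , drop = FALSE], estimator)
      }
      out
    })
    ci <- t(apply(boot, 2, stats::quantile, probs = probs, type = 1,
                  names = FALSE))
  }

  significant <- ci[, 1] > 1 | ci[, 2] < 1
  direction <- ifelse(!significant, "ns",
                      ifelse(point > 1, "larger", "smaller"))
  structure(list(labels = num$labels, pairs = landmark_pairs(num$labels),
                 ratio = point, ci_lo = ci[, 1], ci_hi = ci[, 2],
                 significant = significant, direction = direction,
                 alpha = alpha, n_boot = as.integer(n_boot),
                 seed = seed, estimator = estimator, method = method,
                 numerator_group = numerator_group,
                 denominator_group = denominator_group),
            class = "form_difference")
}

# all ordered with-replacement resamples of the rows of d (n^n of them),
# as a matrix of mean forms
resample_mean_forms <- function(d, estimator) {
  n <- nrow(d)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  out <- matrix(NA_real_, nrow(grid), ncol(d))
  for (i in seq_len(nrow(grid))) {
    out[i, ] <- mean_form_from_rows(d[grid[i, ], , drop = FALSE], estimator)
  }
  out
}

#' Overall bootstrap test of form difference
#'
#' Nonparametric null-hypothesis test that two samples share the same
#' mean form. The observed statistic is
#' `T = max_i(ratio_i) / min_i(ratio_i)` over all inter-landmark distance
#' ratios (T = 1 when all ratios are equal, i.e. the groups differ at
#' most by global scale). The null distribution is built by resampling
#' both pseudo-groups (of the original group sizes) with replacement from
#' the pooled specimen set and recomputing T; the p-value uses the
#' add-one correction `(b + 1) / (n_boot + 1)` where `b` counts null
#' statistics at least as large as the observed one.
#'
#' @inheritParams bootstrap_fdm_ci
#' @param n_boot number of null resamples (default 999).
#' @param region_name optional region label carried into the result.
#' @return object of class `form_difference_test`: list with
#'   `statistic_T`, `p_value`, `n_boot`, `seed`, `region_name`.
#' @export
form_difference_test <- function(num, den, n_boot = 999L, seed = NULL,
                                 estimator = c("arithmetic", "moment"),
                                 region_name = NA_character_) {
  estimator <- match.arg(estimator)
  check_same_labels(num, den)
  if (n_boot < 1L) stop("n_boot must be at least 1")
  n1 <- n_configurations(num)
  n2 <- n_configurations(den)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 specimens")
  d1 <- distance_rows(num)
  d2 <- distance_rows(den)
  t_of <- function(a, b) {
    r <- mean_form_from_rows(a, estimator) / mean_form_from_rows(b, estimator)
    max(r) / min(r)
  }
  t_obs <- t_of(d1, d2)
  pool <- rbind(d1, d2)
  n_pool <- nrow(pool)
  b_ge <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_boot)) {
      i1 <- sample.int(n_pool, n1, replace = TRUE)
      i2 <- sample.int(n_pool, n2, replace = TRUE)
      t_null <- t_of(pool[i1, , drop = FALSE], pool[i2, , drop = FALSE])
      if (t_null >= t_obs) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(statistic_T = t_obs,
                 p_value = (b_ge + 1) / (n_boot + 1),
                 n_boot = as.integer(n_boot), seed = seed,
                 estimator = estimator, region_name = region_name),
            class = "form_difference_test")
}

#' @export
print.form_difference <- function(x, ...) {
  cat("form_difference: ", length(x$ratio), " distance ratios (",
      x$numerator_group, " / ", x$denominator_group, ")\n", sep = "")
  if (!is.null(x$ci_lo)) {
    cat("  alpha =", x$alpha, "  n_boot =", x$n_boot,
        "  significant:", sum(x$significant), "\n")
  }
  invisible(x)
}

#' @export
print.form_difference_test <- function(x, ...) {
  cat("form_difference_test: T =", format(x$statistic_T, digits = 4),
      " p =", format(x$p_value, digits = 4),
      " (n_boot =", x$n_boot, ")\n")
  invisible(x)
}

#' Write a form-difference table as TSV
#' @param fd a `form_difference` with confidence intervals.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fdm_table <- function(fd, path) {
  stopifnot(inherits(fd, "form_difference"))
  tab <- data.frame(pair_label_a = fd$pairs$a, pair_label_b = fd$pairs$b,
                    ratio = fd$ratio, stringsAsFactors = FALSE)
  if (!is.null(fd$ci_lo)) {
    tab$ci_lo <- fd$ci_lo
    tab$ci_hi <- fd$ci_hi
    tab$significant <- fd$significant
    tab$direction <- fd$direction
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
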