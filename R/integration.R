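#' Build a matched two-module distance panel
#'
#' Combines per-specimen inter-landmark distances from two landmark
#' datasets covering distinct anatomical modules (chondrocranium,
#' dermatocranium) into one specimens x distances matrix. Specimens must
#' be matched across the two datasets by `specimen_id` (each dataset one
#' configuration per specimen); rows are aligned on the chondrocranial
#' dataset's specimen order. Columns are module-major (all chondro
#' distances first), in canonical pair order within module. With the
#' built-in 7-landmark MI sets this yields 21 + 21 = 42 columns.
#'
#' @param chondro_ds,dermato_ds [landmark_dataset()]s, one configuration
#'   per specimen, covering the two modules.
#' @param modules names for the two modules.
#' @return object of class `distance_panel`: list with `matrix`
#'   (n x m, rownames specimen ids), `module` (module per column),
#'   `pair_a`, `pair_b` (landmark labels per column).
#' @export
build_distance_panel <- function(chondro_ds, dermato_ds,
                                 modules = c("chondro", "dermato")) {
  stopifnot(inherits(chondro_ds, "landmark_dataset"),
            inherits(dermato_ds, "landmark_dataset"))
  ids1 <- chondro_ds$info$specimen_id
  ids2 <- dermato_ds$info$specimen_id
  if (anyDuplicated(ids1) || anyDuplicated(ids2)) {
    stop("each dataset must have one configuration per specimen ",
         "(average replicates first)")
  }
  only1 <- setdiff(ids1, ids2)
  only2 <- setdiff(ids2, ids1)
  if (length(only1) || length(only2)) {
    stop("unmatched specimen(s): ",
         paste(c(only1, only2), collapse = ", "))
  }
  dermato_ds <- subset_configurations(dermato_ds, match(ids1, ids2))
  d1 <- distance_rows(chondro_ds)
  d2 <- distance_rows(dermato_ds)
  p1 <- landmark_pairs(chondro_ds$labels)
  p2 <- landmark_pairs(dermato_ds$labels)
  mat <- cbind(d1, d2)
  rownames(mat) <- ids1
  module <- c(rep(modules[1], nrow(p1)), rep(modules[2], nrow(p2)))
  pair_a <- c(p1$a, p2$a)
  pair_b <- c(p1$b, p2$b)
  colnames(mat) <- paste0(module, "|", pair_a, "-", pair_b)
  structure(list(matrix = mat, module = module,
                 pair_a = pair_a, pair_b = pair_b, modules = modules),
            class = "distance_panel")
}

#' @export
print.distance_panel <- function(x, ...) {
  cat("distance_panel:", nrow(x$matrix), "specimens x",
      ncol(x$matrix), "distances (",
      paste(sprintf("%s: %d", x$modules, table(x$module)[x$modules]),
            collapse = ", "), ")\n")
  invisible(x)
}

# scope of each unordered pair of panel columns
panel_scopes <- function(panel) {
  m <- ncol(panel$matrix)
  cmb <- utils::combn(m, 2)
  mod_a <- panel$module[cmb[1, ]]
  mod_b <- panel$module[cmb[2, ]]
  scope <- ifelse(mod_a != mod_b, "between",
                  ifelse(mod_a == panel$modules[1],
                         paste0("within_", panel$modules[1]),
                         paste0("within_", panel$modules[2])))
  list(i = cmb[1, ], j = cmb[2, ], scope = scope)
}

#' Correlation structure of a distance panel
#'
#' Pearson correlations across specimens for every unordered pair of
#' distance columns, partitioned into within-module and between-module
#' scopes, with the mean (`r_bar`) and standard deviation (`s`) of the
#' absolute correlations per scope. Distance columns with zero variance
#' yield undefined correlations: these elements are set to `NA`, flagged,
#' and excluded from `r_bar`/`s`.
#'
#' @param panel a [build_distance_panel()] result.
#' @return object of class `correlation_blocks`: list of per-scope lists
#'   with `pairs` (data.frame: `distance_a`, `distance_b`, `r`), `r_bar`,
#'   `s`, `n_pairs`, `n_undefined`; plus `cor_matrix` (full m x m) and
#'   `n` (specimens).
#' @export
correlation_blocks <- function(panel) {
  stopifnot(inherits(panel, "distance_panel"))
  n <- nrow(panel$matrix)
  if (n < 3L) stop("at least 3 specimens required for correlations")
  cm <- panel_correlation(panel$matrix)
  sc <- panel_scopes(panel)
  r <- cm[cbind(sc$i, sc$j)]
  cols <- colnames(panel$matrix)
  blocks <- lapply(unique(sc$scope), function(s) {
    sel <- sc$scope == s
    rv <- r[sel]
    list(scope = s,
         pairs = data.frame(distance_a = cols[sc$i[sel]],
                            distance_b = cols[sc$j[sel]],
                            r = rv, stringsAsFactors = FALSE),
         r_bar = mean(abs(rv), na.rm = TRUE),
         s = stats::sd(abs(rv), na.rm = TRUE),
         n_pairs = sum(sel),
         n_undefined = sum(is.na(rv)))
  })
  names(blocks) <- unique(sc$scope)
  structure(c(blocks, list(cor_matrix = cm, n = n)),
            class = "correlation_blocks")
}

# deterministic per-panel seed offset from the specimen ids (stable
# across R sessions; keeps derived seeds within integer range)
panel_substream <- function(seed, mat) {
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  h <- sum(utf8ToInt(paste(ids, collapse = "|"))) %% 100000L
  if (is.null(seed)) NULL else as.integer(seed) + h
}

resample_indices <- function(n_boot, n, seed) {
  with_seed(seed, {
    matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
  })
}

# correlation matrix with zero-variance columns giving NA (no warning)
panel_correlation <- function(mat) {
  sds <- apply(mat, 2, stats::sd)
  cm <- suppressWarnings(stats::cor(mat))
  cm[sds == 0, ] <- NA_real_
  cm[, sds == 0] <- NA_real_
  cm
}

#' Pattern-classification rule for integration differences
#'
#' Categories used to describe a significant change in the correlation of
#' a distance pair between genotypes, plus the threshold above which an
#' absolute correlation is called a relatively strong association
#' (default 0.60).
#'
#' @param strong_threshold threshold in (0, 1); default 0.60.
#' @return object of class `pattern_rule`.
#' @export
pattern_rule <- function(strong_threshold = 0.60) {
  if (strong_threshold <= 0 || strong_threshold >= 1) {
    stop("strong_threshold must be in (0, 1)")
  }
  structure(list(strong_threshold = strong_threshold,
                 categories = c("stronger_in_affected",
                                "stronger_in_unaffected",
                                "sign_flip_neg_to_pos",
                                "sign_flip_pos_to_neg", "ns")),
            class = "pattern_rule")
}

#' Classify the pattern of a correlation difference
#'
#' For a distance pair with correlation `r_a` in the affected group and
#' `r_u` in the unaffected group: not-significant pairs are `ns`;
#' significant pairs with opposite signs are classified as sign flips
#' (`sign_flip_neg_to_pos` when the unaffected correlation is negative
#' and the affected positive, `sign_flip_pos_to_neg` for the reverse);
#' remaining significant pairs are `stronger_in_affected` or
#' `stronger_in_unaffected` by comparison of absolute correlations (ties
#' resolve to `stronger_in_affected`). The `strong_affected` /
#' `strong_unaffected` flags mark absolute correlations at or above the
#' rule's threshold.
#'
#' @param r_a,r_u correlations in the affected and unaffected group
#'   (vectors accepted).
#' @param significant logical vector.
#' @param rule a [pattern_rule()].
#' @return data.frame with columns `pattern`, `strong_affected`,
#'   `strong_unaffected`.
#' @export
classify_pair_pattern <- function(r_a, r_u, significant,
                                  rule = pattern_rule()) {
  stopifnot(inherits(rule, "pattern_rule"))
  if (any(abs(c(r_a, r_u)) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  pattern <- rep("ns", length(r_a))
  sig <- significant & !is.na(r_a) & !is.na(r_u)
  flip_np <- sig & r_u < 0 & r_a > 0
  flip_pn <- sig & r_u > 0 & r_a < 0
  rest <- sig & !flip_np & !flip_pn
  pattern[flip_np] <- "sign_flip_neg_to_pos"
  pattern[flip_pn] <- "sign_flip_pos_to_neg"
  pattern[rest] <- ifelse(abs(r_a[rest]) >= abs(r_u[rest]),
                          "stronger_in_affected", "stronger_in_unaffected")
  data.frame(pattern = pattern,
             strong_affected = !is.na(r_a) &
               abs(r_a) >= rule$strong_threshold,
             strong_unaffected = !is.na(r_u) &
               abs(r_u) >= rule$strong_threshold,
             stringsAsFactors = FALSE)
}

#' Compare morphological integration between genotypes
#'
#' Tests, element by element, whether the correlation structure of a
#' distance panel differs between two groups. The correlation-difference
#' matrix is the unaffected-group correlation minus the affected-group
#' correlation for every unordered pair of distances. Specimens are
#' resampled with replacement independently within each group `n_boot`
#' times, both correlation matrices and their difference recomputed per
#' replicate, and a percentile confidence interval at level
#' (alpha/2, 1 - alpha/2) taken per element (`type = 1` quantiles). An
#' element is significantly different when its interval excludes zero.
#' Significant elements are classified with [classify_pair_pattern()] and
#' summarized per scope as counts with one-decimal percentages, split by
#' which genotype shows the greater absolute correlation.
#'
#' Bootstrap replicates in which an element is undefined (a resample
#' drew a zero-variance distance column) are dropped for that element
#' and counted in `n_dropped`.
#'
#' @param panel_affected,panel_unaffected [build_distance_panel()]s with
#'   identical distance columns; at least 3 specimens each.
#' @param alpha two-sided miscoverage level (default 0.10).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer seed; caller's RNG state restored on exit.
#' @param rule a [pattern_rule()].
#' @return object of class `integration_comparison`: `table` (data.frame
#'   with distance_a, distance_b, scope, r_affected, r_unaffected, diff,
#'   ci_lo, ci_hi, significant, pattern, strong flags, n_dropped),
#'   `summary` (per-scope data.frame), `alpha`, `n_boot`, `seed`,
#'   `strong_threshold`.
#' @export
compare_integration <- function(panel_affected, panel_unaffected,
                                alpha = 0.10, n_boot = 10000L,
                                seed = NULL, rule = pattern_rule()) {
  stopifnot(inherits(panel_affected, "distance_panel"),
            inherits(panel_unaffected, "distance_panel"))
  if (!identical(colnames(panel_affected$matrix),
                 colnames(panel_unaffected$matrix))) {
    stop("panels must share identical distance columns")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_boot < 1L) stop("n_boot must be at least 1")
  xa <- panel_affected$matrix
  xu <- panel_unaffected$matrix
  na <- nrow(xa)
  nu <- nrow(xu)
  if (na < 3L || nu < 3L) stop("at least 3 specimens per group required")
  sc <- panel_scopes(panel_affected)
  idx <- cbind(sc$i, sc$j)
  r_a <- panel_correlation(xa)[idx]
  r_u <- panel_correlation(xu)[idx]
  diff_obs <- r_u - r_a
  n_el <- nrow(idx)

  # per-panel resample streams are derived from the seed and the panel's
  # own specimen ids, so that swapping the two panels pairs up the exact
  # mirrored resamples: the swapped analysis negates every bootstrap
  # difference and reproduces the same significance set
  ia <- resample_indices(n_boot, na, panel_substream(seed, xa))
  iu <- resample_indices(n_boot, nu, panel_substream(seed, xu))
  boot <- matrix(NA_real_, n_boot, n_el)
  for (b in seq_len(n_boot)) {
    ca <- panel_correlation(xa[ia[b, ], , drop = FALSE])
    cu <- panel_correlation(xu[iu[b, ], , drop = FALSE])
    boot[b, ] <- cu[idx] - ca[idx]
  }
  n_dropped <- colSums(is.na(boot))
  probs <- c(alpha / 2, 1 - alpha / 2)
  ci <- t(apply(boot, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(c(NA_real_, NA_real_))
    stats::quantile(col, probs, type = 1, names = FALSE)
  }))
  significant <- !is.na(ci[, 1]) & (ci[, 1] > 0 | ci[, 2] < 0)
  cls <- classify_pair_pattern(r_a, r_u, significant, rule)
  cols <- colnames(xa)
  tab <- data.frame(distance_a = cols[sc$i], distance_b = cols[sc$j],
                    scope = sc$scope, r_affected = r_a, r_unaffected = r_u,
                    diff = diff_obs, ci_lo = ci[, 1], ci_hi = ci[, 2],
                    significant = significant, pattern = cls$pattern,
                    strong_affected = cls$strong_affected,
                    strong_unaffected = cls$strong_unaffected,
                    n_dropped = n_dropped, stringsAsFactors = FALSE)
  structure(list(table = tab,
                 summary = integration_summary(tab),
                 alpha = alpha, n_boot = as.integer(n_boot), seed = seed,
                 strong_threshold = rule$strong_threshold),
            class = "integration_comparison")
}

#' Per-scope summary of an integration comparison
#'
#' Counts and one-decimal percentages of significantly different
#' correlation elements per scope, split by which genotype carries the
#' greater absolute correlation, plus pattern-class counts.
#'
#' @param tab the `table` element of an `integration_comparison` (also
#'   accepts the comparison object itself).
#' @return data.frame with one row per scope.
#' @export
integration_summary <- function(tab) {
  if (inherits(tab, "integration_comparison")) tab <- tab$table
  scopes <- unique(tab$scope)
  do.call(rbind, lapply(scopes, function(s) {
    d <- tab[tab$scope == s, ]
    n_pairs <- nrow(d)
    sig <- d$significant
    stronger_a <- sig & abs(d$r_affected) >= abs(d$r_unaffected)
    stronger_u <- sig & abs(d$r_affected) < abs(d$r_unaffected)
    data.frame(
      scope = s, n_pairs = n_pairs,
      n_significant = sum(sig),
      pct_significant = round_pct(sum(sig), n_pairs),
      n_stronger_affected = sum(stronger_a),
      pct_stronger_affected = round_pct(sum(stronger_a), n_pairs),
      n_stronger_unaffected = sum(stronger_u),
      pct_stronger_unaffected = round_pct(sum(stronger_u), n_pairs),
      n_sign_flip_neg_to_pos = sum(d$pattern == "sign_flip_neg_to_pos"),
      n_sign_flip_pos_to_neg = sum(d$pattern == "sign_flip_pos_to_neg"),
      stringsAsFactors = FALSE
    )
  }))
}

# one-decimal percentage, round-half-even (R's default rounding)
round_pct <- function(count, total) {
  round(100 * count / total, 1)
}

#' Format a count with its one-decimal percentage
#'
#' Renders `"183 (41.5%)"`-style strings: the raw count followed by its
#' percentage of `total`, rounded to one decimal (round-half-even).
#'
#' @param count integer count(s).
#' @param total denominator.
#' @return character vector.
#' @export
format_count_pct <- function(count, total) {
  sprintf("%d (%.1f%%)", as.integer(count), round_pct(count, total))
}

#' @export
print.integration_comparison <- function(x, ...) {
  cat("integration_comparison: ", nrow(x$table), " correlation elements, ",
      "alpha = ", x$alpha, ", n_boot = ", x$n_boot, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write an integration comparison table as TSV
#' @param cmp an `integration_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_integration_table <- function(cmp, path) {
  stopifnot(inherits(cmp, "integration_comparison"))
  utils::write.table(cmp$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a square correlation matrix as TSV
#'
#' Writes an m x m correlation matrix with distance labels as row and
#' column headers.
#'
#' @param cm square numeric matrix with dimnames, e.g. the `cor_matrix`
#'   element of [correlation_blocks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(cm, path) {
  utils::write.table(cm, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
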