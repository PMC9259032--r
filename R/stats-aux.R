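#' Principal components analysis of form
#'
#' Form-space PCA: every inter-landmark distance is ln-transformed and
#' the eigendecomposition of the variance-covariance matrix of the
#' ln-distances is taken. Total form variation is the sum of the
#' variances of the ln-transformed distances, which equals the sum of the
#' eigenvalues. Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param panel a [build_distance_panel()] result or a plain
#'   specimens x distances matrix of positive distances (mm).
#' @return object of class `pca_form`: `eigenvalues` (descending),
#'   `scores` (specimens x components, zero column means), `loadings`
#'   (ln-distance variables x components), `pct_variance`, `center`
#'   (per-variable means of ln-distances).
#' @export
pca_form <- function(panel) {
  x <- if (inherits(panel, "distance_panel")) panel$matrix else panel
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 specimens required for PCA")
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    nm <- if (!is.null(colnames(x))) colnames(x)[bad[1, 2]] else
      paste("column", bad[1, 2])
    stop("nonpositive distance (cannot ln-transform): ", nm,
         ", specimen row ", bad[1, 1])
  }
  lx <- log(x)
  ctr <- colMeans(lx)
  lc <- sweep(lx, 2, ctr)
  ev <- eigen(stats::cov(lx), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- colnames(x)
  scores <- lc %*% vecs
  rownames(scores) <- rownames(x)
  colnames(scores) <- colnames(vecs) <- paste0("PC", seq_len(ncol(vecs)))
  structure(list(eigenvalues = vals, scores = scores, loadings = vecs,
                 pct_variance = 100 * vals / sum(vals), center = ctr),
            class = "pca_form")
}

#' @export
print.pca_form <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("pca_form:", nrow(x$scores), "specimens,",
      length(x$eigenvalues), "ln-distance variables\n")
  cat("  % variance (first", k, "PCs):",
      paste(sprintf("%.1f", x$pct_variance[seq_len(k)]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided nonparametric comparison of two independent samples,
#' suitable for measurement tables (bone volumes, histomorphometry)
#' where normality or variance homogeneity fails. With a combined sample
#' size of at most 12 and no ties the p-value is exact (full permutation
#' distribution); otherwise a tie-corrected normal approximation with
#' continuity correction is used. U is reported for the first group.
#'
#' @param a,b numeric vectors, each nonempty.
#' @param variable optional variable name carried into the result.
#' @return object of class `group_comparison`: `variable`, `n_a`, `n_b`,
#'   `U`, `p_two_sided`, `method` (`"exact"` or
#'   `"normal_tie_corrected"`).
#' @export
mann_whitney <- function(a, b, variable = NA_character_) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (anyNA(a) || anyNA(b)) stop("missing values not allowed")
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (all(c(a, b) == c(a, b)[1])) {
    # fully tied comparison carries no evidence
    return(structure(list(variable = variable, n_a = n_a, n_b = n_b,
                          U = u, p_two_sided = 1, method = "exact"),
                     class = "group_comparison"))
  }
  if (n_a + n_b <= 12 && !ties) {
    wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    method <- "exact"
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    method <- "normal_tie_corrected"
  }
  structure(list(variable = variable, n_a = n_a, n_b = n_b, U = u,
                 p_two_sided = min(1, wt$p.value), method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("mann_whitney", if (!is.na(x$variable)) paste0("[", x$variable, "]"),
      ": U =", x$U, " p =", format(x$p_two_sided, digits = 4),
      paste0("(", x$method, ", n = ", x$n_a, "/", x$n_b, ")\n"))
  invisible(x)
}

#' Compare a two-group measurement table variable by variable
#'
#' Applies [mann_whitney()] to every variable of a long-format
#' measurement table (columns `specimen_id`, `genotype`, `variable`,
#' `value`). No multiple-testing correction is applied; p-values are
#' per-variable.
#'
#' @param tab data.frame with the columns above.
#' @return data.frame: variable, n_affected, n_unaffected, U,
#'   p_two_sided, method.
#' @export
compare_measurements <- function(tab) {
  req <- c("specimen_id", "genotype", "variable", "value")
  if (!all(req %in% names(tab))) {
    stop("table must have columns: ", paste(req, collapse = ", "))
  }
  do.call(rbind, lapply(split(tab, tab$variable), function(d) {
    a <- d$value[d$genotype == "affected"]
    u <- d$value[d$genotype == "unaffected"]
    mw <- mann_whitney(a, u, variable = d$variable[1])
    data.frame(variable = mw$variable, n_affected = mw$n_a,
               n_unaffected = mw$n_b, U = mw$U,
               p_two_sided = mw$p_two_sided, method = mw$method,
               stringsAsFactors = FALSE)
  }))
}

#' Encode suture-patency scores
#'
#' Normalizes qualitative suture-patency scores to the three categories
#' `open`, `partial`, `fused` (accepting the aliases `"partially open"`,
#' `"partially_open"` and `"closed"`), for the coronal and facial sutures.
#' The result can be joined to PCA scores for plot coding.
#'
#' @param tab data.frame with columns `specimen_id`, `suture`, `state`
#'   and optionally `side`.
#' @return object of class `suture_scores`: data.frame with normalized
#'   `state` factor (levels open, partial, fused).
#' @export
encode_sutures <- function(tab) {
  req <- c("specimen_id", "suture", "state")
  if (!all(req %in% names(tab))) {
    stop("table must have columns: ", paste(req, collapse = ", "))
  }
  sutures_ok <- c("coronal", "maxillary_palatine", "zygomatic_maxillary",
                  "inter_premaxillary")
  bad_s <- setdiff(unique(tab$suture), sutures_ok)
  if (length(bad_s)) {
    stop("unknown suture name(s): ", paste(bad_s, collapse = ", "))
  }
  alias <- c(open = "open",
             partial = "partial",
             "partially open" = "partial",
             partially_open = "partial",
             fused = "fused",
             closed = "fused")
  key <- tolower(trimws(as.character(tab$state)))
  unknown <- setdiff(unique(key), names(alias))
  if (length(unknown)) {
    stop("unknown suture state(s): ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(specimen_id = as.character(tab$specimen_id),
                    suture = as.character(tab$suture),
                    state = factor(alias[key],
                                   levels = c("open", "partial", "fused")),
                    stringsAsFactors = FALSE)
  if ("side" %in% names(tab)) out$side <- as.character(tab$side)
  class(out) <- c("suture_scores", "data.frame")
  out
}

#' Join suture scores to PCA scores for plot coding
#'
#' Left-joins one suture's patency states onto the specimens of a
#' [pca_form()] result. Suture records whose `specimen_id` matches no
#' PCA specimen are returned as flagged orphans rather than silently
#' dropped; PCA specimens without a score get `NA`.
#'
#' @param pca a [pca_form()] result with specimen rownames on `scores`.
#' @param scores a [encode_sutures()] result.
#' @param suture which suture to code by (default `"coronal"`).
#' @return list with `coded` (data.frame: specimen_id, PC1, PC2, state)
#'   and `orphans` (data.frame of unmatched score records).
#' @export
join_suture_scores <- function(pca, scores, suture = "coronal") {
  stopifnot(inherits(pca, "pca_form"), inherits(scores, "suture_scores"))
  sc <- scores[scores$suture == suture, , drop = FALSE]
  ids <- rownames(pca$scores)
  if (is.null(ids)) stop("PCA scores carry no specimen ids")
  coded <- data.frame(specimen_id = ids,
                      PC1 = pca$scores[, 1],
                      PC2 = if (ncol(pca$scores) > 1) pca$scores[, 2]
                            else NA_real_,
                      state = sc$state[match(ids, sc$specimen_id)],
                      stringsAsFactors = FALSE)
  rownames(coded) <- NULL
  orphans <- sc[!sc$specimen_id %in% ids, , drop = FALSE]
  list(coded = coded, orphans = as.data.frame(orphans))
}

#' Summarize suture closure for one suture
#'
#' Counting rule for statements of the form "11/11 show partial or
#' complete closure": among the scored specimens of one suture, how many
#' are partial or fused.
#'
#' @param scores a [encode_sutures()] result.
#' @param suture suture name.
#' @return list with `n_closed_or_partial`, `n_total` and a formatted
#'   `fraction` string like `"11/11"`.
#' @export
summarize_suture_closure <- function(scores, suture = "coronal") {
  stopifnot(inherits(scores, "suture_scores"))
  sc <- scores[scores$suture == suture, , drop = FALSE]
  # a specimen counts as showing closure if any of its scored sides is
  # partial or fused
  by_spec <- tapply(sc$state %in% c("partial", "fused"), sc$specimen_id,
                    any)
  n_tot <- length(by_spec)
  n_closed <- sum(by_spec)
  list(n_closed_or_partial = n_closed, n_total = n_tot,
       fraction = sprintf("%d/%d", n_closed, n_tot))
}
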