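#' Landmark dataset container
#'
#' A `landmark_dataset` holds one or more 3D landmark configurations that
#' share a single ordered label set. Coordinates are stored as an
#' `n x K x 3` array in millimetres; per-configuration metadata
#' (specimen id, genotype, age, digitization trial) is kept in a
#' data frame with one row per configuration.
#'
#' @param coords numeric array of dimension `n x K x 3` (configurations x
#'   landmarks x xyz), or a `K x 3` matrix for a single configuration.
#'   Units are mm throughout the package.
#' @param labels character vector of `K` unique landmark names, in the
#'   canonical order of the governing landmark-set definition.
#' @param specimen_id character vector of length `n`.
#' @param genotype character vector, `"affected"` or `"unaffected"`
#'   (`NA` allowed where group membership is not needed).
#' @param age character vector; one of `"E13.5"`, `"E14.5"`, `"E15.5"`,
#'   `"E16.5"`, `"E17.5"`, `"P0"`, `"P2"` (or `NA`).
#' @param trial integer vector of digitization replicate indices.
#' @param group_label optional single string naming the dataset.
#'
#' @return An object of class `landmark_dataset` with elements `labels`,
#'   `coords` (n x K x 3 array with landmark dimnames), `info`
#'   (data.frame: specimen_id, genotype, age, trial) and `group_label`.
#' @export
landmark_dataset <- function(coords, labels, specimen_id,
                             genotype = NA_character_, age = NA_character_,
                             trial = 1L, group_label = NA_character_) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, nrow(coords), ncol(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop("'coords' must be an n x K x 3 array (or a K x 3 matrix)")
  }
  n <- dim(coords)[1]
  k <- dim(coords)[2]
  labels <- as.character(labels)
  if (length(labels) != k) {
    stop("length of 'labels' (", length(labels),
         ") does not match number of landmarks (", k, ")")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate landmark labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!all(is.finite(coords))) {
    stop("all coordinates must be finite")
  }
  specimen_id <- as.character(specimen_id)
  info <- data.frame(
    specimen_id = rep_len(specimen_id, n),
    genotype    = rep_len(as.character(genotype), n),
    age         = rep_len(as.character(age), n),
    trial       = rep_len(as.integer(trial), n),
    stringsAsFactors = FALSE
  )
  bad_geno <- !is.na(info$genotype) &
    !info$genotype %in% c("affected", "unaffected")
  if (any(bad_geno)) {
    stop("genotype must be 'affected' or 'unaffected'; got: ",
         paste(unique(info$genotype[bad_geno]), collapse = ", "))
  }
  ages_ok <- c("E13.5", "E14.5", "E15.5", "E16.5", "E17.5", "P0", "P2")
  bad_age <- !is.na(info$age) & !info$age %in% ages_ok
  if (any(bad_age)) {
    stop("unknown age value(s): ",
         paste(unique(info$age[bad_age]), collapse = ", "))
  }
  dimnames(coords) <- list(NULL, labels, c("x", "y", "z"))
  structure(
    list(labels = labels, coords = coords, info = info,
         group_label = as.character(group_label)),
    class = "landmark_dataset"
  )
}

#' Number of configurations in a dataset
#' @param ds a `landmark_dataset`.
#' @return integer count of configurations (specimen x trial rows).
#' @export
n_configurations <- function(ds) {
  stopifnot(inherits(ds, "landmark_dataset"))
  dim(ds$coords)[1]
}

#' Subset a landmark dataset by configuration index
#' @param ds a `landmark_dataset`.
#' @param i integer or logical index over configurations.
#' @return a `landmark_dataset` with the selected configurations.
#' @export
subset_configurations <- function(ds, i) {
  stopifnot(inherits(ds, "landmark_dataset"))
  coords <- ds$coords[i, , , drop = FALSE]
  landmark_dataset(coords, ds$labels,
                   specimen_id = ds$info$specimen_id[i],
                   genotype = ds$info$genotype[i],
                   age = ds$info$age[i],
                   trial = ds$info$trial[i],
                   group_label = ds$group_label)
}

#' Split a dataset by genotype
#' @param ds a `landmark_dataset` with genotype metadata.
#' @return named list with elements `affected` and `unaffected`.
#' @export
split_by_genotype <- function(ds) {
  stopifnot(inherits(ds, "landmark_dataset"))
  if (anyNA(ds$info$genotype)) {
    stop("dataset has configurations with missing genotype")
  }
  lapply(stats::setNames(c("affected", "unaffected"),
                         c("affected", "unaffected")),
         function(g) subset_configurations(ds, ds$info$genotype == g))
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("landmark_dataset:", n_configurations(x), "configuration(s),",
      length(x$labels), "landmarks\n")
  if (!is.na(x$group_label)) cat("  group:", x$group_label, "\n")
  cat("  landmarks:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}
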