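#' Read a landmark coordinate table
#'
#' Reads 3D landmark coordinates from either the package's CSV dialect
#' (one row per landmark per digitization trial, columns `specimen_id`,
#' `genotype`, `age`, `trial`, `landmark`, `x`, `y`, `z`) or a TPS file
#' with `LM3` blocks. Coordinates are interpreted as millimetres.
#'
#' Every configuration (specimen x trial) must carry exactly the same
#' landmark label set; the label order of the first configuration in the
#' file is taken as canonical and the remainder are reordered to it.
#'
#' @param path path to the input file.
#' @param dialect `"csv"` (default) or `"tps"`.
#' @return a [landmark_dataset()].
#' @export
read_landmark_table <- function(path, dialect = c("csv", "tps")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         csv = read_landmark_csv(path),
         tps = read_landmark_tps(path))
}

read_landmark_csv <- function(path) {
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop("format error reading ", path, ": ",
                             conditionMessage(e))
  )
  required <- c("specimen_id", "genotype", "age", "trial",
                "landmark", "x", "y", "z")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("format error: file contains no landmark rows")
  for (cc in c("x", "y", "z")) {
    val <- suppressWarnings(as.numeric(tab[[cc]]))
    bad <- which(is.na(val) & !is.na(tab[[cc]]))
    if (length(bad)) {
      stop("parse error: non-numeric coordinate '", tab[[cc]][bad[1]],
           "' in column ", cc, ", data row ", bad[1])
    }
    tab[[cc]] <- val
  }
  tab$trial <- as.integer(tab$trial)
  key <- paste(tab$specimen_id, tab$trial, sep = "\r")
  cfgs <- split(tab, factor(key, levels = unique(key)))
  labels <- cfgs[[1]]$landmark
  if (anyDuplicated(labels)) {
    stop("validation error: duplicate landmark '",
         labels[duplicated(labels)][1], "' within a configuration")
  }
  offenders <- names(cfgs)[!vapply(cfgs, function(cf) {
    setequal(cf$landmark, labels) && !anyDuplicated(cf$landmark)
  }, logical(1))]
  if (length(offenders)) {
    stop("validation error: inconsistent landmark sets for configuration(s): ",
         paste(gsub("\r", "/trial ", offenders), collapse = ", "))
  }
  n <- length(cfgs)
  coords <- array(NA_real_, dim = c(n, length(labels), 3L))
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- cfgs[[i]]
    idx <- match(labels, cf$landmark)
    coords[i, , ] <- as.matrix(cf[idx, c("x", "y", "z")])
    meta[[i]] <- cf[1L, c("specimen_id", "genotype", "age", "trial")]
  }
  meta <- do.call(rbind, meta)
  landmark_dataset(coords, labels,
                   specimen_id = meta$specimen_id,
                   genotype = meta$genotype,
                   age = meta$age,
                   trial = meta$trial)
}

# TPS LM3 dialect: "LM3=K" header, K lines of "x y z", then "ID=name";
# SCALE= records are ignored. Genotype/age are not represented in TPS.
read_landmark_tps <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("format error: empty TPS file")
  i <- 1L
  blocks <- list()
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^LM3=([0-9]+)$", lines[i]))[[1]]
    if (length(m) != 2L) {
      stop("format error: expected LM3= record at line ", i,
           ", got '", lines[i], "'")
    }
    k <- as.integer(m[2])
    if (i + k > length(lines)) stop("format error: truncated LM3 block")
    xyz <- do.call(rbind, lapply(lines[(i + 1L):(i + k)], function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
      if (length(v) != 3L || anyNA(v)) {
        stop("parse error: bad coordinate line '", ln, "'")
      }
      v
    }))
    i <- i + k + 1L
    id <- NA_character_
    while (i <= length(lines) &&
           !grepl("^LM3=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      # SCALE= and IMAGE= records are read and discarded
      i <- i + 1L
    }
    blocks[[length(blocks) + 1L]] <- list(id = id, xyz = xyz)
  }
  k <- nrow(blocks[[1]]$xyz)
  if (any(vapply(blocks, function(b) nrow(b$xyz), integer(1)) != k)) {
    stop("validation error: TPS blocks have differing landmark counts")
  }
  labels <- sprintf("lm%02d", seq_len(k))
  coords <- array(NA_real_, dim = c(length(blocks), k, 3L))
  for (j in seq_along(blocks)) coords[j, , ] <- blocks[[j]]$xyz
  ids <- vapply(blocks, function(b) b$id, character(1))
  ids[is.na(ids)] <- sprintf("specimen%03d", which(is.na(ids)))
  landmark_dataset(coords, labels, specimen_id = ids)
}

#' Write a landmark dataset to the package CSV dialect
#'
#' Inverse of [read_landmark_table()] for the CSV dialect. Coordinates are
#' written with 17 significant digits so a read/write round trip is exact
#' at full double precision.
#'
#' @param ds a [landmark_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(ds, path) {
  stopifnot(inherits(ds, "landmark_dataset"))
  n <- n_configurations(ds)
  k <- length(ds$labels)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rows[[i]] <- data.frame(
      specimen_id = ds$info$specimen_id[i],
      genotype = ds$info$genotype[i],
      age = ds$info$age[i],
      trial = ds$info$trial[i],
      landmark = ds$labels,
      x = sprintf("%.17g", ds$coords[i, , 1]),
      y = sprintf("%.17g", ds$coords[i, , 2]),
      z = sprintf("%.17g", ds$coords[i, , 3]),
      stringsAsFactors = FALSE
    )
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Average digitization replicates with placement-error QC
#'
#' Specimens digitized in multiple trials are reduced to one configuration
#' per specimen by arithmetic averaging of coordinates across trials.
#' Per landmark and specimen, a placement error is reported:
#' 100 * (largest between-trial Euclidean deviation of that landmark) /
#' (mean of all unique inter-landmark distances of the trial-averaged
#' configuration). With the usual two trials this is simply the distance
#' between the two digitizations of the landmark, expressed as a percent of
#' the specimen's mean inter-landmark distance. Landmarks whose error
#' strictly exceeds `max_error_pct` are flagged in the report; nothing is
#' dropped.
#'
#' @param ds a [landmark_dataset()] with `trial` metadata.
#' @param max_error_pct acceptance threshold in percent (default 5).
#' @param min_trials minimum number of trials required per specimen
#'   (default 2; set to 1 to pass single-trial specimens through).
#' @return list with elements `dataset` (one configuration per specimen,
#'   trial set to 1) and `errors` (data.frame: specimen_id, landmark,
#'   error_pct, flagged).
#' @export
average_replicates <- function(ds, max_error_pct = 5.0, min_trials = 2L) {
  stopifnot(inherits(ds, "landmark_dataset"))
  ids <- unique(ds$info$specimen_id)
  k <- length(ds$labels)
  out_coords <- array(NA_real_, dim = c(length(ids), k, 3L))
  meta <- vector("list", length(ids))
  err <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    sel <- which(ds$info$specimen_id == ids[s])
    if (length(sel) < min_trials) {
      stop("specimen ", ids[s], " has ", length(sel),
           " trial(s); at least ", min_trials, " required")
    }
    trials <- ds$coords[sel, , , drop = FALSE]
    avg <- apply(trials, c(2, 3), mean)
    out_coords[s, , ] <- avg
    mean_dist <- mean(stats::dist(avg))
    dev <- numeric(k)
    if (length(sel) >= 2L) {
      prs <- utils::combn(length(sel), 2)
      for (j in seq_len(ncol(prs))) {
        d <- sqrt(rowSums((trials[prs[1, j], , ] -
                           trials[prs[2, j], , ])^2))
        dev <- pmax(dev, d)
      }
    }
    error_pct <- 100 * dev / mean_dist
    meta[[s]] <- ds$info[sel[1L], , drop = FALSE]
    err[[s]] <- data.frame(specimen_id = ids[s], landmark = ds$labels,
                           error_pct = error_pct,
                           flagged = error_pct > max_error_pct,
                           stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  errors <- do.call(rbind, err)
  rownames(errors) <- NULL
  out <- landmark_dataset(out_coords, ds$labels,
                          specimen_id = ids,
                          genotype = meta$genotype,
                          age = meta$age,
                          trial = 1L,
                          group_label = ds$group_label)
  list(dataset = out, errors = errors)
}

#' Write a replicate-error report as TSV
#' @param errors the `errors` element of [average_replicates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_error_report <- function(errors, path) {
  utils::write.table(errors, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Subset a dataset to a named landmark region
#'
#' Restricts every configuration to the landmarks of a [region_spec()],
#' reordering them to the region's canonical order. Metadata are
#' preserved. Selection is idempotent, and composing two nested region
#' selections equals the inner selection.
#'
#' @param ds a [landmark_dataset()].
#' @param region a [region_spec()] or the name of a built-in region
#'   (see [cranio_regions()]).
#' @return a [landmark_dataset()] restricted to the region's landmarks.
#' @export
select_region <- function(ds, region) {
  stopifnot(inherits(ds, "landmark_dataset"))
  if (is.character(region) && length(region) == 1L) {
    region <- cranio_regions()[[region]]
    if (is.null(region)) stop("unknown built-in region name")
  }
  stopifnot(inherits(region, "region_spec"))
  unknown <- setdiff(region$labels, ds$labels)
  if (length(unknown)) {
    stop("region '", region$name, "' refers to landmark(s) absent from the ",
         "dataset: ", paste(unknown, collapse = ", "))
  }
  idx <- match(region$labels, ds$labels)
  landmark_dataset(ds$coords[, idx, , drop = FALSE], region$labels,
                   specimen_id = ds$info$specimen_id,
                   genotype = ds$info$genotype,
                   age = ds$info$age,
                   trial = ds$info$trial,
                   group_label = ds$group_label)
}
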