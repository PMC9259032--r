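#' Analysis configuration
#'
#' Validated configuration object driving the pipeline runners. The
#' configuration is echoed verbatim into every output's metadata and can
#' round-trip through YAML unchanged.
#'
#' @param landmark_file path to a landmark CSV for EDMA analyses
#'   (see [read_landmark_table()]).
#' @param chondro_file,dermato_file paths to the matched chondrocranial
#'   and dermatocranial landmark CSVs for integration analyses.
#' @param regions character vector of region names to analyze (built-ins
#'   of [cranio_regions()]).
#' @param chondro_region,dermato_region region names for the two
#'   integration modules (defaults: the built-in MI sets).
#' @param alpha two-sided miscoverage level (default 0.10).
#' @param n_boot_ci bootstrap replicates for confidence intervals
#'   (default 10000).
#' @param n_boot_test resamples for the overall form-difference test
#'   (default 999).
#' @param estimator mean-form estimator (default "arithmetic").
#' @param seed integer seed (mandatory: pipeline outputs must be
#'   reproducible).
#' @param out_dir output directory.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(landmark_file = NULL,
                            chondro_file = NULL, dermato_file = NULL,
                            regions = character(0),
                            chondro_region = "chondro_MI",
                            dermato_region = "dermato_MI",
                            alpha = 0.10, n_boot_ci = 10000L,
                            n_boot_test = 999L,
                            estimator = "arithmetic",
                            seed, out_dir) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory in pipeline mode")
  }
  if (missing(out_dir) || is.null(out_dir)) stop("out_dir is required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!estimator %in% c("arithmetic", "moment")) {
    stop("estimator must be 'arithmetic' or 'moment'")
  }
  builtin <- names(cranio_regions())
  unknown <- setdiff(c(regions, chondro_region, dermato_region), builtin)
  if (length(unknown)) {
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  }
  structure(list(landmark_file = landmark_file,
                 chondro_file = chondro_file,
                 dermato_file = dermato_file,
                 regions = as.character(regions),
                 chondro_region = chondro_region,
                 dermato_region = dermato_region,
                 alpha = alpha,
                 n_boot_ci = as.integer(n_boot_ci),
                 n_boot_test = as.integer(n_boot_test),
                 estimator = estimator,
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param config an [analysis_config()].
#' @param path YAML file path.
#' @return `path` invisibly (write); an `analysis_config` (read).
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(analysis_config, obj)
}

provenance <- function(config) {
  list(seed = config$seed, alpha = config$alpha,
       n_boot_ci = config$n_boot_ci, n_boot_test = config$n_boot_test,
       estimator = config$estimator,
       package_version = as.character(utils::packageVersion("craniomorph")))
}

load_grouped_dataset <- function(path) {
  ds <- read_landmark_table(path)
  if (any(duplicated(ds$info$specimen_id))) {
    ds <- average_replicates(ds)$dataset
  }
  split_by_genotype(ds)
}

#' Run the regional EDMA form-difference pipeline
#'
#' For every configured region: subsets both genotype groups to the
#' region's landmarks, estimates the form-difference matrix with
#' bootstrap confidence intervals (affected over unaffected), runs the
#' overall bootstrap form-difference test, and writes a
#' `<region>_fdm.tsv` table and `<region>_test.json` per region plus a
#' run log. Replicate trials in the input are averaged first. Outputs
#' are deterministic given the config seed.
#'
#' @param config an [analysis_config()] (or a path to its YAML) with
#'   `landmark_file` and `regions` set.
#' @return invisible list (report bundle): per-region `form_difference`
#'   and `form_difference_test` objects, plus output paths.
#' @export
run_edma_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$landmark_file)) stop("config lacks landmark_file")
  if (!length(config$regions)) stop("config lists no regions")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("run_edma_pipeline seed=%d alpha=%g", config$seed,
                         config$alpha))
  groups <- load_grouped_dataset(config$landmark_file)
  bundle <- list()
  for (ri in seq_along(config$regions)) {
    rg <- config$regions[ri]
    num <- select_region(groups$affected, rg)
    den <- select_region(groups$unaffected, rg)
    fd <- bootstrap_fdm_ci(num, den, alpha = config$alpha,
                           n_boot = config$n_boot_ci,
                           seed = config$seed + 1000L * ri,
                           estimator = config$estimator)
    tst <- form_difference_test(num, den, n_boot = config$n_boot_test,
                                seed = config$seed + 1000L * ri + 500L,
                                estimator = config$estimator,
                                region_name = rg)
    fdm_path <- file.path(config$out_dir, paste0(rg, "_fdm.tsv"))
    write_fdm_table(fd, fdm_path)
    test_path <- file.path(config$out_dir, paste0(rg, "_test.json"))
    jsonlite::write_json(
      c(list(region = rg, T = tst$statistic_T, p = tst$p_value,
             n_affected = n_configurations(num),
             n_unaffected = n_configurations(den)),
        provenance(config)),
      test_path, auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines,
                   sprintf("region=%s significant=%d/%d T=%.6g p=%.4g",
                           rg, sum(fd$significant), length(fd$ratio),
                           tst$statistic_T, tst$p_value))
    bundle[[rg]] <- list(fdm = fd, test = tst,
                         files = c(fdm_path, test_path))
  }
  write_analysis_config(config,
                        file.path(config$out_dir, "config_echo.yaml"))
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(bundle)
}

#' Run the morphological-integration comparison pipeline
#'
#' Builds matched chondrocranium + dermatocranium distance panels per
#' genotype, compares integration between genotypes with
#' [compare_integration()], and writes the element-wise comparison TSV,
#' a per-scope summary JSON with counts and formatted one-decimal
#' percentages, and both genotypes' correlation matrices as square TSV,
#' plus a run log (including dropped-replicate counts from degenerate
#' resamples).
#'
#' @param config an [analysis_config()] (or path to its YAML) with
#'   `chondro_file` and `dermato_file` set.
#' @return invisible list with the `integration_comparison` and output
#'   paths.
#' @export
run_integration_pipeline <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(config$chondro_file) || is.null(config$dermato_file)) {
    stop("config lacks chondro_file/dermato_file")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ch <- load_grouped_dataset(config$chondro_file)
  de <- load_grouped_dataset(config$dermato_file)
  panels <- lapply(c(affected = "affected", unaffected = "unaffected"),
                   function(g) build_distance_panel(
                     select_region(ch[[g]], config$chondro_region),
                     select_region(de[[g]], config$dermato_region)))
  cmp <- compare_integration(panels$affected, panels$unaffected,
                             alpha = config$alpha,
                             n_boot = config$n_boot_ci,
                             seed = config$seed)
  tab_path <- file.path(config$out_dir, "integration_comparison.tsv")
  write_integration_table(cmp, tab_path)
  summ <- cmp$summary
  summ_list <- lapply(seq_len(nrow(summ)), function(i) {
    s <- as.list(summ[i, ])
    s$significant_formatted <-
      format_count_pct(s$n_significant, s$n_pairs)
    s$stronger_affected_formatted <-
      format_count_pct(s$n_stronger_affected, s$n_pairs)
    s$stronger_unaffected_formatted <-
      format_count_pct(s$n_stronger_unaffected, s$n_pairs)
    s
  })
  names(summ_list) <- summ$scope
  summ_path <- file.path(config$out_dir, "integration_summary.json")
  jsonlite::write_json(c(list(scopes = summ_list), provenance(config)),
                       summ_path, auto_unbox = TRUE, digits = NA)
  cor_paths <- vapply(names(panels), function(g) {
    p <- file.path(config$out_dir,
                   paste0("correlation_matrix_", g, ".tsv"))
    write_correlation_matrix(panel_correlation(panels[[g]]$matrix), p)
    p
  }, character(1))
  writeLines(c(sprintf("run_integration_pipeline seed=%d alpha=%g",
                       config$seed, config$alpha),
               sprintf("dropped_replicates_total=%d",
                       sum(cmp$table$n_dropped)),
               sprintf("scope=%s significant=%s", summ$scope,
                       format_count_pct(summ$n_significant,
                                        summ$n_pairs))),
             file.path(config$out_dir, "run.log"))
  write_analysis_config(config,
                        file.path(config$out_dir, "config_echo.yaml"))
  invisible(list(comparison = cmp,
                 files = c(tab_path, summ_path, cor_paths)))
}
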