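#!/usr/bin/env Rscript
# Command-line front end for the craniomorph package.
#
# Usage: Rscript scripts/craniomorph.R <subcommand> [flags]
#
# Subcommands:
#   simulate        --config <spec.yaml> [--seed N] --out <dir>
#   distances       --in <landmarks.csv> --out <distances.tsv>
#   edma            --config <analysis.yaml> [--alpha A --boot B --seed N
#                   --estimator E --out <dir>]
#   integrate       --config <analysis.yaml> [--alpha A --boot B --seed N
#                   --out <dir>]
#   pca             --in <landmarks.csv> --out <prefix>
#   compare-groups  --in <measurements.csv> --out <result.json>
#   report          --in <pipeline out dir> --out <report.json>
#
# Measurement CSVs for compare-groups need columns: genotype, value.

suppressPackageStartupMessages(library(craniomorph))

argv <- commandArgs(trailingOnly = TRUE)
if (!length(argv)) stop("usage: craniomorph.R <subcommand> [flags]",
                        call. = FALSE)
cmd <- argv[1]
flags <- argv[-1]
opt <- function(flag, default = NULL) {
  i <- match(flag, flags)
  if (is.na(i)) return(default)
  if (i == length(flags)) stop("flag needs a value: ", flag, call. = FALSE)
  flags[i + 1]
}
req <- function(flag) {
  v <- opt(flag)
  if (is.null(v)) stop(cmd, " requires ", flag, call. = FALSE)
  v
}
num <- function(x) if (is.null(x)) NULL else as.numeric(x)
int <- function(x) if (is.null(x)) NULL else as.integer(x)

# apply command-line overrides on top of a YAML analysis config
load_config <- function() {
  cfg <- read_analysis_config(req("--config"))
  if (!is.null(opt("--alpha"))) cfg$alpha <- num(opt("--alpha"))
  if (!is.null(opt("--boot"))) {
    cfg$n_boot_ci <- int(opt("--boot"))
    cfg$n_boot_test <- int(opt("--boot"))
  }
  if (!is.null(opt("--seed"))) cfg$seed <- int(opt("--seed"))
  if (!is.null(opt("--estimator"))) cfg$estimator <- opt("--estimator")
  if (!is.null(opt("--out"))) cfg$out_dir <- opt("--out")
  cfg
}

if (cmd == "simulate") {
  sp <- read_synthetic_spec(req("--config"))
  if (!is.null(opt("--seed"))) sp$seed <- int(opt("--seed"))
  out <- req("--out")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_two_genotypes(sp)
  write_landmark_table(sim$affected, file.path(out, "affected.csv"))
  write_landmark_table(sim$unaffected, file.path(out, "unaffected.csv"))
  truth <- data.frame(sim$truth$pairs,
                      is_true_effect = sim$truth$is_true_effect,
                      expected_ratio = sim$truth$expected_ratio)
  writeLines(jsonlite::toJSON(list(seed = sp$seed, truth = truth),
                              auto_unbox = TRUE, digits = NA, na = "null"),
             file.path(out, "truth.json"))
  cat("wrote affected.csv, unaffected.csv, truth.json to", out, "\n")

} else if (cmd == "distances") {
  ds <- read_landmark_table(req("--in"))
  rows <- distance_rows(ds)
  pairs <- landmark_pairs(ds$labels)
  colnames(rows) <- paste0(pairs$a, "-", pairs$b)
  tab <- data.frame(specimen_id = ds$info$specimen_id, rows,
                    check.names = FALSE)
  utils::write.table(tab, req("--out"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat("wrote", ncol(rows), "distances x", nrow(rows), "specimens\n")

} else if (cmd == "edma") {
  invisible(run_edma_pipeline(load_config()))

} else if (cmd == "integrate") {
  invisible(run_integration_pipeline(load_config()))

} else if (cmd == "pca") {
  ds <- read_landmark_table(req("--in"))
  pc <- pca_form(distance_rows(ds))
  prefix <- req("--out")
  utils::write.table(
    data.frame(component = seq_along(pc$eigenvalues),
               eigenvalue = pc$eigenvalues,
               pct_variance = pc$pct_variance),
    paste0(prefix, "_eigenvalues.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(specimen_id = ds$info$specimen_id, pc$scores),
    paste0(prefix, "_scores.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cat("wrote", paste0(prefix, "_eigenvalues.tsv"), "and",
      paste0(prefix, "_scores.tsv"), "\n")

} else if (cmd == "compare-groups") {
  tab <- utils::read.csv(req("--in"), stringsAsFactors = FALSE)
  if (!all(c("genotype", "value") %in% names(tab))) {
    stop("compare-groups input needs columns: genotype, value",
         call. = FALSE)
  }
  res <- mann_whitney(tab$value[tab$genotype == "affected"],
                      tab$value[tab$genotype == "unaffected"])
  writeLines(jsonlite::toJSON(unclass(res), auto_unbox = TRUE,
                              digits = NA), req("--out"))
  cat("p =", res$p_two_sided, "(", res$method, ")\n")

} else if (cmd == "report") {
  src <- req("--in")
  files <- list.files(src, pattern = "\\.(json|tsv|yaml|log)$")
  jsons <- grep("\\.json$", files, value = TRUE)
  bundle <- lapply(file.path(src, jsons), jsonlite::read_json)
  names(bundle) <- sub("\\.json$", "", jsons)
  report <- list(source_dir = src, artifacts = files,
                 package_version =
                   as.character(utils::packageVersion("craniomorph")),
                 results = bundle)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), req("--out"))
  cat("report for", length(files), "artifacts ->", req("--out"), "\n")

} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
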