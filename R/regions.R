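#' Define a landmark region
#'
#' A region is a named, ordered subset of landmark labels used to restrict
#' analyses to an anatomical unit (e.g. olfactory capsule, braincase
#' floor, lateral wall).
#'
#' @param name region name.
#' @param labels ordered character vector of landmark names.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(name, labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels in region '", name, "'")
  if (!length(labels)) stop("region '", name, "' has no labels")
  structure(list(name = as.character(name), labels = labels),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat("region_spec '", x$name, "' (", length(x$labels), " landmarks): ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Built-in craniofacial landmark regions of the embryonic mouse skull
#'
#' Returns the package's built-in region definitions. The chondrocranial
#' sets cover the cartilaginous skull as digitized from soft-tissue
#' contrast-enhanced microCT; the bony (dermatocranium/endochondral) sets
#' cover the mineralizing skull from conventional microCT.
#'
#' Regions:
#' \describe{
#'   \item{chondro_olfactory}{olfactory capsule cartilage landmarks (10).}
#'   \item{chondro_braincase_floor}{braincase floor cartilage landmarks (7).}
#'   \item{chondro_lateral_wall}{lateral wall and roof of the preoccipital
#'     and occipital region (8).}
#'   \item{chondro_MI}{the 7 lateral-wall/roof landmarks used for
#'     morphological integration of the chondrocranium.}
#'   \item{bone_olfactory}{bony facial-skeleton landmarks around the
#'     olfactory capsule (7).}
#'   \item{bone_braincase_floor}{bony braincase floor landmarks (7).}
#'   \item{bone_lateral_wall}{bony lateral wall and roof landmarks (9).}
#'   \item{dermato_MI}{the 7 dermal-bone landmarks used for morphological
#'     integration of the dermatocranium.}
#'   \item{global_skull}{the expanded 24-landmark bony skull set used for
#'     late prenatal and early postnatal comparisons.}
#' }
#'
#' @return named list of [region_spec()] objects.
#' @export
cranio_regions <- function() {
  list(
    chondro_olfactory = region_spec("chondro_olfactory", c(
      "asep", "lncse", "lppi", "lppnc", "nct",
      "psep", "rapnc", "rncse", "rppi", "rppnc")),
    chondro_braincase_floor = region_spec("chondro_braincase_floor", c(
      "lcsp", "llpca", "llat", "nct", "rcsp", "rlpca", "rlat")),
    chondro_lateral_wall = region_spec("chondro_lateral_wall", c(
      "lao", "laottr", "ltpoa", "lttr", "rao", "raottr", "rtpoa", "rttr")),
    chondro_MI = region_spec("chondro_MI", c(
      "laottr", "lncse", "lttr", "psep", "raottr", "rncse", "rttr")),
    bone_olfactory = region_spec("bone_olfactory", c(
      "lfppm", "liohd", "lnasapl", "rfppm", "riohd", "rmaxi", "rnasapl")),
    bone_braincase_floor = region_spec("bone_braincase_floor", c(
      "bas", "loci", "lplpp", "lpsq", "roci", "rplpp", "rpsq")),
    bone_lateral_wall = region_spec("bone_lateral_wall", c(
      "laif", "loci", "lpfl", "lpto", "raif", "ralf", "rpfl", "roci",
      "rpto")),
    # The dermatocranium MI set includes lalf but not ralf, reproducing
    # the published landmark-set definition as printed (not symmetrized).
    dermato_MI = region_spec("dermato_MI", c(
      "laif", "lalf", "lpfl", "lpto", "raif", "rpfl", "rpto")),
    global_skull = region_spec("global_skull", c(
      "amsph", "bas", "ethma", "intpar", "lasph", "lflac", "lfppm",
      "liohd", "lnasapl", "loci", "lpsq", "lpto", "lva", "rasph",
      "rflac", "rfppm", "riohd", "rmaxi", "rnasapl", "roci", "rpns",
      "rpsq", "rpto", "rva"))
  )
}

#' Full chondrocranial landmark label set
#'
#' The 25 chondrocranial landmark labels, in canonical order.
#' @return character vector of length 25.
#' @export
chondro_landmarks <- function() {
  c("asep", "lao", "laottr", "lapnc", "lcsp", "llpca", "llat", "lncse",
    "lppi", "lppnc", "ltpoa", "lttr", "nct", "psep", "rao", "raottr",
    "rapnc", "rcsp", "rlpca", "rlat", "rncse", "rppi", "rppnc", "rtpoa",
    "rttr")
}
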