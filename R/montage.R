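#' Load an electrode montage
#'
#' Reads a montage table (channel label plus 3-D position on the unit
#' sphere) and attaches the 2-D scalp projection used for triangulation and
#' topographic maps. The packaged default is the standard 10-05 template
#' restricted to the 61 analysis channels of a 64-channel cap (EOG and the
#' mastoids excluded; AFz and CPz absent as ground and online reference).
#'
#' @param path CSV with columns `channel,x,y,z`; default = packaged montage.
#' @return A `montage` object: data.frame with columns `channel, x, y, z,
#'   px, py, region` where `(px, py)` is the azimuthal equidistant
#'   projection and `region` a coarse scalp region label.
#' @export
load_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage_1005_61.csv", package = "tntmvpa")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("channel", "x", "y", "z") %in% names(df)),
          "montage CSV needs columns channel,x,y,z")
  .assert(!anyDuplicated(df$channel), "duplicate channel labels in montage")
  .assert(all(is.finite(as.matrix(df[, c("x", "y", "z")]))),
          "non-finite montage positions")
  prj <- project_azimuthal(as.matrix(df[, c("x", "y", "z")]))
  df$px <- prj[, 1]
  df$py <- prj[, 2]
  df$region <- channel_region(df$channel)
  class(df) <- c("montage", "data.frame")
  df
}

#' Azimuthal equidistant projection of scalp positions
#'
#' Projects 3-D electrode positions (any radius) to the plane tangent at the
#' vertex, preserving the angular distance from the vertex. This is the
#' common EEG flattening used before 2-D triangulation.
#'
#' @param xyz n x 3 matrix.
#' @return n x 2 matrix.
#' @export
project_azimuthal <- function(xyz) {
  r <- sqrt(rowSums(xyz^2))
  .assert(all(r > 0), "zero-length position")
  u <- xyz / r
  theta <- acos(pmin(pmax(u[, 3], -1), 1))
  phi <- atan2(u[, 2], u[, 1])
  cbind(theta * cos(phi), theta * sin(phi))
}

#' Coarse scalp region from 10-05 channel labels
#'
#' Used by the synthetic generator to place item patterns (occipital cue
#' pattern, distributed scene pattern) and by tests that check searchlight
#' localization. Matching is by label prefix, longest first.
#'
#' @param channels character vector of 10-05 labels.
#' @return Character vector: one of `"occipital"`, `"parietal"`,
#'   `"frontocentral"`, `"frontal"`, `"central"`, `"temporal"`.
#' @export
channel_region <- function(channels) {
  reg <- function(ch) {
    if (grepl("^(O|PO|I)", ch)) return("occipital")
    if (grepl("^(P|CP)", ch)) return("parietal")
    if (ch %in% c("FC1", "FC2", "FCz", "C1", "C2", "Cz")) return("frontocentral")
    if (grepl("^(FT|TP|T|M)", ch)) return("temporal")
    if (grepl("^(FC|C)", ch)) return("central")
    if (grepl("^(Fp|AF|F)", ch)) return("frontal")
    "central"
  }
  vapply(channels, reg, character(1), USE.NAMES = FALSE)
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", nrow(x), " channels (",
      paste(utils::head(x$channel, 6), collapse = ", "), ", ...)\n", sep = "")
  invisible(x)
}
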