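#' Model configuration
#'
#' Builds the full parameter list of the saliency model, with defaults that
#' reproduce the reference configuration: a 7-level half-octave pyramid,
#' an even-symmetric Gabor bank of wavelength 4 px sampled on a 13 px grid,
#' 15-px circular max-pooling with a 1/7.5 texture downscale, and the
#' border-ownership/grouping stage with von Mises annular kernels.
#'
#' @param ... named overrides, either nested lists (`gabor = list(sigma = 2)`)
#'   or dotted keys (`"gabor.sigma" = 2`) as used in plain-text config files.
#' @return a nested list of class `protoConfig`.
#' @examples
#' cfg <- protoConfig("texture.diameter" = 11)
#' cfg$texture$diameter
#' @export
protoConfig <- function(...) {
  cfg <- list(
    nLevels = 7L,
    scaleFactor = sqrt(2),
    gabor = list(
      wavelength = 4,
      sigma = 13 / 6,
      gamma = 1,
      extent = 13L,
      border_mode = "reflect"
    ),
    texture = list(
      diameter = 15L,
      resize_factor = 1 / 7.5,
      channels = c("J1", "J2", "J3"),
      sources = c("J", "RG", "GR", "BY", "YB")
    ),
    grouping = list(
      cs_span_lowlevel = 3L,
      cs_span_texture = 5L,
      vonmises_kappa = 3,
      annulus_radii = c(2, 3),
      bo_weight = 4,
      min_map_size = 7L
    ),
    combine = list(
      class_weights = NULL   # NULL = equal weights over present classes
    ),
    color_threshold = 0.1
  )
  ov <- list(...)
  for (key in names(ov)) {
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      cfg[[parts]] <- ov[[key]]
    } else if (is.list(ov[[key]]) && is.list(cfg[[key]])) {
      cfg[[key]] <- utils::modifyList(cfg[[key]], ov[[key]])
    } else {
      cfg[[key]] <- ov[[key]]
    }
  }
  class(cfg) <- c("protoConfig", "list")
  cfg
}

#' Read a key = value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments.
#' Keys use dotted paths (`gabor.sigma = 2.2`); values are parsed as numeric
#' vectors when possible, otherwise kept as strings.
#'
#' @param path file path.
#' @return a `protoConfig` list.
#' @export
readProtoConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  ov <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln)
    key <- trimws(kv[1])
    valstr <- trimws(kv[2])
    parts <- trimws(strsplit(valstr, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    ov[[key]] <- if (!anyNA(num)) num else parts
  }
  do.call(protoConfig, ov)
}
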