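# Reinhard-style stain normalization: per-channel moment matching in the
# perceptual CIE Lab space (one lightness + two chroma channels), mapping
# each tile's channel mean/sd onto a reference. Deterministic and
# parameter-free; a stain-vector (Macenko-style) method could be swapped in
# behind the same signatures.

lab_from_raster <- function(raster) {
  assert_raster(raster)
  d <- dim(raster)
  m <- cbind(as.vector(raster[, , 1]), as.vector(raster[, , 2]),
             as.vector(raster[, , 3])) / 255
  list(lab = grDevices::convertColor(m, from = "sRGB", to = "Lab"), dim = d)
}

raster_from_lab <- function(lab, d) {
  m <- grDevices::convertColor(lab, from = "Lab", to = "sRGB")
  m <- pmin(pmax(m, 0), 1)
  array(round(m * 255), d)
}

#' Fit reference color statistics from a tile set
#'
#' Pools all pixels of all tiles in Lab space and records the per-channel
#' mean and (population) standard deviation.
#'
#' @param tiles List of tile rasters (H x W x 3 arrays, 0..255), or of tile
#'   records / `"bl_tile"` objects carrying a `$raster`.
#' @param provenance Free-text identifier of the reference tile set.
#' @return An object of class `"reference_stats"`: channel means `mean`,
#'   standard deviations `sd` (both length 3, Lab order L/a/b), `space`,
#'   `n_pixels`, `n_tiles`, `provenance` and `version`.
#' @export
fit_reference <- function(tiles, provenance = "unspecified") {
  if (is.array(tiles)) tiles <- list(tiles)
  rasters <- lapply(tiles, function(t) if (is.list(t)) t$raster else t)
  stopifnot(length(rasters) >= 1)
  labs <- do.call(rbind, lapply(rasters, function(r) lab_from_raster(r)$lab))
  mu <- colMeans(labs)
  sdv <- sqrt(colMeans(sweep(labs, 2, mu)^2))
  if (any(sdv < 1e-8))
    stop("reference tiles are constant in at least one channel; ",
         "cannot fit reference statistics", call. = FALSE)
  structure(
    list(mean = unname(mu), sd = unname(sdv), space = "Lab",
         n_pixels = nrow(labs), n_tiles = length(rasters),
         provenance = provenance, version = "1"),
    class = "reference_stats"
  )
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference stats v%s, %s> %d tiles / %d px\n  mean %s\n  sd   %s\n",
              x$version, x$space, x$n_tiles, x$n_pixels,
              paste(sprintf("%.2f", x$mean), collapse = " "),
              paste(sprintf("%.2f", x$sd), collapse = " ")))
  invisible(x)
}

#' Normalize a tile to reference color statistics
#'
#' Per channel in Lab space: `out = (in - mu_tile) / sd_tile * sd_ref +
#' mu_ref`, then conversion back to 8-bit sRGB with clipping. Before
#' clipping/quantization the output channel moments equal the reference
#' exactly. A channel with (numerically) zero spread cannot be rescaled; it
#' is shifted to the reference mean and flagged via a message.
#'
#' @param raster Tile raster (H x W x 3, 0..255).
#' @param ref A [fit_reference()] object.
#' @return Normalized raster of the same dimensions.
#' @export
normalize_tile <- function(raster, ref) {
  stopifnot(inherits(ref, "reference_stats"))
  lr <- lab_from_raster(raster)
  raster_from_lab(normalize_lab(lr$lab, ref), lr$dim)
}

# Moment matching in Lab space; the pre-clipping output moments equal the
# reference exactly (up to floating point).
normalize_lab <- function(lab, ref) {
  for (c in 1:3) {
    mu <- mean(lab[, c])
    s <- sqrt(mean((lab[, c] - mu)^2))
    if (s < 1e-8) {
      message("constant channel ", c, "; shifted to reference mean")
      lab[, c] <- ref$mean[c]
    } else {
      lab[, c] <- (lab[, c] - mu) / s * ref$sd[c] + ref$mean[c]
    }
  }
  lab
}

#' Write / read reference statistics as JSON
#'
#' @param ref A `"reference_stats"` object.
#' @param path File path.
#' @return `write_reference()` returns `path` invisibly; `read_reference()`
#'   returns the `"reference_stats"` object.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "reference_stats"))
  jsonlite::write_json(unclass(ref), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("mean", "sd", "space", "n_pixels", "n_tiles", "provenance",
                "version")],
            class = "reference_stats")
}

.pkg_cache <- new.env(parent = emptyenv())

#' Default reference statistics
#'
#' The pipeline's self-contained reference: statistics fitted to six clean
#' synthetic tiles (alternating classes, seeds 0..5), computed once per
#' session and cached. Fully deterministic, so the "fixture" is reproduced
#' identically everywhere.
#'
#' @return A `"reference_stats"` object.
#' @export
default_reference <- function() {
  if (is.null(.pkg_cache$default_ref)) {
    tiles <- lapply(0:5, function(i) {
      generate_tile(if (i %% 2 == 0) "positive" else "negative",
                    "clean", 64, seed = i)
    })
    .pkg_cache$default_ref <- fit_reference(tiles,
                                            provenance = "synthetic-clean-seed0")
  }
  .pkg_cache$default_ref
}
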