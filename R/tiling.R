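# Overlapping fixed-size tiling of slide rasters. Origins are 0-based with
# half-open extents [x, x + size); x indexes columns, y rows. Partial edge
# tiles are dropped so every tile is exactly tile_size_px square.

.magnifications <- c("5x" = 2, "10x" = 1, "20x" = 0.5, "40x" = 0.25) # um/px

#' Plan tile origins for a slide
#'
#' Origins form the stride grid `{0, s, 2s, ...}` with
#' `s = tile_size_px - overlap_px`, truncated to fully in-bounds positions
#' (partial edge tiles are dropped), in row-major order.
#'
#' @param width_px,height_px Slide dimensions in pixels.
#' @param tile_size_px Tile edge length (default 450, the larger of the two
#'   conventional sizes; 400 is the other).
#' @param overlap_px Overlap between adjacent tiles in pixels (default 20).
#' @param slide_id,magnification Optional metadata carried into the plan.
#' @return An object of class `"tile_plan"` with an `origins` data frame
#'   (`x`, `y`) and the planning parameters.
#' @examples
#' plan_tiles(1000, 1000, 450, 20)$origins
#' @export
plan_tiles <- function(width_px, height_px, tile_size_px = 450,
                       overlap_px = 20, slide_id = NULL,
                       magnification = NULL) {
  stopifnot(tile_size_px > 0, overlap_px >= 0)
  if (overlap_px >= tile_size_px)
    stop("overlap_px must be smaller than tile_size_px", call. = FALSE)
  if (width_px < tile_size_px)
    stop("slide width (", width_px, ") is smaller than one tile (",
         tile_size_px, ")", call. = FALSE)
  if (height_px < tile_size_px)
    stop("slide height (", height_px, ") is smaller than one tile (",
         tile_size_px, ")", call. = FALSE)
  stride <- as.integer(tile_size_px - overlap_px)
  xs <- as.integer(seq.int(0L, width_px - tile_size_px, by = stride))
  ys <- as.integer(seq.int(0L, height_px - tile_size_px, by = stride))
  origins <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  origins <- origins[order(origins$y, origins$x), , drop = FALSE]
  rownames(origins) <- NULL
  structure(
    list(slide_id = slide_id, magnification = magnification,
         width_px = width_px, height_px = height_px,
         tile_size_px = tile_size_px, overlap_px = overlap_px,
         stride = stride, origins = origins),
    class = "tile_plan"
  )
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile plan> %dx%d slide, tile %d, overlap %d: %d tiles\n",
              x$width_px, x$height_px, x$tile_size_px, x$overlap_px,
              nrow(x$origins)))
  invisible(x)
}

#' Extract tiles from a slide raster
#'
#' @param raster Slide raster (H x W x 3, 0..255).
#' @param plan A `"tile_plan"` from [plan_tiles()].
#' @return List of tile records, each a list with `slide_id`, `x`, `y`
#'   (0-based origin), `magnification`, `tile_size_px` and `raster` equal to
#'   the slide sub-raster on `[x, x+size) x [y, y+size)`.
#' @export
extract_tiles <- function(raster, plan) {
  assert_raster(raster, "slide raster")
  stopifnot(inherits(plan, "tile_plan"))
  d <- dim(raster)
  size <- plan$tile_size_px
  if (any(plan$origins$x + size > d[2]) || any(plan$origins$y + size > d[1]))
    stop("tile plan extends beyond the slide raster", call. = FALSE)
  lapply(seq_len(nrow(plan$origins)), function(i) {
    x <- plan$origins$x[i]; y <- plan$origins$y[i]
    list(slide_id = plan$slide_id, x = x, y = y,
         magnification = plan$magnification, tile_size_px = size,
         raster = raster[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE])
  })
}

#' Reassemble tiles onto a blank canvas
#'
#' Intended for zero-overlap plans, where the tiles partition the covered
#' region and stitching reproduces the slide exactly; with overlap, later
#' tiles overwrite earlier ones.
#'
#' @param tiles List of tile records from [extract_tiles()].
#' @param width_px,height_px Canvas dimensions.
#' @return An H x W x 3 raster.
#' @export
stitch_tiles <- function(tiles, width_px, height_px) {
  out <- array(0, c(height_px, width_px, 3))
  for (t in tiles) {
    size <- t$tile_size_px
    out[(t$y + 1):(t$y + size), (t$x + 1):(t$x + size), ] <- t$raster
  }
  out
}

# One 2x area-average downsample; odd trailing rows/columns are cropped.
downsample2 <- function(raster) {
  d <- dim(raster)
  h2 <- d[1] %/% 2; w2 <- d[2] %/% 2
  if (h2 < 1 || w2 < 1) stop("raster too small to downsample", call. = FALSE)
  a <- raster[seq_len(2 * h2), seq_len(2 * w2), , drop = FALSE]
  oi <- seq.int(1L, 2L * h2, by = 2L)
  oj <- seq.int(1L, 2L * w2, by = 2L)
  round((a[oi, oj, , drop = FALSE] + a[oi + 1L, oj, , drop = FALSE] +
           a[oi, oj + 1L, , drop = FALSE] + a[oi + 1L, oj + 1L, , drop = FALSE]) / 4)
}

#' Build a magnification pyramid from the highest-resolution raster
#'
#' Mirrors a scanner pyramid (40x = 0.25 um/px down to 5x = 2 um/px): each
#' coarser level is a 2x2 area-average downsample of the previous one, with
#' dimensions halving (floor) per step.
#'
#' @param raster Raster at the highest requested magnification.
#' @param levels Subset of `c("5x", "10x", "20x", "40x")`; the highest one
#'   names the input raster.
#' @return Named list of rasters, ordered from highest to lowest
#'   magnification.
#' @examples
#' pyr <- build_pyramid(generate_slide(synthetic_slide_spec("s", "positive",
#'   seed = 1))$raster, c("40x", "20x"))
#' sapply(pyr, function(r) dim(r)[1])
#' @export
build_pyramid <- function(raster, levels = names(.magnifications)) {
  if (length(levels) == 0) stop("at least one level required", call. = FALSE)
  if (!all(levels %in% names(.magnifications)))
    stop("levels must be among: ",
         paste(names(.magnifications), collapse = ", "), call. = FALSE)
  assert_raster(raster, "slide raster")
  # order from highest magnification (smallest um/px) downwards
  levels <- levels[order(.magnifications[levels])]
  out <- list()
  cur <- raster
  cur_um <- .magnifications[[levels[1]]]
  out[[levels[1]]] <- cur
  for (lv in levels[-1]) {
    while (cur_um < .magnifications[[lv]]) {
      cur <- downsample2(cur)
      cur_um <- cur_um * 2
    }
    out[[lv]] <- cur
  }
  out
}

#' Tile a slide raster at several magnification levels
#'
#' Convenience wrapper: builds the pyramid, plans and extracts tiles at each
#' level, and concatenates the tile records. Levels whose raster is smaller
#' than one tile are skipped with a warning.
#'
#' @inheritParams build_pyramid
#' @inheritParams plan_tiles
#' @param slide_id Identifier stamped on every tile record.
#' @return List of tile records across all usable levels.
#' @export
tile_slide <- function(raster, slide_id, levels = c("40x", "20x"),
                       tile_size_px = 450, overlap_px = 20) {
  pyr <- build_pyramid(raster, levels)
  out <- list()
  for (lv in names(pyr)) {
    d <- dim(pyr[[lv]])
    if (d[1] < tile_size_px || d[2] < tile_size_px) {
      warning("level ", lv, " of slide ", slide_id,
              " is smaller than one tile; skipped", call. = FALSE)
      next
    }
    plan <- plan_tiles(d[2], d[1], tile_size_px, overlap_px,
                       slide_id = slide_id, magnification = lv)
    out <- c(out, extract_tiles(pyr[[lv]], plan))
  }
  out
}

#' Write tile records as PNGs with a manifest
#'
#' @param tiles List of tile records.
#' @param dir Output directory.
#' @return Path of the manifest CSV
#'   (`slide_id,x,y,magnification,tile_size,path`), invisibly.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(tiles, function(t) {
    path <- file.path(dir, sprintf("%s_%s_x%d_y%d.png", t$slide_id,
                                   t$magnification, t$x, t$y))
    write_tile_png(t$raster, path)
    data.frame(slide_id = t$slide_id, x = t$x, y = t$y,
               magnification = t$magnification, tile_size = t$tile_size_px,
               path = path, stringsAsFactors = FALSE)
  })
  mpath <- file.path(dir, "tiles.csv")
  utils::write.csv(do.call(rbind, rows), mpath, row.names = FALSE)
  invisible(mpath)
}
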