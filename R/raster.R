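# Rasters are numeric/integer arrays [H, W, 3] of 8-bit RGB values (0..255).
# Rows index y (top to bottom), columns index x; all tile coordinates in the
# package are 0-based with half-open extents [x, x + size).

assert_raster <- function(x, what = "raster") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop(what, " must be an H x W x 3 RGB array", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop(what, " values must lie in [0, 255]", call. = FALSE)
  invisible(x)
}

#' Convert a raster to HSV channel matrices
#'
#' @param raster An H x W x 3 RGB array with values in 0..255.
#' @return A list with H x W matrices `h` (hue in degrees, \[0, 360)),
#'   `s` (saturation in \[0, 1\]) and `v` (value in \[0, 1\]).
#' @keywords internal
raster_hsv <- function(raster) {
  assert_raster(raster)
  d <- dim(raster)
  hsv <- grDevices::rgb2hsv(
    r = as.vector(raster[, , 1]),
    g = as.vector(raster[, , 2]),
    b = as.vector(raster[, , 3]),
    maxColorValue = 255
  )
  list(
    h = matrix(hsv["h", ] * 360, d[1], d[2]),
    s = matrix(hsv["s", ], d[1], d[2]),
    v = matrix(hsv["v", ], d[1], d[2])
  )
}

# Inverse of raster_hsv for matrix inputs; hue in degrees.
hsv_to_raster <- function(h, s, v) {
  stopifnot(all(dim(h) == dim(s)), all(dim(h) == dim(v)))
  cols <- grDevices::hsv(pmin(pmax(h / 360, 0), 1 - 1e-9),
                         pmin(pmax(s, 0), 1),
                         pmin(pmax(v, 0), 1))
  m <- grDevices::col2rgb(cols)
  array(c(m[1, ], m[2, ], m[3, ]), c(nrow(h), ncol(h), 3))
}

# Luma (ITU-R BT.601) grayscale, rounded to integer 0..255.
raster_luma <- function(raster) {
  assert_raster(raster)
  round(0.299 * raster[, , 1] + 0.587 * raster[, , 2] + 0.114 * raster[, , 3])
}

#' Read / write an 8-bit RGB tile as PNG
#'
#' Thin wrappers over [png::readPNG()] / [png::writePNG()] converting between
#' the package's 0..255 raster arrays and PNG's unit-interval encoding.
#'
#' @param path File path.
#' @param raster Raster array to write.
#' @return `read_tile_png()` returns a raster array; `write_tile_png()`
#'   returns `path` invisibly.
#' @export
read_tile_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  r <- round(img * 255)
  dim(r) <- dim(img)[1:3]
  r
}

#' @rdname read_tile_png
#' @export
write_tile_png <- function(raster, path) {
  assert_raster(raster)
  png::writePNG(raster / 255, path)
  invisible(path)
}

# Bilinear resize of one channel matrix to out_h x out_w.
resize_channel <- function(m, out_h, out_w) {
  in_h <- nrow(m); in_w <- ncol(m)
  if (in_h == out_h && in_w == out_w) return(m)
  # pixel-centre alignment
  ys <- (seq_len(out_h) - 0.5) * in_h / out_h + 0.5
  xs <- (seq_len(out_w) - 0.5) * in_w / out_w + 0.5
  y0 <- pmin(pmax(floor(ys), 1), in_h); y1 <- pmin(y0 + 1, in_h)
  x0 <- pmin(pmax(floor(xs), 1), in_w); x1 <- pmin(x0 + 1, in_w)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  top <- m[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
    m[y0, x1, drop = FALSE] * outer(1 - wy, wx)
  bot <- m[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
    m[y1, x1, drop = FALSE] * outer(wy, wx)
  top + bot
}

# Resize a raster to size_px x size_px (bilinear, channel-wise).
resize_raster <- function(raster, size_px) {
  assert_raster(raster)
  if (all(dim(raster)[1:2] == size_px)) return(raster)
  out <- array(0, c(size_px, size_px, 3))
  for (c in 1:3) out[, , c] <- resize_channel(raster[, , c], size_px, size_px)
  pmin(pmax(out, 0), 255)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a base seed and an index, kept within the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(base_seed, index) {
  as.integer((abs(as.numeric(base_seed)) * 100003 + index * 7919) %% 2147483647)
}
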