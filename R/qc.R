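# Four-stage tile quality control, applied in fixed order with short-circuit
# evaluation: (1) background/outlier removal by pooled RGB standard
# deviation, (2) pen-mark removal by HSV color masks, (3) purple-to-pink
# hue-band ratio (cellularity proxy), (4) Otsu tissue-presence filter on the
# complemented grayscale. The filter structure is the contract; every numeric
# threshold below is a configurable default.

#' QC thresholds and color bands
#'
#' Bundles the tunable constants of the four QC stages. Hue is measured in
#' degrees `[0, 360)`; saturation and value in `[0, 1]`. Each pen range is a
#' box in HSV space given as `list(h = c(lo, hi), s = c(lo, hi),
#' v = c(lo, hi))`; a pixel inside any box counts as pen ink.
#'
#' @param bg_std_min Minimum pooled RGB standard deviation (8-bit units) for
#'   a tile to count as non-background (default 8).
#' @param pen_fraction_max Maximum tolerated fraction of pen pixels
#'   (default 0.05).
#' @param pen_hsv_ranges Named list of HSV boxes for green, blue and gray
#'   ink.
#' @param purple_band,pink_band Hue intervals (degrees) for
#'   hematoxylin-stained nuclei and eosin-stained stroma; must be disjoint.
#' @param saturation_floor Minimum saturation for a pixel to count toward
#'   either stain band (default 0.15; near-white pixels carry no stain
#'   evidence).
#' @param pp_ratio_min Minimum purple-to-pink pixel-count ratio
#'   (default 0.3).
#' @param tissue_fraction_min Minimum tissue fraction from the Otsu stage
#'   (default 0.10).
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(bg_std_min = 8,
                          pen_fraction_max = 0.05,
                          pen_hsv_ranges = list(
                            green = list(h = c(80, 160), s = c(0.25, 1), v = c(0.2, 1)),
                            blue  = list(h = c(200, 260), s = c(0.25, 1), v = c(0.2, 1)),
                            gray  = list(h = c(0, 360), s = c(0, 0.12), v = c(0.2, 0.8))
                          ),
                          purple_band = c(250, 310),
                          pink_band = c(310, 360),
                          saturation_floor = 0.15,
                          pp_ratio_min = 0.3,
                          tissue_fraction_min = 0.10) {
  stopifnot(bg_std_min >= 0,
            pen_fraction_max >= 0, pen_fraction_max <= 1,
            tissue_fraction_min >= 0, tissue_fraction_min <= 1,
            pp_ratio_min > 0, length(purple_band) == 2, length(pink_band) == 2)
  if (max(purple_band[1], pink_band[1]) < min(purple_band[2], pink_band[2]))
    stop("purple_band and pink_band must be disjoint", call. = FALSE)
  for (rg in pen_hsv_ranges)
    stopifnot(length(rg$h) == 2, length(rg$s) == 2, length(rg$v) == 2)
  structure(
    list(bg_std_min = bg_std_min, pen_fraction_max = pen_fraction_max,
         pen_hsv_ranges = pen_hsv_ranges, purple_band = purple_band,
         pink_band = pink_band, saturation_floor = saturation_floor,
         pp_ratio_min = pp_ratio_min,
         tissue_fraction_min = tissue_fraction_min),
    class = "qc_thresholds"
  )
}

#' Background / blank-tile filter
#'
#' Pools all pixels and channels and computes the population standard
#' deviation of the 8-bit values; near-constant tiles (blank glass, saturated
#' outliers) fall below the threshold.
#'
#' @param raster Tile raster (H x W x 3, 0..255).
#' @param bg_std_min Pass threshold on the pooled standard deviation.
#' @return List with `pass` (logical) and `bg_std`.
#' @export
background_filter <- function(raster, bg_std_min = 8) {
  assert_raster(raster, "tile")
  x <- as.numeric(raster)
  bg_std <- sqrt(mean((x - mean(x))^2))
  list(pass = bg_std >= bg_std_min, bg_std = bg_std)
}

hsv_box_mask <- function(hsv, box) {
  hsv$h >= box$h[1] & hsv$h <= box$h[2] &
    hsv$s >= box$s[1] & hsv$s <= box$s[2] &
    hsv$v >= box$v[1] & hsv$v <= box$v[2]
}

ranges_overlap <- function(a, b) {
  all(vapply(c("h", "s", "v"),
             function(k) max(a[[k]][1], b[[k]][1]) < min(a[[k]][2], b[[k]][2]),
             logical(1)))
}

#' Pen-marking filter
#'
#' Converts the tile to HSV, unions the per-ink color masks and measures the
#' fraction of pixels flagged as pen. Overlapping ink ranges trigger a
#' warning (the union is still taken).
#'
#' @inheritParams background_filter
#' @param pen_hsv_ranges,pen_fraction_max See [qc_thresholds()].
#' @return List with `pass` and `pen_fraction`.
#' @export
pen_mark_filter <- function(raster,
                            pen_hsv_ranges = qc_thresholds()$pen_hsv_ranges,
                            pen_fraction_max = 0.05) {
  assert_raster(raster, "tile")
  nr <- length(pen_hsv_ranges)
  if (nr > 1) {
    for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
      if (ranges_overlap(pen_hsv_ranges[[i]], pen_hsv_ranges[[j]]))
        warning("pen HSV ranges ", names(pen_hsv_ranges)[i], " and ",
                names(pen_hsv_ranges)[j], " overlap; taking their union",
                call. = FALSE)
    }
  }
  hsv <- raster_hsv(raster)
  mask <- Reduce(`|`, lapply(pen_hsv_ranges, function(b) hsv_box_mask(hsv, b)))
  pen_fraction <- mean(mask)
  list(pass = pen_fraction <= pen_fraction_max, pen_fraction = pen_fraction)
}

#' Purple-to-pink ratio filter
#'
#' Counts pixels whose hue falls in the hematoxylin (purple) versus eosin
#' (pink) band, ignoring pixels below the saturation floor (no stain
#' evidence). A low ratio flags scant cellularity, fibrosis or fold/tear
#' artifacts. Edge cases: pink count 0 with purple evidence passes
#' (`pp_ratio = Inf`); no qualifying pixels in either band fails
#' (`pp_ratio = NA`).
#'
#' @inheritParams background_filter
#' @param purple_band,pink_band,saturation_floor,pp_ratio_min See
#'   [qc_thresholds()].
#' @return List with `pass` and `pp_ratio`.
#' @export
purple_pink_filter <- function(raster, purple_band = c(250, 310),
                               pink_band = c(310, 360),
                               saturation_floor = 0.15,
                               pp_ratio_min = 0.3) {
  assert_raster(raster, "tile")
  if (max(purple_band[1], pink_band[1]) < min(purple_band[2], pink_band[2]))
    stop("purple_band and pink_band must be disjoint", call. = FALSE)
  hsv <- raster_hsv(raster)
  q <- hsv$s >= saturation_floor
  purple <- sum(q & hsv$h >= purple_band[1] & hsv$h < purple_band[2])
  pink <- sum(q & hsv$h >= pink_band[1] & hsv$h < pink_band[2])
  if (pink == 0 && purple == 0) return(list(pass = FALSE, pp_ratio = NA_real_))
  if (pink == 0) return(list(pass = TRUE, pp_ratio = Inf))
  pp_ratio <- purple / pink
  list(pass = pp_ratio >= pp_ratio_min, pp_ratio = pp_ratio)
}

#' Otsu threshold of an 8-bit sample
#'
#' Selects the threshold `t` in 0..255 maximizing the between-class variance
#' of the split into values `<= t` and `> t`; ties resolve to the lowest
#' threshold.
#'
#' @param x Integer-valued sample in 0..255 (vector, matrix or a 256-bin
#'   count vector when `counts = TRUE`).
#' @param counts Set to `TRUE` if `x` already is a 256-bin histogram.
#' @return The selected threshold (integer in 0..255), or `NA` if the
#'   histogram is degenerate (a single occupied bin).
#' @export
otsu_threshold <- function(x, counts = FALSE) {
  h <- if (counts) {
    stopifnot(length(x) == 256)
    as.numeric(x)
  } else {
    tabulate(as.integer(round(x)) + 1L, nbins = 256L)
  }
  n <- sum(h)
  if (n == 0 || sum(h > 0) < 2) return(NA_integer_)
  lev <- 0:255
  w0 <- cumsum(h) / n              # weight of class {<= t}
  mu0 <- cumsum(h * lev) / pmax(cumsum(h), 1)
  mu <- sum(h * lev) / n
  w1 <- 1 - w0
  mu1 <- (mu - w0 * mu0) / w1
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf
  as.integer(which.max(sigma_b) - 1L)  # which.max returns the first (lowest) maximum
}

#' Otsu tissue-presence filter
#'
#' Converts the tile to grayscale (BT.601 luma), complements it so tissue
#' (dark on a light background) becomes the high class, Otsu-thresholds the
#' 256-bin histogram and measures the fraction of complemented pixels
#' strictly above the threshold. Constant tiles have a degenerate histogram
#' and fail with `tissue_fraction = 0`.
#'
#' @inheritParams background_filter
#' @param tissue_fraction_min Pass threshold on the tissue fraction.
#' @return List with `pass`, `tissue_fraction` and `threshold`.
#' @export
otsu_tissue_filter <- function(raster, tissue_fraction_min = 0.10) {
  assert_raster(raster, "tile")
  comp <- 255 - raster_luma(raster)
  thr <- otsu_threshold(comp)
  if (is.na(thr))
    return(list(pass = FALSE, tissue_fraction = 0, threshold = NA_integer_))
  tissue_fraction <- mean(comp > thr)
  list(pass = tissue_fraction >= tissue_fraction_min,
       tissue_fraction = tissue_fraction, threshold = thr)
}

#' Run the full QC cascade on one tile
#'
#' Applies the four stages in order (background, pen, purple/pink, Otsu) and
#' short-circuits at the first failure; stages after the failure are marked
#' not-executed (`NA`). A pure function of `(raster, thresholds)`.
#'
#' @inheritParams background_filter
#' @param thresholds A [qc_thresholds()] object.
#' @return An object of class `"qc_result"`: list with `passed`,
#'   `stage_flags` (named logical, `NA` = not executed), `fail_stage`
#'   (`NA` if passed) and `scores` (`bg_std`, `pen_fraction`, `pp_ratio`,
#'   `tissue_fraction`).
#' @export
run_qc <- function(raster, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  flags <- c(background = NA, pen = NA, purple_pink = NA, otsu = NA)
  scores <- list(bg_std = NA_real_, pen_fraction = NA_real_,
                 pp_ratio = NA_real_, tissue_fraction = NA_real_)
  fail_stage <- NA_character_

  bg <- background_filter(raster, thresholds$bg_std_min)
  flags["background"] <- bg$pass
  scores$bg_std <- bg$bg_std
  if (bg$pass) {
    pen <- pen_mark_filter(raster, thresholds$pen_hsv_ranges,
                           thresholds$pen_fraction_max)
    flags["pen"] <- pen$pass
    scores$pen_fraction <- pen$pen_fraction
    if (pen$pass) {
      pp <- purple_pink_filter(raster, thresholds$purple_band,
                               thresholds$pink_band,
                               thresholds$saturation_floor,
                               thresholds$pp_ratio_min)
      flags["purple_pink"] <- pp$pass
      scores$pp_ratio <- pp$pp_ratio
      if (pp$pass) {
        ot <- otsu_tissue_filter(raster, thresholds$tissue_fraction_min)
        flags["otsu"] <- ot$pass
        scores$tissue_fraction <- ot$tissue_fraction
      }
    }
  }
  executed <- !is.na(flags)
  passed <- all(flags[executed]) && all(executed)
  if (!passed) fail_stage <- names(flags)[which(!flags)[1]]
  structure(list(passed = passed, stage_flags = flags,
                 fail_stage = fail_stage, scores = scores),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  if (x$passed) cat("<qc> passed all four stages\n")
  else cat("<qc> failed at stage:", x$fail_stage, "\n")
  invisible(x)
}

#' Run QC over a list of tile records
#'
#' @param tiles List of tile records (from [extract_tiles()] or
#'   [tile_slide()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return The tiles with a `$qc` element added to each record.
#' @export
qc_tiles <- function(tiles, thresholds = qc_thresholds()) {
  lapply(tiles, function(t) {
    t$qc <- run_qc(t$raster, thresholds)
    t
  })
}

#' Summarize QC results as a data frame
#'
#' @param tiles List of tile records carrying `$qc` (see [qc_tiles()]).
#' @return Data frame with one row per tile: coordinates, `passed`,
#'   `fail_stage` and the four stage scores.
#' @export
qc_summary <- function(tiles) {
  do.call(rbind, lapply(tiles, function(t) {
    s <- t$qc$scores
    data.frame(slide_id = t$slide_id %||% NA_character_,
               x = t$x %||% NA_integer_, y = t$y %||% NA_integer_,
               magnification = t$magnification %||% NA_character_,
               passed = t$qc$passed, fail_stage = t$qc$fail_stage,
               bg_std = s$bg_std, pen_fraction = s$pen_fraction,
               pp_ratio = s$pp_ratio, tissue_fraction = s$tissue_fraction,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
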