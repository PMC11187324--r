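# Synthetic H&E-like histology. Two classes are separable by nuclear density:
# "positive" (high-cellularity, lymphoma-like) tiles carry a larger area
# fraction of purple (hematoxylin-hued) nucleus blobs on the pink (eosin-hued)
# stroma field than "negative" (benign-control-like) tiles. Contamination
# categories (blank regions, green/blue/gray pen markings, low-tissue tiles)
# are constructed to be caught by the corresponding tile QC stage.

.syn_defaults <- list(
  density_positive = 0.55,
  density_negative = 0.28,
  purple_hue_deg = 270,
  pink_hue_deg = 330,
  hue_jitter_deg = 6,
  sv_jitter = 0.10,
  stroma_s = 0.35, stroma_v = 0.85,
  nucleus_s = 0.55, nucleus_v = 0.45
)

.artifact_levels <- c("clean", "blank", "pen_green", "pen_blue", "pen_gray",
                      "low_tissue")
.truth_levels <- c(background = 0L, tissue = 1L, pen = 2L, blank = 3L)

as_class_label <- function(label) {
  if (is.logical(label)) return(ifelse(label, "positive", "negative"))
  if (is.numeric(label)) return(ifelse(label > 0, "positive", "negative"))
  label <- as.character(label)
  if (!all(label %in% c("positive", "negative")))
    stop("class label must be 'positive' or 'negative' (or logical/0-1)",
         call. = FALSE)
  label
}

class_density <- function(label) {
  ifelse(as_class_label(label) == "positive",
         .syn_defaults$density_positive, .syn_defaults$density_negative)
}

# ---- low-level painters (use the current RNG stream) ------------------------

# Pink stroma field with purple elliptical nucleus blobs drawn until the
# requested area fraction is covered. Returns HSV matrices + nucleus mask.
paint_tissue <- function(h_px, w_px, nuclear_density, nucleus_radius_px,
                         purple_hue_deg = .syn_defaults$purple_hue_deg,
                         pink_hue_deg = .syn_defaults$pink_hue_deg) {
  n <- h_px * w_px
  d <- .syn_defaults
  hue_j <- matrix(stats::runif(n, -d$hue_jitter_deg, d$hue_jitter_deg), h_px, w_px)
  sat_j <- matrix(stats::runif(n, -d$sv_jitter, d$sv_jitter), h_px, w_px)
  val_j <- matrix(stats::runif(n, -d$sv_jitter, d$sv_jitter), h_px, w_px)
  h <- pink_hue_deg + hue_j
  s <- d$stroma_s * (1 + sat_j)
  v <- d$stroma_v * (1 + val_j)
  nuc <- matrix(FALSE, h_px, w_px)
  if (nuclear_density > 0 && nucleus_radius_px > 0) {
    target <- nuclear_density * n
    blob_area <- pi * nucleus_radius_px^2
    max_blobs <- ceiling(target / blob_area * 40) + 50
    for (b in seq_len(max_blobs)) {
      cx <- stats::runif(1, 1, w_px)
      cy <- stats::runif(1, 1, h_px)
      rx <- nucleus_radius_px * stats::runif(1, 0.7, 1.3)
      ry <- nucleus_radius_px * stats::runif(1, 0.7, 1.3)
      th <- stats::runif(1, 0, pi)
      rmax <- max(rx, ry)
      xs <- max(1, floor(cx - rmax)):min(w_px, ceiling(cx + rmax))
      ys <- max(1, floor(cy - rmax)):min(h_px, ceiling(cy + rmax))
      dx <- outer(rep(1, length(ys)), xs - cx)
      dy <- outer(ys - cy, rep(1, length(xs)))
      u <- (dx * cos(th) + dy * sin(th)) / rx
      w2 <- (-dx * sin(th) + dy * cos(th)) / ry
      nuc[ys, xs] <- nuc[ys, xs] | (u^2 + w2^2 <= 1)
      if (sum(nuc) >= target) break
    }
  }
  h[nuc] <- purple_hue_deg + hue_j[nuc]
  s[nuc] <- d$nucleus_s * (1 + sat_j[nuc])
  v[nuc] <- d$nucleus_v * (1 + val_j[nuc])
  list(h = h, s = s, v = v, nucleus = nuc)
}

# White (unstained glass) field: very low saturation, high value.
paint_blank_field <- function(h_px, w_px) {
  n <- h_px * w_px
  list(
    h = matrix(stats::runif(n, 0, 360), h_px, w_px),
    s = matrix(stats::runif(n, 0, 0.01), h_px, w_px),
    v = matrix(stats::runif(n, 0.958, 0.966), h_px, w_px)
  )
}

# Thick, slightly curving pen strokes accumulated until `target_fraction` of
# the canvas is covered. Returns a logical mask.
paint_pen_mask <- function(h_px, w_px, target_fraction, max_strokes = 400) {
  mask <- matrix(FALSE, h_px, w_px)
  if (target_fraction <= 0) return(mask)
  n <- h_px * w_px
  thick <- max(2, round(min(h_px, w_px) / 18))
  r2 <- (thick / 2)^2
  for (st in seq_len(max_strokes)) {
    px <- stats::runif(1, 1, w_px)
    py <- stats::runif(1, 1, h_px)
    ang <- stats::runif(1, 0, 2 * pi)
    steps <- round(stats::runif(1, 0.4, 0.9) * min(h_px, w_px) / (thick / 2))
    for (k in seq_len(max(steps, 2))) {
      xs <- max(1, floor(px - thick / 2)):min(w_px, ceiling(px + thick / 2))
      ys <- max(1, floor(py - thick / 2)):min(h_px, ceiling(py + thick / 2))
      dx <- outer(rep(1, length(ys)), xs - px)
      dy <- outer(ys - py, rep(1, length(xs)))
      mask[ys, xs] <- mask[ys, xs] | (dx^2 + dy^2 <= r2)
      ang <- ang + stats::runif(1, -0.3, 0.3)
      px <- min(max(px + cos(ang) * thick / 2, 1), w_px)
      py <- min(max(py + sin(ang) * thick / 2, 1), h_px)
    }
    if (sum(mask) >= target_fraction * n) break
  }
  mask
}

# Ink colors chosen inside the default QC pen masks.
pen_hsv_values <- function(kind, n) {
  switch(kind,
    green = list(h = stats::runif(n, 115, 125), s = stats::runif(n, 0.65, 0.75),
                 v = stats::runif(n, 0.50, 0.60)),
    blue  = list(h = stats::runif(n, 225, 235), s = stats::runif(n, 0.65, 0.75),
                 v = stats::runif(n, 0.50, 0.60)),
    gray  = list(h = stats::runif(n, 0, 360), s = stats::runif(n, 0.02, 0.08),
                 v = stats::runif(n, 0.40, 0.60)),
    stop("unknown pen kind: ", kind, call. = FALSE)
  )
}

apply_pen <- function(field, mask, kind) {
  n <- sum(mask)
  if (n == 0) return(field)
  ink <- pen_hsv_values(kind, n)
  field$h[mask] <- ink$h
  field$s[mask] <- ink$s
  field$v[mask] <- ink$v
  field
}

# Axis-aligned near-white rectangles until `target_fraction` covered.
paint_blank_rects <- function(h_px, w_px, target_fraction, max_rects = 200) {
  mask <- matrix(FALSE, h_px, w_px)
  if (target_fraction <= 0) return(mask)
  n <- h_px * w_px
  for (r in seq_len(max_rects)) {
    rw <- max(4, round(stats::runif(1, 0.08, 0.16) * w_px))
    rh <- max(4, round(stats::runif(1, 0.08, 0.16) * h_px))
    x0 <- round(stats::runif(1, 1, max(1, w_px - rw)))
    y0 <- round(stats::runif(1, 1, max(1, h_px - rh)))
    mask[y0:(y0 + rh - 1), x0:(x0 + rw - 1)] <- TRUE
    if (sum(mask) >= target_fraction * n) break
  }
  mask
}

apply_blank <- function(field, mask) {
  n <- sum(mask)
  if (n == 0) return(field)
  white <- paint_blank_field(1, n)
  field$h[mask] <- white$h
  field$s[mask] <- white$s
  field$v[mask] <- white$v
  field
}

# ---- public generators ------------------------------------------------------

#' Generate a single synthetic histology tile
#'
#' Produces a deterministic, labelled tile for exercising the QC and learning
#' stages. `"clean"` tiles are pink stroma with purple elliptical nucleus
#' blobs whose area fraction depends on the class label (positive tiles are
#' denser than negative ones). Artifact categories embed the named
#' contamination: `"blank"` is near-constant unstained glass, the three
#' `"pen_*"` categories cover at least 60% of the tile with ink inside the
#' default pen-filter HSV masks, and `"low_tissue"` holds at most 10% tissue
#' on a white field.
#'
#' @param label Class label, `"positive"` or `"negative"` (logical and 0/1
#'   are accepted).
#' @param artifact One of `"clean"`, `"blank"`, `"pen_green"`, `"pen_blue"`,
#'   `"pen_gray"`, `"low_tissue"`.
#' @param size_px Tile edge length in pixels (at least 32).
#' @param seed Integer seed; output is a pure function of the arguments.
#' @return An object of class `"bl_tile"`: a list with elements `raster`
#'   (H x W x 3, 0..255), `truth_mask` (integer matrix, 0 = background,
#'   1 = tissue, 2 = pen, 3 = blank), `label`, `artifact`, `size_px`, `seed`.
#' @examples
#' t1 <- generate_tile("positive", "clean", 64, seed = 1)
#' dim(t1$raster)
#' @export
generate_tile <- function(label, artifact = "clean", size_px = 64, seed = 0) {
  label <- as_class_label(label)
  if (length(artifact) != 1L || !artifact %in% .artifact_levels)
    stop("unknown artifact category '", paste(artifact, collapse = ","),
         "'; must be one of: ", paste(.artifact_levels, collapse = ", "),
         call. = FALSE)
  if (size_px < 32) stop("size_px must be at least 32", call. = FALSE)
  density <- class_density(label)
  radius <- max(2, round(size_px / 22))
  truth <- matrix(.truth_levels[["tissue"]], size_px, size_px)
  field <- with_seed(seed, {
    if (artifact == "clean") {
      paint_tissue(size_px, size_px, density, radius)
    } else if (artifact == "blank") {
      truth[] <- .truth_levels[["blank"]]
      paint_blank_field(size_px, size_px)
    } else if (artifact %in% c("pen_green", "pen_blue", "pen_gray")) {
      f <- paint_tissue(size_px, size_px, density, radius)
      mask <- paint_pen_mask(size_px, size_px, target_fraction = 0.75)
      truth[mask] <- .truth_levels[["pen"]]
      apply_pen(f, mask, sub("^pen_", "", artifact))
    } else { # low_tissue
      f <- paint_blank_field(size_px, size_px)
      truth[] <- .truth_levels[["background"]]
      cx <- size_px / 2 + stats::runif(1, -size_px / 8, size_px / 8)
      cy <- size_px / 2 + stats::runif(1, -size_px / 8, size_px / 8)
      rx <- 0.17 * size_px * stats::runif(1, 0.92, 1.02)
      ry <- 0.17 * size_px * stats::runif(1, 0.92, 1.02)
      xs <- matrix(rep(seq_len(size_px), each = size_px), size_px)
      ys <- matrix(rep(seq_len(size_px), size_px), size_px)
      patch <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
      # a scanty smear: finer nuclear fragments keep the small patch
      # compositionally representative of the class's stain ratio
      tis <- paint_tissue(size_px, size_px, density,
                          max(1, round(size_px / 64)))
      f$h[patch] <- tis$h[patch]
      f$s[patch] <- tis$s[patch]
      f$v[patch] <- tis$v[patch]
      truth[patch] <- .truth_levels[["tissue"]]
      f
    }
  })
  structure(
    list(raster = hsv_to_raster(field$h, field$s, field$v),
         truth_mask = truth, label = label, artifact = artifact,
         size_px = size_px, seed = seed),
    class = "bl_tile"
  )
}

#' Specification for one synthetic pseudo-slide
#'
#' @param slide_id Slide identifier.
#' @param label Class label (`"positive"` or `"negative"`).
#' @param width_px,height_px Raster dimensions in pixels (at least 64).
#' @param nuclear_density Target area fraction of nucleus blobs in \[0, 1\];
#'   defaults to the class-specific value (0.55 positive, 0.28 negative) that
#'   makes the two classes separable downstream.
#' @param nucleus_radius_px Mean nucleus radius in pixels.
#' @param purple_hue_deg,pink_hue_deg Hue centres in degrees for nuclei and
#'   stroma.
#' @param pen_mark_fraction,blank_fraction Target area fractions of pen
#'   contamination and blank (unstained) regions, each in \[0, 1\].
#' @param seed Integer seed making the slide a pure function of its spec.
#' @return An object of class `"slide_spec"`.
#' @export
synthetic_slide_spec <- function(slide_id, label,
                                 width_px = 160, height_px = 160,
                                 nuclear_density = NULL,
                                 nucleus_radius_px = 3,
                                 purple_hue_deg = 270, pink_hue_deg = 330,
                                 pen_mark_fraction = 0.05,
                                 blank_fraction = 0.05,
                                 seed = 0) {
  label <- as_class_label(label)
  if (is.null(nuclear_density)) nuclear_density <- class_density(label)
  stopifnot(width_px >= 64, height_px >= 64,
            nuclear_density >= 0, nuclear_density <= 1,
            pen_mark_fraction >= 0, pen_mark_fraction <= 1,
            blank_fraction >= 0, blank_fraction <= 1,
            nucleus_radius_px > 0)
  if (pen_mark_fraction + blank_fraction > 0.6)
    stop("combined pen and blank fractions above 0.6 leave too little tissue",
         call. = FALSE)
  structure(
    list(slide_id = as.character(slide_id), label = label,
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         nuclear_density = nuclear_density,
         nucleus_radius_px = nucleus_radius_px,
         purple_hue_deg = purple_hue_deg, pink_hue_deg = pink_hue_deg,
         pen_mark_fraction = pen_mark_fraction,
         blank_fraction = blank_fraction, seed = as.integer(seed)),
    class = "slide_spec"
  )
}

#' Generate a synthetic pseudo-slide
#'
#' Renders the tissue field described by a [synthetic_slide_spec()], then adds
#' blank rectangles and pen strokes (cycling through green, blue and gray ink)
#' until their target area fractions are reached. Bit-identical for identical
#' specs.
#'
#' @param spec A `"slide_spec"` object.
#' @return An object of class `"bl_slide"`: list with `spec`, `raster`
#'   (H x W x 3) and `truth_mask` (integer matrix; 0 = background,
#'   1 = tissue, 2 = pen, 3 = blank).
#' @export
generate_slide <- function(spec) {
  if (!inherits(spec, "slide_spec"))
    stop("spec must be created by synthetic_slide_spec()", call. = FALSE)
  h_px <- spec$height_px; w_px <- spec$width_px
  out <- with_seed(spec$seed, {
    field <- paint_tissue(h_px, w_px, spec$nuclear_density,
                          spec$nucleus_radius_px,
                          spec$purple_hue_deg, spec$pink_hue_deg)
    truth <- matrix(.truth_levels[["tissue"]], h_px, w_px)
    blank_mask <- paint_blank_rects(h_px, w_px, spec$blank_fraction)
    field <- apply_blank(field, blank_mask)
    truth[blank_mask] <- .truth_levels[["blank"]]
    pen_mask <- matrix(FALSE, h_px, w_px)
    if (spec$pen_mark_fraction > 0) {
      kinds <- c("green", "blue", "gray")
      ki <- 0
      while (mean(pen_mask) < spec$pen_mark_fraction && ki < 60) {
        ki <- ki + 1
        stroke <- paint_pen_mask(h_px, w_px,
                                 target_fraction = mean(pen_mask) +
                                   min(0.02, spec$pen_mark_fraction),
                                 max_strokes = 1)
        add <- stroke & !pen_mask
        field <- apply_pen(field, add, kinds[(ki - 1) %% 3 + 1])
        pen_mask <- pen_mask | stroke
      }
      truth[pen_mask] <- .truth_levels[["pen"]]
    }
    list(raster = hsv_to_raster(field$h, field$s, field$v), truth = truth)
  })
  structure(list(spec = spec, raster = out$raster, truth_mask = out$truth),
            class = "bl_slide")
}

#' Generate a labelled cohort of synthetic slides
#'
#' Per-slide seeds are derived deterministically from `base_seed`, so the
#' whole cohort is reproducible while slides remain mutually distinct.
#'
#' @param n_positive,n_negative Number of slides per class (non-negative).
#' @param base_seed Integer base seed.
#' @param overrides Named list of [synthetic_slide_spec()] arguments applied
#'   to every slide (e.g. `list(width_px = 208)`).
#' @return List of `"bl_slide"` objects, positives first.
#' @export
generate_cohort <- function(n_positive, n_negative, base_seed = 0,
                            overrides = list()) {
  stopifnot(n_positive >= 0, n_negative >= 0)
  labels <- c(rep("positive", n_positive), rep("negative", n_negative))
  ids <- c(sprintf("POS%03d", seq_len(n_positive)),
           sprintf("NEG%03d", seq_len(n_negative)))
  lapply(seq_along(labels), function(i) {
    args <- c(list(slide_id = ids[i], label = labels[i],
                   seed = derive_seed(base_seed, i)), overrides)
    generate_slide(do.call(synthetic_slide_spec, args))
  })
}

#' Category fractions of a truth mask
#'
#' @param truth_mask Integer matrix as produced by [generate_slide()].
#' @return Named numeric vector of fractions over
#'   background/tissue/pen/blank.
#' @export
truth_fractions <- function(truth_mask) {
  n <- length(truth_mask)
  vapply(.truth_levels, function(code) sum(truth_mask == code) / n,
         numeric(1))
}

#' Write a synthetic cohort to disk
#'
#' Writes, per slide, the raster PNG, a gray-coded truth-mask PNG (levels 0,
#' 85, 170, 255 for background/tissue/pen/blank) and a JSON sidecar with the
#' spec, plus a cohort manifest CSV (`slide_id,label,path,seed`).
#'
#' @param cohort List of `"bl_slide"` objects.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(sl) {
    id <- sl$spec$slide_id
    path <- file.path(dir, paste0(id, ".png"))
    write_tile_png(sl$raster, path)
    png::writePNG(sl$truth_mask * 85 / 255, file.path(dir, paste0(id, "_truth.png")))
    jsonlite::write_json(unclass(sl$spec),
                         file.path(dir, paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(slide_id = id, label = sl$spec$label, path = path,
               seed = sl$spec$seed, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "cohort.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' @export
print.bl_tile <- function(x, ...) {
  cat(sprintf("<synthetic tile> %s/%s %dx%d seed=%d\n",
              x$label, x$artifact, x$size_px, x$size_px, x$seed))
  invisible(x)
}

#' @export
print.bl_slide <- function(x, ...) {
  fr <- truth_fractions(x$truth_mask)
  cat(sprintf("<synthetic slide> %s label=%s %dx%d (tissue %.0f%%, pen %.0f%%, blank %.0f%%)\n",
              x$spec$slide_id, x$spec$label, x$spec$width_px, x$spec$height_px,
              100 * fr[["tissue"]], 100 * fr[["pen"]], 100 * fr[["blank"]]))
  invisible(x)
}
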