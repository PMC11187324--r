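test_that("background filter computes the pooled standard deviation", {
  white <- const_raster(32, c(255, 255, 255))
  bg <- background_filter(white)
  expect_identical(bg$bg_std, 0)
  expect_false(bg$pass)

  half <- const_raster(32, c(0, 0, 0))
  half[1:16, , ] <- 255
  bg2 <- background_filter(half)
  expect_equal(bg2$bg_std, 127.5)
  expect_true(bg2$pass)

  # independent accumulation-loop oracle on a synthetic clean tile
  tl <- generate_tile("positive", "clean", 64, seed = 7)$raster
  acc <- 0; acc2 <- 0; n <- length(tl)
  for (v in as.vector(tl)) { acc <- acc + v; acc2 <- acc2 + v^2 }
  oracle_sd <- sqrt(acc2 / n - (acc / n)^2)
  bg3 <- background_filter(tl)
  expect_equal(bg3$bg_std, oracle_sd, tolerance = 1e-8)
  expect_true(bg3$pass)
})

test_that("pen filter measures mask membership fractions", {
  th <- qc_thresholds()
  # saturated green well inside the green box
  green <- const_raster(32, c(40, 150, 40))
  pf <- pen_mark_filter(green)
  expect_identical(pf$pen_fraction, 1)
  expect_false(pf$pass)

  # strong pink: outside every ink box
  pink <- const_raster(32, c(230, 150, 190))
  pf2 <- pen_mark_filter(pink)
  expect_identical(pf2$pen_fraction, 0)
  expect_true(pf2$pass)

  # one 16x16 green patch on a 64x64 white tile: 256/4096 > 0.05
  tile <- const_raster(64, c(250, 248, 249))
  tile[1:16, 1:16, 1] <- 40; tile[1:16, 1:16, 2] <- 150
  tile[1:16, 1:16, 3] <- 40
  pf3 <- pen_mark_filter(tile)
  expect_equal(pf3$pen_fraction, 256 / 4096)
  expect_false(pf3$pass)
  # per-pixel loop oracle over the union of the three boxes
  oracle <- sum(vapply(th$pen_hsv_ranges, function(b)
    oracle_hsv_box_count(tile, b), integer(1)))
  expect_equal(pf3$pen_fraction * 4096, oracle)
})

test_that("overlapping pen ranges warn and take the union", {
  ranges <- list(a = list(h = c(80, 160), s = c(0.2, 1), v = c(0.2, 1)),
                 b = list(h = c(100, 180), s = c(0.2, 1), v = c(0.2, 1)))
  green <- const_raster(16, c(40, 150, 40))
  expect_warning(res <- pen_mark_filter(green, ranges), "overlap")
  expect_identical(res$pen_fraction, 1)
})

test_that("purple-to-pink ratio follows the band-count definition", {
  purple <- const_raster(32, c(120, 60, 160))   # hue ~ 276
  pp <- purple_pink_filter(purple)
  expect_true(pp$pass)
  expect_identical(pp$pp_ratio, Inf)

  pink <- const_raster(32, c(230, 130, 190))    # hue ~ 324
  pp2 <- purple_pink_filter(pink)
  expect_identical(pp2$pp_ratio, 0)
  expect_false(pp2$pass)

  # 300 purple + 600 pink qualifying pixels, rest unsaturated
  tile <- const_raster(64, c(250, 250, 250))
  tile[1:10, 1:30, ] <- rep(c(120, 60, 160), each = 300)
  tile[21:30, 1:60, ] <- rep(c(230, 130, 190), each = 600)
  pp3 <- purple_pink_filter(tile)
  expect_equal(pp3$pp_ratio, 0.5)
  expect_true(pp3$pass)
  expect_identical(oracle_hue_band_count(tile, 250, 310), 300L)
  expect_identical(oracle_hue_band_count(tile, 310, 360), 600L)

  # no stain evidence at all fails
  blank <- const_raster(16, c(250, 250, 250))
  pp4 <- purple_pink_filter(blank)
  expect_false(pp4$pass)
  expect_true(is.na(pp4$pp_ratio))
})

test_that("otsu filter separates bimodal tiles and fails constants", {
  const <- const_raster(32, c(128, 128, 128))
  ot <- otsu_tissue_filter(const)
  expect_false(ot$pass)
  expect_identical(ot$tissue_fraction, 0)

  bimodal <- const_raster(32, c(240, 240, 240))  # light background
  bimodal[1:16, , ] <- 20                        # dark tissue
  ot2 <- otsu_tissue_filter(bimodal)
  expect_true(ot2$pass)
  expect_equal(ot2$tissue_fraction, 0.5)
  # complement histogram: modes at 15 and 235; threshold must lie between
  expect_true(ot2$threshold >= 15 && ot2$threshold < 235)

  lt <- generate_tile("positive", "low_tissue", 64, seed = 11)
  ot3 <- otsu_tissue_filter(lt$raster)
  expect_false(ot3$pass)
  expect_lte(ot3$tissue_fraction, 0.10)
})

test_that("otsu threshold equals the exhaustive variance scan", {
  set.seed(5)
  for (i in 1:50) {
    counts <- rpois(256, lambda = rexp(256, 1 / 5))
    if (sum(counts > 0) < 2) next
    expect_identical(otsu_threshold(counts, counts = TRUE),
                     oracle_otsu(counts))
  }
  # degenerate single-bin histogram
  h <- rep(0, 256); h[100] <- 50
  expect_true(is.na(otsu_threshold(h, counts = TRUE)))
})

test_that("the QC cascade short-circuits at the first failing stage", {
  blank <- generate_tile("positive", "blank", 64, seed = 3)
  q1 <- run_qc(blank$raster)
  expect_false(q1$passed)
  expect_identical(q1$fail_stage, "background")
  expect_true(all(is.na(q1$stage_flags[c("pen", "purple_pink", "otsu")])))

  pen <- generate_tile("positive", "pen_green", 64, seed = 3)
  q2 <- run_qc(pen$raster)
  expect_identical(q2$fail_stage, "pen")
  expect_true(q2$stage_flags[["background"]])
  expect_true(is.na(q2$stage_flags[["otsu"]]))

  clean <- generate_tile("negative", "clean", 64, seed = 3)
  q3 <- run_qc(clean$raster)
  expect_true(q3$passed)
  expect_true(all(q3$stage_flags))
  # pure function of its inputs
  expect_identical(q3, run_qc(clean$raster))
})

test_that("raising thresholds never converts a failing tile to passing", {
  set.seed(2)
  tiles <- lapply(1:6, function(s)
    generate_tile(if (s %% 2) "positive" else "negative",
                  sample(c("clean", "low_tissue", "pen_gray"), 1),
                  64, seed = s)$raster)
  lax <- qc_thresholds()
  strict <- qc_thresholds(bg_std_min = 12, pen_fraction_max = 0.02,
                          pp_ratio_min = 0.5, tissue_fraction_min = 0.2)
  for (r in tiles) {
    was <- run_qc(r, lax)$passed
    now <- run_qc(r, strict)$passed
    expect_false(!was && now)
    # and per-stage monotonicity
    expect_true(background_filter(r, 12)$pass <= background_filter(r, 8)$pass)
  }
})
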