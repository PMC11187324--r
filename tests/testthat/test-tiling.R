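test_that("the stride grid matches the worked 1000x1000 geometry", {
  plan <- plan_tiles(1000, 1000, 450, 20)
  expect_identical(plan$stride, 430L)
  expect_identical(sort(unique(plan$origins$x)), c(0L, 430L))
  expect_identical(nrow(plan$origins), 4L)
})

test_that("exact-fit and zero-overlap plans enumerate correctly", {
  p1 <- plan_tiles(450, 450, 450, 20)
  expect_identical(nrow(p1$origins), 1L)
  expect_identical(c(p1$origins$x, p1$origins$y), c(0L, 0L))

  p2 <- plan_tiles(900, 450, 450, 0)
  expect_identical(nrow(p2$origins), 2L)
  expect_identical(p2$origins$x, c(0L, 450L))
  expect_identical(p2$origins$y, c(0L, 0L))
})

test_that("undersized slides are rejected naming the dimension", {
  expect_error(plan_tiles(300, 1000, 450, 20), "width")
  expect_error(plan_tiles(1000, 300, 450, 20), "height")
  expect_error(plan_tiles(1000, 1000, 450, 450), "overlap")
})

test_that("plan_tiles agrees with brute-force enumeration", {
  set.seed(42)
  for (i in 1:100) {
    tile <- sample(16:64, 1)
    overlap <- sample(0:(tile - 1), 1)
    width <- tile + sample(0:200, 1)
    height <- tile + sample(0:200, 1)
    got <- plan_tiles(width, height, tile, overlap)$origins
    want <- oracle_plan_origins(width, height, tile, overlap)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 ignore_attr = TRUE)
    s <- tile - overlap
    expect_identical(nrow(got),
                     as.integer(((width - tile) %/% s + 1) *
                                  ((height - tile) %/% s + 1)))
  }
})

test_that("increasing overlap never decreases the tile count", {
  set.seed(7)
  for (i in 1:20) {
    tile <- sample(20:60, 1)
    width <- tile + sample(0:150, 1)
    height <- tile + sample(0:150, 1)
    counts <- vapply(0:(tile - 1), function(ov)
      nrow(plan_tiles(width, height, tile, ov)$origins), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("extracted tiles equal the slide sub-rasters", {
  slide <- const_raster(100, c(10, 20, 30))
  plan <- plan_tiles(100, 100, 50, 0)
  tiles <- extract_tiles(slide, plan)
  expect_length(tiles, 4)
  for (t in tiles) expect_true(all(t$raster == c(10, 20, 30)[
    rep(1:3, each = 2500)]))
})

test_that("marked pixels land in the tiles their half-open extents predict", {
  slide <- const_raster(1000, c(200, 200, 200))
  slide[1, 452, ] <- c(0, 0, 0)  # pixel at x = 451, y = 0 (0-based)
  plan <- plan_tiles(1000, 1000, 450, 20)
  tiles <- extract_tiles(slide, plan)
  hits <- vapply(tiles, function(t) any(t$raster == 0), logical(1))
  # past the overlap band of the first tile: exactly one owner, at x = 430
  expect_identical(sum(hits), 1L)
  expect_identical(tiles[[which(hits)]]$x, 430L)
  expect_identical(tiles[[which(hits)]]$y, 0L)

  # a pixel inside the 20 px overlap strip [430, 450) belongs to both tiles
  slide[1, 452, ] <- c(200, 200, 200)
  slide[1, 432, ] <- c(0, 0, 0)  # x = 431
  tiles <- extract_tiles(slide, plan)
  hits <- vapply(tiles, function(t) any(t$raster == 0), logical(1))
  expect_identical(sum(hits), 2L)
})

test_that("zero-overlap tiles stitch back to the original slide", {
  sl <- generate_slide(synthetic_slide_spec("s", "positive", width_px = 128,
                                            height_px = 128, seed = 4))
  plan <- plan_tiles(128, 128, 64, 0)
  back <- stitch_tiles(extract_tiles(sl$raster, plan), 128, 128)
  expect_equal(back, sl$raster, ignore_attr = TRUE)
})

test_that("pyramid levels halve dimensions by area averaging", {
  r <- generate_slide(synthetic_slide_spec("s", "positive", width_px = 800,
                                           height_px = 800, seed = 1))$raster
  pyr <- build_pyramid(r, c("40x", "20x", "10x", "5x"))
  expect_identical(vapply(pyr, function(x) dim(x)[1], numeric(1)),
                   c("40x" = 800, "20x" = 400, "10x" = 200, "5x" = 100))

  const <- const_raster(64, c(33, 44, 55))
  p2 <- build_pyramid(const, c("40x", "20x"))
  expect_true(all(p2[["20x"]][, , 1] == 33))

  # checkerboard of period 2 averages to uniform mid-gray
  cb <- array(0, c(64, 64, 3))
  cb[, , ] <- ifelse((outer(1:64, 1:64, `+`) %% 2) == 0, 255, 0)
  down <- build_pyramid(cb, c("40x", "20x"))[["20x"]]
  block_mean <- round((cb[1, 1, 1] + cb[1, 2, 1] + cb[2, 1, 1] + cb[2, 2, 1]) / 4)
  expect_true(all(down == block_mean))
  expect_error(build_pyramid(cb, character(0)), "at least one level")
})

test_that("tile manifests round-trip through disk", {
  dir <- withr::local_tempdir()
  sl <- generate_slide(synthetic_slide_spec("sl1", "negative", width_px = 128,
                                            height_px = 128, seed = 2))
  tiles <- tile_slide(sl$raster, "sl1", levels = c("40x", "20x"),
                      tile_size_px = 64, overlap_px = 16)
  mpath <- write_tiles(tiles, dir)
  manifest <- read.csv(mpath)
  expect_identical(nrow(manifest), length(tiles))
  expect_true(all(c("slide_id", "x", "y", "magnification", "tile_size",
                    "path") %in% names(manifest)))
  back <- read_tile_png(manifest$path[1])
  expect_equal(back, tiles[[1]]$raster, ignore_attr = TRUE)
})
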