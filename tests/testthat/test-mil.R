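# Shared desk-scale fixtures: a small preprocessed cohort, built once per run.
fix_cohort <- generate_cohort(6, 6, base_seed = 0,
                              overrides = list(width_px = 128, height_px = 128,
                                               pen_mark_fraction = 0,
                                               blank_fraction = 0))
fix_cfg <- pipeline_config(seed = 0, verbose = FALSE, tile_size_px = 64,
                           overlap_px = 16, levels = "40x")
fix_ids <- vapply(fix_cohort, function(s) s$spec$slide_id, character(1))
fix_labels <- setNames(vapply(fix_cohort, function(s) s$spec$label,
                              character(1)), fix_ids)
fix_tiles <- wsiscreen:::preprocess_cohort(
  lapply(fix_cohort, function(s) s$raster), fix_ids, fix_cfg)$tiles
fix_bags <- build_bags(fix_tiles, fix_labels)

test_that("bags collect QC-passing tiles per slide with inherited labels", {
  bags <- fix_bags
  expect_length(bags, 12)
  for (b in bags) {
    expect_s3_class(b, "mil_bag")
    expect_identical(b$label, unname(fix_labels[b$slide_id]))
    expect_identical(b$instance_count, length(b$instances))
    expect_gte(b$instance_count, 1)
    expect_true(all(vapply(b$instances, function(t) t$slide_id,
                           character(1)) == b$slide_id))
  }
  # deterministic instance ordering across repeated builds
  again <- build_bags(fix_tiles, fix_labels)
  ord <- function(bs) lapply(bs, function(b)
    vapply(b$instances, function(t) paste(t$magnification, t$y, t$x),
           character(1)))
  expect_identical(ord(bags), ord(again))
})

test_that("slides with zero passing tiles are excluded with a warning", {
  blank_tile <- list(slide_id = "EMPTY", x = 0, y = 0, magnification = "40x",
                     tile_size_px = 64,
                     raster = generate_tile("positive", "blank", 64, 1)$raster)
  tiles <- c(fix_tiles[1:5], qc_tiles(list(blank_tile)))
  labels <- c(fix_labels, EMPTY = "positive")
  expect_warning(bags <- build_bags(tiles, labels), "EMPTY")
  expect_identical(attr(bags, "rejects"), "EMPTY")
  expect_false("EMPTY" %in% vapply(bags, function(b) b$slide_id,
                                   character(1)))
})

test_that("slide splits honor largest-remainder 6:2:2 allocation", {
  part_counts <- function(sp) vapply(c("train", "val", "test"),
                                     function(p) sum(sp$assignment == p),
                                     integer(1), USE.NAMES = FALSE)
  sp <- split_slides(sprintf("s%02d", 1:10), seed = 1)
  expect_identical(part_counts(sp), c(6L, 2L, 2L))
  big <- split_slides(sprintf("s%03d", 1:160), seed = 3,
                      labels = rep(c("positive", "negative"), c(90, 70)))
  expect_identical(part_counts(big), c(96L, 32L, 32L))
  # stratification keeps both classes in every partition
  lab <- rep(c("positive", "negative"), c(90, 70))
  names(lab) <- sprintf("s%03d", 1:160)
  for (p in c("train", "val", "test")) {
    in_p <- names(big$assignment)[big$assignment == p]
    expect_identical(length(unique(lab[in_p])), 2L)
  }
})

test_that("splits are seeded and slide-disjoint", {
  ids <- sprintf("s%02d", 1:10)
  a <- split_slides(ids, seed = 5)
  b <- split_slides(ids, seed = 5)
  expect_identical(a$assignment, b$assignment)
  c_ <- split_slides(ids, seed = 6)
  expect_true(any(a$assignment != c_$assignment))
  # disjoint and exhaustive
  expect_identical(sort(names(a$assignment)), sort(ids))
  expect_false(anyDuplicated(names(a$assignment)) > 0)
})

test_that("instance sampling is without replacement with a saturation rule", {
  big <- fix_bags[[1]]
  big$instances <- rep(big$instances, length.out = 100)
  big$instance_count <- 100L
  s <- sample_instances(big, 20, seed = 1)
  expect_length(s, 20)

  small <- fix_bags[[1]]
  small$instances <- small$instances[rep(1, 12)]
  small$instance_count <- 12L
  expect_length(sample_instances(small, 20, seed = 1), 12)

  expect_identical(
    lapply(sample_instances(big, 20, seed = 9), function(t) c(t$x, t$y)),
    lapply(sample_instances(big, 20, seed = 9), function(t) c(t$x, t$y)))

  empty <- structure(list(slide_id = "e", label = "positive",
                          instances = list(), instance_count = 0L),
                     class = "mil_bag")
  expect_error(sample_instances(empty, 5, seed = 1), "empty bag")
})

test_that("marginal inclusion probability of sampling is uniform", {
  bag <- fix_bags[[1]]
  bag$instances <- bag$instances[rep(1, 10)]
  for (i in 1:10) bag$instances[[i]]$x <- i  # tag identity
  bag$instance_count <- 10L
  counts <- integer(10)
  for (s in 1:2000) {
    picked <- sample_instances(bag, 5, seed = s)
    for (t in picked) counts[t$x] <- counts[t$x] + 1L
  }
  p <- stats::chisq.test(counts, p = rep(0.1, 10))$p.value
  expect_gt(p, 0.001)
})

test_that("gradients of both pooling heads match finite differences", {
  set.seed(1)
  for (att in c(FALSE, TRUE)) {
    cfg <- model_config(backbone = "tiny-cnn", attention = att,
                        attention_head_size = 4, input_size_px = 16, seed = 3)
    bb <- wsiscreen:::.backbones[[cfg$backbone]]
    geoms <- wsiscreen:::backbone_geoms(16L, bb$filters)
    params <- wsiscreen:::with_seed(3, c(
      wsiscreen:::init_backbone_params(bb$filters),
      wsiscreen:::init_head_params(bb$filters[3], att, 4L)))
    model <- list(config = cfg, params = params, geoms = geoms)
    X <- matrix(rnorm(4 * 16 * 16 * 3), 4)
    g <- wsiscreen:::mil_loss_grad(model, X, 1L,
                                   wsiscreen:::zero_grads(params))
    eps <- 1e-5
    for (nm in names(params)) {
      for (j in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        m2 <- model
        m2$params[[nm]][j] <- params[[nm]][j] + eps
        lp <- wsiscreen:::mil_loss_grad(m2, X, 1L,
                                        wsiscreen:::zero_grads(params))$loss
        m2$params[[nm]][j] <- params[[nm]][j] - eps
        lm <- wsiscreen:::mil_loss_grad(m2, X, 1L,
                                        wsiscreen:::zero_grads(params))$loss
        num <- (lp - lm) / (2 * eps)
        an <- g$grads[[nm]][j]
        expect_lt(abs(num - an) / max(abs(num), abs(an), 1e-6), 1e-4)
      }
    }
  }
})

test_that("bag pooling reduces correctly for degenerate bags", {
  cfg <- model_config(backbone = "tiny-cnn", input_size_px = 64, seed = 4,
                      max_epochs = 2, patience = 1)
  bags <- fix_bags
  m <- train_model(cfg, bags[c(1, 7)], bags[c(2, 8)])

  # plain head: identical instances give the single-instance probability
  inst <- bags[[1]]$instances[[1]]
  p1 <- forward_bag(m, list(inst))
  p3 <- forward_bag(m, list(inst, inst, inst))
  expect_equal(p3$bag_probability, p1$bag_probability, tolerance = 1e-12)
  expect_equal(p1$bag_probability, unname(p1$instance_probabilities[1]),
               tolerance = 1e-12)

  cfg_a <- model_config(backbone = "tiny-cnn", attention = TRUE,
                        attention_head_size = 8, input_size_px = 64,
                        seed = 4, max_epochs = 2, patience = 1)
  ma <- train_model(cfg_a, bags[c(1, 7)], bags[c(2, 8)])
  pa <- forward_bag(ma, bags[[3]])
  expect_equal(sum(pa$attention_weights), 1, tolerance = 1e-6)
  # single-instance bag: attention weight is 1 and pooling is the identity
  pa1 <- forward_bag(ma, list(inst))
  expect_equal(unname(pa1$attention_weights), 1, tolerance = 1e-12)
})

test_that("training obeys the epoch cap, checkpoint rule and class checks", {
  cfg <- model_config(backbone = "tiny-cnn", input_size_px = 64,
                      max_epochs = 6, patience = 2, sample_size = 8,
                      batch_size = 4, seed = 0)
  bags <- fix_bags
  train <- bags[c(1:4, 7:10)]
  val <- bags[c(5, 11)]
  m <- train_model(cfg, train, val)
  expect_lte(nrow(m$history), 6)
  expect_equal(m$history$val_loss[m$best_epoch], min(m$history$val_loss),
               tolerance = 1e-6)

  only_pos <- bags[1:4]
  expect_error(train_model(cfg, only_pos, val), "both classes")
})

test_that("training is reproducible and learns the separable signal", {
  cfg <- model_config(backbone = "tiny-cnn", input_size_px = 64,
                      max_epochs = 12, patience = 5, sample_size = 8,
                      batch_size = 4, seed = 1)
  bags <- fix_bags
  train <- bags[c(1:4, 7:10)]
  val <- bags[c(5, 6, 11, 12)]
  m1 <- train_model(cfg, train, val)
  m2 <- train_model(cfg, train, val)
  expect_equal(m1$history, m2$history, tolerance = 1e-12)
  expect_identical(
    forward_bag(m1, bags[[6]])$bag_probability,
    forward_bag(m2, bags[[6]])$bag_probability)
  # better than the majority-class baseline (0.5 here) on validation
  expect_gt(max(m1$history$val_acc), 0.5)
})

test_that("model checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  cfg <- model_config(backbone = "tiny-cnn", input_size_px = 64,
                      max_epochs = 2, patience = 1, seed = 2)
  m <- train_model(cfg, fix_bags[c(1, 7)], fix_bags[c(2, 8)])
  path <- save_model(m, file.path(dir, "m.rds"))
  back <- load_model(path)
  expect_identical(back$params, m$params)
  expect_identical(
    forward_bag(back, fix_bags[[3]])$bag_probability,
    forward_bag(m, fix_bags[[3]])$bag_probability)
})
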