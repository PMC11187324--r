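# Multiple-instance learning over slide-level bags. A bag holds all
# QC-passing tiles of one slide across magnifications and inherits the
# slide's weak binary label; training follows the standard protocol for this
# kind of screen: Adam on bag-level cross-entropy, a fixed number of
# instances resampled per bag each epoch, early stopping on validation loss
# with checkpointing of the best epoch.

#' Configuration of one MIL model variant
#'
#' @param backbone One of `"tiny-cnn"`, `"resnet50-like"`,
#'   `"efficientnet-like"`, `"googlenet-like"` — small-CNN presets of
#'   increasing/decreasing width sharing the same 3-block strided
#'   architecture.
#' @param attention Use gated attention pooling (`TRUE`) or plain mean
#'   pooling of instance probabilities (`FALSE`).
#' @param attention_head_size Hidden width of the attention scoring layer
#'   (conventional grid: 10/50 or 16/64).
#' @param batch_size Bags per optimization step (grid 4-16).
#' @param sample_size Instances drawn per bag per epoch (grid 20-80); bags
#'   smaller than this contribute all their instances.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs Epoch cap (default 20).
#' @param patience Early-stopping patience in epochs (default 5); must be
#'   below `max_epochs`.
#' @param input_size_px Square input edge length instances are resized to
#'   (default 224; tests and the synthetic demo use 64).
#' @param channel_means,channel_stds Per-channel standardization constants
#'   (ImageNet conventions by default).
#' @param seed Integer seed controlling initialization, shuffling and
#'   instance sampling.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(backbone = "tiny-cnn", attention = FALSE,
                         attention_head_size = 16, batch_size = 4,
                         sample_size = 20, learning_rate = 0.001,
                         max_epochs = 20, patience = 5,
                         input_size_px = 224,
                         channel_means = c(0.485, 0.456, 0.406),
                         channel_stds = c(0.229, 0.224, 0.225),
                         seed = 0) {
  if (!backbone %in% names(.backbones))
    stop("unknown backbone '", backbone, "'; must be one of: ",
         paste(names(.backbones), collapse = ", "), call. = FALSE)
  stopifnot(sample_size >= 1, batch_size >= 1, patience < max_epochs,
            length(channel_means) == 3, length(channel_stds) == 3,
            input_size_px >= 16, learning_rate > 0)
  structure(
    list(backbone = backbone, attention = isTRUE(attention),
         attention_head_size = as.integer(attention_head_size),
         batch_size = as.integer(batch_size),
         sample_size = as.integer(sample_size),
         learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         input_size_px = as.integer(input_size_px),
         channel_means = channel_means, channel_stds = channel_stds,
         seed = as.integer(seed)),
    class = "model_config"
  )
}

#' The six-variant ensemble configuration
#'
#' The conventional ensemble pairs three backbones with and without
#' attention, at the operating points reported to work best for each
#' (batch/sample/head sizes). `input_size_px` and `backbone` widths default
#' to the desk-scale settings used by the synthetic demo.
#'
#' @param seed Base seed; each model gets a distinct derived seed.
#' @param input_size_px Instance input size (default 64).
#' @param max_epochs,patience Passed through to every [model_config()].
#' @return Named list of six `"model_config"` objects.
#' @export
default_ensemble_configs <- function(seed = 0, input_size_px = 64,
                                     max_epochs = 20, patience = 5) {
  specs <- list(
    resnet_plain       = list(backbone = "resnet50-like", attention = FALSE,
                              batch_size = 8, sample_size = 20),
    efficientnet_plain = list(backbone = "efficientnet-like", attention = FALSE,
                              batch_size = 8, sample_size = 20),
    googlenet_plain    = list(backbone = "googlenet-like", attention = FALSE,
                              batch_size = 4, sample_size = 20),
    resnet_attn        = list(backbone = "resnet50-like", attention = TRUE,
                              attention_head_size = 64, batch_size = 4,
                              sample_size = 20),
    efficientnet_attn  = list(backbone = "efficientnet-like", attention = TRUE,
                              attention_head_size = 50, batch_size = 12,
                              sample_size = 20),
    googlenet_attn     = list(backbone = "googlenet-like", attention = TRUE,
                              attention_head_size = 16, batch_size = 4,
                              sample_size = 80)
  )
  out <- lapply(seq_along(specs), function(i) {
    do.call(model_config, c(specs[[i]],
                            list(input_size_px = input_size_px,
                                 max_epochs = max_epochs, patience = patience,
                                 seed = derive_seed(seed, 1000 + i))))
  })
  names(out) <- names(specs)
  out
}

#' Build MIL bags from QC'd tiles
#'
#' One bag per slide, holding all QC-passing tiles across magnifications in
#' deterministic order (magnification, then y, then x). Slides with zero
#' passing tiles are excluded with a warning and listed in the `"rejects"`
#' attribute.
#'
#' @param tiles List of tile records carrying `$qc` (see [qc_tiles()]).
#' @param labels Named character vector mapping `slide_id` to
#'   `"positive"`/`"negative"`.
#' @return List of `"mil_bag"` objects (`slide_id`, `label`, `instances`,
#'   `instance_count`), with attribute `rejects`.
#' @export
build_bags <- function(tiles, labels) {
  labels <- stats::setNames(as_class_label(labels), names(labels))
  ids <- vapply(tiles, function(t) t$slide_id, character(1))
  if (!all(unique(ids) %in% names(labels)))
    stop("missing labels for slides: ",
         paste(setdiff(unique(ids), names(labels)), collapse = ", "),
         call. = FALSE)
  bags <- list()
  rejects <- character(0)
  for (id in unique(ids)) {
    st <- tiles[ids == id]
    st <- Filter(function(t) isTRUE(t$qc$passed), st)
    if (length(st) == 0) {
      warning("slide ", id, " has no QC-passing tiles; excluded", call. = FALSE)
      rejects <- c(rejects, id)
      next
    }
    mag <- vapply(st, function(t) .magnifications[[t$magnification %||% "40x"]],
                  numeric(1))
    ys <- vapply(st, function(t) t$y, numeric(1))
    xs <- vapply(st, function(t) t$x, numeric(1))
    st <- st[order(mag, ys, xs)]
    bags[[id]] <- structure(
      list(slide_id = id, label = labels[[id]], instances = st,
           instance_count = length(st)),
      class = "mil_bag"
    )
  }
  structure(unname(bags), rejects = rejects)
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<bag> %s (%s): %d instances\n", x$slide_id, x$label,
              x$instance_count))
  invisible(x)
}

largest_remainder <- function(total, ratios) {
  raw <- total * ratios / sum(ratios)
  counts <- floor(raw)
  rem <- raw - counts
  left <- total - sum(counts)
  if (left > 0) {
    # ties broken toward the later position
    ord <- order(-rem, -seq_along(rem))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  as.integer(counts)
}

#' Split slides into train/validation/test partitions
#'
#' Seeded shuffle followed by largest-remainder allocation of the 6:2:2
#' (default) ratios; stratified by label when labels for both classes are
#' supplied, so no partition degenerates to a single class. The split is at
#' slide level: no slide's tiles can straddle partitions.
#'
#' @param slide_ids Character vector of slide identifiers (at least 3).
#' @param ratios Length-3 numeric `(train, val, test)` ratios.
#' @param seed Integer seed.
#' @param labels Optional vector of class labels aligned with `slide_ids`
#'   (or named by them).
#' @return An object of class `"split_assignment"`: list with `ratios`,
#'   `seed` and `assignment` (named vector over
#'   `"train"`/`"val"`/`"test"`).
#' @export
split_slides <- function(slide_ids, ratios = c(0.6, 0.2, 0.2), seed = 0,
                         labels = NULL) {
  stopifnot(length(slide_ids) >= 3, length(ratios) == 3, all(ratios >= 0))
  if (anyDuplicated(slide_ids)) stop("duplicate slide ids", call. = FALSE)
  parts <- c("train", "val", "test")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[slide_ids]
    labels <- as_class_label(labels)
    stopifnot(length(labels) == length(slide_ids))
  }
  strata <- if (is.null(labels) || length(unique(labels)) < 2)
    list(slide_ids)
  else
    split(slide_ids, labels)
  assignment <- character(0)
  with_seed(seed, {
    for (ids in strata) {
      ids <- sample(ids)
      counts <- largest_remainder(length(ids), ratios)
      assignment <- c(assignment,
                      stats::setNames(rep(parts, counts), ids))
    }
  })
  empty <- setdiff(parts, unique(assignment))
  if (length(empty))
    warning("partition(s) with zero slides: ", paste(empty, collapse = ", "),
            call. = FALSE)
  structure(list(ratios = ratios, seed = seed,
                 assignment = assignment[slide_ids]),
            class = "split_assignment")
}

#' Sample instances from a bag without replacement
#'
#' Uniform sampling without replacement; when `sample_size` reaches or
#' exceeds the bag size, all instances are returned unchanged (never
#' duplicated).
#'
#' @param bag A `"mil_bag"` object.
#' @param sample_size Number of instances to draw (at least 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside the training loop).
#' @return A list of instance tile records.
#' @export
sample_instances <- function(bag, sample_size, seed = NULL) {
  stopifnot(inherits(bag, "mil_bag"), sample_size >= 1)
  if (bag$instance_count == 0) stop("empty bag", call. = FALSE)
  if (sample_size >= bag$instance_count) return(bag$instances)
  idx <- if (is.null(seed)) sample(bag$instance_count, sample_size)
  else with_seed(seed, sample(bag$instance_count, sample_size))
  bag$instances[idx]
}

bag_label_int <- function(bag) if (bag$label == "positive") 1L else 0L

# Preprocessed instance matrices for a list of bags, computed once.
preprocess_bags <- function(bags, config) {
  lapply(bags, function(b) {
    preprocess_instances(lapply(b$instances, function(t) t$raster), config)
  })
}

#' Train one MIL model
#'
#' Seeded mini-batch training on bag-level cross-entropy with the Adam
#' optimizer: each epoch shuffles the training bags, draws `sample_size`
#' instances per bag, and averages bag gradients within mini-batches of
#' `batch_size` bags. Validation loss (all instances, no sampling) drives
#' early stopping: training halts once the running minimum has not improved
#' by more than 1e-6 for `patience` consecutive epochs, and the parameters
#' of the best epoch are returned.
#'
#' @param config A [model_config()].
#' @param train_bags,val_bags Lists of `"mil_bag"` objects; the training set
#'   must contain both classes.
#' @param verbose Print per-epoch progress.
#' @return An object of class `"trained_model"`: `config`, `params`,
#'   `geoms`, `history` (per-epoch train/val loss and val accuracy) and
#'   `best_epoch`.
#' @export
train_model <- function(config, train_bags, val_bags, verbose = FALSE) {
  stopifnot(inherits(config, "model_config"),
            length(train_bags) >= 2, length(val_bags) >= 1)
  y_train <- vapply(train_bags, bag_label_int, integer(1))
  if (length(unique(y_train)) < 2)
    stop("training bags must contain both classes", call. = FALSE)
  y_val <- vapply(val_bags, bag_label_int, integer(1))
  bb <- .backbones[[config$backbone]]
  geoms <- backbone_geoms(config$input_size_px, bb$filters)
  Xtr <- preprocess_bags(train_bags, config)
  Xva <- preprocess_bags(val_bags, config)

  with_seed(config$seed, {
    params <- c(init_backbone_params(bb$filters),
                init_head_params(bb$filters[length(bb$filters)],
                                 config$attention, config$attention_head_size))
    model <- list(config = config, params = params, geoms = geoms)
    state <- adam_init(params)
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0), val_acc = numeric(0))
    best_loss <- Inf
    best_params <- params
    best_epoch <- 0L
    wait <- 0L
    nb <- length(train_bags)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(nb)
      epoch_losses <- numeric(0)
      for (start in seq(1, nb, by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1, nb)]
        grads <- zero_grads(model$params)
        bl <- numeric(length(batch))
        for (k in seq_along(batch)) {
          b <- batch[k]
          n_inst <- nrow(Xtr[[b]])
          take <- if (config$sample_size >= n_inst) seq_len(n_inst)
          else sample(n_inst, config$sample_size)
          res <- mil_loss_grad(model, Xtr[[b]][take, , drop = FALSE],
                               y_train[b], grads)
          grads <- res$grads
          bl[k] <- res$loss
        }
        grads <- lapply(grads, function(g) g / length(batch))
        upd <- adam_step(model$params, grads, state, config$learning_rate)
        model$params <- upd$params
        state <- upd$state
        epoch_losses <- c(epoch_losses, bl)
      }
      # validation on full bags, inference mode
      val_probs <- vapply(Xva, function(X) mil_forward(model, X)$bag_prob[2],
                          numeric(1))
      val_loss <- mean(-log(pmax(ifelse(y_val == 1, val_probs, 1 - val_probs),
                                 1e-12)))
      val_acc <- mean((val_probs >= 0.5) == (y_val == 1))
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = mean(epoch_losses),
                                  val_loss = val_loss, val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %2d  train %.4f  val %.4f  acc %.2f",
                        epoch, mean(epoch_losses), val_loss, val_acc))
      if (val_loss < best_loss - 1e-6) {
        best_loss <- val_loss
        best_params <- model$params
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    structure(list(config = config, params = best_params, geoms = geoms,
                   history = history, best_epoch = best_epoch),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained model> %s%s: %d epochs, best epoch %d (val loss %.4f)\n",
              x$config$backbone,
              if (x$config$attention) "+attention" else "",
              nrow(x$history), x$best_epoch,
              x$history$val_loss[x$best_epoch]))
  invisible(x)
}

#' Score a bag with a trained model
#'
#' Inference-mode forward pass over the given instances (all of them, no
#' sampling). For plain models the bag probability is the mean of instance
#' class probabilities; for attention models it comes from the
#' attention-weighted embedding sum, and the (softmax-normalized) attention
#' weights are returned.
#'
#' @param model A `"trained_model"`.
#' @param instances A `"mil_bag"`, a list of tile records, or a list of
#'   rasters.
#' @return List with `bag_probability` (positive-class probability),
#'   `attention_weights` (or `NULL`) and `instance_probabilities` (plain
#'   models only).
#' @export
forward_bag <- function(model, instances) {
  stopifnot(inherits(model, "trained_model"))
  if (inherits(instances, "mil_bag")) instances <- instances$instances
  if (length(instances) == 0) stop("empty instance list", call. = FALSE)
  rasters <- lapply(instances, function(t) if (is.list(t)) t$raster else t)
  X <- preprocess_instances(rasters, model$config)
  fw <- mil_forward(model, X)
  list(bag_probability = fw$bag_prob[2],
       attention_weights = fw$attention_weights,
       instance_probabilities = fw$instance_probs)
}

#' Save / load a trained model checkpoint
#'
#' Checkpoints are RDS files embedding the parameters, the
#' [model_config()] and a format version.
#'
#' @param model A `"trained_model"`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `"trained_model"`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(list(format_version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format_version) || x$format_version != 1L)
    stop("unsupported checkpoint format in ", path, call. = FALSE)
  x$model
}
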