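# Minimal CNN engine for the MIL models, written against base-R matrix
# algebra (BLAS-backed im2col convolution). Instances are flattened rasters
# in [h, w, channel] column-major layout; each backbone is a stack of 3x3
# stride-2 valid convolutions with ReLU, followed by global average pooling
# into an embedding. Two pooling heads turn instance embeddings into a bag
# probability: "plain" (mean of per-instance class probabilities) and gated
# attention (softmax-weighted embedding sum).

# Small-CNN presets. The names mirror the capacity ordering of the family
# each configuration stands in for; all share the same 3-block structure and
# are pluggable via model_config(backbone = ).
.backbones <- list(
  "tiny-cnn"          = list(filters = c(8L, 16L, 32L)),
  "resnet50-like"     = list(filters = c(12L, 24L, 48L)),
  "efficientnet-like" = list(filters = c(8L, 16L, 24L)),
  "googlenet-like"    = list(filters = c(10L, 20L, 40L))
)

conv_out_dim <- function(n, k = 3L, stride = 2L) (n - k) %/% stride + 1L

# Geometry (including im2col gather indices) of one conv layer.
conv_geom <- function(in_h, in_w, in_c, out_c, k = 3L, stride = 2L) {
  out_h <- conv_out_dim(in_h, k, stride)
  out_w <- conv_out_dim(in_w, k, stride)
  if (out_h < 1 || out_w < 1) stop("input too small for conv stack", call. = FALSE)
  P <- out_h * out_w
  K <- k * k * in_c
  oy <- rep(seq_len(out_h), out_w)          # position index p: oh fastest
  ox <- rep(seq_len(out_w), each = out_h)
  base <- (oy - 1L) * stride + ((ox - 1L) * stride) * in_h  # 0-based within channel
  idx <- matrix(0L, P, K)
  col <- 0L
  for (c in seq_len(in_c)) {
    ch_off <- (c - 1L) * in_h * in_w
    for (kx in seq_len(k)) {
      for (ky in seq_len(k)) {
        col <- col + 1L
        idx[, col] <- base + ky + (kx - 1L) * in_h + ch_off
      }
    }
  }
  list(in_h = in_h, in_w = in_w, in_c = in_c, out_h = out_h, out_w = out_w,
       out_c = out_c, P = P, K = K, D_in = in_h * in_w * in_c,
       idx = idx, idxv = as.vector(idx))
}

backbone_geoms <- function(input_size_px, filters) {
  h <- input_size_px; w <- input_size_px; c <- 3L
  geoms <- vector("list", length(filters))
  for (l in seq_along(filters)) {
    geoms[[l]] <- conv_geom(h, w, c, filters[l])
    h <- geoms[[l]]$out_h; w <- geoms[[l]]$out_w; c <- filters[l]
  }
  geoms
}

# Batched conv forward: X is n x D_in; returns activations reshaped for the
# next layer plus the caches needed for backward.
conv_forward <- function(X, W, b, geom) {
  n <- nrow(X)
  cols <- X[, geom$idxv, drop = FALSE]
  dim(cols) <- c(n, geom$P, geom$K)
  cols <- matrix(aperm(cols, c(2, 1, 3)), n * geom$P, geom$K)  # row p within i
  Z <- cols %*% W
  Z <- Z + rep(b, each = nrow(Z))
  A <- Z
  A[A < 0] <- 0
  out <- aperm(array(A, c(geom$P, n, geom$out_c)), c(2, 1, 3))
  dim(out) <- c(n, geom$P * geom$out_c)
  list(cols = cols, Z = Z, out = out)
}

# dOut is n x (P*C_out); returns dW, db and (optionally) dX (n x D_in).
conv_backward <- function(dOut, fwd, W, geom, need_dx = TRUE) {
  n <- nrow(dOut)
  dA <- array(dOut, c(n, geom$P, geom$out_c))
  dA <- matrix(aperm(dA, c(2, 1, 3)), n * geom$P, geom$out_c)
  dZ <- dA * (fwd$Z > 0)
  dW <- crossprod(fwd$cols, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (need_dx) {
    dcols <- dZ %*% t(W)
    dcols <- aperm(array(dcols, c(geom$P, n, geom$K)), c(2, 1, 3))
    dX <- matrix(0, n, geom$D_in)
    for (k in seq_len(geom$K)) {
      j <- geom$idx[, k]
      dX[, j] <- dX[, j] + dcols[, , k]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

row_softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

softmax1 <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

init_backbone_params <- function(filters) {
  params <- list()
  in_c <- 3L
  for (l in seq_along(filters)) {
    K <- 9L * in_c
    params[[paste0("W", l)]] <- matrix(stats::rnorm(K * filters[l], sd = sqrt(2 / K)),
                                       K, filters[l])
    params[[paste0("b", l)]] <- rep(0, filters[l])
    in_c <- filters[l]
  }
  params
}

init_head_params <- function(embed, attention, head_size) {
  params <- list(
    Wc = matrix(stats::rnorm(embed * 2, sd = sqrt(1 / embed)), embed, 2),
    bc = rep(0, 2)
  )
  if (attention) {
    params$V <- matrix(stats::rnorm(embed * head_size, sd = sqrt(1 / embed)),
                       embed, head_size)
    params$U <- matrix(stats::rnorm(embed * head_size, sd = sqrt(1 / embed)),
                       embed, head_size)
    params$w <- stats::rnorm(head_size, sd = sqrt(1 / head_size))
  }
  params
}

# Backbone forward up to instance embeddings (n x embed).
backbone_forward <- function(params, geoms, X, keep_cache = FALSE) {
  n <- nrow(X)
  fwds <- vector("list", length(geoms))
  cur <- X
  for (l in seq_along(geoms)) {
    fwds[[l]] <- conv_forward(cur, params[[paste0("W", l)]],
                              params[[paste0("b", l)]], geoms[[l]])
    cur <- fwds[[l]]$out
  }
  gl <- geoms[[length(geoms)]]
  A3 <- matrix(aperm(array(cur, c(n, gl$P, gl$out_c)), c(2, 1, 3)),
               n * gl$P, gl$out_c)
  e <- rowsum(A3, rep(seq_len(n), each = gl$P)) / gl$P
  list(e = e, fwds = fwds, n = n)
}

# dE (n x embed) back through GAP and the conv stack; adds conv grads.
backbone_backward <- function(params, geoms, bf, dE, grads) {
  gl <- geoms[[length(geoms)]]
  n <- bf$n
  dA3 <- dE[rep(seq_len(n), each = gl$P), , drop = FALSE] / gl$P
  # back to the layer's n x (P*C) layout
  dOut <- aperm(array(dA3, c(gl$P, n, gl$out_c)), c(2, 1, 3))
  dim(dOut) <- c(n, gl$P * gl$out_c)
  for (l in rev(seq_along(geoms))) {
    bk <- conv_backward(dOut, bf$fwds[[l]], params[[paste0("W", l)]],
                        geoms[[l]], need_dx = l > 1)
    grads[[paste0("W", l)]] <- grads[[paste0("W", l)]] + bk$dW
    grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] + bk$db
    if (l > 1) dOut <- bk$dX
  }
  grads
}

# Bag-level forward. Returns bag probability vector (length 2), attention
# weights (or NULL) and per-instance positive-class probabilities (plain
# head only).
mil_forward <- function(model, X, keep_cache = FALSE) {
  p <- model$params
  bf <- backbone_forward(p, model$geoms, X, keep_cache = keep_cache)
  e <- bf$e
  n <- nrow(e)
  if (model$config$attention) {
    Tm <- tanh(e %*% p$V)
    G <- 1 / (1 + exp(-(e %*% p$U)))
    TG <- Tm * G
    sc <- drop(TG %*% p$w)
    al <- softmax1(sc)
    z <- drop(crossprod(al, e))
    logit <- drop(z %*% p$Wc) + p$bc
    bag <- softmax1(logit)
    cache <- if (keep_cache) list(bf = bf, Tm = Tm, G = G, TG = TG, al = al,
                                  z = z, bag = bag) else NULL
    list(bag_prob = bag, attention_weights = al, instance_probs = NULL,
         cache = cache)
  } else {
    logits <- e %*% p$Wc + rep(p$bc, each = n)
    Pm <- row_softmax(logits)
    bag <- colMeans(Pm)
    cache <- if (keep_cache) list(bf = bf, Pm = Pm, bag = bag) else NULL
    list(bag_prob = bag, attention_weights = NULL,
         instance_probs = Pm[, 2], cache = cache)
  }
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

# Cross-entropy loss of one bag and its parameter gradients (accumulated
# onto `grads`). y is 0 (negative) or 1 (positive).
mil_loss_grad <- function(model, X, y, grads) {
  p <- model$params
  fw <- mil_forward(model, X, keep_cache = TRUE)
  yi <- y + 1L
  bag <- fw$bag_prob
  loss <- -log(max(bag[yi], 1e-12))
  e <- fw$cache$bf$e
  n <- nrow(e)
  if (model$config$attention) {
    ch <- fw$cache
    dlogit <- ch$bag
    dlogit[yi] <- dlogit[yi] - 1
    grads$Wc <- grads$Wc + outer(ch$z, dlogit)
    grads$bc <- grads$bc + dlogit
    dz <- drop(p$Wc %*% dlogit)
    dal <- drop(e %*% dz)
    dE <- outer(ch$al, dz)
    ds <- ch$al * (dal - sum(dal * ch$al))
    dTG <- outer(ds, p$w)
    grads$w <- grads$w + drop(crossprod(ch$TG, ds))
    dTpre <- (dTG * ch$G) * (1 - ch$Tm^2)
    dGpre <- (dTG * ch$Tm) * ch$G * (1 - ch$G)
    grads$V <- grads$V + crossprod(e, dTpre)
    grads$U <- grads$U + crossprod(e, dGpre)
    dE <- dE + dTpre %*% t(p$V) + dGpre %*% t(p$U)
  } else {
    ch <- fw$cache
    dbag <- c(0, 0)
    dbag[yi] <- -1 / max(bag[yi], 1e-12)
    dP <- matrix(dbag, n, 2, byrow = TRUE) / n
    dlog <- ch$Pm * (dP - rowSums(dP * ch$Pm))
    grads$Wc <- grads$Wc + crossprod(e, dlog)
    grads$bc <- grads$bc + colSums(dlog)
    dE <- dlog %*% t(p$Wc)
  }
  grads <- backbone_backward(p, model$geoms, fw$cache$bf, dE, grads)
  list(loss = loss, grads = grads, bag_prob = bag)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Flatten instance rasters into the n x D model input matrix: resize to the
# configured input size, scale to [0,1] and standardize per channel.
preprocess_instances <- function(rasters, config) {
  size <- config$input_size_px
  n <- length(rasters)
  D <- size * size * 3L
  X <- matrix(0, n, D)
  for (i in seq_len(n)) {
    r <- rasters[[i]]
    assert_raster(r, "instance raster")
    r <- resize_raster(r, size)
    r <- r / 255
    for (c in 1:3) r[, , c] <- (r[, , c] - config$channel_means[c]) / config$channel_stds[c]
    X[i, ] <- as.vector(r)
  }
  X
}
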