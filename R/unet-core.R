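# U-net architecture: configuration, weight initialization, forward and
# backward passes over the Rcpp layer kernels.

#' U-net architecture configuration
#'
#' A compact encoder-decoder segmentation network: `nStages` contraction
#' stages of two 3x3 ReLU convolutions followed by 2x2 max pooling, a bridge
#' with dropout, and a mirrored expansion path of 2x2 transposed
#' convolutions with skip concatenation. Feature widths double per stage
#' from `baseFeatures`. Input tiles are padded so every pooled dimension is
#' even at every stage.
#'
#' @param nStages number of encoder/decoder stages (default 3)
#' @param baseFeatures feature maps of the first stage (doubling per stage)
#' @param nClasses output classes (3 for per-cell, 2 for monolayer/gap)
#' @param dropoutRate dropout rate at the bridge during training
#' @return a classed parameter list
#' @export
unetConfig <- function(nStages = 3, baseFeatures = 32, nClasses = 3,
                       dropoutRate = 0.5) {
  if (nStages < 1) stop("nStages must be >= 1")
  if (nClasses < 2) stop("nClasses must be >= 2")
  if (dropoutRate < 0 || dropoutRate >= 1) stop("dropoutRate must be in [0, 1)")
  structure(list(nStages = as.integer(nStages),
                 baseFeatures = as.integer(baseFeatures),
                 nClasses = as.integer(nClasses), dropoutRate = dropoutRate),
            class = "unetConfig")
}

#' Tversky loss configuration
#'
#' Asymmetric overlap loss balancing false positives (weight `alpha`) and
#' false negatives (weight `beta`); `alpha = beta = 0.5` reduces to the soft
#' Dice loss. The defaults weight false negatives more strongly.
#'
#' @param alpha false-positive weight (default 0.3)
#' @param beta false-negative weight (default 0.7)
#' @param smooth numerical smoothing constant
#' @param classes 1-based indices of the classes averaged in the loss;
#'   `NULL` (default) averages over all classes. Passing the cell-class
#'   index only trains on cell overlap alone.
#' @return a classed parameter list
#' @export
tverskyConfig <- function(alpha = 0.3, beta = 0.7, smooth = 1e-6,
                          classes = NULL) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (!is.null(classes) && any(classes < 1)) stop("classes must be >= 1")
  structure(list(alpha = alpha, beta = beta, smooth = smooth,
                 classes = classes),
            class = "tverskyConfig")
}

#' Training configuration
#'
#' Adam optimization with a per-epoch multiplicative learning-rate decay;
#' the data are shuffled before each epoch, and up to 100 augmented images
#' may be generated per original training image in each epoch.
#'
#' @param lr initial learning rate (default 0.001)
#' @param lrDecayPerEpoch multiplicative decay per epoch (default 0.9)
#' @param batchSize mini-batch size (default 30)
#' @param epochs number of epochs
#' @param augmentationsPerImage augmented copies per image per epoch (<= 100)
#' @param shuffleEachEpoch shuffle the data before each epoch
#' @param seed RNG seed for init, shuffling, dropout and augmentation
#' @return a classed parameter list
#' @export
trainConfig <- function(lr = 0.001, lrDecayPerEpoch = 0.9, batchSize = 30,
                        epochs = 5, augmentationsPerImage = 0,
                        shuffleEachEpoch = TRUE, seed = 1) {
  if (lr <= 0) stop("lr must be > 0")
  if (batchSize < 1) stop("batchSize must be >= 1")
  if (epochs < 0) stop("epochs must be >= 0")
  if (augmentationsPerImage < 0 || augmentationsPerImage > 100)
    stop("augmentationsPerImage must be in 0..100")
  structure(list(lr = lr, lrDecayPerEpoch = lrDecayPerEpoch,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 augmentationsPerImage = as.integer(augmentationsPerImage),
                 shuffleEachEpoch = shuffleEachEpoch, seed = seed),
            class = "trainConfig")
}

# Layer plan: named list of layer descriptors in forward order.
.unetPlan <- function(cfg) {
  S <- cfg$nStages
  feat <- cfg$baseFeatures * 2^(0:S)  # feat[s] for stage s, feat[S+1] bridge
  plan <- list()
  cin <- 1L
  for (s in 1:S) {
    plan[[paste0("enc", s, "a")]] <- list(type = "conv", k = 3L, cin = cin, cout = feat[s])
    plan[[paste0("enc", s, "b")]] <- list(type = "conv", k = 3L, cin = feat[s], cout = feat[s])
    cin <- feat[s]
  }
  plan[["bridgea"]] <- list(type = "conv", k = 3L, cin = feat[S], cout = feat[S + 1])
  plan[["bridgeb"]] <- list(type = "conv", k = 3L, cin = feat[S + 1], cout = feat[S + 1])
  cin <- feat[S + 1]
  for (s in S:1) {
    plan[[paste0("up", s)]] <- list(type = "upconv", cin = cin, cout = feat[s])
    plan[[paste0("dec", s, "a")]] <- list(type = "conv", k = 3L, cin = 2L * feat[s], cout = feat[s])
    plan[[paste0("dec", s, "b")]] <- list(type = "conv", k = 3L, cin = feat[s], cout = feat[s])
    cin <- feat[s]
  }
  plan[["final"]] <- list(type = "conv", k = 1L, cin = feat[1], cout = cfg$nClasses)
  plan
}

# He-initialized weights for the plan. Uses the current RNG stream.
.unetInit <- function(cfg) {
  plan <- .unetPlan(cfg)
  lapply(plan, function(p) {
    if (p$type == "conv") {
      fanin <- p$k * p$k * p$cin
      list(W = matrix(rnorm(fanin * p$cout, 0, sqrt(2 / fanin)), fanin, p$cout),
           b = rep(0, p$cout), k = p$k, type = "conv")
    } else {
      # the four sub-pixel blocks start identical (upsampling-equivalent
      # init), so the transposed convolution introduces no checkerboard
      # parity at initialization
      W1 <- matrix(rnorm(p$cin * p$cout, 0, sqrt(2 / p$cin)), p$cin, p$cout)
      list(W = W1[, rep(seq_len(p$cout), 4)],
           b = rep(0, p$cout), k = 2L, type = "upconv")
    }
  })
}

# Forward pass. x: H x W matrix (normalized), dims divisible by 2^nStages.
# Returns list(probs, logits, cache) — cache only when keepCache.
.unetForward <- function(x, wts, cfg, training = FALSE, keepCache = FALSE) {
  S <- cfg$nStages
  a <- array(x, dim = c(dim(x), 1L))
  cache <- if (keepCache) list() else NULL
  convRelu <- function(a, nm) {
    z <- .conv_fwd(a, wts[[nm]]$W, wts[[nm]]$b, wts[[nm]]$k)
    if (keepCache) { cache[[paste0(nm, ".x")]] <<- a; cache[[paste0(nm, ".z")]] <<- z }
    z * (z > 0)
  }
  skips <- vector("list", S)
  for (s in 1:S) {
    a <- convRelu(a, paste0("enc", s, "a"))
    a <- convRelu(a, paste0("enc", s, "b"))
    skips[[s]] <- a
    mp <- .maxpool_fwd(a)
    if (keepCache) {
      cache[[paste0("pool", s, ".idx")]] <- mp$idx
      cache[[paste0("pool", s, ".dim")]] <- dim(a)
    }
    a <- mp$y
  }
  a <- convRelu(a, "bridgea")
  a <- convRelu(a, "bridgeb")
  if (training && cfg$dropoutRate > 0) {
    keep <- array(runif(length(a)) >= cfg$dropoutRate, dim = dim(a))
    a <- a * keep / (1 - cfg$dropoutRate)
    if (keepCache) cache[["drop.mask"]] <- keep
  }
  for (s in S:1) {
    nm <- paste0("up", s)
    if (keepCache) cache[[paste0(nm, ".x")]] <- a
    a <- .upconv_fwd(a, wts[[nm]]$W, wts[[nm]]$b)
    skip <- skips[[s]]
    a <- array(c(a, skip), dim = c(dim(a)[1:2], dim(a)[3] + dim(skip)[3]))
    a <- convRelu(a, paste0("dec", s, "a"))
    a <- convRelu(a, paste0("dec", s, "b"))
  }
  if (keepCache) cache[["final.x"]] <- a
  logits <- .conv_fwd(a, wts[["final"]]$W, wts[["final"]]$b, 1L)
  probs <- .softmax3(logits)
  list(probs = probs, logits = logits, cache = cache)
}

.softmax3 <- function(logits) {
  C <- dim(logits)[3]
  mx <- logits[, , 1]
  for (c in seq_len(C)[-1]) mx <- pmax(mx, logits[, , c])
  e <- exp(logits - as.vector(mx))
  s <- e[, , 1]
  for (c in seq_len(C)[-1]) s <- s + e[, , c]
  e / as.vector(s)
}

#' Tversky loss
#'
#' Soft Tversky loss between per-pixel class probabilities and one-hot
#' targets: per class `TI_c = (TP_c + s) / (TP_c + alpha*FP_c + beta*FN_c + s)`
#' with soft (probability-weighted) confusion counts; the loss is the mean
#' of `1 - TI_c` over classes and lies in `[0, 1]`. With
#' `alpha = beta = 0.5` it equals the soft Dice loss.
#'
#' @param pred numeric array `(H, W, C)` (or matrix `(N, C)`) of class
#'   probabilities, each pixel row summing to 1
#' @param target one-hot array/matrix of the same shape
#' @param cfg a [tverskyConfig()]
#' @return scalar loss
#' @export
tverskyLoss <- function(pred, target, cfg = tverskyConfig()) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  d <- dim(pred)
  C <- d[length(d)]
  p <- matrix(pred, ncol = C)
  t <- matrix(target, ncol = C)
  cl <- if (is.null(cfg$classes)) seq_len(C) else intersect(cfg$classes, seq_len(C))
  li <- vapply(cl, function(c) {
    TP <- sum(p[, c] * t[, c])
    FP <- sum(p[, c] * (1 - t[, c]))
    FN <- sum((1 - p[, c]) * t[, c])
    1 - (TP + cfg$smooth) / (TP + cfg$alpha * FP + cfg$beta * FN + cfg$smooth)
  }, numeric(1))
  mean(li)
}

# Loss and gradient wrt probabilities; pred/target are (H, W, C) arrays.
.tverskyLossGrad <- function(pred, target, cfg) {
  d <- dim(pred)
  C <- d[3]
  p <- matrix(pred, ncol = C)
  t <- matrix(target, ncol = C)
  cl <- if (is.null(cfg$classes)) seq_len(C) else intersect(cfg$classes, seq_len(C))
  dp <- matrix(0, nrow(p), C)
  loss <- 0
  for (c in cl) {
    TP <- sum(p[, c] * t[, c])
    FP <- sum(p[, c] * (1 - t[, c]))
    FN <- sum((1 - p[, c]) * t[, c])
    D <- TP + cfg$alpha * FP + cfg$beta * FN
    TI <- (TP + cfg$smooth) / (D + cfg$smooth)
    loss <- loss + (1 - TI)
    # d TI / d p_c = [t*(D+s) - (TP+s)*(t + alpha*(1-t) - beta*t)] / (D+s)^2
    dd <- t[, c] + cfg$alpha * (1 - t[, c]) - cfg$beta * t[, c]
    dTI <- (t[, c] * (D + cfg$smooth) - (TP + cfg$smooth) * dd) /
      (D + cfg$smooth)^2
    dp[, c] <- -dTI / length(cl)
  }
  list(loss = loss / length(cl), dprobs = array(dp, dim = d))
}

# Softmax backward: dlogits from dprobs.
.softmaxBwd <- function(probs, dprobs) {
  C <- dim(probs)[3]
  s <- probs[, , 1] * dprobs[, , 1]
  for (c in seq_len(C)[-1]) s <- s + probs[, , c] * dprobs[, , c]
  probs * (dprobs - as.vector(s))
}

# Backward pass; returns named list of gradients (same shapes as weights).
.unetBackward <- function(dlogits, wts, cfg, cache) {
  S <- cfg$nStages
  grads <- list()
  convBwd <- function(nm, dy) {
    z <- cache[[paste0(nm, ".z")]]
    dz <- dy * (z > 0)
    r <- .conv_bwd(cache[[paste0(nm, ".x")]], wts[[nm]]$W, dz, wts[[nm]]$k)
    grads[[nm]] <<- list(dW = r$dW, db = as.vector(r$db))
    r$dx
  }
  # final 1x1 conv has no ReLU
  r <- .conv_bwd(cache[["final.x"]], wts[["final"]]$W, dlogits, 1L)
  grads[["final"]] <- list(dW = r$dW, db = as.vector(r$db))
  da <- r$dx
  # decoder, in reverse forward order: dec1 ... decS
  dskips <- vector("list", S)
  for (s in 1:S) {
    da <- convBwd(paste0("dec", s, "b"), da)
    da <- convBwd(paste0("dec", s, "a"), da)
    f <- dim(da)[3] / 2
    dup <- da[, , seq_len(f), drop = FALSE]
    dskips[[s]] <- da[, , f + seq_len(f), drop = FALSE]
    nm <- paste0("up", s)
    r <- .upconv_bwd(cache[[paste0(nm, ".x")]], wts[[nm]]$W, dup)
    grads[[nm]] <- list(dW = r$dW, db = as.vector(r$db))
    da <- r$dx
  }
  if (!is.null(cache[["drop.mask"]]))
    da <- da * cache[["drop.mask"]] / (1 - cfg$dropoutRate)
  da <- convBwd("bridgeb", da)
  da <- convBwd("bridgea", da)
  # encoder, from the deepest stage back to the input
  for (s in S:1) {
    pd <- cache[[paste0("pool", s, ".dim")]]
    da <- .maxpool_bwd(da, cache[[paste0("pool", s, ".idx")]], pd[1], pd[2])
    da <- da + dskips[[s]]
    da <- convBwd(paste0("enc", s, "b"), da)
    da <- convBwd(paste0("enc", s, "a"), da)
  }
  grads
}
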