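#' Exponential temperature annealing schedule
#'
#' Temperature of the concrete selection layer at a given epoch:
#' `T(e) = t_start * (t_end / t_start)^(e / total_epochs)`, the geometric
#' (log-linear) interpolation used by concrete autoencoders.  `T(0)` is
#' exactly `t_start` and `T(total_epochs)` exactly `t_end`; the schedule is
#' strictly decreasing in between.
#'
#' @param epoch integer in `[0, total_epochs]`.
#' @param total_epochs integer >= 1.
#' @param t_start,t_end start and end temperatures, `0 < t_end < t_start`.
#' @return numeric temperature.
#' @examples
#' annealTemperature(0, 300)            # 10
#' annealTemperature(150, 300)          # 1  (geometric mean of 10 and 0.1)
#' annealTemperature(300, 300)          # 0.1
#' @export
annealTemperature <- function(epoch, total_epochs, t_start = 10, t_end = 0.1) {
  if (!(t_end > 0 && t_end < t_start))
    stop("temperatures must satisfy 0 < t_end < t_start")
  if (any(epoch < 0) || any(epoch > total_epochs) || total_epochs < 1)
    stop("epoch must lie in [0, total_epochs]")
  t_start * (t_end / t_start)^(epoch / total_epochs)
}

#' Concrete (Gumbel-softmax) selection weights
#'
#' Relaxed one-hot selection weights of a concrete selector node:
#' `softmax((logits + noise) / temperature)`, where `noise` holds standard
#' Gumbel draws.  At high temperature the weights approach the uniform
#' distribution; as the temperature goes to zero they approach the one-hot
#' vector of `argmax(logits + noise)`, while remaining differentiable in the
#' logits for fixed noise.
#'
#' @param logits numeric vector (one node) or k-by-n matrix (one row per
#'   node) of selection logits; must be finite.
#' @param temperature positive relaxation temperature.
#' @param noise standard Gumbel draws, same shape as `logits`; defaults to
#'   fresh draws from the current RNG.
#' @return Non-negative weights of the same shape as `logits`; each node's
#'   weights sum to 1.
#' @examples
#' concreteWeights(c(2, 1, 0), temperature = 1e-6, noise = c(0, 0, 0))
#' concreteWeights(log(c(.5, .3, .2)), temperature = 1, noise = c(0, 0, 0))
#' @export
concreteWeights <- function(logits, temperature, noise = NULL) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (any(!is.finite(logits))) stop("logits must be finite")
  vec <- is.null(dim(logits))
  L <- if (vec) matrix(logits, nrow = 1L) else logits
  if (is.null(noise)) noise <- rgumbel(length(L))
  W <- rowSoftmax((L + noise) / temperature)
  if (vec) drop(W) else W
}

#' Mean-max selection probability
#'
#' Convergence diagnostic of the selection layer: the softmax of each node's
#' logits is its selection probability over features; `meanMaxProb` averages,
#' over the k nodes, the largest probability of each node.  It starts near
#' `1/n` (uniform) and approaches 1 as every node commits to a single
#' feature.
#'
#' @param x a k-by-n logits matrix (rows = selector nodes) or a
#'   [CAERun-class] (its trained logits are used).
#' @return numeric in `(0, 1]`.
#' @export
meanMaxProb <- function(x) {
  if (is(x, "CAERun")) {
    if (!length(x@selectorLogits)) stop("run carries no selector logits")
    x <- x@selectorLogits
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  mean(apply(rowSoftmax(x), 1L, max))
}

# Row-wise softmax with max-shift for numerical stability.
rowSoftmax <- function(M) {
  E <- exp(M - apply(M, 1L, max))
  E / rowSums(E)
}

# Standard Gumbel draws from the current RNG stream.
rgumbel <- function(n) {
  u <- runif(n)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  -log(-log(u))
}

leakyRelu <- function(Z, slope) {
  neg <- Z < 0
  Z[neg] <- slope * Z[neg]
  Z
}

# Glorot-uniform decoder init + near-uniform selector logits.
caeInitParams <- function(n, k, hidden) {
  sizes <- c(k, hidden, n)
  params <- list(A = matrix(rnorm(k * n, sd = 0.01), k, n))
  for (l in seq_len(length(sizes) - 1L)) {
    fin <- sizes[l]; fout <- sizes[l + 1L]
    lim <- sqrt(6 / (fin + fout))
    params[[paste0("W", l)]] <- matrix(runif(fin * fout, -lim, lim), fin, fout)
    params[[paste0("b", l)]] <- numeric(fout)
  }
  params
}

addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Decoder forward pass from already-selected inputs S (batch x k).
# masks: list of dropout masks per hidden layer, or NULL for eval mode.
decoderForward <- function(params, S, slope, dropout, masks = NULL) {
  L <- sum(grepl("^W", names(params)))
  inputs <- vector("list", L)
  Zs <- vector("list", L)
  H <- S
  for (l in seq_len(L)) {
    inputs[[l]] <- H
    Z <- addBias(H %*% params[[paste0("W", l)]], params[[paste0("b", l)]])
    Zs[[l]] <- Z
    if (l < L) {
      H <- leakyRelu(Z, slope)
      if (!is.null(masks)) H <- H * masks[[l]] / (1 - dropout)
    } else H <- Z
  }
  list(Y = H, inputs = inputs, Zs = Zs, L = L)
}

# Loss and analytic gradients of one concrete-autoencoder step with the
# stochastic elements held fixed, so the whole map is deterministic and
# finite-difference checkable.  G carries per-sample Gumbel noise as a
# (k, n, batch) array: each sample draws its own relaxed one-hot weights.
# This is the plain-R reference for the compiled training kernel.
caeLossGrad <- function(params, X, G, temperature, masks, slope, dropout) {
  bsz <- nrow(X); n <- ncol(X); k <- nrow(params$A)
  stopifnot(identical(dim(G), c(k, n, bsz)))
  Wsl <- vector("list", bsz)
  S <- matrix(0, bsz, k)
  for (s in seq_len(bsz)) {
    Wsl[[s]] <- rowSoftmax((params$A + G[, , s]) / temperature)
    S[s, ] <- Wsl[[s]] %*% X[s, ]
  }
  fwd <- decoderForward(params, S, slope, dropout, masks)
  R <- fwd$Y - X
  loss <- mean(R * R)
  grads <- vector("list", length(params)); names(grads) <- names(params)

  dZ <- 2 * R / length(R)
  for (l in fwd$L:1) {
    grads[[paste0("W", l)]] <- crossprod(fwd$inputs[[l]], dZ)
    grads[[paste0("b", l)]] <- colSums(dZ)
    dPrev <- tcrossprod(dZ, params[[paste0("W", l)]])
    if (l > 1L) {
      if (!is.null(masks)) dPrev <- dPrev * masks[[l - 1L]] / (1 - dropout)
      Zp <- fwd$Zs[[l - 1L]]
      dZ <- dPrev * ifelse(Zp > 0, 1, slope)
    } else dS <- dPrev
  }
  dA <- matrix(0, k, n)
  for (s in seq_len(bsz)) {
    dWs <- outer(dS[s, ], X[s, ])
    dA <- dA + Wsl[[s]] * (dWs - rowSums(dWs * Wsl[[s]])) / temperature
  }
  grads$A <- dA
  list(loss = loss, grads = grads)
}

caeEvalLoss <- function(params, X, Wsel, slope) {
  S <- X %*% t(Wsel)
  Y <- decoderForward(params, S, slope, 0, NULL)$Y
  mean((Y - X)^2)
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a single concrete autoencoder
#'
#' Trains the concrete selection layer (k relaxed-categorical nodes over the
#' n input features) jointly with an MLP decoder that reconstructs all n
#' features from the k selected ones, by minimizing mean squared
#' reconstruction error with Adam.  The temperature is annealed once per
#' epoch along the exponential schedule of [annealTemperature()]; during
#' training selection is stochastic (fresh Gumbel noise per minibatch),
#' while the final feature extraction and the reported held-out MSE use hard
#' argmax selection.  Samples are split 80/20 (stratified by `labels` when
#' given) before training; the 20% split provides the validation loss of the
#' characteristic trace and the final `valMSE`.
#'
#' Every stochastic element -- split, parameter init, minibatch order, Gumbel
#' noise, dropout masks -- is drawn from R's RNG seeded with `cfg@seed`, so a
#' run is exactly reproducible.
#'
#' @param x a normalized [ExprMatrix-class] (see [minMaxNormalize()]).
#' @param cfg a [CAEConfig-class]; `cfg@k` must be smaller than the number of
#'   features.
#' @param labels optional named factor for stratifying the 80/20 split.
#' @return A [CAERun-class] with the selected features, per-epoch
#'   characteristic trace, trained parameters and held-out MSE.
#' @seealso [runMrCAE()] for multi-run aggregation, [reconstructionMSE()].
#' @export
trainCAE <- function(x, cfg, labels = NULL) {
  stopifnot(is(x, "ExprMatrix"), is(cfg, "CAEConfig"))
  if (!isNormalized(x))
    stop("trainCAE needs min-max normalized input; run minMaxNormalize() first")
  v <- exprValues(x)
  n <- ncol(v)
  if (cfg@k >= n) stop("k (", cfg@k, ") must be < number of features (", n, ")")
  if (nrow(v) < 2L) stop("need at least 2 samples")
  set.seed(cfg@seed)
  sp <- stratifiedSplit(x, labels, test_fraction = 0.2, seed = NULL)
  Xtr <- v[sp$train, , drop = FALSE]
  Xva <- v[sp$test, , drop = FALSE]

  k <- cfg@k
  L <- length(cfg@hiddenSizes) + 1L
  params <- caeInitParams(n, k, cfg@hiddenSizes)
  res <- .cpp_train_cae(
    Xtr, Xva, params$A,
    params[paste0("W", seq_len(L))], params[paste0("b", seq_len(L))],
    cfg@leakyReluSlope, cfg@dropoutRate, cfg@epochs, cfg@learningRate,
    cfg@tStart, cfg@tEnd, cfg@batchSize)
  decoder <- c(stats::setNames(res$W, paste0("W", seq_len(L))),
               stats::setNames(res$b, paste0("b", seq_len(L))))
  picks <- featureIDs(x)[res$picks]
  new("CAERun",
      selectedUnique = unique(picks), nodePicks = picks,
      trace = as.data.frame(res$trace), valMSE = res$val_mse,
      config = cfg, seed = cfg@seed, selectorLogits = res$A,
      decoder = decoder, featureIDs = featureIDs(x))
}

#' Reconstruction error of a trained run on a data matrix
#'
#' Feeds the run's hard-selected features (per-node argmax) through its
#' trained decoder and returns the mean squared error against all features
#' of `x` -- typically a held-out matrix.  The feature space of `x` must be
#' identical (same IDs, same order) to the one the run was trained on.
#'
#' @param run a [CAERun-class] holding trained decoder weights.
#' @param x an [ExprMatrix-class] on the run's feature space.
#' @return numeric MSE (mean over samples and features).
#' @export
reconstructionMSE <- function(run, x) {
  stopifnot(is(run, "CAERun"), is(x, "ExprMatrix"))
  if (!length(run@decoder))
    stop("run carries no decoder weights (re-read from JSON?)")
  if (!identical(run@featureIDs, featureIDs(x)))
    stop("feature space of 'x' differs from the run's training features")
  v <- exprValues(x)
  idx <- match(run@nodePicks, featureIDs(x))
  if (anyNA(idx)) stop("selected feature missing from 'x'")
  S <- v[, idx, drop = FALSE]
  params <- run@decoder
  Y <- decoderForward(params, S, run@config@leakyReluSlope, 0, NULL)$Y
  mean((Y - v)^2)
}
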