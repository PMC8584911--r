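test_that("annealing schedule hits its endpoints exactly and decreases monotonically", {
  expect_identical(annealTemperature(0, 300), 10)
  expect_identical(annealTemperature(300, 300), 0.1)
  expect_equal(annealTemperature(150, 300), 1.0)    # geometric mean
  temps <- annealTemperature(0:100, 100, 7, 0.05)
  expect_true(all(diff(temps) < 0))
  expect_error(annealTemperature(5, 10, t_start = 0.1, t_end = 10), "t_end")
  expect_error(annealTemperature(-1, 10), "epoch")
})

test_that("concrete weights obey the limits of the relaxation", {
  z <- c(2, 1, 0)
  # high-temperature limit: uniform
  w_hot <- concreteWeights(z, temperature = 1e6, noise = rep(0, 3))
  expect_true(all(abs(w_hot - 1 / 3) < 1e-4))
  # low-temperature limit: argmax one-hot
  w_cold <- concreteWeights(z, temperature = 1e-6, noise = rep(0, 3))
  expect_true(all(abs(w_cold - c(1, 0, 0)) < 1e-6))
  # softmax of log-probabilities at T = 1 is the identity
  p <- c(0.5, 0.3, 0.2)
  expect_equal(concreteWeights(log(p), 1, noise = rep(0, 3)), p,
               tolerance = 1e-12)
  expect_error(concreteWeights(z, temperature = 0), "temperature")
  expect_error(concreteWeights(c(1, Inf), 1), "finite")
})

test_that("concrete weights sum to one for any temperature and noise draw", {
  set.seed(5)
  for (i in 1:50) {
    k <- sample(1:6, 1); n <- sample(2:40, 1)
    L <- matrix(rnorm(k * n, sd = 3), k, n)
    temp <- 10^runif(1, -3, 3)
    W <- concreteWeights(L, temp)
    expect_true(all(W >= 0))
    expect_true(all(abs(rowSums(W) - 1) < 1e-9))
  }
})

test_that("mean-max probability averages per-node maxima", {
  one_hot <- matrix(c(100, 0, 0, 0, 100, 0), 2, 3, byrow = TRUE)
  expect_equal(meanMaxProb(one_hot), 1.0, tolerance = 1e-12)
  expect_equal(meanMaxProb(matrix(0, 3, 8)), 1 / 8)
  two <- rbind(log(c(0.5, 0.5, 1e-12)), log(c(0.7, 0.2, 0.1)))
  expect_equal(meanMaxProb(two), 0.6, tolerance = 1e-9)
})

test_that("analytic gradients of the reference implementation match finite differences", {
  set.seed(42)
  n <- 7L; k <- 3L; b <- 5L; hid <- c(4L, 4L)
  X <- matrix(runif(b * n), b, n)
  params <- mrcae:::caeInitParams(n, k, hid)
  G <- array(mrcae:::rgumbel(k * n * b), dim = c(k, n, b))
  masks <- lapply(hid, function(h) matrix(runif(b * h) >= 0.1, b, h))
  fg <- mrcae:::caeLossGrad(params, X, G, 1.3, masks, 0.1, 0.1)
  num_grad <- function(nm, i) {
    eps <- 1e-6
    p1 <- params; p2 <- params
    p1[[nm]][i] <- p1[[nm]][i] + eps
    p2[[nm]][i] <- p2[[nm]][i] - eps
    (mrcae:::caeLossGrad(p1, X, G, 1.3, masks, 0.1, 0.1)$loss -
       mrcae:::caeLossGrad(p2, X, G, 1.3, masks, 0.1, 0.1)$loss) / (2 * eps)
  }
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(6, length(params[[nm]])))
    for (i in idx)
      expect_equal(fg$grads[[nm]][i], num_grad(nm, i), tolerance = 1e-5)
  }
})

test_that("compiled training step agrees with the plain-R reference", {
  n <- 9L; k <- 3L; ntr <- 12L; nva <- 4L; hid <- c(5L, 5L)
  slope <- 0.1; pdrop <- 0.1; lr <- 0.01; temp_cfg <- c(10, 0.1)
  set.seed(31)
  Xtr <- matrix(runif(ntr * n), ntr, n)
  Xva <- matrix(runif(nva * n), nva, n)

  # R reference for one epoch of one full batch, replicating the kernel's
  # documented draw order (shuffle keys, per-sample Gumbel, dropout masks)
  set.seed(77)
  params <- mrcae:::caeInitParams(n, k, hid)
  temp <- temp_cfg[1] * (temp_cfg[2] / temp_cfg[1])^1   # epoch 1 of 1
  keys <- runif(ntr)
  ord <- order(keys)
  Xb <- Xtr[ord, , drop = FALSE]
  G <- array(NA_real_, c(k, n, ntr))
  for (s in seq_len(ntr)) G[, , s] <- matrix(mrcae:::rgumbel(k * n), k, n)
  masks <- lapply(hid, function(h) matrix(runif(ntr * h) >= pdrop, ntr, h))
  fg <- mrcae:::caeLossGrad(params, Xb, G, temp, masks, slope, pdrop)
  st <- mrcae:::adamStep(params, fg$grads, mrcae:::adamInit(params), lr)

  set.seed(77)
  params2 <- mrcae:::caeInitParams(n, k, hid)
  res <- mrcae:::.cpp_train_cae(Xtr, Xva, params2$A,
                                params2[c("W1", "W2", "W3")],
                                params2[c("b1", "b2", "b3")],
                                slope, pdrop, 1L, lr, temp_cfg[1],
                                temp_cfg[2], ntr)
  # float32 kernel vs double reference: losses agree tightly; every
  # parameter moved the same way (Adam's first step is +-lr per entry)
  expect_equal(res$trace$train_loss, fg$loss, tolerance = 1e-4)
  dA_ref <- st$params$A - params$A
  dA_cpp <- res$A - params$A
  expect_gt(mean(sign(dA_ref) == sign(dA_cpp)), 0.99)
  expect_lt(max(abs(res$W[[2]] - st$params$W2)), 2.5 * lr)
  expect_equal(as.numeric(res$b[[3]]), as.numeric(st$params$b3),
               tolerance = 1e-3)
})

test_that("training is reproducible, descends, and respects its contracts", {
  sim <- small_sim()
  run <- small_run()
  tr <- caeTrace(run)
  expect_equal(nrow(tr), 40)
  expect_true(all(diff(tr$temperature) < 0))
  expect_equal(tr$temperature[40], 0.1)
  expect_lt(tr$train_loss[40], tr$train_loss[1])
  expect_setequal(selectedFeatures(run), unique(nodePicks(run)))
  expect_lte(length(selectedFeatures(run)), 5)
  expect_gte(valMSE(run), 0)

  run2 <- trainCAE(sim$expr, small_cfg(), labels = sim$labels)
  expect_identical(selectedFeatures(run2), selectedFeatures(run))
  expect_identical(caeTrace(run2), tr)
  expect_identical(run2@selectorLogits, run@selectorLogits)

  raw <- ExprMatrix(exprValues(sim$expr) * 2 + 1)
  expect_error(trainCAE(raw, small_cfg()), "normalized")
  expect_error(trainCAE(sim$expr, small_cfg(k = 40L)), "k")
})

test_that("a feature duplicated into exact copies is selected from and reconstructed", {
  set.seed(8)
  base <- matrix(runif(60 * 3), 60, 3)
  v <- cbind(base, base, base)[, 1:8]           # copies of 3 source columns
  dimnames(v) <- list(sprintf("s%02d", 1:60), sprintf("f%d", 1:8))
  em <- minMaxNormalize(ExprMatrix(v))
  cfg <- caeConfig(k = 3, hiddenSizes = c(16L, 16L), epochs = 60L, seed = 2)
  run <- trainCAE(em, cfg)
  tr <- caeTrace(run)
  expect_lt(tr$train_loss[nrow(tr)], tr$train_loss[1])
  expect_lte(length(selectedFeatures(run)), 3)
})

test_that("reconstructionMSE evaluates the trained decoder on a held-out matrix", {
  sim <- small_sim()
  run <- small_run()
  mse <- reconstructionMSE(run, sim$expr)
  expect_gte(mse, 0)
  expect_lt(mse, mean(exprValues(sim$expr)^2))  # better than predicting zero

  # forcing the decoder to output zero gives the closed-form mean square
  zero_run <- run
  zero_run@decoder <- lapply(run@decoder, function(p) p * 0)
  expect_equal(reconstructionMSE(zero_run, sim$expr),
               mean(exprValues(sim$expr)^2), tolerance = 1e-10)

  other <- rand_expr(10, 12, seed = 99)
  expect_error(reconstructionMSE(run, other), "feature space")
})
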