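# Shared fixtures, built once per test run.  Training-based unit tests use a
# deliberately small cohort and decoder so each file stays fast; the
# full-scale study conditions live in test-acceptance.R.

.fixtures <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixtures$sim))
    .fixtures$sim <- generateExpression(
      syntheticSpec(n_samples = 150L, n_features = 40L, n_drivers = 5L,
                    seed = 42L))
  .fixtures$sim
}

small_cfg <- function(...) {
  caeConfig(k = 5L, hiddenSizes = c(32L, 32L), epochs = 40L, seed = 7L, ...)
}

small_run <- function() {
  if (is.null(.fixtures$run)) {
    sim <- small_sim()
    .fixtures$run <- trainCAE(sim$expr, small_cfg(), labels = sim$labels)
  }
  .fixtures$run
}

# A random ExprMatrix with reproducible contents.
rand_expr <- function(n = 20, p = 6, seed = 1, normalized = FALSE) {
  set.seed(seed)
  v <- matrix(runif(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  ExprMatrix(v, normalized = normalized)
}

# Oracle selector, independent of the autoencoder path: greedy forward
# selection of the k columns that minimize linear reconstruction error of
# the whole matrix (orthogonalized residual updates).  Used as the planted
# -driver recoverability reference.
greedy_linear_select <- function(v, k) {
  R <- scale(v, center = TRUE, scale = FALSE)   # targets, residualized
  C <- R                                        # candidates, residualized
  sel <- integer(0)
  for (j in seq_len(k)) {
    nrm <- colSums(C^2)
    score <- rowSums((crossprod(C, R))^2) / pmax(nrm, 1e-12)
    score[nrm < 1e-10] <- -Inf
    score[sel] <- -Inf
    best <- which.max(score)
    sel <- c(sel, best)
    u <- C[, best] / sqrt(nrm[best])
    R <- R - u %*% crossprod(u, R)
    C <- C - u %*% crossprod(u, C)
  }
  colnames(v)[sel]
}

# Random censored survival records for oracle comparisons.
rand_surv <- function(n, seed) {
  set.seed(seed)
  list(time = round(rexp(n, 0.1) + 0.01, 3),
       event = rbinom(n, 1, 0.7))
}
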