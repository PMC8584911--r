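#' Specification of a synthetic expression study
#'
#' Parameter bag for [generateExpression()] / [generateSurvival()].  The
#' generator emulates a multi-class expression cohort in which a small set
#' of "driver" features determines both class identity and, through noisy
#' sparse positive mixing (a regulatory fan-out of 1--3 drivers per target),
#' the values of many dependent features -- the hub structure under which a
#' reconstruction-driven selector should concentrate on the drivers.
#' Defaults describe the desk-scale study used throughout the package
#' tests: 500 samples, 200 features of which 10 are drivers, 4 balanced
#' classes with class-mean separation 1.5 (in units of the within-class SD
#' of a driver), 60% of the non-driver features dependent on the drivers
#' with residual noise SD 2 (driver-target correlations around 0.6--0.7, the
#' realistic regime -- near-noiseless targets would be interchangeable with
#' their drivers and no selector could, or should, prefer one), and a
#' survival process whose hazard doubles (`log(2)`) above the median of
#' driver 1, with ~20% censoring.
#'
#' @param n_samples,n_features,n_drivers,n_classes cohort dimensions;
#'   `n_drivers < n_features`, `n_classes >= 2`, classes balanced within 1.
#' @param class_sep separation of class-specific driver means (SD units).
#' @param dependent_fraction fraction of non-driver features that are noisy
#'   positive mixes of the drivers (the rest are pure noise).
#' @param noise_sd SD of the additive Gaussian noise on dependent features.
#' @param survival_driver index (1..n_drivers) of the driver carrying the
#'   planted survival effect.
#' @param hazard_log_ratio log hazard ratio of high- vs low-expression
#'   (above vs at-or-below the driver's median); 0 plants a null effect.
#' @param censor_rate target fraction of censored subjects, in \[0, 1).
#' @param baseline_hazard exponential event rate of the low-expression
#'   group (time units are opaque; 0.01 puts the baseline median near 69).
#' @param seed integer; every generated object is a deterministic function
#'   of these parameters including this seed.
#' @return validated list of class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(n_samples = 500L, n_features = 200L,
                          n_drivers = 10L, n_classes = 4L, class_sep = 1.5,
                          dependent_fraction = 0.6, noise_sd = 2,
                          survival_driver = 1L, hazard_log_ratio = log(2),
                          censor_rate = 0.2, baseline_hazard = 0.01,
                          seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_features = as.integer(n_features),
               n_drivers = as.integer(n_drivers),
               n_classes = as.integer(n_classes),
               class_sep = as.numeric(class_sep),
               dependent_fraction = as.numeric(dependent_fraction),
               noise_sd = as.numeric(noise_sd),
               survival_driver = as.integer(survival_driver),
               hazard_log_ratio = as.numeric(hazard_log_ratio),
               censor_rate = as.numeric(censor_rate),
               baseline_hazard = as.numeric(baseline_hazard),
               seed = as.integer(seed))
  if (spec$n_drivers >= spec$n_features)
    stop("n_drivers must be < n_features")
  if (spec$n_drivers < 1L || spec$n_samples < spec$n_classes)
    stop("invalid cohort dimensions")
  if (spec$n_classes < 2L) stop("need at least 2 classes")
  if (spec$dependent_fraction < 0 || spec$dependent_fraction > 1)
    stop("dependent_fraction must be in [0, 1]")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$survival_driver < 1L || spec$survival_driver > spec$n_drivers)
    stop("survival_driver must index a driver")
  if (spec$censor_rate < 0 || spec$censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  if (spec$class_sep < 0 || spec$baseline_hazard <= 0)
    stop("class_sep must be >= 0 and baseline_hazard > 0")
  class(spec) <- "syntheticSpec"
  spec
}

#' Generate a synthetic expression cohort with planted drivers
#'
#' Draws balanced class labels, gives each driver feature a class-specific
#' Gaussian mean (means `class_sep * N(0, 1)` per class, within-class SD 1),
#' builds each dependent feature as a positive normalized mix of a
#' round-robin-assigned primary driver and 0--2 random secondary drivers
#' plus `N(0, noise_sd)` noise (balanced sparse fan-out: every driver is a
#' hub influencing a comparable share of targets), fills the
#' remaining features with pure `N(0, 1)` noise, shuffles the feature
#' order, and min-max normalizes.  The planted driver IDs are returned as
#' ground truth.  Deterministic for a fixed `spec$seed`.
#'
#' @param spec a [syntheticSpec()].
#' @return list: `expr` (normalized [ExprMatrix-class]), `labels` (named
#'   factor), `drivers` (character IDs of the planted drivers, in driver
#'   order so `drivers[spec$survival_driver]` is the survival driver).
#' @export
generateExpression <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  set.seed(spec$seed)
  N <- spec$n_samples; P <- spec$n_features; D <- spec$n_drivers
  lab <- factor(rep_len(paste0("class", seq_len(spec$n_classes)), N))
  lab <- lab[sample.int(N)]
  # every driver separates the classes with the same effect size: its
  # class-mean vector is standardized to spread exactly class_sep, so no
  # driver degenerates into a near-uninformative feature by draw luck
  mu <- matrix(rnorm(spec$n_classes * D), spec$n_classes, D)
  mu <- scale(mu) * spec$class_sep
  mu[is.nan(mu)] <- 0                            # degenerate: 1 class
  drv <- mu[as.integer(lab), , drop = FALSE] + matrix(rnorm(N * D), N, D)
  n_dep <- round(spec$dependent_fraction * (P - D))
  n_noise <- P - D - n_dep
  dep <- NULL
  if (n_dep > 0) {
    # balanced fan-out: every driver is the primary regulator of an equal
    # share of targets (so no driver degenerates into a near-orphan), with
    # 0-2 secondary regulators drawn at random
    primary <- rep_len(seq_len(D), n_dep)
    dep <- vapply(seq_len(n_dep), function(j) {
      extra <- sample.int(min(3L, D), 1L) - 1L
      ix <- c(primary[j],
              if (extra > 0) sample(setdiff(seq_len(D), primary[j]), extra))
      w <- abs(rnorm(length(ix)))
      w <- w / sum(w)                           # positive, normalized fan-in
      drop(drv[, ix, drop = FALSE] %*% w) + rnorm(N, sd = spec$noise_sd)
    }, numeric(N))
  }
  noise <- if (n_noise > 0) matrix(rnorm(N * n_noise), N, n_noise)
  vals <- cbind(drv, dep, noise)
  ids <- sprintf("F%04d", seq_len(P))
  perm <- sample.int(P)                          # hide driver positions
  vals <- vals[, order(perm), drop = FALSE]
  colnames(vals) <- ids
  rownames(vals) <- sprintf("S%04d", seq_len(N))
  names(lab) <- rownames(vals)
  drivers <- ids[perm[seq_len(D)]]
  em <- minMaxNormalize(ExprMatrix(vals))
  list(expr = em, labels = lab, drivers = drivers)
}

#' Generate survival outcomes with a planted hazard effect
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(hazard_log_ratio * [value > median])`, where the
#' value is the survival driver's expression per sample.  Censoring times
#' are independent `Uniform(0, u)` with `u` solved (from the exponential
#' mixture's closed form) so the expected censored fraction equals
#' `censor_rate`; `censor_rate = 0` disables censoring.  Deterministic for
#' a fixed `spec$seed` (a stream offset from the expression draw, so the
#' two generators do not reuse the same deviates).
#'
#' @param spec a [syntheticSpec()].
#' @param driver_values named numeric vector (names = sample IDs) of the
#'   survival driver's expression, e.g.
#'   `exprValues(sim$expr)[, sim$drivers[spec$survival_driver]]`.
#' @return data.frame `sample_id`, `time`, `event` satisfying the clinical
#'   table invariants (time > 0, event in {0, 1}).
#' @export
generateSurvival <- function(spec, driver_values) {
  stopifnot(inherits(spec, "syntheticSpec"))
  if (is.null(names(driver_values)))
    stop("driver_values must be named by sample ID")
  set.seed(spec$seed + 777L)
  high <- driver_values > median(driver_values)
  rate <- spec$baseline_hazard * exp(spec$hazard_log_ratio * high)
  time <- rexp(length(rate), rate)
  time <- pmax(time, .Machine$double.eps)
  event <- rep(1L, length(time))
  if (spec$censor_rate > 0) {
    # P(censored | rate r, C ~ U(0,u)) = (1 - exp(-r u)) / (r u)
    p_high <- mean(high)
    cens_frac <- function(u)
      (1 - p_high) * (1 - exp(-spec$baseline_hazard * u)) /
        (spec$baseline_hazard * u) +
      p_high * (1 - exp(-max(rate) * u)) / (max(rate) * u)
    u <- uniroot(function(u) cens_frac(u) - spec$censor_rate,
                 lower = 1e-6 / spec$baseline_hazard,
                 upper = 1e6 / spec$baseline_hazard, tol = 1e-10)$root
    cens <- runif(length(time), 0, u)
    event <- as.integer(time <= cens)
    time <- pmin(time, cens)
    time <- pmax(time, .Machine$double.eps)
  }
  data.frame(sample_id = names(driver_values), time = time, event = event,
             stringsAsFactors = FALSE)
}
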