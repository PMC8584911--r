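#' Expression filter for survival analysis
#'
#' A feature is analyzable for a cohort when the fraction of exactly-zero
#' expression values does not exceed `max_zero_fraction` -- features silent
#' in most samples give meaningless median splits.  The boundary is
#' inclusive: exactly half zeros with the default threshold 0.5 is still
#' analyzable.
#'
#' @param expr numeric vector of per-sample expression values (non-empty).
#' @param max_zero_fraction tolerated zero fraction, strictly in (0, 1);
#'   default 0.5 ("most samples" read as a strict majority).
#' @return logical scalar.
#' @export
filterExpressed <- function(expr, max_zero_fraction = 0.5) {
  stopifnot(max_zero_fraction > 0, max_zero_fraction < 1)
  if (!length(expr)) stop("empty cohort")
  mean(expr == 0) <= max_zero_fraction
}

#' Median split of a cohort by expression
#'
#' Dichotomizes samples at the standard sample median (mean of the middle
#' two values for even n): group A holds samples with expression less than
#' or equal to the median (the low-expression group), group B those above
#' it.  Ties at the median therefore go to A.  A feature whose values cannot
#' produce a non-empty B (e.g. all values equal) raises a degenerate-split
#' error.
#'
#' @param expr named numeric vector (names = sample IDs), length >= 2.
#' @return list with `group_a`, `group_b` (character sample IDs) and
#'   `median` (numeric).
#' @examples
#' medianSplit(c(s1 = 1, s2 = 2, s3 = 3, s4 = 4))
#' @export
medianSplit <- function(expr) {
  if (length(expr) < 2L) stop("need at least 2 samples for a median split")
  if (is.null(names(expr))) names(expr) <- as.character(seq_along(expr))
  med <- median(expr)
  a <- expr <= med
  if (all(a)) stop("degenerate split: no sample above the median")
  list(group_a = names(expr)[a], group_b = names(expr)[!a], median = med)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`
#' over the distinct event times `t_i`, with `d_i` events and `n_i` subjects
#' at risk.  Subjects censored at time t remain at risk for events at t (the
#' standard tie convention); before the first event `S = 1`.
#'
#' @param time positive event/censoring times.
#' @param event 0/1 indicator (1 = event).
#' @return data.frame of class `"kmCurve"`, one row per distinct event time:
#'   `time`, `n_risk`, `n_event`, `surv` (non-increasing).
#' @examples
#' kmEstimate(c(1, 2, 3, 3), c(1, 1, 0, 0))   # S(1)=0.75, S(2)=0.5
#' @export
kmEstimate <- function(time, event) {
  if (!length(time)) stop("no survival records")
  stopifnot(length(time) == length(event), all(time > 0),
            all(event %in% c(0, 1)))
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), 1)
  n_event <- vapply(et, function(t) sum(time == t & event == 1), 1)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event,
                    surv = cumprod(1 - n_event / n_risk))
  class(out) <- c("kmCurve", "data.frame")
  out
}

#' Two-group log-rank test with O/E hazard ratio
#'
#' Standard two-group log-rank accumulation: at each distinct event time the
#' expected events per group are the total events apportioned by the
#' at-risk counts, `E_g = d * n_g / n`.  The reported statistic is
#' `chi^2 = (O_a - E_a)^2 / E_a + (O_b - E_b)^2 / E_b` with a 1-df
#' chi-square p-value, and the hazard ratio is the ratio of
#' observed-over-expected rates, `HR = (O_a / E_a) / (O_b / E_b)` -- group A's
#' hazard relative to group B's, with no proportional-hazards model fitted.
#' When group B has no observed events the HR is reported as `Inf` with
#' `hr_infinite = TRUE`.  The hypergeometric variance `V` of `O_a - E_a` is
#' also returned; it feeds the optional confidence-interval prognostic rule
#' of [prognosticScreen()].
#'
#' @param time_a,event_a times and 0/1 event indicators of group A.
#' @param time_b,event_b times and 0/1 event indicators of group B.
#' @return list of class `"logrankResult"`: `obs_a`, `obs_b`, `exp_a`,
#'   `exp_b`, `chi_square`, `p_value`, `hazard_ratio`, `hr_infinite`,
#'   `var_oe`, `n_a`, `n_b`.
#' @examples
#' r <- logrankTest(c(2, 4, 6), c(1, 1, 0), c(2, 4, 6), c(1, 1, 0))
#' r$chi_square   # identical groups: 0
#' @export
logrankTest <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) == length(event_a),
            length(time_b) == length(event_b))
  if (!length(time_a) || !length(time_b)) stop("both groups must be non-empty")
  d_tot <- sum(event_a == 1) + sum(event_b == 1)
  if (d_tot == 0) stop("log-rank undefined: no events in either group")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(time_a), length(time_b)))
  et <- sort(unique(time[event == 1]))
  exp_a <- 0; exp_b <- 0; var_oe <- 0
  for (t in et) {
    at <- time >= t
    n <- sum(at); na <- sum(at & grp_a)
    d <- sum(time == t & event == 1)
    exp_a <- exp_a + d * na / n
    exp_b <- exp_b + d * (n - na) / n
    if (n > 1)
      var_oe <- var_oe + d * (na / n) * (1 - na / n) * (n - d) / (n - 1)
  }
  obs_a <- sum(event_a == 1); obs_b <- sum(event_b == 1)
  chi <- 0
  if (exp_a > 0) chi <- chi + (obs_a - exp_a)^2 / exp_a
  if (exp_b > 0) chi <- chi + (obs_b - exp_b)^2 / exp_b
  rate_a <- obs_a / exp_a
  rate_b <- obs_b / exp_b
  hr_inf <- rate_b == 0 || !is.finite(rate_a / rate_b)
  out <- list(obs_a = obs_a, obs_b = obs_b, exp_a = exp_a, exp_b = exp_b,
              chi_square = chi,
              p_value = pchisq(chi, df = 1, lower.tail = FALSE),
              hazard_ratio = if (hr_inf) Inf else rate_a / rate_b,
              hr_infinite = hr_inf, var_oe = var_oe,
              n_a = length(time_a), n_b = length(time_b))
  class(out) <- "logrankResult"
  out
}

#' @export
print.logrankResult <- function(x, ...) {
  cat(sprintf(
    "log-rank: O/E A = %d/%.2f, B = %d/%.2f; chi2 = %.4g, p = %.4g, HR(A vs B) = %.4g\n",
    x$obs_a, x$exp_a, x$obs_b, x$exp_b, x$chi_square, x$p_value,
    x$hazard_ratio))
  invisible(x)
}

#' Median-split prognostic screen over a feature set
#'
#' For every feature: drop samples without clinical records (counted and
#' reported once), test analyzability with [filterExpressed()], split the
#' cohort at the median expression ([medianSplit()]), and compare the two
#' groups' survival with [logrankTest()].  A feature is flagged prognostic
#' when `p <= alpha` and `HR != 1` (the literal rule; `|HR - 1| > 1e-9`).
#' Because the literal HR condition is almost always met in floating point,
#' `hr_rule = "ci"` offers a stricter variant requiring the 95% (O-E)/V
#' confidence interval of the HR to exclude 1.  P-values are uncorrected by
#' default, matching a per-feature screening convention;
#' `p_adjust = "BH"` applies Benjamini-Hochberg across the screened
#' features before flagging.
#'
#' Degenerate features (failing the zero filter, or with a degenerate median
#' split) are kept in the output with `analyzable = FALSE` and `NA`
#' statistics rather than aborting the screen.
#'
#' @param x an [ExprMatrix-class].
#' @param clinical data.frame with `sample_id`, `time`, `event` (see
#'   [readClinical()]).
#' @param features feature IDs to screen (default: all features of `x`).
#' @param alpha significance level of the log-rank p (default 0.05).
#' @param max_zero_fraction passed to [filterExpressed()].
#' @param hr_rule `"literal"` (HR numerically different from 1) or `"ci"`
#'   (95% CI excludes 1).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame, one row per feature: `feature_id`, `n`, `analyzable`,
#'   `median`, `obs_a`, `exp_a`, `obs_b`, `exp_b`, `chi_square`, `p_value`,
#'   `hazard_ratio`, `prognostic`.
#' @export
prognosticScreen <- function(x, clinical, features = featureIDs(x),
                             alpha = 0.05, max_zero_fraction = 0.5,
                             hr_rule = c("literal", "ci"),
                             p_adjust = c("none", "BH")) {
  stopifnot(is(x, "ExprMatrix"))
  hr_rule <- match.arg(hr_rule)
  p_adjust <- match.arg(p_adjust)
  validateClinical(clinical)
  features <- unique(as.character(features))
  miss <- setdiff(features, featureIDs(x))
  if (length(miss))
    stop("feature(s) not in matrix: ", paste(head(miss, 3L), collapse = ", "))
  ids <- intersect(sampleIDs(x), clinical$sample_id)
  dropped <- length(sampleIDs(x)) - length(ids)
  if (dropped > 0)
    message(dropped, " expression sample(s) without clinical records dropped")
  if (length(ids) < 4L) stop("fewer than 4 samples with clinical records")
  clin <- clinical[match(ids, clinical$sample_id), ]
  v <- exprValues(x)[ids, features, drop = FALSE]

  rows <- lapply(features, function(f) {
    base <- data.frame(feature_id = f, n = length(ids), analyzable = FALSE,
                       median = NA_real_, obs_a = NA_integer_,
                       exp_a = NA_real_, obs_b = NA_integer_,
                       exp_b = NA_real_, chi_square = NA_real_,
                       p_value = NA_real_, hazard_ratio = NA_real_,
                       prognostic = FALSE, stringsAsFactors = FALSE)
    ex <- stats::setNames(v[, f], ids)
    if (!filterExpressed(ex, max_zero_fraction)) return(base)
    sp <- tryCatch(medianSplit(ex), error = function(e) NULL)
    if (is.null(sp)) return(base)
    ia <- match(sp$group_a, ids); ib <- match(sp$group_b, ids)
    lr <- tryCatch(
      logrankTest(clin$time[ia], clin$event[ia], clin$time[ib],
                  clin$event[ib]),
      error = function(e) NULL)
    if (is.null(lr)) return(base)
    base$analyzable <- TRUE
    base$median <- sp$median
    base$obs_a <- lr$obs_a; base$exp_a <- lr$exp_a
    base$obs_b <- lr$obs_b; base$exp_b <- lr$exp_b
    base$chi_square <- lr$chi_square
    base$p_value <- lr$p_value
    base$hazard_ratio <- lr$hazard_ratio
    attr(base, "var_oe") <- lr$var_oe
    base
  })
  out <- do.call(rbind, rows)
  var_oe <- vapply(rows, function(r)
    if (is.null(attr(r, "var_oe"))) NA_real_ else attr(r, "var_oe"), 1)
  p_use <- if (p_adjust == "BH")
    stats::p.adjust(out$p_value, method = "BH") else out$p_value
  hr_ok <- if (hr_rule == "literal") {
    abs(out$hazard_ratio - 1) > 1e-9
  } else {
    # Peto (O-E)/V approximation: log HR ~ (O_a - E_a)/V, se = 1/sqrt(V)
    lhr <- (out$obs_a - out$exp_a) / var_oe
    abs(lhr) - 1.96 / sqrt(var_oe) > 0
  }
  out$prognostic <- out$analyzable & !is.na(p_use) & p_use <= alpha &
    !is.na(hr_ok) & hr_ok
  rownames(out) <- NULL
  out
}
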