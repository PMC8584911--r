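test_that("well-separated classes on informative features classify perfectly", {
  sim <- generateExpression(
    syntheticSpec(n_samples = 120L, n_features = 30L, n_drivers = 6L,
                  n_classes = 2L, class_sep = 5, seed = 77L))
  m <- scoreFeatureSet(sim$expr, sim$labels, sim$drivers, n_folds = 5,
                       seed = 1)
  expect_equal(m$accuracy, 1.0)
  expect_equal(m$f1, 1.0)
  expect_equal(nrow(m$per_fold), 5)
  expect_equal(m$accuracy, mean(m$per_fold$accuracy))
})

test_that("pure-noise features score at chance for balanced binary labels", {
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    v <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(sprintf("s%03d", 1:200), sprintf("f%02d", 1:10)))
    em <- ExprMatrix(v)
    lab <- stats::setNames(factor(rep(c("A", "B"), 100)), sampleIDs(em))
    scoreFeatureSet(em, lab, featureIDs(em), n_folds = 5, seed = s)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("scoring enforces its preconditions", {
  sim <- small_sim()
  expect_error(scoreFeatureSet(sim$expr, sim$labels, character(0)), "empty")
  expect_error(scoreFeatureSet(sim$expr, sim$labels, "no_such"), "not in matrix")
  one_class <- stats::setNames(factor(rep("A", length(sim$labels))),
                               names(sim$labels))
  expect_error(scoreFeatureSet(sim$expr, one_class, sim$drivers), "2 classes")
  tiny_lab <- sim$labels
  tiny_lab[] <- levels(sim$labels)[1]
  tiny_lab[1:3] <- levels(sim$labels)[2]
  expect_error(
    scoreFeatureSet(sim$expr, droplevels(tiny_lab), sim$drivers, n_folds = 5),
    "smaller than n_folds")
})

test_that("fold assignment is stratified to within one sample and seed-stable", {
  lab <- factor(rep(c("a", "b", "c"), times = c(23, 40, 17)))
  f1 <- mrcae:::stratifiedFolds(lab, 5L, seed = 3)
  f2 <- mrcae:::stratifiedFolds(lab, 5L, seed = 3)
  expect_identical(f1, f2)
  for (cl in levels(lab)) {
    per_fold <- tabulate(f1[lab == cl], 5)
    expect_lte(diff(range(per_fold)), 1)
  }
})

test_that("metrics are invariant under feature-column permutation", {
  sim <- small_sim()
  feats <- featureIDs(sim$expr)[1:12]
  m1 <- scoreFeatureSet(sim$expr, sim$labels, feats, seed = 4)
  v <- exprValues(sim$expr)
  perm <- v[, sample(ncol(v))]
  m2 <- scoreFeatureSet(ExprMatrix(perm, normalized = TRUE), sim$labels,
                        feats, seed = 4)
  expect_equal(m1$accuracy, m2$accuracy)
  expect_equal(m1$f1, m2$f1)
})

test_that("feature-set comparison uses common folds and annotates errors", {
  sim <- small_sim()
  sets <- list(drivers = sim$drivers,
               same_drivers = sim$drivers,
               all = featureIDs(sim$expr))
  tab <- compareFeatureSets(sim$expr, sim$labels, sets, n_folds = 4, seed = 2)
  expect_identical(tab$set, names(sets))
  expect_equal(tab$accuracy[1], tab$accuracy[2])   # identical sets, same folds
  expect_equal(tab$f1[1], tab$f1[2])
  expect_error(
    compareFeatureSets(sim$expr, sim$labels, list(bad = "nope"), seed = 2),
    "set 'bad'")
})

test_that("overlap summaries equal a brute-force intersection oracle", {
  ov <- overlapSummary(list(A = c("a", "b", "c"), B = c("c", "d")))
  expect_identical(unname(ov$sizes), c(3L, 2L))
  expect_identical(ov$intersections$size, 1L)
  expect_identical(ov$common, "c")

  ident <- overlapSummary(list(x = letters[1:4], y = letters[1:4]))
  expect_identical(ident$intersections$size, 4L)
  disj <- overlapSummary(list(x = c("a"), y = c("b"), z = c("c")))
  expect_true(all(disj$intersections$size == 0L))

  set.seed(9)
  pool <- sprintf("g%02d", 1:30)
  sets <- stats::setNames(lapply(1:4, function(i) sample(pool, 12)),
                          paste0("S", 1:4))
  ov <- overlapSummary(sets)
  for (r in seq_len(nrow(ov$intersections))) {
    nm <- strsplit(ov$intersections$combination[r], " & ", fixed = TRUE)[[1]]
    brute <- pool
    for (s in nm) brute <- brute[brute %in% sets[[s]]]
    expect_identical(ov$intersections$size[r], length(brute))
  }
  # inclusion-exclusion on each pair
  for (i in 1:3) for (j in (i + 1):4) {
    key <- paste0("S", i, " & S", j)
    inter <- ov$intersections$size[ov$intersections$combination == key]
    expect_identical(length(union(sets[[i]], sets[[j]])), 24L - inter)
  }
})

test_that("random search draws from the grids deterministically and returns the best", {
  sim <- small_sim()
  cfg <- small_cfg()
  # degenerate grids: the single candidate comes back whatever n_trials is
  one <- randomSearchTune(sim$expr, sim$labels, cfg, epoch_grid = 15L,
                          lr_grid = 0.002, n_trials = 2, seed = 5,
                          n_folds = 4)
  expect_identical(one$best@epochs, 15L)
  expect_identical(one$best@learningRate, 0.002)
  expect_identical(one$log$epochs, c(15L, 15L))

  # same seed, same draws
  d1 <- withr::with_seed(1, {
    tune <- randomSearchTune(sim$expr, sim$labels, cfg,
                             epoch_grid = c(10L, 20L, 30L),
                             lr_grid = c(0.001, 0.002), n_trials = 3,
                             seed = 11, n_folds = 4)
    tune$log[, c("epochs", "learning_rate")]
  })
  d2 <- randomSearchTune(sim$expr, sim$labels, cfg,
                         epoch_grid = c(10L, 20L, 30L),
                         lr_grid = c(0.001, 0.002), n_trials = 3,
                         seed = 11, n_folds = 4)
  expect_identical(d1, d2$log[, c("epochs", "learning_rate")])
  expect_identical(d2$best@learningRate,
                   d2$log$learning_rate[which.max(d2$log$accuracy)])
})

test_that("a severely truncated training underfits relative to full training", {
  sim <- small_sim()
  cfg <- small_cfg()
  tune <- randomSearchTune(sim$expr, sim$labels, cfg,
                           epoch_grid = c(2L, 40L), lr_grid = 0.002,
                           n_trials = 4, seed = 21, n_folds = 4)
  log <- tune$log
  if (length(unique(log$epochs)) == 2) {
    acc2 <- mean(log$accuracy[log$epochs == 2L])
    acc40 <- mean(log$accuracy[log$epochs == 40L])
    expect_gte(acc40, acc2 - 0.05)
    expect_identical(tune$best@epochs,
                     log$epochs[which.max(log$accuracy)])
  } else succeed("draws covered a single grid point")
})
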