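test_that("transfer functions match their closed forms on [0, 1]", {
  expect_equal(transfer("S1", 0), 0.5)
  expect_equal(transfer("V1", 0), 0)
  expect_equal(transfer("V2", 0), 0)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(transfer("S2", x), transfer("S1", 2 * x))
  expect_equal(transfer("S3", x), transfer("S1", x / 2))
  expect_true(all(sapply(c("S1", "S2", "S3", "V1", "V2"), function(nm) {
    v <- transfer(nm, x); all(v >= 0 & v <= 1)
  })))
  # V-family folds the negative branch so a threshold in (0,1) is usable
  expect_equal(transfer("V1", -2), transfer("V1", 2))
  expect_error(transfer("S9", 0), "unknown")
})

test_that("binarization thresholds, repairs empty masks, and shrinks with T", {
  z <- rep(0, 10)                      # S1(0) = 0.5 for every coordinate
  m_hi <- binarize(z, "S1", 0.5)       # strict inequality: ties excluded
  expect_equal(m_hi$R, 1L)             # repair keeps exactly one feature
  m_lo <- binarize(z, "S1", 0.3)
  expect_equal(m_lo$R, 10L)

  set.seed(3)
  pos <- runif(30, -2, 2)
  Rs <- sapply(seq(0.1, 0.9, by = 0.1), function(tt)
    binarize(pos, "S1", tt)$R)
  expect_true(all(diff(Rs) <= 0))
  expect_true(all(Rs >= 1))

  pos2 <- c(0.2, 0.9, 0.1)
  m <- binarize(pos2, "S1", 0.99)      # unattainable threshold on [0,1]
  expect_equal(m$bits, c(0L, 1L, 0L))  # arg-max repair
  expect_error(binarize(z, "S1", 1.2), "threshold")
})

test_that("the wrapper fitness trades accuracy against subset size", {
  expect_equal(selection_fitness(0.9, 10, 10, 0.99), 0.891)
  expect_equal(selection_fitness(1, 1, 1000, 0.99), 0.99 + 0.01 * 0.999)
  # parsimony: fitness strictly decreases as R grows at fixed accuracy
  f <- sapply(1:20, function(R) selection_fitness(0.8, R, 20))
  expect_true(all(diff(f) < 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(selection_fitness(0.5, 11, 10), "exceed")
  expect_error(selection_fitness(1.2, 1, 10), "acc")
})

test_that("stratified folds cover every class and reject impossible k", {
  y <- rep(c("a", "b", "c", "d"), each = 25)
  folds <- make_folds(y, cv_config(k = 10, seed = 1))
  for (f in 1:10)
    expect_true(all(table(y[folds == f]) >= 2))
  expect_error(make_folds(rep(c("a", "b"), c(50, 4)), cv_config(k = 10)),
               "smaller k")
  # holdout mode: one held-out part, stratified
  fh <- make_folds(y, cv_config(mode = "holdout", holdout_frac = 0.2))
  expect_equal(sum(fh == 1L), 20)
})

test_that("mask scoring separates separable classes and is honest under label shuffling", {
  fm <- separable_features(shift = 8)
  res <- evaluate_mask(rep(1L, 4), fm, cv_config(k = 5, seed = 2))
  expect_gt(res$mean_acc, 0.99)
  expect_equal(unname(rowSums(res$confusion)), rep(100, 2),
               tolerance = 1e-9)

  # 4 balanced classes with shuffled labels: accuracy collapses to chance
  set.seed(6)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6)
  X[, 1] <- X[, 1] + rep(c(0, 3, 6, 9), length.out = n)
  fm4 <- structure(list(X = X, y = sample(rep(paste0("c", 1:4), 50)),
                        names = paste0("f", 1:6)), class = "mmg_features")
  res4 <- evaluate_mask(rep(1L, 6), fm4, cv_config(k = 10, seed = 3))
  expect_gt(res4$mean_acc, 0.15)
  expect_lt(res4$mean_acc, 0.35)
})

test_that("fold-averaged metrics are plain means", {
  m <- mean_metrics(c(0.8, 1.0), 5)
  expect_equal(m$mean_acc, 0.9)
  expect_equal(m$mean_R, 5)
  expect_equal(mean_metrics(rep(0.9, 10), 3)$mean_acc, 0.9)
  expect_error(mean_metrics(numeric(0), 1), "empty")
})

test_that("wrapper selection is deterministic and repairs unattainable thresholds", {
  fm <- separable_features(n = 60, p = 6)
  cfg <- optimizer_config(dim = 6, pop_size = 6, max_iter = 8, seed = 5)
  f1 <- select_features(fm, "csa", 0.5, opt_cfg = cfg, cv = cv_config(k = 3))
  f2 <- select_features(fm, "csa", 0.5, opt_cfg = cfg, cv = cv_config(k = 3))
  expect_identical(f1$mask$bits, f2$mask$bits)
  expect_identical(f1$fitness_history, f2$fitness_history)
  expect_equal(f1$mean_acc, f2$mean_acc)

  # S1 on [0,1] never exceeds 0.732, so T = 0.99 forces the repair rule
  f3 <- select_features(fm, "goa", 0.99, opt_cfg = cfg,
                        cv = cv_config(k = 3))
  expect_equal(f3$mask$R, 1L)
  expect_equal(f3$mean_R, 1)
})

test_that("the wrapper recovers planted informative features", {
  pd <- generate_planted(n = 150, p = 20, k_informative = 4,
                         effect_size = 3, seed = 2)
  fm <- planted_features(pd)
  cfg <- optimizer_config(dim = 20, pop_size = 10, max_iter = 15, seed = 3)
  fit <- select_features(fm, "csa", 0.5, opt_cfg = cfg,
                         cv = cv_config(k = 5))
  hits <- sum(pd$informative_indices %in% which(coef(fit) == 1))
  expect_gte(hits, 3)
  expect_gt(fit$mean_acc, 0.8)
})
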