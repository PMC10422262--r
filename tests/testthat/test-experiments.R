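fast_cfg <- function() optimizer_config(dim = 1, pop_size = 4, max_iter = 3)

test_that("the benchmark feature-set list has the seven canonical combinations", {
  fsets <- default_feature_sets()
  expect_length(fsets, 7L)
  expect_true("FD+WE" %in% names(fsets))  # the only set without TD
  expect_setequal(fsets[["TD+FD+NLD"]], c("TD", "FD", "NLD"))
  expect_true(all(vapply(fsets, function(s)
    all(s %in% feature_families()), logical(1))))
})

test_that("feature-set comparison produces one row per set x algorithm x seed", {
  segs <- toy_segments(n_per_class = 8)
  tab <- run_feature_set_comparison(
    segs, feature_sets = list(TD = "TD"), algorithms = "csa",
    opt_cfg = fast_cfg(), cv = cv_config(k = 4), seeds = 1L)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_features, 2 * 10)
  expect_true(tab$mean_acc >= 0 && tab$mean_acc <= 1)
  expect_true(tab$elapsed_s >= 0)
})

test_that("adding a feature family does not hurt attainable accuracy on fixed folds", {
  pd <- generate_planted(n = 160, p = 12, k_informative = 4,
                         effect_size = 2.5, seed = 6)
  fm <- planted_features(pd)
  cv <- cv_config(k = 4, seed = 9)
  folds <- make_folds(fm$y, cv)
  sub_mask <- as.integer(seq_len(12) %in% pd$informative_indices[1:2])
  super_mask <- as.integer(seq_len(12) %in% pd$informative_indices)
  acc_sub <- evaluate_mask(sub_mask, fm, cv, folds)$mean_acc
  acc_super <- evaluate_mask(super_mask, fm, cv, folds)$mean_acc
  # nesting holds up to fold noise on an informative superset
  expect_gte(acc_super, acc_sub - 0.05)
})

test_that("channel combinations enumerate all 3-subsets plus the full set", {
  segs <- toy_segments(n_per_class = 8, n_channels = 4)
  tab <- run_channel_combinations(
    segs, families = "TD", algorithms = "goa",
    opt_cfg = fast_cfg(), cv = cv_config(k = 4), seeds = 1L)
  expect_equal(nrow(tab), 5L)           # C(4,3) = 4 subsets + full set
  expect_equal(sum(tab$n_channels == 3), 4L)
  expect_equal(sum(tab$n_channels == 4), 1L)
})

test_that("a channel with no class information barely changes accuracy", {
  g <- matrix(c(1.0, 0.75, 0.5, 0.5,
                0.75, 1.0, 0.5, 0.5,
                0.5, 0.75, 1.0, 0.5,
                0.5, 0.5, 0.75, 1.0), 4, 4, byrow = TRUE)
  g[, 1] <- 0.6                          # channel 1 identical for all classes
  cfg <- generator_config(reps_per_class = 40, seed = 7, gains = g,
                          centroids_hz = rep(40, 4))  # spectra identical too
  segs <- generate_dataset(cfg)
  fm_all <- build_feature_matrix(segs, families = "TD")
  fm_drop <- build_feature_matrix(segs, channels = 2:4, families = "TD")
  cv <- cv_config(k = 5, seed = 2)
  acc_all <- evaluate_mask(rep(1L, ncol(fm_all$X)), fm_all, cv)$mean_acc
  acc_drop <- evaluate_mask(rep(1L, ncol(fm_drop$X)), fm_drop, cv)$mean_acc
  expect_lt(abs(acc_all - acc_drop), 0.06)
})

test_that("the threshold sweep covers its default grid and reports positive R", {
  expect_equal(eval(formals(run_threshold_sweep)$thresholds),
               seq(0.3, 0.6, by = 0.05))
  fm <- separable_features(n = 60, p = 6)
  sw <- run_threshold_sweep(fm, thresholds = c(0.3, 0.6),
                            algorithms = c("csa", "goa"),
                            opt_cfg = fast_cfg(),
                            cv = cv_config(k = 3), seeds = 1L)
  expect_equal(nrow(sw), 4L)
  expect_true(all(sw$R >= 1))
  expect_true(all(c("rate_A", "rate_B") %in% names(sw)))
  agg <- summarize_sweep(sw)
  expect_equal(nrow(agg), 4L)
  # fewer features survive the higher threshold
  for (alg in c("csa", "goa")) {
    a <- agg[agg$algorithm == alg, ]
    expect_lte(a$R_mean[a$threshold == 0.6], a$R_mean[a$threshold == 0.3])
  }
})
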