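test_that("movement generation is seeded and band-limited", {
  cfg <- generator_config()
  set.seed(100); a <- generate_movement(2, cfg)
  set.seed(100); b <- generate_movement(2, cfg)
  expect_identical(a$data, b$data)

  # negligible spectral power above the 100 Hz MMG band
  set.seed(101)
  rec <- generate_movement(1, cfg)
  x <- rec$data[, 1]
  sp <- Mod(fft(x))^2
  freq <- (seq_along(sp) - 1) * cfg$fs / length(sp)
  half <- freq <= cfg$fs / 2
  frac_high <- sum(sp[half & freq > 100]) / sum(sp[half])
  expect_lt(frac_high, 0.05)

  # silent configuration produces silence
  cfg0 <- generator_config(noise_sd = 0,
                           gains = matrix(0, 4, 4))
  set.seed(102)
  expect_true(all(generate_movement(1, cfg0)$data == 0))
})

test_that("generated movements survive the real preprocessing path", {
  cfg <- generator_config(reps_per_class = 5, seed = 3)
  segs <- generate_dataset(cfg)
  expect_length(segs, 20L)
  labs <- vapply(segs, function(s) s$label, character(1))
  expect_equal(unname(table(labs)), rep(5L, 4), ignore_attr = TRUE)
  # segments are usable excerpts at the configured rate
  expect_true(all(vapply(segs, function(s) nrow(s$data) > 0.3 * 250,
                         logical(1))))
})

test_that("identical class signatures give chance-level accuracy, distinct ones do not", {
  # null control: same gains and same spectral centroid for every class
  cfg_null <- generator_config(reps_per_class = 20, seed = 4,
                               gains = matrix(1, 4, 4),
                               centroids_hz = rep(40, 4))
  fm_null <- build_feature_matrix(generate_dataset(cfg_null),
                                  families = c("TD", "FD"))
  acc_null <- evaluate_mask(rep(1L, ncol(fm_null$X)), fm_null,
                            cv_config(k = 5, seed = 1))$mean_acc
  expect_lt(acc_null, 0.45)

  # strong signal: well-separated gains and centroids, little jitter
  g <- matrix(0.2, 4, 4); diag(g) <- 1
  cfg_hi <- generator_config(reps_per_class = 20, seed = 5, gains = g,
                             centroids_hz = c(20, 40, 60, 80),
                             gain_jitter_sd = 0.1, centroid_jitter_hz = 1)
  fm_hi <- build_feature_matrix(generate_dataset(cfg_hi),
                                families = c("TD", "FD"))
  acc_hi <- evaluate_mask(rep(1L, ncol(fm_hi$X)), fm_hi,
                          cv_config(k = 5, seed = 1))$mean_acc
  expect_gte(acc_hi, 0.8)
})

test_that("planted datasets have the promised structure", {
  pd <- generate_planted(n = 200, p = 50, k_informative = 5,
                         effect_size = 3, seed = 1)
  expect_length(pd$informative_indices, 5L)
  expect_equal(dim(pd$X), c(200L, 50L))
  expect_equal(unname(table(pd$y)), rep(50L, 4), ignore_attr = TRUE)

  # the informative columns alone separate the classes
  fm_inf <- structure(list(X = pd$X[, pd$informative_indices],
                           y = pd$y,
                           names = colnames(pd$X)[pd$informative_indices]),
                      class = "mmg_features")
  acc <- evaluate_mask(rep(1L, 5), fm_inf, cv_config(k = 5, seed = 2))$mean_acc
  expect_gt(acc, 0.9)

  # with zero effect size nothing is learnable
  pd0 <- generate_planted(n = 200, p = 10, k_informative = 5,
                          effect_size = 0, seed = 1)
  fm0 <- planted_features(pd0)
  acc0 <- evaluate_mask(rep(1L, 10), fm0, cv_config(k = 5, seed = 2))$mean_acc
  expect_lt(acc0, 0.4)
})

test_that("accuracy is monotone in planted effect size on average", {
  effects <- c(0.5, 1.5, 3)
  mean_acc <- sapply(effects, function(es) {
    mean(sapply(1:5, function(s) {
      pd <- generate_planted(n = 120, p = 8, k_informative = 3,
                             effect_size = es, seed = s)
      evaluate_mask(rep(1L, 8), planted_features(pd),
                    cv_config(k = 4, seed = s))$mean_acc
    }))
  })
  expect_true(all(diff(mean_acc) >= 0))
})
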