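sphere <- function(x) -sum(x^2)

test_that("initialization fills the box uniformly and respects degenerate bounds", {
  cfg <- optimizer_config(dim = 3, lb = 0.5, ub = 0.5, pop_size = 5)
  set.seed(1)
  expect_true(all(initialize_positions(cfg) == 0.5))

  cfg2 <- optimizer_config(dim = 2, lb = 0, ub = 1, pop_size = 5000)
  set.seed(2)
  X <- initialize_positions(cfg2)
  expect_true(all(X >= 0 & X <= 1))
  expect_true(all(abs(colMeans(X) - 0.5) < 0.05))

  set.seed(3); A <- initialize_positions(cfg2)
  set.seed(3); B <- initialize_positions(cfg2)
  expect_identical(A, B)
})

test_that("CSA exploration decay and hunt acceleration follow their closed forms", {
  expect_equal(csa_mu(0, 100, 4), 1)
  expect_equal(csa_mu(100, 100, 1), exp(-1))
  # decay is monotone in t
  mus <- csa_mu(0:50, 50, 4)
  expect_true(all(diff(mus) <= 0))
  expect_equal(csa_acceleration(10), 2590 * (1 - exp(-1)), tolerance = 1e-12)
  # raw expression vanishes at t = 1; the floor keeps it positive
  expect_equal(csa_acceleration(1), 1e-6)
})

test_that("CSA search phase is a no-op when both exploitation gains vanish", {
  cfg <- optimizer_config(dim = 4, lb = -1, ub = 1, pop_size = 6,
                          max_iter = 10, p1 = 0, p2 = 0, pp = 0)
  set.seed(7)
  X <- initialize_positions(cfg)
  state <- list(X = X, P = X, G = X[1, ])
  out <- csa_search_update(state, cfg, t = 3)
  expect_equal(out$X, X)
})

test_that("eye rotation is an isometry about the centroid", {
  # a 90 degree planar rotation of (1, 0) about the origin gives (0, 1)
  expect_equal(planar_rotate(c(1, 0), c(0, 0), c(1, 2), pi / 2), c(0, 1),
               tolerance = 1e-10)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(6)
    ctr <- mean(x)
    y <- planar_rotate(x, ctr, sample(6, 2), runif(1, -pi, pi))
    expect_equal(sqrt(sum((y - ctr)^2)), sqrt(sum((x - ctr)^2)),
                 tolerance = 1e-10)
  }
})

test_that("hunt phase leaves positions unchanged when the velocity does not change", {
  # with unit inertia and zero attraction gains v_new = v_old, so the
  # squared-velocity difference term vanishes
  cfg <- optimizer_config(dim = 3, lb = -5, ub = 5, pop_size = 4,
                          max_iter = 10, c1 = 0, c2 = 0, p_w = 0)
  set.seed(9)
  X <- initialize_positions(cfg)
  V <- matrix(rnorm(12), 4, 3)
  state <- list(X = X, V = V, V_prev = V, P = X, G = X[1, ])
  out <- csa_hunt_update(state, cfg, t = 5)
  expect_equal(out$X, X)
  # inertia weight hits zero at the final iteration
  expect_equal((1 - 10 / 10)^(1 * 10 / 10), 0)
})

test_that("the grasshopper social force attracts at mid range and repels up close", {
  expect_equal(goa_social_force(0, 0.5, 1.5), -0.5)
  expect_lt(abs(goa_social_force(50, 0.5, 1.5)), 1e-12)
  s <- goa_social_force(seq(0.01, 4, by = 0.01), 0.5, 1.5)
  expect_equal(sum(diff(sign(s)) != 0), 1L)  # one comfort distance in (0, 4]
})

test_that("the GOA coefficient decays linearly between its bounds", {
  cfg <- optimizer_config(dim = 2, max_iter = 100, c_max = 1, c_min = 1e-5)
  expect_equal(goa_decay_coefficient(0, cfg), 1)
  expect_equal(goa_decay_coefficient(100, cfg), 1e-5)
  expect_equal(goa_decay_coefficient(50, cfg), 0.500005)
})

test_that("GOA position update honours the zero-distance convention and symmetry", {
  cfg <- optimizer_config(dim = 2, lb = -10, ub = 10, pop_size = 2,
                          max_iter = 10)
  G <- c(1, -1)
  # coincident individuals feel no social force and move to the best
  st <- list(X = rbind(c(2, 2), c(2, 2)), G = G)
  out <- goa_position_update(st, cfg, t = 1)
  expect_equal(out$X, rbind(G, G), ignore_attr = TRUE)
  # a mirror-symmetric pair about the best stays mirror-symmetric
  st2 <- list(X = rbind(G + c(2, 0), G - c(2, 0)), G = G)
  out2 <- goa_position_update(st2, cfg, t = 1)
  expect_equal(out2$X[1, ] - G, -(out2$X[2, ] - G), tolerance = 1e-12)
})

test_that("both optimizers find the sphere optimum deterministically", {
  for (alg in c("csa", "goa")) {
    cfg <- optimizer_config(dim = 5, lb = -1, ub = 1, pop_size = 20,
                            max_iter = 150, seed = 4)
    r1 <- optimize_swarm(sphere, alg, cfg)
    r2 <- optimize_swarm(sphere, alg, cfg)
    expect_identical(r1$fitness_history, r2$fitness_history)
    expect_gt(r1$best_fitness, -1e-2)
    expect_true(all(diff(r1$fitness_history) >= 0))
    expect_length(r1$fitness_history, 151L)
  }
})

test_that("evaluation bookkeeping and box containment hold throughout a run", {
  seen <- new.env(); seen$n <- 0L; seen$ok <- TRUE
  obj <- function(x) {
    seen$n <- seen$n + 1L
    seen$ok <- seen$ok && all(x >= -1 - 1e-12) && all(x <= 1 + 1e-12)
    -sum(x^2)
  }
  cfg <- optimizer_config(dim = 3, lb = -1, ub = 1, pop_size = 2,
                          max_iter = 1, seed = 1)
  res <- optimize_swarm(obj, "csa", cfg)
  expect_equal(res$evaluations, 2 * (1 + 1))
  expect_equal(seen$n, res$evaluations)
  expect_true(seen$ok)

  cfg2 <- optimizer_config(dim = 4, lb = -1, ub = 1, pop_size = 8,
                           max_iter = 30, seed = 2)
  for (alg in c("csa", "goa")) {
    seen$ok <- TRUE
    invisible(optimize_swarm(obj, alg, cfg2))
    expect_true(seen$ok)
  }
})

test_that("a non-finite objective value is reported with its position", {
  cfg <- optimizer_config(dim = 2, lb = -1, ub = 1, pop_size = 3,
                          max_iter = 2, seed = 1)
  expect_error(optimize_swarm(function(x) NA_real_, "csa", cfg),
               "non-finite")
})
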