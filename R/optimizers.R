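#' Optimizer configuration
#'
#' Settings shared by the two swarm optimizers and their algorithm-specific
#' parameters. The chameleon swarm algorithm (CSA) iterates three phases --
#' prey search, eye rotation about each individual's centroid, and a
#' velocity-based hunt step; the grasshopper optimization algorithm (GOA)
#' moves individuals under pairwise social forces plus attraction to the
#' best solution, with a linearly decaying coefficient.
#'
#' @param dim Number of decision variables.
#' @param lb,ub Lower/upper bounds, scalars (recycled) or length-`dim`
#'   vectors, `lb < ub` elementwise.
#' @param pop_size Swarm size N (>= 2); default 20.
#' @param max_iter Iteration budget Tmax (>= 1); default 50.
#' @param seed Integer seed; all randomness in [optimize_swarm()] flows
#'   from it.
#' @param p1,p2 CSA exploitation gains of the prey-search phase.
#' @param pp CSA perception probability: with probability `1 - pp` an
#'   individual exploits (moves relative to its personal and the global
#'   best), otherwise it explores uniformly in the box.
#' @param alpha_csa CSA sensitivity of the exploration decay
#'   `mu = exp(-(alpha * t / Tmax)^3)`.
#' @param c1,c2 CSA hunt-phase velocity gains (global/personal best pull).
#' @param p_w CSA inertia exponent in `w = (1 - t/Tmax)^(p_w * t/Tmax)`.
#' @param a_min Floor for the hunt acceleration `a = 2590 (1 - e^(-log10 t))`,
#'   which is zero at `t = 1`.
#' @param f_attract,l_scale GOA social force `s(r) = f e^(-r/l) - e^(-r)`
#'   parameters (attraction intensity and length scale).
#' @param c_max,c_min GOA decay coefficient range.
#' @return A list of class `mmg_opt_config`.
#' @export
optimizer_config <- function(dim, lb = 0, ub = 1, pop_size = 20L,
                             max_iter = 50L, seed = 1L,
                             p1 = 2.0, p2 = 1.8, pp = 0.1, alpha_csa = 4.0,
                             c1 = 2.0, c2 = 1.8, p_w = 1.0, a_min = 1e-6,
                             f_attract = 0.5, l_scale = 1.5,
                             c_max = 1, c_min = 1e-5) {
  dim <- as.integer(dim)
  stopifnot(dim >= 1L, pop_size >= 2L, max_iter >= 1L)
  lb <- rep_len(as.numeric(lb), dim)
  ub <- rep_len(as.numeric(ub), dim)
  if (any(lb > ub)) stop("'lb' must not exceed 'ub'")
  structure(list(dim = dim, lb = lb, ub = ub,
                 pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 p1 = p1, p2 = p2, pp = pp, alpha_csa = alpha_csa,
                 c1 = c1, c2 = c2, p_w = p_w, a_min = a_min,
                 f_attract = f_attract, l_scale = l_scale,
                 c_max = c_max, c_min = c_min),
            class = "mmg_opt_config")
}

clamp_box <- function(X, cfg) {
  X <- pmax(X, matrix(cfg$lb, nrow(X), cfg$dim, byrow = TRUE))
  pmin(X, matrix(cfg$ub, nrow(X), cfg$dim, byrow = TRUE))
}

#' Uniform swarm initialization
#'
#' Draws `pop_size` positions uniformly in the box `[lb, ub]` from R's
#' current random stream (seeded once by [optimize_swarm()]).
#'
#' @param cfg An [optimizer_config()].
#' @return A `pop_size x dim` matrix.
#' @export
initialize_positions <- function(cfg) {
  N <- cfg$pop_size; D <- cfg$dim
  U <- matrix(stats::runif(N * D), N, D)
  sweep(U, 2L, cfg$ub - cfg$lb, "*") + matrix(cfg$lb, N, D, byrow = TRUE)
}

#' CSA exploration decay coefficient
#'
#' `mu = exp(-(alpha * t / Tmax)^3)`: 1 at `t = 0`, decaying so the uniform
#' exploration branch of the prey-search phase fades out over the run.
#'
#' @param t Current iteration.
#' @param max_iter Iteration budget Tmax.
#' @param alpha Sensitivity coefficient (default 4).
#' @return A number in (0, 1].
#' @export
csa_mu <- function(t, max_iter, alpha = 4.0) exp(-((alpha * t / max_iter)^3))

#' CSA hunt acceleration
#'
#' `a(t) = 2590 (1 - e^(-log10 t))`, floored at `a_min` because the raw
#' expression vanishes at `t = 1` and enters Eq. as a divisor.
#'
#' @param t Current iteration (>= 1).
#' @param a_min Floor (default `1e-6`).
#' @return Positive acceleration value.
#' @export
csa_acceleration <- function(t, a_min = 1e-6) {
  max(2590 * (1 - exp(-log10(t))), a_min)
}

#' Planar (Givens) rotation of a position about a centroid
#'
#' Rotates `x - centroid` by `angle` in the plane spanned by coordinates
#' `dims[1]` and `dims[2]`, then restores the centroid. An isometry of the
#' offset: `||x' - centroid|| = ||x - centroid||`.
#'
#' @param x Numeric position vector.
#' @param centroid Numeric vector (or scalar, recycled) to rotate about.
#' @param dims Integer vector of the two coordinates defining the plane.
#' @param angle Rotation angle in radians.
#' @return The rotated position vector.
#' @export
planar_rotate <- function(x, centroid, dims, angle) {
  centroid <- rep_len(centroid, length(x))
  off <- x - centroid
  if (length(x) >= 2L) {
    i <- dims[1L]; j <- dims[2L]
    ca <- cos(angle); sa <- sin(angle)
    oi <- off[i]; oj <- off[j]
    off[i] <- ca * oi - sa * oj
    off[j] <- sa * oi + ca * oj
  }
  centroid + off
}

# --- CSA phase updates (state: list with X, V, V_prev, P, pfit, G, gfit) ---

#' @rdname optimize_swarm
#' @param state Swarm state list with elements `X` (positions), `V`
#'   (velocities), `P`/`pfit` (personal bests), `G`/`gfit` (global best).
#' @param t Current iteration (1-based).
#' @export
csa_search_update <- function(state, cfg, t) {
  N <- cfg$pop_size; D <- cfg$dim
  X <- state$X
  mu <- csa_mu(t, cfg$max_iter, cfg$alpha_csa)
  r <- matrix(stats::runif(N * D), N, D)
  r1 <- matrix(stats::runif(N * D), N, D)
  r2 <- matrix(stats::runif(N * D), N, D)
  r3 <- matrix(stats::runif(N * D), N, D)
  sgn <- sign(matrix(stats::runif(N * D), N, D) - 0.5)
  G <- matrix(state$G, N, D, byrow = TRUE)
  exploit <- X + cfg$p1 * r2 * (state$P - G) + cfg$p2 * r1 * (G - X)
  span <- matrix(cfg$ub - cfg$lb, N, D, byrow = TRUE)
  lbm <- matrix(cfg$lb, N, D, byrow = TRUE)
  explore <- X + mu * (r3 * span + lbm) * sgn
  state$X <- clamp_box(ifelse(r >= cfg$pp, exploit, explore), cfg)
  state
}

#' @rdname optimize_swarm
#' @export
csa_eye_update <- function(state, cfg, t) {
  X <- state$X
  D <- cfg$dim
  if (D >= 2L) {
    for (i in seq_len(nrow(X))) {
      dims <- sample.int(D, 2L)
      angle <- stats::runif(1L, -pi, pi)
      X[i, ] <- planar_rotate(X[i, ], mean(X[i, ]), dims, angle)
    }
  }
  state$X <- clamp_box(X, cfg)
  state
}

#' @rdname optimize_swarm
#' @export
csa_hunt_update <- function(state, cfg, t) {
  N <- cfg$pop_size; D <- cfg$dim
  X <- state$X
  w <- (1 - t / cfg$max_iter)^(cfg$p_w * t / cfg$max_iter)
  r1 <- matrix(stats::runif(N * D), N, D)
  r2 <- matrix(stats::runif(N * D), N, D)
  G <- matrix(state$G, N, D, byrow = TRUE)
  v_new <- w * state$V + cfg$c1 * r1 * (G - X) + cfg$c2 * r2 * (state$P - X)
  a <- csa_acceleration(t, cfg$a_min)
  state$X <- clamp_box(X + (v_new^2 - state$V^2) / (2 * a), cfg)
  state$V_prev <- state$V
  state$V <- v_new
  state
}

# --- GOA updates ---

#' GOA social force
#'
#' `s(r) = f e^(-r/l) - e^(-r)`: positive values attract, negative repel;
#' the zero crossing is the swarm's comfort distance.
#'
#' @param r Non-negative distance (vectorized).
#' @param f_attract Attraction intensity f (default 0.5).
#' @param l_scale Attraction length scale l (default 1.5).
#' @return `s(r)`, same length as `r`.
#' @export
goa_social_force <- function(r, f_attract = 0.5, l_scale = 1.5) {
  stopifnot(all(r >= 0))
  f_attract * exp(-r / l_scale) - exp(-r)
}

#' GOA decay coefficient
#'
#' Linear decay `c(t) = c_max - t (c_max - c_min) / Tmax`, shrinking both
#' the comfort zone and the step size over the run.
#'
#' @param t Current iteration (0..Tmax).
#' @param cfg An [optimizer_config()].
#' @return The coefficient value.
#' @export
goa_decay_coefficient <- function(t, cfg) {
  cfg$c_max - t * (cfg$c_max - cfg$c_min) / cfg$max_iter
}

#' @rdname optimize_swarm
#' @export
goa_position_update <- function(state, cfg, t) {
  N <- cfg$pop_size; D <- cfg$dim
  X <- state$X
  cc <- goa_decay_coefficient(t, cfg)
  half_span <- (cfg$ub - cfg$lb) / 2
  Xnew <- matrix(0, N, D)
  for (i in seq_len(N)) {
    S <- numeric(D)
    for (j in seq_len(N)) {
      if (j == i) next
      diff <- X[j, ] - X[i, ]
      d <- sqrt(sum(diff^2))
      if (d == 0) next   # coincident individuals exert no force
      S <- S + cc * half_span * goa_social_force(d, cfg$f_attract,
                                                 cfg$l_scale) * diff / d
    }
    Xnew[i, ] <- cc * S + state$G
  }
  state$X <- clamp_box(Xnew, cfg)
  state
}

#' Run a swarm optimizer
#'
#' Maximizes `objective` over the box in `cfg` with the chameleon swarm
#' algorithm (`"csa"`) or the grasshopper optimization algorithm (`"goa"`).
#' One CSA iteration applies the prey-search, eye-rotation and hunt phases
#' in sequence before re-evaluating the swarm; one GOA iteration updates
#' the decay coefficient and moves every individual under the social forces
#' plus best-solution attraction. The run is deterministic given
#' `cfg$seed`, uses `pop_size * (max_iter + 1)` objective evaluations, and
#' records the best-so-far fitness after initialization and after every
#' iteration (a non-decreasing trace).
#'
#' @param objective Function mapping a position vector to a finite scalar
#'   (maximized).
#' @param algorithm `"csa"` or `"goa"`.
#' @param cfg An [optimizer_config()].
#' @return An object of class `mmg_opt`: list with `best_position`,
#'   `best_fitness`, `fitness_history` (length `max_iter + 1`),
#'   `evaluations`, `algorithm`.
#' @examples
#' cfg <- optimizer_config(dim = 2, lb = -1, ub = 1, pop_size = 10,
#'                         max_iter = 25, seed = 7)
#' optimize_swarm(function(x) -sum(x^2), "csa", cfg)$best_fitness
#' @export
optimize_swarm <- function(objective, algorithm = c("csa", "goa"), cfg) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(cfg, "mmg_opt_config"))
  set.seed(cfg$seed)
  N <- cfg$pop_size

  eval_all <- function(X) {
    vapply(seq_len(nrow(X)), function(i) {
      f <- objective(X[i, ])
      if (!is.finite(f))
        stop("objective returned a non-finite value at position [",
             paste(signif(X[i, ], 4), collapse = ", "), "]")
      f
    }, numeric(1))
  }

  X <- initialize_positions(cfg)
  fit <- eval_all(X)
  best <- which.max(fit)
  state <- list(X = X, V = matrix(0, N, cfg$dim),
                V_prev = matrix(0, N, cfg$dim),
                P = X, pfit = fit, G = X[best, ], gfit = fit[best])
  history <- state$gfit
  evals <- N

  for (t in seq_len(cfg$max_iter)) {
    if (algorithm == "csa") {
      state <- csa_search_update(state, cfg, t)
      state <- csa_eye_update(state, cfg, t)
      state <- csa_hunt_update(state, cfg, t)
    } else {
      state <- goa_position_update(state, cfg, t)
    }
    fit <- eval_all(state$X)
    evals <- evals + N
    improved <- fit > state$pfit
    state$P[improved, ] <- state$X[improved, , drop = FALSE]
    state$pfit[improved] <- fit[improved]
    b <- which.max(state$pfit)
    if (state$pfit[b] > state$gfit) {
      state$gfit <- state$pfit[b]
      state$G <- state$P[b, ]
    }
    history <- c(history, state$gfit)
  }
  structure(list(best_position = state$G, best_fitness = state$gfit,
                 fitness_history = history, evaluations = evals,
                 algorithm = algorithm, config = cfg),
            class = "mmg_opt")
}

#' @export
print.mmg_opt <- function(x, ...) {
  cat(sprintf("<mmg_opt %s: best fitness %.6g after %d evaluations>\n",
              toupper(x$algorithm), x$best_fitness, x$evaluations))
  invisible(x)
}
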