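#' Leader weights for the improved grey wolf optimizer
#'
#' The three best-ranked wolves (alpha, beta, delta in the usual pack
#' vocabulary) jointly define the prey estimate as a weighted average.
#' The weights must satisfy a strict ordering
#' `1 >= w1 > w2 > w3 >= 0` and sum to 1.
#'
#' @param w1,w2,w3 Weights for the best, second and third leader.
#' @return An object of class `"leader_weights"`.
#' @export
leader_weights <- function(w1 = 0.5, w2 = 0.3, w3 = 0.2) {
  w <- c(w1, w2, w3)
  if (any(w < 0) || any(w > 1) || !(w1 > w2 && w2 > w3)) {
    stop("invalid weights: need 1 >= w1 > w2 > w3 >= 0", call. = FALSE)
  }
  if (abs(sum(w) - 1) > 1e-12) {
    stop("invalid weights: must sum to 1", call. = FALSE)
  }
  structure(list(w = w), class = "leader_weights")
}

#' Two-stage convergence coefficient
#'
#' Replaces the canonical linearly decaying GWO coefficient with a
#' schedule that decays faster in the first half of the run and is lifted
#' in the second half:
#' `h = 0.9 * (2 - 2 t / T)` for `t < T/2` and
#' `h = 1.2 * (2 - 2 t / T)` for `t >= T/2`,
#' giving `h(0) = 1.8`, an upward jump at the stage switch, and
#' `h(T) = 0`.
#'
#' @param t Iteration index, `0 <= t <= T_max`.
#' @param T_max Total iterations.
#' @return Coefficient in `[0, 1.8]`.
#' @export
convergence_coefficient <- function(t, T_max) {
  if (any(t < 0) || any(t > T_max)) {
    stop("iteration t out of range 0..T_max", call. = FALSE)
  }
  ifelse(t < T_max / 2,
         0.9 * (2 - 2 * t / T_max),
         1.2 * (2 - 2 * t / T_max))
}

#' Decaying standard deviation of the prey-estimate noise
#'
#' Linear decay from `sigma0` at `t = 0` to `sigma_min` at `t = T_max`;
#' strictly decreasing in `t`, which keeps early iterations exploratory
#' and late iterations nearly deterministic.
#'
#' @param t Iteration index.
#' @param T_max Total iterations.
#' @param sigma0 Initial standard deviation (decision-variable units).
#' @param sigma_min Floor, `0 <= sigma_min < sigma0`.
#' @return The standard deviation at iteration `t`.
#' @export
noise_sigma <- function(t, T_max, sigma0, sigma_min) {
  if (sigma0 <= sigma_min || sigma_min < 0) {
    stop("invalid configuration: need sigma0 > sigma_min >= 0",
         call. = FALSE)
  }
  sigma_min + (sigma0 - sigma_min) * (1 - t / T_max)
}

#' Weighted, noise-perturbed prey estimate
#'
#' Combines the three leader positions with the ordered weights and adds
#' independent Gaussian noise per dimension with standard deviation
#' `sigma_t`.
#'
#' @param alpha_pos,beta_pos,delta_pos Leader positions (equal lengths).
#' @param weights A [leader_weights()] object.
#' @param sigma_t Noise standard deviation at the current iteration.
#' @param noise Optional fixed noise vector for deterministic testing.
#' @return The prey-estimate position.
#' @export
estimate_prey <- function(alpha_pos, beta_pos, delta_pos,
                          weights = leader_weights(), sigma_t = 0,
                          noise = NULL) {
  if (!inherits(weights, "leader_weights")) {
    stop("invalid weights: use leader_weights()", call. = FALSE)
  }
  n <- length(alpha_pos)
  if (length(beta_pos) != n || length(delta_pos) != n) {
    stop("shape error: leader positions must have equal length",
         call. = FALSE)
  }
  if (is.null(noise)) {
    noise <- if (sigma_t > 0) stats::rnorm(n, 0, sigma_t) else numeric(n)
  }
  w <- weights$w
  w[1] * alpha_pos + w[2] * beta_pos + w[3] * delta_pos + noise
}

#' Move a wolf relative to a prey estimate
#'
#' Per dimension, a random coefficient `R = h * (2 r - 1)` with
#' `r ~ U(0,1)` gives the candidate `prey_k - R * (prey_k - x_k)`.
#' A candidate that escapes the box is re-proposed as a random step from
#' the prey toward the violated boundary,
#' `prey_k + v * (U_k - x_k)` above or `prey_k + v * (L_k - x_k)` below
#' with `v ~ U(0,1)`, and finally clamped, so the result is always within
#' bounds.
#'
#' @param x Current position.
#' @param prey Prey-estimate position.
#' @param h Convergence coefficient bounding `|R|`.
#' @param bounds A [bounds()] object.
#' @param r,v Optional fixed uniforms for deterministic testing.
#' @return The new in-bounds position.
#' @export
update_position <- function(x, prey, h, bounds, r = NULL, v = NULL) {
  b <- as_bounds(bounds, dim = length(x))
  if (h < 0) stop("h must be non-negative", call. = FALSE)
  n <- length(x)
  if (is.null(r)) r <- stats::runif(n)
  r <- rep_len(r, n)
  R <- h * (2 * r - 1)
  cand <- prey - R * (prey - x)
  above <- cand > b$upper
  below <- cand < b$lower
  if (any(above) || any(below)) {
    if (is.null(v)) v <- stats::runif(n)
    v <- rep_len(v, n)
    cand[above] <- prey[above] + v[above] * (b$upper[above] - x[above])
    cand[below] <- prey[below] + v[below] * (b$lower[below] - x[below])
    cand <- clamp_to_bounds(cand, b)
  }
  cand
}

#' Sine-cosine mixture of the three leader-guided candidates
#'
#' Escape step against premature convergence: the new position blends the
#' three leader-guided candidate positions with trigonometric weights,
#' `sin(theta) * M1 + sin(theta) cos(theta) * M2 + cos(theta) * M3`,
#' with `theta` in `[0, pi/2]` so all mixing weights are non-negative.
#' At `theta = 0` the move collapses to `M3`, at `theta = pi/2` to `M1`.
#'
#' @param M1,M2,M3 Candidate positions guided by the first, second and
#'   third leader (equal lengths).
#' @param theta Mixing angle in radians, in `[0, pi/2]`.
#' @return The blended position (not yet clamped to bounds).
#' @export
sine_cosine_position <- function(M1, M2, M3, theta) {
  n <- length(M1)
  if (length(M2) != n || length(M3) != n) {
    stop("shape error: M1, M2, M3 must have equal length", call. = FALSE)
  }
  if (theta < 0 || theta > pi / 2) {
    stop("theta must lie in [0, pi/2]", call. = FALSE)
  }
  sin(theta) * M1 + sin(theta) * cos(theta) * M2 + cos(theta) * M3
}

#' Configuration for the (improved) grey wolf optimizer
#'
#' @param pop_size Pack size; at least 3 (the three leaders).
#' @param iterations Iteration count.
#' @param weights A [leader_weights()] object (used by IGWO only; the
#'   baseline GWO averages the leaders with equal weights).
#' @param sigma0 Initial prey-noise standard deviation; default
#'   `0.001 * mean(upper - lower)` of the search bounds, resolved at run
#'   time. The perturbation is meant to break the collapse of the
#'   three-leader prey estimate, not to drive global exploration (the
#'   step coefficient already does that), so it is kept well below the
#'   box scale.
#' @param sigma_min Noise floor; default `1e-4 * sigma0`.
#' @param p_sc Probability of the sine-cosine escape step per wolf per
#'   iteration (IGWO only).
#' @param seed Integer seed.
#' @param max_evals Optional evaluation cap (benchmark budget
#'   equalization).
#' @return A list of class `"igwo_config"`.
#' @export
igwo_config <- function(pop_size = 30, iterations = 200,
                        weights = leader_weights(), sigma0 = NULL,
                        sigma_min = NULL, p_sc = 0.3, seed = 1L,
                        max_evals = Inf) {
  if (pop_size < 3) {
    stop("invalid configuration: pop_size must be at least 3 (alpha, ",
         "beta and delta leaders)", call. = FALSE)
  }
  if (iterations < 1) {
    stop("invalid configuration: iterations must be at least 1",
         call. = FALSE)
  }
  if (p_sc < 0 || p_sc > 1) {
    stop("invalid configuration: p_sc must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(weights, "leader_weights")) {
    stop("invalid weights: use leader_weights()", call. = FALSE)
  }
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 weights = weights,
                 sigma0 = sigma0, sigma_min = sigma_min,
                 p_sc = as.numeric(p_sc), seed = seed,
                 max_evals = max_evals),
            class = "igwo_config")
}

## Shared loop for the improved and baseline grey wolf optimizers.
gwo_engine <- function(objective, bounds, config, improved) {
  b <- as_bounds(bounds)
  cfg <- config
  if (!inherits(cfg, "igwo_config")) stop("config must be an igwo_config()",
                                          call. = FALSE)
  sigma0 <- cfg$sigma0
  if (is.null(sigma0)) sigma0 <- 0.001 * mean(b$upper - b$lower)
  sigma_min <- cfg$sigma_min
  if (is.null(sigma_min)) sigma_min <- 1e-4 * sigma0
  T_max <- cfg$iterations
  with_seed(cfg$seed, {
    n_evals <- 0L
    evaluate <- function(x) {
      n_evals <<- n_evals + 1L
      eval_objective(objective, x)
    }
    pos <- matrix(stats::runif(cfg$pop_size * b$dim), nrow = cfg$pop_size) *
      rep(b$upper - b$lower, each = cfg$pop_size) +
      rep(b$lower, each = cfg$pop_size)
    fit <- apply(pos, 1L, evaluate)
    ord <- order(fit)
    best_pos <- pos[ord[1], ]
    best_fit <- fit[ord[1]]
    trace <- numeric(T_max)
    for (iter in seq_len(T_max)) {
      if (n_evals >= cfg$max_evals) {
        trace[iter:T_max] <- best_fit
        break
      }
      t <- iter - 1L
      ord <- order(fit)
      a_pos <- pos[ord[1], ]; b_pos <- pos[ord[2], ]; d_pos <- pos[ord[3], ]
      if (improved) {
        h <- convergence_coefficient(t, T_max)
        sig <- noise_sigma(t, T_max, sigma0, sigma_min)
      } else {
        h <- 2 * (1 - t / T_max)
      }
      new_pos <- pos
      for (j in seq_len(cfg$pop_size)) {
        if (n_evals >= cfg$max_evals) break
        x <- pos[j, ]
        if (improved && stats::runif(1) < cfg$p_sc) {
          M1 <- update_position(x, a_pos, h, b)
          M2 <- update_position(x, b_pos, h, b)
          M3 <- update_position(x, d_pos, h, b)
          theta <- stats::runif(1, 0, pi / 2)
          cand <- clamp_to_bounds(sine_cosine_position(M1, M2, M3, theta), b)
        } else {
          prey <- if (improved) {
            estimate_prey(a_pos, b_pos, d_pos, cfg$weights, sig)
          } else {
            (a_pos + b_pos + d_pos) / 3
          }
          cand <- update_position(x, clamp_to_bounds(prey, b), h, b)
        }
        new_pos[j, ] <- cand
        fit[j] <- evaluate(cand)
        if (fit[j] < best_fit) {
          best_fit <- fit[j]
          best_pos <- cand
        }
      }
      pos <- new_pos
      trace[iter] <- best_fit
    }
    opt_result(best_pos, best_fit, trace, n_evals, cfg$seed,
               if (improved) "igwo" else "gwo")
  })
}

#' Minimize with the improved grey wolf optimizer
#'
#' Each iteration ranks the pack and takes the three best wolves as
#' leaders. A wolf then either (with probability `p_sc`) takes the
#' sine-cosine escape step over the three leader-guided candidates, or
#' moves toward the weighted, noise-perturbed prey estimate
#' ([estimate_prey()]) under the two-stage convergence coefficient
#' ([convergence_coefficient()]). Replacement is unconditional, but the
#' global best is retained, so the best-so-far trace is non-increasing.
#'
#' @inheritParams tdo_minimize
#' @param config An [igwo_config()].
#' @return An `"opt_result"`.
#' @export
igwo_minimize <- function(objective, bounds, config = igwo_config()) {
  gwo_engine(objective, bounds, config, improved = TRUE)
}

#' Minimize with the baseline grey wolf optimizer
#'
#' Canonical baseline for the convergence comparison: the step
#' coefficient decays linearly (`a = 2 (1 - t/T)`), the three leaders are
#' averaged with equal weights, and there is no noise and no sine-cosine
#' step. All other mechanics (boundary handling, elitism, seeding) match
#' [igwo_minimize()] so differences are attributable to the modified
#' schedule, weighting, noise and escape step.
#'
#' @inheritParams igwo_minimize
#' @return An `"opt_result"`.
#' @export
gwo_minimize <- function(objective, bounds, config = igwo_config()) {
  gwo_engine(objective, bounds, config, improved = FALSE)
}
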