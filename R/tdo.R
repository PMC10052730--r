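#' Configuration for the Tasmanian devil optimizer
#'
#' @param pop_size Number of devils (at least 2: the carrion/prey choice
#'   requires a second population member).
#' @param iterations Maximum iteration count.
#' @param p_explore Probability that a devil takes the exploration
#'   (carrion) branch in a given iteration; otherwise it takes the
#'   exploitation (prey) branch followed by a shrinking local search.
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param max_evals Optional cap on objective evaluations (used by the
#'   benchmark harness to equalize budgets across algorithms).
#' @return A list of class `"tdo_config"`.
#' @export
tdo_config <- function(pop_size = 20, iterations = 100, p_explore = 0.5,
                       seed = 1L, max_evals = Inf) {
  if (pop_size < 2) {
    stop("invalid configuration: pop_size must be at least 2 (the carrion ",
         "and prey choices need another population member)", call. = FALSE)
  }
  if (iterations < 1) {
    stop("invalid configuration: iterations must be at least 1",
         call. = FALSE)
  }
  if (p_explore < 0 || p_explore > 1) {
    stop("invalid configuration: p_explore must lie in [0, 1]",
         call. = FALSE)
  }
  structure(list(pop_size = as.integer(pop_size),
                 iterations = as.integer(iterations),
                 p_explore = as.numeric(p_explore),
                 seed = seed, max_evals = max_evals),
            class = "tdo_config")
}

#' Choose a random population member other than oneself
#'
#' Uniform draw over the other `pop_size - 1` indices; used to pick the
#' carrion (exploration) or prey (exploitation) target.
#'
#' @param j Index of the current member (1-based).
#' @param pop_size Population size (at least 2).
#' @return A single index in `1:pop_size`, never equal to `j`.
#' @export
select_random_other <- function(j, pop_size) {
  if (pop_size < 2) {
    stop("invalid configuration: pop_size must be at least 2", call. = FALSE)
  }
  if (j < 1 || j > pop_size) {
    stop("index j out of range 1..pop_size", call. = FALSE)
  }
  candidates <- seq_len(pop_size)[-j]
  if (length(candidates) == 1L) return(candidates)
  candidates[sample.int(length(candidates), 1L)]
}

#' One guided move toward (or away from) a target devil
#'
#' If the target is fitter than the current position, the devil moves
#' toward it with a per-dimension uniform step, the attraction sharpened
#' by the intensity integer `I`; if the target is no better, the devil
#' moves away from it. Per dimension `k` with `S ~ U(0,1)`:
#' toward: `x_k + S * (target_k - I * x_k)`;
#' away: `x_k + S * (x_k - target_k)`.
#'
#' @param x Current position.
#' @param target Target position (carrion or prey).
#' @param f_x Fitness of `x`.
#' @param f_target Fitness of `target`.
#' @param I Intensity, 1 or 2.
#' @param S Optional fixed step multipliers (length 1 or `length(x)`);
#'   drawn uniformly per dimension when `NULL`. Supplying `S` makes the
#'   move deterministic, which the unit tests use.
#' @return The proposed position (not yet clamped to bounds).
#' @export
tdo_guided_move <- function(x, target, f_x, f_target, I, S = NULL) {
  if (length(x) != length(target)) {
    stop("shape error: x and target must have the same length",
         call. = FALSE)
  }
  if (!I %in% c(1, 2)) {
    stop("intensity I must be 1 or 2", call. = FALSE)
  }
  if (is.null(S)) S <- stats::runif(length(x))
  S <- rep_len(S, length(x))
  if (f_target < f_x) {
    x + S * (target - I * x)
  } else {
    x + S * (x - target)
  }
}

#' Shrinking local-search radius
#'
#' The neighbourhood radius of the exploitation-phase local search decays
#' linearly from 0.01 at the first iteration to 0 at the last:
#' `s = 0.01 * (1 - t / T)`.
#'
#' @param t Current iteration, `0 <= t <= T`.
#' @param T_max Total iteration count.
#' @return Radius in `[0, 0.01]`.
#' @export
local_search_radius <- function(t, T_max) {
  if (T_max < 1) stop("T_max must be at least 1", call. = FALSE)
  if (any(t < 0) || any(t > T_max)) {
    stop("iteration t out of range 0..T_max", call. = FALSE)
  }
  0.01 * (1 - t / T_max)
}

#' Multiplicative local-search perturbation
#'
#' Each coordinate is perturbed within a relative neighbourhood of size
#' `s`: `x_k * (1 + (2 r_k - 1) * s)` with `r_k ~ U(0,1)`. A zero
#' coordinate is left unchanged (the neighbourhood is multiplicative).
#'
#' @param x Position vector.
#' @param s Radius, `s >= 0`.
#' @param r Optional fixed uniforms for deterministic testing.
#' @return Perturbed position.
#' @export
local_search_move <- function(x, s, r = NULL) {
  if (s < 0) stop("radius s must be non-negative", call. = FALSE)
  if (is.null(r)) r <- stats::runif(length(x))
  r <- rep_len(r, length(x))
  x + (2 * r - 1) * s * x
}

#' Minimize a continuous objective with the Tasmanian devil optimizer
#'
#' Population-based search alternating an exploration phase (move relative
#' to a randomly chosen carrion member) and an exploitation phase (move
#' relative to a randomly chosen prey member, followed by a local search
#' in a neighbourhood that shrinks over iterations). Every candidate move
#' is accepted only if it strictly improves the devil's fitness, so the
#' population best never degrades. Positions are clamped to the box
#' bounds before evaluation.
#'
#' @param objective An `"objective"` object ([objective_function()] or
#'   [benchmark_function()]).
#' @param bounds A [bounds()] object matching the problem dimension.
#' @param config A [tdo_config()].
#' @return An `"opt_result"` with the best position, fitness, a
#'   non-increasing best-so-far trace, and the evaluation count.
#' @export
tdo_minimize <- function(objective, bounds, config = tdo_config()) {
  b <- as_bounds(bounds)
  cfg <- config
  if (!inherits(cfg, "tdo_config")) stop("config must be a tdo_config()",
                                         call. = FALSE)
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
    best_idx <- which.min(fit)
    best_pos <- pos[best_idx, ]
    best_fit <- fit[best_idx]
    trace <- numeric(cfg$iterations)
    for (t in seq_len(cfg$iterations)) {
      if (n_evals >= cfg$max_evals) {
        trace[t:cfg$iterations] <- best_fit
        break
      }
      for (j in seq_len(cfg$pop_size)) {
        if (n_evals >= cfg$max_evals) break
        explore <- stats::runif(1) < cfg$p_explore
        other <- select_random_other(j, cfg$pop_size)
        I <- sample(1:2, 1L)
        cand <- tdo_guided_move(pos[j, ], pos[other, ], fit[j], fit[other], I)
        cand <- clamp_to_bounds(cand, b)
        f_cand <- evaluate(cand)
        if (f_cand < fit[j]) {
          pos[j, ] <- cand
          fit[j] <- f_cand
        }
        if (!explore && n_evals < cfg$max_evals) {
          s <- local_search_radius(t, cfg$iterations)
          cand <- local_search_move(pos[j, ], s)
          cand <- clamp_to_bounds(cand, b)
          f_cand <- evaluate(cand)
          if (f_cand < fit[j]) {
            pos[j, ] <- cand
            fit[j] <- f_cand
          }
        }
        if (fit[j] < best_fit) {
          best_fit <- fit[j]
          best_pos <- pos[j, ]
        }
      }
      trace[t] <- best_fit
    }
    opt_result(best_pos, best_fit, trace, n_evals, cfg$seed, "tdo")
  })
}
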