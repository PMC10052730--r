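#' Box bounds for a continuous search space
#'
#' Per-dimension lower and upper limits in the units of the decision
#' variables. Scalars are recycled to `dim` dimensions.
#'
#' @param lower Numeric vector of lower limits (or scalar).
#' @param upper Numeric vector of upper limits (or scalar).
#' @param dim Optional dimension count used to recycle scalar limits.
#' @return An object of class `"bounds"` with elements `lower`, `upper`
#'   and `dim`.
#' @examples
#' bounds(-5, 5, dim = 10)
#' bounds(c(0, 0), c(1, 2))
#' @export
bounds <- function(lower, upper, dim = NULL) {
  if (!is.null(dim)) {
    stopifnot(length(dim) == 1L, dim >= 1L)
    if (length(lower) == 1L) lower <- rep_len(lower, dim)
    if (length(upper) == 1L) upper <- rep_len(upper, dim)
  }
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length", call. = FALSE)
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("bounds must be finite", call. = FALSE)
  }
  if (any(lower >= upper)) {
    stop("invalid bounds: need lower < upper in every dimension",
         call. = FALSE)
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 dim = length(lower)),
            class = "bounds")
}

as_bounds <- function(x, dim = NULL) {
  if (inherits(x, "bounds")) {
    if (!is.null(dim) && x$dim != dim) {
      stop("bounds dimension (", x$dim, ") does not match problem dimension (",
           dim, ")", call. = FALSE)
    }
    return(x)
  }
  stop("expected a 'bounds' object; see bounds()", call. = FALSE)
}

clamp_to_bounds <- function(x, b) {
  pmin(pmax(x, b$lower), b$upper)
}

#' Define a scalar objective function for minimization
#'
#' Wraps an R function into the objective contract used by all the
#' optimizers in the package: a deterministic map from a numeric position
#' vector to a finite scalar, smaller being better.
#'
#' @param fn Function taking a numeric vector and returning a scalar.
#' @param dim Problem dimension (arity); `NA` if the function accepts any.
#' @param name Optional display name.
#' @return An object of class `"objective"`.
#' @seealso [benchmark_function()]
#' @export
objective_function <- function(fn, dim = NA_integer_, name = "objective") {
  stopifnot(is.function(fn))
  structure(list(fn = fn, dim = as.integer(dim), name = name),
            class = "objective")
}

eval_objective <- function(obj, x) {
  val <- obj$fn(x)
  if (!is.finite(val)) {
    stop("objective '", obj$name, "' returned a non-finite value",
         call. = FALSE)
  }
  as.numeric(val)
}

#' Standard benchmark objective functions
#'
#' Closed-form test functions with known global minimum 0: `sphere`
#' (minimum at the origin), `rastrigin` (multimodal, minimum at the
#' origin) and `rosenbrock` (minimum at the all-ones vector).
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @return An `"objective"` object usable with any dimension.
#' @examples
#' f <- benchmark_function("sphere")
#' f$fn(c(1, 2, 3))  # 14
#' @export
benchmark_function <- function(name) {
  fn <- switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      n <- length(x)
      if (n < 2) return((1 - x[1])^2)
      sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
    },
    stop("unknown benchmark function: '", name, "'", call. = FALSE)
  )
  objective_function(fn, dim = NA_integer_, name = name)
}

## Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific sub-seed from a master seed
#'
#' The pipeline splits one master seed into independent per-stage seeds
#' (cohort generation, splitting, feature selection, training) so a stage
#' can be re-run in isolation without reshuffling the others. The map is a
#' deterministic integer hash of the seed and a stage tag, folded into the
#' 32-bit positive range accepted by [set.seed()].
#'
#' @param seed Master seed (integer).
#' @param tag Character stage tag.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Initialize a uniform random population
#'
#' Draws `pop_size` positions independently and uniformly within the box
#' bounds, and evaluates the objective for each row. The same seed
#' reproduces the population exactly.
#'
#' @param bounds A [bounds()] object.
#' @param pop_size Number of candidate solutions (at least 2).
#' @param seed Integer seed.
#' @param objective Optional `"objective"` object; if supplied, the fitness
#'   vector is evaluated for all rows (otherwise it is `NA`).
#' @return A list of class `"population"` with elements `positions`
#'   (`pop_size x dim` matrix), `fitness` (length `pop_size`) and `bounds`.
#' @export
initialize_population <- function(bounds, pop_size, seed, objective = NULL) {
  b <- as_bounds(bounds)
  if (length(pop_size) != 1L || pop_size < 2) {
    stop("invalid configuration: pop_size must be at least 2", call. = FALSE)
  }
  pop_size <- as.integer(pop_size)
  pos <- with_seed(seed, {
    matrix(stats::runif(pop_size * b$dim), nrow = pop_size) *
      rep(b$upper - b$lower, each = pop_size) +
      rep(b$lower, each = pop_size)
  })
  fit <- rep(NA_real_, pop_size)
  if (!is.null(objective)) {
    fit <- apply(pos, 1L, function(x) eval_objective(objective, x))
  }
  structure(list(positions = pos, fitness = fit, bounds = b),
            class = "population")
}

## Optimization result container shared by all optimizers.
opt_result <- function(best_position, best_fitness, trace, evaluations, seed,
                       algorithm) {
  stopifnot(length(best_fitness) == 1L)
  if (any(diff(trace) > 1e-12)) {
    stop("internal error: best-so-far trace must be non-increasing",
         call. = FALSE)
  }
  structure(list(best_position = as.numeric(best_position),
                 best_fitness = as.numeric(best_fitness),
                 trace = as.numeric(trace),
                 iterations = length(trace),
                 evaluations = as.integer(evaluations),
                 seed = seed,
                 algorithm = algorithm),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result: %s>\n", x$algorithm))
  cat(sprintf("  best fitness: %.6g after %d iterations (%d evaluations)\n",
              x$best_fitness, x$iterations, x$evaluations))
  cat(sprintf("  dimension: %d, seed: %s\n",
              length(x$best_position), format(x$seed)))
  invisible(x)
}
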