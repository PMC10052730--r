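default_pipeline_config <- function() {
  list(
    cohort = list(n = 400L, separation = 3, missing_rate = 0.3,
                  weights = c(asthma = 0.25, copd = 0.25, infected = 0.25,
                              healthy = 0.25)),
    split = list(train_frac = 0.7),
    tdo = list(pop_size = 20L, iterations = 60L, alpha = 0.9,
               cv_folds = 3L, p_explore = 0.5),
    igwo = list(pop_size = 30L, iterations = 400L, p_sc = 0.3, n_starts = 3L,
                sigma0 = 0.3, sigma_min = 1e-4,
                weights = c(0.5, 0.3, 0.2)),
    network = list(filters = 4L, kernel = 3L, hidden = 8L,
                   param_bound = 3),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("configuration error: config must be a list or a YAML file path",
         call. = FALSE)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (is.null(cfg$seed)) {
    stop("configuration error: missing key 'seed'", call. = FALSE)
  }
  if (is.null(cfg$cohort_csv) && is.null(cfg$cohort)) {
    stop("configuration error: missing key 'cohort' or 'cohort_csv'",
         call. = FALSE)
  }
  cfg
}

#' Run the full diagnosis pipeline
#'
#' Load (or generate) a cohort, impute missing values, encode and scale
#' features, split 70/30 stratified by diagnosis, select features on the
#' training set with the Tasmanian devil wrapper, train the
#' convolutional classifier on the selected features with IGWO, predict
#' the held-out set and report diagnostic metrics under both the
#' canonical and the as-printed conventions. The master seed is split
#' into independent per-stage sub-seeds (cohort / split / selection /
#' training), so changing one stage's settings does not reshuffle the
#' others. Feature selection sees only training rows; the resulting mask
#' is then applied to the test rows.
#'
#' @param config A configuration list, or the path to a YAML file with
#'   the same structure. Keys: `cohort` (generator settings `n`,
#'   `separation`, `missing_rate`, `weights`) or `cohort_csv` (path to a
#'   cohort CSV), `split`, `tdo`, `igwo`, `network`, and the master
#'   `seed`. Unspecified keys fall back to package defaults.
#' @param out Optional path; when given, the report is written there as
#'   JSON.
#' @return A list of class `"pipeline_report"`: selected features,
#'   held-out metrics under both conventions, training summary and the
#'   per-stage seeds.
#' @export
run_pipeline <- function(config = list(), out = NULL) {
  cfg <- read_pipeline_config(config)
  seeds <- list(cohort = derive_seed(cfg$seed, "cohort"),
                split = derive_seed(cfg$seed, "split"),
                select = derive_seed(cfg$seed, "select"),
                train = derive_seed(cfg$seed, "train"))
  if (!is.null(cfg$cohort_csv)) {
    tab <- read_cohort(cfg$cohort_csv)
  } else {
    spec <- cohort_spec(n = cfg$cohort$n,
                        weights = unlist(cfg$cohort$weights),
                        separation = cfg$cohort$separation,
                        missing_rate = cfg$cohort$missing_rate,
                        seed = seeds$cohort)
    tab <- generate_cohort(spec)
  }
  tab <- impute_missing(tab)
  split <- stratified_split(tab$diagnosis, cfg$split$train_frac,
                            seed = seeds$split)
  prep_train <- prepare_features(tab[split$train, , drop = FALSE])
  prep_test <- prepare_features(tab[split$test, , drop = FALSE],
                                scaling = prep_train$scaling)
  mask <- tdo_select_features(
    prep_train$X, prep_train$y,
    alpha = cfg$tdo$alpha, cv_folds = cfg$tdo$cv_folds,
    config = tdo_config(pop_size = cfg$tdo$pop_size,
                        iterations = cfg$tdo$iterations,
                        p_explore = cfg$tdo$p_explore,
                        seed = seeds$select))
  sel <- mask$selected
  if (sum(sel) < cfg$network$kernel + 1L) {
    ## too few columns for the conv/pool stack; fall back to all features
    sel <- rep(TRUE, ncol(prep_train$X))
  }
  X_train <- prep_train$X[, sel, drop = FALSE]
  X_test <- prep_test$X[, sel, drop = FALSE]
  spec <- network_spec(input_len = ncol(X_train),
                       filters = cfg$network$filters,
                       kernel = cfg$network$kernel,
                       hidden = cfg$network$hidden,
                       classes = length(cohort_classes))
  w <- cfg$igwo$weights
  model <- train_with_igwo(
    spec, X_train, prep_train$y,
    config = igwo_config(pop_size = cfg$igwo$pop_size,
                         iterations = cfg$igwo$iterations,
                         weights = leader_weights(w[1], w[2], w[3]),
                         sigma0 = cfg$igwo$sigma0,
                         sigma_min = cfg$igwo$sigma_min,
                         p_sc = cfg$igwo$p_sc,
                         seed = seeds$train),
    param_bound = cfg$network$param_bound,
    n_starts = if (is.null(cfg$igwo$n_starts)) 1L else cfg$igwo$n_starts)
  pred_test <- predict(model, X_test)
  pred_train <- predict(model, X_train)
  report <- structure(list(
    seeds = seeds,
    n = nrow(tab),
    selected_features = mask$names,
    used_features = colnames(X_train),
    selection_fitness = mask$fitness,
    training_loss = model$result$best_fitness,
    train_accuracy = mean(pred_train == as.character(prep_train$y)),
    metrics = list(
      canonical = macro_report(as.character(prep_test$y), pred_test,
                               classes = cohort_classes,
                               convention = "canonical"),
      as_printed = macro_report(as.character(prep_test$y), pred_test,
                                classes = cohort_classes,
                                convention = "as_printed")
    ),
    model = model
  ), class = "pipeline_report")
  if (!is.null(out)) {
    js <- jsonlite::toJSON(list(
      seeds = seeds,
      n = report$n,
      selected_features = report$selected_features,
      used_features = report$used_features,
      selection_fitness = report$selection_fitness,
      training_loss = report$training_loss,
      train_accuracy = report$train_accuracy,
      test_accuracy = report$metrics$canonical$overall_accuracy,
      metrics = list(
        canonical = jsonlite::fromJSON(report_json(
          report$metrics$canonical)),
        as_printed = jsonlite::fromJSON(report_json(
          report$metrics$as_printed))
      )
    ), auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    writeLines(js, out)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  n = %d, features used: %s\n", x$n,
              paste(x$used_features, collapse = ", ")))
  cat(sprintf("  training loss %.4f, training accuracy %.4f\n",
              x$training_loss, x$train_accuracy))
  cat(sprintf("  held-out accuracy %.4f\n",
              x$metrics$canonical$overall_accuracy))
  print(x$metrics$canonical)
  invisible(x)
}

#' Benchmark the optimizers on standard test functions
#'
#' Runs each requested algorithm on each benchmark function for every
#' seed and collects the final best fitness and the number of objective
#' evaluations. All algorithms receive the same evaluation budget
#' (`pop * iters` plus initialization), enforced through their
#' `max_evals` cap, so comparisons are budget-fair.
#'
#' @param functions Character vector of [benchmark_function()] names.
#' @param algorithms Subset of `c("gwo", "igwo", "tdo")`.
#' @param dim Problem dimension.
#' @param pop_size Population size.
#' @param iterations Iteration count defining the budget.
#' @param seeds Integer vector of seeds (one run per seed).
#' @param lower,upper Box bounds applied in every dimension.
#' @return A data frame with columns `fn`, `algorithm`, `dim`, `seed`,
#'   `best_fitness`, `evaluations`; the per-function-per-algorithm
#'   medians are attached as attribute `"summary"`.
#' @export
benchmark_optimizers <- function(functions = c("sphere", "rastrigin"),
                                 algorithms = c("gwo", "igwo"),
                                 dim = 10L, pop_size = 30L,
                                 iterations = 200L, seeds = 1:20,
                                 lower = -5, upper = 5) {
  algorithms <- match.arg(algorithms, c("gwo", "igwo", "tdo"),
                          several.ok = TRUE)
  b <- bounds(lower, upper, dim = dim)
  budget <- pop_size * iterations + pop_size
  rows <- list()
  for (fn_name in functions) {
    obj <- benchmark_function(fn_name)
    for (alg in algorithms) {
      for (s in seeds) {
        res <- switch(alg,
          gwo = gwo_minimize(obj, b,
            igwo_config(pop_size = pop_size, iterations = iterations,
                        seed = s, max_evals = budget)),
          igwo = igwo_minimize(obj, b,
            igwo_config(pop_size = pop_size, iterations = iterations,
                        seed = s, max_evals = budget)),
          tdo = tdo_minimize(obj, b,
            tdo_config(pop_size = pop_size,
                       iterations = as.integer(ceiling(
                         1.5 * iterations)),
                       seed = s, max_evals = budget))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          fn = fn_name, algorithm = alg, dim = dim, seed = s,
          best_fitness = res$best_fitness,
          evaluations = res$evaluations,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(fn = character(), algorithm = character(),
               dim = integer(), seed = integer(),
               best_fitness = numeric(), evaluations = integer(),
               stringsAsFactors = FALSE)
  }
  if (nrow(out)) {
    summ <- stats::aggregate(best_fitness ~ fn + algorithm, data = out,
                             FUN = stats::median)
    names(summ)[names(summ) == "best_fitness"] <- "median_best_fitness"
    attr(out, "summary") <- summ
  }
  out
}
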