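#' Specification of a synthetic four-group respiratory cohort
#'
#' Describes a cohort emulating the structure of a small
#' saliva-permittivity respiratory dataset: four diagnosis groups
#' (asthma, COPD, infected, healthy), four class-dependent numeric
#' features, demographic fields, and missing numeric cells.
#'
#' @param n Number of patients.
#' @param weights Named class weights over
#'   `asthma`, `copd`, `infected`, `healthy`; must sum to 1.
#' @param separation Distance between class means in units of the
#'   within-class standard deviation (see [generate_cohort()] for the
#'   exact geometry).
#' @param missing_rate Probability that a numeric feature cell is
#'   missing, in `[0, 1)`.
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n = 400L,
                        weights = c(asthma = 0.25, copd = 0.25,
                                    infected = 0.25, healthy = 0.25),
                        separation = 3, missing_rate = 0.3, seed = 1L) {
  if (!setequal(names(weights), cohort_classes)) {
    stop("configuration error: weights must be named ",
         paste(cohort_classes, collapse = ", "), call. = FALSE)
  }
  weights <- weights[cohort_classes]
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
    stop("configuration error: weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (separation < 0) {
    stop("configuration error: separation must be >= 0", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("configuration error: missing_rate must lie in [0, 1)",
         call. = FALSE)
  }
  structure(list(n = as.integer(n), weights = weights,
                 separation = as.numeric(separation),
                 missing_rate = as.numeric(missing_rate), seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' Diagnoses are drawn multinomially from the class weights. Each of the
#' four numeric features has unit within-class standard deviation; class
#' `c` elevates its characteristic feature `c` by `separation` (its mean
#' is `separation` there and 0 elsewhere), so every pair of classes is
#' `sqrt(2) * separation` standard deviations apart in feature space. Age is uniform on 20..80, gender and smoking have
#' fixed marginals (50/50 and 50/30/20), and each numeric cell is blanked
#' independently with probability `missing_rate`. The generating class
#' means are attached as the `"class_means"` attribute so downstream
#' tests are self-describing.
#'
#' @param spec A [cohort_spec()].
#' @return A cohort data frame in the schema of [read_cohort()].
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- length(cohort_classes)
  means <- diag(spec$separation, k)  # class c mean over the 4 features
  dimnames(means) <- list(cohort_classes, cohort_numeric_cols)
  with_seed(spec$seed, {
    diagnosis <- sample(cohort_classes, spec$n, replace = TRUE,
                        prob = spec$weights)
    ci <- match(diagnosis, cohort_classes)
    feat <- means[ci, , drop = FALSE] +
      matrix(stats::rnorm(spec$n * k), nrow = spec$n)
    if (spec$missing_rate > 0) {
      blank <- matrix(stats::runif(spec$n * k) < spec$missing_rate,
                      nrow = spec$n)
      feat[blank] <- NA_real_
    }
    tab <- data.frame(
      patient_id = sprintf("P%04d", seq_len(spec$n)),
      diagnosis = diagnosis,
      age = sample(20:80, spec$n, replace = TRUE),
      gender = sample(cohort_gender_levels, spec$n, replace = TRUE,
                      prob = c(0.5, 0.5)),
      smoking = sample(cohort_smoking_levels, spec$n, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)),
      stringsAsFactors = FALSE
    )
    tab[cohort_numeric_cols] <- as.data.frame(feat)
    attr(tab, "class_means") <- means
    attr(tab, "cohort_spec") <- spec
    tab
  })
}

#' Generate a planted-feature classification dataset
#'
#' Fixture for feature-selection recovery tests: `d_informative` columns
#' carry class-dependent Gaussian means while the remaining columns are
#' pure standard-normal noise. Informative column `j` (in cycling order
#' over classes) gives class `((j - 1) mod n_classes) + 1` a mean of
#' `separation` and all other classes mean 0 (unit within-class sd), so
#' whenever every class owns at least one column the minimum distance
#' between class means over the full informative set is
#' `separation` to `sqrt(2) * separation` standard deviations. Which columns are informative is randomized and
#' returned as ground truth.
#'
#' @param n Number of samples (balanced over classes).
#' @param d Total number of feature columns.
#' @param d_informative Number of informative columns, `<= d`.
#' @param n_classes Number of classes.
#' @param separation Per-column effect size in within-class standard
#'   deviations.
#' @param seed Integer seed.
#' @return List with `X` (n x d matrix), `y` (factor), and `informative`
#'   (integer indices of the planted columns).
#' @export
generate_separable <- function(n, d, d_informative, n_classes = 4L,
                               separation = 4, seed = 1L) {
  if (d_informative > d) {
    stop("configuration error: d_informative must be <= d", call. = FALSE)
  }
  if (n < 10 * n_classes) {
    stop("configuration error: need n >= 10 * n_classes", call. = FALSE)
  }
  if (separation < 0) {
    stop("configuration error: separation must be >= 0", call. = FALSE)
  }
  delta <- separation
  with_seed(seed, {
    y <- factor(sample(rep_len(paste0("class", seq_len(n_classes)), n)))
    ci <- as.integer(y)
    informative <- sort(sample.int(d, d_informative))
    X <- matrix(stats::rnorm(n * d), nrow = n)
    if (d_informative > 0) {
      for (jj in seq_len(d_informative)) {
        owner <- (jj - 1L) %% n_classes + 1L
        X[ci == owner, informative[jj]] <-
          X[ci == owner, informative[jj]] + delta
      }
    }
    colnames(X) <- paste0("f", seq_len(d))
    list(X = X, y = y, informative = informative)
  })
}
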