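## Wrapper feature selection: TDO searches [0,1]^d, positions are
## thresholded at 0.5 into boolean masks, and each mask is scored by the
## cross-validated error of a 1-nearest-neighbour reference classifier
## plus a sparsity term.

#' Fitness of a candidate feature mask
#'
#' Weighted sum of the stratified k-fold cross-validated error of a
#' 1-nearest-neighbour classifier restricted to the masked columns, and a
#' sparsity term (fraction of features kept):
#' `alpha * cv_error + (1 - alpha) * n_selected / d`.
#' An empty mask receives fitness 2, worse than any feasible value.
#'
#' @param mask Logical vector over feature columns.
#' @param features Numeric matrix (samples x features).
#' @param labels Class labels (factor or coercible).
#' @param alpha Weight on the error term, in `[0, 1]`.
#' @param folds Fold assignment vector as produced by
#'   [stratified_folds()], or a fold count (stratified folds are then
#'   built deterministically from `seed`).
#' @param seed Seed used only when `folds` is a count.
#' @return Scalar fitness (smaller is better).
#' @export
feature_selection_fitness <- function(mask, features, labels, alpha = 0.9,
                                      folds = 3L, seed = 1L) {
  mask <- as.logical(mask)
  d <- ncol(features)
  stopifnot(length(mask) == d)
  if (!any(mask)) return(2.0)
  if (length(folds) == 1L) {
    folds <- stratified_folds(labels, folds, seed = seed)
  }
  err <- knn1_cv_error(features[, mask, drop = FALSE], labels, folds)
  alpha * err + (1 - alpha) * sum(mask) / d
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each sample to one of `k` folds so that every class is spread
#' as evenly as possible across folds; the within-class assignment is a
#' seeded shuffle.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

## Cross-validated error of a 1-NN classifier (reference wrapper model).
knn1_cv_error <- function(X, y, folds) {
  y <- as.factor(y)
  wrong <- 0L
  for (f in sort(unique(folds))) {
    test <- folds == f
    pred <- class::knn(train = X[!test, , drop = FALSE],
                       test = X[test, , drop = FALSE],
                       cl = y[!test], k = 1L)
    wrong <- wrong + sum(pred != y[test])
  }
  wrong / length(y)
}

#' Select diagnosis-relevant features with the Tasmanian devil optimizer
#'
#' Runs [tdo_minimize()] over the continuous relaxation `[0,1]^d` of the
#' subset lattice; a position is binarized at 0.5 into a feature mask and
#' scored with [feature_selection_fitness()]. Mask fitness values are
#' memoized, so the cost is governed by the number of distinct masks
#' visited rather than raw objective evaluations.
#'
#' @param features Numeric matrix (samples x features) or data frame.
#' @param labels Class labels; at least two distinct classes required.
#' @param alpha Weight on the classification-error term (`1 - alpha`
#'   weights sparsity).
#' @param cv_folds Number of stratified cross-validation folds.
#' @param config A [tdo_config()] controlling the search.
#' @return An object of class `"feature_mask"`: logical `selected` over
#'   columns, the `position` it was thresholded from, the achieved
#'   `fitness`, selected column `names`, and the search `result`.
#' @export
tdo_select_features <- function(features, labels, alpha = 0.9, cv_folds = 3L,
                                config = tdo_config()) {
  features <- as.matrix(features)
  if (!is.numeric(features)) {
    stop("features must be numeric", call. = FALSE)
  }
  d <- ncol(features)
  if (d < 2) stop("need at least 2 feature columns", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("invalid labels: need at least two classes", call. = FALSE)
  }
  col_sds <- apply(features, 2L, stats::sd)
  if (all(col_sds == 0)) {
    warning("all feature columns are constant; selection is driven by the ",
            "sparsity term only")
  }
  folds <- stratified_folds(labels, cv_folds,
                            seed = derive_seed(config$seed, "cvfolds"))
  cache <- new.env(parent = emptyenv())
  obj <- objective_function(function(pos) {
    mask <- pos > 0.5
    key <- paste(as.integer(mask), collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- feature_selection_fitness(mask, features, labels, alpha, folds)
    cache[[key]] <- val
    val
  }, dim = d, name = "feature-selection")
  res <- tdo_minimize(obj, bounds(0, 1, dim = d), config)
  mask <- res$best_position > 0.5
  if (!any(mask)) {
    ## degenerate: search never left the empty mask; keep the single
    ## coordinate closest to the threshold so the contract (>= 1 feature)
    ## holds
    mask[which.max(res$best_position)] <- TRUE
  }
  cn <- colnames(features)
  if (is.null(cn)) cn <- paste0("V", seq_len(d))
  structure(list(selected = mask,
                 names = cn[mask],
                 position = res$best_position,
                 fitness = res$best_fitness,
                 n_selected = sum(mask),
                 result = res),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask: %d of %d features, fitness %.4f>\n",
              x$n_selected, length(x$selected), x$fitness))
  cat("  selected:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a feature mask to JSON
#'
#' @param x A `"feature_mask"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
feature_mask_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "feature_mask"))
  js <- jsonlite::toJSON(list(selected = x$names,
                              position = x$position),
                         auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
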