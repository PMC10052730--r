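#' One-vs-rest confusion counts
#'
#' Tallies true positives `gp`, true negatives `gf`, false positives
#' `hp` and false negatives `hf` of predictions with respect to one
#' positive class.
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param positive_class The label treated as positive.
#' @return An object of class `"confusion_counts"`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop("shape error: y_true and y_pred must have the same length",
         call. = FALSE)
  }
  tp <- y_true == positive_class
  pp <- y_pred == positive_class
  structure(list(gp = sum(tp & pp),     # true positive
                 gf = sum(!tp & !pp),   # true negative
                 hp = sum(!tp & pp),    # false positive
                 hf = sum(tp & !pp)),   # false negative
            class = "confusion_counts")
}

ratio_or_na <- function(num, den) {
  if (den == 0) NA_real_ else num / den
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `gp/(gp+hf)`, accuracy `(gp+gf)/n` and precision (PPV)
#' `gp/(gp+hp)` are common to both conventions. Under `"canonical"`,
#' specificity is `gf/(gf+hp)`, prevalence `(gp+hf)/n` and NPV
#' `gf/(gf+hf)` — the standard epidemiological definitions. Under
#' `"as_printed"`, specificity is `gf/(gf+hf)`, prevalence `(gp+gf)/n`
#' (identical to accuracy) and NPV `gf/(gf+hp)`, reproducing a published
#' formula set in which the specificity/NPV denominators are swapped and
#' prevalence duplicates the accuracy formula. A metric with a zero
#' denominator is reported as `NA` (undefined), never silently 0.
#'
#' @param counts A [confusion_counts()] object.
#' @param convention `"canonical"` (default) or `"as_printed"`.
#' @return A list of class `"metrics_report"` with `sensitivity`,
#'   `specificity`, `accuracy`, `precision`, `ppv`, `prevalence`, `npv`
#'   and the `convention` tag.
#' @export
binary_metrics <- function(counts,
                           convention = c("canonical", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(counts, "confusion_counts"))
  gp <- counts$gp; gf <- counts$gf; hp <- counts$hp; hf <- counts$hf
  n <- gp + gf + hp + hf
  sens <- ratio_or_na(gp, gp + hf)
  acc <- ratio_or_na(gp + gf, n)
  prec <- ratio_or_na(gp, gp + hp)
  if (convention == "canonical") {
    spec <- ratio_or_na(gf, gf + hp)
    prev <- ratio_or_na(gp + hf, n)
    npv <- ratio_or_na(gf, gf + hf)
  } else {
    spec <- ratio_or_na(gf, gf + hf)
    prev <- ratio_or_na(gp + gf, n)
    npv <- ratio_or_na(gf, gf + hp)
  }
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 precision = prec, ppv = prec, prevalence = prev, npv = npv,
                 convention = convention),
            class = "metrics_report")
}

metric_names <- c("sensitivity", "specificity", "accuracy", "precision",
                  "ppv", "prevalence", "npv")

#' Per-class and macro-averaged multiclass metrics
#'
#' Computes one-vs-rest [binary_metrics()] for every class and the
#' unweighted (macro) mean of each metric over classes, skipping
#' undefined (`NA`) values. `overall_accuracy` is the plain multiclass
#' classification accuracy `mean(y_pred == y_true)`.
#'
#' @param y_true,y_pred Label vectors.
#' @param classes Class labels covering all observed labels; defaults to
#'   the sorted union of observed labels.
#' @param convention Metric convention, see [binary_metrics()].
#' @return A list of class `"macro_report"` with `per_class` (named list
#'   of `"metrics_report"`), `macro` (named numeric vector),
#'   `overall_accuracy` and `convention`.
#' @export
macro_report <- function(y_true, y_pred, classes = NULL,
                         convention = c("canonical", "as_printed")) {
  convention <- match.arg(convention)
  if (length(y_true) != length(y_pred)) {
    stop("shape error: y_true and y_pred must have the same length",
         call. = FALSE)
  }
  observed <- unique(c(as.character(y_true), as.character(y_pred)))
  if (is.null(classes)) classes <- sort(observed)
  outside <- setdiff(observed, as.character(classes))
  if (length(outside)) {
    stop("label error: observed label '", outside[1],
         "' not in `classes`", call. = FALSE)
  }
  per_class <- lapply(classes, function(cl) {
    binary_metrics(confusion_counts(y_true, y_pred, cl), convention)
  })
  names(per_class) <- classes
  macro <- vapply(metric_names, function(m) {
    vals <- vapply(per_class, function(r) r[[m]], numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  structure(list(per_class = per_class,
                 macro = macro,
                 overall_accuracy = mean(as.character(y_pred) ==
                                           as.character(y_true)),
                 convention = convention),
            class = "macro_report")
}

#' @export
print.macro_report <- function(x, ...) {
  cat(sprintf("<macro_report: %s convention, %d classes>\n",
              x$convention, length(x$per_class)))
  cat(sprintf("  overall accuracy: %.4f\n", x$overall_accuracy))
  m <- x$macro
  for (nm in names(m)) {
    cat(sprintf("  macro %-11s %s\n", paste0(nm, ":"),
                ifelse(is.na(m[[nm]]), "undefined", sprintf("%.4f",
                                                            m[[nm]]))))
  }
  invisible(x)
}

#' Serialize a macro report to JSON
#'
#' @param x A `"macro_report"`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "macro_report"))
  js <- jsonlite::toJSON(list(
    convention = x$convention,
    overall_accuracy = x$overall_accuracy,
    macro = as.list(x$macro),
    per_class = lapply(x$per_class, function(r) unclass(r))
  ), auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
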