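## Cohort table schema shared by the generator, the CSV reader/writer and
## the feature preparation step.
cohort_numeric_cols <- c("im_min", "im_avg", "re_min", "re_avg")
cohort_classes <- c("asthma", "copd", "infected", "healthy")
cohort_gender_levels <- c("M", "F")
cohort_smoking_levels <- c("non", "ex", "active")

#' Read / write a cohort table as CSV
#'
#' The schema has columns `patient_id`, `diagnosis` (one of `asthma`,
#' `copd`, `infected`, `healthy`), `age`, `gender` (`M`/`F`), `smoking`
#' (`non`/`ex`/`active`) and four saliva-permittivity-style numeric
#' features `im_min`, `im_avg`, `re_min`, `re_avg`. Empty cells encode
#' missing values.
#'
#' @param path CSV file path.
#' @return A data frame in the cohort schema.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  required <- c("patient_id", "diagnosis", "age", "gender", "smoking",
                cohort_numeric_cols)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(tab$diagnosis)) {
    stop("diagnosis must be present for every row", call. = FALSE)
  }
  tab
}

#' @rdname read_cohort
#' @param table Cohort data frame.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Impute missing cells with class-conditional medians and modes
#'
#' Numeric missing cells are replaced by the median of the same column
#' within the same diagnosis class; if a class has no observed value in
#' that column, the global column median is used. Missing categorical
#' cells get the within-class mode (global mode as fallback). Observed
#' cells are never altered.
#'
#' @param table Cohort data frame (the `diagnosis` column defines the
#'   classes).
#' @param class_col Name of the class column.
#' @return The table with no missing cells.
#' @export
impute_missing <- function(table, class_col = "diagnosis") {
  cls <- table[[class_col]]
  if (is.null(cls)) stop("missing class column '", class_col, "'",
                         call. = FALSE)
  for (col in setdiff(names(table), class_col)) {
    x <- table[[col]]
    if (!anyNA(x)) next
    if (all(is.na(x))) {
      stop("unimputable column '", col, "': no observed values",
           call. = FALSE)
    }
    if (is.numeric(x)) {
      global <- stats::median(x, na.rm = TRUE)
      fill_of <- function(v) {
        if (all(is.na(v))) global else stats::median(v, na.rm = TRUE)
      }
    } else {
      mode_of <- function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA)
        tb <- table(v)
        names(tb)[which.max(tb)]
      }
      global <- mode_of(x)
      fill_of <- function(v) {
        m <- mode_of(v)
        if (is.na(m)) global else m
      }
    }
    for (g in unique(cls)) {
      in_g <- cls == g
      nas <- in_g & is.na(x)
      if (any(nas)) x[nas] <- fill_of(x[in_g])
    }
    table[[col]] <- x
  }
  table
}

#' Encode and scale a cohort table into a model matrix
#'
#' Numeric columns (the four permittivity-style features and age) are
#' z-scored; constant columns map to zeros. `gender` and `smoking` are
#' one-hot encoded over their fixed category sets. When `scaling` is
#' supplied (from a previous call on training data), its centers and
#' scales are reused, so test data is transformed with training-time
#' constants.
#'
#' @param table Imputed cohort data frame (no missing cells).
#' @param scaling Optional scaling constants from a previous call.
#' @return List with `X` (numeric matrix), `y` (factor of diagnoses in
#'   the fixed class order), `columns` (column names of `X`) and
#'   `scaling`.
#' @export
prepare_features <- function(table, scaling = NULL) {
  if (anyNA(table)) {
    stop("table has missing cells; run impute_missing() first",
         call. = FALSE)
  }
  bad <- setdiff(unique(table$gender), cohort_gender_levels)
  if (length(bad)) stop("category error: unseen gender level '", bad[1], "'",
                        call. = FALSE)
  bad <- setdiff(unique(table$smoking), cohort_smoking_levels)
  if (length(bad)) stop("category error: unseen smoking level '", bad[1],
                        "'", call. = FALSE)
  num_cols <- c(cohort_numeric_cols, "age")
  num <- as.matrix(table[num_cols])
  if (is.null(scaling)) {
    center <- colMeans(num)
    scale_ <- apply(num, 2L, stats::sd)
    scaling <- list(center = center, scale = scale_)
  }
  sc <- ifelse(scaling$scale > 0, scaling$scale, 1)
  num_z <- sweep(sweep(num, 2L, scaling$center), 2L, sc, "/")
  num_z[, scaling$scale == 0] <- 0  # zero-variance guard
  onehot <- function(v, levels, prefix) {
    m <- sapply(levels, function(l) as.numeric(v == l))
    colnames(m) <- paste0(prefix, "_", levels)
    m
  }
  X <- cbind(num_z[, cohort_numeric_cols, drop = FALSE],
             onehot(table$gender, cohort_gender_levels, "gender"),
             onehot(table$smoking, cohort_smoking_levels, "smoking"),
             age = num_z[, "age"])
  y <- factor(table$diagnosis, levels = cohort_classes)
  if (anyNA(y)) {
    stop("category error: diagnosis outside ",
         paste(cohort_classes, collapse = "/"), call. = FALSE)
  }
  list(X = X, y = y, columns = colnames(X), scaling = scaling)
}

#' Stratified train/test split
#'
#' Per class with `n_c` members, `floor(train_frac * n_c)` samples go to
#' the training set after a seeded within-class shuffle; the rest go to
#' the test set. Index sets are disjoint and their union covers all
#' samples.
#'
#' @param labels Class labels.
#' @param train_frac Training fraction (default 0.7, the conventional
#'   70/30 split).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_frac = 0.7, seed = 1L) {
  labels <- as.factor(labels)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1", call. = FALSE)
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("stratification error: every class needs at least 2 members",
         call. = FALSE)
  }
  train <- integer(0)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_train <- floor(train_frac * length(idx))
      train <- c(train, idx[seq_len(n_train)])
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
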