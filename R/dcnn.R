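#' Architecture of the compact tabular convolutional classifier
#'
#' A single valid 1-D convolution stage (stride 1) over the feature
#' vector, batch normalization with a learnable affine transform per
#' filter, ReLU, non-overlapping max-pooling of width 2, one
#' fully-connected ReLU hidden layer, and a linear output layer with
#' SoftMax over the classes.
#'
#' @param input_len Length `d` of the input feature vector.
#' @param filters Number of convolution filters `F`.
#' @param kernel Kernel width `J` (`J <= input_len`; the pooled length
#'   `floor((d - J + 1) / 2)` must be at least 1).
#' @param hidden Width `H` of the fully-connected hidden layer.
#' @param classes Number of output classes `C >= 2`.
#' @return An object of class `"network_spec"` with the derived conv
#'   output length and pooled length.
#' @export
network_spec <- function(input_len, filters = 4L, kernel = 3L, hidden = 8L,
                         classes = 4L) {
  if (filters < 1) stop("invalid spec: filters must be >= 1", call. = FALSE)
  if (hidden < 1) stop("invalid spec: hidden must be >= 1", call. = FALSE)
  if (classes < 2) stop("invalid spec: classes must be >= 2", call. = FALSE)
  if (kernel < 1 || kernel > input_len) {
    stop("invalid spec: kernel width must satisfy 1 <= J <= input_len",
         call. = FALSE)
  }
  conv_len <- input_len - kernel + 1L
  pooled_len <- conv_len %/% 2L
  if (pooled_len < 1) {
    stop("invalid spec: pooled length floor((d - J + 1)/2) must be >= 1",
         call. = FALSE)
  }
  structure(list(input_len = as.integer(input_len),
                 filters = as.integer(filters),
                 kernel = as.integer(kernel),
                 hidden = as.integer(hidden),
                 classes = as.integer(classes),
                 conv_len = as.integer(conv_len),
                 pooled_len = as.integer(pooled_len)),
            class = "network_spec")
}

#' Number of trainable parameters of a network
#'
#' `F*J + F` convolution weights and biases, `2F` batch-norm affine
#' parameters, `H * (F * pooled_len) + H` hidden-layer weights and
#' biases, and `C*H + C` output weights and biases.
#'
#' @param spec A [network_spec()].
#' @return Integer parameter count.
#' @export
parameter_count <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with(spec, {
    filters * kernel + filters +          # conv weights + biases
      2L * filters +                      # batch-norm scale + shift
      hidden * (filters * pooled_len) + hidden +  # FC hidden
      classes * hidden + classes          # output layer
  })
}

## Split a flat parameter vector into the layer tensors, in the fixed
## order: conv weights, conv biases, BN scales, BN shifts, hidden
## weights, hidden biases, output weights, output biases.
unflatten_params <- function(theta, spec) {
  p <- parameter_count(spec)
  if (length(theta) != p) {
    stop("shape error: expected ", p, " parameters, got ", length(theta),
         call. = FALSE)
  }
  i <- 0L
  take <- function(n) {
    out <- theta[(i + 1L):(i + n)]
    i <<- i + n
    out
  }
  with(spec, list(
    conv_w = matrix(take(filters * kernel), nrow = filters, byrow = TRUE),
    conv_b = take(filters),
    bn_scale = take(filters),
    bn_shift = take(filters),
    fc_w = matrix(take(hidden * filters * pooled_len), nrow = filters *
                    pooled_len),
    fc_b = take(hidden),
    out_w = matrix(take(classes * hidden), nrow = hidden),
    out_b = take(classes)
  ))
}

## Inverse of unflatten_params.
flatten_params <- function(layers, spec) {
  c(as.vector(t(layers$conv_w)), layers$conv_b,
    layers$bn_scale, layers$bn_shift,
    as.vector(layers$fc_w), layers$fc_b,
    as.vector(layers$out_w), layers$out_b)
}

## Convolution pre-activations for a whole sample matrix.
## Returns an array n x conv_len x filters.
conv_preact <- function(layers, spec, X) {
  n <- nrow(X)
  out <- array(0, dim = c(n, spec$conv_len, spec$filters))
  for (p in seq_len(spec$conv_len)) {
    window <- X[, p:(p + spec$kernel - 1L), drop = FALSE]
    out[, p, ] <- window %*% t(layers$conv_w) +
      rep(layers$conv_b, each = n)
  }
  out
}

#' Batch-normalization statistics of the convolution stage
#'
#' Per-filter mean and variance of the convolution pre-activations over a
#' sample matrix. The batch is the whole training set, so for fixed
#' parameters the statistics -- and hence the training objective -- are
#' deterministic. The statistics of the best parameter vector are stored
#' in the trained model and reused at prediction time.
#'
#' @param theta Flat parameter vector.
#' @param spec A [network_spec()].
#' @param X Sample matrix (n x input_len).
#' @return List with numeric vectors `mean` and `var` of length
#'   `filters`.
#' @export
conv_batch_stats <- function(theta, spec, X) {
  layers <- unflatten_params(theta, spec)
  z <- conv_preact(layers, spec, as_input_matrix(X, spec))
  m <- apply(z, 3L, mean)
  v <- apply(z, 3L, function(a) mean((a - mean(a))^2))
  list(mean = m, var = v)
}

as_input_matrix <- function(X, spec) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != spec$input_len) {
    stop("shape error: input has ", ncol(X), " columns, spec expects ",
         spec$input_len, call. = FALSE)
  }
  X
}

#' Forward pass: class probabilities for one or many samples
#'
#' Valid 1-D convolution, batch normalization with the supplied
#' statistics and the learnable affine scale/shift, ReLU, max-pooling of
#' width 2, fully-connected ReLU hidden layer, linear output and SoftMax.
#'
#' @param theta Flat parameter vector.
#' @param spec A [network_spec()].
#' @param X A feature vector of length `input_len` or a matrix with that
#'   many columns.
#' @param norm_stats Batch-norm statistics from [conv_batch_stats()]; if
#'   `NULL`, statistics are computed from `X` itself.
#' @return Matrix (n x classes) of probabilities; rows sum to 1.
#' @export
dcnn_forward <- function(theta, spec, X, norm_stats = NULL) {
  X <- as_input_matrix(X, spec)
  layers <- unflatten_params(theta, spec)
  n <- nrow(X)
  z <- conv_preact(layers, spec, X)
  if (is.null(norm_stats)) {
    norm_stats <- list(mean = apply(z, 3L, mean),
                       var = apply(z, 3L, function(a) mean((a - mean(a))^2)))
  }
  eps <- 1e-5
  act <- array(0, dim = dim(z))
  for (f in seq_len(spec$filters)) {
    zn <- (z[, , f] - norm_stats$mean[f]) / sqrt(norm_stats$var[f] + eps)
    act[, , f] <- pmax(zn * layers$bn_scale[f] + layers$bn_shift[f], 0)
  }
  ## non-overlapping max-pool of width 2 (a trailing odd position is
  ## dropped, matching the floor in parameter_count)
  pooled <- array(0, dim = c(n, spec$pooled_len, spec$filters))
  for (q in seq_len(spec$pooled_len)) {
    pooled[, q, ] <- pmax(act[, 2L * q - 1L, , drop = FALSE],
                          act[, 2L * q, , drop = FALSE])[, 1L, ]
  }
  flat <- matrix(pooled, nrow = n)  # position-major within filter blocks
  hidden <- pmax(flat %*% layers$fc_w + rep(layers$fc_b, each = n), 0)
  logits <- hidden %*% layers$out_w + rep(layers$out_b, each = n)
  ## numerically stable SoftMax
  logits <- logits - apply(logits, 1L, max)
  e <- exp(logits)
  e / rowSums(e)
}

#' Mean cross-entropy of the network on labelled data
#'
#' Mean over samples of `-log` probability assigned to the true class,
#' with probabilities floored at `1e-12`. This is the training objective
#' minimized by IGWO.
#'
#' @param theta Flat parameter vector.
#' @param spec A [network_spec()].
#' @param X Sample matrix.
#' @param y Labels (factor or coercible); levels define the class order.
#' @param norm_stats Batch-norm statistics (see [conv_batch_stats()]).
#' @param class_levels Optional explicit class ordering.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(theta, spec, X, y, norm_stats = NULL,
                               class_levels = NULL) {
  y <- as.factor(y)
  if (!is.null(class_levels)) {
    if (!all(levels(y) %in% class_levels)) {
      stop("label error: labels outside the model's classes", call. = FALSE)
    }
    y <- factor(y, levels = class_levels)
  }
  if (nlevels(y) > spec$classes) {
    stop("label error: more classes than network outputs", call. = FALSE)
  }
  probs <- dcnn_forward(theta, spec, X, norm_stats)
  idx <- cbind(seq_len(nrow(probs)), as.integer(y))
  if (anyNA(idx)) stop("label error: unknown label", call. = FALSE)
  mean(-log(pmax(probs[idx], 1e-12)))
}

#' Train the convolutional classifier gradient-free with IGWO
#'
#' Flattens all network parameters into one vector and minimizes the
#' training cross-entropy over the box `[-param_bound, param_bound]^P`
#' with [igwo_minimize()]. No backpropagation is used. Batch-norm
#' statistics are computed over the whole training set for each candidate
#' parameter vector (a deterministic function of the candidate), and the
#' statistics of the best vector are stored for prediction.
#'
#' @param spec A [network_spec()]; its `input_len` must match `ncol(X)`.
#' @param X Training matrix.
#' @param y Training labels with at least two classes.
#' @param config An [igwo_config()].
#' @param param_bound Half-width `B` of the symmetric search box; `B = 0`
#'   short-circuits to the all-zero network (uniform predictions).
#' @param n_starts Number of independent IGWO runs (sub-seeded from
#'   `config$seed`); the parameters with the lowest training loss are
#'   kept. Restarts are the usual guard against the run-to-run variance
#'   of population search in high-dimensional parameter spaces.
#' @return An object of class `"igwo_dcnn"`: the spec, best parameters,
#'   class ordering, stored batch-norm statistics and the training
#'   `"opt_result"`.
#' @export
train_with_igwo <- function(spec, X, y, config = igwo_config(),
                            param_bound = 3, n_starts = 1L) {
  X <- as_input_matrix(X, spec)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    stop("invalid labels: training data must contain at least two classes",
         call. = FALSE)
  }
  if (nlevels(y) > spec$classes) {
    stop("invalid labels: more classes than network outputs", call. = FALSE)
  }
  lv <- levels(y)
  p <- parameter_count(spec)
  if (param_bound < 0) stop("param_bound must be >= 0", call. = FALSE)
  if (param_bound == 0) {
    theta <- numeric(p)
    ns <- conv_batch_stats(theta, spec, X)
    loss <- cross_entropy_loss(theta, spec, X, y, ns, lv)
    res <- opt_result(theta, loss, rep(loss, 1L), 1L, config$seed, "igwo")
  } else {
    obj <- objective_function(function(theta) {
      ns <- conv_batch_stats(theta, spec, X)
      cross_entropy_loss(theta, spec, X, y, ns, lv)
    }, dim = p, name = "dcnn-cross-entropy")
    box <- bounds(-param_bound, param_bound, dim = p)
    res <- NULL
    for (k in seq_len(max(1L, n_starts))) {
      cfg_k <- config
      if (n_starts > 1L) cfg_k$seed <- derive_seed(config$seed,
                                                   paste0("start", k))
      res_k <- igwo_minimize(obj, box, cfg_k)
      if (is.null(res) || res_k$best_fitness < res$best_fitness) res <- res_k
    }
    theta <- res$best_position
    ns <- conv_batch_stats(theta, spec, X)
  }
  structure(list(spec = spec,
                 parameters = theta,
                 classes = lv,
                 norm_stats = ns,
                 param_bound = param_bound,
                 result = res),
            class = "igwo_dcnn")
}

#' Predict classes (or probabilities) from a trained model
#'
#' Probabilities come from [dcnn_forward()] with the stored batch-norm
#' statistics; class predictions take the per-row argmax, with ties
#' broken toward the lowest class index so prediction is deterministic.
#'
#' @param object An `"igwo_dcnn"` model.
#' @param newdata Feature matrix with the training dimensionality.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... Unused.
#' @return Character vector of labels, or a probability matrix with one
#'   column per class.
#' @export
predict.igwo_dcnn <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  probs <- dcnn_forward(object$parameters, object$spec, newdata,
                        object$norm_stats)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' @export
print.igwo_dcnn <- function(x, ...) {
  cat(sprintf("<igwo_dcnn: %d -> conv(%d x %d) -> pool -> %d -> %d classes>\n",
              x$spec$input_len, x$spec$filters, x$spec$kernel,
              x$spec$hidden, x$spec$classes))
  cat(sprintf("  %d parameters, training loss %.4f\n",
              parameter_count(x$spec), x$result$best_fitness))
  invisible(x)
}

#' Serialize a trained model to JSON (and read it back)
#'
#' @param model An `"igwo_dcnn"`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
dcnn_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "igwo_dcnn"))
  js <- jsonlite::toJSON(list(
    spec = unclass(model$spec),
    parameters = model$parameters,
    classes = model$classes,
    norm_stats = model$norm_stats,
    param_bound = model$param_bound
  ), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname dcnn_to_json
#' @param json JSON string or file path produced by [dcnn_to_json()].
#' @export
dcnn_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  spec <- do.call(network_spec,
                  x$spec[c("input_len", "filters", "kernel", "hidden",
                           "classes")])
  structure(list(spec = spec,
                 parameters = as.numeric(x$parameters),
                 classes = as.character(x$classes),
                 norm_stats = list(mean = as.numeric(x$norm_stats$mean),
                                   var = as.numeric(x$norm_stats$var)),
                 param_bound = x$param_bound,
                 result = NULL),
            class = "igwo_dcnn")
}
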