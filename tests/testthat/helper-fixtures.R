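# Shared fixtures, built in code at test time.

# Small cohort table with known values for imputation tests.
make_mini_cohort <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:8),
    diagnosis = rep(c("asthma", "copd"), each = 4),
    age = c(30, 40, 50, 60, 35, 45, 55, 65),
    gender = rep(c("M", "F"), 4),
    smoking = rep(c("non", "ex", "active", "non"), 2),
    im_min = c(1, 2, NA, 4, 10, 12, NA, 14),
    im_avg = c(5, 5, 5, 5, 6, 6, 6, 6),
    re_min = c(NA, 2, 4, 6, 1, 3, 5, NA),
    re_avg = 1:8,
    stringsAsFactors = FALSE
  )
}

# Two-feature dataset where feature 1 separates two classes and feature 2
# is pure noise.
make_one_good_feature <- function(n = 60, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(f1 = ifelse(y == "a", -3, 3) + rnorm(n, sd = 0.5),
             f2 = rnorm(n))
  list(X = X, y = factor(y))
}

# Three binary features whose parity defines the class: every proper
# feature subset is uninformative for a nearest-neighbour classifier,
# the full set is perfectly informative.
make_parity_data <- function(n = 96, seed = 1) {
  set.seed(seed)
  bits <- matrix(sample(0:1, n * 3, replace = TRUE), ncol = 3)
  y <- factor(ifelse(rowSums(bits) %% 2 == 0, "even", "odd"))
  X <- bits * 2 - 1 + matrix(rnorm(n * 3, sd = 0.05), ncol = 3)
  colnames(X) <- paste0("b", 1:3)
  list(X = X, y = y)
}

# Independent oracle: tally the one-vs-rest confusion by explicit loops.
enumerate_counts <- function(y_true, y_pred, pos) {
  gp <- gf <- hp <- hf <- 0L
  for (i in seq_along(y_true)) {
    t_pos <- y_true[i] == pos
    p_pos <- y_pred[i] == pos
    if (t_pos && p_pos) gp <- gp + 1L
    if (!t_pos && !p_pos) gf <- gf + 1L
    if (!t_pos && p_pos) hp <- hp + 1L
    if (t_pos && !p_pos) hf <- hf + 1L
  }
  c(gp = gp, gf = gf, hp = hp, hf = hf)
}

# Exhaustive wrapper-fitness search over all non-empty masks (oracle for
# the TDO feature-selection path).
brute_force_best_mask <- function(X, y, alpha, folds) {
  d <- ncol(X)
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))[-1, ,
                                                                drop = FALSE]
  fits <- apply(masks, 1L, function(m) {
    feature_selection_fitness(m, X, y, alpha = alpha, folds = folds)
  })
  list(mask = masks[which.min(fits), ], fitness = min(fits),
       all_masks = masks, all_fitness = fits)
}
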