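test_that("confusion counts match exhaustive enumeration", {
  y_true <- c("+", "+", "-", "-")
  y_pred <- c("+", "-", "+", "-")
  cc <- confusion_counts(y_true, y_pred, "+")
  expect_equal(unlist(cc[c("gp", "gf", "hp", "hf")]),
               c(gp = 1L, gf = 1L, hp = 1L, hf = 1L))
  all_right <- confusion_counts(rep(c("+", "-"), c(4, 6)),
                                rep(c("+", "-"), c(4, 6)), "+")
  expect_equal(unlist(all_right[c("gp", "gf", "hp", "hf")]),
               c(gp = 4L, gf = 6L, hp = 0L, hf = 0L))
  set.seed(10)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    yt <- sample(c("a", "b", "c"), n, replace = TRUE)
    yp <- sample(c("a", "b", "c"), n, replace = TRUE)
    cc <- confusion_counts(yt, yp, "b")
    expect_equal(unlist(cc[c("gp", "gf", "hp", "hf")]),
                 enumerate_counts(yt, yp, "b"))
    expect_equal(cc$gp + cc$gf + cc$hp + cc$hf, n)
  }
  expect_error(confusion_counts(c("a", "b"), "a", "a"), "shape")
})

test_that("binary metrics match hand arithmetic in both conventions", {
  cc <- structure(list(gp = 50L, gf = 40L, hp = 5L, hf = 5L),
                  class = "confusion_counts")
  m <- binary_metrics(cc)
  expect_equal(m$accuracy, 0.90)
  expect_equal(m$sensitivity, 50 / 55)
  expect_equal(m$precision, 50 / 55)
  expect_equal(m$ppv, m$precision)
  expect_equal(m$specificity, 40 / 45)
  expect_equal(m$npv, 40 / 45)
  expect_equal(m$prevalence, 55 / 100)
  p <- binary_metrics(cc, "as_printed")
  # sensitivity / accuracy / precision agree between conventions
  expect_equal(p$sensitivity, m$sensitivity)
  expect_equal(p$accuracy, m$accuracy)
  expect_equal(p$precision, m$precision)
  # the as-printed forms swap the specificity/NPV denominators and
  # duplicate accuracy as prevalence
  expect_equal(p$specificity, 40 / 45)   # gf/(gf+hf) happens to tie here
  expect_equal(p$npv, 40 / 45)
  expect_equal(p$prevalence, p$accuracy)
  cc2 <- structure(list(gp = 50L, gf = 40L, hp = 2L, hf = 8L),
                   class = "confusion_counts")
  m2 <- binary_metrics(cc2); p2 <- binary_metrics(cc2, "as_printed")
  expect_equal(m2$specificity, 40 / 42)
  expect_equal(p2$specificity, 40 / 48)
  expect_equal(m2$npv, 40 / 48)
  expect_equal(p2$npv, 40 / 42)
  expect_equal(m2$prevalence, 58 / 100)
  expect_equal(p2$prevalence, 90 / 100)
})

test_that("perfect classification gives 1 everywhere defined; zero
           denominators give NA", {
  y <- rep(c("a", "b"), c(3, 7))
  cc <- confusion_counts(y, y, "a")
  for (conv in c("canonical", "as_printed")) {
    m <- binary_metrics(cc, conv)
    for (nm in c("sensitivity", "specificity", "accuracy", "precision",
                 "npv")) {
      expect_equal(m[[nm]], 1)
    }
  }
  none_pred <- confusion_counts(y, rep("b", 10), "a")
  m <- binary_metrics(none_pred)
  expect_true(is.na(m$precision))  # gp + hp = 0, undefined not 0
  expect_equal(m$sensitivity, 0)
})

test_that("specificity/sensitivity duality under role swap", {
  set.seed(3)
  for (i in 1:30) {
    counts <- as.list(sample(0:20, 4, replace = TRUE))
    names(counts) <- c("gp", "gf", "hp", "hf")
    cc <- structure(counts, class = "confusion_counts")
    swapped <- structure(list(gp = counts$gf, gf = counts$gp,
                              hp = counts$hf, hf = counts$hp),
                         class = "confusion_counts")
    expect_identical(binary_metrics(cc)$specificity,
                     binary_metrics(swapped)$sensitivity)
  }
})

test_that("macro report averages one-vs-rest metrics and is
           order-invariant", {
  y <- rep(c("a", "b", "c", "d"), each = 5)
  perfect <- macro_report(y, y)
  expect_equal(unname(perfect$macro[c("sensitivity", "specificity",
                                      "accuracy", "precision", "npv")]),
               rep(1, 5))
  expect_equal(perfect$overall_accuracy, 1)
  set.seed(6)
  yt <- sample(c("a", "b"), 40, replace = TRUE)
  yp <- sample(c("a", "b"), 40, replace = TRUE)
  rep2 <- macro_report(yt, yp)
  # two-class identity: macro sensitivity is the mean of the class-1
  # sensitivity and the class-1 canonical specificity
  m1 <- binary_metrics(confusion_counts(yt, yp, "a"))
  expect_equal(unname(rep2$macro["sensitivity"]),
               mean(c(m1$sensitivity, m1$specificity)))
  r_ab <- macro_report(yt, yp, classes = c("a", "b"))
  r_ba <- macro_report(yt, yp, classes = c("b", "a"))
  expect_equal(r_ab$macro, r_ba$macro)
  expect_error(macro_report(yt, yp, classes = "a"), "label error")
})

test_that("metric reports serialize to JSON with the convention tag", {
  y <- rep(c("a", "b"), 10)
  r <- macro_report(y, rev(y), convention = "as_printed")
  js <- jsonlite::fromJSON(report_json(r))
  expect_equal(js$convention, "as_printed")
  expect_equal(js$overall_accuracy, r$overall_accuracy)
  expect_equal(js$per_class$a$sensitivity, r$per_class$a$sensitivity)
})
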