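test_that("a perfectly separating feature is selected first with accuracy 1", {
  set.seed(1)
  df <- data.frame(involved = rep(c(0L, 1L), each = 10),
                   dtv = c(rnorm(10, 10, 2), rnorm(10, 60, 2)),
                   adc = rnorm(20), d = rnorm(20), f = rnorm(20))
  clf <- pln_classifier(df)
  expect_equal(clf$selected[1], "dtv")
  expect_true(clf$separable)
  expect_true(all(is.finite(coef(clf))))
  expect_equal(score_classifier(clf)$accuracy$estimate, 1)
})

test_that("pure-noise features generalise at the majority-class rate", {
  set.seed(77)
  gen <- function(n) data.frame(involved = rbinom(n, 1, 0.42),
                                dtv = rnorm(n), adc = rnorm(n),
                                d = rnorm(n), f = rnorm(n))
  accs <- replicate(30, {
    train <- gen(50)
    if (min(table(train$involved)) < 2) return(NA_real_)
    clf <- pln_classifier(train)
    test <- gen(400)
    mean(predict(clf, test, type = "class") == test$involved)
  })
  maj <- 0.58
  expect_lt(abs(mean(accs, na.rm = TRUE) - maj), 0.05)
})

test_that("selection is deterministic and invariant to row permutation", {
  co <- simulate_cohort(seed = 302)
  clf <- pln_classifier(co)
  for (i in 1:5) {
    set.seed(i)
    clf_p <- pln_classifier(co[sample(nrow(co)), ])
    expect_identical(clf_p$selected, clf$selected)
    expect_equal(coef(clf_p), coef(clf))
  }
})

test_that("a duplicated collinear feature is never selected after the original", {
  co <- simulate_cohort(seed = 17)
  co$f_dup <- co$f
  clf <- pln_classifier(co, candidates = c("dtv", "f", "f_dup"), max_features = 3)
  expect_false("f_dup" %in% clf$selected)
})

test_that("the AIC stop rule halts before the feature budget when nothing helps", {
  set.seed(55)
  df <- data.frame(involved = rep(c(0L, 1L), each = 25),
                   dtv = c(rnorm(25, 0), rnorm(25, 3)),
                   adc = rnorm(50), d = rnorm(50), f = rnorm(50))
  clf <- pln_classifier(df, max_features = 4)
  expect_lt(length(clf$selected), 4L)
  expect_true("dtv" %in% clf$selected)
})

test_that("AUC equals concordant-pair counting and has the expected extremes", {
  y <- rep(c(0, 1), each = 5)
  expect_equal(auc_roc(c(1:5, 6:10), y), 1)
  set.seed(6)
  for (i in 1:20) {
    n <- sample(6:15, 1)
    yy <- c(0, 1, rbinom(n - 2, 1, 0.5))
    sc <- sample(1:5, n, replace = TRUE)  # forces ties
    expect_equal(auc_roc(sc, yy), oracle_auc_pairs(sc, yy))
  }
  set.seed(10)
  yr <- rbinom(1000, 1, 0.5); sr <- rnorm(1000)
  expect_gt(auc_roc(sr, yr), 0.45)
  expect_lt(auc_roc(sr, yr), 0.55)
})

test_that("AUC is invariant to strictly increasing score transforms", {
  set.seed(23)
  y <- rbinom(60, 1, 0.4); s <- rnorm(60)
  a <- auc_roc(s, y)
  expect_equal(auc_roc(exp(s), y), a)
  expect_equal(auc_roc(100 + 3 * s, y), a)
})

test_that("AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(80, 1, 0.5); s <- rnorm(80) + y
  expect_equal(auc_roc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("subgroup accuracy is the positive fraction within the subgroup", {
  pred <- c(rep(1L, 9), 0L, rep(0L, 5))
  sub <- c(rep(TRUE, 10), rep(FALSE, 5))
  expect_equal(subgroup_accuracy(pred, sub), 0.9)
  expect_equal(subgroup_accuracy(rep(1L, 4), rep(TRUE, 4)), 1)
  expect_equal(subgroup_accuracy(rep(0L, 4), rep(TRUE, 4)), 0)
  expect_error(subgroup_accuracy(pred, rep(FALSE, 15)), "empty")
})

test_that("accuracy comparison reproduces the pooled two-proportion Z", {
  eq <- compare_accuracy(0.8, 20, 0.8, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p.value, 1)
  cmp <- compare_accuracy(0.9, 10, 0.3, 10)
  expect_equal(cmp$z, (0.9 - 0.3) / sqrt(0.6 * 0.4 * (1 / 10 + 1 / 10)))
  expect_equal(cmp$z, 2.7386, tolerance = 1e-4)
  expect_equal(cmp$p.value, 0.00616, tolerance = 1e-2)
  # two-sided normal tail against the distribution function directly
  expect_equal(cmp$p.value, 2 * (1 - pnorm(abs(cmp$z))))
  # Wilson interval sanity: covers the estimate, inside [0, 1]
  expect_true(cmp$ci1["lower"] < 0.9 && cmp$ci1["upper"] > 0.9)
  expect_true(all(c(cmp$ci1, cmp$ci2) >= 0 & c(cmp$ci1, cmp$ci2) <= 1))
})

test_that("refitting keeps the selected features but re-estimates coefficients", {
  co <- simulate_cohort(seed = 41)
  clf <- pln_classifier(co)
  co2 <- co
  co2[c("dtv", "adc", "d", "f")] <- co[c("dtv_2", "adc_2", "d_2", "f_2")]
  clf2 <- refit_classifier(clf, co2)
  expect_identical(clf2$selected, clf$selected)
  expect_false(identical(coef(clf2), coef(clf)))
  expect_error(refit_classifier(clf, co2[, "id", drop = FALSE]), "lacks columns")
})

test_that("degenerate labels are rejected", {
  df <- data.frame(involved = rep(1L, 10), dtv = rnorm(10),
                   adc = rnorm(10), d = rnorm(10), f = rnorm(10))
  expect_error(pln_classifier(df), "each class")
  expect_error(pln_classifier(data.frame(involved = c(0, 1, 2), dtv = 1:3),
                              candidates = "dtv"), "binary")
})
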