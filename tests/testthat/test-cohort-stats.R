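test_that("Kruskal-Wallis matches the raw rank formula", {
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(unname(kw$statistic), 7.2)
  expect_equal(unname(kw$statistic), oracle_kw_h(g))
  set.seed(8)
  for (i in 1:10) {
    gr <- lapply(sample(3:6, 3, replace = TRUE), function(n) rpois(n, 10))
    expect_equal(unname(kruskal_wallis(gr)$statistic), oracle_kw_h(gr))
  }
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("all-tied groups give the degenerate H = 0, p = 1", {
  kw <- kruskal_wallis(list(c(5, 5, 5), c(5, 5, 5), c(5, 5, 5)))
  expect_equal(unname(kw$statistic), 0)
  expect_equal(kw$p.value, 1)
  expect_true(kw$degenerate)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(14)
  for (i in 1:10) {
    gr <- lapply(1:3, function(j) runif(5 + j, 0, 10))
    h1 <- unname(kruskal_wallis(gr)$statistic)
    h2 <- unname(kruskal_wallis(lapply(gr, function(x) exp(x / 3)))$statistic)
    expect_equal(h1, h2)
  }
})

test_that("Nemenyi post-hoc behaves on degenerate and separated groups", {
  idp <- nemenyi_pairwise(list(rep(2, 4), rep(2, 4), rep(2, 4)))$p.value
  expect_true(all(idp[upper.tri(idp)] >= 0.999))
  expect_equal(diag(idp), rep(1, 3), ignore_attr = TRUE)
  sep <- nemenyi_pairwise(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))$p.value
  off <- sep[upper.tri(sep)]
  expect_equal(min(off), sep[1, 3])  # extreme pair has the smallest p
  set.seed(2)
  rnd <- nemenyi_pairwise(lapply(1:4, function(i) rnorm(6)))$p.value
  expect_identical(rnd, t(rnd))
  expect_true(all(rnd >= 0 & rnd <= 1))
})

test_that("Fisher 2x2 agrees with hypergeometric enumeration for all n <= 20", {
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2))$p.value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p.value, 2 / 252,
               tolerance = 1e-10)
  for (n in 2:20) {
    for (a in 0:n) for (b in 0:(n - a)) for (c in 0:(n - a - b)) {
      tab <- matrix(c(a, b, c, n - a - b - c), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        expect_true(fisher_exact(tab)$degenerate)
      } else {
        expect_equal(fisher_exact(tab)$p.value, oracle_fisher_2x2(tab),
                     tolerance = 1e-7)
      }
    }
  }
})

test_that("r x c Fisher matches brute-force enumeration and its MC mode", {
  tab <- matrix(c(3, 0, 0, 0, 3, 3), nrow = 2, byrow = TRUE)
  ex <- fisher_exact(tab)
  expect_false(ex$simulated)
  expect_equal(ex$p.value, oracle_fisher_rxc(tab), tolerance = 1e-7)
  set.seed(31)
  for (i in 1:5) {
    t2 <- matrix(rpois(6, 3), 2)
    if (any(rowSums(t2) == 0) || any(colSums(t2) == 0)) next
    expect_equal(fisher_exact(t2)$p.value, oracle_fisher_rxc(t2), tolerance = 1e-6)
  }
  # Monte-Carlo estimate within 3 binomial SEs of the exact value
  mc <- fisher_exact(tab, exact_max = 0, B = 20000L, seed = 7)
  expect_true(mc$simulated)
  se <- sqrt(ex$p.value * (1 - ex$p.value) / mc$B)
  expect_lt(abs(mc$p.value - ex$p.value), 3 * se + 2 / mc$B)
  # degenerate margin
  expect_true(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$degenerate)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("ICC(2,1) is 1 for duplicated ratings and ~0 for independent noise", {
  x <- c(3, 1, 4, 1, 5, 9, 2.5)
  icc <- icc_agreement(cbind(x, x))
  expect_equal(icc$icc, 1)
  expect_identical(icc$band, "excellent")
  set.seed(99)
  noise <- icc_agreement(cbind(rnorm(200), rnorm(200)))
  expect_lt(abs(noise$icc), 0.15)
})

test_that("absolute agreement penalises a constant offset; consistency does not", {
  set.seed(4)
  x <- rnorm(30, 10, 2)
  ratings <- cbind(x, x + 5)
  agr <- icc_agreement(ratings)$icc
  cons <- oracle_icc_consistency(ratings)
  expect_lt(agr, cons)
  expect_equal(cons, 1)
})

test_that("constant ratings give an undefined ICC, flagged not NaN-propagated", {
  icc <- icc_agreement(cbind(rep(2, 5), rep(2, 5)))
  expect_false(icc$defined)
  expect_true(is.na(icc$icc))
})

test_that("agreement bands follow the documented cutpoints at boundaries", {
  band <- ivimtools:::icc_band
  expect_identical(band(0.50), "moderate")
  expect_identical(band(0.75), "moderate")
  expect_identical(band(0.76), "good")
  expect_identical(band(0.90), "good")
  expect_identical(band(0.91), "excellent")
  expect_identical(band(0.49), "poor")
})

test_that("the association table mirrors the feature-by-group layout", {
  co <- simulate_cohort(seed = 5)
  tab <- cohort_association_stats(co)
  expect_equal(tab$feature, c("dtv", "adc", "d", "f"))
  expect_true(all(tab$p.value >= 0 & tab$p.value <= 1))
  expect_equal(ncol(tab), 9L)  # feature, 3 means, 3 sds, H, p
  nem <- attr(tab, "nemenyi")
  expect_identical(names(nem), c("dtv", "adc", "d", "f"))
  expect_identical(dim(nem$f$p.value), c(3L, 3L))
})
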