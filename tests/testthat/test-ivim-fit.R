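test_that("the segmented fit recovers noiseless parameters essentially exactly", {
  b <- bvalue_scheme()
  cases <- list(c(D = 0.9e-3, Ds = 20e-3, f = 0.19),
                c(D = 2.0e-3, Ds = 8e-3, f = 0.35),
                c(D = 0.5e-3, Ds = 10e-3, f = 0.40))
  for (p in cases) {
    s <- ivim_signal(as.numeric(b), 100, p["D"], p["Ds"], p["f"])
    fit <- fit_ivim_voxel(s, b)
    expect_true(fit$converged)
    expect_lt(abs(fit$D - p["D"]) / p["D"], 1e-4)
    expect_lt(abs(fit$f - p["f"]) / p["f"], 1e-4)
    expect_lt(abs(fit$Dstar - p["Ds"]) / p["Ds"], 1e-2)
    expect_equal(fit$S0, 100)
  }
})

test_that("a monoexponential curve yields a near-zero perfusion fraction", {
  b <- bvalue_scheme()
  s <- ivim_signal(as.numeric(b), 100, D = 1e-3)
  fit <- fit_ivim_voxel(s, b)
  expect_lte(fit$f, 1e-3)
  expect_lt(abs(fit$D - 1e-3) / 1e-3, 1e-6)
})

test_that("the fit residual matches an exhaustive grid search over (f, D*)", {
  b <- bvalue_scheme(); bn <- as.numeric(b)
  set.seed(42)
  for (i in 1:20) {
    D <- runif(1, 0.4e-3, 2.5e-3)
    Ds <- runif(1, 4e-3, 80e-3)
    f <- runif(1, 0.03, 0.4)
    s <- ivim_signal(bn, 100, D, Ds, f)
    fit <- fit_ivim_voxel(s, b)
    rss_grid <- oracle_grid_rss(s, bn, 100, fit$D)
    expect_lte(fit$rss, rss_grid * 1.01 + 1e-12)
  }
})

test_that("degenerate voxels are flagged, not thrown", {
  b <- bvalue_scheme()
  z <- fit_ivim_voxel(rep(0, 13), b)
  expect_false(z$valid)
  expect_identical(z$cause, "nonpositive_b0")
  nf <- fit_ivim_voxel(c(100, rep(NA, 12)), b)
  expect_identical(nf$cause, "nonfinite_signal")
  s <- ivim_signal(as.numeric(b), 100, 1e-3)
  s[13] <- 0  # dead signal at b = 1000
  hb <- fit_ivim_voxel(s, b)
  expect_identical(hb$cause, "nonpositive_high_b")
  expect_error(fit_ivim_voxel(s[1:5], b), "differ in length")
})

test_that("fitting a noiseless phantom recovers the truth voxelwise", {
  sim <- simulate_phantom(tiny_phantom(snr = Inf))
  maps <- fit_ivim(sim$study, fit_config(smooth = FALSE))
  expect_true(all(maps$valid))
  expect_lt(max(abs(maps$d - sim$truth$d)), 1e-8)
  expect_lt(max(abs(maps$f - sim$truth$f)), 1e-6)
  expect_lt(max(abs(maps$adc[sim$voi$mask] -
                      adc_two_point(ivim_signal(0, 100, 0.9e-3, 20e-3, 0.19),
                                    ivim_signal(1000, 100, 0.9e-3, 20e-3, 0.19),
                                    1000))), 1e-12)
})

test_that("a curve whose unconstrained best fit has f > 1 is excluded by QC", {
  b <- bvalue_scheme(); bn <- as.numeric(b)
  # forward signal built with f = 1.3 (all samples still positive): the
  # unconstrained global optimum is unphysical, so QC must drop the voxel
  s <- 100 * (1.3 * exp(-bn * (0.7e-3 + 1.2e-3)) + (1 - 1.3) * exp(-bn * 0.7e-3))
  expect_true(all(s > 0))
  vol <- array(rep(s, each = 4), dim = c(2, 2, 1, 13))
  st <- dwi_study(vol, b)
  maps <- fit_ivim(st, fit_config(smooth = FALSE))
  expect_false(any(maps$valid))
  expect_true(all(maps$cause %in%
                    c("f_out_of_range", "d_out_of_range", "adc_out_of_range")))
})

test_that("an all-zero study yields all-invalid maps without crashing", {
  st <- dwi_study(array(0, dim = c(3, 3, 1, 13)), bvalue_scheme())
  maps <- fit_ivim(st)
  expect_false(any(maps$valid))
})

test_that("study fitting is deterministic and the ADC map needs b0/b1000", {
  sim <- simulate_phantom(tiny_phantom(snr = 40), seed = 9)
  m1 <- fit_ivim(sim$study)
  m2 <- fit_ivim(sim$study)
  expect_identical(m1$d, m2$d)
  expect_identical(m1$f, m2$f)
  st <- sim$study
  st$volume <- st$volume[, , , 1:12, drop = FALSE]
  st$bvalues <- bvalue_scheme(as.numeric(sim$study$bvalues)[1:12])
  expect_error(fit_ivim(st), "b = 1000")
})

test_that("D-hat bias shrinks monotonically with SNR", {
  b <- bvalue_scheme(); bn <- as.numeric(b)
  s_true <- ivim_signal(bn, 100, 0.9e-3, 20e-3, 0.19)
  set.seed(1234)
  bias <- sapply(c(10, 25, 50, 200), function(snr) {
    d <- replicate(150, fit_ivim_voxel(rician_curve(s_true, 100 / snr), b)$D)
    abs(mean(d) - 0.9e-3)
  })
  expect_true(all(diff(bias) < 0))
})

test_that("the QC rule excludes exactly the printed threshold violations", {
  eps <- 1e-6
  adc_vals <- c(1e-3, 3e-3 - eps, 3e-3, 3e-3 + eps, -eps, NA)
  d_vals <- c(0.9e-3, 3e-3 - eps, 3e-3, 3e-3 + eps, -eps, Inf)
  f_vals <- c(0.19, 1 - eps, 1, 1 + eps, -eps, NaN)
  grid <- expand.grid(adc = seq_along(adc_vals), d = seq_along(d_vals),
                      f = seq_along(f_vals))
  n <- nrow(grid)
  dims <- c(n, 1, 1)
  maps <- structure(list(adc = array(adc_vals[grid$adc], dims),
                         d = array(d_vals[grid$d], dims),
                         dstar = array(10e-3, dims),
                         f = array(f_vals[grid$f], dims),
                         valid = array(TRUE, dims),
                         cause = array("ok", dims),
                         geometry = list(), config = NULL),
                    class = "ivim_maps")
  out <- qc_filter(maps)
  expect_ok <- is.finite(out$adc) & is.finite(out$d) & is.finite(out$f) &
    out$adc >= 0 & out$adc <= 3e-3 & out$d >= 0 & out$d <= 3e-3 &
    out$f >= 0 & out$f <= 1
  expect_ok[is.na(expect_ok)] <- FALSE
  expect_identical(as.vector(out$valid), as.vector(expect_ok))
  # zero false retentions by construction of the expectation above, and
  # boundary values themselves are retained (rule is strict >)
  keep <- out$adc == 3e-3 & out$d == 3e-3 & out$f == 1
  keep[is.na(keep)] <- FALSE
  expect_true(all(out$valid[keep]))
})
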