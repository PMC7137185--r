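#' Fitting configuration for the segmented IVIM inverse problem
#'
#' Collects the knobs of the voxel-wise two-step fit. Defaults follow
#' common IVIM practice: the perfusion compartment is taken as
#' extinguished above `perfusion_cut` = 200 s/mm^2, so step 1 (the
#' log-linear estimate of D) uses b in {300, 500, 800, 1000} of the
#' default scheme; step 2 then fixes D and S0 and estimates f and D*
#' by bounded Levenberg-Marquardt least squares over all b-values.
#'
#' @param perfusion_cut b-threshold (s/mm^2) above which step 1 treats
#'   the decay as monoexponential. Must leave at least 3 b-values at or
#'   above it.
#' @param smooth Apply the in-plane 3x3 Gaussian pre-filter once to the
#'   whole 4D study before any fitting ([smooth_study]).
#' @param f_max Upper bound on the perfusion fraction in step 2. Kept
#'   above 1 deliberately: physically impossible fits with f > 1 must
#'   surface so that QC can exclude them rather than being clipped into
#'   the valid range.
#' @param dstar_max Upper bound on the pseudo-diffusion coefficient,
#'   mm^2/s.
#' @param dstar_starts Fixed list of D* starting values for the
#'   multi-start step-2 optimisation (declared so fits are
#'   deterministic).
#' @param refine_iter Maximum number of fixed-point refinements of D:
#'   after step 2, the fitted perfusion component is subtracted from
#'   the high-b signals and D re-estimated, then f and D* refitted,
#'   until the relative change in D drops below `refine_tol`. 0
#'   reproduces the plain single-pass segmented fit.
#' @param refine_tol Relative change in D at which refinement stops.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param maxit Maximum optimizer iterations per start.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(perfusion_cut = 200, smooth = TRUE,
                       f_max = 2, dstar_max = 0.5,
                       dstar_starts = c(5e-3, 20e-3, 50e-3),
                       refine_iter = 25L, refine_tol = 1e-9,
                       ftol = 1e-12, ptol = 1e-12, maxit = 200L) {
  if (perfusion_cut <= 0) stop("perfusion_cut must be positive", call. = FALSE)
  if (f_max <= 0 || dstar_max <= 0) stop("bounds must be positive", call. = FALSE)
  structure(list(perfusion_cut = perfusion_cut, smooth = isTRUE(smooth),
                 f_max = f_max, dstar_max = dstar_max,
                 dstar_starts = as.numeric(dstar_starts),
                 refine_iter = as.integer(refine_iter),
                 refine_tol = refine_tol,
                 ftol = ftol, ptol = ptol, maxit = as.integer(maxit)),
            class = "fit_config")
}

invalid_fit <- function(cause) {
  list(S0 = NA_real_, D = NA_real_, Dstar = NA_real_, f = NA_real_,
       rss = NA_real_, converged = FALSE, valid = FALSE, cause = cause)
}

# log-linear least squares for D over the high-b points; returns c(D, intercept)
loglin_d <- function(b, s) {
  y <- log(s)
  bc <- b - mean(b)
  slope <- sum(bc * (y - mean(y))) / sum(bc^2)
  c(D = -slope, intercept = mean(y) - slope * mean(b))
}

#' Two-step (segmented) IVIM fit of a single decay curve
#'
#' Fits the biexponential model [ivim_signal] to one voxel's signal
#' decay. Step 1 estimates the tissue diffusion coefficient D by
#' unweighted log-linear least squares over the b-values at or above
#' the perfusion cut. Step 2 holds D fixed, pins S0 to the measured
#' b = 0 signal, and estimates the perfusion fraction f and the
#' pseudo-diffusion coefficient D* by bound-constrained
#' Levenberg-Marquardt least squares over the full curve, from a fixed
#' list of starting values. Optionally the fit is polished by a few
#' fixed-point iterations in which the fitted perfusion component is
#' subtracted from the high-b signals and D re-estimated; on noiseless
#' data this removes the residual perfusion contamination of step 1.
#'
#' The raw fit is returned without QC clamping: f may exceed 1 (up to
#' the declared bound) and D may come out negative on noisy voxels;
#' [qc_filter] is responsible for excluding such voxels.
#'
#' @param signals Signal vector over the scheme.
#' @param bvalues The [bvalue_scheme] of the acquisition.
#' @param config A [fit_config].
#' @return A list with elements `S0`, `D`, `Dstar`, `f`, `rss`,
#'   `converged`, `valid` (fit feasibility, not QC) and `cause`.
#' @export
fit_ivim_voxel <- function(signals, bvalues, config = fit_config()) {
  b <- as.numeric(bvalues)
  if (length(signals) != length(b))
    stop("signal vector and b-value scheme differ in length", call. = FALSE)
  if (any(!is.finite(signals))) return(invalid_fit("nonfinite_signal"))
  s0 <- signals[b == 0][1L]
  if (!length(s0) || is.na(s0) || s0 <= 0) return(invalid_fit("nonpositive_b0"))
  hi <- b >= config$perfusion_cut
  if (sum(hi) < 3L)
    stop("fewer than 3 b-values at or above the perfusion cut", call. = FALSE)
  if (any(signals[hi] <= 0)) return(invalid_fit("nonpositive_high_b"))

  st1 <- loglin_d(b[hi], signals[hi])
  D <- unname(st1["D"])
  # start f from the step-1 intercept: S0*(1-f) = exp(intercept)
  f0 <- 1 - exp(unname(st1["intercept"])) / s0
  f0 <- min(max(f0, 1e-3), 0.95)

  step2 <- function(D) {
    resid_fn <- function(p)
      signals - ivim_forward_raw(b, s0, D, p[2L], p[1L])
    best <- NULL
    for (ds in config$dstar_starts) {
      fit <- minpack.lm::nls.lm(
        par = c(f = f0, Dstar = ds), fn = resid_fn,
        lower = c(0, 0), upper = c(config$f_max, config$dstar_max),
        control = minpack.lm::nls.lm.control(
          ftol = config$ftol, ptol = config$ptol, maxiter = config$maxit))
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    best
  }

  best <- step2(D)
  for (i in seq_len(config$refine_iter)) {
    p <- best$par
    perf <- s0 * p["f"] * exp(-b[hi] * (D + p["Dstar"]))
    s_corr <- signals[hi] - perf
    if (any(s_corr <= 0)) break
    D_new <- unname(loglin_d(b[hi], s_corr)["D"])
    if (!is.finite(D_new)) break
    if (abs(D_new - D) <= config$refine_tol * max(abs(D), 1e-9)) { D <- D_new; break }
    D <- D_new
    best <- step2(D)
  }

  conv <- best$info %in% 1:3
  list(S0 = s0, D = D, Dstar = unname(best$par["Dstar"]),
       f = unname(best$par["f"]), rss = best$deviance,
       converged = conv, valid = TRUE, cause = "ok")
}

# unchecked forward model used inside optimisation (f may exceed 1 there)
ivim_forward_raw <- function(b, S0, D, Dstar, f) {
  S0 * (f * exp(-b * (D + Dstar)) + (1 - f) * exp(-b * D))
}

#' Voxel-wise IVIM and ADC mapping of a study
#'
#' Runs the full map-level inverse problem: the study is pre-smoothed
#' once (if configured), the ADC map is computed from the smoothed
#' b = 0 and b = 1000 images by [adc_two_point], every voxel's curve
#' is fitted by [fit_ivim_voxel], and the QC mask is derived by
#' [qc_filter]. Fitting is deterministic: there is no randomness and
#' the multi-start list is fixed.
#'
#' @param study A [dwi_study]; the scheme must contain b = 0 and
#'   b = 1000 for the ADC map.
#' @param config A [fit_config].
#' @param mask Optional 3D logical array restricting where voxels are
#'   fitted (outside voxels are marked invalid with cause
#'   `"outside_mask"`); by default every voxel is fitted.
#' @return An object of class `"ivim_maps"`: 3D arrays `adc`, `d`,
#'   `dstar`, `f`, logical `valid`, character `cause`, plus the source
#'   geometry and the effective config.
#' @export
fit_ivim <- function(study, config = fit_config(), mask = NULL) {
  stopifnot(inherits(study, "dwi_study"))
  b <- as.numeric(study$bvalues)
  if (!any(b == 0) || !any(b == 1000))
    stop("ADC mapping requires b = 0 and b = 1000 in the scheme", call. = FALSE)
  if (config$smooth) study <- smooth_study(study)
  vol <- study$volume
  d3 <- dim(vol)[1:3]
  if (!is.null(mask)) {
    mask <- array(as.logical(mask), dim = dim(mask))
    if (any(dim(mask) != d3)) stop("mask grid does not match study", call. = FALSE)
  } else {
    mask <- array(TRUE, dim = d3)
  }

  adc <- adc_two_point(vol[, , , which(b == 0)[1L]],
                       vol[, , , which(b == 1000)[1L]], 1000)
  adc <- array(adc, dim = d3)

  dm <- dsm <- fm <- array(NA_real_, dim = d3)
  valid <- array(FALSE, dim = d3)
  cause <- array("outside_mask", dim = d3)
  nb <- dim(vol)[4L]
  sig_mat <- matrix(vol, nrow = prod(d3), ncol = nb)
  idx <- which(mask)
  for (v in idx) {
    fit <- fit_ivim_voxel(sig_mat[v, ], study$bvalues, config)
    dm[v] <- fit$D; dsm[v] <- fit$Dstar; fm[v] <- fit$f
    valid[v] <- fit$valid
    cause[v] <- fit$cause
  }

  maps <- structure(list(adc = adc, d = dm, dstar = dsm, f = fm,
                         valid = valid, cause = cause,
                         geometry = study$geometry, config = config),
                    class = "ivim_maps")
  qc_filter(maps)
}

#' Quality-control exclusion of incorrectly fitted voxels
#'
#' Marks as invalid every voxel whose fitted values are physically
#' implausible: ADC or D above 3e-3 mm^2/s, ADC or D negative,
#' perfusion fraction outside [0, 1], or any non-finite value. Any
#' single violation excludes the voxel. Voxels already flagged at fit
#' time (non-positive signals, outside the mask) stay invalid. D* is
#' not thresholded: it is excluded from downstream analysis altogether
#' because of its low signal-to-noise ratio, so its QC would have no
#' consumer.
#'
#' @param maps An `ivim_maps` object.
#' @param adc_max,d_max,f_range QC thresholds; defaults 3e-3 mm^2/s and
#'   `[0, 1]`.
#' @return The maps with the `valid` mask and `cause` labels updated.
#' @export
qc_filter <- function(maps, adc_max = 3e-3, d_max = 3e-3, f_range = c(0, 1)) {
  stopifnot(inherits(maps, "ivim_maps"))
  ok <- maps$cause == "ok"
  bad_finite <- !is.finite(maps$adc) | !is.finite(maps$d) | !is.finite(maps$f)
  bad_adc <- !bad_finite & (maps$adc > adc_max | maps$adc < 0)
  bad_d   <- !bad_finite & (maps$d > d_max | maps$d < 0)
  bad_f   <- !bad_finite & (maps$f > f_range[2L] | maps$f < f_range[1L])
  maps$cause[ok & bad_finite] <- "nonfinite_value"
  maps$cause[ok & !bad_finite & bad_adc] <- "adc_out_of_range"
  maps$cause[ok & !bad_finite & !bad_adc & bad_d] <- "d_out_of_range"
  maps$cause[ok & !bad_finite & !bad_adc & !bad_d & bad_f] <- "f_out_of_range"
  maps$valid <- maps$cause == "ok"
  maps
}

#' @export
print.ivim_maps <- function(x, ...) {
  d <- dim(x$valid)
  n <- length(x$valid)
  cat(sprintf("IVIM parametric maps on a %d x %d x %d grid\n", d[1], d[2], d[3]))
  cat(sprintf("  valid voxels: %d / %d (%.1f%%)\n",
              sum(x$valid), n, 100 * mean(x$valid)))
  tab <- table(x$cause[x$cause != "ok"])
  if (length(tab))
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ivim_maps <- function(object, ...) {
  sel <- object$valid
  stats <- function(v) {
    v <- v[sel]
    if (!length(v)) return(c(mean = NA, median = NA, sd = NA))
    c(mean = mean(v), median = stats::median(v), sd = stats::sd(v))
  }
  out <- rbind(adc = stats(object$adc), d = stats(object$d),
               dstar = stats(object$dstar), f = stats(object$f))
  structure(list(table = out, n_valid = sum(sel), n_total = length(sel)),
            class = "summary.ivim_maps")
}

#' @export
print.summary.ivim_maps <- function(x, ...) {
  cat(sprintf("Map summary over %d valid of %d voxels\n", x$n_valid, x$n_total))
  print(signif(x$table, 4))
  invisible(x)
}
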