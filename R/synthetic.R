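#' Specification of a synthetic DWI phantom
#'
#' Describes a desk-scale digital phantom: an ellipsoidal "tumour"
#' embedded in background tissue, each with its own biexponential
#' signal parameters, sampled over a b-value scheme and corrupted by
#' Rician noise at a chosen signal-to-noise ratio. Default geometry
#' mirrors a typical pelvic DWI protocol (about 2.4 mm in-plane
#' resolution, 4 mm contiguous slices); default tumour parameters sit
#' at the node-negative group's typical values (D = 0.9e-3 mm^2/s,
#' f = 0.19) with a fast pseudo-diffusion compartment D* = 20e-3
#' mm^2/s.
#'
#' @param shape Grid dimensions (row, col, slice).
#' @param spacing,thickness,gap Voxel geometry in mm.
#' @param centre,semi_axes Tumour ellipsoid centre and semi-axes in
#'   voxel units (axes must be positive).
#' @param tumour,background Named lists with `S0`, `D`, `Dstar`, `f`.
#' @param snr Signal-to-noise ratio `S0_tumour / sigma`; `Inf` means
#'   noiseless.
#' @param bvalues The b-value scheme.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(shape = c(12, 12, 3),
                         spacing = c(2.42, 2.42), thickness = 4, gap = 0,
                         centre = (shape + 1) / 2,
                         semi_axes = c(4, 4, 1.2),
                         tumour = list(S0 = 100, D = 0.9e-3, Dstar = 20e-3, f = 0.19),
                         background = list(S0 = 80, D = 1.8e-3, Dstar = 10e-3, f = 0.08),
                         snr = 50,
                         bvalues = bvalue_scheme()) {
  if (any(semi_axes <= 0)) stop("tumour semi-axes must be positive", call. = FALSE)
  if (snr <= 0) stop("SNR must be positive", call. = FALSE)
  if (any(centre < 1) || any(centre > shape))
    stop("tumour centre must lie inside the grid", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, thickness = thickness,
                 gap = gap, centre = centre, semi_axes = semi_axes,
                 tumour = tumour, background = background, snr = snr,
                 bvalues = bvalue_scheme(bvalues)),
            class = "phantom_spec")
}

#' Simulate a DWI phantom with Rician noise
#'
#' Generates the noiseless biexponential signal of every voxel via
#' [ivim_signal], then applies Rician noise: each magnitude sample is
#' `sqrt((S + e1)^2 + e2^2)` with independent `e1, e2 ~ N(0, sigma)`
#' and `sigma = S0_tumour / SNR`. The generator is a pure function of
#' (spec, seed): identical calls give bit-identical studies. The
#' ground-truth parameter maps are returned so recovery can be
#' measured.
#'
#' @param spec A [phantom_spec].
#' @param seed Integer seed; mandatory whenever `snr` is finite.
#' @return A list: `study` ([dwi_study]), `voi` ([tumour_voi]),
#'   `truth` (an `ivim_maps` holding the true parameter values, all
#'   voxels valid), `sigma` and the spec.
#' @export
simulate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  noisy <- is.finite(spec$snr)
  if (noisy && is.null(seed))
    stop("a seed is mandatory for noisy phantoms", call. = FALSE)
  d <- spec$shape
  b <- as.numeric(spec$bvalues)
  nb <- length(b)

  ijk <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  inside <- ((ijk$i - spec$centre[1]) / spec$semi_axes[1])^2 +
            ((ijk$j - spec$centre[2]) / spec$semi_axes[2])^2 +
            ((ijk$k - spec$centre[3]) / spec$semi_axes[3])^2 <= 1
  mask <- array(inside, dim = d)

  par_of <- function(field) ifelse(inside, spec$tumour[[field]], spec$background[[field]])
  S0 <- par_of("S0"); D <- par_of("D"); Ds <- par_of("Dstar"); f <- par_of("f")

  sig <- matrix(0, nrow = prod(d), ncol = nb)
  for (bi in seq_len(nb))
    sig[, bi] <- S0 * (f * exp(-b[bi] * (D + Ds)) + (1 - f) * exp(-b[bi] * D))

  sigma <- 0
  if (noisy) {
    sigma <- spec$tumour$S0 / spec$snr
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE)
    e1 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow = nrow(sig))
    e2 <- matrix(stats::rnorm(length(sig), 0, sigma), nrow = nrow(sig))
    sig <- sqrt((sig + e1)^2 + e2^2)
  }

  study <- dwi_study(array(sig, dim = c(d, nb)), spec$bvalues,
                     spacing = spec$spacing, thickness = spec$thickness,
                     gap = spec$gap)
  voi <- tumour_voi(mask, spacing = spec$spacing, thickness = spec$thickness,
                    gap = spec$gap)
  truth <- structure(list(adc = array(D, d), d = array(D, d),
                          dstar = array(Ds, d), f = array(f, d),
                          valid = array(TRUE, d),
                          cause = array("ok", d),
                          geometry = study$geometry, config = NULL),
                     class = "ivim_maps")
  list(study = study, voi = voi, truth = truth, sigma = sigma, spec = spec)
}

#' Specification of a synthetic patient cohort
#'
#' Describes a cohort stratified by nodal status: patients with no
#' pelvic lymph-node involvement, sub-centimetre metastatic
#' involvement, and size-significant (>= 1 cm) involvement. The
#' default group sizes (29 / 10 / 11) and the per-group means and SDs
#' of DTV (cm^3), ADC and D (1e-3 mm^2/s display units) and f are the
#' study conditions this package targets. Features are sampled
#' independently from truncated Gaussians (DTV optionally log-normal,
#' given its visible right skew in practice); a second reader's
#' measurements are derived from the same latent values with
#' calibrated measurement noise targeting a chosen interobserver ICC.
#'
#' @param sizes Named integer vector of group sizes.
#' @param means,sds Numeric matrices, features x groups, rownames
#'   `dtv`, `adc`, `d`, `f`.
#' @param reader_icc Target interobserver ICC for the two synthetic
#'   readers (default 0.95).
#' @param dtv_dist `"truncnorm"` (default) or `"lognormal"`.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(sizes = c(none = 29L, sub_centimetre = 10L,
                                  size_significant = 11L),
                        means = default_cohort_moments()$means,
                        sds = default_cohort_moments()$sds,
                        reader_icc = 0.95,
                        dtv_dist = c("truncnorm", "lognormal")) {
  dtv_dist <- match.arg(dtv_dist)
  if (any(sizes < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  if (any(sds <= 0)) stop("feature SDs must be positive", call. = FALSE)
  if (reader_icc <= 0 || reader_icc > 1)
    stop("reader_icc must lie in (0, 1]", call. = FALSE)
  stopifnot(identical(rownames(means), c("dtv", "adc", "d", "f")),
            identical(dim(means), dim(sds)), ncol(means) == length(sizes))
  structure(list(sizes = sizes, means = means, sds = sds,
                 reader_icc = reader_icc, dtv_dist = dtv_dist),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_moments <- function() {
  groups <- c("none", "sub_centimetre", "size_significant")
  means <- matrix(c(22.84, 54.04, 50.18,
                    1.07, 0.98, 0.93,
                    0.91, 0.84, 0.80,
                    0.19, 0.15, 0.16),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("dtv", "adc", "d", "f"), groups))
  sds <- matrix(c(22.84, 52.42, 34.63,
                  0.15, 0.14, 0.11,
                  0.16, 0.12, 0.09,
                  0.04, 0.03, 0.04),
                nrow = 4, byrow = TRUE,
                dimnames = list(c("dtv", "adc", "d", "f"), groups))
  list(means = means, sds = sds)
}

# truncated-normal sampler by rejection; lower/upper are hard bounds
rtrunc_norm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# log-normal with given arithmetic mean/sd (method of moments)
rlnorm_moments <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Simulate a patient cohort with two synthetic readers
#'
#' Draws each patient's tumour features from the group's
#' truncated-Gaussian marginals (these are reader 1's measurements),
#' then derives a second reader's copy by adding Gaussian measurement
#' noise. The noise SD is calibrated per feature as
#' `sd_latent * sqrt(2 * (1 / reader_icc - 1))`, where `sd_latent` is
#' the empirical between-patient SD of the feature across the whole
#' cohort, so the expected two-reader ICC(2,1) equals `reader_icc`.
#' DTV and f noise is truncated so readers stay in the physical range.
#' Pure function of (spec, seed).
#'
#' @param spec A [cohort_spec].
#' @param seed Integer seed (mandatory).
#' @return A data frame with columns `id`, `group` (factor),
#'   `involved` (0/1), `subcm` (sub-centimetre subgroup flag), reader-1
#'   features `dtv`, `adc`, `d`, `f`, and reader-2 features `dtv_2`,
#'   `adc_2`, `d_2`, `f_2`. ADC and D are in the display unit 1e-3
#'   mm^2/s; DTV in cm^3.
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (missing(seed)) stop("a seed is mandatory for cohort simulation", call. = FALSE)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  groups <- names(spec$sizes)
  g <- factor(rep(groups, times = spec$sizes), levels = groups)
  n <- length(g)
  feats <- rownames(spec$means)
  latent <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  for (gi in seq_along(groups)) {
    rows <- which(g == groups[gi])
    for (ft in feats) {
      m <- spec$means[ft, gi]; s <- spec$sds[ft, gi]
      latent[rows, ft] <-
        if (ft == "dtv" && spec$dtv_dist == "lognormal") {
          rlnorm_moments(length(rows), m, s)
        } else if (ft == "f") {
          rtrunc_norm(length(rows), m, s, lower = 0, upper = 1)
        } else {
          rtrunc_norm(length(rows), m, s, lower = 0)
        }
    }
  }

  # reader 1 reports the latent values; reader 2 adds measurement noise.
  # With noise on one reader only, the expected ICC(2,1) is
  # sigma^2 / (sigma^2 + tau^2 / 2), so tau = sigma * sqrt(2 (1/ICC - 1)).
  r1 <- latent
  r2 <- latent
  if (spec$reader_icc < 1) {
    for (ft in feats) {
      tau <- stats::sd(latent[, ft]) * sqrt(2 * (1 / spec$reader_icc - 1))
      v <- latent[, ft] + stats::rnorm(n, 0, tau)
      upper <- if (ft == "f") 1 else Inf
      r2[, ft] <- pmin(pmax(v, 0), upper)
    }
  }

  out <- data.frame(id = seq_len(n), group = g,
                    involved = as.integer(g != "none"),
                    subcm = g == "sub_centimetre")
  out <- cbind(out, as.data.frame(r1),
               stats::setNames(as.data.frame(r2), paste0(feats, "_2")))
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  out
}
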