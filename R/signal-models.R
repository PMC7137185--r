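#' Diffusion-weighting scheme
#'
#' Validates and classes a vector of b-values (diffusion weightings,
#' s/mm^2). The scheme must start at b = 0, be strictly increasing and
#' non-negative, and contain at least two entries. The default is the
#' 13-value acquisition used throughout the package.
#'
#' @param values Numeric vector of b-values in s/mm^2.
#' @return A numeric vector of class `"bvalue_scheme"`.
#' @examples
#' bvalue_scheme()           # the default 13-value scheme
#' bvalue_scheme(c(0, 1000)) # minimal two-point ADC scheme
#' @export
bvalue_scheme <- function(values = default_bvalues()) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a b-value scheme needs at least 2 entries", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("b-values must be finite", call. = FALSE)
  if (values[1L] != 0)
    stop("the first b-value must be 0", call. = FALSE)
  if (any(diff(values) <= 0))
    stop("b-values must be strictly increasing", call. = FALSE)
  structure(values, class = "bvalue_scheme")
}

#' @rdname bvalue_scheme
#' @export
default_bvalues <- function() {
  c(0, 10, 20, 30, 40, 50, 75, 100, 150, 300, 500, 800, 1000)
}

#' Biexponential IVIM signal model
#'
#' Forward model of the diffusion-weighted signal
#' \deqn{S(b) = S_0 \left[ f e^{-b (D + D^*)} + (1 - f) e^{-b D} \right]}
#' where `D` is the pure (tissue) diffusion coefficient, `Dstar` the
#' pseudo-diffusion coefficient of the perfusion compartment, and `f`
#' the perfusion fraction. With `f = 0` it reduces to the
#' monoexponential model `S0 * exp(-b * D)`.
#'
#' @param b Numeric vector of b-values, s/mm^2, all >= 0.
#' @param S0 Unattenuated signal at b = 0 (arbitrary units), >= 0.
#' @param D Pure diffusion coefficient, mm^2/s, >= 0.
#' @param Dstar Pseudo-diffusion coefficient, mm^2/s, >= 0.
#' @param f Perfusion fraction in `[0, 1]`.
#' @return Numeric vector of signals, one per entry of `b`.
#' @examples
#' ivim_signal(c(0, 1000), S0 = 100, D = 0.9e-3, Dstar = 20e-3, f = 0.19)
#' @export
ivim_signal <- function(b, S0 = 1, D = 0, Dstar = 0, f = 0) {
  if (any(b < 0)) stop("b-values must be non-negative", call. = FALSE)
  if (S0 < 0 || D < 0 || Dstar < 0) stop("S0, D and Dstar must be non-negative", call. = FALSE)
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  S0 * (f * exp(-b * (D + Dstar)) + (1 - f) * exp(-b * D))
}

#' Two-point apparent diffusion coefficient
#'
#' Closed-form ADC from a signal pair under the monoexponential model
#' `S_b / S_0 = exp(-b * ADC)`, i.e. `ADC = log(s0 / sb) / b`.
#' Non-positive signals yield `NA` (an invalid voxel, left to the QC
#' stage) rather than an error, so the function can be applied to whole
#' maps. Signal increase with b gives a negative ADC, which is likewise
#' carried through for QC to flag.
#'
#' @param s0 Signal at b = 0. Vectorised.
#' @param sb Signal at the diffusion-weighted b-value. Vectorised.
#' @param b The non-zero b-value, s/mm^2 (scalar, > 0).
#' @return Numeric vector of ADC values in mm^2/s, `NA` where either
#'   signal is non-positive or non-finite.
#' @examples
#' adc_two_point(100, 100 * exp(-1), 1000)  # 1e-3 mm^2/s
#' @export
adc_two_point <- function(s0, sb, b) {
  if (length(b) != 1L || !is.finite(b) || b <= 0)
    stop("b must be a single positive weighting", call. = FALSE)
  n <- max(length(s0), length(sb))
  s0 <- rep_len(s0, n); sb <- rep_len(sb, n)
  bad <- !is.finite(s0) | !is.finite(sb) | s0 <= 0 | sb <= 0
  adc <- rep(NA_real_, n)
  adc[!bad] <- log(s0[!bad] / sb[!bad]) / b
  adc
}

#' Geometric average of three orthogonal diffusion directions
#'
#' Trace-weighted DWI combines motion-probing gradients applied along
#' three orthogonal axes by the elementwise geometric mean, so that the
#' combined signal decays with the mean diffusivity.
#'
#' @param s1,s2,s3 Equal-length non-negative signal vectors, one per
#'   gradient direction.
#' @return The elementwise cube root of the product of the three.
#' @examples
#' geometric_average(1, 8, 27)  # 6
#' @export
geometric_average <- function(s1, s2, s3) {
  if (length(s1) != length(s2) || length(s2) != length(s3))
    stop("directional signals must have equal length", call. = FALSE)
  if (any(s1 < 0) || any(s2 < 0) || any(s3 < 0))
    stop("directional signals must be non-negative", call. = FALSE)
  (s1 * s2 * s3)^(1 / 3)
}
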