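#' In-plane 3x3 Gaussian pre-smoothing
#'
#' Applies a normalised 3x3 Gaussian smoothing kernel to every 2D slice
#' of every b-value image before fitting. The kernel is the separable
#' binomial approximation `(1,2,1) %o% (1,2,1) / 16`; borders are
#' handled by edge reflection, so the kernel mass is conserved (a
#' constant image is unchanged and an impulse anywhere sums to 1).
#'
#' @param study A [dwi_study].
#' @return A [dwi_study] with the same grid and smoothed signals.
#' @export
smooth_study <- function(study) {
  stopifnot(inherits(study, "dwi_study"))
  vol <- study$volume
  d <- dim(vol)
  for (bi in seq_len(d[4L]))
    for (k in seq_len(d[3L]))
      vol[, , k, bi] <- smooth_slice(vol[, , k, bi])
  study$volume <- vol
  study
}

# separable (1,2,1)/4 pass along rows then columns, reflect border
smooth_slice <- function(m) {
  m <- pass_121(m)
  t(pass_121(t(m)))
}

pass_121 <- function(m) {
  n <- nrow(m)
  if (n == 1L) return(m)
  up <- m[c(1L, seq_len(n - 1L)), , drop = FALSE]    # reflected at the top edge
  dn <- m[c(seq_len(n - 1L) + 1L, n), , drop = FALSE] # reflected at the bottom edge
  (up + 2 * m + dn) / 4
}
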