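#' Diffusion tumour volume
#'
#' DTV is the tumour area on the b1000 images times the slice
#' thickness: (number of mask voxels) x in-plane voxel area x
#' (slice thickness + intersection gap), converted from mm^3 to cm^3.
#' The gap term makes the formula correct for protocols with
#' non-contiguous slices; with gap 0 it is the plain area-times-
#' thickness definition. All mask voxels count: QC exclusion does not
#' shrink the DTV, which is defined purely by b1000 hyperintensity.
#'
#' @param voi A [tumour_voi].
#' @return Volume in cm^3; an empty mask returns 0 with a warning.
#' @examples
#' m <- array(FALSE, c(20, 20, 1)); m[1:10, 1:10, 1] <- TRUE
#' compute_dtv(tumour_voi(m, spacing = c(2, 2), thickness = 4))  # 1.6 cm^3
#' @export
compute_dtv <- function(voi) {
  stopifnot(inherits(voi, "tumour_voi"))
  n <- sum(voi$mask)
  if (n == 0L) {
    warning("empty tumour mask; DTV is 0", call. = FALSE)
    return(0)
  }
  g <- voi$geometry
  n * g$spacing[1L] * g$spacing[2L] * (g$thickness + g$gap) / 1000
}

# sample skewness g1 and (Pearson, non-excess) kurtosis m4/m2^2
sample_skewness <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^3) / s2^1.5
}
sample_kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2
}

#' VOI-level summary of the parametric maps
#'
#' Summarises ADC, D and f over the tumour volume of interest:
#' mean, percentiles (10/25/50/75/90, linear interpolation between
#' order statistics, i.e. [stats::quantile] type 7), skewness and
#' kurtosis, computed over the mask voxels that survived QC. The DTV
#' comes from the full mask regardless of QC. D* is deliberately not
#' summarised.
#'
#' @param maps An [ivim_maps][fit_ivim] object.
#' @param voi A [tumour_voi] on the same grid.
#' @return An object of class `"tumour_summary"`; if no mask voxel is
#'   QC-valid the summary is flagged unusable (`usable = FALSE`).
#' @export
summarize_voi <- function(maps, voi) {
  stopifnot(inherits(maps, "ivim_maps"), inherits(voi, "tumour_voi"))
  if (any(dim(voi$mask) != dim(maps$valid)))
    stop("VOI grid does not match the parametric maps", call. = FALSE)
  sel <- voi$mask & maps$valid
  n_used <- sum(sel)
  dtv <- compute_dtv(voi)
  one <- function(map) {
    v <- map[sel]
    if (!length(v))
      return(c(mean = NA, p10 = NA, p25 = NA, p50 = NA, p75 = NA, p90 = NA,
               skewness = NA, kurtosis = NA))
    q <- stats::quantile(v, c(.10, .25, .50, .75, .90), names = FALSE, type = 7)
    c(mean = mean(v), p10 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p90 = q[5],
      skewness = sample_skewness(v), kurtosis = sample_kurtosis(v))
  }
  structure(list(dtv = dtv,
                 adc = one(maps$adc), d = one(maps$d), f = one(maps$f),
                 n_voxels_mask = sum(voi$mask), n_voxels_used = n_used,
                 usable = n_used > 0L),
            class = "tumour_summary")
}

#' @export
print.tumour_summary <- function(x, ...) {
  cat(sprintf("Tumour summary: DTV %.3f cm^3, %d/%d voxels after QC%s\n",
              x$dtv, x$n_voxels_used, x$n_voxels_mask,
              if (x$usable) "" else "  [UNUSABLE: no valid voxels]"))
  tab <- rbind(adc = x$adc, d = x$d, f = x$f)
  print(signif(tab, 4))
  invisible(x)
}

#' Flatten a tumour summary to one data-frame row
#'
#' Column names are `dtv`, `n_voxels_used`, and `<param>_<stat>` for
#' each of adc/d/f and mean/p10/p25/p50/p75/p90/skewness/kurtosis.
#'
#' @param x A `tumour_summary`.
#' @param row.names,optional,... Passed through for the generic.
#' @export
as.data.frame.tumour_summary <- function(x, row.names = NULL, optional = FALSE, ...) {
  cols <- c(list(dtv = x$dtv, n_voxels_used = x$n_voxels_used),
            as.list(stats::setNames(x$adc, paste0("adc_", names(x$adc)))),
            as.list(stats::setNames(x$d, paste0("d_", names(x$d)))),
            as.list(stats::setNames(x$f, paste0("f_", names(x$f)))))
  as.data.frame(cols, row.names = row.names)
}
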