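#' A diffusion-weighted MR study
#'
#' Container for one patient's 4D DWI acquisition: the signal volume,
#' its b-value scheme and the voxel geometry. The volume is indexed
#' `[row, col, slice, b]`, matching the natural NIfTI axis order with
#' the b-value index last.
#'
#' @param volume 4D numeric array; the 4th dimension must match the
#'   scheme length.
#' @param bvalues A [bvalue_scheme] (or coercible numeric vector).
#' @param spacing In-plane voxel spacing, mm, length-2 (row, col).
#' @param thickness Slice thickness, mm.
#' @param gap Intersection gap between slices, mm (default 0).
#' @return An object of class `"dwi_study"`.
#' @export
dwi_study <- function(volume, bvalues, spacing = c(1, 1), thickness = 1, gap = 0) {
  if (!is.array(volume) || length(dim(volume)) != 4L)
    stop("volume must be a 4D array (row, col, slice, b)", call. = FALSE)
  bvalues <- bvalue_scheme(bvalues)
  if (dim(volume)[4L] != length(bvalues))
    stop(sprintf("volume has %d b-frames but the scheme has %d b-values",
                 dim(volume)[4L], length(bvalues)), call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(spacing <= 0))
    stop("spacing must be two positive lengths (mm)", call. = FALSE)
  if (thickness <= 0) stop("slice thickness must be positive", call. = FALSE)
  if (gap < 0) stop("intersection gap must be non-negative", call. = FALSE)
  structure(list(volume = volume, bvalues = bvalues,
                 geometry = list(spacing = spacing, thickness = thickness, gap = gap)),
            class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  d <- dim(x$volume)
  cat(sprintf("DWI study: %d x %d x %d voxels, %d b-values (%g-%g s/mm^2)\n",
              d[1], d[2], d[3], d[4], min(x$bvalues), max(x$bvalues)))
  cat(sprintf("  voxel %g x %g mm, slice %g mm, gap %g mm\n",
              x$geometry$spacing[1], x$geometry$spacing[2],
              x$geometry$thickness, x$geometry$gap))
  invisible(x)
}

#' Tumour volume of interest
#'
#' A binary mask on the study grid together with the voxel geometry
#' needed for volumetry. Masks are taken as drawn on the b1000 images;
#' no resampling is ever performed, the grid must match exactly.
#'
#' @param mask 3D logical (or 0/1) array.
#' @param spacing,thickness,gap Voxel geometry as in [dwi_study].
#' @return An object of class `"tumour_voi"`.
#' @export
tumour_voi <- function(mask, spacing = c(1, 1), thickness = 1, gap = 0) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  structure(list(mask = mask,
                 geometry = list(spacing = as.numeric(spacing),
                                 thickness = thickness, gap = gap)),
            class = "tumour_voi")
}

#' @export
print.tumour_voi <- function(x, ...) {
  cat(sprintf("Tumour VOI: %d voxels on a %s grid\n",
              sum(x$mask), paste(dim(x$mask), collapse = " x ")))
  invisible(x)
}

#' Read b-values from a plain-text file
#'
#' Reads an FSL-style `.bval` file: whitespace-separated weightings on
#' one (or more) lines.
#'
#' @param path Path to the bval file.
#' @return Numeric vector of b-values (unvalidated; ordering is checked
#'   against the volume by [read_dwi]).
#' @export
read_bvals <- function(path) {
  scan(path, what = numeric(), quiet = TRUE)
}

#' Read a 4D DWI volume with its b-value table
#'
#' Loads a NIfTI-1 volume and an FSL-style bval file into a
#' [dwi_study]. Geometry (in-plane spacing and slice thickness) is
#' taken from the NIfTI `pixdim`; NIfTI does not record an
#' intersection gap, so pass one explicitly if the protocol used one.
#' If the b-values are not ascending, both the table and the volume
#' are reordered to ascending order and a message is emitted.
#'
#' @param volume_path Path to a 4D NIfTI-1 file.
#' @param bval_path Path to the matching bval file.
#' @param gap Intersection gap in mm (default 0).
#' @return A [dwi_study].
#' @export
read_dwi <- function(volume_path, bval_path, gap = 0) {
  img <- RNifti::readNifti(volume_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume, got %d dimensions", length(dim(arr))),
         call. = FALSE)
  bvals <- read_bvals(bval_path)
  if (length(bvals) != dim(arr)[4L])
    stop(sprintf("bval file has %d entries but the volume has %d b-frames",
                 length(bvals), dim(arr)[4L]), call. = FALSE)
  ord <- order(bvals)
  if (any(ord != seq_along(bvals))) {
    message("b-values not ascending; reordering volume to ascending b")
    bvals <- bvals[ord]
    arr <- arr[, , , ord, drop = FALSE]
  }
  pd <- RNifti::pixdim(img)
  dwi_study(arr, bvalues = bvals, spacing = pd[1:2], thickness = pd[3], gap = gap)
}

#' Read a tumour mask on the study grid
#'
#' Loads a binary NIfTI-1 mask and checks it against the study: the 3D
#' grid must match exactly (no silent resampling). Nonzero voxels
#' become `TRUE`.
#'
#' @param path Path to the mask NIfTI file.
#' @param study The [dwi_study] the mask belongs to.
#' @return A [tumour_voi] carrying the study geometry.
#' @export
read_mask <- function(path, study) {
  stopifnot(inherits(study, "dwi_study"))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L)
    arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L || any(dim(arr) != dim(study$volume)[1:3]))
    stop(sprintf("mask grid (%s) does not match study grid (%s)",
                 paste(dim(arr), collapse = "x"),
                 paste(dim(study$volume)[1:3], collapse = "x")), call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  if (any(abs(pd - c(study$geometry$spacing, study$geometry$thickness)) > 1e-4))
    stop("mask voxel dimensions do not match the study", call. = FALSE)
  tumour_voi(arr != 0, spacing = study$geometry$spacing,
             thickness = study$geometry$thickness, gap = study$geometry$gap)
}

#' Write a study to NIfTI + bval files
#'
#' Serialises a [dwi_study] as a 4D NIfTI-1 volume plus an FSL-style
#' bval text file, so that synthetic phantoms round-trip through the
#' same readers as clinical data.
#'
#' @param study A [dwi_study].
#' @param volume_path,bval_path Output paths.
#' @return Invisibly, the volume path.
#' @export
write_dwi <- function(study, volume_path, bval_path) {
  stopifnot(inherits(study, "dwi_study"))
  img <- RNifti::asNifti(study$volume)
  RNifti::pixdim(img) <- c(study$geometry$spacing, study$geometry$thickness, 1)
  RNifti::writeNifti(img, volume_path)
  cat(paste(format(as.numeric(study$bvalues), trim = TRUE), collapse = " "),
      "\n", sep = "", file = bval_path)
  invisible(volume_path)
}

#' Write parametric maps to NIfTI files
#'
#' Writes one 3D float NIfTI per map (`adc`, `d`, `dstar`, `f`,
#' `valid`) plus a JSON fit report (invalid-voxel counts by cause and
#' the fitting configuration). Diffusion coefficients can be written
#' either in SI units (mm^2/s, the default) or in the display unit
#' 1e-3 mm^2/s commonly used in tables.
#'
#' @param maps An [ivim_maps][fit_ivim] object.
#' @param dir Output directory (created if needed).
#' @param units `"si"` for mm^2/s or `"display"` for 1e-3 mm^2/s.
#' @return Invisibly, the named vector of file paths.
#' @export
write_maps <- function(maps, dir, units = c("si", "display")) {
  stopifnot(inherits(maps, "ivim_maps"))
  units <- match.arg(units)
  scale <- if (units == "display") 1e3 else 1
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- maps$geometry
  out <- c(adc = "adc.nii.gz", d = "d.nii.gz", dstar = "dstar.nii.gz",
           f = "f.nii.gz", valid = "valid.nii.gz")
  paths <- file.path(dir, out)
  names(paths) <- names(out)
  vals <- list(adc = maps$adc * scale, d = maps$d * scale,
               dstar = maps$dstar * scale, f = maps$f,
               valid = array(as.numeric(maps$valid), dim = dim(maps$valid)))
  for (nm in names(vals)) {
    img <- RNifti::asNifti(vals[[nm]])
    RNifti::pixdim(img) <- c(g$spacing, g$thickness)
    RNifti::writeNifti(img, paths[[nm]])
  }
  report <- list(units = units,
                 n_voxels = length(maps$valid),
                 n_invalid = sum(!maps$valid),
                 invalid_by_cause = as.list(table(maps$cause[maps$cause != "ok"])),
                 config = if (!is.null(maps$config)) unclass(maps$config))
  jsonlite::write_json(report, file.path(dir, "fit_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
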