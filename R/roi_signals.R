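#' Spherical region-of-interest specification
#'
#' Describes a spherical ROI by its centre in world (MNI) millimetre
#' coordinates and its radius. The default pipeline uses exactly two ROIs:
#' the posterior cingulate cortex (PCC) and the dorsal anterior cingulate
#' cortex (dACC), the canonical default-mode / salience node pair for
#' resting-state connectivity work.
#'
#' @param name Region label.
#' @param center Numeric length-3 vector, centre in mm (world space).
#' @param radius Sphere radius in mm; must be positive.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec("pcc", c(-5, -49, 40), 7.5)
#' @export
roi_spec <- function(name, center, radius) {
  stopifnot(is.character(name), length(name) == 1L)
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center)) {
    stop("`center` must be a numeric 3-vector in mm")
  }
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0) {
    stop("`radius` must be a single positive number (mm)")
  }
  structure(list(name = name, center = center, radius = radius),
            class = "roi_spec")
}

#' Default ROI pair: PCC and dACC
#'
#' Spherical ROIs of radius 7.5 mm centred at MNI (-5, -49, 40) for the
#' posterior cingulate cortex and (8, 7, 38) for the dorsal anterior
#' cingulate cortex.
#'
#' @return A named list of two [roi_spec] objects.
#' @export
default_rois <- function() {
  list(pcc  = roi_spec("pcc",  c(-5, -49, 40), 7.5),
       dacc = roi_spec("dacc", c(8, 7, 38),   7.5))
}

#' Build a spherical voxel mask from an ROI specification
#'
#' A voxel belongs to the mask when its centre, mapped through the volume's
#' voxel-to-world affine, lies within `spec$radius` mm (Euclidean) of the ROI
#' centre. Membership is decided purely by voxel-centre distance; no
#' partial-volume weighting. The affine is authoritative for orientation
#' (RAS vs LPS storage never enters).
#'
#' Voxel indices are 1-based on the R array grid; the affine is assumed to
#' map 0-based voxel coordinates to mm, the NIfTI convention.
#'
#' @param spec An [roi_spec].
#' @param affine 4x4 voxel-to-world matrix (0-based voxel convention).
#' @param grid_shape Integer length-3 vector of grid dimensions.
#' @return Integer matrix with one row per mask voxel and columns i, j, k
#'   (1-based array indices).
#' @export
build_spherical_mask <- function(spec, affine, grid_shape) {
  stopifnot(inherits(spec, "roi_spec"))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps) {
    stop("`affine` must be an invertible 4x4 matrix")
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    stop("`grid_shape` must be three positive integers")
  }

  # Bounding box in voxel space around the sphere keeps the candidate set
  # small: map the centre back to voxel coords and pad by radius / min
  # voxel edge length.
  inv <- solve(affine)
  vcenter <- (inv %*% c(spec$center, 1))[1:3]
  edge <- sqrt(colSums(affine[1:3, 1:3]^2))  # mm per voxel step along each axis
  pad <- ceiling(spec$radius / min(edge)) + 1L
  lo <- pmax(floor(vcenter) - pad, 0)
  hi <- pmin(ceiling(vcenter) + pad, grid_shape - 1L)
  if (any(lo > hi)) {
    stop(sprintf("ROI '%s' lies outside the field of view", spec$name))
  }

  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  mm <- cand %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(cand), 3, byrow = TRUE)
  d2 <- rowSums(sweep(mm, 2, spec$center)^2)
  keep <- cand[d2 <= spec$radius^2, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop(sprintf("ROI '%s': no voxel centre falls within %g mm of (%s)",
                 spec$name, spec$radius,
                 paste(spec$center, collapse = ", ")))
  }
  mask <- keep + 1L  # back to 1-based array indices
  storage.mode(mask) <- "integer"
  colnames(mask) <- c("i", "j", "k")
  mask[order(mask[, 1], mask[, 2], mask[, 3]), , drop = FALSE]
}

#' Extract the mean signal over a voxel mask from a 4D volume sequence
#'
#' The representative signal of a region is the arithmetic mean across mask
#' voxels of the per-volume values, one value per acquired volume.
#'
#' @param volumes 4D numeric array (x, y, z, time).
#' @param mask Integer matrix of 1-based voxel indices (columns i, j, k),
#'   as returned by [build_spherical_mask()].
#' @param subject_id,region Labels attached to the result.
#' @param dt Sampling interval in seconds (the TR).
#' @return An `roi_series` object: list with `subject_id`, `region`,
#'   `values` (length T), `dt`.
#' @export
extract_mean_signal <- function(volumes, mask, subject_id = "subject",
                                region = "roi", dt = 2) {
  stopifnot(length(dim(volumes)) == 4L, is.matrix(mask), ncol(mask) == 3L,
            nrow(mask) >= 1L)
  dims <- dim(volumes)
  if (any(mask < 1L) || any(mask[, 1] > dims[1]) || any(mask[, 2] > dims[2]) ||
      any(mask[, 3] > dims[3])) {
    stop("mask voxel indices fall outside the volume grid")
  }
  n_t <- dims[4]
  flat <- matrix(volumes, prod(dims[1:3]), n_t)
  lin <- mask[, 1] + dims[1] * (mask[, 2] - 1L) +
    dims[1] * dims[2] * (mask[, 3] - 1L)
  values <- colMeans(flat[lin, , drop = FALSE])
  roi_series(subject_id, region, values, dt)
}

#' Construct an ROI time-series object
#'
#' @param subject_id,region Labels.
#' @param values Numeric vector of length T >= 30 (the per-volume signal).
#' @param dt Sampling interval in seconds; must be positive.
#' @return An object of class `roi_series`.
#' @export
roi_series <- function(subject_id, region, values, dt) {
  values <- as.numeric(values)
  if (length(values) < 30L) {
    stop("ROI series must contain at least 30 samples")
  }
  if (anyNA(values)) stop("ROI series contains NA values")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a positive sampling interval in seconds")
  }
  structure(list(subject_id = as.character(subject_id),
                 region = as.character(region),
                 values = values, dt = dt),
            class = "roi_series")
}

#' @export
print.roi_series <- function(x, ...) {
  cat(sprintf("<roi_series> subject %s, region %s: T = %d, dt = %g s\n",
              x$subject_id, x$region, length(x$values), x$dt))
  invisible(x)
}

#' Normalise a signal to mean zero and variance one
#'
#' Uses the population (1/T) variance so the unit-variance property holds
#' exactly on the data at hand. Idempotent up to numerical tolerance.
#'
#' @param x An `roi_series` or plain numeric vector.
#' @return Object of the same type with normalised values.
#' @export
znormalize <- function(x) {
  v <- if (inherits(x, "roi_series")) x$values else as.numeric(x)
  m <- mean(v)
  s2 <- mean((v - m)^2)
  if (s2 <= 0) stop("cannot z-normalize a constant series (zero variance)")
  out <- (v - m) / sqrt(s2)
  if (inherits(x, "roi_series")) {
    x$values <- out
    x
  } else {
    out
  }
}

#' Read a two-column region time-series table
#'
#' Tab-delimited, one header row of region names, one data row per volume.
#' This text path makes the whole pipeline runnable without any imaging file.
#'
#' @param path File path of the TSV.
#' @param dt Sampling interval in seconds.
#' @param subject_id Label attached to each returned series.
#' @return Named list of `roi_series`, one per column.
#' @export
read_series_tsv <- function(path, dt = 2, subject_id = "subject") {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (ncol(tab) < 2L) stop(sprintf("%s: expected at least two region columns", path))
  out <- lapply(names(tab), function(nm) {
    roi_series(subject_id, nm, tab[[nm]], dt)
  })
  names(out) <- names(tab)
  out
}

#' Write region time series as a TSV table
#'
#' @param series Named list of `roi_series` of equal length.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_tsv <- function(series, path) {
  lens <- vapply(series, function(s) length(s$values), integer(1))
  stopifnot(length(unique(lens)) == 1L)
  tab <- as.data.frame(lapply(series, function(s) s$values))
  names(tab) <- vapply(series, function(s) s$region, character(1))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the default ROI pair from a 4D NIfTI file
#'
#' Reads the image, builds the spherical masks through the image's
#' voxel-to-world affine, and returns the z-normalised mean signal of each
#' region.
#'
#' @param nifti_path Path to a 4D NIfTI-1 image in world (MNI) space.
#' @param rois List of [roi_spec]; defaults to the PCC/dACC pair.
#' @param subject_id Label attached to the series.
#' @param normalize Z-normalise each signal (default TRUE).
#' @return Named list of `roi_series`.
#' @export
extract_roi_signals <- function(nifti_path, rois = default_rois(),
                                subject_id = "subject", normalize = TRUE) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop(sprintf("%s: expected a 4D image", nifti_path))
  affine <- structure(RNifti::xform(img), class = NULL)
  dt <- RNifti::pixdim(img)[4]
  if (!is.finite(dt) || dt <= 0) dt <- 2
  out <- lapply(rois, function(spec) {
    mask <- build_spherical_mask(spec, affine, dim(arr)[1:3])
    s <- extract_mean_signal(arr, mask, subject_id, spec$name, dt)
    if (normalize) znormalize(s) else s
  })
  names(out) <- vapply(rois, function(spec) spec$name, character(1))
  out
}
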