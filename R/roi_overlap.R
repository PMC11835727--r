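# Voxel-mask utilities: across-subject density maps of spectroscopy voxel
# placement, overlap percentages between masks (e.g. an fMRI cluster and the
# MRS voxel coverage), ROI mean extraction, and the spectroscopy quality
# filter with CSF-fraction concentration correction. Masks are plain 3-D
# logical arrays in a common, pre-aligned grid; registration/resampling is
# out of scope.

.check_mask <- function(mask, name = "mask") {
  if (!is.array(mask) || length(dim(mask)) != 3) {
    stop(name, " must be a 3-D array")
  }
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  mask
}

#' Across-subject voxel density map
#'
#' Per-voxel fraction of subjects whose mask covers that voxel.
#'
#' @param masks A list of 3-D logical arrays with a common shape.
#' @return A numeric 3-D array of coverage fractions in \[0, 1\], with the
#'   number of subjects attached as attribute `n_subjects`.
#' @export
density_map <- function(masks) {
  stopifnot(length(masks) >= 1)
  masks <- lapply(seq_along(masks), function(i) {
    .check_mask(masks[[i]], paste0("masks[[", i, "]]"))
  })
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("all masks must share the same shape")
  }
  dens <- Reduce(`+`, lapply(masks, function(m) m * 1)) / length(masks)
  attr(dens, "n_subjects") <- length(masks)
  dens
}

#' Threshold a density map into a mask
#'
#' Keeps voxels covered in at least `cutoff` of the subjects (inclusive
#' boundary: a voxel at exactly the cutoff is retained).
#'
#' @param density A density array from [density_map()].
#' @param cutoff Coverage fraction in (0, 1]; default 0.9.
#' @return A 3-D logical mask.
#' @export
threshold_density <- function(density, cutoff = 0.9) {
  stopifnot(is.numeric(density), length(dim(density)) == 3,
            cutoff > 0, cutoff <= 1)
  mask <- density >= cutoff
  attr(mask, "n_subjects") <- NULL
  mask
}

#' Overlap statistics between two masks
#'
#' Percentage of each mask's voxels also present in the other, plus raw
#' voxel counts.
#'
#' @param mask_a,mask_b 3-D logical arrays of identical shape, both
#'   non-empty.
#' @return A list: `pct_a_in_b`, `pct_b_in_a` (percentages), `n_a`, `n_b`,
#'   `n_intersect`.
#' @examples
#' a <- array(FALSE, c(2, 2, 2)); b <- a
#' a[1:2, 1, 1] <- TRUE; b[1, 1, 1:2] <- TRUE
#' overlap_stats(a, b)
#' @export
overlap_stats <- function(mask_a, mask_b) {
  mask_a <- .check_mask(mask_a, "mask_a")
  mask_b <- .check_mask(mask_b, "mask_b")
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shapes differ")
  n_a <- sum(mask_a)
  n_b <- sum(mask_b)
  if (n_a == 0 || n_b == 0) stop("masks must be non-empty")
  n_ab <- sum(mask_a & mask_b)
  list(pct_a_in_b = 100 * n_ab / n_a,
       pct_b_in_a = 100 * n_ab / n_b,
       n_a = n_a, n_b = n_b, n_intersect = n_ab)
}

#' Mean activity within a mask
#'
#' @param activity_grid A numeric 3-D array (e.g. a regression-estimate
#'   map).
#' @param mask A 3-D logical mask of the same shape, non-empty.
#' @return The arithmetic mean of the in-mask voxels.
#' @export
roi_mean <- function(activity_grid, mask) {
  mask <- .check_mask(mask)
  stopifnot(is.numeric(activity_grid),
            identical(dim(activity_grid), dim(mask)))
  if (sum(mask) == 0) stop("mask is empty")
  mean(activity_grid[mask])
}

#' Spectroscopy quality filter and CSF-fraction correction
#'
#' Excludes metabolite concentrations whose Cramer-Rao lower bound exceeds
#' the cutoff (strictly: a CRLB equal to the cutoff is retained) and
#' corrects the survivors for the CSF fraction of the voxel, rescaling to
#' tissue water:
#' `corrected = raw * (fGM wGM + fWM wWM + fCSF wCSF) / (fGM wGM + fWM wWM)`
#' with water concentrations `wGM = 43300`, `wWM = 35880`,
#' `wCSF = 55556` mM. A voxel with no CSF is left unchanged; the correction
#' grows monotonically with the CSF fraction.
#'
#' @param records A data frame with columns `crlb` (fraction), `fGM`, `fWM`,
#'   `fCSF` (tissue fractions summing to 1 within 1e-6) and
#'   `raw_concentration`.
#' @param crlb_cutoff CRLB exclusion cutoff as a fraction (default 0.5).
#' @param water Named numeric vector of water concentrations (mM) for `gm`,
#'   `wm`, `csf`.
#' @return A list: `records` (survivors with a `corrected` column) and
#'   `excluded` (integer row indices of excluded records).
#' @examples
#' qc <- data.frame(crlb = c(0.1, 0.6), fGM = 0.6, fWM = 0.2, fCSF = 0.2,
#'                  raw_concentration = 1)
#' mrs_filter_and_correct(qc)
#' @export
mrs_filter_and_correct <- function(records, crlb_cutoff = 0.5,
                                   water = c(gm = 43300, wm = 35880,
                                             csf = 55556)) {
  needed <- c("crlb", "fGM", "fWM", "fCSF", "raw_concentration")
  if (!all(needed %in% names(records))) {
    stop("records must have columns ", paste(needed, collapse = ", "))
  }
  f <- records[, c("fGM", "fWM", "fCSF")]
  if (any(f < 0) || any(f > 1) ||
      any(abs(rowSums(f) - 1) > 1e-6)) {
    stop("tissue fractions must lie in [0, 1] and sum to 1 (within 1e-6)")
  }
  if (any(records$fGM + records$fWM == 0)) {
    stop("voxel with no brain tissue (fGM + fWM = 0); cannot correct")
  }
  excluded <- which(records$crlb > crlb_cutoff)
  kept <- records[setdiff(seq_len(nrow(records)), excluded), , drop = FALSE]
  tissue_water <- kept$fGM * water[["gm"]] + kept$fWM * water[["wm"]]
  total_water <- tissue_water + kept$fCSF * water[["csf"]]
  kept$corrected <- kept$raw_concentration * total_water / tissue_water
  list(records = kept, excluded = excluded)
}

#' Read a voxel mask from a NIfTI file
#'
#' @param path Path to a NIfTI image.
#' @param threshold Values strictly above this become TRUE (default 0.5).
#' @return A 3-D logical array.
#' @export
read_voxel_mask <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img) > threshold, dim = dim(img)[1:3])
  arr
}

#' Write a voxel mask (or density map) to a NIfTI file
#'
#' @param grid A 3-D logical mask or numeric density array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_voxel_mask <- function(grid, path) {
  stopifnot(length(dim(grid)) == 3)
  RNifti::writeNifti(array(as.numeric(grid), dim = dim(grid)), path)
  invisible(path)
}
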