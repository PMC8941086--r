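# Per-experiment modeled-activation (MA) maps.
#
# Each focus is convolved with an isotropic 3-D Gaussian whose width encodes
# the spatial uncertainty of the reported peak; the width shrinks with the
# sample size of the patient group (between-subject variance averages out)
# towards a floor set by between-template variance.  Within an experiment
# foci are combined voxel-wise by maximum, so several nearby peaks cannot
# inflate one experiment's contribution.

#' Kernel specification for modeled activation
#'
#' `FWHM(n) = sqrt(fwhm_subject^2 / n + fwhm_template^2)`: strictly
#' decreasing in the sample size n with floor `fwhm_template`.  Defaults are
#' the empirical uncertainty constants standard in the ALE literature.
#'
#' @param fwhm_subject_mm between-subject FWHM component (mm), default 11.6.
#' @param fwhm_template_mm between-template FWHM floor (mm), default 5.7.
#' @param truncation_radius_sd kernel support radius in standard deviations,
#'   default 3.5; the discretized kernel is renormalized to unit mass over
#'   this truncated support.
#' @param sample_size which sample size drives the kernel width:
#'   `"cases"` (default; the map encodes the case-vs-control contrast
#'   uncertainty) or `"total"` (cases + controls).
#' @return a `kernel_spec`.
#' @export
kernel_spec <- function(fwhm_subject_mm = 11.6, fwhm_template_mm = 5.7,
                        truncation_radius_sd = 3.5,
                        sample_size = c("cases", "total")) {
  stopifnot(fwhm_subject_mm >= 0, fwhm_template_mm > 0,
            truncation_radius_sd > 0)
  structure(list(fwhm_subject_mm = fwhm_subject_mm,
                 fwhm_template_mm = fwhm_template_mm,
                 truncation_radius_sd = truncation_radius_sd,
                 sample_size = match.arg(sample_size)),
            class = "kernel_spec")
}

#' Sample-size-dependent kernel FWHM
#'
#' @param n_cases sample size (>= 1).
#' @param spec a [kernel_spec()].
#' @return FWHM in mm.
#' @export
kernel_fwhm <- function(n_cases, spec = kernel_spec()) {
  if (any(n_cases < 1)) stop("n_cases must be >= 1")
  sqrt(spec$fwhm_subject_mm^2 / n_cases + spec$fwhm_template_mm^2)
}

FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

# Discretize the truncated Gaussian on the grid's voxel lattice.
# Returns integer voxel offsets (k x 3), probability-per-voxel values
# summing to 1 over the truncated support, and the central (peak) value.
build_kernel <- function(fwhm_mm, grid, spec) {
  sigma <- fwhm_mm * FWHM_TO_SD
  r_mm <- sigma * spec$truncation_radius_sd
  voxel_size <- grid$voxel_size
  half <- floor(r_mm / voxel_size)
  ax <- lapply(1:3, function(k) (-half[k]:half[k]) * voxel_size[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  keep <- d2 <= r_mm^2
  idx <- which(keep, arr.ind = TRUE)
  offsets <- cbind(idx[, 1] - half[1] - 1L, idx[, 2] - half[2] - 1L,
                   idx[, 3] - half[3] - 1L)
  storage.mode(offsets) <- "integer"
  g <- exp(-d2[keep] / (2 * sigma^2))
  vals <- g / sum(g)
  list(offsets = offsets, values = vals,
       peak = max(vals), fwhm_mm = fwhm_mm)
}

#' Build the modeled-activation map of one experiment
#'
#' Places the experiment's discretized Gaussian kernel at each focus (after
#' nearest-voxel rounding) and combines across foci by voxel-wise maximum.
#' Out-of-mask foci are retained: their kernels contribute wherever the
#' truncated support intersects the mask.
#'
#' @param experiment an [experiment_record()] with MNI foci.
#' @param grid a [brain_grid()].
#' @param spec a [kernel_spec()].
#' @return an `ma_map`: list with `experiment_id`, `voxmap` (a
#'   [voxel_map()] with values in `[0, 1]`), `kernel_fwhm_mm`.
#' @export
build_ma_map <- function(experiment, grid, spec = kernel_spec()) {
  n <- if (spec$sample_size == "cases") experiment$n_cases
       else experiment$n_cases + experiment$n_controls
  kern <- build_kernel(kernel_fwhm(n, spec), grid, spec)
  values <- place_kernels(experiment$foci, kern, grid)
  if (max(values) == 0)
    warning("experiment ", experiment$experiment_id,
            ": no focus within the truncation radius of the mask; ",
            "MA map is all-zero")
  structure(list(experiment_id = experiment$experiment_id,
                 voxmap = voxel_map(grid, values),
                 kernel_fwhm_mm = kern$fwhm_mm),
            class = "ma_map")
}

place_kernels <- function(foci_mm, kern, grid) {
  vox <- world_to_voxel(grid, foci_mm)
  cpp_ma_map(vox, kern$offsets, kern$values, grid$shape,
             mask_positions(grid), grid$n_mask_voxels)
}

#' Experiment-by-voxel MA matrix
#'
#' Stacks every experiment's MA map (flattened in mask order) into an
#' `n_experiments x n_mask_voxels` matrix, the input to the similarity /
#' clustering stage.
#'
#' @param corp a `corpus` (>= 2 experiments).
#' @param grid a [brain_grid()].
#' @param spec a [kernel_spec()].
#' @return numeric matrix, rownames = experiment IDs, with attribute
#'   `kernel_fwhm_mm` (per-row kernel width).
#' @export
ma_matrix <- function(corp, grid, spec = kernel_spec()) {
  if (length(corp) < 2L) stop("ma_matrix needs >= 2 experiments")
  mpos <- mask_positions(grid)
  fwhms <- numeric(length(corp))
  kern_cache <- new.env(parent = emptyenv())
  m <- matrix(0, nrow = length(corp), ncol = grid$n_mask_voxels,
              dimnames = list(corpus_ids(corp), NULL))
  for (i in seq_along(corp$experiments)) {
    e <- corp$experiments[[i]]
    n <- if (spec$sample_size == "cases") e$n_cases
         else e$n_cases + e$n_controls
    key <- as.character(n)
    if (is.null(kern_cache[[key]]))
      kern_cache[[key]] <- build_kernel(kernel_fwhm(n, spec), grid, spec)
    kern <- kern_cache[[key]]
    fwhms[i] <- kern$fwhm_mm
    vox <- world_to_voxel(grid, e$foci)
    m[i, ] <- cpp_ma_map(vox, kern$offsets, kern$values, grid$shape,
                         mpos, grid$n_mask_voxels)
    if (max(m[i, ]) == 0)
      warning("experiment ", e$experiment_id, ": all-zero MA row")
  }
  attr(m, "kernel_fwhm_mm") <- setNames(fwhms, corpus_ids(corp))
  m
}
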