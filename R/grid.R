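#' PET voxel grid
#'
#' A `voxel_grid` is a 3D scalar field of standardized uptake values (SUV)
#' together with its physical voxel spacing. It is the in-memory form of a
#' PET volume; [read_pet_nifti()] and [write_pet_nifti()] convert to NIfTI.
#' Physical coordinates are in millimetres with the origin at the centre of
#' the first voxel, so voxel `(i, j, k)` sits at
#' `((i - 1) * sx, (j - 1) * sy, (k - 1) * sz)`.
#'
#' @param values 3D numeric array of SUV values, all non-negative.
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @return An object of class `voxel_grid`: a list with elements `values`
#'   and `spacing_mm`.
#' @examples
#' g <- voxel_grid(array(1, dim = c(4, 4, 4)), spacing_mm = c(2, 2, 2))
#' voxel_volume_ml(g)
#' @export
voxel_grid <- function(values, spacing_mm) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  if (anyNA(values) || any(values < 0))
    stop("SUV values must be non-negative and non-missing")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be a positive numeric triple")
  structure(list(values = values, spacing_mm = spacing_mm),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  SUV range [%.3g, %.3g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Volume of a single voxel in millilitres
#'
#' @param grid a [voxel_grid].
#' @return Scalar voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing_mm) / 1000
}

#' Physical coordinates (mm) of voxels given by linear index
#'
#' @param grid a [voxel_grid].
#' @param index integer vector of linear voxel indices into `grid$values`.
#' @return Numeric matrix with one row per index and columns `x`, `y`, `z`
#'   in mm (origin at the first voxel centre).
#' @export
voxel_coords_mm <- function(grid, index) {
  stopifnot(inherits(grid, "voxel_grid"))
  ijk <- arrayInd(as.integer(index), dim(grid$values))
  out <- sweep(ijk - 1, 2, grid$spacing_mm, `*`)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Organ segmentation mask set
#'
#' Binary masks congruent with a PET grid for the organs the pipeline needs:
#' the two reference organs (liver, blood pool/aorta) and the three anatomic
#' disease compartments (prostate/prostate bed, skeleton for osseous disease,
#' and the nodal region). `bifurcation_z_mm` is the axial coordinate of the
#' common-iliac bifurcation plane: nodal lesions with centroid strictly above
#' it are non-regional, at or below are regional.
#'
#' @param liver,blood_pool,prostate_bed,skeleton,nodal_region logical 3D
#'   arrays, all of the same dimension.
#' @param bifurcation_z_mm axial (z) coordinate of the common-iliac
#'   bifurcation plane, in mm.
#' @return An object of class `organ_mask_set`.
#' @export
organ_mask_set <- function(liver, blood_pool, prostate_bed, skeleton,
                           nodal_region, bifurcation_z_mm) {
  masks <- list(liver = liver, blood_pool = blood_pool,
                prostate_bed = prostate_bed, skeleton = skeleton,
                nodal_region = nodal_region)
  dims <- dim(liver)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.array(m) || !is.logical(m) || length(dim(m)) != 3L)
      stop(sprintf("'%s' must be a logical 3D array", nm))
    if (!identical(dim(m), dims))
      stop(sprintf("'%s' mask dimension does not match the other masks", nm))
  }
  if (!is.numeric(bifurcation_z_mm) || length(bifurcation_z_mm) != 1L)
    stop("'bifurcation_z_mm' must be a single number")
  structure(c(masks, list(bifurcation_z_mm = as.numeric(bifurcation_z_mm))),
            class = "organ_mask_set")
}

#' @export
print.organ_mask_set <- function(x, ...) {
  cat("<organ_mask_set>\n")
  for (nm in c("liver", "blood_pool", "prostate_bed", "skeleton", "nodal_region"))
    cat(sprintf("  %-13s %d voxels\n", nm, sum(x[[nm]])))
  cat(sprintf("  iliac bifurcation plane at z = %.1f mm\n", x$bifurcation_z_mm))
  invisible(x)
}

check_grid_masks <- function(grid, masks) {
  if (!identical(dim(grid$values), dim(masks$liver)))
    stop("mask dimensions do not match the PET grid")
  invisible(TRUE)
}

# Label connected components of a logical 3D mask.
# Vectorised frontier flood fill; connectivity 26 (face+edge+corner) or 6.
# Returns an integer array of the same dimension, 0 = background.
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.array(mask), is.logical(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6, 26))
  dims <- dim(mask)
  lab <- array(0L, dims)
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)

  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(offs)) > 0
  offs <- offs[if (connectivity == 6) nz & rowSums(abs(offs)) == 1 else nz, ,
               drop = FALSE]
  n_off <- nrow(offs)

  cur <- 0L
  for (v in fg) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    lab[v] <- cur
    frontier <- v
    while (length(frontier)) {
      ijk <- arrayInd(frontier, dims)
      nb <- ijk[rep(seq_len(nrow(ijk)), each = n_off), , drop = FALSE] +
        offs[rep(seq_len(n_off), times = nrow(ijk)), , drop = FALSE]
      keep <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[keep, , drop = FALSE]
      lin <- unique((nb[, 3] - 1L) * dims[1] * dims[2] +
                      (nb[, 2] - 1L) * dims[1] + nb[, 1])
      lin <- lin[mask[lin] & lab[lin] == 0L]
      lab[lin] <- cur
      frontier <- lin
    }
  }
  lab
}

# Separable Gaussian smoothing of a 3D array; fwhm in mm, per-axis sigma
# derived from the voxel spacing. Kernel truncated at 3 sigma and
# renormalised at the edges so a constant field stays constant.
smooth_gaussian <- function(values, spacing_mm, fwhm_mm) {
  if (fwhm_mm <= 0) return(values)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
  out <- values
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

convolve_axis <- function(a, kernel, axis) {
  half <- (length(kernel) - 1L) / 2L
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])          # lines along the chosen axis
  n <- dp[1]
  acc <- matrix(0, nrow = n, ncol = ncol(m))
  wt <- numeric(n)                        # edge renormalisation weights
  for (j in seq_along(kernel)) {
    sh <- j - half - 1L                   # shift of this tap
    src <- seq_len(n) + sh
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + kernel[j] * m[src[ok], , drop = FALSE]
    wt[ok] <- wt[ok] + kernel[j]
  }
  acc <- acc / wt
  aperm(array(acc, dp), order(perm))
}
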