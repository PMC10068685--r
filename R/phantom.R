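#' Lesion specification for a synthetic phantom
#'
#' Describes one spherical tracer-avid lesion: where it sits, how large it
#' is, its uniform uptake, and which anatomic compartment it is meant to
#' represent. Spheres are used because their analytic volume
#' (4/3 pi r^3) gives an exact oracle for segmentation accuracy.
#'
#' @param center_mm numeric triple, lesion centre in mm (grid origin at the
#'   first voxel centre).
#' @param radius_mm positive sphere radius in mm.
#' @param suv uniform lesion SUV; must exceed the phantom background for the
#'   lesion to be detectable.
#' @param compartment one of `"prostate_bed"`, `"regional_node"`,
#'   `"nonregional_node"`, `"osseous"`.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center_mm, radius_mm, suv,
                        compartment = c("prostate_bed", "regional_node",
                                        "nonregional_node", "osseous")) {
  compartment <- match.arg(compartment)
  center_mm <- as.numeric(center_mm)
  stopifnot(length(center_mm) == 3L, all(is.finite(center_mm)),
            is.numeric(radius_mm), length(radius_mm) == 1L, radius_mm > 0,
            is.numeric(suv), length(suv) == 1L, suv > 0)
  structure(list(center_mm = center_mm, radius_mm = radius_mm,
                 suv = suv, compartment = compartment),
            class = "lesion_spec")
}

#' Phantom specification
#'
#' Parameters of a synthetic whole-body PET phantom: a uniform soft-tissue
#' background, liver and blood-pool (aorta) reference plateaus at fixed
#' anatomy-like positions, spherical lesions, and optional additive Gaussian
#' SUV noise (truncated at zero, since SUV is non-negative).
#'
#' @param grid_shape integer triple of voxel counts.
#' @param voxel_spacing_mm positive numeric triple (mm).
#' @param background_suv,liver_suv,blood_pool_suv positive plateau SUVs.
#' @param lesions list of [lesion_spec] objects.
#' @param noise_sd non-negative SD of additive Gaussian SUV noise.
#' @param seed integer RNG seed; the phantom is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [phantom_default_spec()]
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 80),
                         voxel_spacing_mm = c(4, 4, 4),
                         background_suv = 0.5,
                         liver_suv = 5,
                         blood_pool_suv = 1.5,
                         lesions = list(),
                         noise_sd = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4L),
            length(voxel_spacing_mm) == 3L, all(voxel_spacing_mm > 0),
            background_suv > 0, liver_suv > 0, blood_pool_suv > 0,
            is.numeric(noise_sd), noise_sd >= 0)
  if (!all(vapply(lesions, inherits, logical(1), "lesion_spec")))
    stop("'lesions' must be a list of lesion_spec objects")
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 background_suv = background_suv, liver_suv = liver_suv,
                 blood_pool_suv = blood_pool_suv, lesions = lesions,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom: one detectable lesion per compartment
#'
#' A convenience spec with lesions in the prostate bed, a regional node
#' (below the iliac bifurcation), a non-regional node (above it, offset from
#' the aorta), and the spine, all well above typical detection thresholds.
#'
#' @param noise_sd,seed passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_default_spec <- function(noise_sd = 0, seed = 1L) {
  shape <- c(48, 48, 80)
  sp <- c(4, 4, 4)
  ext <- (shape - 1) * sp
  lesions <- list(
    lesion_spec(c(0.50, 0.55, 0.08) * ext, radius_mm = 11, suv = 6,
                compartment = "prostate_bed"),
    lesion_spec(c(0.50, 0.45, 0.20) * ext, radius_mm = 8, suv = 8,
                compartment = "regional_node"),
    lesion_spec(c(0.50, 0.45, 0.60) * ext + c(18, 0, 0), radius_mm = 8,
                suv = 8, compartment = "nonregional_node"),
    lesion_spec(c(0.50, 0.67, 0.50) * ext, radius_mm = 8, suv = 7,
                compartment = "osseous"))
  phantom_spec(grid_shape = shape, voxel_spacing_mm = sp, lesions = lesions,
               noise_sd = noise_sd, seed = seed)
}

# Linear indices of voxels whose centres lie within radius_mm of center_mm.
sphere_voxels <- function(dims, spacing_mm, center_mm, radius_mm) {
  # bounding box in voxel indices, then exact distance test
  lo <- pmax(1L, floor((center_mm - radius_mm) / spacing_mm) + 1L)
  hi <- pmin(dims, ceiling((center_mm + radius_mm) / spacing_mm) + 1L)
  if (any(lo > hi)) return(integer(0))
  ijk <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  xyz <- sweep(ijk - 1, 2, spacing_mm, `*`)
  d2 <- rowSums(sweep(xyz, 2, center_mm)^2)
  sel <- ijk[d2 <= radius_mm^2, , drop = FALSE]
  (sel[, 3] - 1L) * dims[1] * dims[2] + (sel[, 2] - 1L) * dims[1] + sel[, 1]
}

# Organ masks at fixed anatomy-like positions, scaled to the grid extent.
# z runs feet-to-head; the aorta is a vertical cylinder, the liver an
# ellipsoid offset to the right, the skeleton a posterior spine column,
# the nodal region a wider cylinder around the aorta path. Masks are made
# pairwise disjoint (priority liver > blood pool > prostate > skeleton >
# nodal) so the labeled-volume serialization is lossless.
phantom_masks <- function(grid_shape, spacing_mm) {
  dims <- as.integer(grid_shape)
  ext <- (dims - 1) * spacing_mm
  ax <- seq(0, ext[1], by = spacing_mm[1])
  ay <- seq(0, ext[2], by = spacing_mm[2])
  az <- seq(0, ext[3], by = spacing_mm[3])
  X <- array(rep(ax, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ay, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(az, each = dims[1] * dims[2]), dims)

  r2_axis <- (X - 0.5 * ext[1])^2 + (Y - 0.45 * ext[2])^2

  lc <- c(0.72, 0.42, 0.72) * ext
  liver <- ((X - lc[1]) / (0.16 * ext[1]))^2 +
    ((Y - lc[2]) / (0.16 * ext[2]))^2 +
    ((Z - lc[3]) / (0.10 * ext[3]))^2 <= 1

  blood_pool <- r2_axis <= 8^2 & Z >= 0.45 * ext[3] & Z <= 0.90 * ext[3] &
    !liver

  pc <- c(0.50, 0.55, 0.08) * ext
  prostate_bed <- (X - pc[1])^2 + (Y - pc[2])^2 + (Z - pc[3])^2 <= 20^2 &
    !(liver | blood_pool)

  skeleton <- X >= 0.45 * ext[1] & X <= 0.55 * ext[1] &
    Y >= 0.62 * ext[2] & Y <= 0.72 * ext[2] &
    Z >= 0.05 * ext[3] & Z <= 0.95 * ext[3] &
    !(liver | blood_pool | prostate_bed)

  nodal_region <- r2_axis <= 25^2 & Z >= 0.12 * ext[3] & Z <= 0.75 * ext[3] &
    !(liver | blood_pool | prostate_bed | skeleton)

  organ_mask_set(liver = liver, blood_pool = blood_pool,
                 prostate_bed = prostate_bed, skeleton = skeleton,
                 nodal_region = nodal_region,
                 bifurcation_z_mm = 0.35 * ext[3])
}

#' Generate a synthetic PET phantom
#'
#' Builds the PET grid (background + liver and blood-pool plateaus +
#' spherical lesions + truncated Gaussian noise), the matching organ mask
#' set, and the ground truth: one record per lesion carrying its voxel
#' mask, analytic volume (4/3 pi r^3, in mL) and nominal SUV.
#'
#' Lesions must lie fully inside the grid and must not intersect a
#' reference organ (liver or blood pool), since that would corrupt the
#' reference SUVmean the whole analysis is normalized by.
#'
#' @param spec a [phantom_spec].
#' @return List with elements `pet` ([voxel_grid]), `masks`
#'   ([organ_mask_set]) and `ground_truth` (list of per-lesion records with
#'   fields `lesion_id`, `compartment`, `voxels`, `volume_ml`, `suv`,
#'   `center_mm`, `radius_mm`).
#' @examples
#' ph <- generate_phantom(phantom_default_spec())
#' length(ph$ground_truth)
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  ext <- (dims - 1) * sp
  masks <- phantom_masks(dims, sp)

  values <- array(spec$background_suv, dims)
  values[masks$liver] <- spec$liver_suv
  values[masks$blood_pool] <- spec$blood_pool_suv

  ground_truth <- vector("list", length(spec$lesions))
  for (i in seq_along(spec$lesions)) {
    les <- spec$lesions[[i]]
    if (any(les$center_mm - les$radius_mm < 0) ||
        any(les$center_mm + les$radius_mm > ext))
      stop(sprintf("lesion %d (%s) extends outside the grid", i, les$compartment))
    vox <- sphere_voxels(dims, sp, les$center_mm, les$radius_mm)
    if (any(masks$liver[vox]) || any(masks$blood_pool[vox]))
      stop(sprintf("lesion %d (%s) overlaps a reference organ", i, les$compartment))
    values[vox] <- les$suv
    ground_truth[[i]] <- list(lesion_id = sprintf("gt_%02d", i),
                              compartment = les$compartment,
                              voxels = vox,
                              volume_ml = 4 / 3 * pi * les$radius_mm^3 / 1000,
                              suv = les$suv,
                              center_mm = les$center_mm,
                              radius_mm = les$radius_mm)
  }

  if (spec$noise_sd > 0) {
    values <- with_seed(spec$seed,
                        values + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims))
    values <- pmax(values, 0)
  }

  list(pet = voxel_grid(values, sp), masks = masks, ground_truth = ground_truth)
}
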