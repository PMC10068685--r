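#' Hot-spot detection and segmentation parameters
#'
#' Parameters of the classical detector that stands in for a learned
#' hot-spot model: optional Gaussian pre-smoothing, a detection threshold
#' that is the larger of an absolute SUV floor and a multiple of the
#' blood-pool SUVmean, an adaptive segmentation threshold expressed as a
#' fraction of the lesion's peak SUV (floored at the blood-pool SUVmean),
#' and a minimum lesion volume to suppress single-voxel noise detections.
#'
#' @param smoothing_fwhm_mm non-negative Gaussian FWHM in mm (0 = none).
#' @param detect_rel multiple of the blood-pool SUVmean a peak must reach;
#'   must exceed 1.
#' @param detect_abs absolute SUV detection floor.
#' @param seg_fraction fraction `f` in (0,1) of the lesion SUVmax defining
#'   the adaptive segmentation threshold; 0.4 is the common PET convention.
#' @param min_volume_ml minimum segmented volume retained, in mL.
#' @return An object of class `hotspot_params`.
#' @export
hotspot_params <- function(smoothing_fwhm_mm = 0, detect_rel = 2,
                           detect_abs = 0, seg_fraction = 0.4,
                           min_volume_ml = 0.1) {
  stopifnot(smoothing_fwhm_mm >= 0, detect_rel > 1, detect_abs >= 0,
            seg_fraction > 0, seg_fraction < 1, min_volume_ml >= 0)
  structure(list(smoothing_fwhm_mm = smoothing_fwhm_mm,
                 detect_rel = detect_rel, detect_abs = detect_abs,
                 seg_fraction = seg_fraction, min_volume_ml = min_volume_ml),
            class = "hotspot_params")
}

detection_threshold <- function(ref, params) {
  max(params$detect_abs, params$detect_rel * ref$blood_pool_suv_mean)
}

#' Detect candidate hot spots
#'
#' Thresholds the (optionally smoothed) PET at
#' `max(detect_abs, detect_rel * blood_pool_suv_mean)`, labels the
#' supra-threshold voxels into 26-connected components, and returns one
#' seed per component at the component's SUV maximum. Voxels inside
#' `exclude` (typically the reference organs, whose physiologic uptake is
#' not disease) are never seeds.
#'
#' @param pet a [voxel_grid].
#' @param ref a `reference_uptake` for the same scan.
#' @param params a [hotspot_params].
#' @param exclude optional logical array of voxels to ignore (e.g.
#'   `masks$liver | masks$blood_pool`).
#' @return Data frame with one row per seed: `seed_index` (linear voxel
#'   index of the component peak), `component_suv_max`, `n_voxels`.
#'   Zero rows when nothing is supra-threshold.
#' @export
detect_hotspots <- function(pet, ref, params = hotspot_params(),
                            exclude = NULL) {
  stopifnot(inherits(pet, "voxel_grid"), inherits(ref, "reference_uptake"),
            inherits(params, "hotspot_params"))
  vals <- smooth_gaussian(pet$values, pet$spacing_mm, params$smoothing_fwhm_mm)
  thr <- detection_threshold(ref, params)
  mask <- vals >= thr
  if (!is.null(exclude)) {
    stopifnot(identical(dim(exclude), dim(pet$values)))
    mask <- mask & !exclude
  }
  empty <- data.frame(seed_index = integer(0), component_suv_max = numeric(0),
                      n_voxels = integer(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask, connectivity = 26)
  idx <- which(lab > 0L)
  comp <- lab[idx]
  v <- vals[idx]
  peaks <- vapply(split(seq_along(idx), comp),
                  function(g) g[which.max(v[g])], integer(1))
  data.frame(seed_index = idx[peaks],
             component_suv_max = v[peaks],
             n_voxels = as.integer(tabulate(comp)[sort(unique(comp))]))
}

#' Segment one hot spot with an adaptive threshold
#'
#' The lesion mask is the 26-connected component containing the seed among
#' voxels with `SUV >= max(seg_fraction * component_suv_max,
#' blood_pool_suv_mean)`: peak-relative, floored at the blood-pool level so
#' the region can never spill into sub-reference background. Volume,
#' SUVmean and SUVmax are computed from the unsmoothed PET over the mask.
#'
#' @param pet a [voxel_grid].
#' @param seed one row of the [detect_hotspots()] output, or a list with
#'   `seed_index` and `component_suv_max`.
#' @param ref a `reference_uptake`.
#' @param params a [hotspot_params].
#' @param lesion_id identifier for the resulting lesion.
#' @return A `psma_lesion` (compartment unset), or `NULL` when the
#'   segmented volume falls below `min_volume_ml`.
#' @export
segment_hotspot <- function(pet, seed, ref, params = hotspot_params(),
                            lesion_id = "lesion_1") {
  stopifnot(inherits(pet, "voxel_grid"), inherits(ref, "reference_uptake"))
  seed_index <- as.integer(seed$seed_index)
  suv_peak <- as.numeric(seed$component_suv_max)
  if (pet$values[seed_index] < detection_threshold(ref, params) &&
      suv_peak < detection_threshold(ref, params))
    stop("seed is below the detection threshold")
  thr <- max(params$seg_fraction * suv_peak, ref$blood_pool_suv_mean)
  mask <- pet$values >= thr
  if (!mask[seed_index])
    stop("seed voxel is below the segmentation threshold")
  lab <- label_components(mask, connectivity = 26)
  vox <- which(lab == lab[seed_index])
  lesion <- new_lesion(lesion_id, vox, pet)
  if (lesion$volume_ml < params$min_volume_ml) return(NULL)
  lesion
}

# Construct a lesion record from a voxel set; stats from the grid.
new_lesion <- function(lesion_id, voxels, pet, compartment = NA_character_,
                       accepted = TRUE) {
  stopifnot(length(voxels) >= 1L)
  v <- pet$values[voxels]
  structure(list(lesion_id = as.character(lesion_id),
                 voxels = as.integer(voxels),
                 compartment = compartment,
                 volume_ml = length(voxels) * voxel_volume_ml(pet),
                 suv_mean = mean(v),
                 suv_max = max(v),
                 accepted = accepted),
            class = "psma_lesion")
}

#' Build a lesion record from a supplied voxel mask
#'
#' For scoring user-supplied or ground-truth segmentations without running
#' the detector (e.g. manually contoured lesions).
#'
#' @param pet a [voxel_grid].
#' @param voxels integer linear voxel indices of the lesion mask.
#' @param lesion_id identifier.
#' @param compartment optional compartment label.
#' @return A `psma_lesion`.
#' @export
lesion_from_mask <- function(pet, voxels, lesion_id = "lesion_1",
                             compartment = NA_character_) {
  new_lesion(lesion_id, voxels, pet, compartment = compartment)
}

#' @export
print.psma_lesion <- function(x, ...) {
  cat(sprintf("<psma_lesion %s> %s, %.3f mL, SUVmean %.2f, SUVmax %.2f, %s\n",
              x$lesion_id,
              if (is.na(x$compartment)) "unassigned" else x$compartment,
              x$volume_ml, x$suv_mean, x$suv_max,
              if (x$accepted) "accepted" else "rejected"))
  invisible(x)
}

#' Apply reviewer accept/reject decisions
#'
#' Mirrors the physician review step: auto-segmented lesions are confirmed
#' as true disease or rejected as false positives. Lesions absent from the
#' decision map default to accepted; rejected lesions are excluded from all
#' downstream scores.
#'
#' @param lesions list of `psma_lesion` objects.
#' @param decisions named character vector or list mapping `lesion_id` to
#'   `"accept"` or `"reject"`.
#' @return The lesion list with `accepted` flags set.
#' @export
apply_review <- function(lesions, decisions = character(0)) {
  decisions <- unlist(decisions)
  ids <- vapply(lesions, `[[`, character(1), "lesion_id")
  unknown <- setdiff(names(decisions), ids)
  if (length(unknown))
    stop("unknown lesion_id in decisions: ", paste(unknown, collapse = ", "))
  bad <- setdiff(unique(decisions), c("accept", "reject"))
  if (length(bad))
    stop("decisions must be 'accept' or 'reject', got: ",
         paste(bad, collapse = ", "))
  lapply(lesions, function(l) {
    d <- decisions[l$lesion_id]
    l$accepted <- is.na(d) || d == "accept"
    l
  })
}

#' Assign a lesion to an anatomic compartment
#'
#' The compartment is the arg-max fractional overlap of the lesion mask
#' with the prostate/bed, skeleton (osseous) and nodal-region masks; exact
#' ties resolve by the fixed priority osseous > nodal > prostate/bed.
#' Nodal lesions are split by the axial position of their centroid relative
#' to the common-iliac bifurcation plane: strictly above is non-regional,
#' at or below is regional. A lesion overlapping no compartment mask is
#' labelled `"unclassified"` with a warning and is excluded from scores.
#'
#' @param lesion a `psma_lesion`.
#' @param masks an [organ_mask_set].
#' @param pet the [voxel_grid] the lesion was segmented on (for centroid
#'   coordinates).
#' @return The lesion with its `compartment` field set.
#' @export
classify_compartment <- function(lesion, masks, pet) {
  stopifnot(inherits(lesion, "psma_lesion"), inherits(masks, "organ_mask_set"),
            inherits(pet, "voxel_grid"))
  check_grid_masks(pet, masks)
  vox <- lesion$voxels
  frac <- c(osseous = mean(masks$skeleton[vox]),
            nodal = mean(masks$nodal_region[vox]),
            prostate_bed = mean(masks$prostate_bed[vox]))
  if (all(frac == 0)) {
    warning(sprintf("lesion %s overlaps no compartment mask; labelled unclassified",
                    lesion$lesion_id))
    lesion$compartment <- "unclassified"
    return(lesion)
  }
  # which.max breaks ties by position; the vector is ordered by priority
  best <- names(frac)[which.max(frac)]
  if (best == "nodal") {
    cz <- mean(voxel_coords_mm(pet, vox)[, "z"])
    best <- if (cz > masks$bifurcation_z_mm) "nonregional_node" else "regional_node"
  }
  lesion$compartment <- best
  lesion
}

#' Full lesion quantification for one scan
#'
#' Convenience pipeline: detect hot spots (excluding the reference organs),
#' segment each with the adaptive threshold, classify compartments, and
#' apply reviewer decisions. Seeds are processed in decreasing peak SUV;
#' voxels already claimed by an earlier lesion are removed from later masks
#' so that lesion masks are pairwise disjoint.
#'
#' @param pet a [voxel_grid].
#' @param masks an [organ_mask_set].
#' @param ref optional precomputed `reference_uptake`; computed from `masks`
#'   when `NULL`.
#' @param params a [hotspot_params].
#' @param decisions reviewer decision map, as in [apply_review()].
#' @param reference_choice passed to [compute_reference_uptake()] when `ref`
#'   is `NULL`.
#' @return List with `lesions` (list of classified `psma_lesion`) and `ref`.
#' @examples
#' ph <- generate_phantom(phantom_default_spec())
#' q <- quantify_lesions(ph$pet, ph$masks)
#' length(q$lesions)
#' @export
quantify_lesions <- function(pet, masks, ref = NULL,
                             params = hotspot_params(),
                             decisions = character(0),
                             reference_choice = "blood_pool") {
  if (is.null(ref))
    ref <- compute_reference_uptake(pet, masks, reference_choice)
  seeds <- detect_hotspots(pet, ref, params,
                           exclude = masks$liver | masks$blood_pool)
  lesions <- list()
  claimed <- integer(0)
  if (nrow(seeds)) {
    seeds <- seeds[order(-seeds$component_suv_max), , drop = FALSE]
    k <- 0L
    for (i in seq_len(nrow(seeds))) {
      if (seeds$seed_index[i] %in% claimed) next
      les <- segment_hotspot(pet, seeds[i, ], ref, params,
                             lesion_id = sprintf("lesion_%02d", k + 1L))
      if (is.null(les)) next
      keep <- setdiff(les$voxels, claimed)
      if (!length(keep)) next
      if (length(keep) < length(les$voxels))
        les <- new_lesion(les$lesion_id, keep, pet)
      if (les$volume_ml < params$min_volume_ml) next
      k <- k + 1L
      claimed <- c(claimed, les$voxels)
      lesions[[k]] <- classify_compartment(les, masks, pet)
    }
  }
  lesions <- apply_review(lesions, decisions)
  list(lesions = lesions, ref = ref)
}
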