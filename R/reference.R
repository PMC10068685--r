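#' Reference uptake from liver and blood-pool segmentations
#'
#' Computes the reference standardized uptake values (SUVref) used to
#' normalize lesion uptake: the arithmetic mean SUV over the liver mask and
#' over the blood-pool (aorta) mask. One of the two is recorded as the
#' active reference for downstream scoring; blood pool is the default.
#'
#' @param pet a [voxel_grid] in SUV units.
#' @param masks an [organ_mask_set] congruent with `pet`; liver and
#'   blood-pool masks must be non-empty.
#' @param reference_choice `"blood_pool"` (default) or `"liver"`.
#' @return An object of class `reference_uptake`: list with
#'   `liver_suv_mean`, `blood_pool_suv_mean`, `reference_choice`.
#' @examples
#' pet <- voxel_grid(array(2, dim = c(4, 4, 4)), c(2, 2, 2))
#' m <- array(FALSE, dim = c(4, 4, 4)); m[1:2, 1:2, 1:2] <- TRUE
#' b <- array(FALSE, dim = c(4, 4, 4)); b[3:4, 3:4, 3:4] <- TRUE
#' masks <- organ_mask_set(m, b, b & FALSE, b & FALSE, b & FALSE, 4)
#' compute_reference_uptake(pet, masks)
#' @export
compute_reference_uptake <- function(pet, masks,
                                     reference_choice = c("blood_pool", "liver")) {
  stopifnot(inherits(pet, "voxel_grid"), inherits(masks, "organ_mask_set"))
  reference_choice <- match.arg(reference_choice)
  check_grid_masks(pet, masks)
  means <- vapply(c("liver", "blood_pool"), function(organ) {
    m <- masks[[organ]]
    if (!any(m)) stop(sprintf("%s mask empty", organ))
    v <- pet$values[m]
    if (any(v < 0)) stop(sprintf("negative SUV under %s mask", organ))
    mean(v)
  }, numeric(1))
  if (any(means <= 0))
    stop("reference SUVmean must be strictly positive")
  structure(list(liver_suv_mean = unname(means["liver"]),
                 blood_pool_suv_mean = unname(means["blood_pool"]),
                 reference_choice = reference_choice),
            class = "reference_uptake")
}

#' The active reference SUVmean
#'
#' @param ref a `reference_uptake` object.
#' @return The SUVmean of the organ selected by `reference_choice`.
#' @export
reference_value <- function(ref) {
  stopifnot(inherits(ref, "reference_uptake"))
  switch(ref$reference_choice,
         blood_pool = ref$blood_pool_suv_mean,
         liver = ref$liver_suv_mean)
}

#' @export
print.reference_uptake <- function(x, ...) {
  cat(sprintf("<reference_uptake> liver SUVmean %.3f, blood-pool SUVmean %.3f (reference: %s)\n",
              x$liver_suv_mean, x$blood_pool_suv_mean, x$reference_choice))
  invisible(x)
}
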