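# Shared builders for small in-memory test objects.

# Uniform grid with given SUV everywhere.
uniform_grid <- function(value, dims = c(8, 8, 8), spacing = c(2, 2, 2)) {
  voxel_grid(array(value, dims), spacing)
}

# Minimal mask set: liver and blood pool in opposite corners, everything
# else empty; bifurcation halfway up.
simple_masks <- function(dims = c(8, 8, 8), spacing = c(2, 2, 2)) {
  e <- array(FALSE, dims)
  liver <- e; liver[1:2, 1:2, 1:2] <- TRUE
  hi <- lapply(dims, function(d) (d - 1):d)
  bp <- e; bp[hi[[1]], hi[[2]], hi[[3]]] <- TRUE
  organ_mask_set(liver = liver, blood_pool = bp, prostate_bed = e,
                 skeleton = e, nodal_region = e,
                 bifurcation_z_mm = (dims[3] - 1) * spacing[3] / 2)
}

# Reference with a fixed blood-pool mean, bypassing mask computation.
fixed_ref <- function(blood_pool = 1.5, liver = 5,
                      choice = "blood_pool") {
  structure(list(liver_suv_mean = liver, blood_pool_suv_mean = blood_pool,
                 reference_choice = choice),
            class = "reference_uptake")
}

# A 32^3, 2 mm phantom spec with one free-floating sphere (clear of the
# reference organs); the spec-example geometry r = 10 mm at 2 mm spacing.
one_sphere_spec <- function(radius = 10, suv = 8, background = 1,
                            noise_sd = 0, seed = 1) {
  phantom_spec(grid_shape = c(32, 32, 32), voxel_spacing_mm = c(2, 2, 2),
               background_suv = background, liver_suv = 5,
               blood_pool_suv = 1.5,
               lesions = list(lesion_spec(c(16, 44, 16), radius, suv,
                                          "prostate_bed")),
               noise_sd = noise_sd, seed = seed)
}

# Lesion built directly from explicit voxels on a grid.
lesion_of <- function(pet, voxels, id = "L1", compartment = NA_character_) {
  lesion_from_mask(pet, voxels, lesion_id = id, compartment = compartment)
}

expect_no_organ_overlap <- function(ph) {
  for (g in ph$ground_truth) {
    expect_false(any(ph$masks$liver[g$voxels]))
    expect_false(any(ph$masks$blood_pool[g$voxels]))
  }
}
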