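test_that("nothing supra-threshold yields zero seeds", {
  g <- uniform_grid(1.5, dims = c(10, 10, 10))
  ref <- fixed_ref(blood_pool = 1.5)
  seeds <- detect_hotspots(g, ref, hotspot_params(detect_rel = 2))
  expect_equal(nrow(seeds), 0)
})

test_that("disjoint spheres each yield exactly one seed at the component peak", {
  dims <- c(30, 30, 30); sp <- c(2, 2, 2)
  g <- uniform_grid(1, dims = dims, spacing = sp)
  centers <- list(c(10, 10, 10), c(40, 40, 40), c(10, 40, 40))
  for (cc in centers)
    g$values[psmaquant:::sphere_voxels(dims, sp, cc, 5)] <- 8
  ref <- fixed_ref(blood_pool = 1.5)
  seeds <- detect_hotspots(g, ref, hotspot_params(detect_rel = 2))
  expect_equal(nrow(seeds), 3)
  expect_true(all(seeds$component_suv_max == 8))
  expect_true(all(g$values[seeds$seed_index] == 8))
  # oracle: the number of 26-connected components of {SUV >= 3}
  expect_equal(max(psmaquant:::label_components(g$values >= 3)), 3)
})

test_that("sub-threshold lesions are not detected", {
  dims <- c(16, 16, 16); sp <- c(2, 2, 2)
  g <- uniform_grid(1, dims = dims, spacing = sp)
  g$values[psmaquant:::sphere_voxels(dims, sp, c(15, 15, 15), 5)] <- 2.5
  ref <- fixed_ref(blood_pool = 1.5)  # threshold = 3.0
  expect_equal(nrow(detect_hotspots(g, ref, hotspot_params(detect_rel = 2))), 0)
})

test_that("reference-organ voxels can be excluded from detection", {
  g <- uniform_grid(1, dims = c(10, 10, 10))
  hot <- array(FALSE, c(10, 10, 10)); hot[4:6, 4:6, 4:6] <- TRUE
  g$values[hot] <- 8
  ref <- fixed_ref()
  expect_equal(nrow(detect_hotspots(g, ref)), 1)
  expect_equal(nrow(detect_hotspots(g, ref, exclude = hot)), 0)
})

test_that("adaptive segmentation recovers a uniform sphere", {
  ph <- generate_phantom(one_sphere_spec(radius = 10, suv = 8, background = 1))
  ref <- fixed_ref(blood_pool = 1.5)
  seeds <- detect_hotspots(ph$pet, ref, hotspot_params(),
                           exclude = ph$masks$liver | ph$masks$blood_pool)
  expect_equal(nrow(seeds), 1)
  les <- segment_hotspot(ph$pet, seeds[1, ], ref,
                         hotspot_params(seg_fraction = 0.4))
  # threshold = max(0.4 * 8, 1.5) = 3.2; background 1 stays out
  expect_lt(abs(les$volume_ml - 4.18879) / 4.18879, 0.15)
  expect_equal(les$suv_mean, 8)
  expect_equal(les$suv_max, 8)
})

test_that("a single hot voxel has one-voxel volume", {
  g <- uniform_grid(1, dims = c(10, 10, 10), spacing = c(2, 2, 2))
  g$values[5, 5, 5] <- 10
  ref <- fixed_ref(blood_pool = 1.5)
  seeds <- detect_hotspots(g, ref)
  les <- segment_hotspot(g, seeds[1, ], ref,
                         hotspot_params(min_volume_ml = 0))
  expect_equal(les$volume_ml, 0.008)
  expect_equal(length(les$voxels), 1L)
  # the default minimum volume suppresses it
  expect_null(segment_hotspot(g, seeds[1, ], ref,
                              hotspot_params(min_volume_ml = 0.1)))
})

test_that("the adaptive threshold excludes a low-uptake rim around a hot core", {
  dims <- c(24, 24, 24); sp <- c(2, 2, 2)
  g <- uniform_grid(1, dims = dims, spacing = sp)
  core <- psmaquant:::sphere_voxels(dims, sp, c(23, 23, 23), 5)
  rim <- setdiff(psmaquant:::sphere_voxels(dims, sp, c(23, 23, 23), 9), core)
  g$values[rim] <- 3
  g$values[core] <- 10
  ref <- fixed_ref(blood_pool = 1.5)
  seeds <- detect_hotspots(g, ref)   # rim and core are one component
  expect_equal(nrow(seeds), 1)
  les <- segment_hotspot(g, seeds[1, ], ref,
                         hotspot_params(seg_fraction = 0.4))  # threshold 4
  expect_setequal(les$voxels, core)   # brute-force: exactly the SUV-10 voxels
})

test_that("increasing the segmentation fraction never enlarges the mask", {
  ph <- generate_phantom(one_sphere_spec(radius = 8, suv = 6, background = 1,
                                         noise_sd = 0.3, seed = 8))
  ref <- compute_reference_uptake(ph$pet, ph$masks)
  seeds <- detect_hotspots(ph$pet, ref, hotspot_params())
  expect_gte(nrow(seeds), 1)
  seed <- seeds[which.max(seeds$component_suv_max), ]
  prev <- NULL
  for (f in c(0.2, 0.4, 0.6, 0.8)) {
    les <- segment_hotspot(ph$pet, seed, ref,
                           hotspot_params(seg_fraction = f, min_volume_ml = 0))
    if (!is.null(prev)) expect_true(all(les$voxels %in% prev))
    prev <- les$voxels
  }
})

test_that("review decisions default to accept and reject unknown ids", {
  g <- uniform_grid(2)
  lesions <- list(lesion_of(g, 1:4, id = "a"), lesion_of(g, 11:14, id = "b"),
                  lesion_of(g, 21:24, id = "c"))
  all_in <- apply_review(lesions)
  expect_true(all(vapply(all_in, `[[`, logical(1), "accepted")))
  rej <- apply_review(lesions, c(b = "reject"))
  expect_equal(vapply(rej, `[[`, logical(1), "accepted"),
               c(TRUE, FALSE, TRUE))
  expect_error(apply_review(lesions, c(zz = "reject")), "unknown lesion_id")
  expect_error(apply_review(lesions, c(a = "maybe")), "accept")
})

test_that("compartment assignment follows overlap, tie-break and bifurcation", {
  ph <- generate_phantom(phantom_default_spec())
  q <- quantify_lesions(ph$pet, ph$masks)
  got <- vapply(q$lesions, `[[`, character(1), "compartment")
  expect_setequal(got, c("prostate_bed", "regional_node", "nonregional_node",
                         "osseous"))

  # tie between skeleton and nodal region resolves to osseous
  g <- uniform_grid(1, dims = c(8, 8, 8))
  masks <- simple_masks()
  masks$skeleton[3:4, 3, 3] <- TRUE
  masks$nodal_region[5:6, 3, 3] <- TRUE
  vox <- which(masks$skeleton | masks$nodal_region)
  les <- classify_compartment(lesion_of(g, vox), masks, g)
  expect_equal(les$compartment, "osseous")

  # no overlap anywhere -> unclassified, with a warning
  expect_warning(
    les2 <- classify_compartment(lesion_of(g, 1:2), masks, g),
    "unclassified")
  expect_equal(les2$compartment, "unclassified")
})

test_that("nodal lesions split at the iliac bifurcation by centroid", {
  g <- uniform_grid(1, dims = c(8, 8, 8), spacing = c(2, 2, 2))
  masks <- simple_masks()                     # bifurcation at z = 7 mm
  masks$nodal_region[, , ] <- TRUE
  below <- which(array(slice.index(g$values, 3) <= 2, dim(g$values)))[1:4]
  above <- which(array(slice.index(g$values, 3) >= 7, dim(g$values)))[1:4]
  expect_equal(classify_compartment(lesion_of(g, below), masks, g)$compartment,
               "regional_node")
  expect_equal(classify_compartment(lesion_of(g, above), masks, g)$compartment,
               "nonregional_node")
})

test_that("lesion masks from full quantification are pairwise disjoint", {
  ph <- generate_phantom(phantom_default_spec(noise_sd = 0.2, seed = 12))
  q <- quantify_lesions(ph$pet, ph$masks)
  all_vox <- unlist(lapply(q$lesions, `[[`, "voxels"))
  expect_equal(length(all_vox), length(unique(all_vox)))
})
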