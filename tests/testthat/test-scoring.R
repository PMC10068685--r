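test_that("lesion PSMA score is volume x SUVmean / reference SUVmean", {
  # 2 mL at SUVmean 4 against reference 2 -> score 4
  g <- uniform_grid(4, dims = c(10, 10, 10), spacing = c(2, 2, 2))
  les <- lesion_of(g, 1:250)               # 250 voxels x 0.008 mL = 2 mL
  expect_equal(lesion_psma_score(les, fixed_ref(blood_pool = 2)), 4)
})

test_that("scores are invariant to a global PET intensity rescaling", {
  ph <- generate_phantom(phantom_default_spec())
  for (fac in c(3, 0.25)) {
    scaled <- voxel_grid(ph$pet$values * fac, ph$pet$spacing_mm)
    q1 <- quantify_lesions(ph$pet, ph$masks)
    q2 <- quantify_lesions(scaled, ph$masks)
    s1 <- compartment_scores(q1$lesions, q1$ref)
    s2 <- compartment_scores(q2$lesions, q2$ref)
    expect_equal(s2$composite, s1$composite, tolerance = 1e-12)
    expect_equal(s2$nodal, s1$nodal, tolerance = 1e-12)
  }
})

test_that("formula score equals the brute-force voxel-sum oracle", {
  ph <- generate_phantom(phantom_default_spec(noise_sd = 0.3, seed = 2))
  ref <- compute_reference_uptake(ph$pet, ph$masks)
  for (gt in ph$ground_truth) {
    les <- lesion_from_mask(ph$pet, gt$voxels)
    oracle <- sum(ph$pet$values[gt$voxels]) * voxel_volume_ml(ph$pet) /
      reference_value(ref)
    expect_equal(lesion_psma_score(les, ref), oracle, tolerance = 1e-14)
  }
})

test_that("compartment scores sum lesions, pool nodal stations, mark absence", {
  g <- uniform_grid(2, dims = c(10, 10, 10), spacing = c(2, 2, 2))
  ref <- fixed_ref(blood_pool = 2)
  mk <- function(vox, comp, id) lesion_of(g, vox, id = id, compartment = comp)
  lesions <- list(mk(1:100, "regional_node", "a"),
                  mk(201:300, "nonregional_node", "b"),
                  mk(401:500, "osseous", "c"))
  sc <- compartment_scores(lesions, ref)
  a <- lesion_psma_score(lesions[[1]], ref)
  expect_equal(sc$nodal, 2 * a)            # both nodal stations pool
  expect_equal(sc$osseous, a)
  expect_true(is.na(sc$prostate_bed))      # missing, not zero
  expect_equal(sc$composite, 3 * a)

  # removing one lesion reduces the compartment by exactly its score
  sc2 <- compartment_scores(apply_review(lesions, c(b = "reject")), ref)
  expect_equal(sc2$nodal, sc$nodal - lesion_psma_score(lesions[[2]], ref))
  expect_equal(sc2$composite, sc$composite - lesion_psma_score(lesions[[2]], ref))
})

test_that("no accepted lesions gives all-missing compartments, composite 0", {
  g <- uniform_grid(2)
  lesions <- apply_review(list(lesion_of(g, 1:4, id = "a",
                                         compartment = "osseous")),
                          c(a = "reject"))
  sc <- compartment_scores(lesions, fixed_ref())
  expect_true(is.na(sc$prostate_bed) && is.na(sc$nodal) && is.na(sc$osseous))
  expect_equal(sc$composite, 0)
})

test_that("composite equals the sum over accepted lesions regardless of grouping", {
  ph <- generate_phantom(phantom_default_spec())
  q <- quantify_lesions(ph$pet, ph$masks)
  sc <- compartment_scores(q$lesions, q$ref)
  per_lesion <- vapply(q$lesions, lesion_psma_score, numeric(1), ref = q$ref)
  expect_equal(sc$composite, sum(per_lesion), tolerance = 1e-12)
})

test_that("per-patient score CSV round-trips bit-exactly", {
  sc <- list(
    "7" = list(baseline = psmaquant:::make_compartment_scores(27.5, NA, 0.62,
                                                              "blood_pool"),
               followup = psmaquant:::make_compartment_scores(0.123456789,
                                                              NA, 0.7,
                                                              "blood_pool")))
  f <- tempfile(fileext = ".csv")
  write_scores_csv(sc, f)
  back <- read_scores_csv(f)
  expect_equal(back[["7"]]$baseline$composite, 28.12)
  expect_equal(back[["7"]]$followup$prostate_bed, 0.123456789)
  expect_true(is.na(back[["7"]]$baseline$nodal))
})
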