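test_that("a cloud identical to the hypothesis maps perfectly", {
  h <- plant_hypothesis(seed = 3)
  cl <- cloud_from_hypothesis(h)
  mr <- map_to_hypothesis(cl, h)
  expect_true(mr$mapped)
  expect_equal(mr$fit, sum(h$features$weight), tolerance = 1e-9)
  expect_equal(max(mr$displacements), 0, tolerance = 1e-7)
  expect_length(mr$omitted, 0)
  expect_equal(compute_fit(mr, h), mr$fit, tolerance = 1e-9)
})

test_that("a missing donor is omitted when one omission is allowed", {
  h <- plant_hypothesis(seed = 3)  # one each of HBA/HBD/HY/RA
  cl <- cloud_from_hypothesis(h, drop_types = "HBD")
  mr <- map_to_hypothesis(cl, h, max_omitted = 1)
  expect_true(mr$mapped)
  expect_equal(nrow(mr$correspondence), 3)
  expect_equal(h$features$ftype[mr$omitted], "HBD")
  # with no omission budget there is no admissible correspondence
  mr0 <- map_to_hypothesis(cl, h, max_omitted = 0)
  expect_false(mr0$mapped)
  expect_equal(mr0$fit, 0)
})

test_that("mapping equals the exhaustive oracle on random instances", {
  for (s in 1:40) {
    inst <- random_instance(s)
    mr <- map_to_hypothesis(inst$cloud, inst$h, max_omitted = inst$max_omitted)
    want <- oracle_best_fit(inst$cloud, inst$h, inst$max_omitted)
    expect_equal(mr$fit, want, tolerance = 1e-6)
    expect_gte(mr$fit, 0)
    expect_lte(mr$fit, sum(inst$h$features$weight) + 1e-9)
  }
})

test_that("fit is non-increasing in any single displacement", {
  h <- plant_hypothesis(seed = 5)
  w <- h$features$weight
  t <- h$features$tolerance
  for (j in 1:4) {
    d <- rep(0.3, 4)
    prev <- Inf
    for (dj in seq(0, 2, by = 0.1)) {
      d[j] <- dj
      mr <- structure(list(mapped = TRUE, displacements = d),
                      class = "pharmacophore_mapping")
      f <- compute_fit(mr, h)
      expect_lte(f, prev + 1e-12)
      expect_gte(f, 0)
      expect_lte(f, sum(w) + 1e-12)
      prev <- f
    }
  }
})

test_that("fit arithmetic matches the weighted parabolic penalty", {
  h <- pharmacophore(tibble::tibble(
    ftype = c("HBA", "HBD", "HY", "RA"),
    x = c(0, 4, 0, 4), y = c(0, 0, 4, 4), z = 0,
    tolerance = 1.6, weight = 2))
  mr <- structure(list(
    mapped = TRUE,
    displacements = c(0, 1.6, 0.8, NA),
    correspondence = tibble::tibble(hypothesis_feature = 1:3, cloud_row = 1:3),
    omitted = 4L), class = "pharmacophore_mapping")
  # w=2,d=0 -> 2; d=t -> 0; w=2,d=t/2 -> 1.5; omitted -> 0
  expect_equal(compute_fit(mr, h), 2 + 0 + 1.5)
})

test_that("activity estimation is the calibrated log-linear relation", {
  h <- pharmacophore(tibble::tibble(
    ftype = c("HBA", "HBD", "HY"), x = c(0, 4, 0), y = c(0, 0, 4), z = 0),
    b0 = 1, b1 = 0.5)
  expect_equal(estimate_activity(h, 2), 1.0)
  fits <- seq(0, 6, by = 0.5)
  expect_true(all(diff(estimate_activity(h, fits)) < 0))
  h_un <- pharmacophore(h$features)
  expect_error(estimate_activity(h_un, 2), "not calibrated")
})

test_that("calibration recovers the planted relation on noiseless data", {
  ht <- plant_hypothesis(seed = 8)
  lib <- generate_library(ht, synthetic_spec(
    n_compounds = 12, noise_sigma = 0, jitter_sigma = 0,
    decoy_fraction = 0, activity_range = c(1e-4, 1e4), seed = 8))
  cal <- phoregen:::calibrate_hypothesis(
    pharmacophore(ht$features), lib, engine_config())
  expect_equal(cal$hypothesis$b0, ht$b0, tolerance = 1e-6)
  expect_equal(cal$hypothesis$b1, ht$b1, tolerance = 1e-9)
  expect_equal(cal$hypothesis$features$weight, rep(2, 4), tolerance = 1e-6)
})
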