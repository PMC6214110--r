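tables <- ano1_activity_tables()
train_tab <- dplyr::filter(tables, split == "training")
test_tab <- dplyr::filter(tables, split == "test")

test_that("activity scales partition the positive axis at 1, 8, 18 uM", {
  expect_equal(classify_activity(c(0.107, 1.02, 18)), c("++++", "+++", "+"))
  expect_equal(classify_activity(c(0.999, 1, 7.999, 8, 17.999, 18)),
               c("++++", "+++", "+++", "++", "++", "+"))
  vals <- withr::with_seed(1, 10^runif(200, -3, 3))
  scales <- classify_activity(vals)
  expect_true(all(scales %in% c("++++", "+++", "++", "+")))
  # each value falls in exactly one bin
  expect_equal(
    (vals < 1) + (vals >= 1 & vals < 8) + (vals >= 8 & vals < 18) + (vals >= 18),
    rep(1, 200))
  expect_error(classify_activity(0), "positive")
})

test_that("error values are signed fold-ratios with magnitude at least one", {
  expect_equal(round(error_value(0.107, 0.128), 1), 1.2)
  expect_equal(error_value(23, 9.2), -2.5)
  expect_equal(error_value(5, 5), 1)
  for (s in 1:20) {
    pr <- withr::with_seed(s, 10^runif(2, -2, 2))
    a <- error_value(pr[1], pr[2]); b <- error_value(pr[2], pr[1])
    expect_gte(abs(a), 1)
    if (pr[1] != pr[2]) {
      expect_equal(abs(a), abs(b))
      expect_equal(sign(a), -sign(b))
    }
  }
  expect_error(error_value(-1, 2), "positive")
})

test_that("regression statistics behave on exact, swapped, and scaled data", {
  d <- withr::with_seed(3, tibble::tibble(
    experimental_uM = 10^runif(10, -1, 1.5)))
  d$estimated_uM <- d$experimental_uM
  st <- regression_stats(d)
  expect_equal(st$r, 1)
  expect_equal(st$rmsd_log, 0)

  d2 <- withr::with_seed(4, dplyr::mutate(
    d, estimated_uM = experimental_uM * 10^rnorm(10, sd = 0.3)))
  st2 <- regression_stats(d2)
  swapped <- regression_stats(
    dplyr::rename(d2, experimental_uM = estimated_uM,
                  estimated_uM = experimental_uM))
  expect_equal(st2$r, swapped$r)
  scaled <- regression_stats(dplyr::mutate(
    d2, experimental_uM = experimental_uM * 7, estimated_uM = estimated_uM * 7))
  expect_equal(scaled$r, st2$r, tolerance = 1e-12)
  expect_equal(scaled$rmsd_log, st2$rmsd_log, tolerance = 1e-12)

  expect_error(regression_stats(d[1:2, ]), "at least 3")
})

test_that("activity records and agreement summarize a series", {
  rec <- activity_records(train_tab)
  agg <- scale_agreement(rec)
  expect_equal(agg$n, 20)
  same <- activity_records(tibble::tibble(
    experimental_uM = c(0.5, 3, 10), estimated_uM = c(0.6, 5, 9)))
  expect_equal(scale_agreement(same)$mismatches, 0)
  expect_equal(scale_agreement(same)$prediction_rate, 100)
})

test_that("permutation counts follow the confidence-level formula", {
  expect_equal(required_permutations(95), 19L)
  expect_equal(required_permutations(90), 9L)
  expect_equal(required_permutations(98), 49L)
  expect_error(required_permutations(100), "between")
  expect_error(required_permutations(0), "between")
})

test_that("leave-one-out regenerates one fold per compound and is stable on recoverable data", {
  ht <- plant_hypothesis(seed = 14)
  lib <- generate_library(ht, synthetic_spec(seed = 14))
  lr <- loo_validation(lib, engine_config(seed = 14))
  expect_equal(nrow(lr), 20)
  expect_setequal(lr$left_out, lib$compound_id)
  expect_lt(attr(lr, "rmsd_r"), 0.05)
})

test_that("validate_model assembles records, agreement, and statistics", {
  ht <- plant_hypothesis(seed = 15)
  lib <- generate_library(ht, synthetic_spec(seed = 15))
  res <- generate_hypotheses(lib, engine_config(seed = 15))
  ext <- generate_library(ht, synthetic_spec(seed = 16))
  vr <- validate_model(ext, res$hypothesis[[1]], engine_config(seed = 15))
  expect_equal(nrow(vr$records), 20)
  expect_true(all(c("error", "experimental_scale", "estimated_scale") %in%
                    names(vr$records)))
  g <- glance(vr)
  expect_equal(g$prediction_rate,
               round(100 * (g$n - g$mismatches) / g$n, 1))
  expect_gt(g$r, 0.5)
})
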