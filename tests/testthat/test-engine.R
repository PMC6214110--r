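# shared synthetic fixture: planted model + library under default conditions
demo_gen <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ht <- plant_hypothesis(seed = 42)
      lib <- generate_library(ht, synthetic_spec(seed = 42))
      cfg <- engine_config(seed = 42)
      res <- generate_hypotheses(lib, cfg)
      cache <<- list(ht = ht, lib = lib, cfg = cfg, res = res)
    }
    cache
  }
})

test_that("lead selection applies the u^2 activity window to the series", {
  # u = 1.5 puts the lead threshold at 2.25 * min(IC50); with the most
  # active compound at 0.107 uM a compound at 0.23 uM is a lead and one
  # at 0.25 uM is not. Candidates must map into every lead, so giving the
  # borderline compound an unrelated cloud empties the candidate list
  # exactly when it crosses the threshold.
  ht <- plant_hypothesis(seed = 1)
  far <- withr::with_seed(2, tibble::tibble(
    compound_id = "border", conformer = 1L,
    ftype = c("HBA", "HBD", "HY", "RA"),
    x = runif(4, 40, 60), y = runif(4, 40, 60), z = runif(4, 40, 60)))
  build <- function(border_ic50) {
    training_set(
      c("top", "border", "mid"), c(0.107, border_ic50, 12),
      list(cloud_from_hypothesis(ht, id = "top"), far,
           { x <- cloud_from_hypothesis(ht, id = "mid"); x }))
  }
  above <- constructive_phase(build(0.25), engine_config())
  expect_gt(length(above), 0)
  expect_true(all(vapply(above, function(h) h$meta$lead == "top", logical(1))))
  below <- constructive_phase(build(0.23), engine_config())
  expect_length(below, 0)

  # with the published training activities only the two most active
  # compounds (0.107 and 0.194 uM) sit below the threshold
  tab <- dplyr::filter(ano1_activity_tables(), split == "training")
  thr <- 1.5^2 * min(tab$experimental_uM)
  expect_equal(tab$compound_id[tab$experimental_uM <= thr], c(1L, 2L))
})

test_that("a single-compound training set yields its own admissible subsets", {
  ht <- plant_hypothesis(seed = 9)
  cl <- cloud_from_hypothesis(ht, id = "solo")
  ts <- training_set("solo", 0.5, list(cl))
  cand <- constructive_phase(ts, engine_config())
  expect_gt(length(cand), 0)
  expect_true(all(vapply(cand, function(h) h$meta$lead == "solo", logical(1))))
  sizes <- vapply(cand, function(h) nrow(h$features), integer(1))
  expect_true(all(sizes >= 3 & sizes <= 4))
})

test_that("the planted arrangement survives construction and subtraction", {
  d <- demo_gen()
  cand <- subtractive_phase(constructive_phase(d$lib, d$cfg), d$lib, d$cfg)
  sigs <- vapply(cand, function(h) paste(sort(h$features$ftype), collapse = "+"),
                 character(1))
  expect_true(paste(sort(d$ht$features$ftype), collapse = "+") %in% sigs)
})

test_that("the subtractive phase removes exactly the candidates explained by inactives", {
  ht <- plant_hypothesis(seed = 11)
  good <- cloud_from_hypothesis(ht, id = "a")
  # an 'inactive' compound carrying the full arrangement
  ts <- training_set(
    c("a", "b", "inact"), c(0.01, 0.012, 100),
    list(good,
         { x <- cloud_from_hypothesis(ht, id = "b"); x$compound_id <- "b"; x },
         { x <- cloud_from_hypothesis(ht, id = "inact"); x$compound_id <- "inact"; x }))
  cfg <- engine_config()
  cand <- constructive_phase(ts, cfg)
  expect_gt(length(cand), 0)
  expect_length(subtractive_phase(cand, ts, cfg), 0)

  # same activities, but the inactive shares nothing: candidates survive
  far <- withr::with_seed(1, tibble::tibble(
    compound_id = "inact", conformer = 1L,
    ftype = c("HY", "HY", "HY"), x = runif(3, 50, 60),
    y = runif(3, 50, 60), z = runif(3, 50, 60)))
  ts2 <- ts
  ts2$clouds[[3]] <- far
  expect_length(subtractive_phase(cand, ts2, cfg), length(cand))

  # nothing exceeds the inactive gap -> unchanged
  ts3 <- ts
  ts3$ic50_uM <- c(0.01, 0.012, 20)
  expect_length(subtractive_phase(cand, ts3, cfg), length(cand))
})

test_that("cost components satisfy their closed forms and identities", {
  cfg <- engine_config()
  sigma <- log10(cfg$uncertainty)
  per_pt <- log2(sigma * sqrt(2 * pi))
  exp_act <- c(0.2, 1.5, 4, 22)

  # perfect predictions, nominal weights
  cr <- phoregen:::cost_report_from(exp_act, exp_act, rep(2, 4), cfg, 8)
  expect_equal(cr$weight_cost, 0)
  expect_equal(cr$error_cost, 4 * per_pt, tolerance = 1e-12)
  expect_equal(cr$config_cost, 3)
  expect_equal(cr$total_cost, cr$error_cost + cr$weight_cost + cr$config_cost,
               tolerance = 1e-9)
  expect_equal(cr$fixed_cost, cr$config_cost + 4 * per_pt, tolerance = 1e-12)

  # equal activities: the geometric-mean null model has zero residuals
  cr2 <- phoregen:::cost_report_from(c(1, 9), c(3, 3), rep(2, 2), cfg, 1)
  expect_equal(cr2$null_cost, 2 * per_pt, tolerance = 1e-12)

  # config cost capped at 17 bits
  cr3 <- phoregen:::cost_report_from(exp_act, exp_act, rep(2, 4), cfg, 2^25)
  expect_equal(cr3$config_cost, 17)

  expect_error(
    compute_cost(plant_hypothesis(1),
                 training_set("a", -1, list(cloud_from_hypothesis(plant_hypothesis(1)))),
                 cfg),
    "positive")
})

test_that("cost is invariant under rigid motion of the hypothesis", {
  d <- demo_gen()
  h <- d$res$hypothesis[[1]]
  cc <- compute_cost(h, d$lib, d$cfg, n_candidates = 10)
  R <- random_rotation(77)
  h2 <- h
  pos <- as.matrix(h$features[, c("x", "y", "z")]) %*% t(R)
  h2$features$x <- pos[, 1] + 3
  h2$features$y <- pos[, 2] - 1
  h2$features$z <- pos[, 3] + 2
  cc2 <- compute_cost(h2, d$lib, d$cfg, n_candidates = 10)
  expect_equal(cc2$total_cost, cc$total_cost, tolerance = 1e-6)
  expect_equal(cc2$null_cost, cc$null_cost, tolerance = 1e-12)
})

test_that("optimization returns ranked, deterministic, cost-sorted hypotheses", {
  d <- demo_gen()
  res <- d$res
  expect_lte(nrow(res), d$cfg$n_hypotheses)
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_false(is.unsorted(res$total_cost))
  expect_true(all(res$total_cost - (res$error_cost + res$weight_cost +
                                      res$config_cost) < 1e-9))
  expect_true(all(res$n_features >= 3 & res$n_features <= 5))
  expect_true(all(res$b1 >= 0))

  res2 <- generate_hypotheses(d$lib, d$cfg)
  expect_equal(res2$total_cost, res$total_cost, tolerance = 1e-12)
  expect_equal(res2$types, res$types)
})

test_that("at zero temperature annealing never worsens the reported model", {
  d <- demo_gen()
  cfg0 <- d$cfg
  cfg0$anneal <- list(t0 = 1e-12, cooling = 0.5, steps = 40)
  cand <- subtractive_phase(constructive_phase(d$lib, cfg0), d$lib, cfg0)
  # initial (refined, calibrated) costs of all candidates
  res <- optimize_hypotheses(cand, d$lib, cfg0)
  init <- vapply(cand, function(h) {
    compute_cost(h, d$lib, cfg0, n_candidates = length(cand))$total_cost
  }, numeric(1))
  expect_lte(res$total_cost[1], min(init) + 1e-9)
})

test_that("the top model's cost is within a bit of the planted truth's", {
  d <- demo_gen()
  truth <- compute_cost(pharmacophore(d$ht$features, min_distance = 0),
                        d$lib, d$cfg,
                        n_candidates = attr(d$res, "n_candidates"))
  expect_lte(d$res$total_cost[1], truth$total_cost + 1)
})

test_that("hypotheses survive a JSON round trip", {
  d <- demo_gen()
  h <- d$res$hypothesis[[1]]
  p <- withr::local_tempfile(fileext = ".json")
  write_hypothesis(h, p)
  back <- read_hypothesis(p)
  expect_equal(back$features, h$features, tolerance = 1e-12)
  expect_equal(back$b0, h$b0, tolerance = 1e-12)
  expect_equal(back$b1, h$b1)
})
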