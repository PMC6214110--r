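test_that("the Lipinski filter applies four strict inequalities", {
  props <- tibble::tibble(
    compound_id = c("big", "eth", "edge_hbd", "greasy"),
    mw = c(600, 46.07, 300, 400),
    hbd = c(2, 1, 5, 0),
    hba = c(4, 1, 3, 2),
    logp = c(2, -0.0014, 1, 5))
  out <- lipinski_filter(props)
  expect_equal(out$lipinski_pass, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$lipinski_violations, c("MW", "", "HBD", "logP"))
})

test_that("the ADMET filter enforces the level criteria", {
  prof <- tibble::tibble(
    compound_id = c("ok3", "ok4", "badbbb", "toxic"),
    solubility = c(3, 4, 3, 3),
    bbb = c(3, 3, 2, 3),
    absorption = c(0, 0, 0, 0),
    cyp2d6 = c(FALSE, FALSE, FALSE, FALSE),
    hepatotoxicity = c(FALSE, FALSE, FALSE, TRUE))
  out <- admet_filter(prof)
  expect_equal(out$admet_pass, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(admet_filter(prof[, 1:3]), "missing")
  lenient <- admet_filter(prof[, 1:3], strict = FALSE)
  expect_true(all(lenient$admet_missing >= 2))
})

test_that("scaffold keys collapse side chains and flag acyclic molecules", {
  tol <- scaffold_key(parse_molecule("Cc1ccccc1", "toluene"))
  etb <- scaffold_key(parse_molecule("CCc1ccccc1", "ethylbenzene"))
  bz <- scaffold_key(parse_molecule("c1ccccc1", "benzene"))
  pyr <- scaffold_key(parse_molecule("c1ccncc1", "pyridine"))
  expect_equal(tol, etb)
  expect_equal(tol, bz)
  expect_false(bz == pyr)
  expect_equal(scaffold_key(parse_molecule("CCCCCC", "hexane")), "ACYCLIC")
})

test_that("scaffold dedup keeps the best-scoring member per framework", {
  hits <- phoregen:::finish_hits(tibble::tibble(
    compound_id = c("a", "b", "c", "d", "e"),
    fit = c(7, 6, 5, 7.5, 6.5),
    estimated_uM = c(0.01, 0.03, 0.05, 0.02, 0.04),
    scaffold = c("s1", "s1", "s1", "s2", "s2"),
    rank = 1:5), tibble::tibble(stage = "library", n = 5))
  out <- dedup_by_scaffold(hits)
  expect_equal(nrow(out), 2)
  expect_setequal(out$compound_id, c("a", "d"))
  expect_equal(out$rank, 1:2)

  distinct <- phoregen:::finish_hits(tibble::tibble(
    compound_id = c("a", "b"), fit = c(7, 6),
    estimated_uM = c(0.01, 0.03), scaffold = c("s1", "s2"), rank = 1:2), NULL)
  expect_equal(nrow(dedup_by_scaffold(distinct)), 2)

  tie <- phoregen:::finish_hits(tibble::tibble(
    compound_id = c("zeta", "alpha"), fit = c(7, 7),
    estimated_uM = c(0.01, 0.01), scaffold = c("s1", "s1"), rank = 1:2), NULL)
  expect_equal(dedup_by_scaffold(tie)$compound_id, "alpha")
})

test_that("geometry-only screening recovers planted binders below the cutoff", {
  hs <- plant_hypothesis(seed = 21, b0 = 6.3)
  lib <- generate_library(hs, synthetic_spec(
    n_compounds = 60, decoy_fraction = 0.8, jitter_sigma = 0.15,
    b0 = 6.3, seed = 21))
  crit <- screening_criteria()
  hits <- screen_library(dplyr::select(lib, compound_id, clouds), hs, crit)
  expect_true(all(hits$estimated_uM < crit$activity_cutoff))
  expect_true(all(diff(hits$estimated_uM) >= 0))
  expect_equal(hits$rank, seq_len(nrow(hits)))
  actives <- lib$compound_id[lib$is_active]
  expect_setequal(hits$compound_id, actives)

  f <- funnel_counts(hits)
  expect_false(is.unsorted(rev(f$n)))

  # order invariance: permuting the library leaves the ranked hits unchanged
  perm <- withr::with_seed(5, sample(nrow(lib)))
  hits2 <- screen_library(dplyr::select(lib[perm, ], compound_id, clouds),
                          hs, crit)
  expect_equal(hits2$compound_id, hits$compound_id)
  expect_equal(hits2$estimated_uM, hits$estimated_uM)

  empty <- screen_library(dplyr::select(lib[0, ], compound_id, clouds), hs, crit)
  expect_equal(nrow(empty), 0)
})

test_that("the molecule route runs properties, filters, mapping, and scaffolds", {
  fx <- chem_fixtures()
  lib <- tibble::tibble(
    compound_id = c("ethanol", "benzene", "pentanol"),
    molecule = list(fx$mols$ethanol, fx$mols$benzene, fx$mols$pentanol))
  admet <- tibble::tibble(
    compound_id = lib$compound_id,
    solubility = 3, bbb = 3, absorption = 0,
    cyp2d6 = FALSE, hepatotoxicity = FALSE)
  h <- pharmacophore(tibble::tibble(
    ftype = c("HBA", "HBD", "HY"), x = c(0, 3, 0), y = c(0, 0, 3), z = 0),
    b0 = 1, b1 = 0.3)
  hits <- screen_library(lib, h, screening_criteria(), admet = admet,
                         conformer_cfg = conformer_config(max_conformers = 5))
  f <- funnel_counts(hits)
  expect_equal(f$stage[1:3], c("library", "lipinski", "admet"))
  expect_false(is.unsorted(rev(f$n)))
  expect_true(all(!is.na(hits$scaffold)))
})
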