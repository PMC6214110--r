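#' Screening criteria
#'
#' The funnel's filter thresholds: Lipinski's rule of five (strict
#' inequalities on HBD, HBA, molecular weight, logP), the ADMET level
#' criteria, and the estimated-activity cutoff (default 0.1 uM, i.e. hits
#' must be estimated below 100 nM).
#'
#' @param max_hbd,max_hba,max_mw,max_logp Lipinski bounds (all strict
#'   "less than").
#' @param admet Named list of allowed ADMET levels/flags: `solubility`
#'   (allowed levels), `bbb` (allowed levels), `absorption` (allowed
#'   levels), `cyp2d6` and `hepatotoxicity` (allowed flag, FALSE = must be
#'   non-inhibitor / non-toxic).
#' @param activity_cutoff Estimated IC50 cutoff in uM (hits strictly
#'   below).
#' @return A `screening_criteria` list.
#' @export
screening_criteria <- function(max_hbd = 5, max_hba = 10, max_mw = 500,
                               max_logp = 5,
                               admet = list(solubility = c(3, 4), bbb = 3,
                                            absorption = 0, cyp2d6 = FALSE,
                                            hepatotoxicity = FALSE),
                               activity_cutoff = 0.1) {
  stopifnot(max_hbd > 0, max_hba > 0, max_mw > 0, activity_cutoff > 0)
  structure(list(max_hbd = max_hbd, max_hba = max_hba, max_mw = max_mw,
                 max_logp = max_logp, admet = admet,
                 activity_cutoff = activity_cutoff),
            class = "screening_criteria")
}

#' Lipinski rule-of-five filter
#'
#' Pass requires all four strict inequalities: HBD < 5, HBA < 10,
#' MW < 500 Da, logP < 5 (under the default criteria). A compound sitting
#' exactly on a bound fails that rule.
#'
#' @param properties Property tibble from [compute_properties()] (columns
#'   `mw`, `hbd`, `hba`, `logp`).
#' @param criteria A [screening_criteria()].
#' @return `properties` plus `lipinski_pass` (logical) and
#'   `lipinski_violations` (comma-separated rule names, "" when passing).
#' @export
lipinski_filter <- function(properties, criteria = screening_criteria()) {
  viol <- function(hbd, hba, mw, logp) {
    v <- c(if (hbd >= criteria$max_hbd) "HBD",
           if (hba >= criteria$max_hba) "HBA",
           if (mw >= criteria$max_mw) "MW",
           if (logp >= criteria$max_logp) "logP")
    paste(v, collapse = ",")
  }
  mutate(properties,
         lipinski_violations = purrr::pmap_chr(
           list(.data$hbd, .data$hba, .data$mw, .data$logp), viol),
         lipinski_pass = .data$lipinski_violations == "")
}

#' ADMET criteria filter
#'
#' Profiles come from a pluggable predictor -- typically a per-compound
#' table of precomputed levels (`solubility`, `bbb`, `absorption` integer
#' levels; `cyp2d6`, `hepatotoxicity` logical flags). Pass requires every
#' criterion present in `criteria$admet` to be satisfied. With
#' `strict = TRUE` a missing property is an error; otherwise it is treated
#' as satisfied but counted in the `admet_missing` column.
#'
#' @param profiles Tibble with `compound_id` and ADMET columns.
#' @param criteria A [screening_criteria()].
#' @param strict Error on missing properties (default `TRUE`).
#' @return `profiles` plus `admet_pass` and `admet_missing`.
#' @export
admet_filter <- function(profiles, criteria = screening_criteria(),
                         strict = TRUE) {
  crit <- criteria$admet
  missing_cols <- setdiff(names(crit), names(profiles))
  if (length(missing_cols) && strict) {
    abort(paste0("ADMET profile is missing: ",
                 paste(missing_cols, collapse = ", ")))
  }
  pass <- rep(TRUE, nrow(profiles))
  nmiss <- rep(length(missing_cols), nrow(profiles))
  for (nm in setdiff(names(crit), missing_cols)) {
    vals <- profiles[[nm]]
    ok <- vals %in% crit[[nm]]
    miss <- is.na(vals)
    if (any(miss) && strict) {
      abort(paste0("missing ", nm, " level for some compounds"))
    }
    pass <- pass & (ok | miss)
    nmiss <- nmiss + miss
  }
  mutate(profiles, admet_pass = pass, admet_missing = nmiss)
}

#' Murcko-style scaffold key
#'
#' The ring-and-linker framework of a molecule: all terminal (degree-1)
#' heavy atoms are pruned iteratively so only ring systems and the linkers
#' between them remain, and the framework is emitted as a canonical
#' SMILES. Acyclic molecules return the sentinel key `"ACYCLIC"`.
#'
#' @param m A [molecule][parse_molecule].
#' @return A single scaffold key string.
#' @examples
#' \dontrun{
#' scaffold_key(parse_molecule("Cc1ccccc1", "toluene"))   # benzene framework
#' scaffold_key(parse_molecule("CCCCCC", "hexane"))       # "ACYCLIC"
#' }
#' @export
scaffold_key <- function(m) {
  stopifnot(inherits(m, "molecule"))
  heavy <- which(!m$atoms$hydrogen)
  bonds <- m$bonds[m$bonds$from %in% heavy & m$bonds$to %in% heavy, ]
  keep <- heavy
  repeat {
    deg <- table(factor(c(bonds$from, bonds$to), levels = keep))
    leaves <- keep[deg <= 1]
    if (!length(leaves) || !length(keep)) break
    keep <- setdiff(keep, leaves)
    bonds <- bonds[bonds$from %in% keep & bonds$to %in% keep, ]
  }
  if (!length(keep)) return("ACYCLIC")
  idx <- setNames(seq_along(keep), keep)
  sub <- new_molecule(
    id = paste0(m$id, "_scaffold"),
    atoms = m$atoms[keep, ],
    bonds = tibble(from = as.integer(idx[as.character(bonds$from)]),
                   to = as.integer(idx[as.character(bonds$to)]),
                   order = bonds$order),
    coords = m$coords[keep, , drop = FALSE]
  )
  canonical_smiles(sub)
}

#' Pharmacophore-based virtual screening funnel
#'
#' Runs the staged funnel over a compound library: drug-likeness
#' properties and Lipinski filter, optional ADMET filter, conformer
#' generation and feature perception, pharmacophore mapping, activity
#' estimation, and the estimated-activity cutoff. Hits are ranked by
#' ascending estimated IC50; stage-wise survivor counts are recorded so
#' the funnel shape can be reported.
#'
#' The library is a tibble with `compound_id` plus either a `molecule`
#' list-column (full chemistry route) or a `clouds` list-column of
#' precomputed feature clouds (geometry-only route; the property and
#' scaffold stages are then skipped).
#'
#' @param library Library tibble (see above).
#' @param h A calibrated [pharmacophore].
#' @param criteria A [screening_criteria()].
#' @param cfg An [engine_config()].
#' @param admet Optional ADMET profile tibble (see [admet_filter()]);
#'   `NULL` skips the ADMET stage.
#' @param conformer_cfg A [conformer_config()] for the chemistry route.
#' @return A `screen_hits` tibble: `compound_id`, `fit`, `estimated_uM`,
#'   `scaffold`, `rank`, sorted by estimated activity. The stage funnel is
#'   in `attr(x, "funnel")` (tibble of stage, n) and via [funnel_counts()].
#' @export
screen_library <- function(library, h, criteria = screening_criteria(),
                           cfg = engine_config(), admet = NULL,
                           conformer_cfg = conformer_config()) {
  stopifnot(inherits(h, "pharmacophore"))
  funnel <- tibble(stage = "library", n = nrow(library))
  log_stage <- function(stage, n) {
    funnel <<- bind_rows(funnel, tibble(stage = stage, n = n))
  }
  if (!nrow(library)) {
    return(finish_hits(empty_hits(), funnel))
  }
  has_mol <- "molecule" %in% names(library)
  surv <- library

  if (has_mol) {
    props <- lipinski_filter(compute_properties(surv), criteria)
    surv <- surv[props$lipinski_pass, , drop = FALSE]
    log_stage("lipinski", nrow(surv))
    if (!is.null(admet)) {
      prof <- admet_filter(admet, criteria)
      pass_ids <- prof$compound_id[prof$admet_pass]
      surv <- surv[surv$compound_id %in% pass_ids, , drop = FALSE]
      log_stage("admet", nrow(surv))
    }
    if (!nrow(surv)) return(finish_hits(empty_hits(), funnel))
    clouds <- lapply(surv$molecule, function(m) {
      perceive_ensemble(generate_conformers(m, conformer_cfg))
    })
  } else {
    if (!is.null(admet)) {
      prof <- admet_filter(admet, criteria)
      pass_ids <- prof$compound_id[prof$admet_pass]
      surv <- surv[surv$compound_id %in% pass_ids, , drop = FALSE]
      log_stage("admet", nrow(surv))
    }
    clouds <- surv$clouds
  }

  fits <- batch_fits(clouds, h, cfg)
  mapped <- fits > 0
  log_stage("mapped", sum(mapped))
  est <- estimate_activity(h, fits)
  hit <- mapped & est < criteria$activity_cutoff
  log_stage("activity_cutoff", sum(hit))

  hits <- tibble(
    compound_id = surv$compound_id[hit],
    fit = fits[hit],
    estimated_uM = est[hit],
    scaffold = if (has_mol) {
      vapply(surv$molecule[hit], scaffold_key, character(1))
    } else NA_character_
  )
  hits <- arrange(hits, .data$estimated_uM, .data$compound_id)
  hits$rank <- seq_len(nrow(hits))
  finish_hits(hits, funnel)
}

empty_hits <- function() {
  tibble(compound_id = character(), fit = double(), estimated_uM = double(),
         scaffold = character(), rank = integer())
}

finish_hits <- function(hits, funnel) {
  attr(hits, "funnel") <- funnel
  class(hits) <- c("screen_hits", class(hits))
  hits
}

#' Stage-wise funnel counts of a screening run
#' @param hits A `screen_hits` tibble from [screen_library()].
#' @return Tibble with `stage` and `n` (non-increasing).
#' @export
funnel_counts <- function(hits) {
  attr(hits, "funnel")
}

#' Keep one hit per scaffold
#'
#' Collapses same-scaffold hits to the best-scoring member (lowest
#' estimated IC50; ties broken by compound id) and re-ranks. Hits without
#' a scaffold key (geometry-only screening) are kept as-is.
#'
#' @param hits A `screen_hits` tibble with scaffold keys assigned.
#' @return Deduplicated, re-ranked `screen_hits`.
#' @export
dedup_by_scaffold <- function(hits) {
  f <- attr(hits, "funnel")
  hits <- mutate(hits, .key = ifelse(is.na(.data$scaffold),
                                     paste0(".na.", .data$compound_id),
                                     .data$scaffold))
  out <- hits |>
    group_by(.data$.key) |>
    arrange(.data$estimated_uM, .data$compound_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select(-".key") |>
    arrange(.data$estimated_uM, .data$compound_id)
  out$rank <- seq_len(nrow(out))
  if (!is.null(f)) {
    f <- bind_rows(f, tibble(stage = "scaffold_dedup", n = nrow(out)))
  }
  finish_hits(out, f)
}
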