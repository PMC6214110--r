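#' Four-bin activity scale
#'
#' Classifies IC50 values (uM) into the standard reporting bins:
#' `++++` (most active, IC50 < 1), `+++` (active, 1 <= IC50 < 8),
#' `++` (moderately active, 8 <= IC50 < 18), `+` (inactive, IC50 >= 18).
#' The bins are half-open, so every positive activity falls in exactly one
#' scale.
#'
#' @param ic50 Positive IC50 value(s), uM.
#' @return Character vector of scales.
#' @examples
#' classify_activity(c(0.107, 1.02, 18))
#' @export
classify_activity <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    abort("IC50 values must be positive and finite")
  }
  dplyr::case_when(
    ic50 < 1 ~ "++++",
    ic50 < 8 ~ "+++",
    ic50 < 18 ~ "++",
    TRUE ~ "+"
  )
}

#' Signed error value between experimental and estimated activity
#'
#' The error value is the fold-ratio between the estimated and the
#' experimental activity: magnitude `max(est, exp) / min(est, exp)`
#' (always >= 1), positive when the estimate is the larger of the two
#' (overestimated IC50, i.e. activity underestimated) and negative when it
#' is smaller. An exact tie returns +1.
#'
#' @param exp,est Positive activities, uM (vectorized).
#' @return Signed error values.
#' @examples
#' error_value(0.107, 0.128)  # +1.196...
#' error_value(23, 9.2)       # -2.5
#' @export
error_value <- function(exp, est) {
  if (any(exp <= 0) || any(est <= 0)) abort("activities must be positive")
  mag <- pmax(exp, est) / pmin(exp, est)
  ifelse(est >= exp, mag, -mag)
}

#' Per-compound activity records
#'
#' Builds the standard per-compound comparison table: experimental and
#' estimated IC50, signed error value, both activity scales, and whether
#' the scales disagree.
#'
#' @param data Data frame with one row per compound.
#' @param experimental,estimated Columns holding the experimental and
#'   estimated IC50 in uM (tidy-eval; default `experimental_uM`,
#'   `estimated_uM`).
#' @return `data` plus columns `error`, `experimental_scale`,
#'   `estimated_scale`, `scale_mismatch`.
#' @export
activity_records <- function(data, experimental = experimental_uM,
                             estimated = estimated_uM) {
  mutate(
    data,
    error = error_value({{ experimental }}, {{ estimated }}),
    experimental_scale = classify_activity({{ experimental }}),
    estimated_scale = classify_activity({{ estimated }}),
    scale_mismatch = .data$experimental_scale != .data$estimated_scale
  )
}

#' Log-scale regression statistics
#'
#' Pearson correlation `r`, its square, and the root-mean-square deviation
#' of residuals, all computed on `log10(IC50)`. Correlating on the log
#' scale is what reproduces the published training/test statistics of the
#' reference inhibitor series; linear-scale correlation does not.
#'
#' @inheritParams activity_records
#' @return One-row tibble with `r`, `r2`, `rmsd_log`, `n`.
#' @export
regression_stats <- function(data, experimental = experimental_uM,
                             estimated = estimated_uM) {
  e <- dplyr::pull(data, {{ experimental }})
  s <- dplyr::pull(data, {{ estimated }})
  if (length(e) < 3) abort("need at least 3 activity pairs")
  if (any(e <= 0) || any(s <= 0)) abort("activities must be positive")
  le <- log10(e); ls <- log10(s)
  r <- cor(le, ls)
  tibble(r = r, r2 = r^2, rmsd_log = sqrt(mean((ls - le)^2)), n = length(e))
}

#' Activity-scale agreement
#'
#' @param records Output of [activity_records()] (needs both scale
#'   columns).
#' @return One-row tibble with `n`, `mismatches`, and `prediction_rate`
#'   (percent of compounds estimated in their experimental scale, one
#'   decimal place).
#' @export
scale_agreement <- function(records) {
  if (!nrow(records)) abort("no activity records")
  n <- nrow(records)
  mism <- sum(records$experimental_scale != records$estimated_scale)
  tibble(n = n, mismatches = mism,
         prediction_rate = round(100 * (n - mism) / n, 1))
}

#' Permutations needed for a Fischer randomization test
#'
#' For a confidence level of `c` percent the randomization test needs
#' `ceiling(100 / (100 - c)) - 1` activity-scrambled regenerations (19 at
#' 95 percent).
#'
#' @param confidence Confidence level in percent, strictly between 0 and
#'   100.
#' @return Integer number of permuted runs.
#' @export
required_permutations <- function(confidence) {
  if (confidence <= 0 || confidence >= 100) {
    abort("confidence must be strictly between 0 and 100 percent")
  }
  as.integer(ceiling(100 / (100 - confidence)) - 1)
}

#' Fischer randomization (Y-scrambling) of a training set
#'
#' Regenerates hypotheses on activity-permuted copies of the training set
#' (identity permutations are excluded) with the same engine
#' configuration, and compares each permuted run's best total cost with
#' the original model's. The model passes when no scrambled run reaches a
#' lower cost.
#'
#' @inheritParams constructive_phase
#' @param confidence Confidence level in percent (95 gives 19 runs).
#' @param original Optional precomputed `hypogen_result` for the unshuffled
#'   training set (recomputed when missing).
#' @return A `fischer_result` tibble: row `run = 0` is the original model,
#'   rows 1..m the permuted runs, with `total_cost` and `r` of each run's
#'   best hypothesis. Attributes: `passed`, `confidence`.
#' @export
fischer_randomization <- function(training, cfg = engine_config(),
                                  confidence = 95, original = NULL) {
  m <- required_permutations(confidence)
  if (is.null(original)) original <- generate_hypotheses(training, cfg)
  if (!nrow(original)) abort("original generation produced no hypotheses")
  rows <- list(tibble(run = 0L, permuted = FALSE,
                      total_cost = original$total_cost[1], r = original$r[1]))
  for (i in seq_len(m)) {
    seed_i <- cfg$seed + i
    perm <- withr::with_seed(seed_i, {
      p <- sample.int(nrow(training))
      tries <- 0
      while (all(p == seq_len(nrow(training))) && tries < 100) {
        p <- sample.int(nrow(training)); tries <- tries + 1
      }
      p
    })
    shuffled <- training
    shuffled$ic50_uM <- training$ic50_uM[perm]
    cfg_i <- cfg; cfg_i$seed <- seed_i
    res <- generate_hypotheses(shuffled, cfg_i)
    rows[[i + 1]] <- tibble(
      run = i, permuted = TRUE,
      total_cost = if (nrow(res)) res$total_cost[1] else Inf,
      r = if (nrow(res)) res$r[1] else NA_real_)
  }
  out <- bind_rows(rows)
  attr(out, "passed") <- all(out$total_cost[out$permuted] >
                               out$total_cost[1] - 1e-9)
  attr(out, "confidence") <- confidence
  class(out) <- c("fischer_result", class(out))
  out
}

#' @export
print.fischer_result <- function(x, ...) {
  cat(sprintf("<fischer_result> %d permuted runs at %s%% confidence: %s\n",
              sum(x$permuted), format(attr(x, "confidence")),
              if (isTRUE(attr(x, "passed"))) "PASS (original cost lowest)"
              else "FAIL (a scrambled run scored lower)"))
  NextMethod()
}

#' Leave-one-out validation
#'
#' Regenerates the model n times, dropping one training compound per fold,
#' and summarizes how much the training correlation depends on any single
#' compound: `rmsd_r = sqrt(mean((r_full - r_fold)^2))`.
#'
#' @inheritParams constructive_phase
#' @param original Optional precomputed full-set `hypogen_result`.
#' @return A `loo_result` tibble with one row per fold (`left_out`,
#'   `total_cost`, `r`); attributes `r_full` and `rmsd_r`.
#' @export
loo_validation <- function(training, cfg = engine_config(), original = NULL) {
  n <- nrow(training)
  if (n < 4) abort("leave-one-out needs at least 4 training compounds")
  if (is.null(original)) original <- generate_hypotheses(training, cfg)
  r_full <- original$r[1]
  rows <- lapply(seq_len(n), function(i) {
    res <- generate_hypotheses(training[-i, ], cfg)
    tibble(left_out = training$compound_id[i],
           total_cost = if (nrow(res)) res$total_cost[1] else NA_real_,
           r = if (nrow(res)) res$r[1] else NA_real_)
  })
  out <- bind_rows(rows)
  attr(out, "r_full") <- r_full
  attr(out, "rmsd_r") <- sqrt(mean((r_full - out$r)^2, na.rm = TRUE))
  class(out) <- c("loo_result", class(out))
  out
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("<loo_result> %d folds; r_full %.3f, rmsd of r %.4f\n",
              nrow(x), attr(x, "r_full"), attr(x, "rmsd_r")))
  NextMethod()
}

#' Full validation report for a calibrated hypothesis on a labelled set
#'
#' Maps every compound, estimates activity, and assembles activity
#' records, scale agreement and log-scale regression statistics.
#'
#' @param test A [training_set()]-shaped tibble (ids, activities, clouds).
#' @param h A calibrated [pharmacophore].
#' @param cfg An [engine_config()].
#' @return A `validation_report` list with elements `records` (tibble),
#'   `agreement` and `stats`.
#' @export
validate_model <- function(test, h, cfg = engine_config()) {
  fits <- batch_fits(test$clouds, h, cfg)
  recs <- activity_records(
    tibble(compound_id = test$compound_id,
           experimental_uM = test$ic50_uM,
           fit = fits,
           estimated_uM = estimate_activity(h, fits)))
  structure(list(records = recs,
                 agreement = scale_agreement(recs),
                 stats = regression_stats(recs)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  a <- x$agreement; s <- x$stats
  cat(sprintf(
    "<validation_report> n %d: %d scale mismatch(es), prediction rate %.1f%%, r %.3f (r2 %.3f), rmsd(log10) %.3f\n",
    a$n, a$mismatches, a$prediction_rate, s$r, s$r2, s$rmsd_log))
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) x$records

#' @export
glance.validation_report <- function(x, ...) {
  dplyr::bind_cols(x$agreement, x$stats[, c("r", "r2", "rmsd_log")])
}
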