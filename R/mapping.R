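#' Engine configuration
#'
#' Tunable parameters of hypothesis generation and mapping. The defaults
#' are the modeling conditions the package is built around: activity
#' uncertainty 1.5 (multiplicative), minimum inter-feature distance 2 A,
#' at most one omitted feature during mapping, 10 reported hypotheses.
#'
#' @param uncertainty Multiplicative activity uncertainty `u` (> 1). Leads
#'   in the constructive phase are compounds with
#'   `IC50 <= u^2 * min(IC50)`; `log10(u)` is the error scale of the
#'   description-length cost model.
#' @param min_feature_distance Minimum distance between hypothesis feature
#'   centroids, Angstrom.
#' @param max_omitted Features a compound may leave unmatched while
#'   mapping (default 1).
#' @param inactive_gap Log10 activity gap above the most active compound
#'   beyond which a compound counts as inactive in the subtractive phase.
#' @param n_hypotheses Number of optimized hypotheses reported.
#' @param tolerance,weight Defaults stamped on candidate features.
#' @param weight_sigma Scale (weight units) of the weight-cost penalty.
#' @param feature_range Allowed hypothesis sizes (min 3, max 5).
#' @param dedup_distance Candidates with identical type multisets whose
#'   sorted inter-feature distances agree within this value (A) are
#'   duplicates.
#' @param anneal Simulated-annealing schedule: `t0` start temperature
#'   (bits), `cooling` multiplicative decay per step, `steps` proposals.
#' @param seed Integer seed for every stochastic step of the engine.
#' @return An `engine_config` list.
#' @export
engine_config <- function(uncertainty = 1.5, min_feature_distance = 2,
                          max_omitted = 1, inactive_gap = 3.5,
                          n_hypotheses = 10, tolerance = 1.6, weight = 2,
                          weight_sigma = 0.5, feature_range = c(3, 5),
                          dedup_distance = 0.5,
                          anneal = list(t0 = 0.5, cooling = 0.93, steps = 60),
                          seed = 20181017) {
  stopifnot(uncertainty > 1, min_feature_distance > 0, n_hypotheses >= 1,
            max_omitted >= 0, weight_sigma > 0,
            feature_range[1] >= 3, feature_range[2] <= 5)
  structure(list(
    uncertainty = uncertainty, min_feature_distance = min_feature_distance,
    max_omitted = as.integer(max_omitted), inactive_gap = inactive_gap,
    n_hypotheses = as.integer(n_hypotheses), tolerance = tolerance,
    weight = weight, weight_sigma = weight_sigma,
    feature_range = as.integer(feature_range),
    dedup_distance = dedup_distance, anneal = anneal,
    seed = as.integer(seed)
  ), class = "engine_config")
}

#' Map a compound onto a hypothesis
#'
#' Exhaustive search over (conformer x type-compatible injective
#' correspondence x allowed omissions) for the fit-maximizing mapping. The
#' matched cloud features are rigidly superposed onto the hypothesis
#' centroids (least squares); each matched feature's displacement `d_f` is
#' its distance from the corresponding centroid after superposition, and
#' the fit value is `sum over matched f of w_f * max(0, 1 - (d_f/t_f)^2)`.
#' Ties are broken by lower superposition RMSD, then lexicographically
#' smallest correspondence, so the result is deterministic.
#'
#' @param cloud Feature-cloud tibble for one compound (one or more
#'   conformers, distinguished by the `conformer` column).
#' @param h A [pharmacophore].
#' @param cfg An [engine_config()]; only `max_omitted` is used here.
#' @param max_omitted Override for the omission budget.
#' @return A `pharmacophore_mapping`: list with `fit`, `rmsd`, `conformer`,
#'   `correspondence` (tibble of hypothesis-feature / cloud-row pairs),
#'   `omitted` (hypothesis feature indices), `displacements`, `transform`
#'   and `mapped` (FALSE when no admissible correspondence exists, in
#'   which case `fit` is 0).
#' @export
map_to_hypothesis <- function(cloud, h, cfg = engine_config(),
                              max_omitted = cfg$max_omitted) {
  stopifnot(inherits(h, "pharmacophore"))
  hm <- hyp_matrices(h)
  if (nrow(cloud) == 0) {
    return(unmapped_result(nrow(h$features)))
  }
  cm <- cloud_matrices(cloud)
  res <- .rcpp_best_mapping(cm[[1]], cm[[2]], cm[[3]], hm$pos, hm$type,
                            hm$tol, hm$wt, as.integer(max_omitted))
  if (!isTRUE(res$found)) {
    return(unmapped_result(nrow(h$features)))
  }
  assign <- res$assignment
  matched <- which(assign > 0)
  structure(list(
    mapped = TRUE,
    fit = res$fit,
    rmsd = res$rmsd,
    conformer = res$conformer,
    correspondence = tibble(hypothesis_feature = matched,
                            cloud_row = assign[matched]),
    omitted = which(assign == 0),
    displacements = res$displacements,
    transform = list(rotation = res$rotation,
                     translation = as.numeric(res$translation)),
    tolerance = h$features$tolerance,
    weight = h$features$weight
  ), class = "pharmacophore_mapping")
}

unmapped_result <- function(k) {
  structure(list(
    mapped = FALSE, fit = 0, rmsd = NA_real_, conformer = NA_integer_,
    correspondence = tibble(hypothesis_feature = integer(),
                            cloud_row = integer()),
    omitted = seq_len(k), displacements = rep(NA_real_, k),
    transform = NULL, tolerance = rep(NA_real_, k), weight = rep(NA_real_, k)
  ), class = "pharmacophore_mapping")
}

#' @export
print.pharmacophore_mapping <- function(x, ...) {
  if (!x$mapped) {
    cat("<mapping> unmapped (fit 0)\n")
  } else {
    cat(sprintf("<mapping> fit %.3f, %d matched / %d omitted, rmsd %.3f A, conformer %d\n",
                x$fit, nrow(x$correspondence), length(x$omitted), x$rmsd,
                x$conformer))
  }
  invisible(x)
}

#' @export
tidy.pharmacophore_mapping <- function(x, ...) {
  k <- length(x$displacements)
  tibble(
    hypothesis_feature = seq_len(k),
    cloud_row = vapply(seq_len(k), function(j) {
      i <- match(j, x$correspondence$hypothesis_feature)
      if (is.na(i)) NA_integer_ else x$correspondence$cloud_row[i]
    }, integer(1)),
    displacement = x$displacements,
    contribution = ifelse(
      is.na(x$displacements), 0,
      x$weight * pmax(0, 1 - (x$displacements / x$tolerance)^2))
  )
}

#' Fit value of a mapping
#'
#' `fit = sum over matched f of w_f * max(0, 1 - (d_f / t_f)^2)`; omitted
#' features contribute 0. Recomputed from the stored displacements.
#'
#' @param mr A `pharmacophore_mapping`.
#' @param h The [pharmacophore] it was mapped against.
#' @return Fit value in `[0, sum of weights]`.
#' @export
compute_fit <- function(mr, h) {
  d <- mr$displacements
  t <- h$features$tolerance
  w <- h$features$weight
  contrib <- ifelse(is.na(d), 0, w * pmax(0, 1 - (d / t)^2))
  sum(contrib)
}

#' Estimate activity from a fit value
#'
#' `IC50 = 10 ^ (b0 - b1 * fit)` in uM: strictly decreasing in fit when
#' `b1 > 0`.
#'
#' @param h A calibrated [pharmacophore] (non-`NA` `b0`, `b1`).
#' @param fit Fit value(s).
#' @return Estimated IC50(s) in uM.
#' @export
estimate_activity <- function(h, fit) {
  if (is.na(h$b0) || is.na(h$b1)) abort("hypothesis is not calibrated")
  10^(h$b0 - h$b1 * fit)
}

# Fit values of many compounds (list of cloud tibbles) against h.
batch_fits <- function(clouds, h, cfg, max_omitted = cfg$max_omitted) {
  batch_fits_prepped(lapply(clouds, cloud_matrices), h, cfg, max_omitted)
}

batch_fits_prepped <- function(prepped, h, cfg, max_omitted = cfg$max_omitted) {
  hm <- hyp_matrices(h)
  as.numeric(.rcpp_batch_fits(prepped, hm$pos, hm$type, hm$tol, hm$wt,
                              as.integer(max_omitted)))
}
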