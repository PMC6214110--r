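#' Assemble a training (or test) set
#'
#' A modeling set is a tibble with one row per compound: `compound_id`,
#' `ic50_uM` (experimental activity, uM, > 0) and `clouds` (list-column of
#' feature-cloud tibbles, one per compound, possibly covering several
#' conformers).
#'
#' @param compound_id Character vector of unique ids.
#' @param ic50_uM Positive experimental activities, uM.
#' @param clouds List of feature-cloud tibbles.
#' @return The validated tibble.
#' @export
training_set <- function(compound_id, ic50_uM, clouds) {
  stopifnot(length(compound_id) == length(ic50_uM),
            length(clouds) == length(ic50_uM))
  if (any(ic50_uM <= 0)) abort("activities must be positive")
  if (anyDuplicated(compound_id)) abort("compound ids must be unique")
  tibble(compound_id = as.character(compound_id),
         ic50_uM = as.numeric(ic50_uM), clouds = clouds)
}

#' Constructive phase: candidate hypotheses from the most active compounds
#'
#' Leads are the compounds with `IC50 <= u^2 * min(IC50)` (`u` the activity
#' uncertainty). Every k-feature subset (3 <= k <= 5) of every lead
#' conformer whose features are pairwise at least `min_feature_distance`
#' apart, and which maps fully (no omissions, every displacement within
#' tolerance) into every other lead, becomes a candidate. Candidates with
#' the same feature-type multiset and matching sorted inter-feature
#' distances (within `dedup_distance`) are collapsed to one.
#'
#' @param training A [training_set()] tibble.
#' @param cfg An [engine_config()].
#' @return List of candidate [pharmacophore] objects (uncalibrated).
#' @export
constructive_phase <- function(training, cfg = engine_config()) {
  stopifnot(nrow(training) >= 1)
  ic50 <- training$ic50_uM
  lead_idx <- which(ic50 <= cfg$uncertainty^2 * min(ic50) + 1e-12)
  prep <- lapply(training$clouds, cloud_matrices)
  candidates <- list()
  for (li in lead_idx) {
    cloud <- training$clouds[[li]]
    for (conf in unique(cloud$conformer)) {
      fc <- cloud[cloud$conformer == conf, , drop = FALSE]
      nf <- nrow(fc)
      kmax <- min(cfg$feature_range[2], nf)
      if (kmax < cfg$feature_range[1]) next
      pos <- as.matrix(fc[, c("x", "y", "z")])
      types <- ftype_code(fc$ftype)
      other_leads <- setdiff(lead_idx, li)
      dmat <- as.matrix(stats::dist(pos))
      for (k in cfg$feature_range[1]:kmax) {
        subsets <- utils::combn(nf, k)
        tol <- rep(cfg$tolerance, k)
        wt <- rep(cfg$weight, k)
        for (ci in seq_len(ncol(subsets))) {
          idx <- subsets[, ci]
          dsub <- dmat[idx, idx]
          if (any(dsub[upper.tri(dsub)] < cfg$min_feature_distance - 1e-9)) next
          sub_pos <- pos[idx, , drop = FALSE]
          hm <- list(pos = sub_pos, type = types[idx], tol = tol, wt = wt)
          ok <- TRUE
          for (lj in other_leads) {
            if (!maps_fully_prepped(prep[[lj]], hm, cfg)) { ok <- FALSE; break }
          }
          if (ok) {
            candidates[[length(candidates) + 1]] <- pharmacophore(
              tibble(ftype = fc$ftype[idx],
                     x = sub_pos[, 1], y = sub_pos[, 2], z = sub_pos[, 3],
                     tolerance = cfg$tolerance, weight = cfg$weight),
              min_distance = cfg$min_feature_distance,
              meta = list(lead = training$compound_id[li], conformer = conf))
          }
        }
      }
    }
  }
  dedup_candidates(candidates, cfg$dedup_distance)
}

# full mapping: every hypothesis feature matched, every displacement within
# its tolerance
maps_fully <- function(cloud, h, cfg) {
  maps_fully_prepped(cloud_matrices(cloud), hyp_matrices(h), cfg)
}

maps_fully_prepped <- function(cm, hm, cfg) {
  res <- .rcpp_best_mapping(cm[[1]], cm[[2]], cm[[3]], hm$pos, hm$type,
                            hm$tol, hm$wt, 0L)
  isTRUE(res$found) && all(res$displacements <= hm$tol + 1e-9)
}

dedup_candidates <- function(candidates, dedup_distance) {
  kept <- list()
  sigs <- character()
  dmats <- list()
  for (h in candidates) {
    sig <- paste(sort(h$features$ftype), collapse = "+")
    dv <- sort(as.numeric(stats::dist(as.matrix(h$features[, c("x", "y", "z")]))))
    dup <- FALSE
    for (i in seq_along(kept)) {
      if (sigs[i] == sig && length(dmats[[i]]) == length(dv) &&
          max(abs(dmats[[i]] - dv)) <= dedup_distance) {
        dup <- TRUE; break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1]] <- h
      sigs <- c(sigs, sig)
      dmats[[length(dmats) + 1]] <- dv
    }
  }
  kept
}

#' Subtractive phase: drop candidates explained by inactive compounds
#'
#' A compound is inactive when its activity exceeds
#' `10^inactive_gap * min(IC50)`. Candidates that map fully (no omissions,
#' all displacements within tolerance) into any inactive compound encode
#' chemistry that does not drive activity and are removed.
#'
#' @inheritParams constructive_phase
#' @param candidates List of candidates from [constructive_phase()].
#' @return Filtered candidate list.
#' @export
subtractive_phase <- function(candidates, training, cfg = engine_config()) {
  inact <- which(training$ic50_uM > 10^cfg$inactive_gap * min(training$ic50_uM))
  if (!length(inact) || !length(candidates)) return(candidates)
  prep <- lapply(training$clouds[inact], cloud_matrices)
  keep <- vapply(candidates, function(h) {
    hm <- hyp_matrices(h)
    !any(vapply(prep, function(cm) maps_fully_prepped(cm, hm, cfg),
                logical(1)))
  }, logical(1))
  candidates[keep]
}

# Calibration of the activity relation log10(IC50) = b0 - fit. The slope is
# fixed at one (the published estimate pairs of the reference series obey
# exactly that relation); the scale is carried by the per-feature weights,
# fit by ridge regression toward the nominal weight -- the MAP estimator
# implied by the Gaussian weight cost. Scoring uses complete mappings only.
calibrate_hypothesis <- function(h, training, cfg,
                                 prep = lapply(training$clouds, cloud_matrices)) {
  y <- log10(training$ic50_uM)
  hm <- hyp_matrices(h)
  for (pass in 1:2) {
    U <- .rcpp_batch_contribs(prep, hm$pos, hm$type, hm$tol, hm$wt, 0L)
    rw <- ridge_weights(U, y, cfg)
    hm$wt <- rw$w
  }
  h$features$weight <- rw$w
  h$b0 <- rw$b0
  h$b1 <- 1
  list(hypothesis = h, fits = as.numeric(U %*% rw$w))
}

# ridge solve of y ~ b0 - U w with Gaussian prior w ~ N(weight, sigma_w^2);
# lambda is the noise-to-prior variance ratio
ridge_weights <- function(U, y, cfg) {
  k <- ncol(U)
  lam <- (log10(cfg$uncertainty) / cfg$weight_sigma)^2
  Uc <- sweep(U, 2, colMeans(U))
  yc <- y - mean(y)
  A <- crossprod(Uc) + diag(lam, k)
  b <- -crossprod(Uc, yc) + lam * cfg$weight
  w <- tryCatch(as.numeric(solve(A, b)), error = function(e) rep(cfg$weight, k))
  w <- pmax(w, 0)
  list(b0 = mean(y) + mean(U %*% w), w = w)
}

#' Description-length cost of a hypothesis (bits)
#'
#' HypoGen-style Gaussian description-length scoring on the log10 activity
#' scale, with error scale `sigma = log10(u)`:
#'
#' * `error_cost  = sum_i [ delta_i^2 / (2 sigma^2 ln 2) + log2(sigma sqrt(2 pi)) ]`
#'   with `delta_i = log10(est_i) - log10(exp_i)`;
#' * `weight_cost = sum_f (w_f - 2)^2 / (2 sigma_w^2 ln 2)`;
#' * `config_cost = log2(candidate count surviving the subtractive phase)`,
#'   capped at 17 bits;
#' * `total_cost  = error_cost + weight_cost + config_cost`;
#' * `null_cost`  = error cost of the featureless constant predictor (the
#'   geometric mean of the experimental activities) -- invariant to the
#'   hypothesis;
#' * `fixed_cost  = config_cost + n * log2(sigma sqrt(2 pi))`, the cost of
#'   an ideal model predicting every activity exactly.
#'
#' `cost_difference = null_cost - total_cost` is the headline statistic: a
#' large value means the hypothesis explains far more than chance.
#'
#' @inheritParams constructive_phase
#' @param h A calibrated [pharmacophore].
#' @param n_candidates Candidate count retained after the subtractive
#'   phase (defaults to the count recorded in `h$meta`, else 1).
#' @return A `cost_report` (see [glance.cost_report()]).
#' @export
compute_cost <- function(h, training, cfg = engine_config(),
                         n_candidates = NULL) {
  if (any(training$ic50_uM <= 0)) abort("activities must be positive")
  n_candidates <- n_candidates %||% h$meta$n_candidates %||% 1
  cal <- if (is.na(h$b0) || is.na(h$b1)) {
    calibrate_hypothesis(h, training, cfg)
  } else {
    list(hypothesis = h,
         fits = batch_fits(training$clouds, h, cfg, max_omitted = 0))
  }

  h <- cal$hypothesis
  est <- estimate_activity(h, cal$fits)
  cost_report_from(est, training$ic50_uM, h$features$weight, cfg, n_candidates)
}

cost_report_from <- function(est, exp, weights, cfg, n_candidates) {
  sigma <- log10(cfg$uncertainty)
  per_pt <- log2(sigma * sqrt(2 * pi))
  ln2 <- log(2)
  delta <- log10(est) - log10(exp)
  error_cost <- sum(delta^2 / (2 * sigma^2 * ln2) + per_pt)
  weight_cost <- sum((weights - cfg$weight)^2) / (2 * cfg$weight_sigma^2 * ln2)
  config_cost <- min(log2(max(n_candidates, 1)), 17)
  delta0 <- mean(log10(exp)) - log10(exp)
  null_cost <- sum(delta0^2 / (2 * sigma^2 * ln2) + per_pt)
  n <- length(exp)
  r <- if (stats::sd(est) > 0 && stats::sd(exp) > 0) {
    cor(log10(exp), log10(est))
  } else NA_real_
  structure(list(
    error_cost = error_cost, weight_cost = weight_cost,
    config_cost = config_cost,
    total_cost = error_cost + weight_cost + config_cost,
    null_cost = null_cost,
    fixed_cost = config_cost + n * per_pt,
    cost_difference = null_cost - (error_cost + weight_cost + config_cost),
    rmsd_log = sqrt(mean(delta^2)), r = r,
    r2 = if (is.na(r)) NA_real_ else r^2, n = n
  ), class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf(
    "<cost_report> total %.3f bits (error %.3f + weight %.3f + config %.3f)\n",
    x$total_cost, x$error_cost, x$weight_cost, x$config_cost))
  cat(sprintf("  null %.3f, fixed %.3f, difference %.3f; rmsd(log10) %.3f, r %.3f\n",
              x$null_cost, x$fixed_cost, x$cost_difference, x$rmsd_log, x$r))
  invisible(x)
}

#' One-row summary of a cost report
#' @param x A `cost_report`.
#' @param ... Unused.
#' @return A one-row tibble of all cost components and regression stats.
#' @export
glance.cost_report <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Optimization phase: simulated annealing over candidate geometry
#'
#' Each candidate is first pulled onto the consensus geometry of the whole
#' series (an EM-style step that moves every centroid to the mean of the
#' superposed matched features, kept only when it lowers the cost) and
#' then refined by simulated annealing: proposals move one feature
#' centroid (uniform direction, step up to 0.5 A); moves violating the
#' minimum inter-feature distance are rejected outright. Tolerances stay
#' at their nominal value and weights are refit by penalized least squares
#' at every evaluation, together with the intercept. Proposals are
#' accepted by the Metropolis rule on the total cost, so as the
#' temperature approaches zero only cost-decreasing moves survive. All
#' randomness is driven by `cfg$seed`.
#'
#' @inheritParams subtractive_phase
#' @return A `hypogen_result` tibble with one row per reported hypothesis,
#'   sorted by ascending total cost: `rank`, `hypothesis` (list-column of
#'   calibrated [pharmacophore] objects), the cost components and the
#'   training regression statistics.
#' @export
optimize_hypotheses <- function(candidates, training, cfg = engine_config()) {
  if (!length(candidates)) return(empty_result(cfg, 0L))
  n_cand <- length(candidates)
  withr::local_seed(cfg$seed)
  prep <- lapply(training$clouds, cloud_matrices)
  y <- log10(training$ic50_uM)
  mo <- 0L  # generation scores complete mappings only
  # matrix-space scoring used throughout the anneal loop; weights are
  # refit (penalized least squares) at every evaluation
  score_state <- function(st) {
    U <- .rcpp_batch_contribs(prep, st$pos, st$type, st$tol, st$wt, mo)
    rw <- ridge_weights(U, y, cfg)
    st$wt <- rw$w
    st$b0 <- rw$b0; st$b1 <- 1
    fits <- as.numeric(U %*% rw$w)
    st$cost <- cost_report_from(10^(rw$b0 - fits), training$ic50_uM,
                                rw$w, cfg, n_cand)
    st
  }
  as_state <- function(h) {
    hm <- hyp_matrices(h)
    list(pos = hm$pos, type = hm$type, tol = hm$tol, wt = hm$wt,
         ftype = h$features$ftype, meta = h$meta)
  }
  # EM-style centroid refinement: superpose every training compound onto
  # the candidate and move each centroid to the mean of the transformed
  # matched cloud features, so centroids converge on the consensus
  # geometry of the whole set instead of one lead's conformer
  refine_state <- function(st, iters = 3) {
    for (it in seq_len(iters)) {
      acc <- matrix(0, nrow(st$pos), 3)
      cnt <- numeric(nrow(st$pos))
      for (cm in prep) {
        res <- .rcpp_best_mapping(cm[[1]], cm[[2]], cm[[3]], st$pos, st$type,
                                  st$tol, st$wt, mo)
        if (!isTRUE(res$found)) next
        a <- res$assignment
        for (j in which(a > 0)) {
          pt <- res$rotation %*% cm[[1]][a[j], ] + res$translation
          acc[j, ] <- acc[j, ] + as.numeric(pt)
          cnt[j] <- cnt[j] + 1
        }
      }
      if (any(cnt == 0)) break
      newpos <- acc / cnt
      if (any(stats::dist(newpos) < cfg$min_feature_distance - 1e-9)) break
      if (max(abs(newpos - st$pos)) < 1e-4) { st$pos <- newpos; break }
      st$pos <- newpos
    }
    st
  }
  as_pharmacophore <- function(st) {
    st$meta$n_candidates <- n_cand
    pharmacophore(
      tibble(ftype = st$ftype, x = st$pos[, 1], y = st$pos[, 2],
             z = st$pos[, 3], tolerance = st$tol, weight = st$wt),
      b0 = st$b0, b1 = st$b1, min_distance = 0, meta = st$meta)
  }
  scored <- lapply(candidates, function(h) {
    raw <- score_state(score_state(as_state(h)))
    ref <- score_state(score_state(refine_state(as_state(h))))
    if (ref$cost$total_cost <= raw$cost$total_cost) ref else raw
  })
  ord <- order(vapply(scored, function(s) s$cost$total_cost, numeric(1)))
  top <- scored[utils::head(ord, cfg$n_hypotheses)]
  refined <- lapply(top, function(s) anneal_one(s, cfg, score_state))
  refined <- refined[order(vapply(refined, function(s) s$cost$total_cost,
                                  numeric(1)))]
  rows <- lapply(seq_along(refined), function(i) {
    st <- refined[[i]]
    dplyr::bind_cols(
      tibble(rank = i, hypothesis = list(as_pharmacophore(st)),
             n_features = length(st$ftype),
             types = paste(sort(st$ftype), collapse = "+"),
             b0 = st$b0, b1 = st$b1),
      glance(st$cost)
    )
  })
  out <- bind_rows(rows)
  attr(out, "n_candidates") <- n_cand
  attr(out, "config") <- cfg
  class(out) <- c("hypogen_result", class(out))
  out
}

empty_result <- function(cfg, n_cand) {
  out <- tibble(rank = integer(), hypothesis = list(), n_features = integer(),
                types = character(), b0 = double(), b1 = double())
  attr(out, "n_candidates") <- n_cand
  attr(out, "config") <- cfg
  class(out) <- c("hypogen_result", class(out))
  out
}

anneal_one <- function(state, cfg, score_state) {
  cur <- state; best <- state
  temp <- cfg$anneal$t0
  for (step in seq_len(cfg$anneal$steps)) {
    prop <- perturb_state(cur, cfg)
    if (!is.null(prop)) {
      prop <- score_state(prop)
      d <- prop$cost$total_cost - cur$cost$total_cost
      if (d <= 0 || runif(1) < exp(-d / max(temp, 1e-9))) {
        cur <- prop
        if (prop$cost$total_cost < best$cost$total_cost) best <- cur
      }
    }
    temp <- temp * cfg$anneal$cooling
  }
  best
}

# Centroid moves only: location tolerances stay at their nominal value,
# as in published hypotheses; letting the anneal tune tolerances hands it
# an uncharged per-feature knob that fits activity noise.
perturb_state <- function(st, cfg) {
  k <- nrow(st$pos)
  j <- sample.int(k, 1)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  st$pos[j, ] <- st$pos[j, ] + dir * runif(1, 0, 0.5)
  if (any(stats::dist(st$pos) < cfg$min_feature_distance - 1e-9)) return(NULL)
  st
}

#' Generate hypotheses end to end
#'
#' Runs the three generation phases (constructive, subtractive,
#' optimization) on a training set and returns the ranked hypotheses.
#'
#' @inheritParams constructive_phase
#' @return A `hypogen_result` tibble (see [optimize_hypotheses()]); the
#'   candidate count surviving the subtractive phase is available as
#'   `attr(x, "n_candidates")`.
#' @examples
#' \dontrun{
#' h_true <- plant_hypothesis(seed = 7)
#' lib <- generate_library(h_true, synthetic_spec(seed = 7))
#' res <- generate_hypotheses(lib, engine_config(seed = 7))
#' res$total_cost
#' }
#' @export
generate_hypotheses <- function(training, cfg = engine_config()) {
  cand <- constructive_phase(training, cfg)
  cand <- subtractive_phase(cand, training, cfg)
  optimize_hypotheses(cand, training, cfg)
}

#' @export
print.hypogen_result <- function(x, ...) {
  cat("<hypogen_result> ", nrow(x), " hypotheses from ",
      attr(x, "n_candidates") %||% NA, " candidates\n", sep = "")
  NextMethod()
}
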