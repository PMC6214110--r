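# Independent reference implementations used as oracles, plus small
# fixture builders. The oracles deliberately share no code with the
# package internals.

# Rigid-superposition RMSD by coarse Euler-angle grid search refined with
# Nelder-Mead; translation is optimal centroid matching at any rotation.
oracle_superpose_rmsd <- function(source, target) {
  euler <- function(ang) {
    c1 <- cos(ang[1]); s1 <- sin(ang[1])
    c2 <- cos(ang[2]); s2 <- sin(ang[2])
    c3 <- cos(ang[3]); s3 <- sin(ang[3])
    rz <- matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, byrow = TRUE)
    ry <- matrix(c(c2, 0, s2, 0, 1, 0, -s2, 0, c2), 3, byrow = TRUE)
    rx <- matrix(c(1, 0, 0, 0, c3, -s3, 0, s3, c3), 3, byrow = TRUE)
    rz %*% ry %*% rx
  }
  sc <- sweep(source, 2, colMeans(source))
  tc <- sweep(target, 2, colMeans(target))
  obj <- function(ang) sqrt(mean(rowSums((sc %*% t(euler(ang)) - tc)^2)))
  best <- Inf; bang <- c(0, 0, 0)
  for (a1 in seq(0, 2 * pi, by = pi / 6))
    for (a2 in seq(0, pi, by = pi / 6))
      for (a3 in seq(0, 2 * pi, by = pi / 6)) {
        v <- obj(c(a1, a2, a3))
        if (v < best) { best <- v; bang <- c(a1, a2, a3) }
      }
  stats::optim(bang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# Exhaustive best-fit mapping by plain R recursion over all injective
# type-compatible correspondences and omission patterns.
oracle_best_fit <- function(cloud, h, max_omitted) {
  hf <- h$features
  k <- nrow(hf)
  hy <- as.matrix(hf[, c("x", "y", "z")])
  best_fit <- 0
  found <- FALSE
  eval_assign <- function(fc, pos, assign) {
    m <- which(assign > 0)
    if (!length(m)) return()
    X <- pos[assign[m], , drop = FALSE]
    Y <- hy[m, , drop = FALSE]
    if (length(m) >= 3) {
      mx <- colMeans(X); my <- colMeans(Y)
      H <- t(sweep(X, 2, mx)) %*% sweep(Y, 2, my)
      sv <- svd(H)
      dd <- sign(det(sv$v %*% t(sv$u)))
      R <- sv$v %*% diag(c(1, 1, dd)) %*% t(sv$u)
      Xt <- sweep(sweep(X, 2, mx) %*% t(R), 2, my, "+")
    } else {
      Xt <- sweep(X, 2, colMeans(Y) - colMeans(X), "+")
    }
    dv <- sqrt(rowSums((Xt - Y)^2))
    fit <- sum(hf$weight[m] * pmax(0, 1 - (dv / hf$tolerance[m])^2))
    found <<- TRUE
    if (fit > best_fit) best_fit <<- fit
  }
  for (conf in unique(cloud$conformer)) {
    fc <- cloud[cloud$conformer == conf, , drop = FALSE]
    pos <- as.matrix(fc[, c("x", "y", "z")])
    n <- nrow(fc)
    rec <- function(j, assign, used, omitted) {
      if (j > k) { eval_assign(fc, pos, assign); return() }
      for (i in seq_len(n)) {
        if (!used[i] && fc$ftype[i] == hf$ftype[j]) {
          assign[j] <- i; used[i] <- TRUE
          rec(j + 1, assign, used, omitted)
          used[i] <- FALSE; assign[j] <- 0
        }
      }
      if (omitted < max_omitted) rec(j + 1, assign, used, omitted + 1)
    }
    rec(1, integer(k), logical(n), 0)
  }
  if (!found) 0 else best_fit
}

# Random small mapping instance (hypothesis + cloud + omission budget).
random_instance <- function(seed) {
  withr::with_seed(seed, {
    k <- sample(3:4, 1)
    h <- pharmacophore(
      tibble::tibble(
        ftype = sample(phoregen:::FEATURE_TYPES, k, replace = TRUE),
        x = runif(k, -5, 5), y = runif(k, -5, 5), z = runif(k, -5, 5),
        tolerance = runif(k, 1, 2), weight = runif(k, 0.5, 3)),
      min_distance = 0)
    n <- sample(4:8, 1)
    n_conf <- sample(1:2, 1)
    cloud <- dplyr::bind_rows(lapply(seq_len(n_conf), function(cf) {
      tibble::tibble(
        compound_id = "inst", conformer = cf,
        ftype = sample(phoregen:::FEATURE_TYPES, n, replace = TRUE),
        x = runif(n, -6, 6), y = runif(n, -6, 6), z = runif(n, -6, 6))
    }))
    list(h = h, cloud = cloud, max_omitted = sample(0:1, 1))
  })
}

# A feature cloud positioned exactly on a hypothesis' features.
cloud_from_hypothesis <- function(h, id = "probe", conformer = 1L,
                                  drop_types = character()) {
  f <- h$features[!h$features$ftype %in% drop_types, ]
  tibble::tibble(compound_id = id, conformer = as.integer(conformer),
                 ftype = f$ftype, x = f$x, y = f$y, z = f$z)
}

random_rotation <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

# One cached chemistry fixture set (conformers are the slow step).
chem_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      mols <- list(
        ethanol = parse_molecule("CCO", "ethanol"),
        benzene = parse_molecule("c1ccccc1", "benzene"),
        methane = parse_molecule("C", "methane"),
        pentanol = parse_molecule("CCCCCO", "pentanol")
      )
      ens <- lapply(mols, generate_conformers,
                    cfg = conformer_config(max_conformers = 10))
      cache <<- list(mols = mols, ens = ens)
    }
    cache
  }
})
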