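test_that("benzene yields one ring-aromatic at the carbon centroid plus one hydrophobe", {
  fx <- chem_fixtures()
  e <- fx$ens$benzene
  cl <- perceive_features(e$molecule, coords = e$conformers[[1]])
  expect_setequal(cl$ftype, c("RA", "HY"))
  ra <- cl[cl$ftype == "RA", ]
  carbons <- which(e$molecule$atoms$element == "C")
  ctr <- colMeans(e$conformers[[1]][carbons, ])
  expect_equal(c(ra$x, ra$y, ra$z), unname(ctr), tolerance = 1e-8)
  expect_equal(sum(cl$ftype == "HY"), 1)
  dir <- unlist(ra[, c("dir_x", "dir_y", "dir_z")])
  expect_equal(sum(dir^2), 1, tolerance = 1e-6)
})

test_that("ethanol yields donor and acceptor on the oxygen; methane yields nothing", {
  fx <- chem_fixtures()
  e <- fx$ens$ethanol
  cl <- perceive_features(e$molecule, coords = e$conformers[[1]])
  expect_setequal(cl$ftype, c("HBD", "HBA"))
  ox <- which(e$molecule$atoms$element == "O")
  expect_true(all(cl$anchor == ox))
  expect_equal(cl$x, rep(e$conformers[[1]][ox, 1], 2))

  em <- fx$ens$methane
  expect_equal(nrow(perceive_features(em$molecule,
                                      coords = em$conformers[[1]])), 0)
})

test_that("acceptor exclusions: amide and pyrrole nitrogens do not accept", {
  amide <- parse_molecule("CC(=O)NC", "nmeacetamide")
  ea <- generate_conformers(amide)
  cl <- perceive_features(ea$molecule, coords = ea$conformers[[1]])
  n_idx <- which(ea$molecule$atoms$element == "N")
  expect_false(any(cl$ftype == "HBA" & cl$anchor == n_idx))
  expect_true(any(cl$ftype == "HBD" & cl$anchor == n_idx))

  pyrrole <- parse_molecule("c1cc[nH]c1", "pyrrole")
  ep <- generate_conformers(pyrrole)
  clp <- perceive_features(ep$molecule, coords = ep$conformers[[1]])
  np <- which(ep$molecule$atoms$element == "N")
  expect_false(any(clp$ftype == "HBA" & clp$anchor == np))
})

test_that("every conformer of an ensemble shows the same feature-type multiset", {
  fx <- chem_fixtures()
  clouds <- perceive_ensemble(fx$ens$pentanol)
  expect_equal(dplyr::n_distinct(clouds$conformer),
               length(fx$ens$pentanol$conformers))
  per_conf <- split(clouds$ftype, clouds$conformer)
  for (tt in per_conf[-1]) expect_equal(sort(tt), sort(per_conf[[1]]))
})

test_that("feature positions are equivariant under rigid motions", {
  fx <- chem_fixtures()
  e <- fx$ens$pentanol
  base <- perceive_features(e$molecule, coords = e$conformers[[1]])
  for (s in 1:3) {
    R <- random_rotation(s)
    tr <- withr::with_seed(s + 100, rnorm(3, sd = 5))
    moved <- sweep(e$conformers[[1]] %*% t(R), 2, tr, "+")
    got <- perceive_features(e$molecule, coords = moved)
    expect_equal(got$ftype, base$ftype)
    exp_pos <- sweep(as.matrix(base[, c("x", "y", "z")]) %*% t(R), 2, tr, "+")
    expect_equal(as.matrix(got[, c("x", "y", "z")]), exp_pos,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("feature counts are invariant under atom reordering", {
  fx <- chem_fixtures()
  e <- fx$ens$ethanol
  m <- e$molecule
  perm <- rev(seq_len(nrow(m$atoms)))
  inv <- order(perm)
  m2 <- m
  m2$atoms <- m$atoms[perm, ]
  m2$coords <- m$coords[perm, , drop = FALSE]
  m2$bonds <- dplyr::mutate(m$bonds, from = inv[from], to = inv[to])
  cl1 <- perceive_features(m, coords = e$conformers[[1]])
  cl2 <- perceive_features(m2, coords = e$conformers[[1]][perm, ])
  expect_equal(sort(cl1$ftype), sort(cl2$ftype))
})

test_that("feature clouds survive a JSON round trip", {
  fx <- chem_fixtures()
  e <- fx$ens$benzene
  cl <- perceive_features(e$molecule, coords = e$conformers[[1]])
  p <- withr::local_tempfile(fileext = ".json")
  write_feature_cloud(cl, p)
  back <- read_feature_cloud(p)
  expect_equal(back$ftype, cl$ftype)
  expect_equal(back$x, cl$x, tolerance = 1e-12)
})
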