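#' Pharmacophore feature perception
#'
#' Converts one conformer of a molecule into a typed 3D feature cloud with
#' the four classic feature classes:
#'
#' * **HBD** -- N/O bearing at least one hydrogen; placed on the heavy
#'   atom, direction along the heavy-atom-to-H axis.
#' * **HBA** -- N/O with an available lone pair; amide nitrogens,
#'   pyrrole-type (aromatic, H-bearing) nitrogens, positively charged and
#'   oxidized nitrogens are excluded. Placed on the heavy atom, direction
#'   pointing away from the mean of its bonded neighbours.
#' * **HY** -- centroid of each connected cluster of two or more carbons /
#'   halogens that have no polar (N, O, S, P) or charged neighbour; a ring
#'   counts as a single cluster.
#' * **RA** -- centroid of each 5- or 6-membered aromatic ring, direction
#'   along the ring normal.
#'
#' The rule set ships as a versioned YAML file
#' (`system.file("extdata", "feature_rules.yaml", package = "phoregen")`)
#' and can be overridden per call. Features are ordered by (type, anchor
#' atom index), so perception is deterministic, and positions are
#' equivariant under rigid motions of the input coordinates.
#'
#' @param m A [molecule][parse_molecule].
#' @param coords Atoms-by-3 coordinate matrix (defaults to the molecule's
#'   own coordinates, which must be a 3D embedding).
#' @param compound_id Id stamped on the cloud (defaults to `m$id`).
#' @param conformer Conformer index stamped on the cloud.
#' @param rules Rule list from [read_feature_rules()].
#' @return A feature-cloud tibble with columns `compound_id`, `conformer`,
#'   `ftype`, `x`, `y`, `z`, `dir_x`, `dir_y`, `dir_z` (unit vector or NA),
#'   `anchor` (anchor atom index). Molecules with no features yield a
#'   zero-row tibble.
#' @export
perceive_features <- function(m, coords = m$coords, compound_id = m$id,
                              conformer = 1L, rules = feature_rules()) {
  stopifnot(inherits(m, "molecule"))
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(m$atoms)) {
    abort("coordinates must cover every atom of the molecule")
  }
  el <- m$atoms$element
  chg <- m$atoms$charge
  nbrs <- neighbor_list(nrow(m$atoms), m$bonds)

  rows <- list()
  add <- function(ftype, pos, dir, anchor) {
    if (!is.null(dir)) {
      nrm <- sqrt(sum(dir^2))
      dir <- if (nrm > 1e-8) dir / nrm else c(NA_real_, NA_real_, NA_real_)
    } else {
      dir <- c(NA_real_, NA_real_, NA_real_)
    }
    rows[[length(rows) + 1]] <<- tibble(
      ftype = ftype, x = pos[1], y = pos[2], z = pos[3],
      dir_x = dir[1], dir_y = dir[2], dir_z = dir[3], anchor = as.integer(anchor))
  }

  don_el <- rules$donor$elements
  acc_el <- rules$acceptor$elements
  for (i in seq_len(nrow(m$atoms))) {
    if (m$atoms$hydrogen[i]) next
    hs <- nbrs[[i]][el[nbrs[[i]]] == "H"]
    heavies <- nbrs[[i]][el[nbrs[[i]]] != "H"]
    # donors
    if (el[i] %in% don_el && length(hs) > 0) {
      add("HBD", coords[i, ], coords[hs[1], ] - coords[i, ], i)
    }
    # acceptors
    if (el[i] %in% acc_el && is_acceptor(m, i, nbrs, hs)) {
      dir <- if (length(nbrs[[i]])) {
        coords[i, ] - colMeans(coords[nbrs[[i]], , drop = FALSE])
      } else NULL
      add("HBA", coords[i, ], dir, i)
    }
  }

  # hydrophobic clusters
  hy <- rules$hydrophobe
  eligible <- !m$atoms$hydrogen & el %in% hy$elements & chg == 0
  if (isTRUE(hy$exclude_charged)) {
    has_bad_nbr <- vapply(seq_along(eligible), function(i) {
      any(el[nbrs[[i]]] %in% hy$polar_neighbors) || any(chg[nbrs[[i]]] != 0)
    }, logical(1))
  } else {
    has_bad_nbr <- vapply(seq_along(eligible), function(i) {
      any(el[nbrs[[i]]] %in% hy$polar_neighbors)
    }, logical(1))
  }
  eligible <- eligible & !has_bad_nbr
  for (cl in graph_clusters(which(eligible), m$bonds)) {
    if (length(cl) >= hy$min_cluster_size) {
      add("HY", colMeans(coords[cl, , drop = FALSE]), NULL, min(cl))
    }
  }

  # ring aromatics
  for (ring in aromatic_rings(m)) {
    if (!(length(ring) %in% rules$ring_aromatic$sizes)) next
    ctr <- colMeans(coords[ring, , drop = FALSE])
    add("RA", ctr, ring_normal(coords[ring, , drop = FALSE]), min(ring))
  }

  out <- if (length(rows)) bind_rows(rows) else {
    tibble(ftype = character(), x = double(), y = double(), z = double(),
           dir_x = double(), dir_y = double(), dir_z = double(),
           anchor = integer())
  }
  out <- arrange(out, .data$ftype, .data$anchor)
  dplyr::bind_cols(
    tibble(compound_id = rep(compound_id, nrow(out)),
           conformer = rep(as.integer(conformer), nrow(out))),
    out
  )
}

is_acceptor <- function(m, i, nbrs, hs) {
  el <- m$atoms$element
  if (el[i] == "O") {
    return(TRUE)
  }
  # nitrogen exclusions
  if (m$atoms$charge[i] > 0) return(FALSE)
  if (m$atoms$aromatic[i] && length(hs) > 0) return(FALSE)   # pyrrole-type
  if (any(el[nbrs[[i]]] == "O")) return(FALSE)               # oxidized N
  for (j in nbrs[[i]]) {
    if (el[j] != "C") next
    # carbonyl carbon? look for C=O from j
    bb <- m$bonds[(m$bonds$from == j | m$bonds$to == j) & m$bonds$order == 2, ]
    other <- ifelse(bb$from == j, bb$to, bb$from)
    if (any(el[other] == "O")) return(FALSE)                 # amide N
  }
  TRUE
}

neighbor_list <- function(n, bonds) {
  nbrs <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$from[k]; b <- bonds$to[k]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  lapply(nbrs, function(x) if (is.null(x)) integer() else sort(x))
}

# connected components of the subgraph induced by `keep` atom indices
graph_clusters <- function(keep, bonds) {
  if (!length(keep)) return(list())
  idx <- setNames(seq_along(keep), keep)
  parent <- seq_along(keep)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(bonds))) {
    a <- as.character(bonds$from[k]); b <- as.character(bonds$to[k])
    if (!is.na(idx[a]) && !is.na(idx[b])) {
      ra <- find(idx[[a]]); rb <- find(idx[[b]])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(keep), find, integer(1))
  unname(lapply(split(keep, roots), sort))
}

# unit normal of a (roughly planar) ring: smallest principal axis of the
# centred coordinates, signed so its first non-zero component is positive
ring_normal <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  v <- svd(ctr)$v[, 3]
  nz <- which(abs(v) > 1e-8)[1]
  if (!is.na(nz) && v[nz] < 0) v <- -v
  v
}

#' @rdname perceive_features
#' @param path Path to a YAML rule file.
#' @export
read_feature_rules <- function(path) {
  yaml::read_yaml(path)
}

feature_rules_cache <- new.env(parent = emptyenv())

feature_rules <- function() {
  if (is.null(feature_rules_cache$rules)) {
    feature_rules_cache$rules <- read_feature_rules(
      system.file("extdata", "feature_rules.yaml", package = "phoregen"))
  }
  feature_rules_cache$rules
}

#' Perceive features for every conformer of an ensemble
#'
#' Perception is topology-driven, so all conformers of a molecule yield the
#' same multiset of feature types; only the positions differ.
#'
#' @param e A [conformer_ensemble][generate_conformers].
#' @param rules Rule list from [read_feature_rules()].
#' @return One feature-cloud tibble covering all conformers (distinguished
#'   by the `conformer` column).
#' @export
perceive_ensemble <- function(e, rules = feature_rules()) {
  stopifnot(inherits(e, "conformer_ensemble"), length(e$conformers) >= 1)
  bind_rows(lapply(seq_along(e$conformers), function(i) {
    perceive_features(e$molecule, coords = e$conformers[[i]],
                      conformer = i, rules = rules)
  }))
}

#' Serialize / deserialize feature clouds as JSON
#' @param cloud A feature-cloud tibble.
#' @param path File path.
#' @return `path` (write) or a feature-cloud tibble (read).
#' @export
write_feature_cloud <- function(cloud, path) {
  jsonlite::write_json(cloud, path, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_feature_cloud
#' @export
read_feature_cloud <- function(path) {
  as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
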