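#' Pharmacophore hypotheses
#'
#' A quantitative pharmacophore hypothesis: 3-5 typed features, each with a
#' centroid (Angstrom), a location tolerance and a weight, plus the two
#' activity-calibration coefficients of the log-linear relation
#' `log10(IC50 [uM]) = b0 - b1 * fit`.
#'
#' @param features Tibble (or data frame) with columns `ftype` (one of
#'   HBA, HBD, HY, RA), `x`, `y`, `z`, and optionally `tolerance`
#'   (default 1.6 A) and `weight` (default 2).
#' @param b0,b1 Activity-regression intercept (log10 uM at fit 0) and
#'   slope (log10 units per fit unit, must be >= 0). `NA` until calibrated.
#' @param min_distance Minimum allowed distance between feature centroids;
#'   violating geometries are rejected.
#' @param meta Free-form provenance list.
#' @return A `pharmacophore` object.
#' @examples
#' h <- pharmacophore(tibble::tibble(
#'   ftype = c("HBA", "HBD", "HY", "RA"),
#'   x = c(0, 3, 0, 3), y = c(0, 0, 4, 4), z = 0))
#' @export
pharmacophore <- function(features, b0 = NA_real_, b1 = NA_real_,
                          min_distance = 2, meta = list()) {
  features <- as_tibble(features)
  stopifnot(all(c("ftype", "x", "y", "z") %in% names(features)))
  if (!"tolerance" %in% names(features)) features$tolerance <- 1.6
  if (!"weight" %in% names(features)) features$weight <- 2
  features <- features[, c("ftype", "x", "y", "z", "tolerance", "weight")]
  k <- nrow(features)
  if (k < 3 || k > 5) abort("a hypothesis needs 3 to 5 features")
  ftype_code(features$ftype)  # validates
  if (any(features$tolerance <= 0)) abort("tolerances must be positive")
  if (any(features$weight < 0)) abort("weights must be non-negative")
  if (!is.na(b1) && b1 < 0) abort("b1 must be non-negative")
  d <- stats::dist(as.matrix(features[, c("x", "y", "z")]))
  if (any(d < min_distance - 1e-9)) {
    abort(sprintf("feature centroids closer than %.2f A", min_distance))
  }
  structure(list(features = features, b0 = b0, b1 = b1, meta = meta),
            class = "pharmacophore")
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat("<pharmacophore> ", nrow(x$features), " features [",
      paste(sort(x$features$ftype), collapse = ", "), "]", sep = "")
  if (!is.na(x$b0)) {
    cat(sprintf("; log10(IC50) = %.3f - %.3f * fit", x$b0, x$b1))
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidy.pharmacophore
#' @export
tidy.pharmacophore <- function(x, ...) x$features

#' Broom-style accessors for pharmacophore hypotheses
#'
#' `tidy()` returns the feature table; `glance()` a one-row summary with
#' feature count, type composition, span, and calibration coefficients.
#'
#' @param x A `pharmacophore`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.pharmacophore <- function(x, ...) {
  d <- stats::dist(as.matrix(x$features[, c("x", "y", "z")]))
  tibble(
    n_features = nrow(x$features),
    types = paste(sort(x$features$ftype), collapse = "+"),
    span = max(d),
    max_fit = sum(x$features$weight),
    b0 = x$b0, b1 = x$b1
  )
}

#' Read / write a hypothesis as JSON
#'
#' Schema: `{features: [{type, xyz, tolerance, weight}], b0, b1, meta}`.
#'
#' @param h A `pharmacophore`.
#' @param path File path.
#' @return `path` (write) or a `pharmacophore` (read).
#' @export
write_hypothesis <- function(h, path) {
  stopifnot(inherits(h, "pharmacophore"))
  obj <- list(
    features = lapply(seq_len(nrow(h$features)), function(i) {
      f <- h$features[i, ]
      list(type = f$ftype, xyz = c(f$x, f$y, f$z),
           tolerance = f$tolerance, weight = f$weight)
    }),
    b0 = h$b0, b1 = h$b1, meta = h$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_hypothesis
#' @export
read_hypothesis <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  features <- bind_rows(lapply(obj$features, function(f) {
    tibble(ftype = f$type, x = f$xyz[[1]], y = f$xyz[[2]], z = f$xyz[[3]],
           tolerance = f$tolerance, weight = f$weight)
  }))
  pharmacophore(features, b0 = obj$b0 %||% NA_real_, b1 = obj$b1 %||% NA_real_,
                min_distance = 0, meta = obj$meta %||% list())
}

# internal: matrices handed to the C++ mapping core
hyp_matrices <- function(h) {
  list(pos = as.matrix(h$features[, c("x", "y", "z")]),
       type = ftype_code(h$features$ftype),
       tol = h$features$tolerance,
       wt = h$features$weight)
}

cloud_matrices <- function(cloud) {
  list(as.matrix(cloud[, c("x", "y", "z")]),
       ftype_code(cloud$ftype),
       as.integer(cloud$conformer))
}
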