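#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that best superposes `source`
#' onto `target` in the least-squares sense (no reflections). With fewer
#' than three points the rotation is left at identity and only the
#' centroids are matched.
#'
#' @param source,target Point matrices (n x 3, same n >= 1), rows in
#'   correspondence.
#' @return List with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd`; the transform maps a source point `p` to
#'   `rotation %*% p + translation`.
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
#' superpose(tri, tri + matrix(c(1, 0, 0), 3, 3, byrow = TRUE))$rmsd
#' @export
superpose <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (ncol(source) != 3 || ncol(target) != 3) abort("points must be n x 3")
  if (nrow(source) != nrow(target)) abort("point sets must have equal length")
  if (nrow(source) < 1) abort("need at least one point")
  res <- .rcpp_kabsch(source, target)
  res$translation <- as.numeric(res$translation)
  res
}

apply_transform <- function(points, transform) {
  sweep(as.matrix(points) %*% t(transform$rotation), 2,
        transform$translation, "+")
}
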