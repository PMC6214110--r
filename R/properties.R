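#' Drug-likeness properties of a molecule
#'
#' Computes the four Lipinski-relevant descriptors through OpenBabel's
#' descriptor engine (via [ChemmineR::propOB()]): molecular weight (sum of
#' atomic masses including implicit hydrogens), hydrogen-bond donor count
#' (N/O atoms bearing at least one hydrogen), hydrogen-bond acceptor count
#' (OpenBabel's JoelLib N/O acceptor typing), and the atomic-contribution
#' logP estimate of Wildman and Crippen. Properties depend only on the
#' molecular graph, never on the conformer.
#'
#' @param m A [molecule][parse_molecule], or a library tibble with a
#'   `molecule` list-column (one row of properties per compound).
#' @return A tibble with columns `compound_id`, `mw` (Da), `hbd`, `hba`,
#'   `logp`.
#' @examples
#' \dontrun{
#' compute_properties(parse_molecule("CCO", "ethanol"))
#' }
#' @export
compute_properties <- function(m) {
  if (inherits(m, "molecule")) {
    lib <- tibble(compound_id = m$id, molecule = list(m))
  } else {
    stopifnot(is.data.frame(m), "molecule" %in% names(m))
    lib <- m
  }
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    mol <- lib$molecule[[i]]
    sdf <- molecule_to_sdfset(mol)
    p <- ChemmineR::propOB(sdf)
    tibble(
      compound_id = lib$compound_id[i],
      mw = as.numeric(p$MW[1]),
      hbd = as.integer(p$HBD[1]),
      hba = as.integer(p$HBA2[1]),
      logp = as.numeric(p$logP[1])
    )
  })
  out <- bind_rows(rows)
  if (any(out$mw <= 0)) abort("non-positive molecular weight computed")
  out
}
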