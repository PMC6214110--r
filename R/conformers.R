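#' Conformer generation settings
#'
#' Defaults mirror the dataset-preparation protocol the model was built
#' for: at most 255 conformers per compound within a strain-energy window
#' of 10 kcal/mol above the ensemble minimum.
#'
#' @param max_conformers Maximum ensemble size (>= 1).
#' @param energy_window Strain-energy window in kcal/mol (> 0) relative to
#'   the lowest-energy conformer kept.
#' @param seed Integer seed for the stochastic embedding; the ensemble is
#'   identical across runs for a fixed seed.
#' @return A `conformer_config` list.
#' @export
conformer_config <- function(max_conformers = 255, energy_window = 10,
                             seed = 20181017) {
  stopifnot(max_conformers >= 1, energy_window > 0)
  structure(list(max_conformers = as.integer(max_conformers),
                 energy_window = energy_window, seed = as.integer(seed)),
            class = "conformer_config")
}

#' Generate a bounded conformer ensemble
#'
#' Distance-geometry embedding (RDKit ETKDG, seeded), per-conformer
#' force-field minimization (MMFF94, falling back to UFF where MMFF94
#' parameters are missing), strain-energy scoring, and pruning: conformers
#' are sorted by strain energy relative to the ensemble minimum, cut at
#' `cfg$energy_window` and capped at `cfg$max_conformers`. Deterministic
#' for a fixed `cfg$seed`.
#'
#' The molecule is embedded from its canonical (pH-adjusted) SMILES, so
#' the returned ensemble carries its own reference `molecule` whose atom
#' order matches the conformer coordinate rows; use that molecule for
#' feature perception.
#'
#' @param m A [molecule][parse_molecule].
#' @param cfg A [conformer_config()].
#' @return A `conformer_ensemble`: list with `molecule`, `conformers`
#'   (list of atoms-by-3 coordinate matrices, Angstrom), `energies`
#'   (kcal/mol relative to the ensemble minimum, ascending) and `config`.
#' @export
generate_conformers <- function(m, cfg = conformer_config()) {
  stopifnot(inherits(m, "molecule"), inherits(cfg, "conformer_config"))
  smi <- canonical_smiles(m)
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(fout), add = TRUE)
  helper <- system.file("python", "conformers.py", package = "phoregen")
  status <- system2(python_binary(),
                    c(helper, shQuote(smi), cfg$seed, cfg$max_conformers,
                      format(cfg$energy_window), fout),
                    stdout = NULL, stderr = NULL)
  if (status == 3) abort(paste0("SMILES of '", m$id, "' rejected by the embedder"))
  if (status != 0 || !file.exists(fout)) {
    abort(paste0("3D embedding failed for molecule '", m$id, "'"))
  }
  lines <- readLines(fout, warn = FALSE)
  recs <- split_sdf_records(lines)
  if (!length(recs)) abort(paste0("no conformers produced for '", m$id, "'"))
  ref <- parse_molfile(recs[[1]], id = m$id)
  if (!identical(sort(ref$atoms$element), sort(m$atoms$element))) {
    abort(paste0("3D embedding changed the formula of '", m$id, "'"))
  }
  ref$smiles <- m$smiles
  coords <- lapply(recs, function(r) {
    na <- as.integer(substr(r[4], 1, 3))
    at <- r[5:(4 + na)]
    cbind(as.numeric(substr(at, 1, 10)),
          as.numeric(substr(at, 11, 20)),
          as.numeric(substr(at, 21, 30)))
  })
  energies <- vapply(recs, function(r) {
    i <- grep("^>\\s*<strain_kcal>", r)
    if (length(i) && length(r) > i[1]) as.numeric(r[i[1] + 1]) else NA_real_
  }, numeric(1))
  if (anyNA(energies)) energies <- rep(0, length(coords))
  ref$coords <- coords[[1]]
  structure(
    list(molecule = ref, conformers = coords,
         energies = energies - min(energies), config = cfg),
    class = "conformer_ensemble"
  )
}

python_binary <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) abort("python interpreter not found on PATH")
  p
}

split_sdf_records <- function(lines) {
  ends <- which(lines == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  recs <- Map(function(s, e) lines[s:(e - 1)], starts, ends)
  Filter(function(r) length(r) >= 4, recs)
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", x$molecule$id, ": ", length(x$conformers),
      " conformer(s), strain 0-",
      sprintf("%.2f", max(x$energies)), " kcal/mol\n", sep = "")
  invisible(x)
}
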