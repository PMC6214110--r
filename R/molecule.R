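#' Molecules and compound libraries
#'
#' `parse_molecule()` turns a SMILES string into a `molecule` object:
#' hydrogens are added explicitly and ionizable groups are set to their
#' pH 7.4 forms (carboxylic acids deprotonated, aliphatic amines
#' protonated) using OpenBabel's pH transform tables. `read_library()` and
#' `write_library()` handle one-record-per-line SMILES files (optional
#' whitespace-separated id) and V2000 SDF.
#'
#' A `molecule` holds an atom table (element, formal charge, aromatic flag,
#' hydrogen flag), a bond table (`from`, `to`, `order`), and an
#' atoms-by-3 coordinate matrix in Angstrom (all-zero until a 3D embedding
#' is generated).
#'
#' @param smiles A single SMILES string.
#' @param id Compound identifier carried through all downstream tables.
#' @param ionize Apply the pH 7.4 protonation rules (default `TRUE`).
#' @return A `molecule` object.
#' @examples
#' \dontrun{
#' m <- parse_molecule("CCO", id = "ethanol")
#' n_heavy_atoms(m)
#' }
#' @export
parse_molecule <- function(smiles, id = "mol1", ionize = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(trimws(smiles))) abort("empty SMILES string")
  check_smiles_tokens(smiles)
  args <- c("-osdf", if (ionize) c("-p", "7.4") else "-h")
  out <- ob_convert(paste0(smiles, " ", id), "smi", args)
  if (length(out$lines) < 4 || out$n_converted < 1) {
    abort(paste0("cannot parse SMILES for '", id, "': ",
                 smiles, if (nzchar(out$err)) paste0(" (", out$err, ")")))
  }
  m <- parse_molfile(out$lines, id = id)
  m$smiles <- smiles
  m
}

# Light lexical check so that obviously malformed strings fail with a
# message naming the offending token (OpenBabel itself is lenient).
check_smiles_tokens <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  ok <- grepl("[][A-Za-z0-9@+()=#$%:/\\\\.*-]", chars)
  if (any(!ok)) abort(paste0("malformed SMILES: unexpected token '",
                             chars[which(!ok)[1]], "'"))
  for (pair in list(c("(", ")"), c("[", "]"))) {
    depth <- cumsum((chars == pair[1]) - (chars == pair[2]))
    if (any(depth < 0) || depth[length(depth)] != 0) {
      abort(paste0("malformed SMILES: unbalanced '", pair[1], "'"))
    }
  }
  invisible(TRUE)
}

new_molecule <- function(id, atoms, bonds, coords, source_line = NA_integer_) {
  structure(
    list(id = id, atoms = atoms, bonds = bonds, coords = coords,
         smiles = NA_character_, source_line = source_line),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  nh <- n_heavy_atoms(x)
  cat("<molecule> ", x$id, ": ", nh, " heavy atoms (",
      nrow(x$atoms), " total), ", nrow(x$bonds), " bonds, ",
      length(aromatic_rings(x)), " aromatic ring(s)\n", sep = "")
  invisible(x)
}

#' Count heavy (non-hydrogen) atoms
#' @param m A `molecule`.
#' @return Integer count.
#' @export
n_heavy_atoms <- function(m) sum(!m$atoms$hydrogen)

#' Ring systems of a molecule
#'
#' Rings (up to 6-membered) with their aromaticity, perceived with
#' [ChemmineR::rings()]. Used for ring-aromatic feature placement.
#'
#' @param m A `molecule`.
#' @return List with integer-vector elements of atom indices; aromatic
#'   rings carry attribute `aromatic = TRUE`.
#' @export
molecule_rings <- function(m) {
  n_comp <- graph_components_count(nrow(m$atoms), m$bonds)
  if (nrow(m$bonds) - nrow(m$atoms) + n_comp <= 0) return(list())
  sdf <- molecule_to_sdfset(m)
  rr <- suppressWarnings(
    tryCatch(ChemmineR::rings(sdf[[1]], upper = 6, type = "all", arom = TRUE),
             error = function(e) NULL))
  if (is.null(rr) || length(rr$RINGS) == 0) return(list())
  out <- lapply(seq_along(rr$RINGS), function(i) {
    idx <- as.integer(sub("^.*_", "", rr$RINGS[[i]]))
    attr(idx, "aromatic") <- isTRUE(unname(rr$AROMATIC[i]))
    idx
  })
  out
}

aromatic_rings <- function(m) {
  Filter(function(r) isTRUE(attr(r, "aromatic")), molecule_rings(m))
}

graph_components_count <- function(n, bonds) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- find(bonds$from[k]); b <- find(bonds$to[k])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# ---- V2000 parsing / writing -------------------------------------------

# Charge codes of the V2000 atom block.
V2000_CHARGE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L,
                  `6` = -2L, `7` = -3L)

parse_molfile <- function(lines, id = NULL, source_line = NA_integer_) {
  if (length(lines) < 4) abort("truncated molfile record")
  na <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nb <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(na) || na < 1) abort("molfile record with no atoms")
  if (length(lines) < 4 + na + max(nb, 0)) abort("truncated molfile record")
  at <- lines[5:(4 + na)]
  coords <- cbind(
    as.numeric(substr(at, 1, 10)),
    as.numeric(substr(at, 11, 20)),
    as.numeric(substr(at, 21, 30))
  )
  element <- trimws(substr(at, 32, 34))
  ccode <- suppressWarnings(as.integer(substr(at, 37, 39)))
  charge <- unname(V2000_CHARGE[as.character(ifelse(is.na(ccode), 0L, ccode))])
  charge[is.na(charge)] <- 0L
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    bonds <- tibble(
      from = as.integer(substr(bl, 1, 3)),
      to = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    bonds <- tibble(from = integer(), to = integer(), order = integer())
  }
  # M CHG property lines override atom-block charge codes
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge[] <- 0L
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
      k <- f[1]
      for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
    }
  }
  if (any(bonds$from > na | bonds$to > na | bonds$from < 1 | bonds$to < 1)) {
    abort("molfile bond references an atom out of range")
  }
  atoms <- tibble(element = element, charge = charge,
                  aromatic = FALSE, hydrogen = element == "H")
  m <- new_molecule(id %||% trimws(lines[1]), atoms, bonds, coords,
                    source_line = source_line)
  arings <- aromatic_rings(m)
  if (length(arings)) {
    m$atoms$aromatic[unique(unlist(arings))] <- TRUE
  }
  m
}

write_molfile <- function(m) {
  na <- nrow(m$atoms); nb <- nrow(m$bonds)
  header <- c(m$id, " phoregen", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                m$coords[, 1], m$coords[, 2], m$coords[, 3], m$atoms$element)
  bl <- if (nb) sprintf("%3d%3d%3d  0  0  0  0", m$bonds$from, m$bonds$to,
                        m$bonds$order) else character()
  chg <- character()
  charged <- which(m$atoms$charge != 0)
  if (length(charged)) {
    # at most 8 atom/charge pairs per M CHG line
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      chg <- c(chg, paste0("M  CHG", sprintf("%3d", length(grp)),
                           paste0(sprintf("%4d%4d", grp, m$atoms$charge[grp]),
                                  collapse = "")))
    }
  }
  c(header, at, bl, chg, "M  END")
}

molecule_to_sdfset <- function(m) {
  txt <- c(write_molfile(m), "$$$$")
  suppressWarnings(ChemmineR::read.SDFset(txt))
}

# ---- OpenBabel plumbing -------------------------------------------------

ob_binary <- function(name) {
  p <- Sys.which(name)
  if (!nzchar(p)) abort(paste0("OpenBabel tool '", name, "' not found on PATH"))
  p
}

# Run obabel on `text` in format `in_fmt`; returns output lines plus the
# number of molecules obabel reports as converted.
ob_convert <- function(text, in_fmt, args) {
  fin <- tempfile(fileext = paste0(".", in_fmt))
  fout <- tempfile(fileext = ".out")
  ferr <- tempfile(fileext = ".err")
  on.exit(unlink(c(fin, fout, ferr)), add = TRUE)
  writeLines(text, fin)
  system2(ob_binary("obabel"), c(fin, args, "-O", fout),
          stdout = NULL, stderr = ferr)
  err <- if (file.exists(ferr)) readLines(ferr, warn = FALSE) else character()
  nconv <- 0L
  hit <- grep("molecule(s?) converted", err, value = TRUE)
  if (length(hit)) {
    nconv <- suppressWarnings(as.integer(sub("^([0-9]+).*", "\\1", hit[1])))
    if (is.na(nconv)) nconv <- 0L
  }
  lines <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character()
  bad <- grep("error|Error|cannot|Cannot", err, value = TRUE)
  list(lines = lines, n_converted = nconv,
       err = paste(utils::head(bad, 2), collapse = "; "))
}

#' Canonical SMILES of a molecule
#' @param m A `molecule`.
#' @return A single canonical SMILES string (hydrogens implicit).
#' @export
canonical_smiles <- function(m) {
  out <- ob_convert(c(write_molfile(m), "$$$$"), "sdf", c("-ocan", "-d"))
  if (!length(out$lines)) abort(paste0("cannot canonicalize molecule ", m$id))
  strsplit(trimws(out$lines[1]), "[ \t]")[[1]][1]
}

# ---- Libraries ----------------------------------------------------------

#' Read a compound library
#'
#' SMILES files have one record per line (`SMILES[ \t]id`); SDF files are
#' read with [ChemmineR::read.SDFset()]. Records that fail to parse are
#' skipped, counted, and reported in a single warning; record order is
#' preserved.
#'
#' @param path Path to the library file.
#' @param format `"smiles"` or `"sdf"`.
#' @param ionize Apply pH 7.4 protonation rules to SMILES records.
#' @return A tibble with columns `compound_id`, `molecule` (list-column of
#'   [molecule][parse_molecule] objects) and `source_line`.
#' @export
read_library <- function(path, format = c("smiles", "sdf"), ionize = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("cannot read library: ", path))
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    recs <- lapply(keep, function(i) {
      f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      cid <- if (length(f) >= 2) f[2] else sprintf("cpd%d", i)
      tryCatch({
        m <- parse_molecule(f[1], id = cid, ionize = ionize)
        m$source_line <- i
        m
      }, error = function(e) NULL)
    })
    ok <- !vapply(recs, is.null, logical(1))
    if (any(!ok)) {
      warn(sprintf("skipped %d of %d records in %s (unparseable)",
                   sum(!ok), length(recs), path))
    }
    lib <- tibble(
      compound_id = vapply(recs[ok], function(m) m$id, character(1)),
      molecule = recs[ok],
      source_line = keep[ok]
    )
  } else {
    sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- suppressWarnings(ChemmineR::validSDF(sdfs))
    if (any(!valid)) {
      warn(sprintf("skipped %d of %d records in %s (invalid SDF)",
                   sum(!valid), length(valid), path))
    }
    idx <- which(valid)
    recs <- lapply(idx, function(i) {
      lines <- as(sdfs[[i]], "character")
      m <- parse_molfile(lines, source_line = i)
      if (!nzchar(m$id)) m$id <- sprintf("cpd%d", i)
      m
    })
    lib <- tibble(
      compound_id = vapply(recs, function(m) m$id, character(1)),
      molecule = recs,
      source_line = idx
    )
  }
  lib
}

#' Write a compound library
#'
#' @param library Tibble with `compound_id` and `molecule` columns, as
#'   returned by [read_library()].
#' @param path Output path.
#' @param format `"smiles"` or `"sdf"` (V2000, coordinates in Angstrom).
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (format == "sdf") {
    txt <- unlist(lapply(library$molecule, function(m) c(write_molfile(m), "$$$$")))
  } else {
    txt <- vapply(library$molecule, function(m) {
      s <- if (!is.na(m$smiles)) m$smiles else canonical_smiles(m)
      paste0(s, "\t", m$id)
    }, character(1))
  }
  writeLines(txt, path)
  invisible(path)
}
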