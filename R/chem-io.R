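#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one record per line: the SMILES string optionally
#' followed by whitespace and a name. SDF input must be V2000; V3000
#' records are rejected. Records that fail to parse are reported with
#' [message()] and skipped; they are never dropped silently.
#'
#' @param path file to read.
#' @param format `"smiles"` or `"sdf"`. Defaults to a guess from the
#'   file extension (`.smi`/`.smiles` vs `.sdf`/`.mol`/`.sd`).
#' @return A named list of [Molecule-class] objects (unprepared: no
#'   explicit hydrogens, coordinates or charges yet; parse-time AlogP
#'   and PSA are already populated).
#' @examples
#' smi <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene"), smi)
#' mols <- readMolecules(smi)
#' length(mols)
#' @export
readMolecules <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      smi = , smiles = , ism = "smiles",
      sdf = , sd = , mol = "sdf",
      stop("cannot guess format from extension '", ext,
           "'; pass format = \"smiles\" or \"sdf\"")
    )
  }
  format <- match.arg(format, c("smiles", "sdf"))
  records <- if (format == "smiles") {
    .smilesRecords(path)
  } else {
    .sdfRecords(path)
  }
  if (length(records) == 0) stop("no records found in ", path)
  reply <- .runChemBackend(records, prepare = FALSE)
  mols <- list()
  nbad <- 0L
  for (k in seq_along(reply$molecules)) {
    entry <- reply$molecules[[k]]
    if (!isTRUE(entry$ok)) {
      nbad <- nbad + 1L
      message(sprintf("skipping record '%s': %s", entry$id, entry$error))
      next
    }
    mols[[entry$id]] <- .moleculeFromBackend(
      entry,
      source = records[[k]]$text, sourceFormat = format, prepared = FALSE
    )
  }
  if (length(mols) == 0) stop("no valid records in ", path)
  mols
}

.smilesRecords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "[[:space:]]+")[[1]]
    id <- if (length(parts) >= 2) {
      paste(parts[-1], collapse = " ")
    } else {
      sprintf("mol_%03d", k)
    }
    recs[[k]] <- list(id = id, format = "smiles", text = parts[1])
  }
  recs
}

.sdfRecords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("V3000", lines, fixed = TRUE))) {
    stop("V3000 SDF records are not supported; please export as V2000")
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  recs <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    body <- block[!grepl("^\\$\\$\\$\\$", block)]
    if (all(!nzchar(trimws(body)))) next
    title <- trimws(body[1])
    id <- if (nzchar(title)) title else sprintf("mol_%03d", k)
    text <- paste(c(body, "$$$$"), collapse = "\n")
    recs[[length(recs) + 1L]] <- list(id = id, format = "sdf", text = text)
  }
  recs
}

#' Prepare molecules: explicit hydrogens, 3D geometry, partial charges
#'
#' Adds explicit hydrogens, embeds one 3D conformer with the seeded
#' ETKDG distance-geometry method followed by MMFF94 minimization
#' (records whose SDF input already carries 3D coordinates keep them),
#' and assigns Gasteiger-Marsili partial charges. The whole operation
#' is deterministic: calling it twice with the same molecule and seed
#' yields bitwise-identical coordinates. Already-prepared molecules are
#' returned unchanged.
#'
#' An external charge set can replace the Gasteiger charges, e.g. when
#' semiempirical QM charges are available: pass `charges` as a numeric
#' vector (one value per atom, in the prepared atom order) or the path
#' of a two-column CSV `atom,charge` with 1-based atom indices.
#'
#' @param m a [Molecule-class].
#' @param mols a list of [Molecule-class] objects (batched backend call).
#' @param seed integer controlling the conformer embedding.
#' @param charges `"gasteiger"` (default), a numeric vector, or a CSV
#'   path, as described above.
#' @return The prepared [Molecule-class] (or list of them).
#' @export
prepareMolecule <- function(m, seed = 7L, charges = "gasteiger") {
  stopifnot(is(m, "Molecule"))
  if (isPrepared(m)) return(m)
  prepareMolecules(list(m), seed = seed, charges = charges)[[1]]
}

#' @rdname prepareMolecule
#' @export
prepareMolecules <- function(mols, seed = 7L, charges = "gasteiger") {
  stopifnot(all(vapply(mols, is, logical(1), "Molecule")))
  todo <- !vapply(mols, isPrepared, logical(1))
  if (!any(todo)) return(mols)
  records <- lapply(mols[todo], function(m) {
    list(id = m@id, format = m@sourceFormat, text = m@source)
  })
  reply <- .runChemBackend(records, seed = seed, prepare = TRUE)
  out <- mols
  idx <- which(todo)
  for (k in seq_along(idx)) {
    entry <- reply$molecules[[k]]
    if (!isTRUE(entry$ok)) {
      stop(sprintf("preparation failed for molecule '%s': %s",
                   entry$id, entry$error))
    }
    mol <- .moleculeFromBackend(
      entry,
      source = mols[[idx[k]]]@source,
      sourceFormat = mols[[idx[k]]]@sourceFormat, prepared = TRUE
    )
    out[[idx[k]]] <- .applyCharges(mol, charges)
  }
  out
}

.applyCharges <- function(mol, charges) {
  if (identical(charges, "gasteiger")) return(mol)
  n <- nrow(mol@atoms)
  if (is.character(charges)) {
    tab <- utils::read.csv(charges)
    if (!all(c("atom", "charge") %in% names(tab))) {
      stop("charge CSV must have columns 'atom' and 'charge'")
    }
    q <- rep(NA_real_, n)
    q[tab$atom] <- tab$charge
    charges <- q
  }
  if (!is.numeric(charges) || length(charges) != n || anyNA(charges)) {
    stop(sprintf(
      "external charges for '%s' must supply one finite value per atom (%d)",
      mol@id, n
    ))
  }
  mol@atoms$charge <- as.numeric(charges)
  validObject(mol)
  mol
}

#' Write / read a descriptor table CSV
#'
#' The table has an `id` column, the descriptor columns (see
#' [descriptorNames()]), and optionally a target column (percent oral
#' bioavailability). Values round-trip losslessly to well below 1e-9
#' relative (full double precision is written).
#'
#' @param table data.frame with an `id` column; all other columns
#'   numeric.
#' @param path CSV file path.
#' @return `writeDescriptorTable` returns `path` invisibly;
#'   `readDescriptorTable` returns the data.frame.
#' @export
writeDescriptorTable <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("descriptor table must be a non-empty data.frame")
  }
  if (!"id" %in% names(table)) stop("descriptor table must have an 'id' column")
  tab <- table
  for (nm in setdiff(names(tab), "id")) {
    tab[[nm]] <- formatC(tab[[nm]], digits = 17, format = "g")
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname writeDescriptorTable
#' @export
readDescriptorTable <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop("not a descriptor table (no 'id' column)")
  tab$id <- as.character(tab$id)
  tab
}

#' Read molecules from an in-memory SMILES vector
#'
#' Convenience front-end to the same parser as [readMolecules()]: names
#' of the vector become molecule ids (auto-generated when absent).
#'
#' @param smiles character vector of SMILES strings, optionally named.
#' @return Named list of unprepared [Molecule-class] objects.
#' @examples
#' \donttest{
#' mols <- readMoleculesFromSmiles(c(ethanol = "CCO", benzene = "c1ccccc1"))
#' }
#' @export
readMoleculesFromSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  ids <- names(smiles)
  if (is.null(ids)) ids <- sprintf("mol_%03d", seq_along(smiles))
  ids[!nzchar(ids)] <- sprintf("mol_%03d", which(!nzchar(ids)))
  records <- Map(
    function(id, smi) list(id = id, format = "smiles", text = smi),
    ids, smiles
  )
  reply <- .runChemBackend(unname(records), prepare = FALSE)
  mols <- list()
  for (k in seq_along(reply$molecules)) {
    entry <- reply$molecules[[k]]
    if (!isTRUE(entry$ok)) {
      message(sprintf("skipping record '%s': %s", entry$id, entry$error))
      next
    }
    mols[[entry$id]] <- .moleculeFromBackend(
      entry,
      source = records[[k]]$text, sourceFormat = "smiles", prepared = FALSE
    )
  }
  if (length(mols) == 0) stop("no valid SMILES records")
  mols
}
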