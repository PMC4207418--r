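# Interface to the bundled RDKit helper (inst/python/chem_backend.py).
# One subprocess call handles a whole batch of records, so the RDKit
# import cost is paid once per batch, not per molecule.

.pythonExecutable <- function() {
  py <- getOption("BioavailQSPR.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no python executable found; set options(BioavailQSPR.python = ...)")
  }
  py
}

# records: list of list(id=, format=, text=)
.runChemBackend <- function(records, seed = 0L, prepare = FALSE) {
  script <- system.file("python", "chem_backend.py", package = "BioavailQSPR")
  if (!nzchar(script)) stop("chem_backend.py not found in installed package")
  job <- list(
    seed = as.integer(seed), prepare = isTRUE(prepare),
    records = lapply(unname(records), function(r) {
      list(id = as.character(r$id), format = r$format, text = r$text)
    })
  )
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(job, fin, auto_unbox = TRUE, digits = NA, null = "null")
  status <- suppressWarnings(system2(
    .pythonExecutable(), c(shQuote(script), shQuote(fin), shQuote(fout)),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0 || !file.exists(fout)) {
    stop("chemistry backend failed (is RDKit importable from python?)")
  }
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

# Build a Molecule from one backend reply entry.
.moleculeFromBackend <- function(entry, source, sourceFormat, prepared) {
  a <- entry$atoms
  coerce_num <- function(v) {
    v[vapply(v, is.null, logical(1))] <- NA_real_
    as.numeric(unlist(v))
  }
  atoms <- data.frame(
    element = unlist(a$element),
    mass = coerce_num(a$mass),
    x = coerce_num(a$x), y = coerce_num(a$y), z = coerce_num(a$z),
    charge = coerce_num(a$charge),
    is_h = as.logical(unlist(a$is_h)),
    stringsAsFactors = FALSE
  )
  atoms$vdw <- vdwRadius(atoms$element)
  b <- entry$bonds
  if (length(b$i) == 0) {
    bonds <- data.frame(
      i = integer(), j = integer(),
      order = character(), aromatic = logical(),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(
      i = as.integer(unlist(b$i)), j = as.integer(unlist(b$j)),
      order = unlist(b$order), aromatic = as.logical(unlist(b$aromatic)),
      stringsAsFactors = FALSE
    )
  }
  new("Molecule",
    id = entry$id, atoms = atoms, bonds = bonds,
    prepared = prepared, source = source, sourceFormat = sourceFormat,
    alogp = as.numeric(entry$alogp), psa = as.numeric(entry$psa)
  )
}
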