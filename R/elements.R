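# Bondi van der Waals radii (Angstrom). Fixed table so surface and
# shadow descriptors are reproducible across toolkit versions.
.BONDI_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Cl = 1.75, Br = 1.85, I = 1.98, S = 1.80, P = 1.80,
  Si = 2.10, B = 1.92, Se = 1.90
)

.DEFAULT_VDW <- 1.70

#' Van der Waals radius lookup (Bondi set)
#'
#' @param element character vector of element symbols.
#' @return Numeric radii in Angstrom. Elements missing from the Bondi
#'   table fall back to 1.70 Angstrom (the carbon radius) with a warning.
#' @examples
#' vdwRadius(c("H", "O", "Cl"))
#' @export
vdwRadius <- function(element) {
  r <- unname(.BONDI_RADII[element])
  if (anyNA(r)) {
    miss <- unique(element[is.na(r)])
    warning(sprintf(
      "no Bondi radius for element(s) %s; using default %.2f A",
      paste(miss, collapse = ", "), .DEFAULT_VDW
    ))
    r[is.na(r)] <- .DEFAULT_VDW
  }
  r
}
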