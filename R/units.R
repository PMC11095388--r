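# CODATA 2018 constants. Internal unit system is atomic units (Hartree, bohr,
# electron charge); lengths arrive in Angstrom and are converted on ingest.
HARTREE_EV <- 27.211386245988
EV_CM1 <- 8065.543937349212
HC_EV_NM <- 1239.841984332002  # h*c in eV*nm
BOHR_PER_ANGSTROM <- 1.8897259886
ANGSTROM_PER_BOHR <- 1 / BOHR_PER_ANGSTROM

.energy_units <- c("hartree", "ev", "mev", "cm-1", "nm")

.normalize_unit <- function(u) {
  u <- tolower(trimws(u))
  u <- switch(u,
    "ha" = "hartree", "hartree" = "hartree", "au" = "hartree",
    "ev" = "ev", "mev" = "mev",
    "cm-1" = "cm-1", "cm^-1" = "cm-1", "wavenumber" = "cm-1",
    "nm" = "nm",
    u)
  if (!u %in% .energy_units) {
    stop("unknown energy unit: '", u, "' (known: ",
         paste(.energy_units, collapse = ", "), ")", call. = FALSE)
  }
  u
}

#' Convert between energy units (and wavelength)
#'
#' Converts energies between Hartree, eV, meV and cm^-1, and between energy
#' and wavelength in nm through the reciprocal relation lambda = hc/E.
#' Wavelength conversions therefore require strictly positive values.
#'
#' @param value numeric vector of energies (or wavelengths for `from = "nm"`).
#' @param from,to unit names: one of `"hartree"`, `"eV"`, `"meV"`, `"cm-1"`,
#'   `"nm"` (case-insensitive; `"Ha"`/`"au"` are accepted for Hartree).
#' @return numeric vector in the target unit.
#' @examples
#' convert_energy(1, "hartree", "eV")      # 27.2114
#' convert_energy(1.852, "eV", "nm")       # 669.46
#' @export
convert_energy <- function(value, from, to) {
  from <- .normalize_unit(from)
  to <- .normalize_unit(to)
  if (from == to) return(value)
  if ((from == "nm" || to == "nm") && any(value <= 0)) {
    stop("nm conversions require positive values (reciprocal relation)",
         call. = FALSE)
  }
  # to eV first
  ev <- switch(from,
    "hartree" = value * HARTREE_EV,
    "ev" = value,
    "mev" = value / 1000,
    "cm-1" = value / EV_CM1,
    "nm" = HC_EV_NM / value)
  switch(to,
    "hartree" = ev / HARTREE_EV,
    "ev" = ev,
    "mev" = ev * 1000,
    "cm-1" = ev * EV_CM1,
    "nm" = HC_EV_NM / ev)
}
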