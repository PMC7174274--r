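#' @keywords internal
"_PACKAGE"

# CODATA 2018 fundamental constants. All internal computation is done in
# Hartree atomic units (hbar = 1); eV, cm-1, amu and angstrom appear only at
# the I/O boundary.
.codata <- list(
  hartree_eV    = 27.211386245988,   # 1 hartree in eV
  hartree_cm1   = 219474.6313632,    # 1 hartree in cm^-1 (E_h / hc)
  amu_me        = 1822.888486209,    # 1 amu in electron masses
  bohr_angstrom = 0.529177210903,    # 1 bohr in angstrom
  kB_eV         = 8.617333262e-5,    # Boltzmann constant, eV / K
  # SI values used for the cross-section prefactor
  e_C      = 1.602176634e-19,
  hbar_Js  = 1.054571817e-34,
  me_kg    = 9.1093837015e-31,
  c_ms     = 2.99792458e8,
  eps0_SI  = 8.8541878128e-12
)

# unit name -> c(dimension, factor to the internal atomic unit of that dimension)
.unit_table <- function() {
  list(
    "hartree"   = c(dim = "energy", to_au = 1),
    "eV"        = c(dim = "energy", to_au = 1 / .codata$hartree_eV),
    "cm-1"      = c(dim = "energy", to_au = 1 / .codata$hartree_cm1),
    "m_e"       = c(dim = "mass",   to_au = 1),
    "amu"       = c(dim = "mass",   to_au = .codata$amu_me),
    "bohr"      = c(dim = "length", to_au = 1),
    "au_length" = c(dim = "length", to_au = 1),
    "angstrom"  = c(dim = "length", to_au = 1 / .codata$bohr_angstrom)
  )
}

#' Convert a physical quantity between spectroscopic units
#'
#' Supported units are `eV`, `cm-1` and `hartree` (energy); `amu` and `m_e`
#' (mass); `bohr`, `au_length` and `angstrom` (length). Conversion factors are
#' CODATA 2018 values; e.g. 1 cm-1 = hc = 1.2398e-4 eV. Converting across
#' dimensions (say eV to bohr) is an error.
#'
#' @param value numeric vector to convert.
#' @param from,to unit names (see above); `from == to` is the identity.
#' @return `value` expressed in `to`.
#' @examples
#' convert_unit(1500, "cm-1", "hartree")  # ~0.0068
#' convert_unit(4.08, "eV", "hartree")    # ~0.15
#' convert_unit(1, "amu", "m_e")          # ~1823
#' @export
convert_unit <- function(value, from, to) {
  tab <- .unit_table()
  for (u in c(from, to)) {
    if (!(is.character(u) && length(u) == 1L && u %in% names(tab)))
      stop("unknown unit name: '", u, "' (supported: ",
           paste(names(tab), collapse = ", "), ")", call. = FALSE)
  }
  uf <- tab[[from]]; ut <- tab[[to]]
  if (uf[["dim"]] != ut[["dim"]])
    stop("cannot convert ", uf[["dim"]], " ('", from, "') to ",
         ut[["dim"]], " ('", to, "')", call. = FALSE)
  value * as.numeric(uf[["to_au"]]) / as.numeric(ut[["to_au"]])
}

# internal shorthands
.ev2ha  <- function(x) x / .codata$hartree_eV
.ha2ev  <- function(x) x * .codata$hartree_eV
.cm12ha <- function(x) x / .codata$hartree_cm1
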