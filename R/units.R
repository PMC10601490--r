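# Unit registry.  Internal units are Hartree atomic units throughout
# (hbar = 1, m_e = 1, bohr = 1, E_h = 1); every user-facing quantity is
# converted on ingest and back-converted on output.

#' Physical constants in atomic units
#'
#' Fixed conversion constants used by the whole package.  All internal
#' computation is done in Hartree atomic units (\eqn{\hbar = m_e = e =
#' a_0 = 1}); these constants define the interface to conventional
#' laboratory units.
#'
#' @format A named list:
#' \describe{
#'   \item{amu_to_me}{1 amu in electron masses (1822.888486).}
#'   \item{ang_to_bohr}{1 Angstrom in bohr (1.8897261258).}
#'   \item{cm1_to_hartree}{1 cm\eqn{^{-1}} in Hartree (4.556335e-6).}
#'   \item{ev_to_hartree}{1 eV in Hartree (3.674932e-2).}
#'   \item{fs_to_au}{1 fs in atomic time units (41.341374).}
#'   \item{kB}{Boltzmann constant, E_h per kelvin (3.166811563e-6).}
#'   \item{hbar}{Reduced Planck constant, 1 by construction.}
#'   \item{nm_ev}{Wavelength-energy product: lambda(nm) * E(eV) = 1239.841984.}
#' }
#' @export
au_constants <- list(
  amu_to_me      = 1822.888486,
  ang_to_bohr    = 1.8897261258,
  cm1_to_hartree = 4.556335e-6,
  ev_to_hartree  = 3.674932e-2,
  fs_to_au       = 41.341374,
  kB             = 3.166811563e-6,
  hbar           = 1.0,
  nm_ev          = 1239.841984
)

# unit name -> (dimension, factor to atomic units)
.unit_table <- local({
  k <- au_constants
  list(
    amu      = list(dim = "mass",   to_au = k$amu_to_me),
    me       = list(dim = "mass",   to_au = 1.0),
    angstrom = list(dim = "length", to_au = k$ang_to_bohr),
    bohr     = list(dim = "length", to_au = 1.0),
    nm       = list(dim = "length", to_au = 10 * k$ang_to_bohr),
    hartree  = list(dim = "energy", to_au = 1.0),
    ev       = list(dim = "energy", to_au = k$ev_to_hartree),
    fs       = list(dim = "time",   to_au = k$fs_to_au),
    ps       = list(dim = "time",   to_au = 1e3 * k$fs_to_au),
    autime   = list(dim = "time",   to_au = 1.0)
  )
})
.unit_table[["cm-1"]] <- list(dim = "energy", to_au = au_constants$cm1_to_hartree)
.unit_table[["cm1"]]  <- .unit_table[["cm-1"]]

#' Convert a value between registered units
#'
#' Exact multiplication by the registry ratio; dimensionally incompatible
#' conversions are an error.  Unit names are case-insensitive; registered
#' units are \code{amu}, \code{me} (mass); \code{angstrom}, \code{bohr},
#' \code{nm} (length); \code{cm-1}/\code{cm1}, \code{ev}, \code{hartree}
#' (energy); \code{fs}, \code{ps}, \code{autime} (time).
#'
#' @param value numeric vector.
#' @param from,to unit names.
#' @return converted numeric vector.
#' @examples
#' unit_convert(1, "amu", "me")        # 1822.888486
#' unit_convert(1000, "cm-1", "hartree")
#' @export
unit_convert <- function(value, from, to) {
  uf <- .unit_table[[tolower(from)]]
  ut <- .unit_table[[tolower(to)]]
  if (is.null(uf)) stop(vib_error("unknown_unit", sprintf("unknown unit '%s'", from)))
  if (is.null(ut)) stop(vib_error("unknown_unit", sprintf("unknown unit '%s'", to)))
  if (uf$dim != ut$dim) {
    stop(vib_error("unit_dimension",
      sprintf("cannot convert '%s' (%s) to '%s' (%s)", from, uf$dim, to, ut$dim)))
  }
  value * (uf$to_au / ut$to_au)
}

# condition constructor: every named error in the package goes through this
# so callers can class-match (e.g. "vibronica_xyz_count" etc.)
vib_error <- function(class, msg, call = sys.call(-1)) {
  structure(
    class = c(paste0("vibronica_", class), "vibronica_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

vib_warn <- function(class, msg) {
  warning(structure(
    class = c(paste0("vibronica_", class), "vibronica_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
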