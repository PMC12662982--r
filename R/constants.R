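# Physical constants (CODATA 2018) and the isotope table used for dipolar
# couplings. Gyromagnetic ratios in rad s^-1 T^-1.

#' Physical constants used throughout the package
#'
#' CODATA-2018 values, full published precision. Exposed so that tests and
#' external oracles can reuse the exact same numbers.
#'
#' @format A named list with elements
#' \describe{
#'   \item{mu0}{vacuum magnetic permeability, N A^-2}
#'   \item{hbar}{reduced Planck constant, J s}
#'   \item{kB}{Boltzmann constant, J K^-1}
#'   \item{hartree_J}{1 hartree in J}
#'   \item{hartree_kJmol}{1 hartree in kJ mol^-1}
#'   \item{avogadro}{Avogadro constant, mol^-1}
#' }
#' @export
aniso_constants <- list(
  mu0           = 1.25663706212e-6,
  hbar          = 1.054571817e-34,
  kB            = 1.380649e-23,
  hartree_J     = 4.3597447222071e-18,
  hartree_kJmol = 2625.4996394799,
  avogadro      = 6.02214076e23
)

#' Gyromagnetic ratios of supported NMR isotopes
#'
#' @format Named numeric vector, rad s^-1 T^-1, keyed by isotope code
#'   (`"1H"`, `"13C"`, `"15N"`, `"19F"`).
#' @export
gyromagnetic_ratios <- c(
  "1H"  =  2.6752218744e8,
  "13C" =  6.728284e7,
  "15N" = -2.7126e7,
  "19F" =  2.518148e8
)

# isotope code for an element symbol (the NMR-active isotope this package
# supports for that element)
.default_isotope <- c(H = "1H", C = "13C", N = "15N", F = "19F")

#' Look up a gyromagnetic ratio
#'
#' @param isotope isotope code, e.g. `"1H"`, `"13C"`, or a bare element
#'   symbol (`"H"`, `"C"`) which is resolved to its NMR-active default.
#' @return gyromagnetic ratio in rad s^-1 T^-1
#' @export
gyromagnetic_ratio <- function(isotope) {
  iso <- as.character(isotope)
  iso <- ifelse(iso %in% names(.default_isotope), .default_isotope[iso], iso)
  unknown <- setdiff(iso, names(gyromagnetic_ratios))
  if (length(unknown) > 0L) {
    stop("unknown isotope(s): ", paste(unique(unknown), collapse = ", "),
         " (supported: ", paste(names(gyromagnetic_ratios), collapse = ", "), ")",
         call. = FALSE)
  }
  unname(gyromagnetic_ratios[iso])
}
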