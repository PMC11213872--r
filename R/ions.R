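# Adduct composition table. Data, not code: each ion species is a label, the
# atoms added to (or removed from) the neutral molecule M, and the charge.
# The electron-mass correction is always applied when forming the ion m/z.
.ADDUCTS <- list(
  "[M+H]+"      = list(add = c(H = 1),                 charge = +1L),
  "[M+NH4]+"    = list(add = c(N = 1, H = 4),          charge = +1L),
  "[M+Na]+"     = list(add = c(Na = 1),                charge = +1L),
  "[M+K]+"      = list(add = c(K = 1),                 charge = +1L),
  "[M+MeCN+H]+" = list(add = c(C = 2, H = 4, N = 1),   charge = +1L),
  "[M+Cl]-"     = list(add = c(Cl = 1),                charge = -1L),
  "[M+MeOH+H]+" = list(add = c(C = 1, H = 5, O = 1),   charge = +1L),
  "[M+H-H2O]+"  = list(add = c(H = -1, O = -1),        charge = +1L),
  "[M+H-NH3]+"  = list(add = c(H = -2, N = -1),        charge = +1L),
  "[M-H]-"      = list(add = c(H = -1),                charge = -1L)
)

.normalize_ion_label <- function(ion) {
  # tolerate unicode minus signs from copy-pasted labels
  gsub("−|–", "-", ion)
}

#' Supported ion species
#'
#' The ten adducts considered during peak picking of the HILIC-HRMS data,
#' acquired with fast polarity switching: protonated/deprotonated molecules
#' plus ammonium, sodium, potassium, acetonitrile, methanol and chloride
#' adducts and in-source water/ammonia losses.
#'
#' @return Character vector of adduct labels.
#' @export
ion_species <- function() names(.ADDUCTS)

#' Ion m/z for a neutral formula and adduct
#'
#' m/z = (mass(M) + mass(adduct atoms) - charge * electron mass) / |charge|.
#' The electron-mass correction is always applied; it matters at the fourth
#' decimal place for fragment-level work.
#'
#' @param formula Neutral `elemental_formula` or formula string.
#' @param ion Adduct label, one of [ion_species()].
#' @return m/z of the singly charged ion.
#' @examples
#' ion_mz("C11H15N5O3S", "[M+H]+")  # methylthioadenosine, 298.097
#' ion_mz("C5H4N4O3", "[M-H]-")     # uric acid, 167.021
#' @export
ion_mz <- function(formula, ion) {
  ion <- .normalize_ion_label(ion)
  if (!ion %in% names(.ADDUCTS)) {
    stop("unsupported adduct label '", ion, "'; supported: ",
         paste(names(.ADDUCTS), collapse = ", "), call. = FALSE)
  }
  spec <- .ADDUCTS[[ion]]
  m <- monoisotopic_mass(formula) + .delta_mass(spec$add) -
    spec$charge * .ELECTRON_MASS
  m / abs(spec$charge)
}

#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be strictly positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}
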