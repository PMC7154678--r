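#' Arrhenius temperature scaling
#'
#' Scales a rate parameter from its value at 25 degC to `tleaf` using the
#' standard Arrhenius form `k25 * exp(Ea * (T - 25) / (298.15 * R * (T + 273.15)))`.
#'
#' @param k25 value at 25 degC.
#' @param ea activation energy (J mol-1).
#' @param tleaf leaf temperature (degC). Vectorised.
#' @return scaled value(s), same shape as `tleaf`.
#' @keywords internal
arrhenius <- function(k25, ea, tleaf) {
  k25 * exp(ea * (tleaf - 25) / (298.15 * 8.314 * (tleaf + 273.15)))
}

# Bernacchi et al. (2001) leaf-kinetics constants at 25 degC and activation
# energies. O2 mole fraction fixed at 210 mmol/mol.
.kin <- list(
  gamma_star25 = 42.75,   # umol/mol
  kc25         = 404.9,   # umol/mol
  ko25         = 278.4,   # mmol/mol
  o2           = 210,     # mmol/mol
  ea_gamma     = 37830,   # J/mol
  ea_kc        = 79430,
  ea_ko        = 36380,
  ea_vcmax     = 65330,
  ea_jmax      = 43540,
  ea_rd        = 46390
)

#' Temperature-dependent kinetic constants of the C3 leaf model
#'
#' Arrhenius-scaled CO2 compensation point (no day respiration), Michaelis
#' constants for CO2 and O2, and the derived effective Michaelis constant
#' `Km_eff = Kc * (1 + O/Ko)`, using the Bernacchi et al. (2001)
#' parameterisation with O2 fixed at 210 mmol/mol. At 25 degC,
#' `gamma_star = 42.75` umol/mol and `Km_eff = 710.32` umol/mol.
#'
#' @param tleaf leaf temperature, degC; must lie in \[-40, 60\]. Vectorised.
#' @return an object of class `kinetic_constants`: a list with fields
#'   `gamma_star` (umol/mol), `Kc` (umol/mol), `Ko` (mmol/mol), `O`
#'   (mmol/mol), `Km_eff` (umol/mol) and `Tleaf` (degC).
#' @examples
#' k <- kinetic_constants(25)
#' k$gamma_star   # 42.75
#' k$Km_eff       # ~710.3
#' @export
kinetic_constants <- function(tleaf) {
  if (any(!is.finite(tleaf)) || any(tleaf < -40) || any(tleaf > 60)) {
    stop("tleaf out of supported range [-40, 60] degC", call. = FALSE)
  }
  kc <- arrhenius(.kin$kc25, .kin$ea_kc, tleaf)
  ko <- arrhenius(.kin$ko25, .kin$ea_ko, tleaf)
  k <- list(
    gamma_star = arrhenius(.kin$gamma_star25, .kin$ea_gamma, tleaf),
    Kc = kc,
    Ko = ko,
    O = .kin$o2,
    Km_eff = kc * (1 + .kin$o2 / ko),
    Tleaf = tleaf
  )
  class(k) <- "kinetic_constants"
  k
}

#' Temperature scaling factors for photosynthetic capacities
#'
#' Plain Arrhenius factors (value 1 at 25 degC) used to scale `Vcmax25`,
#' `Jmax25` and `Rd25` to leaf temperature. A peaked (optimum) response is
#' not represented; the synthetic forcing keeps leaf temperatures below the
#' range where deactivation matters.
#'
#' @param tleaf leaf temperature (degC). Vectorised.
#' @return list with factors `vcmax`, `jmax`, `rd`.
#' @keywords internal
capacity_temp_factors <- function(tleaf) {
  list(
    vcmax = arrhenius(1, .kin$ea_vcmax, tleaf),
    jmax  = arrhenius(1, .kin$ea_jmax, tleaf),
    rd    = arrhenius(1, .kin$ea_rd, tleaf)
  )
}

#' Saturation vapour pressure (kPa) at air temperature (degC)
#' @keywords internal
esat_kpa <- function(tair) 0.6108 * exp(17.27 * tair / (tair + 237.3))
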