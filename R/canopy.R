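#' Canopy state
#'
#' Leaf area, the leaf carbon pool behind it, and a single decomposing
#' ecosystem carbon pool. `lai = leaf_carbon * sla` by construction.
#'
#' @param leaf_carbon leaf carbon (gC m-2).
#' @param ecosystem_carbon decomposing ecosystem pool (gC m-2).
#' @param sla specific leaf area (m2 gC-1).
#' @return object of class `canopy_state` with fields `lai`, `leaf_carbon`,
#'   `ecosystem_carbon`, `sla`.
#' @export
canopy_state <- function(leaf_carbon, ecosystem_carbon = 0, sla = 0.012) {
  stopifnot(all(leaf_carbon >= 0), all(ecosystem_carbon >= 0), all(sla > 0))
  structure(list(lai = leaf_carbon * sla, leaf_carbon = leaf_carbon,
                 ecosystem_carbon = ecosystem_carbon, sla = sla),
            class = "canopy_state")
}

# Beer's-law two-leaf split of incident PAR. Vectorised over all arguments.
# Returns per-leaf absorbed PAR for the sunlit and shaded classes, the class
# LAIs, and the sunlit leaf-area fraction. A fixed fraction of incident PAR
# is treated as diffuse.
.partition_apar <- function(lai, solar_zenith, par_incident,
                            k = 0.5, albedo = 0.05, diffuse_frac = 0.3) {
  n <- max(length(lai), length(solar_zenith), length(par_incident))
  lai <- rep_len(lai, n)
  solar_zenith <- rep_len(solar_zenith, n)
  par_incident <- rep_len(par_incident, n)
  cosz <- cos(pmin(solar_zenith, 90) * pi / 180)
  dark <- solar_zenith >= 90 | par_incident <= 0 | cosz <= 1e-6
  cosz <- pmax(cosz, 1e-6)
  kb <- k / cosz
  lai_sun <- (1 - exp(-kb * lai)) / kb
  lai_sun[dark] <- 0
  lai_sun <- pmin(lai_sun, lai)
  lai_sha <- lai - lai_sun
  fsun <- lai_sun / pmax(lai, 1e-12)
  par0 <- par_incident
  par0[dark] <- 0
  qb <- (1 - albedo) * par0 * (1 - diffuse_frac) * (1 - exp(-kb * lai))
  qd <- (1 - albedo) * par0 * diffuse_frac * (1 - exp(-k * lai))
  # numerators vanish wherever the class LAI does, so the guarded
  # denominators cannot leak light into empty classes
  apar_sun <- (qb + qd * fsun) / pmax(lai_sun, 1e-12)
  apar_sha <- qd * (1 - fsun) / pmax(lai_sha, 1e-12)
  list(apar_sun = apar_sun, apar_sha = apar_sha,
       lai_sun = lai_sun, lai_sha = lai_sha, fsun = fsun,
       absorbed_total = qb + qd)
}

#' Sunlit/shaded canopy partition
#'
#' Splits incident PAR between sunlit and shaded leaves with Beer's law
#' (extinction coefficient `k = 0.5` on a beam path lengthened by the solar
#' zenith; a fixed diffuse fraction penetrates with the unprojected
#' coefficient). The sunlit LAI fraction follows the convention
#' `(1 - exp(-k*lai/cos z)) * cos(z) / (k*lai)`. Total absorbed PAR never
#' exceeds incident PAR; zenith angles at or beyond 90 degrees give an
#' all-shaded, zero-PAR canopy.
#'
#' @param lai leaf area index (m2 m-2).
#' @param solar_zenith solar zenith angle (degrees, 0-90).
#' @param par_incident incident PAR (umol m-2 s-1).
#' @param tleaf,vpd,cs,patm leaf environment shared by the two classes.
#' @param k,albedo,diffuse_frac radiation constants.
#' @return list with `sunlit` and `shaded` [leaf_env()]s (per-leaf absorbed
#'   PAR), `sunlit_fraction`, the class LAIs and total absorbed PAR.
#' @export
sunlit_shaded_partition <- function(lai, solar_zenith, par_incident,
                                    tleaf = 25, vpd = 1, cs = 400,
                                    patm = 101.325,
                                    k = 0.5, albedo = 0.05,
                                    diffuse_frac = 0.3) {
  stopifnot(solar_zenith >= 0, lai >= 0, par_incident >= 0)
  q <- .partition_apar(lai, solar_zenith, par_incident, k, albedo, diffuse_frac)
  list(sunlit = leaf_env(q$apar_sun, tleaf, vpd, cs, patm),
       shaded = leaf_env(q$apar_sha, tleaf, vpd, cs, patm),
       sunlit_fraction = q$fsun,
       lai_sun = q$lai_sun, lai_sha = q$lai_sha,
       absorbed_total = q$absorbed_total)
}

# umol CO2 m-2 s-1 -> gC m-2 per step
.UMOL_TO_GC <- 12.011e-6

#' Daily canopy gross primary production
#'
#' Integrates leaf assimilation over the sub-diurnal steps of one day for
#' the sunlit and shaded leaf classes at the capacities of the supplied
#' coordination state, converting to gC m-2 d-1. When `cs_baseline` differs
#' from the day's CO2, the leaf-level CO2 component is accumulated as the
#' exact difference between GPP at the actual and at the baseline
#' concentration with every other element of the state held fixed (the
#' secant form of the sensitivity diagnostic times the concentration
#' increment).
#'
#' @param forcing_day list with per-step vectors `par`, `tair`, `vpd`,
#'   `zenith` (degrees), scalars `cs`, `step_hours`, and optional per-step
#'   `stress` in \[0, 1\].
#' @param state a [canopy_state()].
#' @param coord a [coordination_state()].
#' @param cfg a [cell_config()].
#' @param cs_baseline reference CO2 (umol/mol) for the leaf-level component;
#'   `NULL` (default) skips the counterfactual.
#' @return list with `gpp` (gC m-2 d-1), `leaf_component` (gC m-2 d-1) and
#'   the per-step partition (for history appends).
#' @export
canopy_gpp <- function(forcing_day, state, coord, cfg, cs_baseline = NULL) {
  stress <- if (is.null(forcing_day$stress)) 1 else forcing_day$stress
  q <- .partition_apar(state$lai, forcing_day$zenith, forcing_day$par)
  p <- cfg$leaf_params
  dt_sec <- forcing_day$step_hours * 3600
  assim_at <- function(cs) {
    rs <- leaf_assim(q$apar_sun, forcing_day$tair, forcing_day$vpd, cs,
                     coord$Vcmax0, coord$Jmax0, p)
    rh <- leaf_assim(q$apar_sha, forcing_day$tair, forcing_day$vpd, cs,
                     coord$Vcmax0, coord$Jmax0, p)
    sum((rs$a * q$lai_sun + rh$a * q$lai_sha) * stress) * dt_sec * .UMOL_TO_GC
  }
  gpp <- assim_at(forcing_day$cs)
  leaf_component <- 0
  if (!is.null(cs_baseline) && cs_baseline != forcing_day$cs) {
    leaf_component <- gpp - assim_at(cs_baseline)
  }
  list(gpp = gpp, leaf_component = leaf_component, partition = q)
}

#' Daily leaf-area and ecosystem-pool dynamics
#'
#' A fixed fraction of NPP (NPP = 0.5 GPP) is allocated to the leaf carbon
#' pool, which turns over at `leaf_turnover`; the remainder and the leaf
#' litter enter a single decomposing ecosystem pool respiring at
#' `reco_base_rate * q10^((T-25)/10)`. The net land sink proxy is
#' `NLS = GPP - Reco` with `Reco` the sum of autotrophic (0.5 GPP) and
#' heterotrophic respiration. Carbon is conserved exactly:
#' `GPP = dLeafC + dEcoC + Ra + Rh`.
#'
#' @param state a [canopy_state()].
#' @param daily_gpp gC m-2 d-1 (non-negative).
#' @param cfg a [cell_config()].
#' @param tair mean air temperature of the day (degC).
#' @param dt_days timestep (days).
#' @return list with the updated `state` and the day's fluxes `npp`, `ra`,
#'   `rh`, `litter`, `nls` (gC m-2 per `dt_days`).
#' @export
lai_dynamics <- function(state, daily_gpp, cfg, tair = 25, dt_days = 1) {
  stopifnot(all(daily_gpp >= 0))
  dt <- dt_days / 365
  npp <- 0.5 * daily_gpp
  ra <- daily_gpp - npp
  alloc <- cfg$allocation_fraction * npp
  litter <- cfg$leaf_turnover * state$leaf_carbon * dt
  leaf_c <- state$leaf_carbon + alloc - litter
  rh <- cfg$reco_base_rate * cfg$q10^((tair - 25) / 10) *
    state$ecosystem_carbon * dt
  eco_c <- state$ecosystem_carbon + (npp - alloc) + litter - rh
  new_state <- structure(list(lai = leaf_c * state$sla, leaf_carbon = leaf_c,
                              ecosystem_carbon = eco_c, sla = state$sla),
                         class = "canopy_state")
  list(state = new_state, npp = npp, ra = ra, rh = rh, litter = litter,
       nls = daily_gpp - ra - rh)
}
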