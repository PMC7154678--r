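#' Scenario definition
#'
#' A factorial experiment: which drivers vary (CO2, temperature,
#' precipitation) while the recycled meteorology block loops underneath.
#' Drivers that do not vary are held at their first-year value.
#'
#' @param label unique scenario label.
#' @param co2 a [co2_trajectory()].
#' @param vary_co2,vary_temperature,vary_precip driver flags.
#' @param years scenario span (defaults to the CO2 trajectory span).
#' @return object of class `scenario`.
#' @export
scenario <- function(label, co2, vary_co2 = TRUE, vary_temperature = FALSE,
                     vary_precip = FALSE, years = co2$span) {
  stopifnot(inherits(co2, "co2_trajectory"))
  structure(list(label = label, co2 = co2, vary_co2 = vary_co2,
                 vary_temperature = vary_temperature,
                 vary_precip = vary_precip, years = years),
            class = "scenario")
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run one scenario on the toy globe
#'
#' Evolves all cells jointly at the sub-diurnal/daily timestep: two-leaf
#' canopy assimilation each step, the coordination update and leaf-area
#' dynamics each day, over `spinup_years` of first-year drivers followed by
#' the scenario span. Deterministic given (scenario, forcing): all
#' randomness lives in the seeded forcing generator.
#'
#' The leaf-level CO2 component is accumulated as the exact difference
#' between assimilation at the actual and at the baseline-year CO2
#' concentration with identical state and meteorology.
#'
#' @param scn a [scenario()].
#' @param cells list of [cell_config()].
#' @param weights area weights (sum to 1).
#' @param forcing a [generate_forcing()] result covering the scenario span.
#' @param coordination enable the daily `bJV` optimization; if `FALSE`, the
#'   coordination-disabled configuration is used (`bJV = 1.3`, `Vcmax25`
#'   scaled by 1.25).
#' @param freeze_lai hold leaf area fixed (diagnostic runs).
#' @param spinup_years years of first-year drivers run and discarded before
#'   the scenario span.
#' @param monthly also record area-aggregated monthly GPP and NLS.
#' @param lai_init initial leaf area index.
#' @param eco_init initial ecosystem carbon pool (gC m-2), or `"steady"`
#'   (default) to reset each cell's pool to the balance value implied by its
#'   last spin-up year (inputs over decay rate), so the NLS proxy starts
#'   near zero instead of reflecting centuries of pool filling.
#' @return object of class `simulation_output`: per-cell annual matrices
#'   `gpp`, `leaf` (leaf-level CO2 component), `nls`, `lai`; an `aggregate`
#'   data.frame of area-weighted means; optional `monthly` data.frame;
#'   `weights`, `label`, `ca` (annual CO2 actually applied).
#' @export
run_scenario <- function(scn, cells, weights, forcing,
                         coordination = TRUE, freeze_lai = FALSE,
                         spinup_years = 5, monthly = FALSE,
                         lai_init = 1, eco_init = "steady") {
  stopifnot(inherits(scn, "scenario"), inherits(forcing, "forcing_series"))
  nc <- length(cells)
  stopifnot(length(weights) == nc, abs(sum(weights) - 1) < 1e-8,
            forcing$ncells == nc)
  if (scn$years > forcing$years || scn$years > scn$co2$span) {
    stop("forcing does not cover the scenario span (", scn$years,
         " years requested)", call. = FALSE)
  }
  spd <- forcing$steps_per_day
  dt_sec <- forcing$step_hours * 3600
  met_years <- forcing$met_years
  p <- cells[[1]]$leaf_params
  cost <- p$c_cost_JV

  vc_prior <- vapply(cells, function(cg) cg$leaf_params$vcmax25, 0)
  bjv_prior <- vapply(cells, function(cg) cg$leaf_params$bJV, 0)
  cfgv <- list(
    allocation_fraction = vapply(cells, function(cg) cg$allocation_fraction, 0),
    leaf_turnover = vapply(cells, function(cg) cg$leaf_turnover, 0),
    reco_base_rate = vapply(cells, function(cg) cg$reco_base_rate, 0),
    q10 = vapply(cells, function(cg) cg$q10, 0))
  sla <- vapply(cells, function(cg) cg$sla, 0)

  if (coordination) {
    neff <- effective_nitrogen(vc_prior, bjv_prior * vc_prior, cost)
    st <- coordination_state(vc_prior, bjv_prior * vc_prior, cost)
  } else {
    st <- coordination_state(1.25 * vc_prior, 1.3 * 1.25 * vc_prior, cost)
  }
  steady_pool <- identical(eco_init, "steady") && spinup_years >= 1
  eco0 <- if (is.numeric(eco_init)) rep(eco_init, nc) else rep(5000, nc)
  state <- canopy_state(rep(lai_init, nc) / sla, eco0, sla)
  pool_in <- pool_rate <- numeric(nc)

  ca <- scn$co2$annual_ca
  cs_base <- ca[1]
  years <- scn$years
  total_years <- spinup_years + years

  gppM <- leafM <- nlsM <- laiM <- matrix(0, years, nc)
  mon_gpp <- mon_nls <- if (monthly) matrix(0, years * 12, 1) else NULL
  mdays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  month_of_day <- rep(1:12, mdays)

  h <- met_history(nc, spd, forcing$step_hours)
  gday <- 0

  for (y in seq_len(total_years)) {
    sy <- y - spinup_years
    block_y <- ((y - 1) %% met_years) + 1
    rows <- ((block_y - 1) * 365 * spd + 1):(block_y * 365 * spd)
    tanom <- if (sy >= 1 && scn$vary_temperature) forcing$annual$tanom[sy] else 0
    pfac <- if (sy >= 1 && scn$vary_precip) forcing$annual$panom[sy] else 1
    cs_y <- if (sy >= 1 && scn$vary_co2) ca[sy] else ca[1]

    TA <- forcing$tair[rows, , drop = FALSE] + tanom
    VPD <- pmax(esat_kpa(TA) * (1 - forcing$rh[rows, , drop = FALSE]), 0.01)
    PAR <- forcing$par[rows, , drop = FALSE]
    CZ <- forcing$cosz[rows, , drop = FALSE]
    W <- .clamp(forcing$w[rows, , drop = FALSE] * pfac, 0.05, 1)

    kk <- kinetic_constants(TA)
    ft <- capacity_temp_factors(TA)
    chi <- if (!is.null(p$chi_fixed)) p$chi_fixed else
      p$g1 / (p$g1 + sqrt(pmax(VPD, 1e-6)))
    ci <- chi * cs_y
    FC <- (ci - kk$gamma_star) / (ci + kk$Km_eff)
    FJ4 <- (ci - kk$gamma_star) / (ci + 2 * kk$gamma_star) / 4
    do_cf <- cs_y != cs_base
    if (do_cf) {
      cib <- chi * cs_base
      FCb <- (cib - kk$gamma_star) / (cib + kk$Km_eff)
      FJ4b <- (cib - kk$gamma_star) / (cib + 2 * kk$gamma_star) / 4
    }

    for (d in 1:365) {
      idx <- ((d - 1) * spd + 1):(d * spd)
      L <- matrix(state$lai, spd, nc, byrow = TRUE)
      par_d <- PAR[idx, , drop = FALSE]
      cz_d <- CZ[idx, , drop = FALSE]
      dark <- cz_d <= 1e-6 | par_d <= 0
      kb <- 0.5 / pmax(cz_d, 1e-6)
      ekbl <- exp(-kb * L)
      lai_sun <- (1 - ekbl) / kb
      lai_sun[dark] <- 0
      lai_sun <- pmin(lai_sun, L)
      lai_sha <- L - lai_sun
      fsun <- lai_sun / pmax(L, 1e-12)
      par0 <- par_d
      par0[dark] <- 0
      qb <- 0.95 * par0 * 0.7 * (1 - ekbl)
      qd <- 0.95 * par0 * 0.3 * (1 - exp(-0.5 * L))
      # numerators vanish wherever the class LAI does, so the guarded
      # denominators cannot leak light into empty classes
      apar_sun <- (qb + qd * fsun) / pmax(lai_sun, 1e-12)
      apar_sha <- qd * (1 - fsun) / pmax(lai_sha, 1e-12)

      VC <- matrix(st$Vcmax0, spd, nc, byrow = TRUE) * ft$vcmax[idx, , drop = FALSE]
      JM <- matrix(st$Jmax0, spd, nc, byrow = TRUE) * ft$jmax[idx, , drop = FALSE]
      th <- p$theta
      jfun <- function(ai, jm) {
        bb <- ai + jm
        (bb - sqrt(pmax(bb * bb - 4 * th * ai * jm, 0))) / (2 * th)
      }
      j_sun <- jfun(p$alpha * apar_sun, JM)
      j_sha <- jfun(p$alpha * apar_sha, JM)
      fc_d <- FC[idx, , drop = FALSE]
      fj_d <- FJ4[idx, , drop = FALSE]
      a_sun <- pmin(VC * fc_d, j_sun * fj_d)
      a_sha <- pmin(VC * fc_d, j_sha * fj_d)
      w_d <- W[idx, , drop = FALSE]
      acan <- (a_sun * lai_sun + a_sha * lai_sha) * w_d
      gpp_day <- colSums(acan) * dt_sec * .UMOL_TO_GC

      if (do_cf) {
        fcb_d <- FCb[idx, , drop = FALSE]
        fjb_d <- FJ4b[idx, , drop = FALSE]
        ab_sun <- pmin(VC * fcb_d, j_sun * fjb_d)
        ab_sha <- pmin(VC * fcb_d, j_sha * fjb_d)
        gpp_cf <- colSums((ab_sun * lai_sun + ab_sha * lai_sha) * w_d) *
          dt_sec * .UMOL_TO_GC
        leaf_day <- gpp_day - gpp_cf
      } else {
        leaf_day <- numeric(nc)
      }

      gday <- gday + 1
      if (h$day_count == 0) {
        for (i in 1:4) {
          h <- history_append_day(h, t(apar_sun), t(apar_sha), t(fsun),
                                  t(TA[idx, , drop = FALSE]),
                                  t(VPD[idx, , drop = FALSE]), cs_y,
                                  t(w_d), p, day_time = gday - 5 + i)
        }
      }
      h <- history_append_day(h, t(apar_sun), t(apar_sha), t(fsun),
                              t(TA[idx, , drop = FALSE]),
                              t(VPD[idx, , drop = FALSE]), cs_y,
                              t(w_d), p, day_time = gday)
      if (coordination && h$day_count >= 5) st <- daily_update(st, h, p)

      tmean_day <- .colMeans(TA[idx, , drop = FALSE], spd, nc)
      ld <- lai_dynamics(state, gpp_day, cfgv, tair = tmean_day)
      if (!freeze_lai) state <- ld$state
      if (steady_pool && y == spinup_years) {
        pool_in <- pool_in + (1 - cfgv$allocation_fraction) * ld$npp + ld$litter
        pool_rate <- pool_rate +
          cfgv$reco_base_rate * cfgv$q10^((tmean_day - 25) / 10) / 365
      }

      if (sy >= 1) {
        gppM[sy, ] <- gppM[sy, ] + gpp_day
        leafM[sy, ] <- leafM[sy, ] + leaf_day
        nlsM[sy, ] <- nlsM[sy, ] + ld$nls
        laiM[sy, ] <- laiM[sy, ] + state$lai / 365
        if (monthly) {
          mrow <- (sy - 1) * 12 + month_of_day[d]
          mon_gpp[mrow] <- mon_gpp[mrow] + sum(gpp_day * weights)
          mon_nls[mrow] <- mon_nls[mrow] + sum(ld$nls * weights)
        }
      }
    }
    if (steady_pool && y == spinup_years) {
      state <- canopy_state(state$leaf_carbon, pool_in / pool_rate, sla)
    }
  }

  agg <- data.frame(
    year = seq_len(years),
    gpp = as.numeric(gppM %*% weights),
    leaf = as.numeric(leafM %*% weights),
    nls = as.numeric(nlsM %*% weights),
    lai = as.numeric(laiM %*% weights))
  mon <- NULL
  if (monthly) {
    mon <- data.frame(year = rep(seq_len(years), each = 12),
                      month = rep(1:12, years),
                      gpp = as.numeric(mon_gpp), nls = as.numeric(mon_nls))
  }
  structure(list(label = scn$label, years = seq_len(years),
                 gpp = gppM, leaf = leafM, nls = nlsM, lai = laiM,
                 aggregate = agg, monthly = mon, weights = weights,
                 ca = if (scn$vary_co2) ca[seq_len(years)] else rep(ca[1], years),
                 met_years = met_years, scenario = scn),
            class = "simulation_output")
}

#' Constant-climate CO2-doubling experiment
#'
#' Runs the default multi-PFT toy globe under recycled synthetic meteorology
#' and the 300-to-600 ppm exponential ramp with coordination and leaf-area
#' dynamics enabled, and reports the percentage GPP increase between the
#' first and last five-year means.
#'
#' @param seed forcing/globe seed.
#' @param n_cells toy-globe size.
#' @param years ramp span (91 years by default: 5-year plateaus at 300 and
#'   600 ppm around the exponential ramp).
#' @param met_years recycled meteorology block length.
#' @param spinup_years spin-up at 300 ppm.
#' @param coordination passed to [run_scenario()].
#' @param window averaging window length (years) at each end.
#' @return list with `percent` (the GPP increase, %), `output` (the
#'   [run_scenario()] result) and `globe`.
#' @export
run_doubling_experiment <- function(seed = 1, n_cells = 20, years = 91,
                                    met_years = 5, spinup_years = 10,
                                    coordination = TRUE, window = 5) {
  globe <- toy_globe(n_cells, seed = seed)
  forcing <- generate_forcing(globe$cells, years, seed = seed + 1,
                              met_years = met_years)
  scn <- scenario("doubling", co2_trajectory("doubling_ramp", years = years),
                  vary_co2 = TRUE)
  out <- run_scenario(scn, globe$cells, globe$weights, forcing,
                      coordination = coordination,
                      spinup_years = spinup_years)
  g <- out$aggregate$gpp
  pct <- 100 * (mean(g[(years - window + 1):years]) / mean(g[1:window]) - 1)
  list(percent = pct, output = out, globe = globe)
}

#' Historic CO2-only experiment with leaf/greening partition
#'
#' Runs the toy globe over the historic CO2 ramp (296 to 389 ppm) with
#' recycled meteorology, then partitions the CO2-driven GPP increase into
#' leaf-level and greening components.
#'
#' @param seed forcing/globe seed.
#' @param n_cells toy-globe size.
#' @param years span of the historic ramp.
#' @param met_years recycled meteorology block length.
#' @param spinup_years spin-up at first-year CO2.
#' @param window years (relative to the span end) averaged for the
#'   partition; default the last 10.
#' @return list with `partition` (from [leaf_greening_partition()]),
#'   `output` and `globe`.
#' @export
run_historic_experiment <- function(seed = 1, n_cells = 20, years = 111,
                                    met_years = 5, spinup_years = 10,
                                    window = 10) {
  globe <- toy_globe(n_cells, seed = seed)
  forcing <- generate_forcing(globe$cells, years, seed = seed + 1,
                              met_years = met_years)
  scn <- scenario("co2_only", co2_trajectory("historic_ramp", years = years),
                  vary_co2 = TRUE)
  out <- run_scenario(scn, globe$cells, globe$weights, forcing,
                      spinup_years = spinup_years)
  part <- leaf_greening_partition(out, window = window)
  list(partition = part, output = out, globe = globe)
}
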