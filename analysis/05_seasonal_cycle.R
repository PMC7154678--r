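#!/usr/bin/env Rscript
# Seasonal-cycle amplitude analysis with the Reco' perturbation ensemble.
#
# A two-cell northern toy biosphere (boreal + temperate) is run for 55 years
# under the historic CO2 ramp with monthly accounting. Monthly GPP and NLS
# are scaled to PgC with a nominal northern-land area, Reco' = GPP - NLS is
# perturbed into the 25-member phase/amplitude ensemble (annual totals
# conserved), each member's NLS drives the one-box concentration surrogate,
# and the change in the detrended seasonal amplitude (ASC) between the
# early and late 3-year epochs is reported for the members whose late-epoch
# ASC matches a reference value within +/-3 ppm.
#
# Writes results/asc_ensemble.csv and results/asc_summary.csv.
# Run from the repository root: Rscript analysis/05_seasonal_cycle.R

library(coordphoto)

dir.create("results", showWarnings = FALSE)

seed <- 1
years <- 55
globe <- toy_globe(2, pft_mix = c(boreal_forest = 0.5,
                                  temperate_forest = 0.5), seed = seed)
forcing <- generate_forcing(globe$cells, years, seed = seed + 1,
                            met_years = 5)
scn <- scenario("nh", co2_trajectory("historic_ramp", years = years,
                                     from = 310, to = 385))
message("running the northern toy biosphere (55 years, monthly) ...")
out <- run_scenario(scn, globe$cells, globe$weights, forcing,
                    spinup_years = 8, monthly = TRUE)

# gC m-2 month-1 -> PgC month-1 over a nominal 3.0e13 m2 of northern land
area_m2 <- 3.0e13
gpp <- flux_series(out$monthly$gpp * area_m2 * 1e-15, kind = "gpp")
nls <- flux_series(out$monthly$nls * area_m2 * 1e-15, kind = "nls")
reco <- residual_ecosystem_flux(gpp, nls)

members <- perturb_ensemble(reco)
epoch_early <- c(1, 3)
epoch_late <- c(years - 2, years)

rows <- lapply(seq_along(members), function(i) {
  m <- members[[i]]
  nls_m <- gpp$values - m$series$values
  conc <- surrogate_concentration(nls_m, c0 = 330)
  a1 <- seasonal_amplitude(conc, epoch = epoch_early)$amplitude
  a2 <- seasonal_amplitude(conc, epoch = epoch_late)$amplitude
  data.frame(member = i, phase_shift = m$phase_shift,
             amplitude_scale = m$amplitude_scale,
             asc_early_ppm = a1, asc_late_ppm = a2,
             asc_change_pct = asc_change(a1, a2))
})
ens <- do.call(rbind, rows)
write.csv(ens, "results/asc_ensemble.csv", row.names = FALSE)

# reference amplitude: the identity member stands in for the observed ASC
idm <- ens[ens$phase_shift == 0 & ens$amplitude_scale == 1, ]
sel <- select_members(ens$asc_late_ppm, idm$asc_late_ppm, tol = 3)
summ <- data.frame(
  n_members = nrow(ens), n_selected = length(sel),
  asc_change_mean_pct = mean(ens$asc_change_pct[sel]),
  asc_change_min_pct = min(ens$asc_change_pct[sel]),
  asc_change_max_pct = max(ens$asc_change_pct[sel]))
write.csv(summ, "results/asc_summary.csv", row.names = FALSE)

cat(sprintf("identity-member ASC: %.2f ppm (early) -> %.2f ppm (late)\n",
            idm$asc_early_ppm, idm$asc_late_ppm))
cat(sprintf("%d of %d members match the reference late ASC within 3 ppm\n",
            length(sel), nrow(ens)))
cat(sprintf("ASC change across selected members: mean %.1f%%, range [%.1f, %.1f]%%\n",
            summ$asc_change_mean_pct, summ$asc_change_min_pct,
            summ$asc_change_max_pct))
cat("Phase/amplitude errors in Reco' alone move the simulated ASC by several\n",
    "ppm while leaving annual carbon budgets untouched — the motivation for\n",
    "selecting members against the observed amplitude before interpreting\n",
    "ASC trends.\n")
cat("wrote results/asc_ensemble.csv, results/asc_summary.csv\n")
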