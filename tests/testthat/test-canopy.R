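test_that("canopy partition handles degenerate geometry", {
  z <- sunlit_shaded_partition(0, 30, 1500)
  expect_equal(z$sunlit$apar, 0)
  expect_equal(z$shaded$apar, 0)
  expect_equal(sunlit_shaded_partition(3, 30, 0)$sunlit$apar, 0)
  nite <- sunlit_shaded_partition(3, 90, 1500)
  expect_equal(nite$sunlit_fraction, 0)
  expect_equal(nite$absorbed_total, 0)
})

test_that("absorbed PAR never exceeds incident and saturates at (1-albedo)", {
  set.seed(5)
  for (i in 1:30) {
    lai <- runif(1, 0, 10); zen <- runif(1, 0, 89); par <- runif(1, 0, 2200)
    q <- sunlit_shaded_partition(lai, zen, par)
    expect_lte(q$absorbed_total, par + 1e-9)
    expect_equal(q$sunlit$apar * q$lai_sun + q$shaded$apar * q$lai_sha,
                 q$absorbed_total, tolerance = 1e-9)
  }
  deep <- sunlit_shaded_partition(200, 0, 1000)
  expect_equal(deep$absorbed_total, 0.95 * 1000, tolerance = 1e-3)
})

test_that("sunlit LAI fraction follows the Beer's-law convention", {
  k <- 0.5
  for (lai in c(0.5, 2, 5)) {
    for (zen in c(0, 40, 70)) {
      q <- sunlit_shaded_partition(lai, zen, 1000)
      cz <- cos(zen * pi / 180)
      expect_equal(q$sunlit_fraction,
                   (1 - exp(-k * lai / cz)) * cz / (k * lai),
                   tolerance = 1e-9)
    }
  }
})

test_that("canopy GPP composes the leaf model with the documented conversion", {
  cfg <- cell_config("temperate_forest")
  coord <- coordination_state(60, 102)
  state <- canopy_state(167, sla = 0.012)   # LAI ~2
  day <- list(par = c(0, 900, 1600, 400), tair = c(12, 18, 24, 20),
              vpd = c(0.4, 0.9, 1.5, 1.0), zenith = c(95, 60, 20, 75),
              cs = 400, step_hours = 6)
  out <- canopy_gpp(day, state, coord, cfg)
  # manual composition of partition + leaf assimilation, step by step
  manual <- 0
  for (s in 1:4) {
    q <- sunlit_shaded_partition(state$lai, day$zenith[s], day$par[s],
                                 tleaf = day$tair[s], vpd = day$vpd[s],
                                 cs = day$cs)
    pa <- cfg$leaf_params
    asun <- leaf_assim(q$sunlit$apar, day$tair[s], day$vpd[s], day$cs,
                       coord$Vcmax0, coord$Jmax0, pa)$a
    asha <- leaf_assim(q$shaded$apar, day$tair[s], day$vpd[s], day$cs,
                       coord$Vcmax0, coord$Jmax0, pa)$a
    manual <- manual + (asun * q$lai_sun + asha * q$lai_sha) * 6 * 3600 *
      12.011e-6
  }
  expect_equal(out$gpp, manual, tolerance = 1e-9)
  expect_equal(out$leaf_component, 0)  # no baseline supplied

  # zero LAI gives zero GPP; unchanged CO2 gives a zero leaf component
  empty <- canopy_state(0, sla = 0.012)
  expect_equal(canopy_gpp(day, empty, coord, cfg)$gpp, 0)
  expect_equal(canopy_gpp(day, state, coord, cfg, cs_baseline = 400)$leaf_component, 0)
  withcf <- canopy_gpp(day, state, coord, cfg, cs_baseline = 350)
  expect_gt(withcf$leaf_component, 0)
})

test_that("leaf-area dynamics conserve carbon and reach the closed-form steady state", {
  cfg <- cell_config("grassland")
  st <- canopy_state(50, 3000, sla = cfg$sla)
  set.seed(3)
  for (i in 1:25) {
    gpp <- runif(1, 0, 12)
    ta <- runif(1, 0, 30)
    ld <- lai_dynamics(st, gpp, cfg, tair = ta)
    dpools <- (ld$state$leaf_carbon - st$leaf_carbon) +
      (ld$state$ecosystem_carbon - st$ecosystem_carbon)
    expect_equal(gpp, dpools + ld$ra + ld$rh, tolerance = 1e-9)
    expect_equal(ld$nls, gpp - ld$ra - ld$rh, tolerance = 1e-12)
    st <- ld$state
  }

  # constant GPP forcing: leaf carbon converges to
  # alloc * 0.5 * GPP / (turnover/365)
  st <- canopy_state(10, 0, sla = cfg$sla)
  gpp <- 8
  for (i in 1:(20 * 365)) st <- lai_dynamics(st, gpp, cfg, tair = 25)$state
  expect_equal(st$leaf_carbon,
               cfg$allocation_fraction * 0.5 * gpp / (cfg$leaf_turnover / 365),
               tolerance = 1e-3)

  # zero flux, empty pools: state unchanged
  z <- canopy_state(0, 0, sla = cfg$sla)
  expect_equal(lai_dynamics(z, 0, cfg)$state, z)
})

test_that("the ecosystem pool balances at long-run equilibrium (NLS -> 0)", {
  cfg <- cell_config("temperate_forest")
  st <- canopy_state(100, 1000, sla = cfg$sla)
  gpp <- 6
  nls <- NA
  for (i in 1:(300 * 365)) {
    ld <- lai_dynamics(st, gpp, cfg, tair = 25)
    st <- ld$state
    nls <- ld$nls
  }
  expect_lt(abs(nls), 1e-6 * gpp)
})

test_that("rising CO2 raises equilibrium leaf area (greening feedback sign)", {
  cfg <- cell_config("grassland")
  coord <- coordination_state(55, 93.5)
  day <- list(par = c(100, 1200, 1700, 300), tair = c(12, 18, 24, 18),
              vpd = c(0.5, 1, 1.5, 1), zenith = c(80, 45, 20, 70),
              cs = 400, step_hours = 6)
  equil_lai <- function(cs) {
    day$cs <- cs
    st <- canopy_state(20, 0, sla = cfg$sla)
    for (i in 1:3000) {
      g <- canopy_gpp(day, st, coord, cfg)$gpp
      st <- lai_dynamics(st, g, cfg, tair = 18)$state
    }
    st$lai
  }
  expect_gt(equil_lai(600), equil_lai(400))
})
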