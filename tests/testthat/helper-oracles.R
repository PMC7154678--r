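# Closed-form elasticity oracles for the Farquhar limited rates at fixed
# chi = ci/cs (so d ln ci = d ln cs). Derived by hand from
# Aj = (J/4)(ci - G)/(ci + 2G) and Ac = V (ci - G)/(ci + Km).
beta_aj_analytic <- function(ci, gs) {
  3 * gs * ci / ((ci - gs) * (ci + 2 * gs))
}

beta_ac_analytic <- function(ci, gs, km) {
  ci * (gs + km) / ((ci - gs) * (ci + km))
}

# Nitrogen-constrained (coordinated) elasticity at the co-limitation point:
# the convex combination of the two regime elasticities with weight
# w = 4 c fc / (fj + 4 c fc) on the electron-transport side, where
# fc = (ci-G)/(ci+Km), fj = (ci-G)/(ci+2G) and c is the Jmax cost.
beta_coord_analytic <- function(ci, gs, km, cost) {
  fc <- (ci - gs) / (ci + km)
  fj <- (ci - gs) / (ci + 2 * gs)
  w <- 4 * cost * fc / (fj + 4 * cost * fc)
  (1 - w) * beta_ac_analytic(ci, gs, km) + w * beta_aj_analytic(ci, gs)
}

# A 5-day history repeating one leaf-level day (sunlit class only).
make_leaf_history <- function(day, p, days = 5) {
  spd <- length(day$apar)
  h <- met_history(1, spd, day$step_hours)
  for (i in seq_len(days)) {
    h <- history_append_day(h, apar_sun = day$apar, apar_sha = 0, fsun = 1,
                            tleaf = day$tleaf, vpd = day$vpd, cs = day$cs,
                            p = p)
  }
  h
}

# A seeded random leaf-level day for optimizer/oracle comparisons.
random_leaf_day <- function(seed, spd = 8, step_hours = 3) {
  set.seed(seed)
  list(apar = stats::runif(spd, 0, 1800),
       tleaf = stats::runif(spd, 5, 35),
       vpd = stats::runif(spd, 0.3, 3),
       cs = stats::runif(spd, 250, 800),
       step_hours = step_hours)
}

# Brute-force grid argmax of the coordination objective for one cell.
grid_argmax_bjv <- function(neff, h, p, n = 2001, bounds = p$bJV_bounds) {
  grid <- seq(bounds[1], bounds[2], length.out = n)
  obj <- vapply(grid,
                function(b) accumulated_photosynthesis(b, neff, h, p) / neff,
                0)
  list(bjv = grid[which.max(obj)], objective = max(obj), grid_obj = obj)
}

# Minimal stand-in for a simulation output as consumed by
# driver_attribution(): only the aggregate GPP series matters.
fake_output <- function(gpp) list(aggregate = data.frame(gpp = gpp))

# Small toy world shared by runner tests: cheap but exercises every code
# path (two PFTs, coordination, LAI dynamics).
small_world <- function(n_cells = 2, years = 6, seed = 11, met_years = 2,
                        pft_mix = c(temperate_forest = 0.5, grassland = 0.5)) {
  globe <- toy_globe(n_cells, pft_mix = pft_mix, seed = seed)
  forcing <- generate_forcing(globe$cells, years, seed = seed + 1,
                              met_years = met_years)
  list(globe = globe, forcing = forcing)
}
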