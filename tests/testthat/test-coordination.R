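test_that("effective nitrogen is the cost-weighted capacity sum", {
  expect_equal(effective_nitrogen(50, 85, 0), 50)
  expect_equal(effective_nitrogen(50, 0, 0.95), 50)
  # 50 + 0.95*85 = 130.75 (hand arithmetic)
  expect_equal(effective_nitrogen(50, 85, 0.95), 130.75)
})

test_that("history ring buffer evicts the oldest day and checks timestamps", {
  p <- leaf_params()
  h <- met_history(1, 2, 12)
  for (d in 1:6) {
    h <- history_append_day(h, apar_sun = c(500, 800), cs = 100 * d, p = p)
  }
  expect_equal(h$day_count, 6)
  expect_equal(ncol(h$cs), 10)           # capacity is fixed at 5 days
  # slot of day 1 now holds day 6
  expect_equal(h$cs[1, 1], 600)
  expect_equal(sort(unique(as.numeric(h$cs))), c(200, 300, 400, 500, 600))
  expect_error(history_append_day(h, apar_sun = c(1, 1), p = p, day_time = 3),
               "increasing")
})

test_that("accumulated photosynthesis: dark history, single record, linearity", {
  p <- leaf_params(theta = 1)
  dark <- list(apar = rep(0, 8), tleaf = rep(20, 8), vpd = rep(1, 8),
               cs = rep(400, 8), step_hours = 3)
  h <- make_leaf_history(dark, p)
  expect_equal(accumulated_photosynthesis(1.7, 113.4, h, p), 0)
  expect_error(accumulated_photosynthesis(1.7, 113.4, met_history(1, 8, 3), p),
               "empty")

  # single record reproduces net_assimilation times the step duration
  h1 <- met_history(1, 1, 3)
  h1 <- history_append_day(h1, apar_sun = 1500, tleaf = 22, vpd = 1.2,
                           cs = 420, p = p)
  neff <- 120; b <- 1.6
  vc0 <- neff / (1 + p$c_cost_JV * b)
  pb <- leaf_params(vcmax25 = vc0, bJV = b, theta = 1)
  a <- net_assimilation(leaf_env(1500, 22, 1.2, 420), pb)$A
  expect_equal(accumulated_photosynthesis(b, neff, h1, p),
               a * 3 * 3600 * 1e-6, tolerance = 1e-9)

  # saturating light, theta = 1: both limited rates are linear in the
  # capacities, so doubling Neff doubles the integral exactly
  bright <- list(apar = rep(3000, 8), tleaf = rep(25, 8), vpd = rep(1, 8),
                 cs = rep(400, 8), step_hours = 3)
  hb <- make_leaf_history(bright, p)
  a1 <- accumulated_photosynthesis(1.7, 100, hb, p)
  a2 <- accumulated_photosynthesis(1.7, 200, hb, p)
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("optimizer matches the 2001-point grid oracle on random histories", {
  p <- leaf_params()
  for (seed in 1:20) {
    day <- random_leaf_day(seed)
    h <- make_leaf_history(day, p)
    neff <- 60 + 5 * seed
    b <- optimize_bjv(neff, h, p)
    oracle <- grid_argmax_bjv(neff, h, p)
    gap <- oracle$objective - attr(b, "objective")
    expect_lte(gap, 1e-9)
    expect_lt(abs(as.numeric(b) - oracle$bjv), 3e-3)  # grid spacing 2.25e-3
  }
})

test_that("boundary optima are returned at the bounds", {
  # deep shade: electron transport always limits, so Jmax investment pays
  # everywhere and the optimum sits on the upper bound
  p <- leaf_params(chi_fixed = 0.8)
  shade <- list(apar = rep(30, 4), tleaf = rep(20, 4), vpd = rep(1, 4),
                cs = rep(400, 4), step_hours = 6)
  hs <- make_leaf_history(shade, p)
  bs <- optimize_bjv(100, hs, p)
  expect_equal(as.numeric(bs), p$bJV_bounds[2])

  # when the admissible interval excludes the interior optimum (~1.67 for
  # this bright history), the nearer bound is returned exactly
  bright <- stationary_leaf_day(cs = 400)
  hb <- make_leaf_history(bright, p)
  expect_equal(as.numeric(optimize_bjv(113.4, hb, p, bounds = c(2.5, 5))),
               2.5)
  expect_equal(as.numeric(optimize_bjv(113.4, hb, p, bounds = c(0.5, 1.2))),
               1.2)
})

test_that("daily update conserves Neff and reaches a fixed point", {
  p <- leaf_params()
  day <- stationary_leaf_day(cs = 400)
  st <- equilibrate_coordination(day, p, neff = 113.4, days = 30)
  expect_equal(st$Neff, 113.4, tolerance = 1e-12)
  expect_equal(st$Vcmax0 + st$c_cost * st$Jmax0, st$Neff, tolerance = 1e-6)
  expect_equal(st$bJV, st$Jmax0 / st$Vcmax0, tolerance = 1e-9)
  expect_lt(attr(st, "delta_bjv"), 1e-3)
  traj <- attr(st, "trajectory")
  expect_lt(max(abs(diff(tail(traj, 10)))), 1e-3)
})

test_that("equilibrium Vcmax0 is non-increasing in CO2 (acclimation direction)", {
  p <- leaf_params()
  vc <- vapply(c(300, 400, 500, 600, 800), function(cs) {
    st <- equilibrate_coordination(stationary_leaf_day(cs = cs), p,
                                   neff = 113.4, days = 20)
    st$Vcmax0
  }, 0)
  expect_true(all(diff(vc) <= 1e-9))
})

test_that("multi-cell optimization agrees with cell-by-cell optimization", {
  p <- leaf_params()
  nc <- 3
  h <- met_history(nc, 4, 6)
  set.seed(31)
  for (d in 1:5) {
    h <- history_append_day(
      h, apar_sun = matrix(runif(nc * 4, 0, 1600), nc, 4),
      apar_sha = matrix(runif(nc * 4, 0, 200), nc, 4),
      fsun = matrix(runif(nc * 4), nc, 4),
      tleaf = matrix(runif(nc * 4, 10, 30), nc, 4),
      vpd = matrix(runif(nc * 4, 0.3, 2), nc, 4),
      cs = 400, p = p)
  }
  neff <- c(80, 110, 140)
  b_joint <- as.numeric(optimize_bjv(neff, h, p))
  for (i in 1:nc) {
    hi <- h
    for (f in c("apar_sun", "apar_sha", "fsun", "tleaf", "vpd", "cs",
                "stress", "FTVFC", "FTJ", "FTRD", "AI", "FJ4", "WT")) {
      hi[[f]] <- h[[f]][i, , drop = FALSE]
    }
    hi$ncells <- 1
    b_i <- as.numeric(optimize_bjv(neff[i], hi, p))
    expect_equal(b_joint[i], b_i, tolerance = 1e-6)
  }
})

test_that("excluding coordination fixes bJV at 1.3 and scales Vcmax by 1.25", {
  p <- exclude_coordination(leaf_params(vcmax25 = 60))
  expect_equal(p$vcmax25, 75)
  expect_equal(p$bJV, 1.3)
  r <- net_assimilation(leaf_env(apar = 1800, cs = 400), p)
  expect_identical(r$limiting, "electron_transport")
})
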