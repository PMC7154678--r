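mk_seasonal <- function(years, amp = 3, mean_ann = 1, phase = 0) {
  m <- rep(1:12, years)
  mean_ann + amp * sin(2 * pi * (m - 1 - phase) / 12)
}

test_that("Reco' is the elementwise GPP - NLS with calendar checks", {
  gpp <- flux_series(mk_seasonal(2, amp = 5), kind = "gpp")
  nls <- flux_series(mk_seasonal(2, amp = 2), kind = "nls")
  rec <- residual_ecosystem_flux(gpp, nls)
  expect_equal(rec$values, gpp$values - nls$values)
  expect_identical(rec$kind, "reco_prime")
  expect_equal(residual_ecosystem_flux(gpp, gpp)$values, rep(0, 24))
  zero <- flux_series(rep(0, 24), kind = "nls")
  expect_equal(residual_ecosystem_flux(gpp, zero)$values, gpp$values)
  off <- flux_series(mk_seasonal(2), start_year = 5, kind = "nls")
  expect_error(residual_ecosystem_flux(gpp, off), "misaligned")
})

test_that("perturbation ensemble: 25 members, identity member, conservation", {
  rec <- flux_series(mk_seasonal(3, amp = 4, mean_ann = 2), kind = "reco_prime")
  members <- perturb_ensemble(rec)
  expect_length(members, 25)
  shifts <- vapply(members, function(m) m$phase_shift, 0)
  scales <- vapply(members, function(m) m$amplitude_scale, 0)
  expect_setequal(unique(shifts), c(-14, -7, 0, 7, 14))
  expect_setequal(unique(scales), c(0.8, 0.9, 1.0, 1.1, 1.2))

  idm <- members[which(shifts == 0 & scales == 1)]
  expect_length(idm, 1)
  expect_identical(idm[[1]]$series$values, rec$values)

  for (m in members) {
    for (yy in 1:3) {
      iy <- (yy - 1) * 12 + 1:12
      expect_equal(sum(m$series$values[iy]), sum(rec$values[iy]),
                   tolerance = 1e-9)
    }
  }
  # a pure phase shift moves the seasonal peak in the right direction
  late <- members[[which(shifts == 14 & scales == 1)]]
  expect_gt(which.max(late$series$values[1:12]),
            which.max(rec$values[1:12]) - 1)
  expect_false(identical(late$series$values, rec$values))
})

test_that("amplitude scaling changes the seasonal range by the scale factor", {
  rec <- flux_series(mk_seasonal(2, amp = 4, mean_ann = 2), kind = "reco_prime")
  members <- perturb_ensemble(rec)
  sc12 <- Filter(function(m) m$phase_shift == 0 && m$amplitude_scale == 1.2,
                 members)[[1]]
  r0 <- diff(range(rec$values[1:12]))
  r12 <- diff(range(sc12$series$values[1:12]))
  expect_equal(r12 / r0, 1.2, tolerance = 1e-9)
})

test_that("detrended max-min amplitude behaves like the definition", {
  # sinusoid sampled symmetrically about its centre: OLS slope is exactly
  # zero and the samples hit both extremes, so the amplitude is exactly 2a
  v <- 2.5 * cos(2 * pi * ((0:48) - 24) / 12)
  expect_equal(seasonal_amplitude(v)$amplitude, 5, tolerance = 0.02 * 5)

  ramp <- seq(0, 10, length.out = 36)
  expect_lt(seasonal_amplitude(ramp)$amplitude, 1e-9)

  both <- v + seq(2, 30, length.out = 49)
  expect_equal(seasonal_amplitude(both)$amplitude, 5, tolerance = 0.02 * 5)

  # invariance under any added linear function of time
  set.seed(12)
  x <- rnorm(48)
  a0 <- seasonal_amplitude(x)$amplitude
  a1 <- seasonal_amplitude(x + 3.2 + 0.7 * seq_along(x))$amplitude
  expect_equal(a0, a1, tolerance = 1e-9)

  expect_error(seasonal_amplitude(rnorm(23)), "24 months")

  # per-epoch restriction
  long <- mk_seasonal(10, amp = 1) + 0.05 * (1:120)
  a_ep <- seasonal_amplitude(long, epoch = c(1, 3))
  expect_equal(a_ep$n_months, 36)
})

test_that("one-box surrogate: zero flux, constant flux, analytic sinusoid gain", {
  expect_equal(surrogate_concentration(rep(0, 24), c0 = 400),
               rep(400, 24))

  # constant flux with effectively infinite mixing: linear drawdown -F/kappa
  cc <- surrogate_concentration(rep(2.124, 36), kappa = 2.124,
                                tau_mix = 1e12, c0 = 400)
  expect_equal(diff(cc), rep(-1, 35), tolerance = 1e-9)

  # sinusoidal flux: first-order discrete system response
  # C[t+1] = a C[t] - F[t]/kappa + const, a = 1 - 1/tau
  kappa <- 2.124; tau <- 24; amp_f <- 3
  n <- 600
  f <- amp_f * sin(2 * pi * (seq_len(n) - 1) / 12)
  cc <- surrogate_concentration(f, kappa = kappa, tau_mix = tau, c0 = 400)
  a <- 1 - 1 / tau
  gain <- Mod(1 / (exp(2i * pi / 12) - a))
  expected_amp <- 2 * (amp_f / kappa) * gain
  meas <- seasonal_amplitude(cc[(n - 119):n])$amplitude
  expect_equal(meas, expected_amp, tolerance = 0.05 * expected_amp)

  # linearity: doubling the flux seasonal anomaly doubles the detrended ASC
  cc2 <- surrogate_concentration(2 * f, kappa = kappa, tau_mix = tau, c0 = 400)
  m1 <- seasonal_amplitude(cc[(n - 119):n])$amplitude
  m2 <- seasonal_amplitude(cc2[(n - 119):n])$amplitude
  expect_equal(m2 / m1, 2, tolerance = 1e-6)
})

test_that("member selection and amplitude change arithmetic", {
  ascs <- c(10, 12.5, 14.9, 18.0, 21)
  expect_equal(select_members(ascs, 15, tol = 3), 2:4)
  expect_equal(select_members(ascs, 15, tol = Inf), 1:5)
  expect_equal(select_members(ascs, 12.5, tol = 0), 2L)
  expect_length(select_members(ascs, 40, tol = 3), 0)

  expect_equal(asc_change(10, 20), 100)
  expect_equal(asc_change(10, 10), 0)
  expect_error(asc_change(0, 5), "positive")
  a1 <- seasonal_amplitude(mk_seasonal(3, amp = 1))
  a2 <- seasonal_amplitude(mk_seasonal(3, amp = 1.5))
  expect_equal(asc_change(a1, a2), 50, tolerance = 0.5)
})

test_that("flux CSV round-trips", {
  fs <- flux_series(mk_seasonal(2, amp = 2), start_year = 1958, kind = "nls")
  path <- tempfile(fileext = ".csv")
  write_flux_csv(fs, path)
  back <- read_flux_csv(path, kind = "nls")
  expect_equal(back$values, fs$values, tolerance = 1e-9)
  expect_equal(back$start_year, 1958)
  unlink(path)
})

test_that("series validation rejects partial years and non-finite values", {
  expect_error(flux_series(1:13), "multiple of 12")
  expect_error(flux_series(c(rep(1, 11), NA)), "finite")
})
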