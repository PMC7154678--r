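test_that("Rubisco-limited rate: compensation, saturation, hand value", {
  k <- list(gamma_star = 42.75, Km_eff = 710)
  expect_equal(rubisco_limited_rate(42.75, 50, k), 0)
  expect_equal(rubisco_limited_rate(1e9, 50, k), 50, tolerance = 1e-5)
  # 50 * 277.25 / 1030 = 13.45874 (hand arithmetic)
  expect_equal(rubisco_limited_rate(320, 50, k), 13.45874, tolerance = 1e-4)
  expect_lt(rubisco_limited_rate(10, 50, k), 0)  # below compensation
})

test_that("electron-transport-limited rate: compensation, saturation, hand value", {
  k <- list(gamma_star = 42.75)
  expect_equal(electron_transport_limited_rate(42.75, 100, k), 0)
  expect_equal(electron_transport_limited_rate(1e9, 100, k), 25,
               tolerance = 1e-5)
  # 25 * 277.25 / 405.5 = 17.09309 (hand arithmetic)
  expect_equal(electron_transport_limited_rate(320, 100, k), 17.09309,
               tolerance = 1e-4)
})

test_that("electron transport light response obeys its bounds and limits", {
  expect_equal(electron_transport(0, 100), 0)
  # theta = 1 degenerates to the exact minimum
  expect_equal(electron_transport(200, 100, alpha = 0.3, theta = 1),
               min(0.3 * 200, 100))
  expect_equal(electron_transport(2000, 100, alpha = 0.3, theta = 1), 100)
  # saturation at high light
  expect_equal(electron_transport(1e8, 100, alpha = 0.3, theta = 0.9), 100,
               tolerance = 1e-3)
  # theta = 0 is the rectangular hyperbola
  ai <- 0.3 * 500
  expect_equal(electron_transport(500, 120, alpha = 0.3, theta = 0),
               ai * 120 / (ai + 120))
  # 0 <= J <= min(alpha I, jmax) across a random grid
  set.seed(42)
  for (i in 1:50) {
    ap <- runif(1, 0, 3000); jm <- runif(1, 20, 300)
    th <- runif(1, 0.05, 1)
    j <- electron_transport(ap, jm, 0.3, th)
    expect_gte(j, 0)
    expect_lte(j, min(0.3 * ap, jm) + 1e-9)
  }
})

test_that("net assimilation honours the prescribed ci/cs ratio and dark limit", {
  p <- leaf_params(chi_fixed = 0.8)
  r <- net_assimilation(leaf_env(apar = 1500, cs = 400), p)
  expect_equal(r$ci, 320)
  expect_identical(net_assimilation(leaf_env(apar = 0, cs = 400), p)$A, 0)
  expect_equal(net_assimilation(leaf_env(apar = 0, cs = 400), p)$limiting,
               "electron_transport")
})

test_that("assimilation result invariants hold across environments", {
  set.seed(7)
  for (i in 1:30) {
    p <- leaf_params(vcmax25 = runif(1, 20, 100), bJV = runif(1, 0.8, 3),
                     chi_fixed = if (i %% 2) runif(1, 0.5, 0.95) else NULL)
    env <- leaf_env(apar = runif(1, 50, 2000), tleaf = runif(1, 5, 40),
                    vpd = runif(1, 0.2, 3), cs = runif(1, 200, 900))
    r <- net_assimilation(env, p)
    expect_lte(r$A, min(r$Ac, r$Aj) + 1e-9)
    if (r$A > 0) {
      expect_gte(r$ci, kinetic_constants(env$tleaf)$gamma_star)
      expect_lte(r$ci, env$cs)
    }
    lim <- if (abs(r$Ac - r$Aj) <= 1e-6 * max(abs(r$Ac), abs(r$Aj)))
      "colimited" else if (r$Ac < r$Aj) "rubisco" else "electron_transport"
    expect_identical(r$limiting, lim)
  }
})

test_that("co-limitation point is detected (crossing found by root-finder oracle)", {
  # find Vcmax25 at which Ac(ci) = Aj(ci) with everything else fixed
  env <- leaf_env(apar = 1000, cs = 400)
  mk <- function(v) leaf_params(vcmax25 = v, bJV = 1.7, chi_fixed = 0.8)
  gap <- function(v) {
    r <- net_assimilation(env, mk(v))
    r$Ac - r$Aj
  }
  vstar <- uniroot(gap, c(5, 200), tol = 1e-10)$root
  r <- net_assimilation(env, mk(vstar))
  expect_identical(r$limiting, "colimited")
  expect_equal(r$A, r$Ac, tolerance = 1e-6)
  expect_equal(r$A, r$Aj, tolerance = 1e-6)
})

test_that("exact-min co-limitation equals min(Ac, Aj); smoothing lies below", {
  set.seed(9)
  for (i in 1:20) {
    env <- leaf_env(apar = runif(1, 100, 2000), tleaf = runif(1, 10, 35),
                    cs = runif(1, 250, 800))
    p_min <- leaf_params(vcmax25 = runif(1, 30, 90), chi_fixed = 0.8)
    r <- net_assimilation(env, p_min)
    expect_identical(r$A, min(r$Ac, r$Aj))
    p_sm <- leaf_params(vcmax25 = p_min$vcmax25, chi_fixed = 0.8,
                        colimit_theta = 0.99)
    rs <- net_assimilation(env, p_sm)
    expect_lte(rs$A, min(rs$Ac, rs$Aj))
    expect_gt(rs$A, 0.8 * min(rs$Ac, rs$Aj))
  }
})

test_that("coupled stomatal closure gives ci/cs = g1/(g1+sqrt(D))", {
  p <- leaf_params(g1 = 5.67)
  r <- net_assimilation(leaf_env(apar = 1200, vpd = 1, cs = 400), p)
  expect_equal(r$ci / 400, 5.67 / 6.67, tolerance = 1e-9)
  r2 <- net_assimilation(leaf_env(apar = 1200, vpd = 2.25, cs = 400), p)
  expect_equal(r2$ci / 400, 5.67 / (5.67 + 1.5), tolerance = 1e-9)
})
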