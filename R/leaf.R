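#' Leaf photosynthetic parameters
#'
#' Bundles the parameters of the C3 leaf: carboxylation capacity at 25 degC,
#' the Jmax:Vcmax ratio `bJV`, quantum yield and curvature of the electron
#' transport light response, the stomatal closure (either a fixed ci/cs ratio
#' `chi_fixed`, or the coupled slope model with parameter `g1`), day
#' respiration, and the relative nitrogen cost of electron-transport capacity
#' `c_cost_JV` used by the coordination optimizer.
#'
#' Defaults: `chi_fixed = NULL` selects the coupled stomatal model with
#' `g1 = 5.67` kPa^0.5, which yields ci/cs = 0.85 at 1 kPa vapour pressure
#' deficit. `c_cost_JV = 0.746` is the shipped calibrated cost constant (see
#' the methods vignette for the calibration).
#'
#' @param vcmax25 maximum carboxylation rate at 25 degC (umol m-2 s-1).
#' @param bJV ratio Jmax25/Vcmax25 (dimensionless).
#' @param rd25 day respiration at 25 degC (umol m-2 s-1).
#' @param alpha quantum yield of electron transport (mol e- / mol photons).
#' @param theta curvature of the light response, in (0, 1].
#' @param chi_fixed optional prescribed ci/cs ratio in (0, 1); `NULL` selects
#'   the coupled stomatal model.
#' @param g1 stomatal slope parameter (kPa^0.5) of the coupled model.
#' @param c_cost_JV relative nitrogen cost of Jmax vs Vcmax (dimensionless).
#' @param bJV_bounds admissible range for `bJV`.
#' @param colimit_theta curvature of quadratic co-limitation smoothing, or
#'   `NULL` (default) for the exact minimum of Ac and Aj.
#' @return object of class `leaf_params`.
#' @export
leaf_params <- function(vcmax25 = 50, bJV = 1.7, rd25 = 0.015 * vcmax25,
                        alpha = 0.3, theta = 0.9,
                        chi_fixed = NULL, g1 = 5.67,
                        c_cost_JV = 0.746,
                        bJV_bounds = c(0.5, 5),
                        colimit_theta = NULL) {
  stopifnot(vcmax25 > 0, theta > 0, theta <= 1, c_cost_JV > 0,
            length(bJV_bounds) == 2, bJV_bounds[1] < bJV_bounds[2])
  if (bJV < bJV_bounds[1] || bJV > bJV_bounds[2]) {
    stop("bJV outside configured bounds [", bJV_bounds[1], ", ",
         bJV_bounds[2], "]", call. = FALSE)
  }
  if (!is.null(chi_fixed) && (chi_fixed <= 0 || chi_fixed >= 1)) {
    stop("chi_fixed must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(colimit_theta) && (colimit_theta <= 0 || colimit_theta >= 1)) {
    stop("colimit_theta must lie in (0, 1)", call. = FALSE)
  }
  structure(list(vcmax25 = vcmax25, bJV = bJV, rd25 = rd25, alpha = alpha,
                 theta = theta, chi_fixed = chi_fixed, g1 = g1,
                 c_cost_JV = c_cost_JV, bJV_bounds = bJV_bounds,
                 colimit_theta = colimit_theta),
            class = "leaf_params")
}

#' Leaf-level environment
#'
#' @param apar absorbed photosynthetically active radiation (umol m-2 s-1).
#' @param tleaf leaf temperature (degC).
#' @param vpd leaf-air vapour pressure difference (kPa).
#' @param cs CO2 mole fraction at the leaf surface (umol/mol).
#' @param patm atmospheric pressure (kPa).
#' @return object of class `leaf_env`.
#' @export
leaf_env <- function(apar, tleaf = 25, vpd = 1, cs = 400, patm = 101.325) {
  stopifnot(apar >= 0, cs > 0, vpd >= 0, patm > 40, patm < 110)
  structure(list(apar = apar, tleaf = tleaf, vpd = vpd, cs = cs, patm = patm),
            class = "leaf_env")
}

#' Rubisco-limited assimilation rate
#'
#' `Ac = vcmax * (ci - gamma_star) / (ci + Km_eff)`; may be negative below
#' the compensation point.
#'
#' @param ci intercellular CO2 (umol/mol).
#' @param vcmax carboxylation capacity at leaf temperature (umol m-2 s-1).
#' @param k kinetic constants (fields `gamma_star`, `Km_eff` are used).
#' @return rate (umol m-2 s-1). Vectorised in all arguments.
#' @export
rubisco_limited_rate <- function(ci, vcmax, k) {
  stopifnot(all(ci >= 0))
  vcmax * (ci - k$gamma_star) / (ci + k$Km_eff)
}

#' Electron-transport-limited assimilation rate
#'
#' `Aj = (J/4) * (ci - gamma_star) / (ci + 2 gamma_star)`.
#'
#' @param ci intercellular CO2 (umol/mol).
#' @param J electron transport rate (umol e- m-2 s-1).
#' @param k kinetic constants (field `gamma_star` is used).
#' @return rate (umol m-2 s-1). Vectorised.
#' @export
electron_transport_limited_rate <- function(ci, J, k) {
  stopifnot(all(ci >= 0), all(J >= 0))
  (J / 4) * (ci - k$gamma_star) / (ci + 2 * k$gamma_star)
}

#' Electron transport rate from absorbed light
#'
#' Smaller root of the non-rectangular hyperbola
#' `theta J^2 - (alpha I + Jmax) J + alpha I Jmax = 0`. `theta = 0` is
#' handled as the rectangular-hyperbola limit.
#'
#' @param apar absorbed PAR (umol photons m-2 s-1).
#' @param jmax maximum electron transport rate at leaf temperature.
#' @param alpha quantum yield (mol e-/mol photons).
#' @param theta curvature in \[0, 1\].
#' @return J (umol e- m-2 s-1), with `0 <= J <= min(alpha*apar, jmax)`.
#'   Vectorised.
#' @export
electron_transport <- function(apar, jmax, alpha = 0.3, theta = 0.9) {
  stopifnot(all(apar >= 0), all(jmax > 0))
  ai <- alpha * apar
  if (theta == 0) return(ai * jmax / (ai + jmax))
  b <- ai + jmax
  disc <- pmax(b * b - 4 * theta * ai * jmax, 0)
  (b - sqrt(disc)) / (2 * theta)
}

# Intercellular CO2 under the coupled slope-form stomatal model.
#
# The coupled closure ties stomatal conductance to assimilation,
# gs = 1.6 (1 + g1/sqrt(D)) A / cs, and ci = cs - 1.6 A / gs. The solution is
# found by bounded fixed-point iteration on ci (tolerance in umol/mol). For
# g0 = 0 the fixed point is ci = cs * g1 / (g1 + sqrt(D)), independent of A;
# the iteration is kept so the closure remains valid if a residual
# conductance is introduced.
.solve_ci_coupled <- function(cs, vpd, g1, tol = 1e-6, maxit = 100) {
  chi <- g1 / (g1 + sqrt(pmax(vpd, 1e-6)))
  ci <- chi * cs
  for (i in seq_len(maxit)) {
    ci_new <- chi * cs
    if (max(abs(ci_new - ci)) < tol) return(ci_new)
    ci <- ci_new
  }
  stop("ci solver failed to converge; residual = ",
       max(abs(chi * cs - ci)), call. = FALSE)
}

# Vectorised leaf assimilation over arbitrary-shaped numeric inputs.
# Returns list(a, ac, aj, ci, j). `vcmax25`/`jmax25` are capacities at 25 degC,
# scaled internally to tleaf. This is the fast path used by the coordination
# objective and the canopy integrator; net_assimilation() wraps it with the
# full typed contract.
leaf_assim <- function(apar, tleaf, vpd, cs, vcmax25, jmax25, p,
                       ci = NULL) {
  k <- kinetic_constants(tleaf)
  ft <- capacity_temp_factors(tleaf)
  if (is.null(ci)) {
    if (!is.null(p$chi_fixed)) {
      ci <- p$chi_fixed * cs
    } else {
      ci <- .solve_ci_coupled(cs, vpd, p$g1)
    }
  }
  vc <- vcmax25 * ft$vcmax
  jm <- pmax(jmax25 * ft$jmax, 1e-12)
  j <- electron_transport(apar, jm, p$alpha, p$theta)
  ac <- vc * (ci - k$gamma_star) / (ci + k$Km_eff)
  aj <- (j / 4) * (ci - k$gamma_star) / (ci + 2 * k$gamma_star)
  if (is.null(p$colimit_theta)) {
    a <- pmin(ac, aj)
  } else {
    th <- p$colimit_theta
    s <- ac + aj
    a <- (s - sqrt(pmax(s * s - 4 * th * ac * aj, 0))) / (2 * th)
  }
  list(a = a, ac = ac, aj = aj, ci = ci, j = j)
}

#' Gross leaf assimilation
#'
#' Evaluates the C3 leaf model at one environment: temperature-scaled
#' kinetics and capacities, electron transport from absorbed light,
#' intercellular CO2 from the prescribed `chi_fixed` ratio or the coupled
#' stomatal closure, and gross assimilation as the minimum (or, optionally,
#' a quadratically smoothed minimum) of the Rubisco- and electron-transport-
#' limited rates.
#'
#' @param env a [leaf_env()].
#' @param p a [leaf_params()].
#' @return object of class `assimilation_result`: list with `A`, `Ac`, `Aj`
#'   (umol m-2 s-1), `ci` (umol/mol) and `limiting` (one of `"rubisco"`,
#'   `"electron_transport"`, `"colimited"`).
#' @examples
#' net_assimilation(leaf_env(apar = 1500, cs = 400), leaf_params(chi_fixed = 0.8))
#' @export
net_assimilation <- function(env, p) {
  stopifnot(inherits(env, "leaf_env"), inherits(p, "leaf_params"))
  r <- leaf_assim(env$apar, env$tleaf, env$vpd, env$cs,
                  p$vcmax25, p$bJV * p$vcmax25, p)
  tol <- 1e-6 * max(abs(r$ac), abs(r$aj), 1e-12)
  limiting <- if (abs(r$ac - r$aj) <= tol) {
    "colimited"
  } else if (r$ac < r$aj) "rubisco" else "electron_transport"
  structure(list(A = r$a, Ac = r$ac, Aj = r$aj, ci = r$ci,
                 limiting = limiting),
            class = "assimilation_result")
}
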