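#' CO2 elasticity of gross assimilation
#'
#' The dimensionless instantaneous sensitivity `beta = (dA/dc) * (c/A)`,
#' evaluated as a central finite difference of `ln A` against `ln c` with a
#' +/- 1 umol/mol step at the reference concentration. The leaf model takes
#' the leaf-surface concentration as input and no boundary layer is
#' represented, so `ca` and `cs` coincide; `mode` records which concentration
#' the diagnostic refers to.
#'
#' With `coordination` supplied, the capacities are re-optimized at each
#' perturbed concentration under the state's fixed effective nitrogen (the
#' nitrogen-constrained elasticity): each perturbed environment forms a
#' stationary history and [optimize_bjv()] redistributes `Neff` before `A`
#' is evaluated. Without it, capacities are held at `p$vcmax25` and
#' `p$bJV * p$vcmax25`.
#'
#' @param env a [leaf_env()]; assimilation must be positive there.
#' @param p a [leaf_params()].
#' @param mode `"wrt_cs"` (default) or `"wrt_ca"` (label only; see above).
#' @param coordination optional [coordination_state()].
#' @param step finite-difference step (umol/mol).
#' @return object of class `elasticity_diagnostic`: list with `beta`,
#'   `reference_concentration`, `mode`.
#' @export
elasticity_beta <- function(env, p, mode = c("wrt_cs", "wrt_ca"),
                            coordination = NULL, step = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(env, "leaf_env"), env$cs > step)
  a_at <- function(cs) {
    if (is.null(coordination)) {
      leaf_assim(env$apar, env$tleaf, env$vpd, cs,
                 p$vcmax25, p$bJV * p$vcmax25, p)$a
    } else {
      h <- met_history(1, 1, 1)
      for (i in 1:5) {
        h <- history_append_day(h, apar_sun = env$apar, fsun = 1,
                                tleaf = env$tleaf, vpd = env$vpd, cs = cs,
                                p = p)
      }
      b <- as.numeric(optimize_bjv(coordination$Neff, h, p))
      vc0 <- coordination$Neff / (1 + coordination$c_cost * b)
      leaf_assim(env$apar, env$tleaf, env$vpd, cs, vc0, b * vc0, p)$a
    }
  }
  a0 <- a_at(env$cs)
  if (!is.finite(a0) || a0 <= 0) {
    stop("assimilation is not positive at the reference concentration",
         call. = FALSE)
  }
  beta <- (log(a_at(env$cs + step)) - log(a_at(env$cs - step))) /
    (log(env$cs + step) - log(env$cs - step))
  structure(list(beta = beta, reference_concentration = env$cs, mode = mode),
            class = "elasticity_diagnostic")
}

#' Table of CO2 elasticities by regime
#'
#' Evaluates the leaf-level elasticity at 25 degC across a grid of
#' leaf-surface CO2 concentrations for three configurations:
#' \describe{
#'   \item{`coordinated`}{capacities re-optimized under the effective-
#'     nitrogen constraint at each concentration (coupled stomatal closure,
#'     ci/cs = 0.85 at 1 kPa VPD).}
#'   \item{`aj_coupled`}{coordination disabled (`bJV = 1.3`, `Vcmax25`
#'     scaled by 1.25) so electron transport always limits, with the coupled
#'     stomatal closure.}
#'   \item{`aj_fixed_chi`}{electron-transport-limited with a prescribed
#'     ci/cs = 0.8.}
#' }
#'
#' @param cs vector of leaf-surface CO2 concentrations (umol/mol).
#' @param tleaf leaf temperature (degC).
#' @param vpd vapour pressure deficit (kPa).
#' @param apar absorbed PAR (saturating by default).
#' @param p base [leaf_params()].
#' @param regimes subset of the three regime names.
#' @return data.frame with columns `cs_ppm`, `regime`, `chi`, `beta`.
#' @export
beta_table <- function(cs = c(400, 800), tleaf = 25, vpd = 1, apar = 1800,
                       p = leaf_params(),
                       regimes = c("coordinated", "aj_coupled",
                                   "aj_fixed_chi")) {
  regimes <- match.arg(regimes, several.ok = TRUE)
  coord <- coordination_state(p$vcmax25, p$bJV * p$vcmax25, p$c_cost_JV)
  p_excl <- exclude_coordination(p)
  p_fix <- exclude_coordination(
    leaf_params(vcmax25 = p$vcmax25, bJV = p$bJV, chi_fixed = 0.8,
                alpha = p$alpha, theta = p$theta, c_cost_JV = p$c_cost_JV))
  rows <- list()
  for (ci_s in cs) {
    env <- leaf_env(apar = apar, tleaf = tleaf, vpd = vpd, cs = ci_s)
    for (rg in regimes) {
      res <- switch(rg,
        coordinated = elasticity_beta(env, p, coordination = coord),
        aj_coupled = elasticity_beta(env, p_excl),
        aj_fixed_chi = elasticity_beta(env, p_fix))
      chi <- if (rg == "aj_fixed_chi") 0.8 else p$g1 / (p$g1 + sqrt(vpd))
      rows[[length(rows) + 1]] <-
        data.frame(cs_ppm = ci_s, regime = rg, chi = chi, beta = res$beta)
    }
  }
  do.call(rbind, rows)
}
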