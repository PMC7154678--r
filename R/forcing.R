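#' Plant-functional-type presets of the toy globe
#'
#' Per-PFT climate and vegetation parameters used by the forcing generator
#' and the canopy surrogate: latitude range, annual-mean temperature and
#' seasonal amplitude (degC), diurnal temperature range, relative humidity,
#' mean soil-water index, capacity prior, allocation fraction, leaf turnover
#' (yr-1), specific leaf area (m2 gC-1) and respiration constants.
#'
#' @return named list of preset parameter lists.
#' @export
pft_presets <- function() {
  list(
    tropical_forest = list(lat = c(-12, 12), tmean = 26, tamp = 2, dtr = 8,
                           rh = 0.80, wbase = 0.85, vcmax25 = 45,
                           alloc = 0.30, turnover = 1.0, sla = 0.012,
                           reco_rate = 0.12, q10 = 2),
    temperate_forest = list(lat = c(35, 55), tmean = 12, tamp = 10, dtr = 9,
                            rh = 0.70, wbase = 0.75, vcmax25 = 60,
                            alloc = 0.30, turnover = 1.0, sla = 0.012,
                            reco_rate = 0.10, q10 = 2),
    boreal_forest = list(lat = c(55, 68), tmean = 2, tamp = 14, dtr = 8,
                         rh = 0.70, wbase = 0.80, vcmax25 = 45,
                         alloc = 0.25, turnover = 0.6, sla = 0.010,
                         reco_rate = 0.06, q10 = 2),
    semiarid = list(lat = c(15, 35), tmean = 22, tamp = 8, dtr = 14,
                    rh = 0.45, wbase = 0.35, vcmax25 = 40,
                    alloc = 0.30, turnover = 1.0, sla = 0.012,
                    reco_rate = 0.10, q10 = 2),
    grassland = list(lat = c(30, 50), tmean = 14, tamp = 10, dtr = 12,
                     rh = 0.60, wbase = 0.55, vcmax25 = 55,
                     alloc = 0.35, turnover = 1.5, sla = 0.015,
                     reco_rate = 0.10, q10 = 2)
  )
}

#' Cell configuration
#'
#' One toy-grid cell: its plant functional type, latitude, leaf parameters
#' and the canopy/respiration surrogate constants.
#'
#' @param pft one of the names of [pft_presets()].
#' @param latitude degrees; defaults to the preset mid-range.
#' @param leaf_params a [leaf_params()]; defaults to the preset capacity
#'   prior with the package-default coordination constants.
#' @param allocation_fraction,leaf_turnover,reco_base_rate,q10,sla canopy
#'   surrogate constants (defaults from the preset).
#' @param climate list overriding preset climate fields (`tmean`, `tamp`,
#'   `dtr`, `rh`, `wbase`).
#' @return object of class `cell_config`.
#' @export
cell_config <- function(pft, latitude = NULL, leaf_params = NULL,
                        allocation_fraction = NULL, leaf_turnover = NULL,
                        reco_base_rate = NULL, q10 = NULL, sla = NULL,
                        climate = list()) {
  presets <- pft_presets()
  if (!pft %in% names(presets)) {
    stop("unknown pft '", pft, "'", call. = FALSE)
  }
  pre <- presets[[pft]]
  cl <- utils::modifyList(pre[c("tmean", "tamp", "dtr", "rh", "wbase")],
                          climate)
  lat <- if (is.null(latitude)) mean(pre$lat) else latitude
  if (abs(lat) > 90) stop("invalid latitude", call. = FALSE)
  lp <- if (is.null(leaf_params)) leaf_params(vcmax25 = pre$vcmax25) else leaf_params
  af <- if (is.null(allocation_fraction)) pre$alloc else allocation_fraction
  stopifnot(af > 0, af < 1)
  lt <- if (is.null(leaf_turnover)) pre$turnover else leaf_turnover
  stopifnot(lt > 0)
  structure(list(pft = pft, latitude = lat, leaf_params = lp,
                 allocation_fraction = af, leaf_turnover = lt,
                 reco_base_rate = if (is.null(reco_base_rate)) pre$reco_rate else reco_base_rate,
                 q10 = if (is.null(q10)) pre$q10 else q10,
                 sla = if (is.null(sla)) pre$sla else sla,
                 climate = cl),
            class = "cell_config")
}

#' Toy globe of PFT cells with area weights
#'
#' Draws `n_cells` cells across the five PFT presets with counts matching
#' the requested proportions (largest-remainder rounding, so counts match
#' the proportions to within one cell) and latitudes sampled uniformly from
#' each preset's range. Cells carry equal, normalized area weights.
#'
#' @param n_cells number of cells (>= 1).
#' @param pft_mix named non-negative weights over the PFT presets; need not
#'   sum to one but must be normalizable.
#' @param seed RNG seed (integer).
#' @return list with `cells` (list of [cell_config()]) and `weights`
#'   (numeric, sums to 1).
#' @export
toy_globe <- function(n_cells = 20,
                      pft_mix = c(tropical_forest = 0.2,
                                  temperate_forest = 0.2,
                                  boreal_forest = 0.2,
                                  semiarid = 0.2, grassland = 0.2),
                      seed = 1) {
  stopifnot(n_cells >= 1)
  if (any(pft_mix < 0) || sum(pft_mix) <= 0) {
    stop("pft_mix is not normalizable", call. = FALSE)
  }
  mix <- pft_mix / sum(pft_mix)
  exact <- mix * n_cells
  counts <- floor(exact)
  rem <- n_cells - sum(counts)
  if (rem > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  set.seed(seed)
  presets <- pft_presets()
  cells <- list()
  for (pft in names(mix)) {
    nk <- counts[[pft]]
    if (nk == 0) next
    rng <- presets[[pft]]$lat
    lats <- stats::runif(nk, rng[1], rng[2])
    for (la in lats) cells[[length(cells) + 1]] <- cell_config(pft, latitude = la)
  }
  list(cells = cells, weights = rep(1 / n_cells, n_cells))
}

# Solar geometry: cosine of the solar zenith angle at latitude `lat`
# (degrees), day of (365-day) year `doy`, and local solar hour `hour`.
.cos_zenith <- function(lat, doy, hour) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  phi <- lat * pi / 180
  ha <- (hour - 12) * 15 * pi / 180
  sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(ha)
}

.ar1 <- function(n, rho, sd) {
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (i in 2:n) x[i] <- rho * x[i - 1] + e[i]
  x
}

#' Synthetic sub-diurnal meteorological forcing
#'
#' Seeded weather-generator surrogate. Produces a recyclable block of
#' `met_years` years of 3-hourly meteorology per cell (PAR from solar
#' geometry times an AR(1) daily cloudiness transmission; air temperature as
#' a diurnal sinusoid around a seasonally varying daily mean with AR(1)
#' daily anomalies; relative humidity with small AR(1) noise, from which
#' vapour pressure deficit is derived at use time; a smooth \[0,1\]
#' soil-water index), plus annual driver-anomaly tables over the full `years`
#' span: a temperature offset (linear trend `warming_total` plus AR(1)
#' interannual variability) and a multiplicative precipitation factor.
#' Identical seed and configuration give bitwise-identical output.
#'
#' @param cells list of [cell_config()].
#' @param years total span covered by the annual anomaly tables.
#' @param seed integer RNG seed.
#' @param met_years length of the recycled meteorology block (years).
#' @param step_hours sub-diurnal step (hours; default 3).
#' @param warming_total linear temperature increase over the span (degC),
#'   applied only when a scenario varies temperature.
#' @param tair_iav_sd standard deviation of annual temperature anomalies.
#' @param precip_iav_sd standard deviation of annual precipitation factors.
#' @return object of class `forcing_series`: met block matrices
#'   (`steps x cells`) `par`, `tair`, `rh`, `w`, `cosz`, plus `annual`
#'   anomaly tables and bookkeeping fields.
#' @export
generate_forcing <- function(cells, years, seed, met_years = min(5, years),
                             step_hours = 3, warming_total = 1.0,
                             tair_iav_sd = 0.3, precip_iav_sd = 0.08) {
  stopifnot(years >= 1, met_years >= 1, met_years <= years)
  for (cfg in cells) {
    if (abs(cfg$latitude) > 90) stop("invalid latitude", call. = FALSE)
  }
  set.seed(as.integer(seed))
  nc <- length(cells)
  spd <- as.integer(24 / step_hours)
  ndays <- met_years * 365L
  nsteps <- ndays * spd
  hour <- rep((seq_len(spd) - 0.5) * step_hours, times = ndays)
  doy <- rep(rep(1:365, times = met_years), each = spd)
  day_idx <- rep(seq_len(ndays), each = spd)

  par <- tair <- rh <- w <- cosz <- matrix(0, nsteps, nc)
  for (i in seq_len(nc)) {
    cfg <- cells[[i]]
    cl <- cfg$climate
    cz <- .cos_zenith(cfg$latitude, doy, hour)
    cz[cz < 0] <- 0
    trans <- 0.35 + 0.5 * stats::pnorm(.ar1(ndays, 0.7, 1))
    peak <- if (cfg$latitude >= 0) 200 else 18
    tday <- cl$tmean + cl$tamp * cos(2 * pi * (doy[seq(1, nsteps, spd)] - peak) / 365) +
      .ar1(ndays, 0.8, 1.5)
    rhday <- pmin(pmax(cl$rh + .ar1(ndays, 0.6, 0.05), 0.2), 0.95)
    wday <- pmin(pmax(cl$wbase + .ar1(ndays, 0.9, 0.12), 0.05), 1)
    par[, i] <- 2000 * cz * trans[day_idx]
    tair[, i] <- tday[day_idx] + 0.5 * cl$dtr * cos(2 * pi * (hour - 14) / 24)
    rh[, i] <- rhday[day_idx]
    w[, i] <- wday[day_idx]
    cosz[, i] <- cz
  }
  zen <- acos(pmin(pmax(cosz, -1), 1)) * 180 / pi
  par[zen >= 90] <- 0

  tanom <- warming_total * (seq_len(years) - 1) / max(years - 1, 1) +
    .ar1(years, 0.3, tair_iav_sd)
  panom <- pmin(pmax(1 + .ar1(years, 0.3, precip_iav_sd), 0.6), 1.4)

  structure(list(par = par, tair = tair, rh = rh, w = w, cosz = cosz,
                 zenith = zen,
                 annual = list(tanom = tanom, panom = panom),
                 met_years = met_years, years = years,
                 step_hours = step_hours, steps_per_day = spd,
                 ncells = nc, seed = seed),
            class = "forcing_series")
}

#' Annual CO2 trajectories
#'
#' @param kind `"constant"`, `"historic_ramp"` (smooth quasi-exponential,
#'   default 296 to 389 ppm over 111 years), `"doubling_ramp"` (exponential
#'   300 to 600 ppm with 5-year plateaus at both ends so endpoint averaging
#'   windows sample the limits exactly), or `"step"`.
#' @param years span (years).
#' @param value constant level (for `"constant"`).
#' @param from,to endpoint concentrations (umol/mol).
#' @param step_year first year at the post-step level (for `"step"`).
#' @param curvature shape parameter of the historic ramp.
#' @param plateau plateau length (years) of the doubling ramp.
#' @return object of class `co2_trajectory` with fields `kind`, `annual_ca`,
#'   `span`.
#' @export
co2_trajectory <- function(kind = c("constant", "historic_ramp",
                                    "doubling_ramp", "step"),
                           years = NULL, value = 400,
                           from = NULL, to = NULL, step_year = NULL,
                           curvature = 2.5, plateau = 5) {
  kind <- match.arg(kind)
  ca <- switch(kind,
    constant = {
      if (is.null(years)) years <- 1
      rep(value, years)
    },
    historic_ramp = {
      if (is.null(years)) years <- 111
      if (is.null(from)) from <- 296
      if (is.null(to)) to <- 389
      s <- (seq_len(years) - 1) / (years - 1)
      from + (to - from) * (exp(curvature * s) - 1) / (exp(curvature) - 1)
    },
    doubling_ramp = {
      if (is.null(years)) years <- 91
      if (is.null(from)) from <- 300
      if (is.null(to)) to <- 600
      stopifnot(years > 2 * plateau)
      i <- seq_len(years)
      frac <- pmin(pmax((i - plateau) / (years - 2 * plateau), 0), 1)
      from * (to / from)^frac
    },
    step = {
      stopifnot(!is.null(from), !is.null(to), !is.null(step_year))
      if (is.null(years)) years <- step_year + 9
      c(rep(from, step_year - 1), rep(to, years - step_year + 1))
    }
  )
  structure(list(kind = kind, annual_ca = ca, span = length(ca)),
            class = "co2_trajectory")
}

#' A stationary leaf-level forcing day
#'
#' One clear-sky diurnal cycle of leaf-level meteorology (absorbed PAR from
#' solar geometry, sinusoidal temperature, VPD from saturation deficit at
#' fixed relative humidity), used for leaf-level coordination experiments
#' under repeating forcing.
#'
#' @param cs CO2 at the leaf surface (umol/mol).
#' @param pft preset supplying temperature/humidity (default temperate
#'   forest); climate fields can be overridden via `...` (e.g. `tmean`).
#' @param latitude,doy location and day of year of the solar geometry.
#' @param step_hours sub-diurnal step.
#' @param apar_clear clear-sky absorbed PAR coefficient (umol m-2 s-1 at
#'   overhead sun).
#' @param ... overrides of the preset climate fields.
#' @return list with per-step `apar`, `tleaf`, `vpd`, `cs` and `step_hours`.
#' @export
stationary_leaf_day <- function(cs = 400, pft = "temperate_forest",
                                latitude = 45, doy = 172, step_hours = 3,
                                apar_clear = 1600, ...) {
  cl <- utils::modifyList(
    pft_presets()[[pft]][c("tmean", "tamp", "dtr", "rh")], list(...))
  spd <- as.integer(24 / step_hours)
  hour <- (seq_len(spd) - 0.5) * step_hours
  cz <- pmax(.cos_zenith(latitude, doy, hour), 0)
  tleaf <- cl$tmean + cl$tamp + 0.5 * cl$dtr * cos(2 * pi * (hour - 14) / 24)
  vpd <- pmax(esat_kpa(tleaf) * (1 - cl$rh), 0.05)
  list(apar = apar_clear * cz, tleaf = tleaf, vpd = vpd,
       cs = rep(cs, spd), step_hours = step_hours)
}
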