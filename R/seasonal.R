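#' Monthly flux series
#'
#' A whole-years monthly flux series (PgC month-1) with a region label and a
#' kind tag.
#'
#' @param values numeric, length divisible by 12, all finite.
#' @param start_year calendar year of the first value.
#' @param kind one of `"gpp"`, `"nls"`, `"reco_prime"`.
#' @param region free-text region label.
#' @return object of class `flux_series`.
#' @export
flux_series <- function(values, start_year = 1, kind = c("gpp", "nls",
                                                         "reco_prime"),
                        region = "nh") {
  kind <- match.arg(kind)
  if (length(values) %% 12 != 0 || length(values) == 0) {
    stop("monthly series length must be a positive multiple of 12",
         call. = FALSE)
  }
  if (any(!is.finite(values))) stop("non-finite flux values", call. = FALSE)
  structure(list(values = as.numeric(values), start_year = start_year,
                 kind = kind, region = region,
                 years = length(values) / 12),
            class = "flux_series")
}

#' Residual ecosystem carbon loss
#'
#' `Reco' = GPP - NLS`: the lumped respiration-plus-fire flux implied by
#' gross uptake and the net land sink.
#'
#' @param gpp,nls aligned [flux_series()] objects (same start year and
#'   length).
#' @return a `flux_series` of kind `"reco_prime"`.
#' @export
residual_ecosystem_flux <- function(gpp, nls) {
  stopifnot(inherits(gpp, "flux_series"), inherits(nls, "flux_series"))
  if (gpp$start_year != nls$start_year ||
      length(gpp$values) != length(nls$values)) {
    stop("GPP and NLS series are misaligned", call. = FALSE)
  }
  flux_series(gpp$values - nls$values, gpp$start_year, "reco_prime",
              gpp$region)
}

# Circular phase shift of one year of monthly values by `shift_days`, via
# linear interpolation to a 360-day (12 x 30) internal calendar and
# re-binning to months. Positive shifts delay the seasonal pattern.
.shift_months <- function(v, shift_days) {
  if (shift_days == 0) return(v)
  mids <- seq(15, 345, by = 30)
  xs <- c(mids[12] - 360, mids, mids[1] + 360)
  ys <- c(v[12], v, v[1])
  d <- seq(0.5, 359.5, by = 1)
  daily <- stats::approx(xs, ys, xout = d)$y
  src <- ((d - shift_days) %% 360)
  shifted <- stats::approx(c(d - 360, d, d + 360),
                           c(daily, daily, daily), xout = src)$y
  colMeans(matrix(shifted, nrow = 30))
}

#' Phase/amplitude perturbation ensemble of a monthly flux
#'
#' Builds the Cartesian product of equally spaced phase shifts (default five
#' values spanning +/-14 days) and amplitude scalings (five values spanning
#' +/-20%), 25 members by default, including the identity member at the grid
#' centre. Phase shifts are applied by circular daily interpolation within
#' each year and re-binning to months (never month-index rounding);
#' amplitude scaling acts on the seasonal anomaly about each year's mean.
#' Each year's total is conserved exactly by a uniform additive rebalance.
#' The identity member reproduces the input bitwise.
#'
#' @param reco a [flux_series()] covering whole years.
#' @param n_phase,n_amp grid sizes.
#' @param phase_range maximum phase shift (days).
#' @param amp_range maximum relative amplitude change.
#' @return list of `perturbation_member` objects: `phase_shift` (days),
#'   `amplitude_scale`, `series` (a `flux_series`).
#' @export
perturb_ensemble <- function(reco, n_phase = 5, n_amp = 5,
                             phase_range = 14, amp_range = 0.2) {
  stopifnot(inherits(reco, "flux_series"))
  shifts <- seq(-phase_range, phase_range, length.out = n_phase)
  scales <- seq(1 - amp_range, 1 + amp_range, length.out = n_amp)
  ny <- reco$years
  members <- list()
  for (sh in shifts) {
    for (sc in scales) {
      vals <- reco$values
      if (sh != 0 || sc != 1) {
        for (yy in seq_len(ny)) {
          iy <- (yy - 1) * 12 + 1:12
          v0 <- reco$values[iy]
          v <- .shift_months(v0, sh)
          m <- mean(v)
          v <- m + sc * (v - m)
          v <- v + (sum(v0) - sum(v)) / 12
          vals[iy] <- v
        }
      }
      members[[length(members) + 1]] <- structure(
        list(phase_shift = sh, amplitude_scale = sc,
             series = flux_series(vals, reco$start_year, reco$kind,
                                  reco$region)),
        class = "perturbation_member")
    }
  }
  members
}

#' Detrended seasonal amplitude
#'
#' Removes an ordinary least-squares linear trend from a monthly series and
#' returns the difference between the maximum and minimum residuals.
#'
#' @param series numeric monthly values (>= 24 months) or a [flux_series()];
#'   for concentration series, ppm.
#' @param epoch optional `c(first, last)` year indices (1-based within the
#'   series) to which the series is restricted (detrending is per-epoch).
#' @return object of class `asc_result`: list with `amplitude`, `epoch`,
#'   `n_months`.
#' @export
seasonal_amplitude <- function(series, epoch = NULL) {
  v <- if (inherits(series, "flux_series")) series$values else as.numeric(series)
  if (!is.null(epoch)) {
    stopifnot(length(epoch) == 2, epoch[1] >= 1)
    v <- v[((epoch[1] - 1) * 12 + 1):(epoch[2] * 12)]
  }
  if (length(v) < 24) {
    stop("need at least 24 months to estimate a seasonal amplitude",
         call. = FALSE)
  }
  t <- seq_along(v)
  r <- stats::lm.fit(cbind(1, t), v)$residuals
  structure(list(amplitude = max(r) - min(r), epoch = epoch,
                 n_months = length(v)),
            class = "asc_result")
}

#' One-box Northern-Hemisphere CO2 concentration surrogate
#'
#' Monthly Euler integration of `dC/dt = -F/kappa - (C - C_background)/tau`:
#' a positive land sink draws the box concentration down, while mixing with
#' the background relaxes it at timescale `tau_mix`. Stands in for full
#' atmospheric tracer transport, which is outside the scope of this package.
#'
#' @param nls a [flux_series()] of the northern (>= 30 degN) net land sink
#'   (PgC month-1), or a numeric monthly vector.
#' @param kappa airborne conversion factor (PgC per ppm; default 2.124).
#' @param tau_mix mixing timescale (months; default 24).
#' @param c0 initial concentration (ppm).
#' @param c_background background concentration (ppm); default `c0`.
#' @return numeric monthly concentration series (ppm), same length as the
#'   flux.
#' @export
surrogate_concentration <- function(nls, kappa = 2.124, tau_mix = 24,
                                    c0 = 400, c_background = c0) {
  f <- if (inherits(nls, "flux_series")) nls$values else as.numeric(nls)
  n <- length(f)
  conc <- numeric(n)
  cc <- c0
  for (t in seq_len(n)) {
    conc[t] <- cc
    cc <- cc - f[t] / kappa - (cc - c_background) / tau_mix
  }
  conc
}

#' Select ensemble members matching an observed seasonal amplitude
#'
#' @param member_asc numeric vector of the members' seasonal-cycle
#'   amplitudes (ppm) for the reference epoch.
#' @param observed_asc observed amplitude (ppm).
#' @param tol tolerance (ppm; default 3).
#' @return integer indices of members with `|ASC - observed| <= tol`
#'   (possibly empty).
#' @export
select_members <- function(member_asc, observed_asc, tol = 3) {
  which(abs(member_asc - observed_asc) <= tol)
}

#' Relative change in seasonal amplitude between two epochs
#'
#' @param epoch1,epoch2 [seasonal_amplitude()] results or bare amplitudes.
#' @return percentage change `100 * (A2 - A1) / A1`.
#' @export
asc_change <- function(epoch1, epoch2) {
  a1 <- if (inherits(epoch1, "asc_result")) epoch1$amplitude else epoch1
  a2 <- if (inherits(epoch2, "asc_result")) epoch2$amplitude else epoch2
  if (a1 <= 0) stop("baseline amplitude must be positive", call. = FALSE)
  100 * (a2 - a1) / a1
}

#' Read/write monthly flux CSV (year, month, value_PgC)
#'
#' @param path file path.
#' @param kind,region passed to [flux_series()].
#' @return a [flux_series()].
#' @export
read_flux_csv <- function(path, kind = "gpp", region = "nh") {
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "month", "value_PgC") %in% names(d)))
  d <- d[order(d$year, d$month), ]
  flux_series(d$value_PgC, start_year = d$year[1], kind = kind,
              region = region)
}

#' @rdname read_flux_csv
#' @param fs a [flux_series()] to write.
#' @export
write_flux_csv <- function(fs, path) {
  d <- data.frame(year = rep(fs$start_year + seq_len(fs$years) - 1, each = 12),
                  month = rep(1:12, fs$years), value_PgC = fs$values)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
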