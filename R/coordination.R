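#' Effective leaf nitrogen
#'
#' The nitrogen-like conserved quantity of the coordination scheme:
#' `Neff = Vcmax0 + c_cost * Jmax0`, the sum of the two capacity priors at
#' 25 degC weighted by the relative nitrogen cost of electron-transport
#' capacity.
#'
#' @param vcmax0 carboxylation capacity at 25 degC (umol m-2 s-1).
#' @param jmax0 electron-transport capacity at 25 degC (umol m-2 s-1).
#' @param c_cost relative cost of Jmax vs Vcmax (dimensionless).
#' @return Neff in capacity units (umol m-2 s-1 equivalent). Vectorised.
#' @export
effective_nitrogen <- function(vcmax0, jmax0, c_cost) {
  stopifnot(all(vcmax0 > 0), all(jmax0 >= 0), all(c_cost >= 0))
  vcmax0 + c_cost * jmax0
}

#' Coordination state
#'
#' Holds the current capacities at 25 degC, their ratio `bJV = Jmax0/Vcmax0`
#' and the conserved effective nitrogen `Neff = Vcmax0 + c_cost*Jmax0`.
#' All fields may be vectors (one element per cell).
#'
#' @param vcmax0,jmax0 capacities at 25 degC (umol m-2 s-1).
#' @param c_cost relative nitrogen cost of Jmax (defaults to the shipped
#'   calibrated constant 0.746).
#' @return object of class `coordination_state`.
#' @export
coordination_state <- function(vcmax0, jmax0, c_cost = 0.746) {
  stopifnot(all(vcmax0 > 0), all(jmax0 > 0), length(vcmax0) == length(jmax0))
  structure(list(Vcmax0 = vcmax0, Jmax0 = jmax0,
                 bJV = jmax0 / vcmax0,
                 Neff = effective_nitrogen(vcmax0, jmax0, c_cost),
                 c_cost = c_cost),
            class = "coordination_state")
}

#' Five-day history of sub-diurnal leaf meteorology
#'
#' A ring buffer holding `days` (default 5) days of sub-diurnal leaf-level
#' conditions for sunlit and shaded leaves, from which accumulated
#' photosynthesis can be reconstructed for any candidate capacity
#' allocation. Appending beyond capacity evicts the oldest day. Supports
#' multiple cells (one row per cell in every stored matrix).
#'
#' @param ncells number of cells tracked in parallel.
#' @param steps_per_day sub-diurnal steps per day.
#' @param step_hours duration of one step (hours).
#' @param days history length in days.
#' @return object of class `met_history`.
#' @export
met_history <- function(ncells = 1, steps_per_day = 8, step_hours = 3,
                        days = 5) {
  stopifnot(ncells >= 1, steps_per_day >= 1, step_hours > 0, days >= 1)
  cap <- days * steps_per_day
  m0 <- function(k = 1) matrix(0, ncells, cap * k)
  structure(list(
    ncells = ncells, steps_per_day = steps_per_day,
    step_hours = step_hours, days = days, capacity = cap,
    day_count = 0, slot_next = 1, day_times = rep(NA_real_, days),
    # raw met (ncells x capacity)
    apar_sun = m0(), apar_sha = m0(), fsun = m0(),
    tleaf = m0(), vpd = m0(), cs = m0(), stress = m0(),
    # derived, class-expanded (ncells x 2*capacity): sunlit block then shaded
    FTVFC = m0(2), FTJ = m0(2), FTRD = m0(2), AI = m0(2), FJ4 = m0(2),
    WT = m0(2)
  ), class = "met_history")
}

.as_hist_mat <- function(x, ncells, spd) {
  if (is.matrix(x)) {
    stopifnot(nrow(x) == ncells, ncol(x) == spd)
    x
  } else {
    matrix(rep(x, length.out = ncells * spd), ncells, spd, byrow = (ncells > 1))
  }
}

#' Append one day of leaf meteorology to a history
#'
#' Arguments may be matrices (`ncells` x `steps_per_day`) or vectors recycled
#' across cells. Derived photosynthetic factors (temperature scalings,
#' intercellular CO2 from the stomatal closure of `p`, and the CO2-dependent
#' factors of the Rubisco- and electron-transport-limited rates) are
#' precomputed at append time so the coordination objective is cheap to
#' evaluate for any candidate `bJV`.
#'
#' @param h a [met_history()].
#' @param apar_sun,apar_sha absorbed PAR per unit sunlit/shaded leaf area.
#' @param fsun sunlit leaf-area fraction in \[0, 1\].
#' @param tleaf leaf temperature (degC); `vpd` (kPa); `cs` (umol/mol).
#' @param stress multiplicative assimilation stress factor in \[0, 1\].
#' @param p the [leaf_params()] providing stomatal closure, alpha/theta and
#'   temperature responses.
#' @param day_time a strictly increasing day stamp (defaults to
#'   `day_count + 1`).
#' @return the updated history.
#' @export
history_append_day <- function(h, apar_sun, apar_sha = 0, fsun = 1,
                               tleaf = 25, vpd = 1, cs = 400, stress = 1,
                               p = leaf_params(), day_time = NULL) {
  stopifnot(inherits(h, "met_history"))
  nc <- h$ncells; spd <- h$steps_per_day
  if (is.null(day_time)) day_time <- h$day_count + 1
  if (h$day_count > 0 && day_time <= max(h$day_times, na.rm = TRUE)) {
    stop("day_time must be strictly increasing", call. = FALSE)
  }
  apar_sun <- .as_hist_mat(apar_sun, nc, spd)
  apar_sha <- .as_hist_mat(apar_sha, nc, spd)
  fsun <- .as_hist_mat(fsun, nc, spd)
  tleaf <- .as_hist_mat(tleaf, nc, spd)
  vpd <- .as_hist_mat(vpd, nc, spd)
  cs <- .as_hist_mat(cs, nc, spd)
  stress <- .as_hist_mat(stress, nc, spd)
  stopifnot(all(fsun >= 0 & fsun <= 1))

  s <- h$slot_next
  cols <- (s - 1L) * spd + seq_len(spd)
  h$apar_sun[, cols] <- apar_sun; h$apar_sha[, cols] <- apar_sha
  h$fsun[, cols] <- fsun; h$tleaf[, cols] <- tleaf
  h$vpd[, cols] <- vpd; h$cs[, cols] <- cs; h$stress[, cols] <- stress

  k <- kinetic_constants(tleaf)
  ft <- capacity_temp_factors(tleaf)
  chi <- if (!is.null(p$chi_fixed)) p$chi_fixed else p$g1 / (p$g1 + sqrt(pmax(vpd, 1e-6)))
  ci <- chi * cs
  fc <- (ci - k$gamma_star) / (ci + k$Km_eff)
  fj4 <- (ci - k$gamma_star) / (ci + 2 * k$gamma_star) / 4
  dt_sec <- h$step_hours * 3600

  csun <- cols; csha <- h$capacity + cols
  h$FTVFC[, csun] <- ft$vcmax * fc;       h$FTVFC[, csha] <- ft$vcmax * fc
  h$FTJ[, csun] <- ft$jmax;               h$FTJ[, csha] <- ft$jmax
  h$FTRD[, csun] <- ft$rd;                h$FTRD[, csha] <- ft$rd
  h$AI[, csun] <- p$alpha * apar_sun;     h$AI[, csha] <- p$alpha * apar_sha
  h$FJ4[, csun] <- fj4;                   h$FJ4[, csha] <- fj4
  h$WT[, csun] <- fsun * stress * dt_sec
  h$WT[, csha] <- (1 - fsun) * stress * dt_sec

  h$day_times[s] <- day_time
  h$day_count <- h$day_count + 1L
  h$slot_next <- if (s == h$days) 1L else s + 1L
  h
}

.history_valid_cols <- function(h) {
  nd <- min(h$day_count, h$days)
  v <- seq_len(nd * h$steps_per_day)
  c(v, h$capacity + v)
}

# Fast weighted assimilation totals (umol m-2 over the history) for a vector
# of candidate bJV, one per cell. Shared by accumulated_photosynthesis and
# the optimizer. When the ring buffer is full no subsetting is done (the hot
# path of the daily optimization).
.coord_total <- function(bjv, neff, h, p, net = FALSE) {
  vc0 <- neff / (1 + p$c_cost_JV * bjv)
  jm0 <- bjv * vc0
  full <- h$day_count >= h$days
  if (full) {
    FTVFC <- h$FTVFC; FTJ <- h$FTJ; AI <- h$AI; FJ4 <- h$FJ4; WT <- h$WT
  } else {
    cols <- .history_valid_cols(h)
    FTVFC <- h$FTVFC[, cols, drop = FALSE]
    FTJ <- h$FTJ[, cols, drop = FALSE]
    AI <- h$AI[, cols, drop = FALSE]
    FJ4 <- h$FJ4[, cols, drop = FALSE]
    WT <- h$WT[, cols, drop = FALSE]
  }
  ac <- FTVFC * vc0                       # recycles vc0 down rows (cells)
  jm <- FTJ * jm0
  b <- AI + jm
  th <- p$theta
  j <- if (th == 0) {
    AI * jm / pmax(AI + jm, 1e-12)
  } else {
    disc <- b * b - 4 * th * AI * jm
    disc[disc < 0] <- 0
    (b - sqrt(disc)) / (2 * th)
  }
  aj <- j * FJ4
  a <- if (is.null(p$colimit_theta)) {
    pmin(ac, aj)
  } else {
    ss <- ac + aj
    disc <- ss * ss - 4 * p$colimit_theta * ac * aj
    disc[disc < 0] <- 0
    (ss - sqrt(disc)) / (2 * p$colimit_theta)
  }
  if (net) {
    ftrd <- if (full) h$FTRD else h$FTRD[, .history_valid_cols(h), drop = FALSE]
    a <- a - (p$rd25 / p$vcmax25) * vc0 * ftrd
  }
  rowSums(a * WT)
}

#' Accumulated photosynthesis over the history for a candidate allocation
#'
#' Given the conserved effective nitrogen and a candidate `bJV`, the implied
#' capacities `Vcmax0 = Neff/(1 + c_cost*bJV)`, `Jmax0 = bJV*Vcmax0` are
#' applied to every record of the 5-day history (sunlit and shaded leaves,
#' weighted by the sunlit fraction and any stress factor) and integrated.
#'
#' @param bJV candidate ratio(s), one per cell.
#' @param neff effective nitrogen per cell (umol m-2 s-1 equivalent).
#' @param history a [met_history()] with at least one appended day.
#' @param p a [leaf_params()].
#' @param net if `TRUE`, day respiration (scaled from `p$rd25/p$vcmax25`)
#'   is subtracted; the default accumulates gross assimilation.
#' @return mol C m-2 accumulated over the stored days (vector, per cell).
#' @export
accumulated_photosynthesis <- function(bJV, neff, history, p, net = FALSE) {
  stopifnot(inherits(history, "met_history"))
  if (history$day_count == 0) stop("history is empty", call. = FALSE)
  .coord_total(bJV, neff, history, p, net = net) * 1e-6
}

#' Optimize the Jmax:Vcmax ratio over a meteorology history
#'
#' Finds `bJV*` maximizing accumulated photosynthesis per unit effective
#' nitrogen over the bounded interval, by a 9-point bracketing scan followed
#' by golden-section refinement (one objective evaluation per iteration,
#' vectorised across cells). If the scan shows more than one interior local
#' maximum the affected cells fall back to a dense 2001-point grid search
#' with a warning. Boundary optima are returned as the boundary value.
#'
#' @inheritParams accumulated_photosynthesis
#' @param bounds admissible `bJV` interval.
#' @param tol absolute tolerance on the returned ratio.
#' @return numeric vector `bJV*`, one per cell, with the objective value at
#'   the optimum in attribute `"objective"`.
#' @export
optimize_bjv <- function(neff, history, p, bounds = p$bJV_bounds,
                         tol = 1e-4, net = FALSE) {
  stopifnot(inherits(history, "met_history"))
  if (history$day_count == 0) stop("history is empty", call. = FALSE)
  nc <- history$ncells
  stopifnot(length(neff) == nc)
  f <- function(b) .coord_total(b, neff, history, p, net = net) / neff

  nscan <- 9L
  xs <- seq(bounds[1], bounds[2], length.out = nscan)
  fs <- matrix(0, nc, nscan)
  for (i in seq_len(nscan)) fs[, i] <- f(rep(xs[i], nc))

  # non-unimodality: more than one sign change in the first differences,
  # judged against a scale-relative tolerance so flat plateaus do not
  # register as structure
  fscale <- pmax(apply(abs(fs), 1, max), 1e-300)
  d <- (fs[, -1, drop = FALSE] - fs[, -nscan, drop = FALSE]) / fscale
  dsign <- sign(d) * (abs(d) > 1e-9)
  nswitch <- rowSums(abs(dsign[, -1, drop = FALSE] -
                           dsign[, -(nscan - 1), drop = FALSE]) > 1)
  multimodal <- nswitch > 1

  best <- max.col(fs, ties.method = "first")
  lo <- xs[pmax(best - 1L, 1L)]
  hi <- xs[pmin(best + 1L, nscan)]

  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  niter <- ceiling(log(tol / max(hi - lo)) / log(gr))
  for (it in seq_len(max(niter, 1))) {
    m <- f1 < f2
    lo[m] <- x1[m]; x1[m] <- x2[m]; f1[m] <- f2[m]
    hi[!m] <- x2[!m]; x2[!m] <- x1[!m]; f2[!m] <- f1[!m]
    xe <- ifelse(m, lo + gr * (hi - lo), hi - gr * (hi - lo))
    fe <- f(xe)
    x2[m] <- xe[m]; f2[m] <- fe[m]
    x1[!m] <- xe[!m]; f1[!m] <- fe[!m]
  }
  bstar <- ifelse(f1 > f2, x1, x2)
  fstar <- pmax(f1, f2)

  # boundary optima win ties (to within a scale-relative tolerance)
  btol <- 1e-9 * fscale
  blo <- fs[, 1] >= fstar - btol
  bhi <- fs[, nscan] >= fstar - btol
  bstar[blo] <- bounds[1]; fstar[blo] <- fs[blo, 1]
  bstar[bhi] <- bounds[2]; fstar[bhi] <- fs[bhi, nscan]

  if (any(multimodal)) {
    warning("non-unimodal coordination objective detected; ",
            "falling back to dense grid search for ", sum(multimodal),
            " cell(s)", call. = FALSE)
    grid <- seq(bounds[1], bounds[2], length.out = 2001L)
    gbest <- rep(-Inf, nc); garg <- bstar
    for (g in grid) {
      fg <- f(rep(g, nc))
      upd <- multimodal & fg > gbest
      gbest[upd] <- fg[upd]; garg[upd] <- g
    }
    upd <- multimodal & gbest > fstar
    bstar[upd] <- garg[upd]; fstar[upd] <- gbest[upd]
  }
  attr(bstar, "objective") <- fstar
  bstar
}

#' End-of-day coordination update
#'
#' Re-optimizes `bJV` against the current 5-day history and redistributes
#' capacities accordingly. `Neff` is conserved exactly.
#'
#' @param state a [coordination_state()].
#' @param history a [met_history()].
#' @param p a [leaf_params()].
#' @param net optimize net instead of gross accumulated photosynthesis.
#' @return the updated `coordination_state`.
#' @export
daily_update <- function(state, history, p, net = FALSE) {
  stopifnot(inherits(state, "coordination_state"))
  b <- as.numeric(optimize_bjv(state$Neff, history, p, net = net))
  vc0 <- state$Neff / (1 + state$c_cost * b)
  structure(list(Vcmax0 = vc0, Jmax0 = b * vc0, bJV = b,
                 Neff = state$Neff, c_cost = state$c_cost),
            class = "coordination_state")
}

#' Disable coordination (fixed low Jmax:Vcmax ratio)
#'
#' Returns leaf parameters configured so electron transport always limits:
#' `bJV` fixed at 1.3 and `Vcmax25` scaled up by 1.25 (compensating present-
#' day assimilation for the loss of the optimization).
#'
#' @param p a [leaf_params()].
#' @return modified `leaf_params`.
#' @export
exclude_coordination <- function(p) {
  leaf_params(vcmax25 = 1.25 * p$vcmax25, bJV = 1.3,
              rd25 = p$rd25, alpha = p$alpha, theta = p$theta,
              chi_fixed = p$chi_fixed, g1 = p$g1,
              c_cost_JV = p$c_cost_JV, bJV_bounds = p$bJV_bounds,
              colimit_theta = p$colimit_theta)
}

#' Spin up coordination to its fixed point under a repeating day
#'
#' Prefills the history with the supplied leaf-level day and applies the
#' end-of-day update for `days` days (the day repeats, emulating stationary
#' forcing). The first optimization happens at day 5, once the history
#' contains five genuinely appended days.
#'
#' @param day list with vectors (one per sub-diurnal step): `apar`, `tleaf`,
#'   `vpd`, `cs`, and scalar `step_hours`.
#' @param p a [leaf_params()].
#' @param neff effective nitrogen to hold fixed.
#' @param days number of simulated days (default 30).
#' @param bjv_init initial ratio (default the `p$bJV` prior).
#' @param net optimize net photosynthesis instead of gross.
#' @return final `coordination_state`, with attributes `history` (the final
#'   [met_history()]), `delta_bjv` (last daily change) and `trajectory`
#'   (per-day `bJV`).
#' @export
equilibrate_coordination <- function(day, p, neff, days = 30,
                                     bjv_init = p$bJV, net = FALSE) {
  spd <- length(day$apar)
  h <- met_history(1, spd, day$step_hours)
  for (i in 1:5) {
    h <- history_append_day(h, apar_sun = day$apar, apar_sha = 0, fsun = 1,
                            tleaf = day$tleaf, vpd = day$vpd, cs = day$cs,
                            p = p, day_time = i - 5)
  }
  vc0 <- neff / (1 + p$c_cost_JV * bjv_init)
  st <- coordination_state(vc0, bjv_init * vc0, p$c_cost_JV)
  traj <- numeric(days)
  prev <- st$bJV
  delta <- NA_real_
  for (d in seq_len(days)) {
    h <- history_append_day(h, apar_sun = day$apar, apar_sha = 0, fsun = 1,
                            tleaf = day$tleaf, vpd = day$vpd, cs = day$cs,
                            p = p, day_time = d)
    if (d >= 5) {
      st <- daily_update(st, h, p, net = net)
      delta <- abs(st$bJV - prev)
      prev <- st$bJV
    }
    traj[d] <- st$bJV
  }
  attr(st, "history") <- h
  attr(st, "delta_bjv") <- delta
  attr(st, "trajectory") <- traj
  st
}

#' Emergent co-limitation diagnostics
#'
#' Evaluates the history at the state's capacities and reports two views of
#' the balance between the Rubisco- and electron-transport-limited rates:
#'
#' * `ratio_growth` — the growth-condition mean Ac/Aj ratio, i.e. the
#'   assimilation-weighted means of the two potential rates over the history
#'   (the leaf-trait co-limitation diagnostic; near 1 when coordination
#'   holds). This is the robust metric: at the optimum the bright hours sit
#'   on the Ac = Aj knife edge.
#' * `total_rubisco` / `total_etr` — the weighted assimilation totals over
#'   records where the Rubisco-limited (resp. electron-transport-limited)
#'   rate is the lesser, with records whose rates agree within 1% split
#'   equally between the two sides; `ratio` is their quotient. Because the
#'   classification of near-co-limited records is a knife edge, this ratio
#'   is far noisier than `ratio_growth`.
#'
#' @param state a [coordination_state()].
#' @param history a [met_history()].
#' @param p a [leaf_params()].
#' @return list with `ratio_growth`, `total_rubisco`, `total_etr`
#'   (mol C m-2) and `ratio` (vectors, per cell).
#' @export
colimitation_summary <- function(state, history, p) {
  cols <- .history_valid_cols(history)
  vc0 <- state$Vcmax0; jm0 <- state$Jmax0
  FTVFC <- history$FTVFC[, cols, drop = FALSE]
  AI <- history$AI[, cols, drop = FALSE]
  jm <- history$FTJ[, cols, drop = FALSE] * jm0
  b <- AI + jm
  th <- p$theta
  j <- (b - sqrt(pmax(b * b - 4 * th * AI * jm, 0))) / (2 * th)
  ac <- FTVFC * vc0
  aj <- j * history$FJ4[, cols, drop = FALSE]
  a <- pmin(ac, aj)
  w <- history$WT[, cols, drop = FALSE]
  wa <- w * a
  wa[a <= 0] <- 0
  ratio_growth <- rowSums(wa * ac) / rowSums(wa * aj)
  near <- abs(ac - aj) <= 0.01 * pmax(abs(ac), abs(aj))
  isc <- (ac < aj & !near) + 0.5 * near
  tc <- rowSums(a * w * isc) * 1e-6
  tj <- rowSums(a * w * (1 - isc)) * 1e-6
  list(ratio_growth = ratio_growth,
       total_rubisco = tc, total_etr = tj, ratio = tc / tj)
}
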