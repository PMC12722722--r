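#' Count complete channel traversals in a trajectory
#'
#' A traversal (permeation event) is registered when the particle, having
#' last been outside the slab `[z_lo, z_hi]` on one side, next appears
#' outside it on the opposite side — regardless of how long it lingered
#' inside. Re-exit through the entry side resets the state without
#' counting, and repeated same-side boundary chatter never increments.
#' Equivalently: drop all in-slab frames, compress consecutive same-side
#' labels, and count side changes.
#'
#' @param trace a `trace` object (see [simulate_langevin_1d()]).
#' @param z_lo,z_hi slab boundaries (A), z_lo < z_hi.
#' @return a `crossing_count`: list with `events` (both directions),
#'   `up`, `down`, `observation_time` (ns), labels, and `inside_only`
#'   (TRUE with a warning when the trace never leaves the slab).
#' @export
count_crossings <- function(trace, z_lo, z_hi) {
  stopifnot(inherits(trace, "trace"), z_lo < z_hi)
  side <- ifelse(trace$z < z_lo, -1L, ifelse(trace$z > z_hi, 1L, 0L))
  s <- side[side != 0L]
  inside_only <- length(s) == 0L
  if (inside_only) {
    warning("trace never leaves the slab [z_lo, z_hi]; zero events")
    up <- down <- 0L
  } else {
    chg <- which(diff(s) != 0L)
    up <- sum(s[chg] == -1L)
    down <- sum(s[chg] == 1L)
  }
  structure(list(events = up + down, up = up, down = down,
                 observation_time = max(trace$time) - min(trace$time),
                 monomer = trace$monomer, replicate = trace$replicate,
                 inside_only = inside_only),
            class = "crossing_count")
}

#' @export
print.crossing_count <- function(x, ...) {
  cat(sprintf("crossing_count: %d events (%d up, %d down) in %.4g ns\n",
              x$events, x$up, x$down, x$observation_time))
  invisible(x)
}

#' Per-monomer permeation rate with bootstrap SEM
#'
#' Each (monomer, replicate) group contributes events/observation_time;
#' the headline rate is the mean over groups and its SEM is estimated by
#' [bootstrap_band()] over groups. Both crossing directions count toward
#' the rate (equilibrium flux); per-direction rates are also reported.
#'
#' @param counts list of `crossing_count` objects (one per group).
#' @param n_boot bootstrap resamples.
#' @param seed integer RNG seed.
#' @return list with `rate` (ns^-1 per monomer), `sem`, `rate_up`,
#'   `rate_down`, and `per_group` (data frame of group rates).
#' @export
permeation_rate <- function(counts, n_boot = 1000L, seed = 1L) {
  stopifnot(length(counts) >= 1,
            all(vapply(counts, inherits, logical(1), "crossing_count")))
  times <- vapply(counts, `[[`, numeric(1), "observation_time")
  if (any(times <= 0)) stop("observation time must be positive")
  per_group <- data.frame(
    monomer = vapply(counts, function(x) as.character(x$monomer), character(1)),
    replicate = vapply(counts, function(x) as.character(x$replicate), character(1)),
    events = vapply(counts, `[[`, numeric(1), "events"),
    up = vapply(counts, `[[`, numeric(1), "up"),
    down = vapply(counts, `[[`, numeric(1), "down"),
    time_ns = times
  )
  per_group$rate <- per_group$events / per_group$time_ns
  rates <- per_group$rate
  sem <- if (length(rates) >= 2) bootstrap_band(rates, n_boot, seed) else NA_real_
  list(rate = mean(rates), sem = sem,
       rate_up = mean(per_group$up / per_group$time_ns),
       rate_down = mean(per_group$down / per_group$time_ns),
       per_group = per_group)
}

#' Kramers-style barrier-crossing rate
#'
#' Computes the diffusive barrier-crossing rate
#' \deqn{k \approx (D/\delta^2)\, e^{-\Delta G^\ddagger / k_B T}}
#' where D is the in-pore diffusion coefficient, delta the pore length and
#' dG the barrier height from the free-energy profile. With the defaults
#' (delta = 50 A, i.e. 5 nm; kT at 300 K) this converts PMF barriers into
#' per-channel permeation rates.
#'
#' @param barrier barrier height dG (kJ/mol).
#' @param D in-pore diffusion coefficient (A^2/ns).
#' @param pore_length delta (A), default 50 (5 nm).
#' @param kT thermal energy (kJ/mol).
#' @return rate in ns^-1.
#' @examples
#' kramers_rate(10, D = 100, pore_length = 50, kT = 2.494) # 7.25e-4
#' @export
kramers_rate <- function(barrier, D, pore_length = 50, kT = kT_at(300)) {
  stopifnot(D > 0, pore_length > 0, kT > 0)
  (D / pore_length^2) * exp(-barrier / kT)
}

#' Ratio of Kramers rates for two solutes
#'
#' The pore length cancels, leaving
#' \deqn{k_a / k_b = (D_a/D_b)\, e^{(\Delta G_b - \Delta G_a)/kT}.}
#' With water and glycerol barriers of ~10 and ~23 kJ/mol and glycerol
#' diffusing 3 times slower, this gives a water:glycerol rate ratio of
#' roughly 500.
#'
#' @param barrier_a,barrier_b barrier heights (kJ/mol) for solutes a, b.
#' @param diffusion_ratio D_a / D_b (dimensionless).
#' @param kT thermal energy (kJ/mol).
#' @return k_a / k_b.
#' @export
solute_rate_ratio <- function(barrier_a, barrier_b, diffusion_ratio = 1,
                              kT = kT_at(300)) {
  stopifnot(kT > 0, diffusion_ratio > 0)
  diffusion_ratio * exp((barrier_b - barrier_a) / kT)
}
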