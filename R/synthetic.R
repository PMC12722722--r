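#' Overdamped Langevin (Brownian dynamics) simulation in one dimension
#'
#' Propagates `z(t)` by the Euler-Maruyama update
#' \deqn{z \leftarrow z - (D\,dt/kT)\, dU/dz + \sqrt{2 D\, dt}\,\xi}
#' with standard-normal noise and reflecting boundaries at the domain
#' edges. This is the synthetic stand-in for a solute diffusing along the
#' channel axis; it reproduces Boltzmann statistics in the supplied
#' potential and so provides exact ground truth for the WHAM and kinetics
#' estimators.
#'
#' @param potential a [potential_spec()].
#' @param D diffusion coefficient (A^2/ns). The default of 230 A^2/ns is
#'   the self-diffusion of bulk water at 300 K.
#' @param dt time step (ns). Must be small enough that the drift per step
#'   is a small fraction of the domain.
#' @param kT thermal energy (kJ/mol), default 300 K.
#' @param n_steps number of integration steps.
#' @param init_z starting position (A), inside the domain.
#' @param seed integer RNG seed; identical seeds give bit-identical traces.
#' @param bias_k optional harmonic bias spring constant in kJ/mol/A^2
#'   (0 disables the bias).
#' @param bias_center center of the harmonic bias (A).
#' @param sample_every record every `sample_every`-th step.
#' @param monomer,replicate labels attached to the returned trace.
#' @return a `trace` object: list with `time` (ns), `z` (A), `monomer`,
#'   `replicate`.
#' @examples
#' pot <- potential_spec(domain = c(-10, 10))
#' tr <- simulate_langevin_1d(pot, D = 100, dt = 1e-4, n_steps = 1000,
#'                            init_z = 0, seed = 1)
#' @export
simulate_langevin_1d <- function(potential, D = 230, dt = 2e-5,
                                 kT = kT_at(300), n_steps = 1e5L,
                                 init_z = 0, seed = 1L, bias_k = 0,
                                 bias_center = 0, sample_every = 1L,
                                 monomer = 1L, replicate = 1L) {
  stopifnot(inherits(potential, "potential_spec"),
            D > 0, dt > 0, kT > 0, n_steps >= 1)
  dom <- potential$domain
  if (init_z < dom[1] || init_z > dom[2]) {
    stop("init_z must lie within the potential domain")
  }
  z <- with_seed(seed, langevin_core(
    potential$heights, potential$centers, potential$widths,
    dom[1], dom[2], D, dt, kT, init_z, as.integer(n_steps),
    bias_k, bias_center, as.integer(sample_every)
  ))
  new_trace(time = dt * sample_every * seq_along(z), z = z,
            monomer = monomer, replicate = replicate)
}

new_trace <- function(time, z, monomer = 1L, replicate = 1L) {
  stopifnot(length(time) == length(z), !is.unsorted(time, strictly = TRUE))
  structure(list(time = time, z = z, monomer = monomer,
                 replicate = replicate),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat(sprintf("trace: %d frames over %.4g ns (monomer %s, replicate %s)\n",
              length(x$z), max(x$time) - min(x$time),
              as.character(x$monomer), as.character(x$replicate)))
  invisible(x)
}

#' Generate a ladder of umbrella-sampling windows over a known potential
#'
#' Simulates one biased window per center, with harmonic bias
#' `0.5 k (z - c)^2`, mirroring the usual umbrella protocol of windows
#' spaced 1 A apart under a 2000 kJ/mol/nm^2 restraint. The first
#' `equilibration_fraction` of each window is discarded, matching the
#' common practice of dropping the initial tenth of each window as
#' equilibration.
#'
#' Two samplers are available. The default, `method = "mc"`, is an
#' independence-Metropolis sampler: proposals come from the bias Gaussian
#' `N(c, kT/k)` and are accepted with the Boltzmann factor of the
#' unbiased potential, so each window's samples follow the biased
#' distribution exactly, with no integrator discretization error and near
#' unit statistical efficiency (on a flat potential every proposal is
#' accepted and the draws are iid). `method = "langevin"` instead runs
#' the overdamped integrator of [simulate_langevin_1d()] under the bias;
#' its samples carry the integrator's correlation time and small-`dt`
#' discretization bias, which is the realistic but noisier regime.
#'
#' @inheritParams simulate_langevin_1d
#' @param centers sorted vector of window centers (A).
#' @param spring_k harmonic restraint in kJ/mol/nm^2 (default 2000).
#' @param steps_per_window samples (MC) or integrator steps (Langevin)
#'   per window.
#' @param method `"mc"` (exact Metropolis, default) or `"langevin"`.
#' @param equilibration_fraction fraction of each window discarded (0.1).
#' @param seed integer seed; window i uses seed + i - 1.
#' @return list of `umbrella_window` objects (see [umbrella_window()]).
#' @export
generate_umbrella_dataset <- function(potential, centers,
                                      spring_k = 2000,
                                      steps_per_window = 1e5L,
                                      method = c("mc", "langevin"),
                                      D = 230, dt = 2e-5, kT = kT_at(300),
                                      equilibration_fraction = 0.1,
                                      seed = 1L, monomer = 1L,
                                      replicate = 1L) {
  method <- match.arg(method)
  stopifnot(!is.unsorted(centers), spring_k > 0,
            equilibration_fraction >= 0, equilibration_fraction < 1)
  k_A2 <- spring_nm2_to_A2(spring_k)
  n_keep_from <- floor(steps_per_window * equilibration_fraction) + 1
  dom <- potential$domain
  lapply(seq_along(centers), function(i) {
    c_i <- centers[i]
    zs <- if (method == "mc") {
      with_seed(seed + i - 1, umbrella_mc_core(
        potential$heights, potential$centers, potential$widths,
        dom[1], dom[2], kT, k_A2, c_i, as.integer(steps_per_window), c_i))
    } else {
      simulate_langevin_1d(potential, D = D, dt = dt, kT = kT,
                           n_steps = steps_per_window, init_z = c_i,
                           seed = seed + i - 1, bias_k = k_A2,
                           bias_center = c_i)$z
    }
    samples <- zs[n_keep_from:length(zs)]
    if (!length(samples)) {
      stop(sprintf("window %d (center %.2f A) empty after equilibration discard",
                   i, c_i))
    }
    umbrella_window(center = c_i, spring_k = spring_k, samples = samples,
                    monomer = monomer, replicate = replicate,
                    equilibration_discarded = (n_keep_from - 1) * dt)
  })
}

#' A single umbrella-sampling window
#'
#' @param center window center c (A).
#' @param spring_k harmonic restraint (kJ/mol/nm^2, as printed in MD
#'   protocols); the bias is w(z) = 0.5 k (z - c)^2.
#' @param samples sampled z values (A) after equilibration discard.
#' @param monomer,replicate group labels.
#' @param equilibration_discarded time discarded (ns), metadata only.
#' @return an `umbrella_window` object.
#' @export
umbrella_window <- function(center, spring_k, samples, monomer = 1L,
                            replicate = 1L, equilibration_discarded = 0) {
  stopifnot(is.numeric(center), length(center) == 1,
            is.numeric(spring_k), spring_k > 0, length(samples) >= 1,
            all(is.finite(samples)))
  structure(list(center = center, spring_k = spring_k,
                 samples = as.numeric(samples), monomer = monomer,
                 replicate = replicate,
                 equilibration_discarded = equilibration_discarded),
            class = "umbrella_window")
}

#' Construct a trajectory with an exact number of channel traversals
#'
#' Builds a piecewise path executing exactly `n_events` complete
#' traversals of the slab `[z_lo, z_hi]`, interleaved with non-crossing
#' excursions that enter the slab and retreat through the entry side, plus
#' additive Gaussian jitter. The base path dwells well outside the slab
#' (margin of half the slab width) and crosses it between consecutive
#' samples, and the jitter is clipped at 2.5 standard deviations, so the
#' constructed traversal count is exact by construction and the fixture
#' serves as ground truth for [count_crossings()].
#'
#' @param n_events number of complete traversals (>= 0).
#' @param channel_bounds numeric `(z_lo, z_hi)` (A), z_lo < z_hi.
#' @param duration total trace length (ns).
#' @param noise_sd jitter standard deviation (A); must be below one eighth
#'   of the slab width, larger values would create spurious boundary
#'   chatter and are rejected.
#' @param seed integer RNG seed.
#' @param n_excursions number of non-crossing excursions to interleave.
#' @param monomer,replicate labels for the returned trace.
#' @return a `trace` object.
#' @export
generate_permeation_trace <- function(n_events, channel_bounds, duration,
                                      noise_sd = 0, seed = 1L,
                                      n_excursions = 2L, monomer = 1L,
                                      replicate = 1L) {
  stopifnot(n_events >= 0, length(channel_bounds) == 2,
            channel_bounds[1] < channel_bounds[2], duration > 0,
            noise_sd >= 0, n_excursions >= 0)
  z_lo <- channel_bounds[1]; z_hi <- channel_bounds[2]
  width <- z_hi - z_lo
  if (noise_sd * 8 >= width) {
    stop("noise_sd must be < (z_hi - z_lo)/8: larger jitter can create ",
         "spurious boundary chatter")
  }
  margin <- width / 2
  lo_base <- z_lo - margin; hi_base <- z_hi + margin
  dwell <- 4L # samples spent at each extreme between moves

  # Base waypoints: alternate extremes for traversals; excursions dip to
  # one third of the slab from the current side and withdraw.
  side <- -1 # -1 = below, +1 = above
  base <- rep(lo_base, dwell)
  add_dwell <- function(v, at) c(v, rep(at, dwell))
  events_done <- 0L
  excursions_done <- 0L
  while (events_done < n_events || excursions_done < n_excursions) {
    if (excursions_done < n_excursions) {
      probe <- if (side < 0) z_lo + width / 3 else z_hi - width / 3
      base <- c(base, probe)
      base <- add_dwell(base, if (side < 0) lo_base else hi_base)
      excursions_done <- excursions_done + 1L
    }
    if (events_done < n_events) {
      side <- -side
      base <- add_dwell(base, if (side < 0) lo_base else hi_base)
      events_done <- events_done + 1L
    }
  }
  n <- length(base)
  time <- seq(0, duration, length.out = n)
  z <- if (noise_sd > 0) {
    jitter <- with_seed(seed, rnorm(n, 0, noise_sd))
    base + pmin(pmax(jitter, -2.5 * noise_sd), 2.5 * noise_sd)
  } else {
    base
  }
  new_trace(time = time, z = z, monomer = monomer, replicate = replicate)
}
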