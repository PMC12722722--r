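#' Generate two-state protonation (lambda) traces at a ladder of pH values
#'
#' Emulates the binary protonation time series produced by constant-pH MD:
#' for each (pH, monomer, replicate) a two-state Markov chain is sampled
#' whose stationary protonated fraction obeys Henderson-Hasselbalch,
#' \deqn{f = 1/(1 + 10^{pH - pK_a})},
#' with transition rates chosen so that k_prot + k_deprot = `k_exchange`.
#' The chain is initialised from its stationary law and sampled with the
#' exact discrete-time propagator, so empirical fractions converge to the
#' Henderson-Hasselbalch value and the fitted apparent pKa can be checked
#' against `pKa_true`.
#'
#' @param pKa_true ground-truth apparent pKa (pH units).
#' @param pH_values numeric vector of simulated pH values.
#' @param k_exchange total exchange rate k_prot + k_deprot (ns^-1).
#' @param duration trace length (ns).
#' @param n_monomers,n_replicates group structure (e.g. 4 monomers x 6
#'   replicates, the usual constant-pH production layout).
#' @param seed integer RNG seed.
#' @param dt sampling interval (ns); should resolve exchange
#'   (`k_exchange * dt` well below 1).
#' @param residue residue label attached to all entries.
#' @return a `lambda_trace_set`: list of entries, each a list with
#'   `residue`, `pH`, `monomer`, `replicate`, `time` (ns) and `state`
#'   (integer 0/1, 1 = protonated). Entries with fewer than 20 expected
#'   transitions carry a `low_transitions` warning flag in the set's
#'   `warnings` attribute.
#' @export
generate_lambda_traces <- function(pKa_true, pH_values, k_exchange = 20,
                                   duration = 1000, n_monomers = 4L,
                                   n_replicates = 6L, seed = 1L,
                                   dt = 0.01, residue = "ASP163") {
  stopifnot(is.numeric(pKa_true), length(pKa_true) == 1,
            length(pH_values) >= 1, k_exchange > 0, duration > 0, dt > 0)
  if (duration < 10 / k_exchange) {
    stop("duration must greatly exceed 1/k_exchange")
  }
  n_steps <- floor(duration / dt)
  time <- dt * seq_len(n_steps)
  entries <- list()
  warnings <- character()
  idx <- 0L
  with_seed(seed, {
    for (pH in pH_values) {
      p_stat <- 1 / (1 + 10^(pH - pKa_true))
      expected_transitions <- 2 * k_exchange * p_stat * (1 - p_stat) * duration
      for (m in seq_len(n_monomers)) {
        for (r in seq_len(n_replicates)) {
          init <- as.integer(runif(1) < p_stat)
          state <- two_state_chain_core(n_steps, p_stat, k_exchange, dt, init)
          idx <- idx + 1L
          entries[[idx]] <- list(residue = residue, pH = pH, monomer = m,
                                 replicate = r, time = time, state = state)
          if (expected_transitions < 20) {
            warnings <- c(warnings, sprintf(
              "entry (pH %.2f, monomer %d, replicate %d): only %.1f expected transitions",
              pH, m, r, expected_transitions))
          }
        }
      }
    }
  })
  structure(entries,
            class = "lambda_trace_set",
            ground_truth = list(pKa = pKa_true, k_exchange = k_exchange),
            warnings = warnings)
}

#' @export
print.lambda_trace_set <- function(x, ...) {
  cat(sprintf("lambda_trace_set: %d entries, %d frames each\n",
              length(x), length(x[[1]]$state)))
  w <- attr(x, "warnings")
  if (length(w)) cat(length(w), "low-transition warnings recorded\n")
  invisible(x)
}

#' Generate Crooks-consistent Gaussian work distributions
#'
#' Draws forward (A to B) and reverse (B to A) nonequilibrium work values
#' from the equal-variance Gaussian pair
#' \deqn{W_F \sim N(\Delta G + \sigma^2/2kT,\ \sigma^2), \quad
#'       W_R \sim N(-\Delta G + \sigma^2/2kT,\ \sigma^2)}
#' which satisfies the Crooks fluctuation theorem
#' P_F(W)/P_R(-W) = exp((W - dG)/kT) exactly. These are the standard test
#' distributions for Bennett acceptance ratio estimators: the dissipated
#' work is sigma^2/2kT in each direction and the estimator must recover
#' `dG_true`.
#'
#' @param dG_true ground-truth free-energy difference (kJ/mol).
#' @param sigma work standard deviation (kJ/mol), > 0.
#' @param n_forward,n_reverse sample counts (>= 2).
#' @param kT thermal energy (kJ/mol).
#' @param seed integer RNG seed.
#' @param residue,monomer,replicate labels.
#' @return a `work_set`: list with `forward`, `reverse` (kJ/mol), `kT`,
#'   labels, and the ground truth in attributes.
#' @export
generate_work_samples <- function(dG_true, sigma, n_forward = 1e4L,
                                  n_reverse = 1e4L, kT = kT_at(300),
                                  seed = 1L, residue = "ASP163",
                                  monomer = 1L, replicate = 1L) {
  stopifnot(sigma > 0, n_forward >= 2, n_reverse >= 2, kT > 0)
  diss <- sigma^2 / (2 * kT)
  with_seed(seed, {
    fw <- rnorm(n_forward, dG_true + diss, sigma)
    rv <- rnorm(n_reverse, -dG_true + diss, sigma)
    work_set(forward = fw, reverse = rv, kT = kT, residue = residue,
             monomer = monomer, replicate = replicate,
             ground_truth = dG_true)
  })
}

#' Construct a set of forward/reverse work values
#'
#' @param forward work values (kJ/mol) for the A to B transitions.
#' @param reverse work values (kJ/mol) for the B to A transitions.
#' @param kT thermal energy (kJ/mol).
#' @param residue,monomer,replicate labels.
#' @param ground_truth optional known dG for synthetic sets.
#' @return a `work_set` object.
#' @export
work_set <- function(forward, reverse, kT = kT_at(300), residue = NA,
                     monomer = NA, replicate = NA, ground_truth = NULL) {
  stopifnot(length(forward) >= 1, length(reverse) >= 1,
            all(is.finite(forward)), all(is.finite(reverse)), kT > 0)
  structure(list(forward = as.numeric(forward),
                 reverse = as.numeric(reverse), kT = kT,
                 residue = residue, monomer = monomer,
                 replicate = replicate),
            class = "work_set", ground_truth = ground_truth)
}

#' @export
print.work_set <- function(x, ...) {
  cat(sprintf("work_set: %d forward / %d reverse values (kT = %.4g kJ/mol)\n",
              length(x$forward), length(x$reverse), x$kT))
  invisible(x)
}
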