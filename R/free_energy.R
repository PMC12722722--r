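#' Bennett acceptance ratio (BAR) free-energy estimate
#'
#' Maximum-likelihood estimator of the free-energy difference from
#' forward and reverse nonequilibrium work values, relying on the Crooks
#' fluctuation theorem. The estimate solves the self-consistency
#' condition
#' \deqn{\sum_F \frac{1}{1 + \frac{n_F}{n_R} e^{(W_F - \Delta G)/kT}}
#'     = \sum_R \frac{1}{1 + \frac{n_R}{n_F} e^{(W_R + \Delta G)/kT}}}
#' (Fermi-function weights with offset M = kT ln(n_F/n_R)) by bracketed
#' root finding on `[min(W) - 10 kT, max(W) + 10 kT]`. Uncertainty is
#' estimated by bootstrap over work values; the asymptotic
#' (Bennett-variance) standard error is also reported.
#'
#' @param works a [work_set()].
#' @param n_boot bootstrap resamples for the standard error.
#' @param seed integer RNG seed.
#' @param tol root-finding tolerance (kJ/mol), default 1e-8.
#' @return a `free_energy_estimate`: list with `dG` (kJ/mol), `se`
#'   (bootstrap), `se_asymptotic`, `method = "bar"`, `n_forward`,
#'   `n_reverse`, `n_boot`, labels.
#' @export
bar_estimate <- function(works, n_boot = 200L, seed = 1L, tol = 1e-8) {
  stopifnot(inherits(works, "work_set"))
  wf <- works$forward; wr <- works$reverse; kT <- works$kT
  if (length(wf) < 2 || length(wr) < 2) {
    stop("BAR needs >= 2 work values in each direction")
  }
  dG <- bar_root(wf, wr, kT, tol)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bar_root(wf[sample.int(length(wf), replace = TRUE)],
               wr[sample.int(length(wr), replace = TRUE)], kT, tol)
    }, numeric(1))
  })
  structure(list(dG = dG, se = sd(boots),
                 se_asymptotic = bar_asymptotic_se(wf, wr, dG, kT),
                 method = "bar", n_forward = length(wf),
                 n_reverse = length(wr), n_boot = n_boot,
                 residue = works$residue, monomer = works$monomer,
                 replicate = works$replicate),
            class = "free_energy_estimate")
}

# Solve the Bennett self-consistency equation for one (wf, wr) pair.
bar_root <- function(wf, wr, kT, tol = 1e-8) {
  M <- log(length(wf) / length(wr)) # dimensionless offset
  fermi <- function(x) 1 / (1 + exp(x))
  g <- function(dG) {
    sum(fermi(M + (wf - dG) / kT)) - sum(fermi(-M + (wr + dG) / kT))
  }
  all_w <- c(wf, wr, -wr)
  lo <- min(all_w) - 10 * kT
  hi <- max(all_w) + 10 * kT
  glo <- g(lo); ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    stop("no sign change of the BAR self-consistency function over the ",
         "bracket: work distributions overlap too poorly; check ",
         "work_overlap() before estimating")
  }
  root <- uniroot(g, c(lo, hi), tol = tol)$root
  # effective-sample diagnostic: with no distribution overlap the Fermi
  # weights all collapse to 0/1 and the root is uninformative
  n_eff_f <- sum(fermi(M + (wf - root) / kT))
  n_eff_r <- sum(fermi(-M + (wr + root) / kT))
  if (min(n_eff_f, n_eff_r) < 1) {
    stop("catastrophically poor overlap between forward and reverse work ",
         "distributions (effective overlap samples < 1); check ",
         "work_overlap() before estimating")
  }
  root
}

# Bennett (1976) asymptotic variance at the solution.
bar_asymptotic_se <- function(wf, wr, dG, kT) {
  M <- log(length(wf) / length(wr))
  ff <- 1 / (1 + exp(M + (wf - dG) / kT))
  fr <- 1 / (1 + exp(-M + (wr + dG) / kT))
  vf <- (mean(ff^2) / mean(ff)^2 - 1) / length(wf)
  vr <- (mean(fr^2) / mean(fr)^2 - 1) / length(wr)
  kT * sqrt(vf + vr)
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("free_energy_estimate [%s]: dG = %.3f +/- %.3f kJ/mol\n",
              x$method, x$dG, x$se))
  invisible(x)
}

#' Overlap of forward and reverse work distributions
#'
#' Histogram overlap coefficient between the forward works and the
#' negated reverse works on a shared grid: 1 for identical distributions,
#' 0 for disjoint ones. Good overlap is the practical prerequisite for a
#' reliable BAR estimate.
#'
#' @param works a [work_set()].
#' @param n_bins number of shared histogram bins (default 50).
#' @return overlap score in `[0, 1]`.
#' @export
work_overlap <- function(works, n_bins = 50L) {
  stopifnot(inherits(works, "work_set"), n_bins >= 2)
  a <- works$forward
  b <- -works$reverse
  breaks <- seq(min(a, b), max(a, b), length.out = n_bins + 1)
  ha <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  hb <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  sum(pmin(ha / length(a), hb / length(b)))
}

#' Combine independent free-energy estimates of the same quantity
#'
#' Combines per-method estimates (e.g. a constant-pH pKa-shift value and
#' an alchemical BAR value for the same residue) as their unweighted mean
#' with errors propagated through the mean:
#' \deqn{se = \sqrt{\sum_i se_i^2} / n.}
#' Inverse-variance weighting is available behind a flag.
#'
#' @param estimates list of `free_energy_estimate` objects (or lists with
#'   `dG` and `se`) for the same residue/state pair.
#' @param inverse_variance use inverse-variance weights instead of the
#'   unweighted mean.
#' @return a `free_energy_estimate` with `method = "combined"` and the
#'   input points echoed in `$points`.
#' @export
combine_state_estimates <- function(estimates, inverse_variance = FALSE) {
  stopifnot(length(estimates) >= 1)
  dg <- vapply(estimates, function(e) e$dG, numeric(1))
  se <- vapply(estimates, function(e) e$se, numeric(1))
  res <- vapply(estimates, function(e) {
    if (is.null(e$residue) || is.na(e$residue)) "" else as.character(e$residue)
  }, character(1))
  res_known <- unique(res[nzchar(res)])
  if (length(res_known) > 1) {
    stop("estimates mix residues/states: ", paste(res_known, collapse = ", "))
  }
  if (length(estimates) == 1) {
    warning("single estimate: combination is a passthrough")
    out_dg <- dg; out_se <- se
  } else if (inverse_variance) {
    w <- 1 / se^2
    out_dg <- sum(w * dg) / sum(w)
    out_se <- sqrt(1 / sum(w))
  } else {
    out_dg <- mean(dg)
    out_se <- sqrt(sum(se^2)) / length(se)
  }
  structure(list(dG = out_dg, se = out_se, method = "combined",
                 residue = if (length(res_known)) res_known else NA,
                 points = data.frame(dG = dg, se = se,
                                     method = vapply(estimates, function(e) {
                                       if (is.null(e$method)) "unknown" else e$method
                                     }, character(1)))),
            class = "free_energy_estimate")
}

#' Jarzynski exponential-average estimates from each direction
#'
#' One-sided estimates `dG_F = -kT ln mean(exp(-W_F/kT))` and
#' `dG_R = +kT ln mean(exp(-W_R/kT))`; on Crooks-consistent data the BAR
#' estimate must lie between them (they are biased toward each other's
#' direction).
#'
#' @param works a [work_set()].
#' @return list with `forward` and `reverse` one-sided estimates (kJ/mol).
#' @export
jarzynski_estimates <- function(works) {
  stopifnot(inherits(works, "work_set"))
  kT <- works$kT
  lse <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
  list(forward = -kT * lse(-works$forward / kT),
       reverse = kT * lse(-works$reverse / kT))
}
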