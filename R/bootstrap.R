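#' Bootstrap SEM over (monomer, replicate) groups
#'
#' Resamples whole groups with replacement `n_boot` times and returns the
#' standard deviation of the resampled means — the bootstrap estimate of
#' the standard error of the mean over independent monomers/replicates.
#' This is the single error engine shared by the PMF band, permeation
#' rates, titration pKa values and contact propensities.
#'
#' @param values either a numeric vector (one scalar per group) or a
#'   matrix with one row per group (e.g. per-group profiles, one column
#'   per bin).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer RNG seed; fixed seeds give identical bands.
#' @return SEM: a scalar for vector input, a per-column vector for matrix
#'   input.
#' @examples
#' bootstrap_band(c(0.5, 0.6, 0.5, 0.4), n_boot = 500, seed = 1)
#' @export
bootstrap_band <- function(values, n_boot = 1000L, seed = 1L) {
  if (is.matrix(values)) {
    n <- nrow(values)
    if (n < 2) stop("SEM undefined for a single group")
    means <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        colMeans(values[sample.int(n, n, replace = TRUE), , drop = FALSE])
      }, numeric(ncol(values)))
    })
    if (is.null(dim(means))) return(unname(sd(means)))
    unname(apply(means, 1, sd))
  } else {
    values <- as.numeric(values)
    n <- length(values)
    if (n < 2) stop("SEM undefined for a single group")
    means <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        mean(values[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
    })
    sd(means)
  }
}
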