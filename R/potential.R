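#' Analytic 1-D potential as a sum of Gaussian terms
#'
#' Defines a smooth free-energy landscape
#' \deqn{U(z) = \mathrm{offset} + \sum_k h_k \exp(-(z-c_k)^2 / 2 w_k^2)}
#' on a bounded domain. Sums of Gaussians are used throughout the synthetic
#' generators because they have a closed-form gradient and can mimic the
#' barrier shapes typical of channel permeation profiles (e.g. a single
#' 10-28 kJ/mol barrier at a selectivity filter, or a well at a binding
#' site), making every downstream estimator testable against an exact
#' oracle.
#'
#' @param heights numeric vector of term heights h_k (kJ/mol); negative
#'   values create wells.
#' @param centers numeric vector of term centers c_k (A).
#' @param widths numeric vector of term widths w_k (A), all > 0.
#' @param offset constant energy offset (kJ/mol).
#' @param domain length-2 numeric `(z_min, z_max)` (A) on which the
#'   potential may be evaluated.
#' @return an object of class `potential_spec`.
#' @examples
#' pot <- potential_spec(heights = 23, centers = 0, widths = 2,
#'                       domain = c(-15, 15))
#' potential_energy(pot, 0) # 23
#' @export
potential_spec <- function(heights = numeric(), centers = numeric(),
                           widths = numeric(), offset = 0,
                           domain = c(-15, 15)) {
  stopifnot(length(heights) == length(centers),
            length(heights) == length(widths),
            length(domain) == 2, domain[1] < domain[2],
            is.numeric(offset), length(offset) == 1)
  if (length(widths) && any(widths <= 0)) {
    stop("all Gaussian term widths must be > 0")
  }
  structure(
    list(heights = as.numeric(heights), centers = as.numeric(centers),
         widths = as.numeric(widths), offset = as.numeric(offset),
         domain = as.numeric(domain)),
    class = "potential_spec"
  )
}

#' Evaluate a potential
#' @param potential a [potential_spec()].
#' @param z numeric vector of positions (A) within the domain.
#' @return U(z) in kJ/mol.
#' @export
potential_energy <- function(potential, z) {
  stopifnot(inherits(potential, "potential_spec"))
  u <- rep(potential$offset, length(z))
  for (k in seq_along(potential$heights)) {
    d <- (z - potential$centers[k]) / potential$widths[k]
    u <- u + potential$heights[k] * exp(-0.5 * d^2)
  }
  u
}

#' Evaluate the force -dU/dz of a potential
#' @inheritParams potential_energy
#' @return -dU/dz in kJ/mol/A.
#' @export
potential_force <- function(potential, z) {
  stopifnot(inherits(potential, "potential_spec"))
  f <- rep(0, length(z))
  for (k in seq_along(potential$heights)) {
    d <- (z - potential$centers[k]) / potential$widths[k]
    f <- f + potential$heights[k] * exp(-0.5 * d^2) * d / potential$widths[k]
  }
  f
}

#' @export
print.potential_spec <- function(x, ...) {
  cat("Sum-of-Gaussians potential on [", x$domain[1], ",", x$domain[2],
      "] A with", length(x$heights), "term(s)\n")
  if (length(x$heights)) {
    print(data.frame(height_kJ_mol = x$heights, center_A = x$centers,
                     width_A = x$widths))
  }
  invisible(x)
}
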