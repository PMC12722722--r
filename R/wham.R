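#' WHAM configuration
#'
#' @param bin_width histogram bin width (A), default 0.1.
#' @param tolerance convergence tolerance on the window offsets f_j
#'   (kJ/mol), default 1e-4.
#' @param max_iterations iteration cap, default 1e5.
#' @param min_bin_count bins whose pooled count falls below this at either
#'   end of the covered range are trimmed before unbiasing (sparse window
#'   tails carry essentially no information and only add noise).
#' @return a `wham_config` list.
#' @export
wham_config <- function(bin_width = 0.1, tolerance = 1e-4,
                        max_iterations = 1e5L, min_bin_count = 25L) {
  stopifnot(bin_width > 0, tolerance > 0, max_iterations >= 1,
            min_bin_count >= 1)
  structure(list(bin_width = bin_width, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 min_bin_count = as.integer(min_bin_count)),
            class = "wham_config")
}

#' Self-consistent WHAM solution of umbrella-sampling windows
#'
#' Iterates the weighted histogram equations
#' \deqn{\rho(z_b) = \frac{\sum_i h_i(z_b)}{\sum_j N_j
#'   \exp((f_j - w_j(z_b))/kT)}, \qquad
#'   f_j = -kT \ln \sum_b \rho(z_b) \exp(-w_j(z_b)/kT)}
#' to self-consistency (max |change in f_j| below the configured
#' tolerance), where h_i are per-window histogram counts and
#' w_j(z) = 0.5 k_j (z - c_j)^2 is the harmonic bias. The unbiased free
#' energy is G(z) = -kT ln rho(z), referenced so that either the bulk
#' region average (`reference = "bulk_zero"`) or the profile minimum
#' (`"min_zero"`) is exactly zero.
#'
#' @param windows list of [umbrella_window()] objects.
#' @param config a [wham_config()].
#' @param kT thermal energy (kJ/mol).
#' @param reference `"bulk_zero"` or `"min_zero"`.
#' @param bulk_region either `NULL` (default: the outer 10% of the covered
#'   range at each end) or a list of one or two `(lo, hi)` intervals in A.
#' @return a `pmf_profile`: list with `z` (bin centers, A), `G` (kJ/mol),
#'   `sem` (NA unless filled by [pmf_by_group()]), `kT`, `reference`,
#'   `bulk_region`, `f` (converged window offsets), `iterations`, and
#'   `residual` (kJ/mol).
#' @export
solve_wham <- function(windows, config = wham_config(), kT = kT_at(300),
                       reference = c("bulk_zero", "min_zero"),
                       bulk_region = NULL) {
  reference <- match.arg(reference)
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, logical(1), "umbrella_window")))
  bw <- config$bin_width
  all_samples <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(all_samples) / bw) * bw
  hi <- ceiling(max(all_samples) / bw) * bw
  breaks <- seq(lo, hi + bw / 2, by = bw)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  nb <- length(mids)
  nw <- length(windows)

  H <- matrix(0, nrow = nw, ncol = nb) # per-window histogram counts
  for (j in seq_len(nw)) {
    idx <- findInterval(windows[[j]]$samples, breaks,
                        rightmost.closed = TRUE, all.inside = TRUE)
    H[j, ] <- tabulate(idx, nbins = nb)
  }
  pooled <- colSums(H)

  # restrict to the windowed range: outside the span of window centers the
  # density rests on a single window's exponential tail and is pure noise
  centers_all <- vapply(windows, `[[`, numeric(1), "center")
  k_all <- spring_nm2_to_A2(vapply(windows, `[[`, numeric(1), "spring_k"))
  margin <- 2 * sqrt(kT / min(k_all)) # ~2 sd of the bias confinement
  in_span <- mids >= min(centers_all) - margin &
    mids <= max(centers_all) + margin
  if (any(in_span)) {
    H <- H[, in_span, drop = FALSE]
    pooled <- pooled[in_span]
    mids <- mids[in_span]
    nb <- length(mids)
  }
  # trim sparse tails, then require contiguous coverage
  covered <- which(pooled > 0)
  first <- covered[1]; last <- covered[length(covered)]
  while (first < last && pooled[first] < config$min_bin_count) first <- first + 1
  while (last > first && pooled[last] < config$min_bin_count) last <- last - 1
  keep <- first:last
  gap <- keep[pooled[keep] == 0]
  if (length(gap)) {
    stop(sprintf(
      "umbrella coverage is not contiguous at bin width %.3g A: empty bins near z = %s A",
      bw, paste(sprintf("%.2f", mids[gap]), collapse = ", ")))
  }
  mids <- mids[keep]
  H <- H[, keep, drop = FALSE]
  pooled <- pooled[keep]
  nb <- length(mids)

  # per-window sample counts ON the retained grid: using raw sample counts
  # here would overstate the edge windows (whose tails fall outside the
  # grid) and bow the whole profile to compensate
  N <- rowSums(H)
  if (any(N == 0)) {
    stop("window(s) ", paste(which(N == 0), collapse = ", "),
         " have no samples on the retained grid")
  }
  centers <- vapply(windows, `[[`, numeric(1), "center")
  k_A2 <- spring_nm2_to_A2(vapply(windows, `[[`, numeric(1), "spring_k"))
  # Bin-averaged Boltzmann factor of the harmonic bias. The bias factor
  # exp(-k(z-c)^2/2kT) is sharply curved on the bin scale (its sd is
  # sqrt(kT/k), comparable to the bin width at the default spring), so
  # evaluating it at bin midpoints biases the unbiased density by a few
  # percent per bin, which accumulates window-to-window into a spurious
  # kT-scale bow of the profile. The harmonic bias integrates exactly:
  #   (1/dz) int_bin exp(-k(z-c)^2/2kT) dz
  #     = sqrt(2 pi kT / k) [Phi(hi) - Phi(lo)] / dz.
  EW <- t(vapply(seq_len(nw), function(j) {
    s <- sqrt(kT / k_A2[j])
    sqrt(2 * pi) * s *
      (pnorm(mids + bw / 2, centers[j], s) -
         pnorm(mids - bw / 2, centers[j], s)) / bw
  }, numeric(nb))) # nw x nb

  f <- rep(0, nw)
  iter <- 0L
  residual <- Inf
  res_hist <- numeric()
  repeat {
    iter <- iter + 1L
    denom <- colSums((N * exp(f / kT)) * EW) # length nb
    rho <- pooled / denom
    f_new <- -kT * log(EW %*% rho)[, 1]
    f_new <- f_new - f_new[1]
    residual <- max(abs(f_new - f))
    res_hist <- c(res_hist, residual)
    f <- f_new
    if (residual < config$tolerance || iter >= config$max_iterations) break
  }
  if (residual >= config$tolerance) {
    stop(sprintf("WHAM failed to converge in %d iterations (residual %.3g kJ/mol)",
                 iter, residual))
  }
  denom <- colSums((N * exp(f / kT)) * EW)
  rho <- pooled / denom
  G <- -kT * log(rho)

  prof <- pmf_profile(z = mids, G = G, kT = kT, reference = reference,
                      bulk_region = bulk_region)
  prof$f <- f
  prof$iterations <- iter
  prof$residual <- residual
  prof$residual_history <- res_hist
  prof
}

#' Construct (and reference) a free-energy profile
#'
#' @param z bin centers (A), strictly increasing.
#' @param G free energy per bin (kJ/mol).
#' @param sem optional standard error per bin (kJ/mol).
#' @param kT thermal energy (kJ/mol).
#' @param reference `"bulk_zero"` (mean over the bulk region is zero) or
#'   `"min_zero"` (profile minimum is zero).
#' @param bulk_region `NULL` for the default outer 10% of the covered
#'   range at each end, or a list of `(lo, hi)` intervals (A).
#' @return a `pmf_profile` object with the reference applied exactly.
#' @export
pmf_profile <- function(z, G, sem = NULL, kT = kT_at(300),
                        reference = c("bulk_zero", "min_zero"),
                        bulk_region = NULL) {
  reference <- match.arg(reference)
  stopifnot(length(z) == length(G), !is.unsorted(z, strictly = TRUE),
            all(is.finite(G)))
  if (is.null(bulk_region)) {
    span <- diff(range(z))
    bulk_region <- list(c(min(z), min(z) + 0.1 * span),
                        c(max(z) - 0.1 * span, max(z)))
  }
  if (!is.list(bulk_region)) bulk_region <- list(bulk_region)
  in_bulk <- Reduce(`|`, lapply(bulk_region, function(iv) {
    z >= iv[1] & z <= iv[2]
  }))
  if (!any(in_bulk)) stop("bulk_region is not covered by the profile")
  shift <- if (reference == "bulk_zero") mean(G[in_bulk]) else min(G)
  structure(list(z = z, G = G - shift, sem = sem, kT = kT,
                 reference = reference, bulk_region = bulk_region,
                 bulk_mask = in_bulk),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins on [%.2f, %.2f] A, reference %s\n",
              length(x$z), min(x$z), max(x$z), x$reference))
  feats <- profile_features(x)
  cat(sprintf("  barrier %.2f kJ/mol at z = %.2f A; deepest well %.2f kJ/mol at z = %.2f A\n",
              feats$barrier, feats$barrier_z, feats$well, feats$well_z))
  invisible(x)
}

#' Barrier and well features of a free-energy profile
#'
#' The barrier height is max(G) minus the mean of G over the bulk region
#' and the deepest well is min(G) minus the same bulk mean; positions are
#' the bin centers of the extrema, ties broken toward smaller z. A warning
#' flag is set in the result when the global extremum falls inside the
#' bulk region (the "barrier" would then be a bulk feature).
#'
#' @param profile a `pmf_profile`.
#' @param bulk_region optional override of the profile's bulk region
#'   (interval or list of intervals, A).
#' @return list with `barrier`, `barrier_z`, `well`, `well_z`, and
#'   `bulk_overlap_warning`.
#' @export
profile_features <- function(profile, bulk_region = NULL) {
  stopifnot(inherits(profile, "pmf_profile"))
  z <- profile$z; G <- profile$G
  if (is.null(bulk_region)) {
    in_bulk <- profile$bulk_mask
  } else {
    if (!is.list(bulk_region)) bulk_region <- list(bulk_region)
    in_bulk <- Reduce(`|`, lapply(bulk_region, function(iv) {
      z >= iv[1] & z <= iv[2]
    }))
    if (!any(in_bulk)) stop("bulk_region is not covered by the profile")
  }
  bulk_mean <- mean(G[in_bulk])
  i_max <- which.max(G) # which.max takes the first (smallest z) on ties
  i_min <- which.min(G)
  barrier <- G[i_max] - bulk_mean
  well <- G[i_min] - bulk_mean
  # flag a bulk region that swallows a substantive extremum; the profile
  # minimum trivially lies in bulk whenever there is no real well
  overlap <- (in_bulk[i_max] && barrier > profile$kT / 2) ||
    (in_bulk[i_min] && well < -profile$kT / 2)
  list(barrier = barrier, barrier_z = z[i_max],
       well = well, well_z = z[i_min],
       bulk_overlap_warning = overlap)
}

#' Per-group free-energy profiles combined as mean with bootstrap SEM
#'
#' Solves WHAM independently for each (monomer, replicate) group of
#' windows, then combines the group profiles as their mean with a
#' bootstrap SEM band over groups — treating the solute in each monomer
#' channel as an independent replicate, the convention used for
#' channel PMFs with per-monomer statistics.
#'
#' @param windows list of [umbrella_window()] objects carrying group
#'   labels.
#' @inheritParams solve_wham
#' @param n_boot bootstrap resamples.
#' @param seed integer RNG seed for the bootstrap.
#' @return a `pmf_profile` on the intersection grid with `sem` filled, and
#'   the per-group profiles in `$group_profiles`.
#' @export
pmf_by_group <- function(windows, config = wham_config(), kT = kT_at(300),
                         reference = c("bulk_zero", "min_zero"),
                         bulk_region = NULL, n_boot = 200L, seed = 1L) {
  reference <- match.arg(reference)
  key <- vapply(windows, function(w) {
    paste(w$monomer, w$replicate, sep = "/")
  }, character(1))
  groups <- split(windows, key)
  if (length(groups) < 2) {
    stop("need >= 2 (monomer, replicate) groups; use solve_wham() for one")
  }
  profs <- lapply(groups, solve_wham, config = config, kT = kT,
                  reference = reference, bulk_region = bulk_region)
  # common grid: intersection of covered ranges, snapped to bin centers
  lo <- max(vapply(profs, function(p) min(p$z), numeric(1)))
  hi <- min(vapply(profs, function(p) max(p$z), numeric(1)))
  zref <- profs[[1]]$z
  grid <- zref[zref >= lo - 1e-9 & zref <= hi + 1e-9]
  Gmat <- do.call(rbind, lapply(profs, function(p) {
    approx(p$z, p$G, xout = grid)$y
  }))
  sem <- bootstrap_band(Gmat, n_boot = n_boot, seed = seed)
  out <- pmf_profile(z = grid, G = colMeans(Gmat), sem = sem, kT = kT,
                     reference = reference, bulk_region = bulk_region)
  out$group_profiles <- profs
  out
}

#' @importFrom stats approx
NULL
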