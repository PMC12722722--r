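# WHAM unbiasing against the analytic potential oracle.

make_windows <- function(pot, centers = seq(-14, 14, 1), seed = 10,
                         steps = 5e4, ...) {
  generate_umbrella_dataset(pot, centers, steps_per_window = steps,
                            seed = seed, ...)
}

test_that("flat-potential windows unbias to a flat profile", {
  prof <- solve_wham(make_windows(flat_potential(), seed = 20))
  expect_lt(max(abs(prof$G)), 0.3)
})

test_that("a 23 kJ/mol Gaussian barrier is recovered within 1 kJ/mol", {
  pot <- barrier_potential(23)
  prof <- solve_wham(make_windows(pot, seed = 21, steps = 1e5))
  feats <- profile_features(prof)
  expect_equal(feats$barrier, 23, tolerance = 1 / 23)
  expect_lt(abs(feats$barrier_z), 0.5)
})

test_that("translation of samples and centers shifts the profile rigidly", {
  pot <- barrier_potential(10, domain = c(-8, 8))
  win <- make_windows(pot, centers = seq(-7, 7, 1), seed = 22)
  shifted <- lapply(win, function(w) {
    umbrella_window(center = w$center + 5, spring_k = w$spring_k,
                    samples = w$samples + 5, monomer = w$monomer,
                    replicate = w$replicate)
  })
  p1 <- solve_wham(win)
  p2 <- solve_wham(shifted)
  expect_equal(p2$z, p1$z + 5, tolerance = 1e-9)
  expect_equal(p2$G, p1$G, tolerance = 1e-6)
})

test_that("profile is invariant to bin-width halving on well-sampled data", {
  pot <- barrier_potential(10, domain = c(-8, 8))
  win <- make_windows(pot, centers = seq(-7, 7, 1), seed = 23, steps = 1e5)
  p1 <- solve_wham(win, wham_config(bin_width = 0.2))
  p2 <- solve_wham(win, wham_config(bin_width = 0.1))
  b1 <- profile_features(p1)$barrier
  b2 <- profile_features(p2)$barrier
  expect_equal(b1, b2, tolerance = 0.25 / b1)
})

test_that("self-consistency residual is non-increasing over the final iterations", {
  prof <- solve_wham(make_windows(barrier_potential(10), seed = 27))
  hist <- prof$residual_history
  last10 <- tail(hist, 10)
  expect_true(all(diff(last10) <= 1e-12))
})

test_that("gauge invariance: shifting all window offsets by a constant leaves referenced G unchanged", {
  win <- make_windows(barrier_potential(10), seed = 28, steps = 2e4)
  prof <- solve_wham(win)
  # recompute the unbiased density from the converged offsets, with and
  # without a constant added to every f_j
  bw <- 0.1
  breaks <- c(prof$z - bw / 2, max(prof$z) + bw / 2)
  pooled <- rowSums(vapply(win, function(w) {
    tabulate(findInterval(w$samples, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = length(prof$z))
  }, numeric(length(prof$z))))
  dens_from <- function(f) {
    denom <- Reduce(`+`, lapply(seq_along(win), function(j) {
      w <- win[[j]]
      bias <- 0.5 * spring_nm2_to_A2(w$spring_k) * (prof$z - w$center)^2
      length(w$samples) * exp((f[j] - bias) / kT300)
    }))
    g <- -kT300 * log(pooled / denom)
    g - mean(g[prof$bulk_mask])
  }
  expect_equal(dens_from(prof$f), dens_from(prof$f + 7), tolerance = 1e-9)
})

test_that("single window yields a profile only over that window's support", {
  pot <- flat_potential(c(-5, 5))
  win <- generate_umbrella_dataset(pot, centers = 0,
                                   steps_per_window = 5e4, seed = 24)
  prof <- solve_wham(win)
  expect_lt(diff(range(prof$z)), 4) # ~ +/- 3 sd of kT/k_spring
  expect_true(all(is.finite(prof$G)))
})

test_that("non-contiguous window coverage raises an error naming the gap", {
  pot <- flat_potential(c(-20, 20))
  win <- generate_umbrella_dataset(pot, centers = c(-10, 10),
                                   steps_per_window = 2e4, seed = 25)
  expect_error(solve_wham(win), "not contiguous")
})

test_that("referencing conventions: bulk mean zero vs minimum zero", {
  pot <- potential_spec(heights = -5, centers = 0, widths = 2,
                        domain = c(-15, 15))
  win <- make_windows(pot, seed = 26)
  pb <- solve_wham(win, reference = "bulk_zero")
  pm <- solve_wham(win, reference = "min_zero")
  expect_equal(mean(pb$G[pb$bulk_mask]), 0, tolerance = 1e-10)
  expect_equal(min(pm$G), 0, tolerance = 1e-10)
  # well depth wrt bulk matches construction
  expect_equal(profile_features(pb)$well, -5, tolerance = 0.5 / 5)
})

test_that("profile_features extracts barrier/well and flags bulk overlap", {
  z <- seq(-10, 10, 0.1)
  G <- 10 * exp(-z^2 / 2)
  prof <- pmf_profile(z, G, reference = "bulk_zero")
  f <- profile_features(prof)
  expect_equal(f$barrier, 10, tolerance = 0.05)
  expect_equal(f$barrier_z, 0, tolerance = 0.11)
  expect_false(f$bulk_overlap_warning)
  # flat profile: barrier and well both ~0
  pf <- pmf_profile(z, rep(1, length(z)), reference = "bulk_zero")
  ff <- profile_features(pf)
  expect_equal(ff$barrier, 0)
  expect_equal(ff$well, 0)
  # bulk region on the extremum triggers the warning flag
  fw <- profile_features(prof, bulk_region = c(-1, 1))
  expect_true(fw$bulk_overlap_warning)
})

test_that("ties in the extremum break toward smaller z", {
  z <- seq(0, 10, 1)
  G <- rep(0, 11); G[c(3, 8)] <- 5
  f <- profile_features(pmf_profile(z, G, reference = "min_zero",
                                    bulk_region = c(0, 1)))
  expect_equal(f$barrier_z, z[3])
})

test_that("per-group WHAM combines monomer profiles with a bootstrap band", {
  pot <- barrier_potential(10, domain = c(-8, 8))
  win <- c(
    make_windows(pot, centers = seq(-7, 7, 1), seed = 30, steps = 2e4,
                 monomer = 1),
    make_windows(pot, centers = seq(-7, 7, 1), seed = 31, steps = 2e4,
                 monomer = 2),
    make_windows(pot, centers = seq(-7, 7, 1), seed = 32, steps = 2e4,
                 monomer = 3)
  )
  prof <- pmf_by_group(win, n_boot = 100, seed = 33)
  expect_length(prof$sem, length(prof$z))
  expect_true(all(prof$sem >= 0))
  expect_equal(profile_features(prof)$barrier, 10, tolerance = 0.15)
  expect_error(pmf_by_group(make_windows(pot, centers = seq(-7, 7, 1),
                                         seed = 30, steps = 1e4)),
               "groups")
})
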