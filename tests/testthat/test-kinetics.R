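# Traversal counting, rates, and Kramers-form conversions.

test_that("constructed traces are counted exactly, with and without jitter", {
  for (n_ev in c(0, 1, 7)) {
    for (sd in c(0, 1)) {
      tr <- generate_permeation_trace(n_ev, c(-10, 10), duration = 50,
                                      noise_sd = sd, seed = 100 + n_ev)
      expect_identical(count_crossings(tr, -10, 10)$events, as.integer(n_ev))
    }
  }
})

test_that("same-side excursions never count", {
  # 50 deep entries that re-exit the entry side
  tr <- generate_permeation_trace(0, c(-10, 10), duration = 100,
                                  noise_sd = 0.5, seed = 1,
                                  n_excursions = 50)
  expect_identical(count_crossings(tr, -10, 10)$events, 0L)
})

test_that("time reversal preserves the total and swaps directions", {
  tr <- generate_permeation_trace(5, c(-8, 8), duration = 40,
                                  noise_sd = 0.8, seed = 9)
  fwd <- count_crossings(tr, -8, 8)
  rev_tr <- tr; rev_tr$z <- rev(tr$z)
  bwd <- count_crossings(rev_tr, -8, 8)
  expect_identical(bwd$events, fwd$events)
  expect_identical(bwd$up, fwd$down)
  expect_identical(bwd$down, fwd$up)
})

test_that("counts are additive when a trace is split at an outside frame", {
  tr <- generate_permeation_trace(6, c(-10, 10), duration = 60,
                                  noise_sd = 0.5, seed = 11)
  total <- count_crossings(tr, -10, 10)$events
  out_idx <- which(abs(tr$z) > 10)
  cut <- out_idx[length(out_idx) %/% 2]
  piece <- function(i, j) {
    poregate:::new_trace(time = tr$time[i:j], z = tr$z[i:j])
  }
  # split point replicated in both pieces so the state is preserved
  n1 <- count_crossings(piece(1, cut), -10, 10)$events
  n2 <- count_crossings(piece(cut, length(tr$z)), -10, 10)$events
  expect_identical(n1 + n2, total)
})

test_that("a trace that never leaves the slab warns and returns zero", {
  tr <- poregate:::new_trace(time = 1:10, z = rep(0, 10))
  expect_warning(cc <- count_crossings(tr, -5, 5), "never leaves")
  expect_identical(cc$events, 0L)
  expect_true(cc$inside_only)
})

test_that("permeation_rate averages per-group rates with bootstrap SEM", {
  counts <- lapply(seq_len(4), function(m) {
    tr <- generate_permeation_trace(c(5, 6, 5, 4)[m], c(-10, 10),
                                    duration = 10, noise_sd = 0.5,
                                    seed = 200 + m, monomer = m)
    count_crossings(tr, -10, 10)
  })
  pr <- permeation_rate(counts, n_boot = 500, seed = 3)
  expect_equal(pr$rate, 0.5)
  expect_gt(pr$sem, 0)
  # all-zero counts: rate 0, SEM 0
  zero <- lapply(1:4, function(m) {
    tr <- generate_permeation_trace(0, c(-10, 10), duration = 10,
                                    seed = m, monomer = m)
    count_crossings(tr, -10, 10)
  })
  pz <- permeation_rate(zero, n_boot = 100, seed = 4)
  expect_equal(pz$rate, 0)
  expect_equal(pz$sem, 0)
})

test_that("kramers_rate matches hand evaluation and its scaling laws", {
  expect_equal(kramers_rate(0, D = 100, pore_length = 50), 100 / 2500)
  expect_equal(kramers_rate(10, D = 100, pore_length = 50, kT = 2.494),
               0.04 * exp(-10 / 2.494), tolerance = 1e-12)
  expect_equal(kramers_rate(10, D = 100, pore_length = 50, kT = 2.494),
               7.25e-4, tolerance = 1e-3)
  # doubling the pore length divides the rate by 4; linear in D
  expect_equal(kramers_rate(5, D = 100, pore_length = 100),
               kramers_rate(5, D = 100, pore_length = 50) / 4)
  expect_equal(kramers_rate(5, D = 200, pore_length = 50),
               2 * kramers_rate(5, D = 100, pore_length = 50))
  # strictly decreasing in the barrier
  b <- seq(0, 30, 5)
  expect_true(all(diff(kramers_rate(b, D = 100, pore_length = 50)) < 0))
})

test_that("solute_rate_ratio closed forms", {
  expect_equal(solute_rate_ratio(5, 5, 1), 1)
  expect_equal(solute_rate_ratio(0, kT_at(300) * log(10), 1), 10,
               tolerance = 1e-12)
  # water vs glycerol: ~500x slower glycerol
  r <- solute_rate_ratio(10, 23, diffusion_ratio = 3, kT = kT_at(300))
  expect_equal(r, 550, tolerance = 0.01)
})

test_that("counted rate ratios between barrier heights follow the Kramers form", {
  # barriers high enough that slab transit is barrier- (not diffusion-)
  # limited, the regime where the Kramers form applies
  count_total <- function(height, seed) {
    pot <- potential_spec(heights = height, centers = 0, widths = 2,
                          domain = c(-8, 8))
    ev <- 0
    for (s in 1:2) {
      tr <- simulate_langevin_1d(pot, D = 230, dt = 1e-4, n_steps = 2e6,
                                 init_z = -6, seed = seed + s,
                                 sample_every = 5)
      ev <- ev + count_crossings(tr, -4, 4)$events
    }
    ev
  }
  n_low <- count_total(6, seed = 50)
  n_high <- count_total(10, seed = 60)
  expect_gt(n_high, 0)
  observed <- n_low / n_high
  predicted <- solute_rate_ratio(6, 10, 1)
  expect_gt(observed, predicted / 2)
  expect_lt(observed, predicted * 2)
})
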