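# Contact propensities, conditioning/cooperativity, stacking, and 3D
# density clustering.

test_that("contact propensity: trivial distances and generator recovery", {
  defn <- contact_definition(cutoff = 3.5)
  always <- data.frame(dist_A = rep(2.8, 100), monomer = 1, replicate = 1)
  expect_equal(contact_propensity(always, defn)$propensity, 1)
  half <- data.frame(dist_A = rep(c(3.0, 9.0), 50), monomer = 1,
                     replicate = 1)
  expect_equal(contact_propensity(half, defn)$propensity, 0.5)
  expect_error(contact_propensity(always[0, , drop = FALSE], defn),
               "zero frames")
  # synthetic generator with target propensity 0.7 over 8 groups
  set.seed(42)
  traj <- do.call(rbind, lapply(1:8, function(g) {
    data.frame(dist_A = ifelse(runif(2000) < 0.7, 3.0, 8.0),
               monomer = (g - 1) %/% 2 + 1, replicate = (g - 1) %% 2 + 1)
  }))
  cp <- contact_propensity(traj, defn, n_boot = 500, seed = 1)
  expect_lt(abs(cp$propensity - 0.7), 2 * cp$sem + 0.02)
  expect_equal(nrow(cp$per_group), 8)
})

test_that("perfect protonation coupling gives conditional propensities 1 and 0", {
  state <- rep(c(1, 0), each = 500)
  traj <- data.frame(dist_A = ifelse(state == 1, 2.9, 8.0),
                     cond_state = state)
  res <- protonation_conditioned_propensity(traj)
  expect_equal(res$p_given_1, 1)
  expect_equal(res$p_given_0, 0)
  expect_false(res$low_occupancy_warning)
})

test_that("independent streams give conditionals equal to marginals", {
  set.seed(7)
  n <- 20000
  traj <- data.frame(dist_A = ifelse(runif(n) < 0.4, 3.0, 8.0),
                     cond_state = as.integer(runif(n) < 0.5))
  res <- protonation_conditioned_propensity(traj)
  expect_equal(res$p_given_1, res$marginal, tolerance = 0.05)
  expect_equal(res$p_given_0, res$marginal, tolerance = 0.05)
})

test_that("law of total probability ties conditionals to the marginal", {
  set.seed(8)
  n <- 5000
  state <- as.integer(runif(n) < 0.3)
  traj <- data.frame(dist_A = ifelse(runif(n) < 0.2 + 0.6 * state, 3, 8),
                     cond_state = state)
  res <- protonation_conditioned_propensity(traj)
  recon <- res$p_given_1 * res$state_fraction +
    res$p_given_0 * (1 - res$state_fraction)
  expect_equal(recon, res$marginal, tolerance = 1e-12)
})

test_that("built-in cooperativity ratio is recovered from paired contacts", {
  # contact AB occurs 5x more often when AC is formed
  set.seed(9)
  n <- 50000
  ac <- runif(n) < 0.5
  p_ab <- ifelse(ac, 0.5, 0.1)
  traj <- data.frame(dist_A = ifelse(runif(n) < p_ab, 3, 8),
                     dist_second = ifelse(ac, 3, 8))
  res <- protonation_conditioned_propensity(traj)
  expect_equal(res$cooperativity_ratio, 5, tolerance = 0.2)
})

test_that("an absent condition state yields NA conditionals, not zero", {
  traj <- data.frame(dist_A = rep(3, 50), cond_state = rep(1, 50))
  res <- protonation_conditioned_propensity(traj)
  expect_true(is.na(res$p_given_0))
  expect_equal(res$p_given_1, 1)
})

test_that("stacking requires both distance and angle criteria", {
  defn <- contact_definition(cutoff = 5.5, angle_max = 30)
  traj <- data.frame(pH = 7, monomer = 1, replicate = 1,
                     dist_A = c(4.0, 4.0, 7.0),
                     angle_deg = c(5, 90, 5))
  out <- stacking_propensity(traj, defn, n_boot = 10, seed = 1)
  expect_equal(out$propensity, 1 / 3)
  # missing angles are a hard error pointing to the plain criterion
  expect_error(stacking_propensity(data.frame(pH = 7, dist_A = 4), defn),
               "angle_deg")
})

test_that("a pH ramp in stacking propensity is detected as monotone", {
  set.seed(11)
  pHs <- seq(5, 9, 1)
  traj <- do.call(rbind, lapply(seq_along(pHs), function(i) {
    p <- 0.1 + 0.18 * (i - 1)
    n <- 4000
    stacked <- runif(n) < p
    data.frame(pH = pHs[i], monomer = rep(1:2, each = n / 2), replicate = 1,
               dist_A = ifelse(stacked, 4, 8),
               angle_deg = ifelse(stacked, 10, 70))
  }))
  out <- stacking_propensity(traj, n_boot = 50, seed = 2)
  expect_gt(cor(out$pH, out$propensity, method = "spearman"), 0)
  expect_true(all(diff(out$propensity) > 0))
})

test_that("density clustering separates two Gaussian blobs and finds centroids", {
  set.seed(12)
  n <- 4000
  blob <- function(center) {
    data.frame(x_A = rnorm(n, center[1], 1), y_A = rnorm(n, center[2], 1),
               z_A = rnorm(n, center[3], 1))
  }
  pos <- rbind(blob(c(0, 0, 0)), blob(c(10, 0, 0)))
  cl <- solute_density_clusters(pos, n_frames = n, voxel = 1,
                                occupancy_threshold = 0.02)
  expect_equal(length(cl), 2)
  cents <- t(vapply(cl, `[[`, numeric(3), "centroid"))
  cents <- cents[order(cents[, 1]), ]
  expect_lt(sqrt(sum((cents[1, ] - c(0, 0, 0))^2)), 0.5)
  expect_lt(sqrt(sum((cents[2, ] - c(10, 0, 0))^2)), 0.5)
})

test_that("point mass gives one cluster; sub-threshold uniform gives none", {
  pos <- data.frame(x_A = rep(1.2, 500), y_A = rep(-3.4, 500),
                    z_A = rep(7.7, 500))
  cl <- solute_density_clusters(pos, n_frames = 500,
                                occupancy_threshold = 0.5)
  expect_equal(length(cl), 1)
  expect_lt(sqrt(sum((cl[[1]]$centroid - c(1.2, -3.4, 7.7))^2)), 0.87)
  set.seed(13)
  unif <- data.frame(x_A = runif(5000, 0, 50), y_A = runif(5000, 0, 50),
                     z_A = runif(5000, 0, 50))
  expect_warning(
    cl0 <- solute_density_clusters(unif, n_frames = 50,
                                   occupancy_threshold = 5),
    "noisy")
  expect_equal(length(cl0), 0)
})

test_that("clustering is invariant to frame order and voxel-aligned translation", {
  set.seed(14)
  n <- 2000
  pos <- data.frame(x_A = rnorm(n, 5, 1), y_A = rnorm(n, 5, 1),
                    z_A = rnorm(n, 5, 1))
  c1 <- solute_density_clusters(pos, n_frames = n, occupancy_threshold = 0.02)
  c2 <- solute_density_clusters(pos[rev(seq_len(n)), ], n_frames = n,
                                occupancy_threshold = 0.02)
  expect_equal(c1[[1]]$centroid, c2[[1]]$centroid)
  shifted <- pos
  shifted$x_A <- shifted$x_A + 7 # integer multiple of the 1 A voxel
  c3 <- solute_density_clusters(shifted, n_frames = n,
                                occupancy_threshold = 0.02)
  expect_equal(c3[[1]]$centroid - c(7, 0, 0), c1[[1]]$centroid,
               tolerance = 1e-9)
})
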