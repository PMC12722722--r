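# Pore profiling, selections/distances, and superposition RMSD.

test_that("toy cylinder profiles to its constructed radius", {
  pore <- generate_toy_pore(data.frame(z = seq(-8, 8, 1), radius = 3))
  prof <- profile_pore(pore, seed_point = c(0, 0, 0), seed = 1)
  mid <- prof[abs(prof$z) <= 6, ]
  expect_lt(max(abs(mid$radius - 3)), 0.25)
  expect_equal(attr(prof, "min_radius"), 3, tolerance = 0.25 / 3)
  expect_false(attr(prof, "closed"))
})

test_that("hourglass constriction is located at the narrow ring", {
  zs <- seq(-8, 8, 1)
  radii <- pmax(1.5, 6 - 4.5 * exp(-zs^2 / 8))
  pore <- generate_toy_pore(data.frame(z = zs, radius = radii))
  prof <- profile_pore(pore, seed_point = c(0, 0, 0), seed = 2)
  expect_equal(attr(prof, "min_radius"), 1.5, tolerance = 0.25 / 1.5)
  expect_lt(abs(attr(prof, "min_z")), 1 + 0.25) # within one ring spacing
})

test_that("a zero-radius ring blocks the pore and is flagged as closure", {
  pore <- generate_toy_pore(
    data.frame(z = seq(-5, 5, 1),
               radius = c(6, 5, 4, 3, 2, 0, 2, 3, 4, 5, 6)))
  prof <- profile_pore(pore, seed_point = c(0, 0, -3), seed = 3)
  expect_lte(attr(prof, "min_radius"), 0.3)
  expect_true(attr(prof, "closed"))
})

test_that("an isolated seed in empty space exits to bulk immediately", {
  lone <- structure_model(data.frame(element = "C", x = 100, y = 100,
                                     z = 100, chain = "A", resno = 1,
                                     resid = "ALA", atom_name = "CA"))
  prof <- profile_pore(lone, seed_point = c(0, 0, 0), seed = 4)
  expect_true(all(attr(prof, "termination") == "end_radius"))
  expect_true(all(prof$radius >= 5))
})

test_that("every profiled sphere clears every atom (non-overlap certificate)", {
  pore <- generate_toy_pore(data.frame(z = seq(-5, 5, 1), radius = 2.5))
  prof <- profile_pore(pore, seed_point = c(0, 0, 0), seed = 5)
  xyz <- as.matrix(pore[, c("x", "y", "z")])
  for (i in seq_len(nrow(prof))) {
    center <- c(prof$cx[i], prof$cy[i], prof$z[i]) # axis frame == lab frame
    clear <- min(sqrt(colSums((t(xyz) - center)^2)) - pore$vdw)
    expect_gte(clear - prof$radius[i], -1e-6)
  }
})

test_that("profile is equivariant under rigid transformation of model+seed+axis", {
  pore <- generate_toy_pore(data.frame(z = seq(-5, 5, 1), radius = 2.5))
  p0 <- profile_pore(pore, seed_point = c(0, 0, 0), seed = 6)
  moved <- rigid_transform(pore, angle = 0.6, axis = c(0, 1, 0),
                           translation = c(5, 1, -2))
  a <- angle <- 0.6
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
              byrow = TRUE)
  new_axis <- as.numeric(R %*% c(0, 0, 1))
  p1 <- profile_pore(moved, seed_point = c(5, 1, -2), axis = new_axis,
                     seed = 6)
  n <- min(nrow(p0), nrow(p1))
  expect_equal(p1$radius[seq_len(n)], p0$radius[seq_len(n)],
               tolerance = 0.05)
})

test_that("seeding inside an atom is an error", {
  pore <- generate_toy_pore(data.frame(z = 0, radius = 3))
  expect_error(profile_pore(pore, seed_point = c(0, 4.5, 0), seed = 1),
               "inside an atom")
})

test_that("atom distances: identity, 3-4-5, selection modes and errors", {
  atoms <- data.frame(element = c("N", "C", "O"),
                      x = c(0, 3, 10), y = c(0, 4, 0), z = c(0, 0, 0),
                      chain = "A", resno = c(1, 2, 2), resid = "ALA",
                      atom_name = c("N", "CA", "O"))
  m <- structure_model(atoms)
  expect_equal(atom_distance(m, "A:1:N", "A:1:N"), 0)
  expect_equal(atom_distance(m, "A:1:N", "A:2:CA", mode = "specific"), 5)
  # min mode over a multi-atom selection picks the closest pair
  expect_equal(atom_distance(m, "A:1:N", "A:2:*"), 5)
  expect_error(atom_distance(m, "A:9:N", "A:1:N"), "matches no atoms")
  expect_error(atom_distance(m, "A:2:*", "A:1:N", mode = "specific"),
               "single-atom")
})

test_that("superposition: self-RMSD 0, rigid invariance, symmetry", {
  m <- toy_protein(40, seed = 2)
  expect_equal(superpose_rmsd(m, m)$rmsd, 0, tolerance = 1e-12)
  moved <- rigid_transform(m)
  sup <- superpose_rmsd(m, moved)
  expect_lt(sup$rmsd, 1e-6)
  # symmetric in its arguments
  m2 <- toy_protein(40, seed = 3)
  expect_equal(superpose_rmsd(m, m2)$rmsd, superpose_rmsd(m2, m)$rmsd,
               tolerance = 1e-9)
})

test_that("superposition agrees with an independent least-squares fit", {
  m <- toy_protein(30, seed = 4)
  m2 <- m
  set.seed(5)
  m2$x <- m2$x + rnorm(nrow(m2), 0, 0.3)
  m2$y <- m2$y + rnorm(nrow(m2), 0, 0.3)
  m2$z <- m2$z + rnorm(nrow(m2), 0, 0.3)
  m2 <- rigid_transform(m2)
  ours <- superpose_rmsd(m, m2, outlier_cycles = 0)$rmsd
  fixed <- as.numeric(t(as.matrix(m[, c("x", "y", "z")])))
  mobile <- as.numeric(t(as.matrix(m2[, c("x", "y", "z")])))
  ref <- bio3d::rmsd(fixed, mobile, fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("outlier rejection discounts a displaced loop from the global fit", {
  m <- toy_protein(60, seed = 6)
  m2 <- m
  loop <- m2$resno %in% 30:35
  m2$x[loop] <- m2$x[loop] + 8
  sup <- superpose_rmsd(m, m2)
  expect_lt(sup$n_atoms_used, nrow(m))
  expect_lt(sup$rmsd, 0.5)
})

test_that("residue-wise RMSD finds the displaced loop as the argmax", {
  m <- toy_protein(60, seed = 7)
  m2 <- m
  loop <- m2$resno %in% 30:35
  m2$x[loop] <- m2$x[loop] + 8
  set.seed(8)
  jig <- function(v) v + rnorm(length(v), 0, 0.1)
  m2$x <- jig(m2$x); m2$y <- jig(m2$y); m2$z <- jig(m2$z)
  rw <- residuewise_rmsd(m, m2)
  expect_true(rw$argmax$resno %in% 30:35)
  expect_true(all(rw$per_residue$rmsd[rw$per_residue$resno %in% 30:35] >
                    max(rw$per_residue$rmsd[!rw$per_residue$resno %in% 28:37])))
  # identical models give all-zero residue RMSDs
  rw0 <- residuewise_rmsd(m, m)
  expect_lt(max(rw0$per_residue$rmsd), 1e-10)
})

test_that("residue-wise RMSD is invariant to atom ordering", {
  m <- toy_protein(20, seed = 9)
  m2 <- m
  m2$x <- m2$x + 0.5
  perm <- sample(nrow(m2))
  m2p <- structure_model(as.data.frame(m2)[perm, ], source = "perm")
  r1 <- residuewise_rmsd(m, m2)
  r2 <- residuewise_rmsd(m, m2p)
  expect_equal(r1$per_residue$rmsd, r2$per_residue$rmsd, tolerance = 1e-9)
})

test_that("unknown elements get the default vdW radius with a warning", {
  atoms <- data.frame(element = "XX", x = 0, y = 0, z = 0, chain = "A",
                      resno = 1, resid = "UNK", atom_name = "X1")
  expect_warning(m <- structure_model(atoms), "default vdW")
  expect_equal(m$vdw, 1.7)
})
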