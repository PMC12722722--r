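#' Contact definition
#'
#' @param cutoff distance cutoff (A); a frame is in contact when the
#'   (minimum heavy-atom) distance is at or below it. Default 3.5 A, the
#'   usual heavy-atom donor-acceptor hydrogen-bond criterion.
#' @param angle_max optional interplanar angle threshold (degrees, in
#'   (0, 90]) for ring-stacking contacts; a frame then requires both
#'   distance and angle criteria.
#' @param label free-text pair label (e.g. "Asn209-Asp163").
#' @return a `contact_definition` list.
#' @export
contact_definition <- function(cutoff = 3.5, angle_max = NULL,
                               label = NA_character_) {
  stopifnot(cutoff > 0)
  if (!is.null(angle_max)) {
    stopifnot(angle_max > 0, angle_max <= 90)
  }
  structure(list(cutoff = cutoff, angle_max = angle_max, label = label),
            class = "contact_definition")
}

contact_frames <- function(traj, defn) {
  ok <- traj$dist_A <= defn$cutoff
  if (!is.null(defn$angle_max)) {
    if (is.null(traj$angle_deg)) {
      stop("contact definition has an angle threshold but the trajectory ",
           "has no angle_deg column; use contact_propensity() with a plain ",
           "distance cutoff instead")
    }
    ok <- ok & (traj$angle_deg <= defn$angle_max)
  }
  ok
}

group_key <- function(traj) {
  m <- if (!is.null(traj$monomer)) traj$monomer else 1
  r <- if (!is.null(traj$replicate)) traj$replicate else 1
  paste(m, r, sep = "/")
}

#' Contact propensity with bootstrap SEM over monomers and replicates
#'
#' Per-group propensity is the fraction of frames satisfying the contact
#' criterion; the headline value is the mean over (monomer, replicate)
#' groups with SEM from [bootstrap_band()] — the per-monomer,
#' per-replicate bootstrap used for interaction propensities.
#'
#' @param traj data frame with columns `dist_A` and optionally
#'   `angle_deg`, `monomer`, `replicate`.
#' @param defn a [contact_definition()].
#' @param n_boot,seed bootstrap controls.
#' @return list with `propensity`, `sem`, `per_group` (data frame),
#'   `definition`.
#' @export
contact_propensity <- function(traj, defn = contact_definition(),
                               n_boot = 1000L, seed = 1L) {
  stopifnot(is.data.frame(traj), "dist_A" %in% names(traj))
  if (!nrow(traj)) stop("trajectory has zero frames")
  ok <- contact_frames(traj, defn)
  key <- group_key(traj)
  per <- tapply(ok, key, mean)
  per_group <- data.frame(group = names(per), propensity = as.numeric(per),
                          row.names = NULL)
  sem <- if (nrow(per_group) >= 2) {
    bootstrap_band(per_group$propensity, n_boot, seed)
  } else {
    NA_real_
  }
  list(propensity = mean(per_group$propensity), sem = sem,
       per_group = per_group, definition = defn)
}

#' Protonation-conditioned and cooperative contact propensities
#'
#' Conditions the contact of a primary pair on a synchronized binary
#' state — the protonation state of a nearby titratable residue, or the
#' contact state of a second pair (cooperativity). Reports P(contact |
#' state 1), P(contact | state 0), the unconditioned marginals, and the
#' joint table. A condition state that never occurs yields `NA`
#' conditionals (undefined, not zero); states occupying under 5% of
#' frames are flagged.
#'
#' @param traj data frame with `dist_A` (primary pair) and either
#'   `cond_state` (binary 0/1) or `dist_second` (distance of the
#'   conditioning pair, A).
#' @param defn [contact_definition()] for the primary pair.
#' @param defn_second [contact_definition()] for the conditioning pair
#'   when `dist_second` is used.
#' @return list with `p_given_1`, `p_given_0`, `marginal`,
#'   `state_fraction`, `joint` (2x2 table of fractions),
#'   `low_occupancy_warning`, and `cooperativity_ratio`
#'   (`p_given_1 / p_given_0`).
#' @export
protonation_conditioned_propensity <- function(traj,
                                               defn = contact_definition(),
                                               defn_second = contact_definition()) {
  stopifnot(is.data.frame(traj), "dist_A" %in% names(traj))
  if (!nrow(traj)) stop("trajectory has zero frames")
  contact <- contact_frames(traj, defn)
  cond <- if (!is.null(traj$cond_state)) {
    as.logical(traj$cond_state)
  } else if (!is.null(traj$dist_second)) {
    traj$dist_second <= defn_second$cutoff
  } else {
    stop("need a cond_state column or a dist_second column to condition on")
  }
  stopifnot(length(cond) == length(contact))
  f1 <- mean(cond)
  p1 <- if (any(cond)) mean(contact[cond]) else NA_real_
  p0 <- if (any(!cond)) mean(contact[!cond]) else NA_real_
  joint <- matrix(c(mean(contact & cond), mean(contact & !cond),
                    mean(!contact & cond), mean(!contact & !cond)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(contact = c("yes", "no"),
                                  condition = c("state1", "state0")))
  list(p_given_1 = p1, p_given_0 = p0, marginal = mean(contact),
       state_fraction = f1, joint = joint,
       low_occupancy_warning = min(f1, 1 - f1) < 0.05,
       cooperativity_ratio = p1 / p0)
}

#' Ring-stacking propensity as a function of pH
#'
#' A frame counts as stacked when the ring-centroid distance is at or
#' below the cutoff AND the interplanar angle is at or below the angle
#' threshold (defaults 5.5 A and 30 degrees). Returns the propensity per
#' pH with bootstrap SEM over (monomer, replicate) groups, enabling a
#' monotonicity check of stacking versus pH.
#'
#' @param traj data frame with `dist_A`, `angle_deg`, `pH`, and
#'   optionally `monomer`, `replicate`.
#' @param defn a [contact_definition()] with `angle_max` set.
#' @param n_boot,seed bootstrap controls.
#' @return data frame with columns `pH`, `propensity`, `sem`.
#' @export
stacking_propensity <- function(traj,
                                defn = contact_definition(cutoff = 5.5,
                                                          angle_max = 30),
                                n_boot = 1000L, seed = 1L) {
  stopifnot(is.data.frame(traj), "pH" %in% names(traj))
  if (is.null(traj$angle_deg)) {
    stop("stacking requires an angle_deg column; for distance-only ",
         "criteria use contact_propensity()")
  }
  if (is.null(defn$angle_max)) {
    stop("stacking definition must include angle_max")
  }
  pHs <- sort(unique(traj$pH))
  rows <- lapply(pHs, function(p) {
    sub <- traj[traj$pH == p, , drop = FALSE]
    cp <- contact_propensity(sub, defn, n_boot, seed)
    data.frame(pH = p, propensity = cp$propensity, sem = cp$sem)
  })
  do.call(rbind, rows)
}

#' 3-D solute density clusters from trajectory positions
#'
#' Histograms solute positions on a cubic voxel grid, keeps voxels whose
#' occupancy (fraction of frames) exceeds a threshold, and groups them by
#' 26-connectivity. Clusters are ranked by total occupancy; the
#' occupancy-weighted centroid of each cluster is reported so it can be
#' compared against modelled ligand sites (e.g. the distance from a
#' cluster centroid to a reference coordinate).
#'
#' @param positions data frame with columns `x_A`, `y_A`, `z_A`, one row
#'   per frame (or per solute copy per frame).
#' @param n_frames number of trajectory frames the positions came from
#'   (defaults to `nrow(positions)`).
#' @param voxel voxel edge length (A), default 1.
#' @param occupancy_threshold voxel occupancy cutoff; `NULL` (default)
#'   uses 10x the mean occupancy over the occupied bounding box.
#' @return list of `density_cluster` objects, each with `centroid` (A),
#'   `occupancy` (summed voxel occupancy), `n_voxels`, `voxels` (integer
#'   grid indices), plus attributes `voxel`, `origin`, `threshold`,
#'   `low_frames_warning`.
#' @export
solute_density_clusters <- function(positions, n_frames = nrow(positions),
                                    voxel = 1.0,
                                    occupancy_threshold = NULL) {
  stopifnot(is.data.frame(positions),
            all(c("x_A", "y_A", "z_A") %in% names(positions)),
            voxel > 0, n_frames >= 1)
  low_frames <- n_frames < 100
  if (low_frames) {
    warning("fewer than 100 frames: density clusters will be noisy")
  }
  xyz <- as.matrix(positions[, c("x_A", "y_A", "z_A")])
  origin <- floor(apply(xyz, 2, min) / voxel) * voxel
  idx <- floor(sweep(xyz, 2, origin) / voxel) + 1L
  dims <- apply(idx, 2, max)
  key <- (idx[, 1] - 1L) + dims[1] * ((idx[, 2] - 1L) + dims[2] * (idx[, 3] - 1L))
  counts <- table(key)
  occ <- as.numeric(counts) / n_frames
  keys <- as.numeric(names(counts))
  if (is.null(occupancy_threshold)) {
    n_vox_box <- prod(dims)
    occupancy_threshold <- 10 * nrow(xyz) / (n_frames * n_vox_box)
  }
  sel <- occ > occupancy_threshold
  if (!any(sel)) {
    return(structure(list(), voxel = voxel, origin = origin,
                     threshold = occupancy_threshold,
                     low_frames_warning = low_frames))
  }
  keys <- keys[sel]; occ <- occ[sel]
  vx <- cbind(keys %% dims[1],
              (keys %/% dims[1]) %% dims[2],
              keys %/% (dims[1] * dims[2])) + 1L

  # 26-connected components by BFS over the occupied voxel set
  keyset <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(keys)) assign(as.character(keys[i]), i, envir = keyset)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  comp <- integer(length(keys))
  nc <- 0L
  for (i in seq_along(keys)) {
    if (comp[i] != 0L) next
    nc <- nc + 1L
    queue <- i
    comp[i] <- nc
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nb <- sweep(offsets, 2, as.numeric(vx[cur, ]), `+`)
      nbkey <- (nb[, 1] - 1) + dims[1] * ((nb[, 2] - 1) + dims[2] * (nb[, 3] - 1))
      for (k in nbkey) {
        j <- keyset[[as.character(k)]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- nc
          queue <- c(queue, j)
        }
      }
    }
  }
  clusters <- lapply(seq_len(nc), function(cid) {
    members <- which(comp == cid)
    centers <- sweep((vx[members, , drop = FALSE] - 0.5) * voxel, 2,
                     origin, `+`)
    w <- occ[members] / sum(occ[members])
    structure(list(centroid = colSums(centers * w),
                   occupancy = sum(occ[members]),
                   n_voxels = length(members),
                   voxels = vx[members, , drop = FALSE]),
              class = "density_cluster")
  })
  clusters <- clusters[order(vapply(clusters, `[[`, numeric(1), "occupancy"),
                             decreasing = TRUE)]
  structure(clusters, voxel = voxel, origin = origin,
            threshold = occupancy_threshold,
            low_frames_warning = low_frames)
}
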