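#' Van der Waals radius tables
#'
#' `"bondi"` is the Bondi (1964) set, the package default. `"hole"` is
#' the simple AMBER-like table traditionally used by sphere-squeezing
#' pore profilers. Unknown elements fall back to 1.70 A with a warning at
#' assignment time.
#'
#' @param table `"bondi"` or `"hole"`.
#' @return named numeric vector of radii (A) by element symbol.
#' @export
vdw_table <- function(table = c("bondi", "hole")) {
  table <- match.arg(table)
  switch(table,
    bondi = c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
              F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90),
    hole = c(H = 1.00, C = 1.85, N = 1.75, O = 1.65, S = 2.00, P = 2.10,
             F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 2.00)
  )
}

DEFAULT_VDW <- 1.70

#' Construct a structure model from an atom table
#'
#' @param atoms data frame with columns `element`, `x`, `y`, `z` (A),
#'   `chain`, `resno`, `resid`, `atom_name`, and optionally `vdw`,
#'   `hetero`.
#' @param source free-text provenance label.
#' @param radii vdW table name passed to [vdw_table()] used to fill a
#'   missing `vdw` column.
#' @return a `structure_model` (data frame of atoms with metadata
#'   attributes).
#' @export
structure_model <- function(atoms, source = "unknown", radii = "bondi") {
  need <- c("element", "x", "y", "z", "chain", "resno", "resid", "atom_name")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  if (is.null(atoms$vdw)) {
    tab <- vdw_table(radii)
    el <- toupper(atoms$element)
    atoms$vdw <- unname(tab[el])
    unknown <- is.na(atoms$vdw)
    if (any(unknown)) {
      warning("unknown element(s) ",
              paste(unique(el[unknown]), collapse = ", "),
              ": using default vdW radius ", DEFAULT_VDW, " A")
      atoms$vdw[unknown] <- DEFAULT_VDW
    }
  }
  stopifnot(all(atoms$vdw > 0))
  if (is.null(atoms$hetero)) atoms$hetero <- FALSE
  structure(atoms, class = c("structure_model", "data.frame"),
            source = source)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chains (source: %s)\n",
              nrow(x), length(unique(x$chain)), attr(x, "source")))
  invisible(x)
}

#' Build a toy pore structure with a prescribed radius profile
#'
#' Places rings of pseudo-atoms around the z axis so that the inner
#' accessible radius at each ring equals the requested radius (the ring
#' of atom centers sits at `radius + vdw_radius` from the axis). Atom
#' spacing along each ring (and between rings, if the caller spaces the
#' profile accordingly) must not exceed the vdW radius so probe spheres
#' cannot leak between wall atoms. A requested radius of 0 blocks the
#' pore at that ring. This is the construction oracle for
#' [profile_pore()].
#'
#' @param profile data frame with columns `z` and `radius` (A),
#'   radii >= 0.
#' @param atom_spacing target spacing of wall atoms along each ring (A).
#' @param vdw_radius vdW radius assigned to every pseudo-atom (A).
#' @return a `structure_model` of the pore wall.
#' @export
generate_toy_pore <- function(profile, atom_spacing = 1.0,
                              vdw_radius = 1.5) {
  stopifnot(is.data.frame(profile),
            all(c("z", "radius") %in% names(profile)),
            all(profile$radius >= 0), atom_spacing > 0,
            atom_spacing <= vdw_radius)
  rows <- lapply(seq_len(nrow(profile)), function(i) {
    r_ring <- profile$radius[i] + vdw_radius
    n_at <- max(6L, ceiling(2 * pi * r_ring / atom_spacing))
    th <- 2 * pi * (seq_len(n_at) - 1) / n_at
    data.frame(element = "C", x = r_ring * cos(th), y = r_ring * sin(th),
               z = profile$z[i], chain = "P", resno = i, resid = "PSE",
               atom_name = "C", vdw = vdw_radius)
  })
  structure_model(do.call(rbind, rows), source = "toy_pore")
}

# --- reading deposited coordinate files -------------------------------

#' Read a PDB or mmCIF file into a structure model
#'
#' Uses bio3d for parsing. Alternate locations are resolved by keeping
#' the highest-occupancy copy of each (chain, residue, atom). Waters and
#' other hetero atoms are retained and flagged in the `hetero` column.
#' vdW radii are assigned from the Bondi table by element.
#'
#' @param path path to a `.pdb` or `.cif` file (format chosen by
#'   extension).
#' @param radii vdW table name (see [vdw_table()]).
#' @return a `structure_model`.
#' @export
read_structure <- function(path, radii = "bondi") {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, rm.alt = FALSE)
  } else {
    bio3d::read.pdb(path, rm.alt = FALSE)
  }
  at <- parsed$atom
  df <- data.frame(
    element = toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                    substr(trimws(at$elety), 1, 1),
                                    at$elesy))),
    x = at$x, y = at$y, z = at$z,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, resid = at$resid,
    atom_name = trimws(at$elety),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    hetero = at$type != "ATOM",
    stringsAsFactors = FALSE
  )
  # altloc policy: keep the highest-occupancy copy per site
  key <- paste(df$chain, df$resno, df$atom_name)
  ord <- order(key, -df$occupancy)
  df <- df[ord, ][!duplicated(key[ord]), ]
  df <- df[order(as.integer(rownames(df))), ]
  rownames(df) <- NULL
  structure_model(df, source = basename(path), radii = radii)
}

# --- selections and distances -----------------------------------------

# Resolve a "chain:resno:atomname" selection (fields may be "*").
resolve_selection <- function(model, selection) {
  parts <- strsplit(selection, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3) {
    stop("selection must be 'chain:resno:atomname' (use * as wildcard): ",
         selection)
  }
  keep <- rep(TRUE, nrow(model))
  if (parts[1] != "*") keep <- keep & model$chain == parts[1]
  if (parts[2] != "*") keep <- keep & model$resno == as.integer(parts[2])
  if (parts[3] != "*") keep <- keep & model$atom_name == parts[3]
  idx <- which(keep)
  if (!length(idx)) {
    cand <- unique(paste(model$chain, model$resno, model$atom_name,
                         sep = ":"))
    stop("selection '", selection, "' matches no atoms; examples of ",
         "available atoms: ",
         paste(head(cand, 5), collapse = ", "))
  }
  idx
}

#' Distance between two atom selections
#'
#' @param model a `structure_model`.
#' @param selection_a,selection_b selection strings
#'   `"chain:resno:atomname"`; `*` is a wildcard for any field.
#' @param mode `"min"` for the minimum over the atom-pair cross product,
#'   `"specific"` to require single-atom selections.
#' @return distance in A.
#' @export
atom_distance <- function(model, selection_a, selection_b,
                          mode = c("min", "specific")) {
  mode <- match.arg(mode)
  ia <- resolve_selection(model, selection_a)
  ib <- resolve_selection(model, selection_b)
  if (mode == "specific" && (length(ia) != 1 || length(ib) != 1)) {
    stop("mode 'specific' requires single-atom selections (got ",
         length(ia), " and ", length(ib), " atoms)")
  }
  A <- as.matrix(model[ia, c("x", "y", "z")])
  B <- as.matrix(model[ib, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

# --- superposition ----------------------------------------------------

# Kabsch least-squares rotation of B onto A (both n x 3, already paired).
kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(t(B0) %*% A0)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = ca - as.numeric(R %*% cb))
}

pair_atoms <- function(model_a, model_b, selection = "*:*:*") {
  ia <- resolve_selection(model_a, selection)
  ib <- resolve_selection(model_b, selection)
  ka <- paste(model_a$chain[ia], model_a$resno[ia], model_a$atom_name[ia])
  kb <- paste(model_b$chain[ib], model_b$resno[ib], model_b$atom_name[ib])
  common <- intersect(ka, kb)
  list(a = ia[match(common, ka)], b = ib[match(common, kb)], keys = common)
}

#' Superpose two structures and report the RMSD
#'
#' Kabsch least-squares superposition of paired atoms (matched by chain,
#' residue number and atom name), followed by `outlier_cycles` rounds of
#' rejecting pairs deviating by more than twice the current RMSD and
#' re-fitting — emulating the iterative-trimming behaviour of common
#' structure viewers' align commands.
#'
#' @param model_a,model_b `structure_model`s.
#' @param selection selection string applied to both models.
#' @param outlier_cycles trimming rounds (default 5; 0 for a plain
#'   all-pair fit).
#' @return list with `rmsd` (A), `n_atoms_used`, `n_atoms_total`,
#'   `rotation` (3x3), `translation` (length 3; maps model_b onto
#'   model_a).
#' @export
superpose_rmsd <- function(model_a, model_b, selection = "*:*:*",
                           outlier_cycles = 5L) {
  pr <- pair_atoms(model_a, model_b, selection)
  if (length(pr$a) < 3) stop("need >= 3 paired atoms")
  A <- as.matrix(model_a[pr$a, c("x", "y", "z")])
  B <- as.matrix(model_b[pr$b, c("x", "y", "z")])
  keep <- rep(TRUE, nrow(A))
  fit <- NULL
  rmsd <- NA_real_
  for (cycle in 0:outlier_cycles) {
    if (sum(keep) < 3) stop("fewer than 3 atom pairs left after rejection")
    fit <- kabsch(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    Bt <- sweep(B %*% t(fit$R), 2, fit$t, `+`)
    dev <- sqrt(rowSums((A - Bt)^2))
    rmsd <- sqrt(mean(dev[keep]^2))
    if (cycle == outlier_cycles) break
    new_keep <- dev <= pmax(2 * rmsd, 1e-8)
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  list(rmsd = rmsd, n_atoms_used = sum(keep), n_atoms_total = nrow(A),
       rotation = fit$R, translation = fit$t)
}

#' Residue-wise backbone RMSD between two conformations
#'
#' After one global backbone superposition ([superpose_rmsd()]), computes
#' the per-residue RMSD over backbone atoms (N, CA, C, O by default) and
#' reports the argmax residue — the site of the largest conformational
#' shift (e.g. a gating loop).
#'
#' @param model_a,model_b `structure_model`s.
#' @param backbone_atoms atom names used (default N, CA, C, O).
#' @param outlier_cycles passed to the global superposition.
#' @return list with `per_residue` (data frame: chain, resno, rmsd,
#'   n_atoms), `argmax` (row of the largest RMSD), `global_rmsd`,
#'   `skipped` (residues lacking backbone atoms).
#' @export
residuewise_rmsd <- function(model_a, model_b,
                             backbone_atoms = c("N", "CA", "C", "O"),
                             outlier_cycles = 5L) {
  bb_a <- model_a[model_a$atom_name %in% backbone_atoms, , drop = FALSE]
  bb_b <- model_b[model_b$atom_name %in% backbone_atoms, , drop = FALSE]
  pr <- pair_atoms(bb_a, bb_b)
  if (length(pr$a) < 3) stop("need >= 3 paired backbone atoms")
  sup <- superpose_rmsd(bb_a, bb_b, outlier_cycles = outlier_cycles)
  A <- as.matrix(bb_a[pr$a, c("x", "y", "z")])
  B <- as.matrix(bb_b[pr$b, c("x", "y", "z")])
  Bt <- sweep(B %*% t(sup$rotation), 2, sup$translation, `+`)
  dev2 <- rowSums((A - Bt)^2)
  res_key <- paste(bb_a$chain[pr$a], bb_a$resno[pr$a])
  agg <- tapply(dev2, res_key, function(v) sqrt(mean(v)))
  n_at <- tapply(dev2, res_key, length)
  parts <- strsplit(names(agg), " ", fixed = TRUE)
  per <- data.frame(chain = vapply(parts, `[`, character(1), 1),
                    resno = as.integer(vapply(parts, `[`, character(1), 2)),
                    rmsd = as.numeric(agg), n_atoms = as.integer(n_at),
                    row.names = NULL)
  per <- per[order(per$chain, per$resno), ]
  rownames(per) <- NULL
  # residues present in only one model, or with no backbone atoms
  all_res_a <- unique(paste(model_a$chain, model_a$resno))
  skipped <- setdiff(all_res_a, names(agg))
  list(per_residue = per, argmax = per[which.max(per$rmsd), ],
       global_rmsd = sup$rmsd, skipped = skipped)
}

# --- pore profiling ---------------------------------------------------

#' Sphere-squeezing pore-radius profile
#'
#' HOLE-style profiling: at each axial station the radius of the largest
#' sphere that clears every atom's vdW sphere is found by maximizing the
#' clearance `min_i(|center - atom_i| - vdw_i)` over the in-plane sphere
#' center, using stochastic restarts around the previous station's center
#' followed by Nelder-Mead polish. The march proceeds in both directions
#' from the seed point and a direction terminates when the radius reaches
#' `end_radius` (exit to bulk) or the station limit is hit. A channel is
#' flagged closed when the minimum radius falls below
#' `closure_threshold`.
#'
#' @param model a `structure_model`.
#' @param seed_point length-3 start coordinate (A) inside the lumen.
#' @param axis channel axis direction (defaults to z); normalized
#'   internally.
#' @param step axial step (A), default 0.25.
#' @param end_radius bulk-exit radius (A), default 5 — the conventional
#'   end radius for channel profiling.
#' @param seed integer RNG seed for the stochastic restarts.
#' @param n_restarts stochastic restarts per station (default 64).
#' @param max_stations station limit per direction.
#' @param max_drift maximum in-plane drift of the sphere center between
#'   stations (A); keeps the probe from escaping sideways out of the
#'   lumen.
#' @param closure_threshold radius (A) below which the profile is flagged
#'   closed.
#' @return a `pore_profile`: data frame `(z, radius, cx, cy)` in axis
#'   coordinates relative to the seed point, with attributes
#'   `termination` (per direction), `min_radius`, `min_z`, `closed`.
#' @export
profile_pore <- function(model, seed_point, axis = c(0, 0, 1),
                         step = 0.25, end_radius = 5, seed = 1L,
                         n_restarts = 64L, max_stations = 200L,
                         max_drift = 1.0, closure_threshold = 0.5) {
  stopifnot(inherits(model, "structure_model"), length(seed_point) == 3,
            length(axis) == 3, step > 0, end_radius > 0)
  a <- axis / sqrt(sum(axis^2))
  # orthonormal in-plane basis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  xyz <- sweep(as.matrix(model[, c("x", "y", "z")]), 2, seed_point)
  P <- cbind(xyz %*% u, xyz %*% v, xyz %*% a) # plane1, plane2, axial
  vdw <- model$vdw
  max_vdw <- max(vdw)

  clearance <- function(cx, cy, z0, sub, sub_vdw) {
    if (!nrow(sub)) return(end_radius)
    min(sqrt((sub[, 1] - cx)^2 + (sub[, 2] - cy)^2 + (sub[, 3] - z0)^2) -
          sub_vdw)
  }
  seed_clear <- clearance(0, 0, 0, P, vdw)
  if (seed_clear < 0) stop("seed_point lies inside an atom")

  best_at_station <- function(z0, c_prev) {
    near <- abs(P[, 3] - z0) <= end_radius + max_vdw
    sub <- P[near, , drop = FALSE]
    sub_vdw <- vdw[near]
    obj <- function(p) {
      drift <- sqrt(sum((p - c_prev)^2))
      pen <- if (drift > max_drift) 1e3 * (drift - max_drift)^2 else 0
      -(clearance(p[1], p[2], z0, sub, sub_vdw) - pen)
    }
    starts <- rbind(c_prev,
                    cbind(c_prev[1] + rnorm(n_restarts - 1, 0, max_drift / 2),
                          c_prev[2] + rnorm(n_restarts - 1, 0, max_drift / 2)))
    # polish only the most promising restarts (plus the previous center)
    init_vals <- -apply(starts, 1, obj)
    polish <- unique(c(1L, order(init_vals, decreasing = TRUE)[seq_len(
      min(8L, nrow(starts)))]))
    best <- NULL; best_val <- -Inf
    for (i in polish) {
      o <- optim(starts[i, ], obj, method = "Nelder-Mead",
                 control = list(maxit = 200, reltol = 1e-10))
      if (-o$value > best_val) {
        best_val <- -o$value
        best <- o$par
      }
      if (best_val >= end_radius) break
    }
    list(center = best, radius = max(best_val, 0))
  }

  march <- function(dir) {
    out <- list()
    c_prev <- c(0, 0)
    termination <- "station_limit"
    for (s in seq_len(max_stations)) {
      z0 <- dir * s * step
      st <- best_at_station(z0, c_prev)
      out[[s]] <- c(z = z0, radius = st$radius, cx = st$center[1],
                    cy = st$center[2])
      c_prev <- st$center
      if (st$radius >= end_radius) {
        termination <- "end_radius"
        break
      }
    }
    list(rows = out, termination = termination)
  }

  res <- with_seed(seed, {
    st0 <- best_at_station(0, c(0, 0))
    up <- march(1)
    down <- march(-1)
    list(st0 = st0, up = up, down = down)
  })
  rows <- c(rev(res$down$rows),
            list(c(z = 0, radius = res$st0$radius, cx = res$st0$center[1],
                   cy = res$st0$center[2])),
            res$up$rows)
  prof <- as.data.frame(do.call(rbind, rows))
  i_min <- which.min(prof$radius)
  structure(prof, class = c("pore_profile", "data.frame"),
            termination = c(down = res$down$termination,
                            up = res$up$termination),
            min_radius = prof$radius[i_min], min_z = prof$z[i_min],
            closed = prof$radius[i_min] < closure_threshold,
            axis = a, seed_point = seed_point)
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf(
    "pore_profile: %d stations, min radius %.2f A at z = %.2f A%s\n",
    nrow(x), attr(x, "min_radius"), attr(x, "min_z"),
    if (attr(x, "closed")) " [CLOSED]" else ""))
  invisible(x)
}
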