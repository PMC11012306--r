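# Rigid-body docking: exhaustive rotational sampling on a deterministic
# quasi-uniform SO(3) grid, FFT translational correlation of
# Katchalski-Katzir-style digitised shapes (surface weight 1, core weight
# 9i so core overlap is penalised through the imaginary channel), then a
# soft pairwise contact potential re-scores the ten best translations per
# rotation and the best re-scored translation is kept per rotation.

ELEMENT_RADII <- c(H = 0.12, C = 0.17, N = 0.155, O = 0.152, P = 0.19,
                   S = 0.18)

element_radius <- function(element) {
  r <- ELEMENT_RADII[element]
  r[is.na(r)] <- 0.17
  unname(r)
}

#' Deterministic quasi-uniform rotation sample of SO(3)
#'
#' Hopf-coordinate grid: a Fibonacci lattice of axis directions crossed
#' with evenly spaced circle angles, sized so the nearest-neighbour
#' geodesic spacing is about `interval_deg` (about 576 rotations at the
#' 15-degree production setting, scaling as the inverse cube of the
#' interval). The identity rotation is always the first element.
#'
#' @param interval_deg target angular spacing, degrees, in (0, 90]
#' @return m x 4 matrix of unit quaternions (w, x, y, z)
#' @export
sample_rotations <- function(interval_deg = 15) {
  if (interval_deg <= 0 || interval_deg > 90)
    stop("interval must be in (0, 90] degrees")
  n_psi <- max(1L, round(360 / interval_deg))
  n_tot <- 576 * (15 / interval_deg)^3
  n_sph <- max(1L, round(n_tot / n_psi))
  sph <- fibonacci_sphere(n_sph)
  theta <- acos(pmin(1, pmax(-1, sph[, 3])))
  phi <- atan2(sph[, 2], sph[, 1])
  psi <- pi * (seq_len(n_psi) - 1) / n_psi   # [0, pi): quaternion half-angles
  q <- matrix(0, n_sph * n_psi, 4)
  k <- 0
  for (i in seq_len(n_sph)) {
    ct <- cos(theta[i] / 2); st <- sin(theta[i] / 2)
    for (ps in psi) {
      k <- k + 1
      q[k, ] <- c(ct * cos(ps), ct * sin(ps),
                  st * cos(phi[i] + ps), st * sin(phi[i] + ps))
    }
  }
  # first point is the pole with psi = 0: exactly the identity
  q[1, ] <- c(1, 0, 0, 0)
  q
}

#' Define a docking grid around a receptor/ligand pair
#'
#' Cubic lattice with power-of-two dimension large enough for the receptor
#' extent plus the ligand diameter plus clearance on every side, so every
#' rigid placement of the ligand against the receptor surface is
#' representable without wrap-around artefacts.
#'
#' @param receptor,ligand `apt_structure`s
#' @param spacing lattice spacing, nm (0.12 at the production setting)
#' @param clearance extra margin, nm
#' @return list of class `dock_grid` with `spacing`, `dim`, `origin`
#' @export
dock_grid_spec <- function(receptor, ligand, spacing = 0.12, clearance = 0.5) {
  if (spacing <= 0) stop("spacing must be positive")
  rc <- coords(receptor, heavy_only = TRUE)
  lc <- coords(ligand, heavy_only = TRUE)
  lig_r <- max(sqrt(rowSums(sweep(lc, 2, colMeans(lc))^2))) + 0.3
  ext <- apply(rc, 2, range)
  need <- max(ext[2, ] - ext[1, ]) + 2 * (lig_r + clearance) + 2 * 0.3
  dim <- 2^ceiling(log2(need / spacing))
  origin <- colMeans(rc) - dim * spacing / 2
  structure(list(spacing = spacing, dim = as.integer(dim), origin = origin),
            class = "dock_grid")
}

#' Digitise a structure onto a docking grid
#'
#' Katchalski-Katzir digitisation: every cell whose centre lies within an
#' atom's element radius is occupied. For the receptor, occupied cells
#' with all six lattice neighbours occupied form the core and carry the
#' imaginary penalty weight `0+9i`; the remaining occupied (surface) cells
#' carry weight 1. The ligand carries weight 1 on all occupied cells.
#'
#' @param s an `apt_structure` (heavy atoms are used)
#' @param g a [dock_grid_spec()]
#' @param role `"receptor"` or `"ligand"`
#' @param core_penalty imaginary core weight (classic value 9)
#' @return complex array of dimension `g$dim^3`
#' @export
grid_project <- function(s, g, role = c("receptor", "ligand"),
                         core_penalty = 9) {
  role <- match.arg(role)
  a <- s$atoms[!s$atoms$is_hydrogen, ]
  if (!nrow(a)) stop("empty structure: nothing to project")
  occ <- project_occupancy(as.matrix(a[, c("x", "y", "z")]),
                           element_radius(a$element), g, wrap = FALSE)
  if (role == "ligand") return(occ * (1 + 0i))
  core <- occ &
    shift_arr(occ, 1, 1) & shift_arr(occ, 1, -1) &
    shift_arr(occ, 2, 1) & shift_arr(occ, 2, -1) &
    shift_arr(occ, 3, 1) & shift_arr(occ, 3, -1)
  surf <- occ & !core
  surf * (1 + 0i) + core * (0 + core_penalty * 1i)
}

# logical occupancy array; wrap = TRUE folds indices periodically (used for
# the mobile ligand, whose translations the FFT treats circularly)
project_occupancy <- function(xyz, radii, g, wrap = FALSE) {
  d <- g$dim
  occ <- array(FALSE, c(d, d, d))
  rel <- sweep(xyz, 2, g$origin)
  if (!wrap) {
    lo <- rel - radii; hi <- rel + radii
    if (any(lo < 0) || any(hi >= d * g$spacing))
      stop("structure exceeds the docking grid")
  }
  for (i in seq_len(nrow(xyz))) {
    r <- radii[i]
    rng <- lapply(1:3, function(ax)
      floor((rel[i, ax] - r) / g$spacing):ceiling((rel[i, ax] + r) / g$spacing))
    cells <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    ctr <- sweep(cells * g$spacing, 2, rel[i, ])
    inside <- rowSums(ctr^2) <= r^2
    cells <- cells[inside, , drop = FALSE]
    if (!nrow(cells)) next
    cells <- cells %% d + 1L
    occ[cells] <- TRUE
  }
  occ
}

# circular shift of a 3-D array along one axis
shift_arr <- function(x, axis, by) {
  d <- dim(x)[axis]
  idx <- ((seq_len(d) - 1 - by) %% d) + 1
  switch(axis, x[idx, , ], x[, idx, ], x[, , idx])
}

#' Translational score map by FFT correlation
#'
#' For every lattice translation `t`, the correlation
#' `C(t) = sum_x R(x) * L(x - t)` is computed by 3-D FFT. Its real part
#' counts surface contact; its imaginary part carries the core-overlap
#' penalty channel. The returned score is `Re(C) - Im(C)` (surface contact
#' minus the weighted core overlap), identical to the direct lattice sum.
#'
#' @param receptor_grid,ligand_grid equal-dimension complex arrays from
#'   [grid_project()]
#' @param components if `TRUE`, also return the surface and core channels
#' @return numeric score array over translations (or a list when
#'   `components = TRUE`)
#' @export
fft_translate_score <- function(receptor_grid, ligand_grid,
                                components = FALSE) {
  if (!all(dim(receptor_grid) == dim(ligand_grid)))
    stop("grid dimension mismatch")
  C <- stats::fft(stats::fft(receptor_grid) * Conj(stats::fft(ligand_grid)),
                  inverse = TRUE) / length(receptor_grid)
  surface <- Re(C); core_pen <- Im(C)
  # round-off guard: both channels are integer-valued lattice sums
  if (components) list(score = surface - core_pen, surface = surface,
                       core_penalty = core_pen)
  else surface - core_pen
}

#' Soft pairwise contact potential between two heavy-atom sets
#'
#' The re-scoring stage's documented stand-in for a knowledge-based
#' potential: +1 per heavy-atom pair in the attractive shell (0.3-0.6 nm),
#' minus `clash_weight` per pair closer than 0.25 nm; higher is better.
#'
#' @param a_coords,b_coords row-wise heavy-atom coordinate matrices, nm
#' @param r_clash hard-repulsion distance, nm
#' @param r_att attractive shell `(min, max)`, nm
#' @param clash_weight penalty per clashing pair
#' @return list with `score`, `n_attractive`, `n_clash`
#' @export
pair_potential <- function(a_coords, b_coords, r_clash = 0.25,
                           r_att = c(0.3, 0.6), clash_weight = 20) {
  d2 <- cross_dist2(a_coords, b_coords)
  n_clash <- sum(d2 < r_clash^2)
  n_att <- sum(d2 >= r_att[1]^2 & d2 <= r_att[2]^2)
  list(score = n_att - clash_weight * n_clash,
       n_attractive = n_att, n_clash = n_clash)
}

#' Rigid-body dock a ligand against an immobilised receptor
#'
#' Two-stage protocol: for each rotation of the deterministic SO(3) grid,
#' the FFT shape-correlation map ranks all lattice translations; the ten
#' best are re-scored with [pair_potential()] and the best re-scored
#' translation is kept for that rotation. The global list, one pose per
#' rotation at most, is returned ranked by re-score (ties broken by pose
#' id, i.e. rotation order).
#'
#' @param receptor,ligand `apt_structure`s; the receptor stays fixed
#' @param interval_deg rotational sampling interval (15 at production
#'   settings; 30 or more for coarse runs)
#' @param spacing grid spacing, nm (0.12 production, 0.3 coarse)
#' @param top_per_rot translations re-scored per rotation
#' @param min_shape minimum shape score for a candidate translation
#' @return data.frame of poses: `pose_id`, quaternion columns `qw..qz`,
#'   translation `tx..tz` (final ligand heavy-atom centroid, nm),
#'   `shape_score`, `rescore`, `n_clash`; zero rows (with a warning) if no
#'   rotation yields a non-clashing contact
#' @export
dock <- function(receptor, ligand, interval_deg = 15, spacing = 0.12,
                 top_per_rot = 10, min_shape = 1) {
  g <- dock_grid_spec(receptor, ligand, spacing)
  rg <- grid_project(receptor, g, "receptor")
  Fr <- stats::fft(rg)
  rots <- sample_rotations(interval_deg)
  lc <- coords(ligand, heavy_only = TRUE)
  lrad <- element_radius(ligand$atoms$element[!ligand$atoms$is_hydrogen])
  lcen <- colMeans(lc)
  lrel <- sweep(lc, 2, lcen)
  rc_heavy <- coords(receptor, heavy_only = TRUE)
  d <- g$dim
  poses <- vector("list", nrow(rots))
  for (ri in seq_len(nrow(rots))) {
    R <- quat_to_mat(rots[ri, ])
    lrot <- lrel %*% t(R)
    locc <- project_occupancy(lrot, lrad, g0_for(g), wrap = TRUE)
    Fl <- stats::fft(locc * (1 + 0i))
    C <- stats::fft(Fr * Conj(Fl), inverse = TRUE) / length(Fr)
    smap <- Re(C) - Im(C)
    ord <- order(-smap)[seq_len(top_per_rot)]
    ord <- ord[smap[ord] >= min_shape]
    if (!length(ord)) next
    best <- NULL
    for (ci in ord) {
      # 0-based lattice translation; the grid is sized so every contacting
      # placement lies inside the box and never wraps
      tt <- arrayInd(ci, c(d, d, d)) - 1L
      tpos <- g$origin + as.numeric(tt) * g$spacing
      pp <- pair_potential(rc_heavy, sweep(lrot, 2, tpos, `+`))
      if (is.null(best) || pp$score > best$pp$score)
        best <- list(ci = ci, tpos = tpos, pp = pp, shape = smap[ci])
    }
    if (best$pp$n_clash > 0 && best$pp$n_attractive == 0) next
    poses[[ri]] <- data.frame(
      pose_id = sprintf("r%04d", ri), rot_index = ri,
      qw = rots[ri, 1], qx = rots[ri, 2], qy = rots[ri, 3], qz = rots[ri, 4],
      tx = best$tpos[1], ty = best$tpos[2], tz = best$tpos[3],
      shape_score = best$shape, rescore = best$pp$score,
      n_clash = best$pp$n_clash, stringsAsFactors = FALSE)
  }
  poses <- do.call(rbind, poses[!vapply(poses, is.null, logical(1))])
  if (is.null(poses) || !nrow(poses)) {
    warning("no rotation yielded a non-clashing pose")
    return(data.frame())
  }
  poses[order(-poses$rescore, poses$pose_id), ]
}

# ligand projection grid: same lattice, origin at zero (ligand coordinates
# are already centroid-relative; translations wrap circularly)
g0_for <- function(g) {
  structure(list(spacing = g$spacing, dim = g$dim, origin = c(0, 0, 0)),
            class = "dock_grid")
}

#' Apply a docking pose to a ligand
#'
#' Rotates the ligand about its heavy-atom centroid by the pose quaternion
#' and places the centroid at the pose translation.
#'
#' @param ligand an `apt_structure`
#' @param pose a single-row pose data.frame from [dock()]
#' @return the posed `apt_structure`
#' @export
apply_pose <- function(ligand, pose) {
  stopifnot(nrow(pose) == 1)
  R <- quat_to_mat(c(pose$qw, pose$qx, pose$qy, pose$qz))
  lc <- coords(ligand, heavy_only = TRUE)
  cen <- colMeans(lc)
  xyz <- sweep(coords(ligand), 2, cen)
  xyz <- xyz %*% t(R)
  set_coords(ligand, sweep(xyz, 2, c(pose$tx, pose$ty, pose$tz), `+`))
}
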