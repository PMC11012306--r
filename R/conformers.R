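# Conformer ensembles: large-scale variants at prescribed centre-of-mass
# distances along the softest distance-coupled elastic-network mode, each
# decorated with small-scale perturbation snapshots. A deterministic
# desk-scale surrogate for biased molecular dynamics: the bias's only role
# is to realise target COM distances along the lowest mode, which
# mode-following plus an ENM-restrained minimisation achieves directly.

#' A centre-of-mass distance grid
#'
#' @param start,stop,step grid extent and spacing, nm
#' @return list of class `distance_grid` with the `targets` vector
#' @export
distance_grid <- function(start, stop, step) {
  if (step <= 0) stop("step must be positive")
  if (stop < start) stop("stop must be >= start")
  n <- floor((stop - start) / step + 1e-9) + 1
  structure(list(start = start, stop = stop, step = step,
                 targets = start + step * (seq_len(n) - 1)),
            class = "distance_grid")
}

#' Distance between the centres of two residue groups
#'
#' Euclidean distance between the unweighted heavy-atom centroids of the
#' two groups (mass weighting would shift either centroid by less than the
#' bead spacing for these near-uniform pseudo-atoms).
#'
#' @param s an `apt_structure`
#' @param map a `domain_map`
#' @param groupA,groupB group names (vectors allowed)
#' @return distance in nm
#' @export
com_distance <- function(s, map, groupA, groupB) {
  comA <- group_com(s, map, groupA)
  comB <- group_com(s, map, groupB)
  sqrt(sum((comB - comA)^2))
}

group_com <- function(s, map, group) {
  idx <- atom_rows_for_residues(s, map_residues(map, group))
  a <- s$atoms[idx, ]
  a <- a[!a$is_hydrogen, ]
  if (!nrow(a)) stop("empty selection for group ", paste(group, collapse = "+"))
  colMeans(as.matrix(a[, c("x", "y", "z")]))
}

# per-residue displacement machinery -------------------------------------
# Mode vectors live on CG nodes (one per residue); atoms move rigidly with
# their residue's node. `residue_of_atom` maps atom row -> node row.
residue_node_map <- function(s, enm) {
  akey <- paste(s$atoms$chain, s$atoms$resseq)
  nkey <- paste(enm$nodes$chain, enm$nodes$resseq)
  match(akey, nkey)
}

# displace all atoms by their residue's node displacement field (3N vector)
displace_by_modes <- function(s, enm, disp3n, node_of_atom) {
  n <- nrow(enm$nodes)
  dm <- matrix(disp3n, ncol = 3, byrow = TRUE)  # node x 3
  xyz <- coords(s) + dm[node_of_atom, , drop = FALSE]
  set_coords(s, xyz)
}

# COM-difference response matrix: column k is the change of (comB - comA)
# per unit amplitude of mode k, accounting for heavy-atom counts/residue
com_response <- function(s, enm, modes, map, groupA, groupB, node_of_atom) {
  heavy <- !s$atoms$is_hydrogen
  resA <- map_residues(map, groupA); resB <- map_residues(map, groupB)
  akey <- paste(s$atoms$chain, s$atoms$resseq)
  inA <- heavy & akey %in% paste(resA$chain, resA$resseq)
  inB <- heavy & akey %in% paste(resB$chain, resB$resseq)
  wts <- function(mask) {
    tab <- table(node_of_atom[mask])
    w <- numeric(nrow(enm$nodes))
    w[as.integer(names(tab))] <- as.numeric(tab) / sum(mask)
    w
  }
  wA <- wts(inA); wB <- wts(inB)
  k <- ncol(modes$vectors)
  W <- matrix(0, 3, k)
  for (j in seq_len(k)) {
    dm <- matrix(modes$vectors[, j], ncol = 3, byrow = TRUE)
    W[, j] <- colSums(dm * wB) - colSums(dm * wA)
  }
  W
}

# amplitude t solving |c0 + t w| = target along a single direction w;
# returns the smaller-|t| real root, or the t minimising the distance gap
solve_amplitude <- function(c0, w, target) {
  a <- sum(w^2); b <- 2 * sum(c0 * w); cc <- sum(c0^2) - target^2
  if (a < 1e-14) return(0)
  disc <- b^2 - 4 * a * cc
  if (disc >= 0) {
    r <- c((-b + sqrt(disc)) / (2 * a), (-b - sqrt(disc)) / (2 * a))
    r[which.min(abs(r))]
  } else {
    -b / (2 * a)   # closest approach
  }
}

#' Drive a structure to a target inter-group distance
#'
#' Displaces coordinates along the low-frequency mode with the largest
#' distance overlap, solving the amplitude so the group-group COM distance
#' hits `target`, then relaxes in the subspace of the `n_modes` lowest
#' non-rigid modes by minimising elastic energy plus a harmonic distance
#' restraint (spring constant `k_restraint`, the value used for the biased
#' sampling this step replaces).
#'
#' @param s an `apt_structure`
#' @param enm its `enm_model`; pass the model built from `s`
#' @param modes a `mode_set` with enough non-rigid modes
#' @param map,groupA,groupB the distance coordinate definition
#' @param target target COM distance, nm
#' @param k_restraint restraint constant, energy/nm^2 in ENM units
#' @param n_modes size of the relaxation subspace
#' @param dist_tol acceptance tolerance on the achieved distance, nm
#' @param overlap_min minimum usable mode-distance overlap
#' @return the driven `apt_structure`; attribute `drive` records the mode
#'   used, the subspace amplitudes, and the achieved distance
#' @export
drive_to_distance <- function(s, enm, modes, map, groupA, groupB, target,
                              k_restraint = 1000, n_modes = 10,
                              dist_tol = 0.05, overlap_min = 0.3) {
  if (target <= 0) stop("target distance must be positive")
  node_of_atom <- residue_node_map(s, enm)
  nr <- nonrigid_modes(modes)
  if (length(nr) < 1) stop("no non-rigid modes available")
  nr <- nr[seq_len(min(n_modes, length(nr)))]
  ov <- mode_distance_overlap(enm, modes, map, groupA, groupB)[nr]
  if (max(ov) < overlap_min)
    stop(sprintf("no mode couples to the distance (max overlap %.2f < %.2f)",
                 max(ov), overlap_min))
  drive <- which.max(ov)
  lam <- modes$values[nr]
  V <- modes$vectors[, nr, drop = FALSE]
  W <- com_response(s, enm, modes, map, groupA, groupB, node_of_atom)[, nr, drop = FALSE]
  comA <- group_com(s, map, groupA); comB <- group_com(s, map, groupB)
  c0 <- comB - comA
  t0 <- solve_amplitude(c0, W[, drive], target)
  a0 <- numeric(length(nr)); a0[drive] <- t0
  fn <- function(a) {
    d <- sqrt(sum((c0 + W %*% a)^2))
    0.5 * sum(lam * a^2) + 0.5 * k_restraint * (d - target)^2
  }
  gr <- function(a) {
    cv <- c0 + as.numeric(W %*% a)
    d <- sqrt(sum(cv^2))
    lam * a + k_restraint * (d - target) * as.numeric(crossprod(W, cv / d))
  }
  opt <- stats::optim(a0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  a <- opt$par
  achieved <- sqrt(sum((c0 + W %*% a)^2))
  if (abs(achieved - target) > dist_tol)
    stop(sprintf("target %.2f nm unreachable; best achieved %.3f nm",
                 target, achieved))
  out <- displace_by_modes(s, enm, as.numeric(V %*% a), node_of_atom)
  attr(out, "drive") <- list(mode = nr[drive], amplitudes = a,
                             achieved = achieved, target = target)
  out
}

#' Generate a restrained conformer ensemble over a distance grid
#'
#' For each grid target the structure is driven to the target COM distance
#' ([drive_to_distance()]); snapshot 0 is the driven structure itself and
#' snapshots 1..n-1 add seeded random superpositions of the lowest
#' non-rigid modes (RMS node amplitude `perturb_amp`), re-restrained to the
#' target by a closed-form correction along the driving mode. Ensemble
#' size is exactly grid size x `n_snapshots` (the 3-9 nm step-1 receptor
#' grid with 20 snapshots gives the canonical 140 = 7 x 20; the 2.0-7.5 nm
#' step-0.5 ligand grid gives 240 = 12 x 20).
#'
#' @param s an `apt_structure`
#' @param map its `domain_map`
#' @param groupA,groupB groups defining the distance coordinate
#' @param grid a [distance_grid()]
#' @param n_snapshots snapshots per grid point (>= 1)
#' @param seed integer seed for the perturbations
#' @param perturb_amp RMS node displacement of a perturbation, nm
#' @param n_modes perturbation/relaxation subspace size
#' @param dist_tol distance tolerance, nm (snapshots allowed 2x)
#' @return object of class `conformer_ensemble`: `members` is a list of
#'   records `(structure, target, achieved, snapshot_index, grid_index)`
#' @export
generate_ensemble <- function(s, map, groupA, groupB, grid, n_snapshots = 20,
                              seed = 1, perturb_amp = 0.1, n_modes = 10,
                              dist_tol = 0.05) {
  stopifnot(inherits(grid, "distance_grid"), n_snapshots >= 1)
  enm <- build_enm(s)
  modes <- compute_modes(enm, k = min(nrow(enm$hessian), n_modes + 8))
  node_of_atom <- residue_node_map(s, enm)
  nr <- nonrigid_modes(modes)
  nr <- nr[seq_len(min(n_modes, length(nr)))]
  V <- modes$vectors[, nr, drop = FALSE]
  W <- com_response(s, enm, modes, map, groupA, groupB, node_of_atom)[, nr, drop = FALSE]
  members <- vector("list", length(grid$targets) * n_snapshots)
  k <- 0
  with_seed(seed, {
    for (gi in seq_along(grid$targets)) {
      tgt <- grid$targets[gi]
      base <- drive_to_distance(s, enm, modes, map, groupA, groupB, tgt,
                                n_modes = n_modes, dist_tol = dist_tol)
      a_base <- attr(base, "drive")$amplitudes
      drive_j <- match(attr(base, "drive")$mode, nr)
      for (si in seq_len(n_snapshots) - 1L) {
        if (si == 0L) {
          snap <- base
          ach <- attr(base, "drive")$achieved
        } else {
          da <- stats::rnorm(length(nr))
          da <- da / sqrt(sum(da^2)) * perturb_amp * sqrt(nrow(enm$nodes))
          a <- a_base + da
          # closed-form re-restraint along the driving mode
          cv <- as.numeric(W %*% a)
          comA <- group_com(s, map, groupA); comB <- group_com(s, map, groupB)
          c0 <- comB - comA
          dt <- solve_amplitude(c0 + cv, W[, drive_j], tgt)
          a[drive_j] <- a[drive_j] + dt
          snap <- displace_by_modes(s, enm, as.numeric(V %*% a), node_of_atom)
          ach <- sqrt(sum((c0 + as.numeric(W %*% a))^2))
        }
        k <- k + 1
        members[[k]] <- list(structure = snap, target = tgt, achieved = ach,
                             snapshot_index = si, grid_index = gi)
      }
    }
  })
  structure(list(members = members,
                 params = list(grid = grid, n_snapshots = n_snapshots,
                               seed = seed, perturb_amp = perturb_amp,
                               groupA = groupA, groupB = groupB)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  err <- vapply(x$members, function(m)
    if (is.na(m$target)) 0 else abs(m$achieved - m$target), numeric(1))
  cat(sprintf("<conformer_ensemble> %d members (%d targets x %d snapshots), max |achieved-target| %.3f nm\n",
              length(x$members),
              length(unique(vapply(x$members, `[[`, numeric(1), "grid_index"))),
              x$params$n_snapshots, max(err)))
  invisible(x)
}

#' Unrestrained perturbation ensemble of a single structure
#'
#' Snapshots of free small-scale motion: member 0 is the input structure,
#' members 1..n-1 superpose seeded random low-mode displacements with no
#' distance restraint (the monomeric-aptamer counterpart of the restrained
#' grid ensembles; 20 snapshots per monomer in the canonical campaign).
#'
#' @param s an `apt_structure`
#' @param n_snapshots ensemble size (>= 1)
#' @param seed integer seed
#' @param perturb_amp RMS node displacement, nm
#' @param n_modes perturbation subspace size
#' @return a `conformer_ensemble` with `target = NA`
#' @export
free_ensemble <- function(s, n_snapshots = 20, seed = 1, perturb_amp = 0.1,
                          n_modes = 10) {
  stopifnot(n_snapshots >= 1)
  enm <- build_enm(s)
  modes <- compute_modes(enm, k = min(nrow(enm$hessian), n_modes + 8))
  node_of_atom <- residue_node_map(s, enm)
  nr <- nonrigid_modes(modes)
  nr <- nr[seq_len(min(n_modes, length(nr)))]
  V <- modes$vectors[, nr, drop = FALSE]
  members <- vector("list", n_snapshots)
  with_seed(seed, {
    for (si in seq_len(n_snapshots) - 1L) {
      snap <- if (si == 0L || perturb_amp == 0) s else {
        a <- stats::rnorm(length(nr))
        a <- a / sqrt(sum(a^2)) * perturb_amp * sqrt(nrow(enm$nodes))
        displace_by_modes(s, enm, as.numeric(V %*% a), node_of_atom)
      }
      members[[si + 1]] <- list(structure = snap, target = NA_real_,
                                achieved = NA_real_, snapshot_index = si,
                                grid_index = 1L)
    }
  })
  structure(list(members = members,
                 params = list(n_snapshots = n_snapshots, seed = seed,
                               perturb_amp = perturb_amp)),
            class = "conformer_ensemble")
}
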