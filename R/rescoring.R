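# Single-trajectory MM/GBSA-style end-point rescoring:
# dG_bind = dE_MM(coulomb + LJ, intermolecular) + dG_GB + dG_SA per
# snapshot, averaged over a snapshot ensemble; the entropy term is
# omitted. The parameter set is a deliberately small built-in table
# (element radii and Lennard-Jones, formal integer charges on charged side
# chains and phosphates), so energies rank poses comparatively rather than
# reproducing any published absolute binding free energy.

KCAL_COUL <- 332.0636  # kcal * angstrom / (mol e^2)

#' The built-in lightweight force field
#'
#' Per-atom parameters keyed on element with residue-specific formal
#' charges: DNA phosphate P carries -1, Lys/Arg side-chain nitrogen +1,
#' Asp/Glu side-chain oxygen -1 (one titratable atom per charged residue).
#' An explicit `charge` or `gb_radius` column on the atom table overrides
#' the table, which is how closed-form test systems are built.
#'
#' @return object of class `ff_lite`
#' @export
ff_lite <- function() {
  structure(list(
    radii = ELEMENT_RADII,                      # nm, shared with docking
    eps = c(H = 0.016, C = 0.11, N = 0.17, O = 0.21, P = 0.20, S = 0.25),
    charged = list(
      protein = c("LYS:NZ" = 1, "ARG:NH1" = 1, "LYS:ND" = 1, "ARG:ND" = 1,
                  "ASP:OD2" = -1, "GLU:OE2" = -1, "ASP:OD" = -1, "GLU:OD" = -1),
      dna_phosphate = -1
    )
  ), class = "ff_lite")
}

#' Assign force-field parameters to every atom of a structure
#'
#' @param s an `apt_structure`
#' @param ff a [ff_lite()]
#' @return data.frame with `charge` (e), `sigma` (nm), `eps` (kcal/mol),
#'   `gb_radius` (nm), row-aligned with `s$atoms`
#' @export
assign_ff <- function(s, ff = ff_lite()) {
  a <- s$atoms
  r <- ff$radii[a$element]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop(sprintf("unparameterized atom: serial %d (%s %s %s%d, element '%s')",
                 a$serial[bad], a$name[bad], a$resname[bad], a$chain[bad],
                 a$resseq[bad], a$element[bad]))
  }
  eps <- ff$eps[a$element]
  q <- numeric(nrow(a))
  key <- paste0(a$resname, ":", a$name)
  hit <- match(key, names(ff$charged$protein))
  q[!is.na(hit)] <- unlist(ff$charged$protein)[hit[!is.na(hit)]]
  q[a$kind == "dna" & a$name == "P"] <- ff$charged$dna_phosphate
  # explicit annotations win
  q <- ifelse(is.na(a$charge), q, a$charge)
  gbr <- ifelse(is.na(a$gb_radius), unname(r), a$gb_radius)
  if (any(gbr <= 0)) stop("non-positive GB radius")
  data.frame(charge = q, sigma = unname(2 * r / 2^(1 / 6)),
             eps = unname(eps), gb_radius = gbr)
}

#' Intermolecular molecular-mechanics interaction energy
#'
#' Coulomb (no cutoff, vacuum constant) and 12-6 Lennard-Jones sums over
#' receptor-ligand atom pairs only; in the single-trajectory scheme the
#' intramolecular terms are identical in bound and free states and cancel
#' exactly, so they are never computed.
#'
#' @param cm a `complex_model`
#' @param ff a [ff_lite()]
#' @return named vector `c(e_coul, e_lj)` in kcal/mol
#' @export
mm_energy <- function(cm, ff = ff_lite()) {
  pr <- assign_ff(cm$receptor, ff); pl <- assign_ff(cm$ligand, ff)
  rc <- coords(cm$receptor); lc <- coords(cm$ligand)
  e_coul <- 0; e_lj <- 0
  chunk <- 2000L
  for (i0 in seq(1, nrow(rc), by = chunk)) {
    ii <- i0:min(i0 + chunk - 1, nrow(rc))
    d2 <- cross_dist2(rc[ii, , drop = FALSE], lc)
    d2[d2 < 1e-8] <- 1e-8
    r <- sqrt(d2)
    qq <- outer(pr$charge[ii], pl$charge)
    e_coul <- e_coul + sum(KCAL_COUL * qq / (10 * r))
    sig <- outer(pr$sigma[ii], pl$sigma, `+`) / 2
    epsm <- sqrt(outer(pr$eps[ii], pl$eps))
    sr6 <- (sig^2 / d2)^3
    e_lj <- e_lj + sum(4 * epsm * (sr6^2 - sr6))
  }
  c(e_coul = e_coul, e_lj = e_lj)
}

# effective Born radii by Hawkins-Cramer-Truhlar pairwise descreening of
# the intrinsic (element) radii; descreening radii are scaled by `s_hct`
born_radii <- function(xyz, rho, s_hct = 0.8) {
  n <- nrow(xyz)
  inv <- 1 / rho
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    r <- sqrt(d2); r[i] <- Inf
    sr <- s_hct * rho
    keep <- which(is.finite(r) & r < 10 & (r + sr) > rho[i])
    if (!length(keep)) next
    rr <- r[keep]; srr <- sr[keep]
    L <- pmax(abs(rr - srr), rho[i])
    U <- rr + srr
    I <- 0.5 * (1 / L - 1 / U + (rr / 4) * (1 / U^2 - 1 / L^2) +
                  (1 / (2 * rr)) * log(L / U) +
                  (srr^2 / (4 * rr)) * (1 / L^2 - 1 / U^2))
    inv[i] <- inv[i] - sum(I)
  }
  1 / pmax(inv, 1 / 30)   # cap effective radii at 30 nm
}

#' Generalized Born polar solvation energy
#'
#' Still-form pairwise GB over all charged atoms,
#' `dG = -tau/2 * sum_ij q_i q_j / f_GB(r_ij, R_i, R_j)` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / (4 R_i R_j)))` and
#' `tau = k_e (1/eps_in - 1/eps_out)`; effective Born radii come from
#' HCT-style pairwise descreening of the intrinsic radii (all heavy atoms
#' descreen). A single ion reduces to the Born formula exactly, and two
#' distant unit charges recover the screened-Coulomb limit.
#'
#' @param mol an `apt_structure`
#' @param ff a [ff_lite()]
#' @param eps_in,eps_out interior / solvent dielectric constants
#' @return energy in kcal/mol
#' @export
gb_energy <- function(mol, ff = ff_lite(), eps_in = 1, eps_out = 78.5) {
  p <- assign_ff(mol, ff)
  heavy <- !mol$atoms$is_hydrogen
  xyz <- coords(mol)[heavy, , drop = FALSE]
  rho <- p$gb_radius[heavy]
  q <- p$charge[heavy]
  if (all(q == 0)) return(0)
  R <- born_radii(xyz, rho)
  ci <- which(q != 0)
  tau <- KCAL_COUL * (1 / eps_in - 1 / eps_out)
  xc <- xyz[ci, , drop = FALSE]; qc <- q[ci]; Rc <- R[ci]
  d2 <- cross_dist2(xc, xc) * 100            # nm^2 -> angstrom^2
  d2[d2 < 0] <- 0
  RR <- outer(Rc, Rc) * 100
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  -0.5 * tau * sum(outer(qc, qc) / fgb)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic spherical quadrature: `n_points` Fibonacci-lattice points
#' on each heavy atom's solvent-expanded sphere (element radius + probe); a
#' point is exposed iff it lies outside every neighbour's expanded sphere.
#' Area is the exposed fraction times `4 pi (r + probe)^2`.
#'
#' @param s an `apt_structure` (or a list `list(xyz =, radii =)` in nm)
#' @param probe probe radius, nm (water: 0.14)
#' @param n_points quadrature points per atom
#' @return list with `total` (nm^2) and `per_atom` (nm^2, heavy atoms in
#'   table order)
#' @export
sasa <- function(s, probe = 0.14, n_points = 256) {
  if (inherits(s, "apt_structure")) {
    heavy <- !s$atoms$is_hydrogen
    xyz <- coords(s)[heavy, , drop = FALSE]
    radii <- ifelse(is.na(s$atoms$gb_radius[heavy]),
                    element_radius(s$atoms$element[heavy]),
                    s$atoms$gb_radius[heavy])
  } else {
    xyz <- as.matrix(s$xyz); radii <- s$radii
  }
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  rex <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rex + rex[i])^2 & d2 > 1e-12)
    sph <- sweep(pts * rex[i], 2, xyz[i, ], `+`)
    if (length(nb)) {
      ok <- rep(TRUE, n_points)
      for (j in nb) {
        dd <- rowSums(sweep(sph, 2, xyz[j, ])^2)
        ok <- ok & dd > rex[j]^2
        if (!any(ok)) break
      }
      frac <- mean(ok)
    } else frac <- 1
    area[i] <- frac * 4 * pi * rex[i]^2
  }
  list(total = sum(area), per_atom = area)
}

#' Ensemble-averaged binding free energy (MM/GBSA style)
#'
#' Single-trajectory end-point estimate per snapshot:
#' `dG = dE_MM + [G_GB(complex) - G_GB(receptor) - G_GB(ligand)] +
#' gamma * [SASA(complex) - SASA(receptor) - SASA(ligand)]`, with bound
#' and free states sharing coordinates (so intramolecular MM cancels) and
#' no entropy term. Returns the per-snapshot breakdown plus ensemble mean
#' and standard deviation.
#'
#' @param snapshots list of `complex_model`s
#' @param ff a [ff_lite()]
#' @param gamma surface-tension coefficient, kcal/(mol angstrom^2)
#' @param eps_in,eps_out GB dielectrics
#' @param probe,n_points SASA settings
#' @return object of class `energy_breakdown`: `per_snapshot` data.frame
#'   (`e_coul`, `e_lj`, `g_gb`, `g_sa`, `total`), `mean`, `sd`
#' @export
binding_free_energy <- function(snapshots, ff = ff_lite(), gamma = 0.0072,
                                eps_in = 1, eps_out = 78.5, probe = 0.14,
                                n_points = 128) {
  if (!length(snapshots)) stop("empty snapshot list")
  rows <- lapply(snapshots, function(cm) {
    mm <- mm_energy(cm, ff)
    merged <- merge_complex(cm)
    g_gb <- gb_energy(merged, ff, eps_in, eps_out) -
      gb_energy(cm$receptor, ff, eps_in, eps_out) -
      gb_energy(cm$ligand, ff, eps_in, eps_out)
    dsasa <- sasa(merged, probe, n_points)$total -
      sasa(cm$receptor, probe, n_points)$total -
      sasa(cm$ligand, probe, n_points)$total
    g_sa <- gamma * dsasa * 100               # nm^2 -> angstrom^2
    data.frame(e_coul = mm["e_coul"], e_lj = mm["e_lj"], g_gb = g_gb,
               g_sa = g_sa,
               total = mm["e_coul"] + mm["e_lj"] + g_gb + g_sa)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  structure(list(per_snapshot = per,
                 mean = colMeans(per),
                 sd = if (nrow(per) > 1) apply(per, 2, stats::sd)
                      else stats::setNames(rep(0, 5), names(per))),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  m <- x$mean; s <- x$sd
  cat(sprintf("<energy_breakdown> %d snapshot(s)\n", nrow(x$per_snapshot)))
  for (k in names(m))
    cat(sprintf("  %-7s %9.3f +/- %.3f kcal/mol\n", k, m[[k]], s[[k]]))
  invisible(x)
}
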