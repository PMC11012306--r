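# Seeded synthetic structures with the topology the pipeline assumes:
# a homodimeric receptor whose two heparin-binding domains hang on slack
# linkers, and DNA aptamers (quadruplex-core monomer, plain monomer,
# 10-residue-linked heterodimer). Globular domains are self-avoiding beads
# on a jittered FCC lattice; linkers are slack interpolated chains; every
# residue carries pseudo side-chain heavy atoms pointing outward plus
# annotated donors (with explicit hydrogens) and acceptors.

#' Parameters for the synthetic-structure generators
#'
#' Defaults encode the modelled system: a 165-residue-scale monomer split
#' into a 110-residue receptor-binding domain and a 55-residue
#' heparin-binding domain joined by a 12-residue linker (the length of the
#' natural RPKKDRARQENP interdomain linker), aptamer units with a
#' 12-residue quadruplex core, and a 10-residue (oligo-dT) heterodimer
#' linker.
#'
#' @param seed integer; all geometry jitter derives from it
#' @param n_res_rbd residues per receptor-binding domain (per monomer)
#' @param n_res_hbd residues per heparin-binding domain
#' @param linker_len_receptor receptor interdomain linker length, residues
#' @param apt_core_len quadruplex core length, residues
#' @param apt_linker_len heterodimer linker length, residues
#' @param bead_spacing nearest-neighbour bead distance inside globules, nm
#' @param domain_radius optional globule radius override, nm (NA = derived
#'   from the residue count and `bead_spacing`)
#' @param hbd_separation distance between the two HBD centres in the relaxed
#'   build, nm (inside the 3-9 nm window the conformer grid spans)
#' @param apt_separation distance between heterodimer unit centres, nm
#' @param lna tag quadruplex-core guanines as locked nucleic acid analogues
#'   (a residue-name tag only; no geometric effect)
#' @return a list of class `gen_params`
#' @export
gen_params <- function(seed = 1, n_res_rbd = 110, n_res_hbd = 55,
                       linker_len_receptor = 12, apt_core_len = 12,
                       apt_linker_len = 10, bead_spacing = 0.55,
                       domain_radius = NA_real_, hbd_separation = 4.4,
                       apt_separation = 4.0, lna = FALSE) {
  p <- list(seed = seed, n_res_rbd = n_res_rbd, n_res_hbd = n_res_hbd,
            linker_len_receptor = linker_len_receptor,
            apt_core_len = apt_core_len, apt_linker_len = apt_linker_len,
            bead_spacing = bead_spacing, domain_radius = domain_radius,
            hbd_separation = hbd_separation, apt_separation = apt_separation,
            lna = lna)
  counts <- c(n_res_rbd, n_res_hbd, linker_len_receptor, apt_core_len,
              apt_linker_len)
  if (any(counts < 1)) stop("all residue counts must be >= 1")
  if (bead_spacing <= 0) stop("bead_spacing must be positive")
  class(p) <- "gen_params"
  p
}

# FCC lattice points (nearest-neighbour distance = spacing) sorted by
# distance from the origin; the first n form a near-spherical globule
fcc_globule <- function(n, spacing, jitter = 0.05) {
  a <- spacing * sqrt(2)          # cubic lattice constant
  m <- ceiling((n * 3)^(1 / 3)) + 2
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, ]
  pts <- as.matrix(g) * (a / 2)
  ord <- order(rowSums(pts^2), pts[, 1], pts[, 2], pts[, 3])
  pts <- pts[ord, , drop = FALSE][seq_len(n), , drop = FALSE]
  pts + matrix(stats::runif(3 * n, -jitter, jitter), ncol = 3)
}

# effective globule radius for placement arithmetic
globule_radius <- function(n, spacing) (3 * n * 0.707 * spacing^3 / (4 * pi))^(1 / 3)

# slack chain between two anchors: quadratic Bezier bulging along `bulge_dir`
slack_chain <- function(from, to, n, bulge = 1.0, bulge_dir = c(0, 0, 1),
                        jitter = 0.03) {
  ctrl <- (from + to) / 2 + bulge * unit_vec(bulge_dir)
  t <- seq_len(n) / (n + 1)
  pts <- outer((1 - t)^2, from) + outer(2 * t * (1 - t), ctrl) + outer(t^2, to)
  pts + matrix(stats::runif(3 * n, -jitter, jitter), ncol = 3)
}

# build toy residues around backbone bead positions; `outward` gives the
# unit direction for the pseudo side chain of each residue
toy_residues <- function(pos, outward, kind, resnames, chain, resseq,
                         serial_start) {
  n <- nrow(pos)
  rows <- vector("list", n)
  serial <- serial_start
  for (i in seq_len(n)) {
    p <- pos[i, ]; u <- outward[i, ]
    # a second, tilted side-chain direction (deterministic per residue)
    tang <- if (abs(u[3]) < 0.9) unit_vec(c(-u[2], u[1], 0)) else c(1, 0, 0)
    v <- unit_vec(u + 0.6 * tang * (if (i %% 2 == 0) 1 else -1))
    if (kind == "protein") {
      rn <- resnames[i]
      qd <- if (rn %in% c("ASP", "GLU")) -1 else 0
      qn <- if (rn %in% c("LYS", "ARG")) 1 else 0
      at <- rbind(
        data.frame(name = "CA", element = "C", x = p[1], y = p[2], z = p[3],
                   is_hydrogen = FALSE, is_sidechain = FALSE,
                   hbond_role = "none", hp = NA_integer_, charge = 0),
        data.frame(name = "CB", element = "C", x = p[1] + 0.15 * u[1],
                   y = p[2] + 0.15 * u[2], z = p[3] + 0.15 * u[3],
                   is_hydrogen = FALSE, is_sidechain = TRUE,
                   hbond_role = "none", hp = NA_integer_, charge = 0),
        data.frame(name = "OD", element = "O", x = p[1] + 0.28 * v[1],
                   y = p[2] + 0.28 * v[2], z = p[3] + 0.28 * v[3],
                   is_hydrogen = FALSE, is_sidechain = TRUE,
                   hbond_role = "acceptor", hp = NA_integer_, charge = qd),
        data.frame(name = "ND", element = "N", x = p[1] + 0.28 * u[1],
                   y = p[2] + 0.28 * u[2], z = p[3] + 0.28 * u[3],
                   is_hydrogen = FALSE, is_sidechain = TRUE,
                   hbond_role = "donor", hp = NA_integer_, charge = qn),
        data.frame(name = "HD", element = "H", x = p[1] + 0.38 * u[1],
                   y = p[2] + 0.38 * u[2], z = p[3] + 0.38 * u[3],
                   is_hydrogen = TRUE, is_sidechain = TRUE,
                   hbond_role = "none", hp = 4L, charge = 0)
      )
    } else {
      rn <- resnames[i]
      at <- rbind(
        data.frame(name = "P", element = "P", x = p[1], y = p[2], z = p[3],
                   is_hydrogen = FALSE, is_sidechain = FALSE,
                   hbond_role = "none", hp = NA_integer_, charge = -1),
        data.frame(name = "C1'", element = "C", x = p[1] + 0.15 * u[1],
                   y = p[2] + 0.15 * u[2], z = p[3] + 0.15 * u[3],
                   is_hydrogen = FALSE, is_sidechain = FALSE,
                   hbond_role = "none", hp = NA_integer_, charge = 0),
        data.frame(name = "O6", element = "O", x = p[1] + 0.28 * v[1],
                   y = p[2] + 0.28 * v[2], z = p[3] + 0.28 * v[3],
                   is_hydrogen = FALSE, is_sidechain = TRUE,
                   hbond_role = "acceptor", hp = NA_integer_, charge = 0),
        data.frame(name = "N2", element = "N", x = p[1] + 0.28 * u[1],
                   y = p[2] + 0.28 * u[2], z = p[3] + 0.28 * u[3],
                   is_hydrogen = FALSE, is_sidechain = TRUE,
                   hbond_role = "donor", hp = NA_integer_, charge = 0),
        data.frame(name = "H2", element = "H", x = p[1] + 0.38 * u[1],
                   y = p[2] + 0.38 * u[2], z = p[3] + 0.38 * u[3],
                   is_hydrogen = TRUE, is_sidechain = TRUE,
                   hbond_role = "none", hp = 4L, charge = 0)
      )
    }
    at$serial <- serial + seq_len(nrow(at)) - 1L
    at$h_parent <- ifelse(is.na(at$hp), NA_integer_, at$serial[at$hp])
    at$hp <- NULL
    at$chain <- chain; at$resseq <- resseq[i]; at$resname <- rn
    serial <- serial + nrow(at)
    rows[[i]] <- at
  }
  do.call(rbind, rows)
}

# charged residues paired early in the cycle so chains of most lengths
# stay net-neutral (the modelled receptor is close to neutral overall,
# unlike the uniformly anionic DNA ligands)
PROT_CYCLE <- c("ALA", "LYS", "ASP", "SER", "ARG", "GLU", "THR", "GLY",
                "ASN", "LEU")
DNA_CYCLE <- c("DA", "DC", "DG", "DT")

#' Generate the synthetic homodimeric two-domain receptor
#'
#' Two receptor-binding-domain globules packed as a dimer core, each
#' tethered by a slack linker chain to a heparin-binding-domain globule.
#' Chains A and B are identical monomers (up to jitter); per chain the
#' residue layout is RBD, linker, HBD in consecutive numbering. The relaxed
#' build places the two HBD centres `hbd_separation` apart, inside the
#' 3-9 nm window that the conformer grid later spans.
#'
#' @param p a [gen_params()] list
#' @return list with `structure` (an `apt_structure`) and `map` (a
#'   `domain_map` with groups RBD1, RBD2, HBD1, HBD2, LNK1, LNK2)
#' @export
make_toy_receptor <- function(p = gen_params()) {
  stopifnot(inherits(p, "gen_params"))
  with_seed(p$seed, {
    sp <- p$bead_spacing
    r_rbd <- if (is.na(p$domain_radius)) globule_radius(p$n_res_rbd, sp) else p$domain_radius
    r_hbd <- if (is.na(p$domain_radius)) globule_radius(p$n_res_hbd, sp) else p$domain_radius
    cx <- 0.8 * r_rbd                      # dimer half-separation
    hx <- p$hbd_separation / 2
    hy <- 0.5 + r_rbd + r_hbd + 1.0        # HBDs held away from the core
    centers <- list(
      rbd = list(A = c(-cx, 0, 0), B = c(cx, 0, 0)),
      hbd = list(A = c(-hx, hy, 0), B = c(hx, hy, 0))
    )
    chains <- list()
    serial <- 1L
    for (ch in c("A", "B")) {
      crbd <- centers$rbd[[ch]]; chbd <- centers$hbd[[ch]]
      rbd_pos <- sweep(fcc_globule(p$n_res_rbd, sp), 2, crbd, `+`)
      hbd_pos <- sweep(fcc_globule(p$n_res_hbd, sp), 2, chbd, `+`)
      dirv <- unit_vec(chbd - crbd)
      from <- crbd + r_rbd * dirv
      to <- chbd - r_hbd * dirv
      # arc the linker out of the scissor plane so the in-plane HBD swing
      # (the distance-coupled motion the conformer stage drives) stays soft
      side <- if (ch == "A") c(-0.25, 0, 1) else c(0.25, 0, -1)
      lnk_pos <- slack_chain(from, to, p$linker_len_receptor,
                             bulge = 1.2, bulge_dir = side)
      pos <- rbind(rbd_pos, lnk_pos, hbd_pos)
      outward <- rbind(
        t(apply(rbd_pos, 1, function(q) unit_vec(q - crbd + c(1e-4, 0, 0)))),
        t(apply(lnk_pos, 1, function(q) unit_vec(side))),
        t(apply(hbd_pos, 1, function(q) unit_vec(q - chbd + c(1e-4, 0, 0))))
      )
      nres <- nrow(pos)
      resnames <- PROT_CYCLE[(seq_len(nres) - 1) %% length(PROT_CYCLE) + 1]
      at <- toy_residues(pos, outward, "protein", resnames, ch,
                         seq_len(nres), serial)
      serial <- serial + nrow(at)
      chains[[ch]] <- at
    }
    s <- new_structure(do.call(rbind, chains), title = "toy VEGF-like receptor",
                       provenance = "synthetic")
    n1 <- p$n_res_rbd; n2 <- n1 + p$linker_len_receptor
    n3 <- n2 + p$n_res_hbd
    cfg <- list(
      RBD1 = list(chain = "A", first = 1, last = n1, role = "RBD"),
      RBD2 = list(chain = "B", first = 1, last = n1, role = "RBD"),
      LNK1 = list(chain = "A", first = n1 + 1, last = n2, role = "LINKER"),
      LNK2 = list(chain = "B", first = n1 + 1, last = n2, role = "LINKER"),
      HBD1 = list(chain = "A", first = n2 + 1, last = n3, role = "HBD"),
      HBD2 = list(chain = "B", first = n2 + 1, last = n3, role = "HBD")
    )
    list(structure = s, map = bind_domain_map(s, cfg))
  })
}

# quadruplex-core monomer geometry: three stacked 4-residue rings plus
# short helical tails; returns backbone positions, outward dirs, core index
quad_unit_geometry <- function(core_len, lead = 5, tail = 5) {
  rings <- core_len / 4
  core <- do.call(rbind, lapply(seq_len(ceiling(rings)) - 1, function(k) {
    ang <- (0:3) * pi / 2 + k * pi / 12
    cbind(0.55 * cos(ang), 0.55 * sin(ang), 0.34 * k)
  }))[seq_len(core_len), , drop = FALSE]
  helix <- function(n, z0, dz) {
    i <- seq_len(n)
    cbind(0.8 * cos(0.8 * i), 0.8 * sin(0.8 * i), z0 + dz * i)
  }
  pos <- rbind(helix(lead, -0.35, -0.35)[rev(seq_len(lead)), , drop = FALSE],
               core,
               helix(tail, 0.34 * (ceiling(rings) - 1) + 0.35, 0.35))
  ax <- colMeans(pos)
  outward <- t(apply(pos, 1, function(q) {
    v <- q - ax; v[3] <- 0.2 * v[3]
    if (sqrt(sum(v^2)) < 1e-3) c(1, 0, 0) else unit_vec(v)
  }))
  list(pos = pos, outward = outward, core_idx = lead + seq_len(core_len))
}

#' Generate a synthetic aptamer
#'
#' Three kinds: `monomer_quad` carries a labelled quadruplex core of
#' `apt_core_len` residues built as stacked 4-residue rings (three quartet
#' planes for the default core of 12) whose reference heavy-atom
#' coordinates are stored on the structure as `core_ref`; `monomer_plain`
#' is a globular single-unit aptamer; `heterodimer` joins one unit of each
#' kind with an `apt_linker_len`-residue oligo-dT linker and tags the units
#' with the binding roles the attachment criteria use.
#'
#' @param kind `"monomer_quad"`, `"monomer_plain"`, or `"heterodimer"`
#' @param p a [gen_params()] list
#' @return list with `structure` and `map`; quadruplex-bearing structures
#'   also carry `$core` (chain/resseq of the core) and `$core_ref`
#'   (reference heavy-atom coordinates, nm)
#' @export
make_toy_aptamer <- function(kind = c("heterodimer", "monomer_quad",
                                      "monomer_plain"),
                             p = gen_params()) {
  kind <- match.arg(kind)
  stopifnot(inherits(p, "gen_params"))
  with_seed(p$seed + 101L, {
    sp <- 0.6
    gname <- if (p$lna) "DGL" else "DG"
    build_quad <- function(resseq0) {
      g <- quad_unit_geometry(p$apt_core_len)
      nres <- nrow(g$pos)
      resnames <- DNA_CYCLE[(seq_len(nres) - 1) %% 4 + 1]
      resnames[g$core_idx] <- gname
      pos <- g$pos + matrix(stats::runif(3 * nres, -0.02, 0.02), ncol = 3)
      list(pos = pos, outward = g$outward, resnames = resnames,
           core = resseq0 + g$core_idx - 1, n = nres)
    }
    build_blob <- function(n, center) {
      pos <- sweep(fcc_globule(n, sp), 2, center, `+`)
      outward <- t(apply(pos, 1, function(q) unit_vec(q - center + c(1e-4, 0, 0))))
      resnames <- DNA_CYCLE[(seq_len(n) - 1) %% 4 + 1]
      list(pos = pos, outward = outward, resnames = resnames, n = n)
    }
    if (kind == "monomer_quad") {
      u <- build_quad(1L)
      at <- toy_residues(u$pos, u$outward, "dna", u$resnames, "C",
                         seq_len(u$n), 1L)
      s <- new_structure(at, title = "toy quadruplex aptamer", provenance = "synthetic")
      cfg <- list(APT_A = list(chain = "C", first = 1, last = u$n,
                               role = "APT_RBD_BINDER"))
      map <- bind_domain_map(s, cfg)
      s$core <- data.frame(chain = "C", resseq = u$core)
      s$core_ref <- coords(s, heavy_only = TRUE)[
        atom_rows_for_residues_heavy(s, s$core), , drop = FALSE]
      return(list(structure = s, map = map))
    }
    if (kind == "monomer_plain") {
      u <- build_blob(20L, c(0, 0, 0))
      at <- toy_residues(u$pos, u$outward, "dna", u$resnames, "C",
                         seq_len(u$n), 1L)
      s <- new_structure(at, title = "toy plain aptamer", provenance = "synthetic")
      map <- bind_domain_map(s, list(APT_A = list(chain = "C", first = 1,
                                                  last = u$n,
                                                  role = "APT_HBD_BINDER")))
      return(list(structure = s, map = map))
    }
    # heterodimer: quad unit at origin, plain unit apt_separation away,
    # oligo-dT linker between them
    ua <- build_quad(1L)
    ub <- build_blob(20L, c(p$apt_separation, 0, 0))
    from <- colMeans(ua$pos) + c(0.9, 0, 0)
    to <- colMeans(ub$pos) - c(globule_radius(ub$n, sp), 0, 0)
    lnk <- slack_chain(from, to, p$apt_linker_len, bulge = 1.5,
                       bulge_dir = c(0, 1, 0.3))
    lnk_out <- matrix(rep(c(0, 1, 0), each = p$apt_linker_len), ncol = 3)
    na <- ua$n; nl <- p$apt_linker_len; nb <- ub$n
    pos <- rbind(ua$pos, lnk, ub$pos)
    outward <- rbind(ua$outward, lnk_out, ub$outward)
    resnames <- c(ua$resnames, rep("DT", nl), ub$resnames)
    at <- toy_residues(pos, outward, "dna", resnames, "C",
                       seq_len(na + nl + nb), 1L)
    s <- new_structure(at, title = "toy aptamer heterodimer", provenance = "synthetic")
    cfg <- list(
      APT_A = list(chain = "C", first = 1, last = na, role = "APT_RBD_BINDER"),
      APT_LNK = list(chain = "C", first = na + 1, last = na + nl, role = "LINKER"),
      APT_B = list(chain = "C", first = na + nl + 1, last = na + nl + nb,
                   role = "APT_HBD_BINDER")
    )
    map <- bind_domain_map(s, cfg)
    s$core <- data.frame(chain = "C", resseq = ua$core)
    s$core_ref <- coords(s, heavy_only = TRUE)[
      atom_rows_for_residues_heavy(s, s$core), , drop = FALSE]
    list(structure = s, map = map)
  })
}

# row indices (within the heavy-atom subset) of atoms in given residues
atom_rows_for_residues_heavy <- function(s, res) {
  a <- s$atoms[!s$atoms$is_hydrogen, ]
  key <- paste(a$chain, a$resseq)
  which(key %in% paste(res$chain, res$resseq))
}

# translate a ligand unit so its centroid reaches `target`, then creep along
# `dir` until the closest (unit heavy atom, receptor-group side-chain heavy
# atom) pair sits at `gap` nm
nudge_unit <- function(lig, unit_res, rec, rec_map, rec_groups, target, dir,
                       gap = 0.30, iters = 12) {
  idx <- atom_rows_for_residues(lig, unit_res)
  cur <- colMeans(as.matrix(lig$atoms[idx, c("x", "y", "z")]))
  lig <- translate_residues(lig, unit_res, target - cur)
  ra <- rec$atoms
  rres <- map_residues(rec_map, rec_groups)
  rsel <- ra[paste(ra$chain, ra$resseq) %in% paste(rres$chain, rres$resseq) &
             ra$is_sidechain & !ra$is_hydrogen, c("x", "y", "z")]
  dir <- unit_vec(dir)
  for (it in seq_len(iters)) {
    lsel <- lig$atoms[idx, ][!lig$atoms$is_hydrogen[idx], c("x", "y", "z")]
    dmin <- sqrt(min(cross_dist2(as.matrix(lsel), as.matrix(rsel))))
    if (abs(dmin - gap) < 0.03) break
    lig <- translate_residues(lig, unit_res, dir * (dmin - gap))
  }
  lig
}

# straight redraw of the heterodimer linker after its flanking units moved
redraw_linker <- function(lig, lmap) {
  lres <- map_residues(lmap, "APT_LNK")
  ares <- map_residues(lmap, "APT_A"); bres <- map_residues(lmap, "APT_B")
  ia <- atom_rows_for_residues(lig, ares); ib <- atom_rows_for_residues(lig, bres)
  from <- colMeans(as.matrix(lig$atoms[ia, c("x", "y", "z")]))
  to <- colMeans(as.matrix(lig$atoms[ib, c("x", "y", "z")]))
  n <- nrow(lres)
  t <- seq_len(n) / (n + 1)
  pts <- outer(1 - t, from) + outer(t, to)
  for (i in seq_len(n)) {
    res_i <- lres[i, , drop = FALSE]
    idx <- atom_rows_for_residues(lig, res_i)
    cur <- colMeans(as.matrix(lig$atoms[idx, c("x", "y", "z")]))
    lig <- translate_residues(lig, res_i, pts[i, ] - cur)
  }
  lig
}

#' Construct a complex fixture with a known binding pose
#'
#' Builds a receptor and a heterodimer aptamer and places the aptamer
#' units so the 0.45 nm contact rules of [classify_pose()] yield exactly
#' the requested label, and the attachment criteria pass. The fixture
#' receptor uses a reduced HBD separation (3.4 nm, still inside the 3-9 nm
#' conformer window) so one rigid aptamer unit can bridge both HBDs in the
#' sandwich geometry.
#'
#' @param label `"sandwich"`, `"side"`, or `"hug"`
#' @param p a [gen_params()] list
#' @return a `complex_model` whose `$label` records the construction target
#' @export
make_pose_fixture <- function(label = c("sandwich", "side", "hug"),
                              p = gen_params()) {
  label <- match.arg(label)
  p$hbd_separation <- 3.4
  rec <- make_toy_receptor(p)
  apt <- make_toy_aptamer("heterodimer", p)
  lig <- apt$structure; lmap <- apt$map
  com_of <- function(map, s, g) {
    idx <- atom_rows_for_residues(s, map_residues(map, g))
    a <- s$atoms[idx, ]; a <- a[!a$is_hydrogen, ]
    colMeans(as.matrix(a[, c("x", "y", "z")]))
  }
  rbd1 <- com_of(rec$map, rec$structure, "RBD1")
  rbd2 <- com_of(rec$map, rec$structure, "RBD2")
  hbd1 <- com_of(rec$map, rec$structure, "HBD1")
  hbd2 <- com_of(rec$map, rec$structure, "HBD2")
  ares <- map_residues(lmap, "APT_A"); bres <- map_residues(lmap, "APT_B")
  out1 <- unit_vec(hbd1 - hbd2)   # outward past HBD1
  outr <- unit_vec(rbd1 - rbd2)   # outward past RBD1
  down <- unit_vec(rbd1 + rbd2 - hbd1 - hbd2)  # away from the HBD side
  if (label == "sandwich") {
    # HBD binder bridges the two HBDs; RBD binder touches RBD1 from outside
    lig <- nudge_unit(lig, bres, rec$structure, rec$map, c("HBD1", "HBD2"),
                      (hbd1 + hbd2) / 2, c(0, 1, 0), gap = 0.25)
    lig <- nudge_unit(lig, ares, rec$structure, rec$map, "RBD1",
                      rbd1 + 3.5 * outr, -outr)
  } else if (label == "side") {
    # HBD binder on one HBD only; RBD binder outside, touching RBD1 only
    lig <- nudge_unit(lig, bres, rec$structure, rec$map, "HBD1",
                      hbd1 + 3.5 * out1, -out1)
    lig <- nudge_unit(lig, ares, rec$structure, rec$map, "RBD1",
                      rbd1 + 3.5 * outr, -outr)
  } else {
    # RBD binder wedged between the two RBDs; HBD binder on one HBD
    lig <- nudge_unit(lig, ares, rec$structure, rec$map, c("RBD1", "RBD2"),
                      (rbd1 + rbd2) / 2 + 3.5 * down, -down, gap = 0.25)
    lig <- nudge_unit(lig, bres, rec$structure, rec$map, "HBD1",
                      hbd1 + 3.5 * out1, -out1)
  }
  lig <- redraw_linker(lig, lmap)
  complex_model(rec$structure, rec$map, lig, lmap, label = label)
}

#' Construct a complex with a planted number of interface hydrogen bonds
#'
#' The returned complex contains exactly `n` donor-H...acceptor triplets
#' satisfying the geometric criteria (donor-acceptor distance <= 3.5
#' angstrom, H-donor-acceptor angle <= 30 degrees) across the
#' receptor/ligand interface, plus decoys violating exactly one criterion
#' each (`n` at 3.6 angstrom with perfect angle, `n` at 3.0 angstrom with a
#' 45-degree angle, and one distance decoy when `n = 0`). Rows are spaced
#' so no accidental cross-row pair can qualify.
#'
#' @param n number of true hydrogen bonds to plant
#' @param p a [gen_params()] list (its seed fixes nothing here; geometry is
#'   fully deterministic)
#' @return a `complex_model`
#' @export
make_hbond_fixture <- function(n, p = gen_params()) {
  stopifnot(n >= 0)
  n_dec <- max(n, 1L)
  mk_prot_row <- function(resseq, y, h_angle_deg, serial0) {
    hdir <- c(cos(h_angle_deg * pi / 180), sin(h_angle_deg * pi / 180), 0)
    data.frame(
      serial = serial0 + 0:2,
      name = c("CA", "ND", "HD"), element = c("C", "N", "H"),
      x = c(-0.3, 0, 0.1 * hdir[1]), y = c(y, y, y + 0.1 * hdir[2]),
      z = 0, chain = "A", resseq = resseq, resname = "ASN",
      is_hydrogen = c(FALSE, FALSE, TRUE), is_sidechain = c(FALSE, TRUE, TRUE),
      hbond_role = c("none", "donor", "none"),
      h_parent = c(NA, NA, serial0 + 1L), charge = 0,
      stringsAsFactors = FALSE)
  }
  mk_dna_row <- function(resseq, y, dx, serial0) {
    data.frame(
      serial = serial0 + 0:1,
      name = c("P", "O4"), element = c("P", "O"),
      x = c(dx + 0.4, dx), y = y, z = 0, chain = "C", resseq = resseq,
      resname = "DT", is_hydrogen = FALSE, is_sidechain = c(FALSE, TRUE),
      hbond_role = c("none", "acceptor"), h_parent = NA_integer_,
      charge = c(-1, 0), stringsAsFactors = FALSE)
  }
  prot <- list(); dna <- list()
  sp <- 1L; sd <- 1L; resp <- 0L; resd <- 0L
  add_pair <- function(y, h_angle, dx) {
    resp <<- resp + 1L; resd <<- resd + 1L
    prot[[length(prot) + 1]] <<- mk_prot_row(resp, y, h_angle, sp)
    dna[[length(dna) + 1]] <<- mk_dna_row(resd, y, dx, sd)
    sp <<- sp + 3L; sd <<- sd + 2L
  }
  y <- 0
  for (i in seq_len(n)) { add_pair(y, 0, 0.30); y <- y + 0.6 }        # true bonds
  for (i in seq_len(n_dec)) { add_pair(y, 0, 0.36); y <- y + 0.6 }    # distance decoys
  for (i in seq_len(n_dec)) { add_pair(y, 45, 0.30); y <- y + 0.6 }   # angle decoys
  rec <- new_structure(do.call(rbind, prot), title = "hbond fixture receptor",
                       provenance = "synthetic")
  lig <- new_structure(do.call(rbind, dna), title = "hbond fixture ligand",
                       provenance = "synthetic")
  rmap <- bind_domain_map(rec, list(RBD1 = list(chain = "A", first = 1,
                                                last = resp, role = "RBD")))
  lmap <- bind_domain_map(lig, list(APT_A = list(chain = "C", first = 1,
                                                 last = resd,
                                                 role = "APT_HBD_BINDER")))
  complex_model(rec, rmap, lig, lmap)
}
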