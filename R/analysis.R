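# Post-selection geometric analysis: hydrogen-bond census, binding-pose
# taxonomy, Kabsch RMSD machinery (quadruplex core stability, trajectory
# time courses), and buried-interface (steric clash) area against a
# reference receptor partner.

#' Detect interface hydrogen bonds by geometric criteria
#'
#' Enumerates all intermolecular donor-H...acceptor triplets (both
#' directions across the interface) and accepts those with donor-acceptor
#' distance at most `d_max` angstrom and H-donor-acceptor angle (vertex at
#' the donor) at most `a_max` degrees. Donors lacking an attached hydrogen
#' are skipped and counted in the `skipped_donors` attribute.
#'
#' @param cm a `complex_model`
#' @param d_max maximum donor-acceptor distance, angstrom
#' @param a_max maximum H-donor-acceptor angle, degrees
#' @return data.frame sorted by (donor serial, acceptor serial):
#'   `donor_serial`, `donor_side`, `hydrogen_serial`, `acceptor_serial`,
#'   `d_da` (angstrom), `angle_hda` (degrees), plus residue identities
#' @export
detect_hbonds <- function(cm, d_max = 3.5, a_max = 30) {
  sides <- list(
    list(don = cm$receptor, acc = cm$ligand, tag = "receptor"),
    list(don = cm$ligand, acc = cm$receptor, tag = "ligand")
  )
  out <- list(); skipped <- 0L
  for (sd in sides) {
    da <- sd$don$atoms; aa <- sd$acc$atoms
    dons <- which(da$hbond_role %in% c("donor", "donor_acceptor") &
                  !da$is_hydrogen)
    accs <- which(aa$hbond_role %in% c("acceptor", "donor_acceptor") &
                  !aa$is_hydrogen)
    if (!length(dons) || !length(accs)) next
    axyz <- as.matrix(aa[accs, c("x", "y", "z")])
    for (di in dons) {
      hyd <- which(!is.na(da$h_parent) & da$h_parent == da$serial[di])
      if (!length(hyd)) { skipped <- skipped + 1L; next }
      dpos <- as.numeric(da[di, c("x", "y", "z")])
      dv <- sweep(axyz, 2, dpos)
      dist <- sqrt(rowSums(dv^2)) * 10          # nm -> angstrom
      near <- which(dist <= d_max)
      for (ai in near) {
        for (hi in hyd) {
          hv <- as.numeric(da[hi, c("x", "y", "z")]) - dpos
          cosang <- sum(hv * dv[ai, ]) /
            (sqrt(sum(hv^2)) * sqrt(sum(dv[ai, ]^2)))
          ang <- acos(min(1, max(-1, cosang))) * 180 / pi
          if (ang <= a_max) {
            out[[length(out) + 1]] <- data.frame(
              donor_serial = da$serial[di], donor_side = sd$tag,
              hydrogen_serial = da$serial[hi],
              acceptor_serial = aa$serial[accs[ai]],
              d_da = dist[ai], angle_hda = ang,
              donor_res = paste0(da$chain[di], da$resseq[di]),
              acceptor_res = paste0(aa$chain[accs[ai]], aa$resseq[accs[ai]]),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(donor_serial = integer(0), donor_side = character(0),
               hydrogen_serial = integer(0), acceptor_serial = integer(0),
               d_da = numeric(0), angle_hda = numeric(0),
               donor_res = character(0), acceptor_res = character(0))
  res <- res[order(res$donor_serial, res$acceptor_serial), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped_donors") <- skipped
  res
}

#' Default key-residue sets of the receptor
#'
#' Seven receptor-binding-domain residues known to face the natural
#' receptor partner and ten basic heparin-binding-domain residues; both
#' lists address `resseq` values per chain.
#'
#' @param rbd_keys,hbd_keys integer resseq vectors
#' @return list of class `key_residue_set`
#' @export
key_residue_set <- function(rbd_keys = c(21, 25, 43, 62, 63, 64, 89),
                            hbd_keys = c(123, 124, 125, 140, 145, 149, 156,
                                         162, 164, 165)) {
  structure(list(rbd_keys = rbd_keys, hbd_keys = hbd_keys),
            class = "key_residue_set")
}

#' Time-averaged hydrogen-bond counts per key residue
#'
#' For every key residue (per chain) the mean number of accepted interface
#' H-bonds per snapshot in which a receptor-side donor or acceptor belongs
#' to that residue; non-key receptor residues are pooled into one `other`
#' row. Counts are multiplicities, not binary presence.
#'
#' @param snapshots list of `complex_model`s over the same receptor
#' @param keys a [key_residue_set()]
#' @param d_max,a_max H-bond criteria passed to [detect_hbonds()]
#' @return data.frame: `chain`, `resseq`, `region` (rbd/hbd/other),
#'   `mean_hbonds`
#' @export
hbond_census <- function(snapshots, keys = key_residue_set(), d_max = 3.5,
                         a_max = 30) {
  if (!length(snapshots)) stop("empty snapshot list")
  rec <- snapshots[[1]]$receptor
  res <- residue_table(rec)
  all_keys <- c(keys$rbd_keys, keys$hbd_keys)
  missing <- setdiff(all_keys, unique(res$resseq))
  if (length(missing))
    stop("key residue(s) not present in receptor: ",
         paste(missing, collapse = ", "))
  chains <- unique(res$chain)
  rows <- expand.grid(chain = chains, resseq = all_keys,
                      stringsAsFactors = FALSE)
  rows$region <- ifelse(rows$resseq %in% keys$rbd_keys, "rbd", "hbd")
  counts <- matrix(0, nrow(rows) + 1, length(snapshots))
  rowkey <- paste0(rows$chain, rows$resseq)
  for (si in seq_along(snapshots)) {
    hb <- detect_hbonds(snapshots[[si]], d_max, a_max)
    if (!nrow(hb)) next
    rec_res <- ifelse(hb$donor_side == "receptor", hb$donor_res,
                      hb$acceptor_res)
    idx <- match(rec_res, rowkey)
    for (j in seq_along(idx)) {
      r <- if (is.na(idx[j])) nrow(rows) + 1 else idx[j]
      counts[r, si] <- counts[r, si] + 1
    }
  }
  out <- rbind(rows, data.frame(chain = "*", resseq = NA_integer_,
                                region = "other"))
  out$mean_hbonds <- rowMeans(counts)
  out
}

#' Classify the binding pose of a receptor-aptamer complex
#'
#' Contact evidence (the 0.45 nm side-chain-heavy/DNA-heavy rule) of every
#' aptamer unit against the four receptor domains, then precedence rules:
#' **sandwich** if any single aptamer unit contacts both heparin-binding
#' domains; else **hug** if the RBD-binding unit contacts both
#' receptor-binding domains (wedged interior) while the HBD-binding unit
#' touches exactly one HBD; else **side** if the HBD-binding unit touches
#' exactly one HBD and the RBD-binding unit at most one RBD (outside);
#' else unclassified. For monomers, clauses referring to the absent unit
#' hold vacuously.
#'
#' @param cm a `complex_model`
#' @param cutoff contact cutoff, nm
#' @return list of class `pose_label`: `value` and the `evidence` matrix
#'   (units x domains, logical)
#' @export
classify_pose <- function(cm, cutoff = 0.45) {
  units <- c(map_groups(cm$ligand_map, "APT_RBD_BINDER"),
             map_groups(cm$ligand_map, "APT_HBD_BINDER"))
  if (!length(units)) stop("ligand map declares no aptamer binding roles")
  doms <- c(RBD = list(map_groups(cm$receptor_map, "RBD")),
            HBD = list(map_groups(cm$receptor_map, "HBD")))
  dom_names <- c(doms$RBD, doms$HBD)
  ev <- matrix(FALSE, length(units), length(dom_names),
               dimnames = list(units, dom_names))
  for (u in units) for (d in dom_names)
    ev[u, d] <- contacts(cm, d, u, cutoff)$contact
  hbd_cols <- doms$HBD; rbd_cols <- doms$RBD
  rbd_unit <- map_groups(cm$ligand_map, "APT_RBD_BINDER")
  hbd_unit <- map_groups(cm$ligand_map, "APT_HBD_BINDER")
  n_hbd <- function(u) sum(ev[u, hbd_cols])
  n_rbd <- function(u) sum(ev[u, rbd_cols])
  sandwich <- any(vapply(units, function(u) n_hbd(u) == 2, logical(1)))
  # hug is defined by the RBD binder wedged between both RBD units; side by
  # the HBD binder on a single HBD (or, for an RBD-only monomer, a single
  # RBD touched from outside). Clauses about an absent unit hold vacuously.
  hug <- length(rbd_unit) > 0 && n_rbd(rbd_unit) == 2 &&
    (!length(hbd_unit) || n_hbd(hbd_unit) == 1)
  side <- if (length(hbd_unit)) {
    n_hbd(hbd_unit) == 1 && (!length(rbd_unit) || n_rbd(rbd_unit) <= 1)
  } else {
    n_rbd(rbd_unit) == 1
  }
  value <- if (sandwich) "sandwich" else if (hug) "hug" else if (side) "side"
           else "unclassified"
  structure(list(value = value, evidence = ev), class = "pose_label")
}

#' @export
print.pose_label <- function(x, ...) {
  cat(sprintf("<pose_label> %s\n", x$value))
  print(x$evidence)
  invisible(x)
}

#' Optimal-superposition RMSD between matched coordinate sets
#'
#' Kabsch least-squares fit with the proper-rotation constraint
#' (determinant +1), returning the RMSD in angstrom for nm inputs.
#'
#' @param mobile,reference matched n x 3 coordinate matrices, nm
#' @return RMSD in angstrom
#' @export
kabsch_rmsd <- function(mobile, reference) {
  fit <- kabsch_fit(mobile, reference)
  fit$rmsd * 10
}

#' RMSD distribution of a quadruplex core over snapshots
#'
#' Per snapshot, the Kabsch RMSD of the core residues' heavy atoms against
#' the stored reference coordinates; reported with a fixed-width histogram
#' for distribution summaries.
#'
#' @param snapshots list of `apt_structure`s (aptamer conformers)
#' @param core data.frame(chain, resseq) naming the core; defaults to the
#'   `$core` stored by [make_toy_aptamer()]
#' @param reference reference heavy-atom coordinate matrix, nm; defaults
#'   to the stored `$core_ref`
#' @param bin_width histogram bin width, angstrom
#' @param core_size expected core residue count (12; set `NULL` to skip
#'   the check)
#' @return list with `rmsd` (angstrom, one per snapshot) and `histogram`
#'   (data.frame mid/count)
#' @export
quadruplex_rmsd_distribution <- function(snapshots, core = NULL,
                                         reference = NULL, bin_width = 0.25,
                                         core_size = 12) {
  if (!length(snapshots)) stop("empty snapshot list")
  core <- core %||% snapshots[[1]]$core
  reference <- reference %||% snapshots[[1]]$core_ref
  if (is.null(core) || is.null(reference))
    stop("no quadruplex core definition available")
  if (!is.null(core_size) && nrow(core) != core_size)
    stop(sprintf("quadruplex core has %d residues; expected %d", nrow(core),
                 core_size))
  rmsd <- vapply(snapshots, function(s) {
    idx <- atom_rows_for_residues_heavy(s, core)
    if (!length(idx)) stop("core residues unresolvable in a snapshot")
    kabsch_rmsd(coords(s, heavy_only = TRUE)[idx, , drop = FALSE], reference)
  }, numeric(1))
  breaks <- seq(0, max(rmsd, bin_width) + bin_width, by = bin_width)
  h <- graphics::hist(rmsd, breaks = breaks, plot = FALSE)
  list(rmsd = rmsd, histogram = data.frame(mid = h$mids, count = h$counts))
}

#' All-heavy-atom RMSD time course over snapshots
#'
#' Kabsch RMSD of every snapshot's merged complex against the snapshot at
#' `reference_index`.
#'
#' @param snapshots list of `complex_model`s (or `apt_structure`s)
#' @param reference_index 1-based index of the reference snapshot
#' @return numeric vector of RMSD values, angstrom
#' @export
rmsd_timecourse <- function(snapshots, reference_index = length(snapshots)) {
  if (!length(snapshots)) stop("empty snapshot list")
  if (reference_index < 1 || reference_index > length(snapshots))
    stop("reference index out of range")
  get_xyz <- function(x) {
    s <- if (inherits(x, "complex_model")) merge_complex(x) else x
    coords(s, heavy_only = TRUE)
  }
  ref <- get_xyz(snapshots[[reference_index]])
  vapply(snapshots, function(x) kabsch_rmsd(get_xyz(x), ref), numeric(1))
}

#' Buried-interface (steric clash) area against a reference partner
#'
#' Superposes the complex onto a reference receptor by Kabsch fit of the
#' `align_group` backbone nodes, transplants the aptamer into the
#' reference frame, and evaluates the buried surface area between the
#' transplanted aptamer and the reference partner:
#' `(SASA(aptamer) + SASA(partner) - SASA(both)) / 2` (set `half = FALSE`
#' for the total SASA loss). A large value means the aptamer would clash
#' with the partner's binding footprint.
#'
#' @param cm a `complex_model` (receptor + aptamer)
#' @param ref_receptor reference receptor `apt_structure` sharing
#'   `align_group` residues
#' @param ref_partner the partner structure bound to the reference receptor
#' @param align_group group name(s) present in `cm$receptor_map`, aligned
#'   via backbone nodes
#' @param ref_map optional `domain_map` of the reference receptor
#'   (defaults to `cm$receptor_map`, for references sharing numbering)
#' @param half divide the SASA loss by two (the convention used here)
#' @param probe,n_points SASA settings
#' @return area in nm^2
#' @export
clash_area <- function(cm, ref_receptor, ref_partner, align_group,
                       ref_map = NULL, half = TRUE, probe = 0.14,
                       n_points = 128) {
  ref_map <- ref_map %||% cm$receptor_map
  res_mob <- map_residues(cm$receptor_map, align_group)
  res_ref <- map_residues(ref_map, align_group)
  nm <- cg_nodes(cm$receptor); nr <- cg_nodes(ref_receptor)
  im <- node_rows(nm, res_mob); ir <- node_rows(nr, res_ref)
  if (length(im) != length(ir) || !length(im))
    stop("alignment group mismatch between complex and reference")
  fit <- kabsch_fit(as.matrix(nm[im, c("x", "y", "z")]),
                    as.matrix(nr[ir, c("x", "y", "z")]))
  apt <- cm$ligand
  apt <- set_coords(apt, apply_kabsch(coords(apt), fit))
  area_pair(apt, ref_partner, half, probe, n_points)
}

node_rows <- function(nodes, res) {
  key <- paste(nodes$chain, nodes$resseq)
  which(key %in% paste(res$chain, res$resseq))
}

# buried area between two structures from three SASA evaluations
area_pair <- function(a, b, half = TRUE, probe = 0.14, n_points = 128) {
  sa <- sasa(a, probe, n_points)$total
  sb <- sasa(b, probe, n_points)$total
  ha <- a$atoms[!a$atoms$is_hydrogen, ]
  hb <- b$atoms[!b$atoms$is_hydrogen, ]
  both <- list(xyz = rbind(as.matrix(ha[, c("x", "y", "z")]),
                           as.matrix(hb[, c("x", "y", "z")])),
               radii = c(ifelse(is.na(ha$gb_radius),
                                element_radius(ha$element), ha$gb_radius),
                         ifelse(is.na(hb$gb_radius),
                                element_radius(hb$element), hb$gb_radius)))
  sab <- sasa(both, probe, n_points)$total
  buried <- sa + sb - sab
  if (half) buried / 2 else buried
}
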