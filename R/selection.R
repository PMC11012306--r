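# Ensemble bookkeeping: the contact rule, the attachment criteria, top-k
# selection per variant pair, and the closed-form manifest arithmetic of
# the cross-docking campaign (140 x 240 = 33600 docked pairs per
# heterodimer, 84 variants x top-3 = 252 selections, and so on).

#' Contact test between a receptor group and a ligand group
#'
#' A contact exists when at least one pair (protein side-chain heavy atom
#' in the receptor group, DNA heavy atom in the ligand group) lies within
#' `cutoff` (0.45 nm is the classification rule used throughout).
#'
#' @param cm a `complex_model`
#' @param receptor_group,ligand_group group names (vectors form unions)
#' @param cutoff contact distance, nm
#' @return list with `contact` (logical) and `n` (pair count)
#' @export
contacts <- function(cm, receptor_group, ligand_group, cutoff = 0.45) {
  ra <- cm$receptor$atoms
  rres <- map_residues(cm$receptor_map, receptor_group)
  rsel <- ra[paste(ra$chain, ra$resseq) %in% paste(rres$chain, rres$resseq) &
             ra$is_sidechain & !ra$is_hydrogen & ra$kind == "protein", ]
  la <- cm$ligand$atoms
  lres <- map_residues(cm$ligand_map, ligand_group)
  lsel <- la[paste(la$chain, la$resseq) %in% paste(lres$chain, lres$resseq) &
             !la$is_hydrogen & la$kind == "dna", ]
  if (!nrow(rsel)) stop("no protein side-chain heavy atoms in receptor group")
  if (!nrow(lsel)) stop("no DNA heavy atoms in ligand group")
  d2 <- cross_dist2(as.matrix(rsel[, c("x", "y", "z")]),
                    as.matrix(lsel[, c("x", "y", "z")]))
  n <- sum(d2 <= cutoff^2)
  list(contact = n > 0, n = n)
}

#' Attachment-criteria filter for a docked complex
#'
#' A heterodimer passes when its RBD-binding unit contacts the union of
#' the receptor-binding domains and its HBD-binding unit contacts the
#' union of the heparin-binding domains; a monomer passes when its single
#' unit contacts the domain set of its declared role. Contacts use
#' [contacts()] at `cutoff`.
#'
#' @param cm a `complex_model`
#' @param cutoff contact distance, nm
#' @return logical
#' @export
attachment_filter <- function(cm, cutoff = 0.45) {
  rbd_units <- map_groups(cm$ligand_map, "APT_RBD_BINDER")
  hbd_units <- map_groups(cm$ligand_map, "APT_HBD_BINDER")
  if (!length(rbd_units) && !length(hbd_units))
    stop("ligand map declares no APT_RBD_BINDER/APT_HBD_BINDER role")
  rbds <- map_groups(cm$receptor_map, "RBD")
  hbds <- map_groups(cm$receptor_map, "HBD")
  ok <- TRUE
  if (length(rbd_units))
    ok <- ok && contacts(cm, rbds, rbd_units, cutoff)$contact
  if (length(hbd_units))
    ok <- ok && contacts(cm, hbds, hbd_units, cutoff)$contact
  ok
}

#' Select the top-k passing poses per variant pair
#'
#' Poses are grouped by (receptor variant, ligand variant); within each
#' group the attachment-passing poses are sorted by score descending (ties
#' broken by `pose_id`) and the first `min(k, available)` are kept.
#'
#' @param poses data.frame with columns `receptor_variant`,
#'   `ligand_variant`, `pose_id`, `score`, `passed`
#' @param k selections per group (3 in the canonical campaign)
#' @return the selected subset, with a `rank` column per group
#' @export
select_top_k <- function(poses, k = 3) {
  req <- c("receptor_variant", "ligand_variant", "pose_id", "score", "passed")
  if (!all(req %in% names(poses))) stop("poses lacks columns: ",
                                        paste(setdiff(req, names(poses)), collapse = ", "))
  poses <- poses[poses$passed, , drop = FALSE]
  if (!nrow(poses)) return(cbind(poses, rank = integer(0)))
  grp <- paste(poses$receptor_variant, poses$ligand_variant, sep = "\r")
  out <- lapply(split(seq_len(nrow(poses)), grp), function(idx) {
    sub <- poses[idx[order(-poses$score[idx], poses$pose_id[idx])], , drop = FALSE]
    sub <- utils::head(sub, k)
    sub$rank <- seq_len(nrow(sub))
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Campaign manifest and its closed-form counts
#'
#' @param n_receptor_variants,n_receptor_snapshots receptor grid size and
#'   snapshots per grid point (7 and 20 canonically)
#' @param n_ligand_variants,n_ligand_snapshots ligand counterpart (12 and
#'   20 for a heterodimer; 1 and 20 for a monomer)
#' @param top_k selections per variant pair
#' @return list of class `ensemble_manifest`
#' @export
ensemble_manifest <- function(n_receptor_variants = 7,
                              n_receptor_snapshots = 20,
                              n_ligand_variants = 12,
                              n_ligand_snapshots = 20, top_k = 3) {
  v <- c(n_receptor_variants, n_receptor_snapshots, n_ligand_variants,
         n_ligand_snapshots, top_k)
  if (any(v < 1)) stop("all manifest counts must be >= 1")
  structure(list(n_receptor_variants = n_receptor_variants,
                 n_receptor_snapshots = n_receptor_snapshots,
                 n_ligand_variants = n_ligand_variants,
                 n_ligand_snapshots = n_ligand_snapshots, top_k = top_k),
            class = "ensemble_manifest")
}

#' Closed-form counts of a docking campaign
#'
#' `docked_pairs` enumerates every receptor conformer against every ligand
#' conformer; `variants` counts variant pairs (large-scale conformer
#' combinations); `max_selected` is `variants * top_k`. The canonical
#' heterodimer manifest (7, 20, 12, 20, 3) gives 33600 / 84 / 252 and the
#' monomer manifest (7, 20, 1, 20, 3) gives 2800 / 7 / 21.
#'
#' @param m an [ensemble_manifest()]
#' @return list with `docked_pairs`, `variants`, `max_selected`
#' @export
manifest_counts <- function(m) {
  stopifnot(inherits(m, "ensemble_manifest"))
  list(docked_pairs = (m$n_receptor_variants * m$n_receptor_snapshots) *
         (m$n_ligand_variants * m$n_ligand_snapshots),
       variants = m$n_receptor_variants * m$n_ligand_variants,
       max_selected = m$n_receptor_variants * m$n_ligand_variants * m$top_k)
}
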