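# Receptor/ligand complex container: two structures with their domain maps,
# an optional rigid docking pose (applied to the ligand at construction),
# and an optional pose-taxonomy label.

#' Build a receptor-ligand complex model
#'
#' If a `pose` (a row of the data.frame returned by [dock()]) is supplied,
#' the ligand is rotated about its heavy-atom centroid and its centroid is
#' moved to the pose translation before storing; the stored ligand is
#' therefore always in the receptor frame.
#'
#' @param receptor,ligand `apt_structure` objects on disjoint chain ids
#' @param receptor_map,ligand_map their `domain_map`s
#' @param pose optional single-row pose data.frame (quaternion + translation)
#' @param label optional pose label string
#' @return object of class `complex_model`
#' @export
complex_model <- function(receptor, receptor_map, ligand, ligand_map,
                          pose = NULL, label = NULL) {
  rc <- unique(receptor$atoms$chain)
  lc <- unique(ligand$atoms$chain)
  if (length(intersect(rc, lc)))
    stop("receptor and ligand share chain id(s): ",
         paste(intersect(rc, lc), collapse = ","))
  if (!is.null(pose)) ligand <- apply_pose(ligand, pose)
  structure(list(receptor = receptor, receptor_map = receptor_map,
                 ligand = ligand, ligand_map = ligand_map,
                 pose = pose, label = label),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model> receptor %d atoms + ligand %d atoms%s%s\n",
              n_atoms(x$receptor), n_atoms(x$ligand),
              if (!is.null(x$pose)) sprintf(", pose %s", x$pose$pose_id) else "",
              if (!is.null(x$label)) sprintf(", label %s", x$label) else ""))
  invisible(x)
}

#' Merge the two halves of a complex into one structure
#'
#' Ligand serials are offset past the receptor's largest serial so the
#' merged atom table has unique serials; `h_parent` references are offset
#' consistently.
#'
#' @param cm a `complex_model`
#' @return an `apt_structure` with provenance `"derived"`
#' @export
merge_complex <- function(cm) {
  ra <- cm$receptor$atoms
  la <- cm$ligand$atoms
  off <- max(ra$serial)
  la$serial <- la$serial + off
  la$h_parent <- la$h_parent + off
  new_structure(rbind(ra, la),
                title = paste0(cm$receptor$title, "+", cm$ligand$title),
                provenance = "derived")
}

# jittered copies of a complex (rigid-ish thermal stand-in used by the
# rescoring and analysis stages): independent gaussian displacement per atom
jitter_complex <- function(cm, n, amp = 0.02, seed = 1) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    r <- cm$receptor; l <- cm$ligand
    r <- set_coords(r, coords(r) + matrix(stats::rnorm(3 * n_atoms(r), 0, amp),
                                          ncol = 3))
    l <- set_coords(l, coords(l) + matrix(stats::rnorm(3 * n_atoms(l), 0, amp),
                                          ncol = 3))
    complex_model(r, cm$receptor_map, l, cm$ligand_map, label = cm$label)
  }))
}
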