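# Shared fixtures, built once per test run and cached. All generated in
# code; no files on disk.

.fix <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# full-size defaults (the canonical study geometry)
full_receptor <- function() cached("rec_full", function() make_toy_receptor(gen_params()))
full_heterodimer <- function() cached("het_full", function() make_toy_aptamer("heterodimer", gen_params()))

# small receptor for ANM/conformer unit tests (same topology, cheaper)
tiny_gen <- function(seed = 2) gen_params(seed = seed, n_res_rbd = 20,
                                          n_res_hbd = 10,
                                          linker_len_receptor = 6)
tiny_receptor <- function() cached("rec_tiny", function() make_toy_receptor(tiny_gen()))
tiny_enm <- function() cached("enm_tiny", function() build_enm(tiny_receptor()$structure))
tiny_modes <- function() cached("modes_tiny", function() compute_modes(tiny_enm(), 20))

pose_fixture <- function(label) cached(paste0("pose_", label),
                                       function() make_pose_fixture(label))

# a bare structure from a coordinate matrix (nm), all heavy carbons
coords_structure <- function(xyz, chain = "A", element = "C",
                             charge = NA_real_, gb_radius = NA_real_) {
  n <- nrow(xyz)
  new_structure(data.frame(
    serial = seq_len(n), name = "CA", element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], chain = chain,
    resseq = seq_len(n), resname = "ALA", is_hydrogen = FALSE,
    is_sidechain = FALSE, hbond_role = "none", h_parent = NA_integer_,
    charge = charge, gb_radius = gb_radius))
}

# independent all-pairs H-bond oracle (no neighbour lists, no sorting
# tricks): scans every donor/H/acceptor triplet across the interface
brute_force_hbonds <- function(cm, d_max = 3.5, a_max = 30) {
  count <- 0
  halves <- list(list(cm$receptor$atoms, cm$ligand$atoms),
                 list(cm$ligand$atoms, cm$receptor$atoms))
  for (h in halves) {
    da <- h[[1]]; aa <- h[[2]]
    for (i in seq_len(nrow(da))) {
      if (!(da$hbond_role[i] %in% c("donor", "donor_acceptor")) ||
          da$is_hydrogen[i]) next
      hyd <- which(!is.na(da$h_parent) & da$h_parent == da$serial[i])
      if (!length(hyd)) next
      for (j in seq_len(nrow(aa))) {
        if (!(aa$hbond_role[j] %in% c("acceptor", "donor_acceptor")) ||
            aa$is_hydrogen[j]) next
        dv <- as.numeric(aa[j, c("x", "y", "z")]) -
          as.numeric(da[i, c("x", "y", "z")])
        if (sqrt(sum(dv^2)) * 10 > d_max) next
        for (k in hyd) {
          hv <- as.numeric(da[k, c("x", "y", "z")]) -
            as.numeric(da[i, c("x", "y", "z")])
          ang <- acos(min(1, max(-1, sum(hv * dv) /
                                   (sqrt(sum(hv^2)) * sqrt(sum(dv^2)))))) * 180 / pi
          if (ang <= a_max) count <- count + 1
        }
      }
    }
  }
  count
}
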