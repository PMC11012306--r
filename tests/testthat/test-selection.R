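# Contact rule, attachment criteria, top-k selection, manifest arithmetic

# minimal complex: one protein side-chain heavy atom vs one DNA heavy atom
# at an adjustable separation
pair_complex <- function(d_nm) {
  rec <- new_structure(data.frame(
    serial = 1:2, name = c("CA", "CB"), element = "C",
    x = c(-0.2, 0), y = 0, z = 0, chain = "A", resseq = 1, resname = "ALA",
    is_hydrogen = FALSE, is_sidechain = c(FALSE, TRUE), hbond_role = "none",
    h_parent = NA_integer_, charge = 0))
  lig <- new_structure(data.frame(
    serial = 1L, name = "P", element = "P", x = d_nm, y = 0, z = 0,
    chain = "C", resseq = 1L, resname = "DT", is_hydrogen = FALSE,
    is_sidechain = FALSE, hbond_role = "none", h_parent = NA_integer_,
    charge = -1))
  rmap <- bind_domain_map(rec, list(RBD1 = list(chain = "A", first = 1,
                                                last = 1, role = "RBD")))
  lmap <- bind_domain_map(lig, list(APT_A = list(chain = "C", first = 1,
                                                 last = 1,
                                                 role = "APT_RBD_BINDER")))
  complex_model(rec, rmap, lig, lmap)
}

test_that("the 0.45 nm contact rule is a sharp threshold", {
  expect_true(contacts(pair_complex(0.44), "RBD1", "APT_A")$contact)
  expect_false(contacts(pair_complex(0.46), "RBD1", "APT_A")$contact)
})

test_that("contact counts match a brute-force double loop", {
  cm <- pose_fixture("sandwich")
  got <- contacts(cm, c("HBD1", "HBD2"), "APT_B")
  ra <- cm$receptor$atoms
  rres <- map_residues(cm$receptor_map, c("HBD1", "HBD2"))
  rsel <- ra[paste(ra$chain, ra$resseq) %in% paste(rres$chain, rres$resseq) &
             ra$is_sidechain & !ra$is_hydrogen & ra$kind == "protein", ]
  la <- cm$ligand$atoms
  lres <- map_residues(cm$ligand_map, "APT_B")
  lsel <- la[paste(la$chain, la$resseq) %in% paste(lres$chain, lres$resseq) &
             !la$is_hydrogen & la$kind == "dna", ]
  cnt <- 0
  for (i in seq_len(nrow(rsel))) for (j in seq_len(nrow(lsel))) {
    d <- sqrt(sum((as.numeric(rsel[i, c("x", "y", "z")]) -
                     as.numeric(lsel[j, c("x", "y", "z")]))^2))
    if (d <= 0.45) cnt <- cnt + 1
  }
  expect_equal(got$n, cnt)
  expect_true(got$contact)
})

test_that("contacts are monotone in the cutoff", {
  cm <- pose_fixture("side")
  cuts <- c(0.3, 0.45, 0.6, 0.9)
  ns <- vapply(cuts, function(cc) contacts(cm, "HBD1", "APT_B", cc)$n,
               numeric(1))
  expect_true(all(diff(ns) >= 0))
  passing <- vapply(cuts, function(cc) attachment_filter(cm, cc), logical(1))
  expect_true(all(diff(as.integer(passing)) >= 0) || all(passing))
})

test_that("attachment criteria require each unit on its own domain set", {
  expect_true(attachment_filter(pose_fixture("sandwich")))
  # detach the RBD binder: the heterodimer must fail
  cm <- pose_fixture("sandwich")
  ares <- map_residues(cm$ligand_map, "APT_A")
  cm$ligand <- aptadock:::translate_residues(cm$ligand, ares, c(0, -30, 0))
  expect_false(attachment_filter(cm))
  # a monomer HBD-binder touching only an RBD fails
  rec <- new_structure(data.frame(
    serial = 1:4, name = rep(c("CA", "CB"), 2), element = "C",
    x = c(-0.2, 0, 9.8, 10), y = 0, z = 0, chain = "A", resseq = c(1, 1, 2, 2),
    resname = "ALA", is_hydrogen = FALSE,
    is_sidechain = rep(c(FALSE, TRUE), 2), hbond_role = "none",
    h_parent = NA_integer_, charge = 0))
  lig <- new_structure(data.frame(
    serial = 1L, name = "P", element = "P", x = 0.4, y = 0, z = 0,
    chain = "C", resseq = 1L, resname = "DT", is_hydrogen = FALSE,
    is_sidechain = FALSE, hbond_role = "none", h_parent = NA_integer_,
    charge = -1))
  wrong <- complex_model(
    rec, bind_domain_map(rec, list(
      RBD1 = list(chain = "A", first = 1, last = 1, role = "RBD"),
      HBD1 = list(chain = "A", first = 2, last = 2, role = "HBD"))),
    lig, bind_domain_map(lig, list(
      APT_A = list(chain = "C", first = 1, last = 1,
                   role = "APT_HBD_BINDER"))))
  expect_false(attachment_filter(wrong))
})

test_that("top-k selection reproduces the campaign arithmetic", {
  mk <- function(n_groups, n_poses, passing = n_poses) {
    do.call(rbind, lapply(seq_len(n_groups), function(g)
      data.frame(receptor_variant = (g - 1) %/% 12 + 1,
                 ligand_variant = (g - 1) %% 12 + 1,
                 pose_id = sprintf("g%03dp%02d", g, seq_len(n_poses)),
                 score = seq_len(n_poses) + g / 100,
                 passed = seq_len(n_poses) <= passing)))
  }
  sel <- select_top_k(mk(84, 5), k = 3)
  expect_equal(nrow(sel), 252)
  sel7 <- select_top_k(mk(7, 5), k = 3)
  expect_equal(nrow(sel7), 21)
  # a group with fewer passing poses keeps what it has
  sel2 <- select_top_k(mk(1, 5, passing = 2), k = 3)
  expect_equal(nrow(sel2), 2)
  # scores sort descending within the group, ties broken by pose id
  tie <- data.frame(receptor_variant = 1, ligand_variant = 1,
                    pose_id = c("b", "a", "c"), score = c(1, 1, 2),
                    passed = TRUE)
  out <- select_top_k(tie, k = 2)
  expect_equal(out$pose_id, c("c", "a"))
})

test_that("manifest counts follow the closed-form arithmetic", {
  het <- manifest_counts(ensemble_manifest(7, 20, 12, 20, 3))
  expect_equal(het$docked_pairs, 33600)
  expect_equal(het$variants, 84)
  expect_equal(het$max_selected, 252)
  mono <- manifest_counts(ensemble_manifest(7, 20, 1, 20, 3))
  expect_equal(mono$docked_pairs, 2800)
  expect_equal(mono$max_selected, 21)
  one <- manifest_counts(ensemble_manifest(1, 1, 1, 1, 1))
  expect_equal(unlist(one), c(docked_pairs = 1, variants = 1, max_selected = 1))
  # property: arithmetic identities over random small manifests
  set.seed(77)
  for (i in 1:25) {
    v <- sample(1:9, 5, replace = TRUE)
    m <- ensemble_manifest(v[1], v[2], v[3], v[4], v[5])
    cc <- manifest_counts(m)
    expect_equal(cc$docked_pairs, v[1] * v[2] * v[3] * v[4])
    expect_equal(cc$max_selected, v[1] * v[3] * v[5])
  }
})

test_that("select_top_k size equals the sum of per-group minima", {
  set.seed(13)
  poses <- do.call(rbind, lapply(1:10, function(g) {
    n <- sample(1:6, 1)
    data.frame(receptor_variant = g, ligand_variant = 1,
               pose_id = sprintf("g%02dp%02d", g, seq_len(n)),
               score = runif(n), passed = runif(n) > 0.4)
  }))
  sel <- select_top_k(poses, k = 3)
  want <- sum(tapply(poses$passed, poses$receptor_variant,
                     function(p) min(3, sum(p))))
  expect_equal(nrow(sel), want)
})
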