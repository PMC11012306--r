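# Geometric analysis: H-bonds, pose taxonomy, RMSD machinery, clash area

test_that("H-bond detection equals the brute-force all-pairs oracle", {
  for (n in c(0, 3, 7)) {
    cm <- make_hbond_fixture(n)
    hb <- detect_hbonds(cm)
    expect_equal(nrow(hb), brute_force_hbonds(cm))
    expect_equal(nrow(hb), n)
  }
  cm <- pose_fixture("sandwich")
  expect_equal(nrow(detect_hbonds(cm)), brute_force_hbonds(cm))
})

test_that("H-bond criteria are sharp in distance and angle", {
  cm <- make_hbond_fixture(1)
  expect_equal(nrow(detect_hbonds(cm, d_max = 3.5)), 1)
  expect_equal(nrow(detect_hbonds(cm, d_max = 2.9)), 0)   # bond sits at 3.0
  expect_equal(nrow(detect_hbonds(cm, a_max = 44)), 1)    # decoy at 45 deg
  expect_equal(nrow(detect_hbonds(cm, a_max = 46)), 2)
})

test_that("rows are ordered by donor then acceptor serial", {
  cm <- make_hbond_fixture(4)
  hb <- detect_hbonds(cm)
  expect_false(is.unsorted(hb$donor_serial))
})

test_that("the census averages counts over snapshots", {
  cm1 <- make_hbond_fixture(1)
  # second snapshot: ligand pulled away, no bonds
  lig2 <- set_coords(cm1$ligand, coords(cm1$ligand) +
                       matrix(rep(c(5, 0, 0), each = n_atoms(cm1$ligand)),
                              ncol = 3))
  cm2 <- complex_model(cm1$receptor, cm1$receptor_map, lig2, cm1$ligand_map)
  keys <- key_residue_set(rbd_keys = 1, hbd_keys = 2)
  cen <- hbond_census(list(cm1, cm2), keys)
  expect_equal(cen$mean_hbonds[cen$resseq == 1 & !is.na(cen$resseq)], 0.5)
  cen2 <- hbond_census(list(cm1, cm1, cm1), keys)
  expect_equal(cen2$mean_hbonds[cen2$resseq == 1 & !is.na(cen2$resseq)], 1)
  expect_error(hbond_census(list(cm1), key_residue_set(rbd_keys = 999)),
               "not present")
})

test_that("pose classification recovers every fixture label exactly", {
  for (lab in c("sandwich", "side", "hug"))
    expect_equal(classify_pose(pose_fixture(lab))$value, lab)
})

test_that("a monomer bridging both HBD units classifies as sandwich", {
  cm <- aptadock:::monomer_fixture("monomer_plain", gen_params(seed = 3),
                                   "bridge")
  expect_equal(classify_pose(cm)$value, "sandwich")
  cm2 <- aptadock:::monomer_fixture("monomer_quad", gen_params(seed = 3),
                                    "interior")
  expect_equal(classify_pose(cm2)$value, "hug")
})

test_that("every complex receives exactly one label; detached is unclassified", {
  labs <- c(vapply(c("sandwich", "side", "hug"), function(l)
    classify_pose(pose_fixture(l))$value, character(1)))
  expect_true(all(labs %in% c("sandwich", "side", "hug", "unclassified")))
  cm <- pose_fixture("side")
  far <- set_coords(cm$ligand, coords(cm$ligand) +
                      matrix(rep(c(40, 0, 0), each = n_atoms(cm$ligand)),
                             ncol = 3))
  cmf <- complex_model(cm$receptor, cm$receptor_map, far, cm$ligand_map)
  expect_equal(classify_pose(cmf)$value, "unclassified")
})

test_that("kabsch RMSD is zero for rigid copies and below the raw RMSD", {
  set.seed(19)
  X <- matrix(rnorm(15), ncol = 3)
  expect_equal(kabsch_rmsd(X, X), 0, tolerance = 1e-12)
  q <- c(cos(0.6), sin(0.6) * c(0, 0.6, 0.8))
  R <- quat_to_mat(q / sqrt(sum(q^2)))
  Y <- X %*% t(R) + matrix(rep(c(1, 2, 3), each = 5), ncol = 3)
  expect_equal(kabsch_rmsd(Y, X), 0, tolerance = 1e-9)
  Z <- X + matrix(rnorm(15, 0, 0.1), ncol = 3)
  raw <- sqrt(mean(rowSums((Z - X)^2))) * 10
  expect_lte(kabsch_rmsd(Z, X), raw + 1e-12)
  expect_error(kabsch_rmsd(X, X[1:3, ]), "mismatch")
})

test_that("kabsch agrees with an independent superposition implementation", {
  set.seed(23)
  X <- matrix(rnorm(21), ncol = 3)
  Y <- X %*% t(quat_to_mat(c(0.8, 0.6, 0, 0))) +
    matrix(rnorm(21, 0, 0.05), ncol = 3)
  got <- kabsch_rmsd(Y, X)
  # bio3d reports in the input units (nm here) rounded to three decimals;
  # ours converts nm -> angstrom
  ref <- bio3d::rmsd(as.vector(t(X)), as.vector(t(Y)), fit = TRUE) * 10
  expect_equal(got, ref, tolerance = 0.01)
})

test_that("kabsch attains the minimum of a coarse quaternion-grid search", {
  set.seed(29)
  X <- matrix(rnorm(15), ncol = 3)
  Y <- X %*% t(quat_to_mat(c(0.9, 0.1, 0.3,.3) / sqrt(sum(c(0.9, 0.1, 0.3, 0.3)^2)))) +
    matrix(rnorm(15, 0, 0.02), ncol = 3)
  got <- kabsch_rmsd(Y, X)
  qs <- sample_rotations(10)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  grid_min <- min(apply(qs, 1, function(q)
    sqrt(mean(rowSums((Yc %*% t(quat_to_mat(q)) - Xc)^2))) * 10))
  expect_lte(got, grid_min + 1e-9)
})

test_that("quadruplex RMSD is zero unperturbed and grows with jitter", {
  apt <- make_toy_aptamer("monomer_quad", gen_params(seed = 7))
  s <- apt$structure
  q0 <- quadruplex_rmsd_distribution(list(s))
  expect_equal(q0$rmsd, 0, tolerance = 1e-9)
  jitter_core <- function(amp, seed) {
    with_seed(seed, set_coords(s, coords(s) +
                                 matrix(rnorm(3 * n_atoms(s), 0, amp), ncol = 3)))
  }
  snaps_a <- lapply(1:6, function(i) {
    x <- jitter_core(0.02, i); x$core <- s$core; x$core_ref <- s$core_ref; x })
  snaps_b <- lapply(1:6, function(i) {
    x <- jitter_core(0.04, i); x$core <- s$core; x$core_ref <- s$core_ref; x })
  ra <- quadruplex_rmsd_distribution(snaps_a)
  rb <- quadruplex_rmsd_distribution(snaps_b)
  expect_lt(mean(ra$rmsd), mean(rb$rmsd))
  # the 12-residue core size is enforced
  bad <- s; bad$core <- s$core[1:10, ]
  expect_error(quadruplex_rmsd_distribution(list(bad)), "expected 12")
})

test_that("RMSD time courses reference the chosen snapshot", {
  apt <- make_toy_aptamer("monomer_plain", gen_params(seed = 2))
  ens <- free_ensemble(apt$structure, 4, seed = 6)
  snaps <- lapply(ens$members, `[[`, "structure")
  tc <- rmsd_timecourse(snaps, 1)
  expect_equal(tc[1], 0, tolerance = 1e-9)
  per <- vapply(snaps, function(x)
    kabsch_rmsd(coords(x, TRUE), coords(snaps[[1]], TRUE)), numeric(1))
  expect_equal(tc, per, tolerance = 1e-12)
  same <- rmsd_timecourse(list(snaps[[1]], snaps[[1]], snaps[[1]]), 2)
  expect_equal(same, rep(0, 3), tolerance = 1e-9)
  expect_error(rmsd_timecourse(snaps, 9), "out of range")
})

test_that("clash area vanishes for distant partners and matches the cap formula", {
  cm <- pose_fixture("side")
  partner_far <- coords_structure(matrix(c(60, 0, 0), 1, 3), chain = "E",
                                  gb_radius = 0.19)
  expect_equal(clash_area(cm, cm$receptor, partner_far, c("RBD1", "RBD2")),
               0, tolerance = 1e-9)
  # two overlapping single spheres: buried area = (cap1 + cap2) / 2
  a <- aptadock:::area_pair(
    coords_structure(matrix(0, 1, 3), chain = "A", gb_radius = 0.19),
    coords_structure(matrix(c(0.4, 0, 0), 1, 3), chain = "B", gb_radius = 0.16),
    n_points = 2048)
  r1 <- 0.33; r2 <- 0.30; d <- 0.4
  cap <- function(ra, rb) { x <- (d^2 + ra^2 - rb^2) / (2 * d); 2 * pi * ra * (ra - x) }
  want <- (cap(r1, r2) + cap(r2, r1)) / 2
  expect_equal(a, want, tolerance = 0.01)
})

test_that("clash area is symmetric and grows as the partner approaches", {
  a <- make_toy_aptamer("monomer_plain", gen_params(seed = 4))$structure
  b <- make_toy_aptamer("monomer_plain", gen_params(seed = 9))$structure
  offs <- c(2.6, 2.2, 1.8)
  areas <- vapply(offs, function(off) {
    b2 <- set_coords(b, sweep(coords(b), 2,
                              colMeans(coords(b, TRUE)) - c(off, 0, 0)))
    aptadock:::area_pair(a, b2, n_points = 128)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
  b2 <- set_coords(b, sweep(coords(b), 2, colMeans(coords(b, TRUE)) - c(2, 0, 0)))
  expect_equal(aptadock:::area_pair(a, b2, n_points = 128),
               aptadock:::area_pair(b2, a, n_points = 128), tolerance = 1e-9)
})
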