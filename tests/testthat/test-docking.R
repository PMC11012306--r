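# FFT docking: rotation sampling, digitisation, correlation, two-stage dock

test_that("rotation samples are unit quaternions, deterministic, include identity", {
  q <- sample_rotations(30)
  expect_equal(sqrt(rowSums(q^2)), rep(1, nrow(q)), tolerance = 1e-12)
  expect_equal(q[1, ], c(1, 0, 0, 0))
  expect_identical(q, sample_rotations(30))
  # count scales roughly as the inverse cube of the interval
  expect_equal(nrow(sample_rotations(15)), 576)
  expect_gt(nrow(sample_rotations(30)), 40)
  expect_lt(nrow(sample_rotations(30)), 110)
})

test_that("a coarse rotation set is well separated", {
  q <- sample_rotations(90)
  n <- nrow(q)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    expect_gte(quat_geodesic_deg(q[i, ], q[j, ]), 45)
})

test_that("single-atom digitisation matches brute-force sphere rasterisation", {
  s <- coords_structure(matrix(c(0.05, -0.02, 0.11), 1, 3))
  g <- structure(list(spacing = 0.1, dim = 16L, origin = c(-0.8, -0.8, -0.8)),
                 class = "dock_grid")
  occ <- grid_project(s, g, "ligand")
  r <- 0.17  # carbon
  cnt <- 0
  for (i in 0:15) for (j in 0:15) for (k in 0:15) {
    ctr <- g$origin + c(i, j, k) * g$spacing
    if (sum((ctr - c(0.05, -0.02, 0.11))^2) <= r^2) cnt <- cnt + 1
  }
  expect_equal(sum(Re(occ)), cnt)
})

test_that("digitisation is equivariant under one-lattice-step translation", {
  s <- coords_structure(matrix(c(0.05, -0.02, 0.11), 1, 3))
  g <- structure(list(spacing = 0.1, dim = 16L, origin = c(-0.8, -0.8, -0.8)),
                 class = "dock_grid")
  a <- Re(grid_project(s, g, "ligand"))
  s2 <- set_coords(s, coords(s) + matrix(c(0.1, 0, 0), 1, 3))
  b <- Re(grid_project(s2, g, "ligand"))
  expect_equal(b[2:16, , ], a[1:15, , ])
})

test_that("projection errors on empty or oversized structures", {
  g <- structure(list(spacing = 0.1, dim = 8L, origin = c(0, 0, 0)),
                 class = "dock_grid")
  s_big <- coords_structure(matrix(c(5, 5, 5), 1, 3))
  expect_error(grid_project(s_big, g, "ligand"), "exceeds")
  h_only <- coords_structure(matrix(0, 1, 3))
  h_only$atoms$is_hydrogen <- TRUE
  expect_error(grid_project(h_only, g, "ligand"), "empty")
})

test_that("the FFT score map equals the direct lattice correlation", {
  set.seed(21)
  d <- 16
  rg <- array(complex(real = rbinom(d^3, 1, 0.06),
                      imaginary = 9 * rbinom(d^3, 1, 0.04)), c(d, d, d))
  lg <- array(complex(real = rbinom(d^3, 1, 0.06)), c(d, d, d))
  got <- fft_translate_score(rg, lg)
  direct <- array(0, c(d, d, d))
  idx <- function(v, s) ((v - 1 - s) %% d) + 1
  for (t1 in 0:(d - 1)) for (t2 in 0:(d - 1)) for (t3 in 0:(d - 1)) {
    L <- Re(lg[idx(1:d, t1), idx(1:d, t2), idx(1:d, t3)])
    direct[t1 + 1, t2 + 1, t3 + 1] <- sum(Re(rg) * L) - sum(Im(rg) * L)
  }
  expect_lt(max(abs(got - direct)), 1e-6)
})

test_that("two single-cell grids correlate at exactly one translation", {
  d <- 8
  rg <- array(0 + 0i, c(d, d, d)); rg[3, 4, 5] <- 1 + 0i
  lg <- array(0 + 0i, c(d, d, d)); lg[2, 2, 2] <- 1 + 0i
  sm <- fft_translate_score(rg, lg)
  expect_equal(sum(abs(sm) > 1e-9), 1)
  expect_equal(sm[2, 3, 4], 1, tolerance = 1e-9)  # shift (1,2,3)
})

test_that("core overlap is penalised relative to surface contact", {
  d <- 16
  rg <- array(0 + 0i, c(d, d, d))
  rg[6:10, 6:10, 6] <- 1 + 0i          # surface slab
  rg[6:10, 6:10, 7:9] <- 0 + 9i        # buried core behind it
  lg <- array(0 + 0i, c(d, d, d))
  lg[6:10, 6:10, 5] <- 1 + 0i          # flat probe
  sm <- fft_translate_score(rg, lg)
  touch <- sm[1, 1, 2]                  # probe shifted onto the surface slab
  deep <- sm[1, 1, 4]                   # probe pushed into the core
  expect_gt(touch, 0)
  expect_lt(deep, touch)
})

test_that("self-docking keeps at most one pose per rotation and is deterministic", {
  s <- make_toy_aptamer("monomer_plain",
                        gen_params(seed = 3, n_res_rbd = 12, n_res_hbd = 6,
                                   linker_len_receptor = 3))$structure
  ps <- dock(s, s, interval_deg = 60, spacing = 0.3)
  expect_lte(nrow(ps), nrow(sample_rotations(60)))
  expect_false(anyDuplicated(ps$rot_index) > 0)
  expect_identical(ps, dock(s, s, interval_deg = 60, spacing = 0.3))
  expect_true(all(diff(ps$rescore) <= 0))
})

test_that("the top self-docking pose has surface contact and no core overlap", {
  s <- make_toy_aptamer("monomer_plain",
                        gen_params(seed = 3, n_res_rbd = 12, n_res_hbd = 6,
                                   linker_len_receptor = 3))$structure
  ps <- dock(s, s, interval_deg = 60, spacing = 0.3)
  top <- ps[1, ]
  g <- dock_grid_spec(s, s, 0.3)
  rg <- grid_project(s, g, "receptor")
  R <- quat_to_mat(c(top$qw, top$qx, top$qy, top$qz))
  lc <- coords(s, TRUE)
  lrel <- sweep(lc, 2, colMeans(lc)) %*% t(R)
  locc <- aptadock:::project_occupancy(
    lrel, aptadock:::element_radius(s$atoms$element[!s$atoms$is_hydrogen]),
    aptadock:::g0_for(g), wrap = TRUE)
  cmp <- fft_translate_score(rg, locc * (1 + 0i), components = TRUE)
  tt <- round((c(top$tx, top$ty, top$tz) - g$origin) / g$spacing)
  expect_equal(cmp$core_penalty[tt[1] + 1, tt[2] + 1, tt[3] + 1], 0,
               tolerance = 1e-9)
  expect_gte(cmp$surface[tt[1] + 1, tt[2] + 1, tt[3] + 1],
             0.5 * max(cmp$surface))
})

test_that("removing ligand atoms never increases the surface-contact score", {
  s <- make_toy_aptamer("monomer_plain",
                        gen_params(seed = 3, n_res_rbd = 12, n_res_hbd = 6,
                                   linker_len_receptor = 3))$structure
  g <- dock_grid_spec(s, s, 0.3)
  rg <- grid_project(s, g, "receptor")
  full <- grid_project(s, g, "ligand")
  half <- s
  half$atoms <- half$atoms[half$atoms$resseq <= 10, ]
  part <- grid_project(half, g, "ligand")
  sm_full <- fft_translate_score(rg, full, components = TRUE)$surface
  sm_part <- fft_translate_score(rg, part, components = TRUE)$surface
  expect_true(all(sm_part <= sm_full + 1e-9))
})

test_that("apply_pose reproduces rotation-then-translation of the centroid", {
  s <- coords_structure(rbind(c(0, 0, 0), c(0.4, 0, 0), c(0, 0.4, 0)))
  pose <- data.frame(pose_id = "p", qw = cos(pi / 4), qx = 0, qy = 0,
                     qz = sin(pi / 4), tx = 1, ty = 2, tz = 3)
  out <- apply_pose(s, pose)
  expect_equal(unname(colMeans(coords(out))), c(1, 2, 3), tolerance = 1e-12)
  # a 90-degree rotation about z maps the 1->2 bond from +x onto +y
  bond <- coords(out)[2, ] - coords(out)[1, ]
  expect_equal(unname(bond), c(0, 0.4, 0), tolerance = 1e-9)
})
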