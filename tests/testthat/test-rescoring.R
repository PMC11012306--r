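# MM/GBSA-style rescoring: closed-form oracles and limit behaviour

single_ion <- function(q = 1, R = 0.2) {
  coords_structure(matrix(0, 1, 3), element = "N", charge = q, gb_radius = R)
}

test_that("two unit charges at 3.32 angstrom give the closed-form Coulomb energy", {
  a <- coords_structure(matrix(0, 1, 3), chain = "A", element = "N", charge = 1)
  b <- coords_structure(matrix(c(0.332, 0, 0), 1, 3), chain = "B",
                        element = "N", charge = 1)
  b$atoms$serial <- 2L
  cm <- complex_model(
    a, bind_domain_map(a, list(G = list(chain = "A", first = 1, last = 1,
                                        role = "RBD"))),
    b, bind_domain_map(b, list(G = list(chain = "B", first = 1, last = 1,
                                        role = "HBD"))))
  e <- mm_energy(cm)
  expect_equal(unname(e["e_coul"]), 332.0636 / 3.32, tolerance = 1e-9)
})

test_that("the Lennard-Jones pair term vanishes at r = sigma", {
  sig <- 2 * 0.17 / 2^(1 / 6)  # carbon pair sigma
  a <- coords_structure(matrix(0, 1, 3), chain = "A", charge = 0)
  b <- coords_structure(matrix(c(sig, 0, 0), 1, 3), chain = "B", charge = 0)
  cm <- complex_model(
    a, bind_domain_map(a, list(G = list(chain = "A", first = 1, last = 1,
                                        role = "RBD"))),
    b, bind_domain_map(b, list(G = list(chain = "B", first = 1, last = 1,
                                        role = "HBD"))))
  e <- mm_energy(cm)
  expect_equal(unname(e["e_lj"]), 0, tolerance = 1e-10)
})

test_that("mm_energy equals a brute-force pair loop on a random fixture", {
  set.seed(41)
  na <- 25; nb <- 25
  a <- coords_structure(matrix(runif(3 * na, 0, 2), ncol = 3), chain = "A",
                        charge = sample(c(-1, 0, 1), na, replace = TRUE))
  b <- coords_structure(matrix(runif(3 * nb, 0, 2) + 2.5, ncol = 3),
                        chain = "B",
                        charge = sample(c(-1, 0, 1), nb, replace = TRUE))
  cm <- complex_model(
    a, bind_domain_map(a, list(G = list(chain = "A", first = 1, last = na,
                                        role = "RBD"))),
    b, bind_domain_map(b, list(G = list(chain = "B", first = 1, last = nb,
                                        role = "HBD"))))
  e <- mm_energy(cm)
  pa <- assign_ff(a); pb <- assign_ff(b)
  ec <- 0; el <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    r <- sqrt(sum((coords(a)[i, ] - coords(b)[j, ])^2))
    ec <- ec + 332.0636 * pa$charge[i] * pb$charge[j] / (10 * r)
    sg <- (pa$sigma[i] + pb$sigma[j]) / 2
    ep <- sqrt(pa$eps[i] * pb$eps[j])
    el <- el + 4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  expect_equal(unname(e["e_coul"]), ec, tolerance = 1e-8)
  expect_equal(unname(e["e_lj"]), el, tolerance = 1e-8)
})

test_that("GB reduces to the Born formula for a single ion", {
  got <- gb_energy(single_ion())
  want <- -0.5 * (1 - 1 / 78.5) * 332.0636 * 1 / 2  # q = 1e, R = 2 angstrom
  expect_equal(got, want, tolerance = 1e-6)
  expect_equal(gb_energy(coords_structure(matrix(0, 1, 3), charge = 0)), 0)
})

test_that("distant charges recover the screened-Coulomb limit", {
  r_nm <- 8
  two <- coords_structure(rbind(c(0, 0, 0), c(r_nm, 0, 0)), element = "N",
                          charge = 1, gb_radius = 0.2)
  interaction <- gb_energy(two) - 2 * gb_energy(single_ion())
  want <- -(1 - 1 / 78.5) * 332.0636 / (10 * r_nm)
  expect_equal(interaction, want, tolerance = 1e-4)
})

test_that("an unparameterized element is reported by name", {
  s <- coords_structure(matrix(0, 1, 3), element = "Zz")
  expect_error(assign_ff(s), "unparameterized atom")
})

test_that("SASA matches the analytic sphere and buried atoms vanish", {
  at <- coords_structure(matrix(0, 1, 3), gb_radius = 0.19)
  expect_equal(sasa(at)$total, 4 * pi * 0.33^2, tolerance = 1e-9)
  # an atom caged inside a tight shell of neighbours is fully buried
  dirs <- rbind(diag(3), -diag(3), cbind(0.577, 0.577, 0.577),
                cbind(-0.577, 0.577, 0.577), cbind(0.577, -0.577, 0.577),
                cbind(0.577, 0.577, -0.577), cbind(-0.577, -0.577, 0.577),
                cbind(-0.577, 0.577, -0.577), cbind(0.577, -0.577, -0.577),
                cbind(-0.577, -0.577, -0.577))
  shell <- sweep(dirs, 1, 0.25, `*`)
  s <- coords_structure(rbind(c(0, 0, 0), shell), gb_radius = 0.19)
  expect_equal(sasa(s)$per_atom[1], 0)
})

test_that("two-sphere SASA matches the spherical-cap closed form", {
  r1 <- 0.19 + 0.14; r2 <- 0.16 + 0.14
  d <- 0.4
  s <- list(xyz = rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(0.19, 0.16))
  got <- sasa(s, n_points = 2048)
  # exposed area of sphere 1: total minus the cap hidden inside sphere 2
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  cap1 <- 2 * pi * r1 * (r1 - x1)
  want1 <- 4 * pi * r1^2 - cap1
  x2 <- (d^2 + r2^2 - r1^2) / (2 * d)
  cap2 <- 2 * pi * r2 * (r2 - x2)
  want2 <- 4 * pi * r2^2 - cap2
  expect_equal(got$per_atom[1], want1, tolerance = 0.01)
  expect_equal(got$per_atom[2], want2, tolerance = 0.01)
})

test_that("SASA quadrature converges under point doubling", {
  s <- make_toy_aptamer("monomer_plain", gen_params(seed = 5))$structure
  a1 <- sasa(s, n_points = 256)$total
  a2 <- sasa(s, n_points = 512)$total
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("binding free energy components add exactly and sd is zero for one snapshot", {
  cm <- make_hbond_fixture(2)
  eb <- binding_free_energy(list(cm), n_points = 64)
  p <- eb$per_snapshot
  expect_equal(p$total, p$e_coul + p$e_lj + p$g_gb + p$g_sa, tolerance = 1e-9)
  expect_equal(unname(eb$sd[["total"]]), 0)
  expect_error(binding_free_energy(list()), "empty")
})

test_that("interaction energies depend only on relative geometry", {
  cm <- make_hbond_fixture(2)
  shift <- matrix(rep(c(3, -1, 2), each = n_atoms(cm$receptor)), ncol = 3)
  rec2 <- set_coords(cm$receptor, coords(cm$receptor) + shift)
  shiftl <- matrix(rep(c(3, -1, 2), each = n_atoms(cm$ligand)), ncol = 3)
  lig2 <- set_coords(cm$ligand, coords(cm$ligand) + shiftl)
  cm2 <- complex_model(rec2, cm$receptor_map, lig2, cm$ligand_map)
  expect_equal(mm_energy(cm2), mm_energy(cm), tolerance = 1e-8)
})

test_that("a tight complementary interface binds tighter than a displaced one", {
  # two small plates of complementary charge, 0.5 nm apart vs 2 nm further
  n <- 9
  gridpts <- as.matrix(expand.grid(x = 0, y = (0:2) * 0.5, z = (0:2) * 0.5))
  plateA <- coords_structure(gridpts, chain = "A", element = "N", charge = 1)
  mk_b <- function(off) {
    b <- coords_structure(sweep(gridpts, 2, c(off, 0, 0), `+`), chain = "B",
                          element = "O", charge = -1)
    b
  }
  mapA <- bind_domain_map(plateA, list(G = list(chain = "A", first = 1,
                                                last = n, role = "RBD")))
  dg <- vapply(c(0.5, 2.5), function(off) {
    b <- mk_b(off)
    mapB <- bind_domain_map(b, list(G = list(chain = "B", first = 1, last = n,
                                             role = "HBD")))
    cm <- complex_model(plateA, mapA, b, mapB)
    unname(binding_free_energy(list(cm), n_points = 128)$mean[["total"]])
  }, numeric(1))
  expect_lt(dg[1], dg[2])
  expect_lt(dg[1], 0)
})
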