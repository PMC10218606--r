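# Printed reference descriptor table: orbital energies (inputs) and derived
# indices, kcal/mol.
ref_descriptors <- data.frame(
  species = c("Ia", "IIa", "CH3SH", "CH3S-"),
  E_HOMO = c(-183.24, -180.38, -183.240, -173.453),
  E_LUMO = c(-35.98, -28.44, -2.979, 77.998),
  gap = c(147.27, 151.94, 180.261, 251.451),
  mu = c(-109.608, -104.405, -93.109, -47.728),
  eta = c(147.264, 151.930, 180.261, 251.451),
  omega = c(40.791, 35.873, 24.047, 4.530)
)

test_that("global descriptors reproduce the reference table from orbital energies", {
  for (i in seq_len(nrow(ref_descriptors))) {
    r <- ref_descriptors[i, ]
    d <- global_descriptors(r$E_HOMO, r$E_LUMO)
    expect_equal(d$gap, r$gap, tolerance = 0.05 / abs(r$gap))
    expect_equal(d$mu, r$mu, tolerance = 0.05 / abs(r$mu))
    expect_equal(d$eta, r$eta, tolerance = 0.05 / abs(r$eta))
    expect_equal(d$omega, r$omega, tolerance = 0.05 / abs(r$omega))
    # stored identity is exact
    expect_identical(d$omega, d$mu^2 / (2 * d$eta))
  }
})

test_that("descriptor edge cases and symmetries behave", {
  # symmetric frontier energies: zero chemical potential and electrophilicity
  d <- global_descriptors(-50, 50)
  expect_equal(d$mu, 0)
  expect_equal(d$omega, 0)
  # omega depends on mu only through mu^2
  expect_equal(global_descriptors(-10, 4)$omega,
               global_descriptors(-4, 10)$omega)
  expect_error(global_descriptors(-10, -10), "degenerate")
  expect_error(global_descriptors(-10, -20), "degenerate")
  expect_error(global_descriptors(NA, 1), "finite")
})

test_that("Koopmans I/A flip signs and their difference is the gap", {
  ia <- koopmans_IA(-183.24, -35.98)
  expect_equal(ia[["I"]], 183.24)
  expect_equal(ia[["A"]], 35.98)
  expect_gt(ia[["I"]], ia[["A"]])
  # negative affinity for a bound-LUMO-free anion-like system
  expect_lt(koopmans_IA(-173.453, 77.998)[["A"]], 0)
  set.seed(2)
  for (i in 1:10) {
    h <- runif(1, -300, -50); l <- h + runif(1, 1, 300)
    ia <- koopmans_IA(h, l)
    expect_equal(ia[["I"]] - ia[["A"]], global_descriptors(h, l)$gap)
  }
})

test_that("condensed Fukui indices follow the finite-difference definitions", {
  f <- condensed_fukui(q_Nminus1 = c(0.6, 0.4), q_N = c(0, 0),
                       q_Nplus1 = c(-0.7, -0.3))
  expect_equal(f$f_plus, c(0.7, 0.3))
  expect_equal(f$f_minus, c(0.6, 0.4))
  expect_equal(f$dual, c(0.1, -0.1))
  expect_equal(f$f_zero, c(0.65, 0.35))
  # single atom: normalization forced
  f1 <- condensed_fukui(1, 0, -1)
  expect_equal(f1$f_plus, 1)
  expect_equal(f1$f_minus, 1)
  expect_error(condensed_fukui(c(1, 0), c(0, 0, 0), c(-1, 0, 0)),
               "equal length")
  expect_error(condensed_fukui(c(0.2, 0.2), c(0, 0), c(-0.5, -0.3)),
               "differ by exactly")
})

test_that("Fukui sums and dual-descriptor zero-sum hold for random triplets", {
  for (s in 1:30) {
    ct <- random_charge_triplet(n = sample(3:12, 1), seed = s)
    f <- condensed_fukui(ct$q_Nminus1, ct$q_N, ct$q_Nplus1)
    expect_lt(abs(sum(f$f_plus) - 1), 1e-3)
    expect_lt(abs(sum(f$f_minus) - 1), 1e-3)
    expect_lt(abs(sum(f$dual)), 2e-3)
    expect_equal(f$f_plus, ct$f_plus_true, tolerance = 1e-10)
  }
})

test_that("local electrophilicity partitions omega and flags the electrophilic site", {
  expect_equal(local_electrophilicity(40.79, 1.0), 40.79)
  expect_equal(local_electrophilicity(40, rep(0.25, 4)), rep(10, 4))
  # toy enone fragment (O, C1 carbonyl, C-alpha, C-beta, CH): charge triplet
  # built so the nucleophilic-attack index concentrates on the beta-carbon
  qN <- c(-0.40, 0.30, -0.10, 0.10, 0.10)
  qNp1 <- qN - c(0.15, 0.20, 0.10, 0.45, 0.10)
  qNm1 <- qN + c(0.30, 0.20, 0.20, 0.20, 0.10)
  f <- condensed_fukui(qNm1, qN, qNp1)
  ds <- global_descriptors(-180.38, -28.44)
  wk <- local_electrophilicity(ds, f$f_plus)
  expect_equal(sum(wk), ds$omega, tolerance = 1e-3)
  expect_equal(which.max(wk), 4L)  # the beta-carbon proxy atom
  expect_error(local_electrophilicity(10, c(0.5, 0.2)), "normalized")
})

test_that("point-charge electrostatic potential obeys Coulomb superposition", {
  # single Z=1 nucleus at origin: V = 1/r
  sys <- point_charge_system("nucleus", 1, matrix(0, 1, 3))
  expect_equal(electrostatic_potential(sys, c(1, 0, 0)), 1.0)
  # co-located nucleus and unit electron charge cancel off-origin
  sys0 <- point_charge_system(c("nucleus", "electron"), c(1, 1),
                              matrix(0, 2, 3))
  expect_equal(electrostatic_potential(sys0, c(0.3, -0.2, 1)), 0)
  # hand-evaluated dipole-like pair
  sysd <- point_charge_system(c("nucleus", "electron"), c(1, 1),
                              rbind(c(0, 0, 0.5), c(0, 0, -0.5)))
  expect_equal(electrostatic_potential(sysd, c(0, 0, 2)), 1 / 1.5 - 1 / 2.5)

  # superposition: potential of a union is the sum of the potentials
  for (s in 1:10) {
    a <- random_pcs(2, 3, seed = s)
    b <- random_pcs(3, 2, seed = s + 100)
    u <- point_charge_system(c(a$kind, b$kind), c(a$q, b$q),
                             rbind(a$xyz, b$xyz))
    pts <- matrix(runif(9, 2, 4), ncol = 3)
    expect_equal(electrostatic_potential(u, pts),
                 electrostatic_potential(a, pts) +
                   electrostatic_potential(b, pts))
  }
})

test_that("far-field potential approaches Q_total / r and singularities are caught", {
  for (s in 1:5) {
    sys <- random_pcs(3, 3, seed = s)
    extent <- max(sqrt(rowSums(sys$xyz^2)))
    Q <- sum(ifelse(sys$kind == "nucleus", sys$q, -sys$q))
    r <- max(50 * extent, 50)
    # evaluate perpendicular to the dipole moment so the leading correction
    # to the monopole term is quadrupolar, well below the 1% band
    dir <- far_field_direction(sys)
    v <- electrostatic_potential(sys, r * dir)
    expect_equal(v, Q / r, tolerance = 0.01)
  }
  sys <- point_charge_system("nucleus", 1, matrix(0, 1, 3))
  expect_error(electrostatic_potential(sys, c(0, 0, 0)), "coincides")
  expect_error(point_charge_system("nucleus", 1.5, matrix(0, 1, 3)),
               "integer")
})

test_that("descriptor tables process rows independently with per-row errors", {
  oe <- data.frame(species = c("ok", "bad"),
                   E_HOMO_kcal_mol = c(-100, -10),
                   E_LUMO_kcal_mol = c(-20, -30))
  tab <- descriptor_table(oe)
  expect_equal(nrow(tab), 2)
  expect_false(is.na(tab$omega[1]))
  expect_true(is.na(tab$omega[2]))
  expect_match(tab$note[2], "degenerate")
  # packaged fixture
  fx <- descriptor_table(system.file("extdata", "orbital_energies.csv",
                                     package = "chalkin"))
  expect_equal(nrow(fx), 4)
  expect_equal(fx$omega, ref_descriptors$omega, tolerance = 2e-3)
})
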