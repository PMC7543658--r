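test_that("identical ADPs give relative occupancy 1 under every estimator", {
  for (b in c(5, 20, 99)) {
    expect_equal(occ_total(b, b, 0.5), 1, tolerance = 1e-12)
    expect_equal(occ_peak(b, b, 0.5), 1, tolerance = 1e-12)
    expect_equal(occ_total_inf(b, b), 1, tolerance = 1e-12)
    expect_equal(occ_peak_inf(b, b), 1, tolerance = 1e-12)
  }
})

test_that("published worked examples are reproduced from the printed medians", {
  # ligand medians vs environment medians at the entry's resolution
  expect_lt(abs(occ_total(252, 53, 1 / 1.99) - 0.21), 0.01)
  expect_lt(abs(occ_total(125, 12, 1 / 1.9) - 0.11), 0.01)
  expect_lt(abs(occ_peak(252, 53, 1 / 1.99) - 0.11), 0.01)
  expect_lt(abs(occ_peak(125, 12, 1 / 1.9) - 0.09), 0.01)
  # atom-level cases: lighter side-chain atom, metal modelled as water,
  # heavier cation (inputs are rounded medians, hence wider tolerances)
  expect_lt(abs(occ_total(37, 20, 1 / 1.8) - 0.64), 0.02)
  expect_lt(abs(occ_total(7, 15, 1 / 1.6) - 1.37), 0.03)
  expect_lt(abs(occ_total(14, 25, 1 / 1.8) - 1.36), 0.03)
  expect_lt(abs(occ_total(99, 37, 1 / 1.8) - 0.41), 0.02)
})

test_that("closed forms match the quadrature oracle on a grid", {
  bs <- c(2, 10, 40, 120, 300)
  ss <- c(0.25, 0.4, 0.6, 0.9)
  for (b1 in bs) for (b2 in bs) for (s in ss) {
    expect_equal(occ_total(b1, b2, s), quad_occ_total(b1, b2, s),
                 tolerance = 1e-9)
    expect_equal(occ_peak(b1, b2, s),
                 quad_peak_height(b1, s) / quad_peak_height(b2, s),
                 tolerance = 1e-9)
  }
})

test_that("finite-resolution estimators converge to their limiting forms", {
  bs <- c(5, 20, 80, 200)
  for (b1 in bs) for (b2 in bs) {
    s_inf <- sqrt(120 / min(b1, b2))   # b s^2 / 4 >= 30 for the smaller B
    expect_equal(occ_total(b1, b2, s_inf), occ_total_inf(b1, b2),
                 tolerance = 1e-4)
    expect_equal(occ_peak(b1, b2, s_inf), occ_peak_inf(b1, b2),
                 tolerance = 1e-4)
  }
})

test_that("total-density occupancy respects its theoretical bounds", {
  expect_equal(occ_total_inf(0, 53), 2^1.5, tolerance = 1e-12)
  expect_equal(occ_total_inf(10, 0), 0, tolerance = 1e-12)
  set.seed(1)
  b1 <- runif(200, 0, 400); b2 <- runif(200, 0.1, 400)
  s <- runif(200, 0.2, 2)
  expect_true(all(occ_total(b1, b2, s) < 2^1.5))
  # monotone decreasing in b_atom at fixed reference
  cs <- occ_total(seq(0, 300, by = 10), 50, 0.5)
  expect_true(all(diff(cs) < 0))
  # swap symmetry at infinite resolution: c * c' <= 1, equality iff equal B
  cc <- occ_total_inf(b1, b2) * occ_total_inf(b2, b1)
  expect_true(all(cc <= 1 + 1e-12))
  expect_true(all(cc[abs(b1 - b2) > 1] < 1))
})

test_that("neighbour contexts exclude own residues and isolated atoms", {
  # octahedral water site: center + six O at 2.1 A, plus a far atom
  oct <- rbind(c(0, 0, 0), c(2.1, 0, 0), c(-2.1, 0, 0), c(0, 2.1, 0),
               c(0, -2.1, 0), c(0, 0, 2.1), c(0, 0, -2.1), c(50, 50, 50))
  m <- make_model(oct, b = c(7, 15, 14, 16, 15, 13, 17, 30), d_max = 1.6,
                  resname = "HOH", atom_name = "O", element = "O",
                  hetero = TRUE)
  ctx <- build_contexts(m, radius = 4.2, min_neighbors = 4)
  expect_identical(ctx$n_neighbors[ctx$atom_idx == 1], 6L)
  expect_false(8 %in% ctx$atom_idx)  # isolated atom emits no context
  expect_equal(ctx$b_env_median[ctx$atom_idx == 1],
               median(c(15, 14, 16, 15, 13, 17)))
  # atoms of the center's own residue are excluded from its environment
  m2 <- make_model(oct[1:7, ], b = c(7, rep(15, 6)), d_max = 1.6,
                   resno = c(1, 1, 2, 3, 4, 5, 6))
  ctx2 <- build_contexts(m2, radius = 4.2, min_neighbors = 4)
  expect_identical(ctx2$n_neighbors[ctx2$atom_idx == 1], 5L)
})

test_that("a homogeneous structure scans clean", {
  xyz <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 1.8
  m <- make_model(xyz, b = rep(25, 125), d_max = 2.0)
  sc <- scan_atoms(m)
  expect_true(all(sc$flag == "ok"))
  expect_equal(sc$c_total, rep(1, nrow(sc)), tolerance = 1e-12)
  expect_equal(sc$c_peak, rep(1, nrow(sc)), tolerance = 1e-12)
})

test_that("planted heavy and light anomalies are the top-ranked flags", {
  toy <- build_toy_structure(tempfile(fileext = ".pdb"),
                             anomaly_background(), n_per_domain = 500,
                             d_max = 1.8,
                             anomalies = c("heavy", "light"), seed = 11)
  m <- read_structure(toy$path)
  sc <- scan_atoms(m)
  heavier <- sc[sc$flag == "heavier", ]
  lighter <- sc[sc$flag == "lighter", ]
  expect_identical(heavier$atom_idx[1], toy$truth$anomaly_idx$heavy)
  expect_identical(lighter$atom_idx[1], toy$truth$anomaly_idx$light)
  # planted B = env/2 puts the heavy flag above the heavy cutoff
  expect_gt(heavier$c_total[1], 1.3)
  expect_lt(lighter$c_total[1], 0.7)
})

test_that("ligand report reproduces a planted construction occupancy", {
  toy <- build_toy_structure(tempfile(fileext = ".pdb"),
                             anomaly_background(), n_per_domain = 500,
                             d_max = 1.8, anomalies = "half_ligand",
                             target_occ = 0.5, seed = 11)
  m <- read_structure(toy$path)
  rep <- ligand_report(m, "LIG")
  expect_equal(rep$c_total, 0.5, tolerance = 0.02)
  expect_identical(rep$n_ligand_atoms, 8L)
  expect_error(ligand_report(m, "XYZ"), "matches no atoms")
})

test_that("a ligand sharing the environment's median B reports occupancy 1", {
  xyz <- as.matrix(expand.grid(x = 0:5, y = 0:5, z = 0:5)) * 1.8
  b <- rep(30, nrow(xyz))
  resn <- rep("GLY", nrow(xyz))
  resn[1:6] <- "LIG"
  m <- make_model(xyz, b, d_max = 2.0, resname = resn)
  m$atoms$residue_seq[1:6] <- 999L
  rep <- ligand_report(m, "LIG")
  expect_equal(rep$c_total, 1, tolerance = 1e-12)
  expect_equal(rep$c_peak, 1, tolerance = 1e-12)
})
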