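test_that("reference fluids respect hard minima and are seed-deterministic", {
  ff <- lj_fluid_forcefield(3.4, 1.0)
  spec <- synthetic_spec(lj_site_template(), n_molecules = 40,
                         density = 0.01, temperature_K = 150,
                         forcefield = ff, seed = 6)
  cons <- constraint_set(floor = 1.0)
  fl <- generate_reference_fluid(spec, n_snapshots = 5, stride = 2,
                                 max_sweeps = 60, constraints = cons)
  for (cf in fl$configs)
    expect_gte(min_intermolecular_distance(cf), 1.0)
  fl2 <- generate_reference_fluid(spec, n_snapshots = 5, stride = 2,
                                  max_sweeps = 60, constraints = cons)
  expect_identical(fl$configs[[5]]$xyz, fl2$configs[[5]]$xyz)
})

test_that("pseudo-experiments carry noise, range and ground truth", {
  ff <- lj_fluid_forcefield()
  spec <- synthetic_spec(lj_site_template(), n_molecules = 40,
                         density = 0.01, temperature_K = 150,
                         forcefield = ff, seed = 6)
  fl <- generate_reference_fluid(spec, n_snapshots = 5, stride = 2,
                                 max_sweeps = 40)
  # default instrument range
  pe <- make_pseudo_experiment(fl)
  expect_equal(min(pe$pattern$Q), 0.6)
  expect_equal(max(pe$pattern$Q), 25.0)
  expect_equal(pe$truth$density, atom_density(fl$configs[[1]]))
  # zero noise reproduces the ensemble average exactly
  pe0 <- make_pseudo_experiment(fl, noise_sigma = 0)
  expect_equal(pe0$pattern$S, pe0$pattern_clean$S)
  # averaging independent noisy replicates converges at the 1/sqrt(n) rate
  reps <- sapply(1:100, function(k)
    make_pseudo_experiment(fl, noise_sigma = 0.005, seed = 1000 + k)$pattern$S)
  z <- abs(rowMeans(reps) - pe0$pattern_clean$S) / (0.005 / sqrt(100))
  expect_lt(mean(z), 1)     # mean |z| of a standard normal is ~0.8
  expect_lt(max(z), 5)      # no gross outlier across ~1200 points
  expect_error(make_pseudo_experiment(list()), "reference_fluid")
})

test_that("planted perturbations are recorded in the ground truth", {
  ff <- lj_fluid_forcefield()
  ep <- empirical_potential_state("LJ_site", r_max = 8)
  ep$u[, 1] <- -exp(-((ep$r - 5) / 0.6)^2)
  spec <- synthetic_spec(lj_site_template(), n_molecules = 30,
                         density = 0.008, temperature_K = 150,
                         forcefield = ff, perturbation = ep, seed = 3)
  fl <- generate_reference_fluid(spec, n_snapshots = 3, stride = 2,
                                 max_sweeps = 30)
  pe <- make_pseudo_experiment(fl)
  expect_identical(pe$truth$perturbation$u, ep$u)
  expect_equal(pe$truth$seed, 3)
})

test_that("insertion failures at impossible densities are reported", {
  spec <- synthetic_spec(nif_template("alpha"), n_molecules = 8,
                         density = 0.4, seed = 1)
  expect_error(generate_reference_fluid(spec, n_snapshots = 1,
                                        max_sweeps = 10),
               "insertion failure")
})
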