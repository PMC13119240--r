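test_that("the Metropolis rule accepts with the Boltzmann probability", {
  kB <- 0.0083144621
  T <- 300
  expect_true(metropolis_accept(-1, T))   # downhill: always
  expect_true(metropolis_accept(0, T))
  set.seed(101)
  n <- 10000
  acc <- mean(vapply(seq_len(n), function(i) metropolis_accept(kB * T, T),
                     TRUE))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the engine reproduces plain Metropolis NVT statistics", {
  # independent bare-bones MC (helper) vs the package engine on the same
  # LJ system; mean potential energies must agree
  sigma <- 3.4; epsilon <- 1.0
  oracle <- plain_lj_mc(40, 0.008, 150, sigma, epsilon, n_sweeps = 300,
                        seed = 31)
  ff <- lj_fluid_forcefield(sigma, epsilon)
  spec <- synthetic_spec(lj_site_template(), n_molecules = 40,
                         density = 0.008, temperature_K = 150,
                         forcefield = ff, seed = 32)
  fl <- generate_reference_fluid(spec, n_snapshots = 150, stride = 2,
                                 max_sweeps = 150)
  e_engine <- vapply(fl$configs, lj_coulomb_energy, 0, ff = ff)
  m1 <- mean(oracle$energies); m2 <- mean(e_engine)
  expect_lt(abs(m1 - m2), 0.12 * abs(m1))
  # and the first peak of g(r) agrees within sampling error
  go <- plain_gr(oracle$snaps, oracle$L, 6, 0.2)
  ps <- compute_partial_gr(fl$configs, r_max = 6, dr = 0.2)
  expect_lt(abs(go$r[which.max(go$g)] - ps$r[which.max(ps$g[[1]])]), 0.45)
  expect_lt(abs(max(go$g) - max(ps$g[[1]])) / max(go$g), 0.25)
})

test_that("identical seeds give bit-identical trajectories", {
  ff <- reference_forcefield()
  run <- function() {
    cfg <- build_configuration(nif_template("alpha"), n_molecules = 6,
                               density = 0.07, seed = 12)
    ctx <- mc_context(cfg, ff, nh_o_constraints())
    set.seed(99)
    mc_sweeps(ctx, 15, tune = TRUE)
    ctx$xyz
  }
  expect_identical(run(), run())
})

test_that("hard NH...O minima are never violated in accepted states", {
  ff <- reference_forcefield()
  cfg <- build_configuration(nif_template("alpha"), n_molecules = 6,
                             density = 0.08, seed = 21)
  ctx <- mc_context(cfg, ff, nh_o_constraints(2.9))
  set.seed(7)
  audit <- function() min(
    min_intermolecular_distance(ctx_config(ctx), "N_NHR", "O_carbonyl"),
    min_intermolecular_distance(ctx_config(ctx), "N_NHR", "O_nitro"),
    min_intermolecular_distance(ctx_config(ctx), "N_NHR", "O_ether"))
  d_prev <- audit()
  for (blk in 1:8) {
    mc_sweeps(ctx, 10, tune = TRUE)
    d <- audit()
    if (d_prev >= 2.9) expect_gte(d, 2.9) # valid states stay valid
    else expect_gte(d, d_prev * 0.999)    # invalid starts repair monotonically
    d_prev <- d
  }
})

test_that("single-step interface works on configurations and rejects bad moves", {
  ff <- reference_forcefield()
  cfg <- build_configuration(nif_template("alpha"), n_molecules = 4,
                             density = 0.05, seed = 3)
  set.seed(1)
  res <- mc_step(cfg, "translate", ff = ff)
  expect_type(res$accepted, "logical")
  expect_s3_class(res$config, "configuration")
  ctx <- mc_context(cfg, ff)
  expect_error(mc_step(ctx, "wiggle"), "arg")
  ctx$T <- -1
  expect_error(mc_step(ctx, "translate"), "temperature")
})

test_that("R-factor and scale fitting match closed forms", {
  Q <- seq(0.6, 10, by = 0.02)
  S1 <- scattering_pattern(Q, 1 + 0.5 * sin(Q))
  expect_equal(r_factor(S1, S1), 0)
  S2 <- scattering_pattern(Q, S1$S + 0.1)
  expect_equal(r_factor(S1, S2), 0.01, tolerance = 1e-12)
  # direct-summation oracle on two arbitrary fixture curves
  a <- 1 + 0.3 * cos(Q); b <- 1 + 0.2 * sin(2 * Q)
  oracle <- sum((a - b)^2) / length(Q)
  expect_equal(r_factor(scattering_pattern(Q, a), scattering_pattern(Q, b)),
               oracle, tolerance = 1e-12)
  expect_error(r_factor(S1, scattering_pattern(Q + 0.01, S1$S)), "mismatch")
  # scale: identical -> 1; damped target -> 1/0.8
  expect_equal(fit_scale(S1, S1), 1)
  S3 <- scattering_pattern(Q, 1 + 0.8 * (S1$S - 1))
  expect_equal(fit_scale(S1, S3), 1.25, tolerance = 1e-9)
  set.seed(5)
  S4 <- scattering_pattern(Q, 1 + 0.8 * (S1$S - 1) + rnorm(length(Q), 0, 0.01))
  expect_lt(abs(fit_scale(S1, S4) - 1.25) / 1.25, 0.02)
  expect_error(fit_scale(S1, scattering_pattern(Q, rep(1, length(Q)))),
               "degenerate")
})

test_that("empirical-potential updates fix nothing at the fixed point and obey the cap", {
  r <- seq(0.01, 10, by = 0.01)
  ps <- structure(list(r = r, dr = 0.01, g = list(`C:C` = rep(1, length(r))),
                       rho = 0.05, c = c(C = 1), n_of = c(C = 100),
                       element_of = c(C = "C"), types = "C"),
                  class = "pair_function_set")
  Q <- seq(0.6, 25, by = 0.05)
  S <- xray_total_sq(ps, Q)
  ep <- empirical_potential_state("C", r_max = 8)
  ep1 <- update_empirical_potential(ep, S, S, ps, 300)
  expect_equal(max(abs(ep1$u)), 0)
  expect_equal(ep1$iteration, 1L)
  expect_length(ep1$r_history, 1)
  # huge repeated residuals never exceed the amplitude cap
  S_far <- scattering_pattern(Q, S$S + 3 * sin(Q * 2))
  ep2 <- ep
  for (k in 1:30)
    ep2 <- update_empirical_potential(ep2, S_far, S, ps, 300)
  expect_lte(max(abs(ep2$u)), ep2$amplitude_cap + 1e-12)
})

test_that("a zero-iteration refinement returns the starting state and its R-factor", {
  ff <- lj_fluid_forcefield()
  cfg <- build_configuration(lj_site_template(), n_molecules = 60,
                             density = 0.012, temperature_K = 120, seed = 8)
  Q <- seq(0.6, 15, by = 0.05)
  target <- scattering_pattern(Q, rep(1, length(Q)))
  set.seed(2)
  fit <- refine_to_data(cfg, ff, target, n_iterations = 0, ensemble_size = 1,
                        ensemble_stride = 0)
  expect_equal(max(abs(fit$config$xyz - cfg$xyz)), 0)
  expect_length(fit$r_history, 1)
  expect_equal(fit$r_history, r_factor(fit$S_model, target))
})

test_that("conformer scans validate inputs and are deterministic at fraction zero", {
  Q <- seq(0.6, 6, by = 0.05)
  target <- scattering_pattern(Q, 1 + 0.2 * sin(Q))
  expect_error(scan_conformer_fraction(c(-0.1, 0.5), target,
                                       list(nif_template("alpha"),
                                            nif_template("flipped"))),
               "fractions")
  # fraction 0 twice with the same seed: identical R (single-conformer path)
  tpls <- list(nif_template("alpha"), nif_template("flipped"))
  r1 <- scan_conformer_fraction(0, target, tpls, n_molecules = 4,
                                density = 0.05, seed = 3, n_iterations = 1,
                                sweeps_per_iter = 2, ensemble_size = 3,
                                equil_sweeps = 5, mode = "rebuild")
  r2 <- scan_conformer_fraction(0, target, tpls, n_molecules = 4,
                                density = 0.05, seed = 3, n_iterations = 1,
                                sweeps_per_iter = 2, ensemble_size = 3,
                                equil_sweeps = 5, mode = "rebuild")
  expect_identical(r1$r_factor, r2$r_factor)
})

test_that("in-place conformer swaps preserve pose and composition", {
  cfg <- build_configuration(nif_template("alpha"), n_molecules = 4,
                             density = 0.04, seed = 6)
  cfg2 <- swap_conformer(cfg, 1:2, nif_template("flipped"))
  expect_equal(sum(cfg2$atoms$conformer == "flipped"), 2 * 43)
  # the rigid core of a swapped molecule is unmoved
  core <- c("N1", "C2", "C3", "C4", "C5", "C6", "CA1", "CA4")
  rows <- which(cfg$atoms$mol == 1 & cfg$atoms$label %in% core)
  rows2 <- which(cfg2$atoms$mol == 1 & cfg2$atoms$label %in% core)
  expect_lt(max(abs(cfg$xyz[rows, ] - cfg2$xyz[rows2, ])), 1e-6)
  # atom count and box unchanged
  expect_equal(dim(cfg2$xyz), dim(cfg$xyz))
})
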