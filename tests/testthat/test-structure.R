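test_that("running coordination reproduces the ideal-gas closed form", {
  r <- seq(0.05, 8, by = 0.1)
  rho <- 0.03
  ps <- structure(list(r = r, dr = 0.1, g = list(`C:C` = rep(1, length(r))),
                       rho = rho, c = c(C = 1), n_of = c(C = 500),
                       element_of = c(C = "C"), types = "C"),
                  class = "pair_function_set")
  n <- running_coordination(ps, "C", "C")
  edges <- r + 0.05
  expect_equal(n$n, 4 / 3 * pi * rho * edges^3, tolerance = 1e-9)
})

test_that("a single isolated pair gives a unit step", {
  cfg <- two_atom_config(3.0)
  ps <- compute_partial_gr(cfg, r_max = 10, dr = 0.05)
  n <- running_coordination(ps, "LJ_site", "LJ_site", threshold = 0.4)
  expect_equal(max(n$n), 1, tolerance = 1e-9)
  expect_equal(min(n$r[n$n > 0.5]), 3.025, tolerance = 0.051)
  expect_lt(abs(n$crossing - 3.0), 0.06)
  expect_error(running_coordination(ps, "A", "B"), "no partial")
})

test_that("coordination numbers match a direct neighbour count", {
  ff <- reference_forcefield()
  cfg <- build_configuration(nif_template("alpha"), n_molecules = 8,
                             density = 0.07, seed = 9)
  ctx <- mc_context(cfg, ff)
  set.seed(4); mc_sweeps(ctx, 20)
  cfg <- ctx_config(ctx)
  ps <- compute_partial_gr(cfg, dr = 0.05)
  nC <- running_coordination(ps, "N_NHR", "O_carbonyl")
  # brute force: average O_carbonyl neighbours per N within each radius
  at <- cfg$atoms
  don <- which(at$type_key == "N_NHR"); acc <- which(at$type_key == "O_carbonyl")
  radii <- nC$r + ps$dr / 2
  oracle <- brute_neighbor_counts(cfg, don, acc, radii)
  expect_equal(nC$n, oracle, tolerance = 1e-9)
})

test_that("hydrogen-bond censuses follow the stated geometry criteria", {
  ff <- reference_forcefield()
  # PVP-only box: no donors at all
  cfgP <- build_configuration(build_pvp_oligomer(2), n_molecules = 3,
                              density = 0.04, seed = 2)
  cen0 <- hbond_census(cfgP)
  expect_equal(nrow(cen0$bonds), 0)
  # NIF box: census invariant under rigid translation; distance-only
  # criterion equals the N...O pair count
  cfg <- build_configuration(nif_template("alpha"), n_molecules = 8,
                             density = 0.07, seed = 9)
  ctx <- mc_context(cfg, ff)
  set.seed(4); mc_sweeps(ctx, 30)
  cfg <- ctx_config(ctx)
  crit <- hbond_criteria(d_max = 4.5, angle_min = 0)
  cen <- hbond_census(cfg, crit)
  at <- cfg$atoms
  don <- which(at$type_key == "N_NHR")
  acc <- which(at$type_key %in% crit$acceptor_types)
  cnt <- 0
  for (i in don) {
    j <- acc[at$mol[acc] != at$mol[i]]
    d <- sqrt(rowSums(epsrlite:::.mimg_vec(
      sweep(cfg$xyz[j, , drop = FALSE], 2, cfg$xyz[i, ]), cfg$box_edge)^2))
    cnt <- cnt + sum(d <= crit$d_max)
  }
  expect_equal(nrow(cen$bonds), cnt)
  shifted <- cfg
  shifted$xyz <- sweep(cfg$xyz, 2, c(5.5, -2.2, 9.1), "+")
  cen2 <- hbond_census(shifted, crit)
  expect_equal(nrow(cen2$bonds), nrow(cen$bonds))
  expect_equal(sort(cen2$bonds$d), sort(cen$bonds$d), tolerance = 1e-9)
  # tightening the angle can only reduce the census
  cen3 <- hbond_census(cfg, hbond_criteria(d_max = 4.5, angle_min = 120))
  expect_lte(nrow(cen3$bonds), nrow(cen$bonds))
  expect_error(hbond_criteria(d_max = -1), "d_max")
  expect_error(hbond_criteria(angle_min = 300), "angle_min")
})

test_that("drug-polymer preference resolves acceptor classes additively", {
  ff <- reference_forcefield()
  mix <- conformer_mixture(list(nif_template("alpha"), build_pvp_oligomer(3)),
                           c(0.5, 0.5), 6)
  cfg <- build_configuration(mix, density = 0.06, seed = 11)
  ctx <- mc_context(cfg, ff)
  set.seed(3); mc_sweeps(ctx, 20)
  cfg <- ctx_config(ctx)
  pref <- drug_polymer_preference(cfg, r_cut = 6)
  expect_true(is.finite(pref$n_drug) && is.finite(pref$n_pvp))
  # class-resolved counts equal the brute-force oracle
  at <- cfg$atoms
  cls <- epsrlite:::acceptor_class(at)
  don <- which(at$type_key == "N_NHR")
  drug_acc <- which(cls %in% c("ester", "nitro") & at$template != "PVP")
  oracle <- brute_neighbor_counts(cfg, don, drug_acc, 6)
  expect_equal(pref$n_drug, oracle, tolerance = 1e-9)
  # additivity: ester + nitro = all drug-acceptor classes
  pref_e <- drug_polymer_preference(cfg, r_cut = 6, drug_classes = "ester")
  pref_n <- drug_polymer_preference(cfg, r_cut = 6, drug_classes = "nitro")
  expect_equal(pref_e$n_drug + pref_n$n_drug, pref$n_drug, tolerance = 1e-9)
  expect_error(drug_polymer_preference(cfg, donor_type = "Zz"), "no donor")
})

test_that("a polymer-only acceptor environment is flagged", {
  # donors on NIF, all drug acceptors stripped by class selection
  mix <- conformer_mixture(list(nif_template("alpha"), build_pvp_oligomer(3)),
                           c(0.5, 0.5), 4)
  cfg <- build_configuration(mix, density = 0.03, seed = 13)
  pref <- drug_polymer_preference(cfg, r_cut = 25.9 / 2,
                                  drug_classes = "none_such")
  expect_equal(pref$n_drug, 0)
  expect_true(is.infinite(pref$ratio))
  expect_equal(attr(pref$ratio, "label"), "polymer-only")
})

test_that("density conversions reproduce the printed benchmark values", {
  expect_equal(density_convert(0.105, "C17H18N2O6"), 1.40, tolerance = 0.005)
  expect_equal(density_convert(0.093, "C18H19Cl2NO4"), 1.35, tolerance = 0.005)
  expect_equal(density_convert(0, "C17H18N2O6"), 0)
  x <- 0.1073
  expect_equal(density_convert_inverse(density_convert(x, "C17H18N2O6"),
                                       "C17H18N2O6"), x, tolerance = 1e-12)
  expect_error(density_convert(0.1, "17C"), "unparseable")
  expect_error(density_convert(-0.1, "C2"), "non-negative")
})
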