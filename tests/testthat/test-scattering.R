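# Hand-built pair function set (single atom type) for transform tests.
fake_pairset <- function(r, g, rho, element = "C") {
  structure(list(r = r, dr = r[2] - r[1], g = list(`C:C` = g), rho = rho,
                 c = c(C = 1), n_of = c(C = 1000),
                 element_of = c(C = element), types = "C"),
            class = "pair_function_set")
}

test_that("histogram g(r) is flat for an ideal gas and matches brute force", {
  tpl <- lj_site_template()
  cfg <- build_configuration(tpl, n_molecules = 1000, box_edge = 20,
                             seed = 4, placement = "random", min_sep = 0)
  ps <- compute_partial_gr(cfg, r_max = 9, dr = 0.25)
  # Poisson noise: 3 sigma per bin off the ideal-gas value
  edges <- seq(0, 9, by = 0.25)
  expected_counts <- 1000^2 / 2 * (4 / 3 * pi * diff(edges^3)) / 20^3
  z <- abs(ps$g[[1]] - 1) * sqrt(expected_counts)
  expect_lt(max(z[ps$r > 1]), 3.5)
  # exact equality with the O(N^2) oracle on a smaller random config
  cfg2 <- build_configuration(tpl, n_molecules = 200, box_edge = 12,
                              seed = 5, placement = "random", min_sep = 0)
  ps2 <- compute_partial_gr(cfg2, r_max = 5.9, dr = 0.1)
  H_oracle <- brute_pair_hist(cfg2, r_max = 5.9, dr = 0.1)
  expect_identical(unname(ps2$counts), unname(matrix(as.numeric(H_oracle),
                                                     nrow(H_oracle))))
})

test_that("a single pair lands in exactly one histogram bin", {
  cfg <- two_atom_config(3.0)
  ps <- compute_partial_gr(cfg, r_max = 10, dr = 0.02)
  expect_equal(sum(ps$counts), 1)
  expect_equal(ps$r[which(ps$counts == 1)], 2.99, tolerance = 0.011)
  expect_error(compute_partial_gr(cfg, r_max = 100), "half the box")
})

test_that("structureless and single-type limits of the X-ray total", {
  r <- seq(0.01, 10, by = 0.01)
  ps <- fake_pairset(r, rep(1, length(r)), rho = 0.05)
  S <- xray_total_sq(ps, seq(0.6, 25, by = 0.1))
  expect_lt(max(abs(S$S - 1)), 1e-12)
  # single atom type: weight is identically 1, independent of f(Q)
  w <- epsrlite:::fz_weights(ps, c(1, 5, 20))
  expect_equal(w[["C:C"]], rep(1, 3), tolerance = 1e-12)
  expect_error(xray_total_sq(ps, c(0, 1)), "must not contain 0")
})

test_that("periodic-histogram transform matches the Debye equation on a cluster", {
  tpl <- fel_template("R")
  xyz <- template_xyz(tpl)
  Q <- seq(0.6, 25, by = 0.2)
  deb <- xray_debye_sq(xyz, tpl$atoms$element, Q)
  cfg <- build_configuration(tpl, n_molecules = 1, box_edge = 60, seed = 1)
  cfg$xyz <- xyz
  ps <- compute_partial_gr(cfg, r_max = 18, dr = 2.5e-4, intra = TRUE,
                           inter = FALSE, by = "element")
  Sft <- xray_total_sq(ps, Q, taper = 0, background = FALSE)
  expect_lt(max(abs(Sft$S - deb$S)), 1e-3)
})

test_that("S(Q) tends to 1 at high Q for molecular configurations", {
  ff <- reference_forcefield()
  cfg <- build_configuration(nif_template("alpha"), n_molecules = 12,
                             density = 0.09, seed = 2)
  ctx <- mc_context(cfg, ff, nh_o_constraints())
  mc_sweeps(ctx, 40, tune = TRUE)
  S <- model_sq(list(ctx_config(ctx)))
  sel <- S$Q >= 0.9 * max(S$Q)
  expect_lt(abs(mean(S$S[sel]) - 1), 0.02)
  # swapping atoms of identical type leaves S(Q) unchanged
  cfg2 <- ctx_config(ctx)
  i1 <- which(cfg2$atoms$mol == 1); i2 <- which(cfg2$atoms$mol == 2)
  cfg3 <- cfg2
  cfg3$xyz[i1, ] <- cfg2$xyz[i2, ]; cfg3$xyz[i2, ] <- cfg2$xyz[i1, ]
  expect_equal(model_sq(list(cfg3))$S, model_sq(list(cfg2))$S,
               tolerance = 1e-12)
})

test_that("S(Q) <-> D(r) transforms behave like the analytic pair", {
  r <- seq(0.01, 20, by = 0.01)
  g <- 1 + 0.8 * exp(-((r - 4) / 0.7)^2)
  rho <- 0.04
  ps <- fake_pairset(r, g, rho)
  Q <- seq(0.01, 30, by = 0.01)
  S <- xray_total_sq(ps, Q, taper = 0)
  # S == 1 gives D == 0
  flat <- scattering_pattern(Q, rep(1, length(Q)))
  expect_lt(max(abs(sq_to_dr(flat, rho)$D)), 1e-12)
  # round trip recovers 4 pi rho r (g - 1) away from termination ripples
  rg <- seq(2, 8, by = 0.02)
  D <- sq_to_dr(S, rho, r_grid = rg)
  D_exact <- 4 * pi * rho * rg * (1 + 0.8 * exp(-((rg - 4) / 0.7)^2) - 1)
  expect_lt(max(abs(D$D - D_exact)), 1e-3)
  # linearity in S - 1
  a <- 0.37
  S2 <- scattering_pattern(Q, 1 + a * (S$S - 1))
  expect_equal(sq_to_dr(S2, rho, r_grid = rg)$D, a * D$D, tolerance = 1e-9)
  expect_error(sq_to_dr(S, -1), "rho")
  bad <- scattering_pattern(Q, S$S + 0.3)
  expect_error(sq_to_dr(bad, rho), "normalized")
})

test_that("the Lorch window damps low-r termination ripples", {
  r <- seq(0.01, 20, by = 0.01)
  g <- ifelse(r < 3.4, 0, 1) # hard-sphere-like
  ps <- fake_pairset(r, g, 0.02)
  Q <- seq(0.02, 25, by = 0.02)
  S <- xray_total_sq(ps, Q, taper = 0)
  rg <- seq(0.1, 1, by = 0.01)
  rip_none <- max(abs(sq_to_dr(S, 0.02, r_grid = rg, window = "none")$D))
  rip_lorch <- max(abs(sq_to_dr(S, 0.02, r_grid = rg, window = "lorch")$D))
  expect_lt(rip_lorch, rip_none)
})

test_that("FSDP metrics locate constructed peaks", {
  Q <- seq(0.6, 5, by = 0.01)
  S <- 1 + 0.5 * exp(-((Q - 1.4) / 0.2)^2)
  f <- fsdp_metrics(scattering_pattern(Q, S))
  expect_equal(f$position, 1.4, tolerance = 1e-3)
  expect_equal(f$height, 1.5, tolerance = 1e-3)
  expect_equal(f$width, 2 * 0.2 * sqrt(log(2)), tolerance = 0.02)
  expect_error(fsdp_metrics(scattering_pattern(Q, rep(1, length(Q)))),
               "no local maximum")
  # inserted peaks of growing height come back in order
  hs <- c(0.2, 0.4, 0.8, 1.6)
  got <- vapply(hs, function(h)
    fsdp_metrics(scattering_pattern(Q, 1 + h * exp(-((Q - 1.4) / 0.2)^2)))$height,
    0)
  expect_true(all(diff(got) > 0))
})

test_that("intramolecular Cl-Cl PDF peaks at the rigid ring separation", {
  tpl <- fel_template("R")
  p <- intramolecular_pair_pdf(tpl, c("Cl", "Cl"), broadening_sigma = 0.1)
  expect_equal(p$peak, 3.12, tolerance = 0.02)
  # near-zero broadening: delta at the stick
  p0 <- intramolecular_pair_pdf(tpl, c("Cl", "Cl"), broadening_sigma = 1e-4)
  expect_equal(p0$peak, p0$distances[1], tolerance = 1e-2)
  # ester rotations do not move the dichlorophenyl pair
  tpl2 <- rotate_group(rotate_group(tpl, 1, 97), 2, -41)
  p2 <- intramolecular_pair_pdf(tpl2, c("Cl", "Cl"), broadening_sigma = 0.1)
  expect_equal(p2$peak, p$peak, tolerance = 1e-9)
  expect_error(intramolecular_pair_pdf(nif_template(), c("Cl", "Cl")),
               "matches no")
})

test_that("S(Q) ASCII files round-trip", {
  p <- scattering_pattern(seq(0.6, 10, 0.1),
                          1 + 0.3 * sin(seq(0.6, 10, 0.1)),
                          sigma = rep(0.005, 95), temperature_K = 300)
  path <- withr::local_tempfile(fileext = ".dat")
  write_sq(p, path)
  back <- read_sq(path)
  expect_equal(back$Q, p$Q, tolerance = 1e-6)
  expect_equal(back$S, p$S, tolerance = 1e-7)
  expect_equal(back$sigma, p$sigma, tolerance = 1e-7)
})
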