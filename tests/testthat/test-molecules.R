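test_that("built-in templates have the right stoichiometry and geometry", {
  nif <- nif_template("alpha")
  expect_equal(nrow(nif$atoms), 43)
  expect_equal(template_formula(nif),
               c(C = 17L, H = 18L, N = 2L, O = 6L))
  fel <- fel_template("R")
  expect_equal(nrow(fel$atoms), 44)
  expect_equal(template_formula(fel),
               c(C = 18L, H = 19L, Cl = 2L, N = 1L, O = 4L))
  # rigid dichlorophenyl Cl...Cl: two adjacent substituents at radius
  # 1.39 + 1.73 separated by 60 degrees -> d = 2 * 3.12 * sin(30 deg)
  cl <- template_xyz(fel)[fel$atoms$element == "Cl", ]
  d_oracle <- 2 * (1.39 + 1.73) * sin(30 * pi / 180)
  expect_equal(as.numeric(dist(cl)), d_oracle, tolerance = 1e-9)
  # all five conformer variants validate
  for (tpl in list(nif_template("beta"), nif_template("flipped"),
                   fel_template("S")))
    expect_s3_class(tpl, "mol_template")
})

test_that("group rotations are exact rigid-body operations", {
  tpl <- nif_template("alpha")
  x0 <- template_xyz(tpl)
  # identity cases
  expect_lt(max(abs(rotate_group(tpl, 1, 360, xyz = x0) - x0)), 1e-9)
  expect_lt(max(abs(rotate_group(tpl, 1, 0, xyz = x0) - x0)), 1e-9)
  expect_error(rotate_group(tpl, 99, 10), "invalid group index")
  # rotation-matrix oracle for the ester rotation: moved atoms follow the
  # explicit axis-angle matrix, unmoved atoms (aryl ring, Cl-free ring) stay
  g <- tpl$groups[[1]]
  x1 <- rotate_group(tpl, 1, 180, xyz = x0)
  idx <- match(c(g$axis, g$moved), tpl$atoms$label)
  a <- x0[idx[1], ]; b <- x0[idx[2], ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  R <- {
    th <- pi
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                byrow = TRUE)
    diag(3) * cos(th) + sin(th) * K + (1 - cos(th)) * (u %o% u)
  }
  mv <- idx[-(1:2)]
  oracle <- sweep(sweep(x0[mv, ], 2, a) %*% t(R), 2, a, "+")
  expect_lt(max(abs(x1[mv, ] - oracle)), 1e-9)
  ring <- match(c("C2", "C3", "C4", "C5", "C6", "CA1", "CA2"), tpl$atoms$label)
  expect_lt(max(abs(x1[ring, ] - x0[ring, ])), 1e-12)
  expect_gt(max(abs(x1[mv, ] - x0[mv, ])), 0.5)
})

test_that("random rotation sequences preserve bonds and non-moved distances", {
  set.seed(42)
  for (tpl0 in list(nif_template("alpha"), fel_template("S"))) {
    tpl <- tpl0
    for (k in 1:20)
      tpl <- rotate_group(tpl, sample(length(tpl$groups), 1),
                          runif(1, -180, 180))
    x0 <- template_xyz(tpl0); x1 <- template_xyz(tpl)
    b0 <- sqrt(rowSums((x0[match(tpl0$bonds[, 1], tpl0$atoms$label), ] -
                        x0[match(tpl0$bonds[, 2], tpl0$atoms$label), ])^2))
    b1 <- sqrt(rowSums((x1[match(tpl0$bonds[, 1], tpl0$atoms$label), ] -
                        x1[match(tpl0$bonds[, 2], tpl0$atoms$label), ])^2))
    expect_lt(max(abs(b1 - b0)), 1e-9)
    moved <- unique(unlist(lapply(tpl0$groups, `[[`, "moved")))
    fixed <- which(!(tpl0$atoms$label %in% moved))
    expect_lt(max(abs(dist(x1[fixed, ]) - dist(x0[fixed, ]))), 1e-9)
  }
})

test_that("PVP oligomers assemble with capped ends and acceptor carbonyls", {
  p5 <- build_pvp_oligomer(5)
  expect_equal(nrow(p5$atoms), 5 * 17 + 2)
  p1 <- build_pvp_oligomer(1)
  expect_equal(nrow(p1$atoms), 19)
  # valence completeness of the single monomer: sp3 C x4, amide
  # (carbonyl) C x3, N x3, O x1, H x1
  adj <- table(c(p1$bonds[, 1], p1$bonds[, 2]))
  deg <- as.integer(adj[p1$atoms$label])
  want <- unname(c(C = 4L, N = 3L, O = 1L, H = 1L)[p1$atoms$element])
  want[p1$atoms$type_key == "C_carbonyl"] <- 3L
  expect_equal(deg, want)
  expect_error(build_pvp_oligomer(0), "n_monomers")
  # every monomer contributes one carbonyl-acceptor oxygen
  expect_equal(sum(p5$atoms$type_key == "O_carbonyl"), 5)
})

test_that("drug-polymer box sizing reproduces the ~28 A mixture cell", {
  mix <- conformer_mixture(list(nif_template("alpha"), build_pvp_oligomer(5)),
                           c(10 / 31, 21 / 31), 31)
  expect_equal(mix$counts, c(10L, 21L))
  n_atoms <- 10 * 43 + 21 * 87
  edge <- (n_atoms / 0.115)^(1 / 3)
  expect_gt(edge, 26.5)
  expect_lt(edge, 28.5)
})

test_that("reference energies match closed-form pair values", {
  ff <- forcefield(data.frame(type_key = "LJ_site", q = 0, sigma = 3.2,
                              epsilon = 0.8))
  cfg <- two_atom_config(3.2)
  expect_equal(lj_coulomb_energy(cfg, ff), 0, tolerance = 1e-12)
  cfg <- two_atom_config(2^(1 / 6) * 3.2)
  expect_equal(lj_coulomb_energy(cfg, ff), -0.8, tolerance = 1e-9)
  # pure Coulomb: 1389.35 * 0.49 / 3.25 kJ/mol
  ffq <- forcefield(data.frame(type_key = "QQ", q = -0.70, sigma = 0,
                               epsilon = 0))
  cfgq <- two_atom_config(3.25, type_key = "QQ")
  expect_equal(lj_coulomb_energy(cfgq, ffq), 1389.35 * 0.49 / 3.25,
               tolerance = 1e-6)
  expect_error(lj_coulomb_energy(cfgq, ff), "unresolvable")
})

test_that("energy is invariant under translation and molecule relabeling", {
  ff <- reference_forcefield()
  cfg <- build_configuration(nif_template("alpha"), n_molecules = 4,
                             density = 0.04, seed = 7)
  e0 <- lj_coulomb_energy(cfg, ff)
  shifted <- cfg
  shifted$xyz <- sweep(cfg$xyz, 2, c(3.1, -8.2, 12.9), "+")
  expect_equal(lj_coulomb_energy(shifted, ff), e0, tolerance = 1e-8)
  # swap the coordinates of two identical molecules
  swapped <- cfg
  i1 <- which(cfg$atoms$mol == 1); i2 <- which(cfg$atoms$mol == 2)
  swapped$xyz[i1, ] <- cfg$xyz[i2, ]
  swapped$xyz[i2, ] <- cfg$xyz[i1, ]
  expect_equal(lj_coulomb_energy(swapped, ff), e0, tolerance = 1e-8)
})

test_that("template charges neutralize and templates round-trip through files", {
  ff <- reference_forcefield()
  for (tpl in list(nif_template("alpha"), fel_template("R"),
                   build_pvp_oligomer(5))) {
    q <- template_charges(tpl, ff)
    expect_lt(abs(sum(q)), 1e-12)
    expect_true(is.finite(attr(q, "raw_net")))
  }
  tpl <- nif_template("beta")
  path <- withr::local_tempfile(fileext = ".tpl")
  write_template(tpl, path)
  back <- read_template(path)
  expect_equal(back$atoms$label, tpl$atoms$label)
  expect_equal(back$atoms$type_key, tpl$atoms$type_key)
  expect_lt(max(abs(template_xyz(back) - template_xyz(tpl))), 1e-8)
  expect_equal(back$bonds, tpl$bonds)
  expect_equal(back$groups, tpl$groups)
})

test_that("template validation rejects malformed inputs", {
  at <- data.frame(label = c("A", "B"), element = c("C", "C"),
                   type_key = "default_C",
                   x = c(0, 5), y = 0, z = 0, stringsAsFactors = FALSE)
  expect_error(mol_template("bad", "x", at, rbind(c("A", "B"))), "0.9-1.9")
  at$x <- c(0, 1.4)
  expect_error(mol_template("bad", "x", at, rbind(c("A", "B")),
                            list(list(axis = c("A", "B"), moved = "A"))),
               "axis atom")
  at2 <- rbind(at, data.frame(label = "C", element = "C",
                              type_key = "default_C", x = 10, y = 10, z = 10))
  expect_error(mol_template("bad", "x", at2, rbind(c("A", "B"))),
               "disconnected")
  expect_error(mol_template("bad", "x",
                            transform(at, element = c("C", "Zz")),
                            rbind(c("A", "B"))),
               "unknown element")
})
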