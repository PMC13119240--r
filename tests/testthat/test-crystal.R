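# In-code CIF fixtures.
toy_cif_text <- function(symtag = "_space_group_symop_operation_xyz",
                         ops = "'x,y,z'") {
  c("data_toy",
    "_cell_length_a 3.0", "_cell_length_b 3.0", "_cell_length_c 3.0",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", symtag, ops,
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0.0 0.0 0.0")
}

test_that("minimal CIFs parse in both symmetry dialects", {
  f1 <- withr::local_tempfile(fileext = ".cif")
  writeLines(toy_cif_text(), f1)
  cs <- parse_cif(f1)
  expect_equal(nrow(cs$atoms), 1)
  expect_equal(cs$ops, "x,y,z")
  expect_equal(unname(cs$cell[1:3]), c(3, 3, 3))
  f2 <- withr::local_tempfile(fileext = ".cif")
  writeLines(toy_cif_text("_symmetry_equiv_pos_as_xyz"), f2)
  expect_equal(parse_cif(f2)$ops, cs$ops)
  # malformed inputs
  f3 <- withr::local_tempfile(fileext = ".cif")
  writeLines("data_x\n_cell_length_a 3.0", f3)
  expect_error(parse_cif(f3), "lacks")
})

test_that("symmetry operators act as affine maps", {
  so <- epsrlite:::parse_symop("x,y,z")
  expect_equal(unname(so$M), diag(3))
  expect_equal(unname(so$t), c(0, 0, 0))
  so2 <- epsrlite:::parse_symop("-x,1/2+y,1/2-z")
  p <- as.vector(so2$M %*% c(0.1, 0.2, 0.3) + so2$t) %% 1
  expect_equal(p, c(0.9, 0.7, 0.2), tolerance = 1e-12)
  expect_error(epsrlite:::parse_symop("x,y"), "unparseable")
})

test_that("a P2_1/c general position has multiplicity four", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_p21c",
               "_cell_length_a 8.0", "_cell_length_b 9.0", "_cell_length_c 10.0",
               "_cell_angle_alpha 90", "_cell_angle_beta 95",
               "_cell_angle_gamma 90",
               "loop_", "_space_group_symop_operation_xyz",
               "'x,y,z'", "'-x,y+1/2,-z+1/2'", "'-x,-y,-z'", "'x,-y+1/2,z+1/2'",
               "loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
               "C1 C 0.13 0.21 0.34"), f)
  ex <- expand_symmetry(parse_cif(f))
  expect_equal(nrow(ex$xyz), 4)
})

test_that("toy crystals recover their planted contact geometry exactly", {
  cs <- make_toy_crystal(3.00)
  ct <- crystal_contacts(cs, d_window = c(2, 3.6))
  expect_equal(ct$d[1], 3.00, tolerance = 1e-9)
  expect_equal(ct$angle[1], 180, tolerance = 1e-6)
  cs2 <- make_toy_crystal(3.028, contact_angle = 160.3)
  ct2 <- crystal_contacts(cs2, d_window = c(2, 3.6))
  expect_equal(ct2$d[1], 3.028, tolerance = 1e-9)
  expect_equal(ct2$angle[1], 160.3, tolerance = 1e-3)
})

test_that("expansion is idempotent and contacts are origin-independent", {
  cs <- make_toy_crystal(3.00)
  ex1 <- expand_symmetry(cs)
  expect_equal(nrow(ex1$xyz), nrow(cs$atoms)) # P1: nothing new
  shifted <- cs
  shifted$atoms$fx <- (shifted$atoms$fx + 0.25) %% 1
  ct1 <- crystal_contacts(cs, d_window = c(2, 3.6))
  ct2 <- crystal_contacts(shifted, d_window = c(2, 3.6))
  expect_equal(ct1$d, ct2$d, tolerance = 1e-9)
})

test_that("crystal density matches hand arithmetic and is supercell-invariant", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(toy_cif_text(), f)
  cs <- parse_cif(f)
  expect_equal(crystal_density(cs), 12.011 / (6.02214076e23 * 27e-24),
               tolerance = 1e-4)
  # mass per volume is the same in any supercell
  ex1 <- expand_symmetry(cs, c(1, 1, 1)); ex2 <- expand_symmetry(cs, c(2, 2, 2))
  m1 <- sum(atomic_mass(ex1$atoms$element)) / det(ex1$cell_matrix)
  m2 <- sum(atomic_mass(ex2$atoms$element)) / det(ex2$cell_matrix)
  expect_equal(m1, m2, tolerance = 1e-12)
  # toy crystal density equals Z M / (N_A V)
  cs2 <- make_toy_crystal(3.0)
  M <- sum(atomic_mass(cs2$atoms$element))
  expect_equal(crystal_density(cs2), M / (6.02214076e23 * 12^3 * 1e-24),
               tolerance = 1e-9)
})

test_that("crystal running coordination steps at the contact distance", {
  cs <- make_toy_crystal(3.00)
  cc <- crystal_running_coordination(cs, "N", "O",
                                     r_grid = seq(0.2, 5, by = 0.05))
  expect_equal(min(cc$r[cc$n >= 1]), 3.0, tolerance = 0.051)
  expect_equal(cc$n[cc$r < 2.9], rep(0, sum(cc$r < 2.9)))
  # integral check: counts at r equal a direct count in the supercell
  ex <- expand_symmetry(cs, c(3, 3, 3))
  Ns <- which(ex$atoms$element == "N")
  Os <- which(ex$atoms$element == "O")
  # central-cell N only
  dists <- sort(unlist(lapply(Ns, function(i)
    sqrt(colSums((t(ex$xyz[Os, , drop = FALSE]) - ex$xyz[i, ])^2)))))
  expect_equal(max(cc$n), sum(dists <= 5) / length(Ns), tolerance = 1)
})

test_that("CIF writing round-trips through the parser", {
  cs <- make_toy_crystal(3.1)
  f <- withr::local_tempfile(fileext = ".cif")
  write_cif(cs, f)
  back <- parse_cif(f)
  expect_equal(unname(back$cell), unname(cs$cell), tolerance = 1e-4)
  # the parser resolves disorder by label, which may reorder sites
  expect_setequal(back$atoms$label, cs$atoms$label)
  m <- match(cs$atoms$label, back$atoms$label)
  expect_equal(back$atoms$fx[m], cs$atoms$fx, tolerance = 1e-5)
})

test_that("templates can be loaded from crystal sources", {
  cs <- make_toy_crystal(3.0)
  tpl <- load_template(cs, name = "TOY")
  expect_s3_class(tpl, "mol_template")
  expect_equal(nrow(tpl$atoms), 2) # first molecule: the N-H fragment
})
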