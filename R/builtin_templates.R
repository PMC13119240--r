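# Idealized 3D builders for the bundled templates.  Geometry is constructed
# from standard bond lengths (aromatic C-C 1.39, ring C-C/C-N 1.40, C-Cl
# 1.73, C=O 1.22, C-O(ester) 1.34/1.43, C-C 1.50-1.54, N-H 1.01, C-H 1.09
# Angstrom) with planar rings and radial substituents.  These are starting
# conformations for the semi-rigid Monte Carlo engine, not DFT minima.

.deg <- function(a) a * pi / 180

# Internal mutable builder for assembling an atom table.
.new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$atoms <- list(); env$bonds <- list()
  env
}
.add_atom <- function(bld, label, element, type_key, pos) {
  bld$atoms[[length(bld$atoms) + 1L]] <-
    data.frame(label = label, element = element, type_key = type_key,
               x = pos[1], y = pos[2], z = pos[3], stringsAsFactors = FALSE)
  invisible(pos)
}
.add_bond <- function(bld, a, b) {
  bld$bonds[[length(bld$bonds) + 1L]] <- c(a, b)
  invisible(NULL)
}
.builder_frames <- function(bld) {
  list(atoms = do.call(rbind, bld$atoms), bonds = do.call(rbind, bld$bonds))
}
.atom_pos <- function(bld, label) {
  for (a in bld$atoms) if (a$label == label) return(c(a$x, a$y, a$z))
  stop("no atom ", label)
}

# Methyl group: carbon already placed at `cpos`, attached along `axis`
# (unit vector from the parent atom towards the methyl carbon).
.add_methyl_h <- function(bld, cname, cpos, axis, htype = "default_H",
                          phi0 = 0) {
  F <- local_frame(axis)
  for (k in 0:2) {
    ph <- .deg(phi0 + 120 * k)
    dir <- 0.3338 * F[, 1] + 0.9426 * (cos(ph) * F[, 2] + sin(ph) * F[, 3])
    .add_atom(bld, sprintf("%sH%d", cname, k + 1), "H", htype,
              cpos + 1.09 * dir)
    .add_bond(bld, cname, sprintf("%sH%d", cname, k + 1))
  }
}

# Ester group -C(=O)-O-R attached at ring atom `at` along unit vector `e1`,
# branch plane spanned by (e1, e2).  `suffix` distinguishes the two esters;
# `alkyl` is "methyl" or "ethyl".  Returns the labels of the group atoms.
.add_ester <- function(bld, at, e1, e2, suffix, alkyl = "methyl") {
  p0 <- .atom_pos(bld, at)
  cc <- paste0("C", suffix, "c")
  pcc <- p0 + 1.50 * e1
  .add_atom(bld, cc, "C", "C_carbonyl", pcc)
  .add_bond(bld, at, cc)
  oc <- paste0("O", suffix, "c") # carbonyl oxygen (acceptor, O2 class)
  .add_atom(bld, oc, "O", "O_carbonyl",
            pcc + 1.22 * (cos(.deg(60)) * e1 + sin(.deg(60)) * e2))
  .add_bond(bld, cc, oc)
  oe <- paste0("O", suffix, "e") # ester (ether) oxygen, O1 class
  poe <- pcc + 1.34 * (cos(.deg(60)) * e1 - sin(.deg(60)) * e2)
  .add_atom(bld, oe, "O", "O_ether", poe)
  .add_bond(bld, cc, oe)
  c1 <- paste0("C", suffix, "m")
  pc1 <- poe + 1.43 * (cos(.deg(5)) * e1 + sin(.deg(5)) * e2)
  .add_atom(bld, c1, "C", "C_methoxy", pc1)
  .add_bond(bld, oe, c1)
  members <- c(oc, oe, c1)
  if (alkyl == "methyl") {
    .add_methyl_h(bld, c1, pc1, pc1 - poe)
    members <- c(members, paste0(c1, "H", 1:3))
  } else {
    F <- local_frame(pc1 - poe)
    for (k in 1:2) {
      h <- sprintf("%sH%d", c1, k)
      .add_atom(bld, h, "H", "default_H",
                pc1 + 1.09 * (0.33 * F[, 1] + c(1, -1)[k] * 0.94 * F[, 3]))
      .add_bond(bld, c1, h)
      members <- c(members, h)
    }
    c2 <- paste0("C", suffix, "t")
    pc2 <- pc1 + 1.52 * (0.40 * F[, 1] + 0.92 * F[, 2])
    .add_atom(bld, c2, "C", "C_alkyl", pc2)
    .add_bond(bld, c1, c2)
    .add_methyl_h(bld, c2, pc2, pc2 - pc1)
    members <- c(members, c2, paste0(c2, "H", 1:3))
  }
  members
}

# Shared dihydropyridine core + aryl ring scaffold for NIF and FEL.
# `aryl_subs` is a named list position -> substituent spec for aryl vertices
# 2..6 (position 1 is the ipso carbon); unlisted positions get aromatic
# hydrogens.  Moving a substituent to the mirror-image vertex (2 -> 6)
# realises the "flipped" aryl conformer.
.build_dhp_molecule <- function(name, conformer_id, cpyr_type, ester2_alkyl,
                                aryl_subs, rot_groups_extra = list()) {
  bld <- .new_builder()
  ring_lab <- c("N1", "C2", "C3", "C4", "C5", "C6")
  ring_type <- c("N_NHR", cpyr_type, "default_C", "default_C", "default_C",
                 cpyr_type)
  ring_el <- c("N", rep("C", 5))
  ang <- .deg(270 + 60 * (0:5))
  rad <- function(k) c(cos(ang[k]), sin(ang[k]), 0)
  for (k in 1:6)
    .add_atom(bld, ring_lab[k], ring_el[k], ring_type[k], 1.40 * rad(k))
  for (k in 1:6) .add_bond(bld, ring_lab[k], ring_lab[k %% 6 + 1])
  # N-H donor
  .add_atom(bld, "H1", "H", "H_NHR", 1.40 * rad(1) + 1.01 * rad(1))
  .add_bond(bld, "N1", "H1")
  # ring methyls on C2 and C6
  for (k in c(2, 6)) {
    cm <- paste0("C", k, "m")
    pc <- 1.40 * rad(k) + 1.50 * rad(k)
    .add_atom(bld, cm, "C", "C_alkyl", pc)
    .add_bond(bld, ring_lab[k], cm)
    .add_methyl_h(bld, cm, pc, rad(k))
  }
  # esters on C3 and C5, branching below the ring plane (the aryl ring
  # occupies the upper side)
  est1 <- .add_ester(bld, "C3", rad(3), c(0, 0, -1), "3", "methyl")
  est2 <- .add_ester(bld, "C5", rad(5), c(0, 0, -1), "5", ester2_alkyl)
  # sp3 C4: aryl ring up, hydrogen down
  b <- .deg(54.75)
  u_up <- cos(b) * rad(4) + sin(b) * c(0, 0, 1)
  u_dn <- cos(b) * rad(4) - sin(b) * c(0, 0, 1)
  p4 <- 1.40 * rad(4)
  .add_atom(bld, "H4", "H", "default_H", p4 + 1.09 * u_dn)
  .add_bond(bld, "C4", "H4")
  # aryl plane spanned by the attachment direction and a vector tilting
  # ortho substituents outward (away from the esters below the ring plane)
  t_hat <- unit(c(-rad(4)[2], rad(4)[1], 0))
  w_hat <- unit(c(t_hat[2] * u_up[3] - t_hat[3] * u_up[2],
                  t_hat[3] * u_up[1] - t_hat[1] * u_up[3],
                  t_hat[1] * u_up[2] - t_hat[2] * u_up[1]))
  ipso <- p4 + 1.51 * u_up
  centre <- ipso + 1.39 * u_up
  aryl_ang <- .deg(180 - 60 * (0:5))
  arad <- function(k) cos(aryl_ang[k]) * u_up + sin(aryl_ang[k]) * w_hat
  alab <- paste0("CA", 1:6)
  for (k in 1:6) {
    type <- "default_C"
    if (!is.null(aryl_subs[[as.character(k)]]) &&
        !is.null(aryl_subs[[as.character(k)]]$ctype))
      type <- aryl_subs[[as.character(k)]]$ctype
    .add_atom(bld, alab[k], "C", type, centre + 1.39 * arad(k))
  }
  for (k in 1:6) .add_bond(bld, alab[k], alab[k %% 6 + 1])
  .add_bond(bld, "C4", "CA1")
  for (k in 2:6) {
    sub <- aryl_subs[[as.character(k)]]
    if (is.null(sub)) {
      h <- paste0("HA", k)
      .add_atom(bld, h, "H", "default_H", centre + (1.39 + 1.08) * arad(k))
      .add_bond(bld, alab[k], h)
    } else if (sub$what == "Cl") {
      cl <- paste0("Cl", k)
      .add_atom(bld, cl, "Cl", "Cl_fel", centre + (1.39 + 1.73) * arad(k))
      .add_bond(bld, alab[k], cl)
    } else if (sub$what == "NO2") {
      pn <- centre + (1.39 + 1.47) * arad(k)
      .add_atom(bld, "N2", "N", "N_nitro", pn)
      .add_bond(bld, alab[k], "N2")
      # O-N-O in the aryl plane, +-60 degrees off the radial direction
      n_hat <- arad(k)
      t2 <- unit(centre + 1.39 * arad(k %% 6 + 1) - (centre + 1.39 * arad(k)))
      t2 <- unit(t2 - sum(t2 * n_hat) * n_hat)
      for (s in 1:2) {
        o <- paste0("O3", c("a", "b")[s])
        .add_atom(bld, o, "O", "O_nitro",
                  pn + 1.22 * (cos(.deg(60)) * n_hat +
                               c(1, -1)[s] * sin(.deg(60)) * t2))
        .add_bond(bld, "N2", o)
      }
    }
  }
  fr <- .builder_frames(bld)
  groups <- c(list(
    list(axis = c("C3", "C3c"), moved = est1),
    list(axis = c("C5", "C5c"), moved = est2),
    list(axis = c("C2", "C2m"), moved = paste0("C2mH", 1:3)),
    list(axis = c("C6", "C6m"), moved = paste0("C6mH", 1:3))
  ), rot_groups_extra)
  mol_template(name, conformer_id, fr$atoms, fr$bonds, groups)
}

# Soft-sphere clash score over included (1-4 and beyond) intramolecular
# pairs; used only to pick starting torsion angles.
.clash_score <- function(tpl, pairs) {
  x <- template_xyz(tpl)
  d2 <- rowSums((x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE])^2)
  sum(1 / d2^6)
}

# Greedy torsion relaxation: scan each rotatable group over
# [-window, window] degrees in `step` increments and keep the angle with
# the lowest clash score.  Deterministic; a small window preserves the
# identity of a conformer while relieving residual build clashes.
.relax_torsions <- function(tpl, step = 10, passes = 2, window = 180) {
  pairs <- template_included_pairs(tpl)
  for (p in seq_len(passes)) {
    for (g in seq_along(tpl$groups)) {
      best <- tpl; best_s <- .clash_score(tpl, pairs)
      for (a in seq(-window, window, by = step)) {
        cand <- rotate_group(tpl, g, a)
        s <- .clash_score(cand, pairs)
        if (s < best_s) { best <- cand; best_s <- s }
      }
      tpl <- best
    }
  }
  tpl
}

#' Built-in nifedipine template
#'
#' Idealized semi-rigid nifedipine (C17H18N2O6, 43 atoms): dihydropyridine
#' ring with N1-H donor, two ring methyls, two methyl esters (carbonyl
#' oxygens are the O2 acceptor class), and an ortho-nitrophenyl ring
#' (nitro oxygens are the O3 acceptor class).  Five rotatable groups: the
#' two esters, the two ring methyls, and the nitro group.
#'
#' @param conformer `"alpha"`, `"beta"`, or `"flipped"` (aryl ring rotated
#'   by 180 degrees so the nitro group sits near the N1-H side).  alpha and
#'   beta share the idealized scaffold and differ by the ester torsions.
#' @return A `mol_template`.
#' @export
nif_template <- function(conformer = c("alpha", "beta", "flipped")) {
  conformer <- match.arg(conformer)
  tpl <- .build_dhp_molecule(
    "NIF", conformer, "C_pyr_nif", "methyl",
    aryl_subs = list(`2` = list(what = "NO2", ctype = "C_nitro")),
    rot_groups_extra = list(list(axis = c("CA2", "N2"),
                                 moved = c("O3a", "O3b"))))
  tpl <- .relax_torsions(tpl)
  # beta: distinct starting conformation via flipped ester torsions,
  # locally relaxed so the flip is preserved
  if (conformer == "beta") {
    tpl <- rotate_group(tpl, 1, 180)
    tpl <- rotate_group(tpl, 2, 180)
    tpl <- .relax_torsions(tpl, window = 60)
  }
  # flipped: the aryl ring rotated by 180 degrees about its attachment
  # bond, so the nitro group sits on the other ortho position.  Defined as
  # this exact rotation of the alpha geometry (everything else identical),
  # which is also how in-place conformer flips realise it.
  if (conformer == "flipped") {
    adj <- template_adjacency(tpl)
    moved <- setdiff(.component(adj, "CA1", drop_bond = c("C4", "CA1")),
                     "CA1")
    xyz <- template_xyz(tpl)
    idx <- match(c("C4", "CA1", moved), tpl$atoms$label)
    a <- xyz[idx[1], ]; b <- xyz[idx[2], ]
    xyz[idx[-(1:2)], ] <- rotate_about_axis(xyz[idx[-(1:2)], , drop = FALSE],
                                            a, b - a, 180)
    tpl$atoms[, c("x", "y", "z")] <- xyz
  }
  tpl
}

#' Built-in felodipine template
#'
#' Idealized semi-rigid felodipine (C18H19Cl2NO4, 44 atoms): dihydropyridine
#' ring, two ring methyls, one methyl and one ethyl ester, and a
#' 2,3-dichlorophenyl ring (the rigid intramolecular Cl...Cl distance is
#' 3.12 Angstrom for a 1.39 Angstrom aromatic ring with 1.73 Angstrom C-Cl
#' bonds).  Four rotatable groups: two esters and two ring methyls.
#' Chirality is encoded by which ring position carries the ethyl ester
#' (R: ethyl on C5; S: ethyl on C3), mirroring the methyl/ethyl interchange
#' convention for the enantiomers.
#'
#' @param enantiomer `"R"` or `"S"`.
#' @return A `mol_template`.
#' @export
fel_template <- function(enantiomer = c("R", "S")) {
  enantiomer <- match.arg(enantiomer)
  subs <- list(`2` = list(what = "Cl"), `3` = list(what = "Cl"))
  if (enantiomer == "R") {
    .relax_torsions(.build_dhp_molecule("FEL", "R", "C_pyr_fel", "ethyl", subs))
  } else {
    tpl <- .build_dhp_molecule("FEL", "S", "C_pyr_fel", "ethyl", subs)
    # swap which side carries the ethyl chain by mirroring through the
    # ring plane x-z: geometric enantiomer with identical topology
    xyz <- template_xyz(tpl)
    xyz[, 2] <- -xyz[, 2]
    tpl$atoms[, c("x", "y", "z")] <- xyz
    tpl$conformer_id <- "S"
    .relax_torsions(tpl)
  }
}

#' Built-in PVP (polyvinylpyrrolidone) oligomer
#'
#' Builds an n-monomer vinylpyrrolidone chain (C6H9NO repeat, 17 atoms per
#' monomer) with hydrogen-capped ends, so a pentamer has 87 atoms.  The
#' pyrrolidone carbonyl oxygen of every monomer carries the carbonyl
#' acceptor type (hydrogen-bond acceptor class "pvp" in mixture analyses).
#' Each pyrrolidone ring is a rotatable group about its N-CH bond.
#'
#' @param n_monomers Number of vinylpyrrolidone monomers (>= 1).
#' @return A `mol_template` named `"PVP"`.
#' @export
build_pvp_oligomer <- function(n_monomers = 5) {
  if (!is.numeric(n_monomers) || n_monomers < 1)
    stop("n_monomers must be >= 1")
  n_monomers <- as.integer(n_monomers)
  bld <- .new_builder()
  dx <- 1.54 * sin(.deg(54.75)); dy <- 1.54 * cos(.deg(54.75))
  groups <- list()
  bb_pos <- function(k) # backbone carbon k (1-based along the chain)
    c((k - 1) * dx, dy * 0.5 * (-1)^(k + 1), 0)
  # two tetrahedral H directions completing a CH2 given its two bond dirs
  ch2_dirs <- function(a1, a2) {
    u <- -unit(unit(a1) + unit(a2))
    w <- unit(c(a1[2] * a2[3] - a1[3] * a2[2],
                a1[3] * a2[1] - a1[1] * a2[3],
                a1[1] * a2[2] - a1[2] * a2[1]))
    list(unit(cos(.deg(54.75)) * u + sin(.deg(54.75)) * w),
         unit(cos(.deg(54.75)) * u - sin(.deg(54.75)) * w))
  }
  for (m in seq_len(n_monomers)) {
    c1 <- sprintf("C%da", m); c2 <- sprintf("C%db", m)
    p1 <- bb_pos(2 * m - 1); p2 <- bb_pos(2 * m)
    .add_atom(bld, c1, "C", "default_C", p1)
    .add_atom(bld, c2, "C", "default_C", p2)
    .add_bond(bld, c1, c2)
    if (m > 1) .add_bond(bld, sprintf("C%db", m - 1), c1)
    # syndiotactic placement: the ring on each backbone CH points
    # alternately above/below the backbone zig-zag plane
    zs <- (-1)^(m + 1)
    u <- c(0, 0.577, 0.816 * zs)   # ring attachment direction
    uh <- c(0, 0.577, -0.816 * zs) # CH hydrogen direction
    .add_atom(bld, paste0(c1, "H"), "H", "default_H", p1 + 1.09 * uh)
    .add_bond(bld, c1, paste0(c1, "H"))
    # CH2 hydrogens
    hh <- ch2_dirs(p1 - p2, bb_pos(2 * m + 1) - p2)
    for (k in 1:2) {
      h <- sprintf("%sH%d", c2, k)
      .add_atom(bld, h, "H", "default_H", p2 + 1.09 * hh[[k]])
      .add_bond(bld, c2, h)
    }
    # pyrrolidone ring in the plane perpendicular to the backbone direction
    np <- p1 + 1.47 * u
    nlab <- sprintf("N%dp", m)
    .add_atom(bld, nlab, "N", "default_N", np)
    .add_bond(bld, c1, nlab)
    r5 <- 1.47 / (2 * sin(.deg(36)))
    centre <- np + r5 * u
    rang <- .deg(180 + 72 * (0:4))
    e2 <- c(0, -u[3], u[2]) # perpendicular to u, still no extent along x
    rpos <- lapply(rang, function(a) centre + r5 * (cos(a) * u + sin(a) * e2))
    rlab <- c(nlab, sprintf("C%dp%d", m, 2:5))
    ring_members <- character(0)
    for (k in 2:5) {
      type <- if (k == 2) "C_carbonyl" else "default_C"
      .add_atom(bld, rlab[k], "C", type, rpos[[k]])
      ring_members <- c(ring_members, rlab[k])
    }
    for (k in 1:5) .add_bond(bld, rlab[k], rlab[k %% 5 + 1])
    # carbonyl oxygen: radial, in the ring plane (acceptor class "pvp")
    o <- sprintf("O%dp", m)
    .add_atom(bld, o, "O", "O_carbonyl",
              rpos[[2]] + 1.22 * unit(rpos[[2]] - centre))
    .add_bond(bld, rlab[2], o)
    ring_members <- c(ring_members, o)
    nrm <- c(1, 0, 0) # ring normal (along the backbone direction)
    for (k in 3:5) {
      crad <- unit(rpos[[k]] - centre)
      for (s in 1:2) {
        h <- sprintf("%sH%d", rlab[k], s)
        .add_atom(bld, h, "H", "default_H",
                  rpos[[k]] + 1.09 * unit(0.5 * crad + c(1, -1)[s] * 0.87 * nrm))
        .add_bond(bld, rlab[k], h)
        ring_members <- c(ring_members, h)
      }
    }
    groups[[length(groups) + 1L]] <-
      list(axis = c(c1, nlab), moved = ring_members)
  }
  # hydrogen caps on the chain ends
  .add_atom(bld, "Hcap1", "H", "default_H",
            .atom_pos(bld, "C1a") + 1.09 * unit(bb_pos(0) - bb_pos(1)))
  .add_bond(bld, "C1a", "Hcap1")
  ct <- sprintf("C%db", n_monomers)
  .add_atom(bld, "Hcap2", "H", "default_H",
            .atom_pos(bld, ct) +
              1.09 * unit(bb_pos(2 * n_monomers + 1) - bb_pos(2 * n_monomers)))
  .add_bond(bld, ct, "Hcap2")
  fr <- .builder_frames(bld)
  .relax_torsions(
    mol_template("PVP", sprintf("K%d", n_monomers), fr$atoms, fr$bonds, groups),
    window = 60)
}
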