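#' Synthetic-data specifications
#'
#' Describes a synthetic study system: the molecular templates and their
#' fractions, box size and density, temperature, measurement-noise model,
#' Q range, an optional planted perturbation potential, and the seed.  The
#' generators are deterministic given the seed, and every dataset carries
#' its ground truth so recovery tests score against what generated the
#' data.
#'
#' @param templates List of `mol_template`s (or a single template).
#' @param fractions Mixture fractions (default: single component).
#' @param n_molecules Number of molecules.
#' @param density Atom number density in atoms/Angstrom^3.
#' @param temperature_K Temperature.
#' @param noise_sigma Gaussian noise sigma added to the pseudo-experimental
#'   S(Q) (constant in Q).
#' @param q_min,q_max,dq Instrument Q range (defaults 0.6-25.0 1/Angstrom).
#' @param perturbation Optional planted perturbation as an `ep_state`.
#' @param forcefield The reference `forcefield`.
#' @param seed RNG seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(templates, fractions = NULL, n_molecules = 16,
                           density = 0.09, temperature_K = 300,
                           noise_sigma = 0.005, q_min = 0.6, q_max = 25.0,
                           dq = 0.02, perturbation = NULL,
                           forcefield = reference_forcefield(), seed = 1) {
  if (inherits(templates, "mol_template")) templates <- list(templates)
  if (is.null(fractions)) fractions <- rep(1 / length(templates),
                                           length(templates))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (density <= 0) stop("density must be positive")
  structure(list(templates = templates, fractions = fractions,
                 n_molecules = n_molecules, density = density,
                 temperature_K = temperature_K, noise_sigma = noise_sigma,
                 q_min = q_min, q_max = q_max, dq = dq,
                 perturbation = perturbation, forcefield = forcefield,
                 seed = seed),
            class = "synthetic_spec")
}

#' Single-site Lennard-Jones particle template
#'
#' A one-atom "molecule" used for reference-fluid validation of the Monte
#' Carlo engine and for planted-perturbation recovery problems.
#'
#' @param element Element symbol used for X-ray weighting (default "C").
#' @param type_key Force-field type (see [lj_fluid_forcefield()]).
#' @return A `mol_template` with a single atom.
#' @export
lj_site_template <- function(element = "C", type_key = "LJ_site") {
  mol_template("LJ", "site",
               data.frame(label = "A1", element = element,
                          type_key = type_key, x = 0, y = 0, z = 0,
                          stringsAsFactors = FALSE),
               matrix(character(0), ncol = 2), list())
}

#' @rdname lj_site_template
#' @param sigma,epsilon LJ parameters of the site.
#' @export
lj_fluid_forcefield <- function(sigma = 3.4, epsilon = 1.0) {
  forcefield(data.frame(type_key = "LJ_site", q = 0, sigma = sigma,
                        epsilon = epsilon))
}

#' Generate an equilibrated reference fluid
#'
#' Plain Metropolis NVT equilibration of the specified molecular box under
#' the reference potential (plus any planted perturbation), with
#' equilibration detected from the slope of the running mean of the total
#' energy, followed by collection of decorrelated snapshots.
#'
#' @param spec A `synthetic_spec`.
#' @param n_snapshots Snapshots returned.
#' @param stride Sweeps between snapshots.
#' @param max_sweeps Equilibration budget.
#' @param slope_tol Relative change of the windowed mean energy below which
#'   the system is considered equilibrated.
#' @param constraints Optional `constraint_set` enforced during generation.
#' @return A `reference_fluid`: list of snapshot `configs`, the final
#'   `config`, the `spec`, and the equilibration energy trace.
#' @export
generate_reference_fluid <- function(spec, n_snapshots = 20, stride = 5,
                                     max_sweeps = 400, slope_tol = 0.02,
                                     constraints = NULL) {
  set.seed(spec$seed)
  mix <- conformer_mixture(spec$templates, spec$fractions, spec$n_molecules)
  cfg <- build_configuration(mix, density = spec$density,
                             temperature_K = spec$temperature_K,
                             seed = spec$seed)
  ctx <- mc_context(cfg, spec$forcefield, constraints,
                    ep_state = spec$perturbation)
  energies <- numeric(0)
  check_every <- 10
  env <- ctx$env
  total_e <- function() {
    cpp_energy_total(ctx$xyz, env$type_idx, env$mol_idx, env$sigma,
                     env$epsilon, env$q, ctx$L, ctx$r_cut, ctx$shift,
                     env$mind * 0, env$intra_i, env$intra_j,
                     ctx$ep_tab, ctx$ep_dr)$energy
  }
  done <- FALSE
  for (blk in seq_len(max_sweeps %/% check_every)) {
    mc_sweeps(ctx, check_every, tune = TRUE)
    energies <- c(energies, total_e())
    if (length(energies) >= 6) {
      w <- 3
      m1 <- mean(head(tail(energies, 2 * w), w))
      m2 <- mean(tail(energies, w))
      sdv <- sd(tail(energies, 2 * w))
      if (abs(m2 - m1) <= slope_tol * max(sdv, 1e-9) * sqrt(w) ||
          abs(m2 - m1) <= 1e-8 * abs(m2)) {
        done <- TRUE
        break
      }
    }
  }
  snaps <- vector("list", n_snapshots)
  for (k in seq_len(n_snapshots)) {
    mc_sweeps(ctx, stride, tune = FALSE)
    snaps[[k]] <- ctx_config(ctx)
  }
  structure(list(configs = snaps, config = ctx_config(ctx), spec = spec,
                 energy_trace = energies, equilibrated = done),
            class = "reference_fluid")
}

#' @export
print.reference_fluid <- function(x, ...) {
  cat(sprintf("reference_fluid: %d snapshots of %d molecules (seed %s)\n",
              length(x$configs), x$spec$n_molecules, format(x$spec$seed)))
  invisible(x)
}

#' Pseudo-experimental S(Q) with ground truth
#'
#' Ensemble-averaged X-ray total structure factor of a reference fluid on
#' the instrument Q range, with additive Gaussian noise; the ground truth
#' (density, partials, conformer fractions, any planted perturbation) is
#' attached for recovery scoring.
#'
#' @param fluid A `reference_fluid` (or list of configurations plus a
#'   `spec` argument).
#' @param noise_sigma Noise level (default from the spec).
#' @param Q Q grid (default: the spec's instrument range).
#' @param seed Noise RNG seed (default: spec seed + 1).
#' @return A `pseudo_experiment`: the noisy `pattern`, the noise-free
#'   `pattern_clean`, and `truth`.
#' @export
make_pseudo_experiment <- function(fluid, noise_sigma = NULL, Q = NULL,
                                   seed = NULL) {
  if (!inherits(fluid, "reference_fluid"))
    stop("fluid must be a reference_fluid")
  if (!length(fluid$configs)) stop("empty ensemble")
  spec <- fluid$spec
  if (is.null(noise_sigma)) noise_sigma <- spec$noise_sigma
  if (is.null(Q)) Q <- seq(spec$q_min, spec$q_max, by = spec$dq)
  if (is.null(seed)) seed <- spec$seed + 1
  clean <- model_sq(fluid$configs, Q)
  clean$temperature_K <- spec$temperature_K
  set.seed(seed)
  noisy <- scattering_pattern(Q, clean$S + rnorm(length(Q), 0, noise_sigma),
                              sigma = rep(noise_sigma, length(Q)),
                              temperature_K = spec$temperature_K)
  truth <- list(density = atom_density(fluid$configs[[1]]),
                fractions = spec$fractions,
                conformers = vapply(spec$templates,
                                    function(t) t$conformer_id, ""),
                perturbation = spec$perturbation,
                pairset = compute_partial_gr(fluid$configs, dr = 0.02),
                seed = spec$seed)
  structure(list(pattern = noisy, pattern_clean = clean, truth = truth),
            class = "pseudo_experiment")
}

#' Toy P1 crystal with a planted contact
#'
#' Builds a single-cell P1 crystal containing an N-H fragment and a C=O
#' fragment whose shortest intermolecular N...O separation equals the
#' requested contact distance (the N-H points at the O, so the planted
#' N-H...O angle is 180 degrees).  A synthetic fixture for the crystal
#' comparators.
#'
#' @param contact_distance Planted N...O distance in Angstrom.
#' @param contact_angle Planted N-H...O angle in degrees (the H is tilted
#'   off the N-O axis to realise it; default 180 = linear).
#' @param cell_edge Cubic cell edge (Angstrom); must exceed the motif so
#'   image contacts stay longer than the planted one.
#' @return A `crystal_structure`.
#' @export
make_toy_crystal <- function(contact_distance = 3.0, contact_angle = 180,
                             cell_edge = 12) {
  if (contact_distance + 4 > cell_edge)
    stop("motif does not fit the cell: increase cell_edge")
  base <- c(2, 2, 2)
  hpos <- c(1.01, 0, 0)
  if (contact_angle < 180) {
    # tilt H off the N-O axis so that the N-H...O angle is as requested
    ang_at_h <- function(phi) {
      h <- 1.01 * c(cos(phi), sin(phi), 0)
      vHN <- -h; vHO <- c(contact_distance, 0, 0) - h
      acos(sum(vHN * vHO) / (sqrt(sum(vHN^2)) * sqrt(sum(vHO^2)))) * 180 / pi
    }
    phi <- optimise(function(p) (ang_at_h(p) - contact_angle)^2,
                    c(0, pi / 2))$minimum
    hpos <- 1.01 * c(cos(phi), sin(phi), 0)
  }
  xyz <- rbind(
    N1 = base,
    H1 = base + hpos,
    O1 = base + c(contact_distance, 0, 0),
    C1 = base + c(contact_distance + 1.22, 0, 0))
  atoms <- data.frame(label = rownames(xyz),
                      element = c("N", "H", "O", "C"),
                      fx = xyz[, 1] / cell_edge, fy = xyz[, 2] / cell_edge,
                      fz = xyz[, 3] / cell_edge, occ = 1,
                      stringsAsFactors = FALSE)
  structure(list(cell = c(a = cell_edge, b = cell_edge, c = cell_edge,
                          alpha = 90, beta = 90, gamma = 90),
                 ops = "x,y,z", atoms = atoms, Z = 1),
            class = "crystal_structure")
}

#' Write a crystal structure as CIF
#'
#' Minimal core-CIF writer (cell, P1-or-listed operators, atom sites);
#' round-trips through [parse_cif()].
#'
#' @param structure A `crystal_structure`.
#' @param path Output path.
#' @export
write_cif <- function(structure, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("data_epsrlite", con)
  nm <- c("a", "b", "c")
  for (i in 1:3)
    writeLines(sprintf("_cell_length_%s %.4f", nm[i], structure$cell[i]), con)
  ang <- c("alpha", "beta", "gamma")
  for (i in 1:3)
    writeLines(sprintf("_cell_angle_%s %.4f", ang[i], structure$cell[3 + i]), con)
  writeLines(c("loop_", "_space_group_symop_operation_xyz"), con)
  writeLines(sprintf("'%s'", structure$ops), con)
  writeLines(c("loop_", "_atom_site_label", "_atom_site_type_symbol",
               "_atom_site_fract_x", "_atom_site_fract_y",
               "_atom_site_fract_z", "_atom_site_occupancy"), con)
  writeLines(sprintf("%s %s %.6f %.6f %.6f %.4f", structure$atoms$label,
                     structure$atoms$element, structure$atoms$fx,
                     structure$atoms$fy, structure$atoms$fz,
                     structure$atoms$occ), con)
  invisible(path)
}
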