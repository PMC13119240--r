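#' Periodic-box configurations of semi-rigid molecules
#'
#' A `configuration` is a cubic periodic box of molecule instances: a flat
#' atom table (molecule index, label, element, type key), an N x 3
#' coordinate matrix in Angstrom (molecules stored whole; minimum-image
#' distances are used for interactions), the box edge, temperature and the
#' RNG seed that built it.
#'
#' @name configuration
NULL

# Included intramolecular nonbonded pairs for a template: all atom pairs at
# graph distance >= 3 bonds (1-2 and 1-3 excluded, 1-4 and beyond at full
# strength).  Returns a 2-column 1-based index matrix into the atom table.
template_included_pairs <- function(tpl) {
  labs <- tpl$atoms$label
  n <- length(labs)
  adj <- template_adjacency(tpl)
  idx <- function(l) match(l, labs)
  keep_i <- integer(0); keep_j <- integer(0)
  for (i in seq_len(n)) {
    # BFS graph distances from atom i
    dist <- rep(Inf, n); dist[i] <- 0
    queue <- i
    while (length(queue)) {
      nxt <- integer(0)
      for (v in queue) {
        nb <- idx(adj[[labs[v]]])
        new <- nb[dist[nb] > dist[v] + 1]
        dist[new] <- dist[v] + 1
        nxt <- c(nxt, new)
      }
      queue <- unique(nxt)
    }
    j <- which(dist >= 3 & seq_len(n) > i)
    keep_i <- c(keep_i, rep(i, length(j))); keep_j <- c(keep_j, j)
  }
  cbind(keep_i, keep_j)
}

#' Build a configuration
#'
#' Instantiates molecules in a cubic box, either on a jittered lattice
#' (robust at any density) or by random insertion with overlap rejection
#' (the classic low-density start that [compress_box()] then densifies).
#'
#' @param mixture A `conformer_mixture`, or a single `mol_template`
#'   (then `n_molecules` is required).
#' @param n_molecules Molecule count when `mixture` is a single template.
#' @param density Atom number density in atoms/Angstrom^3 (used if
#'   `box_edge` is missing).
#' @param box_edge Cubic box edge in Angstrom (overrides `density`).
#' @param temperature_K Temperature annotation used by the Monte Carlo engine.
#' @param seed RNG seed recorded in the configuration.
#' @param placement `"lattice"` or `"random"`.
#' @param min_sep Overlap-rejection minimum intermolecular atom distance
#'   for random insertion (Angstrom).
#' @param max_attempts Insertion attempts per molecule before giving up.
#' @return A `configuration` object.
#' @export
build_configuration <- function(mixture, n_molecules = NULL, density = NULL,
                                box_edge = NULL, temperature_K = 300,
                                seed = 1, placement = c("lattice", "random"),
                                min_sep = 1.5, max_attempts = 400) {
  placement <- match.arg(placement)
  if (inherits(mixture, "mol_template"))
    mixture <- conformer_mixture(list(mixture), 1, n_molecules)
  stopifnot(inherits(mixture, "conformer_mixture"))
  tpl_of_mol <- rep(seq_along(mixture$templates), mixture$counts)
  n_atoms <- sum(vapply(mixture$templates, function(t) nrow(t$atoms), 0L) *
                 mixture$counts)
  if (is.null(box_edge)) {
    if (is.null(density)) stop("supply density or box_edge")
    box_edge <- (n_atoms / density)^(1 / 3)
  }
  set.seed(seed)
  atoms <- list(); xyz <- list()
  nmol <- length(tpl_of_mol)
  ngrid <- ceiling(nmol^(1 / 3))
  cell <- box_edge / ngrid
  cells <- as.matrix(expand.grid(0:(ngrid - 1), 0:(ngrid - 1), 0:(ngrid - 1)))
  cells <- cells[sample.int(nrow(cells), nmol), , drop = FALSE]
  placed_xyz <- NULL; placed_mol <- integer(0)
  for (m in seq_len(nmol)) {
    tpl <- mixture$templates[[tpl_of_mol[m]]]
    base <- template_xyz(tpl)
    base <- sweep(base, 2, colMeans(base))
    # try orientations (and, for random placement, positions), keeping the
    # least-overlapping candidate; accept early once the separation target
    # is met.  At liquid-like densities the lattice route tolerates
    # moderately tight contacts - Monte Carlo relaxation removes them and
    # hard minima are enforced monotonically from the start.
    best <- NULL; best_d <- -Inf
    target <- if (placement == "lattice") 0.7 * min_sep else min_sep
    for (attempt in seq_len(max_attempts)) {
      R <- random_rotation_matrix()
      pos <- if (placement == "lattice")
        (cells[m, ] + 0.5) * cell + runif(3, -0.1, 0.1) * cell
      else runif(3, 0, box_edge)
      cand <- sweep(base %*% t(R), 2, pos, "+")
      dmin <- if (is.null(placed_xyz)) Inf else
        cpp_min_cross_dist(placed_xyz, cand, box_edge,
                           abort_below = max(best_d, 0))
      if (dmin > best_d) { best <- cand; best_d <- dmin }
      if (best_d >= target) break
    }
    if (best_d < 0.45 * min_sep)
      stop("insertion failure for molecule ", m, " after ", max_attempts,
           " attempts at this density")
    cand <- best
    placed_xyz <- rbind(placed_xyz, cand)
    placed_mol <- c(placed_mol, rep(m, nrow(cand)))
    atoms[[m]] <- data.frame(mol = m, template = tpl$name,
                             conformer = tpl$conformer_id,
                             label = tpl$atoms$label,
                             element = tpl$atoms$element,
                             type_key = tpl$atoms$type_key,
                             stringsAsFactors = FALSE)
  }
  structure(list(
    box_edge = box_edge, temperature_K = temperature_K, rng_seed = seed,
    templates = mixture$templates, template_of_mol = tpl_of_mol,
    atoms = do.call(rbind, atoms), xyz = placed_xyz
  ), class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d molecules, %d atoms, box %.2f A, %.3f atoms/A^3, T = %g K (seed %s)\n",
              length(x$template_of_mol), nrow(x$xyz), x$box_edge,
              atom_density(x), x$temperature_K, format(x$rng_seed)))
  invisible(x)
}

#' Atom number density of a configuration
#'
#' @param config A `configuration`.
#' @return Density in atoms/Angstrom^3.
#' @export
atom_density <- function(config) nrow(config$xyz) / config$box_edge^3

#' Constraint set for the Monte Carlo engine
#'
#' Hard minimum intermolecular distances by force-field type pair, plus a
#' global floor preventing unphysical overlap of any intermolecular pair.
#'
#' @param pairs `data.frame(a, b, dmin)` of type-key pairs and their minimum
#'   distances in Angstrom (e.g. the 2.9 Angstrom NH...O constraint).
#' @param floor Global intermolecular minimum distance (Angstrom).
#' @param translate,rotate,group_rotate Move sizes: maximum translation
#'   (Angstrom), whole-molecule rotation and group rotation (degrees).
#' @return A `constraint_set`.
#' @export
constraint_set <- function(pairs = NULL, floor = 1.0, translate = 0.2,
                           rotate = 10, group_rotate = 15) {
  if (!is.null(pairs) && any(pairs$dmin <= 0))
    stop("minimum distances must be positive")
  structure(list(pairs = pairs, floor = floor,
                 moves = list(translate = translate, rotate = rotate,
                              group_rotate = group_rotate)),
            class = "constraint_set")
}

#' Default NH...O constraint set
#'
#' The crystal-structure-motivated hard minimum of 2.9 Angstrom between the
#' amino (donor) nitrogen and every hydrogen-bond-accepting oxygen class.
#'
#' @param dmin Minimum N...O distance in Angstrom.
#' @param ... Passed to [constraint_set()].
#' @return A `constraint_set`.
#' @export
nh_o_constraints <- function(dmin = 2.9, ...) {
  constraint_set(pairs = data.frame(
    a = "N_NHR", b = c("O_carbonyl", "O_nitro", "O_ether"),
    dmin = dmin, stringsAsFactors = FALSE), ...)
}

# Precomputed kernel environment: 0-based type/molecule indices, combined
# sigma/epsilon matrices, per-atom charges, minimum-distance matrix and the
# included intramolecular pair list (0-based).
config_env <- function(config, ff, constraints = NULL) {
  types <- sort(unique(config$atoms$type_key))
  tmap <- ff_pair_matrices(ff, types)
  type_idx <- match(config$atoms$type_key, types) - 1L
  q <- numeric(nrow(config$atoms))
  for (ti in seq_along(config$templates)) {
    tpl <- config$templates[[ti]]
    qt <- template_charges(tpl, ff)
    sel <- which(config$template_of_mol[config$atoms$mol] == ti)
    q[sel] <- rep(as.numeric(qt), length.out = length(sel))
  }
  mind <- matrix(if (is.null(constraints)) 0 else constraints$floor,
                 length(types), length(types),
                 dimnames = list(types, types))
  if (!is.null(constraints) && !is.null(constraints$pairs)) {
    for (k in seq_len(nrow(constraints$pairs))) {
      a <- constraints$pairs$a[k]; b <- constraints$pairs$b[k]
      if (a %in% types && b %in% types)
        mind[a, b] <- mind[b, a] <- constraints$pairs$dmin[k]
    }
  }
  intra_i <- integer(0); intra_j <- integer(0)
  offset <- 0L
  for (m in seq_along(config$template_of_mol)) {
    tpl <- config$templates[[config$template_of_mol[m]]]
    ip <- template_included_pairs(tpl)
    intra_i <- c(intra_i, ip[, 1] + offset - 1L)
    intra_j <- c(intra_j, ip[, 2] + offset - 1L)
    offset <- offset + nrow(tpl$atoms)
  }
  list(types = types, type_idx = type_idx, mol_idx = config$atoms$mol - 1L,
       sigma = tmap$sigma, epsilon = tmap$epsilon, q = q, mind = mind,
       intra_i = intra_i, intra_j = intra_j)
}

#' Reference Lennard-Jones + Coulomb energy of a configuration
#'
#' Total nonbonded reference energy: intermolecular pairs plus included
#' intramolecular pairs (1-4 and beyond), with minimum-image distances,
#' Lorentz-Berthelot combining, and Coulomb term
#' \eqn{k_c q_a q_b / r} (k_c = 1389.35 kJ Angstrom / mol / e^2).
#'
#' @param config A `configuration`.
#' @param ff A `forcefield`.
#' @param r_cut Spherical cutoff in Angstrom (default none).
#' @param shift Shift the Coulomb term to zero at `r_cut`.
#' @return Total energy in kJ/mol.
#' @export
lj_coulomb_energy <- function(config, ff, r_cut = Inf, shift = FALSE) {
  env <- config_env(config, ff)
  res <- cpp_energy_total(config$xyz, env$type_idx, env$mol_idx, env$sigma,
                          env$epsilon, env$q, config$box_edge, r_cut, shift,
                          env$mind * 0, env$intra_i, env$intra_j,
                          matrix(0, 0, 0), 0.02)
  res$energy
}

#' Write a configuration as extended XYZ
#'
#' @param config A `configuration`.
#' @param path Output path.
#' @export
write_config_xyz <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(config$xyz)), con)
  writeLines(sprintf('Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" Properties=species:S:1:pos:R:3:mol:I:1 seed=%s T=%g',
                     config$box_edge, config$box_edge, config$box_edge,
                     format(config$rng_seed), config$temperature_K), con)
  writeLines(sprintf("%s %.8f %.8f %.8f %d", config$atoms$element,
                     config$xyz[, 1], config$xyz[, 2], config$xyz[, 3],
                     config$atoms$mol), con)
  invisible(path)
}
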