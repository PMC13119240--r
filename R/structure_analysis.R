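#' Running coordination number
#'
#' \eqn{n_{ab}(r) = 4\pi\rho c_b \int_0^r g_{ab}(r') r'^2 dr'}: the average
#' number of type-b atoms within r of a type-a atom.  Computed as the exact
#' cumulative shell sum of the histogram estimator, so it agrees with a
#' direct neighbour count on the same configurations.
#'
#' @param pairset A `pair_function_set`.
#' @param a Central type (or element, if the set was built by element).
#' @param b Neighbour type.
#' @param threshold Optional query level; the first r where n crosses it is
#'   reported by linear interpolation.
#' @return A `coordination_curve`: r, n, the pair, and `crossing`.
#' @export
running_coordination <- function(pairset, a, b, threshold = NULL) {
  key <- paste(a, b, sep = ":")
  key2 <- paste(b, a, sep = ":")
  g <- pairset$g[[key]]
  if (is.null(g)) g <- pairset$g[[key2]]
  if (is.null(g)) stop("no partial for pair ", a, ":", b)
  r <- pairset$r; dr <- pairset$dr
  edges <- seq(0, length(r) * dr, by = dr)
  shell <- 4 / 3 * pi * diff(edges^3)
  n <- cumsum(pairset$rho * pairset$c[[b]] * g * shell)
  crossing <- NA_real_
  if (!is.null(threshold)) {
    i <- which(n >= threshold)[1]
    if (!is.na(i) && i > 1)
      crossing <- approx(n[(i - 1):i], r[(i - 1):i], xout = threshold)$y
    else if (!is.na(i)) crossing <- r[i]
  }
  structure(list(r = r, n = n, a = a, b = b, threshold = threshold,
                 crossing = crossing), class = "coordination_curve")
}

#' @export
print.coordination_curve <- function(x, ...) {
  cat(sprintf("coordination_curve %s->%s: n(%.2f A) = %.3f%s\n", x$a, x$b,
              max(x$r), tail(x$n, 1),
              if (!is.na(x$crossing))
                sprintf("; n = %g at r = %.2f A", x$threshold, x$crossing)
              else ""))
  invisible(x)
}

#' Hydrogen-bond criteria
#'
#' Geometric hydrogen-bond definition: donor N-H (by force-field type),
#' acceptor oxygen types, a maximum N...O distance and a minimum N-H...O
#' angle (at the hydrogen).  The distance/angle thresholds are conventions
#' and are echoed in every census output.
#'
#' @param d_max Maximum donor-acceptor N...O distance (Angstrom).
#' @param angle_min Minimum N-H...O angle (degrees, 180 = linear).
#' @param donor_N,donor_H Type keys of the donor nitrogen and its hydrogen.
#' @param acceptor_types Type keys accepted as acceptors.
#' @return An `hbond_criteria` object.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 120, donor_N = "N_NHR",
                           donor_H = "H_NHR",
                           acceptor_types = c("O_carbonyl", "O_nitro")) {
  if (d_max <= 0) stop("d_max must be positive")
  if (angle_min < 0 || angle_min > 180) stop("angle_min must be in [0, 180]")
  structure(list(d_max = d_max, angle_min = angle_min, donor_N = donor_N,
                 donor_H = donor_H, acceptor_types = acceptor_types),
            class = "hbond_criteria")
}

# Acceptor class of each atom: nitro oxygens, PVP carbonyls, or (drug)
# ester carbonyls / other oxygens.
acceptor_class <- function(atoms) {
  cls <- rep(NA_character_, nrow(atoms))
  cls[atoms$type_key == "O_nitro"] <- "nitro"
  cls[atoms$type_key == "O_carbonyl" & atoms$template == "PVP"] <- "pvp"
  cls[atoms$type_key == "O_carbonyl" & atoms$template != "PVP"] <- "ester"
  cls[atoms$type_key == "O_ether"] <- "ether"
  cls
}

.mimg_vec <- function(d, L) d - L * round(d / L)

#' Hydrogen-bond census of a configuration
#'
#' Enumerates intermolecular donor-acceptor contacts satisfying the
#' distance and angle criteria, with minimum-image geometry, and summarizes
#' them by acceptor class (drug ester carbonyl, nitro, PVP carbonyl).
#'
#' @param config A `configuration`.
#' @param criteria An `hbond_criteria`.
#' @return An `hbond_census`: `bonds` data.frame (donor molecule, acceptor
#'   molecule and label, class, d, angle), `per_donor` mean bonds per
#'   donor, `by_class` counts, and the criteria used.
#' @export
hbond_census <- function(config, criteria = hbond_criteria()) {
  at <- config$atoms
  L <- config$box_edge
  don <- which(at$type_key == criteria$donor_N)
  acc <- which(at$type_key %in% criteria$acceptor_types)
  if (!length(don) && !any(at$type_key == criteria$donor_N))
    don <- integer(0)
  cls <- acceptor_class(at)
  bonds <- list()
  for (i in don) {
    hi <- which(at$mol == at$mol[i] & at$type_key == criteria$donor_H)
    if (!length(hi)) stop("donor nitrogen without donor hydrogen in molecule ",
                          at$mol[i])
    hi <- hi[1]
    aj <- acc[at$mol[acc] != at$mol[i]]
    if (!length(aj)) next
    dNO <- sqrt(rowSums(.mimg_vec(
      sweep(config$xyz[aj, , drop = FALSE], 2, config$xyz[i, ]), L)^2))
    sel <- which(dNO <= criteria$d_max)
    for (k in sel) {
      j <- aj[k]
      vHN <- .mimg_vec(config$xyz[i, ] - config$xyz[hi, ], L)
      vHO <- .mimg_vec(config$xyz[j, ] - config$xyz[hi, ], L)
      ang <- acos(max(-1, min(1, sum(vHN * vHO) /
                                (vnorm(vHN) * vnorm(vHO))))) * 180 / pi
      if (ang >= criteria$angle_min)
        bonds[[length(bonds) + 1L]] <- data.frame(
          donor_mol = at$mol[i], acceptor_mol = at$mol[j],
          acceptor = at$label[j], class = cls[j], d = dNO[k], angle = ang)
    }
  }
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    data.frame(donor_mol = integer(0), acceptor_mol = integer(0),
               acceptor = character(0), class = character(0),
               d = numeric(0), angle = numeric(0))
  structure(list(bonds = bonds,
                 per_donor = if (length(don)) nrow(bonds) / length(don) else NA,
                 by_class = table(bonds$class), n_donors = length(don),
                 criteria = criteria),
            class = "hbond_census")
}

#' @export
print.hbond_census <- function(x, ...) {
  cat(sprintf("hbond_census: %d bonds over %d donors (%.2f per donor); d <= %.2f A, angle >= %g deg\n",
              nrow(x$bonds), x$n_donors, x$per_donor, x$criteria$d_max,
              x$criteria$angle_min))
  if (length(x$by_class)) print(x$by_class)
  invisible(x)
}

#' Drug-drug versus drug-polymer bonding preference
#'
#' Class-resolved running coordination of acceptor oxygens around the drug
#' donor nitrogens in a drug-polymer mixture: n(r) to oxygens on other
#' drug molecules versus oxygens on PVP monomers, evaluated by direct
#' minimum-image neighbour counting.
#'
#' @param config A mixture `configuration`.
#' @param r_cut Evaluation radius in Angstrom.
#' @param donor_type Donor nitrogen type key.
#' @param drug_classes Acceptor classes counted as drug-drug (default
#'   ester carbonyl plus nitro oxygens).
#' @param r_grid Grid for the exported class curves.
#' @return List: `n_drug`, `n_pvp` (coordination at `r_cut`), `ratio`
#'   (drug/polymer; `Inf` flagged "polymer-only" when no drug acceptor
#'   oxygen is coordinated), and `curves`.
#' @export
drug_polymer_preference <- function(config, r_cut = 5,
                                    donor_type = "N_NHR",
                                    drug_classes = c("ester", "nitro"),
                                    r_grid = seq(0.1, 8, by = 0.1)) {
  at <- config$atoms
  cls <- acceptor_class(at)
  centers <- which(at$type_key == donor_type) - 1L
  if (!length(centers)) stop("no donor atoms of type ", donor_type)
  sets <- list(drug = which(cls %in% drug_classes & at$template != "PVP") - 1L,
               pvp = which(cls == "pvp") - 1L)
  if (!length(sets$pvp)) stop("acceptor class absent: no PVP carbonyls in box")
  r_grid <- sort(unique(c(r_grid, r_cut)))
  curves <- data.frame(r = r_grid)
  for (nm in names(sets)) {
    curves[[nm]] <- if (length(sets[[nm]]))
      cpp_neighbor_counts(config$xyz, at$mol, centers, sets[[nm]],
                          config$box_edge, r_grid)
    else 0
  }
  n_drug <- curves$drug[match(r_cut, r_grid)]
  n_pvp <- curves$pvp[match(r_cut, r_grid)]
  ratio <- if (n_pvp > 0 && n_drug == 0) {
    structure(Inf, label = "polymer-only")
  } else n_drug / n_pvp
  list(n_drug = n_drug, n_pvp = n_pvp, ratio = ratio, r_cut = r_cut,
       curves = curves)
}

#' Minimum intermolecular distance in a configuration
#'
#' Audit helper: the smallest minimum-image distance between atoms on
#' different molecules, optionally restricted to two type keys (e.g. the
#' donor nitrogen and an acceptor oxygen, to verify a hard constraint).
#'
#' @param config A `configuration`.
#' @param type_a,type_b Optional type keys restricting each side.
#' @return Distance in Angstrom (Inf if no qualifying pair).
#' @export
min_intermolecular_distance <- function(config, type_a = NULL, type_b = NULL) {
  if (is.null(type_a) && is.null(type_b))
    return(cpp_min_intermol_dist(config$xyz, config$atoms$mol,
                                 config$box_edge))
  ia <- if (is.null(type_a)) seq_len(nrow(config$xyz)) else
    which(config$atoms$type_key == type_a)
  ib <- if (is.null(type_b)) seq_len(nrow(config$xyz)) else
    which(config$atoms$type_key == type_b)
  best <- Inf
  for (i in ia) {
    j <- ib[config$atoms$mol[ib] != config$atoms$mol[i]]
    if (!length(j)) next
    d <- sqrt(rowSums(.mimg_vec(
      sweep(config$xyz[j, , drop = FALSE], 2, config$xyz[i, ]),
      config$box_edge)^2))
    best <- min(best, d)
  }
  best
}

#' Convert between number density and mass density
#'
#' \eqn{\rho_m = (n / n_{atoms}) M / N_A \times 10^{24}} g/cm^3 for a
#' number density n in atoms/Angstrom^3 of molecules with formula-derived
#' molar mass M and atom count.
#'
#' @param n_atoms_per_A3 Atom number density (atoms/Angstrom^3).
#' @param formula Molecular formula, e.g. `"C17H18N2O6"`.
#' @return Mass density in g/cm^3.
#' @export
density_convert <- function(n_atoms_per_A3, formula) {
  if (any(n_atoms_per_A3 < 0)) stop("density must be non-negative")
  counts <- parse_formula(formula)
  n_atoms_per_A3 / sum(counts) * molecular_mass(formula) / .NA_CONST * 1e24
}

#' @rdname density_convert
#' @param mass_density_g_cm3 Mass density in g/cm^3.
#' @return For the inverse, atom number density in atoms/Angstrom^3.
#' @export
density_convert_inverse <- function(mass_density_g_cm3, formula) {
  counts <- parse_formula(formula)
  mass_density_g_cm3 * sum(counts) / molecular_mass(formula) * .NA_CONST / 1e24
}
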