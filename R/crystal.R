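#' Crystal structures from CIF
#'
#' A minimal core-CIF reader covering what the crystal comparators need:
#' cell parameters, symmetry operators (either the
#' `_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`
#' dialect), and the atom-site loop (label, type symbol, fractional
#' coordinates, occupancy).  Duplicate disorder sites sharing a label are
#' resolved to the highest occupancy.
#'
#' @param file Path to a CIF file.
#' @return A `crystal_structure`: `cell` (a, b, c, alpha, beta, gamma),
#'   `ops` (operator strings), `atoms` (label, element, fx, fy, fz, occ),
#'   and `Z` if present.
#' @export
parse_cif <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  num <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    v <- sub(paste0("^", key, "\\s+"), "", ln[1])
    as.numeric(sub("\\(.*\\)", "", v))
  }
  cell <- c(a = num("_cell_length_a"), b = num("_cell_length_b"),
            c = num("_cell_length_c"), alpha = num("_cell_angle_alpha"),
            beta = num("_cell_angle_beta"), gamma = num("_cell_angle_gamma"))
  if (anyNA(cell[1:3])) stop("CIF lacks cell parameters")
  cell[4:6][is.na(cell[4:6])] <- 90
  Z <- num("_cell_formula_units_Z")
  # locate loops
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    if (lines[i] == "loop_") {
      hdr <- character(0)
      j <- i + 1
      while (j <= length(lines) && startsWith(lines[j], "_")) {
        hdr <- c(hdr, strsplit(lines[j], "\\s+")[[1]][1])
        j <- j + 1
      }
      rows <- list()
      while (j <= length(lines) && nzchar(lines[j]) &&
             !startsWith(lines[j], "_") && lines[j] != "loop_" &&
             !startsWith(lines[j], "data_")) {
        toks <- regmatches(lines[j],
                           gregexpr("'[^']*'|\"[^\"]*\"|\\S+", lines[j]))[[1]]
        toks <- gsub("^['\"]|['\"]$", "", toks)
        rows[[length(rows) + 1L]] <- toks
        j <- j + 1
      }
      loops[[length(loops) + 1L]] <- list(hdr = hdr, rows = rows)
      i <- j
    } else i <- i + 1
  }
  find_loop <- function(tag) {
    for (lp in loops) if (any(grepl(tag, lp$hdr))) return(lp)
    NULL
  }
  symloop <- find_loop("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz")
  ops <- "x,y,z"
  if (!is.null(symloop)) {
    col <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
                symloop$hdr)
    ops <- vapply(symloop$rows, function(r) r[col], "")
    ops <- tolower(gsub("\\s", "", ops))
  }
  atloop <- find_loop("_atom_site_fract_x")
  if (is.null(atloop)) stop("CIF lacks an atom-site loop")
  col_of <- function(key) match(key, atloop$hdr)
  lab <- col_of("_atom_site_label")
  typ <- col_of("_atom_site_type_symbol")
  fx <- col_of("_atom_site_fract_x"); fy <- col_of("_atom_site_fract_y")
  fz <- col_of("_atom_site_fract_z"); oc <- col_of("_atom_site_occupancy")
  pv <- function(v) as.numeric(sub("\\(.*\\)", "", v))
  at <- do.call(rbind, lapply(atloop$rows, function(r) {
    label <- if (!is.na(lab)) r[lab] else r[typ]
    el <- if (!is.na(typ)) r[typ] else gsub("[0-9'\"]*$", "", label)
    el <- sub("^([A-Z][a-z]?).*", "\\1", el)
    data.frame(label = label, element = el, fx = pv(r[fx]), fy = pv(r[fy]),
               fz = pv(r[fz]),
               occ = if (!is.na(oc)) pv(r[oc]) else 1,
               stringsAsFactors = FALSE)
  }))
  # resolve duplicate disorder sites by occupancy
  at <- at[order(at$label, -at$occ), ]
  at <- at[!duplicated(at$label), ]
  rownames(at) <- NULL
  structure(list(cell = cell, ops = unique(ops), atoms = at, Z = Z),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal_structure: a=%.3f b=%.3f c=%.3f A, angles %.1f/%.1f/%.1f; %d ops, %d sites\n",
              x$cell[1], x$cell[2], x$cell[3], x$cell[4], x$cell[5], x$cell[6],
              length(x$ops), nrow(x$atoms)))
  invisible(x)
}

# Parse a symmetry operator coordinate-triplet string into an affine map
# (3x3 matrix + translation), by evaluating it at the basis vectors.
parse_symop <- function(op) {
  parts <- strsplit(gsub("\\s", "", op), ",")[[1]]
  if (length(parts) != 3) stop("unparseable symmetry operator: ", op)
  evalat <- function(x, y, z) {
    env <- list2env(list(x = x, y = y, z = z))
    vapply(parts, function(p) {
      p <- gsub("([0-9]+)/([0-9]+)", "(\\1/\\2)", p)
      as.numeric(eval(parse(text = p), env))
    }, 0)
  }
  t0 <- evalat(0, 0, 0)
  M <- cbind(evalat(1, 0, 0) - t0, evalat(0, 1, 0) - t0, evalat(0, 0, 1) - t0)
  list(M = M, t = t0)
}

# Cell matrix: columns are the cell vectors in Cartesian Angstrom.
cell_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(ga), b * sin(ga), 0)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- sqrt(max(cc^2 - cx^2 - cy^2, 0))
  cbind(v1, v2, c(cx, cy, cz))
}

cell_volume <- function(cell) abs(det(cell_matrix(cell)))

#' Expand symmetry to a Cartesian supercell
#'
#' Applies every symmetry operator to the asymmetric unit, wraps into the
#' unit cell, merges duplicates (1e-3 fractional tolerance), replicates
#' over the requested supercell, converts to Cartesian coordinates, and
#' regroups atoms into molecules by covalent connectivity (covalent-radius
#' sum x 1.2).
#'
#' @param structure A `crystal_structure`.
#' @param supercell Integer triple (na, nb, nc).
#' @return List: `xyz` (Cartesian), `atoms` (label, element, molecule id),
#'   `cell_matrix` of the supercell, and `n_unit` (atoms per unit cell).
#' @export
expand_symmetry <- function(structure, supercell = c(1, 1, 1)) {
  at <- structure$atoms
  frac <- as.matrix(at[, c("fx", "fy", "fz")])
  allf <- list(); lab <- character(0); el <- character(0)
  for (op in structure$ops) {
    so <- parse_symop(op)
    f2 <- t(so$M %*% t(frac) + so$t)
    f2 <- f2 - floor(f2)
    allf[[length(allf) + 1L]] <- f2
    lab <- c(lab, at$label); el <- c(el, at$element)
  }
  f <- do.call(rbind, allf)
  # merge duplicates with wrap-aware tolerance
  key <- apply(round(f, 3) %% 1, 1, paste, collapse = ",")
  keep <- !duplicated(key)
  f <- f[keep, , drop = FALSE]; lab <- lab[keep]; el <- el[keep]
  n_unit <- nrow(f)
  shifts <- as.matrix(expand.grid(0:(supercell[1] - 1), 0:(supercell[2] - 1),
                                  0:(supercell[3] - 1)))
  bigf <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s)
    sweep(f, 2, shifts[s, ], "+")))
  lab <- rep(lab, nrow(shifts)); el <- rep(el, nrow(shifts))
  M <- cell_matrix(structure$cell)
  xyz <- t(M %*% t(bigf))
  # molecule regrouping by covalent connectivity
  rc <- covalent_radius(el)
  n <- nrow(xyz)
  molid <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (molid[i] > 0) next
    cur <- cur + 1L
    queue <- i; molid[i] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      d <- sqrt(colSums((t(xyz) - xyz[v, ])^2))
      nb <- which(molid == 0 & d < 1.2 * (rc[v] + rc) & d > 1e-6)
      molid[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  list(xyz = xyz, atoms = data.frame(label = lab, element = el, mol = molid,
                                     stringsAsFactors = FALSE),
       cell_matrix = M %*% diag(supercell), n_unit = n_unit)
}

#' Crystal mass density
#'
#' Z M / (N_A V): the expanded unit-cell contents (occupancy-resolved)
#' divided by the cell volume.
#'
#' @param structure A `crystal_structure`.
#' @return Density in g/cm^3.
#' @export
crystal_density <- function(structure) {
  ex <- expand_symmetry(structure, c(1, 1, 1))
  m_cell <- sum(atomic_mass(ex$atoms$element))
  m_cell / (.NA_CONST * cell_volume(structure$cell) * 1e-24)
}

# Donor/acceptor atom pickers for crystal contact searches: by element plus
# an optional label regular expression.
.pick <- function(atoms, element, label_regex = NULL) {
  sel <- atoms$element == element
  if (!is.null(label_regex)) sel <- sel & grepl(label_regex, atoms$label)
  which(sel)
}

#' Intermolecular donor-acceptor contacts in a crystal
#'
#' Expands a supercell, finds the unique shortest intermolecular N...O
#' (or as specified) contacts around the central cell's donors, and
#' reports distances and N-H...O angles.  If the structure lacks
#' hydrogens, the donor hydrogen is placed by riding geometry along the
#' shortest-contact direction and the output flags the placement.
#'
#' @param structure A `crystal_structure`.
#' @param donor_element,donor_label Donor atom selection (element +
#'   optional label regex).
#' @param acceptor_element,acceptor_label Acceptor selection.
#' @param d_window Distance window (Angstrom) for reported contacts.
#' @param supercell Supercell used for the search (must be large enough
#'   that no contact in the window crosses the boundary; checked by a
#'   boundary-sensitivity test against a larger supercell).
#' @return data.frame of unique contacts sorted by distance:
#'   donor label, acceptor label, d, angle (NA if no H), h_placed flag.
#' @export
crystal_contacts <- function(structure, donor_element = "N",
                             donor_label = NULL, acceptor_element = "O",
                             acceptor_label = NULL, d_window = c(2.0, 4.0),
                             supercell = c(3, 3, 3)) {
  search <- function(sc) {
    ex <- expand_symmetry(structure, sc)
    at <- ex$atoms
    # donors in the central cell only
    Minv <- solve(ex$cell_matrix)
    fr <- t(Minv %*% t(ex$xyz))
    centre <- floor(sc / 2) / sc
    don <- .pick(at, donor_element, donor_label)
    incentre <- apply(fr[don, , drop = FALSE], 1, function(p)
      all(p >= centre - 1e-6 & p < centre + 1 / sc + 1e-6))
    don <- don[incentre]
    acc <- .pick(at, acceptor_element, acceptor_label)
    hyd <- which(at$element == "H")
    out <- list()
    for (i in don) {
      aj <- acc[at$mol[acc] != at$mol[i]]
      if (!length(aj)) next
      d <- sqrt(colSums((t(ex$xyz[aj, , drop = FALSE]) - ex$xyz[i, ])^2))
      sel <- which(d >= d_window[1] & d <= d_window[2])
      for (k in sel) {
        j <- aj[k]
        # donor hydrogen: nearest H bonded to the donor, else riding
        h_placed <- FALSE
        if (length(hyd)) {
          dh <- sqrt(colSums((t(ex$xyz[hyd, , drop = FALSE]) - ex$xyz[i, ])^2))
          hb <- hyd[dh < 1.25]
        } else hb <- integer(0)
        if (length(hb)) {
          dh2 <- sqrt(colSums((t(ex$xyz[hb, , drop = FALSE]) - ex$xyz[j, ])^2))
          hpos <- ex$xyz[hb[which.min(dh2)], ]
        } else {
          hpos <- ex$xyz[i, ] + 1.01 * unit(ex$xyz[j, ] - ex$xyz[i, ])
          h_placed <- TRUE
        }
        vHN <- ex$xyz[i, ] - hpos; vHO <- ex$xyz[j, ] - hpos
        ang <- if (vnorm(vHO) < 1e-6) 180 else
          acos(max(-1, min(1, sum(vHN * vHO) / (vnorm(vHN) * vnorm(vHO))))) *
            180 / pi
        out[[length(out) + 1L]] <- data.frame(
          donor = at$label[i], acceptor = at$label[j], d = d[k], angle = ang,
          h_placed = h_placed, stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) return(data.frame(donor = character(0),
                                        acceptor = character(0),
                                        d = numeric(0), angle = numeric(0),
                                        h_placed = logical(0)))
    res <- do.call(rbind, out)
    # unique symmetry-independent contacts: same labels + distance
    res <- res[!duplicated(round(res$d, 3)), , drop = FALSE]
    res[order(res$d), , drop = FALSE]
  }
  res <- search(supercell)
  chk <- search(supercell + 2)
  if (nrow(res) != nrow(chk) ||
      (nrow(res) && max(abs(res$d - chk$d)) > 1e-6))
    stop("supercell too small: contact list changes when it is enlarged")
  rownames(res) <- NULL
  res
}

#' Running coordination number in a crystal
#'
#' Exact neighbour-count step curve of element-b atoms around the central
#' cell's element-a atoms, optionally Gaussian-broadened for comparison
#' with liquid-state curves.
#'
#' @param structure A `crystal_structure`.
#' @param a,b Central and neighbour element symbols.
#' @param a_label,b_label Optional label regexes refining the selection.
#' @param broadening Gaussian sigma (Angstrom); 0 = sharp steps.
#' @param r_grid Output grid.
#' @param supercell Supercell for the search.
#' @return A `coordination_curve`.
#' @export
crystal_running_coordination <- function(structure, a, b, a_label = NULL,
                                         b_label = NULL, broadening = 0,
                                         r_grid = seq(0.05, 8, by = 0.05),
                                         supercell = c(3, 3, 3)) {
  ex <- expand_symmetry(structure, supercell)
  at <- ex$atoms
  Minv <- solve(ex$cell_matrix)
  fr <- t(Minv %*% t(ex$xyz))
  centre <- floor(supercell / 2) / supercell
  ca <- .pick(at, a, a_label)
  incentre <- apply(fr[ca, , drop = FALSE], 1, function(p)
    all(p >= centre - 1e-6 & p < centre + 1 / supercell + 1e-6))
  ca <- ca[incentre]
  cb <- .pick(at, b, b_label)
  if (!length(ca) || !length(cb)) stop("empty selection for ", a, " or ", b)
  dists <- unlist(lapply(ca, function(i) {
    cb2 <- cb[at$mol[cb] != at$mol[i]]
    sqrt(colSums((t(ex$xyz[cb2, , drop = FALSE]) - ex$xyz[i, ])^2))
  }))
  n <- if (broadening > 0) {
    vapply(r_grid, function(r)
      sum(stats::pnorm(r, dists, broadening)), 0) / length(ca)
  } else {
    vapply(r_grid, function(r) sum(dists <= r), 0) / length(ca)
  }
  structure(list(r = r_grid, n = n, a = a, b = b, threshold = NULL,
                 crossing = NA_real_), class = "coordination_curve")
}

# Build a mol_template from the first molecule of an expanded crystal.
template_from_crystal <- function(structure, type_map = NULL, name = "MOL",
                                  conformer_id = "x") {
  ex <- expand_symmetry(structure, c(1, 1, 1))
  sel <- ex$atoms$mol == 1
  at <- ex$atoms[sel, , drop = FALSE]
  xyz <- ex$xyz[sel, , drop = FALSE]
  rc <- covalent_radius(at$element)
  # bonds by covalent radii
  bonds <- list()
  for (i in seq_len(nrow(at) - 1)) for (j in (i + 1):nrow(at)) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 1.2 * (rc[i] + rc[j])) bonds[[length(bonds) + 1L]] <-
        c(at$label[i], at$label[j])
  }
  # riding hydrogens on N and C missing a full valence are NOT inferred
  # automatically here beyond the donor N-H; crystal sources for the
  # bundled drugs include hydrogens.
  tk <- if (is.null(type_map)) paste0("default_", at$element) else {
    out <- type_map[at$label]
    out[is.na(out)] <- paste0("default_", at$element[is.na(out)])
    out
  }
  atoms <- data.frame(label = at$label, element = at$element, type_key = tk,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  mol_template(name, conformer_id, atoms, do.call(rbind, bonds), list())
}
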