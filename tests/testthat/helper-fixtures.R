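# Shared fixtures and independent oracles, built in code at test time.

# Two-site configuration: one atom per "molecule", at given separation,
# with a chosen force-field type, in a large cubic box.
two_atom_config <- function(r, type_key = "LJ_site", element = "C",
                            box_edge = 50, temperature_K = 300) {
  tpl <- mol_template("X", "x",
                      data.frame(label = "A1", element = element,
                                 type_key = type_key, x = 0, y = 0, z = 0,
                                 stringsAsFactors = FALSE),
                      matrix(character(0), ncol = 2), list())
  cfg <- build_configuration(tpl, n_molecules = 2, box_edge = box_edge,
                             temperature_K = temperature_K, seed = 1,
                             min_sep = 0)
  cfg$xyz <- rbind(c(1, 1, 1), c(1 + r, 1, 1))
  cfg
}

# O(N^2) minimum-image pair histogram in plain R: the brute-force oracle.
brute_pair_hist <- function(config, r_max, dr, intra = FALSE, inter = TRUE,
                            by = "type") {
  key <- if (by == "type") config$atoms$type_key else config$atoms$element
  types <- sort(unique(key))
  np <- length(types) * (length(types) + 1) / 2
  nb <- ceiling(r_max / dr)
  H <- matrix(0L, nb, np)
  pidx <- function(a, b) {
    if (a > b) { t <- a; a <- b; b <- t }
    (a - 1) * length(types) - (a - 1) * a / 2 + (b - a) + 1
  }
  n <- nrow(config$xyz)
  L <- config$box_edge
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- config$atoms$mol[i] == config$atoms$mol[j]
    if (same && !intra) next
    if (!same && !inter) next
    d <- config$xyz[i, ] - config$xyz[j, ]
    d <- d - L * round(d / L)
    r <- sqrt(sum(d^2))
    if (r >= r_max) next
    b <- floor(r / dr) + 1
    if (b > nb) next
    k <- pidx(match(key[i], types), match(key[j], types))
    H[b, k] <- H[b, k] + 1L
  }
  H
}

# Plain-R minimum-image neighbour counting: mean number of `nbrs` atoms
# (on other molecules) within each radius of the `centers` atoms.
brute_neighbor_counts <- function(config, centers, nbrs, radii) {
  out <- numeric(length(radii))
  L <- config$box_edge
  for (i in centers) {
    j <- nbrs[config$atoms$mol[nbrs] != config$atoms$mol[i] & nbrs != i]
    if (!length(j)) next
    d <- sweep(config$xyz[j, , drop = FALSE], 2, config$xyz[i, ])
    d <- d - L * round(d / L)
    r <- sqrt(rowSums(d^2))
    for (k in seq_along(radii)) out[k] <- out[k] + sum(r <= radii[k])
  }
  out / length(centers)
}

# Independent bare-bones Metropolis NVT for a single-site LJ fluid
# (translations only), written without touching the package engine.
plain_lj_mc <- function(n, density, temperature_K, sigma, epsilon,
                        n_sweeps, seed, step = 0.35) {
  set.seed(seed)
  L <- (n / density)^(1 / 3)
  kB <- 0.0083144621
  x <- matrix(runif(3 * n, 0, L), n, 3)
  pair_e <- function(r2) {
    s6 <- (sigma^2 / r2)^3
    4 * epsilon * (s6^2 - s6)
  }
  atom_e <- function(x, i) {
    d <- sweep(x[-i, , drop = FALSE], 2, x[i, ])
    d <- d - L * round(d / L)
    r2 <- rowSums(d^2)
    sum(pair_e(r2))
  }
  energies <- numeric(0)
  snaps <- list()
  for (s in seq_len(n_sweeps)) {
    for (i in seq_len(n)) {
      e0 <- atom_e(x, i)
      old <- x[i, ]
      x[i, ] <- x[i, ] + runif(3, -step, step)
      e1 <- atom_e(x, i)
      dU <- e1 - e0
      if (!(dU <= 0 || runif(1) < exp(-dU / (kB * temperature_K))))
        x[i, ] <- old
    }
    if (s > n_sweeps / 2) {
      etot <- 0
      for (i in seq_len(n - 1)) {
        d <- sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ])
        d <- d - L * round(d / L)
        etot <- etot + sum(pair_e(rowSums(d^2)))
      }
      energies <- c(energies, etot)
      snaps[[length(snaps) + 1L]] <- x
    }
  }
  list(x = x, L = L, energies = energies, snaps = snaps)
}

# Ensemble-averaged g(r) of plain coordinate snapshots (single type).
plain_gr <- function(snaps, L, r_max, dr) {
  if (is.matrix(snaps)) snaps <- list(snaps)
  n <- nrow(snaps[[1]])
  nb <- ceiling(r_max / dr)
  counts <- numeric(nb)
  for (x in snaps) {
    for (i in seq_len(n - 1)) {
      d <- sweep(x[(i + 1):n, , drop = FALSE], 2, x[i, ])
      d <- d - L * round(d / L)
      r <- sqrt(rowSums(d^2))
      r <- r[r < r_max]
      if (length(r)) {
        b <- floor(r / dr) + 1
        for (k in b) counts[k] <- counts[k] + 1
      }
    }
  }
  counts <- counts / length(snaps)
  edges <- seq(0, nb * dr, by = dr)
  shell <- 4 / 3 * pi * diff(edges^3)
  expect <- n^2 / 2 * shell / L^3
  list(r = edges[-1] - dr / 2, g = counts / expect)
}
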