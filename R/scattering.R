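#' Scattering patterns
#'
#' Container for a total structure factor S(Q): strictly ascending Q grid
#' (1/Angstrom, Q > 0), S values, optional uncertainties, a temperature
#' annotation and a multiplicative normalization factor.
#'
#' @param Q Ascending Q grid in 1/Angstrom.
#' @param S S(Q) values.
#' @param sigma Optional per-point uncertainties.
#' @param temperature_K Temperature annotation.
#' @param scale Multiplicative normalization factor (default 1).
#' @return A `scattering_pattern`.
#' @export
scattering_pattern <- function(Q, S, sigma = NULL, temperature_K = NA_real_,
                               scale = 1) {
  if (length(Q) != length(S)) stop("Q and S lengths differ")
  if (any(!is.finite(Q)) || any(!is.finite(S))) stop("non-finite values")
  if (Q[1] <= 0 || any(diff(Q) <= 0)) stop("Q must be strictly ascending and positive")
  structure(list(Q = Q, S = S, sigma = sigma, temperature_K = temperature_K,
                 scale = scale), class = "scattering_pattern")
}

#' @export
print.scattering_pattern <- function(x, ...) {
  cat(sprintf("scattering_pattern: %d points, Q %.3g-%.3g 1/A, high-Q mean %.3f\n",
              length(x$Q), min(x$Q), max(x$Q), high_q_mean(x)))
  invisible(x)
}

# Mean of S over the top 10% of the Q range (normalization diagnostic:
# should be ~1 for a normalized pattern).
high_q_mean <- function(pattern) {
  sel <- pattern$Q >= stats::quantile(pattern$Q, 0.9)
  mean(pattern$S[sel])
}

#' Read / write S(Q) ASCII files
#'
#' Two- or three-column ASCII (Q, S, optional sigma) with `#` comments.
#'
#' @param path File path.
#' @return A `scattering_pattern`.
#' @export
read_sq <- function(path) {
  d <- read.table(path, comment.char = "#")
  scattering_pattern(d[[1]], d[[2]],
                     sigma = if (ncol(d) >= 3) d[[3]] else NULL)
}

#' @rdname read_sq
#' @param pattern A `scattering_pattern` to write.
#' @export
write_sq <- function(pattern, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# S(Q): %d points; T = %g K; scale = %g",
                     length(pattern$Q), pattern$temperature_K, pattern$scale), con)
  if (is.null(pattern$sigma)) {
    writeLines(sprintf("%.6f %.8f", pattern$Q, pattern$S), con)
  } else {
    writeLines(sprintf("%.6f %.8f %.8f", pattern$Q, pattern$S, pattern$sigma), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Partial pair distribution functions from configurations
#'
#' Histogram estimator of the partial pair distribution functions
#' g_ab(r) for every force-field type pair, using minimum-image distances
#' and exact spherical-shell volumes.  Accepts a single configuration or a
#' list (ensemble) whose histograms are pooled before normalization.
#'
#' @param config A `configuration` or list of configurations (same
#'   composition and box).
#' @param r_max Maximum distance (must be at most half the box edge).
#' @param dr Bin width in Angstrom.
#' @param intra Include intramolecular pairs.
#' @param inter Include intermolecular pairs (default TRUE).
#' @param by Histogram key: `"type"` (force-field types, default) or
#'   `"element"`.
#' @return A `pair_function_set`: r grid (bin centres), named list `g`
#'   with one curve per unordered pair `"a:b"`, the atom number density
#'   `rho`, concentrations `c`, and the element of each type.
#' @export
compute_partial_gr <- function(config, r_max = NULL, dr = 0.02, intra = FALSE,
                               inter = TRUE, by = c("type", "element")) {
  by <- match.arg(by)
  configs <- if (inherits(config, "configuration")) list(config) else config
  if (!length(configs)) stop("empty configuration list")
  su <- gr_setup(configs[[1]], r_max, dr, by)
  H <- 0
  for (cf in configs)
    H <- H + cpp_pair_hist(cf$xyz, su$tidx, cf$atoms$mol, length(su$types),
                           cf$box_edge, su$r_max, dr, intra, inter)
  gr_normalize(H, length(configs), su)
}

# Histogram bookkeeping shared by compute_partial_gr and the incremental
# ensemble accumulation in the refinement loop.
gr_setup <- function(config, r_max, dr, by = "type") {
  if (nrow(config$xyz) == 0) stop("empty configuration")
  if (is.null(r_max)) r_max <- 0.49 * config$box_edge
  if (r_max > config$box_edge / 2 + 1e-9) stop("r_max exceeds half the box edge")
  if (dr <= 0) stop("dr must be positive")
  key <- if (by == "type") config$atoms$type_key else config$atoms$element
  types <- sort(unique(key))
  elem_of <- character(0)
  for (t in types)
    elem_of[t] <- if (by == "element") t else
      config$atoms$element[match(t, config$atoms$type_key)]
  list(types = types, tidx = match(key, types) - 1L,
       nb = as.integer(ceiling(r_max / dr)), r_max = r_max, dr = dr,
       n_of = as.numeric(table(factor(key, levels = types))),
       V = config$box_edge^3, elem_of = elem_of,
       rho = nrow(config$xyz) / config$box_edge^3)
}

gr_normalize <- function(H, nsnap, su) {
  H <- H / nsnap
  edges <- seq(0, su$nb * su$dr, by = su$dr)
  shell <- 4 / 3 * pi * diff(edges^3)
  r <- edges[-1] - su$dr / 2
  g <- list()
  k <- 0
  for (a in seq_along(su$types)) for (b in a:length(su$types)) {
    k <- k + 1
    # ordered-pair normalization rho * c_b * N_a (same-type pairs counted
    # once, hence N_a^2 / 2)
    npair <- if (a == b) su$n_of[a]^2 / 2
             else su$n_of[a] * su$n_of[b]
    expct <- npair * shell / su$V
    g[[paste(su$types[a], su$types[b], sep = ":")]] <-
      ifelse(expct > 0, H[, k] / expct, 0)
  }
  structure(list(r = r, dr = su$dr, g = g, rho = su$rho,
                 c = setNames(su$n_of / sum(su$n_of), su$types),
                 n_of = setNames(su$n_of, su$types),
                 element_of = su$elem_of, counts = H, types = su$types),
            class = "pair_function_set")
}

#' @export
print.pair_function_set <- function(x, ...) {
  cat(sprintf("pair_function_set: %d partials on r <= %.2f A (dr %.3f), rho %.4f atoms/A^3\n",
              length(x$g), max(x$r), x$dr, x$rho))
  invisible(x)
}

# X-ray weights w_ab(Q) = (2-delta_ab) c_a c_b f_a f_b / D(Q) for the
# unordered pairs of a pair_function_set.  The denominator is the
# Faber-Ziman <f>^2 = (sum_a c_a f_a)^2 for condensed systems ("coherent")
# or the self-scattering <f^2> = sum_a c_a f_a^2 ("self"), the
# normalization of the Debye equation for isolated clusters.
fz_weights <- function(pairset, Q, denominator = c("coherent", "self")) {
  denominator <- match.arg(denominator)
  types <- pairset$types
  f <- sapply(types, function(t) xray_form_factor(pairset$element_of[[t]], Q))
  if (is.null(dim(f))) f <- matrix(f, nrow = length(Q))
  D <- if (denominator == "coherent") as.vector(f %*% pairset$c[types])^2
       else as.vector(f^2 %*% pairset$c[types])
  w <- list()
  for (a in seq_along(types)) for (b in a:length(types)) {
    w[[paste(types[a], types[b], sep = ":")]] <-
      (2 - (a == b)) * pairset$c[[a]] * pairset$c[[b]] *
        f[, a] * f[, b] / D
  }
  w
}

#' X-ray weighted total structure factor
#'
#' Faber-Ziman construction: each partial is sine-transformed,
#' \eqn{S_{ab}(Q) - 1 = 4\pi\rho \int r^2 (g_{ab}(r)-1) \,
#' \mathrm{sinc}(Qr)\, dr}, and combined with concentration and
#' Cromer-Mann form-factor weights normalized by the mean form factor
#' squared.  Hydrogen is included at its true (weak) X-ray weight.
#'
#' @param pairset A `pair_function_set` from [compute_partial_gr()].
#' @param Q Q grid in 1/Angstrom (no zeros).
#' @param temperature_K Annotation copied to the output.
#' @param taper Fraction of the outer r range cosine-tapered before the
#'   transform (0 disables).
#' @param background Subtract the uniform-density background (the `- 1` in
#'   `g - 1`).  Set FALSE for an isolated cluster, where the interference
#'   function has no ideal-gas background; that mode matches the Debye
#'   equation.
#' @return A `scattering_pattern`.
#' @export
xray_total_sq <- function(pairset, Q = default_q_grid(),
                          temperature_K = NA_real_, taper = 0.2,
                          background = TRUE) {
  if (any(Q == 0)) stop("Q grid must not contain 0")
  w <- fz_weights(pairset, Q,
                  denominator = if (background) "coherent" else "self")
  r <- pairset$r; dr <- pairset$dr
  # cosine taper of g-1 over the outer fraction of the r range: suppresses
  # finite-box termination ripples at low Q (set taper = 0 for the exact
  # truncated transform, e.g. when comparing against a Debye sum)
  tp <- rep(1, length(r))
  if (taper > 0) {
    r0 <- max(r) * (1 - taper)
    sel <- r > r0
    tp[sel] <- 0.5 * (1 + cos(pi * (r[sel] - r0) / (max(r) - r0)))
  }
  S <- rep(1, length(Q))
  # sinc kernel matrix (nQ x nr)
  K <- sin(outer(Q, r)) / outer(Q, r)
  for (nm in names(pairset$g)) {
    h <- (pairset$g[[nm]] - if (background) 1 else 0) * tp
    Sab <- 4 * pi * pairset$rho * as.vector(K %*% (r^2 * h * dr))
    S <- S + w[[nm]] * Sab
  }
  scattering_pattern(Q, S, temperature_K = temperature_K)
}

#' Default instrument Q grid
#'
#' @param q_min,q_max,dq Grid limits and spacing in 1/Angstrom.
#' @return Numeric Q grid (defaults 0.6-25.0 1/Angstrom, step 0.02).
#' @export
default_q_grid <- function(q_min = 0.6, q_max = 25.0, dq = 0.02) {
  seq(q_min, q_max, by = dq)
}

#' Debye-equation S(Q) for a finite cluster
#'
#' Direct double sum \eqn{S(Q) = \sum_{ij} f_i f_j \sin(Qr_{ij})/(Qr_{ij})
#' / \sum_i f_i^2} over exact interatomic distances (no periodicity);
#' the independent oracle for the histogram-transform route.
#'
#' @param xyz N x 3 coordinate matrix (Angstrom).
#' @param elements Element symbol per atom.
#' @param Q Q grid.
#' @return A `scattering_pattern`.
#' @export
xray_debye_sq <- function(xyz, elements, Q) {
  f <- sapply(unique(elements), xray_form_factor, Q = Q)
  if (is.null(dim(f))) f <- matrix(f, nrow = length(Q))
  colnames(f) <- unique(elements)
  fi <- f[, elements, drop = FALSE]
  S <- rep(0, length(Q))
  n <- nrow(xyz)
  denom <- rowSums(fi^2)
  for (i in seq_len(n - 1)) {
    d <- sqrt(colSums((t(xyz[(i + 1):n, , drop = FALSE]) - xyz[i, ])^2))
    sinc <- sin(outer(Q, d)) / outer(Q, d)
    S <- S + 2 * rowSums(sinc * (fi[, i] * fi[, (i + 1):n, drop = FALSE]))
  }
  scattering_pattern(Q, 1 + S / denom)
}

#' Model S(Q) of a configuration including intramolecular structure
#'
#' Convenience wrapper: histogram of all pairs (intra- and intermolecular)
#' to `r_max`, then the Faber-Ziman X-ray total.  This is the quantity
#' compared against a measured or pseudo-experimental pattern during
#' refinement.
#'
#' @param config Configuration or list of configurations.
#' @param Q Q grid.
#' @param dr Histogram bin width.
#' @param r_max Histogram range (default just under half the box).
#' @return A `scattering_pattern`.
#' @export
model_sq <- function(config, Q = default_q_grid(), dr = 0.02, r_max = NULL) {
  ps <- compute_partial_gr(config, r_max = r_max, dr = dr, intra = TRUE,
                           inter = TRUE, by = "element")
  t0 <- if (inherits(config, "configuration")) config$temperature_K
        else config[[1]]$temperature_K
  xray_total_sq(ps, Q, temperature_K = t0)
}

# ---------------------------------------------------------------------------

#' Transform S(Q) to the differential PDF D(r)
#'
#' \eqn{D(r) = (2/\pi) \int Q (S(Q)-1) \sin(Qr) dQ} over the measured Q
#' range (trapezoidal rule), optionally with a Lorch window
#' \eqn{\sin(\pi Q/Q_{max})/(\pi Q/Q_{max})} to damp termination ripples.
#' For the X-ray-weighted total g(r), D(r) = 4 pi rho r (g(r)-1).
#'
#' @param pattern A normalized `scattering_pattern` (high-Q mean of S
#'   within 1 +/- 0.05).
#' @param rho Atom number density in atoms/Angstrom^3.
#' @param r_grid Output r grid in Angstrom.
#' @param window `"none"` or `"lorch"`.
#' @return A `differential_pdf`: r, D, and the rho used.
#' @export
sq_to_dr <- function(pattern, rho, r_grid = seq(0.02, 15, by = 0.02),
                     window = c("none", "lorch")) {
  window <- match.arg(window)
  if (rho <= 0) stop("rho must be positive")
  if (abs(high_q_mean(pattern) - 1) > 0.05)
    stop("pattern does not appear to be normalized (high-Q mean ",
         sprintf("%.3f", high_q_mean(pattern)), ")")
  Q <- pattern$Q
  h <- pattern$S - 1
  if (window == "lorch") {
    x <- pi * Q / max(Q)
    h <- h * sin(x) / x
  }
  # trapezoid weights
  wq <- c(diff(Q), 0) / 2 + c(0, diff(Q)) / 2
  D <- (2 / pi) * as.vector(sin(outer(r_grid, Q)) %*% (Q * h * wq))
  structure(list(r = r_grid, D = D, rho = rho, window = window),
            class = "differential_pdf")
}

#' @export
print.differential_pdf <- function(x, ...) {
  cat(sprintf("differential_pdf: r <= %.2f A, window %s\n", max(x$r), x$window))
  invisible(x)
}

#' First sharp diffraction peak metrics
#'
#' Finds the first local maximum of S(Q) in the search window and refines
#' position and height by three-point parabolic interpolation; the width is
#' the full width at half maximum above the local base line S = 1.  If two
#' local maxima fall in the window the lower-Q one is taken (the FSDP is by
#' definition the first).
#'
#' @param pattern A `scattering_pattern` covering the window.
#' @param window Search window in 1/Angstrom (default 0.6-2.0).
#' @return List with `position`, `height` (S at the peak), and `width`
#'   (FWHM of S-1, NA if the half height is not bracketed in the window).
#' @export
fsdp_metrics <- function(pattern, window = c(0.6, 2.0)) {
  sel <- which(pattern$Q >= window[1] & pattern$Q <= window[2])
  if (length(sel) < 3) stop("pattern does not cover the FSDP window")
  Q <- pattern$Q[sel]; S <- pattern$S[sel]
  i <- which(diff(sign(diff(S))) == -2) + 1L
  if (!length(i)) stop("no local maximum in the FSDP window")
  # ignore noise wiggles: keep maxima with prominence over 20% of the
  # window's dynamic range, then take the lowest-Q survivor
  rng <- max(S) - min(S)
  prom <- vapply(i, function(k) S[k] - min(S[1:k]), 0)
  i <- i[prom >= 0.2 * rng]
  if (!length(i)) stop("no local maximum in the FSDP window")
  i <- i[1]
  # parabola through the three points around the maximum
  x <- Q[(i - 1):(i + 1)]; y <- S[(i - 1):(i + 1)]
  d2 <- (y[3] - 2 * y[2] + y[1])
  pos <- x[2] - 0.5 * (x[3] - x[2]) * (y[3] - y[1]) / d2
  hgt <- y[2] - (y[3] - y[1])^2 / (8 * d2)
  half <- 1 + (hgt - 1) / 2
  lo <- suppressWarnings(max(which(S[1:i] <= half)))
  hi_rel <- suppressWarnings(min(which(S[i:length(S)] <= half)))
  width <- NA_real_
  if (is.finite(lo) && is.finite(hi_rel)) {
    ql <- approx(S[c(lo, lo + 1)], Q[c(lo, lo + 1)], xout = half)$y
    hi <- i + hi_rel - 1L
    qh <- approx(S[c(hi - 1, hi)], Q[c(hi - 1, hi)], xout = half)$y
    width <- qh - ql
  }
  list(position = pos, height = hgt, width = width)
}

#' X-ray weighted intramolecular pair PDF
#'
#' Gaussian-broadened stick spectrum of selected intramolecular distances
#' of a template, weighted by the product of the atoms' forward form
#' factors relative to the molecular mean (the X-ray weighting of the
#' intramolecular differential PDF).
#'
#' @param tpl A `mol_template`.
#' @param pair_selector Length-2 character vector of element symbols
#'   (e.g. `c("Cl", "Cl")`) or a function taking the atom table and
#'   returning a 2-column index matrix of pairs.
#' @param broadening_sigma Gaussian sigma in Angstrom.
#' @param r_grid Output grid.
#' @return List with `r`, `p` (weighted density), `distances` (the sticks),
#'   and `peak` (parabolically refined position of the maximum).
#' @export
intramolecular_pair_pdf <- function(tpl, pair_selector, broadening_sigma = 0.1,
                                    r_grid = seq(0.5, 10, by = 0.005)) {
  at <- tpl$atoms
  if (is.function(pair_selector)) {
    pairs <- pair_selector(at)
  } else {
    ia <- which(at$element == pair_selector[1])
    ib <- which(at$element == pair_selector[2])
    pairs <- expand.grid(ia, ib)
    pairs <- as.matrix(pairs[pairs[, 1] < pairs[, 2], , drop = FALSE])
  }
  if (!nrow(pairs)) stop("pair selector matches no intramolecular pair")
  xyz <- template_xyz(tpl)
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                     xyz[pairs[, 2], , drop = FALSE])^2))
  z0 <- mean(atomic_number(at$element))
  wt <- atomic_number(at$element[pairs[, 1]]) *
        atomic_number(at$element[pairs[, 2]]) / z0^2
  p <- rep(0, length(r_grid))
  for (k in seq_along(d))
    p <- p + wt[k] * if (broadening_sigma > 0)
      dnorm(r_grid, d[k], broadening_sigma) else as.numeric(
        abs(r_grid - d[k]) == min(abs(r_grid - d[k])))
  i <- which.max(p)
  peak <- r_grid[i]
  if (i > 1 && i < length(p)) {
    d2 <- p[i + 1] - 2 * p[i] + p[i - 1]
    if (d2 < 0)
      peak <- r_grid[i] - 0.5 * (r_grid[i + 1] - r_grid[i]) *
        (p[i + 1] - p[i - 1]) / d2
  }
  list(r = r_grid, p = p, distances = d, weights = wt, peak = peak)
}
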