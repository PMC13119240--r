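#' Empirical potential state
#'
#' Tabulated correction potential u_ep(r) per force-field type pair, on a
#' regular r grid (bin centres), with an amplitude cap, the feedback factor
#' applied at every update, and the R-factor history of the refinement.
#'
#' @param types Sorted vector of type keys (pair columns follow the same
#'   unordered-pair enumeration as the pair distribution functions).
#' @param r_max Table range in Angstrom (zero beyond).
#' @param dr Table spacing.
#' @param amplitude_cap Maximum |u_ep| in kJ/mol.
#' @param feedback Fraction of the inverted residual added per update.
#' @param smooth_sigma Gaussian smoothing of the update in Angstrom.
#' @return An `ep_state` object.
#' @export
empirical_potential_state <- function(types, r_max = 12, dr = 0.02,
                                      amplitude_cap = 15, feedback = 0.3,
                                      smooth_sigma = 0.3) {
  types <- sort(types)
  nms <- character(0)
  for (a in seq_along(types)) for (b in a:length(types))
    nms <- c(nms, paste(types[a], types[b], sep = ":"))
  nb <- as.integer(ceiling(r_max / dr))
  u <- matrix(0, nb, length(nms), dimnames = list(NULL, nms))
  structure(list(types = types, r = (seq_len(nb) - 0.5) * dr, dr = dr,
                 u = u, amplitude_cap = amplitude_cap, feedback = feedback,
                 smooth_sigma = smooth_sigma, iteration = 0L,
                 r_history = numeric(0)),
            class = "ep_state")
}

#' @export
print.ep_state <- function(x, ...) {
  cat(sprintf("ep_state: %d pair channels, r <= %.1f A, iteration %d, max|u| = %.3f kJ/mol (cap %g)\n",
              ncol(x$u), max(x$r), x$iteration, max(abs(x$u)), x$amplitude_cap))
  invisible(x)
}

#' Goodness-of-fit R-factor
#'
#' Mean squared deviation between two structure factors on a common Q grid.
#'
#' @param S_model,S_target `scattering_pattern`s on identical Q grids.
#' @return Non-negative scalar.
#' @export
r_factor <- function(S_model, S_target) {
  if (length(S_model$Q) != length(S_target$Q) ||
      max(abs(S_model$Q - S_target$Q)) > 1e-9) stop("Q grid mismatch")
  mean((S_model$S - S_target$S)^2)
}

#' Least-squares normalization scale
#'
#' The multiplicative factor s on `S_target - 1` minimizing the R-factor
#' between `S_model` and `1 + s (S_target - 1)` (the adjustment applied to
#' the normalization of measured X-ray data), clipped to `bounds`.
#'
#' @param S_model,S_target Patterns on a common grid.
#' @param bounds Allowed range for the scale, within (0, 2).
#' @return The fitted scale factor.
#' @export
fit_scale <- function(S_model, S_target, bounds = c(0.5, 1.5)) {
  if (length(S_model$Q) != length(S_target$Q) ||
      max(abs(S_model$Q - S_target$Q)) > 1e-9) stop("Q grid mismatch")
  ht <- S_target$S - 1
  hm <- S_model$S - 1
  if (sum(ht^2) < 1e-12) stop("degenerate (constant) target pattern")
  s <- sum(hm * ht) / sum(ht^2)
  min(max(s, bounds[1]), bounds[2])
}

#' Update the empirical potential from the S(Q) residual
#'
#' Direct Fourier-feedback scheme: the residual S_model - S_target is
#' transformed to r space,
#' \eqn{\Delta g(r) = \frac{1}{2\pi^2 \rho r} \int Q\,\Delta S \sin(Qr)dQ},
#' scaled by k_B T times the feedback factor, apportioned to the type-pair
#' channels by their (Q-averaged) X-ray weights, Gaussian-smoothed, added
#' to u_ep and clipped to the amplitude cap.  When S_model equals S_target
#' the state is unchanged (the refinement fixed point).
#'
#' @param ep_state An `ep_state`.
#' @param S_model,S_target Patterns on a common Q grid.
#' @param pairset The `pair_function_set` the model pattern came from
#'   (provides density, concentrations and elements for the weights).
#' @param temperature_K Simulation temperature.
#' @return The updated `ep_state` (R-factor appended to its history).
#' @export
update_empirical_potential <- function(ep_state, S_model, S_target, pairset,
                                       temperature_K = 300) {
  if (length(S_model$Q) != length(S_target$Q) ||
      max(abs(S_model$Q - S_target$Q)) > 1e-9) stop("Q grid mismatch")
  Q <- S_model$Q
  dS <- S_model$S - S_target$S
  r <- ep_state$r
  wq <- c(diff(Q), 0) / 2 + c(0, diff(Q)) / 2
  dg <- as.vector(sin(outer(r, Q)) %*% (Q * dS * wq)) /
    (2 * pi^2 * pairset$rho * r)
  du0 <- .KB * temperature_K * ep_state$feedback * dg
  # Gaussian smoothing
  if (ep_state$smooth_sigma > 0) {
    half <- ceiling(3 * ep_state$smooth_sigma / ep_state$dr)
    kern <- dnorm(seq(-half, half) * ep_state$dr, 0, ep_state$smooth_sigma)
    kern <- kern / sum(kern)
    du0 <- as.vector(stats::filter(c(rep(du0[1], half), du0,
                                     rep(0, half)), kern, sides = 2))
    du0 <- du0[(half + 1):(half + length(r))]
    du0[is.na(du0)] <- 0
  }
  # taper to zero over the outer 2 Angstrom of the table
  rmx <- max(r)
  tap <- ifelse(r > rmx - 2, 0.5 * (1 + cos(pi * (r - (rmx - 2)) / 2)), 1)
  du0 <- du0 * tap
  w <- fz_weights(pairset, Q)
  wbar <- vapply(w, mean, 0)
  share <- wbar / sum(wbar^2)
  for (nm in colnames(ep_state$u)) {
    sh <- if (nm %in% names(share)) share[[nm]] else 0
    ep_state$u[, nm] <- pmin(pmax(ep_state$u[, nm] + sh * du0,
                                  -ep_state$amplitude_cap),
                             ep_state$amplitude_cap)
  }
  ep_state$iteration <- ep_state$iteration + 1L
  ep_state$r_history <- c(ep_state$r_history, r_factor(S_model, S_target))
  ep_state
}

# ---------------------------------------------------------------------------
# Monte Carlo engine

#' Monte Carlo context
#'
#' Precomputes everything the Metropolis engine needs (type indices,
#' combined LJ matrices, charges, minimum-distance matrix, per-molecule
#' intramolecular pair lists and rotatable-group indices) and holds the
#' mutable coordinates.  All randomness is drawn from R's RNG, so a seed
#' set before a run makes the trajectory bit-reproducible.
#'
#' @param config A `configuration`.
#' @param ff A `forcefield`.
#' @param constraints A `constraint_set` (or NULL: no hard minima).
#' @param ep_state An `ep_state` (or NULL: reference potential only).
#' @param r_cut Cutoff for the reference potential; default
#'   `min(12, box/2)`.
#' @param shift Shift the Coulomb term to zero at the cutoff.
#' @return An environment of class `mc_context`.
#' @export
mc_context <- function(config, ff, constraints = NULL, ep_state = NULL,
                       r_cut = NULL, shift = TRUE) {
  ctx <- new.env(parent = emptyenv())
  ctx$config <- config
  ctx$env <- config_env(config, ff, constraints)
  ctx$xyz <- config$xyz
  ctx$L <- config$box_edge
  ctx$T <- config$temperature_K
  ctx$r_cut <- if (is.null(r_cut)) min(12, config$box_edge / 2) else r_cut
  ctx$shift <- shift
  ctx$mol_of <- config$atoms$mol
  nmol <- length(config$template_of_mol)
  ctx$nmol <- nmol
  ctx$atoms_of <- split(seq_len(nrow(config$xyz)), config$atoms$mol)
  # per-molecule intramolecular included pairs (0-based)
  mol_of_pair <- config$atoms$mol[ctx$env$intra_i + 1L]
  ctx$intra_of <- lapply(seq_len(nmol), function(m) {
    sel <- mol_of_pair == m
    list(i = ctx$env$intra_i[sel], j = ctx$env$intra_j[sel])
  })
  # per-molecule rotatable groups as global row indices
  ctx$groups_of <- lapply(seq_len(nmol), function(m) {
    tpl <- config$templates[[config$template_of_mol[m]]]
    off <- ctx$atoms_of[[m]][1] - 1L
    lapply(tpl$groups, function(g) list(
      axis = off + match(g$axis, tpl$atoms$label),
      moved = off + match(g$moved, tpl$atoms$label)))
  })
  ctx$mobile <- seq_len(nmol) # molecules the engine may move
  ctx$moves <- if (is.null(constraints))
    list(translate = 0.2, rotate = 10, group_rotate = 15) else constraints$moves
  ctx$ep_tab <- if (is.null(ep_state)) matrix(0, 0, 0) else ep_state$u
  ctx$ep_dr <- if (is.null(ep_state)) 0.02 else ep_state$dr
  ctx$n_prop <- c(translate = 0, rotate = 0, group_rotate = 0)
  ctx$n_acc <- c(translate = 0, rotate = 0, group_rotate = 0)
  class(ctx) <- c("mc_context", "environment")
  ctx
}

#' @export
print.mc_context <- function(x, ...) {
  cat(sprintf("mc_context: %d molecules, T = %g K, r_cut %.1f A, ep %s\n",
              x$nmol, x$T, x$r_cut,
              if (nrow(x$ep_tab)) "active" else "off"))
  invisible(x)
}

#' Set or replace the empirical potential of a context
#'
#' @param ctx An `mc_context`.
#' @param ep_state An `ep_state` (or NULL to disable).
#' @export
set_ep <- function(ctx, ep_state) {
  ctx$ep_tab <- if (is.null(ep_state)) matrix(0, 0, 0) else ep_state$u
  if (!is.null(ep_state)) ctx$ep_dr <- ep_state$dr
  invisible(ctx)
}

#' Metropolis acceptance rule
#'
#' Accepts an energy change of `dU` kJ/mol at temperature `T`:
#' always if `dU <= 0`, else with probability `exp(-dU / k_B T)`.
#'
#' @param dU Energy change in kJ/mol.
#' @param T Temperature in K.
#' @return Logical.
#' @export
metropolis_accept <- function(dU, T) {
  dU <= 0 || runif(1) < exp(-dU / (.KB * T))
}

.mol_energy <- function(ctx, m) {
  ip <- ctx$intra_of[[m]]
  cpp_energy_mol(ctx$xyz, ctx$env$type_idx, ctx$mol_of - 1L, m - 1L,
                 ctx$env$sigma, ctx$env$epsilon, ctx$env$q, ctx$L,
                 ctx$r_cut, ctx$shift, ctx$env$mind, ip$i, ip$j,
                 ctx$ep_tab, ctx$ep_dr)
}

#' Single Metropolis move
#'
#' Proposes a symmetric random move of one molecule (rigid translation,
#' rigid rotation about its centroid, or rotation of one rotatable group)
#' and applies the Metropolis criterion on the total (reference +
#' empirical) energy change.  Moves violating a hard minimum distance are
#' rejected outright.
#'
#' @param ctx An `mc_context` (modified in place), or a `configuration`
#'   (then `ff` must be given and an updated configuration is returned).
#' @param move_kind `"translate"`, `"rotate"` or `"group_rotate"`.
#' @param ff,constraints,ep_state Used only when `ctx` is a configuration.
#' @return For a context: invisible list(accepted, dU).  For a
#'   configuration: list(config, accepted, dU).
#' @export
mc_step <- function(ctx, move_kind = c("translate", "rotate", "group_rotate"),
                    ff = NULL, constraints = NULL, ep_state = NULL) {
  move_kind <- match.arg(move_kind)
  if (inherits(ctx, "configuration")) {
    if (is.null(ff)) stop("ff required when stepping a configuration")
    c2 <- mc_context(ctx, ff, constraints, ep_state)
    res <- mc_step(c2, move_kind)
    cfg <- ctx; cfg$xyz <- c2$xyz
    return(list(config = cfg, accepted = res$accepted, dU = res$dU))
  }
  if (ctx$T <= 0) stop("temperature must be positive")
  m <- ctx$mobile[sample.int(length(ctx$mobile), 1)]
  rows <- ctx$atoms_of[[m]]
  old <- ctx$xyz[rows, , drop = FALSE]
  e0 <- .mol_energy(ctx, m)
  if (move_kind == "translate") {
    disp <- runif(3, -1, 1) * ctx$moves$translate
    ctx$xyz[rows, ] <- sweep(old, 2, disp, "+")
  } else if (move_kind == "rotate") {
    cen <- colMeans(old)
    ax <- rnorm(3)
    ang <- runif(1, -1, 1) * ctx$moves$rotate
    ctx$xyz[rows, ] <- rotate_about_axis(old, cen, ax, ang)
  } else {
    gs <- ctx$groups_of[[m]]
    if (!length(gs)) stop("molecule has no rotatable groups")
    g <- gs[[sample.int(length(gs), 1)]]
    ang <- runif(1, -1, 1) * ctx$moves$group_rotate
    a <- ctx$xyz[g$axis[1], ]; b <- ctx$xyz[g$axis[2], ]
    ctx$xyz[g$moved, ] <- rotate_about_axis(
      ctx$xyz[g$moved, , drop = FALSE], a, b - a, ang)
  }
  e1 <- .mol_energy(ctx, m)
  dU <- e1$energy - e0$energy
  # hard minima: reject any move that creates or worsens a violation (a
  # valid state can therefore never acquire one; an invalid start can only
  # repair itself monotonically)
  hard_ok <- e1$ok || e1$minratio >= e0$minratio
  acc <- hard_ok && metropolis_accept(dU, ctx$T)
  if (!acc) ctx$xyz[rows, ] <- old
  ctx$n_prop[move_kind] <- ctx$n_prop[move_kind] + 1
  if (acc) ctx$n_acc[move_kind] <- ctx$n_acc[move_kind] + 1
  invisible(list(accepted = acc, dU = dU))
}

#' Run Monte Carlo sweeps
#'
#' One sweep is one attempted move per molecule, cycling through
#' translation, rigid rotation, and (where groups exist) group rotation.
#' Move sizes are optionally auto-tuned towards 30-50% acceptance.
#'
#' @param ctx An `mc_context`.
#' @param n_sweeps Number of sweeps.
#' @param tune Auto-tune move sizes.
#' @return Invisible acceptance-rate vector.
#' @export
mc_sweeps <- function(ctx, n_sweeps, tune = FALSE) {
  kinds <- c("translate", "rotate")
  if (any(vapply(ctx$groups_of, length, 0L) > 0)) kinds <- c(kinds, "group_rotate")
  for (s in seq_len(n_sweeps)) {
    for (i in seq_along(ctx$mobile)) {
      mc_step(ctx, kinds[1 + (i + s) %% length(kinds)])
    }
    if (tune && sum(ctx$n_prop) >= 1000) {
      for (k in names(ctx$n_prop)) {
        if (ctx$n_prop[[k]] == 0) next
        rate <- ctx$n_acc[[k]] / ctx$n_prop[[k]]
        if (rate > 0.5) ctx$moves[[k]] <- min(ctx$moves[[k]] * 1.1,
                                              c(translate = ctx$L / 4,
                                                rotate = 180,
                                                group_rotate = 180)[[k]])
        if (rate < 0.3) ctx$moves[[k]] <- ctx$moves[[k]] * 0.9
      }
      ctx$n_prop[] <- 0; ctx$n_acc[] <- 0
    }
  }
  invisible(ifelse(ctx$n_prop > 0, ctx$n_acc / ctx$n_prop, NA))
}

#' Extract the current configuration from a context
#'
#' @param ctx An `mc_context`.
#' @return A `configuration` with the current coordinates.
#' @export
ctx_config <- function(ctx) {
  cfg <- ctx$config
  cfg$xyz <- ctx$xyz
  cfg
}

# ---------------------------------------------------------------------------

#' Compress a box to match a target FSDP height
#'
#' Starting from a (typically low-density) configuration, the box edge is
#' reduced stepwise - rescaling molecule centroids, keeping internal
#' geometry - with re-equilibration between steps, until the model FSDP
#' height matches the target within tolerance; once the target is
#' bracketed the edge is refined by bisection.  The FSDP is very sensitive
#' to density, which is what makes this a density-refinement protocol.
#'
#' @param config Starting `configuration`.
#' @param ff Force field.
#' @param target_fsdp_height Target peak height of S(Q) in the window.
#' @param constraints Optional `constraint_set`.
#' @param window FSDP search window in 1/Angstrom.
#' @param Q Q grid for the model pattern.
#' @param shrink Edge factor per exploratory step (< 1).
#' @param equil_sweeps Re-equilibration sweeps per step.
#' @param snapshots Snapshots averaged for each exploratory S(Q) estimate.
#' @param snapshots_final Snapshots averaged once the height is within 8%
#'   of the target (measurement noise limits the density resolution).
#' @param tol Relative height tolerance.
#' @param max_steps Step budget.
#' @param density_bounds Allowed density range (atoms/Angstrom^3).
#' @return List: final `config`, `density`, `fsdp` metrics, `converged`,
#'   and the step `trace`.
#' @export
compress_box <- function(config, ff, target_fsdp_height, constraints = NULL,
                         window = c(0.6, 2.0), Q = default_q_grid(),
                         shrink = 0.97, equil_sweeps = 30, snapshots = 8,
                         snapshots_final = 40, tol = 0.02, max_steps = 40,
                         density_bounds = c(1e-4, 0.25)) {
  ctx <- mc_context(config, ff, constraints)
  measure <- function(nsnap = snapshots) {
    snaps <- list()
    for (k in seq_len(nsnap)) {
      mc_sweeps(ctx, 3)
      snaps[[k]] <- ctx_config(ctx)
    }
    fsdp_metrics(model_sq(snaps, Q), window)
  }
  rescale <- function(factor) {
    for (m in seq_len(ctx$nmol)) {
      rows <- ctx$atoms_of[[m]]
      cen <- colMeans(ctx$xyz[rows, , drop = FALSE])
      ctx$xyz[rows, ] <- sweep(ctx$xyz[rows, , drop = FALSE], 2,
                               cen * (factor - 1), "+")
    }
    ctx$L <- ctx$L * factor
    ctx$config$box_edge <- ctx$L
    ctx$r_cut <- min(ctx$r_cut, ctx$L / 2)
  }
  mc_sweeps(ctx, equil_sweeps)
  trace <- data.frame()
  converged <- FALSE
  f <- measure()
  f_precise <- snapshots >= snapshots_final
  for (step in seq_len(max_steps)) {
    if (abs(f$height - target_fsdp_height) <= tol * target_fsdp_height &&
        !f_precise) {
      # confirm an apparent match with a high-precision measurement
      f <- measure(snapshots_final)
      f_precise <- TRUE
    }
    dens <- nrow(ctx$xyz) / ctx$L^3
    trace <- rbind(trace, data.frame(step = step, edge = ctx$L,
                                     density = dens, height = f$height))
    if (abs(f$height - target_fsdp_height) <= tol * target_fsdp_height) {
      converged <- TRUE
      break
    }
    # secant step on the (density, height) relation once two informative
    # points exist; plain geometric step otherwise.  Steps are clamped to
    # the exploratory shrink ratio so a noisy slope cannot cause a jump.
    newL <- if (f$height < target_fsdp_height) ctx$L * shrink
            else ctx$L / shrink
    if (nrow(trace) >= 2) {
      h2 <- trace$height[nrow(trace)]; h1 <- trace$height[nrow(trace) - 1]
      d2 <- trace$density[nrow(trace)]; d1 <- trace$density[nrow(trace) - 1]
      if (abs(h2 - h1) > 1e-3) {
        dsec <- d2 + (target_fsdp_height - h2) * (d2 - d1) / (h2 - h1)
        if (dsec > 0) {
          Lsec <- (nrow(ctx$xyz) / dsec)^(1 / 3)
          newL <- min(max(Lsec, ctx$L * shrink), ctx$L / shrink)
        }
      }
    }
    if (abs(newL / ctx$L - 1) < 0.002) {
      converged <- TRUE # proposed step below resolution: treat as converged
      break
    }
    newdens <- nrow(ctx$xyz) / newL^3
    if (newdens < density_bounds[1] || newdens > density_bounds[2]) {
      warning("density bound reached before FSDP target; returning last valid configuration")
      break
    }
    rescale(newL / ctx$L)
    mc_sweeps(ctx, equil_sweeps)
    # average down measurement noise once the target is within reach
    near <- abs(trace$height[nrow(trace)] - target_fsdp_height) <
      0.08 * target_fsdp_height
    f_precise <- near || snapshots >= snapshots_final
    f <- measure(if (f_precise) snapshots_final else snapshots)
  }
  if (!converged && nrow(trace) == max_steps)
    warning("compress_box did not converge within max_steps")
  list(config = ctx_config(ctx), density = nrow(ctx$xyz) / ctx$L^3,
       fsdp = f, converged = converged, trace = trace)
}

#' Refine a configuration against a target S(Q)
#'
#' The central loop: alternate Metropolis sweeps under reference +
#' empirical potential with empirical-potential updates from the S(Q)
#' residual; after the iteration budget, accumulate ensemble-averaged
#' partial pair distribution functions over `ensemble_size` configurations
#' sampled every `ensemble_stride` sweeps.
#'
#' @param config Starting `configuration`.
#' @param ff Force field.
#' @param S_target Target (measured or pseudo-experimental) pattern; its Q
#'   grid is used for the model.
#' @param n_iterations Empirical-potential iterations (0 = no refinement:
#'   returns the starting state and its R-factor).
#' @param constraints Optional `constraint_set` (hard minima are enforced
#'   throughout).
#' @param sweeps_per_iter MC sweeps between potential updates.
#' @param snapshots_per_iter Snapshots averaged for each model S(Q).
#' @param ensemble_size Configurations accumulated for the production
#'   ensemble after refinement.
#' @param ensemble_stride Sweeps between production snapshots.
#' @param keep_snapshots Also return the production snapshot
#'   configurations (`$snapshots`), e.g. for conformer re-scoring.
#' @param ep_state Starting `ep_state` (default: fresh zero state).
#' @param dr Histogram bin width.
#' @param use_scale Fit the normalization scale of the target each
#'   iteration.
#' @param tune Auto-tune move sizes.
#' @return An `epsr_fit`: final config, ep_state, R-factor history, scale,
#'   ensemble pair functions (by type and by element) and the ensemble
#'   model pattern.
#' @export
refine_to_data <- function(config, ff, S_target, n_iterations = 25,
                           constraints = NULL, sweeps_per_iter = 10,
                           snapshots_per_iter = 4, ensemble_size = 50,
                           ensemble_stride = 2, ep_state = NULL, dr = 0.02,
                           use_scale = FALSE, tune = TRUE,
                           keep_snapshots = FALSE) {
  env0 <- config_env(config, ff, constraints)
  if (is.null(ep_state))
    ep_state <- empirical_potential_state(env0$types,
                                          r_max = 0.49 * config$box_edge,
                                          dr = dr)
  ctx <- mc_context(config, ff, constraints, ep_state)
  Q <- S_target$Q
  su <- gr_setup(config, NULL, dr, by = "type")
  scale <- 1
  target_used <- S_target
  r_hist <- numeric(0)
  snap_sq <- function(nsnap, stride) {
    H <- 0
    for (k in seq_len(nsnap)) {
      mc_sweeps(ctx, stride, tune = tune)
      H <- H + cpp_pair_hist(ctx$xyz, su$tidx, ctx$mol_of, length(su$types),
                             ctx$L, su$r_max, dr, TRUE, TRUE)
    }
    gr_normalize(H, nsnap, su)
  }
  for (it in seq_len(n_iterations)) {
    ps <- snap_sq(snapshots_per_iter, sweeps_per_iter %/% snapshots_per_iter + 1)
    S_model <- xray_total_sq(ps, Q, temperature_K = config$temperature_K)
    if (use_scale) {
      scale <- fit_scale(S_model, S_target)
      target_used <- scattering_pattern(Q, 1 + scale * (S_target$S - 1),
                                        temperature_K = S_target$temperature_K,
                                        scale = scale)
    }
    ep_state <- update_empirical_potential(ep_state, S_model, target_used, ps,
                                           temperature_K = config$temperature_K)
    r_hist <- c(r_hist, tail(ep_state$r_history, 1))
    set_ep(ctx, ep_state)
  }
  # production ensemble
  H_in <- 0; H_all <- 0
  snapshots <- if (keep_snapshots) vector("list", ensemble_size) else NULL
  su_el <- gr_setup(config, NULL, dr, by = "element")
  for (k in seq_len(ensemble_size)) {
    if (n_iterations > 0 || k > 1) mc_sweeps(ctx, ensemble_stride, tune = FALSE)
    H_in <- H_in + cpp_pair_hist(ctx$xyz, su$tidx, ctx$mol_of,
                                 length(su$types), ctx$L, su$r_max, dr,
                                 FALSE, TRUE)
    H_all <- H_all + cpp_pair_hist(ctx$xyz, su_el$tidx, ctx$mol_of,
                                   length(su_el$types), ctx$L, su_el$r_max,
                                   dr, TRUE, TRUE)
    if (keep_snapshots) snapshots[[k]] <- ctx_config(ctx)
  }
  pairset <- gr_normalize(H_in, ensemble_size, su)
  pairset_el <- gr_normalize(H_all, ensemble_size, su_el)
  S_model <- xray_total_sq(pairset_el, Q, temperature_K = config$temperature_K)
  if (n_iterations == 0)
    r_hist <- r_factor(S_model, target_used)
  structure(list(config = ctx_config(ctx), ep_state = ep_state,
                 r_history = r_hist, scale = scale, pairset = pairset,
                 pairset_element = pairset_el, S_model = S_model,
                 S_target = S_target, snapshots = snapshots,
                 final_r = r_factor(S_model, target_used)),
            class = "epsr_fit")
}

#' @export
print.epsr_fit <- function(x, ...) {
  cat(sprintf("epsr_fit: %d ep iterations, R = %.4g (start %.4g), scale %.3f\n",
              length(x$r_history), tail(x$r_history, 1), x$r_history[1],
              x$scale))
  invisible(x)
}

# Kabsch rotation + translation mapping template core points Q onto
# observed core points P (both k x 3).
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(Q, 2, cq)) %*% sweep(P, 2, cp)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = cp - as.vector(R %*% cq))
}

#' Swap the conformer of selected molecules in place
#'
#' Replaces each selected molecule by `template_new`, rigidly aligned
#' (Kabsch) on the atoms common to both templates that no rotatable group
#' moves (the rigid core).  Positions and orientations are preserved;
#' group torsions reset to the new template's values, so a short
#' re-equilibration is advisable.
#'
#' @param config A `configuration`.
#' @param mols Molecule indices to swap.
#' @param template_new The replacement `mol_template`.
#' @return The updated configuration.
#' @export
swap_conformer <- function(config, mols, template_new) {
  if (!length(mols)) return(config)
  ti_new <- length(config$templates) + 1L
  config$templates[[ti_new]] <- template_new
  for (m in mols) {
    tpl_old <- config$templates[[config$template_of_mol[m]]]
    if (nrow(tpl_old$atoms) != nrow(template_new$atoms))
      stop("conformers must have equal atom counts for an in-place swap")
    common <- intersect(tpl_old$atoms$label, template_new$atoms$label)
    moved <- unique(c(unlist(lapply(tpl_old$groups, `[[`, "moved")),
                      unlist(lapply(template_new$groups, `[[`, "moved"))))
    core <- setdiff(common, moved)
    if (length(core) < 3) stop("rigid core too small to align conformers")
    rows <- which(config$atoms$mol == m)
    P <- config$xyz[rows[match(core, tpl_old$atoms$label)], , drop = FALSE]
    Q <- template_xyz(template_new)[match(core, template_new$atoms$label), ,
                                    drop = FALSE]
    kb <- .kabsch(P, Q)
    # atoms that relocated between the conformers (e.g. a substituent on a
    # different ring position) spoil the fit: drop residual outliers and
    # refit on the truly shared scaffold
    res <- sqrt(rowSums((sweep(Q %*% t(kb$R), 2, kb$t, "+") - P)^2))
    keep <- res < 0.5
    if (sum(keep) >= 3 && any(!keep))
      kb <- .kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
    newxyz <- sweep(template_xyz(template_new) %*% t(kb$R), 2, kb$t, "+")
    config$xyz[rows, ] <- newxyz
    config$atoms$label[rows] <- template_new$atoms$label
    config$atoms$element[rows] <- template_new$atoms$element
    config$atoms$type_key[rows] <- template_new$atoms$type_key
    config$atoms$conformer[rows] <- template_new$conformer_id
    config$template_of_mol[m] <- ti_new
  }
  config
}

#' Flip a substituent by 180 degrees about its attachment bond
#'
#' Rotates, for each selected molecule, every atom beyond the `axis` bond
#' by 180 degrees about it — e.g. the aryl-ring flip that converts the
#' nifedipine conformer with the nitro group on one ortho position into
#' the conformer with it on the other.  Unlike a template swap this
#' preserves the molecule's current torsional state exactly; only the
#' substituent orientation changes.
#'
#' @param config A `configuration`.
#' @param mols Molecule indices to flip.
#' @param axis Length-2 character vector of atom labels: the attachment
#'   bond, rotation applied to everything beyond the second atom.
#' @param new_id Conformer id recorded for flipped molecules.
#' @return The updated configuration.
#' @export
flip_substituent <- function(config, mols, axis, new_id = "flipped") {
  if (!length(mols)) return(config)
  for (m in mols) {
    tpl <- config$templates[[config$template_of_mol[m]]]
    adj <- template_adjacency(tpl)
    moved <- setdiff(.component(adj, axis[2], drop_bond = axis), axis[2])
    rows <- which(config$atoms$mol == m)
    ia <- rows[match(axis, tpl$atoms$label)]
    im <- rows[match(moved, tpl$atoms$label)]
    a <- config$xyz[ia[1], ]; b <- config$xyz[ia[2], ]
    config$xyz[im, ] <- rotate_about_axis(config$xyz[im, , drop = FALSE],
                                          a, b - a, 180)
    config$atoms$conformer[rows] <- new_id
  }
  config
}

#' Scan conformer mixture fractions against a target pattern
#'
#' For each fraction of the second conformer, builds a mixture box,
#' runs a fixed refinement budget, and reports R-factor and fitted
#' normalization scale; the minimizing fraction estimates the conformer
#' population consistent with the data.
#'
#' @param fractions Fractions of the second template, each in [0, 1].
#' @param S_target Target pattern.
#' @param templates List of two `mol_template`s (base, alternate).
#' @param n_molecules Box size in molecules.
#' @param density Atom number density.
#' @param ff Force field.
#' @param constraints Optional constraints.
#' @param seed RNG seed (same seed for every fraction, so fraction 0
#'   reproduces the single-conformer pipeline exactly).
#' @param temperature_K Temperature.
#' @param n_iterations,sweeps_per_iter,ensemble_size Refinement budget per
#'   fraction (see [refine_to_data()]).
#' @param equil_sweeps Plain equilibration sweeps of the box before the
#'   refinement (per fraction for `"rebuild"`; once for `"in_place"`).
#' @param mode `"in_place"` (default) refines one base box of the first
#'   template against the target, then scores each fraction by flipping
#'   the `flip_axis` substituent of the appropriate number of molecules in
#'   every production snapshot.  Because the flip preserves positions and
#'   torsions, the R-factor differences between fractions isolate the
#'   conformer signal from box-realization noise.  `"rebuild"` builds and
#'   refines an independent mixture box per fraction (the literal forward
#'   pipeline, noisier at small box sizes).
#' @param flip_axis Attachment bond whose 180-degree rotation converts the
#'   first template's conformer into the second's (default the nifedipine
#'   aryl flip about C4-CA1); required for `"in_place"`.
#' @param n_replicates Independent base boxes pooled in the `"in_place"`
#'   scan ensemble (box-realization noise in the fraction estimate falls
#'   roughly with its square root).
#' @param use_scale Fit the normalization scale.
#' @return data.frame(fraction, r_factor, scale) with attributes `best`
#'   (fraction minimizing the R-factor on the scanned grid) and
#'   `best_interp` (vertex of a quadratic fit through the scan, clipped to
#'   the scanned range; NA when the fit is not convex).
#' @export
scan_conformer_fraction <- function(fractions, S_target, templates,
                                    n_molecules = 16, density = 0.09,
                                    ff = reference_forcefield(),
                                    constraints = NULL, seed = 1,
                                    temperature_K = 470, n_iterations = 5,
                                    sweeps_per_iter = 10, ensemble_size = 20,
                                    equil_sweeps = 150,
                                    mode = c("in_place", "rebuild"),
                                    flip_axis = c("C4", "CA1"),
                                    n_replicates = 1, use_scale = TRUE) {
  mode <- match.arg(mode)
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  out <- data.frame(fraction = fractions, r_factor = NA_real_,
                    scale = NA_real_)
  if (mode == "in_place") {
    # the conformer fraction enters the model S(Q) through the
    # intramolecular scattering of the flipped molecules: one equilibrated
    # ensemble of the first template is collected and, for each fraction f,
    # a fraction f of its intramolecular term is replaced by that of the
    # flipped conformer (computed by the torsion-preserving 180-degree
    # flip on the same snapshots).  R(f) is then an exact quadratic whose
    # vertex is the least-squares fraction estimate, free of
    # box-realization noise between fractions.  The empirical potential is
    # deliberately left out of the scan (`n_iterations` applies to
    # "rebuild" only): it can absorb precisely the composition signal
    # being estimated.
    H_tot <- 0; H_intra <- 0; H_intra_flip <- 0
    su <- NULL
    all_mols <- seq_len(n_molecules)
    for (rep in seq_len(n_replicates)) {
      rseed <- seed + (rep - 1) * 101
      set.seed(rseed)
      base_cfg <- build_configuration(templates[[1]],
                                      n_molecules = n_molecules,
                                      density = density,
                                      temperature_K = temperature_K,
                                      seed = rseed)
      ctx <- mc_context(base_cfg, ff, constraints)
      if (equil_sweeps > 0) mc_sweeps(ctx, equil_sweeps, tune = TRUE)
      if (is.null(su)) su <- gr_setup(base_cfg, NULL, 0.02, by = "element")
      for (s in seq_len(ensemble_size)) {
        mc_sweeps(ctx, max(1, sweeps_per_iter %/% 5), tune = FALSE)
        snap <- ctx_config(ctx)
        H_tot <- H_tot + cpp_pair_hist(snap$xyz, su$tidx, snap$atoms$mol,
                                       length(su$types), snap$box_edge,
                                       su$r_max, su$dr, TRUE, TRUE)
        H_intra <- H_intra + cpp_pair_hist(snap$xyz, su$tidx, snap$atoms$mol,
                                           length(su$types), snap$box_edge,
                                           su$r_max, su$dr, TRUE, FALSE)
        flip <- flip_substituent(snap, all_mols, flip_axis)
        H_intra_flip <- H_intra_flip +
          cpp_pair_hist(flip$xyz, su$tidx, flip$atoms$mol, length(su$types),
                        flip$box_edge, su$r_max, su$dr, TRUE, FALSE)
      }
    }
    nsnap <- ensemble_size * n_replicates
    Q <- S_target$Q
    for (i in seq_along(fractions)) {
      f <- fractions[i]
      H_f <- H_tot + f * (H_intra_flip - H_intra)
      ps <- gr_normalize(H_f, nsnap, su)
      S_model <- xray_total_sq(ps, Q, temperature_K = temperature_K)
      sc <- if (use_scale) fit_scale(S_model, S_target) else 1
      tgt <- scattering_pattern(Q, 1 + sc * (S_target$S - 1))
      out$r_factor[i] <- r_factor(S_model, tgt)
      out$scale[i] <- sc
    }
  } else {
    for (i in seq_along(fractions)) {
      f <- fractions[i]
      set.seed(seed)
      mix <- conformer_mixture(templates, c(1 - f, f), n_molecules)
      cfg <- build_configuration(mix, density = density,
                                 temperature_K = temperature_K, seed = seed)
      if (equil_sweeps > 0) {
        ctx <- mc_context(cfg, ff, constraints)
        mc_sweeps(ctx, equil_sweeps, tune = TRUE)
        cfg <- ctx_config(ctx)
      }
      fit <- refine_to_data(cfg, ff, S_target, n_iterations = n_iterations,
                            constraints = constraints,
                            sweeps_per_iter = sweeps_per_iter,
                            ensemble_size = ensemble_size,
                            use_scale = use_scale)
      out$r_factor[i] <- fit$final_r
      out$scale[i] <- fit$scale
    }
  }
  attr(out, "best") <- out$fraction[which.min(out$r_factor)]
  best_interp <- NA_real_
  if (length(fractions) >= 3) {
    fit2 <- stats::lm(r_factor ~ fraction + I(fraction^2), data = out)
    cf <- stats::coef(fit2)
    if (is.finite(cf[3]) && cf[3] > 0)
      best_interp <- min(max(-cf[2] / (2 * cf[3]), min(fractions)),
                         max(fractions))
  }
  attr(out, "best_interp") <- best_interp
  out
}
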