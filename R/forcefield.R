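#' Construct a force field
#'
#' @param entries data.frame with columns `type_key`, `q` (e), `sigma`
#'   (Angstrom), `epsilon` (kJ/mol).
#' @param combining_rule Only `"lorentz-berthelot"` is implemented.
#' @return A `forcefield`.
#' @export
forcefield <- function(entries, combining_rule = "lorentz-berthelot") {
  stopifnot(all(c("type_key", "q", "sigma", "epsilon") %in% names(entries)))
  if (any(entries$sigma < 0) || any(entries$epsilon < 0))
    stop("sigma and epsilon must be non-negative")
  structure(list(entries = as.data.frame(entries),
                 combining_rule = combining_rule), class = "forcefield")
}

#' Reference force field (partial charges + Lennard-Jones)
#'
#' The starting nonbonded potential for the refinement: per-type partial
#' charges q (e) and Lennard-Jones sigma (Angstrom) / epsilon (kJ/mol),
#' with Lorentz-Berthelot combining (arithmetic sigma, geometric epsilon).
#' The typed entries cover the dihydropyridine core, the methyl-ester and
#' nitro groups, and the felodipine dichlorophenyl chlorines; atoms outside
#' those classes carry per-element default LJ parameters and zero charge.
#'
#' @return A `forcefield` object: data.frame of entries plus combining rule.
#' @export
reference_forcefield <- function() {
  e <- rbind(
    data.frame(type_key = "N_NHR",      q = -0.70, sigma = 3.25, epsilon = 0.170),
    data.frame(type_key = "N_pyridine", q = -0.70, sigma = 3.25, epsilon = 0.170),
    data.frame(type_key = "H_NHR",      q =  0.00, sigma = 0.00, epsilon = 0.000),
    data.frame(type_key = "C_pyr_nif",  q = +0.47, sigma = 3.75, epsilon = 0.105),
    data.frame(type_key = "C_pyr_fel",  q = +0.13, sigma = 3.55, epsilon = 0.700),
    data.frame(type_key = "C_alkyl",    q = +0.20, sigma = 3.50, epsilon = 0.066),
    data.frame(type_key = "Cl_fel",     q =  0.00, sigma = 3.20, epsilon = 0.800),
    data.frame(type_key = "O_carbonyl", q = -0.47, sigma = 2.96, epsilon = 0.210),
    data.frame(type_key = "C_carbonyl", q = +0.47, sigma = 3.75, epsilon = 0.105),
    data.frame(type_key = "O_ether",    q = -0.40, sigma = 2.90, epsilon = 0.140),
    data.frame(type_key = "C_methoxy",  q = +0.20, sigma = 3.50, epsilon = 0.066),
    data.frame(type_key = "N_nitro",    q = +0.45, sigma = 3.25, epsilon = 0.170),
    data.frame(type_key = "O_nitro",    q = -0.36, sigma = 2.96, epsilon = 0.210),
    data.frame(type_key = "C_nitro",    q = +0.18, sigma = 3.75, epsilon = 0.105),
    # per-element defaults for untyped atoms (zero charge)
    data.frame(type_key = "default_C",  q = 0, sigma = 3.55, epsilon = 0.290),
    data.frame(type_key = "default_H",  q = 0, sigma = 2.42, epsilon = 0.100),
    data.frame(type_key = "default_N",  q = 0, sigma = 3.25, epsilon = 0.170),
    data.frame(type_key = "default_O",  q = 0, sigma = 2.96, epsilon = 0.210),
    data.frame(type_key = "default_Cl", q = 0, sigma = 3.20, epsilon = 0.800)
  )
  structure(list(entries = e, combining_rule = "lorentz-berthelot"),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf("forcefield: %d type entries, %s combining\n",
              nrow(x$entries), x$combining_rule))
  invisible(x)
}

ff_lookup <- function(ff, type_keys) {
  i <- match(type_keys, ff$entries$type_key)
  if (anyNA(i))
    stop("unresolvable force-field type(s): ",
         paste(unique(type_keys[is.na(i)]), collapse = ", "))
  ff$entries[i, , drop = FALSE]
}

# Combined sigma/epsilon matrices over an ordered vector of type keys.
ff_pair_matrices <- function(ff, type_keys) {
  ent <- ff_lookup(ff, type_keys)
  sig <- outer(ent$sigma, ent$sigma, function(a, b) (a + b) / 2)
  # sigma=0 marks "no LJ" (e.g. the amino hydrogen): keep the pair off
  zero <- outer(ent$sigma == 0, ent$sigma == 0, "|")
  sig[zero] <- 0
  eps <- outer(ent$epsilon, ent$epsilon, function(a, b) sqrt(a * b))
  dimnames(sig) <- dimnames(eps) <- list(type_keys, type_keys)
  list(sigma = sig, epsilon = eps)
}

#' Per-atom charges for a template, with neutralization
#'
#' Looks up the tabulated partial charge of every atom and, when the raw
#' sum is non-zero, spreads a uniform neutralizing correction over the
#' atoms whose tabulated charge is zero (cutoff Coulomb sums require
#' neutral molecules for box-size-independent energies).
#'
#' @param tpl A `mol_template`.
#' @param ff A `forcefield`.
#' @param neutralize Apply the neutralizing correction (default TRUE).
#' @return Numeric vector of charges (e), with attribute `"raw_net"` giving
#'   the pre-correction net charge.
#' @export
template_charges <- function(tpl, ff, neutralize = TRUE) {
  q <- ff_lookup(ff, tpl$atoms$type_key)$q
  raw <- sum(q)
  z <- which(q == 0)
  # no zero-charge atoms to carry the correction (e.g. a bare ion): the
  # species is genuinely charged and is left alone
  if (neutralize && abs(raw) > 1e-12 && length(z) > 0)
    q[z] <- q[z] - raw / length(z)
  attr(q, "raw_net") <- raw
  q
}

#' Conformer mixture specification
#'
#' @param templates List of `mol_template`s.
#' @param fractions Numeric fractions summing to 1.
#' @param n_total Total molecule count; component counts are the rounded
#'   fraction shares (largest-remainder rounding so they sum to `n_total`).
#' @return A `conformer_mixture` object with integer per-component counts.
#' @export
conformer_mixture <- function(templates, fractions, n_total) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (any(fractions < 0)) stop("fractions must be non-negative")
  raw <- fractions * n_total
  n <- floor(raw)
  rem <- n_total - sum(n)
  if (rem > 0) {
    ord <- order(raw - n, decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1
  }
  structure(list(templates = templates, fractions = fractions,
                 counts = as.integer(n), n_total = as.integer(n_total)),
            class = "conformer_mixture")
}
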