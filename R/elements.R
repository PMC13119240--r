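#' @useDynLib epsrlite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx dnorm fft integrate optimise rnorm runif sd setNames
#' @importFrom utils head read.table tail write.csv
NULL

# Element data for the organic/pharmaceutical set handled here.
# Masses: standard atomic weights (u).  Covalent radii (Angstrom) are used
# for bond perception when regrouping crystal atoms into molecules.
.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Cl"),
  mass = c(1.008, 12.011, 14.007, 15.999, 35.453),
  Z = c(1, 6, 7, 8, 17),
  rcov = c(0.31, 0.76, 0.71, 0.66, 1.02),
  stringsAsFactors = FALSE
)

# Cromer-Mann coefficients (International Tables Vol. C, 4-Gaussian fit):
# f(Q) = sum_i a_i exp(-b_i (Q/4pi)^2) + c, Q in 1/Angstrom.
.CROMER_MANN <- list(
  H = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  Cl = list(a = c(11.4604, 7.19640, 6.25560, 1.64550),
            b = c(0.010400, 1.16620, 18.5194, 47.7784), c = -9.5574)
)

#' Atomic mass of an element
#'
#' @param element Character vector of element symbols (H, C, N, O, Cl).
#' @return Numeric vector of standard atomic weights in u.
#' @export
atomic_mass <- function(element) {
  i <- match(element, .ELEMENTS$symbol)
  if (anyNA(i)) stop("unknown element: ", paste(element[is.na(i)], collapse = ", "))
  .ELEMENTS$mass[i]
}

atomic_number <- function(element) {
  i <- match(element, .ELEMENTS$symbol)
  if (anyNA(i)) stop("unknown element: ", paste(element[is.na(i)], collapse = ", "))
  .ELEMENTS$Z[i]
}

covalent_radius <- function(element) {
  i <- match(element, .ELEMENTS$symbol)
  if (anyNA(i)) stop("unknown element: ", paste(element[is.na(i)], collapse = ", "))
  .ELEMENTS$rcov[i]
}

#' X-ray atomic form factor
#'
#' Cromer-Mann parameterization of the independent-atom X-ray form factor
#' \eqn{f(Q)}, with \eqn{f(0)} equal to the atomic number.
#'
#' @param element Element symbol.
#' @param Q Momentum transfer grid in 1/Angstrom.
#' @return Numeric vector \eqn{f(Q)}.
#' @export
xray_form_factor <- function(element, Q) {
  cm <- .CROMER_MANN[[element]]
  if (is.null(cm)) stop("no form-factor coefficients for element ", element)
  s2 <- (Q / (4 * pi))^2
  out <- rep(cm$c, length(Q))
  for (i in 1:4) out <- out + cm$a[i] * exp(-cm$b[i] * s2)
  out
}

#' Parse a molecular formula
#'
#' @param formula A Hill-style formula such as `"C17H18N2O6"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || !nzchar(formula))
    stop("unparseable formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) stop("unparseable formula: ", formula)
  el <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                         sub("^[A-Za-z]+", "", parts), "1"))
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Molecular mass from a formula
#'
#' @param formula Formula string, e.g. `"C18H19Cl2NO4"`.
#' @return Molar mass in g/mol.
#' @export
molecular_mass <- function(formula) {
  counts <- parse_formula(formula)
  sum(atomic_mass(names(counts)) * counts)
}

# Boltzmann constant, kJ/mol/K; Coulomb constant, kJ Angstrom/mol/e^2;
# Avogadro constant, 1/mol.
.KB <- 0.0083144621
.KCOUL <- 1389.35
.NA_CONST <- 6.02214076e23
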