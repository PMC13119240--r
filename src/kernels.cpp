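#include <Rcpp.h>
using namespace Rcpp;

// Coordinates are column-major N x 3; raw-pointer access in the hot loops.
// L <= 0 means an open (non-periodic) system.

static inline double mi(double d, double L, double invL) {
  if (L > 0.0) d -= L * std::nearbyint(d * invL);
  return d;
}

static inline double pd2(const double *x, int n, int i, int j, double L,
                         double invL) {
  double dx = mi(x[i] - x[j], L, invL);
  double dy = mi(x[i + n] - x[j + n], L, invL);
  double dz = mi(x[i + 2 * n] - x[j + 2 * n], L, invL);
  return dx * dx + dy * dy + dz * dz;
}

// Index of unordered type pair (a,b), 0-based, a<=b, among T*(T+1)/2 pairs.
static inline int pair_idx(int a, int b, int T) {
  if (a > b) std::swap(a, b);
  return a * T - a * (a + 1) / 2 + b;
}

// [[Rcpp::export]]
IntegerMatrix cpp_pair_hist(NumericMatrix xyz, IntegerVector type,
                            IntegerVector mol, int ntypes, double L,
                            double rmax, double dr, bool include_intra,
                            bool include_inter) {
  const int n = xyz.nrow();
  const double *x = REAL(xyz);
  const double invL = L > 0 ? 1.0 / L : 0.0;
  const int nbin = (int)std::ceil(rmax / dr);
  const int np = ntypes * (ntypes + 1) / 2;
  IntegerMatrix H(nbin, np);
  int *h = INTEGER(H);
  const int *tp = INTEGER(type);
  const int *ml = INTEGER(mol);
  const double rmax2 = rmax * rmax, invdr = 1.0 / dr;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool same = ml[i] == ml[j];
      if (same ? !include_intra : !include_inter) continue;
      double r2 = pd2(x, n, i, j, L, invL);
      if (r2 >= rmax2) continue;
      int b = (int)(std::sqrt(r2) * invdr);
      if (b >= nbin) continue;
      h[b + nbin * pair_idx(tp[i], tp[j], ntypes)]++;
    }
  }
  return H;
}

static const double KCOUL = 1389.35; // kJ Angstrom / mol / e^2

struct PairTables {
  const double *sig, *eps, *q, *mind, *ep;
  int T, ep_nb, ep_np;
  double rcut2, rcut, shiftterm, inv_ep_dr;
  bool shift, has_ep;
};

static inline double pair_energy(double r2, int a, int b, int i, int j,
                                 const PairTables &pt) {
  double e = 0.0;
  double s = pt.sig[a + pt.T * b], ep = pt.eps[a + pt.T * b];
  if (ep > 0.0 && s > 0.0) {
    double sr6 = s * s / r2;
    sr6 = sr6 * sr6 * sr6;
    e += 4.0 * ep * (sr6 * sr6 - sr6);
  }
  double qq = pt.q[i] * pt.q[j];
  if (qq != 0.0) {
    double r = std::sqrt(r2);
    e += KCOUL * qq * (1.0 / r - pt.shiftterm);
  }
  return e;
}

// Tabulated empirical potential, linear interpolation; table value k sits
// at r = (k + 0.5) * ep_dr; zero beyond the table.
static inline double ep_energy(double r, int pidx, const PairTables &pt) {
  double xx = r * pt.inv_ep_dr - 0.5;
  const double *col = pt.ep + (size_t)pt.ep_nb * pidx;
  if (xx <= 0.0) return col[0];
  int k = (int)xx;
  if (k >= pt.ep_nb - 1) return 0.0;
  double f = xx - k;
  return (1.0 - f) * col[k] + f * col[k + 1];
}

static PairTables make_tables(NumericMatrix &sig, NumericMatrix &eps,
                              NumericVector &q, NumericMatrix &mind,
                              NumericMatrix &ep_tab, double ep_dr,
                              double rcut, bool shift) {
  PairTables pt;
  pt.sig = REAL(sig); pt.eps = REAL(eps); pt.q = REAL(q);
  pt.mind = REAL(mind); pt.ep = REAL(ep_tab);
  pt.T = sig.nrow();
  pt.ep_nb = ep_tab.nrow(); pt.ep_np = ep_tab.ncol();
  pt.has_ep = pt.ep_nb > 0;
  pt.inv_ep_dr = 1.0 / ep_dr;
  pt.rcut = rcut;
  pt.rcut2 = R_finite(rcut) ? rcut * rcut : R_PosInf;
  pt.shift = shift;
  pt.shiftterm = (shift && R_finite(rcut)) ? 1.0 / rcut : 0.0;
  return pt;
}

// Total energy: intermolecular pairs plus an explicit list of included
// intramolecular pairs (1-4 and beyond; 0-based indices).
// [[Rcpp::export]]
List cpp_energy_total(NumericMatrix xyz, IntegerVector type, IntegerVector mol,
                      NumericMatrix sig, NumericMatrix eps, NumericVector q,
                      double L, double rcut, bool shift, NumericMatrix mind,
                      IntegerVector intra_i, IntegerVector intra_j,
                      NumericMatrix ep_tab, double ep_dr) {
  const int n = xyz.nrow();
  const double *x = REAL(xyz);
  const double invL = L > 0 ? 1.0 / L : 0.0;
  const int *tp = INTEGER(type);
  const int *ml = INTEGER(mol);
  PairTables pt = make_tables(sig, eps, q, mind, ep_tab, ep_dr, rcut, shift);
  double E = 0.0;
  bool ok = true;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (ml[i] == ml[j]) continue;
      double r2 = pd2(x, n, i, j, L, invL);
      if (r2 <= 1e-12) stop("zero interatomic distance");
      int a = tp[i], b = tp[j];
      double md = pt.mind[a + pt.T * b];
      if (md > 0.0 && r2 < md * md) ok = false;
      if (r2 < pt.rcut2) E += pair_energy(r2, a, b, i, j, pt);
      if (pt.has_ep)
        E += ep_energy(std::sqrt(r2), pair_idx(a, b, pt.T), pt);
    }
  }
  for (int k = 0; k < intra_i.size(); ++k) {
    int i = intra_i[k], j = intra_j[k];
    double r2 = pd2(x, n, i, j, L, invL);
    if (r2 <= 1e-12) stop("zero interatomic distance");
    if (r2 < pt.rcut2) E += pair_energy(r2, tp[i], tp[j], i, j, pt);
  }
  return List::create(_["energy"] = E, _["ok"] = ok);
}

// Energy of one molecule against all other molecules, plus its own included
// intramolecular pairs.  Used for Metropolis delta-U evaluation.
// [[Rcpp::export]]
List cpp_energy_mol(NumericMatrix xyz, IntegerVector type, IntegerVector mol,
                    int imol, NumericMatrix sig, NumericMatrix eps,
                    NumericVector q, double L, double rcut, bool shift,
                    NumericMatrix mind, IntegerVector intra_i,
                    IntegerVector intra_j, NumericMatrix ep_tab,
                    double ep_dr) {
  const int n = xyz.nrow();
  const double *x = REAL(xyz);
  const double invL = L > 0 ? 1.0 / L : 0.0;
  const int *tp = INTEGER(type);
  const int *ml = INTEGER(mol);
  PairTables pt = make_tables(sig, eps, q, mind, ep_tab, ep_dr, rcut, shift);
  double E = 0.0;
  bool ok = true;
  double minratio2 = R_PosInf; // min over pairs of (r / minimum-distance)^2
  for (int i = 0; i < n; ++i) {
    if (ml[i] != imol) continue;
    for (int j = 0; j < n; ++j) {
      if (ml[j] == imol) continue;
      double r2 = pd2(x, n, i, j, L, invL);
      if (r2 <= 1e-12) stop("zero interatomic distance");
      int a = tp[i], b = tp[j];
      double md = pt.mind[a + pt.T * b];
      if (md > 0.0) {
        double ratio2 = r2 / (md * md);
        if (ratio2 < minratio2) minratio2 = ratio2;
        if (ratio2 < 1.0) ok = false;
      }
      if (r2 < pt.rcut2) E += pair_energy(r2, a, b, i, j, pt);
      if (pt.has_ep)
        E += ep_energy(std::sqrt(r2), pair_idx(a, b, pt.T), pt);
    }
  }
  for (int k = 0; k < intra_i.size(); ++k) {
    int i = intra_i[k], j = intra_j[k];
    double r2 = pd2(x, n, i, j, L, invL);
    if (r2 <= 1e-12) stop("zero interatomic distance");
    if (r2 < pt.rcut2) E += pair_energy(r2, tp[i], tp[j], i, j, pt);
  }
  return List::create(_["energy"] = E, _["ok"] = ok,
                      _["minratio"] = std::sqrt(minratio2));
}

// Smallest intermolecular distance in the box (overlap audits).
// [[Rcpp::export]]
double cpp_min_intermol_dist(NumericMatrix xyz, IntegerVector mol, double L) {
  const int n = xyz.nrow();
  const double *x = REAL(xyz);
  const double invL = L > 0 ? 1.0 / L : 0.0;
  const int *ml = INTEGER(mol);
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      if (ml[i] == ml[j]) continue;
      double r2 = pd2(x, n, i, j, L, invL);
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

// Minimum cross distance between two coordinate sets, with early abort
// once a distance below `abort_below` is found (insertion screening).
// [[Rcpp::export]]
double cpp_min_cross_dist(NumericMatrix A, NumericMatrix B, double L,
                          double abort_below) {
  const int na = A.nrow(), nb = B.nrow();
  const double *a = REAL(A), *b = REAL(B);
  const double invL = L > 0 ? 1.0 / L : 0.0;
  const double ab2 = abort_below * abort_below;
  double best = R_PosInf;
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double dx = mi(a[i] - b[j], L, invL);
      double dy = mi(a[i + na] - b[j + nb], L, invL);
      double dz = mi(a[i + 2 * na] - b[j + 2 * nb], L, invL);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) {
        best = r2;
        if (best < ab2) return std::sqrt(best);
      }
    }
  return std::sqrt(best);
}

// Per-center counts of selected neighbour atoms (on other molecules)
// within each radius; brute-force oracle for running coordination numbers
// and class-resolved censuses.
// [[Rcpp::export]]
NumericVector cpp_neighbor_counts(NumericMatrix xyz, IntegerVector mol,
                                  IntegerVector centers, IntegerVector nbrs,
                                  double L, NumericVector radii) {
  const int n = xyz.nrow();
  const double *x = REAL(xyz);
  const double invL = L > 0 ? 1.0 / L : 0.0;
  NumericVector out(radii.size());
  for (int ci = 0; ci < centers.size(); ++ci) {
    int i = centers[ci];
    for (int nj = 0; nj < nbrs.size(); ++nj) {
      int j = nbrs[nj];
      if (i == j || mol[i] == mol[j]) continue;
      double r = std::sqrt(pd2(x, n, i, j, L, invL));
      for (int k = 0; k < radii.size(); ++k)
        if (r <= radii[k]) out[k] += 1.0;
    }
  }
  if (centers.size() > 0) out = out / (double)centers.size();
  return out;
}
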