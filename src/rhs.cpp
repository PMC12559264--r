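#include <Rcpp.h>
using namespace Rcpp;

// Network right-hand side, mirroring rhs_r() in R/hemodynamics.R
// exactly: secant-conductance freeze of the algebraic edges, exact
// linear solve of the chamber viscoelastic pressure conditions, one
// refresh pass, then flows and volume derivatives.  The double-Hill
// elastance uses the normalization constant precomputed in R so both
// implementations see an identical waveform.

static inline double wrap01(double x) {
  return x - std::floor(x);
}

static void solve_small(std::vector<double>& A, std::vector<double>& b,
                        int n) {
  // Gaussian elimination with partial pivoting on an n x n system
  for (int col = 0; col < n; ++col) {
    int piv = col;
    for (int r = col + 1; r < n; ++r)
      if (std::fabs(A[r * n + col]) > std::fabs(A[piv * n + col])) piv = r;
    if (piv != col) {
      for (int c2 = 0; c2 < n; ++c2)
        std::swap(A[col * n + c2], A[piv * n + c2]);
      std::swap(b[col], b[piv]);
    }
    double d = A[col * n + col];
    for (int r = col + 1; r < n; ++r) {
      double f = A[r * n + col] / d;
      for (int c2 = col; c2 < n; ++c2) A[r * n + c2] -= f * A[col * n + c2];
      b[r] -= f * b[col];
    }
  }
  for (int r = n - 1; r >= 0; --r) {
    double s = b[r];
    for (int c2 = r + 1; c2 < n; ++c2) s -= A[r * n + c2] * b[c2];
    b[r] = s / A[r * n + r];
  }
}

// [[Rcpp::export]]
List fontan_rhs(double t, NumericVector y, List p) {
  const int nv = as<int>(p["nv"]);
  const int ni = as<int>(p["ni"]);
  NumericVector C = p["C"], V0 = p["V0"];
  IntegerVector ch_node = p["ch_node"];
  NumericMatrix ch_par = p["ch_par"];
  IntegerVector a_from = p["a_from"], a_to = p["a_to"], a_type = p["a_type"];
  NumericVector a_R = p["a_R"], a_g = p["a_g"], a_n = p["a_n"], a_w = p["a_w"];
  IntegerVector i_from = p["i_from"], i_to = p["i_to"];
  NumericVector i_R = p["i_R"], i_L = p["i_L"];
  IntegerVector alg_edge = p["alg_edge"], inr_edge = p["inr_edge"];
  const double period = as<double>(p["period"]);
  const int na = a_from.size();
  const int nch = ch_node.size();
  const int ne = alg_edge.size() + inr_edge.size();

  for (int i = 0; i < nv + ni; ++i)
    if (!R_finite(y[i]))
      stop("non-finite state encountered in state variable %d", i + 1);

  std::vector<double> P(nv), Pe(nch), ceff(na), dV(nv, 0.0);
  std::vector<int> ch_of(nv, -1);

  for (int i = 0; i < nv; ++i)
    P[i] = (C[i] > 0) ? (y[i] - V0[i]) / C[i] : 0.0;

  bool any_visc = false;
  for (int c = 0; c < nch; ++c) {
    double tn = wrap01(t / period - ch_par(c, 4));
    double h1 = std::pow(tn / ch_par(c, 5), ch_par(c, 7));
    double phi = (h1 / (1.0 + h1)) /
                 (1.0 + std::pow(tn / ch_par(c, 6), ch_par(c, 8))) /
                 ch_par(c, 9);
    double E = ch_par(c, 1) + (ch_par(c, 0) - ch_par(c, 1)) * phi;
    Pe[c] = E * (y[ch_node[c] - 1] - ch_par(c, 2));
    P[ch_node[c] - 1] = Pe[c];
    ch_of[ch_node[c] - 1] = c;
    if (ch_par(c, 3) > 0) any_visc = true;
  }

  for (int pass = 0; pass < 2; ++pass) {
    for (int k = 0; k < na; ++k) {
      double dp = P[a_from[k] - 1] - P[a_to[k] - 1];
      double ce;
      if (a_type[k] == 2) {           // valve (regularized diode)
        if (dp >= 2.0 * a_w[k]) ce = (dp - a_w[k]) / (dp * a_R[k]);
        else if (dp > 0) ce = dp / (4.0 * a_w[k] * a_R[k]);
        else ce = a_g[k];
      } else if (a_type[k] == 3) {    // shunt
        ce = a_g[k] * std::pow(std::fabs(dp), a_n[k] - 1.0);
      } else {                        // resistor
        ce = 1.0 / a_R[k];
      }
      ceff[k] = ce;
    }
    if (nch == 0 || !any_visc) continue;

    std::vector<double> A(nch * nch, 0.0), b(nch);
    for (int c = 0; c < nch; ++c) { A[c * nch + c] = 1.0; b[c] = Pe[c]; }
    for (int k = 0; k < na; ++k) {
      int ends[2] = {a_from[k] - 1, a_to[k] - 1};
      for (int s = 0; s < 2; ++s) {
        int c = ch_of[ends[s]];
        if (c < 0) continue;
        int o = ends[1 - s];
        double vc = ch_par(c, 3);
        A[c * nch + c] += vc * ceff[k];
        int d = ch_of[o];
        if (d < 0) b[c] += vc * ceff[k] * P[o];
        else A[c * nch + d] -= vc * ceff[k];
      }
    }
    for (int k = 0; k < ni; ++k) {
      int c = ch_of[i_to[k] - 1];
      if (c >= 0) b[c] += ch_par(c, 3) * y[nv + k];
      c = ch_of[i_from[k] - 1];
      if (c >= 0) b[c] -= ch_par(c, 3) * y[nv + k];
    }
    solve_small(A, b, nch);
    for (int c = 0; c < nch; ++c) P[ch_node[c] - 1] = b[c];
  }

  std::vector<double> Qa(na);
  for (int k = 0; k < na; ++k) {
    Qa[k] = ceff[k] * (P[a_from[k] - 1] - P[a_to[k] - 1]);
    dV[a_from[k] - 1] -= Qa[k];
    dV[a_to[k] - 1] += Qa[k];
  }
  for (int k = 0; k < ni; ++k) {
    double q = y[nv + k];
    dV[i_from[k] - 1] -= q;
    dV[i_to[k] - 1] += q;
  }

  NumericVector dy(nv + ni);
  for (int i = 0; i < nv; ++i) dy[i] = dV[i];
  for (int k = 0; k < ni; ++k)
    dy[nv + k] = (P[i_from[k] - 1] - P[i_to[k] - 1] - i_R[k] * y[nv + k]) /
                 i_L[k];

  NumericVector aux(nv + ne);
  for (int i = 0; i < nv; ++i) aux[i] = P[i];
  for (int k = 0; k < na; ++k) aux[nv + alg_edge[k] - 1] = Qa[k];
  for (int k = 0; k < ni; ++k) aux[nv + inr_edge[k] - 1] = y[nv + k];

  return List::create(dy, aux);
}
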