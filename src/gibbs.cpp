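// Single full Gibbs sweep over liabilities and location effects for the
// threshold random-regression animal model. All randomness comes from R's
// RNG stream (R::*), so chains are reproducible from set.seed() and can be
// resumed mid-stream. State vectors are updated in place; the R driver owns
// them and never aliases them.
//
// The per-animal and per-ewe full conditionals are q x q systems (q <= 8);
// they are solved with hand-rolled Cholesky routines on stack arrays, which
// is an order of magnitude faster than calling LAPACK at this size.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#define QMAX 16

// Inverse-CDF truncated-normal draw, safe in extreme tails (no rejection).
static double rtnorm1(double mu, double sd, double lo, double hi) {
  double a = (lo - mu) / sd, b = (hi - mu) / sd;
  double pa = std::isfinite(a) ? R::pnorm(a, 0.0, 1.0, 1, 0) : 0.0;
  double pb = std::isfinite(b) ? R::pnorm(b, 0.0, 1.0, 1, 0) : 1.0;
  double u = R::unif_rand();
  double z = R::qnorm(pa + u * (pb - pa), 0.0, 1.0, 1, 0);
  if (z < a) z = a;
  if (z > b) z = b;
  if (!std::isfinite(z)) z = std::isfinite(b) ? b : a;  // negligible-mass interval
  return mu + sd * z;
}

// Lower Cholesky of the q x q matrix C (row-major indexing C[i*q+j]).
static bool chol_small(const double* C, double* L, int q) {
  for (int i = 0; i < q; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = C[i * q + j];
      for (int k = 0; k < j; ++k) s -= L[i * q + k] * L[j * q + k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i * q + i] = std::sqrt(s);
      } else {
        L[i * q + j] = s / L[j * q + j];
      }
    }
    for (int j = i + 1; j < q; ++j) L[i * q + j] = 0.0;
  }
  return true;
}

// Solve L y = x in place (forward substitution).
static void solve_lower(const double* L, double* x, int q) {
  for (int i = 0; i < q; ++i) {
    double s = x[i];
    for (int k = 0; k < i; ++k) s -= L[i * q + k] * x[k];
    x[i] = s / L[i * q + i];
  }
}

// Solve L' y = x in place (back substitution).
static void solve_upper(const double* L, double* x, int q) {
  for (int i = q - 1; i >= 0; --i) {
    double s = x[i];
    for (int k = i + 1; k < q; ++k) s -= L[k * q + i] * x[k];
    x[i] = s / L[i * q + i];
  }
}

// Draw from N(C^-1 rhs, C^-1) into out; returns false on a singular C.
static bool draw_block(const double* C, const double* rhs, double* out, int q) {
  double L[QMAX * QMAX];
  if (!chol_small(C, L, q)) return false;
  double m[QMAX];
  for (int k = 0; k < q; ++k) m[k] = rhs[k];
  solve_lower(L, m, q);
  solve_upper(L, m, q);
  double z[QMAX];
  for (int k = 0; k < q; ++k) z[k] = R::norm_rand();
  solve_upper(L, z, q);
  for (int k = 0; k < q; ++k) out[k] = m[k] + z[k];
  return true;
}

// [[Rcpp::export(name = ".gibbs_sweep_cpp")]]
void gibbs_sweep_cpp(NumericVector l, NumericVector e, NumericVector b,
                     NumericMatrix a, NumericMatrix p,
                     const IntegerVector year_col,   // 1-based column of b
                     const IntegerVector month_col,  // 0 = reference, else 1-based
                     const IntegerVector anim_idx,   // 1-based
                     const IntegerVector ewe_idx,    // 1-based
                     const IntegerVector par_idx,    // 1-based parity class
                     const IntegerVector cls_idx,    // 1-based residual class
                     const IntegerVector cat_idx,    // 1-based category
                     const NumericMatrix phi,        // q x n_parity
                     const NumericMatrix Ginv, const NumericMatrix Pinv,
                     const NumericVector sig2e,      // per residual class
                     const NumericVector tau,        // length n_cat + 1, +-Inf ends
                     const IntegerVector Ap, const IntegerVector Ai,
                     const NumericVector Ax,         // A-inverse, CSC, 0-based
                     const IntegerVector arec_ptr, const IntegerVector arec_idx,
                     const IntegerVector erec_ptr, const IntegerVector erec_idx,
                     const IntegerVector ewe_anim,  // 1-based animal of each ewe
                     const int ny, const int nmcol, const double fixed_prec,
                     const bool update_liab,
                     NumericMatrix Sa_out,           // q x q scatter a' Ainv a
                     NumericMatrix Sp_out,           // q x q scatter p p'
                     NumericVector sse_out) {        // residual SS per class
  const int nrec = l.size();
  const int q = a.nrow();
  if (2 * q > QMAX) stop("polynomial order too high for the compiled sweep");
  const int n_anim = a.ncol();
  const int n_ewe = p.ncol();
  const int nb = b.size();
  const int qf = nb - ny - nmcol;
  double winv[3];
  for (int k = 0; k < 3 && k < sig2e.size(); ++k) winv[k] = 1.0 / sig2e[k];

  // --- liabilities -------------------------------------------------------
  if (update_liab) {
    for (int r = 0; r < nrec; ++r) {
      double mu = l[r] - e[r];
      double sd = std::sqrt(sig2e[cls_idx[r] - 1]);
      int c = cat_idx[r];
      double ln = rtnorm1(mu, sd, tau[c - 1], tau[c]);
      e[r] += ln - l[r];
      l[r] = ln;
    }
  }

  // --- year effects (disjoint indicator block: one joint pass) -----------
  {
    std::vector<double> num(ny, 0.0), den(ny, fixed_prec), bn(ny);
    for (int r = 0; r < nrec; ++r) {
      int j = year_col[r] - 1;
      double w = winv[cls_idx[r] - 1];
      num[j] += w * (e[r] + b[j]);
      den[j] += w;
    }
    for (int j = 0; j < ny; ++j) {
      double m = (den[j] > 0) ? num[j] / den[j] : 0.0;
      double s = (den[j] > 0) ? std::sqrt(1.0 / den[j]) : 1.0;
      bn[j] = m + s * R::norm_rand();
    }
    for (int r = 0; r < nrec; ++r) {
      int j = year_col[r] - 1;
      e[r] -= bn[j] - b[j];
    }
    for (int j = 0; j < ny; ++j) b[j] = bn[j];
  }

  // --- month effects (disjoint as well) ----------------------------------
  if (nmcol > 0) {
    std::vector<double> num(nmcol, 0.0), den(nmcol, fixed_prec), bn(nmcol);
    for (int r = 0; r < nrec; ++r) {
      int j = month_col[r];
      if (j == 0) continue;
      double w = winv[cls_idx[r] - 1];
      num[j - 1] += w * (e[r] + b[ny + j - 1]);
      den[j - 1] += w;
    }
    for (int j = 0; j < nmcol; ++j) {
      double m = (den[j] > 0) ? num[j] / den[j] : 0.0;
      double s = (den[j] > 0) ? std::sqrt(1.0 / den[j]) : 1.0;
      bn[j] = m + s * R::norm_rand();
    }
    for (int r = 0; r < nrec; ++r) {
      int j = month_col[r];
      if (j > 0) e[r] -= bn[j - 1] - b[ny + j - 1];
    }
    for (int j = 0; j < nmcol; ++j) b[ny + j] = bn[j];
  }

  // --- fixed-regression coefficients, single site -------------------------
  for (int k = 0; k < qf; ++k) {
    int jb = ny + nmcol + k;
    double num = 0.0, den = fixed_prec;
    for (int r = 0; r < nrec; ++r) {
      double x = phi(k, par_idx[r] - 1);
      double w = winv[cls_idx[r] - 1];
      num += w * x * (e[r] + x * b[jb]);
      den += w * x * x;
    }
    double m = (den > 0) ? num / den : 0.0;
    double s = (den > 0) ? std::sqrt(1.0 / den) : 1.0;
    double bn = m + s * R::norm_rand();
    for (int r = 0; r < nrec; ++r) {
      double x = phi(k, par_idx[r] - 1);
      e[r] -= x * (bn - b[jb]);
    }
    b[jb] = bn;
  }

  // --- additive genetic coefficients of animals without records -----------
  // Recorded ewes are handled below in a joint (a, p) block per ewe, which
  // mixes the genetic/permanent-environment partition far better than
  // alternating single blocks (a and p are strongly confounded per ewe).
  double C[4 * QMAX * QMAX], rhs[2 * QMAX], sum[QMAX], bnew[2 * QMAX];
  for (int i = 0; i < n_anim; ++i) {
    if (arec_ptr[i + 1] > arec_ptr[i]) continue;  // recorded: joint block below
    double aii = 0.0;
    for (int k = 0; k < q; ++k) sum[k] = 0.0;
    for (int idx = Ap[i]; idx < Ap[i + 1]; ++idx) {
      int j = Ai[idx];
      if (j == i) aii = Ax[idx];
      else {
        double v = Ax[idx];
        for (int k = 0; k < q; ++k) sum[k] += v * a(k, j);
      }
    }
    for (int ki = 0; ki < q; ++ki) {
      double ri = 0.0;
      for (int kj = 0; kj < q; ++kj) {
        C[ki * q + kj] = aii * Ginv(ki, kj);
        ri += Ginv(ki, kj) * sum[kj];
      }
      rhs[ki] = -ri;
    }
    if (!draw_block(C, rhs, bnew, q))
      stop("singular conditional covariance in genetic block");
    for (int k = 0; k < q; ++k) a(k, i) = bnew[k];
  }

  // --- joint (genetic, permanent-environment) block per recorded ewe ------
  const int q2 = 2 * q;
  for (int iw = 0; iw < n_ewe; ++iw) {
    int i = ewe_anim[iw] - 1;                   // animal index of this ewe
    double aii = 0.0;
    for (int k = 0; k < q; ++k) sum[k] = 0.0;
    for (int idx = Ap[i]; idx < Ap[i + 1]; ++idx) {
      int j = Ai[idx];
      if (j == i) aii = Ax[idx];
      else {
        double v = Ax[idx];
        for (int k = 0; k < q; ++k) sum[k] += v * a(k, j);
      }
    }
    for (int ki = 0; ki < q2; ++ki)
      for (int kj = 0; kj < q2; ++kj) C[ki * q2 + kj] = 0.0;
    for (int ki = 0; ki < q; ++ki) {
      double ri = 0.0;
      for (int kj = 0; kj < q; ++kj) {
        C[ki * q2 + kj] = aii * Ginv(ki, kj);
        C[(q + ki) * q2 + (q + kj)] = Pinv(ki, kj);
        ri += Ginv(ki, kj) * sum[kj];
      }
      rhs[ki] = -ri;
      rhs[q + ki] = 0.0;
    }
    for (int ptr = erec_ptr[iw]; ptr < erec_ptr[iw + 1]; ++ptr) {
      int r = erec_idx[ptr];
      const double* ph = &phi(0, par_idx[r] - 1);
      double w = winv[cls_idx[r] - 1];
      double ytil = e[r];
      for (int k = 0; k < q; ++k) ytil += ph[k] * (a(k, i) + p(k, iw));
      double wy = w * ytil;
      for (int ki = 0; ki < q; ++ki) {
        rhs[ki] += wy * ph[ki];
        rhs[q + ki] += wy * ph[ki];
        for (int kj = 0; kj < q; ++kj) {
          double ww = w * ph[ki] * ph[kj];
          C[ki * q2 + kj] += ww;
          C[(q + ki) * q2 + (q + kj)] += ww;
          C[ki * q2 + (q + kj)] += ww;
          C[(q + ki) * q2 + kj] += ww;
        }
      }
    }
    if (!draw_block(C, rhs, bnew, q2))
      stop("singular conditional covariance in ewe block");
    for (int ptr = erec_ptr[iw]; ptr < erec_ptr[iw + 1]; ++ptr) {
      int r = erec_idx[ptr];
      const double* ph = &phi(0, par_idx[r] - 1);
      double de = 0.0;
      for (int k = 0; k < q; ++k)
        de += ph[k] * (bnew[k] - a(k, i) + bnew[q + k] - p(k, iw));
      e[r] -= de;
    }
    for (int k = 0; k < q; ++k) {
      a(k, i) = bnew[k];
      p(k, iw) = bnew[q + k];
    }
  }

  // --- scatter matrices and residual sums of squares ----------------------
  // Sa = a' A^-1 a over coefficient vectors; exploits CSC symmetry.
  for (int ki = 0; ki < q; ++ki)
    for (int kj = 0; kj < q; ++kj) Sa_out(ki, kj) = 0.0;
  for (int i = 0; i < n_anim; ++i) {
    for (int idx = Ap[i]; idx < Ap[i + 1]; ++idx) {
      int j = Ai[idx];
      double v = Ax[idx];
      for (int ki = 0; ki < q; ++ki)
        for (int kj = 0; kj < q; ++kj)
          Sa_out(ki, kj) += v * a(ki, j) * a(kj, i);
    }
  }
  for (int ki = 0; ki < q; ++ki)
    for (int kj = 0; kj < q; ++kj) Sp_out(ki, kj) = 0.0;
  for (int i = 0; i < n_ewe; ++i)
    for (int ki = 0; ki < q; ++ki)
      for (int kj = 0; kj <= ki; ++kj)
        Sp_out(ki, kj) += p(ki, i) * p(kj, i);
  for (int ki = 0; ki < q; ++ki)
    for (int kj = ki + 1; kj < q; ++kj) Sp_out(ki, kj) = Sp_out(kj, ki);
  for (int k = 0; k < sse_out.size(); ++k) sse_out[k] = 0.0;
  for (int r = 0; r < nrec; ++r) sse_out[cls_idx[r] - 1] += e[r] * e[r];
}

// Vectorized inverse-CDF truncated normal used by the R-facing wrapper.
// [[Rcpp::export(name = ".rtnorm_cpp")]]
NumericVector rtnorm_cpp(int n, NumericVector mean, NumericVector sd,
                         NumericVector lower, NumericVector upper) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = rtnorm1(mean[i % mean.size()], sd[i % sd.size()],
                     lower[i % lower.size()], upper[i % upper.size()]);
  }
  return out;
}
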