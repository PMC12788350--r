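// Fused elementwise / gather kernels for the training loop.  Everything the
// network does that is not a BLAS matmul is memory-bound in plain R because
// each elementwise step allocates a full temporary; these kernels fuse the
// passes.  Site matrices are (B*T*J) x C with rows ordered b fastest, then
// t, then j (column-major R layout of a (B, T, J, C) array).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// y[i, c] = x[i, c] + b[c]
// [[Rcpp::export]]
NumericMatrix addColVec(const NumericMatrix& x, const NumericVector& b) {
  const R_xlen_t n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (R_xlen_t j = 0; j < c; ++j) {
    const double bj = b[j];
    const double* xc = x.begin() + j * n;
    double* yc = y.begin() + j * n;
    for (R_xlen_t i = 0; i < n; ++i) yc[i] = xc[i] + bj;
  }
  return y;
}

// y[i, c] = x[i, c] * s[c] + b[c]
// [[Rcpp::export]]
NumericMatrix colScaleShift(const NumericMatrix& x, const NumericVector& s,
                            const NumericVector& b) {
  const R_xlen_t n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (R_xlen_t j = 0; j < c; ++j) {
    const double sj = s[j], bj = b[j];
    const double* xc = x.begin() + j * n;
    double* yc = y.begin() + j * n;
    for (R_xlen_t i = 0; i < n; ++i) yc[i] = xc[i] * sj + bj;
  }
  return y;
}

// max(x * s[c] + b[c], 0)
// [[Rcpp::export]]
NumericMatrix scaleShiftRelu(const NumericMatrix& x, const NumericVector& s,
                             const NumericVector& b) {
  const R_xlen_t n = x.nrow(), c = x.ncol();
  NumericMatrix y(n, c);
  for (R_xlen_t j = 0; j < c; ++j) {
    const double sj = s[j], bj = b[j];
    const double* xc = x.begin() + j * n;
    double* yc = y.begin() + j * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double v = xc[i] * sj + bj;
      yc[i] = v > 0 ? v : 0;
    }
  }
  return y;
}

// per-column mean and population variance in one pass
// [[Rcpp::export]]
List colMoments(const NumericMatrix& x) {
  const R_xlen_t n = x.nrow(), c = x.ncol();
  NumericVector mean(c), var(c);
  for (R_xlen_t j = 0; j < c; ++j) {
    const double* xc = x.begin() + j * n;
    double s = 0, q = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; q += xc[i] * xc[i]; }
    const double m = s / n;
    mean[j] = m;
    const double v = q / n - m * m;
    var[j] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// Training-mode batch norm, optionally fused with ReLU:
//   out = (relu of) xhat * gamma[c] + beta[c],  xhat = (x - mean)/sd(batch)
// [[Rcpp::export]]
List bnTrainC(const NumericMatrix& x, const NumericVector& gamma,
              const NumericVector& beta, double eps, bool relu) {
  const R_xlen_t n = x.nrow(), c = x.ncol();
  NumericMatrix out(n, c), xhat(n, c);
  NumericVector mean(c), var(c);
  for (R_xlen_t j = 0; j < c; ++j) {
    const double* xc = x.begin() + j * n;
    double s = 0, q = 0;
    for (R_xlen_t i = 0; i < n; ++i) { s += xc[i]; q += xc[i] * xc[i]; }
    const double m = s / n;
    double v = q / n - m * m;
    if (v < 0) v = 0;
    mean[j] = m; var[j] = v;
    const double inv = 1.0 / std::sqrt(v + eps);
    const double g = gamma[j], b = beta[j];
    double* oc = out.begin() + j * n;
    double* hc = xhat.begin() + j * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double h = (xc[i] - m) * inv;
      hc[i] = h;
      const double y = h * g + b;
      oc[i] = (relu && y < 0) ? 0 : y;
    }
  }
  return List::create(_["out"] = out, _["xhat"] = xhat, _["mean"] = mean,
                      _["var"] = var);
}

// Eval-mode batch norm with running statistics, optional fused ReLU.
// [[Rcpp::export]]
NumericMatrix bnEvalC(const NumericMatrix& x, const NumericVector& gamma,
                      const NumericVector& beta, const NumericVector& mean,
                      const NumericVector& var, double eps, bool relu) {
  const R_xlen_t n = x.nrow(), c = x.ncol();
  NumericMatrix out(n, c);
  for (R_xlen_t j = 0; j < c; ++j) {
    const double inv = 1.0 / std::sqrt(var[j] + eps);
    const double g = gamma[j], b = beta[j], m = mean[j];
    const double* xc = x.begin() + j * n;
    double* oc = out.begin() + j * n;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double y = (xc[i] - m) * inv * g + b;
      oc[i] = (relu && y < 0) ? 0 : y;
    }
  }
  return out;
}

// Full batch-norm backward given the normalised activations:
//   t1 = dy * gammaInv[c];  dx = t1 - mean_col(t1) - xhat * mean_col(t1*xhat)
//   dgamma = colSums(dy * xhat);  dbeta = colSums(dy)
// [[Rcpp::export]]
List bnBwd(const NumericMatrix& dy, const NumericMatrix& xhat,
           const NumericVector& gammaInv) {
  const R_xlen_t n = dy.nrow(), c = dy.ncol();
  NumericMatrix dx(n, c);
  NumericVector dgamma(c), dbeta(c);
  for (R_xlen_t j = 0; j < c; ++j) {
    const double gi = gammaInv[j];
    const double* dyc = dy.begin() + j * n;
    const double* xhc = xhat.begin() + j * n;
    double s1 = 0, s2 = 0, sg = 0, sb = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      const double t1 = dyc[i] * gi;
      s1 += t1;
      s2 += t1 * xhc[i];
      sg += dyc[i] * xhc[i];
      sb += dyc[i];
    }
    dgamma[j] = sg; dbeta[j] = sb;
    const double m1 = s1 / n, m2 = s2 / n;
    double* dxc = dx.begin() + j * n;
    for (R_xlen_t i = 0; i < n; ++i)
      dxc[i] = dyc[i] * gi - m1 - xhc[i] * m2;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// max(x, 0)
// [[Rcpp::export]]
NumericMatrix reluFwdC(const NumericMatrix& x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const R_xlen_t n = x.length();
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0;
  return y;
}

// dy * (ref > 0)
// [[Rcpp::export]]
NumericMatrix reluBwdMask(const NumericMatrix& dy, const NumericMatrix& ref) {
  NumericMatrix y(dy.nrow(), dy.ncol());
  const R_xlen_t n = dy.length();
  const double* dp = dy.begin();
  const double* rp = ref.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = rp[i] > 0 ? dp[i] : 0;
  return y;
}

// max(a + b, 0)
// [[Rcpp::export]]
NumericMatrix reluSum(const NumericMatrix& a, const NumericMatrix& b) {
  NumericMatrix y(a.nrow(), a.ncol());
  const R_xlen_t n = a.length();
  const double* ap = a.begin();
  const double* bp = b.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = ap[i] + bp[i];
    yp[i] = s > 0 ? s : 0;
  }
  return y;
}

// target[idx[i], ] += val[i, ]   (1-based idx; target modified in place --
// only ever called on a freshly allocated accumulator)
// [[Rcpp::export]]
void rowsAddInPlace(NumericMatrix target, const IntegerVector& idx,
                    const NumericMatrix& val) {
  const R_xlen_t n = val.nrow(), c = val.ncol(), N = target.nrow();
  double* tp = target.begin();
  const double* vp = val.begin();
  for (R_xlen_t j = 0; j < c; ++j) {
    double* tc = tp + j * N;
    const double* vc = vp + j * n;
    for (R_xlen_t i = 0; i < n; ++i) tc[idx[i] - 1] += vc[i];
  }
}

// ---- attention kernels ------------------------------------------------------
// X, Y, V are (D*H*N) x L with a column per token, rows ordered d fastest
// then (h, n); A and S are (H*N*L_i) x L_j.  All loops are blocked over
// (h, n) so the per-block D x L panels stay cache resident.

// S[(hn, i), j] = sum_d X[(d, hn), i] * Y[(d, hn), j]
// [[Rcpp::export]]
NumericMatrix attScores(const NumericMatrix& X, const NumericMatrix& Y,
                        int D) {
  const R_xlen_t L = X.ncol();
  const R_xlen_t DHN = X.nrow();
  const R_xlen_t HN = DHN / D;
  NumericMatrix S(HN * L, L);
  for (R_xlen_t hn = 0; hn < HN; ++hn) {
    const double* xb = X.begin() + hn * D;
    const double* yb = Y.begin() + hn * D;
    for (R_xlen_t j = 0; j < L; ++j) {
      const double* yc = yb + j * DHN;
      double* sc = S.begin() + j * HN * L + hn;
      for (R_xlen_t i = 0; i < L; ++i) {
        const double* xc = xb + i * DHN;
        double acc = 0;
        for (int d = 0; d < D; ++d) acc += xc[d] * yc[d];
        sc[i * HN] = acc;
      }
    }
  }
  return S;
}

// transposed = false:  Z[, i] = sum_j V[, j] * A[(hn, i), j]
// transposed = true :  Z[, j] = sum_i V[, i] * A[(hn, i), j]
// [[Rcpp::export]]
NumericMatrix attApply(const NumericMatrix& V, const NumericMatrix& A,
                       int D, bool transposed) {
  const R_xlen_t L = V.ncol();
  const R_xlen_t DHN = V.nrow();
  const R_xlen_t HN = DHN / D;
  NumericMatrix Z(DHN, L);            // allocVector memory is uninitialised
  std::fill(Z.begin(), Z.end(), 0.0);
  for (R_xlen_t hn = 0; hn < HN; ++hn) {
    const double* vb = V.begin() + hn * D;
    double* zb = Z.begin() + hn * D;
    for (R_xlen_t j = 0; j < L; ++j) {
      const double* ac = A.begin() + j * HN * L + hn;
      for (R_xlen_t i = 0; i < L; ++i) {
        const double w = ac[i * HN];
        if (w == 0) continue;
        const double* vp = vb + (transposed ? i : j) * DHN;
        double* zp = zb + (transposed ? j : i) * DHN;
        for (int d = 0; d < D; ++d) zp[d] += w * vp[d];
      }
    }
  }
  return Z;
}

// ---- SADG site-matrix kernels ----------------------------------------------

// Population std over the time axis of a site matrix.
// Returns M and MU of shape (B*J) x C, rows ordered b fastest then j.
// [[Rcpp::export]]
List timeStdC(const NumericMatrix& x, int B, int T, int J) {
  const R_xlen_t C = x.ncol(), n = x.nrow();
  NumericMatrix M(B * J, C), MU(B * J, C);
  std::vector<double> s(B), q(B);
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int j = 0; j < J; ++j) {
      const double* xc = x.begin() + c * n + (R_xlen_t)B * T * j;
      std::fill(s.begin(), s.end(), 0.0);
      std::fill(q.begin(), q.end(), 0.0);
      for (int t = 0; t < T; ++t) {
        const double* p = xc + (R_xlen_t)B * t;
        for (int b = 0; b < B; ++b) { const double v = p[b]; s[b] += v; q[b] += v * v; }
      }
      double* mc = M.begin() + c * (R_xlen_t)B * J + (R_xlen_t)B * j;
      double* uc = MU.begin() + c * (R_xlen_t)B * J + (R_xlen_t)B * j;
      for (int b = 0; b < B; ++b) {
        const double mu = s[b] / T;
        double v = q[b] / T - mu * mu;
        if (v < 0) v = 0;
        mc[b] = std::sqrt(v);
        uc[b] = mu;
      }
    }
  }
  return List::create(_["M"] = M, _["MU"] = MU);
}

// dx[(b,t,j), c] = dM[(b,j), c] * (x - mu) / (T * M), 0 where M ~ 0.
// [[Rcpp::export]]
NumericMatrix timeStdBwdC(const NumericMatrix& dM, const NumericMatrix& x,
                          const NumericMatrix& MU, const NumericMatrix& M,
                          int B, int T, int J) {
  const R_xlen_t C = x.ncol(), n = x.nrow();
  NumericMatrix dx(n, C);
  std::vector<double> g(B), mu(B);
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int j = 0; j < J; ++j) {
      const double* mc = M.begin() + c * (R_xlen_t)B * J + (R_xlen_t)B * j;
      const double* uc = MU.begin() + c * (R_xlen_t)B * J + (R_xlen_t)B * j;
      const double* dmc = dM.begin() + c * (R_xlen_t)B * J + (R_xlen_t)B * j;
      for (int b = 0; b < B; ++b) {
        mu[b] = uc[b];
        g[b] = mc[b] < 1e-12 ? 0.0 : dmc[b] / (T * mc[b]);
      }
      const double* xc = x.begin() + c * n + (R_xlen_t)B * T * j;
      double* dc = dx.begin() + c * n + (R_xlen_t)B * T * j;
      for (int t = 0; t < T; ++t) {
        const double* xp = xc + (R_xlen_t)B * t;
        double* dp = dc + (R_xlen_t)B * t;
        for (int b = 0; b < B; ++b) dp[b] = (xp[b] - mu[b]) * g[b];
      }
    }
  }
  return dx;
}

// Group projection: out[(b,t,g), c] = sum_j alpha[b,g,j] * x[(b,t,j), c].
// alpha is a (B, G, J) array.
// [[Rcpp::export]]
NumericMatrix projGC(const NumericMatrix& x, const NumericVector& alpha,
                     int B, int T, int J, int G) {
  const R_xlen_t C = x.ncol(), n = x.nrow();
  const R_xlen_t BT = (R_xlen_t)B * T;
  NumericMatrix out(BT * G, C);
  std::fill(out.begin(), out.end(), 0.0);
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int g = 0; g < G; ++g) {
      double* oc = out.begin() + c * BT * G + BT * g;
      for (int j = 0; j < J; ++j) {
        const double* ap = alpha.begin() + (R_xlen_t)B * g + (R_xlen_t)B * G * j;
        const double* xc = x.begin() + c * n + BT * j;
        for (int t = 0; t < T; ++t) {
          const double* xp = xc + (R_xlen_t)B * t;
          double* op = oc + (R_xlen_t)B * t;
          for (int b = 0; b < B; ++b) op[b] += ap[b] * xp[b];
        }
      }
    }
  }
  return out;
}

// Backward of projGC: dx[(b,t,j), c] = sum_g alpha[b,g,j] * dXg[(b,t,g), c]
// and dalpha[b,g,j] = sum_{t,c} dXg[(b,t,g), c] * x[(b,t,j), c].
// [[Rcpp::export]]
List projGBwdC(const NumericMatrix& dXg, const NumericMatrix& x,
               const NumericVector& alpha, int B, int T, int J, int G) {
  const R_xlen_t C = x.ncol(), n = x.nrow();
  const R_xlen_t BT = (R_xlen_t)B * T;
  NumericMatrix dx(n, C);
  std::fill(dx.begin(), dx.end(), 0.0);
  NumericVector dalpha((R_xlen_t)B * G * J);
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int j = 0; j < J; ++j) {
      const double* xc = x.begin() + c * n + BT * j;
      double* dc = dx.begin() + c * n + BT * j;
      for (int g = 0; g < G; ++g) {
        const double* ap = alpha.begin() + (R_xlen_t)B * g + (R_xlen_t)B * G * j;
        double* dap = dalpha.begin() + (R_xlen_t)B * g + (R_xlen_t)B * G * j;
        const double* gc = dXg.begin() + c * BT * G + BT * g;
        for (int t = 0; t < T; ++t) {
          const double* gp = gc + (R_xlen_t)B * t;
          const double* xp = xc + (R_xlen_t)B * t;
          double* dp = dc + (R_xlen_t)B * t;
          for (int b = 0; b < B; ++b) {
            dp[b] += ap[b] * gp[b];
            dap[b] += gp[b] * xp[b];
          }
        }
      }
    }
  }
  dalpha.attr("dim") = IntegerVector::create(B, G, J);
  return List::create(_["dx"] = dx, _["dalpha"] = dalpha);
}

// Back-projection: out[(b,t,j), c] = sum_g alpha[b,g,j] * z[(b,t,g), c].
// [[Rcpp::export]]
NumericMatrix backPC(const NumericMatrix& z, const NumericVector& alpha,
                     int B, int T, int J, int G) {
  const R_xlen_t C = z.ncol();
  const R_xlen_t BT = (R_xlen_t)B * T;
  NumericMatrix out(BT * J, C);
  std::fill(out.begin(), out.end(), 0.0);
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int j = 0; j < J; ++j) {
      double* oc = out.begin() + c * BT * J + BT * j;
      for (int g = 0; g < G; ++g) {
        const double* ap = alpha.begin() + (R_xlen_t)B * g + (R_xlen_t)B * G * j;
        const double* zc = z.begin() + c * BT * G + BT * g;
        for (int t = 0; t < T; ++t) {
          const double* zp = zc + (R_xlen_t)B * t;
          double* op = oc + (R_xlen_t)B * t;
          for (int b = 0; b < B; ++b) op[b] += ap[b] * zp[b];
        }
      }
    }
  }
  return out;
}

// Backward of backPC: dz[(b,t,g), c] = sum_j alpha[b,g,j] * dZ[(b,t,j), c]
// and dalpha[b,g,j] = sum_{t,c} z[(b,t,g), c] * dZ[(b,t,j), c].
// [[Rcpp::export]]
List backPBwdC(const NumericMatrix& dZ, const NumericMatrix& z,
               const NumericVector& alpha, int B, int T, int J, int G) {
  const R_xlen_t C = z.ncol();
  const R_xlen_t BT = (R_xlen_t)B * T;
  NumericMatrix dz(BT * G, C);
  std::fill(dz.begin(), dz.end(), 0.0);
  NumericVector dalpha((R_xlen_t)B * G * J);
  for (R_xlen_t c = 0; c < C; ++c) {
    for (int j = 0; j < J; ++j) {
      const double* dc = dZ.begin() + c * BT * J + BT * j;
      for (int g = 0; g < G; ++g) {
        const double* ap = alpha.begin() + (R_xlen_t)B * g + (R_xlen_t)B * G * j;
        double* dap = dalpha.begin() + (R_xlen_t)B * g + (R_xlen_t)B * G * j;
        double* zgc = dz.begin() + c * BT * G + BT * g;
        const double* zc = z.begin() + c * BT * G + BT * g;
        for (int t = 0; t < T; ++t) {
          const double* dp = dc + (R_xlen_t)B * t;
          const double* zp = zc + (R_xlen_t)B * t;
          double* zg = zgc + (R_xlen_t)B * t;
          for (int b = 0; b < B; ++b) {
            zg[b] += ap[b] * dp[b];
            dap[b] += zp[b] * dp[b];
          }
        }
      }
    }
  }
  dalpha.attr("dim") = IntegerVector::create(B, G, J);
  return List::create(_["dz"] = dz, _["dalpha"] = dalpha);
}

// Mean over (t, j) per (b, c): site matrix -> B x C.
// [[Rcpp::export]]
NumericMatrix poolTJC(const NumericMatrix& x, int B, int T, int J) {
  const R_xlen_t C = x.ncol(), n = x.nrow();
  NumericMatrix out(B, C);
  std::fill(out.begin(), out.end(), 0.0);
  const double invTJ = 1.0 / ((double)T * J);
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* xc = x.begin() + c * n;
    double* oc = out.begin() + c * B;
    for (R_xlen_t tj = 0; tj < (R_xlen_t)T * J; ++tj) {
      const double* xp = xc + (R_xlen_t)B * tj;
      for (int b = 0; b < B; ++b) oc[b] += xp[b];
    }
    for (int b = 0; b < B; ++b) oc[b] *= invTJ;
  }
  return out;
}

// Backward of poolTJC: broadcast dpool/(T*J) over all (t, j) sites.
// [[Rcpp::export]]
NumericMatrix poolBwdC(const NumericMatrix& dpool, int B, int T, int J) {
  const R_xlen_t C = dpool.ncol();
  const R_xlen_t n = (R_xlen_t)B * T * J;
  NumericMatrix dx(n, C);
  const double invTJ = 1.0 / ((double)T * J);
  for (R_xlen_t c = 0; c < C; ++c) {
    const double* pc = dpool.begin() + c * B;
    double* dc = dx.begin() + c * n;
    for (R_xlen_t tj = 0; tj < (R_xlen_t)T * J; ++tj) {
      double* dp = dc + (R_xlen_t)B * tj;
      for (int b = 0; b < B; ++b) dp[b] = pc[b] * invTJ;
    }
  }
  return dx;
}

// ---- stride-1 temporal convolution via offset dgemm -------------------------
// For stride 1 the (b, t) rows of each joint block are contiguous, so each
// kernel tap is a plain dgemm on a row-offset submatrix (LDA = full rows);
// no gather/scatter buffers are needed.

#include <R_ext/BLAS.h>

// x: (B*T*J) x Cin, W: (3*Cin) x Cout.  out[t] += W_k x[t + k - 2] per tap.
// Each shifted tap is ONE full dgemm over all rows (treating the site
// matrix as a single time axis) followed by (J-1) tiny alpha = -1 dgemms
// that cancel the spill-over across joint-block boundaries.
// [[Rcpp::export]]
NumericMatrix tconv1FwdC(const NumericMatrix& x, const NumericMatrix& W,
                         int B, int T, int J) {
  const int Cin = x.ncol(), Cout = W.ncol();
  const int n = x.nrow();
  NumericMatrix y(n, Cout);
  std::fill(y.begin(), y.end(), 0.0);
  const double one = 1.0, neg = -1.0;
  const int ldw = 3 * Cin;
  const int m0 = n - B;
  // centre tap: exact full matmul
  F77_CALL(dgemm)("N", "N", &n, &Cout, &Cin, &one, x.begin(), &n,
                  W.begin() + Cin, &ldw, &one, y.begin(), &n FCONE FCONE);
  // k = 1 (input frame t-1): y rows [B, n) += x rows [0, n-B)
  F77_CALL(dgemm)("N", "N", &m0, &Cout, &Cin, &one, x.begin(), &n,
                  W.begin(), &ldw, &one, y.begin() + B, &n FCONE FCONE);
  // k = 3 (input frame t+1): y rows [0, n-B) += x rows [B, n)
  F77_CALL(dgemm)("N", "N", &m0, &Cout, &Cin, &one, x.begin() + B, &n,
                  W.begin() + 2 * Cin, &ldw, &one, y.begin(), &n
                  FCONE FCONE);
  // cancel cross-joint spill at the block boundaries
  for (int j = 1; j < J; ++j) {
    const R_xlen_t r0 = (R_xlen_t)B * T * j;   // first row of block j
    // k=1 contaminated y rows [r0, r0+B) with x rows [r0-B, r0)
    F77_CALL(dgemm)("N", "N", &B, &Cout, &Cin, &neg, x.begin() + r0 - B,
                    &n, W.begin(), &ldw, &one, y.begin() + r0, &n
                    FCONE FCONE);
    // k=3 contaminated y rows [r0-B, r0) with x rows [r0, r0+B)
    F77_CALL(dgemm)("N", "N", &B, &Cout, &Cin, &neg, x.begin() + r0, &n,
                    W.begin() + 2 * Cin, &ldw, &one, y.begin() + r0 - B,
                    &n FCONE FCONE);
  }
  return y;
}

// Backward: dx[f] += dy[t] W_k^T for f = t + k - 2; dW_k += x[f]^T dy[t];
// same full-dgemm-plus-boundary-correction scheme.
// [[Rcpp::export]]
List tconv1BwdC(const NumericMatrix& dy, const NumericMatrix& x,
                const NumericMatrix& W, int B, int T, int J) {
  const int Cin = x.ncol(), Cout = dy.ncol();
  const int n = x.nrow();
  NumericMatrix dx(n, Cin);
  std::fill(dx.begin(), dx.end(), 0.0);
  NumericMatrix dW(3 * Cin, Cout);
  std::fill(dW.begin(), dW.end(), 0.0);
  const double one = 1.0, neg = -1.0;
  const int ldw = 3 * Cin;
  const int m0 = n - B;
  // centre tap
  F77_CALL(dgemm)("N", "T", &n, &Cin, &Cout, &one, dy.begin(), &n,
                  W.begin() + Cin, &ldw, &one, dx.begin(), &n FCONE FCONE);
  F77_CALL(dgemm)("T", "N", &Cin, &Cout, &n, &one, x.begin(), &n,
                  dy.begin(), &n, &one, dW.begin() + Cin, &ldw
                  FCONE FCONE);
  // k=1: dx rows [0, n-B) += dy rows [B, n); dW1 += x[0,n-B)^T dy[B,n)
  F77_CALL(dgemm)("N", "T", &m0, &Cin, &Cout, &one, dy.begin() + B, &n,
                  W.begin(), &ldw, &one, dx.begin(), &n FCONE FCONE);
  F77_CALL(dgemm)("T", "N", &Cin, &Cout, &m0, &one, x.begin(), &n,
                  dy.begin() + B, &n, &one, dW.begin(), &ldw FCONE FCONE);
  // k=3: dx rows [B, n) += dy rows [0, n-B); dW3 += x[B,n)^T dy[0,n-B)
  F77_CALL(dgemm)("N", "T", &m0, &Cin, &Cout, &one, dy.begin(), &n,
                  W.begin() + 2 * Cin, &ldw, &one, dx.begin() + B, &n
                  FCONE FCONE);
  F77_CALL(dgemm)("T", "N", &Cin, &Cout, &m0, &one, x.begin() + B, &n,
                  dy.begin(), &n, &one, dW.begin() + 2 * Cin, &ldw
                  FCONE FCONE);
  for (int j = 1; j < J; ++j) {
    const R_xlen_t r0 = (R_xlen_t)B * T * j;
    // cancel k=1 spill: pairs (x[r0-B, r0), dy[r0, r0+B))
    F77_CALL(dgemm)("N", "T", &B, &Cin, &Cout, &neg, dy.begin() + r0, &n,
                    W.begin(), &ldw, &one, dx.begin() + r0 - B, &n
                    FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &Cin, &Cout, &B, &neg, x.begin() + r0 - B,
                    &n, dy.begin() + r0, &n, &one, dW.begin(), &ldw
                    FCONE FCONE);
    // cancel k=3 spill: pairs (x[r0, r0+B), dy[r0-B, r0))
    F77_CALL(dgemm)("N", "T", &B, &Cin, &Cout, &neg, dy.begin() + r0 - B,
                    &n, W.begin() + 2 * Cin, &ldw, &one, dx.begin() + r0,
                    &n FCONE FCONE);
    F77_CALL(dgemm)("T", "N", &Cin, &Cout, &B, &neg, x.begin() + r0, &n,
                    dy.begin() + r0 - B, &n, &one, dW.begin() + 2 * Cin,
                    &ldw FCONE FCONE);
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}
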