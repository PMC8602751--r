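#include <Rcpp.h>
using namespace Rcpp;

// Linear predictors are clipped to +/- LINK_CLIP; exp(30) ~ 1e13 already
// signals a degenerate iterate and larger values overflow variance terms.
static const double LINK_CLIP = 30.0;

static inline double clip_eta(double eta) {
  if (eta > LINK_CLIP) return LINK_CLIP;
  if (eta < -LINK_CLIP) return -LINK_CLIP;
  return eta;
}

// Log-likelihood of gene i's counts across all cells, as a function of its
// latent coordinate z, dropping terms constant in z:
//   sum_cells x * eta - (x + theta) * log(theta + exp(eta))
// Bt is the L x N transposed loading matrix (contiguous per cell); xw and
// thj are the per-cell x + theta and theta for this gene.  Only the upper
// link clip matters here: exp underflow of a very negative eta is harmless.
static double gene_loglik(const double* x, const double* alpha,
                          const double* Bt, int N, int L,
                          const double* xw, const double* thj,
                          const double* z) {
  double ll = 0.0;
#pragma omp simd reduction(+:ll)
  for (int j = 0; j < N; ++j) {
    double eta = alpha[j];
    for (int l = 0; l < L; ++l) eta += Bt[(size_t)j * L + l] * z[l];
    eta = eta > LINK_CLIP ? LINK_CLIP : eta;
    ll += x[j] * eta - xw[j] * log(thj[j] + exp(eta));
  }
  return ll;
}

// Random-walk Metropolis-Hastings over each gene's latent coordinate,
// targeting phi(z) * prod_cells NB(x | exp(alpha + B z), theta).
// Returns post-burn-in means, variances and acceptance rates; optionally the
// full retained sample array (nsave x L x m) for diagnostics.
// [[Rcpp::export]]
List cpp_sample_latents(NumericMatrix X, NumericVector alpha,
                        NumericMatrix B, NumericMatrix theta,
                        IntegerVector cell_dataset, NumericMatrix Z0,
                        int nsave, int nburn, NumericVector prop_sd,
                        bool keep_samples) {
  const int m = X.nrow(), N = X.ncol(), L = Z0.ncol();
  NumericMatrix Zmean(m, L), Zvar(m, L);
  NumericVector accept(m);
  NumericVector samples(keep_samples ? (R_xlen_t)nsave * L * m : 0);

  std::vector<double> xrow(N), xw(N), thj(N), z(L), zprop(L);
  std::vector<int> cd(N);
  for (int j = 0; j < N; ++j) cd[j] = cell_dataset[j];
  std::vector<double> Bt((size_t)N * L);
  for (int j = 0; j < N; ++j)
    for (int l = 0; l < L; ++l) Bt[(size_t)j * L + l] = B(j, l);

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < N; ++j) {
      xrow[j] = X(i, j);
      thj[j] = theta(i, cd[j]);
      xw[j] = xrow[j] + thj[j];
    }
    for (int l = 0; l < L; ++l) z[l] = Z0(i, l);

    double ll = gene_loglik(xrow.data(), &alpha[0], Bt.data(), N, L,
                            xw.data(), thj.data(), z.data());
    double lprior = 0.0;
    for (int l = 0; l < L; ++l) lprior -= 0.5 * z[l] * z[l];

    std::vector<double> sum(L, 0.0), sumsq(L, 0.0);
    int nacc = 0;
    const int total = nburn + nsave;
    const double sd_i = prop_sd[i % prop_sd.size()];
    for (int s = 0; s < total; ++s) {
      for (int l = 0; l < L; ++l) zprop[l] = z[l] + R::rnorm(0.0, sd_i);
      double llp = gene_loglik(xrow.data(), &alpha[0], Bt.data(), N, L,
                               xw.data(), thj.data(), zprop.data());
      double lpp = 0.0;
      for (int l = 0; l < L; ++l) lpp -= 0.5 * zprop[l] * zprop[l];
      if (log(R::unif_rand()) < (llp + lpp) - (ll + lprior)) {
        z = zprop; ll = llp; lprior = lpp; ++nacc;
      }
      if (s >= nburn) {
        for (int l = 0; l < L; ++l) {
          sum[l] += z[l];
          sumsq[l] += z[l] * z[l];
        }
        if (keep_samples) {
          const int idx = s - nburn;
          for (int l = 0; l < L; ++l)
            samples[idx + (R_xlen_t)nsave * (l + (R_xlen_t)L * i)] = z[l];
        }
      }
    }
    for (int l = 0; l < L; ++l) {
      double mu = sum[l] / nsave;
      Zmean(i, l) = mu;
      Zvar(i, l) = sumsq[l] / nsave - mu * mu;
    }
    accept[i] = (double)nacc / total;
  }

  List out = List::create(_["mean"] = Zmean, _["var"] = Zvar,
                          _["accept"] = accept);
  if (keep_samples) {
    samples.attr("dim") = IntegerVector::create(nsave, L, m);
    out["samples"] = samples;
  }
  return out;
}

// Penalized NB objective for one cell (negative log-likelihood up to
// constants in (a, b), plus the L1 penalty on b):
//   sum_i (x_i + theta_i) log(theta_i + u_i) - x_i eta_i  + delta ||b||_1
static double cell_objective(const double* x, const double* Z, int m, int L,
                             const double* theta, double a, const double* b,
                             double delta) {
  double obj = 0.0;
  for (int i = 0; i < m; ++i) {
    double eta = a;
    for (int l = 0; l < L; ++l) eta += Z[i + (size_t)m * l] * b[l];
    eta = clip_eta(eta);
    obj += (x[i] + theta[i]) * log(theta[i] + exp(eta)) - x[i] * eta;
  }
  for (int l = 0; l < L; ++l) obj += delta * std::abs(b[l]);
  return obj;
}

static inline double soft(double v, double t) {
  if (v > t) return v - t;
  if (v < -t) return v + t;
  return 0.0;
}

// IRLS with coordinate-wise soft-thresholding for one cell's penalized NB
// regression of counts on the latent coordinates; the intercept a is never
// penalized.  Step-halving keeps the objective non-increasing.
static void fit_one_cell(const double* x, const double* Z, int m, int L,
                         const double* theta, double delta,
                         double& a, double* b, int maxit, double tol) {
  std::vector<double> eta(m), u(m), w(m), zeta(m), r(m);
  double obj = cell_objective(x, Z, m, L, theta, a, b, delta);
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < m; ++i) {
      double e = a;
      for (int l = 0; l < L; ++l) e += Z[i + (size_t)m * l] * b[l];
      eta[i] = clip_eta(e);
      u[i] = exp(eta[i]);
      w[i] = u[i] * theta[i] / (theta[i] + u[i]);
      if (w[i] < 1e-10) w[i] = 1e-10;
      zeta[i] = eta[i] + (x[i] - u[i]) / u[i];
    }
    double a_old = a;
    std::vector<double> b_old(b, b + L);
    // coordinate descent on the penalized weighted least-squares surrogate
    for (int inner = 0; inner < 100; ++inner) {
      double maxdel = 0.0;
      double num = 0.0, den = 0.0;
      for (int i = 0; i < m; ++i) {
        double fit = 0.0;
        for (int l = 0; l < L; ++l) fit += Z[i + (size_t)m * l] * b[l];
        num += w[i] * (zeta[i] - fit);
        den += w[i];
      }
      double a_new = num / den;
      maxdel = std::max(maxdel, std::abs(a_new - a));
      a = a_new;
      for (int l = 0; l < L; ++l) {
        double num_l = 0.0, den_l = 0.0;
        for (int i = 0; i < m; ++i) {
          double fit = a;
          for (int l2 = 0; l2 < L; ++l2)
            if (l2 != l) fit += Z[i + (size_t)m * l2] * b[l2];
          const double zi = Z[i + (size_t)m * l];
          num_l += w[i] * zi * (zeta[i] - fit);
          den_l += w[i] * zi * zi;
        }
        double b_new = (den_l > 1e-12) ? soft(num_l, delta) / den_l : 0.0;
        maxdel = std::max(maxdel, std::abs(b_new - b[l]));
        b[l] = b_new;
      }
      if (maxdel < 1e-8) break;
    }
    // step-halving toward the previous iterate if the true objective rose
    double obj_new = cell_objective(x, Z, m, L, theta, a, b, delta);
    int halves = 0;
    while (obj_new > obj + 1e-10 && halves < 20) {
      a = 0.5 * (a + a_old);
      for (int l = 0; l < L; ++l) b[l] = 0.5 * (b[l] + b_old[l]);
      obj_new = cell_objective(x, Z, m, L, theta, a, b, delta);
      ++halves;
    }
    double rel = std::abs(obj - obj_new) / (std::abs(obj) + 1.0);
    obj = obj_new;
    if (rel < tol) break;
  }
}

// M-step over all cells.  X is genes x cells (cells from all datasets,
// canonical order), theta genes x datasets, delta one penalty per cell.
// [[Rcpp::export]]
List cpp_update_cells(NumericMatrix X, NumericMatrix Z, NumericMatrix theta,
                      IntegerVector cell_dataset, NumericVector delta,
                      NumericVector alpha0, NumericMatrix beta0,
                      int maxit, double tol, double zero_floor_log) {
  const int m = X.nrow(), N = X.ncol(), L = Z.ncol();
  NumericVector alpha = clone(alpha0);
  NumericMatrix beta = clone(beta0);
  IntegerVector zero_cells;
  std::vector<double> x(m), thg(m), b(L);

  for (int j = 0; j < N; ++j) {
    double tot = 0.0;
    for (int i = 0; i < m; ++i) { x[i] = X(i, j); tot += x[i]; }
    if (tot == 0.0) {
      alpha[j] = zero_floor_log;
      for (int l = 0; l < L; ++l) beta(j, l) = 0.0;
      zero_cells.push_back(j + 1);
      continue;
    }
    const int k = cell_dataset[j];
    for (int i = 0; i < m; ++i) thg[i] = theta(i, k);
    double a = alpha[j];
    for (int l = 0; l < L; ++l) b[l] = beta(j, l);
    fit_one_cell(x.data(), &Z[0], m, L, thg.data(), delta[j], a, b.data(),
                 maxit, tol);
    alpha[j] = a;
    for (int l = 0; l < L; ++l) beta(j, l) = b[l];
  }
  return List::create(_["alpha"] = alpha, _["beta"] = beta,
                      _["zero_cells"] = zero_cells);
}

// Objective evaluator exposed for tests (oracle comparisons).
// [[Rcpp::export]]
double cpp_cell_objective(NumericVector x, NumericMatrix Z,
                          NumericVector theta, double a, NumericVector b,
                          double delta) {
  return cell_objective(&x[0], &Z[0], x.size(), Z.ncol(), &theta[0], a,
                        &b[0], delta);
}
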