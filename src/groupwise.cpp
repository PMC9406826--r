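// Groupwise non-rigid registration core: cubic B-spline free-form
// deformations for every frame of an ASL series, optimised jointly with an
// adaptive stochastic gradient descent against the eigenvalue-weighted
// PCA dissimilarity of the inter-frame correlation matrix (PCAMetric2),
// under a zero-mean-displacement constraint (implicit mean reference).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace arma;

// ---------- cubic B-spline interpolation with prefiltering ----------

// recursive prefilter along one line (pole of the cubic B-spline)
static void prefilter_line(double* c, int n, int stride) {
  const double z = std::sqrt(3.0) - 2.0;
  if (n == 1) return;
  const double lambda = (1.0 - z) * (1.0 - 1.0 / z);
  // causal init (mirror boundary)
  int horizon = std::min(n, 28);  // |z|^28 < 1e-16
  double sum = c[0];
  double zn = z;
  for (int i = 1; i < horizon; ++i) {
    sum += zn * c[i * stride];
    zn *= z;
  }
  double prev = lambda * sum / (1.0 - std::pow(z, 2 * horizon));
  // scale then causal pass
  c[0] = prev;
  for (int i = 1; i < n; ++i) {
    c[i * stride] = lambda * c[i * stride] + z * c[(i - 1) * stride];
  }
  // anticausal init
  c[(n - 1) * stride] = (z / (z * z - 1.0)) *
    (z * c[(n - 2) * stride] + c[(n - 1) * stride]);
  for (int i = n - 2; i >= 0; --i) {
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
  }
}

// note: the standard algorithm applies gain lambda inside the causal pass
static void prefilter_image(mat& img) {
  const int nr = img.n_rows, nc = img.n_cols;
  for (int j = 0; j < nc; ++j) prefilter_line(img.colptr(j), nr, 1);
  for (int i = 0; i < nr; ++i) prefilter_line(img.memptr() + i, nc, nr);
}

static inline void bspline_w(double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static inline void bspline_dw(double t, double* w) {
  const double t2 = t * t;
  w[0] = (-3.0 + 6.0 * t - 3.0 * t2) / 6.0;
  w[1] = (-12.0 * t + 9.0 * t2) / 6.0;
  w[2] = (3.0 + 6.0 * t - 9.0 * t2) / 6.0;
  w[3] = 3.0 * t2 / 6.0;
}

static inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// interpolate prefiltered coefficients at 0-based (x, y); optionally the
// spatial gradient
static double interp_bspline(const mat& coef, double x, double y,
                             double* gx = nullptr, double* gy = nullptr) {
  const int nr = coef.n_rows, nc = coef.n_cols;
  if (x < 0) x = 0; else if (x > nr - 1) x = nr - 1;
  if (y < 0) y = 0; else if (y > nc - 1) y = nc - 1;
  const int ix = (int)std::floor(x), iy = (int)std::floor(y);
  const double tx = x - ix, ty = y - iy;
  double wx[4], wy[4], dwx[4], dwy[4];
  bspline_w(tx, wx); bspline_w(ty, wy);
  if (gx) { bspline_dw(tx, dwx); bspline_dw(ty, dwy); }
  double v = 0, vx = 0, vy = 0;
  for (int m = 0; m < 4; ++m) {
    const int r = mirror_idx(ix - 1 + m, nr);
    for (int l = 0; l < 4; ++l) {
      const int c = mirror_idx(iy - 1 + l, nc);
      const double cv = coef(r, c);
      v += wx[m] * wy[l] * cv;
      if (gx) {
        vx += dwx[m] * wy[l] * cv;
        vy += wx[m] * dwy[l] * cv;
      }
    }
  }
  if (gx) { *gx = vx; *gy = vy; }
  return v;
}

// ---------- PCAMetric2 ----------

// metric J = sum_j j * lambda_j (eigenvalues of the frame correlation
// matrix, sorted descending) and, if requested, dJ/dM for the sample
// intensity matrix M (Ns x G)
static double pca_metric_grad(const mat& M, mat* dJdM, bool* degenerate) {
  const int G = M.n_cols;
  const int Ns = M.n_rows;
  rowvec mu = mean(M, 0);
  mat Mc = M.each_row() - mu;
  rowvec nrm = sqrt(sum(square(Mc), 0));
  uvec bad = find(nrm < 1e-12);
  *degenerate = bad.n_elem > 0;
  rowvec nrm_safe = nrm;
  nrm_safe.elem(bad).fill(1.0);
  mat Z = Mc.each_row() / nrm_safe;
  Z.cols(bad).zeros();
  mat K = Z.t() * Z;
  for (uword b = 0; b < bad.n_elem; ++b) K(bad[b], bad[b]) = 1.0;
  vec eval;
  mat evec;
  eig_sym(eval, evec, K);
  // ascending order: weight G - a gives the descending-order weights 1..G
  vec w(G);
  for (int a = 0; a < G; ++a) w[a] = (double)(G - a);
  double J = dot(w, eval);
  if (dJdM) {
    mat Q = evec * diagmat(w) * evec.t();
    mat Gz = 2.0 * Z * Q;                 // dJ/dZ
    rowvec gbar = mean(Gz, 0);
    rowvec gz = sum(Gz % Z, 0);
    *dJdM = (Gz.each_row() - gbar) - (Z.each_row() % gz);
    dJdM->each_row() /= nrm_safe;
    dJdM->cols(bad).zeros();
    (void)Ns;
  }
  return J;
}

// [[Rcpp::export]]
Rcpp::List pca_metric_cpp(const arma::mat& M) {
  bool degenerate = false;
  double J = pca_metric_grad(M, nullptr, &degenerate);
  return Rcpp::List::create(Rcpp::Named("metric") = J,
                            Rcpp::Named("degenerate") = degenerate);
}

// ---------- FFD evaluation ----------

struct FFDGrid {
  int s;        // control spacing in voxels
  int ncr, ncc; // control counts (first control at image coord -s)
};

static FFDGrid make_grid(int nr, int nc, int s) {
  FFDGrid g;
  g.s = s;
  g.ncr = (int)std::floor((nr - 1.0) / s) + 4;
  g.ncc = (int)std::floor((nc - 1.0) / s) + 4;
  return g;
}

// B-spline FFD displacement at 0-based pixel (r, c) for one component
static inline double ffd_eval(const mat& P, const FFDGrid& g,
                              double r, double c) {
  const int cellr = (int)std::floor(r / g.s), cellc = (int)std::floor(c / g.s);
  const double tr = r / g.s - cellr, tc = c / g.s - cellc;
  double wr[4], wc[4];
  bspline_w(tr, wr); bspline_w(tc, wc);
  double v = 0;
  for (int m = 0; m < 4; ++m)
    for (int l = 0; l < 4; ++l)
      v += wr[m] * wc[l] * P(cellr + m, cellc + l);
  return v;
}

// ---------- main optimisation ----------

// discrete bending energy of one control-point lattice and its gradient;
// penalises curvature (ring compression / local squeeze) while leaving
// translations and affine-like deformations free
static double bending_energy_grad(const mat& P, mat& grad) {
  const int nr = P.n_rows, nc = P.n_cols;
  double E = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 1; i < nr - 1; ++i) {
      const double e = P(i - 1, j) - 2.0 * P(i, j) + P(i + 1, j);
      E += e * e;
      grad(i - 1, j) += 2.0 * e;
      grad(i, j) -= 4.0 * e;
      grad(i + 1, j) += 2.0 * e;
    }
  for (int j = 1; j < nc - 1; ++j)
    for (int i = 0; i < nr; ++i) {
      const double e = P(i, j - 1) - 2.0 * P(i, j) + P(i, j + 1);
      E += e * e;
      grad(i, j - 1) += 2.0 * e;
      grad(i, j) -= 4.0 * e;
      grad(i, j + 1) += 2.0 * e;
    }
  for (int j = 0; j < nc - 1; ++j)
    for (int i = 0; i < nr - 1; ++i) {
      const double e = P(i + 1, j + 1) - P(i + 1, j) - P(i, j + 1) + P(i, j);
      E += 2.0 * e * e;
      grad(i + 1, j + 1) += 4.0 * e;
      grad(i + 1, j) -= 4.0 * e;
      grad(i, j + 1) -= 4.0 * e;
      grad(i, j) += 4.0 * e;
    }
  return E;
}

// [[Rcpp::export]]
Rcpp::List gw_register_cpp(const arma::cube& raw, Rcpp::List smoothed_levels,
                           const arma::ivec& spacings, int iterations,
                           double subsample, int seed, double step0,
                           double decay_A, double decay_alpha,
                           double max_update, double bend_weight,
                           const arma::ivec& frame_type,
                           double split_weight) {
  const int nr = raw.n_rows, nc = raw.n_cols, G = raw.n_slices;
  const int n_levels = smoothed_levels.size();
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> rrow(0, nr - 1), rcol(0, nc - 1);

  cube Ur(nr, nc, G, fill::zeros), Uc(nr, nc, G, fill::zeros);
  mat trace(iterations, n_levels, fill::value(datum::nan));

  const int Ns = std::max(100, (int)std::lround(subsample * nr * nc));

  // translation pre-alignment: per-frame rigid shifts converge much
  // faster than the equivalent B-spline mode and absorb the bulk of the
  // respiratory displacement (including the control/label group offset)
  // before the non-rigid levels refine locally
  {
    mat T(2, G, fill::zeros);
    for (int sub = 0; sub < 2 && sub < n_levels; ++sub) {
      cube stack = Rcpp::as<cube>(smoothed_levels[sub == 0 ? 1 : 2]);
      std::vector<mat> coef(G);
      for (int g = 0; g < G; ++g) {
        coef[g] = stack.slice(g);
        prefilter_image(coef[g]);
      }
      double a_gain = -1.0, t_adapt = 0.0;
      mat Tprev;
      bool have_prev = false;
      const int it_trans = std::max(100, iterations / 2);
      for (int it = 0; it < it_trans; ++it) {
        std::vector<int> sr(Ns), sc(Ns);
        for (int s = 0; s < Ns; ++s) { sr[s] = rrow(rng); sc[s] = rcol(rng); }
        mat M(Ns, G), Gr(Ns, G), Gc(Ns, G);
        for (int g = 0; g < G; ++g)
          for (int s = 0; s < Ns; ++s) {
            double gx, gy;
            M(s, g) = interp_bspline(coef[g], sr[s] + T(0, g),
                                     sc[s] + T(1, g), &gx, &gy);
            Gr(s, g) = gx;
            Gc(s, g) = gy;
          }
        bool degenerate = false;
        mat dJdM;
        pca_metric_grad(M, &dJdM, &degenerate);
        mat Gt(2, G, fill::zeros);
        for (int g = 0; g < G; ++g) {
          Gt(0, g) = dot(dJdM.col(g), Gr.col(g));
          Gt(1, g) = dot(dJdM.col(g), Gc.col(g));
        }
        Gt.each_col() -= mean(Gt, 1);
        double gmax = arma::abs(Gt).max();
        if (gmax < 1e-12) continue;
        if (a_gain < 0)
          a_gain = step0 * std::pow(decay_A + 1.0, decay_alpha) / gmax;
        if (have_prev) {
          double num = accu(Gt % Tprev);
          double den = std::sqrt(accu(square(Gt)) * accu(square(Tprev))) +
            1e-300;
          double x = -num / den;
          double f = 2.0 / (1.0 + std::exp(-x / 0.2)) - 0.5;
          t_adapt = std::max(0.0, t_adapt + f);
        } else {
          have_prev = true;
        }
        Tprev = Gt;
        double gamma = a_gain / std::pow(decay_A + t_adapt + 1.0, decay_alpha);
        if (gamma * gmax > max_update) gamma = max_update / gmax;
        T -= gamma * Gt;
        T.each_col() -= mean(T, 1);   // implicit-mean constraint
        T.clamp(-8.0, 8.0);           // respiratory translations are bounded
      }
    }
    for (int g = 0; g < G; ++g) {
      Ur.slice(g) += T(0, g);
      Uc.slice(g) += T(1, g);
    }
  }

  for (int lev = 0; lev < n_levels; ++lev) {
    cube stack = Rcpp::as<cube>(smoothed_levels[lev]);
    std::vector<mat> coef(G);
    for (int g = 0; g < G; ++g) {
      coef[g] = stack.slice(g);
      prefilter_image(coef[g]);
    }
    FFDGrid grid = make_grid(nr, nc, spacings[lev]);
    std::vector<cube> P(2, cube(grid.ncr, grid.ncc, G, fill::zeros));
    double a_gain = -1.0;
    // adaptive stochastic gradient descent time: advances quickly when
    // successive gradients anti-correlate (noise-dominated regime), slowly
    // while descent is consistent, so steps shrink once aligned
    double t_adapt = 0.0;
    std::vector<cube> Gprev(2);
    bool have_prev = false;

    for (int it = 0; it < iterations; ++it) {
      // sample pixels
      std::vector<int> sr(Ns), sc(Ns);
      for (int s = 0; s < Ns; ++s) { sr[s] = rrow(rng); sc[s] = rcol(rng); }

      mat M(Ns, G), Gr(Ns, G), Gc(Ns, G);
      for (int g = 0; g < G; ++g) {
        for (int s = 0; s < Ns; ++s) {
          const double r0 = sr[s], c0 = sc[s];
          const double yr = r0 + Ur(sr[s], sc[s], g) +
            ffd_eval(P[0].slice(g), grid, r0, c0);
          const double yc = c0 + Uc(sr[s], sc[s], g) +
            ffd_eval(P[1].slice(g), grid, r0, c0);
          double gx, gy;
          M(s, g) = interp_bspline(coef[g], yr, yc, &gx, &gy);
          Gr(s, g) = gx;
          Gc(s, g) = gy;
        }
      }

      bool degenerate = false;
      mat dJdM;
      double J = pca_metric_grad(M, &dJdM, &degenerate);
      trace(it, lev) = J;

      // scatter dJ/dM into control-point gradients
      std::vector<cube> Gp(2, cube(grid.ncr, grid.ncc, G, fill::zeros));
      for (int s = 0; s < Ns; ++s) {
        const double r0 = sr[s], c0 = sc[s];
        const int cellr = (int)(r0 / grid.s), cellc = (int)(c0 / grid.s);
        const double tr = r0 / grid.s - cellr, tc = c0 / grid.s - cellc;
        double wr[4], wc[4];
        bspline_w(tr, wr); bspline_w(tc, wc);
        for (int g = 0; g < G; ++g) {
          const double dr = dJdM(s, g) * Gr(s, g);
          const double dc = dJdM(s, g) * Gc(s, g);
          for (int m = 0; m < 4; ++m)
            for (int l = 0; l < 4; ++l) {
              const double w = wr[m] * wc[l];
              Gp[0](cellr + m, cellc + l, g) += w * dr;
              Gp[1](cellr + m, cellc + l, g) += w * dc;
            }
        }
      }
      // bending-energy regularisation (per frame and component)
      if (bend_weight > 0) {
        const double kappa = bend_weight * G;
        for (int d = 0; d < 2; ++d)
          for (int g = 0; g < G; ++g) {
            mat bg(grid.ncr, grid.ncc, fill::zeros);
            bending_energy_grad(P[d].slice(g), bg);
            Gp[d].slice(g) += kappa * bg;
          }
      }
      // soft penalty on the control-vs-label group displacement split:
      // the perfusion-contrast-erasure failure mode deforms the two frame
      // groups apart. A *uniform craniocaudal* (row-direction) group
      // offset is real — the random phase split gives the two groups
      // different mean breathing displacement and it must be corrected —
      // so for the row component only the spatially varying part of the
      // split field is penalised; the left-right component and all
      // structured splits carry no physical motion and are damped fully.
      uvec ctrl_idx = find(frame_type == 1), lab_idx = find(frame_type == 2);
      if (split_weight > 0 && ctrl_idx.n_elem > 0 && lab_idx.n_elem > 0) {
        const double rho = split_weight * G;
        for (int d = 0; d < 2; ++d) {
          mat mc(grid.ncr, grid.ncc, fill::zeros);
          mat ml(grid.ncr, grid.ncc, fill::zeros);
          for (uword k = 0; k < ctrl_idx.n_elem; ++k)
            mc += P[d].slice(ctrl_idx[k]);
          for (uword k = 0; k < lab_idx.n_elem; ++k)
            ml += P[d].slice(lab_idx[k]);
          mc /= (double)ctrl_idx.n_elem;
          ml /= (double)lab_idx.n_elem;
          mat D = mc - ml;
          if (d == 0) D -= accu(D) / D.n_elem;
          for (uword k = 0; k < ctrl_idx.n_elem; ++k)
            Gp[d].slice(ctrl_idx[k]) += rho * D / (double)ctrl_idx.n_elem;
          for (uword k = 0; k < lab_idx.n_elem; ++k)
            Gp[d].slice(lab_idx[k]) -= rho * D / (double)lab_idx.n_elem;
        }
      }
      // zero-mean-over-frames projection of the gradient
      for (int d = 0; d < 2; ++d) {
        mat mg = mean(Gp[d], 2);
        for (int g = 0; g < G; ++g) Gp[d].slice(g) -= mg;
      }
      double gmax = std::max(Gp[0].max(), -Gp[0].min());
      gmax = std::max(gmax, std::max(Gp[1].max(), -Gp[1].min()));
      if (gmax < 1e-12) continue;
      if (a_gain < 0) a_gain = step0 * std::pow(decay_A + 1.0, decay_alpha) / gmax;
      if (have_prev) {
        double num = accu(Gp[0] % Gprev[0]) + accu(Gp[1] % Gprev[1]);
        double den = std::sqrt((accu(square(Gp[0])) + accu(square(Gp[1]))) *
                               (accu(square(Gprev[0])) + accu(square(Gprev[1])))) +
          1e-300;
        double x = -num / den;                       // >0: noise regime
        double f = 2.0 / (1.0 + std::exp(-x / 0.2)) - 0.5;
        t_adapt = std::max(0.0, t_adapt + f);
      } else {
        have_prev = true;
      }
      Gprev[0] = Gp[0];
      Gprev[1] = Gp[1];
      double gamma = a_gain / std::pow(decay_A + t_adapt + 1.0, decay_alpha);
      if (gamma * gmax > max_update) gamma = max_update / gmax;
      for (int d = 0; d < 2; ++d) {
        P[d] -= gamma * Gp[d];
        mat mp = mean(P[d], 2);            // keep the implicit-mean constraint
        for (int g = 0; g < G; ++g) P[d].slice(g) -= mp;
      }
    }

    // fold this level's FFD into the dense displacement fields
    for (int g = 0; g < G; ++g)
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          Ur(r, c, g) += ffd_eval(P[0].slice(g), grid, r, c);
          Uc(r, c, g) += ffd_eval(P[1].slice(g), grid, r, c);
        }
  }

  // final resampling of the raw frames through the total deformation
  cube aligned(nr, nc, G);
  for (int g = 0; g < G; ++g) {
    mat cf = raw.slice(g);
    prefilter_image(cf);
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r)
        aligned(r, c, g) =
          interp_bspline(cf, r + Ur(r, c, g), c + Uc(r, c, g));
  }

  return Rcpp::List::create(
    Rcpp::Named("aligned") = aligned,
    Rcpp::Named("u_row") = Ur,
    Rcpp::Named("u_col") = Uc,
    Rcpp::Named("metric_trace") = trace);
}

// cubic B-spline warp of a single image through a dense displacement field
// [[Rcpp::export]]
arma::mat bspline_warp_cpp(const arma::mat& img, const arma::mat& u_row,
                           const arma::mat& u_col) {
  mat cf = img;
  prefilter_image(cf);
  mat out(img.n_rows, img.n_cols);
  for (uword c = 0; c < img.n_cols; ++c)
    for (uword r = 0; r < img.n_rows; ++r)
      out(r, c) = interp_bspline(cf, r + u_row(r, c), c + u_col(r, c));
  return out;
}
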