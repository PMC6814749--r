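// Numerical core: simplex-constrained least squares, archetypal analysis,
// successive-projection initialization, and the sqrt-Jensen-Shannon /
// k*-nearest-neighbor kernels. Kept in C++ because every routine here sits
// inside an O(n_cells) or O(n_cells^2) loop.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Solve min ||A x - b||^2 subject to x >= 0, sum(x) = 1 by an active-set
// method. At the optimum the gradient g = A'(Ax - b) satisfies g_i = mu on
// the support and g_i >= mu off it; each inner solve is the
// equality-constrained least-squares problem on the current passive set.
static vec simplex_ls(const mat& A, const vec& b, const vec* x0 = nullptr) {
  const uword n = A.n_cols;
  if (n == 1) return ones<vec>(1);

  std::vector<uword> P;
  vec x = zeros<vec>(n);
  if (x0 != nullptr && x0->n_elem == n && accu(*x0) > 0.5) {
    // warm start from a feasible point's support
    for (uword i = 0; i < n; ++i)
      if ((*x0)(i) > 1e-10) { P.push_back(i); x(i) = (*x0)(i); }
    x /= accu(x);
  }
  if (P.empty()) {
    // start at the best single vertex
    vec Ab = A.t() * b;
    vec cn(n);
    for (uword i = 0; i < n; ++i) cn(i) = dot(A.col(i), A.col(i));
    uword i0 = index_max(Ab - 0.5 * cn);
    P.push_back(i0);
    x(i0) = 1.0;
  }

  const double tol = 1e-10;
  const int max_outer = 4 * (int)std::min<uword>(n, A.n_rows + 4) + 20;
  bool need_solve = (x0 != nullptr) && P.size() > 1;

  for (int outer = 0; outer < max_outer; ++outer) {
    if (!need_solve) {
      vec r = A * x - b;
      vec g = A.t() * r;
      double mu = 0.0;
      for (size_t t = 0; t < P.size(); ++t) mu += g(P[t]);
      mu /= (double)P.size();

      // most-violating off-support variable
      double best = -std::max(tol, tol * std::abs(mu));
      sword j = -1;
      for (uword i = 0; i < n; ++i) {
        if (x(i) > 0) continue;
        double v = g(i) - mu;
        if (v < best) { best = v; j = (sword)i; }
      }
      if (j < 0) break;
      P.push_back((uword)j);
    }
    need_solve = false;

    // inner loop: re-solve on P, stepping back when components go negative
    for (int inner = 0; inner < 2 * (int)n + 10; ++inner) {
      uvec Pv = conv_to<uvec>::from(P);
      mat AP = A.cols(Pv);
      mat G = AP.t() * AP;
      G.diag() += 1e-12 * (trace(G) / (double)G.n_rows + 1.0);
      vec rhs = AP.t() * b;
      vec onesp = ones<vec>(Pv.n_elem);
      vec z1, z2;
      bool ok = solve(z1, G, rhs, solve_opts::no_approx);
      if (ok) ok = solve(z2, G, onesp, solve_opts::no_approx);
      if (!ok) {
        mat Gi = pinv(G);
        z1 = Gi * rhs;
        z2 = Gi * onesp;
      }
      double denom = accu(z2);
      double lam = (std::abs(denom) > 1e-300) ? (accu(z1) - 1.0) / denom : 0.0;
      vec xp = z1 - lam * z2;

      if (xp.min() > -1e-12) {
        x.zeros();
        for (uword t = 0; t < Pv.n_elem; ++t) x(Pv(t)) = std::max(xp(t), 0.0);
        double s = accu(x);
        if (s > 0) x /= s;
        break;
      }
      // step from current x toward xp until the first component hits zero
      double alpha = 1.0;
      for (uword t = 0; t < Pv.n_elem; ++t) {
        if (xp(t) < 1e-12) {
          double xi = x(Pv(t));
          double d = xi - xp(t);
          if (d > 1e-300) {
            double a = xi / d;
            if (a < alpha) alpha = a;
          }
        }
      }
      vec xnew = zeros<vec>(n);
      for (uword t = 0; t < Pv.n_elem; ++t) {
        double v = x(Pv(t)) + alpha * (xp(t) - x(Pv(t)));
        xnew(Pv(t)) = (v > 1e-12) ? v : 0.0;
      }
      double s = accu(xnew);
      if (s > 0) xnew /= s;
      x = xnew;
      std::vector<uword> P2;
      for (uword t = 0; t < Pv.n_elem; ++t)
        if (x(Pv(t)) > 0) P2.push_back(Pv(t));
      if (P2.empty()) { P2.push_back(Pv(0)); x(Pv(0)) = 1.0; }
      P = P2;
    }
  }
  return x;
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_simplex_ls(const arma::mat& A, const arma::mat& B) {
  mat X(A.n_cols, B.n_cols);
  for (uword i = 0; i < B.n_cols; ++i) X.col(i) = simplex_ls(A, B.col(i));
  return X;
}

// Successive projection: greedily pick k near-orthogonal extreme columns.
// start < 0 picks the largest-norm column first; otherwise the given column.
// [[Rcpp::export]]
arma::uvec cpp_spa(const arma::mat& S, int k, int start) {
  mat R = S;
  uvec sel(k);
  for (int j = 0; j < k; ++j) {
    uword i;
    if (j == 0 && start >= 0) {
      i = (uword)start;
    } else {
      vec nr = trans(sum(square(R), 0));
      if (j > 0) for (int t = 0; t < j; ++t) nr(sel(t)) = -1.0;
      i = index_max(nr);
    }
    sel(j) = i;
    vec u = R.col(i);
    double nu = norm(u);
    if (nu > 1e-12) {
      u /= nu;
      R -= u * (u.t() * R);
    }
  }
  return sel + 1; // 1-based for R
}

// Archetypal analysis of S (d x n): minimize ||S - S C H||_F over
// column-stochastic C (n x k) and H (k x n), alternating exact
// simplex-constrained least-squares solves for the columns of H and of C.
// init_cols: 1-based candidate cells; init_C/init_H optionally warm-start.
// [[Rcpp::export]]
Rcpp::List cpp_archetypal(const arma::mat& S, int k,
                          const arma::uvec& init_cols,
                          const arma::mat& init_C,
                          const arma::mat& init_H,
                          int max_iter, double tol) {
  const uword n = S.n_cols;
  mat C(n, (uword)k, fill::zeros);
  mat H((uword)k, n, fill::zeros);
  if (init_C.n_rows == n && init_C.n_cols == (uword)k &&
      init_H.n_rows == (uword)k && init_H.n_cols == n) {
    C = init_C;
    H = init_H;
  } else {
    for (int j = 0; j < k; ++j) C(init_cols(j) - 1, j) = 1.0;
    mat W = S * C;
    for (uword i = 0; i < n; ++i) H.col(i) = simplex_ls(W, S.col(i));
  }

  double s2 = accu(square(S));
  double prev = datum::inf;
  double rss = prev;
  bool converged = false;
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    mat W = S * C;
    // H step: n independent simplex LS problems against W (d x k),
    // warm-started from the previous sweep's footprints
    for (uword i = 0; i < n; ++i) {
      vec h0 = H.col(i);
      H.col(i) = (it == 0) ? simplex_ls(W, S.col(i))
                           : simplex_ls(W, S.col(i), &h0);
    }

    // C step: cycle archetypes; for fixed H the column c_j solves a
    // simplex LS against S for the target R_j h_j / ||h_j||^2
    mat R = S - W * H;
    for (int j = 0; j < k; ++j) {
      rowvec hj = H.row(j);
      double hn = dot(hj, hj);
      mat Rj = R + W.col(j) * hj;
      if (hn < 1e-12) {
        // dead archetype: relocate to the worst-reconstructed cell
        vec cres = trans(sum(square(R), 0));
        uword iw = index_max(cres);
        vec cj = zeros<vec>(n);
        cj(iw) = 1.0;
        C.col(j) = cj;
        W.col(j) = S * cj;
        R = Rj - W.col(j) * hj;
        continue;
      }
      vec target = (Rj * hj.t()) / hn;
      vec c0 = C.col(j);
      vec cj = (it == 0) ? simplex_ls(S, target)
                         : simplex_ls(S, target, &c0);
      vec wj = S * cj;
      C.col(j) = cj;
      W.col(j) = wj;
      R = Rj - wj * hj;
    }
    rss = accu(square(R));
    if (prev - rss <= tol * std::max(s2, 1e-12)) { converged = true; break; }
    prev = rss;
  }
  // final H refresh so (C, H) are mutually consistent
  mat W = S * C;
  for (uword i = 0; i < n; ++i) {
    vec h0 = H.col(i);
    H.col(i) = simplex_ls(W, S.col(i), &h0);
  }
  rss = accu(square(S - W * H));

  return Rcpp::List::create(
      Rcpp::Named("C") = C, Rcpp::Named("H") = H,
      Rcpp::Named("rss") = rss, Rcpp::Named("iterations") = it + 1,
      Rcpp::Named("converged") = converged);
}

static inline double row_entropy(const double* p, uword L) {
  double h = 0.0;
  for (uword l = 0; l < L; ++l)
    if (p[l] > 0) h -= p[l] * std::log2(p[l]);
  return h;
}

// sqrt Jensen-Shannon distance matrix; rows of P are probability vectors.
// [[Rcpp::export]]
arma::mat cpp_jsd_matrix(const arma::mat& P) {
  const uword n = P.n_rows, L = P.n_cols;
  vec H(n);
  mat Pt = P.t(); // column-major access per cell
  for (uword i = 0; i < n; ++i) H(i) = row_entropy(Pt.colptr(i), L);
  mat D(n, n, fill::zeros);
  for (uword i = 0; i < n; ++i) {
    const double* pi = Pt.colptr(i);
    for (uword j = i + 1; j < n; ++j) {
      const double* pj = Pt.colptr(j);
      double hm = 0.0;
      for (uword l = 0; l < L; ++l) {
        double m = 0.5 * (pi[l] + pj[l]);
        if (m > 0) hm -= m * std::log2(m);
      }
      double jsd = hm - 0.5 * (H(i) + H(j));
      if (jsd < 0) jsd = 0;
      double d = std::sqrt(jsd);
      if (d > 1) d = 1;
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// k*-NN neighborhoods under the adaptive rule: with neighbor distances
// sorted ascending, keep adding while the next distance does not exceed
// beta_j = (1/j) * (sum_{i<=j} d_i + sqrt(j*lambda + (sum d_i)^2 - j*sum d_i^2)).
// Returns the directed edge triplets (i, j, d); symmetrization is done in R.
// [[Rcpp::export]]
Rcpp::List cpp_kstar_edges(const arma::mat& P, int max_k, double lambda) {
  const uword n = P.n_rows, L = P.n_cols;
  if (max_k > (int)n - 1) max_k = (int)n - 1;
  vec H(n);
  mat Pt = P.t();
  for (uword i = 0; i < n; ++i) H(i) = row_entropy(Pt.colptr(i), L);

  std::vector<int> from, to;
  std::vector<double> dist;
  vec di(n);
  for (uword i = 0; i < n; ++i) {
    const double* pi = Pt.colptr(i);
    for (uword j = 0; j < n; ++j) {
      if (j == i) { di(j) = datum::inf; continue; }
      const double* pj = Pt.colptr(j);
      double hm = 0.0;
      for (uword l = 0; l < L; ++l) {
        double m = 0.5 * (pi[l] + pj[l]);
        if (m > 0) hm -= m * std::log2(m);
      }
      double jsd = hm - 0.5 * (H(i) + H(j));
      if (jsd < 0) jsd = 0;
      double d = std::sqrt(jsd);
      di(j) = (d > 1) ? 1.0 : d;
    }
    uvec ord = sort_index(di);
    // nearest neighbor always included, then extend while the rule holds
    uword kept = 1;
    double s1 = di(ord(0)), s2 = di(ord(0)) * di(ord(0));
    while ((int)kept < max_k) {
      double j = (double)kept;
      double disc = j * lambda + s1 * s1 - j * s2;
      if (disc < 0) disc = 0;
      double beta = (s1 + std::sqrt(disc)) / j;
      double dnext = di(ord(kept));
      if (dnext > beta) break;
      s1 += dnext;
      s2 += dnext * dnext;
      ++kept;
    }
    for (uword t = 0; t < kept; ++t) {
      from.push_back((int)i + 1);
      to.push_back((int)ord(t) + 1);
      dist.push_back(di(ord(t)));
    }
  }
  return Rcpp::List::create(Rcpp::Named("from") = from,
                            Rcpp::Named("to") = to,
                            Rcpp::Named("dist") = dist);
}
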