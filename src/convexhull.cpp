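// Convex-hull geometry in dimension 1..4 for functional hypervolume overlap.
// Brute-force facet enumeration is used: richness per site and the dimension
// cap (k <= 4) keep the combinatorics small, and degenerate (flat) inputs are
// detected and reported as zero volume rather than guessed at.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double REL_TOL = 1e-9;

struct Facet {
  vec a;      // outward normal, unit length
  double b;   // a . x <= b for all hull points
};

static double coord_scale(const mat& X) {
  double s = abs(X).max();
  return (s > 1.0) ? s : 1.0;
}

// next combination of k indices out of n, lexicographic; returns false when done
static bool next_comb(uvec& idx, unsigned int n, unsigned int k) {
  int i = k - 1;
  while (i >= 0 && idx[i] == n - k + i) --i;
  if (i < 0) return false;
  ++idx[i];
  for (unsigned int j = i + 1; j < k; ++j) idx[j] = idx[j - 1] + 1;
  return true;
}

// Enumerate facets of conv(X), X: n x d, points assumed full-dimensional.
static std::vector<Facet> facets_of(const mat& X, double tol) {
  unsigned int n = X.n_rows, d = X.n_cols;
  std::vector<Facet> out;
  if (n < d + 1) return out;
  uvec idx = regspace<uvec>(0, d - 1);
  do {
    mat M(d - 1 > 0 ? d - 1 : 1, d, fill::zeros);
    if (d == 1) {
      // hyperplane through one point: normal is +-1
      M.zeros();
    } else {
      for (unsigned int r = 1; r < d; ++r)
        M.row(r - 1) = X.row(idx[r]) - X.row(idx[0]);
    }
    vec a;
    if (d == 1) {
      a = vec(1); a[0] = 1.0;
    } else {
      mat N = null(M);
      if (N.n_cols != 1) continue;   // affinely dependent subset
      a = N.col(0);
    }
    double b = dot(a, X.row(idx[0]).t());
    vec s = X * a - b;
    bool below = s.max() <= tol, above = s.min() >= -tol;
    if (!below && !above) continue;
    if (above) { a = -a; b = -b; }
    // dedupe: coplanar d-subsets of one facet all yield the same hyperplane
    bool dup = false;
    for (const Facet& f : out)
      if (std::abs(dot(f.a, a) - 1.0) < 1e-7 && std::abs(f.b - b) < tol * 10 + 1e-12) { dup = true; break; }
    if (!dup) out.push_back({a, b});
  } while (next_comb(idx, n, d));
  return out;
}

// d-volume of conv(X), X: n x d; recursive over facet (d-1)-volumes
static double hull_vol(const mat& X, double tol);

static double facet_area(const mat& Fpts, const vec& a, double tol) {
  // (d-1)-volume of points lying on the hyperplane with normal a
  unsigned int d = Fpts.n_cols;
  if (d == 1) return 1.0; // 0-dim facet (a point) has measure 1 by convention
  mat Q = null(a.t());    // d x (d-1) orthonormal tangent basis
  mat Y = (Fpts.each_row() - Fpts.row(0)) * Q;
  return hull_vol(Y, tol);
}

static double hull_vol(const mat& X, double tol) {
  unsigned int n = X.n_rows, d = X.n_cols;
  if (d == 0) return 1.0;
  if (n < d + 1) return 0.0;
  if (d == 1) {
    return X.max() - X.min();
  }
  // flat input => zero d-volume
  mat C = X.each_row() - X.row(0);
  if (arma::rank(C, tol * 100) < d) return 0.0;
  std::vector<Facet> fs = facets_of(X, tol);
  if (fs.empty()) return 0.0;
  rowvec cen = mean(X, 0);
  double V = 0.0;
  for (const Facet& f : fs) {
    vec s = X * f.a - f.b;
    uvec on = find(abs(s) <= tol * 10 + 1e-12);
    if (on.n_elem < d) continue;
    double h = f.b - dot(f.a, cen.t());
    if (h < 0) h = 0;
    V += h * facet_area(X.rows(on), f.a, tol) / d;
  }
  return V;
}

// [[Rcpp::export(name = ".chull_volume")]]
double chull_volume(const arma::mat& X) {
  if (X.n_rows == 0 || X.n_cols == 0) return 0.0;
  double tol = REL_TOL * coord_scale(X);
  return hull_vol(X, tol);
}

// [[Rcpp::export(name = ".chull_facets")]]
Rcpp::List chull_facets(const arma::mat& X) {
  double tol = REL_TOL * coord_scale(X);
  unsigned int d = X.n_cols;
  if (d == 1) {
    mat A(2, 1); A(0, 0) = 1; A(1, 0) = -1;
    vec b(2); b[0] = X.max(); b[1] = -X.min();
    return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("b") = b);
  }
  std::vector<Facet> fs = facets_of(X, tol);
  mat A(fs.size(), d);
  vec b(fs.size());
  for (size_t i = 0; i < fs.size(); ++i) { A.row(i) = fs[i].a.t(); b[i] = fs[i].b; }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("b") = b);
}

// Vertices of the intersection polytope of {A1 x <= b1} and {A2 x <= b2}.
// Candidate vertices are solutions of d-subsets of the pooled hyperplanes
// that satisfy every constraint. Returns 0 x d matrix when empty, or a
// 1 x d NaN sentinel when the combinatorial budget is exceeded.
// [[Rcpp::export(name = ".chull_intersect_vertices")]]
arma::mat chull_intersect_vertices(const arma::mat& A1, const arma::vec& b1,
                                   const arma::mat& A2, const arma::vec& b2,
                                   double budget) {
  unsigned int d = A1.n_cols;
  mat A = join_cols(A1, A2);
  vec b = join_cols(b1, b2);
  unsigned int m = A.n_rows;
  if (m < d) return mat(0, d);
  // combinatorial budget: C(m, d)
  double ncomb = 1.0;
  for (unsigned int i = 0; i < d; ++i) ncomb = ncomb * (m - i) / (i + 1);
  if (ncomb > budget) { mat bad(1, d); bad.fill(datum::nan); return bad; }
  double scale = std::max(abs(b).max(), 1.0);
  double tol = 1e-8 * scale;
  std::vector<rowvec> verts;
  uvec idx = regspace<uvec>(0, d - 1);
  do {
    mat As = A.rows(idx);
    vec bs = b(idx);
    vec x;
    bool ok = solve(x, As, bs, solve_opts::no_approx);
    if (ok && x.is_finite()) {
      vec s = A * x - b;
      if (s.max() <= tol) {
        rowvec xr = x.t();
        bool dup = false;
        for (const rowvec& v : verts)
          if (norm(v - xr, 2) < tol * 10) { dup = true; break; }
        if (!dup) verts.push_back(xr);
      }
    }
  } while (next_comb(idx, m, d));
  mat out(verts.size(), d);
  for (size_t i = 0; i < verts.size(); ++i) out.row(i) = verts[i];
  return out;
}
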