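// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Knight's O(m log m) Kendall concordant-minus-discordant count.
// Pairs tied in either variable contribute zero. Returns C - D.
static long long merge_count(std::vector<double> &y, std::vector<double> &buf,
                             size_t lo, size_t hi) {
  if (hi - lo < 2) return 0;
  size_t mid = lo + (hi - lo) / 2;
  long long inv = merge_count(y, buf, lo, mid) + merge_count(y, buf, mid, hi);
  size_t i = lo, j = mid, k = lo;
  while (i < mid && j < hi) {
    if (y[j] < y[i]) {            // strict inversion only (ties not counted)
      inv += (long long)(mid - i);
      buf[k++] = y[j++];
    } else {
      buf[k++] = y[i++];
    }
  }
  while (i < mid) buf[k++] = y[i++];
  while (j < hi) buf[k++] = y[j++];
  std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
  return inv;
}

static long long tie_pairs(const std::vector<double> &v) {
  long long t = 0, run = 1;
  for (size_t i = 1; i <= v.size(); ++i) {
    if (i < v.size() && v[i] == v[i - 1]) {
      ++run;
    } else {
      t += run * (run - 1) / 2;
      run = 1;
    }
  }
  return t;
}

// [[Rcpp::export]]
double kendall_cd(NumericVector x, NumericVector y) {
  size_t m = x.size();
  if ((size_t)y.size() != m) stop("length mismatch");
  std::vector<size_t> ord(m);
  for (size_t i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  std::vector<double> xs(m), ys(m);
  for (size_t i = 0; i < m; ++i) { xs[i] = x[ord[i]]; ys[i] = y[ord[i]]; }

  long long n0 = (long long)m * (m - 1) / 2;
  long long n1 = tie_pairs(xs);              // xs is sorted
  // ties in both: runs of equal (x, y)
  long long n3 = 0, run = 1;
  for (size_t i = 1; i <= m; ++i) {
    if (i < m && xs[i] == xs[i - 1] && ys[i] == ys[i - 1]) {
      ++run;
    } else {
      n3 += run * (run - 1) / 2;
      run = 1;
    }
  }
  std::vector<double> buf(m), ysorted(ys);
  long long swaps = merge_count(ys, buf, 0, m); // ys now sorted
  long long n2 = tie_pairs(ys);
  long long nt = n0 - n1 - n2 + n3;          // pairs untied in both
  return (double)(nt - 2 * swaps);
}

// analytic diagonal-target shrinkage weight for one run of centered
// residuals (rows = frames)
static double analytic_lambda(const arma::mat &Xc) {
  double n = (double)Xc.n_rows;
  arma::mat S = Xc.t() * Xc / n;
  arma::mat X2 = Xc % Xc;
  arma::mat phi = X2.t() * X2 / n;
  arma::mat var_s = (n * n) * (phi - S % S) / std::pow(n - 1.0, 3);
  double num = arma::accu(var_s) - arma::accu(var_s.diag());
  double den = arma::accu(S % S) - arma::accu(arma::square(S.diag()));
  if (den <= 0) return 1.0;
  double lam = num / den;
  return std::min(1.0, std::max(0.0, lam));
}

// Spherical-searchlight crossnobis map for one subject.
//
// betas: list of (ncond x V) matrices, one per run
// resid: list of (frames x V) matrices, one per run
// dims: grid dims (3); in_mask: logical V; offsets: k x 3 integer voxel
// displacements; lambda < 0 requests the analytic shrinkage estimate;
// cell_select: logical over the ncond*(ncond-1)/2 upper-triangle cells
// (column-major order, matching R's upper.tri); the map holds the mean
// crossnobis distance over the selected cells.
// [[Rcpp::export]]
List searchlight_crossnobis(List betas, List resid, IntegerVector dims,
                            LogicalVector in_mask, IntegerMatrix offsets,
                            double min_frac, double lambda,
                            LogicalVector cell_select, bool return_rdms) {
  int R = betas.size();
  if (R < 2) stop("need at least 2 runs");
  int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  int V = d1 * d2 * d3;
  int K = offsets.nrow();
  std::vector<arma::mat> B(R), E(R);
  for (int r = 0; r < R; ++r) {
    B[r] = as<arma::mat>(betas[r]);
    E[r] = as<arma::mat>(resid[r]);
    if ((int)B[r].n_cols != V || (int)E[r].n_cols != V)
      stop("beta/residual voxel count does not match the grid");
  }
  int ncond = B[0].n_rows;
  int npairs = ncond * (ncond - 1) / 2;
  if (cell_select.size() != npairs) stop("cell mask has wrong length");
  std::vector<int> sel;
  for (int c = 0; c < npairs; ++c) if (cell_select[c]) sel.push_back(c);
  if (sel.empty()) stop("empty cell mask");

  // upper-triangle (i < j), column-major, 0-based
  std::vector<int> pi(npairs), pj(npairs);
  {
    int c = 0;
    for (int j = 1; j < ncond; ++j)
      for (int i = 0; i < j; ++i) { pi[c] = i; pj[c] = j; ++c; }
  }

  NumericVector map(V, NA_REAL);
  std::vector<int> centers;
  std::vector<std::vector<double>> rdm_rows;
  arma::uvec idx(K);
  double denom_runs = (double)R * (R - 1);

  for (int v = 0; v < V; ++v) {
    if (!in_mask[v]) continue;
    int z = v / (d1 * d2), rem = v % (d1 * d2);
    int y = rem / d1, x = rem % d1;
    int P = 0;
    for (int k = 0; k < K; ++k) {
      int xx = x + offsets(k, 0), yy = y + offsets(k, 1), zz = z + offsets(k, 2);
      if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3)
        continue;
      int lin = xx + yy * d1 + zz * d1 * d2;
      if (!in_mask[lin]) continue;
      idx(P++) = (arma::uword)lin;
    }
    if ((double)P / K < min_frac || P < 1) continue;
    arma::uvec cols = idx.head(P);

    // run-averaged shrinkage covariance of the sphere's residuals
    arma::mat S_bar(P, P, arma::fill::zeros);
    double lam_sum = 0.0;
    for (int r = 0; r < R; ++r) {
      arma::mat Xc = E[r].cols(cols);
      Xc.each_row() -= arma::mean(Xc, 0);
      double n = (double)Xc.n_rows;
      S_bar += Xc.t() * Xc / n;
      if (lambda < 0) lam_sum += analytic_lambda(Xc);
    }
    S_bar /= (double)R;
    double lam = (lambda < 0) ? lam_sum / R : lambda;
    arma::mat Sig = (1.0 - lam) * S_bar;
    Sig.diag() = S_bar.diag();

    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, Sig)) continue;
    double floor_ev = std::max(eval.max(), 1e-300) * 1e-10;
    eval.transform([&](double e) { return e < floor_ev ? floor_ev : e; });
    arma::mat W = evec * arma::diagmat(1.0 / arma::sqrt(eval)) * evec.t();

    arma::mat H(ncond, ncond, arma::fill::zeros);
    std::vector<arma::mat> Bw(R);
    for (int r = 0; r < R; ++r) Bw[r] = B[r].cols(cols) * W;
    for (int m = 0; m < R - 1; ++m)
      for (int n = m + 1; n < R; ++n) {
        arma::mat G = Bw[m] * Bw[n].t();
        H += G + G.t();
      }
    double scale = 1.0 / ((double)P * denom_runs);
    double acc = 0.0;
    std::vector<double> row;
    if (return_rdms) row.resize(npairs);
    if (return_rdms) {
      for (int c = 0; c < npairs; ++c)
        row[c] = (H(pi[c], pi[c]) + H(pj[c], pj[c]) - 2.0 * H(pi[c], pj[c])) * scale;
      for (size_t s = 0; s < sel.size(); ++s) acc += row[sel[s]];
    } else {
      for (size_t s = 0; s < sel.size(); ++s) {
        int c = sel[s];
        acc += (H(pi[c], pi[c]) + H(pj[c], pj[c]) - 2.0 * H(pi[c], pj[c])) * scale;
      }
    }
    map[v] = acc / sel.size();
    centers.push_back(v + 1);                 // 1-based for R
    if (return_rdms) rdm_rows.push_back(std::move(row));
  }

  SEXP rdms = R_NilValue;
  if (return_rdms) {
    NumericMatrix M(rdm_rows.size(), npairs);
    for (size_t r = 0; r < rdm_rows.size(); ++r)
      for (int c = 0; c < npairs; ++c) M(r, c) = rdm_rows[r][c];
    rdms = M;
  }
  return List::create(_["map"] = map,
                      _["centers"] = wrap(centers),
                      _["rdms"] = rdms);
}
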