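#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Two-sample Wald-Wolfowitz runs machinery.
//
// Pool the two blocks, sort ascending, label each value by block of origin
// and count runs of consecutive equal labels. Ties spanning the two blocks
// are resolved deterministically: within a tied group labels are laid out
// alternately (starting with the left block) until one side is exhausted.
// Alternation maximizes the run count for tied values, which is conservative
// for breakpoint detection (ties are evidence of similarity).

static int count_runs(const double* x, int n1, const double* y, int n2) {
  int n = n1 + n2;
  std::vector<std::pair<double, int> > v;
  v.reserve(n);
  for (int i = 0; i < n1; ++i) v.push_back(std::make_pair(x[i], 0));
  for (int i = 0; i < n2; ++i) v.push_back(std::make_pair(y[i], 1));
  std::stable_sort(v.begin(), v.end());
  std::vector<int> lab(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && v[j].first == v[i].first) ++j;
    int c0 = 0, c1 = 0;
    for (int k = i; k < j; ++k) (v[k].second == 0 ? c0 : c1)++;
    int turn = 0;
    for (int k = i; k < j; ++k) {
      if ((turn == 0 && c0 > 0) || c1 == 0) { lab[k] = 0; --c0; }
      else                                  { lab[k] = 1; --c1; }
      turn = 1 - turn;
    }
    i = j;
  }
  int runs = 1;
  for (int k = 1; k < n; ++k)
    if (lab[k] != lab[k - 1]) ++runs;
  return runs;
}

// log pmf of the run count R under exchangeability (classic closed form):
//   P(R = 2k)   = 2 C(n1-1,k-1) C(n2-1,k-1) / C(n,n1)
//   P(R = 2k+1) = [C(n1-1,k-1) C(n2-1,k) + C(n1-1,k) C(n2-1,k-1)] / C(n,n1)
static double pmf_runs(int r, int n1, int n2) {
  int n = n1 + n2;
  double denom = R::lchoose((double)n, (double)n1);
  if (r < 2 || r > n) return 0.0;
  if (r % 2 == 0) {
    int k = r / 2;
    if (k - 1 > n1 - 1 || k - 1 > n2 - 1) return 0.0;
    return 2.0 * exp(R::lchoose(n1 - 1.0, k - 1.0) +
                     R::lchoose(n2 - 1.0, k - 1.0) - denom);
  }
  int k = (r - 1) / 2;
  double a = 0.0, b = 0.0;
  if (k - 1 <= n1 - 1 && k <= n2 - 1)
    a = exp(R::lchoose(n1 - 1.0, k - 1.0) + R::lchoose(n2 - 1.0, (double)k) - denom);
  if (k <= n1 - 1 && k - 1 <= n2 - 1)
    b = exp(R::lchoose(n1 - 1.0, (double)k) + R::lchoose(n2 - 1.0, k - 1.0) - denom);
  return a + b;
}

// Two-sided p: double the smaller tail, capped at 1.
static double p_exact(int r, int n1, int n2) {
  double lo = 0.0, hi = 0.0;
  int n = n1 + n2;
  for (int s = 2; s <= r; ++s) lo += pmf_runs(s, n1, n2);
  for (int s = r; s <= n; ++s) hi += pmf_runs(s, n1, n2);
  double p = 2.0 * std::min(lo, hi);
  return std::min(1.0, p);
}

static double p_normal(int r, int n1, int n2) {
  double n = n1 + n2;
  double mu = 1.0 + 2.0 * n1 * n2 / n;
  double var = 2.0 * n1 * n2 * (2.0 * n1 * n2 - n) / (n * n * (n - 1.0));
  if (var <= 0.0) return 1.0;
  double sd = sqrt(var);
  // continuity-corrected tails
  double lo = R::pnorm(r + 0.5, mu, sd, 1, 0);
  double hi = R::pnorm(r - 0.5, mu, sd, 0, 0);
  double p = 2.0 * std::min(lo, hi);
  return std::min(1.0, p);
}

static double runs_p_one(const double* x, int n1, const double* y, int n2,
                         int exact_limit) {
  if (n1 < 5 || n2 < 5) return 1.0;
  // all values identical: no distributional evidence either way
  bool same = true;
  for (int i = 1; i < n1 && same; ++i) same = (x[i] == x[0]);
  for (int i = 0; i < n2 && same; ++i) same = (y[i] == x[0]);
  if (same) return 1.0;
  int r = count_runs(x, n1, y, n2);
  if (n1 + n2 <= exact_limit) return p_exact(r, n1, n2);
  return p_normal(r, n1, n2);
}

// [[Rcpp::export(name = ".runs_p_cpp")]]
double runs_p_cpp(NumericVector x, NumericVector y, int exact_limit) {
  return runs_p_one(x.begin(), x.size(), y.begin(), y.size(), exact_limit);
}

// [[Rcpp::export(name = ".runs_count_cpp")]]
int runs_count_cpp(NumericVector x, NumericVector y) {
  return count_runs(x.begin(), x.size(), y.begin(), y.size());
}

// [[Rcpp::export(name = ".runs_null_pmf_cpp")]]
NumericVector runs_null_pmf_cpp(int n1, int n2) {
  int n = n1 + n2;
  NumericVector out(n + 1); // out[r] = P(R = r), index 0..n
  for (int r = 2; r <= n; ++r) out[r] = pmf_runs(r, n1, n2);
  return out;
}

// Sliding scan: p-value at every interior boundary b (1-based; boundary
// between positions b and b+1) using the `block` values on each side.
// NA where a full block is not available.
// [[Rcpp::export(name = ".scan_runs_cpp")]]
NumericVector scan_runs_cpp(NumericVector r, int block, int exact_limit) {
  int n = r.size();
  NumericVector out(std::max(0, n - 1), NA_REAL);
  if (n < 2 * block) return out;
  for (int b = block; b <= n - block; ++b) {
    out[b - 1] = runs_p_one(r.begin() + (b - block), block,
                            r.begin() + b, block, exact_limit);
  }
  return out;
}
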