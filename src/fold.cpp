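#include <Rcpp.h>
#include <string>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted Nussinov minimisation over nested canonical structures.
// W(i,j) = min( W(i+1,j),
//               min_k { S(i,k) + W(i+1,k-1) + W(k+1,j) : k > i + min_loop } )
// with S(i,k) the pairing score (NA / +inf = pair disallowed). Because all
// admissible scores are <= 0 and leaving k unpaired is always an option,
// zero-score pairs are never chosen. Deterministic traceback: prefer
// leaving i unpaired, otherwise pair i with the smallest admissible k.

static const double INF = 1e18;
static const double FEPS = 1e-9;

static void nussinov_fill(const std::vector<double>& S, int n, int min_loop,
                          std::vector<double>& W) {
  W.assign(n * n, 0.0);
  auto at = [n](int i, int j) { return i * n + j; };
  for (int span = 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      double best = W[at(i + 1, j)]; // i unpaired (i + 1 <= j since span >= 2)
      for (int k = i + min_loop + 1; k <= j; ++k) {
        double s = S[at(i, k)];
        if (s >= INF / 2) continue;
        double inner = (i + 1 <= k - 1) ? W[at(i + 1, k - 1)] : 0.0;
        double right = (k + 1 <= j) ? W[at(k + 1, j)] : 0.0;
        double cand = s + inner + right;
        if (cand < best - FEPS) best = cand;
      }
      W[at(i, j)] = best;
    }
  }
}

static void nussinov_trace(const std::vector<double>& S,
                           const std::vector<double>& W, int n, int min_loop,
                           std::vector<int>& partner) {
  partner.assign(n, -1);
  auto at = [n](int i, int j) { return i * n + j; };
  std::vector<std::pair<int, int>> stack;
  if (n >= 2) stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    double cur = W[at(i, j)];
    double un = (i + 1 <= j) ? W[at(i + 1, j)] : 0.0;
    if (std::fabs(cur - un) < FEPS) {
      stack.push_back({i + 1, j});
      continue;
    }
    bool placed = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      double s = S[at(i, k)];
      if (s >= INF / 2) continue;
      double inner = (i + 1 <= k - 1) ? W[at(i + 1, k - 1)] : 0.0;
      double right = (k + 1 <= j) ? W[at(k + 1, j)] : 0.0;
      if (std::fabs(cur - (s + inner + right)) < FEPS) {
        partner[i] = k;
        partner[k] = i;
        stack.push_back({i + 1, k - 1});
        stack.push_back({k + 1, j});
        placed = true;
        break;
      }
    }
    if (!placed) stack.push_back({i + 1, j}); // numeric safety net
  }
}

static List fold_from_scores(const std::vector<double>& S, int n,
                             int min_loop) {
  std::vector<double> W;
  std::vector<int> partner;
  if (n < 2) {
    std::string dots(n, '.');
    return List::create(_["structure"] = dots, _["energy"] = 0.0,
                        _["pairs"] = IntegerMatrix(0, 2));
  }
  nussinov_fill(S, n, min_loop, W);
  nussinov_trace(S, W, n, min_loop, partner);
  std::string db(n, '.');
  int npairs = 0;
  double energy = 0.0;
  auto at = [n](int i, int j) { return i * n + j; };
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      db[i] = '(';
      db[partner[i]] = ')';
      energy += S[at(i, partner[i])];
      ++npairs;
    }
  }
  IntegerMatrix pairs(npairs, 2); // 1-based positions
  int r = 0;
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      pairs(r, 0) = i + 1;
      pairs(r, 1) = partner[i] + 1;
      ++r;
    }
  }
  return List::create(_["structure"] = db, _["energy"] = energy,
                      _["pairs"] = pairs);
}

static inline double pair_score(char a, char b, double gc, double au,
                                double gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return gc;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return au;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return gu;
  return INF;
}

// [[Rcpp::export]]
List cpp_fold(std::string seq, double gc, double au, double gu, int min_loop) {
  int n = seq.size();
  std::vector<double> S(std::max(1, n * n), INF);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      S[i * n + j] = pair_score(seq[i], seq[j], gc, au, gu);
  return fold_from_scores(S, n, min_loop);
}

// Fold directly from a column-pair score matrix (consensus folding);
// scores[i][j] = NA_real_ marks a disallowed pair.
// [[Rcpp::export]]
List cpp_fold_matrix(NumericMatrix scores, int min_loop) {
  int n = scores.nrow();
  std::vector<double> S(std::max(1, n * n), INF);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      S[i * n + j] = NumericMatrix::is_na(scores(i, j)) ? INF : scores(i, j);
  return fold_from_scores(S, n, min_loop);
}
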