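#include <Rcpp.h>
#include <string>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state DP).
// A gap of length L costs gap_open + L * gap_extend (open charged once,
// every gapped residue pays the extension), the blast/Biostrings convention.
// 'N' mismatches everything, including 'N'.
//
// Deterministic traceback: at every tie prefer diagonal (match state),
// then up (gap in subject), then left (gap in query), then - for local
// alignment - the zero restart; the best local cell is the first maximum
// in row-major order, and ties between continuing a zero-valued path and
// restarting prefer continuing (smallest start coordinate).

static const double NEG = -1e18;
static const double EPS = 1e-9;

static inline double subst(char a, char b, double match, double mismatch) {
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

struct AlnResult {
  double score;
  std::string qaln, taln;
  int q_start, q_end, t_start, t_end; // 0-based half-open on originals
  bool empty;
};

// type: 0 = global (Needleman-Wunsch, end gaps penalized), 1 = local (SW)
static AlnResult align_core(const std::string& a, const std::string& b,
                            int type, double match, double mismatch,
                            double go, double ge,
                            const std::vector<bool>& mask_b) {
  const int n = a.size(), m = b.size();
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto id = [m](int i, int j) { return i * (m + 1) + j; };

  M[id(0, 0)] = 0.0;
  if (type == 0) {
    for (int i = 1; i <= n; ++i) X[id(i, 0)] = -go - i * ge;
    for (int j = 1; j <= m; ++j) Y[id(0, j)] = -go - j * ge;
  } else {
    for (int i = 0; i <= n; ++i) M[id(i, 0)] = 0.0;
    for (int j = 0; j <= m; ++j) M[id(0, j)] = 0.0;
  }

  double best = 0.0;
  int bi = -1, bj = -1;
  const bool local = (type == 1);
  const bool use_mask = !mask_b.empty();
  const double goe = go + ge;
  const int W = m + 1;

  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    double* Mi = &M[i * W];
    double* Xi = &X[i * W];
    double* Yi = &Y[i * W];
    const double* Mp = &M[(i - 1) * W];
    const double* Xp = &X[(i - 1) * W];
    const double* Yp = &Y[(i - 1) * W];
    for (int j = 1; j <= m; ++j) {
      if (use_mask && mask_b[j - 1]) {
        Mi[j] = Xi[j] = Yi[j] = NEG;
        continue;
      }
      const char bc = b[j - 1];
      const double s =
          (ai == 'N' || bc == 'N') ? mismatch : (ai == bc ? match : mismatch);
      double dbest = Mp[j - 1];
      if (Xp[j - 1] > dbest) dbest = Xp[j - 1];
      if (Yp[j - 1] > dbest) dbest = Yp[j - 1];
      if (local && dbest < 0.0) dbest = 0.0;
      const double mij = dbest + s;
      Mi[j] = mij;
      const double xo = Mp[j] - goe, xe = Xp[j] - ge;
      Xi[j] = xo > xe ? xo : xe;
      const double yo = Mi[j - 1] - goe, ye = Yi[j - 1] - ge;
      Yi[j] = yo > ye ? yo : ye;
      if (local && mij > best + EPS) {
        best = mij; bi = i; bj = j;
      }
    }
  }

  AlnResult r;
  r.empty = false;
  std::string qa, ta;
  int i, j, state; // 0 = M, 1 = X (up, gap in b), 2 = Y (left, gap in a)

  if (type == 1) {
    r.score = best;
    if (bi < 0) {
      r.empty = true;
      r.q_start = r.q_end = r.t_start = r.t_end = 0;
      r.qaln = r.taln = "";
      return r;
    }
    i = bi; j = bj; state = 0;
    r.q_end = bi; r.t_end = bj;
  } else {
    i = n; j = m;
    double fM = M[id(n, m)], fX = X[id(n, m)], fY = Y[id(n, m)];
    r.score = std::max(fM, std::max(fX, fY));
    state = (fM >= fX - EPS && fM >= fY - EPS) ? 0 : (fX >= fY - EPS ? 1 : 2);
    r.q_start = 0; r.q_end = n; r.t_start = 0; r.t_end = m;
  }

  while (true) {
    if (type == 0 && i == 0 && j == 0) break;
    if (state == 0) {
      if (i == 0 || j == 0) break; // local path start on a border
      double target = M[id(i, j)] - subst(a[i - 1], b[j - 1], match, mismatch);
      qa.push_back(a[i - 1]);
      ta.push_back(b[j - 1]);
      --i; --j;
      if (std::fabs(M[id(i, j)] - target) < EPS) {
        // border zeros in local mode are initialization, not path cells
        if (type == 1 && std::fabs(target) < EPS && (i == 0 || j == 0)) break;
        state = 0;
      } else if (std::fabs(X[id(i, j)] - target) < EPS) {
        state = 1;
      } else if (std::fabs(Y[id(i, j)] - target) < EPS) {
        state = 2;
      } else {
        break; // local zero restart: path starts at current (i, j)
      }
    } else if (state == 1) {
      double cur = X[id(i, j)];
      qa.push_back(a[i - 1]);
      ta.push_back('-');
      bool from_open = (M[id(i - 1, j)] > NEG / 2) &&
                       std::fabs(M[id(i - 1, j)] - go - ge - cur) < EPS;
      --i;
      state = from_open ? 0 : 1;
    } else {
      double cur = Y[id(i, j)];
      qa.push_back('-');
      ta.push_back(b[j - 1]);
      bool from_open = (M[id(i, j - 1)] > NEG / 2) &&
                       std::fabs(M[id(i, j - 1)] - go - ge - cur) < EPS;
      --j;
      state = from_open ? 0 : 2;
    }
  }

  if (type == 1) { r.q_start = i; r.t_start = j; }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  r.qaln = qa; r.taln = ta;
  return r;
}

static List as_list(const AlnResult& r) {
  return List::create(
      _["score"] = r.score, _["qaln"] = r.qaln, _["taln"] = r.taln,
      _["q_start"] = r.q_start, _["q_end"] = r.q_end,
      _["t_start"] = r.t_start, _["t_end"] = r.t_end,
      _["empty"] = r.empty);
}

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b, std::string type,
               double match, double mismatch, double gap_open,
               double gap_extend) {
  std::vector<bool> nomask;
  AlnResult r = align_core(a, b, type == "global" ? 0 : 1, match, mismatch,
                           gap_open, gap_extend, nomask);
  return as_list(r);
}

// Iterative blast-like multi-hit scan: repeatedly take the best local
// alignment, then mask its subject interval so later hits cannot reuse it.
// [[Rcpp::export]]
List cpp_scan(std::string query, std::string target, double match,
              double mismatch, double gap_open, double gap_extend,
              double min_score, int max_matches) {
  std::vector<bool> mask(target.size(), false);
  List out;
  for (int k = 0; k < max_matches; ++k) {
    AlnResult r = align_core(query, target, 1, match, mismatch, gap_open,
                             gap_extend, mask);
    if (r.empty || r.score < min_score) break;
    out.push_back(as_list(r));
    for (int j = r.t_start; j < r.t_end; ++j) mask[j] = true;
  }
  return out;
}
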