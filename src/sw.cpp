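#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Local alignment with affine gaps and a neutral-base rule: a column in
// which either base is 'N' scores `neutral` (used for ambiguous and
// QV-masked bases). A gap of length L costs gap_open + (L-1)*gap_extend.
static double sw_score(const std::string& q, const std::string& t,
                       double match, double mismatch,
                       double gap_open, double gap_extend, double neutral,
                       int* qs, int* qe, int* ts, int* te) {
  const int n = q.size(), m = t.size();
  // H: best score ending at (i,j) with q[i-1] aligned to t[j-1] or gap states
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, R_NegInf));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, R_NegInf));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      char a = q[i - 1], b = t[j - 1];
      double s;
      if (a == 'N' || b == 'N') s = neutral;
      else s = (a == b) ? match : mismatch;
      E[i][j] = std::max(H[i][j - 1] + gap_open, E[i][j - 1] + gap_extend);
      F[i][j] = std::max(H[i - 1][j] + gap_open, F[i - 1][j] + gap_extend);
      double h = H[i - 1][j - 1] + s;
      h = std::max(h, E[i][j]);
      h = std::max(h, F[i][j]);
      h = std::max(h, 0.0);
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  // traceback for the aligned span
  int i = bi, j = bj;
  if (best > 0.0) {
    while (i > 0 && j > 0 && H[i][j] > 0.0) {
      char a = q[i - 1], b = t[j - 1];
      double s = (a == 'N' || b == 'N') ? neutral : ((a == b) ? match : mismatch);
      if (H[i][j] == H[i - 1][j - 1] + s) { --i; --j; }
      else if (H[i][j] == E[i][j]) {
        // walk left through the gap
        while (j > 1 && E[i][j] == E[i][j - 1] + gap_extend) --j;
        --j;
      } else if (H[i][j] == F[i][j]) {
        while (i > 1 && F[i][j] == F[i - 1][j] + gap_extend) --i;
        --i;
      } else break;
    }
  }
  if (qs) { *qs = i + 1; *qe = bi; *ts = j + 1; *te = bj; }
  return best;
}

// [[Rcpp::export]]
List cpp_smith_waterman(std::string query, std::string target,
                        double match, double mismatch,
                        double gap_open, double gap_extend, double neutral) {
  int qs = 0, qe = 0, ts = 0, te = 0;
  double sc = sw_score(query, target, match, mismatch, gap_open, gap_extend,
                       neutral, &qs, &qe, &ts, &te);
  return List::create(_["score"] = sc,
                      _["queryStart"] = qs, _["queryEnd"] = qe,
                      _["targetStart"] = ts, _["targetEnd"] = te);
}

// Score a batch of query segments against a set of target references.
// Returns a length(queries) x length(targets) score matrix.
// [[Rcpp::export]]
NumericMatrix cpp_sw_batch(CharacterVector queries, CharacterVector targets,
                           double match, double mismatch,
                           double gap_open, double gap_extend, double neutral) {
  const int nq = queries.size(), nt = targets.size();
  NumericMatrix out(nq, nt);
  std::vector<std::string> tg(nt);
  for (int j = 0; j < nt; ++j) tg[j] = as<std::string>(targets[j]);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    for (int j = 0; j < nt; ++j)
      out(i, j) = sw_score(q, tg[j], match, mismatch, gap_open, gap_extend,
                           neutral, nullptr, nullptr, nullptr, nullptr);
  }
  return out;
}
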