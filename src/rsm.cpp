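#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// ---- sorted-vector set helpers -------------------------------------------

static int isect_count(const std::vector<int>& a, const std::vector<int>& b) {
  int n = 0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

static std::vector<int> isect(const std::vector<int>& a, const std::vector<int>& b) {
  std::vector<int> out;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { out.push_back(a[i]); ++i; ++j; }
  }
  return out;
}

static std::vector<std::vector<int>> as_reads(const List& subs) {
  std::vector<std::vector<int>> reads(subs.size());
  for (R_xlen_t i = 0; i < subs.size(); ++i) {
    IntegerVector s = subs[i];
    reads[i].assign(s.begin(), s.end());
    std::sort(reads[i].begin(), reads[i].end());
  }
  return reads;
}

// Modified Jaccard index between reads i and j (Eq.-8 style): shared
// substitution codes over all codes of either read falling in the code
// window of the overlapped interval. The minimal-overlap rule is relative
// to read i's length: overlap < l_min_frac * (e_i - b_i)  =>  0.
static double jaccard_ij(const std::vector<int>& Si, const std::vector<int>& Sj,
                         int bi, int ei, int bj, int ej, double l_min_frac) {
  const int mb = std::max(bi, bj), me = std::min(ei, ej);
  if (me < mb) return 0.0;
  if ((double)(me - mb + 1) < l_min_frac * (double)(ei - bi)) return 0.0;
  const int lo = 4 * mb, hi = 4 * me + 3;
  int inter = 0, uni = 0;
  size_t i = 0, j = 0;
  while (i < Si.size() || j < Sj.size()) {
    int v;
    bool both = false;
    if (i < Si.size() && j < Sj.size()) {
      if (Si[i] < Sj[j]) v = Si[i++];
      else if (Si[i] > Sj[j]) v = Sj[j++];
      else { v = Si[i]; ++i; ++j; both = true; }
    } else if (i < Si.size()) v = Si[i++];
    else v = Sj[j++];
    if (v >= lo && v <= hi) { ++uni; if (both) ++inter; }
  }
  if (uni == 0) return 0.0;
  return (double)inter / (double)uni;
}

// [[Rcpp::export]]
double cpp_read_jaccard(IntegerVector si, IntegerVector sj,
                        int bi, int ei, int bj, int ej, double l_min_frac) {
  std::vector<int> a(si.begin(), si.end()), b(sj.begin(), sj.end());
  std::sort(a.begin(), a.end());
  std::sort(b.begin(), b.end());
  return jaccard_ij(a, b, bi, ei, bj, ej, l_min_frac);
}

// Full (asymmetric) modified-Jaccard matrix; row i holds Jaccard(R_i, R_j)
// with the minimal-overlap rule taken relative to read i.
// [[Rcpp::export]]
NumericMatrix cpp_jaccard_matrix(List subs, IntegerVector b, IntegerVector e,
                                 double l_min_frac) {
  auto reads = as_reads(subs);
  const int m = reads.size();
  NumericMatrix out(m, m);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j)
      if (i != j)
        out(i, j) = jaccard_ij(reads[i], reads[j], b[i], e[i], b[j], e[j],
                               l_min_frac);
  return out;
}

static std::vector<std::vector<int>> top_neighbors(
    const std::vector<std::vector<int>>& reads,
    const IntegerVector& b, const IntegerVector& e,
    int w, double l_min_frac) {
  const int m = reads.size();
  std::vector<std::vector<int>> nb(m);
  std::vector<std::pair<double, int>> js;
  for (int i = 0; i < m; ++i) {
    js.clear();
    for (int j = 0; j < m; ++j) {
      if (j == i) continue;
      double jc = jaccard_ij(reads[i], reads[j], b[i], e[i], b[j], e[j],
                             l_min_frac);
      if (jc > 0.0) js.push_back({jc, j});
    }
    int keep = std::min<int>(w, js.size());
    std::partial_sort(js.begin(), js.begin() + keep, js.end(),
                      [](const std::pair<double,int>& a,
                         const std::pair<double,int>& p) {
                        if (a.first != p.first) return a.first > p.first;
                        return a.second < p.second;
                      });
    nb[i].reserve(keep);
    for (int t = 0; t < keep; ++t) nb[i].push_back(js[t].second);
  }
  return nb;
}

// w highest-Jaccard neighbours of each read (1-based indices; only
// neighbours with positive Jaccard, ties by read order).
// [[Rcpp::export]]
List cpp_top_neighbors(List subs, IntegerVector b, IntegerVector e,
                       int w, double l_min_frac) {
  auto reads = as_reads(subs);
  auto nb = top_neighbors(reads, b, e, w, l_min_frac);
  List out(nb.size());
  for (size_t i = 0; i < nb.size(); ++i) {
    IntegerVector v(nb[i].size());
    for (size_t t = 0; t < nb[i].size(); ++t) v[t] = nb[i][t] + 1;
    out[i] = v;
  }
  return out;
}

// ---- greedy maximal conditional substitution rate ------------------------

typedef std::unordered_map<int, std::vector<int>> CarrierMap;

struct GreedyResult {
  double h = NA_REAL;
  int den = 0;
  std::vector<int> chosen;
  std::vector<double> rates;  // accepted-step conditional rates
};

static int hd_runs(const IntegerVector& run_id, int k, int g) {
  int d = std::abs(run_id[k] - run_id[g]) - 1;
  return d < 0 ? 0 : d;
}

// Candidates are sorted by single-conditioning rate (desc), ties by larger
// denominator, lower locus, lower code. A candidate whose single denominator
// is below v_min can never reach v_min jointly (denominators shrink under
// intersection) and is dropped up front. Extension stops at the first
// candidate that fails to strictly increase the rate or drops the
// denominator below v_min.
static GreedyResult greedy_core(const CarrierMap& car,
                                const IntegerVector& b, const IntegerVector& e,
                                int xk, const std::vector<int>& cand,
                                int v_min, int hd_min,
                                const IntegerVector& run_id) {
  GreedyResult res;
  const int k = xk / 4;
  static const std::vector<int> empty;
  auto itx = car.find(xk);
  const std::vector<int>& cx = (itx == car.end()) ? empty : itx->second;
  struct C { int code; double rate; int den; std::vector<int> denlist; };
  std::vector<C> cs;
  for (int c : cand) {
    const int g = c / 4;
    if (g == k) continue;
    if (hd_min > 0 && hd_runs(run_id, k, g) < hd_min) continue;
    auto it = car.find(c);
    if (it == car.end()) continue;
    std::vector<int> dl;
    for (int i : it->second)
      if (b[i] <= k && k <= e[i]) dl.push_back(i);
    if ((int)dl.size() < v_min) continue;
    const int num = isect_count(dl, cx);
    const int den = (int)dl.size();
    cs.push_back({c, (double)num / den, den, std::move(dl)});
  }
  if (cs.empty()) return res;
  std::sort(cs.begin(), cs.end(), [](const C& a, const C& p) {
    if (a.rate != p.rate) return a.rate > p.rate;
    if (a.den != p.den) return a.den > p.den;
    if (a.code / 4 != p.code / 4) return a.code / 4 < p.code / 4;
    return a.code < p.code;
  });
  std::vector<int> cur = cs[0].denlist;
  double currate = cs[0].rate;
  res.chosen.push_back(cs[0].code);
  res.rates.push_back(currate);
  res.den = cs[0].den;
  for (size_t t = 1; t < cs.size(); ++t) {
    std::vector<int> nl = isect(cur, cs[t].denlist);
    if ((int)nl.size() < v_min) break;
    const double r = (double)isect_count(nl, cx) / (double)nl.size();
    if (r > currate) {
      cur = std::move(nl);
      currate = r;
      res.chosen.push_back(cs[t].code);
      res.rates.push_back(r);
      res.den = (int)cur.size();
    } else break;
  }
  res.h = currate;
  return res;
}

static CarrierMap build_carriers(const std::vector<std::vector<int>>& reads) {
  CarrierMap car;
  for (size_t i = 0; i < reads.size(); ++i)
    for (int c : reads[i]) car[c].push_back((int)i);
  return car;  // lists sorted because reads are visited in order
}

// [[Rcpp::export]]
List cpp_greedy(List subs, IntegerVector b, IntegerVector e,
                int xk, IntegerVector candidates,
                IntegerVector run_id, int v_min, int hd_min) {
  auto reads = as_reads(subs);
  CarrierMap car = build_carriers(reads);
  std::vector<int> cand(candidates.begin(), candidates.end());
  GreedyResult g = greedy_core(car, b, e, xk, cand, v_min, hd_min, run_id);
  return List::create(_["h"] = g.h, _["den"] = g.den,
                      _["chosen"] = IntegerVector(g.chosen.begin(), g.chosen.end()),
                      _["rates"] = NumericVector(g.rates.begin(), g.rates.end()));
}

// Random-subspace scan: for every code present in at least one subspace
// C_ij = S_i `intersect` S_j (j among the w best neighbours of i), run the
// greedy search inside the subspace and keep the best estimate per code.
// Returns one row per evaluated code with the best H, its denominator, the
// marginal carrier count t and the coverage n at the code's locus.
// [[Rcpp::export]]
DataFrame cpp_rsm_scan(List subs, IntegerVector b, IntegerVector e,
                       IntegerVector run_id, int w, int v_min, int hd_min,
                       double l_min_frac) {
  auto reads = as_reads(subs);
  const int m = reads.size();
  CarrierMap car = build_carriers(reads);
  auto nb = top_neighbors(reads, b, e, w, l_min_frac);

  struct Best { double h; int den; };
  std::unordered_map<int, Best> best;
  std::unordered_set<uint64_t> seen;
  std::vector<int> cand;
  for (int i = 0; i < m; ++i) {
    for (int j : nb[i]) {
      const uint64_t key = (uint64_t)std::min(i, j) * (uint64_t)m +
                           (uint64_t)std::max(i, j);
      if (!seen.insert(key).second) continue;
      std::vector<int> C = isect(reads[i], reads[j]);
      if (C.empty()) continue;
      for (int x : C) {
        const int k = x / 4;
        cand.clear();
        for (int c : C) if (c / 4 != k) cand.push_back(c);
        if (cand.empty()) continue;
        GreedyResult g = greedy_core(car, b, e, x, cand, v_min, hd_min, run_id);
        if (ISNA(g.h)) continue;
        auto it = best.find(x);
        if (it == best.end() || g.h > it->second.h ||
            (g.h == it->second.h && g.den > it->second.den))
          best[x] = {g.h, g.den};
      }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // coverage per locus
  const int L = run_id.size();
  std::vector<int> cov(L + 1, 0);
  for (int i = 0; i < m; ++i) {
    int bi = std::max(0, (int)b[i]), ei = std::min(L - 1, (int)e[i]);
    if (bi <= ei) { cov[bi] += 1; cov[ei + 1] -= 1; }
  }
  for (int k = 1; k <= L; ++k) cov[k] += cov[k - 1];

  std::vector<int> codes;
  codes.reserve(best.size());
  for (auto& kv : best) codes.push_back(kv.first);
  std::sort(codes.begin(), codes.end());
  const int nr = codes.size();
  IntegerVector code(nr), den(nr), tt(nr), nn(nr);
  NumericVector h(nr);
  for (int r = 0; r < nr; ++r) {
    const int x = codes[r];
    code[r] = x;
    h[r] = best[x].h;
    den[r] = best[x].den;
    auto it = car.find(x);
    tt[r] = it == car.end() ? 0 : (int)it->second.size();
    nn[r] = cov[x / 4];
  }
  return DataFrame::create(_["code"] = code, _["hHat"] = h, _["nDen"] = den,
                           _["t"] = tt, _["n"] = nn);
}
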