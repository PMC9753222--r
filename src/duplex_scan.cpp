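#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sequences arrive encoded A=0, C=1, G=2, T/U=3, N=-1.
// Duplexes are antiparallel and ungapped: lnc position p pairs mRNA position
// q with p + q = d constant along one alignment (one "diagonal" d).

static inline bool wc_pair(int a, int b) {
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 1 && b == 2) || (a == 2 && b == 1);
}

static inline bool gu_pair(int a, int b) {
  return (a == 2 && b == 3) || (a == 3 && b == 2);
}

static inline double pair_energy(int a, int b, double eGC, double eAU,
                                 double eGU, double mismatch) {
  if (a < 0 || b < 0) return mismatch;
  if (a + b == 3 && a != b) return (a == 1 || a == 2) ? eGC : eAU; // WC
  if (gu_pair(a, b)) return eGU;
  return mismatch;
}

struct Cand {
  int pl, pr, d;      // lnc span [pl, pr], diagonal d (q = d - p)
  int paired;
  double energy;
};

// Exact Watson-Crick seeds: lnc[i..i+k-1] antiparallel-complementary to
// mrna[j..j+k-1] (no G:U). Returns 0-based (i, j) start pairs.
static void find_seeds_core(const IntegerVector& lnc,
                            const IntegerVector& mrna, int k,
                            std::vector<std::pair<int,int> >& seeds) {
  int L1 = lnc.size(), L2 = mrna.size();
  if (L1 < k || L2 < k) return;
  std::unordered_map<int, std::vector<int> > index;
  index.reserve(L2);
  for (int j = 0; j + k <= L2; ++j) {
    int code = 0; bool ok = true;
    for (int t = 0; t < k; ++t) {
      int b = mrna[j + t];
      if (b < 0) { ok = false; break; }
      code = code * 4 + b;
    }
    if (ok) index[code].push_back(j);
  }
  for (int i = 0; i + k <= L1; ++i) {
    int code = 0; bool ok = true;
    // required mRNA window read 5'->3' is the reverse complement of the
    // lnc window: mrna[j + t] == comp(lnc[i + k - 1 - t])
    for (int t = 0; t < k; ++t) {
      int b = lnc[i + k - 1 - t];
      if (b < 0) { ok = false; break; }
      code = code * 4 + (3 - b);
    }
    if (!ok) continue;
    std::unordered_map<int, std::vector<int> >::iterator it =
      index.find(code);
    if (it == index.end()) continue;
    for (size_t u = 0; u < it->second.size(); ++u)
      seeds.push_back(std::make_pair(i, it->second[u]));
  }
}

// [[Rcpp::export]]
IntegerMatrix find_seeds_cpp(IntegerVector lnc, IntegerVector mrna,
                             int seed_len) {
  std::vector<std::pair<int,int> > seeds;
  find_seeds_core(lnc, mrna, seed_len, seeds);
  IntegerMatrix out(seeds.size(), 2);
  for (size_t u = 0; u < seeds.size(); ++u) {
    out(u, 0) = seeds[u].first;
    out(u, 1) = seeds[u].second;
  }
  return out;
}

// x-drop extension of one seed; G:U allowed in extension only.
static Cand extend_one(const IntegerVector& lnc, const IntegerVector& mrna,
                       int i, int j, int k, double eGC, double eAU,
                       double eGU, double mismatch, double xdrop) {
  int L1 = lnc.size(), L2 = mrna.size();
  int d = i + j + k - 1;
  double seedE = 0.0;
  for (int p = i; p <= i + k - 1; ++p)
    seedE += pair_energy(lnc[p], mrna[d - p], eGC, eAU, eGU, mismatch);

  // rightward in lnc (leftward in mRNA)
  double cum = 0.0, best = 0.0; int pr = i + k - 1;
  for (int p = i + k; p < L1 && d - p >= 0; ++p) {
    cum += pair_energy(lnc[p], mrna[d - p], eGC, eAU, eGU, mismatch);
    if (cum < best) { best = cum; pr = p; }
    if (cum > best + xdrop) break;
  }
  double rightE = best;

  // leftward in lnc (rightward in mRNA)
  cum = 0.0; best = 0.0; int pl = i;
  for (int p = i - 1; p >= 0 && d - p < L2; --p) {
    cum += pair_energy(lnc[p], mrna[d - p], eGC, eAU, eGU, mismatch);
    if (cum < best) { best = cum; pl = p; }
    if (cum > best + xdrop) break;
  }
  double leftE = best;

  Cand c;
  c.pl = pl; c.pr = pr; c.d = d;
  c.energy = seedE + leftE + rightE;
  c.paired = 0;
  for (int p = pl; p <= pr; ++p) {
    int a = lnc[p], b = mrna[d - p];
    if (a >= 0 && b >= 0 && (wc_pair(a, b) || gu_pair(a, b))) c.paired++;
  }
  return c;
}

// [[Rcpp::export]]
List extend_duplex_cpp(IntegerVector lnc, IntegerVector mrna,
                       int i, int j, int seed_len, double eGC, double eAU,
                       double eGU, double mismatch, double xdrop) {
  Cand c = extend_one(lnc, mrna, i, j, seed_len, eGC, eAU, eGU,
                      mismatch, xdrop);
  return List::create(_["lnc_start"] = c.pl, _["lnc_end"] = c.pr + 1,
                      _["mrna_start"] = c.d - c.pr,
                      _["mrna_end"] = c.d - c.pl + 1,
                      _["paired_len"] = c.paired, _["energy"] = c.energy);
}

static bool cand_less(const Cand& a, const Cand& b) {
  if (a.energy != b.energy) return a.energy < b.energy;
  if (a.pl != b.pl) return a.pl < b.pl;
  return a.d < b.d;
}

// [[Rcpp::export]]
DataFrame scan_pair_cpp(IntegerVector lnc, IntegerVector mrna, int seed_len,
                        double eGC, double eAU, double eGU, double mismatch,
                        double xdrop, double max_energy, int min_len) {
  std::vector<std::pair<int,int> > seeds;
  find_seeds_core(lnc, mrna, seed_len, seeds);

  std::vector<Cand> cands;
  std::unordered_map<long long, bool> seen;
  for (size_t u = 0; u < seeds.size(); ++u) {
    Cand c = extend_one(lnc, mrna, seeds[u].first, seeds[u].second,
                        seed_len, eGC, eAU, eGU, mismatch, xdrop);
    long long key = ((long long)c.d << 40) ^ ((long long)c.pl << 20) ^ c.pr;
    if (seen.find(key) != seen.end()) continue;
    seen[key] = true;
    cands.push_back(c);
  }
  std::sort(cands.begin(), cands.end(), cand_less);

  // keep the best-energy candidate of every overlapping group: accept in
  // energy order, discard later candidates overlapping an accepted one on
  // both molecules
  std::vector<Cand> kept;
  for (size_t u = 0; u < cands.size(); ++u) {
    const Cand& c = cands[u];
    bool clash = false;
    for (size_t v = 0; v < kept.size(); ++v) {
      const Cand& k2 = kept[v];
      bool lnc_ov = c.pl <= k2.pr && k2.pl <= c.pr;
      int cj1 = c.d - c.pr, cj2 = c.d - c.pl;
      int kj1 = k2.d - k2.pr, kj2 = k2.d - k2.pl;
      bool mrna_ov = cj1 <= kj2 && kj1 <= cj2;
      if (lnc_ov && mrna_ov) { clash = true; break; }
    }
    if (!clash) kept.push_back(c);
  }

  std::vector<int> ls, le, ms, me, pl;
  std::vector<double> en;
  for (size_t u = 0; u < kept.size(); ++u) {
    const Cand& c = kept[u];
    if (!(c.energy < max_energy)) continue;
    if (c.paired < min_len) continue;
    ls.push_back(c.pl); le.push_back(c.pr + 1);
    ms.push_back(c.d - c.pr); me.push_back(c.d - c.pl + 1);
    pl.push_back(c.paired); en.push_back(c.energy);
  }
  return DataFrame::create(_["lnc_start"] = ls, _["lnc_end"] = le,
                           _["mrna_start"] = ms, _["mrna_end"] = me,
                           _["paired_len"] = pl, _["energy"] = en,
                           _["stringsAsFactors"] = false);
}
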