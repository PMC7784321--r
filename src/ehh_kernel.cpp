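#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shared kernel for the EHH statistic family.  A decay curve is the
// haplotype-class partition refined marker by marker away from a core
// site; the statistic at span core..t is sum_k n_k (n_k - 1) divided by a
// core normalizer, so every curve starts at 1 and is non-increasing
// (refining a partition can only reduce the pair count).

struct SideDecay {
  std::vector<int> idx;     // 0-based site indices, core first
  std::vector<double> val;  // statistic at each recorded marker (>= cutoff)
  bool censored;            // hit the chromosome edge while still >= cutoff
};

static double pair_stat(const std::vector<int> &classes, int k) {
  std::vector<double> cnt(k, 0.0);
  for (size_t i = 0; i < classes.size(); ++i) cnt[classes[i]] += 1.0;
  double s = 0.0;
  for (int c = 0; c < k; ++c) s += cnt[c] * (cnt[c] - 1.0);
  return s;
}

// Extend from `core` in direction `dir` (+1/-1).  `classes` is the class
// label (0..k0-1) of each tracked haplotype over the core span; `norm` the
// pair count of that span.  Markers are recorded while the normalized
// statistic stays >= cutoff; the first sub-cutoff marker truncates the
// curve and is not recorded.
static SideDecay decay_side(const IntegerMatrix &hap,
                            const std::vector<int> &rows,
                            std::vector<int> classes, int k0,
                            int core, int dir, double cutoff, double norm) {
  SideDecay out;
  out.censored = false;
  const int S = hap.ncol();
  const int m = (int)rows.size();
  int k = k0;

  out.idx.push_back(core);
  out.val.push_back(pair_stat(classes, k) / norm);

  // class labels stay < m, so refinement keys fit a flat relabel table
  std::vector<int> remap(2 * m, -1);
  std::vector<double> cnt(m, 0.0);
  for (int t = core + dir; t >= 0 && t < S; t += dir) {
    std::fill(remap.begin(), remap.begin() + 2 * k, -1);
    int knew = 0;
    for (int i = 0; i < m; ++i) {
      int key = classes[i] * 2 + hap(rows[i], t);
      if (remap[key] < 0) { remap[key] = knew; cnt[knew] = 0.0; ++knew; }
      classes[i] = remap[key];
      cnt[classes[i]] += 1.0;
    }
    k = knew;
    double stat = 0.0;
    for (int c = 0; c < k; ++c) stat += cnt[c] * (cnt[c] - 1.0);
    double v = stat / norm;
    if (v < cutoff) return out;
    out.idx.push_back(t);
    out.val.push_back(v);
  }
  out.censored = true;  // ran off the chromosome without crossing the cutoff
  return out;
}

static double side_area(const SideDecay &d, const NumericVector &pos) {
  double a = 0.0;
  for (size_t i = 1; i < d.idx.size(); ++i) {
    double w = std::fabs(pos[d.idx[i]] - pos[d.idx[i - 1]]);
    a += 0.5 * (d.val[i] + d.val[i - 1]) * w;
  }
  return a;
}

static List side_to_list(const SideDecay &d) {
  IntegerVector idx(d.idx.begin(), d.idx.end());
  NumericVector val(d.val.begin(), d.val.end());
  for (int i = 0; i < idx.size(); ++i) idx[i] += 1;  // back to 1-based
  return List::create(_["idx"] = idx, _["value"] = val,
                      _["censored"] = d.censored);
}

// Decay curve for one core.  site_mode = true gives the site statistic
// (EHHS: all tracked haplotypes, classes seeded by core allele); false
// gives the allele-specific statistic (EHH: rows are the carriers, one
// initial class).  rows1/core1 are 1-based.
// [[Rcpp::export]]
List cpp_decay(const IntegerMatrix &hap, const IntegerVector &rows1,
               int core1, bool site_mode, double cutoff) {
  const int core = core1 - 1;
  std::vector<int> rows(rows1.size());
  for (int i = 0; i < rows1.size(); ++i) rows[i] = rows1[i] - 1;
  const int m = (int)rows.size();

  std::vector<int> classes(m, 0);
  int k0 = 1;
  if (site_mode) {
    for (int i = 0; i < m; ++i) classes[i] = hap(rows[i], core);
    k0 = 2;
  }
  double norm = pair_stat(classes, k0);
  if (norm <= 0.0) return R_NilValue;  // fewer than 2 pairable haplotypes

  SideDecay L = decay_side(hap, rows, classes, k0, core, -1, cutoff, norm);
  SideDecay R = decay_side(hap, rows, classes, k0, core, +1, cutoff, norm);
  return List::create(_["left"] = side_to_list(L),
                      _["right"] = side_to_list(R));
}

// iES for every site of a complete single-chromosome panel: trapezoid area
// of the two-sided EHHS decay over physical positions, NA when either side
// is edge-censored or fewer than 2 haplotypes are pairable.
// [[Rcpp::export]]
NumericVector cpp_ies_scan(const IntegerMatrix &hap, const NumericVector &pos,
                           double cutoff) {
  const int S = hap.ncol(), H = hap.nrow();
  NumericVector out(S, NA_REAL);
  std::vector<int> rows(H);
  for (int i = 0; i < H; ++i) rows[i] = i;

  for (int s = 0; s < S; ++s) {
    std::vector<int> classes(H);
    for (int i = 0; i < H; ++i) classes[i] = hap(i, s);
    double norm = pair_stat(classes, 2);
    if (norm <= 0.0) continue;
    SideDecay L = decay_side(hap, rows, classes, 2, s, -1, cutoff, norm);
    if (L.censored) continue;
    SideDecay R = decay_side(hap, rows, classes, 2, s, +1, cutoff, norm);
    if (R.censored) continue;
    out[s] = side_area(L, pos) + side_area(R, pos);
  }
  return out;
}

// iHH for the ancestral (column 1) and derived (column 2) allele at every
// site.  anc[s] in {0,1} names the ancestral allele.  NA when the allele
// has fewer than min_carriers carriers or the decay is edge-censored.
// [[Rcpp::export]]
NumericMatrix cpp_ihh_scan(const IntegerMatrix &hap, const NumericVector &pos,
                           const IntegerVector &anc, double cutoff,
                           int min_carriers) {
  const int S = hap.ncol(), H = hap.nrow();
  NumericMatrix out(S, 2);
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int s = 0; s < S; ++s) {
    for (int a = 0; a < 2; ++a) {
      int allele = (a == 0) ? anc[s] : 1 - anc[s];
      std::vector<int> rows;
      for (int i = 0; i < H; ++i)
        if (hap(i, s) == allele) rows.push_back(i);
      if ((int)rows.size() < min_carriers) continue;
      std::vector<int> classes(rows.size(), 0);
      double norm = (double)rows.size() * (rows.size() - 1.0);
      SideDecay L = decay_side(hap, rows, classes, 1, s, -1, cutoff, norm);
      if (L.censored) continue;
      SideDecay R = decay_side(hap, rows, classes, 1, s, +1, cutoff, norm);
      if (R.censored) continue;
      out(s, a) = side_area(L, pos) + side_area(R, pos);
    }
  }
  return out;
}
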