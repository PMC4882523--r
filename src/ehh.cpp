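#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// One-sided EHH decay from a core SNP over phased haplotypes.
//
// Haplotypes are partitioned by identity of the extended segment
// [core..current] (inclusive of the core allele); EHH at each extension is
// sum_k C(m_k,2) / C(n,2) over partition class sizes. The curve starts at
// (0, 1) and is truncated when EHH drops below `cutoff` (that point is
// kept), when the physical distance exceeds `max_ext`, when the gap to the
// next SNP exceeds `max_gap`, or at the chromosome bound [lo, hi].
static void ehh_side(const IntegerMatrix& H, int core, int dir,
                     const NumericVector& pos, int lo, int hi,
                     double cutoff, double max_ext, double max_gap,
                     std::vector<double>& dist, std::vector<double>& ehh,
                     std::string& reason) {
  const int n = H.nrow();
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> group(n), relab(2 * n + 2, -1), touched;
  std::vector<int> csize;
  touched.reserve(2 * n);

  for (int i = 0; i < n; ++i) group[i] = H(i, core);
  dist.push_back(0.0);
  ehh.push_back(1.0);
  reason = "end";

  int j = core;
  while (true) {
    int jn = j + dir;
    if (jn < lo || jn > hi) { reason = "end"; break; }
    double gap = std::abs(pos[jn] - pos[j]);
    if (gap > max_gap) { reason = "gap"; break; }
    double d = std::abs(pos[jn] - pos[core]);
    if (d > max_ext) { reason = "max_extension"; break; }
    j = jn;

    // relabel groups by (old group, allele) pairs
    int ng = 0;
    touched.clear();
    for (int i = 0; i < n; ++i) {
      int key = group[i] * 2 + H(i, j);
      if (relab[key] < 0) { relab[key] = ng++; touched.push_back(key); }
      group[i] = relab[key];
    }
    csize.assign(ng, 0);
    for (int i = 0; i < n; ++i) csize[group[i]]++;
    for (size_t t = 0; t < touched.size(); ++t) relab[touched[t]] = -1;

    double pairs = 0.0;
    for (int k = 0; k < ng; ++k)
      pairs += (double)csize[k] * (csize[k] - 1) / 2.0;
    double e = pairs / denom;
    dist.push_back(d);
    ehh.push_back(e);
    if (e < cutoff) { reason = "cutoff"; break; }
  }
}

// [[Rcpp::export(name = ".ehh_side_cpp")]]
List ehh_side_cpp(IntegerMatrix H, int core, int dir, NumericVector pos,
                  int lo, int hi, double cutoff, double max_ext,
                  double max_gap) {
  std::vector<double> dist, ehh;
  std::string reason;
  ehh_side(H, core - 1, dir, pos, lo - 1, hi - 1, cutoff, max_ext, max_gap,
           dist, ehh, reason);
  return List::create(_["dist"] = wrap(dist), _["ehh"] = wrap(ehh),
                      _["reason"] = reason);
}
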