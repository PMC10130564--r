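#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Integrated EHH (iES) at every site of one chromosome.
//
// For a core site, haplotypes are extended outwards one SNP at a time; at
// each step haplotypes are partitioned into classes identical over the sites
// visited so far (the core site itself is not used for splitting, so EHH at
// distance 0 is 1 by convention). EHH is the probability that two random
// haplotypes fall in the same class: sum_h C(n_h,2) / C(n,2). The curve is
// integrated over physical distance by the trapezoid rule, including the
// first point that falls below `min_ehh`, and truncated there or at a gap
// larger than `max_gap` or at the chromosome end. Both directions are summed.
//
// Missing alleles (NA) are treated as a third allele state, which splits
// classes conservatively.
// [[Rcpp::export]]
NumericVector ies_scan_cpp(IntegerMatrix hap, NumericVector pos,
                           double min_ehh, double max_gap) {
  const int n = hap.nrow(), m = hap.ncol();
  NumericVector ies(m);
  const double denom = (double)n * (n - 1) / 2.0;
  std::vector<int> grp(n);
  std::vector<int> counts;
  for (int core = 0; core < m; ++core) {
    double total = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      std::fill(grp.begin(), grp.end(), 0);
      double prev_pos = pos[core];
      double prev_ehh = 1.0;
      for (int j = core + dir; j >= 0 && j < m; j += dir) {
        double step = std::abs(pos[j] - prev_pos);
        if (step > max_gap) break;
        std::unordered_map<long long, int> relab;
        counts.clear();
        int next = 0;
        for (int h = 0; h < n; ++h) {
          int allele = hap(h, j);
          if (allele == NA_INTEGER) allele = 2;
          long long key = (long long)grp[h] * 3LL + allele;
          auto it = relab.find(key);
          int id;
          if (it == relab.end()) {
            id = next++;
            relab.emplace(key, id);
            counts.push_back(0);
          } else {
            id = it->second;
          }
          grp[h] = id;
          counts[id]++;
        }
        double s = 0.0;
        for (int g = 0; g < next; ++g)
          s += (double)counts[g] * (counts[g] - 1) / 2.0;
        double e = s / denom;
        total += (prev_ehh + e) / 2.0 * step;
        prev_ehh = e;
        prev_pos = pos[j];
        if (e < min_ehh) break;
      }
    }
    ies[core] = total;
  }
  return ies;
}
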