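// Random non-overlapping placement of query intervals and the permutation
// null loop for enrichment testing. All randomness uses R's RNG so set.seed()
// makes replicates reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Placement { int chrom; double start, end; };

// place regions sequentially: chromosome drawn proportional to length,
// start uniform over the feasible range, rejection on overlap
bool place_all(const NumericVector& region_len, const NumericVector& chrom_len,
               const NumericVector& cum_prob, int max_tries,
               std::vector<Placement>& out, int& stuck) {
  const int nr = region_len.size();
  out.clear();
  out.reserve(nr);
  for (int r = 0; r < nr; ++r) {
    const double L = region_len[r];
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      const double u = unif_rand();
      int c = (int)(std::lower_bound(cum_prob.begin(), cum_prob.end(), u) -
                    cum_prob.begin());
      if (c >= chrom_len.size()) c = chrom_len.size() - 1;
      const double room = chrom_len[c] - L;
      if (room < 0) continue;
      const double s = std::floor(unif_rand() * (room + 1.0));
      bool clash = false;
      for (size_t p = 0; p < out.size(); ++p) {
        if (out[p].chrom == c && s < out[p].end && out[p].start < s + L) {
          clash = true;
          break;
        }
      }
      if (!clash) {
        Placement pl; pl.chrom = c; pl.start = s; pl.end = s + L;
        out.push_back(pl);
        placed = true;
        break;
      }
    }
    if (!placed) { stuck = r + 1; return false; }
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
DataFrame cpp_place_regions(NumericVector region_len, NumericVector chrom_len,
                            int max_tries) {
  NumericVector cum(chrom_len.size());
  double tot = 0;
  for (int i = 0; i < chrom_len.size(); ++i) tot += chrom_len[i];
  double acc = 0;
  for (int i = 0; i < chrom_len.size(); ++i) {
    acc += chrom_len[i] / tot;
    cum[i] = acc;
  }
  std::vector<Placement> pl;
  int stuck = 0;
  if (!place_all(region_len, chrom_len, cum, max_tries, pl, stuck)) {
    stop("random placement failed after max_tries for region %d", stuck);
  }
  const int n = pl.size();
  IntegerVector chrom(n);
  NumericVector start(n), end(n);
  for (int i = 0; i < n; ++i) {
    chrom[i] = pl[i].chrom + 1;
    start[i] = pl[i].start;
    end[i] = pl[i].end;
  }
  return DataFrame::create(_["chrom"] = chrom, _["start"] = start,
                           _["end"] = end);
}

// Null distribution of the overlap statistic over n_reps random placements.
// Landmarks arrive merged and sorted by (chrom, start); lm_offset[c] ..
// lm_offset[c+1]-1 index chromosome c's landmarks. mode: 0 = count of
// landmark intervals hit, 1 = total overlapping bases, 2 = count of placed
// query regions hitting any landmark.
// [[Rcpp::export]]
NumericVector cpp_null_stats(NumericVector region_len, NumericVector chrom_len,
                             IntegerVector lm_offset, NumericVector lm_start,
                             NumericVector lm_end, int mode, int n_reps,
                             int max_tries) {
  NumericVector cum(chrom_len.size());
  double tot = 0;
  for (int i = 0; i < chrom_len.size(); ++i) tot += chrom_len[i];
  double acc = 0;
  for (int i = 0; i < chrom_len.size(); ++i) {
    acc += chrom_len[i] / tot;
    cum[i] = acc;
  }
  const int n_lm = lm_start.size();
  std::vector<char> hit(n_lm, 0);
  NumericVector stats(n_reps);
  std::vector<Placement> pl;

  for (int rep = 0; rep < n_reps; ++rep) {
    int stuck = 0;
    if (!place_all(region_len, chrom_len, cum, max_tries, pl, stuck)) {
      stop("random placement failed after max_tries for region %d (replicate %d)",
           stuck, rep + 1);
    }
    double stat = 0;
    if (mode == 0) std::fill(hit.begin(), hit.end(), 0);
    for (size_t p = 0; p < pl.size(); ++p) {
      const int c = pl[p].chrom;
      const int lo = lm_offset[c], hi = lm_offset[c + 1];
      // first landmark with end > region start
      int a = lo, b = hi;
      while (a < b) {
        int mid = (a + b) / 2;
        if (lm_end[mid] <= pl[p].start) a = mid + 1; else b = mid;
      }
      for (int m = a; m < hi && lm_start[m] < pl[p].end; ++m) {
        if (mode == 0) {
          if (!hit[m]) { hit[m] = 1; stat += 1; }
        } else if (mode == 1) {
          stat += std::min(lm_end[m], pl[p].end) -
                  std::max(lm_start[m], pl[p].start);
        } else {
          stat += 1;
          break; // this placed region already counts as hitting a landmark
        }
      }
    }
    stats[rep] = stat;
  }
  return stats;
}
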