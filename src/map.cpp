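// Pigeonhole short-read mapper: a read with <= max_mm mismatches against the
// reference must match one of (max_mm + 1) non-overlapping exact seed parts,
// so every qualifying locus is found. Both strands are searched; equal-best
// loci share the read's depth contribution equally.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <climits>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int base2m(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char compm(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

// [[Rcpp::export]]
List cpp_map_reads(std::string ref, CharacterVector reads, int read_len,
                   int max_mm) {
  const int64_t N = (int64_t)ref.size();
  const int parts = max_mm + 1;
  const int s = read_len / parts;
  if (s < 8) stop("reads too short for the pigeonhole seed length");

  // sorted (s-mer, position) index of the reference
  std::vector<std::pair<uint64_t, int> > idx;
  {
    uint64_t kmer = 0;
    const uint64_t mask = (1ULL << (2 * s)) - 1;
    int run = 0;
    for (int64_t i = 0; i < N; ++i) {
      int b = base2m(ref[i]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= s) idx.push_back(std::make_pair(kmer, (int)(i - s + 1)));
    }
    std::sort(idx.begin(), idx.end());
  }

  std::vector<int> out_read, out_pos, out_mm;
  std::vector<int> out_strand;
  std::vector<double> out_w;
  int unmapped = 0;

  std::string rc(read_len, 'N');
  std::vector<int> cand;
  std::vector<int> best_pos;
  std::vector<int> best_strand;

  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    const char* fwd = CHAR(STRING_ELT(reads, ri));
    if ((int)strlen(fwd) != read_len) stop("all reads must share read_len");
    for (int i = 0; i < read_len; ++i) rc[i] = compm(fwd[read_len - 1 - i]);

    int best_mm = max_mm + 1;
    best_pos.clear(); best_strand.clear();

    for (int strand = 0; strand < 2; ++strand) {
      const char* rseq = (strand == 0) ? fwd : rc.c_str();
      cand.clear();
      for (int p = 0; p < parts; ++p) {
        const int off = p * s;
        uint64_t kmer = 0; bool ok = true;
        for (int i = 0; i < s; ++i) {
          int b = base2m(rseq[off + i]);
          if (b < 0) { ok = false; break; }
          kmer = (kmer << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        std::pair<uint64_t, int> lo(kmer, -1), hi(kmer, INT_MAX);
        std::vector<std::pair<uint64_t, int> >::iterator a =
          std::lower_bound(idx.begin(), idx.end(), lo);
        std::vector<std::pair<uint64_t, int> >::iterator b =
          std::upper_bound(idx.begin(), idx.end(), hi);
        for (; a != b; ++a) {
          int start = a->second - off;
          if (start >= 0 && start + read_len <= N) cand.push_back(start);
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (size_t c = 0; c < cand.size(); ++c) {
        const int64_t start = cand[c];
        int mm = 0;
        for (int i = 0; i < read_len; ++i) {
          if (ref[start + i] != rseq[i]) {
            if (++mm > max_mm) break;
          }
        }
        if (mm > max_mm || mm > best_mm) continue;
        if (mm < best_mm) { best_mm = mm; best_pos.clear(); best_strand.clear(); }
        best_pos.push_back((int)start);
        best_strand.push_back(strand);
      }
    }

    if (best_pos.empty()) { ++unmapped; continue; }
    const double w = 1.0 / (double)best_pos.size();
    for (size_t h = 0; h < best_pos.size(); ++h) {
      out_read.push_back((int)ri + 1);
      out_pos.push_back(best_pos[h]);
      out_strand.push_back(best_strand[h]);
      out_mm.push_back(best_mm);
      out_w.push_back(w);
    }
  }

  return List::create(
    _["read"] = wrap(out_read), _["pos"] = wrap(out_pos),
    _["strand"] = wrap(out_strand), _["mismatches"] = wrap(out_mm),
    _["weight"] = wrap(out_w), _["unmapped"] = unmapped);
}
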