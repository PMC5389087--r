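// Gap-free seed-merge-extend self-alignment kernel (WGAC stage), plus an
// independent brute-force diagonal scanner used as a test oracle.
//
// Sequences arrive concatenated with >= 60 'N' separator bases between
// chromosomes; alignments can never bridge a separator because k-mers
// containing N are skipped, extension stops at N, and the trim step never
// keeps non-ACGT columns.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

typedef std::pair<uint64_t, int> KPos;

// All valid k-mers of s as (2-bit code, position), sorted.
static std::vector<KPos> collect_kmers(const std::string& s, int k) {
  std::vector<KPos> out;
  const int64_t n = (int64_t)s.size();
  out.reserve(n > k ? (size_t)(n - k + 1) : 0);
  uint64_t kmer = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0; // length of current valid-base run
  for (int64_t i = 0; i < n; ++i) {
    int b = base2(s[i]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) out.push_back(KPos(kmer, (int)(i - k + 1)));
  }
  std::sort(out.begin(), out.end());
  return out;
}

struct Hit { int a_start, b_start, len, matches, strand; };

// Maximal-sum subsegment of the match indicator with score
// match: (1 - t), mismatch: -t  (t = min identity); sum >= 0 over a
// segment iff its identity >= t. Ties broken leftmost-longest.
static bool kadane_trim(const std::string& A, const std::string& B,
                        int64_t a0, int64_t b0, int len, double t,
                        int& out_l, int& out_r, int& out_matches) {
  double best = -1.0, cur = 0.0;
  int cur_l = 0, best_l = 0, best_r = -1;
  for (int i = 0; i < len; ++i) {
    char ca = A[a0 + i], cb = B[b0 + i];
    bool valid = base2(ca) >= 0 && base2(cb) >= 0;
    double sc = (valid && ca == cb) ? (1.0 - t) : -t;
    if (cur < 0.0) { cur = 0.0; cur_l = i; }
    cur += sc;
    if (cur > best + 1e-12 ||
        (cur > best - 1e-12 && best_r - best_l < i + 1 - cur_l)) {
      best = cur; best_l = cur_l; best_r = i + 1;
    }
  }
  if (best < -1e-9 || best_r <= best_l) return false;
  int m = 0;
  for (int i = best_l; i < best_r; ++i) {
    if (A[a0 + i] == B[b0 + i] && base2(A[a0 + i]) >= 0) ++m;
  }
  out_l = best_l; out_r = best_r; out_matches = m;
  return true;
}

// X-drop gap-free extension of [l, r) along a diagonal of (A, B); match +1,
// mismatch -mis_pen, hard stop at non-ACGT. Returns extended bounds.
static void xdrop_extend(const std::string& A, const std::string& B,
                         int64_t a_off, int64_t b_off, int64_t& l, int64_t& r,
                         double xdrop, double mis_pen) {
  const int64_t nA = (int64_t)A.size(), nB = (int64_t)B.size();
  // left
  {
    double sc = 0, best = 0; int64_t i = l - 1, best_i = l;
    while (i >= 0 && b_off + i - a_off >= 0) {
      char ca = A[i], cb = B[b_off + i - a_off];
      if (base2(ca) < 0 || base2(cb) < 0) break;
      sc += (ca == cb) ? 1.0 : -mis_pen;
      if (sc > best) { best = sc; best_i = i; }
      if (best - sc > xdrop) break;
      --i;
    }
    l = best_i;
  }
  // right
  {
    double sc = 0, best = 0; int64_t i = r, best_i = r;
    while (i < nA && b_off + i - a_off < nB) {
      char ca = A[i], cb = B[b_off + i - a_off];
      if (base2(ca) < 0 || base2(cb) < 0) break;
      sc += (ca == cb) ? 1.0 : -mis_pen;
      if (sc > best) { best = sc; best_i = i + 1; }
      if (best - sc > xdrop) break;
      ++i;
    }
    r = best_i;
  }
}

// Sweep seed pairs (packed diag<<32|pos, sorted), merge same-diagonal seeds
// within max_gap, extend, trim, emit.
static void sweep_pairs(std::vector<uint64_t>& pairs, int k, int max_gap,
                        const std::string& A, const std::string& B,
                        int64_t diag_bias, int min_len, double min_identity,
                        double xdrop, double mis_pen, int strand,
                        std::vector<Hit>& hits) {
  std::sort(pairs.begin(), pairs.end());
  size_t i = 0;
  const size_t n = pairs.size();
  while (i < n) {
    const uint64_t diag_key = pairs[i] >> 32;
    const int64_t diag = (int64_t)diag_key - diag_bias;
    size_t j = i;
    int64_t prev_emitted_end = -1;
    while (j < n && (pairs[j] >> 32) == diag_key) {
      // merge run of seeds with gaps <= max_gap
      int64_t run_s = (int64_t)(uint32_t)pairs[j];
      int64_t run_e = run_s + k;
      size_t j2 = j + 1;
      while (j2 < n && (pairs[j2] >> 32) == diag_key) {
        int64_t p = (int64_t)(uint32_t)pairs[j2];
        if (p <= run_e + max_gap) {
          if (p + k > run_e) run_e = p + k;
          ++j2;
        } else break;
      }
      j = j2;
      if (run_s < prev_emitted_end) continue; // covered by previous emission
      int64_t l = run_s, r = run_e;
      xdrop_extend(A, B, 0, diag, l, r, xdrop, mis_pen);
      int tl, tr, m;
      if (kadane_trim(A, B, l, l + diag, (int)(r - l), min_identity, tl, tr, m)) {
        if (tr - tl >= min_len) {
          Hit h;
          h.a_start = (int)(l + tl);
          h.b_start = (int)(l + tl + diag);
          h.len = tr - tl;
          h.matches = m;
          h.strand = strand;
          hits.push_back(h);
          prev_emitted_end = l + tr;
        }
      }
    }
    i = j;
  }
}

// [[Rcpp::export]]
DataFrame cpp_self_align(std::string s, int k, int min_len,
                         double min_identity, double xdrop, double mis_pen,
                         int max_gap, int max_occ) {
  const int64_t N = (int64_t)s.size();
  if (N < k) stop("genome shorter than the seed length k");
  std::string t(s.rbegin(), s.rend());
  for (size_t i = 0; i < t.size(); ++i) t[i] = comp(t[i]);

  std::vector<KPos> ks = collect_kmers(s, k);
  std::vector<KPos> kt = collect_kmers(t, k);

  std::vector<Hit> hits;

  // forward: pairs within ks groups, diag = p2 - p1 > 0
  {
    std::vector<uint64_t> pairs;
    size_t i = 0;
    while (i < ks.size()) {
      size_t j = i;
      while (j < ks.size() && ks[j].first == ks[i].first) ++j;
      const size_t g = j - i;
      if ((int)g >= 2 && (int)g <= max_occ) {
        for (size_t a = i; a < j; ++a)
          for (size_t b = a + 1; b < j; ++b) {
            uint64_t diag = (uint64_t)(ks[b].second - ks[a].second);
            pairs.push_back((diag << 32) | (uint32_t)ks[a].second);
          }
      }
      i = j;
    }
    sweep_pairs(pairs, k, max_gap, s, s, 0, min_len, min_identity,
                xdrop, mis_pen, 0, hits);
  }

  // reverse: pairs across ks x kt groups, diag = pT - pS (biased by N)
  {
    std::vector<uint64_t> pairs;
    size_t i = 0, j = 0;
    while (i < ks.size() && j < kt.size()) {
      if (ks[i].first < kt[j].first) { ++i; continue; }
      if (kt[j].first < ks[i].first) { ++j; continue; }
      size_t i2 = i, j2 = j;
      while (i2 < ks.size() && ks[i2].first == ks[i].first) ++i2;
      while (j2 < kt.size() && kt[j2].first == ks[i].first) ++j2;
      if ((int)(i2 - i) <= max_occ && (int)(j2 - j) <= max_occ) {
        for (size_t a = i; a < i2; ++a)
          for (size_t b = j; b < j2; ++b) {
            int64_t diag = (int64_t)kt[b].second - (int64_t)ks[a].second;
            pairs.push_back(((uint64_t)(diag + N) << 32) |
                            (uint32_t)ks[a].second);
          }
      }
      i = i2; j = j2;
    }
    // A = s, B = t, b_pos = a_pos + diag
    std::vector<Hit> rhits;
    sweep_pairs(pairs, k, max_gap, s, t, N, min_len, min_identity,
                xdrop, mis_pen, 1, rhits);
    // convert B coordinates from revcomp space back to forward space
    for (size_t h = 0; h < rhits.size(); ++h) {
      int64_t bl = rhits[h].b_start;          // start in t
      int64_t br = bl + rhits[h].len;         // end in t
      rhits[h].b_start = (int)(N - br);       // forward-space start
      hits.push_back(rhits[h]);
    }
  }

  const size_t nh = hits.size();
  IntegerVector a_start(nh), b_start(nh), len(nh), matches(nh), strand(nh);
  for (size_t h = 0; h < nh; ++h) {
    a_start[h] = hits[h].a_start;
    b_start[h] = hits[h].b_start;
    len[h] = hits[h].len;
    matches[h] = hits[h].matches;
    strand[h] = hits[h].strand;
  }
  return DataFrame::create(
    _["a_start"] = a_start, _["b_start"] = b_start, _["length"] = len,
    _["matches"] = matches, _["strand"] = strand);
}

// ---------------------------------------------------------------------------
// Brute-force oracle: scan every diagonal (forward and reverse-complement),
// recursively extracting maximal-identity segments. No seeding, no
// extension heuristics; used only to cross-check cpp_self_align in tests.

static void scan_segment(const std::string& A, const std::string& B,
                         int64_t a0, int64_t b0, int64_t lo, int64_t hi,
                         int min_len, double t, int strand,
                         std::vector<Hit>& hits) {
  if (hi - lo < min_len) return;
  int tl, tr, m;
  if (!kadane_trim(A, B, a0 + lo, b0 + lo, (int)(hi - lo), t, tl, tr, m))
    return;
  if (tr - tl >= min_len) {
    Hit h;
    h.a_start = (int)(a0 + lo + tl);
    h.b_start = (int)(b0 + lo + tl);
    h.len = tr - tl; h.matches = m; h.strand = strand;
    hits.push_back(h);
  }
  scan_segment(A, B, a0, b0, lo, lo + tl, min_len, t, strand, hits);
  scan_segment(A, B, a0, b0, lo + tr, hi, min_len, t, strand, hits);
}

// [[Rcpp::export]]
DataFrame cpp_diagonal_scan(std::string s, int min_len, double min_identity) {
  const int64_t N = (int64_t)s.size();
  std::string t(s.rbegin(), s.rend());
  for (size_t i = 0; i < t.size(); ++i) t[i] = comp(t[i]);
  std::vector<Hit> hits;

  for (int64_t d = 1; d < N; ++d) { // forward, diag > 0
    const int64_t L = N - d;
    if (L < min_len) break;
    scan_segment(s, s, 0, d, 0, L, min_len, min_identity, 0, hits);
  }
  for (int64_t d = -(N - 1); d < N; ++d) { // vs revcomp
    int64_t lo = std::max<int64_t>(0, -d);
    int64_t hi = std::min<int64_t>(N, N - d);
    if (hi - lo < min_len) continue;
    std::vector<Hit> rh;
    scan_segment(s, t, 0, d, lo, hi, min_len, min_identity, 1, rh);
    for (size_t h = 0; h < rh.size(); ++h) {
      int64_t bl = rh[h].b_start;
      rh[h].b_start = (int)(N - (bl + rh[h].len));
      hits.push_back(rh[h]);
    }
  }

  const size_t nh = hits.size();
  IntegerVector a_start(nh), b_start(nh), len(nh), matches(nh), strand(nh);
  for (size_t h = 0; h < nh; ++h) {
    a_start[h] = hits[h].a_start; b_start[h] = hits[h].b_start;
    len[h] = hits[h].len; matches[h] = hits[h].matches;
    strand[h] = hits[h].strand;
  }
  return DataFrame::create(
    _["a_start"] = a_start, _["b_start"] = b_start, _["length"] = len,
    _["matches"] = matches, _["strand"] = strand);
}
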