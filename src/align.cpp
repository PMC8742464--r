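// Local alignment machinery: exact-word seed finding and affine-gap
// Smith-Waterman with traceback (Gotoh).  Scores: match +1, mismatch -2,
// gap of length k costs open + k * extend (open 5, extend 2 by default,
// i.e. -7 for a length-1 gap), matching the BLAST convention.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Exact shared words between two integer-coded sequences (0..3; negative
// codes never seed).  Returns a two-column matrix of 0-based (q, s)
// seed start positions.  self_lower: only report pairs with s > q
// (self-comparison; excludes the trivial diagonal and mirror pairs).
// Words occurring more than max_occ times in the subject are skipped as
// low-complexity.
// [[Rcpp::export(name = ".seed_hits")]]
IntegerMatrix seed_hits(IntegerVector q, IntegerVector s, int word_size,
                        bool self_lower, int max_occ) {
  const int nq = q.size(), ns = s.size();
  std::vector<std::pair<int, int>> hits;
  if (word_size < 4) stop("word_size must be >= 4");
  if (nq >= word_size && ns >= word_size) {
    std::unordered_map<uint64_t, std::vector<int>> index;
    uint64_t key = 0, mask = (word_size >= 32) ? ~0ULL
                     : ((1ULL << (2 * word_size)) - 1);
    int run = 0;
    for (int i = 0; i < ns; ++i) {
      if (s[i] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)s[i]) & mask;
      if (++run >= word_size) index[key].push_back(i - word_size + 1);
    }
    key = 0; run = 0;
    for (int i = 0; i < nq; ++i) {
      if (q[i] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)q[i]) & mask;
      if (++run >= word_size) {
        auto it = index.find(key);
        if (it == index.end()) continue;
        if ((int)it->second.size() > max_occ) continue;
        int qpos = i - word_size + 1;
        for (int spos : it->second) {
          if (self_lower && spos <= qpos) continue;
          hits.push_back({qpos, spos});
        }
      }
    }
  }
  IntegerMatrix out(hits.size(), 2);
  for (size_t i = 0; i < hits.size(); ++i) {
    out(i, 0) = hits[i].first;
    out(i, 1) = hits[i].second;
  }
  return out;
}

// Affine-gap local alignment (Gotoh) with traceback.  Returns the single
// optimal local alignment: score, 0-based half-open intervals on a and
// b, number of matched columns and total alignment length.
// When use_forbid is true, diagonal (substitution) steps are disallowed
// on cells with j - i == forbid_delta: used in forward self-comparison
// to keep the trivial identity diagonal out of alignments whose search
// windows overlap it.  use_forbid_anti blocks cells with
// i + j == forbid_anti: in reverse-complement self-comparison these are
// the cells pairing a base with its own complement (the mirror
// anti-diagonal of a palindromic self-alignment).
// [[Rcpp::export(name = ".sw_align")]]
List sw_align(IntegerVector a, IntegerVector b, double match,
              double mismatch, double gap_open, double gap_extend,
              bool use_forbid = false, int forbid_delta = 0,
              bool use_forbid_anti = false, int forbid_anti = 0) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  // rolling rows for scores, full byte traceback
  std::vector<double> M0(m + 1, 0), M1(m + 1, 0);
  std::vector<double> E0(m + 1, NEG), E1(m + 1, NEG);  // gap in b (up)
  std::vector<double> F1(m + 1, NEG);                  // gap in a (left)
  // traceback codes: tbM: 0 stop, 1 diag from M, 2 from E, 3 from F
  //                  tbE: 0 open (from M above), 1 extend
  //                  tbF: 0 open (from M left),  1 extend
  std::vector<uint8_t> tbM((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);

  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    M1[0] = 0; E1[0] = NEG; F1[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t at = (size_t)i * (m + 1) + j;
      // E: gap consuming a (vertical)
      double e_open = M0[j] - (gap_open + gap_extend);
      double e_ext  = E0[j] - gap_extend;
      double e = std::max(e_open, e_ext);
      tbE[at] = e_ext > e_open ? 1 : 0;
      E1[j] = e;
      // F: gap consuming b (horizontal)
      double f_open = M1[j - 1] - (gap_open + gap_extend);
      double f_ext  = F1[j - 1] - gap_extend;
      double f = std::max(f_open, f_ext);
      tbF[at] = f_ext > f_open ? 1 : 0;
      F1[j] = f;
      // M
      double sub = (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ? match : mismatch;
      if (use_forbid && (j - i) == forbid_delta) sub = NEG;
      if (use_forbid_anti && (i + j) == forbid_anti) sub = NEG;
      double diag = M0[j - 1] + sub;
      double v = diag; uint8_t code = 1;
      if (e > v) { v = e; code = 2; }
      if (f > v) { v = f; code = 3; }
      if (v <= 0) { v = 0; code = 0; }
      tbM[at] = code;
      M1[j] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(M0, M1); std::swap(E0, E1);
    std::fill(F1.begin(), F1.end(), NEG);
  }

  // traceback
  int i = bi, j = bj, matches = 0, alen = 0;
  int state = 0;  // 0 = M, 1 = E, 2 = F
  int ai_end = bi, bj_end = bj;
  while (i > 0 && j > 0) {
    size_t at = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t c = tbM[at];
      if (c == 0) break;
      if (c == 1) {
        if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) matches++;
        alen++; i--; j--;
      } else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      alen++;
      state = tbE[at] == 1 ? 1 : 0;
      i--;
    } else {
      alen++;
      state = tbF[at] == 1 ? 2 : 0;
      j--;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = ai_end,
                      _["b_start"] = j, _["b_end"] = bj_end,
                      _["matches"] = matches, _["align_len"] = alen);
}
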