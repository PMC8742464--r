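// Consensus-scoring tandem repeat scan (ETANDEM-style).
//
// For each candidate period p the sequence is swept; copies of the unit
// are stacked as rows of a p-column matrix and a column consensus is
// maintained incrementally.  The score of a run of k copies is
// (#matches to consensus) - (#mismatches) = 2 * sum(column max counts)
// - k*p.  Candidate runs with score >= threshold are collected and a
// greedy non-overlapping selection per period (score desc, then leftmost
// start, then fewer copies) gives the reported maximal runs.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>
using namespace Rcpp;

struct Cand {
  int start, period, copies, score;
};

// [[Rcpp::export(name = ".etandem_scan")]]
DataFrame etandem_scan(IntegerVector seq, int min_period, int max_period,
                       int threshold, bool mismatch_allowed,
                       bool prefilter) {
  const int L = seq.size();
  std::vector<Cand> out;

  std::vector<int> pre(L + 1);

  for (int p = min_period; p <= max_period; ++p) {
    if (2 * p > L) break;

    const bool use_pre = prefilter && L > 2000;
    if (use_pre) {
      // pre[i+1]-pre[a]: count of positions j in [a,i] with s[j]==s[j+p]
      pre[0] = 0;
      for (int i = 0; i + p < L; ++i) {
        int same = (seq[i] >= 0 && seq[i] == seq[i + p]) ? 1 : 0;
        pre[i + 1] = pre[i] + same;
      }
      for (int i = L - p; i < L; ++i) pre[i + 1] = pre[i];
    }

    std::vector<Cand> cands;
    std::vector<int> cnt(4 * p);
    const int xdrop = std::max({2 * p, 2 * threshold, 50});

    for (int a = 0; a + 2 * p <= L; ++a) {
      if (use_pre) {
        // require the first adjacent copy pair to agree at >= p/2 sites
        if (2 * (pre[a + p] - pre[a]) < p) continue;
      }
      std::fill(cnt.begin(), cnt.end(), 0);
      int sum_max = 0;           // sum over columns of max base count
      int best = INT_MIN;
      int k = 0;
      bool stop = false;
      while (!stop && a + (k + 1) * p <= L) {
        ++k;
        for (int c = 0; c < p; ++c) {
          int b = seq[a + (k - 1) * p + c];
          int *col = &cnt[4 * c];
          int oldmax = std::max(std::max(col[0], col[1]),
                                std::max(col[2], col[3]));
          if (b >= 0) col[b]++;
          int newmax = std::max(std::max(col[0], col[1]),
                                std::max(col[2], col[3]));
          sum_max += newmax - oldmax;
        }
        int score = 2 * sum_max - k * p;
        if (!mismatch_allowed && score < k * p) break;
        if (k >= 2 && score >= threshold) {
          cands.push_back({a, p, k, score});
        }
        if (score > best) best = score;
        if (score < best - xdrop) stop = true;
      }
    }

    // greedy non-overlapping selection within this period
    std::sort(cands.begin(), cands.end(), [](const Cand &x, const Cand &y) {
      if (x.score != y.score) return x.score > y.score;
      if (x.start != y.start) return x.start < y.start;
      return x.copies < y.copies;
    });
    std::vector<std::pair<int, int>> taken;
    for (const Cand &c : cands) {
      int s = c.start, e = c.start + c.copies * c.period;
      bool ok = true;
      for (auto &iv : taken) {
        if (s < iv.second && iv.first < e) { ok = false; break; }
      }
      if (ok) {
        taken.push_back({s, e});
        out.push_back(c);
      }
    }
  }

  // recompute consensus unit and mismatch count for reported runs
  const int n = out.size();
  IntegerVector start(n), period(n), copies(n), score(n), mism(n);
  CharacterVector unit(n);
  const char *bases = "ACGT";
  for (int i = 0; i < n; ++i) {
    const Cand &c = out[i];
    start[i] = c.start; period[i] = c.period;
    copies[i] = c.copies; score[i] = c.score;
    mism[i] = (c.copies * c.period - c.score) / 2;
    std::string u(c.period, 'N');
    for (int col = 0; col < c.period; ++col) {
      int cntb[4] = {0, 0, 0, 0};
      for (int k = 0; k < c.copies; ++k) {
        int b = seq[c.start + k * c.period + col];
        if (b >= 0) cntb[b]++;
      }
      int bi = 0;
      for (int b = 1; b < 4; ++b) if (cntb[b] > cntb[bi]) bi = b;
      if (cntb[bi] > 0) u[col] = bases[bi];
    }
    unit[i] = u;
  }
  return DataFrame::create(_["start"] = start, _["period"] = period,
                           _["copies"] = copies, _["score"] = score,
                           _["mismatches"] = mism, _["unit"] = unit,
                           _["stringsAsFactors"] = false);
}
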