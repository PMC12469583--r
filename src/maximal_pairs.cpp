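#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// Maximal pair discovery between two strings under a Hamming-mismatch
// budget, by seed-and-extend.  A pair (i, j, L) is maximal when
// Hamming(s1[i..i+L), s2[j..j+L)) <= max_mismatch and extending the window
// by one position on either side would exceed the budget or run off an end.
// Pigeonhole: any qualifying window of length >= min_len with <= m
// mismatches contains an exact run of >= (min_len - m)/(m + 1) positions,
// so exact k-mer seeds of that length find every window.  Windows are
// enumerated per seed from the mismatch positions collected on the seed's
// diagonal and deduplicated globally on (diagonal, window start).

static inline int code_of(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return 4;  // N / anything else: never matches
  }
}

// [[Rcpp::export]]
DataFrame maximal_pairs_cpp(std::string s1, std::string s2,
                            int min_len, int max_mismatch,
                            bool skip_diag0 = false) {
  const int n1 = (int) s1.size(), n2 = (int) s2.size();
  std::vector<int> a(n1), b(n2);
  for (int i = 0; i < n1; ++i) a[i] = code_of(s1[i]);
  for (int j = 0; j < n2; ++j) b[j] = code_of(s2[j]);

  std::vector<int> ri, rj, rl, rm;
  const int mm = max_mismatch;
  if (n1 >= min_len && n2 >= min_len && min_len >= 1) {
    // m mismatches cut a window of length L into m+1 exact runs totalling
    // L - m, so the longest run has >= ceil((L - m)/(m + 1)) positions
    int k = (min_len - mm + (mm + 1) - 1) / (mm + 1);
    if (k < 1) k = 1;
    if (k > 31) k = 31;

    // hash all exact k-mers of s1 (skipping any containing N)
    std::unordered_map<uint64_t, std::vector<int> > seeds;
    seeds.reserve((size_t) n1 * 2);
    {
      uint64_t h = 0;
      const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
      int run = 0;
      for (int i = 0; i < n1; ++i) {
        if (a[i] > 3) { run = 0; h = 0; continue; }
        h = ((h << 2) | (uint64_t) a[i]) & mask;
        if (++run >= k) seeds[h].push_back(i - k + 1);
      }
    }

    std::unordered_set<uint64_t> seen;           // (diag, window start)
    std::unordered_map<int64_t, int> run_hi;     // mm==0: end of last run per diag

    uint64_t h = 0;
    const uint64_t mask = (1ULL << (2 * k)) - 1ULL;
    int run = 0;
    std::vector<int> mpos;
    for (int j = 0; j < n2; ++j) {
      if (b[j] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) b[j]) & mask;
      if (++run < k) continue;
      const int j0 = j - k + 1;
      auto it = seeds.find(h);
      if (it == seeds.end()) continue;
      for (int i0 : it->second) {
        const int64_t d = (int64_t) j0 - (int64_t) i0;
        if (skip_diag0 && d == 0) continue;
        if (mm == 0) {
          auto rh = run_hi.find(d);
          if (rh != run_hi.end() && i0 + k - 1 <= rh->second) continue;
        }
        const int diag_start = (d >= 0) ? 0 : (int) (-d);
        const int diag_end = (int) std::min((int64_t) n1, (int64_t) n2 - d); // excl
        // collect mismatch offsets (s1 coordinates) around the seed:
        // up to mm+1 on each side; a virtual sentinel marks a diagonal end
        // reached first.  All interior elements of `mpos` are real
        // mismatches; a virtual sentinel can only sit at either extreme.
        mpos.clear();
        {
          int p = i0 - 1, q = j0 - 1, got = 0;
          std::vector<int> left;
          while (p >= 0 && q >= 0) {
            if (a[p] != b[q] || a[p] > 3) {
              left.push_back(p);
              if (++got > mm) break;
            }
            --p; --q;
          }
          if (got <= mm) left.push_back(diag_start - 1);  // virtual
          mpos.assign(left.rbegin(), left.rend());
        }
        {
          int p = i0 + k, q = j0 + k, got = 0;
          while (p < n1 && q < n2) {
            if (a[p] != b[q] || a[p] > 3) {
              mpos.push_back(p);
              if (++got > mm) break;
            }
            ++p; ++q;
          }
          if (got <= mm) mpos.push_back(diag_end);  // virtual
        }
        const int T = (int) mpos.size();
        // maximal windows: (mpos[t], mpos[t+mm+1]) open intervals; when the
        // whole diagonal carries fewer than mm mismatches (T-2 < mm, both
        // boundaries virtual) the single window is (mpos[0], mpos[T-1]).
        auto emit = [&](int t, int u) {
          if (mpos[t] >= i0 || mpos[u] <= i0 + k - 1) return;  // must contain seed
          const int ws = mpos[t] + 1, we = mpos[u] - 1;
          const int L = we - ws + 1;
          if (L < min_len) return;
          const uint64_t key = (((uint64_t) (d + n2)) << 32) | (uint64_t) ws;
          if (!seen.insert(key).second) return;
          ri.push_back(ws + 1);
          rj.push_back((int) (ws + d) + 1);
          rl.push_back(L);
          rm.push_back(u - t - 1);
        };
        if (T - 2 < mm) {
          if (T >= 2) emit(0, T - 1);
        } else {
          for (int t = 0; t + mm + 1 <= T - 1; ++t) emit(t, t + mm + 1);
        }
        if (mm == 0 && T >= 2) run_hi[d] = mpos[1] - 1;
      }
    }
  }
  return DataFrame::create(_["i"] = ri, _["j"] = rj,
                           _["len"] = rl, _["mism"] = rm);
}
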