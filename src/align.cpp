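#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Myers bit-parallel edit distance (block-based), used to pick subread
// orientation. Unit costs; full (unbanded) Levenshtein distance.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_edit_distance")]]
int cpp_edit_distance(const std::string& a, const std::string& b) {
  const std::string& pat = a;
  const std::string& txt = b;
  size_t m = pat.size(), n = txt.size();
  if (m == 0) return (int)n;
  if (n == 0) return (int)m;

  const int W = 64;
  size_t nblk = (m + W - 1) / W;
  std::vector<uint64_t> peq(256 * nblk, 0);
  for (size_t i = 0; i < m; ++i)
    peq[(unsigned char)pat[i] * nblk + i / W] |= 1ULL << (i % W);

  std::vector<uint64_t> Pv(nblk, ~0ULL), Mv(nblk, 0);
  int score = (int)m;
  const uint64_t last_bit = 1ULL << ((m - 1) % W);
  const uint64_t top_bit = 1ULL << (W - 1);

  for (size_t j = 0; j < n; ++j) {
    unsigned char c = (unsigned char)txt[j];
    int hin = 1; // D[0][j] = j: global alignment boundary
    for (size_t b = 0; b < nblk; ++b) {
      uint64_t eq = peq[c * nblk + b];
      uint64_t pv = Pv[b], mv = Mv[b];
      uint64_t xv = eq | mv;
      if (hin < 0) eq |= 1ULL;
      uint64_t xh = (((eq & pv) + pv) ^ pv) | eq;
      uint64_t ph = mv | ~(xh | pv);
      uint64_t mh = pv & xh;
      uint64_t chk = (b + 1 == nblk) ? last_bit : top_bit;
      int hout = 0;
      if (ph & chk) hout = 1;
      else if (mh & chk) hout = -1;
      ph <<= 1;
      mh <<= 1;
      if (hin < 0) mh |= 1ULL;
      else if (hin > 0) ph |= 1ULL;
      Pv[b] = mh | ~(xv | ph);
      Mv[b] = ph & xv;
      hin = hout;
    }
    score += hin;
  }
  return score;
}

// ---------------------------------------------------------------------------
// Banded global alignment + weighted column voting.
//
// Each read is globally aligned to the template inside a diagonal band; the
// traceback votes per template column (base or gap) and per inter-column gap
// (inserted strings). Consensus is then called column-by-column.
//
// tie_mode 0 ("ccs"):   gap wins only on strict majority of spanning weight
//                       (gap-majority columns drop); base ties prefer the
//                       template's own base, then A<C<G<T.
// tie_mode 1 ("polish"): plurality among {A,C,G,T,gap}; ties prefer the
//                       template's own base, then A<C<G<T, gap last.
// Insertions (both modes): emitted only on strict majority of reads carrying
// a non-empty insertion at that junction; inserted string = highest weight,
// ties to the lexicographically smallest.
// ---------------------------------------------------------------------------

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return 0; // non-ACGT collapses to A; inputs are validated upstream
}

// [[Rcpp::export(name = ".cpp_column_consensus")]]
List cpp_column_consensus(const std::string& templ,
                          const std::vector<std::string>& reads,
                          const std::vector<double>& weights,
                          int band,
                          int tie_mode) {
  const int L = (int)templ.size();
  const int n_reads = (int)reads.size();
  if (L == 0) stop("empty template");
  if ((int)weights.size() != n_reads) stop("weights length mismatch");

  std::vector<double> votes(5 * (size_t)L, 0.0); // A,C,G,T,gap per column
  std::vector<std::map<std::string, double> > ins_votes(L + 1);
  std::vector<double> ins_w(L + 1, 0.0);
  double total_w = 0.0;

  const int NEG = INT_MIN / 4;
  std::vector<int> lo(L + 1), hi(L + 1);
  std::vector<int> Dm;   // (L+1) x width DP values
  std::vector<signed char> Tb; // traceback: 1 diag, 2 up, 3 left

  for (int r = 0; r < n_reads; ++r) {
    const std::string& rd = reads[r];
    const int M = (int)rd.size();
    const double w = weights[r];
    total_w += w;
    if (M == 0) continue;

    int b_eff = band;
    int dlen = (L > M) ? (L - M) : (M - L);
    if (b_eff < dlen + 8) b_eff = dlen + 8;
    const int smax = (M + L - 1) / L + 1; // max per-row shift of the band center
    const int width = 2 * b_eff + smax + 3; // + sentinel columns at both rims

    std::vector<int> off(L + 1);
    for (int i = 0; i <= L; ++i) {
      int c = (int)((double)i * M / L + 0.5);
      lo[i] = std::max(0, c - b_eff);
      hi[i] = std::min(M, c + b_eff);
      off[i] = c - b_eff;
    }
    Dm.assign((size_t)(L + 1) * width, NEG);
    Tb.assign((size_t)(L + 1) * width, 0);
    // cell (i, j) lives at row i, array column j - off[i] + 1 (column 0 is a
    // NEG sentinel, so out-of-band neighbours are read as NEG, never chosen)

    { // row 0: leading insertions
      int* cur = &Dm[1];
      signed char* tb = &Tb[1];
      for (int j = lo[0]; j <= hi[0]; ++j) {
        cur[j - off[0]] = -j;
        tb[j - off[0]] = (j == 0) ? 0 : 3;
      }
    }
    for (int i = 1; i <= L; ++i) {
      const int s = off[i] - off[i - 1];
      int* cur = &Dm[(size_t)i * width + 1];
      const int* prv = &Dm[(size_t)(i - 1) * width + 1];
      signed char* tb = &Tb[(size_t)i * width + 1];
      const char ta = templ[i - 1];
      const int k0 = lo[i] - off[i], k1 = hi[i] - off[i];
      for (int k = k0; k <= k1; ++k) {
        const int j = off[i] + k;
        int best, dir;
        if (j > 0) {
          best = prv[k + s - 1] - (ta == rd[j - 1] ? 0 : 1); // diag
          dir = 1;
          const int up = prv[k + s] - 1;
          if (up > best) { best = up; dir = 2; }
          const int left = cur[k - 1] - 1;
          if (left > best) { best = left; dir = 3; }
        } else {
          best = prv[k + s] - 1; // j == 0: only a template-consuming step
          dir = 2;
        }
        cur[k] = best;
        tb[k] = (signed char)dir;
      }
    }

    // traceback from (L, M), voting as we go
    auto T = [&](int i, int j) -> signed char& {
      return Tb[(size_t)i * width + (j - off[i]) + 1];
    };
    int i = L, j = M;
    std::string insbuf;
    auto flush_ins = [&](int gap_pos) {
      if (!insbuf.empty()) {
        std::reverse(insbuf.begin(), insbuf.end());
        ins_votes[gap_pos][insbuf] += w;
        ins_w[gap_pos] += w;
        insbuf.clear();
      }
    };
    while (i > 0 || j > 0) {
      signed char dir = T(i, j);
      if (dir == 3) {
        insbuf.push_back(rd[j - 1]);
        --j;
      } else if (dir == 2) {
        flush_ins(i);
        votes[4 * (size_t)L + (i - 1)] += w;
        --i;
      } else { // diag (dir==1); dir==0 only at origin
        flush_ins(i);
        votes[(size_t)base_idx(rd[j - 1]) * L + (i - 1)] += w;
        --i; --j;
      }
    }
    flush_ins(0);
  }

  // ---- call the consensus ----
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string cons;
  cons.reserve(L + 16);
  double acc_sum = 0.0;
  long n_cols = 0;
  long edits = 0;

  auto emit_ins = [&](int g) {
    if (2.0 * ins_w[g] > total_w) {
      const std::map<std::string, double>& mv = ins_votes[g];
      std::string best_s;
      double best_w = -1.0;
      for (std::map<std::string, double>::const_iterator it = mv.begin();
           it != mv.end(); ++it) {
        if (it->second > best_w) { best_w = it->second; best_s = it->first; }
        // map iterates in lexicographic order, so the first maximum seen is
        // the lexicographically smallest among ties
      }
      cons += best_s;
      for (size_t k = 0; k < best_s.size(); ++k) {
        acc_sum += best_w / total_w;
        ++n_cols;
      }
      ++edits;
    }
  };

  for (int i = 0; i <= L; ++i) {
    emit_ins(i);
    if (i == L) break;
    double wb[5];
    for (int k = 0; k < 5; ++k) wb[k] = votes[(size_t)k * L + i];
    char tb = templ[i];
    int ti = base_idx(tb);
    bool drop = false;
    char win = 'A';
    double win_w = 0.0;
    { // plurality among {A,C,G,T,gap}; ties prefer the template's own base,
      // then A<C<G<T, with gap last (tie_mode is kept for interface
      // stability; both consensus stages use the same deterministic rule)
      (void)tie_mode;
      int order[5];
      order[0] = ti;
      int p = 1;
      for (int k = 0; k < 4; ++k) if (k != ti) order[p++] = k;
      order[4] = 4;
      int bi = order[0];
      for (int q = 1; q < 5; ++q) if (wb[order[q]] > wb[bi]) bi = order[q];
      if (bi == 4) { drop = true; win_w = wb[4]; }
      else { win = BASES[bi]; win_w = wb[bi]; }
    }
    if (drop) {
      ++edits;
    } else {
      cons.push_back(win);
      acc_sum += (total_w > 0 ? win_w / total_w : 1.0);
      ++n_cols;
      if (win != tb) ++edits;
    }
  }

  double accuracy = (n_cols > 0) ? acc_sum / n_cols : 0.0;
  return List::create(_["consensus"] = cons,
                      _["accuracy"] = accuracy,
                      _["edits"] = (double)edits,
                      _["n_columns"] = (double)n_cols);
}

// ---------------------------------------------------------------------------
// Overlap alignment for the tiling assembler.
//
// mode 0 (dovetail): a suffix of `a` aligns to a prefix of `b`
//   (free leading gap in a, free trailing gap in b).
// mode 1 (containment): all of `b` aligns inside `a`
//   (free leading and trailing gaps in a).
// Scoring: match +1, mismatch -2, gap -3. Returns the best-scoring placement
// with its match/column counts so the caller can apply identity thresholds.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_overlap_align")]]
List cpp_overlap_align(const std::string& a, const std::string& b, int mode) {
  const int n = (int)a.size(), m = (int)b.size();
  const int MATCH = 1, MISM = -2, GAP = -3;
  const int NEG = INT_MIN / 4;
  std::vector<int> S((size_t)(n + 1) * (m + 1), NEG);
  std::vector<signed char> T((size_t)(n + 1) * (m + 1), 0);
  auto idx = [&](int i, int j) { return (size_t)i * (m + 1) + j; };

  for (int i = 0; i <= n; ++i) { S[idx(i, 0)] = 0; T[idx(i, 0)] = 0; }
  for (int j = 1; j <= m; ++j) { S[idx(0, j)] = GAP * j; T[idx(0, j)] = 3; }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sc = S[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? MATCH : MISM);
      signed char dir = 1;
      int up = S[idx(i - 1, j)] + GAP;
      if (up > sc) { sc = up; dir = 2; }
      int left = S[idx(i, j - 1)] + GAP;
      if (left > sc) { sc = left; dir = 3; }
      S[idx(i, j)] = sc;
      T[idx(i, j)] = dir;
    }
  }

  int bi = n, bj = m, best = NEG;
  if (mode == 0) { // end: a exhausted, any j in b (j>=1)
    for (int j = 1; j <= m; ++j)
      if (S[idx(n, j)] > best) { best = S[idx(n, j)]; bj = j; }
    bi = n;
  } else {         // end: b exhausted, any i in a
    for (int i = 0; i <= n; ++i)
      if (S[idx(i, m)] > best) { best = S[idx(i, m)]; bi = i; }
    bj = m;
  }

  // traceback until we leave the aligned region (hit column 0)
  int i = bi, j = bj;
  long matches = 0, cols = 0;
  while (j > 0) {
    signed char dir = T[idx(i, j)];
    if (dir == 1) {
      ++cols;
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (dir == 2) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i,   // 0-based start of the overlap in a
                      _["a_end"] = bi,
                      _["b_end"] = bj,
                      _["matches"] = (double)matches,
                      _["columns"] = (double)cols);
}
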