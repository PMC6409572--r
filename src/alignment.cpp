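// Smith-Waterman local alignment with affine gaps and exact-k-mer seed
// window detection. Sequences arrive as 0-based integer codes into the
// substitution matrix alphabet. Gap of length L costs open + L * ext
// (BLAST convention), matching Biostrings::pairwiseAlignment.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

const int NEG = INT32_MIN / 4;

struct Hsp {
  int score;
  int qstart, qend;   // 0-based half-open in query
  int tstart, tend;   // 0-based half-open in target
  int n_ident, n_pairs, aln_cols, n_gapopen;
};

// Full DP with traceback over query a (length m) x target slice b[lo, hi).
// Traceback ties broken preferring diagonal > up (gap in target) > left.
bool sw_one(const int* a, int m, const int* b, int lo, int hi,
            const int* S, int ns, int go, int ge, Hsp& out) {
  const int n = hi - lo;
  if (m == 0 || n <= 0) return false;
  std::vector<int> H(n + 1, 0);       // H[i-1][*] rolling into H[i][*]
  std::vector<int> E(n + 1, NEG);     // E[i][j]: gap in query (left moves)
  std::vector<int> Fv(n + 1, NEG);    // F[*][j]: gap in target (up moves)
  // direction byte: bits 0-1 H source (0 stop, 1 diag, 2 up, 3 left),
  // bit 2: E run extends left; bit 3: F run extends up
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;       // H[i-1][j-1]
    int Erow = NEG;      // E[i][j-1]
    const int* Srow = S + (size_t)a[i - 1] * ns;
    uint8_t* tbrow = tb.data() + (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      uint8_t flags = 0;
      // E: arrive from the left (H[i][j-1] already updated this row)
      int opnE = H[j - 1] - go - ge;
      int extE = Erow - ge;
      int Eij = opnE;
      if (extE > opnE) { Eij = extE; flags |= 4; }
      // F: arrive from above (H[j] holds H[i-1][j])
      int opnF = H[j] - go - ge;
      int extF = Fv[j] - ge;
      int Fij = opnF;
      if (extF > opnF) { Fij = extF; flags |= 8; }
      int diag = Hdiag + Srow[b[lo + j - 1]];
      int h = diag; uint8_t src = 1;          // diagonal wins all ties
      if (Fij > h) { h = Fij; src = 2; }      // then up
      if (Eij > h) { h = Eij; src = 3; }      // then left
      if (h <= 0) { h = 0; src = 0; }         // local alignment restarts
      Hdiag = H[j];
      H[j] = h; Erow = Eij; Fv[j] = Fij;
      tbrow[j] = (uint8_t)(src | flags);
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  int i = bi, j = bj, st = 0;
  int n_id = 0, n_pairs = 0, cols = 0, gapopen = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    if (st == 0) {
      int src = t & 3;
      if (src == 0) break;
      if (src == 1) {
        ++cols; ++n_pairs;
        if (a[i - 1] == b[lo + j - 1]) ++n_id;
        --i; --j;
      } else if (src == 2) { st = 2; ++gapopen; } else { st = 3; ++gapopen; }
    } else if (st == 2) {        // gap in target: consume query residue
      ++cols; st = (t & 8) ? 2 : 0; --i;
    } else {                     // gap in query: consume target residue
      ++cols; st = (t & 4) ? 3 : 0; --j;
    }
  }
  out.score = best;
  out.qstart = i; out.qend = bi;
  out.tstart = lo + j; out.tend = lo + bj;
  out.n_ident = n_id; out.n_pairs = n_pairs;
  out.aln_cols = cols; out.n_gapopen = gapopen;
  return true;
}

void collect_hsps(const int* a, int m, const int* b, int lo, int hi,
                  const int* S, int ns, int go, int ge,
                  int min_score, int max_hsps, std::vector<Hsp>& acc) {
  if ((int)acc.size() >= max_hsps || hi - lo < 4) return;
  Hsp h;
  if (!sw_one(a, m, b, lo, hi, S, ns, go, ge, h)) return;
  if (h.score < min_score) return;
  acc.push_back(h);
  collect_hsps(a, m, b, lo, h.tstart, S, ns, go, ge, min_score, max_hsps, acc);
  collect_hsps(a, m, b, h.tend, hi, S, ns, go, ge, min_score, max_hsps, acc);
}

}  // namespace

// [[Rcpp::export]]
List cpp_sw_align(IntegerVector a, IntegerVector b, IntegerMatrix S,
                  int gap_open, int gap_extend) {
  int ns = S.nrow();
  std::vector<int> Sv((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) Sv[(size_t)i * ns + j] = S(i, j);
  Hsp h;
  bool ok = sw_one(a.begin(), a.size(), b.begin(), 0, b.size(),
                   Sv.data(), ns, gap_open, gap_extend, h);
  if (!ok) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["tstart"] = NA_INTEGER,
                        _["tend"] = NA_INTEGER, _["identities"] = 0,
                        _["pairs"] = 0, _["columns"] = 0, _["gapopen"] = 0);
  }
  return List::create(_["score"] = h.score, _["qstart"] = h.qstart,
                      _["qend"] = h.qend, _["tstart"] = h.tstart,
                      _["tend"] = h.tend, _["identities"] = h.n_ident,
                      _["pairs"] = h.n_pairs, _["columns"] = h.aln_cols,
                      _["gapopen"] = h.n_gapopen);
}

// Extract up to max_hsps_per_window non-target-overlapping local alignments
// with score >= min_score inside each target window (0-based half-open rows
// of `windows`), by best-first recursive splitting.
// [[Rcpp::export]]
IntegerMatrix cpp_sw_hsps(IntegerVector a, IntegerVector b, IntegerMatrix S,
                          int gap_open, int gap_extend, int min_score,
                          IntegerMatrix windows, int max_hsps_per_window) {
  int ns = S.nrow();
  std::vector<int> Sv((size_t)ns * ns);
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j) Sv[(size_t)i * ns + j] = S(i, j);
  std::vector<Hsp> acc;
  for (int w = 0; w < windows.nrow(); ++w) {
    std::vector<Hsp> local;
    collect_hsps(a.begin(), a.size(), b.begin(), windows(w, 0), windows(w, 1),
                 Sv.data(), ns, gap_open, gap_extend, min_score,
                 max_hsps_per_window, local);
    for (auto& h : local) acc.push_back(h);
  }
  IntegerMatrix out((int)acc.size(), 9);
  for (size_t i = 0; i < acc.size(); ++i) {
    out(i, 0) = acc[i].score;
    out(i, 1) = acc[i].qstart; out(i, 2) = acc[i].qend;
    out(i, 3) = acc[i].tstart; out(i, 4) = acc[i].tend;
    out(i, 5) = acc[i].n_ident; out(i, 6) = acc[i].n_pairs;
    out(i, 7) = acc[i].aln_cols; out(i, 8) = acc[i].n_gapopen;
  }
  colnames(out) = CharacterVector::create("score", "qstart", "qend", "tstart",
                                          "tend", "identities", "pairs",
                                          "columns", "gapopen");
  return out;
}

// Exact k-mer two-hit seed windows: merged candidate target windows
// (0-based half-open) where two distinct seeds share a diagonal band within
// max_seed_dist target positions.
// [[Rcpp::export]]
IntegerMatrix cpp_seed_windows(IntegerVector q, IntegerVector t, int k,
                               int nletters, int diag_band, int max_seed_dist,
                               int pad) {
  int m = q.size(), n = t.size();
  if (m < k || n < k) return IntegerMatrix(0, 2);
  long tablesize = 1;
  for (int i = 0; i < k; ++i) tablesize *= nletters;
  std::vector<int> count((size_t)tablesize + 1, 0);
  std::vector<int> codes(m - k + 1);
  for (int i = 0; i + k <= m; ++i) {
    long c = 0;
    for (int j = 0; j < k; ++j) c = c * nletters + q[i + j];
    codes[i] = (int)c;
    ++count[c + 1];
  }
  for (long c = 0; c < tablesize; ++c) count[c + 1] += count[c];
  std::vector<int> pos(m - k + 1);
  {
    std::vector<int> cur(count.begin(), count.end() - 1);
    for (int i = 0; i + k <= m; ++i) pos[(size_t)cur[codes[i]]++] = i;
  }
  std::vector<std::pair<int, int>> seeds;  // (diagonal, target pos)
  long c = 0;
  long topmod = tablesize / nletters;
  for (int i = 0; i < n; ++i) {
    c = (c % topmod) * nletters + t[i];
    if (i >= k - 1) {
      int tp = i - k + 1;
      for (int s = count[c]; s < count[c + 1]; ++s)
        seeds.emplace_back(tp - pos[s], tp);
    }
  }
  if (seeds.empty()) return IntegerMatrix(0, 2);
  std::sort(seeds.begin(), seeds.end());
  std::vector<std::pair<int, int>> spans;
  for (size_t i = 1; i < seeds.size(); ++i) {
    if (seeds[i].first - seeds[i - 1].first <= diag_band &&
        std::abs(seeds[i].second - seeds[i - 1].second) <= max_seed_dist &&
        seeds[i].second != seeds[i - 1].second) {
      int lo = std::min(seeds[i - 1].second, seeds[i].second) - pad;
      int hi = std::max(seeds[i - 1].second, seeds[i].second) + k + pad;
      spans.emplace_back(std::max(0, lo), std::min(n, hi));
    }
  }
  if (spans.empty()) return IntegerMatrix(0, 2);
  std::sort(spans.begin(), spans.end());
  std::vector<std::pair<int, int>> merged;
  merged.push_back(spans[0]);
  for (size_t i = 1; i < spans.size(); ++i) {
    if (spans[i].first <= merged.back().second) {
      merged.back().second = std::max(merged.back().second, spans[i].second);
    } else {
      merged.push_back(spans[i]);
    }
  }
  IntegerMatrix out((int)merged.size(), 2);
  for (size_t i = 0; i < merged.size(); ++i) {
    out(i, 0) = merged[i].first;
    out(i, 1) = merged[i].second;
  }
  return out;
}
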