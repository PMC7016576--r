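// Affine-gap Smith-Waterman (local) and fitting (query-global / target-local)
// alignment engines. Integer scores; a gap of length L costs
// gap_open + L * gap_extend (both penalties are <= 0). 'N' never matches,
// not even another 'N'. Deterministic tie-breaks: among co-optimal local
// alignments the one with the smallest target start, then query start,
// then target end, then query end is returned.

#include <Rcpp.h>
#include <vector>
#include <climits>
#include <cstdint>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

static inline int score_pair(char a, char b, int match, int mismatch) {
  if (a == b && a != 'N') return match;
  return mismatch;
}

// trace codes for the H (main) state
enum { TR_STOP = 0, TR_DIAG = 1, TR_E = 2, TR_F = 3 };

struct TraceResult {
  int qs, qe, ts, te;   // 0-based half-open spans
  int matches, ncols;
};

// Walk the trace matrices back from (i, j) in state H.
// stop_at_top: fitting alignment stops at row 0; local stops at TR_STOP.
static TraceResult traceback(const std::vector<uint8_t>& trH,
                             const std::vector<uint8_t>& trE,
                             const std::vector<uint8_t>& trF,
                             const char* q, const char* t,
                             int m1, int i, int j, bool stop_at_top) {
  TraceResult r;
  r.qe = i; r.te = j; r.matches = 0; r.ncols = 0;
  int state = 0; // 0 = H, 1 = E, 2 = F
  while (true) {
    if (state == 0) {
      if (stop_at_top ? (i == 0) : (trH[(size_t)i * m1 + j] == TR_STOP)) break;
      uint8_t tr = trH[(size_t)i * m1 + j];
      if (!stop_at_top && tr == TR_STOP) break;
      if (stop_at_top && i == 0) break;
      if (tr == TR_DIAG) {
        r.ncols++;
        if (q[i - 1] == t[j - 1] && q[i - 1] != 'N') r.matches++;
        i--; j--;
      } else if (tr == TR_E) {
        state = 1;
      } else { // TR_F
        state = 2;
      }
    } else if (state == 1) { // E: gap in query, consumes target base j
      uint8_t tr = trE[(size_t)i * m1 + j];
      r.ncols++;
      j--;
      state = (tr == 0) ? 0 : 1;
    } else {                 // F: gap in target, consumes query base i
      uint8_t tr = trF[(size_t)i * m1 + j];
      r.ncols++;
      i--;
      state = (tr == 0) ? 0 : 2;
    }
  }
  r.qs = i; r.ts = j;
  return r;
}

// [[Rcpp::export]]
List cpp_local_align(std::string query, std::string target,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)query.size(), m = (int)target.size();
  const int m1 = m + 1;
  const char* q = query.c_str();
  const char* t = target.c_str();

  std::vector<uint8_t> trH((size_t)(n + 1) * m1, TR_STOP);
  std::vector<uint8_t> trE((size_t)(n + 1) * m1, 0);
  std::vector<uint8_t> trF((size_t)(n + 1) * m1, 0);

  std::vector<int> Hprev(m1, 0), Hcur(m1, 0);
  std::vector<int> Eprev(m1, NEG_INF), Ecur(m1, NEG_INF);
  std::vector<int> Fprev(m1, NEG_INF), Fcur(m1, NEG_INF);

  int best = 0;
  std::vector<std::pair<int,int> > ends; // co-optimal end cells (capped)
  const size_t END_CAP = 64;

  for (int i = 1; i <= n; i++) {
    Hcur[0] = 0; Ecur[0] = NEG_INF; Fcur[0] = NEG_INF;
    for (int j = 1; j <= m; j++) {
      // E: gap in query (consume target j)
      int e_open = Hcur[j - 1] + gap_open + gap_extend;
      int e_ext  = Ecur[j - 1] + gap_extend;
      int e = std::max(e_open, e_ext);
      trE[(size_t)i * m1 + j] = (e_open >= e_ext) ? 0 : 1;
      // F: gap in target (consume query i)
      int f_open = Hprev[j] + gap_open + gap_extend;
      int f_ext  = Fprev[j] + gap_extend;
      int f = std::max(f_open, f_ext);
      trF[(size_t)i * m1 + j] = (f_open >= f_ext) ? 0 : 1;
      // H
      int diag = Hprev[j - 1] + score_pair(q[i - 1], t[j - 1], match, mismatch);
      int h = 0; uint8_t tr = TR_STOP;
      if (diag > h) { h = diag; tr = TR_DIAG; }
      if (e > h)    { h = e;    tr = TR_E; }
      if (f > h)    { h = f;    tr = TR_F; }
      Hcur[j] = h; Ecur[j] = e; Fcur[j] = f;
      trH[(size_t)i * m1 + j] = tr;
      if (h > best) {
        best = h; ends.clear(); ends.push_back(std::make_pair(i, j));
      } else if (h == best && h > 0 && ends.size() < END_CAP) {
        ends.push_back(std::make_pair(i, j));
      }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best == 0 || ends.empty()) {
    return List::create(_["score"] = 0, _["matches"] = 0, _["n_columns"] = 0,
                        _["q_start"] = 0, _["q_end"] = 0,
                        _["t_start"] = 0, _["t_end"] = 0);
  }

  TraceResult bestTr; bool have = false;
  for (size_t k = 0; k < ends.size(); k++) {
    TraceResult r = traceback(trH, trE, trF, q, t, m1,
                              ends[k].first, ends[k].second, false);
    if (!have ||
        r.ts < bestTr.ts ||
        (r.ts == bestTr.ts && r.qs < bestTr.qs) ||
        (r.ts == bestTr.ts && r.qs == bestTr.qs && r.te < bestTr.te) ||
        (r.ts == bestTr.ts && r.qs == bestTr.qs && r.te == bestTr.te &&
         r.qe < bestTr.qe)) {
      bestTr = r; have = true;
    }
  }

  return List::create(_["score"] = best,
                      _["matches"] = bestTr.matches,
                      _["n_columns"] = bestTr.ncols,
                      _["q_start"] = bestTr.qs, _["q_end"] = bestTr.qe,
                      _["t_start"] = bestTr.ts, _["t_end"] = bestTr.te);
}

// Fitting alignment: the whole query is aligned to some substring of the
// target; leading/trailing target is free. Score may be negative.
// [[Rcpp::export]]
List cpp_fit_align(std::string query, std::string target,
                   int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)query.size(), m = (int)target.size();
  const int m1 = m + 1;
  const char* q = query.c_str();
  const char* t = target.c_str();

  std::vector<uint8_t> trH((size_t)(n + 1) * m1, TR_STOP);
  std::vector<uint8_t> trE((size_t)(n + 1) * m1, 0);
  std::vector<uint8_t> trF((size_t)(n + 1) * m1, 0);

  std::vector<int> Hprev(m1, 0), Hcur(m1, 0);
  std::vector<int> Eprev(m1, NEG_INF), Ecur(m1, NEG_INF);
  std::vector<int> Fprev(m1, NEG_INF), Fcur(m1, NEG_INF);

  for (int i = 1; i <= n; i++) {
    // column 0: query consumed against a target gap
    Hcur[0] = gap_open + i * gap_extend;
    Ecur[0] = NEG_INF;
    Fcur[0] = gap_open + i * gap_extend;
    trH[(size_t)i * m1 + 0] = TR_F;
    trF[(size_t)i * m1 + 0] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; j++) {
      int e_open = Hcur[j - 1] + gap_open + gap_extend;
      int e_ext  = Ecur[j - 1] + gap_extend;
      int e = std::max(e_open, e_ext);
      trE[(size_t)i * m1 + j] = (e_open >= e_ext) ? 0 : 1;
      int f_open = Hprev[j] + gap_open + gap_extend;
      int f_ext  = Fprev[j] + gap_extend;
      int f = std::max(f_open, f_ext);
      trF[(size_t)i * m1 + j] = (f_open >= f_ext) ? 0 : 1;
      int diag = Hprev[j - 1] + score_pair(q[i - 1], t[j - 1], match, mismatch);
      int h = diag; uint8_t tr = TR_DIAG;
      if (e > h) { h = e; tr = TR_E; }
      if (f > h) { h = f; tr = TR_F; }
      Hcur[j] = h; Ecur[j] = e; Fcur[j] = f;
      trH[(size_t)i * m1 + j] = tr;
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  // Hprev now holds row n. Best end: smallest j among maxima.
  int best = NEG_INF, bj = 0;
  for (int j = 0; j <= m; j++) {
    if (Hprev[j] > best) { best = Hprev[j]; bj = j; }
  }

  TraceResult r = traceback(trH, trE, trF, q, t, m1, n, bj, true);
  return List::create(_["score"] = best,
                      _["matches"] = r.matches,
                      _["n_columns"] = r.ncols,
                      _["q_start"] = r.qs, _["q_end"] = r.qe,
                      _["t_start"] = r.ts, _["t_end"] = r.te);
}
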