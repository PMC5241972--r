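// Tandem-repeat candidate generation by wraparound dynamic programming.
//
// Scoring (normative for the package): a candidate region [a, b) with unit
// u = S[a .. a+k) is scored by the best alignment of the region against the
// infinite periodic extension of u, anchored at phase 0, free end phase,
// match +1, mismatch -mm, indel -ind, minus k (so a perfect repeat of
// length L scores L - k). Extension from an anchor is abandoned when the
// running best falls more than (25 + 2k) below the best seen (bounded
// look-back), or when the residual window cannot reach the score threshold
// nor improve the current best; both rules are part of the operational
// definition and are applied identically by the seeded detector and the
// exhaustive reference scanner.
//
// Two independent candidate generators are provided:
//   tr_candidates_seeded():     period-k match-run seeds -> windows -> DP
//   tr_candidates_exhaustive(): every anchor of every sequence position
// The second exists as a brute-force reference for validating the first.

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const double NEG = -1e18;

struct Cand {
  int start, end, k;
  double score;
  int matches, cols;
};

// Anchor rule (normative, applied identically by both generators): a
// candidate anchor (a, k) must be followed by a period-k self-match run of
// length min(4, minScore) immediately after its unit, and enough sequence
// must remain for any region to reach the score threshold. A perfect repeat
// tract anchors at its first position, so detection of passing perfect
// repeats is unaffected; imperfect tracts with an error within the first
// few post-unit positions are reported from the next clean anchor instead.
static bool anchor_ok(const char* s, int a, int k, int L, double minScore) {
  int need = (int)minScore; // matches beyond the unit needed to pass
  if (a + k + need > L) return false;
  int m = need < 4 ? need : 4;
  for (int i = a + k; i < a + k + m; ++i)
    if (s[i] != s[i - k]) return false;
  return true;
}

static bool unit_is_primitive(const char* s, int a, int k) {
  for (int d = 1; d < k; ++d) {
    if (k % d != 0) continue;
    bool periodic = true;
    for (int j = d; j < k && periodic; ++j)
      if (s[a + j] != s[a + j - d]) periodic = false;
    if (periodic) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// Route A: rolling-array DP used by the seeded detector.
// ---------------------------------------------------------------------------
static bool dp_extend_rolling(const char* s, int a, int k, int wEnd,
                              double minScore, double mm, double ind,
                              Cand& out) {
  const char* u = s + a;
  int maxLen = wEnd - a;
  if (maxLen < k) return false;

  std::vector<double> D(k, NEG), Dn(k);
  std::vector<int> M(k, 0), C(k, 0), Mn(k), Cn(k);
  D[0] = 0.0;
  for (int pass = 0; pass < 2; ++pass)
    for (int j = 0; j < k; ++j) {
      int jn = (j + 1) % k;
      if (D[j] > NEG / 2 && D[j] - ind > D[jn]) {
        D[jn] = D[j] - ind; M[jn] = M[j]; C[jn] = C[j] + 1;
      }
    }

  double bestCand = NEG, maxRawEver = 0.0;
  int bestI = -1, bestM = 0, bestC = 0;
  double xdrop = 25.0 + 2.0 * k;

  for (int i = 1; i <= maxLen; ++i) {
    char c = s[a + i - 1];
    std::fill(Dn.begin(), Dn.end(), NEG);
    // diagonal (consume region char against unit char)
    for (int j = 0; j < k; ++j) {
      if (D[j] <= NEG / 2) continue;
      int jn = (j + 1) % k;
      bool match = (c == u[j]);
      double v = D[j] + (match ? 1.0 : -mm);
      if (v > Dn[jn]) {
        Dn[jn] = v; Mn[jn] = M[j] + (match ? 1 : 0); Cn[jn] = C[j] + 1;
      }
    }
    // region-skip (gap in pattern)
    for (int j = 0; j < k; ++j) {
      if (D[j] <= NEG / 2) continue;
      double v = D[j] - ind;
      if (v > Dn[j]) { Dn[j] = v; Mn[j] = M[j]; Cn[j] = C[j] + 1; }
    }
    // unit-skip (gap in region), wraparound: two passes
    for (int pass = 0; pass < 2; ++pass)
      for (int j = 0; j < k; ++j) {
        int jn = (j + 1) % k;
        if (Dn[j] > NEG / 2 && Dn[j] - ind > Dn[jn]) {
          Dn[jn] = Dn[j] - ind; Mn[jn] = Mn[j]; Cn[jn] = Cn[j] + 1;
        }
      }
    D.swap(Dn); M.swap(Mn); C.swap(Cn);

    double bestRow = NEG; int bj = 0;
    for (int j = 0; j < k; ++j)
      if (D[j] > bestRow) { bestRow = D[j]; bj = j; }
    if (bestRow > maxRawEver) maxRawEver = bestRow;
    if (i >= k && bestRow - k > bestCand) {
      bestCand = bestRow - k; bestI = i; bestM = M[bj]; bestC = C[bj];
    }
    double residual = (double)(maxLen - i);
    double need = std::max(minScore + k, bestCand + k + 1.0);
    if (bestRow + residual < need) break;
    if (bestRow < maxRawEver - xdrop) break;
  }
  if (bestI < 0 || bestCand < minScore) return false;
  out.start = a; out.end = a + bestI; out.k = k;
  out.score = bestCand; out.matches = bestM; out.cols = bestC;
  return true;
}

// ---------------------------------------------------------------------------
// Route B: independently written full-table DP for the reference scanner.
// ---------------------------------------------------------------------------
static bool dp_extend_table(const char* s, int a, int k, int wEnd,
                            double minScore, double mm, double ind,
                            Cand& out) {
  int maxLen = wEnd - a;
  if (maxLen < k) return false;

  // prev/cur rows of (score, matches, cols) triples
  std::vector<double> prevS(k), curS(k);
  std::vector<int> prevM(k), curM(k), prevC(k), curC(k);
  for (int j = 0; j < k; ++j) { prevS[j] = NEG; prevM[j] = prevC[j] = 0; }
  prevS[0] = 0.0;
  for (int rep = 0; rep < 2; ++rep)
    for (int j = 0; j < k; ++j) {
      int jn = j + 1 == k ? 0 : j + 1;
      if (prevS[j] > NEG / 2 && prevS[j] - ind > prevS[jn]) {
        prevS[jn] = prevS[j] - ind; prevM[jn] = prevM[j];
        prevC[jn] = prevC[j] + 1;
      }
    }

  double best = NEG, peak = 0.0;
  int bestLen = -1, bestM = 0, bestC = 0;
  const double drop = 25.0 + 2.0 * k;

  for (int i = 1; i <= maxLen; ++i) {
    char c = s[a + i - 1];
    for (int j = 0; j < k; ++j) curS[j] = NEG;
    for (int j = 0; j < k; ++j) {
      if (prevS[j] <= NEG / 2) continue;
      int jn = j + 1 == k ? 0 : j + 1;
      bool eq = (c == s[a + j]);
      double v = prevS[j] + (eq ? 1.0 : -mm);
      if (v > curS[jn]) {
        curS[jn] = v; curM[jn] = prevM[j] + (eq ? 1 : 0);
        curC[jn] = prevC[j] + 1;
      }
    }
    for (int j = 0; j < k; ++j) {
      if (prevS[j] <= NEG / 2) continue;
      if (prevS[j] - ind > curS[j]) {
        curS[j] = prevS[j] - ind; curM[j] = prevM[j]; curC[j] = prevC[j] + 1;
      }
    }
    for (int rep = 0; rep < 2; ++rep)
      for (int j = 0; j < k; ++j) {
        int jn = j + 1 == k ? 0 : j + 1;
        if (curS[j] > NEG / 2 && curS[j] - ind > curS[jn]) {
          curS[jn] = curS[j] - ind; curM[jn] = curM[j]; curC[jn] = curC[j] + 1;
        }
      }
    prevS.swap(curS); prevM.swap(curM); prevC.swap(curC);

    double rowBest = NEG; int at = 0;
    for (int j = 0; j < k; ++j)
      if (prevS[j] > rowBest) { rowBest = prevS[j]; at = j; }
    if (rowBest > peak) peak = rowBest;
    if (i >= k && rowBest - k > best) {
      best = rowBest - k; bestLen = i; bestM = prevM[at]; bestC = prevC[at];
    }
    double canReach = rowBest + (maxLen - i);
    if (canReach < std::max(minScore + k, best + k + 1.0)) break;
    if (rowBest < peak - drop) break;
  }
  if (bestLen < 0 || best < minScore) return false;
  out.start = a; out.end = a + bestLen; out.k = k;
  out.score = best; out.matches = bestM; out.cols = bestC;
  return true;
}

static DataFrame cands_to_df(const std::vector<Cand>& cs) {
  int n = cs.size();
  IntegerVector start(n), end(n), k(n), matches(n), cols(n);
  NumericVector score(n);
  for (int i = 0; i < n; ++i) {
    start[i] = cs[i].start; end[i] = cs[i].end; k[i] = cs[i].k;
    score[i] = cs[i].score; matches[i] = cs[i].matches; cols[i] = cs[i].cols;
  }
  return DataFrame::create(_["start"] = start, _["end"] = end,
                           _["unit_size"] = k, _["score"] = score,
                           _["matches"] = matches, _["cols"] = cols);
}

// [[Rcpp::export(name = ".tr_candidates_seeded")]]
DataFrame tr_candidates_seeded(std::string seq, int maxUnit, double minScore,
                               double mm, double ind) {
  const char* s = seq.c_str();
  int L = seq.size();
  std::vector<Cand> cands;
  Cand c;
  for (int k = 1; k <= maxUnit && k < L; ++k) {
    // seeds: runs of >=4 positions with s[i] == s[i-k]
    int pad = 2 * k + 32;
    std::vector<std::pair<int, int> > windows;
    int run = 0;
    for (int i = k; i <= L; ++i) {
      bool hit = (i < L) && (s[i] == s[i - k]);
      if (hit) {
        ++run;
      } else {
        if (run >= 4) {
          int i0 = i - run;  // first profile index of the run
          int w0 = std::max(0, i0 - k - pad);
          int w1 = std::min(L, i + pad);
          if (!windows.empty() && w0 <= windows.back().second)
            windows.back().second = std::max(windows.back().second, w1);
          else
            windows.push_back(std::make_pair(w0, w1));
        }
        run = 0;
      }
    }
    for (size_t w = 0; w < windows.size(); ++w) {
      int w0 = windows[w].first, w1 = windows[w].second;
      for (int a = w0; a + k <= w1; ++a) {
        if (!anchor_ok(s, a, k, L, minScore)) continue;
        if (!unit_is_primitive(s, a, k)) continue;
        if (dp_extend_rolling(s, a, k, w1, minScore, mm, ind, c))
          cands.push_back(c);
      }
    }
  }
  return cands_to_df(cands);
}

// [[Rcpp::export(name = ".tr_candidates_exhaustive")]]
DataFrame tr_candidates_exhaustive(std::string seq, int maxUnit,
                                   double minScore, double mm, double ind) {
  const char* s = seq.c_str();
  int L = seq.size();
  std::vector<Cand> cands;
  Cand c;
  for (int k = 1; k <= maxUnit && k < L; ++k)
    for (int a = 0; a + k <= L; ++a) {
      if (!anchor_ok(s, a, k, L, minScore)) continue;
      if (!unit_is_primitive(s, a, k)) continue;
      if (dp_extend_table(s, a, k, L, minScore, mm, ind, c))
        cands.push_back(c);
    }
  return cands_to_df(cands);
}
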