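// Alignment kernels: affine-gap pairwise DP (local / global, optionally banded)
// and a k-mer seeded, banded, x-drop local search used for genome scanning.
// Scoring convention: a gap of length L costs gap_open + L * gap_ext.
// N (or any non-ACGT base) never matches anything, including itself.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <map>
#include <algorithm>
using namespace Rcpp;

static const int NEG = -(1 << 28);

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static inline int max3(int a, int b, int c) {
  return std::max(a, std::max(b, c));
}

// traceback codes: 0 = from M, 1 = from X, 2 = from Y, 3 = local fresh start
// (consume the pair then stop), 4 = empty cell (never entered).

// ---------------------------------------------------------------------------
// Affine alignment with traceback. local = Smith-Waterman; global =
// Needleman-Wunsch over the full lengths, optionally banded around the
// corner-to-corner diagonal (band > 0).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_align(std::string a, std::string b,
               int match = 1, int mismatch = -1,
               int gap_open = 2, int gap_ext = 1,
               bool local = true, int band = 0) {
  std::vector<int> va = encode(a), vb = encode(b);
  const int n = (int)va.size(), m = (int)vb.size();
  if (n == 0 || m == 0) stop("cpp_align: empty sequence");

  const int go = gap_open + gap_ext;  // cost of the first gap column
  const int ge = gap_ext;

  const bool banded = (!local) && band > 0;
  int blo = band, bhi = band;
  if (banded) { if (m >= n) bhi += (m - n); else blo += (n - m); }
  const int W = banded ? (blo + bhi + 1) : (m + 1);

  auto jlo = [&](int i) { return banded ? std::max(0, i - blo) : 0; };
  auto jhi = [&](int i) { return banded ? std::min(m, i + bhi) : m; };
  auto idx = [&](int i, int j) {
    return banded ? ((size_t)i * W + (j - (i - blo))) : ((size_t)i * W + j);
  };

  std::vector<int> M((size_t)(n + 1) * W, NEG), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 4),
      tX((size_t)(n + 1) * W, 4), tY((size_t)(n + 1) * W, 4);

  M[idx(0, 0)] = 0;
  for (int j = std::max(1, jlo(0)); j <= jhi(0); ++j) {
    Y[idx(0, j)] = -(gap_open + ge * j);
    tY[idx(0, j)] = (j == 1) ? 0 : 2;
    if (local) M[idx(0, j)] = 0;
  }
  int best = local ? 0 : NEG, bi = local ? -1 : n, bj = local ? -1 : m;
  char bs = 'M';

  for (int i = 1; i <= n; ++i) {
    const int lo = jlo(i), hi = jhi(i);
    if (lo == 0) {
      X[idx(i, 0)] = -(gap_open + ge * i);
      tX[idx(i, 0)] = (i == 1) ? 0 : 1;
      if (local) M[idx(i, 0)] = 0;
    }
    for (int j = std::max(1, lo); j <= hi; ++j) {
      const bool inD = (j - 1 >= jlo(i - 1) && j - 1 <= jhi(i - 1));
      const bool inU = (j >= jlo(i - 1) && j <= jhi(i - 1));
      const bool inL = (j - 1 >= lo);
      const int sub =
          (va[i - 1] < 4 && va[i - 1] == vb[j - 1]) ? match : mismatch;
      const int dM = inD ? M[idx(i - 1, j - 1)] : NEG;
      const int dX = inD ? X[idx(i - 1, j - 1)] : NEG;
      const int dY = inD ? Y[idx(i - 1, j - 1)] : NEG;
      int pm = max3(dM, dX, dY);
      int v; unsigned char tr;
      if (local) {
        if (pm > 0) { v = pm + sub; tr = (pm == dM) ? 0 : (pm == dX ? 1 : 2); }
        else { v = sub; tr = 3; }
        if (v <= 0) { v = 0; tr = 4; }
      } else {
        if (pm <= NEG / 2) { v = NEG; tr = 4; }
        else { v = pm + sub; tr = (pm == dM) ? 0 : (pm == dX ? 1 : 2); }
      }
      M[idx(i, j)] = v; tM[idx(i, j)] = tr;
      if (local && v > best) { best = v; bi = i; bj = j; bs = 'M'; }

      const int uM = inU ? M[idx(i - 1, j)] : NEG;
      const int uX = inU ? X[idx(i - 1, j)] : NEG;
      const int uY = inU ? Y[idx(i - 1, j)] : NEG;
      int xv = max3(uM - go, uX - ge, uY - go);
      if (xv > NEG / 2) {
        X[idx(i, j)] = xv;
        tX[idx(i, j)] = (xv == uM - go) ? 0 : (xv == uX - ge ? 1 : 2);
      }
      const int lM = inL ? M[idx(i, j - 1)] : NEG;
      const int lX = inL ? X[idx(i, j - 1)] : NEG;
      const int lY = inL ? Y[idx(i, j - 1)] : NEG;
      int yv = max3(lM - go, lX - go, lY - ge);
      if (yv > NEG / 2) {
        Y[idx(i, j)] = yv;
        tY[idx(i, j)] = (yv == lM - go) ? 0 : (yv == lY - ge ? 2 : 1);
      }
    }
  }

  if (!local) {
    const int em = M[idx(n, m)], ex = X[idx(n, m)], ey = Y[idx(n, m)];
    best = max3(em, ex, ey);
    bs = (best == em) ? 'M' : (best == ex ? 'X' : 'Y');
    if (best <= NEG / 2) stop("cpp_align: band too narrow for a global path");
  }

  std::string aa, bb;
  int matches = 0, mismatches = 0, gapcols = 0;
  int i = (bi < 0) ? 0 : bi, j = (bj < 0) ? 0 : bj;
  char s = bs;
  if (!(local && bi < 0)) {  // empty local alignment: skip traceback
    while (!(i == 0 && j == 0)) {
      if (s == 'M') {
        const unsigned char tr = tM[idx(i, j)];
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
        if (va[i - 1] < 4 && va[i - 1] == vb[j - 1]) ++matches;
        else ++mismatches;
        --i; --j;
        if (local && tr == 3) break;
        if (tr <= 2) s = (tr == 0) ? 'M' : (tr == 1 ? 'X' : 'Y');
        else break;  // (0,0) start in global
      } else if (s == 'X') {
        const unsigned char tr = tX[idx(i, j)];
        aa.push_back(a[i - 1]); bb.push_back('-'); ++gapcols;
        --i;
        s = (tr == 0) ? 'M' : (tr == 1 ? 'X' : 'Y');
      } else {
        const unsigned char tr = tY[idx(i, j)];
        aa.push_back('-'); bb.push_back(b[j - 1]); ++gapcols;
        --j;
        s = (tr == 0) ? 'M' : (tr == 1 ? 'X' : 'Y');
      }
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(
      _["score"] = best,
      _["a_start"] = i, _["a_end"] = (bi < 0) ? 0 : bi,
      _["b_start"] = j, _["b_end"] = (bj < 0) ? 0 : bj,
      _["a_aln"] = aa, _["b_aln"] = bb,
      _["matches"] = matches, _["mismatches"] = mismatches,
      _["gap_columns"] = gapcols);
}

// ---------------------------------------------------------------------------
// Banded local DP around one diagonal (the gapped extension of a seed).
// Coordinates 0-based half-open.
// ---------------------------------------------------------------------------
struct BandHit {
  int score, qs, qe, ts, te, matches, mismatches, gapcols;
};

static bool banded_local(const std::vector<int>& q, const std::vector<int>& t,
                         int diag, int band, int match, int mismatch,
                         int go, int ge, int xdrop, BandHit& out) {
  const int n = (int)q.size(), m = (int)t.size();
  const int W = 2 * band + 1;
  // row i in 0..n; column slot c in 0..W-1 maps to j = i + diag - band + c
  std::vector<int> M((size_t)(n + 1) * W, NEG), X((size_t)(n + 1) * W, NEG),
      Y((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> tM((size_t)(n + 1) * W, 4),
      tX((size_t)(n + 1) * W, 4), tY((size_t)(n + 1) * W, 4);
  auto id = [&](int i, int c) { return (size_t)i * W + c; };
  int best = 0, bi = -1, bc = -1;

  for (int c = 0; c < W; ++c) {
    const int j = diag - band + c;
    if (j >= 0 && j <= m) M[id(0, c)] = 0;
  }
  for (int i = 1; i <= n; ++i) {
    int rowmax = NEG;
    for (int c = 0; c < W; ++c) {
      const int j = i + diag - band + c;
      if (j < 0 || j > m) continue;
      if (j == 0) { M[id(i, c)] = 0; continue; }
      const int sub = (q[i - 1] < 4 && q[i - 1] == t[j - 1]) ? match : mismatch;
      const int dM = M[id(i - 1, c)], dX = X[id(i - 1, c)], dY = Y[id(i - 1, c)];
      int pm = max3(dM, dX, dY);
      int v; unsigned char tr;
      if (pm > 0) { v = pm + sub; tr = (pm == dM) ? 0 : (pm == dX ? 1 : 2); }
      else { v = sub; tr = 3; }
      if (v <= 0) { v = 0; tr = 4; }
      M[id(i, c)] = v; tM[id(i, c)] = tr;
      if (v > best) { best = v; bi = i; bc = c; }
      if (v > rowmax) rowmax = v;
      if (c + 1 < W) {
        const int uM = M[id(i - 1, c + 1)], uX = X[id(i - 1, c + 1)],
                  uY = Y[id(i - 1, c + 1)];
        const int xv = max3(uM - go, uX - ge, uY - go);
        if (xv > NEG / 2) {
          X[id(i, c)] = xv;
          tX[id(i, c)] = (xv == uM - go) ? 0 : (xv == uX - ge ? 1 : 2);
          if (xv > rowmax) rowmax = xv;
        }
      }
      if (c - 1 >= 0) {
        const int lM = M[id(i, c - 1)], lX = X[id(i, c - 1)], lY = Y[id(i, c - 1)];
        const int yv = max3(lM - go, lX - go, lY - ge);
        if (yv > NEG / 2) {
          Y[id(i, c)] = yv;
          tY[id(i, c)] = (yv == lM - go) ? 0 : (yv == lY - ge ? 2 : 1);
          if (yv > rowmax) rowmax = yv;
        }
      }
    }
    if (best > 0 && rowmax < best - xdrop) break;
  }
  if (bi < 0 || best <= 0) return false;

  int i = bi, c = bc;
  char s = 'M';
  int matches = 0, mismatches = 0, gapcols = 0;
  int qs = 0, ts = 0;
  const int qe = bi, te = bi + diag - band + bc;
  while (true) {
    const int j = i + diag - band + c;
    if (s == 'M') {
      const unsigned char tr = tM[id(i, c)];
      if (q[i - 1] < 4 && q[i - 1] == t[j - 1]) ++matches; else ++mismatches;
      if (tr == 3) { qs = i - 1; ts = j - 1; break; }
      s = (tr == 0) ? 'M' : (tr == 1 ? 'X' : 'Y');
      --i;
    } else if (s == 'X') {
      const unsigned char tr = tX[id(i, c)];
      ++gapcols;
      s = (tr == 0) ? 'M' : (tr == 1 ? 'X' : 'Y');
      --i; ++c;
    } else {
      const unsigned char tr = tY[id(i, c)];
      ++gapcols;
      s = (tr == 0) ? 'M' : (tr == 1 ? 'X' : 'Y');
      --c;
    }
  }
  out.score = best; out.qs = qs; out.qe = qe; out.ts = ts; out.te = te;
  out.matches = matches; out.mismatches = mismatches; out.gapcols = gapcols;
  return true;
}

// ---------------------------------------------------------------------------
// Seeded search: index query k-mers, stream the target, extend each seed on a
// not-yet-covered diagonal by banded local DP. Plus strand only; the caller
// handles the reverse complement. Coordinates 0-based half-open.
// ---------------------------------------------------------------------------

// cheap ungapped x-drop extension from a seed; returns best ungapped score
static int ungapped_score(const std::vector<int>& q, const std::vector<int>& t,
                          int qpos, int tpos, int k, int match, int mismatch,
                          int xdrop) {
  const int n = (int)q.size(), m = (int)t.size();
  int score = k * match, best = score;
  int i = qpos + k, j = tpos + k;
  while (i < n && j < m) {
    score += (q[i] < 4 && q[i] == t[j]) ? match : mismatch;
    if (score > best) best = score;
    if (score < best - xdrop) break;
    ++i; ++j;
  }
  int right = best;
  score = right; best = right;
  i = qpos - 1; j = tpos - 1;
  while (i >= 0 && j >= 0) {
    score += (q[i] < 4 && q[i] == t[j]) ? match : mismatch;
    if (score > best) best = score;
    if (score < best - xdrop) break;
    --i; --j;
  }
  return best;
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string target,
                          int k = 12, int match = 1, int mismatch = -1,
                          int gap_open = 2, int gap_ext = 1,
                          int xdrop = 20, int band = 32, int min_score = 30,
                          int gapped_trigger = 16) {
  if (k < 2 || k > 31) stop("seed size k must be in [2, 31]");
  std::vector<int> q = encode(query), t = encode(target);
  const int n = (int)q.size(), m = (int)t.size();
  if (n < k) stop("query shorter than seed size k");
  const int go = gap_open + gap_ext, ge = gap_ext;

  std::unordered_map<uint64_t, std::vector<int>> index;
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  {
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      if (q[i] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)q[i]) & mask;
      if (++run >= k) index[h].push_back(i - k + 1);
    }
  }
  std::vector<BandHit> hits;
  if (!index.empty()) {
    std::map<int, int> covered;  // diagonal -> target end already explained
    uint64_t h = 0; int run = 0;
    for (int i = 0; i < m; ++i) {
      if (t[i] > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)t[i]) & mask;
      if (++run < k) continue;
      auto it = index.find(h);
      if (it == index.end()) continue;
      const int tpos = i - k + 1;
      const int trigger = std::min(gapped_trigger, min_score);
      for (int qpos : it->second) {
        const int diag = tpos - qpos;
        auto cv = covered.find(diag);
        if (cv != covered.end() && cv->second > tpos) continue;
        if (ungapped_score(q, t, qpos, tpos, k, match, mismatch,
                           xdrop) < trigger) {
          covered[diag] = tpos + 1;
          continue;
        }
        BandHit bh;
        if (banded_local(q, t, diag, band, match, mismatch, go, ge, xdrop, bh)) {
          for (int dd = diag - band; dd <= diag + band; ++dd) {
            auto c2 = covered.find(dd);
            if (c2 == covered.end() || c2->second < bh.te) covered[dd] = bh.te;
          }
          if (bh.score >= min_score) hits.push_back(bh);
        } else {
          covered[diag] = tpos + 1;
        }
      }
    }
  }

  const int nh = (int)hits.size();
  IntegerVector qs(nh), qe(nh), ts(nh), te(nh), sc(nh), ma(nh), mi(nh), gp(nh);
  for (int i = 0; i < nh; ++i) {
    qs[i] = hits[i].qs; qe[i] = hits[i].qe;
    ts[i] = hits[i].ts; te[i] = hits[i].te;
    sc[i] = hits[i].score; ma[i] = hits[i].matches;
    mi[i] = hits[i].mismatches; gp[i] = hits[i].gapcols;
  }
  return DataFrame::create(
      _["qstart"] = qs, _["qend"] = qe, _["tstart"] = ts, _["tend"] = te,
      _["score"] = sc, _["matches"] = ma, _["mismatches"] = mi,
      _["gap_columns"] = gp);
}

// ---------------------------------------------------------------------------
// Lag-match profile for tandem period detection: 0/1 vector of positions i
// (0-based) with seq[i] == seq[i + lag]; N never matches.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_lag_matches(std::string seq, int lag) {
  std::vector<int> v = encode(seq);
  const int n = (int)v.size();
  if (lag <= 0 || lag >= n) return IntegerVector(0);
  IntegerVector out(n - lag);
  for (int i = 0; i + lag < n; ++i)
    out[i] = (v[i] < 4 && v[i] == v[i + lag]) ? 1 : 0;
  return out;
}
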