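#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// ---- encoding ------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector encode_dna_cpp(std::string s) {
  int n = s.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    switch (s[i]) {
      case 'A': case 'a': out[i] = 0; break;
      case 'C': case 'c': out[i] = 1; break;
      case 'G': case 'g': out[i] = 2; break;
      case 'T': case 't': out[i] = 3; break;
      default: out[i] = -1;
    }
  }
  return out;
}

// rolling base-4 index into the 4^Q current table
// [[Rcpp::export]]
NumericVector qmer_currents_cpp(IntegerVector seq, NumericVector currents, int Q) {
  int n = seq.size();
  if (n < Q) stop("sequence shorter than Q");
  int nw = n - Q + 1;
  NumericVector out(nw);
  uint64_t code = 0, mask4 = 1;
  for (int j = 0; j < Q - 1; ++j) mask4 *= 4;  // 4^(Q-1)
  for (int i = 0; i < Q; ++i) {
    if (seq[i] < 0 || seq[i] > 3) stop("non-ACGT symbol at position %d", i + 1);
    code = code * 4 + (uint64_t)seq[i];
  }
  out[0] = currents[(R_xlen_t)code];
  for (int i = 1; i < nw; ++i) {
    int sin = seq[i + Q - 1];
    if (sin < 0 || sin > 3) stop("non-ACGT symbol at position %d", i + Q);
    code = (code - (uint64_t)seq[i - 1] * mask4) * 4 + (uint64_t)sin;
    out[i] = currents[(R_xlen_t)code];
  }
  return out;
}

// ---- edit distance (full DP, two rows) -----------------------------------

// [[Rcpp::export]]
int edit_distance_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (ai == b[j - 1] ? 0 : 1);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      cur[j] = std::min(d, std::min(u, l));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// ---- banded global alignment with traceback ------------------------------
// rows = query (I consumes query), cols = target (D consumes target).
// Band on the diagonal offset j - i, covering [min(0,m-n)-b, max(0,m-n)+b].
// Computed distance D is exact whenever D <= b (unit-cost Ukkonen argument).

static void push_op(std::string &cig, char op, int len, char &last, int &run) {
  if (op == last) { run += len; return; }
  if (last != 0) cig += std::to_string(run) + last;
  last = op; run = len;
}

// [[Rcpp::export]]
List banded_global_cpp(IntegerVector a, IntegerVector b, int band_init, int band_max) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) {
    std::string cig;
    if (n > 0) cig = std::to_string(n) + "I";
    if (m > 0) cig = std::to_string(m) + "D";
    return List::create(_["edit"] = n + m, _["cigar"] = cig,
                        _["nmatch"] = 0, _["exact"] = true);
  }
  int diff = m - n;
  int band = std::max(band_init, 1);
  if (band_max < band) band_max = band;
  const int INF = n + m + 10;
  while (true) {
    int lo_off = std::min(0, diff) - band;   // smallest allowed j - i
    int hi_off = std::max(0, diff) + band;   // largest allowed j - i
    int W = hi_off - lo_off + 1;
    // D values for current and previous row over band; ops matrix for traceback
    std::vector<int> prev(W, INF), cur(W, INF);
    std::vector<uint8_t> ops((size_t)(n + 1) * W, 255); // 0 diag, 1 up(I), 2 left(D)
    // row 0: D[0][j] = j
    for (int off = 0; off < W; ++off) {
      int j = lo_off + off;  // since i = 0
      if (j >= 0 && j <= m) { prev[off] = j; if (j > 0) ops[off] = 2; }
    }
    for (int i = 1; i <= n; ++i) {
      std::fill(cur.begin(), cur.end(), INF);
      int ai = a[i - 1];
      int jlo = std::max(0, i + lo_off), jhi = std::min(m, i + hi_off);
      for (int j = jlo; j <= jhi; ++j) {
        int off = j - i - lo_off;
        int best = INF; uint8_t op = 255;
        // diag (i-1, j-1): offset of (j-1)-(i-1) = j-i -> same off
        if (j >= 1) {
          int v = prev[off];
          if (v < INF) { int c = v + (ai == b[j - 1] ? 0 : 1); if (c < best) { best = c; op = 0; } }
        }
        // up (i-1, j): offset (j)-(i-1) = off+1
        if (off + 1 < W) {
          int v = prev[off + 1];
          if (v < INF) { int c = v + 1; if (c < best) { best = c; op = 1; } }
        }
        // left (i, j-1): offset off-1
        if (off - 1 >= 0) {
          int v = cur[off - 1];
          if (v < INF) { int c = v + 1; if (c < best) { best = c; op = 2; } }
        }
        cur[off] = best;
        ops[(size_t)i * W + off] = op;
      }
      std::swap(prev, cur);
    }
    int final_off = m - n - lo_off;
    int D = (final_off >= 0 && final_off < W) ? prev[final_off] : INF;
    bool exact = (D <= band) || (band >= n + m);
    if (!exact && band < band_max) { band = std::min(band * 2, band_max); continue; }
    // traceback
    std::string cig_rev;
    char last = 0; int run = 0; int nmatch = 0;
    {
      std::string cig;
      int i = n, j = m;
      std::vector<std::pair<char,int>> rev;
      while (i > 0 || j > 0) {
        int off = j - i - lo_off;
        uint8_t op = ops[(size_t)i * W + off];
        if (op == 0) { if (a[i-1] == b[j-1]) ++nmatch; rev.push_back({'M',1}); --i; --j; }
        else if (op == 1) { rev.push_back({'I',1}); --i; }
        else if (op == 2) { rev.push_back({'D',1}); --j; }
        else break; // unreachable cell (shouldn't happen when exact)
      }
      for (int r = (int)rev.size() - 1; r >= 0; --r) push_op(cig, rev[r].first, rev[r].second, last, run);
      if (last != 0) cig += std::to_string(run) + last;
      cig_rev = cig;
    }
    return List::create(_["edit"] = D, _["cigar"] = cig_rev,
                        _["nmatch"] = nmatch, _["exact"] = exact);
  }
}

// ---- score-based banded extension from (0,0) ------------------------------
// Maximises match/mismatch/gap score over all cells reachable within the band;
// used to extend chain ends so that chimeric tails soft-clip naturally.

// [[Rcpp::export]]
List extend_align_cpp(IntegerVector q, IntegerVector t, int match, int mismatch,
                      int gap, int band, int xdrop) {
  int n = q.size(), m = t.size();
  const int NEG = -1000000000;
  int W = 2 * band + 1;
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<uint8_t> ops((size_t)(n + 1) * W, 255);
  // i = 0 row: j in [0, band]; gap is a negative score
  for (int j = 0; j <= std::min(m, band); ++j) {
    prev[j + band] = j * gap;
    if (j > 0) ops[j + band] = 2;
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    int qi = q[i - 1];
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int off = j - i + band;
      int bestc = NEG; uint8_t op = 255;
      if (j >= 1) { // diag: (i-1,j-1) same off
        int v = prev[off];
        if (v > NEG) { int c = v + (qi == t[j - 1] ? match : mismatch); if (c > bestc) { bestc = c; op = 0; } }
      }
      if (off + 1 < W) { // up: (i-1, j) -> consumes query (I)
        int v = prev[off + 1];
        if (v > NEG) { int c = v + gap; if (c > bestc) { bestc = c; op = 1; } }
      }
      if (off - 1 >= 0) { // left: (i, j-1) -> consumes target (D)
        int v = cur[off - 1];
        if (v > NEG) { int c = v + gap; if (c > bestc) { bestc = c; op = 2; } }
      }
      cur[off] = bestc;
      ops[(size_t)i * W + off] = op;
      if (bestc > best || (bestc == best && i > bi)) { best = bestc; bi = i; bj = j; }
    }
    // x-drop: stop when the whole row has fallen far below the best score
    int rowbest = NEG;
    for (int j = jlo; j <= jhi; ++j) rowbest = std::max(rowbest, cur[j - i + band]);
    std::swap(prev, cur);
    if (rowbest < best - xdrop) break;
  }
  // traceback from (bi, bj)
  std::string cig; char last = 0; int run = 0;
  int edit = 0, nmatch = 0;
  {
    std::vector<std::pair<char,int>> rev;
    int i = bi, j = bj;
    while (i > 0 || j > 0) {
      int off = j - i + band;
      uint8_t op = ops[(size_t)i * W + off];
      if (op == 0) { bool eq = q[i-1] == t[j-1]; if (eq) ++nmatch; else ++edit; rev.push_back({'M',1}); --i; --j; }
      else if (op == 1) { ++edit; rev.push_back({'I',1}); --i; }
      else if (op == 2) { ++edit; rev.push_back({'D',1}); --j; }
      else break;
    }
    for (int r = (int)rev.size() - 1; r >= 0; --r) push_op(cig, rev[r].first, rev[r].second, last, run);
    if (last != 0) cig += std::to_string(run) + last;
  }
  return List::create(_["score"] = best, _["q_used"] = bi, _["t_used"] = bj,
                      _["cigar"] = cig, _["edit"] = edit, _["nmatch"] = nmatch);
}

// ---- minimizers -----------------------------------------------------------

static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30; x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27; x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

// [[Rcpp::export]]
List minimizers_cpp(IntegerVector seq, int k, int w, int alphabet, bool canonical) {
  int n = seq.size();
  std::vector<int> pos; std::vector<double> hash; std::vector<int> strand;
  if (n < k) {
    return List::create(_["pos"] = IntegerVector(0), _["hash"] = NumericVector(0),
                        _["strand"] = IntegerVector(0));
  }
  if (canonical && alphabet != 4) stop("canonical minimizers require alphabet_size 4");
  int nk = n - k + 1;
  uint64_t top = 1;
  for (int j = 0; j < k - 1; ++j) top *= (uint64_t)alphabet; // alpha^(k-1)
  const uint64_t MASK53 = ((uint64_t)1 << 53) - 1;
  std::vector<double> hv(nk);
  std::vector<int> sv(nk, 1);
  for (int i = 0; i < n; ++i) {
    int s = seq[i];
    if (s < 0 || s >= alphabet) stop("symbol out of range at position %d", i + 1);
  }
  uint64_t code = 0;
  for (int i = 0; i < n; ++i) {
    int s = seq[i];
    if (i >= k) code -= (uint64_t)seq[i - k] * top;
    code = code * alphabet + (uint64_t)s;
    if (i >= k - 1) {
      int p = i - k + 1;
      uint64_t c = code;
      int str = 1;
      if (canonical) {
        // reverse-complement code recomputed directly (k is small)
        uint64_t rc = 0;
        for (int j = 0; j < k; ++j) rc = rc * 4 + (uint64_t)(3 - seq[i - j]);
        if (rc < c) { c = rc; str = -1; }
      }
      hv[p] = (double)(mix64(c + 1) & MASK53);
      sv[p] = str;
    }
  }
  int nwin = (nk >= w) ? (nk - w + 1) : 1;
  std::vector<bool> sel(nk, false);
  if (nk < w) {
    // single short window over whatever k-mers exist
    double mn = hv[0];
    for (int p = 1; p < nk; ++p) mn = std::min(mn, hv[p]);
    for (int p = 0; p < nk; ++p) if (hv[p] == mn) sel[p] = true;
  } else {
    for (int ws = 0; ws < nwin; ++ws) {
      double mn = hv[ws];
      for (int p = ws + 1; p < ws + w; ++p) mn = std::min(mn, hv[p]);
      for (int p = ws; p < ws + w; ++p) if (hv[p] == mn) sel[p] = true;
    }
  }
  for (int p = 0; p < nk; ++p) if (sel[p]) { pos.push_back(p); hash.push_back(hv[p]); strand.push_back(sv[p]); }
  return List::create(_["pos"] = wrap(pos), _["hash"] = wrap(hash), _["strand"] = wrap(strand));
}

// ---- anchor collection -----------------------------------------------------

// [[Rcpp::export]]
List collect_anchors_cpp(IntegerVector qpos, NumericVector qhash, IntegerVector qstrand,
                         IntegerVector tpos, NumericVector thash, IntegerVector tstrand,
                         int qlen, int k, int max_occ) {
  std::unordered_multimap<uint64_t, int> idx;
  idx.reserve(thash.size() * 2);
  for (int i = 0; i < thash.size(); ++i) idx.insert({(uint64_t)thash[i], i});
  std::vector<int> aq, at, astr;
  for (int i = 0; i < qhash.size(); ++i) {
    uint64_t h = (uint64_t)qhash[i];
    auto rng = idx.equal_range(h);
    int occ = 0;
    for (auto it = rng.first; it != rng.second; ++it) ++occ;
    if (occ == 0 || occ > max_occ) continue;
    for (auto it = rng.first; it != rng.second; ++it) {
      int j = it->second;
      int s = qstrand[i] * tstrand[j];
      int q = (s > 0) ? qpos[i] : (qlen - qpos[i] - k);
      aq.push_back(q); at.push_back(tpos[j]); astr.push_back(s);
    }
  }
  return List::create(_["q"] = wrap(aq), _["t"] = wrap(at), _["strand"] = wrap(astr));
}

// ---- chaining --------------------------------------------------------------
// minimap2-style DP: f(i) = max_j f(j) + min(k, dq, dt) - gap(dq, dt),
// gap = gap_scale*|dt-dq| + 0.5*log2(|dt-dq|+1); pairs with dq<=0, dt<=0 or
// max(dq,dt) > max_gap are unchainable. Multiple chains by backtracking from
// high-scoring unused anchors.

// [[Rcpp::export]]
List chain_cpp(IntegerVector q, IntegerVector t, int k, int max_gap,
               double gap_scale, double min_score, int max_lookback, int top_n) {
  int n = q.size();
  if (n == 0) return List::create();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (t[a] != t[b]) return t[a] < t[b];
    return q[a] < q[b];
  });
  std::vector<double> f(n);
  std::vector<int> par(n, -1);
  for (int i = 0; i < n; ++i) {
    int oi = ord[i];
    f[i] = (double)k;
    int lo = std::max(0, i - max_lookback);
    for (int j = i - 1; j >= lo; --j) {
      int oj = ord[j];
      int dt = t[oi] - t[oj];
      if (dt > max_gap) break; // t ascending in ord
      int dq = q[oi] - q[oj];
      if (dq <= 0 || dt <= 0 || dq > max_gap) continue;
      int gd = std::abs(dt - dq);
      double cost = gd > 0 ? gap_scale * gd + 0.5 * std::log2((double)gd + 1.0) : 0.0;
      double inc = (double)std::min(k, std::min(dq, dt));
      double sc = f[j] + inc - cost;
      if (sc > f[i]) { f[i] = sc; par[i] = j; }
    }
  }
  std::vector<int> byf(n);
  for (int i = 0; i < n; ++i) byf[i] = i;
  std::stable_sort(byf.begin(), byf.end(), [&](int a, int b) {
    if (f[a] != f[b]) return f[a] > f[b];
    return t[ord[a]] < t[ord[b]]; // tie-break: leftmost target start
  });
  std::vector<bool> used(n, false);
  List out;
  int made = 0;
  for (int ii = 0; ii < n && made < top_n; ++ii) {
    int i = byf[ii];
    if (used[i]) continue;
    std::vector<int> path;
    int j = i; double base = 0.0;
    while (j != -1 && !used[j]) { path.push_back(j); used[j] = true; j = par[j]; }
    if (j != -1) base = f[j];
    double score = f[i] - base;
    if (score < min_score) continue;
    IntegerVector idx(path.size());
    for (size_t p = 0; p < path.size(); ++p) idx[p] = ord[path[path.size() - 1 - p]] + 1; // 1-based, ascending
    out.push_back(List::create(_["idx"] = idx, _["score"] = score));
    ++made;
  }
  return out;
}

// ---- simulator: biased read mutation ---------------------------------------
// Substitutions prefer, with probability confusion_weight, the alternative
// base whose Q-mer (window starting at the substituted position, original
// context) has the current level closest to the original Q-mer's.

// [[Rcpp::export]]
IntegerVector mutate_read_cpp(IntegerVector seq, NumericVector currents, int Q,
                              double p_sub, double p_ins, double p_del,
                              double confusion_weight) {
  int n = seq.size();
  std::vector<int> out;
  out.reserve((size_t)(n * 1.1) + 16);
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    double u = unif_rand();
    if (u < p_del) continue;               // deletion: drop base
    if (u < p_del + p_ins) {               // insertion before base
      out.push_back((int)(unif_rand() * 4) & 3);
      out.push_back(seq[i]);
      continue;
    }
    if (u < p_del + p_ins + p_sub) {       // substitution
      int orig = seq[i];
      int alt = -1;
      bool biased = (confusion_weight > 0.0) && (unif_rand() < confusion_weight) &&
                    (n >= Q) && (currents.size() > 0);
      if (biased) {
        // total current perturbation across every Q-window containing i,
        // per candidate base (original sequence context)
        double bestd = R_PosInf;
        for (int b = 0; b < 4; ++b) {
          if (b == orig) continue;
          double d = 0.0;
          int slo = std::max(0, i - Q + 1), shi = std::min(i, n - Q);
          for (int s = slo; s <= shi; ++s) {
            uint64_t code0 = 0, code1 = 0;
            for (int j = 0; j < Q; ++j) {
              int base = seq[s + j];
              code0 = code0 * 4 + (uint64_t)base;
              code1 = code1 * 4 + (uint64_t)(s + j == i ? b : base);
            }
            d += std::fabs(currents[(R_xlen_t)code1] - currents[(R_xlen_t)code0]);
          }
          if (d < bestd) { bestd = d; alt = b; }
        }
        if (!(bestd < R_PosInf)) alt = -1;
      }
      if (alt < 0) {
        alt = (int)(unif_rand() * 3);
        if (alt >= orig) ++alt;
        if (alt > 3) alt = 3;
      }
      out.push_back(alt);
      continue;
    }
    out.push_back(seq[i]);
  }
  PutRNGstate();
  return wrap(out);
}

// ---- banded affine-gap (Gotoh) global alignment ----------------------------
// Used for CIGAR generation where gap consolidation matters (SV-scale
// indels): unit-cost edit paths scatter long gaps through chance matches,
// affine penalties keep them as single runs. Scores: match/mismatch,
// gap = -(open + ext) for the first base, -ext per further base.

// [[Rcpp::export]]
List affine_global_cpp(IntegerVector a, IntegerVector b, int band,
                       int match, int mismatch, int gap_open, int gap_ext) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) {
    std::string cig;
    if (n > 0) cig = std::to_string(n) + "I";
    if (m > 0) cig = std::to_string(m) + "D";
    return List::create(_["edit"] = n + m, _["cigar"] = cig, _["nmatch"] = 0);
  }
  int diff = m - n;
  int lo_off = std::min(0, diff) - band;
  int hi_off = std::max(0, diff) + band;
  int W = hi_off - lo_off + 1;
  const int NEG = -1000000000;
  // three layers: 0 = M (diag), 1 = X (gap in query, consumes target, D),
  // 2 = Y (gap in target, consumes query, I)
  std::vector<int> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<int> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // trace: 2 bits per layer: source layer of the transition
  std::vector<uint8_t> tr((size_t)(n + 1) * W, 0xFF);
  int go = gap_open, ge = gap_ext;
  // row 0: only X (leading deletions)
  {
    int off0 = 0 - lo_off;
    if (off0 >= 0 && off0 < W) Mp[off0] = 0;
    for (int j = 1; j <= m; ++j) {
      int off = j - lo_off;
      if (off < 0 || off >= W) break;
      Xp[off] = -(go + ge * j);
      tr[off] = (uint8_t)((j == 1 ? 0 : 1) << 2); // X from M (open) or X (ext)
    }
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    int ai = a[i - 1];
    int jlo = std::max(0, i + lo_off), jhi = std::min(m, i + hi_off);
    for (int j = jlo; j <= jhi; ++j) {
      int off = j - i - lo_off;
      uint8_t t8 = 0;
      // M: from (i-1, j-1), same off
      if (j >= 1) {
        int s = (ai == b[j - 1]) ? match : mismatch;
        int bm = NEG; uint8_t src = 0;
        if (Mp[off] > NEG && Mp[off] >= Xp[off] && Mp[off] >= Yp[off]) { bm = Mp[off]; src = 0; }
        else if (Xp[off] >= Yp[off] && Xp[off] > NEG) { bm = Xp[off]; src = 1; }
        else if (Yp[off] > NEG) { bm = Yp[off]; src = 2; }
        if (bm > NEG) { Mc[off] = bm + s; t8 |= src; }
        else Mc[off] = NEG;
      }
      // X: from (i, j-1), off-1 in current row
      if (off - 1 >= 0) {
        int fromM = (Mc[off - 1] > NEG) ? Mc[off - 1] - (go + ge) : NEG;
        int fromX = (Xc[off - 1] > NEG) ? Xc[off - 1] - ge : NEG;
        int fromY = (Yc[off - 1] > NEG) ? Yc[off - 1] - (go + ge) : NEG;
        int bx = std::max(fromM, std::max(fromX, fromY));
        if (bx > NEG) {
          uint8_t src = (fromX >= fromM && fromX >= fromY) ? 1 :
                        ((fromM >= fromY) ? 0 : 2);
          Xc[off] = bx; t8 |= (uint8_t)(src << 2);
        }
      }
      // Y: from (i-1, j), off+1 in previous row
      if (off + 1 < W) {
        int fromM = (Mp[off + 1] > NEG) ? Mp[off + 1] - (go + ge) : NEG;
        int fromY = (Yp[off + 1] > NEG) ? Yp[off + 1] - ge : NEG;
        int fromX = (Xp[off + 1] > NEG) ? Xp[off + 1] - (go + ge) : NEG;
        int by = std::max(fromM, std::max(fromY, fromX));
        if (by > NEG) {
          uint8_t src = (fromY >= fromM && fromY >= fromX) ? 2 :
                        ((fromM >= fromX) ? 0 : 1);
          Yc[off] = by; t8 |= (uint8_t)(src << 4);
        }
      }
      tr[(size_t)i * W + off] = t8;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  int foff = m - n - lo_off;
  int layer = 0; int fs = NEG;
  if (foff >= 0 && foff < W) {
    fs = Mp[foff]; layer = 0;
    if (Xp[foff] > fs) { fs = Xp[foff]; layer = 1; }
    if (Yp[foff] > fs) { fs = Yp[foff]; layer = 2; }
  }
  // traceback
  std::vector<std::pair<char, int>> rev;
  int i = n, j = m, edit = 0, nmatch = 0;
  while (i > 0 || j > 0) {
    int off = j - i - lo_off;
    if (off < 0 || off >= W) break;
    uint8_t t8 = tr[(size_t)i * W + off];
    if (t8 == 0xFF) break;
    if (layer == 0) {
      if (i < 1 || j < 1) break;
      if (a[i - 1] == b[j - 1]) ++nmatch; else ++edit;
      rev.push_back({'M', 1});
      layer = t8 & 3; --i; --j;
    } else if (layer == 1) {
      ++edit; rev.push_back({'D', 1});
      layer = (t8 >> 2) & 3; --j;
    } else {
      ++edit; rev.push_back({'I', 1});
      layer = (t8 >> 4) & 3; --i;
    }
  }
  // anything left unreached in the band: emit leading gaps
  if (i > 0) { rev.push_back({'I', i}); edit += i; }
  if (j > 0) { rev.push_back({'D', j}); edit += j; }
  std::string cig; char last = 0; int run = 0;
  for (int r = (int)rev.size() - 1; r >= 0; --r) push_op(cig, rev[r].first, rev[r].second, last, run);
  if (last != 0) cig += std::to_string(run) + last;
  return List::create(_["edit"] = edit, _["cigar"] = cig, _["nmatch"] = nmatch,
                      _["score"] = fs);
}
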