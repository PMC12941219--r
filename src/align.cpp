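#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Seed-and-extend gapped local aligner (plus strand only; the R wrapper
// handles the minus strand by searching the reverse complement).
// Scoring: match/mismatch, affine gaps (first gap residue costs
// open + extend, each further residue costs extend), x-drop termination.
// N never matches anything.

static const int NEG = -1000000000;

struct ExtResult {
  int di, dj;      // residues consumed in query / subject
  int score;
  int nident;
  int ncols;
};

struct Hsp {
  int q0, q1, s0, s1;  // 0-based half-open
  int score, nident, ncols;
};

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// X-drop affine-gap extension of q starting at qpos, s at spos, in direction
// dir (+1 extends to the right over q[qpos..], s[spos..]; -1 extends to the
// left over the preceding residues). Returns the best-scoring extension that
// ends on an aligned residue pair, with identity stats from traceback.
static ExtResult xdrop_extend(const std::vector<int>& q, const std::vector<int>& s,
                              int qpos, int spos, int dir,
                              int match, int mismatch, int gap_first, int gap_ext,
                              int xdrop) {
  int Lq = dir > 0 ? (int)q.size() - qpos : qpos;
  int Ls = dir > 0 ? (int)s.size() - spos : spos;
  ExtResult res = {0, 0, 0, 0, 0};
  if (Lq == 0 || Ls == 0) return res;

  // rows i = 1..Lq (query residues consumed), cols j (subject residues)
  std::vector<int> Mprev(1, 0), Xprev(1, NEG), Yprev(1, NEG);
  int lo_prev = 0, hi_prev = 0;  // inclusive j range of previous row
  int best = 0, best_i = 0, best_j = 0;

  std::vector<int> row_lo;          // per stored row: lo
  std::vector<std::vector<uint8_t>> tb;  // per stored row: traceback bytes
  row_lo.reserve(256); tb.reserve(256);

  for (int i = 1; i <= Lq; ++i) {
    int lo = std::max(1, lo_prev);      // j >= 1 once i >= 1 (no leading gap cols kept)
    int hi_cap = Ls;
    int hi = std::min(hi_cap, hi_prev + 1);
    if (lo > hi) break;
    std::vector<int> Mrow(hi - lo + 2 + 16, NEG), Xrow(hi - lo + 2 + 16, NEG),
        Yrow(hi - lo + 2 + 16, NEG);
    std::vector<uint8_t> tbrow;
    tbrow.reserve(hi - lo + 8);
    int qi = dir > 0 ? q[qpos + (i - 1)] : q[qpos - i];
    int row_best = NEG;
    int j = lo;
    int first_j = lo, last_j = lo - 1;
    bool row_alive = false;
    while (j <= hi_cap) {
      // fetch previous row values at j-1 and j
      int pm_d = NEG, px_d = NEG, py_d = NEG;  // (i-1, j-1)
      int pm_v = NEG, px_v = NEG;              // (i-1, j)
      if (i == 1) {
        if (j == 1) pm_d = 0;                  // origin
      } else {
        if (j - 1 >= lo_prev && j - 1 <= hi_prev) {
          pm_d = Mprev[j - 1 - lo_prev];
          px_d = Xprev[j - 1 - lo_prev];
          py_d = Yprev[j - 1 - lo_prev];
        } else if (j - 1 == 0) {
          // previous row at column 0 only valid if i-1 == 0; not here
        }
        if (j >= lo_prev && j <= hi_prev) {
          pm_v = Mprev[j - lo_prev];
          px_v = Xprev[j - lo_prev];
        }
      }
      int sj = dir > 0 ? s[spos + (j - 1)] : s[spos - j];
      bool isid = (qi == sj) && qi != 4 && sj != 4;
      int sub = isid ? match : mismatch;
      int m_from = 0;
      int mbest = pm_d;
      if (px_d > mbest) { mbest = px_d; m_from = 1; }
      if (py_d > mbest) { mbest = py_d; m_from = 2; }
      int Mv = (mbest == NEG) ? NEG : mbest + sub;

      int x_from_m = (pm_v == NEG) ? NEG : pm_v - gap_first;
      int x_from_x = (px_v == NEG) ? NEG : px_v - gap_ext;
      int Xv, xf;
      if (x_from_m >= x_from_x) { Xv = x_from_m; xf = 1; } else { Xv = x_from_x; xf = 0; }

      int idx_jm1 = j - 1 - first_j;  // current row, previous column
      int cm_h = (j - 1 >= first_j && j - 1 <= last_j) ? Mrow[idx_jm1] : NEG;
      int cy_h = (j - 1 >= first_j && j - 1 <= last_j) ? Yrow[idx_jm1] : NEG;
      int y_from_m = (cm_h == NEG) ? NEG : cm_h - gap_first;
      int y_from_y = (cy_h == NEG) ? NEG : cy_h - gap_ext;
      int Yv, yf;
      if (y_from_m >= y_from_y) { Yv = y_from_m; yf = 1; } else { Yv = y_from_y; yf = 0; }

      int cellmax = std::max(Mv, std::max(Xv, Yv));
      if (j > hi && cellmax < best - xdrop) break;  // stop horizontal overflow
      int idx = j - first_j;
      if ((int)Mrow.size() <= idx) {
        Mrow.resize(idx + 16, NEG); Xrow.resize(idx + 16, NEG); Yrow.resize(idx + 16, NEG);
      }
      if (cellmax < best - xdrop) {
        Mrow[idx] = NEG; Xrow[idx] = NEG; Yrow[idx] = NEG;
        tbrow.push_back(0);
      } else {
        row_alive = true;
        Mrow[idx] = Mv; Xrow[idx] = Xv; Yrow[idx] = Yv;
        uint8_t b = (uint8_t)((m_from & 3) | (xf << 2) | (yf << 3) | (isid ? 16 : 0));
        tbrow.push_back(b);
        if (Mv > best) { best = Mv; best_i = i; best_j = j; }
        if (cellmax > row_best) row_best = cellmax;
      }
      last_j = j;
      ++j;
    }
    if (!row_alive) break;
    // trim dead cells at both ends for the next row's band
    int new_lo = first_j, new_hi = last_j;
    while (new_lo <= new_hi) {
      int idx = new_lo - first_j;
      if (std::max(Mrow[idx], std::max(Xrow[idx], Yrow[idx])) >= best - xdrop) break;
      ++new_lo;
    }
    while (new_hi >= new_lo) {
      int idx = new_hi - first_j;
      if (std::max(Mrow[idx], std::max(Xrow[idx], Yrow[idx])) >= best - xdrop) break;
      --new_hi;
    }
    row_lo.push_back(first_j);
    tb.push_back(std::move(tbrow));
    // compact previous-row storage to the surviving band
    int width = new_hi - new_lo + 1;
    std::vector<int> M2(width), X2(width), Y2(width);
    for (int k = 0; k < width; ++k) {
      int idx = new_lo + k - first_j;
      M2[k] = Mrow[idx]; X2[k] = Xrow[idx]; Y2[k] = Yrow[idx];
    }
    Mprev = std::move(M2); Xprev = std::move(X2); Yprev = std::move(Y2);
    lo_prev = new_lo; hi_prev = new_hi;
    if (row_best < best - xdrop) break;
  }

  if (best <= 0) return res;
  // traceback from (best_i, best_j) in state M
  int i = best_i, j = best_j, state = 0;
  int nid = 0, ncols = 0;
  while (i > 0 || j > 0) {
    if (i == 0 || j == 0) break;  // reached origin edge
    const std::vector<uint8_t>& trow = tb[i - 1];
    int idx = j - row_lo[i - 1];
    if (idx < 0 || idx >= (int)trow.size()) break;  // safety
    uint8_t b = trow[idx];
    if (state == 0) {
      ++ncols;
      if (b & 16) ++nid;
      state = b & 3;
      --i; --j;
    } else if (state == 1) {
      ++ncols;
      state = (b & 4) ? 0 : 1;
      --i;
    } else {
      ++ncols;
      state = (b & 8) ? 0 : 2;
      --j;
    }
  }
  res.di = best_i; res.dj = best_j; res.score = best; res.nident = nid; res.ncols = ncols;
  return res;
}

// [[Rcpp::export(name = ".cpp_local_align")]]
DataFrame cpp_local_align(std::string query, std::string subject,
                          int word_size, double min_pident, int min_len,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int xdrop) {
  int Lq = (int)query.size(), Ls = (int)subject.size();
  std::vector<int> q(Lq), s(Ls);
  for (int i = 0; i < Lq; ++i) q[i] = enc(query[i]);
  for (int i = 0; i < Ls; ++i) s[i] = enc(subject[i]);
  int gap_first = gap_open + gap_extend;

  std::vector<Hsp> hsps;
  if (Lq >= word_size && Ls >= word_size) {
    // hash all clean query words
    std::unordered_map<uint32_t, std::vector<int>> index;
    uint32_t mask = (word_size >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word_size)) - 1u);
    uint32_t w = 0; int run = 0;
    for (int i = 0; i < Lq; ++i) {
      if (q[i] == 4) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)q[i]) & mask;
      if (++run >= word_size) index[w].push_back(i - word_size + 1);
    }
    // collect maximal exact runs >= word_size
    struct Run { int rq, rs, len; };
    std::vector<Run> runs;
    w = 0; run = 0;
    for (int j = 0; j < Ls; ++j) {
      if (s[j] == 4) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint32_t)s[j]) & mask;
      if (++run < word_size) continue;
      auto it = index.find(w);
      if (it == index.end()) continue;
      int spos = j - word_size + 1;
      for (int qpos : it->second) {
        // only record at run starts to get maximal runs once
        if (qpos > 0 && spos > 0 && q[qpos - 1] == s[spos - 1] && q[qpos - 1] != 4)
          continue;
        int len = word_size;
        while (qpos + len < Lq && spos + len < Ls && q[qpos + len] == s[spos + len] &&
               q[qpos + len] != 4)
          ++len;
        runs.push_back({qpos, spos, len});
      }
    }
    std::sort(runs.begin(), runs.end(),
              [](const Run& a, const Run& b) { return a.len > b.len; });
    for (const Run& r : runs) {
      bool covered = false;
      int rdiag = r.rq - r.rs;
      for (const Hsp& h : hsps) {
        // must lie inside the HSP's rectangle AND near its diagonal band,
        // so repeat-induced off-diagonal matches are kept
        int dlo = std::min(h.q0 - h.s0, h.q1 - h.s1) - 10;
        int dhi = std::max(h.q0 - h.s0, h.q1 - h.s1) + 10;
        if (r.rq >= h.q0 && r.rq + r.len <= h.q1 && r.rs >= h.s0 &&
            r.rs + r.len <= h.s1 && rdiag >= dlo && rdiag <= dhi) {
          covered = true; break;
        }
      }
      if (covered) continue;
      ExtResult left = xdrop_extend(q, s, r.rq, r.rs, -1, match, mismatch,
                                    gap_first, gap_extend, xdrop);
      ExtResult right = xdrop_extend(q, s, r.rq + r.len, r.rs + r.len, +1, match,
                                     mismatch, gap_first, gap_extend, xdrop);
      Hsp h;
      h.q0 = r.rq - left.di; h.q1 = r.rq + r.len + right.di;
      h.s0 = r.rs - left.dj; h.s1 = r.rs + r.len + right.dj;
      h.score = left.score + r.len * match + right.score;
      h.nident = left.nident + r.len + right.nident;
      h.ncols = left.ncols + r.len + right.ncols;
      hsps.push_back(h);
    }
  }
  // filter, then drop near-duplicates contained in better-scoring HSPs
  std::vector<Hsp> pass;
  for (const Hsp& h : hsps) {
    double pid = 100.0 * h.nident / h.ncols;
    if (h.ncols >= min_len && pid >= min_pident) pass.push_back(h);
  }
  std::sort(pass.begin(), pass.end(), [](const Hsp& a, const Hsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.q0 != b.q0) return a.q0 < b.q0;
    return a.s0 < b.s0;
  });
  std::vector<Hsp> keep;
  for (const Hsp& h : pass) {
    bool dup = false;
    int hdlo = std::min(h.q0 - h.s0, h.q1 - h.s1);
    int hdhi = std::max(h.q0 - h.s0, h.q1 - h.s1);
    for (const Hsp& k : keep) {
      int kdlo = std::min(k.q0 - k.s0, k.q1 - k.s1) - 10;
      int kdhi = std::max(k.q0 - k.s0, k.q1 - k.s1) + 10;
      if (hdhi < kdlo || hdlo > kdhi) continue;  // different diagonal band
      int qov = std::min(h.q1, k.q1) - std::max(h.q0, k.q0);
      int sov = std::min(h.s1, k.s1) - std::max(h.s0, k.s0);
      if (qov > 0 && sov > 0 && qov >= 0.9 * (h.q1 - h.q0) && sov >= 0.9 * (h.s1 - h.s0)) {
        dup = true; break;
      }
    }
    if (!dup) keep.push_back(h);
  }
  int n = (int)keep.size();
  IntegerVector qstart(n), qend(n), sstart(n), send(n), score(n), alen(n), nident(n);
  NumericVector pident(n);
  for (int i = 0; i < n; ++i) {
    qstart[i] = keep[i].q0; qend[i] = keep[i].q1;
    sstart[i] = keep[i].s0; send[i] = keep[i].s1;
    score[i] = keep[i].score; alen[i] = keep[i].ncols; nident[i] = keep[i].nident;
    pident[i] = 100.0 * keep[i].nident / keep[i].ncols;
  }
  return DataFrame::create(_["qstart"] = qstart, _["qend"] = qend,
                           _["sstart"] = sstart, _["send"] = send,
                           _["pident"] = pident, _["length"] = alen,
                           _["score"] = score, _["nident"] = nident);
}
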