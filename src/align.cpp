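// Local alignment of short barcode queries against read prefixes.
//
// The dynamic program is classic Smith-Waterman with linear gap costs, plus
// an optional non-linear bonus awarded once per maximal run of >= run_min
// consecutive matches.  The run bonus is implemented with layered DP states:
// layer r means "the alignment ending here has a trailing diagonal match run
// of length r" (capped at run_min, where the bonus has been banked).
//
// Coordinate/tie-break convention: among all maximum-score local alignments
// the one with the smallest read (target) start is returned, then the
// smallest read end.  Zero-contribution diagonal prefixes are therefore kept
// when they extend an optimum leftward; alignments never begin or end with
// an indel.  Cells track the start coordinates of their best path so no
// traceback is needed for classification; the single-pair entry point also
// records backtrace ops for reporting.

#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:  return -1;  // N etc.: mismatch against every barcode base
  }
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

struct Params {
  int match, mismatch, gap, run_bonus, run_min;
};

struct Aln {
  int score;              // <= 0: no alignment
  int rstart, rend;       // 1-based on target (read)
  int qstart, qend;       // 1-based on query (barcode)
  int end_layer;          // DP layer of the winning end cell
};

// backtrace op codes
enum { BT_NONE = 0, BT_DIAG = 1, BT_UP = 2, BT_LEFT = 3, BT_FRESH = 4 };

struct Workspace {
  int L, m, n;
  std::vector<int> H, SJ, SI;
  std::vector<signed char> OP, FR;  // op code, predecessor layer
  void resize(int L_, int m_, int n_) {
    L = L_; m = m_; n = n_;
    size_t sz = (size_t)L * (m + 1) * (n + 1);
    H.assign(sz, NEG); SJ.assign(sz, 0); SI.assign(sz, 0);
    OP.assign(sz, BT_NONE); FR.assign(sz, 0);
  }
  inline size_t at(int r, int i, int j) const {
    return ((size_t)r * (m + 1) + i) * (n + 1) + j;
  }
};

// candidate bookkeeping: keep (score, sj, si) lexicographically best
// (max score, then min sj, then min si); fixed op order breaks exact ties.
struct Cand {
  int h, sj, si; signed char op, fr;
  Cand() : h(NEG), sj(0), si(0), op(BT_NONE), fr(0) {}
  inline void offer(int h2, int sj2, int si2, signed char op2, signed char fr2) {
    if (h2 < 0) return;
    if (h2 > h || (h2 == h && (sj2 < sj || (sj2 == sj && si2 < si)))) {
      h = h2; sj = sj2; si = si2; op = op2; fr = fr2;
    }
  }
};

static Aln sw_core(const int* q, int m, const int* t, int n,
                   const Params& p, Workspace& ws) {
  Aln best; best.score = 0; best.rstart = best.rend = best.qstart = best.qend = 0;
  best.end_layer = 0;
  if (m == 0 || n == 0) return best;
  const int L = (p.run_bonus > 0) ? p.run_min + 1 : 1;
  const int cap = L - 1;
  ws.resize(L, m, n);

  int bh = 0, bsj = 0, bj = 0, bi = 0, bsi = 0, br = 0;
  bool have = false;

  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int tj = t[j - 1];
      const bool is_match = (qi >= 0 && qi == tj);
      const int s_diag = is_match ? p.match : p.mismatch;

      // gap moves close any trailing run -> layer 0 only
      {
        Cand c;
        for (int r = 0; r < L; ++r) {
          size_t u = ws.at(r, i - 1, j);
          if (ws.H[u] >= 0)
            c.offer(ws.H[u] + p.gap, ws.SJ[u], ws.SI[u], BT_UP, (signed char)r);
          size_t l = ws.at(r, i, j - 1);
          if (ws.H[l] >= 0)
            c.offer(ws.H[l] + p.gap, ws.SJ[l], ws.SI[l], BT_LEFT, (signed char)r);
        }
        if (!is_match) {
          // mismatch: diagonal into layer 0 from any layer
          for (int r = 0; r < L; ++r) {
            size_t d = ws.at(r, i - 1, j - 1);
            if (ws.H[d] >= 0)
              c.offer(ws.H[d] + s_diag, ws.SJ[d], ws.SI[d], BT_DIAG, (signed char)r);
          }
          if (s_diag >= 0) c.offer(s_diag, j, i, BT_FRESH, 0);
        } else if (L == 1) {
          // classic SW: matches live in the single layer too
          size_t d = ws.at(0, i - 1, j - 1);
          if (ws.H[d] >= 0)
            c.offer(ws.H[d] + s_diag, ws.SJ[d], ws.SI[d], BT_DIAG, 0);
          c.offer(s_diag, j, i, BT_FRESH, 0);
        }
        size_t k = ws.at(0, i, j);
        if (c.h >= 0) {
          ws.H[k] = c.h; ws.SJ[k] = c.sj; ws.SI[k] = c.si;
          ws.OP[k] = c.op; ws.FR[k] = c.fr;
          if (c.h > 0 && (!have || c.h > bh ||
              (c.h == bh && (c.sj < bsj || (c.sj == bsj && (j < bj ||
               (j == bj && (i < bi || (i == bi && c.si < bsi))))))))) {
            have = true; bh = c.h; bsj = c.sj; bj = j; bi = i; bsi = c.si; br = 0;
          }
        }
      }

      // match: layered transitions (only when run bonus is active)
      if (is_match && L > 1) {
        for (int r = 1; r <= cap; ++r) {
          Cand c;
          size_t d = ws.at(r - 1, i - 1, j - 1);
          int bonus = (r == cap) ? p.run_bonus : 0;
          if (ws.H[d] >= 0)
            c.offer(ws.H[d] + p.match + bonus, ws.SJ[d], ws.SI[d], BT_DIAG,
                    (signed char)(r - 1));
          if (r == cap) {
            size_t d2 = ws.at(cap, i - 1, j - 1);
            if (ws.H[d2] >= 0)
              c.offer(ws.H[d2] + p.match, ws.SJ[d2], ws.SI[d2], BT_DIAG,
                      (signed char)cap);
          }
          if (r == 1) c.offer(p.match, j, i, BT_FRESH, 0);
          size_t k = ws.at(r, i, j);
          if (c.h >= 0) {
            ws.H[k] = c.h; ws.SJ[k] = c.sj; ws.SI[k] = c.si;
            ws.OP[k] = c.op; ws.FR[k] = c.fr;
            if (c.h > 0 && (!have || c.h > bh ||
                (c.h == bh && (c.sj < bsj || (c.sj == bsj && (j < bj ||
                 (j == bj && (i < bi || (i == bi && c.si < bsi))))))))) {
              have = true; bh = c.h; bsj = c.sj; bj = j; bi = i; bsi = c.si; br = r;
            }
          }
        }
        // ensure layer 0 cell stays dead for matches when L > 1: nothing to do
      }
    }
  }

  if (!have) return best;
  best.score = bh; best.rstart = bsj; best.rend = bj;
  best.qstart = bsi; best.qend = bi; best.end_layer = br;
  return best;
}

static std::string traceback_ops(const int* q, int m, const int* t, int n,
                                 const Aln& a, const Workspace& ws, int end_layer) {
  std::string rev;
  int r = end_layer, i = a.qend, j = a.rend;
  while (i > 0 && j > 0) {
    size_t k = ws.at(r, i, j);
    signed char op = ws.OP[k], fr = ws.FR[k];
    if (op == BT_FRESH) {
      rev.push_back((q[i - 1] >= 0 && q[i - 1] == t[j - 1]) ? 'M' : 'X');
      break;
    } else if (op == BT_DIAG) {
      rev.push_back((q[i - 1] >= 0 && q[i - 1] == t[j - 1]) ? 'M' : 'X');
      --i; --j; r = fr;
    } else if (op == BT_UP) {
      rev.push_back('D');
      --i; r = fr;
    } else if (op == BT_LEFT) {
      rev.push_back('I');
      --j; r = fr;
    } else {
      break;  // dead cell: should not happen
    }
  }
  return std::string(rev.rbegin(), rev.rend());
}

// Lean two-row DP for the classic scheme (no run bonus, no traceback);
// identical scores/coordinates to sw_core, used by the batch scanner.
static Aln sw_fast_classic(const int* q, int m, const int* t, int n,
                           const Params& p,
                           std::vector<int>& h0, std::vector<int>& h1,
                           std::vector<int>& sj0, std::vector<int>& sj1,
                           std::vector<int>& si0, std::vector<int>& si1) {
  Aln best; best.score = 0; best.rstart = best.rend = 0;
  best.qstart = best.qend = 0; best.end_layer = 0;
  if (m == 0 || n == 0) return best;
  if ((int)h0.size() < n + 1) {
    h0.resize(n + 1); h1.resize(n + 1);
    sj0.resize(n + 1); sj1.resize(n + 1);
    si0.resize(n + 1); si1.resize(n + 1);
  }
  int* hp = h0.data(); int* hc = h1.data();
  int* sjp = sj0.data(); int* sjc = sj1.data();
  int* sip = si0.data(); int* sic = si1.data();
  for (int j = 0; j <= n; ++j) hp[j] = NEG;
  int bh = 0, bsj = 0, bj = 0, bi = 0, bsi = 0; bool have = false;
  for (int i = 1; i <= m; ++i) {
    const int qi = q[i - 1];
    hc[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      const int s = (qi >= 0 && qi == t[j - 1]) ? p.match : p.mismatch;
      int h = NEG, sj = 0, si = 0;
      if (hp[j - 1] >= 0) {                       // diag continue
        h = hp[j - 1] + s; sj = sjp[j - 1]; si = sip[j - 1];
      }
      if (s >= 0 && (s > h || (s == h && j < sj))) {  // fresh start
        h = s; sj = j; si = i;
      }
      if (hp[j] >= 0) {                           // up (barcode deletion)
        int h2 = hp[j] + p.gap;
        if (h2 > h || (h2 == h && (sjp[j] < sj ||
            (sjp[j] == sj && sip[j] < si)))) {
          h = h2; sj = sjp[j]; si = sip[j];
        }
      }
      if (hc[j - 1] >= 0) {                       // left (read insertion)
        int h2 = hc[j - 1] + p.gap;
        if (h2 > h || (h2 == h && (sjc[j - 1] < sj ||
            (sjc[j - 1] == sj && sic[j - 1] < si)))) {
          h = h2; sj = sjc[j - 1]; si = sic[j - 1];
        }
      }
      if (h < 0) { hc[j] = NEG; continue; }
      hc[j] = h; sjc[j] = sj; sic[j] = si;
      if (h > 0 && (!have || h > bh || (h == bh && (sj < bsj ||
          (sj == bsj && (j < bj || (j == bj && (i < bi ||
           (i == bi && si < bsi))))))))) {
        have = true; bh = h; bsj = sj; bj = j; bi = i; bsi = si;
      }
    }
    std::swap(hp, hc); std::swap(sjp, sjc); std::swap(sip, sic);
  }
  if (!have) return best;
  best.score = bh; best.rstart = bsj; best.rend = bj;
  best.qstart = bsi; best.qend = bi;
  return best;
}

static std::vector<int> encode_seq(const char* s, int len) {
  std::vector<int> v(len);
  for (int i = 0; i < len; ++i) v[i] = enc_base(s[i]);
  return v;
}

// [[Rcpp::export]]
List sw_align_pair_cpp(std::string query, std::string target,
                       int match, int mismatch, int gap,
                       int run_bonus, int run_min) {
  Params p{match, mismatch, gap, run_bonus, run_min};
  Workspace ws;
  std::vector<int> q = encode_seq(query.c_str(), (int)query.size());
  std::vector<int> t = encode_seq(target.c_str(), (int)target.size());
  Aln a = sw_core(q.data(), (int)q.size(), t.data(), (int)t.size(), p, ws);
  if (a.score <= 0)
    return List::create(_["score"] = 0);
  std::string ops = traceback_ops(q.data(), (int)q.size(), t.data(), (int)t.size(),
                                  a, ws, a.end_layer);
  return List::create(_["score"] = a.score,
                      _["read_start"] = a.rstart, _["read_end"] = a.rend,
                      _["barcode_start"] = a.qstart, _["barcode_end"] = a.qend,
                      _["ops"] = ops);
}

// Batch scan: every barcode (optionally also its reverse complement) against
// the first scan_window bases of every read.  Returns per-(read, barcode)
// best score and coordinates; score 0 marks "no positive alignment".
// [[Rcpp::export]]
List sw_scan_batch_cpp(CharacterVector reads, CharacterVector barcodes,
                       int scan_window, int match, int mismatch, int gap,
                       int run_bonus, int run_min, bool scan_revcomp) {
  const int nr = reads.size(), nb = barcodes.size();
  Params p{match, mismatch, gap, run_bonus, run_min};
  Workspace ws;

  std::vector<std::vector<int>> enc_bc(nb), enc_rc(nb);
  for (int b = 0; b < nb; ++b) {
    const char* s = CHAR(STRING_ELT(barcodes, b));
    int len = (int)LENGTH(STRING_ELT(barcodes, b));
    enc_bc[b] = encode_seq(s, len);
    if (scan_revcomp) {
      std::string rc(len, 'N');
      for (int i = 0; i < len; ++i) rc[i] = comp_char(s[len - 1 - i]);
      enc_rc[b] = encode_seq(rc.c_str(), len);
    }
  }

  const bool fast = (run_bonus <= 0);
  std::vector<int> h0, h1, sj0, sj1, si0, si1;
  IntegerMatrix score(nr, nb), rstart(nr, nb), rend(nr, nb), orient(nr, nb);
  for (int i = 0; i < nr; ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int len = (int)LENGTH(STRING_ELT(reads, i));
    int n = len < scan_window ? len : scan_window;
    std::vector<int> t = encode_seq(s, n);
    for (int b = 0; b < nb; ++b) {
      const int* bq = enc_bc[b].data();
      const int bm = (int)enc_bc[b].size();
      Aln a = fast ? sw_fast_classic(bq, bm, t.data(), n, p,
                                     h0, h1, sj0, sj1, si0, si1)
                   : sw_core(bq, bm, t.data(), n, p, ws);
      int ori = 0;
      if (scan_revcomp) {
        const int* rq = enc_rc[b].data();
        Aln a2 = fast ? sw_fast_classic(rq, bm, t.data(), n, p,
                                        h0, h1, sj0, sj1, si0, si1)
                      : sw_core(rq, bm, t.data(), n, p, ws);
        bool better = a2.score > a.score ||
          (a2.score == a.score && a2.score > 0 &&
           (a2.rstart < a.rstart ||
            (a2.rstart == a.rstart && a2.rend < a.rend)));
        if (better) { a = a2; ori = 1; }
      }
      if (a.score > 0) {
        score(i, b) = a.score; rstart(i, b) = a.rstart; rend(i, b) = a.rend;
        orient(i, b) = ori;
      } else {
        score(i, b) = 0; rstart(i, b) = NA_INTEGER; rend(i, b) = NA_INTEGER;
        orient(i, b) = NA_INTEGER;
      }
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["score"] = score, _["read_start"] = rstart,
                      _["read_end"] = rend, _["orient"] = orient);
}
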