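// Affine-gap local duplex alignment kernel.
//
// All routines align a query q against r = reverse(t) using a symmetric
// 5x5 pairing-score matrix over A,C,G,T,N, so that column (q[i], r[j])
// corresponds to the antiparallel duplex pair (q[i], t[|t|-1-j]).
// Gap convention: a gap run of length g costs gap_open + g * gap_extend
// (both negative), i.e. a length-1 gap costs gap_open + gap_extend.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const int NEG = -(1 << 29);

static inline int bidx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    case 'N': return 4;
    default:  return -1;
  }
}

struct Aln {
  int qs, qe, rs, re, score;
  std::string qrow, rrow;
};

// One full DP pass over q x r honouring used-position masks; returns the
// best local alignment (ties: smallest q start, then smallest mapped
// target start = |t| - r_end, i.e. largest r end).
static bool sw_pass(const std::string& q, const std::string& r,
                    const std::vector<int>& qi, const std::vector<int>& ri,
                    const IntegerMatrix& sub, int go, int ge,
                    const std::vector<char>& usedQ,
                    const std::vector<char>& usedR,
                    Aln& out) {
  const int n = (int)q.size(), m = (int)r.size();
  const size_t W = (size_t)(m + 1);
  std::vector<int> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  // traceback codes: H 0=stop,1=diag,2=E,3=F; E/F 0=open(from H),1=extend
  std::vector<unsigned char> tH((size_t)(n + 1) * W, 0),
      tE((size_t)(n + 1) * W, 0), tF((size_t)(n + 1) * W, 0);

  int best = 0;
  std::vector<std::pair<int, int> > ties;

  for (int i = 1; i <= n; ++i) {
    const bool uq = usedQ[i - 1] != 0;
    const int qb = qi[i - 1];
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const bool ur = usedR[j - 1] != 0;
      // E: gap in q consuming r[j-1]
      int e = NEG;
      unsigned char te = 0;
      if (!ur) {
        const int eo = H[row + j - 1] + go + ge;
        const int ex = (E[row + j - 1] <= NEG / 2) ? NEG : E[row + j - 1] + ge;
        if (ex > eo) { e = ex; te = 1; } else { e = eo; te = 0; }
      }
      E[row + j] = e; tE[row + j] = te;
      // F: gap in t consuming q[i-1]
      int f = NEG;
      unsigned char tf = 0;
      if (!uq) {
        const int fo = H[prow + j] + go + ge;
        const int fx = (F[prow + j] <= NEG / 2) ? NEG : F[prow + j] + ge;
        if (fx > fo) { f = fx; tf = 1; } else { f = fo; tf = 0; }
      }
      F[row + j] = f; tF[row + j] = tf;
      // H
      int d = NEG;
      if (!uq && !ur) d = H[prow + j - 1] + sub(qb, ri[j - 1]);
      int h = 0; unsigned char th = 0;
      if (d > h) { h = d; th = 1; }
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      H[row + j] = h; tH[row + j] = th;
      if (h > best) { best = h; ties.clear(); ties.push_back(std::make_pair(i, j)); }
      else if (h == best && best > 0 && ties.size() < 64)
        ties.push_back(std::make_pair(i, j));
    }
  }
  if (best <= 0) return false;

  // traceback each tied endpoint, keep smallest (q_start, |t|-r_end)
  bool have = false;
  for (size_t k = 0; k < ties.size(); ++k) {
    int i = ties[k].first, j = ties[k].second;
    const int re = j;
    std::string qa, ra;
    int state = 0;  // 0 = H, 1 = E, 2 = F
    while (true) {
      const size_t row = (size_t)i * W;
      if (state == 0) {
        const unsigned char c = tH[row + j];
        if (c == 0) break;
        if (c == 1) { qa.push_back(q[i - 1]); ra.push_back(r[j - 1]); --i; --j; }
        else if (c == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        const unsigned char c = tE[row + j];
        qa.push_back('-'); ra.push_back(r[j - 1]); --j;
        if (c == 0) state = 0;
      } else {
        const unsigned char c = tF[row + j];
        qa.push_back(q[i - 1]); ra.push_back('-'); --i;
        if (c == 0) state = 0;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ra.begin(), ra.end());
    Aln cand;
    cand.qs = i; cand.qe = ties[k].first;
    cand.rs = j; cand.re = re;
    cand.score = best; cand.qrow = qa; cand.rrow = ra;
    if (!have ||
        cand.qs < out.qs ||
        (cand.qs == out.qs && (m - cand.re) < (m - out.re))) {
      out = cand; have = true;
    }
  }
  return have;
}

// [[Rcpp::export(name = ".cpp_sw_all")]]
List cpp_sw_all(std::string q, std::string r, IntegerMatrix sub,
                int gap_open, int gap_extend, int min_score,
                int max_hits = 1000) {
  const int n = (int)q.size(), m = (int)r.size();
  std::vector<int> qi(n), ri(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = bidx(q[i]);
    if (qi[i] < 0) stop("invalid base in query: '%c'", q[i]);
  }
  for (int j = 0; j < m; ++j) {
    ri[j] = bidx(r[j]);
    if (ri[j] < 0) stop("invalid base in target: '%c'", r[j]);
  }
  std::vector<char> usedQ(n, 0), usedR(m, 0);
  List res;
  for (int it = 0; it < max_hits; ++it) {
    Aln a;
    if (!sw_pass(q, r, qi, ri, sub, gap_open, gap_extend, usedQ, usedR, a))
      break;
    if (a.score < min_score) break;
    for (int i = a.qs; i < a.qe; ++i) usedQ[i] = 1;
    for (int j = a.rs; j < a.re; ++j) usedR[j] = 1;
    res.push_back(List::create(
        _["qs"] = a.qs, _["qe"] = a.qe, _["rs"] = a.rs, _["re"] = a.re,
        _["score"] = a.score, _["qrow"] = a.qrow, _["rrow"] = a.rrow));
  }
  return res;
}

// Best local score only (no traceback, rolling rows) — calibration workhorse.
// [[Rcpp::export(name = ".cpp_sw_best")]]
int cpp_sw_best(std::string q, std::string r, IntegerMatrix sub,
                int gap_open, int gap_extend) {
  const int n = (int)q.size(), m = (int)r.size();
  std::vector<int> qi(n), ri(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = bidx(q[i]);
    if (qi[i] < 0) stop("invalid base in query: '%c'", q[i]);
  }
  for (int j = 0; j < m; ++j) {
    ri[j] = bidx(r[j]);
    if (ri[j] < 0) stop("invalid base in target: '%c'", r[j]);
  }
  std::vector<int> Hp(m + 1, 0), H(m + 1, 0), E(m + 1, NEG), Fp(m + 1, NEG),
      F(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    H[0] = 0; E[0] = NEG; F[0] = NEG;
    int e = NEG;
    const int qb = qi[i - 1];
    for (int j = 1; j <= m; ++j) {
      const int eo = H[j - 1] + gap_open + gap_extend;
      e = std::max(eo, (e <= NEG / 2) ? NEG : e + gap_extend);
      const int fo = Hp[j] + gap_open + gap_extend;
      F[j] = std::max(fo, (Fp[j] <= NEG / 2) ? NEG : Fp[j] + gap_extend);
      int h = Hp[j - 1] + sub(qb, ri[j - 1]);
      if (h < 0) h = 0;
      if (e > h) h = e;
      if (F[j] > h) h = F[j];
      H[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hp, H);
    std::swap(Fp, F);
  }
  return best;
}

// TRUE iff some diagonal carries a gapless run of positively-scoring
// pairing columns with total score >= seed_score. Any local alignment with
// score above min(-mismatch, -(gap_open+gap_extend)) must contain such a
// run, which makes this a complete search trigger.
// [[Rcpp::export(name = ".cpp_seed_scan")]]
bool cpp_seed_scan(std::string q, std::string r, IntegerMatrix sub,
                   int seed_score) {
  const int n = (int)q.size(), m = (int)r.size();
  std::vector<int> qi(n), ri(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = bidx(q[i]);
    if (qi[i] < 0) stop("invalid base in query: '%c'", q[i]);
  }
  for (int j = 0; j < m; ++j) {
    ri[j] = bidx(r[j]);
    if (ri[j] < 0) stop("invalid base in target: '%c'", r[j]);
  }
  for (int d = -(m - 1); d < n; ++d) {
    int i = std::max(0, d), j = i - d;
    int run = 0;
    for (; i < n && j < m; ++i, ++j) {
      const int s = sub(qi[i], ri[j]);
      if (s > 0) {
        run += s;
        if (run >= seed_score) return true;
      } else {
        run = 0;
      }
    }
  }
  return false;
}
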