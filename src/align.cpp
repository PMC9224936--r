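#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap pairwise alignment (Smith-Waterman / Needleman-Wunsch).
// Gap cost convention: a gap run of length L costs gap_open + L * gap_extend
// (NCBI BLAST semantics for "11/1").
//
// Deterministic tie-breaks, applied during traceback:
//   residue pair (state M) > deletion (query residue vs gap, state D)
//   > insertion (gap vs subject residue, state I) > local restart.
// For local alignment the best cell is the one with maximal score; ties are
// resolved toward the smallest query index, then the smallest subject index.

static const double NEG_BIG = -1e30; // effective -infinity; never reachable

struct AlignOut {
  double score;
  std::vector<int> qpos; // 0 = gap
  std::vector<int> spos;
};

// Reusable aligner: flat substitution table + letter lookup + DP buffers.
struct Aligner {
  int nl; // number of letters
  std::vector<double> smat;
  int lut[256];
  double go, ge, open;
  std::vector<double> M, D, I;
  std::vector<unsigned char> tbM, tbD, tbI;

  Aligner(const NumericMatrix& sub, double gap_open, double gap_extend)
      : go(gap_open), ge(gap_extend), open(gap_open + gap_extend) {
    nl = sub.nrow();
    smat.resize(nl * nl);
    for (int a = 0; a < nl; ++a)
      for (int b = 0; b < nl; ++b) smat[a * nl + b] = sub(a, b);
    for (int i = 0; i < 256; ++i) lut[i] = -1;
    CharacterVector rn = rownames(sub);
    for (int k = 0; k < rn.size(); ++k) {
      std::string s = as<std::string>(rn[k]);
      lut[(unsigned char)s[0]] = k;
    }
  }

  int code(char c) const {
    int v = lut[(unsigned char)c];
    if (v < 0) stop("residue '%s' not present in the scoring matrix",
                    std::string(1, c).c_str());
    return v;
  }

  AlignOut align(const std::string& q, const std::string& s, bool local) {
    const int n = (int)q.size(), m = (int)s.size();
    std::vector<int> qi(n), si(m);
    for (int i = 0; i < n; ++i) qi[i] = code(q[i]);
    for (int j = 0; j < m; ++j) si[j] = code(s[j]);

    const size_t W = (size_t)(m + 1), sz = (size_t)(n + 1) * W;
    M.assign(sz, NEG_BIG); D.assign(sz, NEG_BIG); I.assign(sz, NEG_BIG);
    tbM.assign(sz, 3); tbD.assign(sz, 0); tbI.assign(sz, 0);

    M[0] = 0.0;
    if (!local) {
      for (int i = 1; i <= n; ++i) { D[i * W] = -(go + ge * i); tbD[i * W] = (i == 1) ? 0 : 1; }
      for (int j = 1; j <= m; ++j) { I[j] = -(go + ge * j); tbI[j] = (j == 1) ? 0 : 2; }
    }

    double best = 0.0; int bi = -1, bj = -1;

    for (int i = 1; i <= n; ++i) {
      const double* srow = &smat[qi[i - 1] * nl];
      double *Mr = &M[i * W], *Dr = &D[i * W], *Ir = &I[i * W];
      const double *Mp = &M[(i - 1) * W], *Dp = &D[(i - 1) * W],
                   *Ip = &I[(i - 1) * W];
      unsigned char *tMr = &tbM[i * W], *tDr = &tbD[i * W], *tIr = &tbI[i * W];
      for (int j = 1; j <= m; ++j) {
        // M: preference M > D > I > (local restart)
        double pm = Mp[j - 1], pd = Dp[j - 1], pi = Ip[j - 1];
        double bestp; unsigned char tb;
        if (pm >= pd && pm >= pi) { bestp = pm; tb = 0; }
        else if (pd >= pi)        { bestp = pd; tb = 1; }
        else                      { bestp = pi; tb = 2; }
        if (local && 0.0 > bestp) { bestp = 0.0; tb = 3; }
        Mr[j] = bestp + srow[si[j - 1]];
        tMr[j] = tb;

        // D: consume query residue i (gap in subject); preference M > D > I
        double dm = Mp[j] - open, dd = Dp[j] - ge, di = Ip[j] - open;
        if (dm >= dd && dm >= di) { Dr[j] = dm; tDr[j] = 0; }
        else if (dd >= di)        { Dr[j] = dd; tDr[j] = 1; }
        else                      { Dr[j] = di; tDr[j] = 2; }

        // I: consume subject residue j; preference M > I > D
        double im = Mr[j - 1] - open, id = Dr[j - 1] - open, ii = Ir[j - 1] - ge;
        if (im >= id && im >= ii) { Ir[j] = im; tIr[j] = 0; }
        else if (ii >= id)        { Ir[j] = ii; tIr[j] = 2; }
        else                      { Ir[j] = id; tIr[j] = 1; }

        if (local && Mr[j] > best) { best = Mr[j]; bi = i; bj = j; }
      }
    }

    AlignOut out;
    std::vector<int> rq, rs;
    int i, j, state;
    if (local) {
      if (bi < 0 || best <= 0.0) { out.score = 0.0; return out; }
      out.score = best; i = bi; j = bj; state = 0;
    } else {
      const size_t c = (size_t)n * W + m;
      double fm = M[c], fd = D[c], fi = I[c];
      if (n == 0 && m == 0) { out.score = 0.0; return out; }
      if (fm >= fd && fm >= fi) { out.score = fm; state = 0; }
      else if (fd >= fi)        { out.score = fd; state = 1; }
      else                      { out.score = fi; state = 2; }
      i = n; j = m;
    }

    while (i > 0 || j > 0) {
      const size_t c = (size_t)i * W + j;
      if (state == 0) {
        unsigned char tb = tbM[c];
        rq.push_back(i); rs.push_back(j);
        --i; --j;
        if (local && tb == 3) break; // local restart
        state = tb;
      } else if (state == 1) {
        unsigned char tb = tbD[c];
        rq.push_back(i); rs.push_back(0);
        --i;
        state = tb;
      } else {
        unsigned char tb = tbI[c];
        rq.push_back(0); rs.push_back(j);
        --j;
        state = tb;
      }
    }
    out.qpos.assign(rq.rbegin(), rq.rend());
    out.spos.assign(rs.rbegin(), rs.rend());
    return out;
  }
};

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string query, std::string subject, NumericMatrix sub,
                      double gap_open, double gap_extend, bool local) {
  Aligner al(sub, gap_open, gap_extend);
  AlignOut out = al.align(query, subject, local);
  return List::create(_["score"] = out.score,
                      _["q_pos"] = IntegerVector(out.qpos.begin(), out.qpos.end()),
                      _["s_pos"] = IntegerVector(out.spos.begin(), out.spos.end()));
}

// Profile score of one candidate against the anchor-coordinate PSSM:
// global alignment candidate<->anchor, then sum of column log-odds over
// residue-residue columns whose anchor position is retained in the profile;
// every gap column adds gap_penalty; dropped or unknown (X) columns add 0.
static double profile_score_one(Aligner& al, const std::string& cand,
                                const std::string& anchor,
                                const IntegerVector& colmap,
                                const NumericMatrix& colscores,
                                const int* lut20, double gap_penalty) {
  AlignOut path = al.align(cand, anchor, false);
  double sc = 0.0;
  for (size_t k = 0; k < path.qpos.size(); ++k) {
    int qi = path.qpos[k], sj = path.spos[k];
    if (qi > 0 && sj > 0) {
      int col = colmap[sj - 1];
      if (col > 0) {
        int li = lut20[(unsigned char)cand[qi - 1]];
        if (li >= 0) sc += colscores(li, col - 1); // X and friends score 0
      }
    } else {
      sc += gap_penalty;
    }
  }
  return sc;
}

static void build_lut20(const NumericMatrix& colscores, int* lut20) {
  for (int i = 0; i < 256; ++i) lut20[i] = -1;
  CharacterVector rn = rownames(colscores);
  for (int k = 0; k < rn.size(); ++k) {
    std::string s = as<std::string>(rn[k]);
    lut20[(unsigned char)s[0]] = k;
  }
}

// [[Rcpp::export(name = ".profile_score_cpp")]]
double profile_score_cpp(std::string cand, std::string anchor, NumericMatrix sub,
                         double gap_open, double gap_extend, IntegerVector colmap,
                         NumericMatrix colscores, double gap_penalty) {
  Aligner al(sub, gap_open, gap_extend);
  int lut20[256];
  build_lut20(colscores, lut20);
  return profile_score_one(al, cand, anchor, colmap, colscores, lut20,
                           gap_penalty);
}

// Permutation null: scores of n_perm uniform residue shuffles of the
// candidate, each re-aligned to the anchor. Uses R's RNG (set.seed-driven).
// [[Rcpp::export(name = ".perm_profile_scores_cpp")]]
NumericVector perm_profile_scores_cpp(std::string cand, std::string anchor,
                                      NumericMatrix sub, double gap_open,
                                      double gap_extend, IntegerVector colmap,
                                      NumericMatrix colscores, double gap_penalty,
                                      int n_perm) {
  Aligner al(sub, gap_open, gap_extend);
  int lut20[256];
  build_lut20(colscores, lut20);
  RNGScope scope;
  NumericVector out(n_perm);
  std::string sh = cand;
  const int L = (int)sh.size();
  for (int r = 0; r < n_perm; ++r) {
    // Fisher-Yates
    for (int i = L - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(sh[i], sh[j]);
    }
    out[r] = profile_score_one(al, sh, anchor, colmap, colscores, lut20,
                               gap_penalty);
    if ((r & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
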