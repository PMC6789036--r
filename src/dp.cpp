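// Dynamic-programming kernels: global pairwise alignment (affine gaps),
// profile-profile alignment for the progressive aligner, and the Plan7-style
// local multi-hit Viterbi / Forward recursions of the profile-HMM engine.
// All scoring conventions (tie-breaking order, gap costs, log2 score space)
// are fixed here so results are deterministic across platforms.

#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log2(2^a + 2^b) without overflow
static inline double logsum2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a < b) std::swap(a, b);
  return a + std::log1p(std::exp2(b - a)) / M_LN2;
}

// ---------------------------------------------------------------------------
// Global Needleman-Wunsch with affine gaps.
// Residue codes are 1-based: 1..20 amino acids, 21 = X. `smat` is a 21 x 21
// score matrix. Ties are broken diagonal > up (gap in b) > left (gap in a).
// Returns the alignment score, the number of identical non-X aligned pairs,
// and both aligned code vectors (0 = gap).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix smat,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  // three layers: 0 = M (diag), 1 = X-gap in b (consume a, "up"),
  // 2 = Y-gap in a (consume b, "left")
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GA((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GB((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbA((n + 1) * (m + 1), -1);
  std::vector<signed char> tbB((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    GA[idx(i, 0)] = gap_open + (i - 1) * gap_extend;
    tbA[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    GB[idx(0, j)] = gap_open + (j - 1) * gap_extend;
    tbB[idx(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = smat(a[i - 1] - 1, b[j - 1] - 1);
      // M: from M, GA, GB at (i-1, j-1); ties prefer M then GA then GB
      double best = M[idx(i - 1, j - 1)];
      signed char arg = 0;
      if (GA[idx(i - 1, j - 1)] > best) { best = GA[idx(i - 1, j - 1)]; arg = 1; }
      if (GB[idx(i - 1, j - 1)] > best) { best = GB[idx(i - 1, j - 1)]; arg = 2; }
      M[idx(i, j)] = best + s;
      tbM[idx(i, j)] = arg;
      // GA (gap in b, consume a): open from M, extend from GA
      double oa = M[idx(i - 1, j)] + gap_open;
      double ea = GA[idx(i - 1, j)] + gap_extend;
      if (oa >= ea) { GA[idx(i, j)] = oa; tbA[idx(i, j)] = 0; }
      else          { GA[idx(i, j)] = ea; tbA[idx(i, j)] = 1; }
      // GB (gap in a, consume b)
      double ob = M[idx(i, j - 1)] + gap_open;
      double eb = GB[idx(i, j - 1)] + gap_extend;
      if (ob >= eb) { GB[idx(i, j)] = ob; tbB[idx(i, j)] = 0; }
      else          { GB[idx(i, j)] = eb; tbB[idx(i, j)] = 2; }
    }
  }

  double score = M[idx(n, m)];
  int layer = 0;
  if (GA[idx(n, m)] > score) { score = GA[idx(n, m)]; layer = 1; }
  if (GB[idx(n, m)] > score) { score = GB[idx(n, m)]; layer = 2; }

  std::vector<int> ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      signed char prev = tbM[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; layer = prev;
    } else if (layer == 1) {
      signed char prev = tbA[idx(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(0);
      --i; layer = prev;
    } else {
      signed char prev = tbB[idx(i, j)];
      ra.push_back(0); rb.push_back(b[j - 1]);
      --j; layer = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] > 0 && ra[k] == rb[k] && ra[k] != 21) ++matches;
  }
  return List::create(_["score"] = score, _["matches"] = matches,
                      _["a"] = wrap(ra), _["b"] = wrap(rb));
}

// ---------------------------------------------------------------------------
// Profile-profile alignment for the progressive aligner. `pa` and `pb` are
// 20 x nA / 20 x nB column frequency profiles (column sums equal the non-gap
// occupancy of the column). Column pair score is the expected BLOSUM62 value
// sum_{x,y} pa(x,i) pb(y,j) B62(x,y). Affine gap costs, ties broken
// diagonal > up (gap column in B) > left.
// Returns a move vector (1 = aligned pair, 2 = gap in B, 3 = gap in A).
// [[Rcpp::export(name = ".profile_align_cpp")]]
IntegerVector profile_align_cpp(NumericMatrix pa, NumericMatrix pb,
                                NumericMatrix smat20,
                                double gap_open, double gap_extend) {
  const int n = pa.ncol(), m = pb.ncol();
  // precompute ua = t(smat) %*% pa : 20 x n
  NumericMatrix ua(20, n);
  for (int i = 0; i < n; ++i) {
    for (int y = 0; y < 20; ++y) {
      double s = 0.0;
      for (int x = 0; x < 20; ++x) s += pa(x, i) * smat20(x, y);
      ua(y, i) = s;
    }
  }
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GA((n + 1) * (m + 1), NEG_INF);
  std::vector<double> GB((n + 1) * (m + 1), NEG_INF);
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbA((n + 1) * (m + 1), -1);
  std::vector<signed char> tbB((n + 1) * (m + 1), -1);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    GA[idx(i, 0)] = gap_open + (i - 1) * gap_extend;
    tbA[idx(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    GB[idx(0, j)] = gap_open + (j - 1) * gap_extend;
    tbB[idx(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = 0.0;
      for (int y = 0; y < 20; ++y) s += ua(y, i - 1) * pb(y, j - 1);
      double best = M[idx(i - 1, j - 1)];
      signed char arg = 0;
      if (GA[idx(i - 1, j - 1)] > best) { best = GA[idx(i - 1, j - 1)]; arg = 1; }
      if (GB[idx(i - 1, j - 1)] > best) { best = GB[idx(i - 1, j - 1)]; arg = 2; }
      M[idx(i, j)] = best + s;
      tbM[idx(i, j)] = arg;
      double oa = M[idx(i - 1, j)] + gap_open;
      double ea = GA[idx(i - 1, j)] + gap_extend;
      if (oa >= ea) { GA[idx(i, j)] = oa; tbA[idx(i, j)] = 0; }
      else          { GA[idx(i, j)] = ea; tbA[idx(i, j)] = 1; }
      double ob = M[idx(i, j - 1)] + gap_open;
      double eb = GB[idx(i, j - 1)] + gap_extend;
      if (ob >= eb) { GB[idx(i, j)] = ob; tbB[idx(i, j)] = 0; }
      else          { GB[idx(i, j)] = eb; tbB[idx(i, j)] = 2; }
    }
  }
  double score = M[idx(n, m)];
  int layer = 0;
  if (GA[idx(n, m)] > score) { score = GA[idx(n, m)]; layer = 1; }
  if (GB[idx(n, m)] > score) { score = GB[idx(n, m)]; layer = 2; }
  std::vector<int> moves;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      signed char prev = tbM[idx(i, j)];
      moves.push_back(1); --i; --j; layer = prev;
    } else if (layer == 1) {
      signed char prev = tbA[idx(i, j)];
      moves.push_back(2); --i; layer = prev;
    } else {
      signed char prev = tbB[idx(i, j)];
      moves.push_back(3); --j; layer = prev;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}

// ---------------------------------------------------------------------------
// Plan7-style local alignment DP. All inputs are precomputed log2 scores:
//   msc:  M x 21 match emission log-odds (column 21 = X, scored 0)
//   tmm/tmi/tmd/tim/tii/tdm/tdd: per-node transition scores, node k entry is
//     the transition *leaving* node k (1-based; k = M entries are -Inf where
//     the transition does not exist)
//   tbm:  entry scores B->M_k; tme: exit scores M_k->E
//   loop: N/C/J self-loop; move_nb/move_jb/move_ct: N->B, J->B, C->T
//   ej/ec: E->J and E->C
// Insert and flanking emissions are background (score 0). Returns the
// log-odds of the best path; with `traceback`, also the state path as a
// 3-column matrix (type, node, residue index) with type codes
// 1=N 2=B 3=M 4=I 5=D 6=E 7=J 8=C.
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(NumericMatrix msc,
                 NumericVector tmm, NumericVector tmi, NumericVector tmd,
                 NumericVector tim, NumericVector tii,
                 NumericVector tdm, NumericVector tdd,
                 NumericVector tbm, NumericVector tme,
                 IntegerVector seq,
                 double loop, double move_nb, double move_jb, double move_ct,
                 double ej, double ec,
                 bool traceback) {
  const int M = msc.nrow();
  const int L = seq.size();
  std::vector<double> vM(M + 1, NEG_INF), vI(M + 1, NEG_INF), vD(M + 1, NEG_INF);
  std::vector<double> pM(M + 1, NEG_INF), pI(M + 1, NEG_INF), pD(M + 1, NEG_INF);
  double vN, vB, vE, vJ, vC;

  // traceback stores: for each i,k the chosen predecessor
  // cM: 0=B 1=M 2=I 3=D ; cI: 0=M 1=I ; cD: 0=M 1=D
  // cE: argmax node k ; cJ: 0=J 1=E ; cC: 0=C 1=E ; cB: 0=N 1=J
  std::vector<signed char> cM, cI, cD, cJ, cC, cB;
  std::vector<int> cE;
  if (traceback) {
    cM.assign((size_t)(L + 1) * (M + 1), -1);
    cI.assign((size_t)(L + 1) * (M + 1), -1);
    cD.assign((size_t)(L + 1) * (M + 1), -1);
    cJ.assign(L + 1, -1); cC.assign(L + 1, -1); cB.assign(L + 1, -1);
    cE.assign(L + 1, -1);
  }
  auto cidx = [M](int i, int k) { return (size_t)i * (M + 1) + k; };

  vN = 0.0;
  vB = vN + move_nb;
  vE = NEG_INF; vJ = NEG_INF; vC = NEG_INF;
  if (traceback) cB[0] = 0;
  double prevN = vN, prevB = vB, prevJ = vJ, prevC = vC;

  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1]; // 1..21
    std::swap(pM, vM); std::swap(pI, vI); std::swap(pD, vD);
    std::fill(vM.begin(), vM.end(), NEG_INF);
    std::fill(vI.begin(), vI.end(), NEG_INF);
    std::fill(vD.begin(), vD.end(), NEG_INF);
    double curE = NEG_INF; int argE = -1;
    for (int k = 1; k <= M; ++k) {
      // M state
      double best = prevB + tbm[k - 1];
      signed char arg = 0;
      if (k > 1) {
        double v = pM[k - 1] + tmm[k - 2];
        if (v > best) { best = v; arg = 1; }
        v = pI[k - 1] + tim[k - 2];
        if (v > best) { best = v; arg = 2; }
        v = pD[k - 1] + tdm[k - 2];
        if (v > best) { best = v; arg = 3; }
      }
      vM[k] = best + msc(k - 1, x - 1);
      if (traceback) cM[cidx(i, k)] = arg;
      // I state (emits at background, score 0)
      double vi = pM[k] + tmi[k - 1];
      signed char argi = 0;
      double v2 = pI[k] + tii[k - 1];
      if (v2 > vi) { vi = v2; argi = 1; }
      vI[k] = vi;
      if (traceback) cI[cidx(i, k)] = argi;
      // D state (no emission; uses current column)
      if (k > 1) {
        double vd = vM[k - 1] + tmd[k - 2];
        signed char argd = 0;
        double v3 = vD[k - 1] + tdd[k - 2];
        if (v3 > vd) { vd = v3; argd = 1; }
        vD[k] = vd;
        if (traceback) cD[cidx(i, k)] = argd;
      }
      double ve = vM[k] + tme[k - 1];
      if (ve > curE) { curE = ve; argE = k; }
    }
    vE = curE;
    if (traceback) cE[i] = argE;
    // specials
    double jj = prevJ + loop, je = vE + ej;
    if (jj >= je) { vJ = jj; if (traceback) cJ[i] = 0; }
    else          { vJ = je; if (traceback) cJ[i] = 1; }
    double ccx = prevC + loop, ce = vE + ec;
    if (ccx >= ce) { vC = ccx; if (traceback) cC[i] = 0; }
    else           { vC = ce;  if (traceback) cC[i] = 1; }
    vN = prevN + loop;
    double bn = vN + move_nb, bj = vJ + move_jb;
    if (bn >= bj) { vB = bn; if (traceback) cB[i] = 0; }
    else          { vB = bj; if (traceback) cB[i] = 1; }
    prevN = vN; prevB = vB; prevJ = vJ; prevC = vC;
    if (traceback) {
      // store layer values needed for path reconstruction of M/I/D at i
      // (already stored via cM/cI/cD); specials stored above
    }
  }
  double score = vC + move_ct;

  List out = List::create(_["score"] = score);
  if (!traceback || score == NEG_INF) {
    if (traceback) out["path"] = IntegerMatrix(0, 3);
    return out;
  }

  // Reconstruct path. We need per-i values of M/I/D to know where E came
  // from; the choice arrays alone suffice because every choice is recorded.
  std::vector<int> ptype, pnode, ppos;
  int i = L;
  int state = 8; // C
  int k = 0;
  // walk backwards; 'i' is the number of residues consumed so far
  while (!(state == 1 && i == 0)) {
    ptype.push_back(state); pnode.push_back(k); ppos.push_back(i);
    switch (state) {
    case 8: { // C: emits on self-loop arrival
      signed char ch = cC[i];
      if (ch == 0) { state = 8; --i; } else { state = 6; }
      break;
    }
    case 7: { // J
      signed char ch = cJ[i];
      if (ch == 0) { state = 7; --i; } else { state = 6; }
      break;
    }
    case 6: { // E
      state = 3; k = cE[i];
      break;
    }
    case 3: { // M emitted residue i at node k
      signed char ch = cM[cidx(i, k)];
      if (ch == 0) { state = 2; --i; k = 0; }
      else if (ch == 1) { state = 3; --i; --k; }
      else if (ch == 2) { state = 4; --i; --k; }
      else { state = 5; --i; --k; }
      break;
    }
    case 4: { // I emitted residue i at node k
      signed char ch = cI[cidx(i, k)];
      if (ch == 0) { state = 3; --i; }
      else { state = 4; --i; }
      break;
    }
    case 5: { // D at node k, column i
      signed char ch = cD[cidx(i, k)];
      if (ch == 0) { state = 3; --k; }
      else { state = 5; --k; }
      break;
    }
    case 2: { // B at position i
      signed char ch = cB[i];
      k = 0;
      if (ch == 0) { state = 1; }
      else { state = 7; }
      break;
    }
    case 1: { // N: emits on self-loop arrival
      state = 1; --i;
      break;
    }
    }
  }
  ptype.push_back(1); pnode.push_back(0); ppos.push_back(0);
  const int np = ptype.size();
  IntegerMatrix path(np, 3);
  for (int r = 0; r < np; ++r) {
    path(r, 0) = ptype[np - 1 - r];
    path(r, 1) = pnode[np - 1 - r];
    path(r, 2) = ppos[np - 1 - r];
  }
  out["path"] = path;
  return out;
}

// Forward (log-sum over all paths) under the same parameterization.
// [[Rcpp::export(name = ".forward_cpp")]]
double forward_cpp(NumericMatrix msc,
                   NumericVector tmm, NumericVector tmi, NumericVector tmd,
                   NumericVector tim, NumericVector tii,
                   NumericVector tdm, NumericVector tdd,
                   NumericVector tbm, NumericVector tme,
                   IntegerVector seq,
                   double loop, double move_nb, double move_jb, double move_ct,
                   double ej, double ec) {
  const int M = msc.nrow();
  const int L = seq.size();
  std::vector<double> vM(M + 1, NEG_INF), vI(M + 1, NEG_INF), vD(M + 1, NEG_INF);
  std::vector<double> pM(M + 1, NEG_INF), pI(M + 1, NEG_INF), pD(M + 1, NEG_INF);
  double vN = 0.0;
  double vB = vN + move_nb;
  double vE = NEG_INF, vJ = NEG_INF, vC = NEG_INF;
  double prevN = vN, prevB = vB, prevJ = vJ, prevC = vC;
  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    std::swap(pM, vM); std::swap(pI, vI); std::swap(pD, vD);
    std::fill(vM.begin(), vM.end(), NEG_INF);
    std::fill(vI.begin(), vI.end(), NEG_INF);
    std::fill(vD.begin(), vD.end(), NEG_INF);
    double curE = NEG_INF;
    for (int k = 1; k <= M; ++k) {
      double acc = prevB + tbm[k - 1];
      if (k > 1) {
        acc = logsum2(acc, pM[k - 1] + tmm[k - 2]);
        acc = logsum2(acc, pI[k - 1] + tim[k - 2]);
        acc = logsum2(acc, pD[k - 1] + tdm[k - 2]);
      }
      vM[k] = acc + msc(k - 1, x - 1);
      vI[k] = logsum2(pM[k] + tmi[k - 1], pI[k] + tii[k - 1]);
      if (k > 1) {
        vD[k] = logsum2(vM[k - 1] + tmd[k - 2], vD[k - 1] + tdd[k - 2]);
      }
      curE = logsum2(curE, vM[k] + tme[k - 1]);
    }
    vE = curE;
    vJ = logsum2(prevJ + loop, vE + ej);
    vC = logsum2(prevC + loop, vE + ec);
    vN = prevN + loop;
    vB = logsum2(vN + move_nb, vJ + move_jb);
    prevN = vN; prevB = vB; prevJ = vJ; prevC = vC;
  }
  return vC + move_ct;
}
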