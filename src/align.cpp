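#include <Rcpp.h>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh, three-state).
// A gap run of length L costs gap_open + L * gap_extend (BLAST convention).
// States: M (residue-residue column), E (gap in query, consumes subject),
// F (gap in subject, consumes query). All inter-state transitions allowed.
// Tie-breaks are fixed: predecessors preferred M > E > F, and the best local
// cell is the one with the smallest subject end, then smallest query end.

static const int NEG = std::numeric_limits<int>::min() / 4;

struct LookupTable {
  int idx[256];
  LookupTable(const std::vector<std::string> &letters) {
    for (int i = 0; i < 256; ++i) idx[i] = -1;
    for (size_t k = 0; k < letters.size(); ++k)
      idx[(unsigned char)letters[k][0]] = (int)k;
  }
  int operator()(char c) const {
    int v = idx[(unsigned char)c];
    if (v < 0) stop("residue '%s' not present in substitution matrix",
                    std::string(1, c).c_str());
    return v;
  }
};

// pointer codes: 0 = stop/start, 1 = from M, 2 = from E, 3 = from F
static inline int best3(int m, int e, int f, int &ptr) {
  // preference M > E > F on ties
  int b = m; ptr = 1;
  if (e > b) { b = e; ptr = 2; }
  if (f > b) { b = f; ptr = 3; }
  return b;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string query, std::string subject,
                    IntegerMatrix smat, CharacterVector letters,
                    int gap_open, int gap_extend,
                    bool local, bool traceback) {
  int m = (int)query.size(), n = (int)subject.size();
  if (m == 0 || n == 0) stop("empty sequence in alignment");
  std::vector<std::string> lets(letters.size());
  for (int k = 0; k < letters.size(); ++k) lets[k] = as<std::string>(letters[k]);
  LookupTable lut(lets);
  std::vector<int> qi(m), sj(n);
  for (int i = 0; i < m; ++i) qi[i] = lut(query[i]);
  for (int j = 0; j < n; ++j) sj[j] = lut(subject[j]);

  int go = gap_open, ge = gap_extend;
  std::vector<int> M((m + 1) * (n + 1), NEG), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  // pointer matrices only if traceback requested
  std::vector<unsigned char> pM, pE, pF;
  if (traceback) {
    pM.assign((m + 1) * (n + 1), 0);
    pE.assign((m + 1) * (n + 1), 0);
    pF.assign((m + 1) * (n + 1), 0);
  }
  const int W = n + 1;
  M[0] = 0;
  if (!local) {
    for (int j = 1; j <= n; ++j) {
      E[j] = -(go + j * ge);
      if (traceback) pE[j] = (j == 1) ? 1 : 2;
    }
    for (int i = 1; i <= m; ++i) {
      F[i * W] = -(go + i * ge);
      if (traceback) pF[i * W] = (i == 1) ? 1 : 3;
    }
  } else {
    for (int j = 1; j <= n; ++j) M[j] = 0;
    for (int i = 1; i <= m; ++i) M[i * W] = 0;
  }

  int best = local ? 0 : NEG, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int c = i * W + j, up = (i - 1) * W + j, lf = c - 1, dg = up - 1;
      int s = smat(qi[i - 1], sj[j - 1]);
      int ptr;
      // M
      int from = best3(M[dg], E[dg], F[dg], ptr);
      int mval = (from <= NEG / 2) ? NEG : from + s;
      if (local && s >= mval) { mval = s; ptr = 0; } // fresh local start
      if (local && mval < 0) { mval = NEG; }
      M[c] = mval;
      if (traceback) pM[c] = (unsigned char)ptr;
      // E: gap in query, consume subject (move left)
      {
        int a = (M[lf] <= NEG / 2) ? NEG : M[lf] - go - ge;
        int b = (E[lf] <= NEG / 2) ? NEG : E[lf] - ge;
        int d = (F[lf] <= NEG / 2) ? NEG : F[lf] - go - ge;
        int p; E[c] = best3(a, b, d, p);
        if (traceback) pE[c] = (unsigned char)p;
      }
      // F: gap in subject, consume query (move up)
      {
        int a = (M[up] <= NEG / 2) ? NEG : M[up] - go - ge;
        int b = (F[up] <= NEG / 2) ? NEG : F[up] - ge;
        int d = (E[up] <= NEG / 2) ? NEG : E[up] - go - ge;
        int p; int v = a; p = 1;
        if (d > v) { v = d; p = 2; }
        if (b > v) { v = b; p = 3; }
        F[c] = v;
        if (traceback) pF[c] = (unsigned char)p;
      }
      if (local && M[c] > best) { best = M[c]; bi = i; bj = j; }
      // ties keep the earlier (smaller j, then smaller i) cell: row-major
      // scan with strict '>' already prefers smaller i; enforce smaller j
      // within a row by strict '>' as well (first hit wins).
    }
  }

  int score, state = 1;
  if (local) {
    score = best;
    // re-scan for deterministic tie-break: smallest subject end, then query end
    for (int j = 1; j <= n && best > 0; ++j) {
      for (int i = 1; i <= m; ++i) {
        if (M[i * W + j] == best) { bi = i; bj = j; j = n + 1; break; }
      }
    }
  } else {
    bi = m; bj = n;
    int p;
    score = best3(M[m * W + n], E[m * W + n], F[m * W + n], p);
    state = p;
  }

  List out = List::create(_["score"] = score);
  if (!traceback) {
    if (local) { out["qend"] = bi; out["send"] = bj; }
    return out;
  }

  std::string qa, sa;
  int i = bi, j = bj, st = local ? 1 : state;
  if (local && score == 0) {
    out["qstart"] = 0; out["qend"] = 0; out["sstart"] = 0; out["send"] = 0;
    out["qaln"] = ""; out["saln"] = "";
    return out;
  }
  while (i > 0 || j > 0) {
    int c = i * W + j;
    if (st == 1) { // M
      int p = pM[c];
      qa.push_back(query[i - 1]); sa.push_back(subject[j - 1]);
      --i; --j;
      if (local && p == 0) break;
      if (!local && i == 0 && j == 0) break;
      st = p;
    } else if (st == 2) { // E: gap in query
      int p = pE[c];
      qa.push_back('-'); sa.push_back(subject[j - 1]);
      --j;
      if (!local && i == 0 && j == 0) break;
      st = p;
    } else { // F: gap in subject
      int p = pF[c];
      qa.push_back(query[i - 1]); sa.push_back('-');
      --i;
      if (!local && i == 0 && j == 0) break;
      st = p;
    }
    if (!local && (i == 0 && j == 0)) break;
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  out["qstart"] = local ? (i + 1) : 1;
  out["qend"] = bi;
  out["sstart"] = local ? (j + 1) : 1;
  out["send"] = bj;
  out["qaln"] = qa;
  out["saln"] = sa;
  return out;
}

// Best local score of one query against each of many subjects (score only).
// [[Rcpp::export(name = ".sw_scores_cpp")]]
List sw_scores_cpp(std::string query, CharacterVector subjects,
                   IntegerMatrix smat, CharacterVector letters,
                   int gap_open, int gap_extend) {
  int m = (int)query.size();
  std::vector<std::string> lets(letters.size());
  for (int k = 0; k < letters.size(); ++k) lets[k] = as<std::string>(letters[k]);
  LookupTable lut(lets);
  std::vector<int> qi(m);
  for (int i = 0; i < m; ++i) qi[i] = lut(query[i]);
  int go = gap_open, ge = gap_extend;
  int N = subjects.size();
  IntegerVector scores(N);
  // rolling two-row Gotoh, score only
  for (int s = 0; s < N; ++s) {
    std::string subj = as<std::string>(subjects[s]);
    int n = (int)subj.size();
    if (n == 0 || m == 0) { scores[s] = 0; continue; }
    std::vector<int> sj(n);
    for (int j = 0; j < n; ++j) sj[j] = lut(subj[j]);
    std::vector<int> Mp(n + 1, 0), Ep(n + 1, NEG), Fp(n + 1, NEG);
    std::vector<int> Mc(n + 1, 0), Ec(n + 1, NEG), Fc(n + 1, NEG);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      Mc[0] = 0; Ec[0] = NEG; Fc[0] = NEG;
      const int *srow = &smat(qi[i - 1], 0);
      int ncolmat = smat.nrow();
      for (int j = 1; j <= n; ++j) {
        int sc = srow[(size_t)sj[j - 1] * ncolmat];
        int dg = std::max(Mp[j - 1], std::max(Ep[j - 1], Fp[j - 1]));
        int mval = (dg <= NEG / 2 ? NEG : dg + sc);
        if (sc >= mval) mval = sc;
        if (mval < 0) mval = 0;
        Mc[j] = mval;
        int a = (Mc[j - 1] <= NEG / 2) ? NEG : Mc[j - 1] - go - ge;
        int b = (Ec[j - 1] <= NEG / 2) ? NEG : Ec[j - 1] - ge;
        int d = (Fc[j - 1] <= NEG / 2) ? NEG : Fc[j - 1] - go - ge;
        Ec[j] = std::max(a, std::max(b, d));
        a = (Mp[j] <= NEG / 2) ? NEG : Mp[j] - go - ge;
        b = (Fp[j] <= NEG / 2) ? NEG : Fp[j] - ge;
        d = (Ep[j] <= NEG / 2) ? NEG : Ep[j] - go - ge;
        Fc[j] = std::max(a, std::max(b, d));
        if (Mc[j] > best) best = Mc[j];
      }
      std::swap(Mp, Mc); std::swap(Ep, Ec); std::swap(Fp, Fc);
    }
    scores[s] = best;
  }
  return List::create(_["score"] = scores);
}
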