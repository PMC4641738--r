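#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Gotoh affine-gap local alignment over protein sequences.
// Gap of length k scores gap_open + k * gap_extend (both negative), the
// NCBI existence/extension convention (-11/-1 => a length-1 gap costs 12).

namespace {

// letter -> row index of the substitution matrix; -1 for letters absent
std::vector<int> build_lut(const IntegerMatrix& sub) {
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(sub);
  for (int i = 0; i < rn.size(); ++i) {
    std::string ch = as<std::string>(rn[i]);
    if (ch.size() != 1) stop("substitution matrix row names must be single letters");
    lut[static_cast<unsigned char>(ch[0])] = i;
  }
  return lut;
}

std::vector<int> encode(const std::string& s, const std::vector<int>& lut) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int v = lut[static_cast<unsigned char>(s[i])];
    if (v < 0)
      stop("residue '%s' not covered by the substitution matrix",
           std::string(1, s[i]).c_str());
    out[i] = v;
  }
  return out;
}

int sw_score_rows(const std::vector<int>& q, const std::vector<int>& s,
                  const int* sub, int nrow, int go, int ge) {
  const int n = static_cast<int>(s.size());
  const int m = static_cast<int>(q.size());
  if (m == 0 || n == 0) return 0;
  const int NEG = INT_MIN / 4;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> E(n + 1, NEG);   // gap in query (consumes subject)
  std::vector<int> F(n + 1, NEG);   // gap in subject (consumes query)
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0;
    E[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(Hcur[j - 1] + go + ge, E[j - 1] + ge);
      F[j] = std::max(Hprev[j] + go + ge, F[j] + ge);
      int h = Hprev[j - 1] + sub[q[i - 1] + s[j - 1] * nrow];
      if (E[j] > h) h = E[j];
      if (F[j] > h) h = F[j];
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

}  // namespace

// [[Rcpp::export(name = ".sw_score_matrix_c")]]
IntegerMatrix sw_score_matrix_c(CharacterVector queries, CharacterVector subjects,
                                IntegerMatrix sub, int gap_open, int gap_extend) {
  std::vector<int> lut = build_lut(sub);
  const int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<int>> qs(nq), ss(ns);
  for (int i = 0; i < nq; ++i) qs[i] = encode(as<std::string>(queries[i]), lut);
  for (int j = 0; j < ns; ++j) ss[j] = encode(as<std::string>(subjects[j]), lut);
  std::vector<int> flat(sub.begin(), sub.end());
  const int nrow = sub.nrow();
  IntegerMatrix out(nq, ns);
  for (int i = 0; i < nq; ++i)
    for (int j = 0; j < ns; ++j)
      out(i, j) = sw_score_rows(qs[i], ss[j], flat.data(), nrow,
                                gap_open, gap_extend);
  return out;
}

// Full-matrix alignment with traceback. Among co-optimal alignments returns
// the one with smallest query start, then smallest subject start (ties beyond
// that: smallest end coordinates). Traceback prefers diagonal, then gap in
// subject, then gap in query.
// [[Rcpp::export(name = ".sw_traceback_c")]]
List sw_traceback_c(std::string query, std::string subject, IntegerMatrix sub,
                    int gap_open, int gap_extend) {
  std::vector<int> lut = build_lut(sub);
  std::vector<int> q = encode(query, lut), s = encode(subject, lut);
  const int m = static_cast<int>(q.size()), n = static_cast<int>(s.size());
  const int NEG = INT_MIN / 4;
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int>> F(m + 1, std::vector<int>(n + 1, NEG));
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[i][j] = std::max(H[i][j - 1] + gap_open + gap_extend,
                         E[i][j - 1] + gap_extend);
      F[i][j] = std::max(H[i - 1][j] + gap_open + gap_extend,
                         F[i - 1][j] + gap_extend);
      int h = H[i - 1][j - 1] + sub(q[i - 1], s[j - 1]);
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best) best = h;
    }
  }
  if (best <= 0)
    return List::create(_["score"] = 0, _["q_start"] = NA_INTEGER,
                        _["q_end"] = NA_INTEGER, _["s_start"] = NA_INTEGER,
                        _["s_end"] = NA_INTEGER, _["matches"] = 0,
                        _["aln_length"] = 0);

  // trace one end cell back to its start; returns (qs, ss, matches, len)
  auto trace = [&](int ei, int ej, int& qs_, int& ss_, int& mat, int& len) {
    int i = ei, j = ej;
    mat = 0; len = 0;
    int state = 0;  // 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    while (true) {
      if (state == 0) {
        if (H[i][j] == 0) break;
        int diag = H[i - 1][j - 1] + sub(q[i - 1], s[j - 1]);
        if (H[i][j] == diag) {
          if (q[i - 1] == s[j - 1] && query[i - 1] != 'X') ++mat;
          --i; --j; ++len;
        } else if (H[i][j] == F[i][j]) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 2) {  // gap consuming query row i
        ++len;
        if (F[i][j] == H[i - 1][j] + gap_open + gap_extend) { --i; state = 0; }
        else { --i; }
      } else {  // E: gap consuming subject column j
        ++len;
        if (E[i][j] == H[i][j - 1] + gap_open + gap_extend) { --j; state = 0; }
        else { --j; }
      }
      if (i == 0 || j == 0) break;
    }
    qs_ = i + 1;
    ss_ = j + 1;
  };

  int bi = -1, bj = -1, bqs = INT_MAX, bss = INT_MAX, bmat = 0, blen = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (H[i][j] != best) continue;
      int qs_, ss_, mat, len;
      trace(i, j, qs_, ss_, mat, len);
      bool better = false;
      if (qs_ < bqs) better = true;
      else if (qs_ == bqs && ss_ < bss) better = true;
      else if (qs_ == bqs && ss_ == bss && (bi < 0 || i < bi || (i == bi && j < bj)))
        better = true;
      if (better) {
        bi = i; bj = j; bqs = qs_; bss = ss_; bmat = mat; blen = len;
      }
    }
  }
  return List::create(_["score"] = best, _["q_start"] = bqs, _["q_end"] = bi,
                      _["s_start"] = bss, _["s_end"] = bj, _["matches"] = bmat,
                      _["aln_length"] = blen);
}
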