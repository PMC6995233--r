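#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine gap convention throughout (BLAST-style): a gap of length L costs
// gap_open + L * gap_extend.

static const int NEG_INF = -1000000000;

inline int subst(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N' || x == 'X' || y == 'X') return mismatch;
  return (x == y) ? match : mismatch;
}

// Needleman-Wunsch / Gotoh global alignment.
// Tie-break in traceback: diagonal > gap in a > gap in b.
// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  size_t W = (size_t)(m + 1);
  std::vector<int> M((n + 1) * W, NEG_INF), Ia((n + 1) * W, NEG_INF),
      Ib((n + 1) * W, NEG_INF);
  M[0] = 0;
  for (int j = 1; j <= m; ++j) Ia[j] = -(gap_open + j * gap_extend);
  for (int i = 1; i <= n; ++i) Ib[i * W] = -(gap_open + i * gap_extend);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
             l = i * W + (j - 1);
      int s = subst(a[i - 1], b[j - 1], match, mismatch);
      int best = M[d];
      if (Ia[d] > best) best = Ia[d];
      if (Ib[d] > best) best = Ib[d];
      M[c] = (best <= NEG_INF / 2) ? NEG_INF : best + s;
      int open = std::max(M[l], Ib[l]);
      Ia[c] = std::max(open <= NEG_INF / 2 ? NEG_INF : open - gap_open - gap_extend,
                       Ia[l] <= NEG_INF / 2 ? NEG_INF : Ia[l] - gap_extend);
      open = std::max(M[u], Ia[u]);
      Ib[c] = std::max(open <= NEG_INF / 2 ? NEG_INF : open - gap_open - gap_extend,
                       Ib[u] <= NEG_INF / 2 ? NEG_INF : Ib[u] - gap_extend);
    }
  }
  size_t e = (size_t)n * W + m;
  int score = std::max(M[e], std::max(Ia[e], Ib[e]));
  // traceback; state 0 = M, 1 = Ia (gap in a), 2 = Ib (gap in b)
  int state = (M[e] == score) ? 0 : (Ia[e] == score ? 1 : 2);
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (i == 0) state = 1;
    else if (j == 0) state = 2;
    if (state == 0) {
      size_t d = (size_t)(i - 1) * W + (j - 1);
      int s = subst(a[i - 1], b[j - 1], match, mismatch);
      ra += a[i - 1]; rb += b[j - 1];
      int prev = M[c] - s;
      state = (M[d] == prev) ? 0 : (Ia[d] == prev ? 1 : 2);
      --i; --j;
    } else if (state == 1) {
      size_t l = (size_t)i * W + (j - 1);
      ra += '-'; rb += b[j - 1];
      if (M[l] == Ia[c] + gap_open + gap_extend) state = 0;
      else if (Ia[l] == Ia[c] + gap_extend) state = 1;
      else state = 2;
      --j;
    } else {
      size_t u = (size_t)(i - 1) * W + j;
      ra += a[i - 1]; rb += '-';
      if (M[u] == Ib[c] + gap_open + gap_extend) state = 0;
      else if (Ia[u] == Ib[c] + gap_open + gap_extend) state = 1;
      else state = 2;
      --i;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}

// Smith-Waterman local alignment with affine gaps. Returns the single best
// alignment; ties resolved toward the smallest subject (b) end coordinate,
// then the smallest query (a) end coordinate.
// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_extend) {
  int n = a.size(), m = b.size();
  size_t W = (size_t)(m + 1);
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, NEG_INF),
      F((n + 1) * W, NEG_INF);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
             l = i * W + (j - 1);
      int e = std::max(H[l] - gap_open - gap_extend,
                       E[l] <= NEG_INF / 2 ? NEG_INF : E[l] - gap_extend);
      int f = std::max(H[u] - gap_open - gap_extend,
                       F[u] <= NEG_INF / 2 ? NEG_INF : F[u] - gap_extend);
      E[c] = e; F[c] = f;
      int h = H[d] + subst(a[i - 1], b[j - 1], match, mismatch);
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[c] = h;
      if (h > best || (h == best && (j < bj || (j == bj && i < bi)))) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
  }
  if (best == 0)
    return List::create(_["score"] = 0);
  // traceback from (bi, bj)
  std::string ra, rb;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      if (H[c] == 0) break;
      size_t d = (size_t)(i - 1) * W + (j - 1);
      int s = subst(a[i - 1], b[j - 1], match, mismatch);
      if (H[c] == H[d] + s) {
        ra += a[i - 1]; rb += b[j - 1]; --i; --j;
      } else if (H[c] == E[c]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      size_t c2 = (size_t)i * W + j, l = (size_t)i * W + (j - 1);
      ra += '-'; rb += b[j - 1];
      if (E[c2] == H[l] - gap_open - gap_extend) state = 0;
      --j;
    } else {
      size_t c2 = (size_t)i * W + j, u = (size_t)(i - 1) * W + j;
      ra += a[i - 1]; rb += '-';
      if (F[c2] == H[u] - gap_open - gap_extend) state = 0;
      --i;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["aligned_a"] = ra, _["aligned_b"] = rb);
}

// Exact shared words of length k between a (query) and b (subject),
// skipping words containing anything outside ACGT. Returns a two-column
// matrix of 1-based (query position, subject position) pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_find_seeds(std::string a, std::string b, int k) {
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  int n = a.size(), m = b.size();
  std::unordered_map<uint64_t, std::vector<int> > idx;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t h = 0; int run = 0;
  for (int j = 0; j < m; ++j) {
    int c = code(b[j]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | c) & mask;
    if (++run >= k) idx[h].push_back(j - k + 2);  // 1-based start
  }
  std::vector<int> qs, ss;
  h = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    int c = code(a[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | c) & mask;
    if (++run >= k) {
      auto it = idx.find(h);
      if (it != idx.end())
        for (int sp : it->second) { qs.push_back(i - k + 2); ss.push_back(sp); }
    }
  }
  IntegerMatrix out(qs.size(), 2);
  for (size_t r = 0; r < qs.size(); ++r) { out(r, 0) = qs[r]; out(r, 1) = ss[r]; }
  colnames(out) = CharacterVector::create("qpos", "spos");
  return out;
}
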