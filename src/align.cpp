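#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh three-state DP).
// A gap of length L costs gap_open + L * gap_extend. Traceback tie-breaking
// is deterministic: prefer the diagonal (match) state, then a gap in the
// second sequence (up), then a gap in the first (left).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string a, std::string b,
                      NumericMatrix sub, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // residue -> matrix index lookup
  std::vector<int> idx(256, -1);
  CharacterVector rn = rownames(sub);
  for (int k = 0; k < rn.size(); ++k) {
    std::string s = as<std::string>(rn[k]);
    if (s.size() == 1) idx[(unsigned char)s[0]] = k;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = idx[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' not in substitution table",
                        std::string(1, a[i]).c_str());
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = idx[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' not in substitution table",
                        std::string(1, b[j]).c_str());
  }

  const double open = gap_open + gap_extend;  // cost of the first gap column
  const int W = m + 1;
  // states: 0 = M (diagonal), 1 = Ix (gap in b, consume a, "up"),
  //         2 = Iy (gap in a, consume b, "left")
  std::vector<double> M((n + 1) * W, NEG_INF), Ix((n + 1) * W, NEG_INF),
      Iy((n + 1) * W, NEG_INF);
  // predecessor state per cell per state
  std::vector<signed char> pM((n + 1) * W, -1), pIx((n + 1) * W, -1),
      pIy((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[i * W] = -(gap_open + i * gap_extend);
    pIx[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[j] = -(gap_open + j * gap_extend);
    pIy[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, cd = (i - 1) * W + (j - 1),
                cu = (i - 1) * W + j, cl = i * W + (j - 1);
      // M: preference M > Ix > Iy on ties
      double best = M[cd]; signed char st = 0;
      if (Ix[cd] > best) { best = Ix[cd]; st = 1; }
      if (Iy[cd] > best) { best = Iy[cd]; st = 2; }
      M[c] = best + sub(ai[i - 1], bi[j - 1]);
      pM[c] = st;
      // Ix (consume a)
      best = M[cu] - open; st = 0;
      if (Ix[cu] - gap_extend > best) { best = Ix[cu] - gap_extend; st = 1; }
      if (Iy[cu] - open > best) { best = Iy[cu] - open; st = 2; }
      Ix[c] = best; pIx[c] = st;
      // Iy (consume b)
      best = M[cl] - open; st = 0;
      if (Ix[cl] - open > best) { best = Ix[cl] - open; st = 1; }
      if (Iy[cl] - gap_extend > best) { best = Iy[cl] - gap_extend; st = 2; }
      Iy[c] = best; pIy[c] = st;
    }
  }

  const int end = n * W + m;
  double score = M[end]; int state = 0;
  if (Ix[end] > score) { score = Ix[end]; state = 1; }
  if (Iy[end] > score) { score = Iy[end]; state = 2; }

  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      state = pIx[c]; --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      state = pIy[c]; --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());

  return List::create(_["aligned_a"] = ga, _["aligned_b"] = gb,
                      _["score"] = score);
}
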