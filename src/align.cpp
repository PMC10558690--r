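#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Needleman-Wunsch-Gotoh) with a fixed,
// deterministic tie-break: substitution (M) is preferred over a gap in the
// homolog row (Ix, query residue consumed) which is preferred over a gap in
// the query row (Iy, homolog residue consumed).
//
// A gap run of length g scores gap_open + (g - 1) * gap_ext; both penalties
// are supplied as (non-positive) scores, not costs.
//
// qx / hy are 0-based indices into the substitution matrix.
// Returns the optimal score plus aligned index vectors in which gap columns
// are encoded as NA.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(IntegerVector qx, IntegerVector hy, NumericMatrix sub,
                 double gap_open, double gap_ext) {
  const int n = qx.size(), m = hy.size();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF);
  std::vector<double> Ix((n + 1) * W, NEG_INF);
  std::vector<double> Iy((n + 1) * W, NEG_INF);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) Ix[i * W] = gap_open + (i - 1) * gap_ext;
  for (int j = 1; j <= m; ++j) Iy[j] = gap_open + (j - 1) * gap_ext;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1);
      const int u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = sub(qx[i - 1], hy[j - 1]);
      M[c] = s + std::max(M[d], std::max(Ix[d], Iy[d]));
      Ix[c] = std::max(M[u] + gap_open,
                       std::max(Ix[u] + gap_ext, Iy[u] + gap_open));
      Iy[c] = std::max(M[l] + gap_open,
                       std::max(Iy[l] + gap_ext, Ix[l] + gap_open));
    }
  }

  const int end = n * W + m;
  double best = std::max(M[end], std::max(Ix[end], Iy[end]));

  // traceback; preference order M > Ix > Iy resolves every tie
  int state;  // 0 = M, 1 = Ix, 2 = Iy
  if (M[end] >= best) state = 0;
  else if (Ix[end] >= best) state = 1;
  else state = 2;
  if (n == 0) state = 2;
  if (m == 0) state = 1;

  std::vector<int> qa, ha;  // reversed aligned indices, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    if (j == 0) state = 1;
    if (state == 0) {
      qa.push_back(i); ha.push_back(j);
      const int d = (i - 1) * W + (j - 1);
      double v = std::max(M[d], std::max(Ix[d], Iy[d]));
      if (M[d] >= v) state = 0;
      else if (Ix[d] >= v) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      qa.push_back(i); ha.push_back(0);
      const int u = (i - 1) * W + j;
      double v = Ix[i * W + j];
      if (M[u] + gap_open >= v) state = 0;
      else if (Ix[u] + gap_ext >= v) state = 1;
      else state = 2;
      --i;
    } else {
      qa.push_back(0); ha.push_back(j);
      const int l = i * W + (j - 1);
      double v = Iy[i * W + j];
      if (M[l] + gap_open >= v) state = 0;
      else if (Iy[l] + gap_ext >= v) state = 2;
      else state = 1;
      --j;
    }
  }

  const int len = qa.size();
  IntegerVector qout(len), hout(len);
  for (int t = 0; t < len; ++t) {
    qout[t] = qa[len - 1 - t] == 0 ? NA_INTEGER : qa[len - 1 - t];
    hout[t] = ha[len - 1 - t] == 0 ? NA_INTEGER : ha[len - 1 - t];
  }
  return List::create(_["score"] = best, _["query_idx"] = qout,
                      _["homolog_idx"] = hout);
}
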