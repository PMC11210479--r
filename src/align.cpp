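#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP).
//
// A gap of length k costs gap_open + k * gap_extend. States: M (match),
// X (gap in b, consumes a, "up"), Y (gap in a, consumes b, "left").
// Transitions between the two gap states reopen a gap. Traceback is
// deterministic with the fixed preference M > X > Y (diagonal > up > left)
// applied both to the final state and to every predecessor choice.
//
// Returns the optimal score and the column path as an integer vector with
// codes 0 = diagonal, 1 = up (gap in b), 2 = left (gap in a), ordered from
// the start of the alignment.
// [[Rcpp::export]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double openc = gap_open + gap_extend;

  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // predecessor state per cell/state: 0=M,1=X,2=Y, -1 boundary
  std::vector<signed char> pm((n + 1) * (m + 1), -1), px((n + 1) * (m + 1), -1),
      py((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(gap_open + i * gap_extend);
    px[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(gap_open + j * gap_extend);
    py[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1] - 1, b[j - 1] - 1);
      // M: from any state diagonally, preference M > X > Y on ties
      {
        double best = M[at(i - 1, j - 1)];
        signed char arg = 0;
        if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; arg = 1; }
        if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; arg = 2; }
        M[at(i, j)] = best + s;
        pm[at(i, j)] = arg;
      }
      // X: consume a[i-1], gap in b
      {
        double vM = M[at(i - 1, j)] - openc;
        double vX = X[at(i - 1, j)] - gap_extend;
        double vY = Y[at(i - 1, j)] - openc;
        double best = vM; signed char arg = 0;
        if (vX > best) { best = vX; arg = 1; }
        if (vY > best) { best = vY; arg = 2; }
        X[at(i, j)] = best;
        px[at(i, j)] = arg;
      }
      // Y: consume b[j-1], gap in a
      {
        double vM = M[at(i, j - 1)] - openc;
        double vX = X[at(i, j - 1)] - openc;
        double vY = Y[at(i, j - 1)] - gap_extend;
        double best = vM; signed char arg = 0;
        if (vX > best) { best = vX; arg = 1; }
        if (vY > best) { best = vY; arg = 2; }
        Y[at(i, j)] = best;
        py[at(i, j)] = arg;
      }
    }
  }

  double score = M[at(n, m)];
  int state = 0;
  if (X[at(n, m)] > score) { score = X[at(n, m)]; state = 1; }
  if (Y[at(n, m)] > score) { score = Y[at(n, m)]; state = 2; }

  std::vector<int> path;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      path.push_back(0);
      state = pm[at(i, j)];
      --i; --j;
    } else if (state == 1) {
      path.push_back(1);
      state = px[at(i, j)];
      --i;
    } else {
      path.push_back(2);
      state = py[at(i, j)];
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
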