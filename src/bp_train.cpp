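#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Full-batch gradient descent with classical momentum on a 1-hidden-layer
// network: u = sigmoid(v1 x + b1), yhat = act(w2 u + b2).
// X: nSamples x nIn, Y: nSamples x nOut. Objective E = 0.5 * sum((Y-Yhat)^2).
// Stops before the update as soon as E < targetError.
// [[Rcpp::export]]
List cpp_bp_train(NumericMatrix v1_, NumericVector b1_, NumericMatrix w2_,
                  NumericVector b2_, NumericMatrix X, NumericMatrix Y,
                  double lr, double momentum, int maxEpochs,
                  double targetError, bool linearOutput) {
  const int nh = v1_.nrow(), ni = v1_.ncol(), no = w2_.nrow(), ns = X.nrow();
  std::vector<double> v1(v1_.begin(), v1_.end()), b1(b1_.begin(), b1_.end());
  std::vector<double> w2(w2_.begin(), w2_.end()), b2(b2_.begin(), b2_.end());
  std::vector<double> mv1(v1.size(), 0.0), mb1(b1.size(), 0.0);
  std::vector<double> mw2(w2.size(), 0.0), mb2(b2.size(), 0.0);
  std::vector<double> U(nh * ns), Yh(no * ns), dZ(no * ns), dU(nh * ns);
  std::vector<double> gv1(v1.size()), gb1(b1.size()), gw2(w2.size()), gb2(b2.size());
  std::vector<double> hist;
  hist.reserve(maxEpochs + 1);
  bool converged = false;
  int updates = 0;
  double E = R_PosInf;

  for (int ep = 0; ep <= maxEpochs; ++ep) {
    // forward
    for (int s = 0; s < ns; ++s) {
      for (int h = 0; h < nh; ++h) {
        double a = b1[h];
        for (int i = 0; i < ni; ++i) a += v1[h + nh * i] * X(s, i);
        U[h + nh * s] = sigm(a);
      }
      for (int o = 0; o < no; ++o) {
        double a = b2[o];
        for (int h = 0; h < nh; ++h) a += w2[o + no * h] * U[h + nh * s];
        Yh[o + no * s] = linearOutput ? a : sigm(a);
      }
    }
    E = 0.0;
    for (int s = 0; s < ns; ++s)
      for (int o = 0; o < no; ++o) {
        double r = Yh[o + no * s] - Y(s, o);
        E += 0.5 * r * r;
      }
    hist.push_back(E);
    if (!std::isfinite(E))
      stop("training diverged (non-finite error) at epoch %d", ep);
    if (E < targetError) { converged = true; break; }
    if (ep == maxEpochs) break;

    // backward (full batch)
    std::fill(gv1.begin(), gv1.end(), 0.0);
    std::fill(gb1.begin(), gb1.end(), 0.0);
    std::fill(gw2.begin(), gw2.end(), 0.0);
    std::fill(gb2.begin(), gb2.end(), 0.0);
    for (int s = 0; s < ns; ++s) {
      for (int o = 0; o < no; ++o) {
        double r = Yh[o + no * s] - Y(s, o);
        double d = linearOutput ? r : r * Yh[o + no * s] * (1.0 - Yh[o + no * s]);
        dZ[o + no * s] = d;
        gb2[o] += d;
        for (int h = 0; h < nh; ++h) gw2[o + no * h] += d * U[h + nh * s];
      }
      for (int h = 0; h < nh; ++h) {
        double acc = 0.0;
        for (int o = 0; o < no; ++o) acc += w2[o + no * h] * dZ[o + no * s];
        double d = acc * U[h + nh * s] * (1.0 - U[h + nh * s]);
        dU[h + nh * s] = d;
        gb1[h] += d;
        for (int i = 0; i < ni; ++i) gv1[h + nh * i] += d * X(s, i);
      }
    }
    for (size_t k = 0; k < v1.size(); ++k) { mv1[k] = momentum * mv1[k] - lr * gv1[k]; v1[k] += mv1[k]; }
    for (size_t k = 0; k < b1.size(); ++k) { mb1[k] = momentum * mb1[k] - lr * gb1[k]; b1[k] += mb1[k]; }
    for (size_t k = 0; k < w2.size(); ++k) { mw2[k] = momentum * mw2[k] - lr * gw2[k]; w2[k] += mw2[k]; }
    for (size_t k = 0; k < b2.size(); ++k) { mb2[k] = momentum * mb2[k] - lr * gb2[k]; b2[k] += mb2[k]; }
    ++updates;
  }

  NumericMatrix ov1(nh, ni), ow2(no, nh);
  std::copy(v1.begin(), v1.end(), ov1.begin());
  std::copy(w2.begin(), w2.end(), ow2.begin());
  return List::create(_["v1"] = ov1, _["b1"] = NumericVector(b1.begin(), b1.end()),
                      _["w2"] = ow2, _["b2"] = NumericVector(b2.begin(), b2.end()),
                      _["errors"] = NumericVector(hist.begin(), hist.end()),
                      _["epochs"] = updates, _["finalError"] = E,
                      _["converged"] = converged);
}

// Connected-component labeling of all cells equal to classLabel,
// 4- or 8-connectivity, BFS. Returns 0 for non-class cells, 1..k patch ids
// in discovery (row-major) order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_patches(IntegerMatrix grid, int classLabel,
                                int connectivity) {
  const int nr = grid.nrow(), nc = grid.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (grid(i, j) != classLabel || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + nr * j);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int ci = cur % nr, cj = cur / nr;
        for (int d = 0; d < nd; ++d) {
          int ii = ci + dr[d], jj = cj + dc[d];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (grid(ii, jj) == classLabel && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            stack.push_back(ii + nr * jj);
          }
        }
      }
    }
  return lab;
}
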