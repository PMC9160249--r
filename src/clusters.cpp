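#include <Rcpp.h>
using namespace Rcpp;

// Spatio-temporal connected components over a channel x time grid.
// Points are adjacent when they share a channel at consecutive time samples
// or are neighbouring channels at the same time sample, and carry the same
// sign. Point index (0-based): c + t * nchan, matching R's column-major
// channel x time matrices.

static const double TCLAMP = 1e12;

static int label_grid(const std::vector<signed char> &state, int nchan,
                      int ntime, const std::vector<std::vector<int>> &adj,
                      std::vector<int> &labels) {
  std::fill(labels.begin(), labels.end(), 0);
  int nlab = 0;
  std::vector<int> stack;
  const int np = nchan * ntime;
  for (int p0 = 0; p0 < np; ++p0) {
    if (state[p0] == 0 || labels[p0] != 0) continue;
    ++nlab;
    labels[p0] = nlab;
    stack.push_back(p0);
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      int c = p % nchan, t = p / nchan;
      signed char s = state[p];
      if (t > 0) {
        int q = p - nchan;
        if (state[q] == s && labels[q] == 0) { labels[q] = nlab; stack.push_back(q); }
      }
      if (t < ntime - 1) {
        int q = p + nchan;
        if (state[q] == s && labels[q] == 0) { labels[q] = nlab; stack.push_back(q); }
      }
      for (size_t k = 0; k < adj[c].size(); ++k) {
        int q = adj[c][k] + t * nchan;
        if (state[q] == s && labels[q] == 0) { labels[q] = nlab; stack.push_back(q); }
      }
    }
  }
  return nlab;
}

static std::vector<std::vector<int>> adj_from_list(List adj_list) {
  int nchan = adj_list.size();
  std::vector<std::vector<int>> adj(nchan);
  for (int c = 0; c < nchan; ++c) {
    IntegerVector v = adj_list[c];
    adj[c] = std::vector<int>(v.begin(), v.end());
  }
  return adj;
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_clusters(IntegerMatrix sign_mask, List adj_list) {
  int nchan = sign_mask.nrow(), ntime = sign_mask.ncol();
  std::vector<signed char> state(nchan * ntime);
  for (int i = 0; i < nchan * ntime; ++i)
    state[i] = (signed char)sign_mask[i];
  std::vector<int> labels(nchan * ntime);
  std::vector<std::vector<int>> adj = adj_from_list(adj_list);
  label_grid(state, nchan, ntime, adj, labels);
  IntegerMatrix out(nchan, ntime);
  for (int i = 0; i < nchan * ntime; ++i) out[i] = labels[i];
  return out;
}

// Sign-flip permutation null for the paired cluster-mass test.
// D: participants x points matrix of condition differences (points ordered
// channel-fastest). Returns nperm x 2 matrix: per permutation, the maximum
// |sum of t| over positive clusters (col 0) and negative clusters (col 1)
// meeting the minimum-electrode rule; 0 when no such cluster. Uses R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_perm_null(NumericMatrix D, int nchan, int ntime,
                            List adj_list, double tcrit, int nperm,
                            int min_electrodes) {
  const int n = D.nrow(), np = D.ncol();
  if (np != nchan * ntime) stop("point count mismatch");
  std::vector<std::vector<int>> adj = adj_from_list(adj_list);
  std::vector<double> sq(np, 0.0);
  for (int p = 0; p < np; ++p) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += D(i, p) * D(i, p);
    sq[p] = s;
  }
  std::vector<double> tval(np);
  std::vector<signed char> state(np);
  std::vector<int> labels(np);
  std::vector<double> flip(n);
  NumericMatrix out(nperm, 2);
  RNGScope scope;
  for (int b = 0; b < nperm; ++b) {
    for (int i = 0; i < n; ++i) flip[i] = (unif_rand() < 0.5) ? 1.0 : -1.0;
    for (int p = 0; p < np; ++p) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += flip[i] * D(i, p);
      double m = s / n;
      double v = (sq[p] - n * m * m) / (n - 1);
      double t;
      if (v <= 0.0) t = (m == 0.0) ? 0.0 : (m > 0 ? TCLAMP : -TCLAMP);
      else {
        t = m / std::sqrt(v / n);
        if (t > TCLAMP) t = TCLAMP;
        if (t < -TCLAMP) t = -TCLAMP;
      }
      tval[p] = t;
      state[p] = (t > tcrit) ? 1 : (t < -tcrit ? -1 : 0);
    }
    int nlab = label_grid(state, nchan, ntime, adj, labels);
    if (nlab == 0) continue;
    std::vector<double> mass(nlab, 0.0);
    std::vector<int> nelec(nlab, 0);
    for (int p = 0; p < np; ++p)
      if (labels[p] > 0) mass[labels[p] - 1] += tval[p];
    // distinct electrode count: for each channel, collect labels seen
    for (int c = 0; c < nchan; ++c) {
      // walk times for this channel; count each label once per channel
      int prev = -1; // labels along time can repeat non-contiguously; use set
      std::vector<int> seen_labs;
      for (int t = 0; t < ntime; ++t) {
        int lab = labels[c + t * nchan];
        if (lab == 0 || lab == prev) { prev = lab; continue; }
        prev = lab;
        bool found = false;
        for (size_t k = 0; k < seen_labs.size(); ++k)
          if (seen_labs[k] == lab) { found = true; break; }
        if (!found) { seen_labs.push_back(lab); ++nelec[lab - 1]; }
      }
    }
    double maxpos = 0.0, maxneg = 0.0;
    for (int lab = 0; lab < nlab; ++lab) {
      if (nelec[lab] < min_electrodes) continue;
      if (mass[lab] > maxpos) maxpos = mass[lab];
      if (-mass[lab] > maxneg) maxneg = -mass[lab];
    }
    out(b, 0) = maxpos;
    out(b, 1) = maxneg;
  }
  return out;
}
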