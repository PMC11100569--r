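#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mean nearest-neighbour distance between populations, for a stack of
// labelings of one fixed point pattern.
//
// D:      n x n symmetric Euclidean distance matrix (positions never move)
// labels: n x P integer matrix, one labeling per column, values in 1..npop
//         (column 1 is typically the observed labeling, the rest null draws)
//
// Returns an npop x npop x P array: [a, b, p] = mean over population-a cells
// of the distance to the nearest population-b cell under labeling p, the cell
// itself excluded. Entries with no defined value (empty source, or target
// reduced to the focal cell alone) are NA.
// [[Rcpp::export]]
NumericVector perm_nearest_means(NumericMatrix D, IntegerMatrix labels,
                                 int npop) {
  const int n = D.nrow(), P = labels.ncol();
  if (labels.nrow() != n) stop("labels must have one row per cell");
  NumericVector out(npop * npop * P, NA_REAL);

  // neighbours of each cell sorted by distance (self excluded), computed
  // once: each labeling then only scans until every population is seen
  std::vector<int> ord((size_t)n * (n - 1));
  {
    std::vector<std::pair<double, int> > row(n - 1);
    for (int i = 0; i < n; ++i) {
      int m = 0;
      const double *col = &D(0, i);
      for (int j = 0; j < n; ++j)
        if (j != i) row[m++] = std::make_pair(col[j], j);
      std::sort(row.begin(), row.end());
      for (int t = 0; t < n - 1; ++t)
        ord[(size_t)i * (n - 1) + t] = row[t].second;
    }
  }

  std::vector<double> best(npop);
  std::vector<double> sum((size_t)npop * npop);
  std::vector<int> cnt((size_t)npop * npop);
  std::vector<int> lab(n), popn(npop);

  for (int p = 0; p < P; ++p) {
    std::fill(sum.begin(), sum.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    std::fill(popn.begin(), popn.end(), 0);
    for (int i = 0; i < n; ++i) {
      lab[i] = labels(i, p) - 1;
      if (lab[i] < 0 || lab[i] >= npop) stop("label out of range");
      popn[lab[i]]++;
    }
    int npresent = 0;
    for (int l = 0; l < npop; ++l) if (popn[l] > 0) npresent++;
    for (int i = 0; i < n; ++i) {
      std::fill(best.begin(), best.end(), R_PosInf);
      const int li = lab[i];
      // the focal cell does not count towards its own population's target
      int needed = npresent - (popn[li] == 1 ? 1 : 0);
      const int *oi = &ord[(size_t)i * (n - 1)];
      const double *col = &D(0, i);
      for (int t = 0; t < n - 1 && needed > 0; ++t) {
        const int j = oi[t];
        const int lj = lab[j];
        if (!R_FINITE(best[lj])) {
          best[lj] = col[j];
          needed--;
        }
      }
      for (int l = 0; l < npop; ++l) {
        if (R_FINITE(best[l])) {
          sum[(size_t)li * npop + l] += best[l];
          cnt[(size_t)li * npop + l]++;
        }
      }
    }
    for (int a = 0; a < npop; ++a)
      for (int b = 0; b < npop; ++b) {
        const int c = cnt[(size_t)a * npop + b];
        if (c > 0)
          out[(size_t)p * npop * npop + (size_t)b * npop + a] =
              sum[(size_t)a * npop + b] / c;
      }
  }
  out.attr("dim") = IntegerVector::create(npop, npop, P);
  return out;
}

// Mean local clustering coefficient of each population's vertex-induced
// subgraph, for a stack of labelings of one fixed graph.
//
// Adjacency in CSR form: indptr (length n+1, 0-based offsets) and indices
// (0-based neighbour ids, sorted within each row). labels as above.
//
// Per node: neighbours sharing the node's label form the induced
// neighbourhood; local coefficient = triangles / possible pairs, with
// induced degree < 2 contributing 0. Returns npop x P matrix of means over
// each population's nodes (NA when the population is absent). The R caller
// applies the < 3-member flagging rule.
// [[Rcpp::export]]
NumericMatrix perm_pop_clustering(IntegerVector indptr, IntegerVector indices,
                                  IntegerMatrix labels, int npop) {
  const int n = labels.nrow(), P = labels.ncol();
  if (indptr.size() != n + 1) stop("indptr must have length n + 1");
  NumericMatrix out(npop, P);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> nb;
  nb.reserve(64);

  for (int p = 0; p < P; ++p) {
    std::vector<double> sum(npop, 0.0);
    std::vector<int> cnt(npop, 0);
    for (int i = 0; i < n; ++i) {
      const int li = labels(i, p) - 1;
      nb.clear();
      for (int t = indptr[i]; t < indptr[i + 1]; ++t) {
        const int j = indices[t];
        if (labels(j, p) - 1 == li) nb.push_back(j);
      }
      const int k = (int)nb.size();
      double c = 0.0;
      if (k >= 2) {
        int tri = 0;
        for (int a = 0; a < k; ++a) {
          IntegerVector::iterator lo = indices.begin() + indptr[nb[a]];
          IntegerVector::iterator hi = indices.begin() + indptr[nb[a] + 1];
          for (int b = a + 1; b < k; ++b)
            if (std::binary_search(lo, hi, nb[b])) tri++;
        }
        c = 2.0 * tri / ((double)k * (k - 1));
      }
      sum[li] += c;
      cnt[li]++;
    }
    for (int l = 0; l < npop; ++l)
      if (cnt[l] > 0) out(l, p) = sum[l] / cnt[l];
  }
  return out;
}
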