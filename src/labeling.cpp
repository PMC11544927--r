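#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find over the suprathreshold cells of a frames x heights matrix,
// 8-connectivity. Region score = sum over frames of the per-frame maximum
// value inside the region.

static int uf_find(std::vector<int>& par, int x) {
  while (par[x] != x) {
    par[x] = par[par[x]];
    x = par[x];
  }
  return x;
}

static void uf_union(std::vector<int>& par, int a, int b) {
  a = uf_find(par, a);
  b = uf_find(par, b);
  if (a != b) par[b < a ? a : b] = (b < a ? b : a);
}

// [[Rcpp::export(name = ".label_regions_cpp")]]
List label_regions_cpp(NumericMatrix rho, double threshold) {
  const int nr = rho.nrow(), nc = rho.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> par(1, 0); // parent array; provisional labels from 1
  int next = 1;

  // first pass: provisional labels, merging with W, NW, N, NE neighbours
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!(rho(i, j) > threshold)) continue;
      int best = 0;
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      for (int q = 0; q < 4; ++q) {
        int ii = nb[q][0], jj = nb[q][1];
        if (ii < 0 || ii >= nr || jj < 0) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(par, best, l);
          best = uf_find(par, best);
        }
      }
      if (best == 0) {
        best = next++;
        par.push_back(best);
      }
      lab(i, j) = best;
    }
  }

  // compact labels
  std::vector<int> remap(next, 0);
  int L = 0;
  for (int l = 1; l < next; ++l)
    if (uf_find(par, l) == l) remap[l] = ++L;
  for (int l = 1; l < next; ++l) remap[l] = remap[uf_find(par, l)];

  NumericVector scores(L);
  IntegerVector sizes(L);
  std::vector<double> cur(L + 1, R_NegInf);
  std::vector<int> touched;
  touched.reserve(64);
  // second pass row-wise: per-frame maxima accumulate into region scores
  for (int i = 0; i < nr; ++i) {
    touched.clear();
    for (int j = 0; j < nc; ++j) {
      int l = lab(i, j);
      if (l == 0) continue;
      l = remap[l];
      lab(i, j) = l; // each cell is rewritten exactly once in this pass
      if (cur[l] == R_NegInf) touched.push_back(l);
      if (rho(i, j) > cur[l]) cur[l] = rho(i, j);
      sizes[l - 1] += 1;
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      scores[touched[t] - 1] += cur[touched[t]];
      cur[touched[t]] = R_NegInf;
    }
  }

  return List::create(_["labels"] = lab, _["n_regions"] = L,
                      _["scores"] = scores, _["sizes"] = sizes);
}
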