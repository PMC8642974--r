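#include <Rcpp.h>
using namespace Rcpp;

// Meiosis on one chromosome under the Haldane (no-interference) model.
// A homolog is a run-length tiling: brk = segment end positions (cM,
// strictly increasing, last = chromosome length), fdr = founder labels.
// Segment j covers (brk[j-1], brk[j]] with brk[-1] = 0.  Crossover count
// ~ Poisson(L/100), positions uniform; uses R's RNG so results are
// reproducible under set.seed().

// [[Rcpp::export(name = ".meiose_chrom_cpp")]]
List meiose_chrom_cpp(NumericVector brk1, IntegerVector fdr1,
                      NumericVector brk2, IntegerVector fdr2) {
  double L = brk1[brk1.size() - 1];
  int nxo = (int) R::rpois(L / 100.0);
  if (nxo == 0) {
    if (unif_rand() < 0.5)
      return List::create(_["brk"] = brk1, _["fdr"] = fdr1);
    else
      return List::create(_["brk"] = brk2, _["fdr"] = fdr2);
  }
  std::vector<double> xo(nxo);
  for (int i = 0; i < nxo; i++) xo[i] = unif_rand() * L;
  std::sort(xo.begin(), xo.end());
  int cur = (unif_rand() < 0.5) ? 0 : 1;

  std::vector<double> brk;
  std::vector<int> fdr;
  brk.reserve(nxo + brk1.size() + brk2.size());
  fdr.reserve(nxo + brk1.size() + brk2.size());

  double lo = 0.0;
  for (int k = 0; k <= nxo; k++) {
    double hi = (k < nxo) ? xo[k] : L;
    if (hi > lo) {
      const NumericVector& b = (cur == 0) ? brk1 : brk2;
      const IntegerVector& f = (cur == 0) ? fdr1 : fdr2;
      // first segment whose end exceeds lo
      int jj = (int)(std::upper_bound(b.begin(), b.end(), lo) - b.begin());
      if (jj >= b.size()) jj = b.size() - 1;
      while (true) {
        double end = std::min((double) b[jj], hi);
        if (end > lo) {
          if (!fdr.empty() && fdr.back() == f[jj]) {
            brk.back() = end; // merge identical adjacent founders
          } else {
            brk.push_back(end);
            fdr.push_back(f[jj]);
          }
          lo = end;
        }
        if (end >= hi || jj == (int) b.size() - 1) break;
        jj++;
      }
      lo = hi;
    }
    cur = 1 - cur;
  }
  return List::create(_["brk"] = NumericVector(brk.begin(), brk.end()),
                      _["fdr"] = IntegerVector(fdr.begin(), fdr.end()));
}

// Teosinte dosage for one individual at arbitrary positions: segment index
// is the first breakpoint >= pos (positions at 0 fall in the first segment).
// [[Rcpp::export(name = ".dosage_chrom_cpp")]]
IntegerVector dosage_chrom_cpp(NumericVector brk1, IntegerVector fdr1,
                               NumericVector brk2, IntegerVector fdr2,
                               NumericVector pos) {
  int m = pos.size();
  IntegerVector out(m);
  for (int i = 0; i < m; i++) {
    double p = pos[i];
    int a = (int)(std::lower_bound(brk1.begin(), brk1.end(), p) - brk1.begin());
    if (a >= brk1.size()) a = brk1.size() - 1;
    int b = (int)(std::lower_bound(brk2.begin(), brk2.end(), p) - brk2.begin());
    if (b >= brk2.size()) b = brk2.size() - 1;
    out[i] = fdr1[a] + fdr2[b];
  }
  return out;
}
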