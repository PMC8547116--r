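#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo exact Hardy-Weinberg test on one (population, locus) sample.
//
// Each step randomly re-pairs the 2n observed gene copies into n diploid
// genotypes, which is an exact i.i.d. draw from Levene's conditional null
// distribution of genotype tables given the allele counts. The table
// log-probability kernel (terms that vary across tables with fixed allele
// counts) is H*log(2) - sum(log n_ij!), with H the heterozygote count.
// The p-value is the fraction of sampled tables with kernel <= observed
// (probability-based rejection region, i.e. Fisher's exact probability
// test). Uses R's RNG so results are reproducible via set.seed().
//
// alleles: integer codes 0..k-1 of the 2n observed gene copies
// obs_kernel: kernel of the observed table
// [[Rcpp::export]]
double hwe_mc_pvalue_cpp(IntegerVector alleles, int n_steps,
                         double obs_kernel) {
  const int two_n = alleles.size();
  const int n = two_n / 2;
  std::vector<int> a(alleles.begin(), alleles.end());
  int k = 0;
  for (int i = 0; i < two_n; ++i) if (a[i] + 1 > k) k = a[i] + 1;
  std::vector<int> tab(k * k);
  long hits = 0;
  const double tol = 1e-9;
  for (int s = 0; s < n_steps; ++s) {
    for (int i = two_n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(a[i], a[j]);
    }
    std::fill(tab.begin(), tab.end(), 0);
    int H = 0;
    for (int i = 0; i < n; ++i) {
      int x = a[2 * i], y = a[2 * i + 1];
      if (x > y) std::swap(x, y);
      ++tab[x * k + y];
      if (x != y) ++H;
    }
    double kern = H * M_LN2;
    for (int x = 0; x < k; ++x)
      for (int y = x; y < k; ++y)
        if (tab[x * k + y] > 1) kern -= lgamma(tab[x * k + y] + 1.0);
    if (kern <= obs_kernel + tol) ++hits;
  }
  return (double)hits / n_steps;
}
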