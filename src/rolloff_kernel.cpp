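#include <Rcpp.h>
using namespace Rcpp;

// Per-chromosome accumulation of binned LD-score / weight-product sums
// over all SNP pairs with genetic separation in (0, d_max]. Genotypes
// are SNP x individual with NA for missing; weights must be defined
// (non-NA) for every SNP passed in. Returns an n_bins x 6 matrix of
// per-bin sums: n, sum z, sum ww, sum z^2, sum ww^2, sum z*ww.
// [[Rcpp::export(name = ".rolloff_chrom_acc_cpp")]]
NumericMatrix rolloff_chrom_acc_cpp(IntegerMatrix geno, NumericVector pos,
                                    NumericVector w, double bin_m,
                                    double d_max_m, int n_bins) {
  const int m = geno.nrow();
  const int n_ind = geno.ncol();
  NumericMatrix acc(n_bins, 6);

  for (int i = 0; i < m - 1; ++i) {
    const double pos_i = pos[i];
    const double w_i = w[i];
    for (int j = i + 1; j < m; ++j) {
      const double d = pos[j] - pos_i;
      if (d > d_max_m) break;
      if (d <= 0) continue;
      const int bin = (int)(d / bin_m); // 0-based
      if (bin >= n_bins) continue;
      // pairwise-complete sums over individuals
      int n = 0;
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      for (int k = 0; k < n_ind; ++k) {
        const int x = geno(i, k);
        const int y = geno(j, k);
        if (x == NA_INTEGER || y == NA_INTEGER) continue;
        ++n;
        sx += x; sy += y;
        sxx += (double)x * x; syy += (double)y * y; sxy += (double)x * y;
      }
      if (n < 4) continue;
      const double vx = n * sxx - sx * sx;
      const double vy = n * syy - sy * sy;
      if (vx <= 0 || vy <= 0) continue; // constant genotype vector
      double r = (n * sxy - sx * sy) / std::sqrt(vx * vy);
      if (r > 0.9) r = 0.9;
      if (r < -0.9) r = -0.9;
      const double z = std::atanh(r) * std::sqrt((double)n - 3.0);
      const double ww = w_i * w[j];
      acc(bin, 0) += 1.0;
      acc(bin, 1) += z;
      acc(bin, 2) += ww;
      acc(bin, 3) += z * z;
      acc(bin, 4) += ww * ww;
      acc(bin, 5) += z * ww;
    }
  }
  return acc;
}
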