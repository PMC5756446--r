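#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haplotypes are stored as a raw matrix with one row per locus and one
// column per haplotype; animal i (0-based) owns columns 2i and 2i+1.
// Loci are ordered by (chromosome, genetic position); chrom_off holds the
// 0-based locus offset of each chromosome plus a final sentinel.

// Fill one gamete from the two parental haplotype columns under the Haldane
// model: crossover count ~ Poisson(chromosome length in Morgans), crossover
// positions uniform, no interference, starting strand uniform.
static void gamete_fill(const Rbyte* h1, const Rbyte* h2, Rbyte* out,
                        const double* pos_M, const int* chrom_off, int n_chrom,
                        const double* chrom_len_M) {
  std::vector<double> cx;
  for (int c = 0; c < n_chrom; ++c) {
    const int lo = chrom_off[c], hi = chrom_off[c + 1];
    const double len = chrom_len_M[c];
    const int ncx = (int) R::rpois(len);
    cx.resize(ncx);
    for (int k = 0; k < ncx; ++k) cx[k] = unif_rand() * len;
    std::sort(cx.begin(), cx.end());
    bool first = unif_rand() < 0.5;
    int k = 0;
    for (int l = lo; l < hi; ++l) {
      while (k < ncx && cx[k] < pos_M[l]) { first = !first; ++k; }
      out[l] = first ? h1[l] : h2[l];
    }
  }
}

// Recurrent biallelic mutation: flip each locus of a gamete with prob mu.
static void mutate_gamete(Rbyte* g, int n_loci, double mu) {
  if (mu <= 0) return;
  const int nm = (int) R::rbinom((double) n_loci, mu);
  for (int k = 0; k < nm; ++k) {
    int l = (int) (unif_rand() * n_loci);
    if (l >= n_loci) l = n_loci - 1;
    g[l] ^= 1;
  }
}

// One recombinant (and possibly mutated) gamete per entry of `parents`
// (0-based animal indices into haps).
// [[Rcpp::export]]
RawMatrix cpp_gametes(RawMatrix haps, IntegerVector parents,
                      NumericVector pos_M, IntegerVector chrom_off,
                      NumericVector chrom_len_M, double mu) {
  const int L = haps.nrow();
  const int ng = parents.size();
  RawMatrix out(L, ng);
  const Rbyte* H = haps.begin();
  Rbyte* O = out.begin();
  for (int g = 0; g < ng; ++g) {
    const int a = parents[g];
    gamete_fill(H + (size_t) (2 * a) * L, H + (size_t) (2 * a + 1) * L,
                O + (size_t) g * L, pos_M.begin(), chrom_off.begin(),
                chrom_off.size() - 1, chrom_len_M.begin());
    mutate_gamete(O + (size_t) g * L, L, mu);
  }
  return out;
}

// Offspring haplotypes for given sire/dam index pairs: offspring k gets its
// paternal gamete in column 2k and its maternal gamete in column 2k+1.
// [[Rcpp::export]]
RawMatrix cpp_mate(RawMatrix haps, IntegerVector sires, IntegerVector dams,
                   NumericVector pos_M, IntegerVector chrom_off,
                   NumericVector chrom_len_M, double mu) {
  const int L = haps.nrow();
  const int no = sires.size();
  if (dams.size() != no) stop("sires and dams must have equal length");
  RawMatrix out(L, 2 * no);
  const Rbyte* H = haps.begin();
  Rbyte* O = out.begin();
  const int n_chrom = chrom_off.size() - 1;
  for (int k = 0; k < no; ++k) {
    const int s = sires[k], d = dams[k];
    Rbyte* pat = O + (size_t) (2 * k) * L;
    Rbyte* mat = O + (size_t) (2 * k + 1) * L;
    gamete_fill(H + (size_t) (2 * s) * L, H + (size_t) (2 * s + 1) * L, pat,
                pos_M.begin(), chrom_off.begin(), n_chrom, chrom_len_M.begin());
    mutate_gamete(pat, L, mu);
    gamete_fill(H + (size_t) (2 * d) * L, H + (size_t) (2 * d + 1) * L, mat,
                pos_M.begin(), chrom_off.begin(), n_chrom, chrom_len_M.begin());
    mutate_gamete(mat, L, mu);
  }
  return out;
}

// Allele dosage (0/1/2) for the given animals (0-based) at the given loci
// (0-based row indices); rows = animals, columns = loci.
// [[Rcpp::export]]
NumericMatrix cpp_dosage(RawMatrix haps, IntegerVector animals,
                         IntegerVector loci) {
  const int L = haps.nrow();
  const int na = animals.size(), nl = loci.size();
  NumericMatrix out(na, nl);
  const Rbyte* H = haps.begin();
  for (int j = 0; j < nl; ++j) {
    const int l = loci[j];
    double* col = &out(0, j);
    for (int i = 0; i < na; ++i) {
      const size_t a = (size_t) animals[i];
      col[i] = (double) H[2 * a * L + l] + (double) H[(2 * a + 1) * L + l];
    }
  }
  return out;
}

// Allele frequency at every locus over the given animals (0-based).
// [[Rcpp::export]]
NumericVector cpp_allele_freq(RawMatrix haps, IntegerVector animals) {
  const int L = haps.nrow();
  const int na = animals.size();
  std::vector<double> acc(L, 0.0);
  const Rbyte* H = haps.begin();
  for (int i = 0; i < na; ++i) {
    const size_t a = (size_t) animals[i];
    const Rbyte* h1 = H + 2 * a * L;
    const Rbyte* h2 = H + (2 * a + 1) * L;
    for (int l = 0; l < L; ++l) acc[l] += (double) h1[l] + (double) h2[l];
  }
  NumericVector out(L);
  const double denom = 2.0 * na;
  for (int l = 0; l < L; ++l) out[l] = acc[l] / denom;
  return out;
}
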