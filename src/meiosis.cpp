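#include <Rcpp.h>
using namespace Rcpp;

// Meiosis over one chromosome: crossover count ~ Poisson(genetic length in
// Morgans), crossover positions uniform on the chromosome, no interference
// (Haldane model). The gamete starts on a random parental haplotype and
// switches at every crossover. Loci are walked in map order, so `pos` must be
// sorted within a chromosome.
static inline void meiose_chromosome(const unsigned char *hapA,
                                     const unsigned char *hapB,
                                     unsigned char *out,
                                     const double *pos, int n_loci,
                                     double chr_len) {
  int n_xo = (int) R::rpois(chr_len);
  std::vector<double> xo(n_xo);
  for (int i = 0; i < n_xo; ++i) xo[i] = unif_rand() * chr_len;
  std::sort(xo.begin(), xo.end());
  bool useA = unif_rand() < 0.5;
  int next_xo = 0;
  for (int l = 0; l < n_loci; ++l) {
    while (next_xo < n_xo && xo[next_xo] <= pos[l]) {
      useA = !useA;
      ++next_xo;
    }
    out[l] = useA ? hapA[l] : hapB[l];
  }
}

// Produce one recombinant gamete per offspring. Gamete i recombines row
// rowA[i] of hapA with row rowB[i] of hapB (0-based rows). Both matrices are
// individuals x loci with alleles in {0,1} stored as raw bytes. For a
// heterozygous individual pass its two haplotype matrices with rowA == rowB;
// for a cross between two fully inbred parents pass the shared parent
// haplotype matrix twice with rowA/rowB indexing the two parents (an inbred's
// gamete equals its haplotype, so the offspring's meiosis acts directly on
// the two parental haplotypes).
// [[Rcpp::export]]
RawMatrix meiosis_gametes_cpp(RawMatrix hapA, RawMatrix hapB,
                              IntegerVector rowA, IntegerVector rowB,
                              IntegerVector chr_start, IntegerVector chr_len_loci,
                              NumericVector pos, NumericVector chr_len) {
  const int n_out = rowA.size();
  const int n_loci = hapA.ncol();
  const int n_chr = chr_start.size();
  if (hapB.ncol() != n_loci) stop("haplotype matrices differ in locus count");
  if (rowB.size() != n_out) stop("rowA and rowB differ in length");
  RawMatrix out(n_out, n_loci);
  const int nA = hapA.nrow(), nB = hapB.nrow();
  std::vector<unsigned char> bufA(n_loci), bufB(n_loci), bufO(n_loci);
  for (int i = 0; i < n_out; ++i) {
    int ra = rowA[i], rb = rowB[i];
    if (ra < 0 || ra >= nA || rb < 0 || rb >= nB) stop("parent row out of range");
    for (int l = 0; l < n_loci; ++l) {
      bufA[l] = hapA(ra, l);
      bufB[l] = hapB(rb, l);
    }
    for (int c = 0; c < n_chr; ++c) {
      int s = chr_start[c], m = chr_len_loci[c];
      meiose_chromosome(&bufA[s], &bufB[s], &bufO[s], &pos[s], m, chr_len[c]);
    }
    for (int l = 0; l < n_loci; ++l) out(i, l) = bufO[l];
  }
  return out;
}

// Dosage matrix (0/1/2) from two raw haplotype matrices, restricted to the
// given 0-based locus columns.
// [[Rcpp::export]]
IntegerMatrix dosage_cpp(RawMatrix hapA, RawMatrix hapB, IntegerVector cols) {
  const int n = hapA.nrow(), k = cols.size();
  IntegerMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    int l = cols[j];
    if (l < 0 || l >= hapA.ncol()) stop("locus column out of range");
    for (int i = 0; i < n; ++i)
      out(i, j) = (int) hapA(i, l) + (int) hapB(i, l);
  }
  return out;
}
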