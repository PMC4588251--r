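// Pair hidden Markov model read likelihood P(r|H).
//
// Forward algorithm over match/insert/delete states with affine gap
// structure: probabilities of all alignments of the read to the haplotype
// are summed, not maximized.  The read must be fully consumed; the
// alignment may start before any haplotype position (uniform 1/n start
// prior) and end anywhere, so the model is global in the read and local in
// the haplotype.
//
// Emissions: a match column emits 1-eps for an agreeing base and eps/3
// otherwise, where eps is the base error probability from the Phred
// quality, capped by the read MAPQ.  Inserted read bases emit with
// probability 1; deletions emit nothing.
//
// Transitions: gap opening from the match state uses a PCR error model
// keyed to the homopolymer run length of the haplotype at that column,
// gap_open(run) = 10^-(4 - 0.5*min(run, 6)); gap extension is a constant.

#include "rapidseq.h"
using namespace Rcpp;

static std::vector<double> hp_gap_open(const std::string& hap,
                                       double scale, double slope,
                                       int max_run) {
  int n = (int)hap.size();
  std::vector<int> run(n, 1);
  for (int j = 1; j < n; ++j)
    if (hap[j] == hap[j - 1]) run[j] = run[j - 1] + 1;
  // propagate the full run length back across the run
  for (int j = n - 2; j >= 0; --j)
    if (hap[j] == hap[j + 1]) run[j] = run[j + 1];
  std::vector<double> go(n);
  for (int j = 0; j < n; ++j)
    go[j] = std::pow(10.0, -(scale - slope * std::min(run[j], max_run)));
  return go;
}

double phmm_logp(const std::string& read, const std::vector<int>& qual,
                 const std::string& hap, int mapq, double gap_ext,
                 double pcr_scale, double pcr_slope, int pcr_max_run) {
  int m = (int)read.size(), n = (int)hap.size();
  if (m == 0 || n == 0) return R_NegInf;
  std::vector<double> go = hp_gap_open(hap, pcr_scale, pcr_slope, pcr_max_run);
  std::vector<double> eps(m);
  for (int i = 0; i < m; ++i) {
    int q = std::min(qual[i], mapq);
    eps[i] = std::pow(10.0, -q / 10.0);
  }
  // rows over read positions; columns 0..n over haplotype prefix
  std::vector<double> M(n + 1, 0.0), I(n + 1, 0.0), D(n + 1, 0.0);
  std::vector<double> Mn(n + 1), In(n + 1), Dn(n + 1);
  double init = 1.0 / n;
  // virtual row 0: the path may start (in a pseudo-match state) before any
  // haplotype column with uniform probability
  for (int j = 0; j <= n; ++j) { M[j] = init; I[j] = 0.0; D[j] = 0.0; }
  for (int i = 1; i <= m; ++i) {
    Mn[0] = 0.0;
    In[0] = I[0] * gap_ext + M[0] * go[0];
    Dn[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      double em = (read[i - 1] == hap[j - 1] && is_acgt(read[i - 1]))
                      ? 1.0 - eps[i - 1]
                      : eps[i - 1] / 3.0;
      double goj = go[j - 1];
      Mn[j] = em * (M[j - 1] * (1.0 - 2.0 * go[j - 1]) +
                    I[j - 1] * (1.0 - gap_ext) + D[j - 1] * (1.0 - gap_ext));
      In[j] = M[j] * goj + I[j] * gap_ext;
      Dn[j] = Mn[j - 1] * goj + Dn[j - 1] * gap_ext;
    }
    std::swap(M, Mn);
    std::swap(I, In);
    std::swap(D, Dn);
  }
  double p = 0.0;
  for (int j = 0; j <= n; ++j) p += M[j] + I[j];
  if (p < 1e-300) p = 1e-300;
  return std::log10(p);
}

// [[Rcpp::export(name = ".pair_hmm_cpp")]]
double pair_hmm_cpp(std::string read, IntegerVector qual, std::string hap,
                    int mapq, double gap_ext, double pcr_scale,
                    double pcr_slope, int pcr_max_run) {
  if (read.empty() || hap.empty())
    stop("pair_hmm: read and haplotype must be non-empty");
  if ((int)qual.size() != (int)read.size())
    stop("pair_hmm: quality length must equal read length");
  std::vector<int> q(qual.begin(), qual.end());
  return phmm_logp(read, q, hap, mapq, gap_ext, pcr_scale, pcr_slope,
                   pcr_max_run);
}

// Batched evaluation: all reads against all haplotypes; returns a
// reads x haplotypes matrix of log10 P(r|H).
// [[Rcpp::export(name = ".pair_hmm_batch_cpp")]]
NumericMatrix pair_hmm_batch_cpp(CharacterVector reads, List quals,
                                 CharacterVector haps, IntegerVector mapqs,
                                 double gap_ext, double pcr_scale,
                                 double pcr_slope, int pcr_max_run) {
  int nr = reads.size(), nh = haps.size();
  NumericMatrix out(nr, nh);
  std::vector<std::string> hv(nh);
  for (int h = 0; h < nh; ++h) hv[h] = as<std::string>(haps[h]);
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    IntegerVector qv = quals[r];
    std::vector<int> q(qv.begin(), qv.end());
    for (int h = 0; h < nh; ++h)
      out(r, h) = phmm_logp(rd, q, hv[h], mapqs[r], gap_ext, pcr_scale,
                            pcr_slope, pcr_max_run);
  }
  return out;
}
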