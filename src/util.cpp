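#include "rapidseq.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// Plant substitution errors into reads: err_read / err_pos (1-based) give
// the base to mutate; err_shift in {1,2,3} picks one of the three other
// bases cyclically so the result is always a real substitution.
// [[Rcpp::export(name = ".mutate_bases_cpp")]]
CharacterVector mutate_bases_cpp(CharacterVector reads, IntegerVector err_read,
                                 IntegerVector err_pos,
                                 IntegerVector err_shift) {
  static const char* bases = "ACGT";
  std::vector<std::string> rd(reads.size());
  for (int i = 0; i < reads.size(); ++i) rd[i] = as<std::string>(reads[i]);
  for (int k = 0; k < err_read.size(); ++k) {
    std::string& r = rd[err_read[k] - 1];
    int p = err_pos[k] - 1;
    if (p < 0 || p >= (int)r.size()) continue;
    const char* b = strchr(bases, r[p]);
    if (!b) continue;
    int bi = (int)(b - bases);
    r[p] = bases[(bi + err_shift[k]) % 4];
  }
  return wrap(rd);
}
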