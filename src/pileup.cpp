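// Single-pass pileup scan over coordinate-sorted alignments of one contig:
// per-column aligned depth, non-reference evidence (mismatches, indels,
// long soft-clip boundaries), and indel-specific evidence.  Only reads at
// or above the MAPQ floor and not flagged as duplicates contribute.

#include "rapidseq.h"
using namespace Rcpp;

// [[Rcpp::export(name = ".pileup_scan_cpp")]]
List pileup_scan_cpp(std::string contig_seq, IntegerVector pos,
                     CharacterVector cigar, CharacterVector seq,
                     IntegerVector mapq, LogicalVector dup, int min_mapq,
                     int min_clip) {
  int n = (int)contig_seq.size();
  IntegerVector depth(n), nonref(n), indel(n);
  for (int r = 0; r < pos.size(); ++r) {
    if (mapq[r] < min_mapq || dup[r]) continue;
    std::string cg = as<std::string>(cigar[r]);
    if (cg == "*") continue;
    std::string sq = as<std::string>(seq[r]);
    int rp = pos[r];  // 0-based reference cursor
    int qp = 0;       // read cursor
    size_t ci = 0;
    bool first_op = true;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && isdigit(cg[ci])) len = len * 10 + (cg[ci++] - '0');
      char op = cg[ci++];
      if (op == 'M') {
        for (int i = 0; i < len; ++i) {
          int c = rp + i;
          if (c < 0 || c >= n) continue;
          depth[c]++;
          if (qp + i < (int)sq.size() && sq[qp + i] != contig_seq[c]) nonref[c]++;
        }
        rp += len;
        qp += len;
      } else if (op == 'I') {
        int c = rp;
        if (c >= 0 && c < n) { nonref[c]++; indel[c]++; }
        qp += len;
      } else if (op == 'D') {
        for (int i = 0; i < len; ++i) {
          int c = rp + i;
          if (c < 0 || c >= n) continue;
          depth[c]++;
          nonref[c]++;
          indel[c]++;
        }
        rp += len;
      } else if (op == 'S') {
        // a long clip marks possible structural/indel evidence at its edge
        if (len >= min_clip) {
          int c = first_op ? rp : rp - 1;
          if (c >= 0 && c < n) { nonref[c]++; indel[c]++; }
        }
        qp += len;
      } else if (op == 'H' || op == 'P') {
        // no-op
      } else if (op == 'N') {
        rp += len;
      }
      first_op = false;
    }
  }
  return List::create(_["depth"] = depth, _["nonref"] = nonref,
                      _["indel"] = indel);
}
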