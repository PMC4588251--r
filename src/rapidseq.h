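#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

inline bool has_non_acgt(const std::string& s, size_t from, size_t len) {
  for (size_t i = from; i < from + len; ++i)
    if (!is_acgt(s[i])) return true;
  return false;
}

// ---- hash index -----------------------------------------------------------

enum IdxEntryType { ENTRY_HITS = 0, ENTRY_EXTEND = 1, ENTRY_HIFREQ = 2 };

struct IdxEntry {
  int type = ENTRY_HITS;
  // hit positions are the start of the *primary* seed on the forward strand
  std::vector<std::pair<int32_t, int32_t> > hits;  // (contig idx, pos)
  int ext_left = 0;   // additional nt to join on each side for EXTEND
  int ext_right = 0;
};

struct HashIndex {
  int seed_len, max_hits, max_ext, ext_step, stride;
  std::vector<std::string> contig_names;
  std::vector<std::string> contigs;  // uppercase, forward strand
  std::unordered_map<std::string, IdxEntry> table;
};

// result of one oriented seed query
struct SeedQueryResult {
  std::vector<std::pair<int32_t, int32_t> > hits;  // (contig, primary-seed pos)
  bool high_frequency = false;
};

SeedQueryResult query_index_oriented(const HashIndex& idx, const std::string& read,
                                     int offset);

// ---- alignment ------------------------------------------------------------

struct CigarOp {
  char op;
  int len;
};

struct AlnResult {
  int score = 0;
  int ref_start = 0;   // 0-based offset in the reference window
  int read_start = 0;  // leading soft clip length
  int read_end = 0;    // one past last aligned read base
  int n_gapops = 0;
  std::vector<CigarOp> cigar;  // M/I/D only (clips added by caller)
};

AlnResult sw_align(const std::string& read, const std::string& ref,
                   int match, int mismatch, int gap_open, int gap_extend);

AlnResult nw_align(const std::string& a, const std::string& b,
                   double match, double mismatch, double gap_open,
                   double gap_extend);

std::string cigar_string(const AlnResult& a, int read_len);
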