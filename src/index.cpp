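// Hash-table index of a reference genome with dynamic seed extension.
//
// Primary seeds (default 21 nt) that match more than max_hits reference
// locations are not stored as hit lists; instead an EXTEND record directs
// the query to join additional flanking bases (ext_step per side, up to
// max_ext per side) and re-query with the longer seed, iteratively.  Seeds
// still exceeding max_hits at maximum extension carry a high-frequency
// marker and return no hits.

#include "rapidseq.h"
using namespace Rcpp;

static void extend_group(HashIndex& idx, const std::string& key,
                         const std::vector<std::pair<int32_t, int32_t> >& occs,
                         int cur_ext) {
  if (cur_ext >= idx.max_ext) {
    IdxEntry e;
    e.type = ENTRY_HIFREQ;
    idx.table[key] = e;
    return;
  }
  int step = std::min(idx.ext_step, idx.max_ext - cur_ext);
  int new_ext = cur_ext + step;
  IdxEntry rec;
  rec.type = ENTRY_EXTEND;
  rec.ext_left = step;
  rec.ext_right = step;
  idx.table[key] = rec;

  // group occurrences by the extended seed sequence; occurrences too close
  // to a contig edge to extend symmetrically are dropped
  int ext_len = idx.seed_len + 2 * new_ext;
  std::unordered_map<std::string, std::vector<std::pair<int32_t, int32_t> > > groups;
  for (const auto& oc : occs) {
    const std::string& seq = idx.contigs[oc.first];
    int64_t start = (int64_t)oc.second - new_ext;
    if (start < 0 || start + ext_len > (int64_t)seq.size()) continue;
    std::string ext_key = seq.substr((size_t)start, (size_t)ext_len);
    if (has_non_acgt(ext_key, 0, ext_key.size())) continue;
    groups[ext_key].push_back(oc);
  }
  for (auto& g : groups) {
    if ((int)g.second.size() <= idx.max_hits) {
      IdxEntry e;
      e.type = ENTRY_HITS;
      e.hits = g.second;
      idx.table[g.first] = e;
    } else {
      extend_group(idx, g.first, g.second, new_ext);
    }
  }
}

// [[Rcpp::export(name = ".build_index_cpp")]]
SEXP build_index_cpp(CharacterVector contig_names, CharacterVector contig_seqs,
                     int seed_len, int max_hits, int max_ext, int ext_step,
                     int stride) {
  HashIndex* idx = new HashIndex();
  idx->seed_len = seed_len;
  idx->max_hits = max_hits;
  idx->max_ext = max_ext;
  idx->ext_step = ext_step;
  idx->stride = stride;
  for (int i = 0; i < contig_names.size(); ++i) {
    idx->contig_names.push_back(as<std::string>(contig_names[i]));
    idx->contigs.push_back(as<std::string>(contig_seqs[i]));
  }

  // collect primary-seed occurrences (forward strand only)
  std::unordered_map<std::string, std::vector<std::pair<int32_t, int32_t> > > occ;
  for (size_t c = 0; c < idx->contigs.size(); ++c) {
    const std::string& seq = idx->contigs[c];
    if ((int64_t)seq.size() < seed_len) continue;
    for (int64_t p = 0; p + seed_len <= (int64_t)seq.size(); ++p) {
      if (has_non_acgt(seq, (size_t)p, (size_t)seed_len)) continue;
      occ[seq.substr((size_t)p, (size_t)seed_len)].push_back(
          std::make_pair((int32_t)c, (int32_t)p));
    }
  }
  for (auto& kv : occ) {
    if ((int)kv.second.size() <= max_hits) {
      IdxEntry e;
      e.type = ENTRY_HITS;
      e.hits = kv.second;
      idx->table[kv.first] = e;
    } else {
      extend_group(*idx, kv.first, kv.second, 0);
    }
  }
  XPtr<HashIndex> ptr(idx, true);
  return ptr;
}

SeedQueryResult query_index_oriented(const HashIndex& idx, const std::string& read,
                                     int offset) {
  SeedQueryResult res;
  int L = (int)read.size();
  int left = 0, right = 0;  // cumulative extension applied so far
  if (offset + idx.seed_len > L) return res;
  if (has_non_acgt(read, (size_t)offset, (size_t)idx.seed_len)) return res;
  std::string key = read.substr((size_t)offset, (size_t)idx.seed_len);
  for (;;) {
    auto it = idx.table.find(key);
    if (it == idx.table.end()) return res;
    const IdxEntry& e = it->second;
    if (e.type == ENTRY_HITS) {
      res.hits = e.hits;
      return res;
    }
    if (e.type == ENTRY_HIFREQ) {
      res.high_frequency = true;
      return res;
    }
    // EXTEND: join flanking read bases on each side and re-query
    int nl = left + e.ext_left, nr = right + e.ext_right;
    if (offset - nl < 0 || offset + idx.seed_len + nr > L) {
      res.high_frequency = true;  // too few flanking bases to extend
      return res;
    }
    key = read.substr((size_t)(offset - nl), (size_t)(idx.seed_len + nl + nr));
    if (has_non_acgt(key, 0, key.size())) return res;
    left = nl;
    right = nr;
  }
}

// [[Rcpp::export(name = ".query_seed_cpp")]]
List query_seed_cpp(SEXP idx_ptr, std::string read_seq, int offset) {
  XPtr<HashIndex> idx(idx_ptr);
  int L = (int)read_seq.size();
  std::vector<int> contig, pos, orient, off_frame;
  bool hifreq = false;

  SeedQueryResult fw = query_index_oriented(*idx, read_seq, offset);
  hifreq = hifreq || fw.high_frequency;
  for (auto& h : fw.hits) {
    contig.push_back(h.first + 1);
    pos.push_back(h.second);
    orient.push_back(0);
    off_frame.push_back(offset);
  }
  std::string rc = revcomp(read_seq);
  int rc_offset = L - offset - idx->seed_len;
  if (rc_offset >= 0) {
    SeedQueryResult rv = query_index_oriented(*idx, rc, rc_offset);
    hifreq = hifreq || rv.high_frequency;
    for (auto& h : rv.hits) {
      contig.push_back(h.first + 1);
      pos.push_back(h.second);
      orient.push_back(1);
      off_frame.push_back(rc_offset);
    }
  }
  return List::create(_["contig"] = contig, _["pos"] = pos,
                      _["orient"] = orient, _["offset_frame"] = off_frame,
                      _["high_frequency"] = hifreq);
}

// [[Rcpp::export(name = ".index_params_cpp")]]
List index_params_cpp(SEXP idx_ptr) {
  XPtr<HashIndex> idx(idx_ptr);
  return List::create(_["primary_seed_len"] = idx->seed_len,
                      _["max_hits"] = idx->max_hits,
                      _["max_ext_per_side"] = idx->max_ext,
                      _["ext_increment"] = idx->ext_step,
                      _["seed_stride"] = idx->stride,
                      _["n_contigs"] = (int)idx->contigs.size(),
                      _["n_keys"] = (double)idx->table.size());
}

// [[Rcpp::export(name = ".index_contigs_cpp")]]
List index_contigs_cpp(SEXP idx_ptr) {
  XPtr<HashIndex> idx(idx_ptr);
  return List::create(_["names"] = wrap(idx->contig_names),
                      _["lengths"] = [&] {
                        IntegerVector l(idx->contigs.size());
                        for (size_t i = 0; i < idx->contigs.size(); ++i)
                          l[i] = (int)idx->contigs[i].size();
                        return l;
                      }());
}

// Tabular dump of the whole table (key, type, ext_left, ext_right, hits as
// "contig:pos;..."), sorted by key -- used for serialization and for the
// byte-identical determinism check.
// [[Rcpp::export(name = ".index_dump_cpp")]]
DataFrame index_dump_cpp(SEXP idx_ptr) {
  XPtr<HashIndex> idx(idx_ptr);
  std::vector<std::string> keys;
  keys.reserve(idx->table.size());
  for (auto& kv : idx->table) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector key(keys.size()), hitstr(keys.size());
  IntegerVector type(keys.size()), el(keys.size()), er(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    const IdxEntry& e = idx->table[keys[i]];
    key[i] = keys[i];
    type[i] = e.type;
    el[i] = e.ext_left;
    er[i] = e.ext_right;
    std::string hs;
    for (auto& h : e.hits) {
      if (!hs.empty()) hs += ";";
      hs += std::to_string(h.first) + ":" + std::to_string(h.second);
    }
    hitstr[i] = hs;
  }
  return DataFrame::create(_["key"] = key, _["type"] = type,
                           _["ext_left"] = el, _["ext_right"] = er,
                           _["hits"] = hitstr,
                           _["stringsAsFactors"] = false);
}
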