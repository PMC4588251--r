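// Paired-end read mapping driver.
//
// For each mate: overlapping seeds at every stride-th offset are looked up
// in the hash index (both orientations, EXTEND chains followed), hits are
// grouped into seed chains by exact alignment diagonal, chains mostly
// overlapped in the read by a chain at least four times longer are
// filtered, and each surviving chain is extended by gapless alignment on
// its diagonal; heuristics decide when Smith-Waterman gapped alignment is
// worth running.  Candidate placements for the two mates are combined into
// pair scores (sum of alignment scores minus an insert-deviation penalty),
// unpaired mates trigger a rescue scan of the expected insert window, and
// the best pair is reported with MAPQ from the best/second-best score gap.

#include "rapidseq.h"
using namespace Rcpp;

namespace {

struct MapParams {
  int match, mismatch, gap_open, gap_extend, unclipped_bonus;
  double trigger_fraction;
  int clip_trigger, sw_band;
  double insert_mean, insert_sd, insert_window;
  bool fit_insert;
  int insert_fit_n;
  int rescue_kmer, rescue_hamming;
  double mapq_coeff, mapq_beta;
  int near_window;
  double cover_fraction;
  double pair_pen_coeff;
  int pair_pen_cap, min_score, max_chains;
};

struct Candidate {
  int contig = -1;
  int pos = 0;  // 0-based leftmost aligned reference base
  bool rc = false;
  int score = 0;
  std::string cigar = "*";
  int read_start = 0, read_end = 0;  // aligned span, output-strand frame
};

struct Chain {
  int contig;
  bool rc;
  int diag;
  int span_start, span_end;  // read interval covered (strand frame)
  int len() const { return span_end - span_start; }
};

struct RawHit {
  int contig;
  bool rc;
  int diag;
  int off;
};

std::vector<Chain> chains_from_hits(std::vector<RawHit>& hits, int seed_len) {
  std::sort(hits.begin(), hits.end(), [](const RawHit& a, const RawHit& b) {
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.rc != b.rc) return a.rc < b.rc;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.off < b.off;
  });
  std::vector<Chain> chains;
  size_t i = 0;
  while (i < hits.size()) {
    size_t j = i;
    int lo = hits[i].off, hi = hits[i].off;
    while (j < hits.size() && hits[j].contig == hits[i].contig &&
           hits[j].rc == hits[i].rc && hits[j].diag == hits[i].diag) {
      lo = std::min(lo, hits[j].off);
      hi = std::max(hi, hits[j].off);
      ++j;
    }
    chains.push_back({hits[i].contig, hits[i].rc, hits[i].diag, lo,
                      hi + seed_len});
    i = j;
  }
  return chains;
}

// a chain is dropped when another at least 4x longer overlaps > 50% of its
// read span
void filter_chains(std::vector<Chain>& chains) {
  std::vector<bool> keep(chains.size(), true);
  for (size_t b = 0; b < chains.size(); ++b) {
    for (size_t a = 0; a < chains.size(); ++a) {
      if (a == b || !keep[a]) continue;
      if (chains[a].len() < 4 * chains[b].len()) continue;
      int ov = std::min(chains[a].span_end, chains[b].span_end) -
               std::max(chains[a].span_start, chains[b].span_start);
      if (ov * 2 > chains[b].len()) { keep[b] = false; break; }
    }
  }
  size_t w = 0;
  for (size_t i = 0; i < chains.size(); ++i)
    if (keep[i]) chains[w++] = chains[i];
  chains.resize(w);
}

Candidate align_at(const HashIndex& idx, const std::string& oriented_read,
                   int contig, bool rc, int diag, const MapParams& P) {
  Candidate cand;
  const std::string& ref = idx.contigs[contig];
  int L = (int)oriented_read.size(), clen = (int)ref.size();
  int ws = std::max(0, diag - P.sw_band);
  int we = std::min(clen, diag + L + P.sw_band);
  if (we - ws < P.rescue_kmer || we <= ws) return cand;
  std::string window = ref.substr(ws, we - ws);
  bool needs_gapped = true;
  int gl_score = 0, clip_l = 0, clip_r = 0;
  if (diag >= 0 && diag + L <= clen) {
    // gapless fixed-diagonal alignment with optional end clips
    int anchor = diag - ws;
    int best = 0, best_a = 0, best_b = 0, cur = 0, cur_a = 0;
    for (int i = 0; i < L; ++i) {
      int s = (oriented_read[i] == window[anchor + i] &&
               is_acgt(oriented_read[i]))
                  ? P.match
                  : -P.mismatch;
      if (cur <= 0) { cur = 0; cur_a = i; }
      cur += s;
      if (cur > best) { best = cur; best_a = cur_a; best_b = i + 1; }
    }
    gl_score = best;
    clip_l = best_a;
    clip_r = L - best_b;
    needs_gapped = gl_score < P.trigger_fraction * (L * P.match) ||
                   std::max(clip_l, clip_r) > P.clip_trigger;
  }
  if (!needs_gapped) {
    cand.contig = contig;
    cand.rc = rc;
    cand.pos = diag + clip_l;
    cand.score = gl_score;
    cand.read_start = clip_l;
    cand.read_end = L - clip_r;
    std::string cg;
    if (clip_l) cg += std::to_string(clip_l) + "S";
    cg += std::to_string(L - clip_l - clip_r) + "M";
    if (clip_r) cg += std::to_string(clip_r) + "S";
    cand.cigar = cg;
  } else {
    AlnResult a = sw_align(oriented_read, window, P.match, P.mismatch,
                           P.gap_open, P.gap_extend);
    if (a.score <= 0 || a.cigar.empty()) return cand;
    cand.contig = contig;
    cand.rc = rc;
    cand.pos = ws + a.ref_start;
    cand.score = a.score;
    cand.read_start = a.read_start;
    cand.read_end = a.read_end;
    cand.cigar = cigar_string(a, L);
  }
  if (cand.read_start == 0 && cand.read_end == L)
    cand.score += P.unclipped_bonus;
  return cand;
}

int ref_span_of(const Candidate& c) {
  // parse the CIGAR M/D footprint
  int span = 0, len = 0;
  for (char ch : c.cigar) {
    if (isdigit(ch)) len = len * 10 + (ch - '0');
    else {
      if (ch == 'M' || ch == 'D') span += len;
      len = 0;
    }
  }
  return span;
}

std::vector<Candidate> candidates_for(const HashIndex& idx,
                                      const std::string& read,
                                      const std::string& rcread,
                                      const MapParams& P) {
  int L = (int)read.size();
  std::vector<RawHit> hits;
  for (int off = 0; off + idx.seed_len <= L; off += idx.stride) {
    SeedQueryResult fw = query_index_oriented(idx, read, off);
    for (auto& h : fw.hits)
      hits.push_back({h.first, false, h.second - off, off});
    int rco = L - off - idx.seed_len;
    SeedQueryResult rv = query_index_oriented(idx, rcread, rco);
    for (auto& h : rv.hits)
      hits.push_back({h.first, true, h.second - rco, rco});
  }
  std::vector<Chain> chains = chains_from_hits(hits, idx.seed_len);
  filter_chains(chains);
  if ((int)chains.size() > P.max_chains) {
    std::sort(chains.begin(), chains.end(),
              [](const Chain& a, const Chain& b) { return a.len() > b.len(); });
    chains.resize(P.max_chains);
  }
  std::vector<Candidate> cands;
  for (auto& ch : chains) {
    const std::string& oread = ch.rc ? rcread : read;
    Candidate c = align_at(idx, oread, ch.contig, ch.rc, ch.diag, P);
    if (c.contig < 0) continue;
    bool dup = false;
    for (auto& o : cands)
      if (o.contig == c.contig && o.rc == c.rc &&
          std::abs(o.pos - c.pos) < 5) {
        if (c.score > o.score) o = c;
        dup = true;
        break;
      }
    if (!dup) cands.push_back(c);
  }
  return cands;
}

// scan [wstart, wend) of a contig for positions matching the first k bases
// of `target` within `max_h` mismatches
std::vector<int> hamming_scan(const std::string& ref, int wstart, int wend,
                              const std::string& target, int k, int max_h) {
  std::vector<int> out;
  int clen = (int)ref.size();
  wstart = std::max(0, wstart);
  wend = std::min(clen, wend);
  if ((int)target.size() < k) k = (int)target.size();
  for (int p = wstart; p + k <= wend; ++p) {
    int d = 0;
    for (int i = 0; i < k && d <= max_h; ++i)
      if (ref[p + i] != target[i]) ++d;
    if (d <= max_h) out.push_back(p);
  }
  return out;
}

struct PairChoice {
  int i = -1, j = -1;  // indices into candidate lists (-1 = unmapped)
  double pair_score = -1e18;
  bool proper = false;
  double insert = 0;
};

double pairing_penalty(const Candidate& a, const Candidate& b,
                       const MapParams& P, bool& proper, double& insert) {
  proper = false;
  insert = 0;
  if (a.contig != b.contig || a.rc == b.rc) return P.pair_pen_cap;
  const Candidate& fw = a.rc ? b : a;
  const Candidate& rv = a.rc ? a : b;
  double ins = (rv.pos + ref_span_of(rv)) - fw.pos;
  insert = ins;
  if (ins <= 0 || ins > P.insert_mean + P.insert_window * P.insert_sd)
    return P.pair_pen_cap;
  proper = true;
  double pen = std::round(P.pair_pen_coeff * std::fabs(ins - P.insert_mean) /
                          P.insert_sd);
  return std::min(pen, (double)P.pair_pen_cap);
}

PairChoice choose_pair(const std::vector<Candidate>& c1,
                       const std::vector<Candidate>& c2, const MapParams& P) {
  PairChoice best;
  for (size_t i = 0; i < c1.size(); ++i) {
    for (size_t j = 0; j < c2.size(); ++j) {
      bool proper;
      double insert;
      double pen = pairing_penalty(c1[i], c2[j], P, proper, insert);
      double ps = c1[i].score + c2[j].score - pen;
      if (ps > best.pair_score) {
        best = {(int)i, (int)j, ps, proper, insert};
      }
    }
  }
  // single-ended fallbacks
  if (best.i < 0) {
    int bi = -1, bj = -1;
    for (size_t i = 0; i < c1.size(); ++i)
      if (bi < 0 || c1[i].score > c1[bi].score) bi = (int)i;
    for (size_t j = 0; j < c2.size(); ++j)
      if (bj < 0 || c2[j].score > c2[bj].score) bj = (int)j;
    best.i = bi;
    best.j = bj;
    best.proper = false;
    best.pair_score = (bi >= 0 ? c1[bi].score : 0) +
                      (bj >= 0 ? c2[bj].score : 0) - P.pair_pen_cap;
  }
  return best;
}

int mapq_for(const std::vector<Candidate>& cands, int chosen, int L,
             const MapParams& P) {
  if (chosen < 0) return 0;
  int S1 = cands[chosen].score;
  int S2 = INT_MIN;
  int n_near = 0;
  for (size_t k = 0; k < cands.size(); ++k) {
    if ((int)k == chosen) continue;
    const Candidate& o = cands[k];
    const Candidate& c = cands[chosen];
    bool same_locus = o.contig == c.contig && o.rc == c.rc &&
                      std::abs(o.pos - c.pos) <= L / 2;
    if (same_locus) continue;
    // candidates placing a mostly disjoint read segment are chimeric
    // segments (supplementary material), not alternative placements;
    // spans are normalized to the original read frame before comparing
    int os = o.rc ? L - o.read_end : o.read_start;
    int oe = o.rc ? L - o.read_start : o.read_end;
    int cs = c.rc ? L - c.read_end : c.read_start;
    int ce = c.rc ? L - c.read_start : c.read_end;
    int ov = std::min(oe, ce) - std::max(os, cs);
    int shorter = std::min(oe - os, ce - cs);
    if (shorter > 0 && 2 * ov < shorter) continue;
    S2 = std::max(S2, o.score);
  }
  if (S2 == INT_MIN) return 60;  // sole candidate: cap
  for (size_t k = 0; k < cands.size(); ++k) {
    if ((int)k == chosen) continue;
    if (std::abs(cands[k].score - S2) <= P.near_window) ++n_near;
  }
  double alpha = P.mapq_coeff / L;
  double q = std::round(alpha * (S1 - S2)) -
             P.mapq_beta * std::log2(1.0 + n_near);
  if (q < 0) q = 0;
  if (q > 60) q = 60;
  return (int)q;
}

}  // namespace

// [[Rcpp::export(name = ".rescue_scan_cpp")]]
IntegerVector rescue_scan_cpp(std::string ref, int wstart, int wend,
                              std::string target, int kmer_len,
                              int max_hamming) {
  std::vector<int> v =
      hamming_scan(ref, wstart, wend, target, kmer_len, max_hamming);
  return wrap(v);
}

// [[Rcpp::export(name = ".map_pairs_cpp")]]
List map_pairs_cpp(SEXP idx_ptr, CharacterVector id, CharacterVector seq1,
                   CharacterVector qual1, CharacterVector seq2,
                   CharacterVector qual2, List params) {
  XPtr<HashIndex> idxp(idx_ptr);
  const HashIndex& idx = *idxp;
  MapParams P;
  P.match = params["match"];
  P.mismatch = params["mismatch"];
  P.gap_open = params["gap_open"];
  P.gap_extend = params["gap_extend"];
  P.unclipped_bonus = params["unclipped_bonus"];
  P.trigger_fraction = params["trigger_fraction"];
  P.clip_trigger = params["clip_trigger"];
  P.sw_band = params["sw_band"];
  P.insert_mean = params["insert_mean"];
  P.insert_sd = params["insert_sd"];
  P.insert_window = params["insert_window"];
  P.fit_insert = params["fit_insert"];
  P.insert_fit_n = params["insert_fit_n"];
  P.rescue_kmer = params["rescue_kmer"];
  P.rescue_hamming = params["rescue_hamming"];
  P.mapq_coeff = params["mapq_coeff"];
  P.mapq_beta = params["mapq_beta"];
  P.near_window = params["near_window"];
  P.cover_fraction = params["cover_fraction"];
  P.pair_pen_coeff = params["pair_pen_coeff"];
  P.pair_pen_cap = params["pair_pen_cap"];
  P.min_score = params["min_score"];
  P.max_chains = params["max_chains"];

  int n_pairs = seq1.size();

  // insert-model fit: first pass over up to insert_fit_n pairs, proper FR
  // pairs aligned without rescue; fall back to the configured mean/sd
  if (P.fit_insert) {
    std::vector<double> inserts;
    int fit_n = std::min(n_pairs, P.insert_fit_n);
    for (int r = 0; r < fit_n; ++r) {
      std::string s1 = as<std::string>(seq1[r]), s2 = as<std::string>(seq2[r]);
      std::string r1 = revcomp(s1), r2 = revcomp(s2);
      std::vector<Candidate> c1 = candidates_for(idx, s1, r1, P);
      std::vector<Candidate> c2 = candidates_for(idx, s2, r2, P);
      PairChoice pc = choose_pair(c1, c2, P);
      if (pc.proper && pc.i >= 0 && pc.j >= 0 &&
          c1[pc.i].score >= P.min_score && c2[pc.j].score >= P.min_score)
        inserts.push_back(pc.insert);
    }
    if (inserts.size() >= 200) {
      double mu = 0;
      for (double v : inserts) mu += v;
      mu /= inserts.size();
      double s2 = 0;
      for (double v : inserts) s2 += (v - mu) * (v - mu);
      double sd = std::sqrt(s2 / (inserts.size() - 1));
      P.insert_mean = mu;
      P.insert_sd = std::max(sd, 1.0);
    }
  }

  std::vector<std::string> o_qname;
  std::vector<int> o_flag, o_contig, o_pos, o_mapq, o_mcontig, o_mpos, o_tlen,
      o_score, o_read;
  std::vector<double> o_pairscore;
  std::vector<std::string> o_cigar, o_seq, o_qual;

  int n_proper = 0, n_rescued = 0;

  for (int r = 0; r < n_pairs; ++r) {
    std::string qn = as<std::string>(id[r]);
    std::string s[2] = {as<std::string>(seq1[r]), as<std::string>(seq2[r])};
    std::string q[2] = {as<std::string>(qual1[r]), as<std::string>(qual2[r])};
    std::string rc[2] = {revcomp(s[0]), revcomp(s[1])};
    std::vector<Candidate> cands[2];
    cands[0] = candidates_for(idx, s[0], rc[0], P);
    cands[1] = candidates_for(idx, s[1], rc[1], P);
    PairChoice pc = choose_pair(cands[0], cands[1], P);

    // rescue scan when a mate is unpaired: search the expected insert
    // window of the anchored mate for k-mer matches of the missing mate
    if (!pc.proper) {
      bool added = false;
      for (int m = 0; m < 2; ++m) {
        int other = 1 - m;
        const std::vector<Candidate>& anch = cands[m];
        if (anch.empty()) continue;
        int bi = 0;
        for (size_t k = 1; k < anch.size(); ++k)
          if (anch[k].score > anch[bi].score) bi = (int)k;
        const Candidate& a = anch[bi];
        if (a.score < P.min_score) continue;
        const std::string& ref = idx.contigs[a.contig];
        int Lo = (int)s[other].size();
        double win = P.insert_window * P.insert_sd;
        int wstart, wend;
        std::string target;
        bool o_rc;
        if (!a.rc) {  // mate expected downstream, reverse-complemented
          wstart = (int)(a.pos + P.insert_mean - win) - Lo;
          wend = (int)(a.pos + P.insert_mean + win);
          target = rc[other];
          o_rc = true;
        } else {  // mate expected upstream, forward
          int aend = a.pos + ref_span_of(a);
          wstart = (int)(aend - P.insert_mean - win);
          wend = (int)(aend - P.insert_mean + win) + Lo;
          target = s[other];
          o_rc = false;
        }
        std::vector<int> hits = hamming_scan(ref, wstart, wend, target,
                                             P.rescue_kmer, P.rescue_hamming);
        for (int hpos : hits) {
          Candidate c = align_at(idx, o_rc ? rc[other] : s[other], a.contig,
                                 o_rc, hpos, P);
          if (c.contig < 0) continue;
          bool dup = false;
          for (auto& o : cands[other])
            if (o.contig == c.contig && o.rc == c.rc &&
                std::abs(o.pos - c.pos) < 5) {
              dup = true;
              break;
            }
          if (!dup) {
            cands[other].push_back(c);
            added = true;
          }
        }
      }
      if (added) {
        PairChoice pc2 = choose_pair(cands[0], cands[1], P);
        if (pc2.pair_score > pc.pair_score || pc2.proper) {
          pc = pc2;
          ++n_rescued;
        }
      }
    }
    if (pc.proper) ++n_proper;

    int chosen[2] = {pc.i, pc.j};
    bool mapped[2];
    for (int m = 0; m < 2; ++m)
      mapped[m] = chosen[m] >= 0 && cands[m][chosen[m]].score >= P.min_score;

    for (int m = 0; m < 2; ++m) {
      int other = 1 - m;
      int L = (int)s[m].size();
      int flag = 0x1 | (m == 0 ? 0x40 : 0x80);
      int contig = 0, pos = 0, mapq = 0, score = 0;
      std::string cg = "*";
      bool rcflag = false;
      if (mapped[m]) {
        const Candidate& c = cands[m][chosen[m]];
        contig = c.contig + 1;
        pos = c.pos;
        cg = c.cigar;
        score = c.score;
        rcflag = c.rc;
        if (rcflag) flag |= 0x10;
        if (pc.proper && mapped[other]) flag |= 0x2;
        mapq = mapq_for(cands[m], chosen[m], L, P);
      } else {
        flag |= 0x4;
      }
      int mcontig = 0, mpos = 0;
      if (mapped[other]) {
        const Candidate& oc = cands[other][chosen[other]];
        mcontig = oc.contig + 1;
        mpos = oc.pos;
        if (oc.rc) flag |= 0x20;
      } else {
        flag |= 0x8;
      }
      if (!mapped[m] && mapped[other]) {  // convention: place with mate
        contig = mcontig;
        pos = mpos;
      }
      int tlen = 0;
      if (mapped[m] && mapped[other] && pc.proper) {
        const Candidate& c = cands[m][chosen[m]];
        const Candidate& oc = cands[other][chosen[other]];
        int lo = std::min(c.pos, oc.pos);
        int hi = std::max(c.pos + ref_span_of(c), oc.pos + ref_span_of(oc));
        tlen = (c.pos <= oc.pos) ? (hi - lo) : -(hi - lo);
      }
      std::string oseq = rcflag ? rc[m] : s[m];
      std::string oq = q[m];
      if (rcflag) std::reverse(oq.begin(), oq.end());
      o_qname.push_back(qn);
      o_flag.push_back(flag);
      o_contig.push_back(contig);
      o_pos.push_back(pos);
      o_mapq.push_back(mapq);
      o_cigar.push_back(cg);
      o_mcontig.push_back(mcontig);
      o_mpos.push_back(mpos);
      o_tlen.push_back(tlen);
      o_seq.push_back(oseq);
      o_qual.push_back(oq);
      o_score.push_back(score);
      o_pairscore.push_back(pc.pair_score);
      o_read.push_back(m + 1);

      // supplementary alignments for poorly covered reads
      if (mapped[m]) {
        const Candidate& c = cands[m][chosen[m]];
        if (c.read_end - c.read_start < P.cover_fraction * L) {
          int n_supp = 0;
          std::vector<size_t> order;
          for (size_t k = 0; k < cands[m].size(); ++k)
            if ((int)k != chosen[m]) order.push_back(k);
          std::sort(order.begin(), order.end(), [&](size_t x, size_t y) {
            return cands[m][x].score > cands[m][y].score;
          });
          for (size_t k : order) {
            if (n_supp >= 3) break;
            const Candidate& sc = cands[m][k];
            if (sc.score < P.min_score) continue;
            int ov = std::min(sc.read_end, c.read_end) -
                     std::max(sc.read_start, c.read_start);
            int slen = sc.read_end - sc.read_start;
            if (slen <= 0 || ov * 2 > slen) continue;
            ++n_supp;
            o_qname.push_back(qn);
            o_flag.push_back(flag | 0x800);
            o_contig.push_back(sc.contig + 1);
            o_pos.push_back(sc.pos);
            o_mapq.push_back(mapq);  // segment confidence follows the primary
            o_cigar.push_back(sc.cigar);
            o_mcontig.push_back(mcontig);
            o_mpos.push_back(mpos);
            o_tlen.push_back(0);
            std::string sseq = sc.rc ? rc[m] : s[m];
            std::string sq = q[m];
            if (sc.rc) std::reverse(sq.begin(), sq.end());
            o_seq.push_back(sseq);
            o_qual.push_back(sq);
            o_score.push_back(sc.score);
            o_pairscore.push_back(pc.pair_score);
            o_read.push_back(m + 1);
          }
        }
      }
    }
  }

  return List::create(
      _["qname"] = wrap(o_qname), _["flag"] = wrap(o_flag),
      _["contig"] = wrap(o_contig), _["pos"] = wrap(o_pos),
      _["mapq"] = wrap(o_mapq), _["cigar"] = wrap(o_cigar),
      _["mcontig"] = wrap(o_mcontig), _["mpos"] = wrap(o_mpos),
      _["tlen"] = wrap(o_tlen), _["seq"] = wrap(o_seq),
      _["qual"] = wrap(o_qual), _["score"] = wrap(o_score),
      _["pair_score"] = wrap(o_pairscore), _["read"] = wrap(o_read),
      _["n_proper"] = n_proper, _["n_rescued"] = n_rescued,
      _["insert_mean"] = P.insert_mean, _["insert_sd"] = P.insert_sd);
}

// [[Rcpp::export(name = ".build_chains_cpp")]]
DataFrame build_chains_cpp(IntegerVector offset, IntegerVector contig,
                           IntegerVector pos, IntegerVector orient,
                           int seed_len) {
  std::vector<RawHit> hits;
  for (int i = 0; i < offset.size(); ++i)
    hits.push_back({contig[i], orient[i] == 1, pos[i] - offset[i], offset[i]});
  std::vector<Chain> chains = chains_from_hits(hits, seed_len);
  filter_chains(chains);
  int n = (int)chains.size();
  IntegerVector c(n), d(n), ss(n), se(n), ln(n), ori(n);
  for (int i = 0; i < n; ++i) {
    c[i] = chains[i].contig;
    ori[i] = chains[i].rc ? 1 : 0;
    d[i] = chains[i].diag;
    ss[i] = chains[i].span_start;
    se[i] = chains[i].span_end;
    ln[i] = chains[i].len();
  }
  return DataFrame::create(_["contig"] = c, _["orient"] = ori,
                           _["diagonal"] = d, _["span_start"] = ss,
                           _["span_end"] = se, _["length"] = ln,
                           _["stringsAsFactors"] = false);
}
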