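// Affine-gap alignment engines.
//
// sw_align: local (Smith-Waterman) alignment of a read against a reference
// window, full O(mn) dynamic program with traceback to a CIGAR; unaligned
// read ends become soft clips.  Ties are broken toward the earliest
// reference position, then the fewest gap openings (diagonal moves are
// preferred during traceback).
//
// nw_align: global (ends-anchored) alignment used to read variant events
// off assembled haplotypes; double-precision scores so gentle long-gap
// schemes can be expressed.

#include "rapidseq.h"
using namespace Rcpp;

// traceback codes
enum { TB_NONE = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };

AlnResult sw_align(const std::string& read, const std::string& ref,
                   int match, int mismatch, int gap_open, int gap_extend) {
  int m = (int)read.size(), n = (int)ref.size();
  AlnResult out;
  if (m == 0 || n == 0) return out;
  int go = gap_open + gap_extend;  // cost of a 1-long gap
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), INT_MIN / 2),
      F((m + 1) * (n + 1), INT_MIN / 2);
  std::vector<uint8_t> tbH((m + 1) * (n + 1), TB_NONE),
      tbE((m + 1) * (n + 1), 0), tbF((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int s = (read[i - 1] == ref[j - 1] && is_acgt(read[i - 1])) ? match
                                                                  : -mismatch;
      // E: gap in reference (insertion in read, consumes read)
      int e_open = H[at(i - 1, j)] - go, e_ext = E[at(i - 1, j)] - gap_extend;
      E[at(i, j)] = std::max(e_open, e_ext);
      tbE[at(i, j)] = e_open >= e_ext ? 1 : 0;  // 1 = came from H
      // F: gap in read (deletion, consumes reference)
      int f_open = H[at(i, j - 1)] - go, f_ext = F[at(i, j - 1)] - gap_extend;
      F[at(i, j)] = std::max(f_open, f_ext);
      tbF[at(i, j)] = f_open >= f_ext ? 1 : 0;
      int diag = H[at(i - 1, j - 1)] + s;
      int h = diag;
      uint8_t tb = TB_DIAG;
      if (E[at(i, j)] > h) { h = E[at(i, j)]; tb = TB_UP; }
      if (F[at(i, j)] > h) { h = F[at(i, j)]; tb = TB_LEFT; }
      if (h <= 0) { h = 0; tb = TB_NONE; }
      H[at(i, j)] = h;
      tbH[at(i, j)] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  out.score = best;
  if (best <= 0) {  // zero homology: fully soft-clipped, empty alignment
    out.read_start = 0;
    out.read_end = 0;
    return out;
  }
  // traceback
  std::vector<CigarOp> rev;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  int n_gapops = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      uint8_t tb = tbH[at(i, j)];
      if (tb == TB_NONE) break;
      if (tb == TB_DIAG) {
        if (!rev.empty() && rev.back().op == 'M') rev.back().len++;
        else rev.push_back({'M', 1});
        --i; --j;
      } else if (tb == TB_UP) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      if (!rev.empty() && rev.back().op == 'I') rev.back().len++;
      else { rev.push_back({'I', 1}); ++n_gapops; }
      bool from_h = tbE[at(i, j)] == 1;
      --i;
      state = from_h ? 0 : 1;
    } else {
      if (!rev.empty() && rev.back().op == 'D') rev.back().len++;
      else { rev.push_back({'D', 1}); ++n_gapops; }
      bool from_h = tbF[at(i, j)] == 1;
      --j;
      state = from_h ? 0 : 2;
    }
  }
  out.ref_start = j;
  out.read_start = i;
  out.read_end = bi;
  out.n_gapops = n_gapops;
  out.cigar.assign(rev.rbegin(), rev.rend());
  return out;
}

AlnResult nw_align(const std::string& a, const std::string& b,
                   double match, double mismatch, double gap_open,
                   double gap_extend) {
  int m = (int)a.size(), n = (int)b.size();
  AlnResult out;
  const double NEG = -1e18;
  double go = gap_open + gap_extend;
  std::vector<double> H((m + 1) * (n + 1), NEG), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  std::vector<uint8_t> tbH((m + 1) * (n + 1), TB_NONE),
      tbE((m + 1) * (n + 1), 0), tbF((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  H[at(0, 0)] = 0;
  for (int i = 1; i <= m; ++i) {
    E[at(i, 0)] = -go - gap_extend * (i - 1);
    H[at(i, 0)] = E[at(i, 0)];
    tbH[at(i, 0)] = TB_UP;
    tbE[at(i, 0)] = (i == 1) ? 1 : 0;
  }
  for (int j = 1; j <= n; ++j) {
    F[at(0, j)] = -go - gap_extend * (j - 1);
    H[at(0, j)] = F[at(0, j)];
    tbH[at(0, j)] = TB_LEFT;
    tbF[at(0, j)] = (j == 1) ? 1 : 0;
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = (a[i - 1] == b[j - 1] && is_acgt(a[i - 1])) ? match : -mismatch;
      double e_open = H[at(i - 1, j)] - go, e_ext = E[at(i - 1, j)] - gap_extend;
      E[at(i, j)] = std::max(e_open, e_ext);
      tbE[at(i, j)] = e_open >= e_ext ? 1 : 0;
      double f_open = H[at(i, j - 1)] - go, f_ext = F[at(i, j - 1)] - gap_extend;
      F[at(i, j)] = std::max(f_open, f_ext);
      tbF[at(i, j)] = f_open >= f_ext ? 1 : 0;
      double diag = H[at(i - 1, j - 1)] + s;
      double h = diag;
      uint8_t tb = TB_DIAG;
      if (E[at(i, j)] > h) { h = E[at(i, j)]; tb = TB_UP; }
      if (F[at(i, j)] > h) { h = F[at(i, j)]; tb = TB_LEFT; }
      H[at(i, j)] = h;
      tbH[at(i, j)] = tb;
    }
  }
  out.score = (int)std::lround(H[at(m, n)]);
  std::vector<CigarOp> rev;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      uint8_t tb = tbH[at(i, j)];
      if (tb == TB_DIAG) {
        if (!rev.empty() && rev.back().op == 'M') rev.back().len++;
        else rev.push_back({'M', 1});
        --i; --j;
      } else if (tb == TB_UP) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (!rev.empty() && rev.back().op == 'I') rev.back().len++;
      else { rev.push_back({'I', 1}); ++out.n_gapops; }
      bool from_h = tbE[at(i, j)] == 1;
      --i;
      state = from_h ? 0 : 1;
    } else {
      if (!rev.empty() && rev.back().op == 'D') rev.back().len++;
      else { rev.push_back({'D', 1}); ++out.n_gapops; }
      bool from_h = tbF[at(i, j)] == 1;
      --j;
      state = from_h ? 0 : 2;
    }
  }
  out.ref_start = 0;
  out.read_start = 0;
  out.read_end = m;
  out.cigar.assign(rev.rbegin(), rev.rend());
  return out;
}

std::string cigar_string(const AlnResult& a, int read_len) {
  if (a.cigar.empty()) return "*";  // empty alignment (fully clipped)
  std::string s;
  if (a.read_start > 0) s += std::to_string(a.read_start) + "S";
  for (auto& op : a.cigar) s += std::to_string(op.len) + op.op;
  if (read_len - a.read_end > 0) s += std::to_string(read_len - a.read_end) + "S";
  if (s.empty()) s = "*";
  return s;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string ref, int match, int mismatch,
                  int gap_open, int gap_extend) {
  if (read.empty() || ref.empty())
    stop("smith_waterman: both sequences must be non-empty");
  AlnResult a = sw_align(read, ref, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = a.score, _["ref_start"] = a.ref_start,
                      _["cigar"] = cigar_string(a, (int)read.size()),
                      _["read_start"] = a.read_start,
                      _["read_end"] = a.read_end, _["n_gapops"] = a.n_gapops);
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend) {
  AlnResult r = nw_align(a, b, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = r.score,
                      _["cigar"] = cigar_string(r, (int)a.size()));
}

// Fixed-diagonal (gapless) local alignment: the read is placed at a single
// anchor offset in the window; the best-scoring contiguous read segment is
// kept and the rest soft-clipped (Kadane over per-base scores).
// [[Rcpp::export(name = ".gapless_align_cpp")]]
List gapless_align_cpp(std::string read, std::string window, int anchor,
                       int match, int mismatch) {
  int m = (int)read.size();
  if (anchor < 0 || anchor + m > (int)window.size())
    stop("gapless_align: anchor places the read outside the window");
  int best = 0, best_a = 0, best_b = 0, cur = 0, cur_a = 0;
  for (int i = 0; i < m; ++i) {
    int s = (read[i] == window[anchor + i] && is_acgt(read[i])) ? match
                                                                : -mismatch;
    if (cur <= 0) { cur = 0; cur_a = i; }
    cur += s;
    if (cur > best) { best = cur; best_a = cur_a; best_b = i + 1; }
  }
  return List::create(_["score"] = best, _["clip_left"] = best_a,
                      _["clip_right"] = m - best_b,
                      _["perfect"] = m * match);
}
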