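#' Extract overlapping seeds from a read
#'
#' Seeds of the primary seed length start at offsets 0, stride, 2*stride,
#' ... such that the seed fits in the read; seeds containing non-ACGT
#' bases are omitted.
#'
#' @param read_seq read sequence
#' @param params an [index_params()]
#' @return data.table with columns offset (0-based) and seed
#' @export
extract_seeds <- function(read_seq, params = index_params()) {
  L <- nchar(read_seq)
  k <- params$primary_seed_len
  if (L < k) {
    return(data.table::data.table(offset = integer(), seed = character()))
  }
  offs <- seq(0L, L - k, by = params$seed_stride)
  seeds <- substring(read_seq, offs + 1L, offs + k)
  ok <- !grepl("[^ACGT]", seeds)
  data.table::data.table(offset = offs[ok], seed = seeds[ok])
}

#' Group seed hits into chains by alignment diagonal
#'
#' Hits sharing a (contig, orientation, diagonal) are merged into one
#' chain (diagonal = reference position - read offset).  A chain is
#' conservatively filtered out when another chain at least four times
#' longer overlaps more than half of its read span.
#'
#' @param hits data.frame with columns offset, contig (integer id), pos,
#'   orient (0 forward / 1 reverse-complement)
#' @param seed_len seed length in nt
#' @return data.table of chains: contig, orient, diagonal, span_start,
#'   span_end, length
#' @export
build_chains <- function(hits, seed_len = 21L) {
  if (nrow(hits) == 0L) {
    return(data.table::data.table(contig = integer(), orient = integer(),
                                  diagonal = integer(),
                                  span_start = integer(),
                                  span_end = integer(), length = integer()))
  }
  data.table::as.data.table(
    .build_chains_cpp(as.integer(hits$offset), as.integer(hits$contig),
                      as.integer(hits$pos), as.integer(hits$orient),
                      as.integer(seed_len)))
}

#' Gapless fixed-diagonal alignment
#'
#' Places the read at a single anchor offset in the reference window and
#' finds the best-scoring contiguous read segment, soft-clipping the
#' rest.  The `needs_gapped` heuristic flags candidates for which gapped
#' Smith-Waterman has a non-trivial chance of improving the result: score
#' below `trigger_fraction` of the perfect score, or a clip longer than
#' `clip_trigger`.
#'
#' @param read_seq read sequence
#' @param ref_window reference window sequence
#' @param anchor 0-based offset of the read start within the window
#' @param scheme a [scoring_scheme()]
#' @param trigger_fraction,clip_trigger gapped-alignment triggers
#' @return list(score, clip_left, clip_right, perfect, needs_gapped)
#' @export
gapless_align <- function(read_seq, ref_window, anchor,
                          scheme = scoring_scheme(),
                          trigger_fraction = 0.9, clip_trigger = 5L) {
  r <- .gapless_align_cpp(read_seq, ref_window, as.integer(anchor),
                          scheme$match, scheme$mismatch)
  r$needs_gapped <- r$score < trigger_fraction * r$perfect ||
    max(r$clip_left, r$clip_right) > clip_trigger
  r
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Full O(mn) dynamic program with traceback; unaligned read ends are
#' reported as soft clips in the CIGAR.  Ties are broken toward the
#' earliest reference position, then toward fewer gap openings.
#'
#' @param read_seq read sequence
#' @param ref_window reference window
#' @param scheme a [scoring_scheme()]
#' @return list(score, ref_start (0-based in window), cigar, read_start,
#'   read_end, n_gapops)
#' @export
smith_waterman <- function(read_seq, ref_window, scheme = scoring_scheme()) {
  .sw_align_cpp(read_seq, ref_window, scheme$match, scheme$mismatch,
                scheme$gap_open, scheme$gap_extend)
}

#' Rescue scan: approximate k-mer search in a mate window
#'
#' Scans `[wstart, wend)` (0-based, half-open) of a contig for positions
#' whose first `kmer_len` bases match the target sequence within
#' `max_hamming` mismatches.
#'
#' @param contig_seq contig sequence
#' @param wstart,wend window bounds (0-based, half-open)
#' @param target expected mate sequence in reference orientation
#' @param kmer_len k-mer length
#' @param max_hamming maximum Hamming distance
#' @return integer vector of matching 0-based positions
#' @export
rescue_scan <- function(contig_seq, wstart, wend, target, kmer_len = 24L,
                        max_hamming = 3L) {
  .rescue_scan_cpp(contig_seq, as.integer(wstart), as.integer(wend),
                   target, as.integer(kmer_len), as.integer(max_hamming))
}

#' Map paired-end reads against an indexed reference
#'
#' The full mapping pipeline per pair: seed extraction and index lookup,
#' diagonal chaining with the 4x overlap filter, insert-based pairing
#' with a rescue scan for unpaired mates, gapless then (when triggered)
#' Smith-Waterman alignment, pair scoring, MAPQ estimation, and up to
#' three supplementary alignments for reads whose primary alignment
#' covers less than `cover_fraction` of the read.
#'
#' @param idx a `seq_index` from [build_index()]
#' @param reads1,reads2 data.tables with columns id, seq, qual (as from
#'   [read_fastq()]); mates in matching row order
#' @param params a [map_params()]
#' @return data.table of alignment records (0-based positions) with
#'   attributes `pairing` (proper-pair and rescue counts) and
#'   `insert_model`
#' @export
map_reads <- function(idx, reads1, reads2, params = map_params()) {
  stopifnot(inherits(idx, "seq_index"), nrow(reads1) == nrow(reads2))
  r <- .map_pairs_cpp(idx$ptr, reads1$id, reads1$seq, reads1$qual,
                      reads2$seq, reads2$qual, unclass(params))
  aln <- data.table::data.table(
    qname = r$qname, flag = r$flag, contig = r$contig, pos = r$pos,
    mapq = r$mapq, cigar = r$cigar, mcontig = r$mcontig, mpos = r$mpos,
    tlen = r$tlen, seq = r$seq, qual = r$qual, score = r$score,
    pair_score = r$pair_score, read = r$read
  )
  data.table::setattr(aln, "pairing",
                      list(n_pairs = nrow(reads1), n_proper = r$n_proper,
                           n_rescued = r$n_rescued))
  data.table::setattr(aln, "insert_model",
                      list(mean = r$insert_mean, sd = r$insert_sd))
  data.table::setattr(aln, "contig_names", names(idx$ref))
  aln
}
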