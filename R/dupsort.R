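#' Coordinate-sort alignments and flag PCR duplicates
#'
#' Records are ordered by (contig order in the header, position,
#' orientation); read pairs sharing both mates' 5'-unclipped positions
#' and orientations form a duplicate group, of which only the member with
#' the highest pair score stays unflagged (ties broken by read id).  The
#' duplicate flag is SAM FLAG bit 0x400.  Unmapped, supplementary and
#' single-end-mapped records are never flagged.
#'
#' @param aln alignment data.table as from [map_reads()]
#' @param mark flag duplicates? (sorting happens either way)
#' @return a new, sorted data.table with updated `flag`
#' @export
sort_and_mark_duplicates <- function(aln, mark = TRUE) {
  aln <- data.table::copy(aln)
  # clear any previous duplicate flags so the operation is idempotent
  aln[, flag := bitwAnd(flag, bitwNot(0x400L))]

  if (mark && nrow(aln) > 0L) {
    is_rev <- bitwAnd(aln$flag, 0x10L) != 0L
    mapped <- bitwAnd(aln$flag, 0x4L) == 0L
    primary <- bitwAnd(aln$flag, 0x800L) == 0L
    # 5' unclipped coordinate: clip-adjusted alignment start (forward) or
    # end (reverse)
    lead_clip <- integer(nrow(aln))
    tail_clip <- integer(nrow(aln))
    refspan <- integer(nrow(aln))
    has_cigar <- aln$cigar != "*"
    lead <- regmatches(aln$cigar, regexpr("^[0-9]+S", aln$cigar))
    lead_clip[has_cigar & grepl("^[0-9]+S", aln$cigar)] <-
      as.integer(sub("S", "", lead))
    tail <- regmatches(aln$cigar, regexpr("[0-9]+S$", aln$cigar))
    tail_clip[has_cigar & grepl("[0-9]+S$", aln$cigar)] <-
      as.integer(sub("S", "", tail))
    ucig <- unique(aln$cigar[has_cigar])
    uspan <- vapply(ucig, cigar_ref_span, numeric(1))
    refspan[has_cigar] <- uspan[match(aln$cigar[has_cigar], ucig)]
    key5 <- ifelse(is_rev, aln$pos + refspan + tail_clip,
                   aln$pos - lead_clip)
    mate_key <- paste(aln$contig, key5, as.integer(is_rev), sep = ":")
    dkey <- rep(NA_character_, nrow(aln))
    use <- mapped & primary
    # pair the two primary mates by qname and build an unordered pair key
    prim <- data.table::data.table(row = which(use),
                                   qname = aln$qname[use],
                                   mk = mate_key[use])
    pairs <- prim[, if (.N == 2L) {
      list(row = row, key = paste(sort(mk), collapse = "|"))
    }, by = qname]
    if (nrow(pairs) > 0L) {
      dkey[pairs$row] <- pairs$key
      grp <- data.table::data.table(
        row = pairs$row, gkey = pairs$key,
        score = aln$pair_score[pairs$row], qname = aln$qname[pairs$row])
      # keep the highest pair-score pair per group unflagged
      best <- grp[order(gkey, -score, qname)][!duplicated(gkey)]
      keep_q <- best$qname[match(grp$gkey, best$gkey)]
      flag_rows <- grp$row[grp$qname != keep_q]
      aln$flag[flag_rows] <- bitwOr(aln$flag[flag_rows], 0x400L)
      # a flagged primary also flags its supplementary records
      dup_q <- unique(aln$qname[flag_rows])
      supp <- which(!primary & aln$qname %in% dup_q)
      aln$flag[supp] <- bitwOr(aln$flag[supp], 0x400L)
    }
  }

  unmapped <- bitwAnd(aln$flag, 0x4L) != 0L
  ord <- order(unmapped, aln$contig, aln$pos,
               bitwAnd(aln$flag, 0x10L) != 0L, aln$qname, aln$read,
               method = "radix")
  aln[ord]
}
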