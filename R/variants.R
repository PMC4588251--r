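# Variant-event representation and left-normalization.
#
# Internally an event is (contig, pos, ref, alt) with 0-based pos and
# VCF-style anchored alleles for indels (first base shared).  Events are
# always stored left-normalized.

#' Left-normalize a variant event
#'
#' Shifts an insertion or deletion to its leftmost equivalent placement
#' against the reference sequence and strips redundant shared bases, the
#' usual VCF normalization.  SNVs are returned unchanged (after shared
#' prefix/suffix trimming).
#'
#' @param contig_seq the full contig sequence the event lies on
#' @param pos 0-based event position
#' @param ref,alt reference and alternate alleles
#' @return list(pos, ref, alt), 0-based, anchored, left-normalized
#' @export
normalize_variant <- function(contig_seq, pos, ref, alt) {
  # trim shared suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim shared prefix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) == nchar(alt)) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  # indel: reduce to an inserted/deleted segment at a 0-based cut point
  if (nchar(ref) < nchar(alt)) {  # insertion
    anchored <- substr(alt, 1L, 1L) == substr(ref, 1L, 1L) && nchar(ref) == 1L
    if (anchored) {
      seg <- substr(alt, 2L, nchar(alt))
      cut <- pos + 1L  # insertion before contig_seq[cut] (0-based)
    } else {
      seg <- alt
      cut <- pos
    }
    L <- nchar(seg)
    repeat {
      if (cut <= 0L) break
      prev <- substr(contig_seq, cut, cut)  # base at 0-based cut-1
      if (substr(seg, L, L) != prev) break
      seg <- paste0(prev, substr(seg, 1L, L - 1L))
      cut <- cut - 1L
    }
    if (cut <= 0L) {  # cannot anchor on the left: anchor on the right
      anchor <- substr(contig_seq, 1L, 1L)
      return(list(pos = 0L, ref = anchor, alt = paste0(seg, anchor)))
    }
    anchor <- substr(contig_seq, cut, cut)
    return(list(pos = cut - 1L, ref = anchor, alt = paste0(anchor, seg)))
  }
  # deletion
  anchored <- substr(alt, 1L, 1L) == substr(ref, 1L, 1L) && nchar(alt) == 1L
  if (anchored) {
    del_start <- pos + 1L  # 0-based start of the deleted segment
    L <- nchar(ref) - 1L
  } else {
    del_start <- pos
    L <- nchar(ref)
  }
  while (del_start > 0L &&
         substr(contig_seq, del_start, del_start) ==
         substr(contig_seq, del_start + L, del_start + L)) {
    del_start <- del_start - 1L
  }
  if (del_start <= 0L) {
    seg <- substr(contig_seq, 1L, L)
    anchor <- substr(contig_seq, L + 1L, L + 1L)
    return(list(pos = 0L, ref = paste0(seg, anchor), alt = anchor))
  }
  anchor <- substr(contig_seq, del_start, del_start)
  seg <- substr(contig_seq, del_start + 1L, del_start + L)
  list(pos = del_start - 1L, ref = paste0(anchor, seg), alt = anchor)
}

#' Classify a variant event
#' @param ref,alt alleles
#' @return "SNV", "insertion", or "deletion"
#' @export
variant_type <- function(ref, alt) {
  data.table::fifelse(nchar(ref) == nchar(alt), "SNV",
                      data.table::fifelse(nchar(ref) < nchar(alt),
                                          "insertion", "deletion"))
}

# parse a CIGAR string into op letters and lengths
parse_cigar <- function(cigar) {
  if (cigar == "*") return(list(op = character(), len = integer()))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(op = op, len = len)
}

# reference footprint (M/D/N) of a CIGAR
cigar_ref_span <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "D", "N", "=", "X")])
}

# read bases consumed (M/I/S) by a CIGAR
cigar_read_span <- function(cigar) {
  p <- parse_cigar(cigar)
  sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
}

#' Extract variant events from a haplotype's alignment to the reference
#'
#' The haplotype is globally aligned (ends anchored to the region bounds)
#' to the reference segment; mismatching columns yield SNVs and gap runs
#' yield indels, each left-normalized against the contig.
#'
#' @param hap haplotype sequence
#' @param ref_seg reference segment the region spans
#' @param contig_seq full contig sequence (for left-normalization)
#' @param region_start 0-based contig offset of `ref_seg`
#' @param max_event_len discard indels longer than this (assembly noise)
#' @return data.table of events: pos (0-based, contig coords), ref, alt,
#'   type
#' @export
haplotype_events <- function(hap, ref_seg, contig_seq, region_start = 0L,
                             max_event_len = 470L) {
  empty <- data.table::data.table(pos = integer(), ref = character(),
                                  alt = character(), type = character())
  if (hap == ref_seg) return(empty)
  # gentle long-gap scheme so a single long indel beats a mismatch run
  a <- .nw_align_cpp(hap, ref_seg, 2, 3, 6, 0.2)
  p <- parse_cigar(a$cigar)
  events <- list()
  hp <- 0L  # cursor in hap
  rp <- 0L  # cursor in ref_seg
  for (i in seq_along(p$op)) {
    op <- p$op[i]
    len <- p$len[i]
    if (op == "M") {
      hseg <- substr(hap, hp + 1L, hp + len)
      rseg <- substr(ref_seg, rp + 1L, rp + len)
      if (hseg != rseg) {
        hb <- strsplit(hseg, "")[[1]]
        rb <- strsplit(rseg, "")[[1]]
        mm <- which(hb != rb)
        for (j in mm) {
          events[[length(events) + 1L]] <-
            list(pos = region_start + rp + j - 1L, ref = rb[j], alt = hb[j])
        }
      }
      hp <- hp + len
      rp <- rp + len
    } else if (op == "I") {  # present in hap, absent from ref
      if (len <= max_event_len && rp > 0L) {
        ins <- substr(hap, hp + 1L, hp + len)
        anchor <- substr(ref_seg, rp, rp)
        events[[length(events) + 1L]] <-
          list(pos = region_start + rp - 1L, ref = anchor,
               alt = paste0(anchor, ins))
      }
      hp <- hp + len
    } else if (op == "D") {  # deleted from hap
      if (len <= max_event_len && rp > 0L) {
        del <- substr(ref_seg, rp + 1L, rp + len)
        anchor <- substr(ref_seg, rp, rp)
        events[[length(events) + 1L]] <-
          list(pos = region_start + rp - 1L, ref = paste0(anchor, del),
               alt = anchor)
      }
      rp <- rp + len
    }
  }
  if (length(events) == 0L) return(empty)
  ev <- data.table::rbindlist(events)
  norm <- lapply(seq_len(nrow(ev)), function(i) {
    normalize_variant(contig_seq, ev$pos[i], ev$ref[i], ev$alt[i])
  })
  out <- data.table::data.table(
    pos = vapply(norm, `[[`, integer(1), "pos"),
    ref = vapply(norm, `[[`, character(1), "ref"),
    alt = vapply(norm, `[[`, character(1), "alt")
  )
  out$type <- variant_type(out$ref, out$alt)
  unique(out)
}
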