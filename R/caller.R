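#' Detect callable and active regions from sorted alignments
#'
#' Callable columns have at least `min_depth` aligned reads with MAPQ at
#' or above `min_mapq` (duplicates excluded).  Active regions are maximal
#' runs of callable columns whose non-reference evidence fraction
#' (mismatches, indels, long soft-clip boundaries) reaches
#' `evidence_threshold` with at least `min_evidence` supporting reads;
#' runs are padded by `base_pad` nt, or `indel_pad` nt when the run
#' carries indel evidence, then merged.
#'
#' @param aln sorted alignment data.table (see [sort_and_mark_duplicates()])
#' @param ref reference genome (named character vector)
#' @param params a [caller_params()]
#' @param min_evidence minimum non-reference read count per trigger column
#' @return list with `regions` (data.table: contig, start, end, 0-based
#'   half-open, has_indel) and `callable` (per-contig logical vectors)
#' @export
detect_regions <- function(aln, ref, params = caller_params(),
                           min_evidence = 3L) {
  regions <- list()
  callable <- list()
  # supplementary records stay in: their aligned segments are disjoint
  # from the primary's, and their clips mark indel/breakpoint junctions
  usable <- bitwAnd(aln$flag, 0x4L) == 0L & bitwAnd(aln$flag, 0x400L) == 0L
  for (ci in seq_along(ref)) {
    cn <- names(ref)[ci]
    sub <- aln[usable & aln$contig == ci]
    clen <- nchar(ref[[ci]])
    if (nrow(sub) == 0L) {
      callable[[cn]] <- rep(FALSE, clen)
      next
    }
    ps <- .pileup_scan_cpp(ref[[ci]], sub$pos, sub$cigar, sub$seq, sub$mapq,
                           rep(FALSE, nrow(sub)), params$min_mapq, 5L)
    call_vec <- ps$depth >= params$min_depth
    callable[[cn]] <- call_vec
    active <- call_vec & ps$depth > 0L &
      ps$nonref >= min_evidence &
      ps$nonref / pmax(ps$depth, 1L) >= params$evidence_threshold
    if (!any(active)) next
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.table::data.table(start = starts[r$values],
                                   end = ends[r$values])
    runs[, has_indel := vapply(seq_len(.N), function(i) {
      any(ps$indel[runs$start[i]:runs$end[i]] > 0L)
    }, logical(1))]
    pad <- ifelse(runs$has_indel, params$indel_pad, params$base_pad)
    runs[, `:=`(start = pmax(0L, start - 1L - pad),
                end = pmin(clen, end + pad))]
    data.table::setorder(runs, start)
    # merge overlapping padded runs
    merged <- list()
    cs <- runs$start[1]; ce <- runs$end[1]; ind <- runs$has_indel[1]
    if (nrow(runs) > 1L) {
      for (i in 2:nrow(runs)) {
        if (runs$start[i] <= ce) {
          ce <- max(ce, runs$end[i])
          ind <- ind || runs$has_indel[i]
        } else {
          merged[[length(merged) + 1L]] <- list(start = cs, end = ce,
                                                has_indel = ind)
          cs <- runs$start[i]; ce <- runs$end[i]; ind <- runs$has_indel[i]
        }
      }
    }
    merged[[length(merged) + 1L]] <- list(start = cs, end = ce,
                                          has_indel = ind)
    m <- data.table::rbindlist(merged)
    m[, contig := cn]
    regions[[length(regions) + 1L]] <- m
  }
  regs <- if (length(regions)) {
    data.table::rbindlist(regions)[, .(contig, start, end, has_indel)]
  } else {
    data.table::data.table(contig = character(), start = integer(),
                           end = integer(), has_indel = logical())
  }
  list(regions = regs, callable = callable)
}

#' Assemble candidate haplotypes for an active region
#'
#' Builds a De Bruijn graph from the region's reads over the reference
#' backbone, trying each k in the schedule until the graph is
#' non-degenerate (backbone k-mers unique, acyclic from the source), and
#' enumerates source-to-sink paths as haplotypes, preferring higher-weight
#' paths when the cap binds.  If every k is degenerate the reference
#' haplotype alone is returned, flagged.
#'
#' @param reads character vector of read sequences assigned to the region
#' @param ref_seg reference backbone sequence for the region
#' @param params a [caller_params()]
#' @return list(haplotypes, weights, k, degenerate)
#' @export
assemble_haplotypes <- function(reads, ref_seg, params = caller_params()) {
  stopifnot(length(reads) >= 1L)
  .assemble_region_cpp(ref_seg, reads, params$k_schedule,
                       params$prune_weight, params$max_haplotypes)
}

#' Pair-HMM read likelihood P(r|H)
#'
#' Forward-algorithm sum over all alignments of the read to the
#' haplotype under an affine-gap HMM; see [caller_params()] for the gap
#' and PCR error model.  Returns log10 P(r|H).
#'
#' @param read_seq read sequence
#' @param qual integer base qualities (or a Phred+33 string)
#' @param hap haplotype sequence
#' @param mapq read mapping quality, caps the base qualities
#' @param params a [caller_params()]
#' @return log10 probability (scalar, <= 0)
#' @export
pair_hmm <- function(read_seq, qual, hap, mapq = 60L,
                     params = caller_params()) {
  if (is.character(qual)) qual <- phred_decode(qual)
  .pair_hmm_cpp(read_seq, as.integer(qual), hap, as.integer(mapq),
                params$hmm_gap_ext, params$pcr_scale, params$pcr_slope,
                params$pcr_max_run)
}

#' Genotype one position from event-supported read likelihoods
#'
#' Candidate genotypes are all diploid combinations of the alleles
#' observed at the position (reference included).  Per read,
#' P(r|e) is the maximum P(r|H) over haplotypes supporting the event;
#' a diplotype's per-read likelihood is the even mixture
#' 0.5 P(r|e1) + 0.5 P(r|e2), multiplied over overlapping reads and
#' combined with the heterozygosity prior by Bayes' formula.
#'
#' @param allele_logp matrix of log10 P(r|e): rows = reads overlapping the
#'   position, columns = alleles, column 1 = reference
#' @param theta heterozygosity prior mass shared by non-reference
#'   diplotypes
#' @return list(a1, a2 (column indices, a1 <= a2), posterior, gq,
#'   posteriors (named vector over all diplotypes))
#' @export
genotype_site <- function(allele_logp, theta = 0.001) {
  na <- ncol(allele_logp)
  combos <- which(upper.tri(matrix(0, na, na), diag = TRUE), arr.ind = TRUE)
  n_dip <- nrow(combos)
  n_nonref <- n_dip - 1L
  logpost <- numeric(n_dip)
  for (d in seq_len(n_dip)) {
    a1 <- combos[d, 1L]; a2 <- combos[d, 2L]
    p1 <- allele_logp[, a1]; p2 <- allele_logp[, a2]
    m <- pmax(p1, p2)
    lik <- sum(m + log10(0.5 * 10^(p1 - m) + 0.5 * 10^(p2 - m)))
    prior <- if (a1 == 1L && a2 == 1L) log10(1 - theta)
             else log10(theta / n_nonref)
    logpost[d] <- lik + prior
  }
  mx <- max(logpost)
  post <- 10^(logpost - mx)
  post <- post / sum(post)
  names(post) <- paste(combos[, 1L], combos[, 2L], sep = "/")
  win <- which.max(post)
  gq <- min(99, round(-10 * log10(max(1 - post[win], 1e-10))))
  list(a1 = unname(combos[win, 1L]), a2 = unname(combos[win, 2L]),
       posterior = unname(post[win]), gq = as.integer(gq),
       posteriors = post)
}

# gather the rows of a contig's alignment table relevant to one region
.region_reads <- function(sub, start, end, insert_reach = 600L) {
  mapped <- bitwAnd(sub$flag, 0x4L) == 0L
  ov <- mapped & sub$pos < end & sub$aend > start
  un <- !mapped & sub$pos >= (start - insert_reach) &
    sub$pos <= (end + insert_reach) & sub$contig > 0L
  list(mapped = which(ov), unmapped = which(un))
}

#' Call small variants from sorted alignments
#'
#' The haplotype-based calling pipeline: active-region detection, De
#' Bruijn assembly of candidate haplotypes, global realignment of each
#' haplotype to the reference to extract its variant events, pair-HMM
#' read likelihoods, and Bayesian diplotype genotyping per event
#' position.  Unmapped reads placed near a region by their mates join the
#' assembly (both orientations, since their strand is unknown) but do not
#' genotype.
#'
#' @param aln sorted, duplicate-marked alignment data.table
#' @param ref reference genome (named character vector)
#' @param params a [caller_params()]
#' @param verbose print per-contig progress?
#' @return data.table of calls: contig, pos (0-based), ref, alt, qual,
#'   gt, ad_ref, ad_alt, dp, gq, type; attribute `regions` holds the
#'   active-region table
#' @export
call_variants <- function(aln, ref, params = caller_params(),
                          verbose = FALSE) {
  det <- detect_regions(aln, ref, params)
  regs <- det$regions
  calls <- list()
  primary <- bitwAnd(aln$flag, 0x800L) == 0L & bitwAnd(aln$flag, 0x400L) == 0L
  for (ci in seq_along(ref)) {
    cn <- names(ref)[ci]
    creg <- regs[regs$contig == cn]
    if (nrow(creg) == 0L) next
    contig_seq <- ref[[ci]]
    sub <- aln[primary & aln$contig == ci]
    mapped_ok <- bitwAnd(sub$flag, 0x4L) == 0L
    keep <- !mapped_ok | sub$mapq >= params$min_mapq
    sub <- sub[keep]
    ucig <- unique(sub$cigar)
    uspan <- vapply(ucig, cigar_ref_span, numeric(1))
    sub[, aend := pos + uspan[match(cigar, ucig)]]
    if (verbose) {
      message(cn, ": ", nrow(creg), " active region(s)")
    }
    for (ri in seq_len(nrow(creg))) {
      s <- creg$start[ri]; e <- creg$end[ri]
      rr <- .region_reads(sub, s, e)
      idx_m <- rr$mapped
      if (length(idx_m) == 0L) next
      if (length(idx_m) > params$max_region_reads) {
        idx_m <- sort(sample(idx_m, params$max_region_reads))
      }
      ref_seg <- substr(contig_seq, s + 1L, e)
      asm_reads <- sub$seq[idx_m]
      if (length(rr$unmapped)) {
        useq <- sub$seq[rr$unmapped]
        asm_reads <- c(asm_reads, useq, vapply(useq, function(x) {
          paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                collapse = "")
        }, character(1)))
      }
      asm <- assemble_haplotypes(asm_reads, ref_seg, params)
      haps <- asm$haplotypes
      if (length(haps) == 1L && haps[[1]] == ref_seg) next
      ev_by_hap <- lapply(haps, function(h) {
        haplotype_events(h, ref_seg, contig_seq, s, params$max_event_len)
      })
      all_ev <- unique(data.table::rbindlist(ev_by_hap))
      if (nrow(all_ev) == 0L) next
      # read likelihoods against every haplotype
      logp <- .pair_hmm_batch_cpp(
        sub$seq[idx_m], lapply(sub$qual[idx_m], phred_decode), unlist(haps),
        sub$mapq[idx_m], params$hmm_gap_ext, params$pcr_scale,
        params$pcr_slope, params$pcr_max_run)
      ev_key_by_hap <- lapply(ev_by_hap, function(d) {
        if (nrow(d) == 0L) character() else paste(d$pos, d$ref, d$alt)
      })
      rs <- sub$pos[idx_m]
      re <- sub$aend[idx_m]
      for (p in sort(unique(all_ev$pos))) {
        site_ev <- all_ev[all_ev$pos == p]
        ref_len <- max(nchar(site_ev$ref))
        # haplotypes supporting each allele; reference = no event at p
        alt_keys <- paste(site_ev$pos, site_ev$ref, site_ev$alt)
        hap_has_ev_at_p <- vapply(ev_by_hap, function(d) {
          nrow(d) > 0L && any(d$pos <= p + ref_len - 1L & d$pos +
                                nchar(d$ref) - 1L >= p)
        }, logical(1))
        support <- list(which(!hap_has_ev_at_p))
        for (k in alt_keys) {
          support[[length(support) + 1L]] <-
            which(vapply(ev_key_by_hap, function(x) k %in% x, logical(1)))
        }
        ok <- vapply(support, length, integer(1)) > 0L
        if (!ok[1L] || sum(ok) < 2L) next  # need ref plus >= 1 alt
        site_ev <- site_ev[ok[-1L]]
        support <- support[ok]
        over <- rs <= p & re > p
        if (!any(over)) next
        al <- vapply(support, function(hs) {
          if (length(hs) == 1L) logp[over, hs] else
            apply(logp[over, hs, drop = FALSE], 1L, max)
        }, numeric(sum(over)))
        al <- matrix(al, nrow = sum(over))
        g <- genotype_site(al, params$theta)
        if (g$a1 == 1L && g$a2 == 1L) next
        best_allele <- max.col(al, ties.method = "first")
        dp <- nrow(al)
        p_ref_post <- g$posteriors["1/1"]
        qual <- min(99, round(-10 * log10(max(p_ref_post, 1e-10))))
        for (a in unique(c(g$a1, g$a2))) {
          if (a == 1L) next
          evr <- site_ev[a - 1L]
          gt <- if (g$a1 == g$a2) "1/1" else "0/1"
          calls[[length(calls) + 1L]] <- data.table::data.table(
            contig = cn, pos = evr$pos, ref = evr$ref, alt = evr$alt,
            qual = as.numeric(qual), gt = gt,
            ad_ref = sum(best_allele == 1L), ad_alt = sum(best_allele == a),
            dp = dp, gq = g$gq, type = evr$type)
        }
      }
    }
  }
  out <- if (length(calls)) {
    unique(data.table::rbindlist(calls), by = c("contig", "pos", "ref", "alt"))
  } else {
    data.table::data.table(contig = character(), pos = integer(),
                           ref = character(), alt = character(),
                           qual = numeric(), gt = character(),
                           ad_ref = integer(), ad_alt = integer(),
                           dp = integer(), gq = integer(),
                           type = character())
  }
  data.table::setorder(out, contig, pos)
  data.table::setattr(out, "regions", regs)
  out
}
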