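# Independent oracles used to derive expected values.  These deliberately
# use naive algorithms (full dynamic programs, exhaustive enumeration,
# substring scans) so they stay independent of the package's optimized
# code paths.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# --- full-matrix affine-gap local alignment score (Smith-Waterman oracle)
sw_oracle_score <- function(read, ref, match = 2, mismatch = 3,
                            gap_open = 5, gap_extend = 1) {
  m <- nchar(read)
  n <- nchar(ref)
  rb <- strsplit(read, "")[[1]]
  fb <- strsplit(ref, "")[[1]]
  go <- gap_open + gap_extend
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      s <- if (rb[i - 1] == fb[j - 1]) match else -mismatch
      E[i, j] <- max(H[i - 1, j] - go, E[i - 1, j] - gap_extend)
      F[i, j] <- max(H[i, j - 1] - go, F[i, j - 1] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# --- exhaustive alignment-path enumeration for the pair-HMM
# Mirrors the model definition: global in the read, local in the
# haplotype (uniform 1/n start prior over columns 0..n), transitions
# priced at the destination column, insertions emit with probability 1,
# and paths terminate the moment the read is consumed (so they end in a
# match or insert state).
phmm_enum_oracle <- function(read, qual, hap, mapq = 60, gap_ext = 0.1,
                             pcr_scale = 4, pcr_slope = 0.5,
                             pcr_max_run = 6) {
  m <- nchar(read)
  n <- nchar(hap)
  hb <- strsplit(hap, "")[[1]]
  rb <- strsplit(read, "")[[1]]
  run <- integer(n)
  for (j in seq_len(n)) {
    a <- j
    while (a > 1 && hb[a - 1] == hb[j]) a <- a - 1
    b <- j
    while (b < n && hb[b + 1] == hb[j]) b <- b + 1
    run[j] <- b - a + 1L
  }
  go <- 10^(-(pcr_scale - pcr_slope * pmin(run, pcr_max_run)))
  eps <- 10^(-pmin(qual, mapq) / 10)
  em <- function(i, j) if (rb[i] == hb[j]) 1 - eps[i] else eps[i] / 3
  goc <- function(j) go[max(j, 1L)]  # column 0 borrows column 1's rate
  rec <- function(i, j, state) {
    if (i == m) return(1)
    tot <- 0
    if (j < n) {  # -> match at (i+1, j+1)
      tM <- if (state == "M") 1 - 2 * go[j + 1] else 1 - gap_ext
      tot <- tot + tM * em(i + 1, j + 1) * rec(i + 1, j + 1, "M")
    }
    # -> insertion at (i+1, j): no deletion-to-insertion transition
    if (state != "D") {
      tI <- if (state == "M") goc(j) else gap_ext
      tot <- tot + tI * rec(i + 1, j, "I")
    }
    # -> deletion at (i, j+1): no insertion-to-deletion transition, and
    # no deletions before the first read base (a later start column
    # already covers those placements)
    if (j < n && state != "I" && i > 0) {
      tD <- if (state == "M") go[j + 1] else gap_ext
      tot <- tot + tD * rec(i, j + 1, "D")
    }
    tot
  }
  p <- 0
  for (j0 in 0:n) p <- p + (1 / n) * rec(0, j0, "M")
  log10(p)
}

# --- naive substring scan for seed occurrences on both strands
# Returns forward-strand start positions (0-based) of exact occurrences
# of `seed` and of its reverse complement.
naive_seed_scan <- function(ref_seq, seed) {
  scan1 <- function(pat) {
    hits <- integer()
    start <- 1L
    repeat {
      p <- regexpr(pat, substr(ref_seq, start, nchar(ref_seq)),
                   fixed = TRUE)
      if (p < 0) break
      hits <- c(hits, start + p - 2L)  # 0-based
      start <- start + p
    }
    hits
  }
  list(fwd = scan1(seed), rcp = scan1(rc(seed)))
}

# --- brute-force leftmost placement of an indel
# Enumerates every cut point that yields the same altered sequence and
# returns the smallest, as (pos, ref, alt) in anchored VCF form.
leftnorm_oracle <- function(contig_seq, pos, ref, alt) {
  apply_ev <- function(p, r, a) {
    paste0(substr(contig_seq, 1, p), a,
           substr(contig_seq, p + nchar(r) + 1, nchar(contig_seq)))
  }
  target <- apply_ev(pos, ref, alt)
  if (nchar(ref) == nchar(alt)) return(list(pos = pos, ref = ref, alt = alt))
  if (nchar(ref) < nchar(alt)) {  # insertion of L bases
    L <- nchar(alt) - nchar(ref)
    for (q in 1:nchar(contig_seq)) {  # anchored at 0-based q-1
      anchor <- substr(contig_seq, q, q)
      # inserted segment must reproduce the target when placed at q
      seg <- substr(target, q + 1, q + L)
      cand_alt <- paste0(anchor, seg)
      if (apply_ev(q - 1, anchor, cand_alt) == target) {
        return(list(pos = q - 1L, ref = anchor, alt = cand_alt))
      }
    }
  } else {  # deletion of L bases
    L <- nchar(ref) - nchar(alt)
    for (q in 1:nchar(contig_seq)) {
      anchor <- substr(contig_seq, q, q)
      cand_ref <- substr(contig_seq, q, q + L)
      if (nchar(cand_ref) < L + 1) next
      if (apply_ev(q - 1, cand_ref, anchor) == target) {
        return(list(pos = q - 1L, ref = cand_ref, alt = anchor))
      }
    }
  }
  stop("no equivalent placement found")
}

# --- brute-force duplicate grouping by 5'-unclipped key pairs
# Expects one row per primary mate with columns qname, contig, pos,
# rev (logical), lead_clip, tail_clip, refspan, pair_score.
dup_oracle <- function(d) {
  key5 <- ifelse(d$rev, d$pos + d$refspan + d$tail_clip, d$pos - d$lead_clip)
  mk <- paste(d$contig, key5, as.integer(d$rev), sep = ":")
  pk <- tapply(mk, d$qname, function(x) paste(sort(x), collapse = "|"))
  qn <- names(pk)
  sc <- d$pair_score[match(qn, d$qname)]
  dup <- logical(length(qn))
  for (k in unique(pk)) {
    idx <- which(pk == k)
    keep <- idx[order(-sc[idx], qn[idx])][1]
    dup[setdiff(idx, keep)] <- TRUE
  }
  names(dup) <- qn
  dup
}

# assemble the per-mate table dup_oracle() needs from primary mapped
# alignment rows
dup_oracle_input <- function(prim) {
  lead <- integer(nrow(prim))
  has_lead <- grepl("^[0-9]+S", prim$cigar)
  lead[has_lead] <- as.integer(sub("S.*$", "",
                                   prim$cigar[has_lead]))
  tail_ <- integer(nrow(prim))
  has_tail <- grepl("[0-9]+S$", prim$cigar)
  tail_[has_tail] <- as.integer(sub("^.*[MID]([0-9]+)S$", "\\1",
                                    prim$cigar[has_tail]))
  data.frame(qname = prim$qname, contig = prim$contig, pos = prim$pos,
             rev = bitwAnd(prim$flag, 0x10L) != 0L, lead_clip = lead,
             tail_clip = tail_,
             refspan = vapply(prim$cigar, rapidseq:::cigar_ref_span,
                              numeric(1)),
             pair_score = prim$pair_score)
}

# observed duplicate flag per fragment, as a plain named logical vector
dup_flags_by_qname <- function(prim) {
  t <- tapply(bitwAnd(prim$flag, 0x400L) != 0L, prim$qname, any)
  stats::setNames(as.logical(t), names(t))
}

# tiny deterministic diploid fixture used by several files
make_small_sim <- function(genome_length = 20000L, coverage = 30,
                           seed = 3L, ...) {
  cfg <- sim_config(genome_length = genome_length, coverage = coverage,
                    seed = seed, ...)
  sim <- simulate_truth(cfg)
  rd <- simulate_reads(sim$haplotypes, cfg)
  list(cfg = cfg, sim = sim, reads = rd)
}
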