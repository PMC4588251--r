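#' Simulation configuration
#'
#' Defaults emulate the sequencing conditions this package is tested
#' against: 2 x 101 nt paired reads, insert ~ Normal(350, 50), one SNV
#' per kilobase, one indel per 8 kb with geometric sizes (mean 3, capped
#' at 470 nt), 0.2% uniform base error, constant Q30 base qualities with
#' an optional linear 3' decay.
#'
#' @param genome_length total genome length (nt)
#' @param n_contigs number of contigs (length split evenly)
#' @param snv_rate per-nt SNV rate
#' @param indel_rate per-nt indel rate
#' @param indel_mean mean of the geometric indel size distribution
#' @param indel_max indel size cap (nt)
#' @param read_len read length (nt)
#' @param insert_mean,insert_sd insert size model (nt)
#' @param coverage fold coverage
#' @param error_rate per-base sequencing error rate
#' @param base_qual constant reported base quality
#' @param qual_decay linear quality drop from 5' to 3' end (0 = flat)
#' @param seed RNG seed for reproducibility
#' @return object of class `sim_config`
#' @export
sim_config <- function(genome_length = 250000L, n_contigs = 1L,
                       snv_rate = 0.001, indel_rate = 1.25e-4,
                       indel_mean = 3, indel_max = 470L, read_len = 101L,
                       insert_mean = 350, insert_sd = 50, coverage = 40,
                       error_rate = 0.002, base_qual = 30L, qual_decay = 0,
                       seed = 1L) {
  stopifnot(snv_rate >= 0, snv_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            coverage > 0, genome_length > 0)
  structure(list(genome_length = as.integer(genome_length),
                 n_contigs = as.integer(n_contigs), snv_rate = snv_rate,
                 indel_rate = indel_rate, indel_mean = indel_mean,
                 indel_max = as.integer(indel_max),
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 coverage = coverage, error_rate = error_rate,
                 base_qual = as.integer(base_qual), qual_decay = qual_decay,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# apply a sorted event table to one contig sequence, returning the
# haplotype string; events must be non-overlapping, anchored VCF-style
.apply_events <- function(contig_seq, events) {
  if (nrow(events) == 0L) return(contig_seq)
  ev <- events[order(events$pos)]
  pieces <- character(2L * nrow(ev) + 1L)
  cur <- 1L  # 1-based cursor into contig_seq
  for (i in seq_len(nrow(ev))) {
    p1 <- ev$pos[i] + 1L  # 1-based event start
    pieces[2L * i - 1L] <- substr(contig_seq, cur, p1 - 1L)
    pieces[2L * i] <- ev$alt[i]
    cur <- p1 + nchar(ev$ref[i])
  }
  pieces[length(pieces)] <- substr(contig_seq, cur, nchar(contig_seq))
  paste(pieces, collapse = "")
}

# draw one diploid genome's planted events for one contig
.draw_events <- function(contig_seq, cfg) {
  L <- nchar(contig_seq)
  bases <- c("A", "C", "G", "T")
  snv_pos <- which(stats::runif(L) < cfg$snv_rate) - 1L   # 0-based
  ind_pos <- which(stats::runif(L) < cfg$indel_rate) - 1L
  ind_pos <- ind_pos[ind_pos >= 1L & ind_pos < L - cfg$indel_max - 2L]
  ev <- list()
  for (p in snv_pos) {
    rb <- substr(contig_seq, p + 1L, p + 1L)
    ab <- sample(setdiff(bases, rb), 1L)
    ev[[length(ev) + 1L]] <- list(pos = p, ref = rb, alt = ab)
  }
  for (p in ind_pos) {
    len <- min(stats::rgeom(1L, 1 / cfg$indel_mean) + 1L, cfg$indel_max)
    anchor <- substr(contig_seq, p + 1L, p + 1L)
    if (stats::runif(1L) < 0.5) {  # deletion
      ev[[length(ev) + 1L]] <- list(
        pos = p, ref = substr(contig_seq, p + 1L, p + 1L + len),
        alt = anchor)
    } else {  # insertion of random sequence
      ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
      ev[[length(ev) + 1L]] <- list(pos = p, ref = anchor,
                                    alt = paste0(anchor, ins))
    }
  }
  if (length(ev) == 0L) {
    return(data.table::data.table(pos = integer(), ref = character(),
                                  alt = character(), gt = character()))
  }
  evt <- data.table::rbindlist(ev)
  data.table::setorder(evt, pos)
  # drop events whose reference footprint overlaps an earlier event's
  end <- evt$pos + nchar(evt$ref)  # half-open footprint
  keep <- rep(TRUE, nrow(evt))
  last_end <- -1L
  for (i in seq_len(nrow(evt))) {
    if (evt$pos[i] < last_end + 1L) keep[i] <- FALSE
    else last_end <- end[i]
  }
  evt <- evt[keep]
  evt$gt <- sample(c("het1", "het2", "hom"), nrow(evt), replace = TRUE,
                   prob = c(0.25, 0.25, 0.5))
  evt
}

# left-normalize a planted event table against its contig
.normalize_events <- function(contig_seq, evt) {
  if (nrow(evt) == 0L) return(evt)
  norm <- lapply(seq_len(nrow(evt)), function(i) {
    normalize_variant(contig_seq, evt$pos[i], evt$ref[i], evt$alt[i])
  })
  out <- data.table::copy(evt)
  out$pos <- vapply(norm, `[[`, integer(1), "pos")
  out$ref <- vapply(norm, `[[`, character(1), "ref")
  out$alt <- vapply(norm, `[[`, character(1), "alt")
  out
}

#' Simulate a diploid genome with planted variants
#'
#' Generates a random reference, draws SNVs and indels at the configured
#' per-site rates (events are half heterozygous, half homozygous;
#' overlapping draws are dropped), and applies them to produce two
#' haplotype sequences per contig.  The truth set is reported
#' left-normalized in VCF-style anchored form.  In trio mode, two parents
#' are simulated independently and the child receives one haplotype from
#' each, plus optional de novo SNVs.
#'
#' @param cfg a [sim_config()]
#' @param trio simulate a parent-child trio?
#' @param de_novo_count de novo SNVs added to the child (trio mode)
#' @return list with `ref` (named character vector), `haplotypes` (list:
#'   per contig, two sequences; in trio mode, per sample), and `truth`
#'   (data.table: contig, pos 0-based, ref, alt, gt in {het, hom}; trio
#'   mode adds a `sample` column)
#' @export
simulate_truth <- function(cfg = sim_config(), trio = FALSE,
                           de_novo_count = 2L) {
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  clen <- rep(cfg$genome_length %/% cfg$n_contigs, cfg$n_contigs)
  clen[cfg$n_contigs] <- cfg$genome_length - sum(clen[-cfg$n_contigs])
  ref <- vapply(clen, function(L) {
    paste(sample(bases, L, replace = TRUE), collapse = "")
  }, character(1))
  names(ref) <- paste0("contig", seq_along(ref))

  draw_sample <- function() {
    haps <- list()
    truth <- list()
    for (cn in names(ref)) {
      evt <- .draw_events(ref[[cn]], cfg)
      h1 <- .apply_events(ref[[cn]], evt[evt$gt %in% c("het1", "hom")])
      h2 <- .apply_events(ref[[cn]], evt[evt$gt %in% c("het2", "hom")])
      haps[[cn]] <- c(h1, h2)
      tr <- .normalize_events(ref[[cn]], evt)
      if (nrow(tr) > 0L) {
        tr$contig <- cn
        tr$gt <- ifelse(tr$gt == "hom", "hom", "het")
        truth[[length(truth) + 1L]] <- tr
      }
    }
    tt <- if (length(truth)) data.table::rbindlist(truth) else
      data.table::data.table(pos = integer(), ref = character(),
                             alt = character(), gt = character(),
                             contig = character())
    data.table::setcolorder(tt, c("contig", "pos", "ref", "alt", "gt"))
    list(haplotypes = haps, truth = tt)
  }

  if (!trio) {
    s <- draw_sample()
    return(list(ref = ref, haplotypes = s$haplotypes, truth = s$truth))
  }
  mother <- draw_sample()
  father <- draw_sample()
  child_h <- list()
  child_tr <- list()
  for (cn in names(ref)) {
    hm <- sample(1:2, 1L)
    hf <- sample(1:2, 1L)
    ch1 <- mother$haplotypes[[cn]][hm]
    ch2 <- father$haplotypes[[cn]][hf]
    # de novo SNVs applied to the maternal haplotype
    if (de_novo_count > 0L) {
      dn_pos <- sort(sample(nchar(ref[[cn]]) - 1L, de_novo_count))
      for (p in dn_pos) {
        rb <- substr(ch1, p + 1L, p + 1L)
        if (!rb %in% bases) next
        ab <- sample(setdiff(bases, rb), 1L)
        substr(ch1, p + 1L, p + 1L) <- ab
      }
    }
    child_h[[cn]] <- c(ch1, ch2)
  }
  list(ref = ref,
       haplotypes = list(mother = mother$haplotypes,
                         father = father$haplotypes, child = child_h),
       truth = list(mother = mother$truth, father = father$truth))
}

#' Simulate paired-end reads from haplotype sequences
#'
#' Fragment count is `round(coverage * genome_length / (2 * read_len))`;
#' fragments are drawn uniformly from the two haplotypes with insert
#' sizes from a truncated normal (minimum twice the read length), and
#' i.i.d. substitution errors are planted at the configured rate.  Read
#' ids encode the source (`sim:<contig>:<hap>:<start0>:<insert>`), which
#' lets tests verify placement.
#'
#' @param haplotypes per-contig list of haplotype sequence vectors, as
#'   from [simulate_truth()]
#' @param cfg a [sim_config()]
#' @param seed RNG seed for read drawing (defaults to `cfg$seed + 1`)
#' @return list of two data.tables (`reads1`, `reads2`) with id/seq/qual
#' @export
simulate_reads <- function(haplotypes, cfg = sim_config(), seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  L <- cfg$read_len
  genome_len <- sum(vapply(haplotypes, function(h) nchar(h[1]), numeric(1)))
  n_pairs <- round(cfg$coverage * genome_len / (2 * L))
  contigs <- names(haplotypes)
  cw <- vapply(haplotypes, function(h) nchar(h[1]), numeric(1))
  ci <- sample(length(contigs), n_pairs, replace = TRUE, prob = cw / sum(cw))
  hi <- sample(2L, n_pairs, replace = TRUE)
  hlen <- vapply(seq_len(n_pairs), function(i) {
    nchar(haplotypes[[ci[i]]][hi[i]])
  }, numeric(1))
  ins <- pmax(2L * L, round(stats::rnorm(n_pairs, cfg$insert_mean,
                                         cfg$insert_sd)))
  ins <- pmin(ins, hlen)
  start <- floor(stats::runif(n_pairs) * (hlen - ins + 1))  # 0-based
  hseq <- vapply(seq_len(n_pairs), function(i) haplotypes[[ci[i]]][hi[i]],
                 character(1))
  r1 <- substring(hseq, start + 1L, start + L)
  r2 <- .revcomp_cpp(substring(hseq, start + ins - L + 1L, start + ins))
  # substitution errors
  plant <- function(reads) {
    nerr <- stats::rbinom(length(reads), L, cfg$error_rate)
    idx <- rep(seq_along(reads), nerr)
    if (length(idx) > 0L) {
      pos <- sample.int(L, length(idx), replace = TRUE)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      reads <- .mutate_bases_cpp(reads, idx, pos, shift)
    }
    reads
  }
  r1 <- plant(r1)
  r2 <- plant(r2)
  q <- pmax(2L, round(cfg$base_qual - cfg$qual_decay * (seq_len(L) - 1L)))
  qual <- phred_encode(q)
  ids <- paste("sim", contigs[ci], hi, start, ins, seq_len(n_pairs),
               sep = ":")
  list(reads1 = data.table::data.table(id = ids, seq = r1,
                                       qual = rep(qual, n_pairs)),
       reads2 = data.table::data.table(id = ids, seq = r2,
                                       qual = rep(qual, n_pairs)))
}

#' Compare a call set against a planted truth set
#'
#' Records are matched on (contig, pos, ref, alt) after left-normalizing
#' both sets against the same reference; the genotype-level comparison
#' additionally requires the called diplotype (het/hom) to agree.
#' Variant-call specificity uses confident-region non-variant positions
#' (genome length minus truth count) as its denominator.
#'
#' @param calls data.table with contig, pos (0-based), ref, alt, gt
#'   ("0/1" / "1/1" or "het" / "hom")
#' @param truth truth data.table from [simulate_truth()]
#' @param ref the reference both sets are called against
#' @return list of class `concordance_report`: counts (TP, FP, FN,
#'   genotype_TP), rates in percent (sensitivity, specificity,
#'   genotype_sensitivity, genotype_specificity), and the per-record
#'   match table
#' @export
evaluate_concordance <- function(calls, truth, ref) {
  genome_len <- sum(nchar(ref))
  norm_keys <- function(d) {
    if (nrow(d) == 0L) return(character())
    vapply(seq_len(nrow(d)), function(i) {
      n <- normalize_variant(ref[[d$contig[i]]], d$pos[i], d$ref[i],
                             d$alt[i])
      paste(d$contig[i], n$pos, n$ref, n$alt)
    }, character(1))
  }
  gt_std <- function(g) {
    data.table::fifelse(g %in% c("1/1", "hom"), "hom",
                        data.table::fifelse(g %in% c("0/1", "1/0", "het"),
                                            "het", g))
  }
  ck <- norm_keys(calls)
  tk <- norm_keys(truth)
  if (anyDuplicated(tk)) stop("truth set contains duplicate records")
  tp_mask <- tk %in% ck
  fp_mask <- !(ck %in% tk)
  TP <- sum(tp_mask)
  FN <- sum(!tp_mask)
  FP <- sum(fp_mask)
  m <- match(tk, ck)
  gt_match <- tp_mask & gt_std(truth$gt) == gt_std(calls$gt[m])
  gTP <- sum(gt_match, na.rm = TRUE)
  nonvar <- genome_len - nrow(truth)
  sens <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  spec <- 100 * (1 - FP / nonvar)
  gsens <- if (TP + FN > 0) 100 * gTP / (TP + FN) else NA_real_
  gspec <- 100 * (1 - (FP + (TP - gTP)) / nonvar)
  structure(list(TP = TP, FP = FP, FN = FN, genotype_TP = gTP,
                 sensitivity = sens, specificity = spec,
                 genotype_sensitivity = gsens,
                 genotype_specificity = gspec,
                 n_truth = nrow(truth), n_calls = nrow(calls),
                 denominator = nonvar,
                 missed = truth[!tp_mask],
                 false_positives = calls[fp_mask]),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance: TP %d  FP %d  FN %d | sensitivity %.3f%%  specificity %.3f%%\n",
    x$TP, x$FP, x$FN, x$sensitivity, x$specificity))
  cat(sprintf(
    "genotype level: TP %d | sensitivity %.3f%%  specificity %.3f%%\n",
    x$genotype_TP, x$genotype_sensitivity, x$genotype_specificity))
  cat("specificity denominator: confident-region non-variant positions (",
      x$denominator, ")\n", sep = "")
  invisible(x)
}

#' Write a concordance report as TSV
#' @param report a `concordance_report`
#' @param path output path
#' @export
write_concordance_tsv <- function(report, path) {
  hdr <- "# specificity denominator: confident-region non-variant positions"
  d <- data.table::data.table(
    metric = c("TP", "FP", "FN", "genotype_TP", "sensitivity",
               "specificity", "genotype_sensitivity",
               "genotype_specificity"),
    value = c(report$TP, report$FP, report$FN, report$genotype_TP,
              report$sensitivity, report$specificity,
              report$genotype_sensitivity, report$genotype_specificity))
  writeLines(c(hdr, paste(d$metric, d$value, sep = "\t")), path)
  invisible(path)
}

#' Run the full mapping and calling pipeline on simulated data
#'
#' Convenience driver: index the reference, map the read pairs, sort and
#' flag duplicates, call variants.
#'
#' @param ref reference genome (named character vector)
#' @param reads1,reads2 paired reads (data.tables with id/seq/qual)
#' @param map_par a [map_params()]
#' @param call_par a [caller_params()]
#' @param verbose report stage progress?
#' @return list(calls, aln, index)
#' @export
run_pipeline <- function(ref, reads1, reads2, map_par = map_params(),
                         call_par = caller_params(), verbose = FALSE) {
  idx <- build_index(ref)
  aln <- map_reads(idx, reads1, reads2, map_par)
  aln <- sort_and_mark_duplicates(aln)
  calls <- call_variants(aln, ref, call_par, verbose = verbose)
  list(calls = calls, aln = aln, index = idx)
}

#' Depth titration of variant-call sensitivity
#'
#' Re-simulates reads from the same planted genome at each coverage and
#' reports variant-call sensitivity and specificity per depth.
#'
#' @param sim a [simulate_truth()] result
#' @param cfg the [sim_config()] used to generate `sim`
#' @param coverages fold coverages to titrate
#' @return data.table: coverage, sensitivity, specificity, TP, FP, FN
#' @export
depth_titration <- function(sim, cfg, coverages = c(10, 20, 30, 40)) {
  out <- lapply(coverages, function(cv) {
    c2 <- cfg
    c2$coverage <- cv
    rd <- simulate_reads(sim$haplotypes, c2,
                         seed = cfg$seed + 100L + as.integer(cv))
    res <- run_pipeline(sim$ref, rd$reads1, rd$reads2)
    cc <- evaluate_concordance(res$calls, sim$truth, sim$ref)
    data.table::data.table(coverage = cv, sensitivity = cc$sensitivity,
                           specificity = cc$specificity, TP = cc$TP,
                           FP = cc$FP, FN = cc$FN)
  })
  data.table::rbindlist(out)
}
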