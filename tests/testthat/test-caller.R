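# Haplotype caller: region detection, assembly, event extraction,
# pair-HMM likelihoods, diplotype genotyping.

# build an alignment table for synthetic pileups without the mapper
pileup_aln <- function(ref, reads) {
  # reads: data.frame with pos (0-based), seq
  n <- nrow(reads)
  data.table::data.table(
    qname = paste0("r", seq_len(n)), flag = rep(0L, n), contig = 1L,
    pos = reads$pos, mapq = 60L,
    cigar = paste0(nchar(reads$seq), "M"), mcontig = 0L, mpos = 0L,
    tlen = 0L, seq = reads$seq,
    qual = vapply(nchar(reads$seq), function(L) phred_encode(rep(30L, L)),
                  character(1)),
    score = 0L, pair_score = 0, read = 1L)
}

test_that("an error-free reference pileup is callable with zero active regions", {
  set.seed(81)
  ref <- c(chrA = rand_seq(1500))
  starts <- rep(seq(0L, 1400L, by = 25L), each = 8L)  # ~40x tiling
  reads <- data.frame(pos = starts,
                      seq = substring(ref[[1]], starts + 1L, starts + 100L))
  det <- detect_regions(pileup_aln(ref, reads), ref)
  expect_equal(nrow(det$regions), 0L)
  # interior columns are deeply covered, hence callable
  expect_true(all(det$callable$chrA[200:1300]))
})

test_that("a column with 30% non-reference bases becomes one active region", {
  set.seed(82)
  ref <- c(chrA = rand_seq(1200))
  starts <- rep(seq(0L, 1100L, by = 20L), each = 4L)
  seqs <- substring(ref[[1]], starts + 1L, starts + 100L)
  # plant an alternate base at reference column 600 in ~30% of
  # overlapping reads
  over <- which(starts < 600L & starts + 100L > 600L)
  carriers <- over[seq_along(over) %% 3 == 0L]
  for (i in carriers) {
    off <- 600L - starts[i]
    base <- substr(ref[[1]], 601L, 601L)
    substr(seqs[i], off + 1L, off + 1L) <- setdiff(c("A", "C", "G", "T"),
                                                   base)[1]
  }
  frac <- length(carriers) / length(over)
  stopifnot(frac >= 0.15)  # arithmetic on the constructed pileup
  det <- detect_regions(pileup_aln(ref, data.frame(pos = starts, seq = seqs)),
                        ref)
  expect_equal(nrow(det$regions), 1L)
  expect_true(det$regions$start <= 600L && det$regions$end > 600L)
})

test_that("depth below min_depth is not callable", {
  set.seed(83)
  ref <- c(chrA = rand_seq(400))
  reads <- data.frame(pos = c(100L, 150L),
                      seq = substring(ref[[1]], c(101L, 151L),
                                      c(200L, 250L)))
  det <- detect_regions(pileup_aln(ref, reads), ref,
                        caller_params(min_depth = 4L))
  expect_false(any(det$callable$chrA))
})

test_that("assembly returns the backbone for reference-identical reads", {
  set.seed(84)
  ref_seg <- rand_seq(200)
  reads <- substring(ref_seg, seq(1, 100, by = 10), seq(80, 179, by = 10))
  asm <- assemble_haplotypes(reads, ref_seg)
  expect_identical(unlist(asm$haplotypes), ref_seg)
  expect_false(asm$degenerate)
})

test_that("a clean heterozygous SNV assembles exactly two haplotypes", {
  set.seed(85)
  ref_seg <- rand_seq(200)
  alt_seg <- ref_seg
  substr(alt_seg, 100, 100) <- setdiff(c("A", "C", "G", "T"),
                                       substr(ref_seg, 100, 100))[1]
  starts <- rep(seq(1, 120, by = 10), 2)
  hap <- rep(c(TRUE, FALSE), each = length(starts) / 2)
  reads <- ifelse(hap, substring(alt_seg, starts, starts + 79),
                  substring(ref_seg, starts, starts + 79))
  asm <- assemble_haplotypes(reads, ref_seg)
  expect_equal(length(asm$haplotypes), 2L)
  expect_setequal(unlist(asm$haplotypes), c(ref_seg, alt_seg))
})

test_that("a tandem repeat that cycles at k=10 is rebuilt at a longer k", {
  set.seed(86)
  # a 12-nt unit repeated 4 times duplicates every 10-mer inside it
  unit <- "ACGTTGCAAGGC"
  ref_seg <- paste0(rand_seq(60), strrep(unit, 4L), rand_seq(60))
  reads <- substring(ref_seg, seq(1, nchar(ref_seg) - 80, by = 7),
                     seq(81, nchar(ref_seg), by = 7))
  asm <- assemble_haplotypes(reads, ref_seg)
  expect_false(asm$degenerate)
  expect_gt(asm$k, 10L)
  expect_true(ref_seg %in% unlist(asm$haplotypes))
})

test_that("haplotype events: identity, substitution, and left-shifted deletion", {
  set.seed(87)
  contig <- rand_seq(400)
  seg <- substr(contig, 101, 300)
  expect_equal(nrow(haplotype_events(seg, seg, contig, 100L)), 0L)
  # single substitution at offset 50 of the segment
  hap <- seg
  substr(hap, 51, 51) <- setdiff(c("A", "C", "G", "T"),
                                 substr(seg, 51, 51))[1]
  ev <- haplotype_events(hap, seg, contig, 100L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pos, 150L)
  expect_identical(ev$type, "SNV")
  # 3-nt deletion inside a planted homopolymer shifts to the leftmost
  # equivalent placement (checked against the brute-force oracle)
  contig2 <- paste0(substr(contig, 1, 150), "AAAAAAAA",
                    substr(contig, 159, 400))
  seg2 <- substr(contig2, 101, 300)
  hap2 <- paste0(substr(seg2, 1, 54), substr(seg2, 58, 200))  # del 3 in run
  ev2 <- haplotype_events(hap2, seg2, contig2, 100L)
  expect_equal(nrow(ev2), 1L)
  ora <- leftnorm_oracle(contig2, ev2$pos, ev2$ref, ev2$alt)
  expect_equal(ev2$pos, ora$pos)
  expect_identical(ev2$ref, ora$ref)
  expect_identical(ev2$alt, ora$alt)
  # the deletion sits at the left edge of the A run
  expect_equal(ev2$pos, 149L)
})

test_that("left-normalization matches the brute-force oracle on random indels", {
  set.seed(88)
  for (rep in 1:40) {
    contig <- paste0(rand_seq(30), strrep(sample(c("A", "TG", "CTT"), 1),
                                          sample(3:6, 1)), rand_seq(30))
    L <- nchar(contig)
    pos <- sample(5:(L - 10), 1)
    if (runif(1) < 0.5) {
      len <- sample(1:4, 1)
      ref <- substr(contig, pos + 1, pos + 1 + len)
      alt <- substr(contig, pos + 1, pos + 1)
    } else {
      ref <- substr(contig, pos + 1, pos + 1)
      alt <- paste0(ref, rand_seq(sample(1:4, 1)))
    }
    got <- normalize_variant(contig, pos, ref, alt)
    ora <- leftnorm_oracle(contig, pos, ref, alt)
    expect_equal(got$pos, ora$pos)
    expect_identical(got$ref, ora$ref)
    expect_identical(got$alt, ora$alt)
  }
})

test_that("pair-HMM equals exhaustive path enumeration on small cases", {
  set.seed(89)
  for (rep in 1:60) {
    m <- sample(1:4, 1)
    n <- sample(2:6, 1)
    read <- rand_seq(m)
    hap <- rand_seq(n)
    qual <- sample(10:40, m, replace = TRUE)
    got <- pair_hmm(read, qual, hap)
    ora <- phmm_enum_oracle(read, qual, hap)
    expect_equal(got, ora, tolerance = 1e-10)
  }
  # homopolymer-sensitive gap model exercised explicitly
  got <- pair_hmm("AAT", c(30L, 30L, 30L), "AAAAAT")
  ora <- phmm_enum_oracle("AAT", c(30, 30, 30), "AAAAAT")
  expect_equal(got, ora, tolerance = 1e-10)
})

test_that("a read identical to its haplotype is dominated by the match term", {
  read <- rand_seq(4)
  q <- rep(30L, 4L)
  got <- pair_hmm(read, q, read)
  ora <- phmm_enum_oracle(read, q, read)
  expect_equal(got, ora, tolerance = 1e-10)
  # dominant term: (1 - 1e-3)^L times the start prior, within the total
  expect_gt(10^got, (1 - 1e-3)^4 * (1 / 4) * 0.9)
  expect_lte(10^got, 1)
})

test_that("lowering the quality of a mismatched base does not decrease P(r|H)", {
  set.seed(90)
  hap <- rand_seq(30)
  read <- substr(hap, 6, 20)
  substr(read, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                substr(read, 8, 8))[1]
  qs <- c(40L, 30L, 20L, 10L, 5L)
  ps <- vapply(qs, function(q) {
    qual <- rep(35L, nchar(read))
    qual[8] <- q
    pair_hmm(read, qual, hap)
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("diplotype posteriors follow brute-force Bayes and normalize", {
  # 15 alt / 16 ref high-quality reads at a SNV: heterozygous call
  lp_ref <- c(rep(-0.5, 16), rep(-8, 15))
  lp_alt <- c(rep(-8, 16), rep(-0.5, 15))
  al <- cbind(lp_ref, lp_alt)
  g <- genotype_site(al, theta = 0.001)
  expect_equal(sum(g$posteriors), 1, tolerance = 1e-9)
  expect_equal(c(g$a1, g$a2), c(1L, 2L))  # het
  # independent Bayes computation over the three diplotypes
  lik <- function(p1, p2) sum(log10(0.5 * 10^p1 + 0.5 * 10^p2))
  logpost <- c(lik(lp_ref, lp_ref) + log10(1 - 0.001),
               lik(lp_ref, lp_alt) + log10(0.001 / 2),
               lik(lp_alt, lp_alt) + log10(0.001 / 2))
  post <- 10^(logpost - max(logpost))
  post <- post / sum(post)
  expect_equal(unname(g$posteriors), unname(post), tolerance = 1e-9)
  # all reads reference: homozygous-reference wins
  g0 <- genotype_site(cbind(rep(-0.5, 20), rep(-8, 20)))
  expect_equal(c(g0$a1, g0$a2), c(1L, 1L))
})

test_that("calls are invariant to read input order", {
  fx <- make_small_sim(genome_length = 12000L, coverage = 30, seed = 91L)
  res1 <- run_pipeline(fx$sim$ref, fx$reads$reads1, fx$reads$reads2)
  perm <- sample(nrow(fx$reads$reads1))
  res2 <- run_pipeline(fx$sim$ref, fx$reads$reads1[perm],
                       fx$reads$reads2[perm])
  key <- function(d) paste(d$contig, d$pos, d$ref, d$alt, d$gt)
  expect_setequal(key(res1$calls), key(res2$calls))
})

test_that("VCF round trip preserves calls", {
  fx <- make_small_sim(genome_length = 10000L, coverage = 30, seed = 92L)
  res <- run_pipeline(fx$sim$ref, fx$reads$reads1, fx$reads$reads2)
  f <- tempfile(fileext = ".vcf")
  write_vcf(res$calls, fx$sim$ref, f)
  back <- read_vcf(f)
  expect_equal(nrow(back), nrow(res$calls))
  expect_identical(back$pos, res$calls$pos)
  expect_identical(back$ref, res$calls$ref)
  expect_identical(back$alt, res$calls$alt)
  expect_identical(back$gt, res$calls$gt)
})
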