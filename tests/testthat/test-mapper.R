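# Mapper: seed extraction, chaining, gapless and gapped alignment,
# pairing/rescue, MAPQ, round-trip placement.

test_that("seed extraction enumerates even offsets that fit the read", {
  p <- index_params()
  s101 <- extract_seeds(strrep("ACGTT", 21L), p)  # length 105
  expect_equal(s101$offset, seq(0L, 84L, by = 2L))
  read101 <- rand_seq(101)
  s <- extract_seeds(read101, p)
  expect_equal(nrow(s), 41L)  # offsets 0,2,...,80
  expect_equal(s$offset, seq(0L, 80L, by = 2L))
  expect_equal(nrow(extract_seeds(rand_seq(21), p)), 1L)
  expect_equal(extract_seeds(rand_seq(21), p)$offset, 0L)
  expect_equal(nrow(extract_seeds(rand_seq(20), p)), 0L)
  # seeds containing N are omitted
  r <- rand_seq(101)
  substr(r, 11, 11) <- "N"
  sn <- extract_seeds(r, p)
  expect_false(any(sn$offset %in% seq(0L, 10L, by = 2L)))
})

test_that("hits on one diagonal merge into one chain spanning the read", {
  hits <- data.frame(offset = c(0L, 2L, 10L), contig = 0L,
                     pos = c(100L, 102L, 110L), orient = 0L)
  ch <- build_chains(hits, seed_len = 21L)
  expect_equal(nrow(ch), 1L)
  expect_equal(ch$diagonal, 100L)
  expect_equal(ch$span_start, 0L)
  expect_equal(ch$span_end, 31L)
})

test_that("a chain four times longer that mostly overlaps filters the short one", {
  # chain A covers read [0, 100); chain B [30, 51) lies fully inside it
  hits <- data.frame(
    offset = c(seq(0L, 79L, by = 1L), 30L),
    contig = 0L,
    pos = c(seq(0L, 79L, by = 1L) + 500L, 30L + 9000L),
    orient = 0L)
  ch <- build_chains(hits, seed_len = 21L)
  expect_equal(nrow(ch), 1L)  # 100 >= 4 * 21 and B fully overlapped
  expect_equal(ch$diagonal, 500L)
  # chains with disjoint read spans are both kept
  hits2 <- data.frame(offset = c(0L, 60L), contig = 0L,
                      pos = c(100L, 5060L), orient = 0L)
  expect_equal(nrow(build_chains(hits2, 21L)), 2L)
})

test_that("gapless alignment scores a perfect read and triggers on indels", {
  set.seed(31)
  win <- rand_seq(200)
  read <- substr(win, 51, 150)
  g <- gapless_align(read, win, 50L)
  expect_equal(g$score, 100L * 2L)
  expect_equal(g$clip_left, 0L)
  expect_equal(g$clip_right, 0L)
  expect_false(g$needs_gapped)
  # a 1-nt insertion in the read degrades the fixed-diagonal score below
  # the trigger, while the gapped aligner recovers it
  read_ins <- paste0(substr(read, 1, 50), "A", substr(read, 51, 99))
  gi <- gapless_align(read_ins, win, 50L)
  expect_true(gi$needs_gapped)
  sw <- smith_waterman(read_ins, win)
  expect_gt(sw$score, gi$score)
  expect_match(sw$cigar, "I")
})

test_that("the gapless clip point equals the brute-force argmax over clips", {
  set.seed(32)
  for (rep in 1:25) {
    win <- rand_seq(120)
    read <- paste0(rand_seq(40), substr(win, 61, 120))  # half junk, half match
    m <- nchar(read)
    g <- gapless_align(read, win, 20L)
    scheme <- scoring_scheme()
    base <- ifelse(strsplit(read, "")[[1]] ==
                     strsplit(substr(win, 21, 20 + m), "")[[1]],
                   scheme$match, -scheme$mismatch)
    # oracle: best contiguous segment sum over all prefix/suffix clips
    best <- 0
    for (a in 0:(m - 1)) for (b in (a + 1):m) {
      s <- sum(base[(a + 1):b])
      if (s > best) best <- s
    }
    expect_equal(g$score, best)
  }
})

test_that("Smith-Waterman reproduces the classic worked examples", {
  ten <- rand_seq(10)
  r <- smith_waterman(ten, ten, scoring_scheme(match = 1))
  expect_equal(r$score, 10L)
  expect_identical(r$cigar, "10M")
  # read ACGTACGT vs ref ACGTTACGT: one 1-nt deletion.  Under the default
  # scheme the 1-nt-deletion alignment (score 10) ties with clipping the
  # first three bases, so a milder gap-open makes the deletion uniquely
  # optimal for the CIGAR check.
  sch <- scoring_scheme(gap_open = 3L)
  r2 <- smith_waterman("ACGTACGT", "ACGTTACGT", sch)
  expect_match(r2$cigar, "D")
  expect_equal(r2$score,
               sw_oracle_score("ACGTACGT", "ACGTTACGT", gap_open = 3))
  # zero homology: empty alignment, fully soft-clipped, score 0
  r3 <- smith_waterman(strrep("A", 10L), strrep("C", 10L))
  expect_equal(r3$score, 0L)
  expect_identical(r3$cigar, "*")
  expect_error(smith_waterman("", "ACGT"), "non-empty")
})

test_that("Smith-Waterman equals the full-DP oracle on random pairs", {
  set.seed(33)
  for (rep in 1:80) {
    m <- sample(5:50, 1)
    n <- sample(5:50, 1)
    read <- rand_seq(m)
    ref <- if (runif(1) < 0.5) rand_seq(n) else {
      # related pair: mutated copy
      x <- substr(paste0(read, rand_seq(50)), 1, n)
      idx <- sample(n, max(1, rpois(1, 2)), replace = TRUE)
      for (i in idx) substr(x, i, i) <- sample(c("A", "C", "G", "T"), 1)
      x
    }
    got <- smith_waterman(read, ref)
    expect_equal(got$score, sw_oracle_score(read, ref))
  }
})

test_that("CIGAR read-consuming length equals the read length on mapped records", {
  fx <- make_small_sim(genome_length = 8000L, coverage = 20, seed = 21L)
  idx <- build_index(fx$sim$ref)
  aln <- map_reads(idx, fx$reads$reads1, fx$reads$reads2)
  mapped <- aln[bitwAnd(aln$flag, 4L) == 0L]
  spans <- vapply(mapped$cigar, rapidseq:::cigar_read_span, numeric(1))
  expect_true(all(spans == nchar(mapped$seq)))
})

test_that("rescue scan finds a mate within the Hamming budget", {
  set.seed(41)
  ref <- rand_seq(2000)
  target <- substr(ref, 501, 600)
  mutated <- target
  substr(mutated, 5, 5) <- "A"; substr(mutated, 12, 12) <- "C"
  n_mm <- sum(strsplit(mutated, "")[[1]][1:24] !=
                strsplit(target, "")[[1]][1:24])
  stopifnot(n_mm >= 1, n_mm <= 3)  # 2 planted mismatches in the k-mer
  hits <- rescue_scan(ref, 0L, 2000L, mutated, 24L, 3L)
  expect_true(500L %in% hits)
  # no position within the budget: nothing added
  expect_length(rescue_scan(ref, 0L, 2000L, strrep("A", 24L), 24L, 0L), 0L)
})

test_that("a mate with no seed hits is rescued through its paired mate", {
  set.seed(42)
  ref <- c(chrA = rand_seq(6000))
  idx <- build_index(ref)
  r1 <- substr(ref[[1]], 2001, 2101)
  mate <- substr(ref[[1]], 2251, 2351)
  # corrupt every 18 nt so no 21-mer survives, staying within rescue
  # k-mer Hamming distance 3 over the first 24 nt
  mb <- strsplit(mate, "")[[1]]
  for (p in seq(10, 101, by = 18)) mb[p] <- setdiff(c("A","C","G","T"), mb[p])[1]
  mate_mut <- paste(mb, collapse = "")
  q <- paste(rep("?", 101), collapse = "")  # Q30
  reads1 <- data.table::data.table(id = "p1", seq = r1, qual = q)
  reads2 <- data.table::data.table(id = "p1", seq = rc(mate_mut), qual = q)
  aln <- map_reads(idx, reads1, reads2,
                   map_params(fit_insert = FALSE, insert_mean = 350,
                              insert_sd = 50))
  m2 <- aln[aln$read == 2L & bitwAnd(aln$flag, 0x800L) == 0L]
  expect_equal(bitwAnd(m2$flag, 4L), 0L)
  expect_equal(m2$pos, 2250L)
  expect_equal(attr(aln, "pairing")$n_rescued, 1L)
})

test_that("MAPQ is monotone in the best/second-best gap and capped correctly", {
  set.seed(43)
  seg <- rand_seq(300)
  q <- paste(rep("?", 101), collapse = "")
  mapqs <- integer(0)
  for (k in c(0L, 2L, 4L, 8L, 16L)) {
    seg2 <- seg
    if (k > 0) {
      pos <- seq(5L, 101L, length.out = k)
      for (p in pos) {
        substr(seg2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                      substr(seg2, p, p))[1]
      }
    }
    ref <- c(chrA = paste0(rand_seq(500), seg, rand_seq(1000), seg2,
                           rand_seq(500)))
    idx <- build_index(ref)
    reads1 <- data.table::data.table(id = "r", seq = substr(seg, 1, 101),
                                     qual = q)
    reads2 <- data.table::data.table(id = "r",
                                     seq = rc(substr(seg, 200, 300)),
                                     qual = q)
    aln <- map_reads(idx, reads1, reads2,
                     map_params(fit_insert = FALSE))
    mapqs <- c(mapqs, aln$mapq[aln$read == 1L][1])
  }
  # identical duplicate locus: MAPQ 0; gap widens: MAPQ non-decreasing
  expect_equal(mapqs[1], 0L)
  expect_true(all(diff(mapqs) >= 0L))
  # a unique perfect read with no second-best candidate gets the cap
  ref_u <- c(chrA = rand_seq(4000))
  idx_u <- build_index(ref_u)
  a <- map_reads(idx_u,
                 data.table::data.table(id = "u",
                                        seq = substr(ref_u[[1]], 1001, 1101),
                                        qual = q),
                 data.table::data.table(id = "u",
                                        seq = rc(substr(ref_u[[1]], 1251,
                                                        1351)),
                                        qual = q),
                 map_params(fit_insert = FALSE))
  expect_equal(a$mapq, c(60L, 60L))
  expect_true(all(bitwAnd(a$flag, 2L) != 0L))  # proper pair at mean insert
})

test_that("error-free reads from a unique genome map back to their origin", {
  fx <- make_small_sim(genome_length = 30000L, coverage = 15, seed = 51L,
                       snv_rate = 0, indel_rate = 0, error_rate = 0)
  idx <- build_index(fx$sim$ref)
  aln <- map_reads(idx, fx$reads$reads1, fx$reads$reads2)
  prim <- aln[bitwAnd(aln$flag, 0x800L) == 0L]
  f <- data.table::tstrsplit(prim$qname, ":", fixed = TRUE)
  start0 <- as.integer(f[[4]])
  insert <- as.integer(f[[5]])
  L <- fx$cfg$read_len
  expected_pos <- ifelse(prim$read == 1L, start0, start0 + insert - L)
  expected_rev <- prim$read == 2L
  ok <- bitwAnd(prim$flag, 4L) == 0L & prim$pos == expected_pos &
    (bitwAnd(prim$flag, 0x10L) != 0L) == expected_rev
  expect_gte(mean(ok), 0.999)
})

test_that("SAM round trip preserves the alignment table", {
  fx <- make_small_sim(genome_length = 6000L, coverage = 10, seed = 61L)
  idx <- build_index(fx$sim$ref)
  aln <- map_reads(idx, fx$reads$reads1, fx$reads$reads2)
  f <- tempfile(fileext = ".sam")
  write_sam(aln, fx$sim$ref, f)
  back <- read_sam(f)
  expect_identical(unname(back$contigs),
                   unname(nchar(fx$sim$ref)))
  expect_equal(nrow(back$aln), nrow(aln))
  expect_identical(back$aln$pos, aln$pos)
  expect_identical(back$aln$cigar, aln$cigar)
  expect_identical(back$aln$flag, aln$flag)
  expect_identical(back$aln$score, aln$score)
})
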