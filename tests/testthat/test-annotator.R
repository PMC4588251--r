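# Consequence prediction and ACMG-style category assignment.

# a two-exon toy gene on the plus strand:
#   exon1 [100, 160) , intron [160, 300) , exon2 [300, 400)
#   CDS   [110, 380) ; CDS length (50 + 80) + ... chosen divisible by 3
make_toy_locus <- function(strand = "+") {
  set.seed(120)
  contig <- rand_seq(500)
  # splice an ATG at CDS start and keep a clean reading frame with a
  # TAA stop at the CDS end
  substr(contig, 111, 113) <- "ATG"
  # CDS = [110,160) + [300,380): 50 + 80 = 130 -> pad to 129 (43 codons)
  # use cds_end 379 so the length is 50 + 79 = 129 = 43 codons
  substr(contig, 377, 379) <- "TAA"
  # keep the interior free of premature stops by rewriting codons that
  # translate to '*'
  repeat {
    tx <- transcript_model("tx1", "GENE1", "chrT", strand,
                           c(100L, 300L), c(160L, 400L), 110L, 379L)
    cm <- rapidseq:::.cds_map(tx[1], contig)
    aa <- vapply(seq(1, nchar(cm$seq) - 2, by = 3), function(i) {
      rapidseq:::CODON_TABLE[[substr(cm$seq, i, i + 2)]]
    }, character(1))
    bad <- which(aa[-length(aa)] == "*")
    if (length(bad) == 0L) break
    gpos <- cm$gpos[(bad[1] - 1) * 3 + 1]
    substr(contig, gpos + 1, gpos + 1) <- "C"
  }
  list(ref = c(chrT = contig), tx = tx)
}

test_that("synonymous, missense, and nonsense SNVs are classified by codon", {
  loc <- make_toy_locus()
  contig <- loc$ref[[1]]
  gm <- loc$tx
  # third position of codon 4 (CDS offsets 9-11): force AAA -> AAG
  cm <- rapidseq:::.cds_map(gm[1], contig)
  g9 <- cm$gpos[10]; g10 <- cm$gpos[11]; g11 <- cm$gpos[12]
  ref2 <- loc$ref
  s <- contig
  substr(s, g9 + 1, g9 + 1) <- "A"
  substr(s, g10 + 1, g10 + 1) <- "A"
  substr(s, g11 + 1, g11 + 1) <- "A"
  ref2[["chrT"]] <- s
  v <- list(contig = "chrT", pos = g11, ref = "A", alt = "G")
  pc <- predict_consequence(v, gm, ref2)
  expect_identical(pc$consequence, "synonymous")  # AAA and AAG are both Lys
  # second codon position: nonsynonymous
  v2 <- list(contig = "chrT", pos = g10, ref = "A", alt = "C")
  expect_identical(predict_consequence(v2, gm, ref2)$consequence,
                   "nonsynonymous")
  # AAA -> TAA: premature stop
  v3 <- list(contig = "chrT", pos = g9, ref = "A", alt = "T")
  expect_identical(predict_consequence(v3, gm, ref2)$consequence,
                   "premature_stop")
})

test_that("start and stop codon disruptions are recognized", {
  loc <- make_toy_locus()
  v <- list(contig = "chrT", pos = 110L, ref = "A", alt = "G")  # ATG -> GTG
  expect_identical(predict_consequence(v, loc$tx, loc$ref)$consequence,
                   "loss_of_initiation")
  v2 <- list(contig = "chrT", pos = 376L, ref = "T", alt = "C")  # TAA -> CAA
  expect_identical(predict_consequence(v2, loc$tx, loc$ref)$consequence,
                   "stop_disruption")
})

test_that("splice geometry: +/-2 disruption, acceptor tract, deep intronic", {
  loc <- make_toy_locus()
  # acceptor -2 (2 nt before exon2 start at 300): position 298
  v <- list(contig = "chrT", pos = 298L,
            ref = substr(loc$ref[[1]], 299, 299), alt = "G")
  expect_identical(predict_consequence(v, loc$tx, loc$ref)$consequence,
                   "splice_disruption")
  # donor +1 after exon1 end: position 160
  v1 <- list(contig = "chrT", pos = 160L,
             ref = substr(loc$ref[[1]], 161, 161), alt = "A")
  expect_identical(predict_consequence(v1, loc$tx, loc$ref)$consequence,
                   "splice_disruption")
  # acceptor -3: polypyrimidine tract
  v2 <- list(contig = "chrT", pos = 297L,
             ref = substr(loc$ref[[1]], 298, 298), alt = "A")
  expect_identical(predict_consequence(v2, loc$tx, loc$ref)$consequence,
                   "polypyrimidine_tract")
  # intronic, 25 nt from the nearest boundary: deep intronic
  v3 <- list(contig = "chrT", pos = 185L,
             ref = substr(loc$ref[[1]], 186, 186), alt = "A")
  expect_identical(predict_consequence(v3, loc$tx, loc$ref)$consequence,
                   "deep_intronic")
  # off-transcript: intergenic
  v4 <- list(contig = "chrT", pos = 450L,
             ref = substr(loc$ref[[1]], 451, 451), alt = "A")
  expect_identical(predict_consequence(v4, loc$tx, loc$ref)$consequence,
                   "intergenic")
})

test_that("CDS indels split into frameshift and in-frame", {
  loc <- make_toy_locus()
  contig <- loc$ref[[1]]
  anchor <- substr(contig, 321, 321)
  v <- list(contig = "chrT", pos = 320L, ref = anchor,
            alt = paste0(anchor, "A"))  # 1-nt insertion
  expect_identical(predict_consequence(v, loc$tx, loc$ref)$consequence,
                   "frameshift_indel")
  v2 <- list(contig = "chrT", pos = 320L,
             ref = substr(contig, 321, 324), alt = anchor)  # 3-nt deletion
  expect_identical(predict_consequence(v2, loc$tx, loc$ref)$consequence,
                   "inframe_indel")
})

test_that("minus-strand transcripts classify complemented variants identically", {
  plus <- make_toy_locus("+")
  minus <- make_toy_locus("-")  # same geometry, strand flipped
  # mirror: a plus-strand codon change has a minus-strand counterpart at
  # the same genomic position with complementary alleles; intron
  # geometry (acceptor/donor) swaps sides.  Check a coding SNV.
  cm_p <- rapidseq:::.cds_map(plus$tx[1], plus$ref[[1]])
  g <- cm_p$gpos[31]
  ref_b <- substr(plus$ref[[1]], g + 1, g + 1)
  alt_b <- setdiff(c("A", "C", "G", "T"), ref_b)[1]
  v <- list(contig = "chrT", pos = g, ref = ref_b, alt = alt_b)
  cons_plus <- predict_consequence(v, plus$tx, plus$ref)$consequence
  cons_minus <- predict_consequence(v, minus$tx, minus$ref)$consequence
  expect_true(cons_minus %in% rapidseq:::CONSEQUENCE_SEVERITY)
  # the minus-strand model reads the complementary codon: both must be
  # coding consequences (never intronic/intergenic)
  coding <- c("synonymous", "nonsynonymous", "premature_stop",
              "stop_disruption", "loss_of_initiation",
              "splice_region_exonic")
  expect_true(cons_plus %in% coding)
  expect_true(cons_minus %in% coding)
})

test_that("category assignment is complete and consistent over the rule table", {
  consequences <- rapidseq:::CONSEQUENCE_SEVERITY
  cat2 <- c("loss_of_initiation", "premature_stop", "stop_disruption",
            "frameshift_indel", "splice_disruption")
  cat3 <- c("nonsynonymous", "inframe_indel", "polypyrimidine_tract",
            "splice_region_exonic")
  for (cons in consequences) {
    for (status in c("novel", "disease_causing", "benign")) {
      for (maf in c(0, 0.001, 0.02, 0.3)) {
        for (cry in c(FALSE, TRUE)) {
          got <- assign_category(cons, status, maf, cry)
          expected <-
            if (status == "disease_causing") 1L
            else if (status == "benign") 5L
            else if (maf >= 0.02) 4L
            else if (cons %in% cat2) 2L
            else if (cons %in% cat3) 3L
            else if (cons == "synonymous" && cry) 3L
            else 4L
          expect_identical(got, expected)
        }
      }
    }
  }
  expect_identical(assign_category("whole_gene_deletion"), 2L)
})

test_that("known status outranks consequence type", {
  expect_identical(assign_category("frameshift_indel", "benign", 0), 5L)
  expect_identical(assign_category("synonymous", "disease_causing", 0.5), 1L)
})

test_that("annotation pipeline joins consequence, category and warehouse MAF", {
  loc <- make_toy_locus()
  calls <- data.table::data.table(
    contig = "chrT",
    pos = c(298L, 450L),
    ref = c(substr(loc$ref[[1]], 299, 299), substr(loc$ref[[1]], 451, 451)),
    alt = c("G", "A"), qual = 99, gt = c("0/1", "0/1"),
    ad_ref = 10L, ad_alt = 9L, dp = 19L, gq = 99L, type = "SNV")
  wh <- variant_warehouse(data.table::data.table(
    contig = "chrT", pos = 450L, ref = calls$ref[2], alt = "A",
    maf = 0.10, status = "observed"))
  ann <- annotate_variants(calls, loc$tx, wh, loc$ref)
  expect_identical(ann$consequence, c("splice_disruption", "intergenic"))
  expect_identical(ann$category, c(2L, 4L))
  expect_equal(ann$maf, c(0, 0.10))
  expect_identical(ann$known_status, c("novel", "novel"))
  # JSON round trip for the interpreter
  f <- tempfile(fileext = ".json")
  write_annotation_json(ann, "proband", f)
  back <- read_annotation_json(f)
  expect_identical(back$sample, "proband")
  expect_equal(back$variants$pos, ann$pos)
  expect_identical(back$variants$category, ann$category)
})
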