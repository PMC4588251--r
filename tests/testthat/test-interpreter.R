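# Phenotype differential, trio inheritance inference, and candidate
# filtering/ranking.

toy_disease_table <- function() {
  disease_table(
    disease_id = c("D1", "D2", "D3", "D4"),
    disease_name = c("Alpha syndrome", "Beta disease", "Gamma disorder",
                     "Delta disease"),
    terms = list(c("HP:1", "HP:2", "HP:3", "HP:9"),
                 c("HP:2", "HP:8"),
                 c("HP:7"),
                 c("HP:1", "HP:4")),
    genes = list(c("GENEA", "GENEB"), "GENEC", "GENED", "GENEA"),
    inheritance = list("recessive", "dominant", "any", "recessive"))
}

ann_row <- function(contig = "chrT", pos, ref = "A", alt = "T",
                    gt = "0/1", gq = 99L, gene, category = 3L, maf = 0,
                    known_status = "novel",
                    consequence = "nonsynonymous") {
  data.table::data.table(contig = contig, pos = pos, ref = ref, alt = alt,
                         qual = 99, gt = gt, ad_ref = 10L, ad_alt = 9L,
                         dp = 19L, gq = gq, type = "SNV", gene = gene,
                         consequence = consequence, category = category,
                         maf = maf, known_status = known_status)
}

test_that("differential ranks diseases by matching term count", {
  tab <- toy_disease_table()
  d <- build_differential(c("HP:1", "HP:2", "HP:3", "HP:5", "HP:6"), tab)
  # D1 matches 3, D4 matches 1, D2 matches 1; D3 matches 0 and is absent
  expect_identical(d$differential$disease_id, c("D1", "D2", "D4"))
  expect_identical(d$differential$n_match, c(3L, 1L, 1L))
  expect_false("D3" %in% d$differential$disease_id)
  # a disease matching exactly 1 of 5 entered terms is included
  expect_true("D2" %in% d$differential$disease_id)
  expect_setequal(d$genes, c("GENEA", "GENEB", "GENEC"))
  # disjoint terms: empty differential
  d0 <- build_differential("HP:999", tab)
  expect_equal(nrow(d0$differential), 0L)
})

test_that("diseases without genes or terms are dropped from the table", {
  tab <- disease_table(c("D1", "D2"), c("with", "without"),
                       list("HP:1", "HP:2"), list("G1", character()),
                       list("any", "any"))
  expect_identical(tab$disease_id, "D1")
})

test_that("inheritance patterns follow trio genotypes", {
  pro <- rbind(ann_row(pos = 100L, gene = "GENEA"),
               ann_row(pos = 200L, gene = "GENEA"),
               ann_row(pos = 300L, gene = "GENEB", gt = "1/1"),
               ann_row(pos = 400L, gene = "GENEC"))
  mot <- rbind(ann_row(pos = 100L, gene = "GENEA"),   # maternal carrier
               ann_row(pos = 300L, gene = "GENEB"))
  fat <- rbind(ann_row(pos = 200L, gene = "GENEA"),   # paternal carrier
               ann_row(pos = 300L, gene = "GENEB"))
  trio <- infer_inheritance(merge_trio(pro, mot, fat))
  expect_identical(trio$de_novo, c(FALSE, FALSE, FALSE, TRUE))
  expect_identical(trio$recessive_hom, c(FALSE, FALSE, TRUE, FALSE))
  expect_identical(trio$maternal, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(trio$paternal, c(FALSE, TRUE, FALSE, FALSE))
  # proband het with a het mother is not de novo
  expect_false(trio$de_novo[1])
  # low genotype quality blocks de novo assertions
  pro2 <- data.table::copy(pro)
  pro2$gq[4] <- 10L
  trio2 <- infer_inheritance(merge_trio(pro2, mot, fat), gq_min = 30L)
  expect_false(trio2$de_novo[4])
})

test_that("compound heterozygotes require one allele from each parent", {
  tab <- toy_disease_table()
  diff <- build_differential(c("HP:1", "HP:2"), tab)
  pro <- rbind(ann_row(pos = 100L, gene = "GENEA",
                       consequence = "splice_disruption", category = 2L),
               ann_row(pos = 200L, gene = "GENEA",
                       consequence = "polypyrimidine_tract", category = 3L))
  mot <- ann_row(pos = 100L, gene = "GENEA")
  fat <- ann_row(pos = 200L, gene = "GENEA")
  trio <- infer_inheritance(merge_trio(pro, mot, fat))
  res <- filter_and_rank(trio, filter_spec(inheritance = "recessive",
                                           maf_max = 0.001),
                         diff, tab)
  expect_identical(res$gene, "GENEA")
  expect_identical(res$pattern, "compound_het")
  expect_equal(res$n_variants, 2L)
  # both alleles from one parent: not compound het
  mot2 <- pro[, 1:11]
  trio2 <- infer_inheritance(merge_trio(pro, mot2,
                                        ann_row(pos = 999L, gene = "X")))
  res2 <- filter_and_rank(trio2, filter_spec(inheritance = "recessive",
                                             maf_max = 0.001), diff, tab)
  expect_false("compound_het" %in% res2$pattern)
})

test_that("category, MAF and inheritance filters are strict and monotone", {
  pro <- rbind(ann_row(pos = 100L, gene = "GENEA", category = 2L,
                       maf = 0.001),
               ann_row(pos = 200L, gene = "GENEB", category = 4L,
                       maf = 0),
               ann_row(pos = 300L, gene = "GENEC", category = 3L,
                       maf = 0.01))
  mot <- ann_row(pos = 100L, gene = "GENEA")
  trio <- infer_inheritance(merge_trio(pro, mot, pro[0]))
  # maf exactly equal to the cutoff is excluded (strict <)
  r1 <- filter_and_rank(trio, filter_spec(categories = 1:3,
                                          maf_max = 0.01,
                                          inheritance = "any"))
  expect_true(all(r1$gene != "GENEC"))
  # loosening the MAF cutoff or adding categories never removes genes
  r2 <- filter_and_rank(trio, filter_spec(categories = 1:3, maf_max = 0.05,
                                          inheritance = "any"))
  expect_true(all(r1$gene %in% r2$gene))
  r3 <- filter_and_rank(trio, filter_spec(categories = 1:4, maf_max = 0.05,
                                          inheritance = "any"))
  expect_true(all(r2$gene %in% r3$gene))
  # empty input: empty output
  expect_equal(nrow(filter_and_rank(trio[0], filter_spec())), 0L)
})

test_that("a planted compound het in a differential gene beats the decoys", {
  tab <- toy_disease_table()
  diff <- build_differential(c("HP:1", "HP:2", "HP:3"), tab)
  set.seed(131)
  # planted: two splice-region variants in GENEA, one per parent, MAF 0
  pro <- rbind(
    ann_row(pos = 1000L, gene = "GENEA", category = 2L,
            consequence = "splice_disruption"),
    ann_row(pos = 2000L, gene = "GENEA", category = 3L,
            consequence = "polypyrimidine_tract"))
  mot <- ann_row(pos = 1000L, gene = "GENEA", category = 2L,
                 consequence = "splice_disruption")
  fat <- ann_row(pos = 2000L, gene = "GENEA", category = 3L,
                 consequence = "polypyrimidine_tract")
  # >= 20 decoys violating category, MAF, or phase
  decoys <- list()
  for (i in 1:8) {  # category violations
    decoys[[length(decoys) + 1L]] <-
      ann_row(pos = 10000L + i, gene = paste0("DECOY_CAT", i),
              category = sample(4:5, 1L))
  }
  for (i in 1:6) {  # MAF violations
    decoys[[length(decoys) + 1L]] <-
      ann_row(pos = 20000L + i, gene = paste0("DECOY_MAF", i),
              category = 3L, maf = 0.05)
  }
  phase_genes <- paste0("DECOY_PHASE", 1:7)
  for (i in 1:7) {  # phase violations: both hets from the mother
    decoys[[length(decoys) + 1L]] <-
      ann_row(pos = 30000L + 2L * i, gene = phase_genes[i], category = 3L)
    decoys[[length(decoys) + 1L]] <-
      ann_row(pos = 30001L + 2L * i, gene = phase_genes[i], category = 3L)
  }
  decoys <- data.table::rbindlist(decoys)
  expect_gte(nrow(decoys), 20L)
  pro_all <- rbind(pro, decoys)
  mot_all <- rbind(mot, decoys)  # every decoy variant is maternal
  trio <- infer_inheritance(merge_trio(pro_all, mot_all, fat))
  res <- filter_and_rank(trio, filter_spec(categories = 1:3,
                                           maf_max = 0.001,
                                           inheritance = "recessive"),
                         diff, tab)
  expect_identical(unique(res$gene), "GENEA")
  expect_identical(res$pattern, "compound_het")
  expect_true(res$in_differential)
})

test_that("pedigree and disease-table files round trip", {
  f <- tempfile()
  writeLines(c("child\tdad\tmom\tM\t1", "dad\t0\t0\t1\t0",
               "mom\t0\t0\t2\t0"), f)
  ped <- read_ped(f)
  expect_identical(ped$sex, c("M", "M", "F"))
  expect_identical(ped$affected, c(TRUE, FALSE, FALSE))
  f2 <- tempfile()
  writeLines(c("disease_id\tdisease_name\thpo_terms\tgenes\tinheritance",
               "D1\tAlpha\tHP:1;HP:2\tG1;G2\trecessive",
               "D2\tBeta\tHP:3\t\tdominant"), f2)
  tab <- read_disease_table(f2)
  expect_identical(tab$disease_id, "D1")  # D2 has no causative gene
  expect_identical(tab$terms[[1]], c("HP:1", "HP:2"))
})
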