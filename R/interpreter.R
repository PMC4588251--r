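# Phenotype-driven differential diagnosis and inheritance-aware trio
# filtering: an HPO-term match-count differential over a disease
# annotation table, genotype-based inheritance pattern inference in a
# parent-child trio, and dynamic variant filtering by ACMG-style
# category, allele frequency and inheritance mode down to candidate
# diagnoses.

#' Read a disease annotation table
#'
#' TSV columns: disease_id, disease_name, hpo_terms (semicolon- or
#' comma-separated), genes (same), inheritance (one of de_novo,
#' recessive, dominant, x_linked, mitochondrial, any; multiple allowed).
#' Entries without at least one term and one gene are removed.
#'
#' @param path TSV path
#' @return data.table with list columns terms, genes, inheritance
#' @export
read_disease_table <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  disease_table(d$disease_id, d$disease_name, strsplit(d$hpo_terms, "[;,]"),
                strsplit(d$genes, "[;,]"),
                strsplit(d$inheritance, "[;,]"))
}

#' Build a disease annotation table programmatically
#'
#' @param disease_id,disease_name character vectors
#' @param terms,genes,inheritance lists of character vectors
#' @return data.table, one row per disease
#' @export
disease_table <- function(disease_id, disease_name, terms, genes,
                          inheritance) {
  d <- data.table::data.table(
    disease_id = disease_id, disease_name = disease_name,
    terms = lapply(terms, function(x) unique(trimws(x))),
    genes = lapply(genes, function(x) unique(trimws(x))),
    inheritance = lapply(inheritance, function(x) trimws(x)))
  # diagnoses without known causative genes (or without terms) are removed
  keep <- vapply(d$genes, function(g) length(g) > 0L && any(nzchar(g)),
                 logical(1)) &
    vapply(d$terms, function(t) length(t) > 0L && any(nzchar(t)),
           logical(1))
  d[keep]
}

#' Build a ranked differential diagnosis from patient phenotype terms
#'
#' Diseases matching at least one entered HPO term are ranked by the
#' number of matching terms (descending), ties alphabetical by disease
#' id.  The gene superset is the union of genes of all listed diseases.
#'
#' @param patient_terms character vector of HPO term ids
#' @param table disease annotation table ([disease_table()])
#' @param max_diseases optional cap on the differential length
#' @return list(differential (data.table: disease_id, disease_name,
#'   n_match, rank), genes (character))
#' @export
build_differential <- function(patient_terms, table, max_diseases = NULL) {
  stopifnot(length(patient_terms) >= 1L)
  patient_terms <- unique(patient_terms)
  n_match <- vapply(table$terms, function(t) {
    length(intersect(patient_terms, t))
  }, integer(1))
  keep <- n_match >= 1L
  d <- data.table::data.table(disease_id = table$disease_id[keep],
                              disease_name = table$disease_name[keep],
                              n_match = n_match[keep])
  data.table::setorder(d, -n_match, disease_id)
  if (!is.null(max_diseases) && nrow(d) > max_diseases) {
    d <- d[seq_len(max_diseases)]
  }
  d[, rank := seq_len(.N)]
  genes <- unique(unlist(table$genes[keep][order(-n_match[keep])]))
  list(differential = d, genes = genes)
}

#' Read a pedigree file
#'
#' Tab-separated: id, father, mother, sex (M/F or 1/2), affected (0/1);
#' "0" or "." denote a missing parent.
#'
#' @param path file path
#' @return data.table
#' @export
read_ped <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = FALSE,
                         col.names = c("id", "father", "mother", "sex",
                                       "affected"),
                         colClasses = "character")
  d$sex <- ifelse(d$sex %in% c("1", "M", "m"), "M",
                  ifelse(d$sex %in% c("2", "F", "f"), "F", NA))
  d$affected <- d$affected %in% c("1", "2", "yes")
  d
}

#' Merge three samples' annotated variants into a trio table
#'
#' Variants are joined on (contig, pos, ref, alt); absent genotypes
#' become "0/0" when the sample was genotyped over the region (this
#' desk-scale merger assumes jointly covered variants) .
#'
#' @param proband,mother,father annotated call tables
#' @return trio data.table with gt/gq columns per member
#' @export
merge_trio <- function(proband, mother, father) {
  key <- function(d) paste(d$contig, d$pos, d$ref, d$alt)
  tr <- data.table::copy(proband)
  data.table::setnames(tr, c("gt", "gq"), c("gt_proband", "gq_proband"),
                       skip_absent = TRUE)
  mk <- key(mother)
  fk <- key(father)
  m <- match(key(tr), mk)
  f <- match(key(tr), fk)
  tr$gt_mother <- ifelse(is.na(m), "0/0", mother$gt[m])
  tr$gq_mother <- ifelse(is.na(m), 99L, mother$gq[m])
  tr$gt_father <- ifelse(is.na(f), "0/0", father$gt[f])
  tr$gq_father <- ifelse(is.na(f), 99L, father$gq[f])
  tr
}

.has_alt <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/0", "1/1", "1")
.is_hom <- function(gt) !is.na(gt) & gt %in% c("1/1", "1")
.is_het <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/0")

#' Infer candidate inheritance patterns per variant
#'
#' Labels each trio variant with every monogenic pattern it could
#' support: de novo (proband alt, both parents reference, all genotype
#' qualities at or above `gq_min`), recessive_hom (proband homozygous,
#' both parents carriers), hemizygous (X contig, male proband, alt),
#' dominant (proband heterozygous, affected-only model), mitochondrial
#' (MT contig), plus maternal / paternal carrier flags used for
#' compound-heterozygote phasing.  A missing parental genotype marks the
#' pattern unresolved rather than excluded.
#'
#' @param trio merged trio table from [merge_trio()]
#' @param proband_sex "M" or "F" (required for X-linked logic)
#' @param gq_min minimum genotype quality for de novo assertions
#' @param x_contigs,mt_contigs contig names treated as X / mitochondrial
#' @return the trio table with logical pattern columns added
#' @export
infer_inheritance <- function(trio, proband_sex = "F", gq_min = 30L,
                              x_contigs = c("X", "chrX"),
                              mt_contigs = c("MT", "chrM")) {
  t <- data.table::copy(trio)
  pa <- .has_alt(t$gt_proband)
  mo_na <- is.na(t$gt_mother)
  fa_na <- is.na(t$gt_father)
  t[, de_novo := pa & !mo_na & !fa_na &
      !.has_alt(gt_mother) & !.has_alt(gt_father) &
      gq_proband >= gq_min & gq_mother >= gq_min & gq_father >= gq_min]
  t[, unresolved := pa & (mo_na | fa_na)]
  t[, recessive_hom := .is_hom(gt_proband) &
      (mo_na | .has_alt(gt_mother)) & (fa_na | .has_alt(gt_father))]
  t[, hemizygous := pa & contig %in% x_contigs & proband_sex == "M"]
  t[, dominant := .is_het(gt_proband)]
  t[, mitochondrial := pa & contig %in% mt_contigs]
  t[, maternal := pa & !mo_na & .has_alt(gt_mother) & !.has_alt(gt_father)]
  t[, paternal := pa & !fa_na & .has_alt(gt_father) & !.has_alt(gt_mother)]
  t
}

#' Variant filter specification
#'
#' @param categories ACMG-style categories kept (default 1-3)
#' @param maf_max strict upper bound on warehouse MAF; one of the usual
#'   interpretation cutoffs (0.01, 0.005, 0.001) or any fraction
#' @param inheritance one of "de_novo", "recessive", "dominant",
#'   "x_linked", "mitochondrial", "any"
#' @param gene_list optional restriction to a gene set
#' @param unique_only keep only variants absent from the warehouse
#' @return object of class `filter_spec`
#' @export
filter_spec <- function(categories = 1:3, maf_max = 0.01,
                        inheritance = "any", gene_list = NULL,
                        unique_only = FALSE) {
  stopifnot(maf_max > 0, maf_max <= 1,
            inheritance %in% c("de_novo", "recessive", "dominant",
                               "x_linked", "mitochondrial", "any"))
  structure(list(categories = as.integer(categories), maf_max = maf_max,
                 inheritance = inheritance, gene_list = gene_list,
                 unique_only = unique_only),
            class = "filter_spec")
}

#' Filter trio variants and rank candidate diagnoses
#'
#' Keeps variants whose category is in the filter set and whose MAF is
#' strictly below the cutoff (or warehouse-absent in uniqueness mode),
#' applies the inheritance mode (recessive requires a homozygous or
#' hemizygous variant, or two heterozygous variants in one gene
#' inherited in trans, one from each parent), groups by gene, and ranks
#' candidates by presence and rank of the gene in the phenotype
#' differential, then by best category.
#'
#' @param trio inheritance-annotated trio table ([infer_inheritance()])
#' @param spec a [filter_spec()]
#' @param differential result of [build_differential()], or NULL
#' @param disease_tab the disease annotation table (for gene-to-disease
#'   ranks)
#' @return data.table of candidate diagnoses: gene, pattern, n_variants,
#'   variant keys, in_differential, best_disease_rank, best_category
#' @export
filter_and_rank <- function(trio, spec = filter_spec(),
                            differential = NULL, disease_tab = NULL) {
  empty <- data.table::data.table(
    gene = character(), pattern = character(), n_variants = integer(),
    variants = character(), in_differential = logical(),
    best_disease_rank = integer(), best_category = integer())
  if (nrow(trio) == 0L) return(empty)
  keep <- trio$category %in% spec$categories
  keep <- keep & if (spec$unique_only) trio$known_status == "novel" &
    trio$maf == 0 else trio$maf < spec$maf_max
  if (!is.null(spec$gene_list)) {
    keep <- keep & trio$gene %in% spec$gene_list
  }
  d <- trio[keep & !is.na(gene)]
  if (nrow(d) == 0L) return(empty)

  gene_rank <- function(g) {
    if (is.null(differential) || is.null(disease_tab)) return(NA_integer_)
    dd <- differential$differential
    has <- vapply(disease_tab$genes, function(x) g %in% x, logical(1))
    ranks <- dd$rank[dd$disease_id %in% disease_tab$disease_id[has]]
    if (length(ranks) == 0L) NA_integer_ else min(ranks)
  }

  out <- list()
  for (g in sort(unique(d$gene))) {
    dg <- d[d$gene == g]
    pats <- list()
    if (spec$inheritance %in% c("de_novo", "any")) {
      if (any(dg$de_novo)) pats$de_novo <- which(dg$de_novo)
    }
    if (spec$inheritance %in% c("recessive", "any")) {
      if (any(dg$recessive_hom)) {
        pats$recessive_hom <- which(dg$recessive_hom)
      }
      if (any(dg$hemizygous)) pats$hemizygous <- which(dg$hemizygous)
      mat <- which(dg$maternal & .is_het(dg$gt_proband))
      pat <- which(dg$paternal & .is_het(dg$gt_proband))
      if (length(mat) >= 1L && length(pat) >= 1L) {
        pats$compound_het <- union(mat, pat)
      }
    }
    if (spec$inheritance %in% c("dominant", "any")) {
      if (any(dg$dominant & dg$de_novo)) {
        # affected-only model: dominant candidates must be de novo
        # unless a parent is flagged affected upstream
        pats$dominant <- which(dg$dominant & dg$de_novo)
      }
    }
    if (spec$inheritance %in% c("x_linked", "any")) {
      if (any(dg$hemizygous)) pats$x_linked <- which(dg$hemizygous)
    }
    if (spec$inheritance %in% c("mitochondrial", "any")) {
      if (any(dg$mitochondrial)) {
        pats$mitochondrial <- which(dg$mitochondrial)
      }
    }
    for (pn in names(pats)) {
      rows <- dg[pats[[pn]]]
      out[[length(out) + 1L]] <- data.table::data.table(
        gene = g, pattern = pn, n_variants = nrow(rows),
        variants = paste(rows$contig, rows$pos, rows$ref, rows$alt,
                         sep = ":", collapse = ";"),
        in_differential = !is.na(gene_rank(g)),
        best_disease_rank = gene_rank(g),
        best_category = min(rows$category))
    }
  }
  if (length(out) == 0L) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, -in_differential, best_disease_rank,
                       best_category, gene, pattern, na.last = TRUE)
  res
}

#' Interpret a trio end to end
#'
#' Convenience wrapper: build the differential, merge and
#' inheritance-annotate the trio, filter and rank.
#'
#' @param proband,mother,father annotated call tables
#' @param patient_terms HPO term ids observed in the proband
#' @param disease_tab disease annotation table
#' @param spec a [filter_spec()]
#' @param proband_sex "M" or "F"
#' @param gq_min de novo genotype-quality floor
#' @return list(candidates, differential, trio)
#' @export
interpret_trio <- function(proband, mother, father, patient_terms,
                           disease_tab, spec = filter_spec(),
                           proband_sex = "F", gq_min = 30L) {
  diff <- build_differential(patient_terms, disease_tab)
  trio <- merge_trio(proband, mother, father)
  trio <- infer_inheritance(trio, proband_sex = proband_sex,
                            gq_min = gq_min)
  cands <- filter_and_rank(trio, spec, diff, disease_tab)
  list(candidates = cands, differential = diff, trio = trio)
}
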