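# Consequence prediction and ACMG-style categorization.
#
# Gene models are transcript tables (exon structure plus a CDS interval);
# consequences are derived from transcript geometry and codon translation,
# taking the most severe across transcripts.  Categories follow the
# five-level ACMG-style scheme: 1 known disease-causing, 2 expected
# pathogenic by consequence type, 3 unknown significance but potentially
# causal, 4 probably not causative, 5 known benign.

CONSEQUENCE_SEVERITY <- c(
  "loss_of_initiation", "premature_stop", "stop_disruption",
  "frameshift_indel", "splice_disruption", "polypyrimidine_tract",
  "splice_region_exonic", "nonsynonymous", "inframe_indel", "synonymous",
  "deep_intronic", "other", "intergenic")

CODON_TABLE <- {
  b <- c("T", "C", "A", "G")
  # TTT, TTC, TTA, TTG, TCT, ... : third base fastest, first slowest
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), times = 4L),
                   rep(b, times = 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
}

.rc_chr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a transcript model
#'
#' Exon intervals are 0-based half-open genomic coordinates on the
#' forward strand regardless of transcript strand; the CDS interval is
#' genomic as well.
#'
#' @param tx_id transcript id
#' @param gene gene symbol
#' @param contig contig name
#' @param strand "+" or "-"
#' @param exon_starts,exon_ends integer vectors (0-based half-open),
#'   ascending, non-overlapping
#' @param cds_start,cds_end genomic CDS interval (0-based half-open);
#'   equal for non-coding transcripts
#' @return one-row data.table with list columns
#' @export
transcript_model <- function(tx_id, gene, contig, strand, exon_starts,
                             exon_ends, cds_start, cds_end) {
  stopifnot(length(exon_starts) == length(exon_ends),
            all(exon_ends > exon_starts),
            !is.unsorted(exon_starts), strand %in% c("+", "-"))
  if (length(exon_starts) > 1L) {
    stopifnot(all(exon_starts[-1L] >= exon_ends[-length(exon_ends)]))
  }
  data.table::data.table(
    tx_id = tx_id, gene = gene, contig = contig, strand = strand,
    exon_starts = list(as.integer(exon_starts)),
    exon_ends = list(as.integer(exon_ends)),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
}

#' Read gene models from a tab-separated table
#'
#' Columns: tx_id, gene, contig, strand, exon_starts (comma-separated,
#' 1-based starts), exon_ends (comma-separated, 1-based inclusive ends),
#' cds_start (1-based), cds_end (1-based inclusive).  BED12 input uses
#' the standard 12 columns (0-based; name column carries "tx|gene").
#'
#' @param path file path
#' @param format "tsv" or "bed12"
#' @return data.table of transcript models
#' @export
read_gene_models <- function(path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character")
    models <- lapply(seq_len(nrow(d)), function(i) {
      es <- as.integer(strsplit(d$exon_starts[i], ",")[[1]]) - 1L
      ee <- as.integer(strsplit(d$exon_ends[i], ",")[[1]])
      transcript_model(d$tx_id[i], d$gene[i], d$contig[i], d$strand[i],
                       es, ee, as.integer(d$cds_start[i]) - 1L,
                       as.integer(d$cds_end[i]))
    })
  } else {
    d <- data.table::fread(path, sep = "\t", header = FALSE)
    models <- lapply(seq_len(nrow(d)), function(i) {
      nm <- strsplit(as.character(d[[4]][i]), "|", fixed = TRUE)[[1]]
      sizes <- as.integer(strsplit(sub(",$", "", d[[11]][i]), ",")[[1]])
      offs <- as.integer(strsplit(sub(",$", "", d[[12]][i]), ",")[[1]])
      es <- d[[2]][i] + offs
      transcript_model(nm[1], if (length(nm) > 1L) nm[2] else nm[1],
                       as.character(d[[1]][i]), as.character(d[[6]][i]),
                       es, es + sizes, d[[7]][i], d[[8]][i])
    })
  }
  data.table::rbindlist(models)
}

# spliced CDS sequence (transcript orientation) and a map from genomic
# position to 0-based CDS offset
.cds_map <- function(tx, contig_seq) {
  es <- tx$exon_starts[[1]]
  ee <- tx$exon_ends[[1]]
  keep <- ee > tx$cds_start & es < tx$cds_end
  cs <- pmax(es[keep], tx$cds_start)
  ce <- pmin(ee[keep], tx$cds_end)
  gpos <- unlist(lapply(seq_along(cs), function(i) seq(cs[i], ce[i] - 1L)))
  seq_fwd <- paste(substring(contig_seq, cs + 1L, ce), collapse = "")
  if (tx$strand == "+") {
    list(seq = seq_fwd, gpos = gpos)
  } else {
    list(seq = .rc_chr(seq_fwd), gpos = rev(gpos))
  }
}

#' Assess cryptic splice-site creation
#'
#' A variant is flagged when the alternate sequence creates a GT (donor)
#' or AG (acceptor) dinucleotide within 3 nt of the variant that the
#' reference sequence lacks at the corresponding offset.
#'
#' @param contig_seq contig sequence
#' @param pos 0-based variant position
#' @param ref,alt alleles
#' @return logical
#' @export
cryptic_splice_flag <- function(contig_seq, pos, ref, alt) {
  lo <- max(0L, pos - 3L)
  hi <- min(nchar(contig_seq), pos + nchar(ref) + 3L)
  before <- substr(contig_seq, lo + 1L, hi)
  after <- paste0(substr(contig_seq, lo + 1L, pos), alt,
                  substr(contig_seq, pos + nchar(ref) + 1L, hi))
  has <- function(x) grepl("GT", x, fixed = TRUE) ||
    grepl("AG", x, fixed = TRUE)
  has(after) && !has(before)
}

# consequence of one variant on one transcript
.tx_consequence <- function(tx, contig_seq, pos, ref, alt) {
  es <- tx$exon_starts[[1]]
  ee <- tx$exon_ends[[1]]
  tx_start <- min(es)
  tx_end <- max(ee)
  vstart <- pos
  vend <- pos + nchar(ref)  # half-open genomic footprint
  if (vend <= tx_start || vstart >= tx_end) return("intergenic")
  is_indel <- nchar(ref) != nchar(alt)
  # for anchored indels the informative footprint starts after the anchor
  if (is_indel && nchar(ref) >= 1L && nchar(alt) >= 1L &&
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    vstart <- pos + 1L
    if (vend <= vstart) vend <- vstart + 1L  # pure insertion point
  }
  in_exon <- any(vstart < ee & vend > es)
  if (!in_exon) {
    # intron: distances to the flanking splice boundaries
    donor_d <- acceptor_d <- Inf
    for (i in seq_along(es)) {
      if (tx$strand == "+") {
        if (i < length(es) && vstart >= ee[i] && vend <= es[i + 1L]) {
          donor_d <- vstart - ee[i] + 1L          # +1, +2, ... after donor
          acceptor_d <- es[i + 1L] - (vend - 1L)  # -1, -2, ... before acceptor
        }
      } else {
        if (i < length(es) && vstart >= ee[i] && vend <= es[i + 1L]) {
          acceptor_d <- vstart - ee[i] + 1L
          donor_d <- es[i + 1L] - (vend - 1L)
        }
      }
    }
    d <- min(donor_d, acceptor_d)
    if (d <= 2) return("splice_disruption")
    if (acceptor_d <= 20) return("polypyrimidine_tract")
    if (d > 20) return("deep_intronic")
    return("other")  # donor-side intron 3-20 nt: no specific class
  }
  # exonic: near-boundary context (first/last 3 exonic nt of an exon with
  # a neighboring intron)
  near_splice <- FALSE
  for (i in seq_along(es)) {
    if (vstart < ee[i] && vend > es[i]) {
      if (i > 1L && vstart - es[i] < 3L) near_splice <- TRUE
      if (i < length(es) && ee[i] - (vend - 1L) <= 3L) near_splice <- TRUE
    }
  }
  no_cds <- tx$cds_end <= tx$cds_start
  in_cds <- !no_cds && vstart < tx$cds_end && vend > tx$cds_start
  if (!in_cds) {
    return(if (near_splice) "splice_region_exonic" else "other")
  }
  if (is_indel) {
    cm <- .cds_map(tx, contig_seq)
    ncds <- nchar(cm$seq)
    cds_hit <- which(cm$gpos >= vstart & cm$gpos < vend)
    if (nchar(ref) > nchar(alt)) {  # deletion
      if (any(cds_hit <= 3L)) return("loss_of_initiation")
      if (any(cds_hit > ncds - 3L)) return("stop_disruption")
    }
    delta <- abs(nchar(ref) - nchar(alt))
    cons <- if (delta %% 3L == 0L) "inframe_indel" else "frameshift_indel"
    if (near_splice &&
        which(CONSEQUENCE_SEVERITY == "splice_region_exonic") <
          which(CONSEQUENCE_SEVERITY == cons)) {
      cons <- "splice_region_exonic"
    }
    return(cons)
  }
  # SNV (or MNV treated base by base; first differing base decides)
  cm <- .cds_map(tx, contig_seq)
  ci <- match(pos, cm$gpos)
  if (is.na(ci)) {
    return(if (near_splice) "splice_region_exonic" else "other")
  }
  base <- if (tx$strand == "+") alt else chartr("ACGT", "TGCA", alt)
  codon_i <- (ci - 1L) %/% 3L
  off <- (ci - 1L) %% 3L
  codon_ref <- substr(cm$seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  codon_alt <- codon_ref
  substr(codon_alt, off + 1L, off + 1L) <- base
  if (nchar(codon_ref) < 3L) return("other")  # truncated model
  aa_ref <- CODON_TABLE[[codon_ref]]
  aa_alt <- CODON_TABLE[[codon_alt]]
  cons <- if (codon_i == 0L && aa_alt != "M") "loss_of_initiation"
    else if (aa_ref == "*" && aa_alt != "*") "stop_disruption"
    else if (aa_alt == "*" && aa_ref != "*") "premature_stop"
    else if (aa_alt == aa_ref) "synonymous"
    else "nonsynonymous"
  if (near_splice &&
      which(CONSEQUENCE_SEVERITY == "splice_region_exonic") <
        which(CONSEQUENCE_SEVERITY == cons)) {
    cons <- "splice_region_exonic"
  }
  cons
}

#' Predict the consequence of a variant on a gene model set
#'
#' Geometry rules: intronic positions 1-2 nt from a splice boundary are
#' splice disruptions; acceptor-side positions 3-20 nt into the intron
#' hit the polypyrimidine tract; intronic positions more than 20 nt from
#' any boundary are deep intronic.  Exonic consequences come from codon
#' translation of the spliced CDS.  The most severe consequence across
#' transcripts is returned, with the gene of the deciding transcript.
#'
#' @param variant list or one-row data.frame with contig, pos (0-based),
#'   ref, alt (left-normalized)
#' @param gene_models data.table of transcript models
#' @param ref reference genome (named character vector)
#' @return list(consequence, gene, cryptic)
#' @export
predict_consequence <- function(variant, gene_models, ref) {
  contig_seq <- ref[[variant$contig]]
  gm <- gene_models[gene_models$contig == variant$contig]
  if (nrow(gm) == 0L) {
    return(list(consequence = "intergenic", gene = NA_character_,
                cryptic = FALSE))
  }
  cons <- vapply(seq_len(nrow(gm)), function(i) {
    .tx_consequence(gm[i], contig_seq, variant$pos, variant$ref,
                    variant$alt)
  }, character(1))
  sev <- match(cons, CONSEQUENCE_SEVERITY)
  best <- which.min(sev)
  gene <- if (cons[best] == "intergenic") NA_character_ else gm$gene[best]
  list(consequence = cons[best], gene = gene,
       cryptic = cryptic_splice_flag(contig_seq, variant$pos, variant$ref,
                                     variant$alt))
}

#' Assign an ACMG-style category 1-5
#'
#' Known status wins (1 disease-causing, 5 benign); then common variants
#' (MAF at or above `common_threshold`) are category 4; then expected
#' pathogenic consequence types are category 2, possibly-causal types
#' (including synonymous variants with a cryptic-splice flag) category
#' 3, and the rest (synonymous, deep intronic, intergenic, other)
#' category 4.
#'
#' @param consequence consequence string
#' @param known_status "disease_causing", "benign", or "novel"
#' @param maf warehouse minor allele frequency
#' @param cryptic cryptic-splice flag for synonymous variants
#' @param common_threshold MAF at or above which a variant is "commonly
#'   observed in unaffected individuals"
#' @return integer category 1-5
#' @export
assign_category <- function(consequence, known_status = "novel", maf = 0,
                            cryptic = FALSE, common_threshold = 0.02) {
  stopifnot(consequence %in% c(CONSEQUENCE_SEVERITY, "whole_gene_deletion"))
  if (known_status == "disease_causing") return(1L)
  if (known_status == "benign") return(5L)
  if (!is.na(maf) && maf >= common_threshold) return(4L)
  cat2 <- c("loss_of_initiation", "premature_stop", "stop_disruption",
            "frameshift_indel", "splice_disruption", "whole_gene_deletion")
  cat3 <- c("nonsynonymous", "inframe_indel", "polypyrimidine_tract",
            "splice_region_exonic")
  if (consequence %in% cat2) return(2L)
  if (consequence %in% cat3) return(3L)
  if (consequence == "synonymous" && isTRUE(cryptic)) return(3L)
  4L
}

#' Read a variant warehouse from TSV
#'
#' Expected columns: contig, pos (1-based), ref, alt, allele_count,
#' sample_count, and optionally status ("disease_causing" / "benign").
#' MAF is allele_count / (2 * sample_count).
#'
#' @param path TSV path
#' @return object of class `variant_warehouse`
#' @export
read_warehouse <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE)
  d[, key := paste(contig, pos - 1L, ref, alt)]
  d[, maf := allele_count / (2 * sample_count)]
  if (!"status" %in% names(d)) d[, status := "observed"]
  structure(list(table = d), class = "variant_warehouse")
}

#' Build a warehouse programmatically
#' @param table data.table with contig, pos (0-based), ref, alt, maf and
#'   optionally status
#' @return object of class `variant_warehouse`
#' @export
variant_warehouse <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.table::data.table(contig = character(), pos = integer(),
                                    ref = character(), alt = character(),
                                    maf = numeric(), status = character())
  }
  d <- data.table::as.data.table(table)
  if (!"status" %in% names(d)) d[, status := "observed"]
  d[, key := paste(contig, pos, ref, alt)]
  structure(list(table = d), class = "variant_warehouse")
}

.warehouse_lookup <- function(wh, keys) {
  m <- match(keys, wh$table$key)
  list(maf = ifelse(is.na(m), 0, wh$table$maf[m]),
       status = ifelse(is.na(m), "novel",
                       data.table::fifelse(
                         wh$table$status[m] == "disease_causing",
                         "disease_causing",
                         data.table::fifelse(wh$table$status[m] == "benign",
                                             "benign", "observed"))))
}

#' Annotate a call set with consequences, categories and warehouse MAF
#'
#' @param calls call data.table (contig, pos 0-based, ref, alt, gt, gq,
#'   dp optional)
#' @param gene_models transcript model table
#' @param warehouse a `variant_warehouse`
#' @param ref reference genome
#' @param common_threshold see [assign_category()]
#' @return annotated data.table adding gene, consequence, category, maf,
#'   known_status
#' @export
annotate_variants <- function(calls, gene_models, warehouse, ref,
                              common_threshold = 0.02) {
  out <- data.table::copy(calls)
  if (nrow(out) == 0L) {
    out[, `:=`(gene = character(), consequence = character(),
               category = integer(), maf = numeric(),
               known_status = character())]
    return(out)
  }
  res <- lapply(seq_len(nrow(out)), function(i) {
    predict_consequence(out[i], gene_models, ref)
  })
  out$consequence <- vapply(res, `[[`, character(1), "consequence")
  out$gene <- vapply(res, `[[`, character(1), "gene")
  cry <- vapply(res, `[[`, logical(1), "cryptic")
  wl <- .warehouse_lookup(warehouse, paste(out$contig, out$pos, out$ref,
                                           out$alt))
  out$maf <- wl$maf
  out$known_status <- ifelse(wl$status == "observed", "novel", wl$status)
  out$category <- vapply(seq_len(nrow(out)), function(i) {
    assign_category(out$consequence[i], out$known_status[i], out$maf[i],
                    cry[i], common_threshold)
  }, integer(1))
  out
}

#' Write annotated variants as a JSON document
#'
#' The interpretation tool consumes one JSON document per sample with
#' 1-based positions.
#'
#' @param annotated annotated call table from [annotate_variants()]
#' @param sample sample id
#' @param path output path
#' @export
write_annotation_json <- function(annotated, sample, path) {
  doc <- list(sample = sample,
              variants = data.frame(
                contig = annotated$contig, pos = annotated$pos + 1L,
                ref = annotated$ref, alt = annotated$alt,
                gt = annotated$gt,
                gq = if ("gq" %in% names(annotated)) annotated$gq else NA,
                gene = annotated$gene,
                consequence = annotated$consequence,
                category = annotated$category, maf = annotated$maf,
                known_status = annotated$known_status))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a sample's annotated-variant JSON document
#' @param path JSON path
#' @return list(sample, variants) with 0-based positions restored
#' @export
read_annotation_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- data.table::as.data.table(doc$variants)
  if (nrow(v) > 0L) v$pos <- as.integer(v$pos) - 1L
  list(sample = doc$sample, variants = v)
}
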