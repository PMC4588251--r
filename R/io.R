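#' Read a multi-contig FASTA file
#'
#' Contig sequences are uppercased and concatenated across wrapped lines.
#' The result is a named character vector of sequences, the container used
#' for reference genomes throughout the package.
#'
#' @param path path to a FASTA file
#' @return named character vector, one element per contig
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  grp <- cumsum(hdr)
  names_ <- sub("^>", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  names(seqs) <- names_
  if (anyDuplicated(names_)) stop("duplicate contig names in ", path)
  if (any(!nzchar(seqs))) stop("empty contig sequence in ", path)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path path to an uncompressed FASTQ file
#' @return a data.table with columns id, seq, qual (quality string)
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines) %/% 4L
  if (n == 0L) stop("empty FASTQ: ", path)
  idx <- seq_len(n)
  data.table::data.table(
    id = sub("^@", "", sub("\\s.*$", "", lines[(idx - 1L) * 4L + 1L])),
    seq = toupper(lines[(idx - 1L) * 4L + 2L]),
    qual = lines[(idx - 1L) * 4L + 4L]
  )
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.table with columns id, seq, qual
#' @param path output path
#' @export
write_fastq <- function(reads, path) {
  out <- character(nrow(reads) * 4L)
  out[seq(1L, length(out), 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), 4L)] <- reads$seq
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#' @param qual quality string
#' @return integer vector
#' @export
phred_decode <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}

#' Encode integer Phred scores as a Phred+33 string
#' @param q integer vector of scores
#' @return character scalar
#' @export
phred_encode <- function(q) {
  rawToChar(as.raw(q + 33L))
}

#' Write an alignment set to SAM
#'
#' Emits a valid header (\code{@HD}, \code{@SQ} from the reference) and the
#' 11 mandatory fields; alignment score goes in the \code{AS:i} tag and the
#' pair score in \code{ps:f}.  Positions in the alignment table are 0-based
#' and are converted to SAM's 1-based convention here.
#'
#' @param aln alignment data.table as returned by [map_reads()]
#' @param ref reference genome (named character vector)
#' @param path output path
#' @export
write_sam <- function(aln, ref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", names(ref), "\tLN:", nchar(ref)))
  rname <- ifelse(aln$contig == 0L, "*", names(ref)[aln$contig])
  rnext <- ifelse(aln$mcontig == 0L, "*",
                  ifelse(aln$mcontig == aln$contig & aln$contig != 0L, "=",
                         names(ref)[pmax(aln$mcontig, 1L)]))
  body <- paste(aln$qname, aln$flag, rname, aln$pos + 1L, aln$mapq, aln$cigar,
                rnext, aln$mpos + 1L, aln$tlen, aln$seq, aln$qual,
                paste0("AS:i:", aln$score),
                paste0("ps:f:", aln$pair_score),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Only the fields used by this pipeline are retained; positions are
#' converted back to the package's 0-based convention.
#'
#' @param path path to a SAM file
#' @return list with \code{aln} (data.table) and \code{contigs}
#'   (named integer vector of lengths from the header)
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  cn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  cl <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  names(cl) <- cn
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    return(list(aln = data.table::data.table(), contigs = cl))
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:11)
  aln <- data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]),
    contig = ifelse(f[[3]] == "*", 0L, match(f[[3]], cn)),
    pos = as.integer(f[[4]]) - 1L, mapq = as.integer(f[[5]]),
    cigar = f[[6]],
    mcontig = ifelse(f[[7]] == "*", 0L,
                     ifelse(f[[7]] == "=", match(f[[3]], cn),
                            match(f[[7]], cn))),
    mpos = as.integer(f[[8]]) - 1L, tlen = as.integer(f[[9]]),
    seq = f[[10]], qual = f[[11]]
  )
  aln$read <- data.table::fifelse(bitwAnd(aln$flag, 0x80L) != 0L, 2L, 1L)
  as_tag <- regmatches(body, regexpr("AS:i:-?[0-9]+", body))
  aln$score <- 0L
  aln$score[grepl("AS:i:", body)] <- as.integer(sub("AS:i:", "", as_tag))
  ps_tag <- regmatches(body, regexpr("ps:f:[-0-9.e+]+", body))
  aln$pair_score <- 0
  aln$pair_score[grepl("ps:f:", body)] <- as.numeric(sub("ps:f:", "", ps_tag))
  list(aln = aln, contigs = cl)
}

#' Write variant calls to VCF 4.2
#'
#' @param calls data.table with columns contig, pos (0-based), ref, alt,
#'   qual, gt, ad_ref, ad_alt, dp, gq
#' @param ref reference genome (named character vector)
#' @param path output path
#' @param sample sample name for the genotype column
#' @export
write_vcf <- function(calls, ref, path, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", names(ref), ",length=", nchar(ref), ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  body <- paste(calls$contig, calls$pos + 1L, ".", calls$ref, calls$alt,
                formatC(calls$qual, format = "f", digits = 2), "PASS",
                paste0("DP=", calls$dp), "GT:AD:DP:GQ",
                paste0(calls$gt, ":", calls$ad_ref, ",", calls$ad_alt, ":",
                       calls$dp, ":", calls$gq),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into a call table
#'
#' A deliberately small reader for the subset of VCF this package writes:
#' single-sample, one ALT allele per row, GT as the first FORMAT field.
#'
#' @param path path to an uncompressed VCF
#' @return data.table with contig, pos (0-based), ref, alt, qual, gt
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.table::data.table(contig = character(), pos = integer(),
                                  ref = character(), alt = character(),
                                  qual = numeric(), gt = character()))
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  out <- data.table::data.table(
    contig = f[[1]], pos = as.integer(f[[2]]) - 1L, ref = f[[4]],
    alt = f[[5]], qual = suppressWarnings(as.numeric(f[[6]])),
    gt = NA_character_
  )
  if (length(f) >= 10L) {
    keys <- strsplit(f[[9]], ":", fixed = TRUE)
    vals <- strsplit(f[[10]], ":", fixed = TRUE)
    pick <- function(i, key) {
      j <- match(key, keys[[i]])
      if (is.na(j) || j > length(vals[[i]])) NA_character_ else vals[[i]][j]
    }
    out$gt <- vapply(seq_along(keys), pick, character(1), key = "GT")
    out$gq <- suppressWarnings(as.integer(
      vapply(seq_along(keys), pick, character(1), key = "GQ")))
    out$dp <- suppressWarnings(as.integer(
      vapply(seq_along(keys), pick, character(1), key = "DP")))
  }
  out
}
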