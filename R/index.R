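#' Hash-index construction parameters
#'
#' Defaults follow the rapid-WGS mapper this package emulates: 21-nt
#' primary seeds, at most 16 reference locations per seed before dynamic
#' extension kicks in, symmetric extension in 3-nt increments per side up
#' to 64 nt per side (so the maximum extended seed is 21 + 2*64 = 149 nt),
#' and seed extraction at every even read offset (50% density).
#'
#' @param primary_seed_len primary seed length in nt
#' @param max_hits maximum reference locations stored per seed
#' @param max_ext_per_side maximum extension in nt on each side
#' @param ext_increment extension step in nt per side per EXTEND record
#' @param seed_stride distance between seed start offsets in a read
#' @return an object of class `index_params`
#' @export
index_params <- function(primary_seed_len = 21L, max_hits = 16L,
                         max_ext_per_side = 64L, ext_increment = 3L,
                         seed_stride = 2L) {
  p <- list(primary_seed_len = as.integer(primary_seed_len),
            max_hits = as.integer(max_hits),
            max_ext_per_side = as.integer(max_ext_per_side),
            ext_increment = as.integer(ext_increment),
            seed_stride = as.integer(seed_stride))
  stopifnot(all(vapply(p, function(x) x > 0L, logical(1))))
  p$max_seed_len <- p$primary_seed_len + 2L * p$max_ext_per_side
  class(p) <- "index_params"
  p
}

#' Build a hash-table index of a reference genome
#'
#' Every primary seed occurring in the reference maps either to a list of
#' at most `max_hits` forward-strand locations, or to a chain of EXTEND
#' records directing the query to join flanking read bases and re-query
#' with a longer seed.  Seeds still matching more than `max_hits`
#' locations at the maximum extended length carry a high-frequency marker
#' and return no hits.  Seeds containing non-ACGT bases are not indexed;
#' only the forward strand is stored (orientation is resolved at query
#' time).
#'
#' @param ref reference genome: named character vector of contig sequences
#' @param params an [index_params()] object
#' @return an opaque index handle of class `seq_index`
#' @export
build_index <- function(ref, params = index_params()) {
  if (length(ref) == 0L || all(!nzchar(ref)))
    stop("build_index: empty reference")
  if (is.null(names(ref)) || anyDuplicated(names(ref)))
    stop("build_index: contigs must have unique names")
  short <- nchar(ref) < params$primary_seed_len
  if (any(short)) {
    warning("skipping contig(s) shorter than the primary seed: ",
            paste(names(ref)[short], collapse = ", "))
  }
  ptr <- .build_index_cpp(names(ref), unname(toupper(ref)),
                          params$primary_seed_len, params$max_hits,
                          params$max_ext_per_side, params$ext_increment,
                          params$seed_stride)
  structure(list(ptr = ptr, params = params, ref = ref),
            class = "seq_index")
}

#' Query a read seed against the index
#'
#' Looks up the primary seed starting at `offset` (0-based) in the read,
#' in both orientations, following EXTEND records by joining flanking read
#' bases.  Hit positions are reported at the forward-strand start of the
#' primary seed.  When the read has too few flanking bases to satisfy an
#' EXTEND record, the seed is treated as high-frequency and returns no
#' hits.
#'
#' @param idx a `seq_index` from [build_index()]
#' @param read_seq read sequence
#' @param offset 0-based offset of the seed start in the read
#' @return list with `hits` (data.table: contig, pos, orientation) and
#'   `high_frequency` (logical)
#' @export
query_seed <- function(idx, read_seq, offset) {
  stopifnot(inherits(idx, "seq_index"))
  if (offset + idx$params$primary_seed_len > nchar(read_seq))
    stop("query_seed: seed extends past the read end")
  r <- .query_seed_cpp(idx$ptr, toupper(read_seq), as.integer(offset))
  hits <- data.table::data.table(
    contig = names(idx$ref)[r$contig],
    pos = r$pos,
    orientation = ifelse(r$orient == 1L, "rc", "fwd")
  )
  list(hits = hits, high_frequency = r$high_frequency)
}

#' Dump the index table in a deterministic tabular form
#'
#' One row per hash key, sorted by key: entry type (`hits`, `extend`,
#' `hifreq`), extension increments, and hit locations.  Byte-identical
#' across rebuilds from the same inputs, which makes it the index's
#' serialized form.
#'
#' @param idx a `seq_index`
#' @return data.table
#' @export
index_dump <- function(idx) {
  stopifnot(inherits(idx, "seq_index"))
  d <- data.table::as.data.table(.index_dump_cpp(idx$ptr))
  d$type <- c("hits", "extend", "hifreq")[d$type + 1L]
  d
}

#' Serialize an index to a tabular text file
#'
#' The file stores a version line, the parameters, the reference contigs,
#' and the full key table; [read_index()] reconstructs an equivalent index
#' (construction is deterministic, so the rebuilt handle's dump is
#' byte-identical to the original's).
#'
#' @param idx a `seq_index`
#' @param path output path
#' @export
write_index <- function(idx, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- idx$params
  writeLines(c("#rapidseq-index\tv1",
               paste("#params", p$primary_seed_len, p$max_hits,
                     p$max_ext_per_side, p$ext_increment, p$seed_stride,
                     sep = "\t"),
               paste0("#contig\t", names(idx$ref), "\t", idx$ref)), con)
  d <- index_dump(idx)
  writeLines(paste(d$key, d$type, d$ext_left, d$ext_right, d$hits,
                   sep = "\t"), con)
  invisible(path)
}

#' Load a serialized index
#' @param path file written by [write_index()]
#' @return a `seq_index`
#' @export
read_index <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#rapidseq-index"))
    stop("not a rapidseq index file: ", path)
  pf <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  params <- index_params(as.integer(pf[2]), as.integer(pf[3]),
                         as.integer(pf[4]), as.integer(pf[5]),
                         as.integer(pf[6]))
  cl <- lines[startsWith(lines, "#contig\t")]
  cf <- data.table::tstrsplit(cl, "\t", fixed = TRUE)
  ref <- cf[[3]]
  names(ref) <- cf[[2]]
  build_index(ref, params)
}

#' @export
print.seq_index <- function(x, ...) {
  info <- .index_params_cpp(x$ptr)
  cat("rapidseq hash index:", info$n_contigs, "contig(s),",
      format(info$n_keys, big.mark = ","), "keys;",
      "seed", info$primary_seed_len, "nt, max extended seed",
      info$primary_seed_len + 2L * info$max_ext_per_side, "nt\n")
  invisible(x)
}
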