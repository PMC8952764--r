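#' BLASTN-like scoring scheme with Karlin-Altschul statistics
#'
#' Defaults mirror common BLASTN megablast-style parameters: match +2,
#' mismatch -3, gap open -5, gap extend -2 (a gap of length L costs
#' `gap_open + L * gap_extend`), with Karlin-Altschul `lambda` = 0.625
#' nats per raw-score unit and `K` = 0.41, and 11-nt seeds. The x-drop
#' extension threshold defaults to 50 raw-score units (about 45 bits):
#' BLASTN's effective final-extension dropoff is of this order, and a smaller
#' value makes the extension give up on indels longer than a few nt, splitting
#' alignments that full Smith-Waterman would bridge.
#'
#' @param match_reward Positive integer match score.
#' @param mismatch_penalty Negative integer mismatch score.
#' @param gap_open,gap_extend Negative integer gap penalties.
#' @param lambda Karlin-Altschul scale (> 0).
#' @param K Karlin-Altschul search-space constant in (0, 1).
#' @param kmer_size Seed length in nt (8..32).
#' @param x_drop Extension termination threshold in raw-score units (> 0).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match_reward = 2L, mismatch_penalty = -3L,
                           gap_open = -5L, gap_extend = -2L,
                           lambda = 0.625, K = 0.41,
                           kmer_size = 11L, x_drop = 50L) {
  stopifnot(match_reward > 0, mismatch_penalty < 0,
            gap_open < 0, gap_extend < 0,
            lambda > 0, K > 0, K < 1,
            kmer_size >= 8, kmer_size <= 32, x_drop > 0)
  structure(list(match_reward = as.integer(match_reward),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K,
                 kmer_size = as.integer(kmer_size),
                 x_drop = as.integer(x_drop)),
            class = "scoring_scheme")
}

#' Karlin-Altschul bit score
#'
#' `bits = (lambda * raw - ln K) / ln 2`; strictly increasing in the raw
#' score.
#'
#' @param raw_score Non-negative raw alignment score(s).
#' @param scheme A [scoring_scheme()].
#' @return Bit score(s).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  if (any(raw_score < 0)) stop("raw_score must be >= 0")
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' Build a k-mer index over both strands of a subject genome
#'
#' Exact k-mers are indexed on the forward strand and on the reverse
#' complement of each contig; k-mers containing ambiguous bases are skipped,
#' so an all-`N` sequence yields an empty index (with a warning).
#'
#' @param subject Named character vector of contig sequences (or a single
#'   unnamed sequence).
#' @param kmer_size Seed length (default from [scoring_scheme()]).
#' @return An object of class `kmer_index`.
#' @export
index_subject <- function(subject, kmer_size = 11L) {
  subject <- as_genome(subject, "subject")
  if (kmer_size > max(nchar(subject)))
    warning("kmer_size exceeds every contig length; index is empty")
  ptrs <- lapply(unname(subject), cpp_index_build, k = as.integer(kmer_size))
  n_kmers <- sum(vapply(ptrs, cpp_index_size, integer(1)))
  if (n_kmers == 0L && kmer_size <= max(nchar(subject)))
    warning("no indexable k-mers (ambiguous-base-only sequence?)")
  structure(list(ptrs = ptrs, contig_ids = names(subject),
                 contig_lengths = unname(nchar(subject)),
                 kmer_size = as.integer(kmer_size)),
            class = "kmer_index")
}

#' Look up the indexed positions of one exact k-mer (forward strand)
#'
#' Intended for inspection and testing.
#'
#' @param index A [index_subject()] result.
#' @param kmer Character scalar of length `kmer_size`.
#' @return Integer vector of 0-based forward-strand start positions, per
#'   contig concatenated.
#' @export
kmer_positions <- function(index, kmer) {
  stopifnot(inherits(index, "kmer_index"),
            nchar(kmer) == index$kmer_size)
  unlist(lapply(index$ptrs,
                function(p) cpp_index_lookup(p, toupper(kmer))$fwd))
}

# Coerce a genome argument to a validated named character vector of contigs.
as_genome <- function(x, what = "genome") {
  if (!is.character(x) || length(x) < 1L)
    stop(what, " must be a character vector of contig sequences")
  if (any(!nzchar(x))) stop(what, " has an empty contig")
  if (is.null(names(x))) {
    if (length(x) == 1L) names(x) <- what
    else names(x) <- paste0(what, "_", seq_along(x))
  }
  toupper(x)
}

#' Find high-scoring segment pairs (HSPs) of a query against an indexed subject
#'
#' Seed-chain-extend local alignment: exact k-mer seeds on both subject
#' strands, banded gapped extension with an x-drop rule, identities and raw
#' score recomputed from the final alignment, HSPs overlapping on the same
#' diagonal resolved in favor of the higher-scoring one. Coordinates are
#' 0-based half-open on the forward strand of both sequences; `strand` gives
#' the subject orientation.
#'
#' @param query Named character vector of query contig sequences.
#' @param index A [index_subject()] result (or a subject genome, which will be
#'   indexed with the scheme's `kmer_size`).
#' @param scheme A [scoring_scheme()].
#' @return Data frame of HSPs sorted by bit score (desc), ties by
#'   (query_start, subject_start): columns query_id, subject_id, query_start,
#'   query_end, subject_start, subject_end, strand, alignment_length,
#'   identities, raw_score, bit_score.
#' @export
find_hsps <- function(query, index, scheme = scoring_scheme()) {
  query <- as_genome(query, "query")
  if (!inherits(index, "kmer_index"))
    index <- index_subject(index, scheme$kmer_size)
  out <- list()
  for (qi in seq_along(query)) {
    for (si in seq_along(index$ptrs)) {
      df <- cpp_find_hsps(query[[qi]], index$ptrs[[si]], scheme)
      if (nrow(df)) {
        df$query_id <- names(query)[qi]
        df$subject_id <- index$contig_ids[si]
        out[[length(out) + 1L]] <- df
      }
    }
  }
  if (!length(out)) return(empty_hsps())
  hsps <- do.call(rbind, out)
  hsps$bit_score <- bit_score(hsps$raw_score, scheme)
  hsps <- hsps[order(-hsps$bit_score, hsps$query_start, hsps$subject_start), ]
  rownames(hsps) <- NULL
  hsps[, c("query_id", "subject_id", "query_start", "query_end",
           "subject_start", "subject_end", "strand", "alignment_length",
           "identities", "raw_score", "bit_score")]
}

empty_hsps <- function() {
  data.frame(query_id = character(), subject_id = character(),
             query_start = integer(), query_end = integer(),
             subject_start = integer(), subject_end = integer(),
             strand = character(), alignment_length = integer(),
             identities = integer(), raw_score = integer(),
             bit_score = numeric(), stringsAsFactors = FALSE)
}

#' Ingest tabular alignment output in place of the internal aligner
#'
#' Reads an outfmt-6-like TSV with columns (qid, sid, pident, length, qstart,
#' qend, sstart, send, bitscore, rawscore), 1-based inclusive coordinates,
#' and converts to the package's 0-based half-open HSP convention. Rows with
#' `sstart > send` are minus-strand matches.
#'
#' @param path TSV path (no header).
#' @return HSP data frame as from [find_hsps()].
#' @export
read_hsps_tsv <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 10) stop("expected 10 columns (qid sid pident length qstart ",
                         "qend sstart send bitscore rawscore)")
  names(d)[1:10] <- c("qid", "sid", "pident", "length", "qstart", "qend",
                      "sstart", "send", "bitscore", "rawscore")
  minus <- d$sstart > d$send
  s1 <- ifelse(minus, d$send, d$sstart)
  s2 <- ifelse(minus, d$sstart, d$send)
  out <- data.frame(
    query_id = d$qid, subject_id = d$sid,
    query_start = d$qstart - 1L, query_end = d$qend,
    subject_start = s1 - 1L, subject_end = s2,
    strand = ifelse(minus, "-", "+"),
    alignment_length = d$length,
    identities = as.integer(round(d$pident / 100 * d$length)),
    raw_score = d$rawscore,
    bit_score = d$bitscore,
    stringsAsFactors = FALSE)
  out[order(-out$bit_score, out$query_start, out$subject_start), ]
}
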