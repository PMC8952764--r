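#' Parameters for fragment-based average nucleotide identity (ANIb)
#'
#' The query genome is cut into consecutive non-overlapping fragments
#' (default 1020 nt); each fragment's best HSP against the subject is accepted
#' when its identity fraction is at least `min_identity_fraction` (default
#' 0.30) and it covers at least `min_alignable_fraction` of the fragment
#' (default 0.70). The ANIb value is the mean identity percentage over
#' accepted fragments.
#'
#' @param fragment_length Fragment size in nt (>= 100).
#' @param min_identity_fraction Identity acceptance threshold in (0, 1].
#' @param min_alignable_fraction Coverage acceptance threshold in (0, 1].
#' @return An object of class `anib_params`.
#' @export
anib_params <- function(fragment_length = 1020L,
                        min_identity_fraction = 0.30,
                        min_alignable_fraction = 0.70) {
  stopifnot(fragment_length >= 100,
            min_identity_fraction > 0, min_identity_fraction <= 1,
            min_alignable_fraction > 0, min_alignable_fraction <= 1)
  structure(list(fragment_length = as.integer(fragment_length),
                 min_identity_fraction = min_identity_fraction,
                 min_alignable_fraction = min_alignable_fraction),
            class = "anib_params")
}

#' Cut a genome into consecutive non-overlapping fragments
#'
#' Windows are per contig, 0-based half-open; a trailing remainder shorter
#' than `fragment_length` is discarded so per-fragment identities stay
#' comparable.
#'
#' @param genome Named character vector of contig sequences.
#' @param fragment_length Window size in nt.
#' @return Data frame with columns contig, start, end, seq.
#' @export
fragment_genome <- function(genome, fragment_length = 1020L) {
  genome <- as_genome(genome)
  out <- lapply(seq_along(genome), function(i) {
    len <- nchar(genome[[i]])
    n <- len %/% fragment_length
    if (n == 0L) return(NULL)
    start <- (seq_len(n) - 1L) * fragment_length
    data.frame(contig = names(genome)[i], start = start,
               end = start + fragment_length,
               seq = substring(genome[[i]], start + 1L,
                               start + fragment_length),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig = character(), start = integer(),
                      end = integer(), seq = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Directional: the query is fragmented and searched against the subject.
#' Fragments whose best HSP (highest bit score, ties broken by lowest
#' subject start) passes the identity and coverage filters contribute their
#' identity percentage (identities / alignment columns) to the mean. When no
#' fragment is accepted the ANIb value is undefined and reported as `NA`,
#' never as 0.
#'
#' @param query,subject Genomes as named character vectors of contigs.
#' @param params An [anib_params()].
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Labels used in the result.
#' @param index Optional prebuilt [index_subject()] of the subject.
#' @return An object of class `anib_result`: list with query_id, subject_id,
#'   n_fragments, n_accepted, anib_percent (NA if undefined) and a
#'   per_fragment data frame (fragment, identity_percent, coverage, accepted).
#' @export
anib <- function(query, subject, params = anib_params(),
                 scheme = scoring_scheme(),
                 query_id = "query", subject_id = "subject",
                 index = NULL) {
  query <- as_genome(query, "query")
  frags <- fragment_genome(query, params$fragment_length)
  if (nrow(frags) == 0L)
    stop("query genome yields no fragments of length ", params$fragment_length)
  if (is.null(index)) {
    subject <- as_genome(subject, "subject")
    index <- index_subject(subject, scheme$kmer_size)
  }

  n <- nrow(frags)
  idpct <- rep(NA_real_, n)
  cov <- rep(0, n)
  for (i in seq_len(n)) {
    h <- find_hsps(c(frag = frags$seq[i]), index, scheme)
    if (nrow(h) == 0L) next
    # best HSP: highest bit score; deterministic tie-break on subject_start
    best <- h[1L, ]
    idpct[i] <- 100 * best$identities / best$alignment_length
    cov[i] <- (best$query_end - best$query_start) / params$fragment_length
  }
  accepted <- !is.na(idpct) &
    idpct / 100 >= params$min_identity_fraction &
    cov >= params$min_alignable_fraction
  anib_percent <- if (any(accepted)) mean(idpct[accepted]) else NA_real_

  structure(list(query_id = query_id, subject_id = subject_id,
                 n_fragments = n, n_accepted = sum(accepted),
                 anib_percent = anib_percent,
                 per_fragment = data.frame(
                   fragment = seq_len(n) - 1L,
                   contig = frags$contig,
                   identity_percent = idpct,
                   coverage = cov,
                   accepted = accepted,
                   stringsAsFactors = FALSE)),
            class = "anib_result")
}

#' @export
print.anib_result <- function(x, ...) {
  val <- if (is.na(x$anib_percent)) "undefined (no accepted fragments)"
         else sprintf("%.2f%%", x$anib_percent)
  cat(sprintf("ANIb %s -> %s: %s (%d/%d fragments accepted)\n",
              x$query_id, x$subject_id, val, x$n_accepted, x$n_fragments))
  invisible(x)
}

#' All-pairs directional ANIb table
#'
#' ANIb is directional (the query is fragmented, the subject searched), so
#' all ordered pairs are computed.
#'
#' @param genomes Named list of genomes (each a named character vector of
#'   contigs or a single sequence).
#' @param params An [anib_params()].
#' @param scheme A [scoring_scheme()].
#' @return Data frame with one row per ordered pair: query, subject,
#'   anib_percent, n_fragments, n_accepted. Self pairs are included
#'   (diagonal = 100).
#' @export
anib_matrix <- function(genomes, params = anib_params(),
                        scheme = scoring_scheme()) {
  stopifnot(is.list(genomes), length(genomes) >= 2L,
            !is.null(names(genomes)))
  ids <- names(genomes)
  indexes <- lapply(genomes, function(g)
    index_subject(as_genome(g), scheme$kmer_size))
  rows <- list()
  for (q in ids) for (s in ids) {
    r <- anib(genomes[[q]], genomes[[s]], params, scheme,
              query_id = q, subject_id = s, index = indexes[[s]])
    rows[[length(rows) + 1L]] <- data.frame(
      query = q, subject = s, anib_percent = r$anib_percent,
      n_fragments = r$n_fragments, n_accepted = r$n_accepted,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
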