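#' Read a nucleotide FASTA file
#'
#' Record IDs are taken from the first whitespace-delimited token of each
#' header; sequences are upper-cased and validated against the alphabet
#' `{A, C, G, T, N}`. A genome is represented as a named character vector of
#' contig sequences.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector (contig/record id -> sequence).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(c(chr1 = "ACGTACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (no leading '>'): ", path)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # records may be empty-bodied only by error
  if (length(seqs) != length(ids) || any(!nzchar(seqs)))
    stop("FASTA record with empty sequence in: ", path)
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(sprintf("illegal character '%s' at position %d of record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 80 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
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

#' Reverse complement
#'
#' @param x Character vector of nucleotide sequences.
#' @return Reverse-complemented sequences; ambiguous bases become `N`.
#' @export
reverse_complement <- function(x) {
  vapply(x, cpp_revcomp, character(1), USE.NAMES = FALSE)
}
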