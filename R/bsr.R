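#' Reference (self) bit scores of genes against their source genome
#'
#' Each gene's best HSP against the genome it was annotated on must be a
#' (near-)full-length self match; a gene without one signals an
#' annotation/sequence mismatch and is an error.
#'
#' @param genes Named character vector of gene nucleotide sequences.
#' @param source_genome The genes' source genome.
#' @param scheme A [scoring_scheme()].
#' @param min_self_coverage Minimum fraction of the gene the self-HSP must
#'   span (default 0.9).
#' @return Named numeric vector gene_id -> reference bit score.
#' @export
reference_scores <- function(genes, source_genome,
                             scheme = scoring_scheme(),
                             min_self_coverage = 0.9) {
  stopifnot(is.character(genes), !is.null(names(genes)))
  idx <- index_subject(as_genome(source_genome, "source"), scheme$kmer_size)
  out <- vapply(names(genes), function(id) {
    h <- find_hsps(stats::setNames(genes[[id]], id), idx, scheme)
    if (nrow(h) == 0L)
      stop("gene '", id, "' has no match in its source genome")
    best <- h[1L, ]
    if ((best$query_end - best$query_start) <
        min_self_coverage * nchar(genes[[id]]))
      stop("gene '", id, "' lacks a near-full-length self match ",
           "(annotation/sequence mismatch?)")
    best$bit_score
  }, numeric(1))
  out
}

#' BLAST score ratio of one gene against one target genome
#'
#' `ratio = best query bit score / reference bit score`, clipped to \[0, 1\]
#' (a target match can outscore an imperfect self score); 0 when the gene has
#' no HSP against the target. Ratios strictly above 0.4 are called homologs.
#'
#' @param gene Single gene sequence (character scalar) or named length-1
#'   vector.
#' @param target Target genome, or a prebuilt [index_subject()].
#' @param reference_bits The gene's self bit score (> 0).
#' @param scheme A [scoring_scheme()].
#' @param gene_id,genome_id Labels used in the result.
#' @param min_bits HSPs below this bit score are treated as "no match"
#'   (default 50), suppressing chance k-mer seed hits on unrelated genomes.
#' @return A list of class `bsr_value`: gene_id, genome_id, query_bits,
#'   reference_bits, ratio, homolog.
#' @export
bsr <- function(gene, target, reference_bits, scheme = scoring_scheme(),
                gene_id = "gene", genome_id = "genome", min_bits = 50) {
  stopifnot(reference_bits > 0)
  h <- find_hsps(stats::setNames(as.character(gene)[1L], gene_id),
                 target, scheme)
  qb <- if (nrow(h) == 0L || h$bit_score[1L] < min_bits) 0
        else h$bit_score[1L]
  ratio <- min(1, max(0, qb / reference_bits))
  structure(list(gene_id = gene_id, genome_id = genome_id,
                 query_bits = qb, reference_bits = reference_bits,
                 ratio = ratio, homolog = ratio > BSR_HOMOLOG_THRESHOLD),
            class = "bsr_value")
}

# presence call: ratios strictly over 0.4 indicate a gene homolog
BSR_HOMOLOG_THRESHOLD <- 0.4

#' BSR matrix of genes x genomes
#'
#' Rows follow the input gene order and columns the input genome order; the
#' source genome's column is all 1 by construction.
#'
#' @param genes Named character vector of gene sequences.
#' @param genomes Named list of target genomes.
#' @param source_genome Genome the genes were annotated on (for reference
#'   self-scores).
#' @param scheme A [scoring_scheme()].
#' @return Numeric matrix of ratios in \[0, 1\] with dimnames
#'   (gene_id, genome_id).
#' @export
homology_matrix <- function(genes, genomes, source_genome,
                            scheme = scoring_scheme()) {
  stopifnot(length(genes) >= 1L, length(genomes) >= 1L,
            !is.null(names(genomes)))
  ref <- reference_scores(genes, source_genome, scheme)
  m <- matrix(0, nrow = length(genes), ncol = length(genomes),
              dimnames = list(names(genes), names(genomes)))
  for (g in names(genomes)) {
    idx <- index_subject(as_genome(genomes[[g]], g), scheme$kmer_size)
    for (id in names(genes)) {
      m[id, g] <- bsr(genes[[id]], idx, ref[[id]], scheme,
                      gene_id = id, genome_id = g)$ratio
    }
  }
  m
}

#' Per-category percent of homologous genes
#'
#' For each genome and category, the integer-rounded (half-up) percentage of
#' genes whose BSR exceeds 0.4.
#'
#' @param matrix BSR matrix from [homology_matrix()].
#' @param categories Data frame with columns gene_id and category covering
#'   every matrix row.
#' @return Data frame: genome_id, category, n_genes, n_homologs, percent.
#' @export
percent_homologous <- function(matrix, categories) {
  stopifnot(is.matrix(matrix),
            all(c("gene_id", "category") %in% names(categories)))
  if (!all(rownames(matrix) %in% categories$gene_id))
    stop("uncategorized genes: ",
         paste(setdiff(rownames(matrix), categories$gene_id), collapse = ", "))
  cat_of <- stats::setNames(categories$category, categories$gene_id)
  cats <- unique(cat_of[rownames(matrix)])
  if (length(cats) == 0L) stop("empty category set")
  rows <- list()
  for (g in colnames(matrix)) {
    for (cc in cats) {
      sel <- rownames(matrix)[cat_of[rownames(matrix)] == cc]
      n <- length(sel)
      nh <- sum(matrix[sel, g] > BSR_HOMOLOG_THRESHOLD)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = g, category = cc, n_genes = n, n_homologs = nh,
        percent = as.integer(round_half_up(100 * nh / n)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
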