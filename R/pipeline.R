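#' Pipeline configuration
#'
#' Two run modes: `"full"` aligns genomes from FASTA (ANIb, dDDH, BSR, then
#' regression/correlation), `"stats-only"` ingests a precomputed relatedness
#' table (such as the packaged strain comparison table) and runs only the
#' regression/correlation stage.
#'
#' @param mode `"full"` or `"stats-only"`.
#' @param reference_fasta Path to the reference genome FASTA (full mode).
#' @param genome_fastas Named character vector of paths to comparison genome
#'   FASTAs (full mode).
#' @param genes_fasta Path to the categorized gene FASTA (full mode,
#'   optional).
#' @param categories_tsv Path to a TSV with columns gene_id, category.
#' @param taxonomy_tsv Path to a TSV with columns strain, species, genus,
#'   family, order, subphylum covering the reference and every genome.
#' @param relatedness_tsv Path to a precomputed relatedness table
#'   (stats-only mode; defaults to the packaged table).
#' @param mortality_tsv Optional dose-mortality TSV to analyze.
#' @param out_dir Output directory (created if missing).
#' @param anib An [anib_params()].
#' @param ddh A [ddh_params()].
#' @param scheme A [scoring_scheme()].
#' @param seed Global seed echoed into the report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("full", "stats-only"),
                            reference_fasta = NULL, genome_fastas = NULL,
                            genes_fasta = NULL, categories_tsv = NULL,
                            taxonomy_tsv = NULL, relatedness_tsv = NULL,
                            mortality_tsv = NULL,
                            out_dir = tempfile("genrelate_run_"),
                            anib = anib_params(), ddh = ddh_params(),
                            scheme = scoring_scheme(), seed = 1L) {
  mode <- match.arg(mode)
  paths <- c(reference_fasta, genome_fastas, genes_fasta, categories_tsv,
             taxonomy_tsv, relatedness_tsv, mortality_tsv)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (mode == "full") {
    if (is.null(reference_fasta) || is.null(genome_fastas) ||
        is.null(taxonomy_tsv))
      stop("full mode needs reference_fasta, genome_fastas and taxonomy_tsv")
    if (is.null(names(genome_fastas)) || any(!nzchar(names(genome_fastas))))
      stop("genome_fastas must be a named vector (genome id -> path)")
  }
  structure(list(mode = mode, reference_fasta = reference_fasta,
                 genome_fastas = genome_fastas, genes_fasta = genes_fasta,
                 categories_tsv = categories_tsv,
                 taxonomy_tsv = taxonomy_tsv,
                 relatedness_tsv = relatedness_tsv,
                 mortality_tsv = mortality_tsv,
                 out_dir = out_dir, anib = anib, ddh = ddh,
                 scheme = scheme, seed = as.integer(seed)),
            class = "pipeline_config")
}

# TSV with '#'-prefixed metadata lines; coordinates in outputs are 0-based
# half-open.
write_tsv_meta <- function(d, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in c(meta, "coordinates: 0-based half-open"))
    writeLines(paste0("# ", m), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_taxonomy_tsv <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("strain", "species", "genus", "family", "order", "subphylum")
  stopifnot(all(need %in% names(d)))
  recs <- lapply(seq_len(nrow(d)), function(i)
    taxonomy_record(d$strain[i], d$species[i], d$genus[i], d$family[i],
                    d$order[i], d$subphylum[i]))
  stats::setNames(recs, d$strain)
}

#' Run the relatedness pipeline
#'
#' Full mode: per comparison genome, directional ANIb (genome as query,
#' reference as subject, matching the published design), dDDH, BSR homology
#' percentages per category, and the taxonomic degree; then regression of
#' ANIb/dDDH on degree and the 6 x 6 correlation matrix. Stats-only mode
#' starts from a precomputed relatedness table. Per-stage failures are
#' recorded and dependent stages skipped.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list: per-stage output paths, software version,
#'   config echo, the relatedness table, regression/correlation results, and
#'   input checksums.
#' @export
run_relatedness <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  errors <- character()
  table <- NULL

  if (config$mode == "stats-only") {
    table <- load_epf_table(config$relatedness_tsv) # NULL -> packaged table
  } else {
    tax <- read_taxonomy_tsv(config$taxonomy_tsv)
    ref_genome <- read_fasta(config$reference_fasta)
    ref_id <- setdiff(names(tax), names(config$genome_fastas))[1L]
    genes <- categories <- NULL
    if (!is.null(config$genes_fasta)) {
      genes <- read_fasta(config$genes_fasta)
      categories <- read.delim(config$categories_tsv, comment.char = "#",
                               stringsAsFactors = FALSE)
    }
    ref_bits <- if (!is.null(genes))
      tryCatch(reference_scores(genes, ref_genome, config$scheme),
               error = function(e) {
                 errors <<- c(errors, conditionMessage(e)); NULL
               })
    ref_index <- index_subject(ref_genome, config$scheme$kmer_size)

    rows <- list()
    for (g in names(config$genome_fastas)) {
      row <- list(strain = g, anib_percent = NA_real_, ddh_percent = NA_real_,
                  exoenzyme_pct = NA_real_, toxin_pct = NA_real_,
                  nrps_pct = NA_real_, pks_pct = NA_real_,
                  degree = NA_integer_)
      gen <- tryCatch(read_fasta(config$genome_fastas[[g]]),
                      error = function(e) {
                        errors <<- c(errors, paste0(g, ": ",
                                                    conditionMessage(e)))
                        NULL
                      })
      if (!is.null(gen)) {
        an <- anib(gen, ref_genome, config$anib, config$scheme,
                   query_id = g, subject_id = ref_id, index = ref_index)
        row$anib_percent <- an$anib_percent
        dd <- ddh(gen, ref_genome, config$scheme, config$ddh,
                  a_id = g, b_id = ref_id)
        row$ddh_percent <- dd$ddh_percent
        if (!is.null(genes) && !is.null(ref_bits)) {
          m <- matrix(0, length(genes), 1,
                      dimnames = list(names(genes), g))
          idx <- index_subject(gen, config$scheme$kmer_size)
          for (id in names(genes))
            m[id, g] <- bsr(genes[[id]], idx, ref_bits[[id]], config$scheme,
                            gene_id = id, genome_id = g)$ratio
          ph <- percent_homologous(m, categories)
          for (cc in ph$category) {
            col <- c(exoenzyme = "exoenzyme_pct", toxin = "toxin_pct",
                     NRPS = "nrps_pct", PKS = "pks_pct")[[cc]]
            row[[col]] <- ph$percent[ph$category == cc]
          }
        }
        if (g %in% names(tax) && ref_id %in% names(tax))
          row$degree <- encode_degree(tax[[ref_id]], tax[[g]])
      }
      rows[[g]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
    table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }

  tbl_path <- file.path(config$out_dir, "relatedness_table.tsv")
  write_tsv_meta(table, tbl_path,
                 c(paste0("genrelate relatedness table, mode=", config$mode),
                   paste0("seed=", config$seed)))
  outputs <- c(outputs, relatedness_table = tbl_path)

  report <- list(software_version =
                   as.character(packageVersion("genrelate")),
                 config = config, table = table, errors = errors)

  cols_ok <- all(RELATEDNESS_VARS %in% names(table)) &&
    !anyNA(table[RELATEDNESS_VARS]) && !anyNA(table$degree)
  if (cols_ok && nrow(table) >= 3) {
    rep2 <- relatedness_report(table)
    report$anib_fit <- rep2$anib_fit
    report$ddh_fit <- rep2$ddh_fit
    report$correlations <- rep2$correlations
    report$coefficients <- rep2$summary
    cor_path <- file.path(config$out_dir, "correlation_matrix.tsv")
    write_tsv_meta(data.frame(variable = rownames(rep2$correlations),
                              rep2$correlations, check.names = FALSE),
                   cor_path, "Pearson correlation matrix")
    coef_path <- file.path(config$out_dir, "headline_coefficients.tsv")
    write_tsv_meta(rep2$summary, coef_path, "headline Pearson coefficients")
    outputs <- c(outputs, correlation_matrix = cor_path,
                 headline_coefficients = coef_path)
  } else {
    report$errors <- c(report$errors,
                       "regression/correlation skipped: incomplete table")
  }

  if (!is.null(config$mortality_tsv)) {
    mt <- read.delim(config$mortality_tsv, comment.char = "#",
                     stringsAsFactors = FALSE)
    ba <- bioassay_analysis(mt)
    report$bioassay <- ba
    ba_path <- file.path(config$out_dir, "bioassay_summary.tsv")
    write_tsv_meta(cbind(ba$summaries,
                         letters = unname(ba$lsd$letter_groups)),
                   ba_path,
                   sprintf("one-way ANOVA F=%.4f p=%.4g, Fisher LSD",
                           ba$lsd$f_statistic, ba$lsd$p_value))
    outputs <- c(outputs, bioassay_summary = ba_path)
  }

  inputs <- unlist(config[c("reference_fasta", "genome_fastas", "genes_fasta",
                            "categories_tsv", "taxonomy_tsv",
                            "relatedness_tsv", "mortality_tsv")])
  report$checksums <- if (length(inputs)) tools::md5sum(inputs) else character()
  report$outputs <- outputs
  class(report) <- "run_report"

  json_path <- file.path(config$out_dir, "run_report.json")
  echo <- config
  echo$anib <- unclass(echo$anib); echo$ddh <- unclass(echo$ddh)
  echo$scheme <- unclass(echo$scheme)
  jsonlite::write_json(
    list(software_version = report$software_version,
         mode = config$mode, seed = config$seed,
         config = unclass(echo)[!vapply(echo, is.null, logical(1))],
         outputs = as.list(outputs),
         checksums = as.list(report$checksums),
         errors = report$errors),
    json_path, auto_unbox = TRUE, digits = NA, null = "null")
  report$report_path <- json_path
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("genrelate run (mode =", x$config$mode, ")\n")
  cat("  outputs:\n")
  for (o in x$outputs) cat("   ", o, "\n")
  if (!is.null(x$coefficients)) {
    cat("  headline coefficients:\n")
    print(x$coefficients)
  }
  if (length(x$errors)) cat("  errors:", paste(x$errors, collapse = "; "),
                            "\n")
  invisible(x)
}
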