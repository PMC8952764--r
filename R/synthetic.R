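#' Parameters for simulated genome evolution
#'
#' @param substitution_rate Fraction of sites substituted (0 <= rate < 1).
#' @param indel_rate Expected indel events per kb (>= 0).
#' @param indel_length_mean Mean of the geometric indel-length distribution
#'   (nt); lengths are capped at 50 nt.
#' @param rearrangement_count Number of segment rearrangement events.
#' @param rearrangement_type `"translocation"` (default; conserves the residue
#'   multiset) or `"inversion"` (reverse complement; conserves duplex content).
#' @param seed Integer random seed.
#' @return An object of class `evolution_params`.
#' @export
evolution_params <- function(substitution_rate = 0, indel_rate = 0,
                             indel_length_mean = 3, rearrangement_count = 0,
                             rearrangement_type = c("translocation",
                                                    "inversion"),
                             seed = 1L) {
  rearrangement_type <- match.arg(rearrangement_type)
  stopifnot(substitution_rate >= 0, substitution_rate < 1,
            indel_rate >= 0, indel_length_mean >= 1,
            rearrangement_count >= 0)
  structure(list(substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 indel_length_mean = indel_length_mean,
                 rearrangement_count = as.integer(rearrangement_count),
                 rearrangement_type = rearrangement_type,
                 seed = as.integer(seed)),
            class = "evolution_params")
}

BASES <- c("A", "C", "G", "T")

#' Generate a random ancestral genome sequence
#'
#' Draws i.i.d. bases with P(G) = P(C) = gc_content/2 and
#' P(A) = P(T) = (1 - gc_content)/2.
#'
#' @param length Sequence length in nt (>= 1).
#' @param gc_content Target GC fraction, strictly inside (0, 1).
#' @param seed Integer random seed.
#' @return A single character string of length `length` over `{A,C,G,T}`.
#' @export
generate_ancestor <- function(length, gc_content = 0.5, seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  with_stream_seed(seed, "ancestor", {
    p <- c((1 - gc_content) / 2, gc_content / 2,
           gc_content / 2, (1 - gc_content) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Evolve a genome copy under substitutions, indels and rearrangements
#'
#' Events are applied in a fixed order: substitutions first (uniform over the
#' three alternative bases, so the original base is never rewritten), then
#' indels (Poisson number of events at `indel_rate` per kb, geometric lengths
#' capped at 50 nt, insertions and deletions equally likely), then
#' rearrangements. The realized divergence is the fraction of sites actually
#' substituted, measured before any indel or rearrangement.
#'
#' @param ancestor A single nucleotide sequence (character scalar).
#' @param params An [evolution_params()] object.
#' @return A list with `sequence` (the evolved copy) and `realized_divergence`.
#' @export
evolve_genome <- function(ancestor, params) {
  stopifnot(inherits(params, "evolution_params"),
            is.character(ancestor), length(ancestor) == 1L)
  n <- nchar(ancestor)
  if (n == 0L) stop("ancestor is empty")
  v <- strsplit(ancestor, "", fixed = TRUE)[[1L]]

  # substitutions
  nsub <- 0L
  if (params$substitution_rate > 0) {
    sub_res <- with_stream_seed(params$seed, "substitutions", {
      hit <- which(runif(n) < params$substitution_rate)
      if (length(hit)) {
        code <- match(v[hit], BASES)
        shift <- sample.int(3L, length(hit), replace = TRUE)
        v[hit] <- BASES[((code - 1L + shift) %% 4L) + 1L]
      }
      list(v = v, nsub = length(hit))
    })
    v <- sub_res$v
    nsub <- sub_res$nsub
  }
  realized <- nsub / n

  # indels
  n_events <- 0L
  if (params$indel_rate > 0) {
    v <- with_stream_seed(params$seed, "indels", {
      n_events <- rpois(1L, params$indel_rate * length(v) / 1000)
      if (n_events > length(v))
        stop("indel_rate implies more events than sites")
      for (i in seq_len(n_events)) {
        len <- min(1L + rgeom(1L, 1 / params$indel_length_mean), 50L)
        pos <- sample.int(length(v), 1L)
        if (runif(1) < 0.5) { # deletion
          drop <- pos:min(pos + len - 1L, length(v))
          if (length(drop) < length(v)) v <- v[-drop]
        } else {             # insertion
          ins <- sample(BASES, len, replace = TRUE)
          v <- append(v, ins, after = pos)
        }
      }
      v
    })
  }

  # rearrangements
  if (params$rearrangement_count > 0) {
    v <- with_stream_seed(params$seed, "rearrangements", {
      for (i in seq_len(params$rearrangement_count)) {
        m <- length(v)
        a <- sort(sample.int(m, 2L))
        seg <- v[a[1L]:a[2L]]
        if (params$rearrangement_type == "inversion") {
          comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
          v[a[1L]:a[2L]] <- unname(comp[rev(seg)])
        } else { # translocation: excise and reinsert elsewhere
          rest <- v[-(a[1L]:a[2L])]
          at <- sample.int(length(rest) + 1L, 1L) - 1L
          v <- append(rest, seg, after = at)
        }
      }
      v
    })
  }

  list(sequence = paste(v, collapse = ""), realized_divergence = realized)
}

#' Specification of a simulated categorized gene-family set
#'
#' Retention probabilities emulate the decay of detectable homologs with
#' decreasing taxonomic relatedness (degree 1 = same species ... degree 5 =
#' shared subphylum only).
#'
#' @param n_genes_per_category Named integer vector; names from
#'   `{exoenzyme, toxin, NRPS, PKS}`.
#' @param retention_prob_by_degree Numeric vector indexed by degree 1..5,
#'   non-increasing, each in \[0, 1\].
#' @param divergence_by_degree Substitution rate applied to retained homologs,
#'   indexed by degree 1..5.
#' @param gene_length Gene length in nt (default 1000).
#' @param seed Integer random seed.
#' @return An object of class `gene_family_sim_spec`.
#' @export
gene_family_sim_spec <- function(n_genes_per_category = c(exoenzyme = 20L,
                                                          toxin = 10L,
                                                          NRPS = 10L,
                                                          PKS = 10L),
                                 retention_prob_by_degree =
                                   c(0.98, 0.85, 0.55, 0.15, 0.05),
                                 divergence_by_degree =
                                   c(0.02, 0.06, 0.12, 0.18, 0.25),
                                 gene_length = 1000L, seed = 1L) {
  if (length(n_genes_per_category) == 0L) stop("empty category list")
  stopifnot(!is.null(names(n_genes_per_category)),
            all(names(n_genes_per_category) %in% GENE_CATEGORIES),
            all(n_genes_per_category >= 0),
            length(retention_prob_by_degree) == 5L,
            all(retention_prob_by_degree >= 0),
            all(retention_prob_by_degree <= 1),
            all(diff(retention_prob_by_degree) <= 0),
            length(divergence_by_degree) == 5L,
            all(divergence_by_degree >= 0), all(divergence_by_degree < 1),
            gene_length >= 50)
  structure(list(n_genes_per_category = n_genes_per_category,
                 retention_prob_by_degree = retention_prob_by_degree,
                 divergence_by_degree = divergence_by_degree,
                 gene_length = as.integer(gene_length),
                 seed = as.integer(seed)),
            class = "gene_family_sim_spec")
}

GENE_CATEGORIES <- c("exoenzyme", "toxin", "NRPS", "PKS")

#' Simulate categorized gene families across genomes of varying relatedness
#'
#' Genes are carved verbatim from non-overlapping windows of the reference
#' genome (so each gene's self-match is exact). For each target genome a gene
#' is retained with the degree's retention probability; retained homologs are
#' implanted at a random position after substitution at the degree's
#' divergence. The truth table records ground-truth presence for validating
#' BSR presence/absence calls.
#'
#' @param spec A [gene_family_sim_spec()].
#' @param reference_genome Single sequence the genes are carved from.
#' @param genomes_by_degree Named list of single sequences; names are genome
#'   IDs. `degree_by_genome` maps each to a degree.
#' @param degree_by_genome Named integer vector (genome id -> degree 1..5).
#' @return List with `genes` (named character), `categories` (data.frame
#'   gene_id/category), `genomes` (modified named list), `truth`
#'   (data.frame gene_id/genome_id/present).
#' @export
simulate_gene_families <- function(spec, reference_genome, genomes_by_degree,
                                   degree_by_genome) {
  stopifnot(inherits(spec, "gene_family_sim_spec"),
            length(genomes_by_degree) >= 1L,
            !is.null(names(genomes_by_degree)),
            all(names(genomes_by_degree) %in% names(degree_by_genome)),
            all(degree_by_genome %in% 1:5))
  n_total <- sum(spec$n_genes_per_category)
  glen <- spec$gene_length
  if (nchar(reference_genome) < n_total * glen)
    stop("reference genome too short to carve ", n_total, " genes of ",
         glen, " nt")

  categories <- rep(names(spec$n_genes_per_category),
                    times = spec$n_genes_per_category)
  gene_ids <- sprintf("%s_%03d", categories,
                      unlist(lapply(spec$n_genes_per_category, seq_len)))

  genes <- with_stream_seed(spec$seed, "gene_carving", {
    # non-overlapping windows in shuffled order
    starts <- sample(seq(1L, n_total) ) # permute window order
    vapply(starts, function(w) {
      substr(reference_genome, (w - 1L) * glen + 1L, w * glen)
    }, character(1))
  })
  names(genes) <- gene_ids

  truth <- list()
  genomes <- genomes_by_degree
  for (g in names(genomes)) {
    deg <- degree_by_genome[[g]]
    if (nchar(genomes[[g]]) < n_total * glen)
      stop("genome '", g, "' too short to host ", n_total, " homolog slots")
    keep <- with_stream_seed(spec$seed, paste0("retention_", g),
                             runif(n_total) < spec$retention_prob_by_degree[deg])
    seqs <- genomes[[g]]
    # one non-overlapping slot per gene so homologs never overwrite each other
    slot <- nchar(seqs) %/% n_total
    for (i in which(keep)) {
      hom <- evolve_genome(genes[[i]], evolution_params(
        substitution_rate = spec$divergence_by_degree[deg],
        seed = derive_seed(spec$seed, paste0("homolog_", g, "_", i))))$sequence
      slack <- max(1L, slot - nchar(hom))
      off <- with_stream_seed(spec$seed, paste0("implant_", g, "_", i),
                              sample.int(slack, 1L)) - 1L
      pos <- (i - 1L) * slot + off + 1L
      end <- min(pos + nchar(hom) - 1L, nchar(seqs))
      substr(seqs, pos, end) <- substr(hom, 1L, end - pos + 1L)
    }
    genomes[[g]] <- seqs
    truth[[g]] <- data.frame(gene_id = gene_ids, genome_id = g,
                             present = keep, stringsAsFactors = FALSE)
  }

  list(genes = genes,
       categories = data.frame(gene_id = gene_ids, category = categories,
                               stringsAsFactors = FALSE),
       genomes = genomes,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Specification of a simulated injection-bioassay mortality experiment
#'
#' Defaults mirror a design with six dose groups (a buffer control plus five
#' extract doses in ug per larva), ten larvae per replicate, triplicates, and
#' four independent experiments.
#'
#' @param doses Numeric vector of doses (ug/larva).
#' @param true_mortality_by_dose Per-dose true mortality probabilities.
#' @param n_larvae_per_replicate Larvae injected per replicate (>= 1).
#' @param n_replicates Replicates per experiment (>= 1).
#' @param n_experiments Independent experiments (>= 1).
#' @param timepoint Observation timepoint in days.
#' @param seed Integer random seed.
#' @return An object of class `mortality_sim_spec`.
#' @export
mortality_sim_spec <- function(doses = c(0, 0.70, 1.75, 3.50, 5.25, 7.00),
                               true_mortality_by_dose =
                                 c(0.01, 0.43, 0.38, 0.50, 0.64, 0.64),
                               n_larvae_per_replicate = 10L,
                               n_replicates = 3L, n_experiments = 4L,
                               timepoint = 21, seed = 1L) {
  stopifnot(length(doses) == length(true_mortality_by_dose),
            all(true_mortality_by_dose >= 0),
            all(true_mortality_by_dose <= 1),
            n_larvae_per_replicate >= 1, n_replicates >= 1,
            n_experiments >= 1)
  structure(list(doses = doses,
                 true_mortality_by_dose = true_mortality_by_dose,
                 n_larvae_per_replicate = as.integer(n_larvae_per_replicate),
                 n_replicates = as.integer(n_replicates),
                 n_experiments = as.integer(n_experiments),
                 timepoint = timepoint,
                 seed = as.integer(seed)),
            class = "mortality_sim_spec")
}

#' Simulate a dose-mortality count table
#'
#' Dead counts per dose x experiment x replicate are independent binomial
#' draws with the dose's true mortality probability.
#'
#' @param spec A [mortality_sim_spec()].
#' @return Data frame with columns dose, experiment, replicate, n_larvae,
#'   dead, timepoint.
#' @export
simulate_mortality <- function(spec) {
  stopifnot(inherits(spec, "mortality_sim_spec"))
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      experiment = seq_len(spec$n_experiments),
                      dose_i = seq_along(spec$doses))
  with_stream_seed(spec$seed, "mortality", {
    data.frame(
      dose = spec$doses[grid$dose_i],
      experiment = grid$experiment,
      replicate = grid$replicate,
      n_larvae = spec$n_larvae_per_replicate,
      dead = rbinom(nrow(grid), spec$n_larvae_per_replicate,
                    spec$true_mortality_by_dose[grid$dose_i]),
      timepoint = spec$timepoint)
  })
}
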