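make_bsr_fixture <- function(seed = 81) {
  ref <- random_genome(30000, seed)
  spec <- gene_family_sim_spec(
    n_genes_per_category = c(exoenzyme = 8L, toxin = 4L, NRPS = 4L,
                             PKS = 4L),
    retention_prob_by_degree = c(1, 0.8, 0.6, 0.2, 0),
    divergence_by_degree = c(0.02, 0.06, 0.12, 0.15, 0.15),
    gene_length = 800L, seed = seed + 1)
  genomes <- list(near = random_genome(30000, seed + 2),
                  mid = random_genome(30000, seed + 3),
                  none = random_genome(30000, seed + 4))
  sim <- simulate_gene_families(spec, ref, genomes,
                                c(near = 1L, mid = 3L, none = 5L))
  list(ref = ref, sim = sim)
}

test_that("reference self-scores are exact full-length matches", {
  fx <- make_bsr_fixture()
  ref_bits <- reference_scores(fx$sim$genes, fx$ref)
  # verbatim gene: self raw score is 2 nt per base, bits via the closed form
  expect_equal(unname(ref_bits),
               rep(bit_score(2 * 800), length(fx$sim$genes)))
  # identical paralogs get equal reference bits
  genes2 <- c(p1 = substr(fx$ref, 1, 600), p2 = substr(fx$ref, 1, 600))
  rb2 <- reference_scores(genes2, fx$ref)
  expect_equal(rb2[["p1"]], rb2[["p2"]])
  # a gene absent from the source genome is an error
  expect_error(reference_scores(c(bad = random_genome(600, 99)), fx$ref),
               "no match|near-full-length")
})

test_that("BSR is 1 on the source genome and 0 with no match", {
  fx <- make_bsr_fixture(101)
  ref_bits <- reference_scores(fx$sim$genes, fx$ref)
  id <- names(fx$sim$genes)[1]
  self <- bsr(fx$sim$genes[[id]], c(ref = fx$ref), ref_bits[[id]],
              gene_id = id, genome_id = "ref")
  expect_equal(self$ratio, 1)
  expect_true(self$homolog)
  none <- bsr(fx$sim$genes[[id]], c(x = random_genome(20000, 102)),
              ref_bits[[id]], gene_id = id, genome_id = "x")
  expect_equal(none$ratio, 0)
  expect_false(none$homolog)
})

test_that("a 10%-diverged homolog scores between 0.4 and 1", {
  gene <- random_genome(1000, 103)
  hom <- evolve_genome(gene, evolution_params(substitution_rate = 0.10,
                                              seed = 104))$sequence
  flank <- random_genome(5000, 105)
  target <- paste0(flank, hom, random_genome(5000, 106))
  source <- paste0(random_genome(2000, 107), gene, random_genome(2000, 108))
  rb <- reference_scores(c(g1 = gene), c(src = source))
  v <- bsr(gene, c(t = target), rb[["g1"]], gene_id = "g1", genome_id = "t")
  expect_gt(v$ratio, 0.4)
  expect_lt(v$ratio, 1)
  expect_true(v$homolog)
  # cross-check the query bits against the Smith-Waterman oracle
  sw_bits <- bit_score(sw_local_score(substr(gene, 1, 400),
                                      substr(target, 5001, 5400)))
  h <- find_hsps(c(g1 = substr(gene, 1, 400)),
                 c(t = substr(target, 5001, 5400)))
  expect_gte(h$bit_score[1], 0.95 * sw_bits)
})

test_that("the BSR matrix matches per-gene recomputation and the truth table", {
  fx <- make_bsr_fixture(111)
  genomes <- c(list(ref = fx$ref), fx$sim$genomes)
  m <- homology_matrix(fx$sim$genes, genomes, fx$ref)
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(m[, "ref"] == 1))
  expect_true(all(m[, "none"] <= 0.4)) # retention 0 at degree 5

  # recomputation oracle on a few entries
  ref_bits <- reference_scores(fx$sim$genes, fx$ref)
  for (id in names(fx$sim$genes)[c(1, 10, 20)]) {
    v <- bsr(fx$sim$genes[[id]], c(mid = fx$sim$genomes$mid),
             ref_bits[[id]], gene_id = id, genome_id = "mid")
    expect_equal(m[id, "mid"], v$ratio)
  }

  # >= 95% agreement with ground truth at divergence <= 15%
  tr <- fx$sim$truth
  calls <- m[, c("near", "mid", "none")] > 0.4
  agree <- mean(calls[cbind(tr$gene_id, tr$genome_id)] == tr$present)
  expect_gte(agree, 0.95)
})

test_that("ratios are invariant under duplication of target contigs", {
  gene <- random_genome(800, 121)
  hom <- evolve_genome(gene, evolution_params(substitution_rate = 0.08,
                                              seed = 122))$sequence
  target1 <- c(c1 = paste0(random_genome(3000, 123), hom))
  target2 <- c(target1, c2 = unname(target1))
  src <- c(s = paste0(gene, random_genome(3000, 124)))
  rb <- reference_scores(c(g = gene), src)
  r1 <- bsr(gene, target1, rb[["g"]])$ratio
  r2 <- bsr(gene, target2, rb[["g"]])$ratio
  expect_equal(r1, r2)
})

test_that("category percentages use the strict 0.4 rule and half-up rounding", {
  m <- matrix(c(1, 0.41, 0.4, 0.39, 0.8,
                0.2, 0.5, 0.45, 0.1, 0),
              nrow = 5, ncol = 2,
              dimnames = list(paste0("g", 1:5), c("A", "B")))
  cats <- data.frame(gene_id = paste0("g", 1:5),
                     category = c("toxin", "toxin", "toxin", "toxin",
                                  "NRPS"))
  ph <- percent_homologous(m, cats)
  # toxins in A: 1 and 0.41 pass, 0.4 (not strictly over) and 0.39 fail
  expect_equal(ph$percent[ph$genome_id == "A" & ph$category == "toxin"], 50)
  expect_equal(ph$n_homologs[ph$genome_id == "A" & ph$category == "toxin"], 2)
  expect_equal(ph$percent[ph$genome_id == "A" & ph$category == "NRPS"], 100)
  expect_equal(ph$percent[ph$genome_id == "B" & ph$category == "toxin"], 50)
  expect_equal(ph$percent[ph$genome_id == "B" & ph$category == "NRPS"], 0)

  # 16 of 20 -> 80% (and permutation invariance in gene order)
  m2 <- matrix(c(rep(0.9, 16), rep(0.1, 4)), ncol = 1,
               dimnames = list(paste0("t", 1:20), "G"))
  cats2 <- data.frame(gene_id = paste0("t", 1:20), category = "toxin")
  expect_equal(percent_homologous(m2, cats2)$percent, 80)
  perm <- sample(20)
  expect_equal(percent_homologous(m2[perm, , drop = FALSE], cats2)$percent,
               80)

  # half-up integer rounding: 1 of 8 = 12.5 -> 13
  m3 <- matrix(c(0.9, rep(0, 7)), ncol = 1,
               dimnames = list(paste0("e", 1:8), "G"))
  cats3 <- data.frame(gene_id = paste0("e", 1:8), category = "exoenzyme")
  expect_equal(percent_homologous(m3, cats3)$percent, 13)
})
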