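test_that("ancestor generation respects length, alphabet, GC and seed", {
  g <- generate_ancestor(10000, 0.517, seed = 1)
  expect_equal(nchar(g), 10000)
  expect_false(grepl("[^ACGT]", g))
  gc <- lengths(regmatches(g, gregexpr("[GC]", g))) / 10000
  band <- 2.576 * sqrt(0.517 * (1 - 0.517) / 10000) # 99% binomial band
  expect_lt(abs(gc - 0.517), band)

  expect_equal(nchar(generate_ancestor(1, 0.5, seed = 0)), 1)
  expect_identical(generate_ancestor(500, 0.4, seed = 7),
                   generate_ancestor(500, 0.4, seed = 7))
  expect_false(identical(generate_ancestor(500, 0.4, seed = 7),
                         generate_ancestor(500, 0.4, seed = 8)))
  expect_error(generate_ancestor(0, 0.5), "length")
  expect_error(generate_ancestor(10, 1), "gc_content")
})

test_that("evolution identity case returns the ancestor unchanged", {
  g <- random_genome(2000, 3)
  out <- evolve_genome(g, evolution_params(seed = 1))
  expect_identical(out$sequence, g)
  expect_equal(out$realized_divergence, 0)
})

test_that("substitutions hit the binomial expectation and never rewrite a base", {
  n <- 20000
  g <- random_genome(n, 4)
  out <- evolve_genome(g, evolution_params(substitution_rate = 0.05,
                                           seed = 11))
  # binomial oracle: count within 3 SD of n * p
  sdev <- sqrt(n * 0.05 * 0.95)
  expect_lt(abs(out$realized_divergence * n - n * 0.05), 3 * sdev)
  # every substituted site differs, so hamming distance = realized count
  a <- strsplit(g, "")[[1]]
  b <- strsplit(out$sequence, "")[[1]]
  expect_equal(sum(a != b), out$realized_divergence * n)
})

test_that("rearrangement-only evolution conserves residue content", {
  g <- random_genome(10000, 5)
  out <- evolve_genome(g, evolution_params(rearrangement_count = 3,
                                           seed = 2))
  expect_equal(out$realized_divergence, 0)
  expect_identical(sort(strsplit(out$sequence, "")[[1]]),
                   sort(strsplit(g, "")[[1]]))
  # inversion conserves duplex content (A+T and C+G counts)
  inv <- evolve_genome(g, evolution_params(rearrangement_count = 2,
                                           rearrangement_type = "inversion",
                                           seed = 2))
  count_at <- function(s) lengths(regmatches(s, gregexpr("[AT]", s)))
  expect_equal(count_at(inv$sequence), count_at(g))
  expect_equal(nchar(inv$sequence), nchar(g))
})

test_that("indels change length but realized divergence tracks substitutions only", {
  g <- random_genome(5000, 6)
  out <- evolve_genome(g, evolution_params(substitution_rate = 0.02,
                                           indel_rate = 2,
                                           indel_length_mean = 3, seed = 9))
  expect_gt(out$realized_divergence, 0)
  expect_false(nchar(out$sequence) == nchar(g) &&
                 identical(out$sequence, g))
})

test_that("gene-family simulation honors retention probabilities", {
  ref <- random_genome(40000, 21)
  spec <- gene_family_sim_spec(
    n_genes_per_category = c(exoenzyme = 20L, toxin = 5L, NRPS = 5L,
                             PKS = 5L),
    retention_prob_by_degree = c(1, 0.8, 0.5, 0.2, 0),
    seed = 13)
  genomes <- list(d1 = random_genome(40000, 22),
                  d2 = random_genome(40000, 23),
                  d5 = random_genome(40000, 24))
  sim <- simulate_gene_families(spec, ref, genomes,
                                c(d1 = 1L, d2 = 2L, d5 = 5L))
  tr <- sim$truth
  expect_true(all(tr$present[tr$genome_id == "d1"]))   # retention 1
  expect_false(any(tr$present[tr$genome_id == "d5"]))  # retention 0
  # binomial oracle at degree 2: 35 genes, p = 0.8
  k <- sum(tr$present[tr$genome_id == "d2"])
  expect_lt(abs(k - 35 * 0.8), 3 * sqrt(35 * 0.8 * 0.2))
  # genes are carved verbatim from the reference
  expect_true(all(vapply(sim$genes, function(s) grepl(s, ref, fixed = TRUE),
                         logical(1))))
  expect_equal(nrow(sim$categories), 35)
})

test_that("mortality simulation matches its binomial model", {
  all0 <- simulate_mortality(mortality_sim_spec(
    true_mortality_by_dose = rep(0, 6), seed = 1))
  expect_true(all(all0$dead == 0))
  all1 <- simulate_mortality(mortality_sim_spec(
    true_mortality_by_dose = rep(1, 6), seed = 1))
  expect_true(all(all1$dead == all1$n_larvae))

  sp <- mortality_sim_spec(doses = 7, true_mortality_by_dose = 0.79,
                           n_larvae_per_replicate = 10L, n_replicates = 3L,
                           n_experiments = 4L, seed = 5)
  mt <- simulate_mortality(sp)
  expect_equal(nrow(mt), 12)
  pooled <- sum(mt$dead) / sum(mt$n_larvae)
  expect_lt(abs(pooled - 0.79), 3 * sqrt(0.79 * 0.21 / 120))
})

test_that("identical spec and seed give byte-identical simulated files", {
  run <- function() {
    g <- generate_ancestor(3000, 0.5, seed = 42)
    ev <- evolve_genome(g, evolution_params(substitution_rate = 0.03,
                                            indel_rate = 1, seed = 42))
    mt <- simulate_mortality(mortality_sim_spec(seed = 42))
    f <- tempfile(fileext = ".fasta")
    write_fasta(c(anc = g, evo = ev$sequence), f)
    list(hash = unname(tools::md5sum(f)), table = mt)
  }
  a <- run(); b <- run()
  expect_identical(a$hash, b$hash)
  expect_identical(a$table, b$table)
})
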