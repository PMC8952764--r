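test_that("k-mer index reports exact forward positions", {
  idx <- index_subject(c(s = "ACGTACGT"), kmer_size = 4)
  expect_equal(sort(kmer_positions(idx, "ACGT")), c(0L, 4L))
  expect_equal(length(kmer_positions(idx, "TTTT")), 0)

  expect_warning(idx2 <- index_subject(c(s = "ACGT"), kmer_size = 10),
                 "exceeds")
  expect_warning(index_subject(c(s = strrep("N", 100)), kmer_size = 8),
                 "ambiguous")

  # brute-force scan oracle on a random subject
  g <- random_genome(2000, 31)
  idx3 <- index_subject(c(s = g), kmer_size = 12)
  for (start in c(1, 500, 1500)) {
    kmer <- substr(g, start, start + 11)
    pos <- kmer_positions(idx3, kmer)
    expect_true((start - 1) %in% pos)
    for (p in pos) expect_identical(substr(g, p + 1, p + 12), kmer)
  }
})

test_that("bit score follows the Karlin-Altschul closed form", {
  sc <- scoring_scheme(lambda = 0.625, K = 0.41)
  expect_equal(bit_score(0, sc), -log(0.41) / log(2), tolerance = 1e-12)
  expect_equal(bit_score(100, sc), (62.5 - log(0.41)) / log(2),
               tolerance = 1e-12)
  expect_gt(bit_score(101, sc), bit_score(100, sc))
  expect_error(bit_score(-1, sc), ">= 0")
})

test_that("an exact query region gives one full-identity plus-strand HSP", {
  g <- random_genome(5000, 32)
  q <- substr(g, 1001, 2020) # 1020 nt region
  h <- find_hsps(c(q = q), c(s = g))
  expect_gte(nrow(h), 1)
  top <- h[1, ]
  expect_equal(top$strand, "+")
  expect_equal(top$identities, 1020)
  expect_equal(top$alignment_length, 1020)
  expect_equal(top$query_start, 0)
  expect_equal(top$query_end, 1020)
  expect_equal(top$subject_start, 1000)
  expect_equal(top$subject_end, 2020)
  expect_equal(top$raw_score, 2 * 1020)
})

test_that("a reverse-complement query maps to the minus strand", {
  g <- random_genome(5000, 33)
  region <- substr(g, 3001, 3800)
  h <- find_hsps(c(q = reverse_complement(region)), c(s = g))
  top <- h[1, ]
  expect_equal(top$strand, "-")
  expect_equal(top$identities, 800)
  expect_equal(top$subject_start, 3000)
  expect_equal(top$subject_end, 3800)
})

test_that("diverged pairs give binomial identity and match the SW oracle", {
  g <- random_genome(400, 34)
  set.seed(91)
  for (i in 1:3) {
    q <- evolve_genome(g, evolution_params(substitution_rate = 0.05,
                                           seed = 100 + i))$sequence
    h <- find_hsps(c(q = q), c(s = g))
    top <- h[1, ]
    idfrac <- top$identities / top$alignment_length
    expect_lt(abs(idfrac - 0.95), 3 * sqrt(0.95 * 0.05 / 400) + 0.01)
    # gap-free pair: x-drop extension must equal full Smith-Waterman
    expect_equal(top$raw_score, sw_local_score(q, g))
  }
})

test_that("top HSP score is within 95% of Smith-Waterman when gaps occur", {
  g <- random_genome(400, 35)
  for (i in 1:3) {
    q <- evolve_genome(g, evolution_params(substitution_rate = 0.04,
                                           indel_rate = 5,
                                           indel_length_mean = 2,
                                           seed = 200 + i))$sequence
    h <- find_hsps(c(q = q), c(s = g))
    sw <- sw_local_score(q, g)
    expect_gte(h$raw_score[1], 0.95 * sw)
  }
})

test_that("identity counts are invariant under query/subject role swap", {
  g <- random_genome(600, 36)
  q <- evolve_genome(g, evolution_params(substitution_rate = 0.06,
                                         seed = 77))$sequence
  h1 <- find_hsps(c(a = q), c(b = g))
  h2 <- find_hsps(c(b = g), c(a = q))
  expect_equal(h1$identities[1], h2$identities[1])
  expect_equal(h1$raw_score[1], h2$raw_score[1])
})

test_that("HSP coordinates round-trip: extracted substrings re-score exactly", {
  g <- random_genome(3000, 37)
  q <- evolve_genome(g, evolution_params(substitution_rate = 0.05,
                                         seed = 55))$sequence
  h <- find_hsps(c(q = q), c(s = g))
  gapfree <- h[(h$query_end - h$query_start) == h$alignment_length &
               (h$subject_end - h$subject_start) == h$alignment_length, ]
  expect_gt(nrow(gapfree), 0)
  for (i in seq_len(min(nrow(gapfree), 5))) {
    r <- gapfree[i, ]
    qs <- substr(q, r$query_start + 1, r$query_end)
    ss <- substr(g, r$subject_start + 1, r$subject_end)
    if (r$strand == "-") ss <- reverse_complement(ss)
    ident <- sum(strsplit(qs, "")[[1]] == strsplit(ss, "")[[1]])
    expect_equal(ident, r$identities)
    raw <- 2 * ident - 3 * (r$alignment_length - ident)
    expect_equal(raw, r$raw_score)
  }
})

test_that("ambiguous bases never count as identities", {
  s <- random_genome(300, 38)
  q <- s
  substr(q, 50, 52) <- "NNN"
  h <- find_hsps(c(q = q), c(s = s))
  expect_equal(h$alignment_length[1], 300)
  expect_equal(h$identities[1], 297) # the three N columns are not identities
})

test_that("tabular alignment ingest converts coordinates and strand", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t95.0\t100\t1\t100\t201\t300\t150.5\t160",
               "q1\ts1\t90.0\t50\t10\t59\t400\t351\t80.2\t85"), f)
  h <- read_hsps_tsv(f)
  expect_equal(nrow(h), 2)
  plus <- h[h$strand == "+", ]
  expect_equal(plus$query_start, 0)
  expect_equal(plus$subject_start, 200)
  expect_equal(plus$subject_end, 300)
  expect_equal(plus$identities, 95L)
  minus <- h[h$strand == "-", ]
  expect_equal(minus$subject_start, 350)
  expect_equal(minus$subject_end, 400)
})
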