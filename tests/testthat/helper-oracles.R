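# Independent oracles used to check the package's own computations.

# Full Smith-Waterman local alignment score (Gotoh affine gaps), brute force.
# A gap of length L costs gap_open + L * gap_extend, matching the package's
# scoring convention. Intended for short fixtures only (O(n*m)).
sw_local_score <- function(q, s, match = 2, mismatch = -3,
                           gap_open = -5, gap_extend = -2) {
  qv <- strsplit(toupper(q), "")[[1]]
  sv <- strsplit(toupper(s), "")[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in subject (consumes query)
  Y <- matrix(NEG, n + 1, m + 1) # gap in query (consumes subject)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (qv[i] == sv[j] && qv[i] %in% c("A", "C", "G", "T"))
        match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + sub
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

# Pearson correlation from the definitional sums, long-hand.
pearson_longhand <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# One-way ANOVA F from the definitional sums of squares.
anova_f_longhand <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Substitute exactly `positions` of `seq` with a different base (deterministic
# cyclic shift), so the true per-column identity is known exactly.
mutate_at <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  v[positions] <- bases[(match(v[positions], bases) %% 4) + 1]
  paste(v, collapse = "")
}

random_genome <- function(n, seed) genrelate::generate_ancestor(n, 0.5, seed)
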