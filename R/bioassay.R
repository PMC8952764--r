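#' Per-dose mortality summaries at a timepoint
#'
#' Replicate-level mortality is `100 * dead / n_larvae`; the mean and sample
#' SD are reported per dose.
#'
#' @param table Mortality data frame with columns dose, experiment, replicate,
#'   n_larvae, dead, timepoint (as from [simulate_mortality()]).
#' @param timepoint Timepoint (days) to summarize; must exist in the table.
#' @return Data frame: dose, n, mean_mortality_pct, sd_mortality_pct.
#' @export
group_summaries <- function(table, timepoint = NULL) {
  stopifnot(all(c("dose", "n_larvae", "dead") %in% names(table)),
            all(table$dead >= 0), all(table$dead <= table$n_larvae))
  if (!is.null(timepoint)) {
    if (!any(table$timepoint == timepoint))
      stop("timepoint ", timepoint, " not present in the table")
    table <- table[table$timepoint == timepoint, , drop = FALSE]
  }
  pct <- 100 * table$dead / table$n_larvae
  agg <- split(pct, table$dose)
  data.frame(dose = as.numeric(names(agg)),
             n = vapply(agg, length, integer(1)),
             mean_mortality_pct = vapply(agg, mean, numeric(1)),
             sd_mortality_pct = vapply(agg, sd, numeric(1)),
             row.names = NULL)
}

#' One-way analysis of variance over replicate groups
#'
#' Standard between/within decomposition via [stats::aov()].
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 replicates).
#' @return List: f_statistic, p_value, df_between, df_within, mse, grand
#'   means per group.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("every group needs at least 2 replicates")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(y = unlist(groups, use.names = FALSE),
                  g = factor(rep(names(groups),
                                 vapply(groups, length, integer(1))),
                             levels = names(groups)))
  fit <- stats::aov(y ~ g, data = d)
  tab <- suppressWarnings(stats::anova(fit))
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  # identical groups: between-group variation is numerically zero
  if (is.nan(f) || tab[["Sum Sq"]][1L] <= 1e-10 * max(1, sum(d$y^2))) {
    f <- 0
    p <- 1
  }
  list(f_statistic = f, p_value = p,
       df_between = tab$Df[1L], df_within = tab$Df[2L],
       mse = tab[["Mean Sq"]][2L],
       means = vapply(groups, mean, numeric(1)))
}

#' Protected Fisher's LSD with compact-letter display
#'
#' Run only after a significant omnibus ANOVA (protected LSD); a pair (i, j)
#' differs when `|mean_i - mean_j| > t(1 - alpha/2, df_within) *
#' sqrt(mse * (1/n_i + 1/n_j))`, which handles unbalanced groups via per-pair
#' standard errors. Letters come from the insert-and-absorb compact-letter
#' algorithm and are deterministic in group order. A non-significant ANOVA
#' gives every group the same letter (documented behavior, not an error).
#'
#' @param groups Named list of numeric replicate vectors.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `anova_lsd_result`: the ANOVA fields plus
#'   `lsd_value` (for the harmonic-mean group size), `significant` (logical
#'   group x group matrix) and `letter_groups` (named character vector).
#' @export
fisher_lsd <- function(groups, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  a <- one_way_anova(groups)
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  tcrit <- qt(1 - alpha / 2, a$df_within)
  nh <- k / sum(1 / n) # harmonic mean group size
  lsd_value <- tcrit * sqrt(a$mse * 2 / nh)

  sig <- matrix(FALSE, k, k, dimnames = list(names(groups), names(groups)))
  if (a$p_value < alpha) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      se <- sqrt(a$mse * (1 / n[i] + 1 / n[j]))
      if (abs(a$means[i] - a$means[j]) > tcrit * se)
        sig[i, j] <- sig[j, i] <- TRUE
    }
  }
  letters <- compact_letter_display(sig)
  structure(c(a, list(alpha = alpha, lsd_value = lsd_value,
                      significant = sig, letter_groups = letters)),
            class = "anova_lsd_result")
}

# Insert-and-absorb compact-letter display. `sig` is a logical symmetric
# matrix of significant pairwise differences. Groups sharing a letter are not
# significantly different.
compact_letter_display <- function(sig) {
  k <- nrow(sig)
  ids <- rownames(sig)
  cols <- list(seq_len(k)) # letter columns as index sets
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i || !sig[i, j]) next
    for (ci in seq_along(cols)) {
      cc <- cols[[ci]]
      if (i %in% cc && j %in% cc) {
        # split the violating column into two
        cols[[ci]] <- setdiff(cc, i)
        cols[[length(cols) + 1L]] <- setdiff(cc, j)
      }
    }
    # absorb columns that are subsets of another
    keep <- rep(TRUE, length(cols))
    for (x in seq_along(cols)) for (y in seq_along(cols)) {
      if (x != y && keep[x] && keep[y] &&
          all(cols[[x]] %in% cols[[y]]) &&
          !(all(cols[[y]] %in% cols[[x]]) && x < y))
        keep[x] <- FALSE
    }
    cols <- cols[keep]
  }
  # deterministic letter order: by smallest member index
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, function(cc) g %in% cc, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(out, ids)
}

#' @export
print.anova_lsd_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g; MSE = %.3f\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value, x$mse))
  cat(sprintf("Fisher LSD (alpha = %g, harmonic-n LSD = %.3f):\n",
              x$alpha, x$lsd_value))
  for (g in names(x$means))
    cat(sprintf("  %-10s mean %7.2f  %s\n", g, x$means[[g]],
                x$letter_groups[[g]]))
  invisible(x)
}

#' Full bioassay analysis of a mortality table
#'
#' Summaries, one-way ANOVA on replicate-level mortality percentages (the
#' arcsine square-root transform is optional; plain percentages are the
#' default), and protected Fisher's LSD with letters.
#'
#' @param table Mortality data frame (dose, experiment, replicate, n_larvae,
#'   dead, timepoint).
#' @param timepoint Timepoint to analyze.
#' @param alpha Significance level.
#' @param transform `"none"` (default) or `"arcsine"`.
#' @return List with `summaries` and `lsd` (an `anova_lsd_result`).
#' @export
bioassay_analysis <- function(table, timepoint = NULL, alpha = 0.05,
                              transform = c("none", "arcsine")) {
  transform <- match.arg(transform)
  summ <- group_summaries(table, timepoint)
  if (!is.null(timepoint))
    table <- table[table$timepoint == timepoint, , drop = FALSE]
  p <- table$dead / table$n_larvae
  y <- if (transform == "arcsine") asin(sqrt(p)) else 100 * p
  groups <- split(y, table$dose)
  names(groups) <- paste0("dose_", names(groups))
  list(summaries = summ, lsd = fisher_lsd(groups, alpha))
}
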