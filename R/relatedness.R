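#' Create a taxonomy record
#'
#' @param strain_id Strain label.
#' @param species,genus,family,order,subphylum Non-empty rank labels.
#' @return A list of class `taxonomy_record`.
#' @export
taxonomy_record <- function(strain_id, species, genus, family, order,
                            subphylum) {
  ranks <- c(species = species, genus = genus, family = family,
             order = order, subphylum = subphylum)
  if (any(!nzchar(ranks)) || anyNA(ranks))
    stop("all five ranks must be non-empty")
  structure(list(strain_id = strain_id, species = species, genus = genus,
                 family = family, order = order, subphylum = subphylum),
            class = "taxonomy_record")
}

#' Encode the degree of taxonomic relatedness between two strains
#'
#' 1 = same species, 2 = same genus, 3 = same family, 4 = same order,
#' 5 = same subphylum only; an error if not even the subphylum is shared.
#' Symmetric in its arguments.
#'
#' @param reference,other [taxonomy_record()] objects.
#' @return Integer degree in 1..5.
#' @export
encode_degree <- function(reference, other) {
  stopifnot(inherits(reference, "taxonomy_record"),
            inherits(other, "taxonomy_record"))
  if (reference$species == other$species) return(1L)
  if (reference$genus == other$genus) return(2L)
  if (reference$family == other$family) return(3L)
  if (reference$order == other$order) return(4L)
  if (reference$subphylum == other$subphylum) return(5L)
  stop("strains '", reference$strain_id, "' and '", other$strain_id,
       "' share no rank down to subphylum")
}

#' Pearson product-moment correlation
#'
#' Thin wrapper over [stats::cor()] with the preconditions made explicit:
#' equal lengths of at least 3 and non-zero variance in both variables.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  cor(x, y)
}

#' Linear regression with confidence and prediction bands
#'
#' Ordinary least squares of `y` on `x`, reporting the Pearson coefficient,
#' R-squared as a percentage, the residual standard deviation, and evaluable
#' 95% confidence (mean response) and prediction (new observation) bands.
#'
#' @param x Numeric predictor (e.g. taxonomic degree), not constant.
#' @param y Numeric response (e.g. ANIb %).
#' @param level Band confidence level (default 0.95).
#' @return An object of class `regression_fit`: slope, intercept, r,
#'   r_squared (percent), residual_sd, and `bands(newx)` returning a data
#'   frame with fit/conf low-high/pred low-high.
#' @export
linear_regression <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("constant x: regression undefined")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  co <- unname(stats::coef(fit))
  r <- pearson(x, y)
  bands <- function(newx) {
    nd <- data.frame(x = newx)
    cb <- predict(fit, nd, interval = "confidence", level = level)
    pb <- predict(fit, nd, interval = "prediction", level = level)
    data.frame(x = newx, fit = cb[, "fit"],
               conf_low = cb[, "lwr"], conf_high = cb[, "upr"],
               pred_low = pb[, "lwr"], pred_high = pb[, "upr"])
  }
  structure(list(slope = co[2L], intercept = co[1L], r = r,
                 r_squared = 100 * r^2,
                 residual_sd = suppressWarnings(summary(fit)$sigma),
                 level = level, bands = bands, model = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.3f + %.3f x;  r = %.3f, R-squared = %.1f%%, ",
              x$intercept, x$slope, x$r, x$r_squared))
  cat(sprintf("residual SD = %.3f\n", x$residual_sd))
  invisible(x)
}

RELATEDNESS_VARS <- c("anib_percent", "ddh_percent", "toxin_pct",
                      "exoenzyme_pct", "nrps_pct", "pks_pct")

#' Pearson correlation matrix over relatedness and homology variables
#'
#' The six variables are ANIb %, dDDH %, and the per-category percentages of
#' homologous toxin, exoenzyme, NRPS and PKS genes. Zero-variance columns are
#' flagged as missing entries (NA) rather than an error.
#'
#' @param table Data frame containing the columns in `RELATEDNESS_VARS`
#'   (anib_percent, ddh_percent, toxin_pct, exoenzyme_pct, nrps_pct, pks_pct).
#' @return Symmetric 6 x 6 matrix with unit diagonal.
#' @export
correlation_matrix <- function(table) {
  stopifnot(all(RELATEDNESS_VARS %in% names(table)), nrow(table) >= 3)
  m <- as.matrix(table[, RELATEDNESS_VARS])
  out <- matrix(NA_real_, 6, 6, dimnames = list(RELATEDNESS_VARS,
                                                RELATEDNESS_VARS))
  diag(out) <- 1
  for (i in 1:5) for (j in (i + 1):6) {
    xi <- m[, i]; xj <- m[, j]
    if (sd(xi) > 0 && sd(xj) > 0) {
      out[i, j] <- out[j, i] <- cor(xi, xj)
    }
  }
  out
}

#' Load the packaged EPF strain comparison table
#'
#' A transcription of the published 27-strain comparison against the
#' reference strain RGM 2184: per strain the taxonomy (species through
#' subphylum), ANIb and dDDH percentages, and the percentage of homologous
#' exoenzyme/toxin/NRPS/PKS genes. The taxonomic degree (1-5) is computed
#' with [encode_degree()] against the reference taxonomy.
#'
#' @param path Optional path to a compatible TSV (defaults to the packaged
#'   fixture).
#' @return Data frame with the table columns plus `degree`.
#' @export
load_epf_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_epf_strains.tsv",
                        package = "genrelate", mustWork = TRUE)
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("strain", "species", "genus", "family", "order", "subphylum",
            "anib_percent", "ddh_percent", "exoenzyme_pct", "toxin_pct",
            "nrps_pct", "pks_pct")
  stopifnot(all(need %in% names(d)))
  ref <- reference_taxonomy()
  d$degree <- vapply(seq_len(nrow(d)), function(i) {
    encode_degree(ref, taxonomy_record(d$strain[i], d$species[i], d$genus[i],
                                       d$family[i], d$order[i],
                                       d$subphylum[i]))
  }, integer(1))
  d
}

#' Taxonomy of the reference strain RGM 2184
#'
#' @return A [taxonomy_record()] for *Beauveria pseudobassiana* RGM 2184.
#' @export
reference_taxonomy <- function() {
  taxonomy_record("RGM 2184", "Beauveria pseudobassiana", "Beauveria",
                  "Cordycipitaceae", "Hypocreales", "Pezizomycotina")
}

#' Regression and correlation report over a relatedness table
#'
#' Fits ANIb-vs-degree and dDDH-vs-degree regressions and the 6 x 6
#' correlation matrix.
#'
#' @param table Data frame as returned by [load_epf_table()] (must contain
#'   the `RELATEDNESS_VARS` columns and `degree`).
#' @return List with `anib_fit`, `ddh_fit`, `correlations`, and `summary`
#'   (the headline coefficients, rounded half-even to 2 decimals).
#' @export
relatedness_report <- function(table) {
  stopifnot("degree" %in% names(table))
  anib_fit <- linear_regression(table$degree, table$anib_percent)
  ddh_fit <- linear_regression(table$degree, table$ddh_percent)
  cm <- correlation_matrix(table)
  summary <- data.frame(
    quantity = c("r_anib_degree", "r_ddh_degree", "r_anib_exoenzyme",
                 "r_anib_nrps", "r_anib_pks", "r_anib_toxin"),
    r = c(anib_fit$r, ddh_fit$r,
          cm["anib_percent", "exoenzyme_pct"],
          cm["anib_percent", "nrps_pct"],
          cm["anib_percent", "pks_pct"],
          cm["anib_percent", "toxin_pct"]),
    stringsAsFactors = FALSE)
  summary$r_2dp <- round2(summary$r)
  list(anib_fit = anib_fit, ddh_fit = ddh_fit, correlations = cm,
       summary = summary)
}
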