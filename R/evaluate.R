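#' Genomic prediction accuracy
#'
#' Pearson correlation between true breeding values and GEBVs in the
#' validation set.
#'
#' @param tbv,gebv aligned numeric vectors.
#' @return correlation in [-1, 1].
#' @export
genomic_accuracy <- function(tbv, gebv) {
  stopifnot(length(tbv) == length(gebv))
  if (sd(tbv) == 0 || sd(gebv) == 0)
    stop("zero variance: accuracy is undefined")
  cor(tbv, gebv)
}

#' Phenotype prediction accuracy
#'
#' Pearson correlation between GEBVs and phenotypes adjusted for the
#' systematic effects (here only the overall mean).
#'
#' @param gebv,phenotype aligned numeric vectors.
#' @param mu_hat estimated overall mean removed from the phenotypes.
#' @return correlation in [-1, 1].
#' @export
phenotype_accuracy <- function(gebv, phenotype, mu_hat = 0) {
  stopifnot(length(gebv) == length(phenotype))
  adj <- phenotype - mu_hat
  if (sd(adj) == 0 || sd(gebv) == 0)
    stop("zero variance: accuracy is undefined")
  cor(gebv, adj)
}

#' QTL tagging and genetic variance explained by a SNP set
#'
#' A QTL counts as tagged when its squared dosage correlation (composite
#' LD r2) with at least one SNP of the set exceeds `threshold`. The
#' percentage of genetic variance explained is the Hardy-Weinberg
#' single-locus share of the tagged QTL,
#' \eqn{100 \sum_{tagged} 2 p_k q_k a_k^2 / \sum_{poly} 2 p_k q_k a_k^2}
#' (monomorphic QTL are excluded from the denominator).
#'
#' @param qtl_dosages matrix (animals x QTL) of QTL dosages in the LD
#'   reference population.
#' @param snp_dosages matrix (same animals x selected SNPs); may have zero
#'   columns.
#' @param qtl_effects per-QTL additive effects (for the variance share);
#'   omit to get tagging counts only.
#' @param threshold r2 threshold, 0.7 in the study design.
#' @return list with `n_tagged`, `max_r2` (per QTL; NA for monomorphic
#'   QTL), `tagged` (logical), `gv_explained_pct` (NA without effects) and
#'   `n_monomorphic_qtl`.
#' @export
tag_qtl <- function(qtl_dosages, snp_dosages, qtl_effects = NULL,
                    threshold = 0.7) {
  stopifnot(is.matrix(qtl_dosages),
            is.matrix(snp_dosages) || is.null(snp_dosages))
  n_qtl <- ncol(qtl_dosages)
  qtl_sd <- apply(qtl_dosages, 2L, sd)
  mono <- qtl_sd == 0
  max_r2 <- rep(NA_real_, n_qtl)
  if (!is.null(snp_dosages) && ncol(snp_dosages) > 0L) {
    stopifnot(nrow(snp_dosages) == nrow(qtl_dosages))
    snp_sd <- apply(snp_dosages, 2L, sd)
    keep_snp <- snp_sd > 0
    if (any(keep_snp) && any(!mono)) {
      r <- suppressWarnings(
        cor(qtl_dosages[, !mono, drop = FALSE],
            snp_dosages[, keep_snp, drop = FALSE]))
      max_r2[!mono] <- apply(r^2, 1L, max)
    } else if (any(!mono)) {
      max_r2[!mono] <- 0
    }
  } else if (any(!mono)) {
    max_r2[!mono] <- 0
  }
  tagged <- !is.na(max_r2) & max_r2 > threshold
  gv_pct <- NA_real_
  if (!is.null(qtl_effects)) {
    stopifnot(length(qtl_effects) == n_qtl)
    p <- colMeans(qtl_dosages) / 2
    v <- 2 * p * (1 - p) * qtl_effects^2
    v[mono] <- 0
    gv_pct <- if (sum(v) > 0) 100 * sum(v[tagged]) / sum(v) else NA_real_
  }
  list(n_tagged = sum(tagged), max_r2 = max_r2, tagged = tagged,
       gv_explained_pct = gv_pct, n_monomorphic_qtl = sum(mono))
}

#' Aggregate per-replicate accuracy rows
#'
#' Means and standard errors (sd / sqrt(R)) over replicates, grouped by all
#' non-numeric identifier columns.
#'
#' @param reports data.frame with one row per replicate; numeric columns are
#'   aggregated, the rest act as grouping keys (a `replicate` column is
#'   dropped from the keys).
#' @return data.frame of means with `<col>_se` columns and `n_replicates`.
#' @export
aggregate_accuracy <- function(reports) {
  stopifnot(is.data.frame(reports))
  num <- vapply(reports, is.numeric, logical(1))
  num["replicate"] <- FALSE
  keys <- names(reports)[!num & names(reports) != "replicate"]
  dt <- data.table::as.data.table(reports)
  vals <- names(reports)[num & names(reports) != "replicate"]
  agg <- dt[, c(
    stats::setNames(lapply(.SD, mean), vals),
    stats::setNames(lapply(.SD, function(v) sd(v) / sqrt(length(v))),
                    paste0(vals, "_se")),
    list(n_replicates = .N)
  ), by = keys, .SDcols = vals]
  as.data.frame(agg)
}
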