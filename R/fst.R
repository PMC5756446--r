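#' Split animals into phenotype-extreme subpopulations
#'
#' Ranks the genotyped animals on phenotype and takes the lowest tail as S1,
#' the highest tail as S2 and the remainder as S0. Tail sizes are enforced
#' by rank so the two groups are exactly equal: either `group_size / 2` per
#' tail when `group_size` is given, or `round(q_low * n)` animals per tail
#' (with `q_high` mirroring `q_low`). Ties are broken deterministically by
#' id order.
#'
#' @param phenotypes numeric vector aligned with `ids`.
#' @param ids animal ids (the genotyped set).
#' @param q_low,q_high lower/upper phenotype quantiles delimiting the tails.
#' @param group_size optional total number of tail animals (split equally).
#' @return An object of class `subpop_split` with `s1_ids`, `s2_ids`,
#'   `s0_ids`, the quantiles and the tail size.
#' @export
split_by_phenotype <- function(phenotypes, ids = seq_along(phenotypes),
                               q_low = 0.05, q_high = 0.95,
                               group_size = NULL) {
  stopifnot(length(phenotypes) == length(ids),
            all(is.finite(phenotypes)),
            q_low > 0, q_high < 1, q_low < q_high)
  n <- length(ids)
  if (diff(range(phenotypes)) == 0)
    stop("constant phenotype vector: quantile split is undefined")
  n_tail <- if (!is.null(group_size)) {
    if (group_size %% 2L != 0L) stop("group_size must be even")
    group_size %/% 2L
  } else {
    round(q_low * n)
  }
  if (n_tail < 1L) stop("tail size is zero; increase q_low or group_size")
  if (2L * n_tail > n) stop("group_size exceeds the number of available animals")
  ord <- order(phenotypes, ids)
  s1 <- ids[ord[seq_len(n_tail)]]
  s2 <- ids[ord[seq.int(n - n_tail + 1L, n)]]
  structure(list(s1_ids = s1, s2_ids = s2,
                 s0_ids = setdiff(ids, c(s1, s2)),
                 quantile_low = q_low, quantile_high = q_high,
                 n_tail = n_tail), class = "subpop_split")
}

#' Allele frequencies from a dosage matrix
#'
#' @param genotypes matrix of 0/1/2 dosages, animals in rows (NA allowed;
#'   frequencies are computed over observed calls).
#' @param ids optional row subset (rownames or indices).
#' @return per-locus alternate-allele frequency (mean dosage / 2).
#' @export
allele_freq <- function(genotypes, ids = NULL) {
  if (!is.null(ids)) {
    genotypes <- genotypes[as.character(ids), , drop = FALSE]
  }
  if (nrow(genotypes) == 0L) stop("empty id set")
  colMeans(genotypes, na.rm = TRUE) / 2
}

#' Nei's global FST between two subpopulations
#'
#' \deqn{F_{ST} = (H_T - H_S) / H_T} with \eqn{H_{Si} = 2 p_{Si} q_{Si}},
#' \eqn{H_S} the size-weighted mean of the two subpopulation
#' heterozygosities, and \eqn{H_T = 2 p q} computed at the size-weighted
#' pooled frequency. Loci monomorphic in the pooled sample (\eqn{H_T = 0})
#' score 0 by convention.
#'
#' @param p_s1,p_s2 per-locus allele frequencies in the two subpopulations.
#' @param n_s1,n_s2 subpopulation sizes.
#' @return per-locus FST in [0, 1].
#' @export
nei_fst <- function(p_s1, p_s2, n_s1, n_s2) {
  stopifnot(length(p_s1) == length(p_s2), n_s1 > 0, n_s2 > 0,
            all(p_s1 >= 0 & p_s1 <= 1), all(p_s2 >= 0 & p_s2 <= 1))
  p <- (p_s1 * n_s1 + p_s2 * n_s2) / (n_s1 + n_s2)
  h_t <- 2 * p * (1 - p)
  h_s <- (2 * p_s1 * (1 - p_s1) * n_s1 + 2 * p_s2 * (1 - p_s2) * n_s2) /
    (n_s1 + n_s2)
  fst <- ifelse(h_t > 0, (h_t - h_s) / h_t, 0)
  pmin(pmax(fst, 0), 1)
}

#' Threshold FST scores at an empirical quantile
#'
#' The threshold is the empirical `quantile` of the score distribution over
#' all loci; every locus scoring at or above it is selected (ties at the
#' threshold are included, so counts can exceed `(1 - quantile) * n`).
#'
#' @param fst per-locus scores.
#' @param quantile quantile of the score distribution in (0, 1), typically
#'   0.975, 0.99 or 0.995.
#' @return list with `threshold` and `selected` (locus indices).
#' @export
select_by_quantile <- function(fst, quantile = 0.995) {
  stopifnot(all(is.finite(fst)), length(quantile) == 1L,
            quantile > 0, quantile < 1)
  thr <- as.numeric(stats::quantile(fst, quantile, names = FALSE))
  list(threshold = thr, selected = which(fst >= thr))
}

#' Phenotype-stratified FST scan
#'
#' The core prioritization step: genotyped animals are split on phenotype
#' into extreme tails, Nei's FST is computed per SNP between the tails, and
#' SNPs at or above the chosen quantile of the score distribution are
#' selected. With `strata` given, the scan runs independently within each
#' stratum (the within-breed mode recommended for admixed populations) and
#' a list of per-stratum results is returned.
#'
#' @param genotypes dosage matrix (animals x SNPs) with animal ids as
#'   rownames.
#' @param phenotypes numeric vector aligned with the rows of `genotypes`.
#' @param quantile FST-distribution quantile for selection.
#' @param q_low,q_high phenotype-tail quantiles.
#' @param group_size optional total tail-animal count (split equally).
#' @param strata optional factor aligned with rows; triggers within-stratum
#'   scans.
#' @return An object of class `fst_result`: per-locus `fst`, `p_total`,
#'   `p_s1`, `p_s2`, `h_t`, `h_s`, the `threshold`, `selected` (SNP
#'   indices), `selected_ids`, `quantile` and the `split`. With `strata`, a
#'   named list of such objects.
#' @export
fst_scan <- function(genotypes, phenotypes, quantile = 0.995,
                     q_low = 0.05, q_high = 0.95, group_size = NULL,
                     strata = NULL) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) == length(phenotypes))
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- as.character(seq_len(nrow(genotypes)))
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(genotypes))
    return(lapply(split(seq_len(nrow(genotypes)), strata), function(i) {
      fst_scan(genotypes[i, , drop = FALSE], phenotypes[i], quantile,
               q_low, q_high, group_size)
    }))
  }
  ids <- rownames(genotypes)
  split <- split_by_phenotype(phenotypes, ids, q_low, q_high, group_size)
  p1 <- allele_freq(genotypes, split$s1_ids)
  p2 <- allele_freq(genotypes, split$s2_ids)
  n1 <- length(split$s1_ids)
  n2 <- length(split$s2_ids)
  fst <- nei_fst(p1, p2, n1, n2)
  sel <- select_by_quantile(fst, quantile)
  p <- (p1 * n1 + p2 * n2) / (n1 + n2)
  structure(list(
    fst = fst, p_total = p, p_s1 = p1, p_s2 = p2,
    h_t = 2 * p * (1 - p),
    h_s = (2 * p1 * (1 - p1) * n1 + 2 * p2 * (1 - p2) * n2) / (n1 + n2),
    threshold = sel$threshold, selected = sel$selected,
    selected_ids = colnames(genotypes)[sel$selected],
    quantile = quantile, n_s1 = n1, n_s2 = n2, split = split
  ), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(paste0("<fst_result> %d loci scored between tails of %d/%d ",
                     "animals\n  quantile %.4g -> threshold %.4g, %d SNPs ",
                     "selected\n"),
              length(x$fst), x$n_s1, x$n_s2, x$quantile, x$threshold,
              length(x$selected)))
  invisible(x)
}

#' Write an FST scan result as a per-locus TSV
#'
#' @param result an `fst_result`.
#' @param map data.frame with `chrom`, `id`, `pos` rows aligned with the
#'   scored loci (optional).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fst_result <- function(result, path, map = NULL) {
  df <- data.frame(
    id = names(result$fst) %||% as.character(seq_along(result$fst)),
    p_s1 = result$p_s1, p_s2 = result$p_s2, fst = result$fst,
    selected = seq_along(result$fst) %in% result$selected
  )
  if (!is.null(map)) df <- cbind(map[, c("chrom", "id", "pos")],
                                 df[, c("p_s1", "p_s2", "fst", "selected")])
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
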