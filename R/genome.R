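#' Define a simulated genome map
#'
#' A genome is a set of chromosomes carrying two disjoint classes of
#' biallelic loci on a genetic (cM) map: neutral marker SNPs (the panel that
#' gets genotyped) and QTL (the causal loci that carry the trait's additive
#' effects). Positions are genetic distances, so recombination fractions
#' follow directly from the map via the Haldane function.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cM map length per chromosome in centimorgans; recycled
#'   to `n_chromosomes`.
#' @param markers data.frame with columns `chrom`, `id`, `pos_cM`; positions
#'   must be strictly increasing within a chromosome.
#' @param qtl data.frame with the same columns; QTL positions must not
#'   coincide with marker positions.
#' @return An object of class `genome_spec`: the inputs plus a combined locus
#'   table `loci` (ordered by chromosome and position, with a `type` column)
#'   and index vectors `marker_idx`/`qtl_idx` into that table.
#' @export
genome_spec <- function(n_chromosomes, chrom_length_cM, markers, qtl) {
  n_chromosomes <- as.integer(n_chromosomes)
  stopifnot(n_chromosomes >= 1L)
  chrom_length_cM <- rep_len(as.numeric(chrom_length_cM), n_chromosomes)
  for (df in list(markers, qtl)) {
    stopifnot(is.data.frame(df), all(c("chrom", "id", "pos_cM") %in% names(df)))
  }
  loci <- rbind(
    data.frame(chrom = as.integer(markers$chrom), id = as.character(markers$id),
               pos_cM = as.numeric(markers$pos_cM), type = "marker",
               stringsAsFactors = FALSE),
    data.frame(chrom = as.integer(qtl$chrom), id = as.character(qtl$id),
               pos_cM = as.numeric(qtl$pos_cM), type = "qtl",
               stringsAsFactors = FALSE)
  )
  loci <- loci[order(loci$chrom, loci$pos_cM), , drop = FALSE]
  rownames(loci) <- NULL
  for (c in seq_len(n_chromosomes)) {
    p <- loci$pos_cM[loci$chrom == c]
    if (any(p < 0) || any(p > chrom_length_cM[c]))
      stop("locus positions must lie in [0, chromosome length]")
    if (anyDuplicated(p))
      stop("marker and QTL positions must be distinct within a chromosome")
    if (is.unsorted(p, strictly = TRUE))
      stop("locus positions must be strictly increasing within a chromosome")
  }
  if (anyDuplicated(loci$id)) stop("locus ids must be unique")
  structure(list(
    n_chromosomes = n_chromosomes,
    chrom_length_cM = chrom_length_cM,
    loci = loci,
    marker_idx = which(loci$type == "marker"),
    qtl_idx = which(loci$type == "qtl")
  ), class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("<genome_spec> %d chromosomes (%s cM), %d markers, %d QTL\n",
              x$n_chromosomes, paste(unique(x$chrom_length_cM), collapse = "/"),
              length(x$marker_idx), length(x$qtl_idx)))
  invisible(x)
}

# chromosome offsets (0-based, with sentinel) and positions in Morgans,
# as the C++ kernels expect them
genome_cpp_map <- function(genome) {
  tab <- table(factor(genome$loci$chrom, levels = seq_len(genome$n_chromosomes)))
  list(
    pos_M = genome$loci$pos_cM / 100,
    chrom_off = as.integer(c(0L, cumsum(as.integer(tab)))),
    chrom_len_M = genome$chrom_length_cM / 100
  )
}

# evenly spaced candidate markers + uniformly placed candidate QTL, with QTL
# nudged off marker positions; panel membership is decided later from
# realized allele frequencies
place_candidate_loci <- function(n_chromosomes, chrom_length_cM, n_markers,
                                 n_qtl) {
  chrom_length_cM <- rep_len(chrom_length_cM, n_chromosomes)
  per_chr <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
  markers <- do.call(rbind, lapply(seq_len(n_chromosomes), function(c) {
    k <- per_chr[c]
    pos <- chrom_length_cM[c] * (seq_len(k) - 0.5) / k
    data.frame(chrom = c, id = sprintf("M%d_%d", c, seq_len(k)), pos_cM = pos)
  }))
  qtl_per_chr <- diff(round(seq(0, n_qtl, length.out = n_chromosomes + 1)))
  qtl <- do.call(rbind, lapply(seq_len(n_chromosomes), function(c) {
    k <- qtl_per_chr[c]
    if (k == 0L) return(NULL)
    pos <- sort(runif(k, 0, chrom_length_cM[c]))
    mpos <- markers$pos_cM[markers$chrom == c]
    # nudge off marker positions (and apart from each other)
    eps <- chrom_length_cM[c] * 1e-7
    for (i in seq_along(pos)) {
      while (any(abs(pos[i] - mpos) < eps) ||
             any(abs(pos[i] - pos[-i]) < eps)) {
        pos[i] <- runif(1, 0, chrom_length_cM[c])
      }
    }
    data.frame(chrom = c, id = sprintf("Q%d_%d", c, seq_len(k)),
               pos_cM = sort(pos))
  }))
  genome_spec(n_chromosomes, chrom_length_cM, markers, qtl)
}
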