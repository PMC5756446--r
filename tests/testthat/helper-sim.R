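# shared fixtures, all generated in code

# a tiny two-chromosome genome with hand-placed loci
tiny_genome <- function(n_markers_per_chr = 5, n_qtl_per_chr = 1,
                        len = 100) {
  markers <- do.call(rbind, lapply(1:2, function(c) data.frame(
    chrom = c, id = sprintf("M%d_%d", c, seq_len(n_markers_per_chr)),
    pos_cM = seq(10, len - 10, length.out = n_markers_per_chr))))
  qtl <- do.call(rbind, lapply(1:2, function(c) data.frame(
    chrom = c, id = sprintf("Q%d_%d", c, seq_len(n_qtl_per_chr)),
    pos_cM = seq(15, len - 15, length.out = n_qtl_per_chr) + 1.234)))
  genome_spec(2, len, markers, qtl)
}

# fast desk config for unit tests (not the study-scale config)
tiny_sim_config <- function(...) {
  defaults <- list(n_markers = 400, n_qtl = 10,
                   hist_generations = 40, hist_size = 60,
                   expand_size_start = 200, expand_size_end = 260,
                   n_males = 40, n_females = 400,
                   marker_oversample = 4, qtl_oversample = 8)
  do.call(scaled_sim_config, modifyList(defaults, list(...)))
}

random_dosage_matrix <- function(n, m, p = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.9)
  g <- vapply(p, function(pp) rbinom(n, 2L, pp), numeric(n))
  dimnames(g) <- list(sprintf("a%d", seq_len(n)), sprintf("s%d", seq_len(m)))
  g
}

# independent-SNP trait simulator for GWR tests (no LD, direct betas)
simulate_gwr_data <- function(n, m, n_qtl, h2 = 0.4, seed = 1) {
  set.seed(seed)
  g <- random_dosage_matrix(n, m)
  qtl <- sample(m, n_qtl)
  beta <- numeric(m)
  beta[qtl] <- rnorm(n_qtl)
  tbv <- as.numeric(scale(g, scale = FALSE) %*% beta)
  vg <- var(tbv)
  y <- tbv + rnorm(n, 0, sqrt(vg * (1 - h2) / h2))
  list(geno = g, y = y, beta = beta, tbv = tbv, qtl = qtl, sigma2_g = vg,
       sigma2_e = vg * (1 - h2) / h2)
}
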