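test_that("genome_spec validates positions and disjointness", {
  g <- tiny_genome()
  expect_s3_class(g, "genome_spec")
  expect_equal(length(g$marker_idx), 10L)
  expect_true(all(diff(g$loci$pos_cM[g$loci$chrom == 1]) > 0))
  # marker/QTL collision rejected
  bad_qtl <- data.frame(chrom = 1, id = "Qx", pos_cM = 10)
  mk <- g$loci[g$loci$type == "marker", ]
  expect_error(genome_spec(2, 100, mk, bad_qtl), "distinct")
  # out-of-range position rejected
  expect_error(genome_spec(2, 100, mk,
                           data.frame(chrom = 1, id = "Qx", pos_cM = 101)),
               "0, chromosome length")
})

test_that("meiosis copies identical parents and respects the genetic map", {
  g <- tiny_genome(n_markers_per_chr = 30, n_qtl_per_chr = 1)
  L <- nrow(g$loci)
  set.seed(1)
  hap <- matrix(rbinom(L, 1, 0.5), L, 2)  # identical pair
  for (k in 1:5) expect_identical(meiosis(hap, g), hap[, 1])

  # mean crossover count on a 1-Morgan chromosome is Poisson(1):
  # count strand switches between distinct parental haplotypes
  g1 <- genome_spec(1, 100,
                    markers = data.frame(chrom = 1, id = sprintf("m%d", 1:201),
                                         pos_cM = seq(0, 100, by = 0.5)),
                    qtl = data.frame(chrom = 1, id = "q1", pos_cM = 0.25))
  L1 <- nrow(g1$loci)
  par <- cbind(rep(0L, L1), rep(1L, L1))
  set.seed(42)
  n_mei <- 10000
  switches <- vapply(seq_len(n_mei), function(i) {
    gam <- meiosis(par, g1)
    sum(diff(gam) != 0)
  }, numeric(1))
  # observed switches at 0.5 cM resolution slightly undercount Poisson(1)
  # crossovers (double hits in one interval cancel); the effect is < 0.3%
  expect_equal(mean(switches), 1.0, tolerance = 0.05)

  # recombination fraction across 100 cM: Haldane 0.5*(1 - exp(-2)) = 0.432
  ends <- vapply(seq_len(n_mei), function(i) {
    gam <- meiosis(par, g1)
    gam[1] != gam[L1]
  }, logical(1))
  expect_equal(mean(ends), 0.5 * (1 - exp(-2)), tolerance = 0.02)
})

test_that("allele frequencies are conserved in expectation without mutation", {
  cfg <- tiny_sim_config(mutation_rate = 0, seed = 5)
  set.seed(5)
  genome <- tiny_genome(n_markers_per_chr = 50, n_qtl_per_chr = 2)
  map <- fstprior:::genome_cpp_map(genome)
  L <- nrow(genome$loci)
  n <- 2000
  p0 <- runif(L, 0.2, 0.8)
  haps <- matrix(as.raw(rbinom(L * 2 * n, 1, rep(p0, 2 * n))), L, 2 * n)
  start <- as.numeric(fstprior:::cpp_allele_freq(haps, seq_len(n) - 1L))
  for (gen in 1:10) {
    s <- sample.int(n, n, replace = TRUE)
    d <- sample.int(n, n, replace = TRUE)
    haps <- fstprior:::cpp_mate(haps, s - 1L, d - 1L, map$pos_M,
                                map$chrom_off, map$chrom_len_M, 0)
  }
  end <- as.numeric(fstprior:::cpp_allele_freq(haps, seq_len(n) - 1L))
  # drift moves individual loci; the mean change over 102 loci is ~0
  expect_equal(mean(end - start), 0, tolerance = 0.01)
  expect_gt(var(end - start), 0)  # but drift did happen
})

test_that("founders mirror historical frequencies and counts", {
  cfg <- tiny_sim_config(seed = 3)
  hist_pop <- run_historical(cfg, 3)
  g0 <- found_population(hist_pop, n_males = 40, n_females = 400, rng_seed = 4)
  expect_equal(nrow(g0$pedigree), 440L)
  expect_equal(sum(g0$pedigree$sex == 1L), 40L)
  expect_equal(unique(g0$pedigree$generation), 0L)
  f_hist <- as.numeric(fstprior:::cpp_allele_freq(
    hist_pop$haplotypes, seq_len(nrow(hist_pop$pedigree)) - 1L))
  f_g0 <- as.numeric(fstprior:::cpp_allele_freq(
    g0$haplotypes, seq_len(440L) - 1L))
  # binomial sampling error around the source frequencies
  se <- sqrt(pmax(f_hist * (1 - f_hist), 1e-6) / (2 * 440))
  expect_lt(mean(abs(f_g0 - f_hist) / se > 4), 0.01)
  # two founders, one of each sex
  g2 <- found_population(hist_pop, 1, 1, rng_seed = 9)
  expect_equal(sort(g2$pedigree$sex), c(1L, 2L))
  expect_error(found_population(g2, 5, 5, replace = FALSE),
               "without replacement")
})

test_that("gamma QTL effects give a few-large-many-small architecture", {
  set.seed(11)
  checks <- t(replicate(20, {
    p <- runif(100, 0.05, 0.95)
    a <- assign_qtl_effects_gamma(p, shape = 0.4, sigma2_g = 0.4)
    f <- sort(2 * p * (1 - p) * a^2 / 0.4, decreasing = TRUE)
    c(total = sum(2 * p * (1 - p) * a^2), largest = f[1],
      top15 = sum(f[1:15]), bottom50 = sum(f[51:100]))
  }))
  expect_equal(unname(checks[, "total"]), rep(0.4, 20), tolerance = 1e-12)
  expect_true(all(checks[, "top15"] > checks[, "bottom50"]))
  expect_gte(sum(checks[, "largest"] > 0.10), 16)
  # monomorphic QTL are excluded
  a <- assign_qtl_effects_gamma(c(0, 0.5, 1, 0.3))
  expect_identical(a[c(1, 3)], c(0, 0))
})

test_that("predefined QTL effects bound every variance fraction", {
  set.seed(12)
  p <- runif(100, 0.05, 0.95)
  a <- assign_qtl_effects_predefined(p, sigma2_g = 0.4, min_fraction = 0.005)
  f <- 2 * p * (1 - p) * a^2 / sum(2 * p * (1 - p) * a^2)
  expect_equal(sum(f), 1)
  expect_gte(min(f), 0.005 * 0.95)   # renormalization tolerance
  expect_lte(max(f), 3 * min(f) + 1e-12)
  expect_equal(sum(2 * p * (1 - p) * a^2), 0.4, tolerance = 1e-12)
})

test_that("phenotype policies control the residual variance", {
  set.seed(13)
  tbv <- rnorm(10000, 0, sqrt(0.37))
  y <- simulate_phenotypes(tbv, "rescale_to_realized_h2", h2 = 0.4)
  expect_equal(var(tbv) / var(as.numeric(y)), 0.4, tolerance = 0.03)
  expect_equal(attr(y, "sigma2_e"), var(tbv) * 1.5)
  y0 <- simulate_phenotypes(tbv, "nominal", sigma2_e = 0)
  expect_identical(as.numeric(y0), tbv)
  yn <- simulate_phenotypes(tbv, "nominal", sigma2_e = 0.6)
  expect_equal(attr(yn, "sigma2_e"), 0.6)
  expect_error(simulate_phenotypes(rep(1, 5), "rescale_to_realized_h2"),
               "undefined")
})

test_that("BLUP matches a dense mixed-model-equation oracle", {
  # 2 founders + 3 offspring, all phenotyped
  ped <- data.frame(id = 1:5, sire = c(0L, 0L, 1L, 1L, 1L),
                    dam = c(0L, 0L, 2L, 2L, 2L))
  y <- c(1.2, -0.5, 0.3, 2.0, -1.1)
  lambda <- 1.5
  fit <- blup_ebv(ped, y, lambda)
  expect_true(fit$converged)
  # dense oracle: direct inversion of the same MME
  A <- diag(5)
  A[3:5, 1] <- A[1, 3:5] <- 0.5
  A[3:5, 2] <- A[2, 3:5] <- 0.5
  A[3, 4] <- A[4, 3] <- A[3, 5] <- A[5, 3] <- A[4, 5] <- A[5, 4] <- 0.5
  Ai <- solve(A)
  C <- rbind(c(5, rep(1, 5)), cbind(1, diag(5) + lambda * Ai))
  sol <- solve(C, c(sum(y), y))
  expect_equal(fit$mu, sol[1], tolerance = 1e-6)
  expect_equal(fit$ebv, sol[-1], tolerance = 1e-6)

  # lambda -> 0 on unrelated phenotyped singletons: EBV ranking = phenotype
  ped0 <- data.frame(id = 1:5, sire = 0L, dam = 0L)
  fit0 <- blup_ebv(ped0, y, lambda = 1e-8)
  expect_identical(order(fit0$ebv), order(y))
})

test_that("replacement rates retain the right parent counts", {
  # toy generation: 10 sires, 20 dams, candidates of both sexes
  set.seed(21)
  g <- tiny_genome()
  L <- nrow(g$loci)
  n <- 70
  ped <- data.frame(id = 1:n, sire = 0L, dam = 0L, generation = 0L,
                    sex = c(rep(1L, 10), rep(2L, 20),
                            rep(c(1L, 2L), each = 20)),
                    genotyped = FALSE)
  pop <- fstprior:::new_haplo_pop(
    matrix(as.raw(rbinom(L * 2 * n, 1, 0.5)), L, 2 * n), ped, g)
  cfg <- tiny_sim_config(selection = "phenotypic")
  sel <- ebv_and_select(pop, rnorm(n), sires = 1:10, dams = 11:30,
                        candidates = 31:70, cfg)
  expect_equal(length(sel$sires), 10L)
  expect_equal(length(sel$dams), 20L)
  expect_equal(sum(sel$sires <= 10), 5L)   # 50% replaced
  expect_equal(sum(sel$dams <= 30), 16L)   # 20% replaced
  # replacements are the top-EBV young of the right sex
  young_m <- 31:50
  expect_true(all(setdiff(sel$sires, 1:10) %in%
                    young_m[rank(-sel$ebv[young_m]) <= 5]))
})

test_that("run_simulation is reproducible, consistent and acyclic", {
  cfg <- tiny_sim_config(seed = 77)
  sim <- run_simulation(cfg)
  sim2 <- run_simulation(cfg)
  expect_identical(sim$pop$haplotypes, sim2$pop$haplotypes)
  expect_identical(sim$trait$phenotype, sim2$trait$phenotype)

  ped <- sim$pop$pedigree
  # pedigree acyclicity / generation monotonicity
  has_par <- ped$sire > 0L
  expect_true(all(ped$generation[ped$sire[has_par]] <
                    ped$generation[has_par]))
  expect_true(all(ped$generation[ped$dam[ped$dam > 0L]] <
                    ped$generation[ped$dam > 0L]))
  # genotyping restricted to G3/G4
  expect_setequal(unique(ped$generation[ped$genotyped]), c(3L, 4L))
  # one progeny per dam: cohort sizes equal the dam count
  expect_true(all(table(ped$generation[ped$generation > 0]) == 400L))
  # TBV identity: recomputing from stored haplotypes is exact
  qd <- dosages(sim$pop, loci = "qtl")
  expect_equal(as.numeric(qd %*% sim$trait$qtl_effects), sim$trait$tbv)
  # marker and QTL panels respect the MAF floors at panel selection
  expect_equal(length(sim$genome$marker_idx), cfg$n_markers)
  expect_equal(length(sim$genome$qtl_idx), cfg$n_qtl)
})

test_that("adjacent-marker LD rises with bottleneck severity", {
  r2 <- vapply(c(200, 80, 30), function(N) {
    cfg <- tiny_sim_config(hist_size = N, hist_generations = 50,
                           n_select_generations = 0, seed = 31,
                           marker_oversample = 6)
    run_simulation(cfg)$ld$adjacent_r2_g0
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("degenerate configs are rejected with clear messages", {
  expect_error(sim_config(n_markers = 0), "positive")
  expect_error(sim_config(hist_size = 0), "positive")
  expect_error(sim_config(mutation_rate = 1.2), "mutation_rate")
  # full-scale settings are accepted without error (not executed)
  cfg <- sim_config()
  expect_equal(cfg$n_markers, 200000L)
  expect_equal(cfg$hist_generations, 300L)
  expect_equal(cfg$n_females, 15000L)
})
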