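test_that("phenotype split takes equal tails by rank", {
  set.seed(1)
  y <- rnorm(100)
  sp <- split_by_phenotype(y, q_low = 0.05, q_high = 0.95)
  expect_equal(length(sp$s1_ids), 5L)
  expect_equal(length(sp$s2_ids), 5L)
  # full-sort oracle
  ord <- order(y)
  expect_setequal(sp$s1_ids, ord[1:5])
  expect_setequal(sp$s2_ids, ord[96:100])
  expect_length(intersect(sp$s1_ids, sp$s2_ids), 0)
  expect_equal(sort(c(sp$s0_ids, sp$s1_ids, sp$s2_ids)), 1:100)

  # group_size pins the tail count exactly
  sp2 <- split_by_phenotype(y, group_size = 30)
  expect_equal(length(sp2$s1_ids), 15L)
  expect_equal(length(sp2$s2_ids), 15L)

  expect_error(split_by_phenotype(rep(1, 50)), "constant")
  expect_error(split_by_phenotype(y, group_size = 300), "exceeds")
})

test_that("allele_freq matches one-by-one allele counting", {
  g <- random_dosage_matrix(20, 10, seed = 2)
  f <- allele_freq(g)
  brute <- vapply(seq_len(10), function(j) {
    alleles <- 0
    for (i in 1:20) alleles <- alleles + g[i, j]
    alleles / 40
  }, numeric(1))
  expect_equal(unname(f), brute)
  expect_equal(unname(allele_freq(matrix(1, 5, 1))), 0.5)
  expect_equal(unname(allele_freq(matrix(c(0, 1, 2), 3, 1))), 0.5)
  expect_error(allele_freq(g[0, , drop = FALSE]), "empty")
})

test_that("Nei FST reproduces hand-computed values", {
  expect_equal(nei_fst(0.3, 0.3, 100, 100), 0)
  # p1=0.2, p2=0.8, equal n: p=0.5, H_T=0.5, H_S=0.32, FST=0.36
  expect_equal(nei_fst(0.2, 0.8, 50, 50), 0.36)
  expect_equal(nei_fst(0, 1, 75, 75), 1)
  expect_equal(nei_fst(0, 0, 10, 10), 0)  # monomorphic convention
  # unequal sizes: weighted pooled frequency
  p <- (0.2 * 30 + 0.6 * 10) / 40
  ht <- 2 * p * (1 - p)
  hs <- (2 * .2 * .8 * 30 + 2 * .6 * .4 * 10) / 40
  expect_equal(nei_fst(0.2, 0.6, 30, 10), (ht - hs) / ht)
})

test_that("FST is within [0,1] and symmetric under relabeling", {
  set.seed(3)
  n <- 10000
  p1 <- runif(n)
  p2 <- runif(n)
  f <- nei_fst(p1, p2, 120, 380)
  expect_true(all(f >= 0 & f <= 1))
  # swapping subpopulations (with sizes) changes nothing
  expect_equal(nei_fst(p2, p1, 380, 120), f)
  # allele-label flip changes nothing
  expect_equal(nei_fst(1 - p1, 1 - p2, 120, 380), f)
})

test_that("quantile selection matches a full-sort oracle and keeps ties", {
  set.seed(4)
  s <- round(runif(1000), 3)  # rounded scores force ties
  sel <- select_by_quantile(s, 0.99)
  expect_equal(sel$selected, which(s >= sel$threshold))
  # the threshold is the empirical quantile of the sorted scores
  expect_equal(sel$threshold, unname(quantile(sort(s), 0.99)))
  expect_gte(length(sel$selected), 10)
  # all-equal scores: everything is selected
  expect_length(select_by_quantile(rep(0.2, 50), 0.995)$selected, 50)
  expect_error(select_by_quantile(s, 1.2), "quantile")
  # expected count ~ (1-q) * n up to ties
  set.seed(5)
  u <- runif(200000)
  expect_equal(length(select_by_quantile(u, 0.995)$selected), 1000,
               tolerance = 0.05)
})

test_that("fst_scan wires split, frequencies and threshold together", {
  set.seed(6)
  g <- random_dosage_matrix(200, 50)
  y <- rnorm(200)
  res <- fst_scan(g, y, quantile = 0.9, group_size = 40)
  expect_s3_class(res, "fst_result")
  expect_equal(res$n_s1, 20L)
  p1 <- allele_freq(g, res$split$s1_ids)
  expect_equal(res$p_s1, p1)
  expect_equal(res$fst, nei_fst(res$p_s1, res$p_s2, 20, 20))
  expect_true(all(res$fst[res$selected] >= res$threshold))
  # selected SNPs are reported by id for the downstream regression
  expect_identical(res$selected_ids, colnames(g)[res$selected])

  # stratified mode scores within stratum
  strata <- rep(c("b1", "b2"), each = 100)
  rs <- fst_scan(g, y, quantile = 0.9, strata = strata)
  expect_named(rs, c("b1", "b2"))
  direct <- fst_scan(g[1:100, ], y[1:100], quantile = 0.9)
  expect_equal(rs$b1$fst, direct$fst)
})
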