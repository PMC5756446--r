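test_that("single-SNP preselection fit matches the conjugate closed form", {
  set.seed(1)
  n <- 500
  x <- rbinom(n, 2, 0.4)
  y <- 2 + 0.8 * x + rnorm(n)
  X <- matrix(x, ncol = 1, dimnames = list(NULL, "s1"))
  # known-variance limit: df -> Inf pins both variances at their scales
  spec <- gwr_spec("fst_preselect", prior_scale_g = 0.5, prior_scale_e = 1,
                   df_g = 1e8, df_e = 1e8, chain_length = 6000,
                   burn_in = 1000, thin = 2, seed = 3)
  fit <- gwr_fit(X, y, spec)
  p <- mean(x) / 2
  s2b <- 0.5 / (2 * p * (1 - p))  # scale rule at m = 1
  xc <- x - mean(x)
  closed <- sum(xc * y) / (sum(xc^2) + 1 / s2b)
  expect_equal(unname(fit$beta_hat), closed, tolerance = 0.01)
  expect_equal(unname(fit$include_prob), 1)
})

test_that("a strong effect is recovered against an OLS oracle", {
  set.seed(3)
  n <- 2000
  g <- random_dosage_matrix(n, 5, p = rep(0.5, 5))
  y <- as.numeric(g %*% c(2, 0, 0, 0, 0)) + rnorm(n)  # ~10 sigma effect
  fit <- gwr_fit(g, y, gwr_spec("bayesC", pi_zero = 0.5,
                                chain_length = 4000, burn_in = 500,
                                seed = 1))
  ols <- unname(coef(lm(y ~ g))[-1])
  expect_equal(unname(fit$beta_hat[1]), ols[1], tolerance = 0.1 * abs(ols[1]))
  expect_equal(unname(fit$beta_hat[1]), 2, tolerance = 0.2)
  expect_gt(fit$include_prob[1], 0.95)
  expect_true(all(fit$include_prob[-1] < 0.5))
})

test_that("the pi_zero grid of the study is accepted", {
  set.seed(4)
  g <- random_dosage_matrix(100, 20)
  y <- rnorm(100)
  for (pi0 in c(0.90, 0.95, 0.98, 0.99)) {
    f <- gwr_fit(g, y, gwr_spec("bayesC", pi_zero = pi0, chain_length = 200,
                                burn_in = 50, thin = 1, seed = 1))
    expect_true(all(f$include_prob >= 0 & f$include_prob <= 1))
  }
  expect_error(gwr_spec("bayesB", pi_zero = 0), "pi_zero")
  expect_error(gwr_spec(chain_length = 100, burn_in = 200))
})

test_that("fits are seed-deterministic and exchangeable in column order", {
  d <- simulate_gwr_data(300, 40, 5, seed = 5)
  spec <- gwr_spec("bayesB", pi_zero = 0.9, chain_length = 600,
                   burn_in = 100, thin = 2, seed = 7)
  f1 <- gwr_fit(d$geno, d$y, spec)
  f2 <- gwr_fit(d$geno, d$y, spec)
  expect_identical(f1$beta_hat, f2$beta_hat)
  expect_identical(f1$sigma2_e_hat, f2$sigma2_e_hat)
  # permuting SNP columns permutes the posterior identically: the sampler
  # must draw per-SNP randomness in a column-indexed order for this to hold
  # exactly, so compare against a re-seeded fit on the permuted design
  set.seed(8)
  perm <- sample(ncol(d$geno))
  f3 <- gwr_fit(d$geno[, perm], d$y, spec)
  expect_equal(sort(names(f3$beta_hat)), sort(names(f1$beta_hat)))
  expect_equal(cor(f3$beta_hat[names(f1$beta_hat)], f1$beta_hat),
               1, tolerance = 0.05)
})

test_that("BayesC shrinkage strengthens with the exclusion prior", {
  d <- simulate_gwr_data(500, 60, 8, seed = 9)
  mab <- vapply(c(0.3, 0.9, 0.99), function(pi0) {
    f <- gwr_fit(d$geno, d$y, gwr_spec("bayesC", pi_zero = pi0,
                                       chain_length = 3000, burn_in = 500,
                                       thin = 2, seed = 11))
    mean(abs(f$beta_hat))
  }, numeric(1))
  expect_true(all(diff(mab) < 0))
})

test_that("whole-genome fits recover simulated signal and predict", {
  # 20 true QTL among 2000 SNPs, n = 2000, h2 = 0.4
  accs <- vapply(1:20, function(r) {
    d <- simulate_gwr_data(2000, 2000, 20, h2 = 0.4, seed = 100 + r)
    tr <- 1:1600
    va <- 1601:2000
    f <- gwr_fit(d$geno[tr, ], d$y[tr],
                 gwr_spec("fst_preselect", prior_scale_g = d$sigma2_g,
                          prior_scale_e = d$sigma2_e, chain_length = 500,
                          burn_in = 150, thin = 2, seed = r))
    expect_gt(cor(f$beta_hat, d$beta), 0)
    cor(predict_gebv(f, d$geno[va, ]), d$tbv[va])
  }, numeric(1))
  # validation accuracy significantly above zero over 20 replicates
  expect_gt(mean(accs) / (sd(accs) / sqrt(20)), 5)
  expect_gt(mean(accs), 0.3)
})

test_that("GEBV prediction is the centered linear form", {
  set.seed(12)
  g_train <- random_dosage_matrix(100, 20)
  y <- rnorm(100)
  fit <- gwr_fit(g_train, y, gwr_spec(chain_length = 200, burn_in = 50,
                                      thin = 1, seed = 1))
  g_valid <- random_dosage_matrix(50, 20, seed = 13)
  gebv <- predict_gebv(fit, g_valid)
  # independent dot-product loop oracle
  oracle <- vapply(1:50, function(i)
    sum((g_valid[i, ] - fit$centers) * fit$beta_hat), numeric(1))
  expect_equal(unname(gebv), oracle)

  # all-zero effects give identically zero GEBV
  fit0 <- fit
  fit0$beta_hat[] <- 0
  expect_equal(unname(predict_gebv(fit0, g_valid)), rep(0, 50))

  # single SNP, beta = 2: dosages 0/1/2 map to 0/2/4 up to centering
  fit1 <- fit
  fit1$beta_hat <- c(s1 = 2)
  fit1$centers <- c(s1 = 0.9)
  fit1$snp_ids <- "s1"
  gv <- predict_gebv(fit1, matrix(0:2, 3, 1, dimnames = list(NULL, "s1")))
  expect_equal(unname(diff(gv)), c(2, 2))

  # column mismatch by id is an error
  colnames(g_valid)[1] <- "other"
  expect_error(predict_gebv(fit, g_valid), "missing")
})

test_that("fractional (imputed) dosages take the double path unchanged", {
  set.seed(14)
  g <- random_dosage_matrix(200, 30)
  y <- rnorm(200)
  spec <- gwr_spec(chain_length = 400, burn_in = 100, thin = 1, seed = 2)
  f_int <- gwr_fit(g, y, spec)
  g_frac <- g
  g_frac[1, 1] <- g_frac[1, 1] + 1e-9  # forces the double path
  f_frac <- gwr_fit(g_frac, y, spec)
  expect_equal(f_frac$beta_hat, f_int$beta_hat, tolerance = 1e-4)
})
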