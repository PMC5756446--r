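#' Gamma-distributed QTL effects
#'
#' Absolute effect sizes are drawn from a gamma distribution with the given
#' shape (scale 1; the subsequent normalization removes the scale), signs are
#' +/- with probability 1/2, and all effects are rescaled so the
#' Hardy-Weinberg additive variance \eqn{\sum_k 2 p_k q_k a_k^2} equals
#' `sigma2_g`. This yields the classical few-large/many-small architecture:
#' a handful of QTL carry most of the genetic variance.
#'
#' @param frequencies per-QTL allele frequency in the founder cohort.
#' @param shape gamma shape parameter.
#' @param sigma2_g target additive genetic variance.
#' @return numeric vector of signed effects; monomorphic QTL (frequency 0 or
#'   1) are excluded from the sampling pool and get effect 0.
#' @export
assign_qtl_effects_gamma <- function(frequencies, shape = 0.4,
                                     sigma2_g = 0.4) {
  p <- as.numeric(frequencies)
  stopifnot(all(p >= 0), all(p <= 1), shape > 0, sigma2_g > 0)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all QTL are monomorphic; no variance to assign")
  a <- numeric(length(p))
  a[poly] <- rgamma(sum(poly), shape = shape, rate = 1) *
    sample(c(-1, 1), sum(poly), replace = TRUE)
  rescale_qtl_effects(a, p, sigma2_g)
}

#' Predefined QTL effects as genetic-variance fractions
#'
#' Each polymorphic QTL is assigned a genetic-variance fraction drawn from
#' Uniform(`min_fraction`, 3 * `min_fraction`), the fractions are
#' renormalized to sum to one, and effects are recovered as
#' \eqn{a_k = \sqrt{f_k \sigma^2_g / (2 p_k q_k)}} with random signs. Every
#' QTL then explains at least `min_fraction` of the genetic variance up to
#' the renormalization factor, giving a deliberately "flat" architecture
#' with no large-effect loci.
#'
#' @inheritParams assign_qtl_effects_gamma
#' @param min_fraction minimum per-QTL genetic-variance fraction before
#'   renormalization.
#' @return numeric vector of signed effects (0 for monomorphic QTL).
#' @export
assign_qtl_effects_predefined <- function(frequencies, sigma2_g = 0.4,
                                          min_fraction = 0.005) {
  p <- as.numeric(frequencies)
  stopifnot(all(p >= 0), all(p <= 1), min_fraction > 0, sigma2_g > 0)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all QTL are monomorphic; no variance to assign")
  k <- sum(poly)
  f <- runif(k, min_fraction, 3 * min_fraction)
  f <- f / sum(f)
  a <- numeric(length(p))
  a[poly] <- sqrt(f * sigma2_g / (2 * p[poly] * (1 - p[poly]))) *
    sample(c(-1, 1), k, replace = TRUE)
  a
}

# rescale signed effects so sum(2 p q a^2) over polymorphic loci = sigma2_g
rescale_qtl_effects <- function(a, p, sigma2_g) {
  v <- sum(2 * p * (1 - p) * a^2)
  if (v <= 0) stop("assigned effects carry no variance")
  a * sqrt(sigma2_g / v)
}

# Hardy-Weinberg per-QTL genetic-variance fractions
qtl_gv_fractions <- function(effects, frequencies) {
  v <- 2 * frequencies * (1 - frequencies) * effects^2
  v / sum(v)
}

#' Simulate phenotypes from true breeding values
#'
#' Adds a normal residual to each TBV. Under the `"rescale_to_realized_h2"`
#' policy the residual variance is set from the realized TBV variance,
#' \eqn{\sigma^2_e = Var(tbv) (1 - h^2) / h^2}, so the realized heritability
#' is held at `h2` whatever LD among the QTL did to the genetic variance;
#' under `"nominal"` the supplied `sigma2_e` is used as is.
#'
#' @param tbv numeric vector of true breeding values.
#' @param policy residual-variance policy.
#' @param h2 target heritability (rescale policy).
#' @param sigma2_e nominal residual variance (nominal policy).
#' @return numeric phenotype vector with attribute `sigma2_e` (the value
#'   actually used).
#' @export
simulate_phenotypes <- function(tbv,
                                policy = c("rescale_to_realized_h2", "nominal"),
                                h2 = 0.4, sigma2_e = 0.6) {
  policy <- match.arg(policy)
  stopifnot(all(is.finite(tbv)))
  if (policy == "rescale_to_realized_h2") {
    vg <- var(tbv)
    if (!is.finite(vg) || vg <= 0)
      stop("TBV variance is zero; heritability is undefined under the rescale policy")
    sigma2_e <- vg * (1 - h2) / h2
  }
  y <- tbv + rnorm(length(tbv), 0, sqrt(sigma2_e))
  attr(y, "sigma2_e") <- sigma2_e
  y
}
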