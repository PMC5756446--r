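#' Henderson's inverse numerator relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules,
#' ignoring inbreeding in the Mendelian-sampling variances (the standard
#' fast approximation). Animals must be coded 1..n with parents appearing
#' before offspring; 0 marks an unknown parent.
#'
#' @param sire,dam integer vectors of parent codes (0 = unknown).
#' @return A sparse symmetric `dgCMatrix`.
#' @export
pedigree_ainverse <- function(sire, dam) {
  n <- length(sire)
  stopifnot(length(dam) == n)
  sire <- as.integer(sire); dam <- as.integer(dam)
  if (any(sire > seq_len(n)) || any(dam > seq_len(n)))
    stop("parents must precede offspring in the pedigree")
  known <- (sire > 0L) + (dam > 0L)
  alpha <- c(1, 4 / 3, 2)[known + 1L]
  i <- seq_len(n)
  ii <- i; jj <- i; xx <- alpha
  hs <- sire > 0L
  if (any(hs)) {
    ii <- c(ii, i[hs], sire[hs], sire[hs])
    jj <- c(jj, sire[hs], i[hs], sire[hs])
    xx <- c(xx, -alpha[hs] / 2, -alpha[hs] / 2, alpha[hs] / 4)
  }
  hd <- dam > 0L
  if (any(hd)) {
    ii <- c(ii, i[hd], dam[hd], dam[hd])
    jj <- c(jj, dam[hd], i[hd], dam[hd])
    xx <- c(xx, -alpha[hd] / 2, -alpha[hd] / 2, alpha[hd] / 4)
  }
  hb <- hs & hd
  if (any(hb)) {
    ii <- c(ii, sire[hb], dam[hb])
    jj <- c(jj, dam[hb], sire[hb])
    xx <- c(xx, alpha[hb] / 4, alpha[hb] / 4)
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

#' Pedigree animal-model BLUP breeding values
#'
#' Solves the single-trait mixed-model equations
#' \deqn{y = 1\mu + Z a + e, \quad a \sim N(0, A\sigma^2_g),}
#' with a known variance ratio `lambda` = sigma2_e / sigma2_g, by Jacobi
#' preconditioned conjugate gradients on the sparse coefficient matrix.
#' Animals without phenotype contribute through the pedigree only.
#'
#' @param pedigree data.frame with integer columns `sire` and `dam`
#'   (0 = unknown), one row per animal in id order 1..n, parents first.
#' @param phenotype numeric vector, NA for unphenotyped animals.
#' @param lambda variance ratio sigma2_e / sigma2_g.
#' @param tol relative-residual convergence tolerance.
#' @param max_iter iteration cap.
#' @return list with `mu`, `ebv` (length n), `iterations`, `converged`.
#' @export
blup_ebv <- function(pedigree, phenotype, lambda, tol = 1e-8,
                     max_iter = 5000L) {
  n <- nrow(pedigree)
  if (n == 0L) stop("empty pedigree")
  if (length(phenotype) != n)
    stop("phenotype must have one entry per pedigree animal (NA if missing)")
  obs <- !is.na(phenotype)
  if (!any(obs)) stop("no phenotyped animals")
  Ainv <- pedigree_ainverse(pedigree$sire, pedigree$dam)
  zz <- as.numeric(obs)
  C <- rbind(
    cbind(Matrix::Matrix(sum(obs), 1, 1, sparse = TRUE),
          Matrix::Matrix(zz, 1, n, sparse = TRUE)),
    cbind(Matrix::Matrix(zz, n, 1, sparse = TRUE),
          Matrix::Diagonal(n, zz) + lambda * Ainv)
  )
  y0 <- ifelse(obs, phenotype, 0)
  b <- c(sum(y0), y0)
  d <- Matrix::diag(C)
  d[d <= 0] <- 1
  x <- numeric(n + 1L)
  r <- b - as.numeric(C %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Cp <- as.numeric(C %*% p)
    a <- rz / sum(p * Cp)
    x <- x + a * p
    r <- r - a * Cp
    if (sqrt(sum(r^2)) / bnorm < tol) { converged <- TRUE; break }
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(mu = x[1L], ebv = x[-1L], iterations = it, converged = converged)
}
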