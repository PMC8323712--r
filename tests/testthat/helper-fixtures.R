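# Fixture builders shared across test files. Everything is generated in code;
# no binary fixtures.

toy_records <- function(ids, beta, se, ea = "A", oa = "G", eaf = NULL,
                        chrom = NULL, pos = NULL, pvalue = NULL, n = NULL) {
  df <- data.frame(
    variant_id = ids,
    effect_allele = rep_len(ea, length(ids)),
    other_allele = rep_len(oa, length(ids)),
    beta = beta, se = se, stringsAsFactors = FALSE
  )
  if (!is.null(eaf)) df$eaf <- eaf
  if (!is.null(chrom)) df$chrom <- rep_len(chrom, length(ids))
  if (!is.null(pos)) df$pos <- pos
  if (!is.null(pvalue)) df$pvalue <- pvalue
  if (!is.null(n)) df$n <- rep_len(n, length(ids))
  df
}

toy_set <- function(trait, beta, se, ids = paste0("rs", seq_along(beta)), ...) {
  summary_stat_set(trait, "quantitative",
                   toy_records(ids, beta, se, ...))
}

# small single-exposure panel with outcome, for MR estimator tests
toy_panel <- function(bx, by, sex = rep(0.01, length(bx)),
                      sey = rep(0.05, length(by)),
                      ids = sprintf("rs%03d", seq_along(bx)),
                      exposure = "X") {
  harmonized_panel(ids, exposure, matrix(bx, ncol = 1),
                   matrix(sex, ncol = 1), bY = by, seY = sey)
}

# random panel for oracle-equivalence loops
rand_panel <- function(J, seed, K = 1) {
  set.seed(seed)
  harmonized_panel(
    sprintf("rs%03d", seq_len(J)), paste0("X", seq_len(K)),
    bX = matrix(rnorm(J * K, 0, 0.1), J, K),
    seX = matrix(runif(J * K, 0.005, 0.02), J, K),
    bY = rnorm(J, 0, 0.05), seY = runif(J, 0.02, 0.1)
  )
}

# random PSD correlation matrix over the panel's variants
rand_ld <- function(ids, seed, strength = 0.5) {
  set.seed(seed)
  J <- length(ids)
  A <- matrix(rnorm(J * J), J, J)
  S <- crossprod(A) + diag(J) * J * (1 - strength)
  ld_matrix(cov2cor(S), ids)
}

# textbook (independent-instrument) IVW closed form: the oracle for GLS
ivw_closed_form <- function(bx, by, sey) {
  w <- 1 / sey^2
  theta <- sum(bx * by * w) / sum(bx^2 * w)
  se <- 1 / sqrt(sum(bx^2 * w))
  list(theta = theta, se = se)
}

# independent GLS oracle: whiten with the Cholesky factor and use lm.fit
gls_oracle <- function(X, y, Omega) {
  W <- solve(t(chol(Omega)))
  fit <- lm.fit(W %*% X, as.numeric(W %*% y))
  list(coef = unname(fit$coefficients),
       vcov = chol2inv(qr.R(fit$qr)))
}

# log marginal likelihood by 1-D quadrature (K = 1 only):
# log integral N(y | X theta, I) N(theta | 0, sigma^2) dtheta
evidence_quadrature <- function(y, x, sigma) {
  logf <- function(th) {
    vapply(th, function(t) {
      sum(dnorm(y, x * t, 1, log = TRUE)) + dnorm(t, 0, sigma, log = TRUE)
    }, numeric(1))
  }
  m <- optimize(logf, c(-50 * sigma, 50 * sigma), maximum = TRUE)$objective
  val <- integrate(function(t) exp(logf(t) - m), -Inf, Inf,
                   rel.tol = 1e-10)$value
  m + log(val)
}
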