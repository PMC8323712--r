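## Univariable and multivariable summary-data MR estimators.
##
## All estimators are generalized weighted least squares of the variant-outcome
## associations on the variant-exposure associations with weight matrix
## Omega^-1, Omega = diag(seY) R diag(seY); R is the LD correlation (identity
## for independent instruments). p-values use the normal distribution, the
## summary-data MR convention at moderate J.

.mr_estimate <- function(method, exposure, theta, se, J, Q = NA_real_,
                         egger_intercept = NA_real_, intercept_se = NA_real_,
                         outcome = "outcome", flags = "") {
  z <- theta / se
  data.frame(
    method = method, exposure = exposure, outcome = outcome,
    theta = theta, se = se,
    ci_low = theta - stats::qnorm(0.975) * se,
    ci_high = theta + stats::qnorm(0.975) * se,
    pvalue = 2 * stats::pnorm(-abs(z)),
    or = exp(theta),
    n_variants = J, Q = Q,
    egger_intercept = egger_intercept, intercept_se = intercept_se,
    flags = flags,
    stringsAsFactors = FALSE
  )
}

## GLS fit of y on X with covariance Omega; returns coef, cov(coef), residual
## chi-square Q. Solved by whitening with the Cholesky factor of Omega.
.gls <- function(X, y, Omega) {
  U <- tryCatch(chol(Omega), error = function(e) {
    stop("singular weight matrix Omega; regularize the LD matrix ",
         "(see ld_matrix ridge)", call. = FALSE)
  })
  Xw <- backsolve(U, X, transpose = TRUE)
  yw <- backsolve(U, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  bread <- tryCatch(solve(XtX), error = function(e) {
    stop("design is rank deficient in GLS fit", call. = FALSE)
  })
  coef <- as.numeric(bread %*% crossprod(Xw, yw))
  resid <- yw - Xw %*% coef
  list(coef = coef, vcov = bread, Q = sum(resid^2))
}

.panel_omega <- function(panel, ld) {
  seY <- panel$seY
  if (is.null(ld)) return(diag(seY^2, length(seY)))
  r <- unclass(ld)
  miss <- setdiff(panel$variant_ids, rownames(r))
  if (length(miss)) {
    stop("LD matrix does not cover variant: ", miss[1L], call. = FALSE)
  }
  r <- r[panel$variant_ids, panel$variant_ids, drop = FALSE]
  outer(seY, seY) * r
}

#' Wald ratio estimate from a single variant
#'
#' @param bx,sex Variant-exposure association and its SE.
#' @param by,sey Variant-outcome association and its SE.
#' @param exposure,outcome Labels.
#' @return A one-row MR estimate data frame (`theta = by/bx`,
#'   `se = |sey/bx|`, first order).
#' @export
wald_ratio <- function(bx, sex, by, sey, exposure = "exposure",
                       outcome = "outcome") {
  if (bx == 0) stop("wald_ratio: bx = 0, ratio undefined", call. = FALSE)
  .mr_estimate("wald", exposure, by / bx, abs(sey / bx), J = 1L,
               outcome = outcome)
}

#' Inverse-variance weighted MR (LD-aware)
#'
#' Generalized weighted least squares of `bY` on a single exposure's `bX`
#' through the origin with weight matrix `Omega^-1`,
#' `Omega = diag(seY) R diag(seY)`. With identity `R` this reproduces the
#' classical IVW estimate `sum(bx by / sey^2) / sum(bx^2 / sey^2)` exactly.
#' Random-effects inflates the SE by `max(1, sqrt(Q/(J-1)))`, `Q` the GLS
#' residual chi-square; the random-effects SE is therefore never below the
#' fixed-effects SE.
#'
#' @param panel A [harmonized_panel()] with K = 1 and outcome attached.
#' @param ld Optional [ld_matrix()]; `NULL` for independent instruments.
#' @param effects `"random"` (default) or `"fixed"`.
#' @return A one-row MR estimate data frame.
#' @export
mr_ivw <- function(panel, ld = NULL, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  stopifnot(inherits(panel, "HarmonizedPanel"), !is.null(panel$bY))
  if (length(panel$exposure_names) != 1L) {
    stop("mr_ivw: panel must have exactly one exposure (use mr_mvmr)",
         call. = FALSE)
  }
  J <- length(panel$variant_ids)
  if (J < 2L && effects == "random") {
    stop("mr_ivw: random effects needs J >= 2", call. = FALSE)
  }
  X <- matrix(panel$bX[, 1L], ncol = 1L)
  fit <- .gls(X, panel$bY, .panel_omega(panel, ld))
  se <- sqrt(fit$vcov[1L, 1L])
  infl <- 1
  if (effects == "random" && J > 1L) infl <- max(1, sqrt(fit$Q / (J - 1)))
  .mr_estimate(paste0("ivw_", effects), panel$exposure_names, fit$coef[1L],
               se * infl, J = J, Q = fit$Q, outcome = panel$outcome_name)
}

#' MR-Egger regression (LD-aware)
#'
#' GLS regression of `bY` on `[1, bX]`: the slope is the causal estimate, the
#' intercept the average directional pleiotropy. Each variant is first
#' oriented so that its exposure association is non-negative (flipping the
#' signs of `bX`, `bY` and the corresponding LD rows), the method's standard
#' convention, required for the intercept to be interpretable.
#' Random-effects scaling uses `max(1, sqrt(Q/(J-2)))`.
#'
#' @inheritParams mr_ivw
#' @return A one-row MR estimate data frame with `egger_intercept` and
#'   `intercept_se` filled in.
#' @export
mr_egger <- function(panel, ld = NULL, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  stopifnot(inherits(panel, "HarmonizedPanel"), !is.null(panel$bY))
  if (length(panel$exposure_names) != 1L) {
    stop("mr_egger: panel must have exactly one exposure", call. = FALSE)
  }
  J <- length(panel$variant_ids)
  if (J < 3L) stop("mr_egger: needs J >= 3 variants", call. = FALSE)
  bx <- panel$bX[, 1L]; by <- panel$bY
  flip <- sign(bx); flip[flip == 0] <- 1
  bx <- bx * flip; by <- by * flip
  Omega <- .panel_omega(panel, ld)
  Omega <- outer(flip, flip) * Omega
  if (stats::var(bx) < 1e-24 * mean(bx)^2 || stats::var(bx) == 0) {
    stop("mr_egger: degenerate design, exposure associations are constant ",
         "(collinear with intercept)", call. = FALSE)
  }
  X <- cbind(1, bx)
  fit <- .gls(X, by, Omega)
  infl <- 1
  if (effects == "random") infl <- max(1, sqrt(fit$Q / (J - 2)))
  .mr_estimate("egger_slope", panel$exposure_names, fit$coef[2L],
               sqrt(fit$vcov[2L, 2L]) * infl, J = J, Q = fit$Q,
               egger_intercept = fit$coef[1L],
               intercept_se = sqrt(fit$vcov[1L, 1L]) * infl,
               outcome = panel$outcome_name)
}

#' Multivariable MR (LD-aware)
#'
#' GLS regression of `bY` on all K exposure columns through the origin:
#' each exposure's estimate is its direct effect conditional on the others.
#' An all-zero exposure column yields `theta = 0` with infinite SE and a
#' `zero_column` flag; other rank deficiency is an error naming the collinear
#' exposure pairs (pairwise |r| > 0.999).
#'
#' @inheritParams mr_ivw
#' @return One MR estimate row per exposure.
#' @export
mr_mvmr <- function(panel, ld = NULL, effects = c("random", "fixed")) {
  effects <- match.arg(effects)
  stopifnot(inherits(panel, "HarmonizedPanel"), !is.null(panel$bY))
  K <- length(panel$exposure_names)
  J <- length(panel$variant_ids)
  if (K == 1L) return(mr_ivw(panel, ld, effects))
  if (J <= K) stop("mr_mvmr: needs more variants than exposures", call. = FALSE)

  zero_cols <- which(colSums(panel$bX^2) == 0)
  use <- setdiff(seq_len(K), zero_cols)
  X <- panel$bX[, use, drop = FALSE]
  if (ncol(X) >= 2L) {
    cc <- stats::cor(X)
    bad <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(bad)) {
      pairs <- apply(bad, 1L, function(ij) {
        paste(panel$exposure_names[use][ij], collapse = " ~ ")
      })
      stop("mr_mvmr: collinear exposures (|r| > 0.999): ",
           paste(pairs, collapse = "; "), call. = FALSE)
    }
  }
  fit <- .gls(X, panel$bY, .panel_omega(panel, ld))
  infl <- 1
  if (effects == "random" && J > ncol(X)) {
    infl <- max(1, sqrt(fit$Q / (J - ncol(X))))
  }
  rows <- lapply(seq_along(use), function(i) {
    .mr_estimate("mvmr", panel$exposure_names[use[i]], fit$coef[i],
                 sqrt(fit$vcov[i, i]) * infl, J = J, Q = fit$Q,
                 outcome = panel$outcome_name)
  })
  if (length(zero_cols)) {
    rows <- c(rows, lapply(zero_cols, function(k) {
      est <- .mr_estimate("mvmr", panel$exposure_names[k], 0, Inf, J = J,
                          Q = fit$Q, outcome = panel$outcome_name,
                          flags = "zero_column")
      est$pvalue <- 1
      est
    }))
  }
  out <- do.call(rbind, rows)
  out[match(panel$exposure_names, out$exposure), , drop = FALSE]
}
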