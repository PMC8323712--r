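## Bayesian model averaging over multivariable MR models.
##
## The outcome associations are inverse-variance standardized (y~ = bY/seY,
## X~ = bX/seY, columns scaled to unit norm) and every non-empty exposure
## subset S up to max_model_size is scored by the closed-form Gaussian
## marginal likelihood of y~ = X~_S theta_S + eps, eps ~ N(0, I),
## theta_S ~ N(0, sigma_prior^2 I). Model priors are independent-inclusion;
## posteriors are normalized over the enumerated models. An exposure's
## marginal inclusion probability (MIP) is the posterior mass of models
## containing it; its model-averaged causal effect (MACE) the
## posterior-weighted posterior-mean effect, back-transformed to per-SD units.

#' MR-BMA configuration
#'
#' @param sigma_prior Prior SD of causal effects on the standardized design,
#'   expressed relative to the Euclidean norm of the standardized outcome
#'   vector (default 0.5, i.e. a one-prior-SD coefficient carries half the
#'   outcome signal). The relative form makes the prior scale-equivariant:
#'   a fully explanatory single exposure has a standardized coefficient of
#'   about `||y||` on unit-norm columns, so an absolute prior SD would be
#'   sample-size dependent.
#' @param prior_inclusion Prior probability that each exposure is causal
#'   (default 0.1, prior mean model size K/10).
#' @param max_model_size Largest exposure subset enumerated (default K, set
#'   at run time).
#' @param n_permutations Permutations for empirical p-values (default 1000).
#' @param seed Integer seed for the permutation procedure.
#' @param cooks_threshold Cook's distance flag threshold; `NULL` means the
#'   conventional 4/J, resolved at run time.
#' @param q_outlier_threshold Flag threshold for a variant's squared
#'   standardized residual (default `qchisq(0.95, 1)`).
#' @return A list of class `BMAConfig`.
#' @export
bma_config <- function(sigma_prior = 0.5, prior_inclusion = 0.1,
                       max_model_size = NULL, n_permutations = 1000L,
                       seed = 1L, cooks_threshold = NULL,
                       q_outlier_threshold = stats::qchisq(0.95, 1)) {
  stopifnot(sigma_prior > 0, prior_inclusion > 0, prior_inclusion < 1,
            n_permutations >= 1)
  structure(
    list(sigma_prior = sigma_prior, prior_inclusion = prior_inclusion,
         max_model_size = max_model_size,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         cooks_threshold = cooks_threshold,
         q_outlier_threshold = q_outlier_threshold),
    class = "BMAConfig"
  )
}

#' Inverse-variance standardization of a panel
#'
#' Returns `y = bY/seY` and `X` with `X[j,k] = bX[j,k]/seY[j]`, each column
#' then scaled to unit Euclidean norm. The scale factors are retained for
#' back-transforming effects to per-SD units.
#'
#' @param panel A [harmonized_panel()] with outcome attached.
#' @return A list `y`, `X`, `scale`, `exposure_names`, `J`.
#' @export
standardize_panel <- function(panel) {
  stopifnot(inherits(panel, "HarmonizedPanel"), !is.null(panel$bY))
  if (any(panel$seY <= 0)) stop("standardize_panel: seY must be > 0", call. = FALSE)
  y <- panel$bY / panel$seY
  X <- panel$bX / panel$seY
  scl <- sqrt(colSums(X^2))
  zero <- which(scl == 0)
  if (length(zero)) {
    stop("standardize_panel: zero-norm exposure column: ",
         paste(panel$exposure_names[zero], collapse = ", "), call. = FALSE)
  }
  X <- sweep(X, 2L, scl, "/")
  colnames(X) <- panel$exposure_names
  list(y = y, X = X, scale = scl, exposure_names = panel$exposure_names,
       J = length(y))
}

## Precomputed cross-products reused across all subset evaluations (and all
## permutations): evidence and posterior means need only X'X, X'y, y'y.
.design_gram <- function(design) {
  list(XtX = crossprod(design$X), Xty = drop(crossprod(design$X, design$y)),
       yty = sum(design$y^2), J = design$J)
}

## log marginal likelihood via the Woodbury/determinant-lemma identities:
## logdet(I_J + s2 X_S X_S') = logdet(I_s + s2 X_S'X_S)
## y'(I_J + s2 X_S X_S')^-1 y = y'y - s2 Xty_S' (I_s + s2 X_S'X_S)^-1 Xty_S
.log_evidence_gram <- function(S, gram, sigma_prior, with_const = TRUE) {
  s2 <- sigma_prior^2
  M <- diag(length(S)) + s2 * gram$XtX[S, S, drop = FALSE]
  ch <- chol(M)
  logdet <- 2 * sum(log(diag(ch)))
  v <- backsolve(ch, backsolve(ch, gram$Xty[S], transpose = TRUE))
  quad <- gram$yty - s2 * sum(gram$Xty[S] * v)
  out <- -0.5 * logdet - 0.5 * quad
  if (with_const) out <- out - gram$J / 2 * log(2 * pi)
  if (!is.finite(out)) stop("model evidence is not finite", call. = FALSE)
  out
}

#' Log marginal likelihood of one exposure subset
#'
#' Closed-form Gaussian evidence of the standardized regression
#' `y ~ N(X_S theta_S, I)` with `theta_S ~ N(0, sigma_prior^2 I)`:
#' `logML = -J/2 log(2 pi) - 1/2 logdet(I + s2 X_S X_S') -
#' 1/2 y'(I + s2 X_S X_S')^-1 y`.
#'
#' @param S Integer or character vector naming the exposures in the model.
#' @param design Output of [standardize_panel()].
#' @param sigma_prior Prior SD of standardized effects.
#' @return The log marginal likelihood (including the normal constant, so it
#'   is directly comparable with numerical quadrature).
#' @export
model_log_evidence <- function(S, design, sigma_prior = 0.5) {
  if (is.character(S)) S <- match(S, design$exposure_names)
  if (!length(S) || anyNA(S)) stop("invalid model subset", call. = FALSE)
  .log_evidence_gram(sort(unique(as.integer(S))), .design_gram(design),
                     sigma_prior)
}

## posterior mean of theta under model S (ridge with penalty 1/s2), on the
## standardized scale
.posterior_mean_gram <- function(S, gram, sigma_prior) {
  M <- gram$XtX[S, S, drop = FALSE] + diag(1 / sigma_prior^2, length(S))
  drop(solve(M, gram$Xty[S]))
}

.enumerate_models <- function(K, max_size) {
  out <- list()
  for (s in seq_len(max_size)) {
    cmb <- utils::combn(K, s)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(i) cmb[, i]))
  }
  out
}

## Effective (absolute) prior SD on the unit-norm design: relative
## sigma_prior times the norm of the standardized outcome vector.
.sigma_eff <- function(gram, config) config$sigma_prior * sqrt(gram$yty)

## Core scoring shared by run_mr_bma and the permutation loop.
.bma_score <- function(gram, K, config, models) {
  logpri <- vapply(models, function(S) {
    length(S) * log(config$prior_inclusion) +
      (K - length(S)) * log(1 - config$prior_inclusion)
  }, numeric(1))
  logml <- vapply(models, .log_evidence_gram, numeric(1), gram = gram,
                  sigma_prior = .sigma_eff(gram, config), with_const = FALSE)
  lp <- logpri + logml
  lp <- lp - max(lp)
  post <- exp(lp) / sum(exp(lp))
  mip <- numeric(K)
  for (i in seq_along(models)) mip[models[[i]]] <- mip[models[[i]]] + post[i]
  list(post = post, mip = mip, logml = logml)
}

#' Run MR-BMA on a harmonized panel
#'
#' Enumerates all non-empty exposure subsets up to `max_model_size`, scores
#' them by prior x marginal likelihood, and reports per-exposure marginal
#' inclusion probabilities and model-averaged causal effects (per-SD units),
#' ordered by descending MIP. Instruments are assumed (approximately)
#' independent; use r^2 < 0.001 pruned panels.
#'
#' @param panel A [harmonized_panel()] with outcome attached.
#' @param config A [bma_config()].
#' @return A list of class `MRBMAResult`: `exposures` (data frame: exposure,
#'   mip, mace, in descending MIP order), `models` (subset, log evidence,
#'   posterior), `posterior_sum` check, `config`.
#' @export
run_mr_bma <- function(panel, config = bma_config()) {
  design <- standardize_panel(panel)
  K <- length(design$exposure_names)
  if (K > 20L) {
    stop("run_mr_bma: K > 20 exposures; restrict max_model_size or reduce ",
         "the exposure set (stochastic model search is out of scope)",
         call. = FALSE)
  }
  max_size <- min(if (is.null(config$max_model_size)) K else config$max_model_size, K)
  models <- .enumerate_models(K, max_size)
  gram <- .design_gram(design)
  sc <- .bma_score(gram, K, config, models)

  mace <- numeric(K)
  sig <- .sigma_eff(gram, config)
  for (i in seq_along(models)) {
    S <- models[[i]]
    th <- .posterior_mean_gram(S, gram, sig) / design$scale[S]
    mace[S] <- mace[S] + sc$post[i] * th
  }

  ord <- order(-sc$mip, design$exposure_names)
  exposures <- data.frame(
    exposure = design$exposure_names[ord],
    mip = sc$mip[ord], mace = mace[ord],
    stringsAsFactors = FALSE
  )
  model_df <- data.frame(
    model = vapply(models, function(S) {
      paste(design$exposure_names[S], collapse = "+")
    }, character(1)),
    size = lengths(models),
    log_evidence = sc$logml,
    posterior = sc$post,
    stringsAsFactors = FALSE
  )
  model_df <- model_df[order(-model_df$posterior), , drop = FALSE]
  rownames(model_df) <- NULL
  structure(
    list(exposures = exposures, models = model_df,
         mip = stats::setNames(sc$mip, design$exposure_names),
         mace = stats::setNames(mace, design$exposure_names),
         posterior_sum = sum(sc$post), config = config),
    class = "MRBMAResult"
  )
}

#' @export
print.MRBMAResult <- function(x, ...) {
  cat("MR-BMA over", nrow(x$models), "models\n")
  print(x$exposures, row.names = FALSE)
  invisible(x)
}

#' Empirical permutation p-values for MR-BMA marginal inclusion probabilities
#'
#' For each permutation the `(bY, seY)` pairs are permuted jointly across
#' variants (breaking the exposure-outcome linkage while preserving the
#' outcome SE structure and the exposure correlation the MIPs condition on),
#' MR-BMA is rerun, and each exposure's permuted MIP recorded. The p-value is
#' `(1 + #{perm MIP >= observed MIP}) / (n_permutations + 1)`; q-values are
#' Benjamini-Hochberg over the K p-values.
#'
#' @param panel A [harmonized_panel()] with outcome attached.
#' @param config A [bma_config()]; `n_permutations` and `seed` are honoured.
#' @param observed Optional precomputed [run_mr_bma()] result for the panel.
#' @return A list: `p` and `q` (named per exposure), `observed_mip`,
#'   `n_permutations`, `seed`.
#' @export
permutation_pvalues <- function(panel, config = bma_config(),
                                observed = NULL) {
  if (config$n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
  if (is.null(observed)) observed <- run_mr_bma(panel, config)
  design <- standardize_panel(panel)
  K <- length(design$exposure_names)
  max_size <- min(if (is.null(config$max_model_size)) K else config$max_model_size, K)
  models <- .enumerate_models(K, max_size)
  obs_mip <- observed$mip[design$exposure_names]

  J <- length(panel$bY)
  count_ge <- numeric(K)
  set.seed(config$seed)
  for (b in seq_len(config$n_permutations)) {
    perm <- sample.int(J)
    y <- panel$bY[perm] / panel$seY[perm]
    X <- panel$bX / panel$seY[perm]
    scl <- sqrt(colSums(X^2))
    X <- sweep(X, 2L, scl, "/")
    gram <- list(XtX = crossprod(X), Xty = drop(crossprod(X, y)),
                 yty = sum(y^2), J = J)
    mip_b <- .bma_score(gram, K, config, models)$mip
    count_ge <- count_ge + (mip_b >= obs_mip - 1e-12)
  }
  p <- (1 + count_ge) / (config$n_permutations + 1)
  names(p) <- design$exposure_names
  q <- bh_fdr(p)
  list(p = p, q = q, observed_mip = obs_mip,
       n_permutations = config$n_permutations, seed = config$seed)
}

#' Nyholt effective number of independent tests
#'
#' `Meff = 1 + (K - 1) (1 - var(lambda)/K)` where `lambda` are the
#' eigenvalues of the trait correlation matrix and `var` is the sample
#' variance. `Meff` equals K for independent traits and 1 when all traits are
#' perfectly correlated. The adjusted significance threshold is `0.05/Meff`;
#' an adjusted p-value is `min(1, p * Meff)`.
#'
#' @param trait_correlation Symmetric K x K correlation matrix of the traits.
#' @param alpha Nominal significance level for the adjusted threshold.
#' @return A list: `meff`, `n_traits`, `adjusted_threshold`, and
#'   `adjust` (a function mapping p to Nyholt-adjusted p).
#' @export
nyholt_meff <- function(trait_correlation, alpha = 0.05) {
  r <- as.matrix(trait_correlation)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8) {
    stop("nyholt_meff: input must be a symmetric correlation matrix",
         call. = FALSE)
  }
  K <- nrow(r)
  lam <- eigen((r + t(r)) / 2, symmetric = TRUE, only.values = TRUE)$values
  meff <- if (K == 1L) 1 else 1 + (K - 1) * (1 - stats::var(lam) / K)
  meff <- min(max(meff, 1), K)
  list(meff = meff, n_traits = K, adjusted_threshold = alpha / meff,
       adjust = function(p) pmin(1, p * meff))
}

#' Influence diagnostics for the top MR-BMA model
#'
#' Per-variant Cook's distance from the weighted (standardized) least-squares
#' fit of the given model, and each variant's squared standardized residual
#' (its contribution to the heterogeneity statistic Q). Variants exceeding
#' `cooks_threshold` (default 4/J) or `q_outlier_threshold` are flagged;
#' a refit excluding flagged variants is the documented sensitivity mode
#' (subset the panel with [panel_subset()] and rerun).
#'
#' @param panel A [harmonized_panel()] with outcome attached.
#' @param model Exposure names (or indices) of the model to diagnose;
#'   defaults to the top-posterior model of a fresh [run_mr_bma()].
#' @param config A [bma_config()] supplying the thresholds.
#' @return Data frame: `variant_id`, `cooks_d`, `q_contribution`,
#'   `flag_cooks`, `flag_q`.
#' @export
influence_diagnostics <- function(panel, model = NULL, config = bma_config()) {
  design <- standardize_panel(panel)
  if (is.null(model)) {
    res <- run_mr_bma(panel, config)
    model <- strsplit(res$models$model[1L], "+", fixed = TRUE)[[1L]]
  }
  S <- if (is.character(model)) match(model, design$exposure_names) else as.integer(model)
  if (anyNA(S)) stop("influence_diagnostics: unknown exposure in model", call. = FALSE)
  J <- design$J
  fit <- stats::lm(design$y ~ 0 + design$X[, S, drop = FALSE])
  cd <- stats::cooks.distance(fit)
  resid2 <- stats::residuals(fit)^2
  cooks_threshold <- if (is.null(config$cooks_threshold)) 4 / J else config$cooks_threshold
  data.frame(
    variant_id = panel$variant_ids,
    cooks_d = as.numeric(cd),
    q_contribution = as.numeric(resid2),
    flag_cooks = as.numeric(cd) > cooks_threshold,
    flag_q = as.numeric(resid2) > config$q_outlier_threshold,
    stringsAsFactors = FALSE
  )
}
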