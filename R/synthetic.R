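## Synthetic GWAS summary statistics with known causal truth.
##
## Summary statistics are simulated directly (no individual-level genotypes).
## Variant-exposure effects follow a sparse factor model B = Lambda Gamma' + E
## so exposure columns are genetically correlated the way lipoprotein traits
## are; the outcome is generated from a sparse causal subset plus optional
## direct (pleiotropic) variant effects.

#' Synthetic-data configuration
#'
#' Defaults emulate a lipoprotein-trait instrument panel: ~150 independent
#' variants, five factor-correlated exposures, one causal exposure, a
#' biobank-scale exposure GWAS (n = 360,000) and a case-control outcome GWAS of
#' 31,307 cases / 211,753 controls (effective n via 4/(1/cases + 1/controls)).
#'
#' @param n_variants Number of instruments J.
#' @param n_exposures Number of exposures K.
#' @param n_latent_factors Number of latent genetic factors F.
#' @param loading_scale SD of a variant's (single) factor loading, in exposure
#'   SD units per allele.
#' @param idio_sd SD of the idiosyncratic per-exposure effect component; this
#'   is what makes correlated exposures statistically distinguishable.
#' @param gamma Optional K x F factor-composition matrix; rows are exposures.
#'   If `NULL` one is drawn (primary factor weight 1, others N(0, 0.3)).
#' @param exposure_names Exposure labels.
#' @param causal_set Names (or indices) of causal exposures.
#' @param theta Causal effect per causal exposure, log-odds per 1 SD.
#' @param outcomes Optional named list of full-length theta vectors, one per
#'   outcome, overriding `causal_set`/`theta` (used to simulate several
#'   outcomes, e.g. PAD-like and CAD-like, from the same genetic effects).
#' @param n_exposure_gwas Exposure GWAS sample size.
#' @param n_outcome_cases,n_outcome_controls Outcome GWAS case/control counts.
#' @param maf_range Range of minor-allele frequencies, within (0, 0.5].
#' @param ld_block_size Variants per LD block (1 = independent panel).
#' @param ld_rho Within-block AR(1) correlation, |rho| < 1.
#' @param noise_mode `"independent"` or `"ld"` (estimation noise with
#'   covariance proportional to LD, for deliberately correlated gene-region
#'   instruments).
#' @param pleiotropy_frac Fraction of variants with a direct outcome effect.
#' @param pleiotropy_mean Mean direct (pleiotropic) effect alpha.
#' @param pleiotropy_sd SD of the direct effect around its mean.
#' @param seed Integer seed; all output is reproducible from it.
#' @return A list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_variants = 150L, n_exposures = 5L,
                             n_latent_factors = 2L,
                             loading_scale = 0.08,
                             idio_sd = 0.3 * loading_scale,
                             gamma = NULL,
                             exposure_names = paste0("exposure", seq_len(n_exposures)),
                             causal_set = exposure_names[min(4L, n_exposures)],
                             theta = 0.25,
                             outcomes = NULL,
                             n_exposure_gwas = 360000L,
                             n_outcome_cases = 31307L,
                             n_outcome_controls = 211753L,
                             maf_range = c(0.05, 0.5),
                             ld_block_size = 1L, ld_rho = 0,
                             noise_mode = c("independent", "ld"),
                             pleiotropy_frac = 0, pleiotropy_mean = 0,
                             pleiotropy_sd = 0, seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(n_variants >= 1, n_exposures >= 1, n_latent_factors >= 1,
            loading_scale > 0, idio_sd >= 0, abs(ld_rho) < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  if (ld_block_size > n_variants) {
    stop("synthetic_config: ld_block_size > n_variants", call. = FALSE)
  }
  if (is.numeric(causal_set)) causal_set <- exposure_names[causal_set]
  if (!all(causal_set %in% exposure_names)) {
    stop("synthetic_config: causal_set must be a subset of the exposures",
         call. = FALSE)
  }
  if (!is.null(gamma)) {
    gamma <- as.matrix(gamma)
    stopifnot(nrow(gamma) == n_exposures, ncol(gamma) == n_latent_factors)
  }
  theta_full <- stats::setNames(numeric(n_exposures), exposure_names)
  theta_full[causal_set] <- rep_len(theta, length(causal_set))
  if (is.null(outcomes)) outcomes <- list(outcome = theta_full)
  outcomes <- lapply(outcomes, function(th) {
    stopifnot(length(th) == n_exposures)
    stats::setNames(as.numeric(th), exposure_names)
  })
  structure(
    list(n_variants = as.integer(n_variants),
         n_exposures = as.integer(n_exposures),
         n_latent_factors = as.integer(n_latent_factors),
         loading_scale = loading_scale, idio_sd = idio_sd, gamma = gamma,
         exposure_names = exposure_names, causal_set = causal_set,
         theta = theta_full, outcomes = outcomes,
         n_exposure_gwas = n_exposure_gwas,
         n_outcome_cases = n_outcome_cases,
         n_outcome_controls = n_outcome_controls,
         maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
         ld_rho = ld_rho, noise_mode = noise_mode,
         pleiotropy_frac = pleiotropy_frac,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         seed = as.integer(seed)),
    class = "SyntheticConfig"
  )
}

#' Preset configurations mirroring the lipoprotein analyses
#'
#' `"major-lipids"`: K = 5 exposures (TC, LDL-C, HDL-C, TG, ApoB) on F = 2
#' latent axes, causal exposure ApoB. `"subfractions"`: K = 10 ApoB-containing
#' particle-concentration traits on F = 3 axes with strong mutual correlation,
#' causal exposure XS.VLDL.P.
#'
#' @param preset `"major-lipids"` or `"subfractions"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [synthetic_config()].
#' @return A `SyntheticConfig`.
#' @export
preset_config <- function(preset = c("major-lipids", "subfractions"),
                          seed = 1L, ...) {
  preset <- match.arg(preset)
  if (preset == "major-lipids") {
    nm <- c("TC", "LDL.C", "HDL.C", "TG", "ApoB")
    gamma <- rbind(
      TC    = c(0.90,  0.30),
      LDL.C = c(0.95,  0.05),
      HDL.C = c(-0.20, 0.90),
      TG    = c(0.50, -0.75),
      ApoB  = c(0.95,  0.15)
    )
    args <- list(n_variants = 150L, n_exposures = 5L, n_latent_factors = 2L,
                 gamma = gamma, exposure_names = nm, causal_set = "ApoB",
                 theta = 0.25, seed = seed)
  } else {
    nm <- c("XXL.VLDL.P", "XL.VLDL.P", "L.VLDL.P", "M.VLDL.P", "S.VLDL.P",
            "XS.VLDL.P", "IDL.P", "L.LDL.P", "M.LDL.P", "S.LDL.P")
    gamma <- rbind(
      XXL.VLDL.P = c(0.90, 0.00, 0.30),
      XL.VLDL.P  = c(0.90, 0.05, 0.30),
      L.VLDL.P   = c(0.85, 0.10, 0.35),
      M.VLDL.P   = c(0.80, 0.15, 0.40),
      S.VLDL.P   = c(0.70, 0.25, 0.45),
      XS.VLDL.P  = c(0.55, 0.40, 0.50),
      IDL.P      = c(0.35, 0.60, 0.50),
      L.LDL.P    = c(0.15, 0.85, 0.45),
      M.LDL.P    = c(0.10, 0.90, 0.40),
      S.LDL.P    = c(0.10, 0.90, 0.35)
    )
    args <- list(n_variants = 150L, n_exposures = 10L, n_latent_factors = 3L,
                 gamma = gamma, exposure_names = nm, causal_set = "XS.VLDL.P",
                 theta = 0.25, seed = seed)
  }
  do.call(synthetic_config, utils::modifyList(args, list(...)))
}

## closed-form GWAS standard error for an additive per-allele effect
.gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

.effective_n <- function(cases, controls) 4 / (1 / cases + 1 / controls)

## block-diagonal AR(1) LD over J variants
.block_ld <- function(ids, block_size, rho) {
  J <- length(ids)
  r <- diag(1, J)
  if (block_size > 1L && rho != 0) {
    starts <- seq(1L, J, by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1L, J)
      idx <- s:e
      r[idx, idx] <- rho^abs(outer(idx, idx, "-"))
    }
  }
  dimnames(r) <- list(ids, ids)
  ld_matrix(r, ids)
}

## correlated noise draw: one N(0, R) vector per block structure
.ld_noise <- function(J, ld) {
  u <- chol(unclass(ld))
  as.numeric(crossprod(u, stats::rnorm(J)))
}

#' Simulate a harmonized GWAS summary-statistic panel with known truth
#'
#' Draws minor-allele frequencies, assigns each variant a latent factor and a
#' loading, builds true exposure effects `B = Lambda Gamma' + E`, generates
#' the true outcome effect of each variant as `sum_k theta_k B[j,k] + alpha_j`
#' (alpha = direct/pleiotropic effects), and adds estimation noise with the
#' closed-form GWAS standard errors `1/sqrt(2 maf (1-maf) n)` (effective n
#' `4/(1/cases + 1/controls)` for the binary outcome). LD is block-diagonal
#' AR(1); with `noise_mode = "ld"` the estimation noise is drawn with
#' covariance proportional to LD, matching deliberately correlated
#' gene-region instruments.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `panel` (a [harmonized_panel()] for the first
#'   outcome), `panels` (one panel per configured outcome), `ld` (an
#'   [ld_matrix()]), and `truth` (class `SyntheticTruth`: `theta`, `alpha`,
#'   `B`, the factor-implied exposure correlation, maf, and the seed).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  J <- config$n_variants; K <- config$n_exposures; F_ <- config$n_latent_factors
  ids <- sprintf("rs%05d", seq_len(J))

  maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
  gamma <- config$gamma
  if (is.null(gamma)) {
    gamma <- matrix(stats::rnorm(K * F_, 0, 0.3), K, F_)
    gamma[cbind(seq_len(K), rep_len(seq_len(F_), K))] <- 1
  }
  fac <- sample.int(F_, J, replace = TRUE)
  lam <- stats::rnorm(J, 0, config$loading_scale)
  E <- matrix(stats::rnorm(J * K, 0, config$idio_sd), J, K)
  B <- matrix(0, J, K)
  for (f in seq_len(F_)) {
    rows <- fac == f
    if (any(rows)) B[rows, ] <- outer(lam[rows], gamma[, f])
  }
  B <- B + E
  colnames(B) <- config$exposure_names

  n_pleio <- round(config$pleiotropy_frac * J)
  alpha <- numeric(J)
  if (n_pleio > 0) {
    idx <- sample.int(J, n_pleio)
    alpha[idx] <- stats::rnorm(n_pleio, config$pleiotropy_mean,
                               config$pleiotropy_sd)
  }

  seX_vec <- .gwas_se(maf, config$n_exposure_gwas)
  n_eff <- .effective_n(config$n_outcome_cases, config$n_outcome_controls)
  seY <- .gwas_se(maf, n_eff)
  seX <- matrix(seX_vec, J, K)

  ld <- .block_ld(ids, config$ld_block_size, config$ld_rho)
  draw_noise <- function() {
    if (config$noise_mode == "ld") .ld_noise(J, ld) else stats::rnorm(J)
  }

  bX <- B + seX * vapply(seq_len(K), function(k) draw_noise(), numeric(J))
  pX <- 2 * stats::pnorm(-abs(bX / seX))
  info <- data.frame(
    chrom = "1", pos = 1000000L + (seq_len(J) - 1L) * 50000L,
    effect_allele = "A", other_allele = "G", eaf = maf,
    stringsAsFactors = FALSE
  )

  panels <- lapply(names(config$outcomes), function(out_nm) {
    th <- config$outcomes[[out_nm]]
    bY_true <- as.numeric(B %*% th) + alpha
    bY <- bY_true + seY * draw_noise()
    harmonized_panel(ids, config$exposure_names, bX, seX, bY, seY,
                     pX = pX, info = info, outcome_name = out_nm)
  })
  names(panels) <- names(config$outcomes)

  ## factor-implied exposure correlation (uniform factor assignment)
  ls2 <- config$loading_scale^2
  covm <- ls2 * (gamma %*% t(gamma)) / F_ + diag(config$idio_sd^2, K)
  implied_cor <- stats::cov2cor(covm)
  dimnames(implied_cor) <- list(config$exposure_names, config$exposure_names)

  truth <- structure(
    list(theta = config$theta, outcomes = config$outcomes, alpha = alpha,
         B = B, exposure_cor = implied_cor, maf = maf, seX = seX_vec,
         seY = seY, seed = config$seed, config = config),
    class = "SyntheticTruth"
  )
  list(panel = panels[[1L]], panels = panels, ld = ld, truth = truth)
}

#' Simulate a TWAS fixture with designed effect genes
#'
#' Generates, per gene, a sparse cis eQTL weight vector over `variants_per_gene`
#' variants with AR(1) LD, plus per-trait GWAS Z-scores constructed so that
#' designated effect genes carry an expression-trait association of mean
#' `effect_size` on the Z scale: the per-variant Z mean is
#' `lambda * R S w / sigma_g`, so the gene-level TWAS statistic is
#' `N(lambda, 1)`; non-effect genes are standard-normal nulls.
#'
#' @param n_genes Number of genes.
#' @param variants_per_gene Cis variants per gene.
#' @param weight_sparsity Fraction of cis variants with nonzero weight.
#' @param effect_genes Named list of gene indices (or `g<k>` names) per trait,
#'   e.g. `list(traitA = 1:7, traitB = c(1, 2, 8))`; a bare vector is treated
#'   as a single trait `traitA`.
#' @param effect_size Mean gene-level association (Z scale) of effect genes.
#' @param ld_rho Within-gene AR(1) LD.
#' @param seed Integer seed.
#' @return A list: `models` (per-gene weight models: `gene`, `variant_ids`,
#'   `weights`, `eaf`, `ld_ref`), `z` (named per-trait vectors of variant
#'   Z-scores), and `truth` (`effect_genes`, `lambda` gene x trait matrix).
#' @export
simulate_twas_fixture <- function(n_genes, variants_per_gene = 5L,
                                  weight_sparsity = 0.6,
                                  effect_genes = list(),
                                  effect_size = 6, ld_rho = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1, variants_per_gene >= 1,
            weight_sparsity > 0, weight_sparsity <= 1)
  if (!is.list(effect_genes)) effect_genes <- list(traitA = effect_genes)
  if (length(effect_genes) && is.null(names(effect_genes))) {
    names(effect_genes) <- paste0("trait", LETTERS[seq_along(effect_genes)])
  }
  traits <- if (length(effect_genes)) names(effect_genes) else "traitA"
  genes <- sprintf("g%03d", seq_len(n_genes))
  effect_idx <- lapply(effect_genes, function(g) {
    if (is.character(g)) g <- match(g, genes)
    if (anyNA(g) || any(g < 1 | g > n_genes)) {
      stop("simulate_twas_fixture: effect_genes outside the gene set",
           call. = FALSE)
    }
    as.integer(g)
  })

  set.seed(seed)
  lambda <- matrix(0, n_genes, length(traits),
                   dimnames = list(genes, traits))
  for (t in seq_along(traits)) {
    tr <- traits[t]
    if (!is.null(effect_idx[[tr]])) {
      sgn <- sample(c(-1, 1), length(effect_idx[[tr]]), replace = TRUE)
      lambda[effect_idx[[tr]], t] <- sgn * effect_size
    }
  }

  models <- vector("list", n_genes)
  z <- lapply(traits, function(t) numeric(0))
  names(z) <- traits
  for (g in seq_len(n_genes)) {
    L <- variants_per_gene
    vids <- sprintf("%s_v%02d", genes[g], seq_len(L))
    eaf <- stats::runif(L, 0.05, 0.5)
    R <- ld_matrix(ld_rho^abs(outer(seq_len(L), seq_len(L), "-")), vids)
    nz <- max(1L, round(weight_sparsity * L))
    w <- numeric(L)
    w[sample.int(L, nz)] <- stats::rnorm(nz)
    if (all(w == 0)) w[1L] <- 1
    S <- sqrt(2 * eaf * (1 - eaf))
    sw <- S * w
    sigma_g <- sqrt(as.numeric(t(sw) %*% unclass(R) %*% sw))
    u <- chol(unclass(R))
    for (t in traits) {
      mu <- as.numeric(unclass(R) %*% sw) * lambda[g, t] / sigma_g
      zg <- mu + as.numeric(crossprod(u, stats::rnorm(L)))
      names(zg) <- vids
      z[[t]] <- c(z[[t]], zg)
    }
    models[[g]] <- twas_weight_model(genes[g], vids, w, eaf, R)
  }
  list(models = models, z = z,
       truth = list(effect_genes = lapply(effect_idx, function(i) genes[i]),
                    lambda = lambda, seed = seed))
}
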