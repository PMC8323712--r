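## Gene-region (drug-target) instrument selection, gene-based MR scaled per
## 1-SD exposure decrease, and the bootstrap ratio-of-effects comparison
## between two outcomes.

#' Define a gene region with flank
#'
#' Coordinates are 1-based inclusive; the instrument window is the closed
#' interval `[max(1, start - flank_bp), end + flank_bp]`.
#'
#' @param gene Gene symbol.
#' @param chrom Chromosome (character).
#' @param start,end Gene coordinates, `start <= end`.
#' @param flank_bp Flank in base pairs (default 200 kb, the conventional
#'   cis-window for drug-target proxies).
#' @return A list of class `GeneRegion` with `window_start`/`window_end`.
#' @export
gene_region <- function(gene, chrom, start, end, flank_bp = 200000L) {
  stopifnot(start <= end, flank_bp >= 0)
  structure(
    list(gene = gene, chrom = as.character(chrom),
         start = as.integer(start), end = as.integer(end),
         flank_bp = as.integer(flank_bp),
         window_start = max(1L, as.integer(start) - as.integer(flank_bp)),
         window_end = as.integer(end) + as.integer(flank_bp)),
    class = "GeneRegion"
  )
}

#' Select gene-region instruments from an exposure GWAS
#'
#' Variants inside the closed flanked window with exposure `p < p_threshold`,
#' greedily pruned at `r^2 < r2_threshold` (via [ld_prune()]). An empty
#' result is a reported (warning), not fatal, outcome.
#'
#' @param exposure A `SummaryStatSet` carrying `chrom`/`pos`/`pvalue`.
#' @param region A [gene_region()].
#' @param ld An [ld_matrix()] covering the region's significant variants.
#' @param p_threshold Exposure significance threshold (default 5e-8).
#' @param r2_threshold Pruning threshold (default 0.1; gene-region
#'   instruments are deliberately allowed to be mildly correlated).
#' @return An instrument-only [harmonized_panel()] (K = 1, no outcome); use
#'   [attach_outcome()] to harmonize an outcome onto it. Empty selection
#'   returns `NULL` with a warning.
#' @export
region_instruments <- function(exposure, region, ld, p_threshold = 5e-8,
                               r2_threshold = 0.1) {
  stopifnot(inherits(exposure, "SummaryStatSet"), inherits(region, "GeneRegion"))
  rec <- exposure$records
  if (is.null(rec$chrom) || is.null(rec$pos) || anyNA(rec$pos)) {
    stop("region_instruments: exposure records need chrom and pos", call. = FALSE)
  }
  inside <- rec$chrom == region$chrom &
    rec$pos >= region$window_start & rec$pos <= region$window_end
  p <- if (!is.null(rec$pvalue)) rec$pvalue else 2 * stats::pnorm(-abs(rec$beta / rec$se))
  sel <- inside & p < p_threshold
  if (!any(sel)) {
    warning("region_instruments: no significant instruments in region ",
            region$gene, call. = FALSE)
    return(NULL)
  }
  sub <- rec[sel, , drop = FALSE]
  panel <- harmonized_panel(
    variant_ids = sub$variant_id, exposure_names = exposure$trait_name,
    bX = matrix(sub$beta, ncol = 1L), seX = matrix(sub$se, ncol = 1L),
    pX = if (!is.null(sub$pvalue)) matrix(sub$pvalue, ncol = 1L) else NULL,
    info = data.frame(chrom = sub$chrom, pos = sub$pos,
                      effect_allele = sub$effect_allele,
                      other_allele = sub$other_allele,
                      eaf = if (!is.null(sub$eaf)) sub$eaf else NA_real_,
                      stringsAsFactors = FALSE)
  )
  ld_prune(panel, ld, r2_threshold)
}

#' Attach an outcome to an instrument-only panel
#'
#' Matches outcome records to the panel's variants, flipping signs where the
#' outcome's alleles are swapped relative to the panel orientation; variants
#' missing from the outcome or with irreconcilable alleles are dropped.
#'
#' @param panel An instrument-only [harmonized_panel()].
#' @param outcome A `SummaryStatSet`.
#' @return The panel with `bY`/`seY` filled in.
#' @export
attach_outcome <- function(panel, outcome) {
  rec <- outcome$records
  m <- match(panel$variant_ids, rec$variant_id)
  keep <- !is.na(m)
  if (!any(keep)) stop("attach_outcome: no shared variants", call. = FALSE)
  panel <- panel_subset(panel, which(keep))
  rec <- rec[m[keep], , drop = FALSE]
  ea <- panel$info$effect_allele; oa <- panel$info$other_allele
  same <- rec$effect_allele == ea & rec$other_allele == oa
  swap <- rec$effect_allele == oa & rec$other_allele == ea
  beta <- ifelse(swap, -rec$beta, rec$beta)
  ok <- same | swap
  if (!any(ok)) stop("attach_outcome: no allele-compatible variants", call. = FALSE)
  panel <- panel_subset(panel, which(ok))
  harmonized_panel(
    panel$variant_ids, panel$exposure_names, panel$bX, panel$seX,
    bY = beta[ok], seY = rec$se[ok], pX = panel$pX, info = panel$info,
    outcome_name = outcome$trait_name
  )
}

#' Gene-based (drug-target) MR across outcomes
#'
#' LD-aware IVW per outcome with the estimate negated to the per-1-SD
#' *decrease* convention (so a protective exposure-lowering effect reports
#' OR < 1); MR-Egger is run as a sensitivity analysis when more than two
#' variants are present, and skipped (with a recorded flag) otherwise.
#' When exactly two outcomes are supplied, the bootstrap
#' [ratio_of_effects()] between the first and second outcome is computed.
#'
#' @param gene Gene label.
#' @param panels Named list of [harmonized_panel()]s, one per outcome, over
#'   the same harmonized variant set.
#' @param ld Optional [ld_matrix()].
#' @param effects `"random"` or `"fixed"` IVW.
#' @param n_boot Bootstrap replicates for the ratio of effects.
#' @param seed Seed for the bootstrap.
#' @return A list of class `GeneTargetResult`: `gene`, `estimates` (IVW and
#'   Egger rows per outcome, per-SD-decrease scale), `ratio`
#'   (a `RatioOfEffects` or `NULL`), `egger_skipped`.
#' @export
gene_based_mr <- function(gene, panels, ld = NULL,
                          effects = c("random", "fixed"),
                          n_boot = 10000L, seed = 1L) {
  effects <- match.arg(effects)
  stopifnot(is.list(panels), length(panels) >= 1)
  if (is.null(names(panels))) names(panels) <- paste0("outcome", seq_along(panels))
  est_rows <- list()
  ivw_by_outcome <- list()
  egger_skipped <- character(0)
  for (nm in names(panels)) {
    p <- panels[[nm]]
    if (is.null(p)) next
    est <- mr_ivw(p, ld, effects)
    est <- .rescale_per_sd_decrease(est)
    est$outcome <- nm
    ivw_by_outcome[[nm]] <- est
    est_rows[[length(est_rows) + 1L]] <- est
    if (length(p$variant_ids) > 2L) {
      eg <- mr_egger(p, ld, effects)
      eg <- .rescale_per_sd_decrease(eg)
      eg$outcome <- nm
      est_rows[[length(est_rows) + 1L]] <- eg
    } else {
      egger_skipped <- c(egger_skipped, nm)
    }
  }
  if (!length(est_rows)) {
    return(structure(list(gene = gene, estimates = NULL, ratio = NULL,
                          egger_skipped = egger_skipped, estimable = FALSE),
                     class = "GeneTargetResult"))
  }
  ratio <- NULL
  if (length(panels) == 2L && length(ivw_by_outcome) == 2L) {
    nms <- names(panels)
    ratio <- ratio_of_effects(ivw_by_outcome[[nms[1L]]],
                              ivw_by_outcome[[nms[2L]]],
                              panels[[nms[1L]]], panels[[nms[2L]]],
                              ld = ld, effects = effects,
                              n_boot = n_boot, seed = seed)
  }
  structure(
    list(gene = gene, estimates = do.call(rbind, est_rows), ratio = ratio,
         egger_skipped = egger_skipped, estimable = TRUE),
    class = "GeneTargetResult"
  )
}

## flip an MR estimate to the per-1-SD-decrease reporting convention
.rescale_per_sd_decrease <- function(est) {
  est$theta <- -est$theta
  ci <- c(-est$ci_high, -est$ci_low)
  est$ci_low <- ci[1L]; est$ci_high <- ci[2L]
  est$or <- exp(est$theta)
  if (!is.na(est$egger_intercept)) est$egger_intercept <- -est$egger_intercept
  est$flags <- paste0(est$flags, ifelse(nzchar(est$flags), ";", ""),
                      "per_sd_decrease")
  est
}

## IVW point estimate only, with a small ridge so bootstrap-duplicated
## variants (r = 1 between copies) keep Omega invertible
.ivw_theta <- function(bx, by, seY, R = NULL, ridge = 1e-6) {
  if (is.null(R)) {
    w <- 1 / seY^2
    return(sum(bx * by * w) / sum(bx^2 * w))
  }
  Omega <- outer(seY, seY) * (R + diag(ridge, nrow(R)))
  U <- chol(Omega)
  xw <- backsolve(U, bx, transpose = TRUE)
  yw <- backsolve(U, by, transpose = TRUE)
  sum(xw * yw) / sum(xw^2)
}

#' Bootstrap ratio of effects between two outcomes
#'
#' Point estimate `theta_A / theta_B` on the log-odds scale, with a
#' percentile 95% CI and two-sided p-value against ratio = 1 from a variant
#' bootstrap: variants are resampled with replacement -- jointly for both
#' outcomes when the panels share the variant set, preserving cross-outcome
#' dependence -- and both IVW fits and their ratio recomputed per replicate.
#' Replicates with `|theta_B|` below `tol` are excluded and counted
#' (a warning is raised above 5% exclusions).
#'
#' @param estA,estB MR estimate rows for outcomes A and B (only `theta` is
#'   used for the point ratio).
#' @param panelA,panelB The panels behind the two estimates; `NULL` panels
#'   give a point estimate without CI.
#' @param ld Optional [ld_matrix()] used in the per-replicate fits.
#' @param effects IVW flavour used in replicates (point estimate only, so
#'   fixed/random coincide).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param tol Exclusion tolerance on `|theta_B|` (log-odds).
#' @return A list of class `RatioOfEffects`: `ratio`, `ci_low`, `ci_high`,
#'   `pvalue`, `n_boot`, `n_excluded`, `seed`.
#' @export
ratio_of_effects <- function(estA, estB, panelA = NULL, panelB = NULL,
                             ld = NULL, effects = "random",
                             n_boot = 10000L, seed = 1L, tol = 1e-4) {
  thA <- if (is.data.frame(estA)) estA$theta else as.numeric(estA)
  thB <- if (is.data.frame(estB)) estB$theta else as.numeric(estB)
  if (abs(thB) < tol) stop("ratio_of_effects: denominator effect ~ 0", call. = FALSE)
  point <- thA / thB
  if (is.null(panelA) || is.null(panelB)) {
    return(structure(list(ratio = point, ci_low = NA_real_, ci_high = NA_real_,
                          pvalue = NA_real_, n_boot = 0L, n_excluded = 0L,
                          seed = seed),
                     class = "RatioOfEffects"))
  }
  shared <- identical(panelA$variant_ids, panelB$variant_ids)
  JA <- length(panelA$variant_ids); JB <- length(panelB$variant_ids)
  RA <- if (is.null(ld)) NULL else
    unclass(ld)[panelA$variant_ids, panelA$variant_ids, drop = FALSE]
  RB <- if (is.null(ld)) NULL else
    unclass(ld)[panelB$variant_ids, panelB$variant_ids, drop = FALSE]

  set.seed(seed)
  ratios <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ia <- sample.int(JA, JA, replace = TRUE)
    ib <- if (shared) ia else sample.int(JB, JB, replace = TRUE)
    tA <- .ivw_theta(panelA$bX[ia, 1L], panelA$bY[ia], panelA$seY[ia],
                     if (is.null(RA)) NULL else RA[ia, ia, drop = FALSE])
    tB <- .ivw_theta(panelB$bX[ib, 1L], panelB$bY[ib], panelB$seY[ib],
                     if (is.null(RB)) NULL else RB[ib, ib, drop = FALSE])
    if (abs(tB) >= tol) ratios[b] <- tA / tB
  }
  ok <- !is.na(ratios)
  n_excl <- sum(!ok)
  if (n_excl > 0.05 * n_boot) {
    warning("ratio_of_effects: ", n_excl, " of ", n_boot,
            " replicates excluded (|theta_B| < ", tol, ")", call. = FALSE)
  }
  r <- ratios[ok]
  ci <- as.numeric(stats::quantile(r, c(0.025, 0.975), type = 1))
  nb <- length(r)
  p_le <- (1 + sum(r <= 1)) / (nb + 1)
  p_ge <- (1 + sum(r >= 1)) / (nb + 1)
  structure(
    list(ratio = point, ci_low = ci[1L], ci_high = ci[2L],
         pvalue = min(1, 2 * min(p_le, p_ge)),
         n_boot = as.integer(n_boot), n_excluded = as.integer(n_excl),
         seed = seed),
    class = "RatioOfEffects"
  )
}

#' @export
print.RatioOfEffects <- function(x, ...) {
  cat(sprintf("ratio of effects %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
              x$ratio, x$ci_low, x$ci_high, x$pvalue))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input validation.
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @return q-values, names preserved.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::setNames(stats::p.adjust(p, method = "BH"), names(pvalues))
}

#' Bundled synthetic drug-target gene annotation
#'
#' Returns the package's bundled annotation of canonical ApoB-pathway
#' drug-target genes with placeholder coordinates on the synthetic genome
#' used by the simulator (real analyses must supply real coordinates).
#'
#' @return Data frame: `gene`, `chrom`, `start`, `end`.
#' @export
synthetic_target_genes <- function() {
  read_gene_annotation(system.file("extdata", "apob_target_genes_synthetic.tsv",
                                   package = "lipidmr", mustWork = TRUE))
}
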