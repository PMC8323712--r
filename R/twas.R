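## Summary-based TWAS: gene-level association Z from eQTL weight models and
## GWAS variant Z-scores, the between-trait differential-effect statistic,
## and shared/unique gene classification.

#' Construct a TWAS weight model
#'
#' Per-gene eQTL weights over cis variants, with the per-variant effect
#' allele frequencies (for the Hardy-Weinberg genotype SD) and the LD
#' reference over the weighted variants.
#'
#' @param gene Gene symbol.
#' @param variant_ids Cis variant ids.
#' @param weights Per-variant expression weights (at least one nonzero).
#' @param eaf Effect-allele frequencies in (0, 1).
#' @param ld_ref An [ld_matrix()] covering all weighted variants.
#' @return A list of class `TwasWeightModel`.
#' @export
twas_weight_model <- function(gene, variant_ids, weights, eaf, ld_ref) {
  stopifnot(length(variant_ids) == length(weights),
            length(eaf) == length(weights))
  if (all(weights == 0)) {
    stop("twas_weight_model: all weights are zero for ", gene, call. = FALSE)
  }
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("twas_weight_model: eaf must be in (0, 1)", call. = FALSE)
  }
  miss <- setdiff(variant_ids, rownames(ld_ref))
  if (length(miss)) {
    stop("twas_weight_model: ld_ref missing variant ", miss[1L], call. = FALSE)
  }
  structure(
    list(gene = gene, variant_ids = as.character(variant_ids),
         weights = as.numeric(weights), eaf = as.numeric(eaf),
         ld_ref = ld_ref),
    class = "TwasWeightModel"
  )
}

#' Read TWAS weight models from delimited text
#'
#' Expects columns `gene`, `variant_id`, `weight`, `eaf`; one LD matrix is
#' supplied per call (global) and subset per gene.
#'
#' @param path Weight table path.
#' @param ld An [ld_matrix()] covering all weighted variants.
#' @return List of [twas_weight_model()]s.
#' @export
read_twas_weights <- function(path, ld) {
  header <- readLines(path, n = 1L)
  sep <- .detect_delim(header)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("gene", "variant_id", "weight", "eaf")
  if (!all(need %in% names(tab))) {
    stop("weights file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(tab, tab$gene), function(g) {
    ids <- g$variant_id
    twas_weight_model(g$gene[1L], ids, g$weight, g$eaf,
                      ld_matrix(unclass(ld)[ids, ids, drop = FALSE], ids))
  })
}

#' Gene-level TWAS association statistic
#'
#' `Z_g = sum_l w_l sigma_l Z_l / sigma_g` with `sigma_l = sqrt(2 eaf_l
#' (1 - eaf_l))` (Hardy-Weinberg genotype SD) and `sigma_g = sqrt(w' S R S w)`,
#' `S = diag(sigma_l)`, `R` the LD reference. Weighted variants missing from
#' the GWAS are dropped with a coverage report; coverage below
#' `min_coverage` flags the result.
#'
#' @param model A [twas_weight_model()].
#' @param gwas_z Named per-variant Z-scores for the trait.
#' @param min_coverage Minimum fraction of weighted variants that must have a
#'   GWAS Z (default 0.5); below it the result is flagged `low_coverage`.
#' @return A one-row data frame: `gene`, `z`, `pvalue`, `effect` (= z),
#'   `se` (= 1), `coverage`, `flag`.
#' @export
twas_z <- function(model, gwas_z, min_coverage = 0.5) {
  stopifnot(inherits(model, "TwasWeightModel"))
  have <- model$variant_ids %in% names(gwas_z)
  coverage <- mean(have[model$weights != 0])
  use <- have & model$weights != 0
  if (!any(use)) stop("twas_z: no weighted variant has a GWAS Z for gene ",
                      model$gene, call. = FALSE)
  ids <- model$variant_ids[use]
  w <- model$weights[use]
  sig <- sqrt(2 * model$eaf[use] * (1 - model$eaf[use]))
  R <- unclass(model$ld_ref)[ids, ids, drop = FALSE]
  sw <- sig * w
  var_g <- as.numeric(t(sw) %*% R %*% sw)
  if (var_g <= 0) stop("twas_z: degenerate model (sigma_g = 0) for gene ",
                       model$gene, call. = FALSE)
  z <- sum(sw * gwas_z[ids]) / sqrt(var_g)
  data.frame(
    gene = model$gene, z = z, pvalue = 2 * stats::pnorm(-abs(z)),
    effect = z, se = 1, coverage = coverage,
    flag = if (coverage < min_coverage) "low_coverage" else "",
    stringsAsFactors = FALSE
  )
}

#' TWAS over many genes
#'
#' @param models List of [twas_weight_model()]s.
#' @param gwas_z Named per-variant Z-scores.
#' @param min_coverage Passed to [twas_z()].
#' @return Data frame with one row per gene plus BH `q_fdr`.
#' @export
twas_scan <- function(models, gwas_z, min_coverage = 0.5) {
  res <- do.call(rbind, lapply(models, twas_z, gwas_z = gwas_z,
                               min_coverage = min_coverage))
  res$q_fdr <- bh_fdr(res$pvalue)
  rownames(res) <- NULL
  res
}

#' Between-trait differential-effect statistic
#'
#' Signed mode: `(effect1 - effect2) / sqrt(se1^2 + se2^2)`; magnitude mode
#' replaces the effects by their absolute values (testing which trait has
#' the larger-magnitude effect). Two-sided normal p-value. Both modes are
#' exposed; reports must name the mode used.
#'
#' @param effect1,se1 Effect and SE for trait 1.
#' @param effect2,se2 Effect and SE for trait 2.
#' @param mode `"signed"` or `"magnitude"`.
#' @param gene Optional gene label.
#' @return A one-row data frame: `gene`, `zdiff`, `pvalue`, `direction`
#'   (which trait has the larger (magnitude-mode: larger-|effect|) effect),
#'   `mode`.
#' @export
zdiff <- function(effect1, se1, effect2, se2,
                  mode = c("signed", "magnitude"), gene = NA_character_) {
  mode <- match.arg(mode)
  if (any(c(se1, se2) <= 0)) stop("zdiff: standard errors must be > 0", call. = FALSE)
  e1 <- if (mode == "magnitude") abs(effect1) else effect1
  e2 <- if (mode == "magnitude") abs(effect2) else effect2
  z <- (e1 - e2) / sqrt(se1^2 + se2^2)
  data.frame(
    gene = gene, zdiff = z, pvalue = 2 * stats::pnorm(-abs(z)),
    direction = ifelse(z > 0, "trait1", ifelse(z < 0, "trait2", "equal")),
    mode = mode, stringsAsFactors = FALSE
  )
}

#' Classify genes as unique to either trait or shared
#'
#' Per-trait FDR (BH over each trait's p-values, computed before
#' classification) at `q_threshold`; genes significant for both traits are
#' shared, genes significant for exactly one are unique to it.
#'
#' @param resultsA,resultsB Data frames from [twas_scan()] (or with columns
#'   `gene`, `pvalue`) over a shared gene universe.
#' @param q_threshold FDR threshold (default 0.05).
#' @return A list: `unique_a`, `unique_b`, `shared` (gene vectors), `counts`.
#' @export
classify_genes <- function(resultsA, resultsB, q_threshold = 0.05) {
  qa <- if ("q_fdr" %in% names(resultsA)) resultsA$q_fdr else bh_fdr(resultsA$pvalue)
  qb <- if ("q_fdr" %in% names(resultsB)) resultsB$q_fdr else bh_fdr(resultsB$pvalue)
  siga <- resultsA$gene[qa < q_threshold]
  sigb <- resultsB$gene[qb < q_threshold]
  shared <- intersect(siga, sigb)
  unique_a <- setdiff(siga, shared)
  unique_b <- setdiff(sigb, shared)
  list(unique_a = unique_a, unique_b = unique_b, shared = shared,
       counts = c(unique_a = length(unique_a), unique_b = length(unique_b),
                  shared = length(shared)))
}

#' Correlation of per-gene effects between two traits
#'
#' Pearson correlation over the common gene set, with the usual
#' normal-approximation p-value.
#'
#' @param resultsA,resultsB Data frames with columns `gene` and `effect`.
#' @return A list: `r`, `pvalue`, `n_genes`.
#' @export
effect_correlation <- function(resultsA, resultsB) {
  common <- intersect(resultsA$gene, resultsB$gene)
  if (length(common) < 3L) {
    stop("effect_correlation: need at least 3 paired genes", call. = FALSE)
  }
  ea <- resultsA$effect[match(common, resultsA$gene)]
  eb <- resultsB$effect[match(common, resultsB$gene)]
  ct <- stats::cor.test(ea, eb, method = "pearson")
  list(r = unname(ct$estimate), pvalue = ct$p.value, n_genes = length(common))
}
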