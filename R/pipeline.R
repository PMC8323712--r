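## End-to-end orchestration: simulate (or load) inputs, prioritize risk
## factors by MR-BMA, run drug-target gene-region MR with the bootstrap
## ratio of effects, the TWAS classification, and a univariable +
## multivariable MR stage for an Lp(a)-style locus-specific exposure.
## Every numeric output is reproducible from (config, seed) alone: the run
## log records a deterministic step counter, not wall-clock time.

#' Pipeline configuration
#'
#' @param preset Synthetic preset for the prioritization stage
#'   (`"major-lipids"` or `"subfractions"`).
#' @param seed Global seed; per-stage child seeds are derived as
#'   `(seed * 10007 + stage_index) mod 2^31-1`.
#' @param out_dir Output directory (created if missing).
#' @param stages Character vector of stages to run, in pipeline order, among
#'   `"prioritize"`, `"drug_target"`, `"twas"`, `"lpa"`.
#' @param n_permutations Permutations for the MR-BMA empirical p-values.
#' @param correction `"perm-fdr"` (BH over permutation p) or `"nyholt"`.
#' @param sigma_prior,prior_inclusion MR-BMA prior hyperparameters.
#' @param n_boot Bootstrap replicates for ratios of effects.
#' @param drug_variants_per_gene Simulated instruments per gene region.
#' @param drug_ld_rho Within-region AR(1) LD for the drug-target stage.
#' @param twas_n_genes Genes in the TWAS stage.
#' @param zdiff_mode `"signed"` or `"magnitude"`.
#' @param q_threshold FDR threshold for TWAS classification.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(preset = "major-lipids", seed = 1L,
                            out_dir = tempfile("lipidmr_run_"),
                            stages = c("prioritize", "drug_target", "twas", "lpa"),
                            n_permutations = 200L,
                            correction = c("perm-fdr", "nyholt"),
                            sigma_prior = 0.5, prior_inclusion = 0.1,
                            n_boot = 2000L,
                            drug_variants_per_gene = 8L, drug_ld_rho = 0.4,
                            twas_n_genes = 50L,
                            zdiff_mode = c("signed", "magnitude"),
                            q_threshold = 0.05) {
  correction <- match.arg(correction)
  zdiff_mode <- match.arg(zdiff_mode)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(
    list(preset = preset, seed = as.integer(seed), out_dir = out_dir,
         stages = stages, n_permutations = as.integer(n_permutations),
         correction = correction, sigma_prior = sigma_prior,
         prior_inclusion = prior_inclusion, n_boot = as.integer(n_boot),
         drug_variants_per_gene = as.integer(drug_variants_per_gene),
         drug_ld_rho = drug_ld_rho, twas_n_genes = as.integer(twas_n_genes),
         zdiff_mode = zdiff_mode, q_threshold = q_threshold),
    class = "PipelineConfig"
  )
}

#' Derive a per-stage child seed from the global seed
#'
#' @param seed Global integer seed.
#' @param stage_index Stage position (1-based).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage_index) {
  as.integer((as.double(seed) * 10007 + stage_index) %% 2147483647)
}

## structured run log, parseable by tests; `step` replaces wall-clock time so
## reruns at the same seed are byte-identical
.logger <- function() {
  rows <- list()
  list(
    add = function(stage, event, detail = "", count = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        step = length(rows) + 1L, stage = stage, event = event,
        detail = detail, count = count, stringsAsFactors = FALSE)
    },
    table = function() {
      if (length(rows)) do.call(rbind, rows) else
        data.frame(step = integer(), stage = character(), event = character(),
                   detail = character(), count = integer())
    }
  )
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Simulate drug-target gene-region summary data
#'
#' Builds, for each annotated gene, a set of cis instruments with AR(1) LD
#' (`rho`), genome-wide-significant exposure (ApoB-like) associations, and
#' two binary outcomes generated from per-SD causal effects `theta_outcomes`
#' with LD-correlated estimation noise. Default outcome effects are
#' `-log(0.87)` (PAD-like) and `-log(0.66)` (CAD-like) per 1 SD exposure
#' increase -- i.e. true per-1-SD-decrease odds ratios of 0.87 and 0.66 and
#' a true CAD/PAD ratio of effects of log(0.66)/log(0.87) = 2.98.
#'
#' @param genes Data frame (`gene`, `chrom`, `start`, `end`), e.g.
#'   [synthetic_target_genes()].
#' @param variants_per_gene Instruments simulated per region.
#' @param rho Within-region AR(1) LD.
#' @param theta_outcomes Named per-outcome causal effect (log-odds per SD).
#' @param n_exposure_gwas Exposure GWAS sample size (NMR-scale default).
#' @param n_cases,n_controls Outcome GWAS counts.
#' @param seed Integer seed.
#' @return A list: `exposure` (`SummaryStatSet`), `outcomes` (list of
#'   `SummaryStatSet`), `ld` (block-diagonal [ld_matrix()]), `genes`,
#'   `truth`.
#' @export
simulate_drug_target_data <- function(genes,
                                      variants_per_gene = 8L, rho = 0.4,
                                      theta_outcomes = c(PAD = -log(0.87),
                                                         CAD = -log(0.66)),
                                      n_exposure_gwas = 24925L,
                                      n_cases = 31307L, n_controls = 211753L,
                                      seed = 1L) {
  set.seed(seed)
  n_eff <- .effective_n(n_cases, n_controls)
  rows <- list(); out_rows <- lapply(theta_outcomes, function(...) list())
  ld_blocks <- list()
  for (g in seq_len(nrow(genes))) {
    L <- variants_per_gene
    ids <- sprintf("%s_v%02d", tolower(genes$gene[g]), seq_len(L))
    pos <- as.integer(round(seq(genes$start[g], genes$end[g], length.out = L)))
    maf <- stats::runif(L, 0.1, 0.5)
    R <- rho^abs(outer(seq_len(L), seq_len(L), "-"))
    dimnames(R) <- list(ids, ids)
    ld_blocks[[g]] <- R
    u <- chol(R)
    ## true exposure effects: LD-smeared signal, large enough to reach
    ## genome-wide significance at the NMR-scale exposure GWAS
    b_true <- as.numeric(R %*% (sample(c(-1, 1), 1) *
                                  stats::runif(L, 0.06, 0.12)))
    seX <- .gwas_se(maf, n_exposure_gwas)
    bx <- b_true + seX * as.numeric(crossprod(u, stats::rnorm(L)))
    rows[[g]] <- data.frame(
      variant_id = ids, chrom = genes$chrom[g], pos = pos,
      effect_allele = "A", other_allele = "G", eaf = maf,
      beta = bx, se = seX, pvalue = 2 * stats::pnorm(-abs(bx / seX)),
      n = n_exposure_gwas, stringsAsFactors = FALSE)
    seY <- .gwas_se(maf, n_eff)
    for (o in names(theta_outcomes)) {
      by <- theta_outcomes[[o]] * b_true +
        seY * as.numeric(crossprod(u, stats::rnorm(L)))
      out_rows[[o]][[g]] <- data.frame(
        variant_id = ids, chrom = genes$chrom[g], pos = pos,
        effect_allele = "A", other_allele = "G", eaf = maf,
        beta = by, se = seY, pvalue = 2 * stats::pnorm(-abs(by / seY)),
        n = n_cases + n_controls, stringsAsFactors = FALSE)
    }
  }
  exp_rec <- do.call(rbind, rows)
  all_ids <- exp_rec$variant_id
  Rall <- diag(1, length(all_ids))
  dimnames(Rall) <- list(all_ids, all_ids)
  at <- 1L
  for (g in seq_along(ld_blocks)) {
    L <- nrow(ld_blocks[[g]])
    Rall[at:(at + L - 1L), at:(at + L - 1L)] <- ld_blocks[[g]]
    at <- at + L
  }
  list(
    exposure = summary_stat_set("ApoB", "quantitative", exp_rec),
    outcomes = lapply(stats::setNames(names(theta_outcomes),
                                      names(theta_outcomes)), function(o) {
      summary_stat_set(o, "binary", do.call(rbind, out_rows[[o]]))
    }),
    ld = ld_matrix(Rall, all_ids),
    genes = genes,
    truth = list(theta_outcomes = theta_outcomes,
                 ratio = if (length(theta_outcomes) >= 2L)
                   theta_outcomes[[2L]] / theta_outcomes[[1L]] else NA_real_,
                 seed = seed)
  )
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on synthetic inputs generated from
#' the configured preset and seed, writing one delimited table per stage, a
#' structured run log and a key-value summary file to `out_dir`. Reruns with
#' the same config produce byte-identical outputs.
#'
#' @param config A [pipeline_config()], or a path to a YAML file of its
#'   fields.
#' @return Invisibly, a list with the per-stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- .logger()
  results <- list()
  summary_lines <- c(
    paste0("seed\t", config$seed),
    paste0("preset\t", config$preset)
  )
  all_stages <- c("prioritize", "drug_target", "twas", "lpa")

  for (stage in config$stages) {
    idx <- match(stage, all_stages)
    sseed <- stage_seed(config$seed, idx)
    res <- tryCatch(
      switch(stage,
        prioritize = .stage_prioritize(config, sseed, log),
        drug_target = .stage_drug_target(config, sseed, log),
        twas = .stage_twas(config, sseed, log),
        lpa = .stage_lpa(config, sseed, log)
      ),
      error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }
    )
    results[[stage]] <- res
    summary_lines <- c(summary_lines, res$summary)
  }

  .write_tsv(log$table(), file.path(config$out_dir, "run_log.tsv"))
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))
  invisible(c(results, list(out_dir = config$out_dir, config = config)))
}

.stage_prioritize <- function(config, sseed, log) {
  log$add("prioritize", "start", config$preset)
  sim <- simulate_panel(preset_config(config$preset, seed = sseed))
  panel <- sim$panel
  log$add("prioritize", "simulated_variants", count = length(panel$variant_ids))
  bc <- bma_config(sigma_prior = config$sigma_prior,
                   prior_inclusion = config$prior_inclusion,
                   n_permutations = config$n_permutations, seed = sseed)
  bma <- run_mr_bma(panel, bc)
  perm <- permutation_pvalues(panel, bc, observed = bma)
  p_unc <- perm$p[bma$exposures$exposure]
  if (config$correction == "nyholt") {
    ny <- nyholt_meff(sim$truth$exposure_cor)
    p_cor <- ny$adjust(p_unc)
    meff <- ny$meff
  } else {
    p_cor <- perm$q[bma$exposures$exposure]
    meff <- NA_real_
  }
  p_cor <- pmax(p_cor, p_unc) # corrected p can never undercut uncorrected
  tab <- data.frame(
    exposure = bma$exposures$exposure,
    MIP = bma$exposures$mip,
    MACE = bma$exposures$mace,
    p_uncorrected = as.numeric(p_unc),
    p_corrected = as.numeric(p_cor),
    correction = config$correction,
    stringsAsFactors = FALSE
  )
  .write_tsv(tab, file.path(config$out_dir, "prioritize.tsv"))
  log$add("prioritize", "done", tab$exposure[1L], count = nrow(tab))
  list(table = tab, bma = bma, perm = perm, truth = sim$truth,
       nyholt_meff = meff,
       summary = c(
         paste0("prioritize.top_exposure\t", tab$exposure[1L]),
         paste0("prioritize.top_mip\t", format(tab$MIP[1L], digits = 15)),
         paste0("prioritize.true_causal\t",
                paste(sim$truth$config$causal_set, collapse = ","))
       ))
}

.stage_drug_target <- function(config, sseed, log) {
  log$add("drug_target", "start")
  genes <- synthetic_target_genes()
  dat <- simulate_drug_target_data(
    genes, variants_per_gene = config$drug_variants_per_gene,
    rho = config$drug_ld_rho, seed = sseed)
  out_names <- names(dat$outcomes)
  rows <- list(); pooled_panels <- stats::setNames(vector("list", 2), out_names)
  gene_results <- list()
  for (g in seq_len(nrow(genes))) {
    region <- gene_region(genes$gene[g], genes$chrom[g], genes$start[g],
                          genes$end[g], flank_bp = 0L)
    inst <- region_instruments(dat$exposure, region, dat$ld,
                               r2_threshold = 0.1)
    if (is.null(inst)) {
      log$add("drug_target", "no_instruments", genes$gene[g], count = 0L)
      next
    }
    panels <- lapply(dat$outcomes, function(o) attach_outcome(inst, o))
    ## ratio reported as second/first outcome (e.g. CAD/PAD), the
    ## stronger-vs-weaker convention
    gt <- gene_based_mr(genes$gene[g], panels[rev(out_names)], ld = dat$ld,
                        n_boot = config$n_boot,
                        seed = stage_seed(sseed, g))
    gene_results[[genes$gene[g]]] <- gt
    ivw <- gt$estimates[gt$estimates$method != "egger_slope", , drop = FALSE]
    a <- ivw[ivw$outcome == out_names[1L], ]; b <- ivw[ivw$outcome == out_names[2L], ]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = genes$gene[g], J = a$n_variants,
      or_a = a$or, or_a_low = exp(a$ci_low), or_a_high = exp(a$ci_high),
      or_b = b$or, or_b_low = exp(b$ci_low), or_b_high = exp(b$ci_high),
      p_a = a$pvalue,
      ratio = gt$ratio$ratio, ratio_low = gt$ratio$ci_low,
      ratio_high = gt$ratio$ci_high, ratio_p = gt$ratio$pvalue,
      stringsAsFactors = FALSE)
    for (nm in out_names) {
      pooled_panels[[nm]] <- c(pooled_panels[[nm]], list(panels[[nm]]))
    }
    log$add("drug_target", "gene_done", genes$gene[g],
            count = a$n_variants)
  }
  tab <- do.call(rbind, rows)
  tab$q <- bh_fdr(tab$p_a)

  ## polygenic row: all gene-region instruments pooled
  pool <- lapply(pooled_panels, .rbind_panels)
  poly <- gene_based_mr("Polygenic Targets", pool[rev(out_names)], ld = dat$ld,
                        n_boot = config$n_boot, seed = stage_seed(sseed, 999L))
  ivw <- poly$estimates[poly$estimates$method != "egger_slope", , drop = FALSE]
  a <- ivw[ivw$outcome == out_names[1L], ]; b <- ivw[ivw$outcome == out_names[2L], ]
  tab <- rbind(tab, data.frame(
    gene = "Polygenic Targets", J = a$n_variants,
    or_a = a$or, or_a_low = exp(a$ci_low), or_a_high = exp(a$ci_high),
    or_b = b$or, or_b_low = exp(b$ci_low), or_b_high = exp(b$ci_high),
    p_a = a$pvalue, ratio = poly$ratio$ratio, ratio_low = poly$ratio$ci_low,
    ratio_high = poly$ratio$ci_high, ratio_p = poly$ratio$pvalue,
    q = NA_real_, stringsAsFactors = FALSE))
  names(tab) <- sub("^or_a", paste0("or_", out_names[1L]), names(tab))
  names(tab) <- sub("^or_b", paste0("or_", out_names[2L]), names(tab))
  names(tab) <- sub("^p_a$", paste0("p_", out_names[1L]), names(tab))
  .write_tsv(tab, file.path(config$out_dir, "drug_target.tsv"))
  log$add("drug_target", "done", count = nrow(tab))
  list(table = tab, genes = gene_results, polygenic = poly,
       truth = dat$truth,
       summary = c(
         paste0("drug_target.polygenic_or_", out_names[1L], "\t",
                format(a$or, digits = 15)),
         paste0("drug_target.polygenic_or_", out_names[2L], "\t",
                format(b$or, digits = 15)),
         paste0("drug_target.polygenic_ratio\t",
                format(poly$ratio$ratio, digits = 15))
       ))
}

## concatenate instrument panels over disjoint variant sets
.rbind_panels <- function(panels) {
  harmonized_panel(
    variant_ids = unlist(lapply(panels, `[[`, "variant_ids")),
    exposure_names = panels[[1L]]$exposure_names,
    bX = do.call(rbind, lapply(panels, `[[`, "bX")),
    seX = do.call(rbind, lapply(panels, `[[`, "seX")),
    bY = unlist(lapply(panels, `[[`, "bY")),
    seY = unlist(lapply(panels, `[[`, "seY")),
    pX = if (!is.null(panels[[1L]]$pX))
      do.call(rbind, lapply(panels, `[[`, "pX")) else NULL,
    info = do.call(rbind, lapply(panels, `[[`, "info")),
    outcome_name = panels[[1L]]$outcome_name
  )
}

.stage_twas <- function(config, sseed, log) {
  log$add("twas", "start", count = config$twas_n_genes)
  n <- config$twas_n_genes
  if (n < 10L) stop("twas stage needs at least 10 genes", call. = FALSE)
  fx <- simulate_twas_fixture(
    n_genes = n,
    effect_genes = list(traitA = c(1:5, 9:10), traitB = c(6:8, 9:10)),
    effect_size = 6, seed = sseed)
  resA <- twas_scan(fx$models, fx$z$traitA)
  resB <- twas_scan(fx$models, fx$z$traitB)
  zd <- do.call(rbind, lapply(seq_len(nrow(resA)), function(i) {
    zdiff(resA$effect[i], resA$se[i], resB$effect[i], resB$se[i],
          mode = config$zdiff_mode, gene = resA$gene[i])
  }))
  cls <- classify_genes(resA, resB, q_threshold = config$q_threshold)
  tab <- data.frame(
    gene = resA$gene,
    z_a = resA$z, q_a = resA$q_fdr, z_b = resB$z, q_b = resB$q_fdr,
    zdiff = zd$zdiff, zdiff_p = zd$pvalue, zdiff_mode = zd$mode,
    stringsAsFactors = FALSE)
  .write_tsv(tab, file.path(config$out_dir, "twas.tsv"))
  corr <- effect_correlation(resA, resB)
  log$add("twas", "done", count = nrow(tab))
  list(table = tab, classification = cls, correlation = corr, truth = fx$truth,
       summary = c(
         paste0("twas.unique_a\t", cls$counts[["unique_a"]]),
         paste0("twas.unique_b\t", cls$counts[["unique_b"]]),
         paste0("twas.shared\t", cls$counts[["shared"]])
       ))
}

.stage_lpa <- function(config, sseed, log) {
  log$add("lpa", "start")
  cfg <- synthetic_config(
    n_variants = 40L, n_exposures = 2L, n_latent_factors = 2L,
    gamma = rbind(Lpa = c(1, 0), ApoB = c(0, 1)),
    exposure_names = c("Lpa", "ApoB"),
    causal_set = c("Lpa", "ApoB"), theta = c(0.30, 0.14),
    loading_scale = 0.15, idio_sd = 0.01, seed = sseed)
  sim <- simulate_panel(cfg)
  ## Lp(a)-significant instruments only, then univariable IVW and
  ## multivariable MR adjusting for the ApoB association of the same variants
  inst <- select_instruments(sim$panel, 5e-8, exposures = "Lpa")
  uni <- mr_ivw(panel_keep_exposures(inst, "Lpa"))
  mv <- mr_mvmr(inst)
  tab <- rbind(uni, mv)
  .write_tsv(tab, file.path(config$out_dir, "lpa.tsv"))
  log$add("lpa", "done", count = nrow(tab))
  lpa_mv <- mv[mv$exposure == "Lpa", ]
  list(table = tab, truth = sim$truth,
       summary = c(
         paste0("lpa.univariable_or\t", format(uni$or, digits = 15)),
         paste0("lpa.multivariable_or\t", format(lpa_mv$or, digits = 15))
       ))
}

#' Restrict a panel to a subset of exposures
#'
#' @param panel A [harmonized_panel()].
#' @param exposures Exposure names to keep.
#' @return The panel with only those exposure columns.
#' @export
panel_keep_exposures <- function(panel, exposures) {
  k <- match(exposures, panel$exposure_names)
  if (anyNA(k)) stop("unknown exposure(s): ",
                     paste(exposures[is.na(k)], collapse = ", "), call. = FALSE)
  harmonized_panel(
    panel$variant_ids, panel$exposure_names[k],
    panel$bX[, k, drop = FALSE], panel$seX[, k, drop = FALSE],
    bY = panel$bY, seY = panel$seY,
    pX = if (!is.null(panel$pX)) panel$pX[, k, drop = FALSE] else NULL,
    info = panel$info, alignment_log = panel$alignment_log,
    outcome_name = panel$outcome_name
  )
}
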