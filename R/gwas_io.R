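## Default column names understood by read_summary_stats(). Users override any
## of these through `column_map`.
.default_columns <- c(
  variant_id = "variant_id", chrom = "chrom", pos = "pos",
  effect_allele = "effect_allele", other_allele = "other_allele",
  eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue", n = "n"
)

.required_columns <- c("variant_id", "effect_allele", "other_allele", "beta", "se")

.valid_alleles <- c("A", "C", "G", "T")

#' Construct a summary-statistic set
#'
#' A `SummaryStatSet` bundles per-variant GWAS associations (`beta`, `se`,
#' optionally `eaf`, `pvalue`, `n`, coordinates) for one trait. Effects are on
#' the standard-deviation scale for quantitative traits and the log-odds scale
#' for binary traits.
#'
#' @param trait_name Character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param records Data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `chrom`, `pos`, `eaf`,
#'   `pvalue`, `n`.
#' @return An object of class `SummaryStatSet`.
#' @export
summary_stat_set <- function(trait_name, trait_type = c("quantitative", "binary"),
                             records) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.required_columns, names(records))
  if (length(missing_cols)) {
    stop("summary_stat_set: missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$variant_id)) {
    dup <- records$variant_id[duplicated(records$variant_id)][1L]
    stop("duplicate variant_id in '", trait_name, "': ", dup, call. = FALSE)
  }
  if (any(records$se <= 0)) stop("summary_stat_set: all se must be > 0", call. = FALSE)
  bad_eaf <- !is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1)
  if (!is.null(records$eaf) && any(bad_eaf)) {
    stop("summary_stat_set: eaf must be in (0,1) or NA", call. = FALSE)
  }
  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         records = as.data.frame(records, stringsAsFactors = FALSE)),
    class = "SummaryStatSet"
  )
}

#' @export
print.SummaryStatSet <- function(x, ...) {
  cat("SummaryStatSet:", x$trait_name, sprintf("(%s)", x$trait_type), "\n")
  cat("  variants:", nrow(x$records), "\n")
  invisible(x)
}

.detect_delim <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a header-ed table of per-variant associations. The delimiter
#' (tab, comma, or whitespace) is auto-detected from the header line.
#' Rows with non-positive standard errors or with alleles that are not a
#' single base in A/C/G/T (indels, multi-allelic codes) are dropped and
#' counted in the load report attached as `attr(x, "load_report")`.
#'
#' @param path Path to the file.
#' @param column_map Named character vector/list mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's column names. Unmapped names
#'   fall back to the canonical defaults.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_name Trait label; defaults to the file base name.
#' @return A [summary_stat_set()] with a `load_report` attribute
#'   (`n_input`, `n_dropped`, `reasons`).
#' @export
read_summary_stats <- function(path, column_map = list(),
                               trait_type = c("quantitative", "binary"),
                               trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty table: ", path, call. = FALSE)
  sep <- .detect_delim(header)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!nrow(tab)) stop("empty table: ", path, call. = FALSE)

  cmap <- .default_columns
  if (length(column_map)) {
    column_map <- unlist(column_map)
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown)) {
      stop("unknown column_map keys: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    cmap[names(column_map)] <- column_map
  }
  missing_req <- .required_columns[!cmap[.required_columns] %in% names(tab)]
  if (length(missing_req)) {
    stop("missing required column(s): ",
         paste(cmap[missing_req], collapse = ", "), call. = FALSE)
  }

  take <- function(canon) {
    col <- cmap[[canon]]
    if (col %in% names(tab)) tab[[col]] else NULL
  }
  rec <- data.frame(
    variant_id = as.character(take("variant_id")),
    effect_allele = toupper(as.character(take("effect_allele"))),
    other_allele = toupper(as.character(take("other_allele"))),
    beta = as.numeric(take("beta")),
    se = as.numeric(take("se")),
    stringsAsFactors = FALSE
  )
  for (opt in c("chrom", "pos", "eaf", "pvalue", "n")) {
    v <- take(opt)
    if (!is.null(v)) rec[[opt]] <- if (opt == "chrom") as.character(v) else as.numeric(v)
  }

  n_input <- nrow(rec)
  bad_allele <- !(rec$effect_allele %in% .valid_alleles) |
    !(rec$other_allele %in% .valid_alleles) |
    rec$effect_allele == rec$other_allele
  bad_se <- is.na(rec$se) | rec$se <= 0
  bad_beta <- is.na(rec$beta)
  drop <- bad_allele | bad_se | bad_beta
  reasons <- c(invalid_allele = sum(bad_allele),
               nonpositive_se = sum(bad_se & !bad_allele),
               missing_beta = sum(bad_beta & !bad_allele & !bad_se))
  rec <- rec[!drop, , drop = FALSE]
  if (!nrow(rec)) stop("empty table after filtering: ", path, call. = FALSE)
  if (anyDuplicated(rec$variant_id)) {
    dup <- rec$variant_id[duplicated(rec$variant_id)][1L]
    stop("duplicate variant_id: ", dup, call. = FALSE)
  }
  rownames(rec) <- NULL
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  out <- summary_stat_set(trait_name, trait_type, rec)
  attr(out, "load_report") <- list(n_input = n_input,
                                   n_dropped = as.integer(sum(drop)),
                                   reasons = reasons)
  out
}

## ---------------------------------------------------------------------------
## LD matrices

#' Construct (and regularize) an LD correlation matrix
#'
#' Validates symmetry, unit diagonal and entry range, then guarantees
#' positive semi-definiteness: if the smallest eigenvalue is below `1e-8`, a
#' ridge is added to the diagonal (starting at `1e-8` and doubling until the
#' matrix is PSD) and the result is rescaled back to a correlation matrix.
#' The applied ridge is recorded in `attr(x, "ridge")`.
#'
#' @param r Square numeric matrix of pairwise correlations.
#' @param variant_ids Variant identifiers; defaults to `rownames(r)`.
#' @return A matrix of class `LDMatrix` with `dimnames` set to the ids.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(variant_ids)) stop("LD matrix needs variant ids", call. = FALSE)
  if (length(variant_ids) != nrow(r)) stop("variant_ids length mismatch", call. = FALSE)
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix must be symmetric", call. = FALSE)
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-6) stop("LD matrix must have unit diagonal", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8)) stop("LD entries must be in [-1, 1]", call. = FALSE)
  ridge <- 0
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < 1e-8) {
    eps <- 1e-8
    while (TRUE) {
      r2 <- r + diag(eps, nrow(r))
      if (min(eigen(r2, symmetric = TRUE, only.values = TRUE)$values) >= 1e-8) break
      eps <- eps * 2
    }
    ridge <- eps
    r <- stats::cov2cor(r2)
  }
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(r, class = c("LDMatrix", "matrix"), ridge = ridge)
}

#' Read an LD matrix from delimited text
#'
#' Accepts either a square matrix with a header row of variant ids, or a
#' long-format triplet table with columns `id1`, `id2`, `r` (missing pairs
#' default to 0, the diagonal to 1).
#'
#' @param path Path to the file.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- .detect_delim(header)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) == 3L && all(c("id1", "id2") %in% names(tab))) {
    ids <- unique(c(tab$id1, tab$id2))
    r <- diag(1, length(ids))
    dimnames(r) <- list(ids, ids)
    for (i in seq_len(nrow(tab))) {
      r[tab$id1[i], tab$id2[i]] <- tab[[3L]][i]
      r[tab$id2[i], tab$id1[i]] <- tab[[3L]][i]
    }
    ld_matrix(r, ids)
  } else {
    m <- as.matrix(tab)
    ids <- colnames(tab)
    rownames(m) <- ids
    ld_matrix(m, ids)
  }
}

#' Read gene annotation
#'
#' Four-column delimited text: `gene`, `chrom`, `start`, `end`
#' (1-based inclusive coordinates).
#'
#' @param path Path to the annotation file.
#' @return Data frame with character `gene`/`chrom` and integer `start`/`end`.
#' @export
read_gene_annotation <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- .detect_delim(header)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("gene annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$chrom <- as.character(tab$chrom)
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  if (any(tab$start > tab$end)) stop("gene annotation: start > end", call. = FALSE)
  tab
}

## ---------------------------------------------------------------------------
## HarmonizedPanel

#' Construct a harmonized panel
#'
#' The container every MR estimator consumes: a J x K matrix of
#' variant-exposure associations (`bX`, `seX`), the variant-outcome vector
#' (`bY`, `seY`), all expressed on the same effect allele per variant.
#' An instrument-only panel (outcome not yet attached) has `bY = NULL`.
#'
#' @param variant_ids Character vector of J variant ids.
#' @param exposure_names Character vector of K exposure names.
#' @param bX,seX J x K matrices of exposure betas and standard errors.
#' @param bY,seY Length-J outcome beta and standard error vectors, or `NULL`.
#' @param pX Optional J x K matrix of exposure p-values.
#' @param info Optional per-variant data frame (`chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`).
#' @param alignment_log Optional data frame of harmonization actions.
#' @param outcome_name Outcome label.
#' @return An object of class `HarmonizedPanel`.
#' @export
harmonized_panel <- function(variant_ids, exposure_names, bX, seX,
                             bY = NULL, seY = NULL, pX = NULL, info = NULL,
                             alignment_log = NULL, outcome_name = "outcome") {
  bX <- as.matrix(bX); seX <- as.matrix(seX)
  J <- length(variant_ids); K <- length(exposure_names)
  stopifnot(J >= 1, K >= 1, nrow(bX) == J, ncol(bX) == K,
            all(dim(seX) == dim(bX)))
  if (any(seX <= 0)) stop("harmonized_panel: all seX must be > 0", call. = FALSE)
  if (!is.null(bY)) {
    stopifnot(length(bY) == J, length(seY) == J)
    if (any(seY <= 0)) stop("harmonized_panel: all seY must be > 0", call. = FALSE)
  }
  dimnames(bX) <- list(variant_ids, exposure_names)
  dimnames(seX) <- dimnames(bX)
  if (!is.null(pX)) {
    pX <- as.matrix(pX); dimnames(pX) <- dimnames(bX)
  }
  structure(
    list(variant_ids = as.character(variant_ids),
         exposure_names = as.character(exposure_names),
         bX = bX, seX = seX, bY = bY, seY = seY, pX = pX,
         info = info, alignment_log = alignment_log,
         outcome_name = outcome_name),
    class = "HarmonizedPanel"
  )
}

#' @export
print.HarmonizedPanel <- function(x, ...) {
  cat("HarmonizedPanel:", length(x$variant_ids), "variants x",
      length(x$exposure_names), "exposures\n")
  cat("  exposures:", paste(x$exposure_names, collapse = ", "), "\n")
  cat("  outcome:", if (is.null(x$bY)) "<not attached>" else x$outcome_name, "\n")
  invisible(x)
}

#' @export
dim.HarmonizedPanel <- function(x) c(length(x$variant_ids), length(x$exposure_names))

#' Subset a panel by variant index or id
#'
#' @param panel A [harmonized_panel()].
#' @param i Integer/logical index or character variant ids.
#' @return The panel restricted to the selected variants, order as given.
#' @export
panel_subset <- function(panel, i) {
  if (is.character(i)) i <- match(i, panel$variant_ids)
  if (anyNA(i)) stop("panel_subset: unknown variant", call. = FALSE)
  harmonized_panel(
    variant_ids = panel$variant_ids[i],
    exposure_names = panel$exposure_names,
    bX = panel$bX[i, , drop = FALSE],
    seX = panel$seX[i, , drop = FALSE],
    bY = if (!is.null(panel$bY)) panel$bY[i] else NULL,
    seY = if (!is.null(panel$seY)) panel$seY[i] else NULL,
    pX = if (!is.null(panel$pX)) panel$pX[i, , drop = FALSE] else NULL,
    info = if (!is.null(panel$info)) panel$info[i, , drop = FALSE] else NULL,
    alignment_log = panel$alignment_log,
    outcome_name = panel$outcome_name
  )
}

.is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize exposure and outcome summary statistics onto shared alleles
#'
#' Takes the intersection of variant ids across all sets and expresses every
#' trait's effect on the first exposure's effect allele. Where a source's
#' effect/other alleles are swapped relative to the reference, its beta sign
#' is flipped and its eaf replaced by `1 - eaf`. Strand-ambiguous (A/T, C/G)
#' variants are dropped when `drop_palindromic = TRUE`; otherwise they are
#' kept only when the reference and source eafs lie on the same side of 0.5
#' and both are farther than `eaf_threshold` from 0.5. Variants with
#' irreconcilable alleles are dropped. Every flip/drop is recorded in the
#' returned panel's `alignment_log`.
#'
#' @param exposures A `SummaryStatSet` or list of them (first one is the
#'   allele reference).
#' @param outcome A `SummaryStatSet` for the outcome.
#' @param drop_palindromic Drop strand-ambiguous variants outright (default).
#' @param eaf_threshold Minimum distance of eaf from 0.5 used to resolve
#'   palindromic variants when `drop_palindromic = FALSE`.
#' @return A [harmonized_panel()].
#' @export
harmonize <- function(exposures, outcome, drop_palindromic = TRUE,
                      eaf_threshold = 0.08) {
  if (inherits(exposures, "SummaryStatSet")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "SummaryStatSet"))
  sets <- c(exposures, list(outcome))
  ids <- Reduce(intersect, lapply(sets, function(s) s$records$variant_id))
  if (!length(ids)) stop("harmonize: no shared variants", call. = FALSE)

  ref <- exposures[[1L]]$records
  ref <- ref[match(ids, ref$variant_id), , drop = FALSE]
  J <- length(ids); K <- length(exposures)
  exposure_names <- vapply(exposures, function(s) s$trait_name, character(1))

  log_rows <- list()
  log_add <- function(id, trait, action, reason) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      variant_id = id, trait = trait, action = action, reason = reason,
      stringsAsFactors = FALSE)
  }

  keep <- rep(TRUE, J)
  pal <- .is_palindromic(ref$effect_allele, ref$other_allele)

  ## per-set aligned records
  aligned <- vector("list", length(sets))
  for (s in seq_along(sets)) {
    rec <- sets[[s]]$records
    rec <- rec[match(ids, rec$variant_id), , drop = FALSE]
    trait <- sets[[s]]$trait_name
    same <- rec$effect_allele == ref$effect_allele &
      rec$other_allele == ref$other_allele
    swap <- rec$effect_allele == ref$other_allele &
      rec$other_allele == ref$effect_allele
    mism <- !(same | swap)
    if (any(swap)) {
      rec$beta[swap] <- -rec$beta[swap]
      if (!is.null(rec$eaf)) rec$eaf[swap] <- 1 - rec$eaf[swap]
      tmp <- rec$effect_allele[swap]
      rec$effect_allele[swap] <- rec$other_allele[swap]
      rec$other_allele[swap] <- tmp
      for (id in ids[swap]) log_add(id, trait, "flip", "allele swap")
    }
    if (any(mism)) {
      keep[mism] <- FALSE
      for (id in ids[mism]) log_add(id, trait, "drop", "allele mismatch")
    }
    aligned[[s]] <- rec
  }

  ## palindromic handling on the reference orientation
  if (any(pal)) {
    if (drop_palindromic) {
      for (id in ids[pal & keep]) log_add(id, "*", "drop", "palindromic")
      keep[pal] <- FALSE
    } else {
      for (j in which(pal & keep)) {
        eafs <- vapply(aligned, function(r) {
          if (is.null(r$eaf)) NA_real_ else r$eaf[j]
        }, numeric(1))
        ok <- !anyNA(eafs) &&
          (all(eafs < 0.5) || all(eafs > 0.5)) &&
          all(abs(eafs - 0.5) > eaf_threshold)
        if (ok) {
          log_add(ids[j], "*", "keep", "palindromic resolved by eaf")
        } else {
          log_add(ids[j], "*", "drop", "palindromic unresolvable")
          keep[j] <- FALSE
        }
      }
    }
  }

  if (!any(keep)) stop("harmonize: no variants survive harmonization", call. = FALSE)
  idx <- which(keep)
  bX <- sapply(aligned[seq_len(K)], function(r) r$beta[idx])
  seX <- sapply(aligned[seq_len(K)], function(r) r$se[idx])
  bX <- matrix(bX, ncol = K); seX <- matrix(seX, ncol = K)
  pX <- NULL
  if (all(vapply(aligned[seq_len(K)], function(r) !is.null(r$pvalue), logical(1)))) {
    pX <- matrix(sapply(aligned[seq_len(K)], function(r) r$pvalue[idx]), ncol = K)
  }
  out_rec <- aligned[[K + 1L]]
  info <- data.frame(
    chrom = if (!is.null(ref$chrom)) ref$chrom[idx] else NA_character_,
    pos = if (!is.null(ref$pos)) ref$pos[idx] else NA_integer_,
    effect_allele = ref$effect_allele[idx],
    other_allele = ref$other_allele[idx],
    eaf = if (!is.null(ref$eaf)) ref$eaf[idx] else NA_real_,
    stringsAsFactors = FALSE
  )
  alignment_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(variant_id = character(), trait = character(),
               action = character(), reason = character(),
               stringsAsFactors = FALSE)
  harmonized_panel(
    variant_ids = ids[idx], exposure_names = exposure_names,
    bX = bX, seX = seX,
    bY = out_rec$beta[idx], seY = out_rec$se[idx],
    pX = pX, info = info, alignment_log = alignment_log,
    outcome_name = outcome$trait_name
  )
}

.panel_pvalues <- function(panel) {
  if (!is.null(panel$pX)) return(panel$pX)
  2 * stats::pnorm(-abs(panel$bX / panel$seX))
}

#' Select genome-wide significant instruments
#'
#' Retains variants whose minimum exposure p-value across the selection rule's
#' trait set falls below `p_threshold`; input order is preserved.
#'
#' @param panel A [harmonized_panel()].
#' @param p_threshold Significance threshold (default genome-wide, 5e-8).
#' @param exposures `NULL` for the any-exposure rule, or names of the
#'   exposures whose p-values drive selection.
#' @return The filtered panel.
#' @export
select_instruments <- function(panel, p_threshold = 5e-8, exposures = NULL) {
  p <- .panel_pvalues(panel)
  if (is.null(exposures)) {
    cols <- seq_along(panel$exposure_names)
  } else {
    cols <- match(exposures, panel$exposure_names)
    if (anyNA(cols)) {
      stop("select_instruments: unknown exposure(s): ",
           paste(exposures[is.na(cols)], collapse = ", "), call. = FALSE)
    }
  }
  pmin_row <- apply(p[, cols, drop = FALSE], 1L, min)
  panel_subset(panel, which(pmin_row < p_threshold))
}

#' Greedy LD pruning
#'
#' Iterates variants in ascending order of their minimum exposure p-value
#' (ties broken by variant id) and keeps a variant iff its squared
#' correlation with every previously kept variant is below `r2_threshold`.
#' The returned panel preserves the input row order of the survivors.
#'
#' @param panel A [harmonized_panel()].
#' @param ld An [ld_matrix()] covering all panel variants.
#' @param r2_threshold Squared-correlation threshold (e.g. 0.001 for
#'   independent instruments, 0.1 for gene-region sets).
#' @return The pruned panel.
#' @export
ld_prune <- function(panel, ld, r2_threshold) {
  miss <- setdiff(panel$variant_ids, rownames(ld))
  if (length(miss)) {
    stop("ld_prune: variant absent from LD matrix: ", miss[1L], call. = FALSE)
  }
  p <- .panel_pvalues(panel)
  pmin_row <- apply(p, 1L, min)
  ord <- order(pmin_row, panel$variant_ids)
  r <- unclass(ld)[panel$variant_ids, panel$variant_ids, drop = FALSE]
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(r[j, kept]^2 < r2_threshold)) kept <- c(kept, j)
  }
  panel_subset(panel, sort(kept))
}

#' Write a harmonized panel as a delimited table
#'
#' One row per variant; columns `beta_<exposure>`/`se_<exposure>` per
#' exposure plus `beta_outcome`/`se_outcome`.
#'
#' @param panel A [harmonized_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- data.frame(variant_id = panel$variant_ids, stringsAsFactors = FALSE)
  if (!is.null(panel$info)) df <- cbind(df, panel$info)
  for (k in seq_along(panel$exposure_names)) {
    nm <- panel$exposure_names[k]
    df[[paste0("beta_", nm)]] <- panel$bX[, k]
    df[[paste0("se_", nm)]] <- panel$seX[, k]
  }
  if (!is.null(panel$bY)) {
    df$beta_outcome <- panel$bY
    df$se_outcome <- panel$seY
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a harmonized panel written by [write_panel()]
#'
#' @param path Path to the delimited panel table.
#' @return A [harmonized_panel()].
#' @export
read_panel <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- .detect_delim(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  beta_cols <- grep("^beta_", names(df), value = TRUE)
  exposures <- sub("^beta_", "", setdiff(beta_cols, "beta_outcome"))
  if (!length(exposures)) stop("read_panel: no exposure columns", call. = FALSE)
  bX <- as.matrix(df[paste0("beta_", exposures)])
  seX <- as.matrix(df[paste0("se_", exposures)])
  info_cols <- intersect(c("chrom", "pos", "effect_allele", "other_allele", "eaf"),
                         names(df))
  harmonized_panel(
    variant_ids = df$variant_id, exposure_names = exposures,
    bX = bX, seX = seX,
    bY = if ("beta_outcome" %in% names(df)) df$beta_outcome else NULL,
    seY = if ("se_outcome" %in% names(df)) df$se_outcome else NULL,
    info = if (length(info_cols)) df[info_cols] else NULL
  )
}
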