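# Reading, harmonization, instrument selection and LD pruning.

write_tmp <- function(df, sep = "\t") {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

test_that("read_summary_stats parses, filters and reports drops", {
  df <- toy_records(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                    se = c(0.01, 0.02, 0.01), eaf = c(0.2, 0.3, 0.4))
  s <- read_summary_stats(write_tmp(df), trait_name = "LDL")
  expect_s3_class(s, "SummaryStatSet")
  expect_equal(nrow(s$records), 3L)
  expect_equal(attr(s, "load_report")$n_dropped, 0L)

  # non-positive SE and indel alleles are dropped and counted
  df2 <- df
  df2$se[2] <- 0
  df2$effect_allele[3] <- "AT"
  s2 <- read_summary_stats(write_tmp(df2))
  expect_equal(nrow(s2$records), 1L)
  expect_equal(attr(s2, "load_report")$n_dropped, 2L)

  # comma-delimited autodetection
  s3 <- read_summary_stats(write_tmp(df, sep = ","))
  expect_equal(s3$records$beta, df$beta)

  # duplicated id is an error naming the id
  df4 <- rbind(df, df[1, ])
  expect_error(read_summary_stats(write_tmp(df4)), "rs1")

  # missing required column is a configuration error
  expect_error(read_summary_stats(write_tmp(df[, -4])), "beta")

  # column_map remaps nonstandard headers
  df5 <- df
  names(df5)[names(df5) == "beta"] <- "Effect"
  s5 <- read_summary_stats(write_tmp(df5), column_map = c(beta = "Effect"))
  expect_equal(s5$records$beta, df$beta)
})

test_that("harmonize flips swapped alleles and drops mismatches", {
  exp1 <- toy_set("X", beta = c(0.2, 0.1, 0.3), se = rep(0.01, 3),
                  ids = c("rs1", "rs2", "rs3"),
                  ea = c("A", "A", "A"), oa = c("G", "G", "G"))
  out <- summary_stat_set("Y", "binary", toy_records(
    c("rs1", "rs2", "rs3"), beta = c(0.1, 0.05, 0.2), se = rep(0.02, 3),
    ea = c("G", "A", "A"), oa = c("A", "G", "C")))
  p <- harmonize(exp1, out)
  # rs1 outcome was on the other allele: sign flipped
  expect_equal(p$bY[p$variant_ids == "rs1"], -0.1)
  expect_equal(p$bY[p$variant_ids == "rs2"], 0.05)
  # rs3 alleles A/G vs A/C are irreconcilable
  expect_false("rs3" %in% p$variant_ids)
  log3 <- p$alignment_log[p$alignment_log$variant_id == "rs3", ]
  expect_true(any(grepl("allele mismatch", log3$reason)))
})

test_that("palindromic variants follow the eaf resolution rule", {
  mk <- function(eaf_exp, eaf_out, drop_palindromic, threshold = 0.08) {
    e <- toy_set("X", beta = c(0.2, 0.1), se = c(0.01, 0.01),
                 ids = c("rs2", "rs9"), ea = c("A", "A"), oa = c("T", "G"),
                 eaf = c(eaf_exp, 0.3))
    o <- summary_stat_set("Y", "binary", toy_records(
      c("rs2", "rs9"), beta = c(0.1, 0.1), se = c(0.02, 0.02),
      ea = c("A", "A"), oa = c("T", "G"), eaf = c(eaf_out, 0.3)))
    harmonize(e, o, drop_palindromic = drop_palindromic,
              eaf_threshold = threshold)
  }
  # default: dropped outright
  expect_false("rs2" %in% mk(0.10, 0.12, TRUE)$variant_ids)
  # both eafs far from 0.5 on the same side: retained, aligned by frequency
  expect_true("rs2" %in% mk(0.10, 0.12, FALSE)$variant_ids)
  # opposite sides of 0.5: dropped
  expect_false("rs2" %in% mk(0.10, 0.88, FALSE)$variant_ids)
  # too close to 0.5: dropped
  expect_false("rs2" %in% mk(0.46, 0.48, FALSE)$variant_ids)
})

test_that("harmonization is idempotent and sign-consistent", {
  set.seed(42)
  J <- 20
  ids <- sprintf("rs%02d", 1:J)
  ea <- sample(c("A", "C"), J, TRUE)
  oa <- ifelse(ea == "A", "G", "T")
  e1 <- toy_set("X1", beta = rnorm(J, 0, 0.1), se = runif(J, 0.005, 0.02),
                ids = ids, ea = ea, oa = oa, eaf = runif(J, 0.1, 0.45))
  e2 <- toy_set("X2", beta = rnorm(J, 0, 0.1), se = runif(J, 0.005, 0.02),
                ids = ids, ea = ea, oa = oa, eaf = runif(J, 0.1, 0.45))
  out <- summary_stat_set("Y", "binary", toy_records(
    ids, beta = rnorm(J, 0, 0.05), se = runif(J, 0.01, 0.05),
    ea = ea, oa = oa, eaf = runif(J, 0.1, 0.45)))
  p1 <- harmonize(list(e1, e2), out)

  # idempotence: rebuild sets from the harmonized panel and re-harmonize
  rebuild <- function(k) {
    toy_set(p1$exposure_names[k], beta = p1$bX[, k], se = p1$seX[, k],
            ids = p1$variant_ids, ea = p1$info$effect_allele,
            oa = p1$info$other_allele, eaf = p1$info$eaf)
  }
  out2 <- summary_stat_set("Y", "binary", toy_records(
    p1$variant_ids, beta = p1$bY, se = p1$seY,
    ea = p1$info$effect_allele, oa = p1$info$other_allele,
    eaf = p1$info$eaf))
  p2 <- harmonize(list(rebuild(1), rebuild(2)), out2)
  expect_equal(p2$bX, p1$bX)
  expect_equal(p2$bY, p1$bY)

  # sign consistency: flipping both alleles and the beta sign of one input
  # leaves the panel numerically identical
  r2 <- e2$records
  r2$beta <- -r2$beta
  r2$eaf <- 1 - r2$eaf
  tmp <- r2$effect_allele
  r2$effect_allele <- r2$other_allele
  r2$other_allele <- tmp
  e2f <- summary_stat_set("X2", "quantitative", r2)
  p3 <- harmonize(list(e1, e2f), out)
  expect_equal(p3$bX, p1$bX)
  expect_equal(p3$bY, p1$bY)
})

test_that("select_instruments applies the min-p rule over the trait set", {
  set.seed(7)
  panel <- rand_panel(5, seed = 7, K = 2)
  panel$pX <- matrix(c(4e-9, 6e-8, 1e-10, 0.5, 0.2,
                       0.9, 0.9, 0.9, 3e-9, 0.7), ncol = 2)
  kept <- select_instruments(panel, 5e-8)
  expect_equal(length(kept$variant_ids), 3L) # rs001, rs003, rs004
  expect_true(all(c("rs001", "rs003", "rs004") %in% kept$variant_ids))
  # named-exposure rule restricted to X1
  kept1 <- select_instruments(panel, 5e-8, exposures = "X1")
  expect_equal(length(kept1$variant_ids), 2L)
  # threshold 1.0 returns the input unchanged
  all_kept <- select_instruments(panel, 1.0)
  expect_equal(all_kept$variant_ids, panel$variant_ids)
  expect_equal(all_kept$bX, panel$bX)
  # unknown exposure in the rule is a configuration error
  expect_error(select_instruments(panel, 5e-8, exposures = "nope"), "nope")
})

test_that("ld_prune matches a hand-traced greedy pass and yields an independent set", {
  # 4 variants; p-value order rs2 < rs1 < rs3 < rs4
  panel <- toy_panel(bx = c(0.10, 0.12, 0.08, 0.07), by = rep(0, 4),
                     ids = paste0("rs", 1:4))
  panel$pX <- matrix(c(1e-6, 1e-8, 1e-5, 1e-4), ncol = 1)
  r <- diag(4)
  r2 <- matrix(c(
    1, 0.30, 0.05, 0.08,
    0.30, 1, 0.20, 0.05,
    0.05, 0.20, 1, 0.09,
    0.08, 0.05, 0.09, 1), 4, 4) # these are r^2 values
  r <- sqrt(r2)
  ld <- ld_matrix(r, paste0("rs", 1:4))
  # hand trace at threshold 0.1: keep rs2; rs1 excluded (r2 .30); rs3 excluded
  # (r2 .20 with rs2); rs4 kept (r2 .05 with rs2)
  pruned <- ld_prune(panel, ld, 0.1)
  expect_equal(sort(pruned$variant_ids), c("rs2", "rs4"))
  rr <- unclass(ld)[pruned$variant_ids, pruned$variant_ids]
  expect_true(max(rr[upper.tri(rr)]^2) < 0.1)

  # two correlated variants: only the smaller-p one survives
  p2 <- toy_panel(bx = c(0.1, 0.1), by = c(0, 0), ids = c("rsA", "rsB"))
  p2$pX <- matrix(c(1e-4, 1e-9), ncol = 1)
  ld2 <- ld_matrix(matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2), c("rsA", "rsB"))
  expect_equal(ld_prune(p2, ld2, 0.1)$variant_ids, "rsB")

  # identity LD keeps everything
  ld_id <- ld_matrix(diag(4), paste0("rs", 1:4))
  expect_equal(ld_prune(panel, ld_id, 0.01)$variant_ids, panel$variant_ids)

  # missing variant is a data error naming it
  expect_error(ld_prune(panel, ld2, 0.1), "rs1")
})

test_that("ld_matrix regularizes indefinite input and records the ridge", {
  ids <- c("a", "b", "c")
  r <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.9, -0.99, 0.9, 1), 3, 3)
  expect_true(min(eigen(r, symmetric = TRUE)$values) < 0)
  ld <- ld_matrix(r, ids)
  expect_gt(attr(ld, "ridge"), 0)
  expect_true(min(eigen(unclass(ld), symmetric = TRUE)$values) >= 0)
  expect_equal(unname(diag(unclass(ld))), rep(1, 3))
  expect_error(ld_matrix(matrix(c(1, 0.5, 0.2, 1), 2), c("a", "b")),
               "symmetric")
})

test_that("panel round-trips through write_panel/read_panel", {
  p <- rand_panel(8, seed = 3, K = 2)
  f <- tempfile(fileext = ".tsv")
  write_panel(p, f)
  q <- read_panel(f)
  expect_equal(q$variant_ids, p$variant_ids)
  expect_equal(unname(q$bX), unname(p$bX), tolerance = 1e-12)
  expect_equal(q$bY, p$bY, tolerance = 1e-12)
})
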