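# Bayesian model averaging: standardization, evidence against quadrature,
# posterior bookkeeping, permutation p-values, Nyholt, diagnostics.

test_that("standardize_panel weights by seY and normalizes columns", {
  p <- rand_panel(3, seed = 1, K = 2)
  p$seY <- rep(1, 3)
  d <- standardize_panel(p)
  expect_equal(d$y, p$bY)
  expect_equal(unname(colSums(d$X^2)), c(1, 1), tolerance = 1e-12)
  # pre-scaling a column leaves the standardized column unchanged
  p2 <- p; p2$bX[, 1] <- p$bX[, 1] * 10; p2$seX[, 1] <- p$seX[, 1] * 10
  expect_equal(standardize_panel(p2)$X, d$X, tolerance = 1e-12)
  # zero-norm column is an error naming the exposure
  p3 <- p; p3$bX[, 2] <- 0
  expect_error(standardize_panel(p3), "X2")
})

test_that("model evidence matches 1-D quadrature for K = 1", {
  for (i in 1:20) {
    p <- rand_panel(10, seed = 400 + i)
    d <- standardize_panel(p)
    sigma <- runif(1, 0.3, 3)
    expect_equal(model_log_evidence(1, d, sigma),
                 evidence_quadrature(d$y, d$X[, 1], sigma),
                 tolerance = 1e-6)
  }
})

test_that("evidence limits and symmetries hold", {
  p <- rand_panel(12, seed = 50, K = 2)
  p$bX[, 2] <- p$bX[, 1]; p$seX[, 2] <- p$seX[, 1]
  d <- standardize_panel(p)
  # identical columns give identical single-exposure evidences
  expect_equal(model_log_evidence(1, d), model_log_evidence(2, d),
               tolerance = 1e-12)
  # prior collapse: sigma -> 0 sends all model evidences to the null
  # log-likelihood, so differences vanish
  e1 <- model_log_evidence(1, d, 1e-8)
  e2 <- model_log_evidence(c(1, 2), d, 1e-8)
  expect_lt(abs(e1 - e2), 1e-6)
  # improving the single-exposure fit never decreases the evidence
  th <- sum(d$X[, 1] * d$y)
  evs <- sapply(seq(0, 1, 0.25), function(w) {
    dd <- d; dd$y <- (1 - w) * d$y + w * d$X[, 1] * th
    model_log_evidence(1, dd, 0.5)
  })
  expect_true(all(diff(evs) > -1e-8))
})

test_that("run_mr_bma normalizes posteriors and respects symmetry and order", {
  sim <- simulate_panel(preset_config("major-lipids", seed = 3))
  res <- run_mr_bma(sim$panel)
  expect_equal(res$posterior_sum, 1, tolerance = 1e-10)
  expect_true(all(res$mip >= 0 & res$mip <= 1))
  # column order invariance: permute exposures, results permute identically
  perm <- c(3, 1, 5, 2, 4)
  p2 <- panel_keep_exposures(sim$panel, sim$panel$exposure_names[perm])
  res2 <- run_mr_bma(p2)
  expect_equal(res2$mip[names(res$mip)], res$mip, tolerance = 1e-10)
  expect_equal(res2$exposures$exposure, res$exposures$exposure)

  # duplicated exposure columns share their MIP exactly
  pd <- sim$panel
  pd$bX[, 2] <- pd$bX[, 5]; pd$seX[, 2] <- pd$seX[, 5]
  resd <- run_mr_bma(pd)
  expect_equal(unname(resd$mip[2]), unname(resd$mip[5]), tolerance = 1e-10)
})

test_that("MR-BMA separates a causal exposure from pure noise", {
  cfg <- synthetic_config(n_variants = 100, n_exposures = 2,
                          gamma = rbind(c(1, 0), c(0, 1)),
                          causal_set = "exposure1", theta = 0.3, seed = 17)
  sim <- simulate_panel(cfg)
  res <- run_mr_bma(sim$panel)
  expect_gt(res$mip["exposure1"], res$mip["exposure2"])
  expect_equal(res$exposures$exposure[1], "exposure1")
  # MACE of the causal exposure lands near the true effect
  expect_lt(abs(res$mace["exposure1"] - 0.3), 0.1)
})

test_that("max_model_size caps enumeration and K > 20 errors", {
  sim <- simulate_panel(preset_config("major-lipids", seed = 3))
  res <- run_mr_bma(sim$panel, bma_config(max_model_size = 2))
  expect_true(all(res$models$size <= 2))
  expect_equal(nrow(res$models), 5 + 10)
  big <- harmonized_panel(sprintf("v%d", 1:30), paste0("E", 1:21),
                          matrix(rnorm(30 * 21), 30), matrix(0.01, 30, 21),
                          bY = rnorm(30), seY = rep(0.01, 30))
  expect_error(run_mr_bma(big), "K > 20")
})

test_that("permutation p-values are seeded, bounded and extreme when MIP = 1", {
  # exact proportionality bY = c bX1 with ||y|| just past evidence
  # saturation: the observed MIP is 1 and no permutation can reach it
  set.seed(33)
  J <- 50
  bx1 <- rnorm(J)
  panel <- harmonized_panel(
    sprintf("v%02d", 1:J), c("exposure1", "exposure2"),
    bX = cbind(bx1, rnorm(J)), seX = matrix(0.01, J, 2),
    bY = bx1 / sqrt(sum(bx1^2)) * 10, seY = rep(1, J))
  bc <- bma_config(n_permutations = 99, seed = 101)
  obs <- run_mr_bma(panel, bc)
  expect_equal(unname(obs$mip["exposure1"]), 1, tolerance = 1e-12)
  pp <- permutation_pvalues(panel, bc, observed = obs)
  expect_true(all(pp$p >= 1 / 100 & pp$p <= 1))
  expect_equal(unname(pp$p["exposure1"]), 1 / 100)
  # reproducible under the same seed
  pp2 <- permutation_pvalues(panel, bc)
  expect_identical(pp$p, pp2$p)
  # q-values are BH over the exposure p-values
  expect_equal(unname(pp$q), unname(bh_fdr(pp$p)))
})

test_that("Nyholt effective tests match canonical closed forms", {
  expect_equal(nyholt_meff(diag(10))$meff, 10)
  ones <- matrix(1, 10, 10)
  expect_equal(nyholt_meff(ones)$meff, 1)
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  # eigenvalues {2, 0.5, 0.5}: sample variance 0.75, Meff = 1 + 2 * 0.75
  expect_equal(nyholt_meff(r)$meff, 2.5, tolerance = 1e-12)
  ny <- nyholt_meff(r)
  expect_equal(ny$adjusted_threshold, 0.05 / 2.5)
  expect_equal(ny$adjust(0.02), 0.05)
  expect_equal(ny$adjust(0.9), 1)
  expect_error(nyholt_meff(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("influence diagnostics single out an injected outlier", {
  sim <- simulate_panel(synthetic_config(n_variants = 40, n_exposures = 2,
                                         causal_set = "exposure1",
                                         theta = 0.3, seed = 25))
  panel <- sim$panel
  fit <- mr_ivw(panel_keep_exposures(panel, "exposure1"))
  j <- 7
  panel$bY[j] <- 10 * panel$bX[j, 1] * fit$theta + 0.5
  diag_df <- influence_diagnostics(panel, model = "exposure1")
  expect_equal(which.max(diag_df$cooks_d), j)
  expect_equal(which.max(diag_df$q_contribution), j)
  expect_true(diag_df$flag_cooks[j])

  # duplicated rows receive identical diagnostics
  p2 <- panel_subset(sim$panel, c(1:10, 1))
  d2 <- influence_diagnostics(p2, model = "exposure1")
  expect_equal(d2$cooks_d[11], d2$cooks_d[1], tolerance = 1e-12)
})
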