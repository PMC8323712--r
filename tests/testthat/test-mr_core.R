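# Wald ratio, IVW (GLS), MR-Egger, MVMR: closed-form oracles, reductions,
# equivariances.

test_that("wald_ratio divides through and flags bx = 0", {
  est <- wald_ratio(bx = 0.2, sex = 0.01, by = 0.1, sey = 0.05)
  expect_equal(est$theta, 0.5)
  expect_equal(est$se, 0.25)
  null <- wald_ratio(bx = 0.2, sex = 0.01, by = 0, sey = 1)
  expect_equal(null$theta, 0)
  expect_gt(null$pvalue, 0.99)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "bx = 0")
})

test_that("IVW with identity LD equals the textbook closed form", {
  for (seed in 1:25) {
    p <- rand_panel(sample(2:8, 1), seed = seed)
    oracle <- ivw_closed_form(p$bX[, 1], p$bY, p$seY)
    est <- mr_ivw(p, effects = "fixed")
    expect_equal(est$theta, oracle$theta, tolerance = 1e-10)
    expect_equal(est$se, oracle$se, tolerance = 1e-10)
    # explicit identity LD matrix changes nothing
    ld <- ld_matrix(diag(length(p$variant_ids)), p$variant_ids)
    est2 <- mr_ivw(p, ld, effects = "fixed")
    expect_equal(est2$theta, oracle$theta, tolerance = 1e-10)
  }
})

test_that("IVW with correlated LD equals an independent GLS oracle", {
  for (seed in 1:10) {
    J <- 6
    p <- rand_panel(J, seed = seed)
    ld <- rand_ld(p$variant_ids, seed = seed + 100)
    Omega <- outer(p$seY, p$seY) * unclass(ld)
    oracle <- gls_oracle(matrix(p$bX[, 1], ncol = 1), p$bY, Omega)
    est <- mr_ivw(p, ld, effects = "fixed")
    expect_equal(est$theta, oracle$coef[1], tolerance = 1e-10)
    expect_equal(est$se, sqrt(oracle$vcov[1, 1]), tolerance = 1e-10)
  }
})

test_that("J = 1 IVW reduces to the Wald ratio", {
  p <- toy_panel(bx = 0.2, by = 0.1, sex = 0.01, sey = 0.05)
  est <- mr_ivw(p, effects = "fixed")
  w <- wald_ratio(0.2, 0.01, 0.1, 0.05)
  expect_equal(est$theta, w$theta, tolerance = 1e-12)
  expect_equal(est$se, w$se, tolerance = 1e-12)
  expect_error(mr_ivw(p, effects = "random"), "J >= 2")
})

test_that("duplicating a variant with r = 1 (ridged) barely moves the estimate", {
  p <- rand_panel(5, seed = 4)
  base <- mr_ivw(p, effects = "fixed")
  ids2 <- c(p$variant_ids, "rs_dup")
  p2 <- harmonized_panel(ids2, "X1",
                         rbind(p$bX, p$bX[5, , drop = FALSE]),
                         rbind(p$seX, p$seX[5, , drop = FALSE]),
                         bY = c(p$bY, p$bY[5]), seY = c(p$seY, p$seY[5]))
  r <- diag(6); r[5, 6] <- r[6, 5] <- 1
  ld <- ld_matrix(r, ids2) # ridge regularization kicks in
  est <- mr_ivw(p2, ld, effects = "fixed")
  expect_equal(est$theta, base$theta, tolerance = 1e-3)
})

test_that("random-effects SE is never below fixed-effects SE", {
  for (seed in 1:10) {
    p <- rand_panel(8, seed = seed)
    expect_gte(mr_ivw(p, effects = "random")$se,
               mr_ivw(p, effects = "fixed")$se)
  }
})

test_that("scale and sign equivariance hold", {
  p <- rand_panel(10, seed = 6)
  est <- mr_ivw(p, effects = "fixed")
  # multiplying bX and seX by c divides theta by c
  p2 <- p
  p2$bX <- p$bX * 4; p2$seX <- p$seX * 4
  expect_equal(mr_ivw(p2, effects = "fixed")$theta, est$theta / 4,
               tolerance = 1e-10)
  # negating bY negates theta
  p3 <- p; p3$bY <- -p$bY
  expect_equal(mr_ivw(p3, effects = "fixed")$theta, -est$theta,
               tolerance = 1e-12)
})

test_that("MR-Egger recovers constant directional pleiotropy in the intercept", {
  # adding c to every bY (on the oriented scale, where Egger's intercept is
  # defined) shifts the intercept by c and leaves the slope alone
  shifts <- sapply(1:100, function(seed) {
    cfg <- synthetic_config(n_variants = 60, n_exposures = 1,
                            causal_set = "exposure1", theta = 0.2,
                            seed = seed)
    sim <- simulate_panel(cfg)
    panel <- sim$panel
    flip <- sign(panel$bX[, 1])
    panel$bX[, 1] <- abs(panel$bX[, 1])
    panel$bY <- panel$bY * flip
    clean <- mr_egger(panel)
    dirty_panel <- panel
    dirty_panel$bY <- dirty_panel$bY + 0.02
    dirty <- mr_egger(dirty_panel)
    c(d_int = dirty$egger_intercept - clean$egger_intercept,
      d_slope = dirty$theta - clean$theta,
      int_se = clean$intercept_se)
  })
  expect_lt(max(abs(shifts["d_int", ] - 0.02)), 3 * max(shifts["int_se", ]))
  expect_lt(abs(mean(shifts["d_int", ]) - 0.02), 1e-10)
  expect_lt(max(abs(shifts["d_slope", ])), 1e-10)
})

test_that("MR-Egger intercept is null on clean data and errors on degenerate design", {
  set.seed(77)
  cfg <- synthetic_config(n_variants = 80, n_exposures = 1,
                          causal_set = "exposure1", theta = 0.2, seed = 15)
  sim <- simulate_panel(cfg)
  est <- mr_egger(sim$panel)
  expect_lt(abs(est$egger_intercept), 3 * est$intercept_se)
  p <- toy_panel(bx = rep(0.1, 5), by = rnorm(5, 0, 0.01))
  expect_error(mr_egger(p), "degenerate")
  expect_error(mr_egger(toy_panel(bx = c(1, 2), by = c(1, 2))), "J >= 3")
})

test_that("MVMR reduces to IVW at K = 1 and recovers multivariable truth", {
  p <- rand_panel(10, seed = 8)
  expect_equal(mr_mvmr(p, effects = "fixed")$theta,
               mr_ivw(p, effects = "fixed")$theta)
  # K = 2 with theta = (0.5, 0): strong instruments, estimates within 3 SE
  cfg <- synthetic_config(n_variants = 100, n_exposures = 2,
                          n_latent_factors = 2,
                          gamma = rbind(c(1, 0.3), c(0.3, 1)),
                          causal_set = "exposure1", theta = 0.5, seed = 23)
  sim <- simulate_panel(cfg)
  est <- mr_mvmr(sim$panel)
  e1 <- est[est$exposure == "exposure1", ]
  e2 <- est[est$exposure == "exposure2", ]
  expect_lt(abs(e1$theta - 0.5), 3 * e1$se)
  expect_lt(abs(e2$theta - 0), 3 * e2$se)
})

test_that("MVMR handles zero columns and flags collinearity", {
  p <- rand_panel(10, seed = 12, K = 2)
  p$bX[, 2] <- 0
  est <- mr_mvmr(p)
  e2 <- est[est$exposure == "X2", ]
  expect_equal(e2$theta, 0)
  expect_equal(e2$se, Inf)
  expect_match(e2$flags, "zero_column")
  # duplicated column is collinear, error names the pair
  p2 <- rand_panel(10, seed = 12, K = 2)
  p2$bX[, 2] <- p2$bX[, 1]
  expect_error(mr_mvmr(p2), "collinear")
})

test_that("GLS residual Q matches the whitened residual sum of squares", {
  p <- rand_panel(7, seed = 30)
  ld <- rand_ld(p$variant_ids, seed = 31)
  est <- mr_ivw(p, ld, effects = "fixed")
  Omega <- outer(p$seY, p$seY) * unclass(ld)
  resid <- p$bY - p$bX[, 1] * est$theta
  expect_equal(est$Q, as.numeric(t(resid) %*% solve(Omega) %*% resid),
               tolerance = 1e-8)
})
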