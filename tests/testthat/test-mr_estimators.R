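test_that("Wald ratios scale correctly and ignore joint sign flips", {
  tab <- make_table(bx = c(1, 2), by = c(0.5, 0.5), sy = c(0.1, 0.1))
  r <- wald_ratios(tab, "hdl")
  expect_equal(r$ratio, c(0.5, 0.25))
  expect_equal(r$se_ratio, c(0.1, 0.05))
  expect_equal(r$weight, 1 / r$se_ratio^2)

  flip <- make_table(bx = c(-1, 2), by = c(-0.5, 0.5), sy = c(0.1, 0.1))
  expect_equal(wald_ratios(flip, "hdl")$ratio, r$ratio)

  zero <- make_table(bx = c(0, 1), by = c(0.5, 0.5), sy = c(0.1, 0.1))
  expect_warning(rz <- wald_ratios(zero, "hdl"), "zero")
  expect_equal(nrow(rz), 1)
})

test_that("IVW equals the zero-intercept weighted least-squares oracle", {
  # frozen hand-computed case: sum(w x y)/sum(w x^2) = 3/5
  tab <- make_table(bx = c(1, 2), by = c(1, 1), sy = c(1, 1))
  expect_equal(mr_ivw(tab, "hdl")$estimate, 0.6)

  # degenerate agreement: equal ratios give that ratio
  tab <- make_table(bx = c(1, 2), by = c(0.5, 1), sy = c(0.1, 0.2))
  expect_equal(mr_ivw(tab, "hdl")$estimate, 0.5)

  set.seed(7)
  for (i in 1:20) {
    t2 <- rand_table(sample(3:40, 1))
    for (re in c(TRUE, FALSE)) {
      est <- mr_ivw(t2, "hdl", random_effects = re)
      ora <- ivw_oracle(t2$beta_hdl, t2$beta_mat, t2$se_mat, re)
      expect_equal(est$estimate, ora$estimate, tolerance = 1e-12)
      expect_equal(est$se, ora$se, tolerance = 1e-12)
    }
  }

  single <- make_table(bx = 1, by = 0.5, sy = 0.1)
  expect_error(mr_ivw(single, "hdl"), "wald_ratios")
})

test_that("Egger regression fits the weighted free-intercept line", {
  tab <- make_table(bx = c(1, 2, 3), by = c(0.3, 0.5, 0.7),
                    sy = c(0.1, 0.1, 0.1), oriented = "hdl")
  e <- mr_egger(tab, "hdl")
  expect_equal(e$estimate, 0.2)
  expect_equal(e$intercept, 0.1)

  # data exactly through the origin: intercept vanishes, slope = IVW
  tab0 <- make_table(bx = c(1, 2, 3), by = c(0.2, 0.4, 0.6),
                     sy = c(0.1, 0.2, 0.1), oriented = "hdl")
  e0 <- mr_egger(tab0, "hdl")
  expect_equal(e0$intercept, 0, tolerance = 1e-12)
  expect_equal(e0$estimate, mr_ivw(tab0, "hdl")$estimate, tolerance = 1e-12)

  # unoriented tables are refused
  expect_error(mr_egger(make_table(bx = 1:3, by = 1:3 / 10, sy = rep(.1, 3)),
                        "hdl"), "orient_positive")

  # lm oracle on random oriented tables
  set.seed(8)
  for (i in 1:15) {
    t2 <- orient_positive(rand_table(sample(4:40, 1)), "hdl")
    e2 <- mr_egger(t2, "hdl")
    ora <- egger_oracle(t2$beta_hdl, t2$beta_mat, t2$se_mat)
    expect_equal(e2$estimate, ora$slope, tolerance = 1e-12)
    expect_equal(e2$intercept, ora$intercept, tolerance = 1e-12)
    expect_equal(e2$se, unname(ora$se_slope), tolerance = 1e-12)
    expect_equal(e2$intercept_se, unname(ora$se_intercept), tolerance = 1e-12)
  }
})

test_that("weighted median interpolates cumulative weight midpoints", {
  # equal weights: plain median
  tab <- make_table(bx = rep(1, 3), by = c(1, 2, 3), sy = rep(1, 3))
  wm <- mr_weighted_median(tab, "hdl", n_boot = 200, seed = 1)
  expect_equal(wm$estimate, 2)

  # frozen interpolation case: weights (.4,.2,.2,.2) on ratios (1,2,3,10)
  # put p_2 = (0.6 - 0.1) = 0.5 exactly, so the estimate is ratio 2
  sy <- 1 / sqrt(c(0.4, 0.2, 0.2, 0.2))
  tab <- make_table(bx = rep(1, 4), by = c(1, 2, 3, 10), sy = sy)
  wm <- mr_weighted_median(tab, "hdl", n_boot = 200, seed = 1)
  expect_equal(wm$estimate, 2.0)

  # estimate always inside the ratio range; bootstrap is seed-deterministic
  set.seed(10)
  for (i in 1:10) {
    t2 <- rand_table(9)
    r <- wald_ratios(t2, "hdl")$ratio
    a <- mr_weighted_median(t2, "hdl", n_boot = 150, seed = 3)
    b <- mr_weighted_median(t2, "hdl", n_boot = 150, seed = 3)
    expect_gte(a$estimate, min(r))
    expect_lte(a$estimate, max(r))
    expect_identical(a$se, b$se)
  }

  expect_warning(mr_weighted_median(rand_table(5), "hdl", n_boot = 50,
                                    seed = 1), "n_boot")
  expect_error(mr_weighted_median(rand_table(2), "hdl", n_boot = 200,
                                  seed = 1), ">= 3")
})

test_that("mode-based estimator finds the dominant ratio cluster", {
  tab <- make_table(bx = rep(1, 4), by = c(1, 1, 1, 5), sy = rep(0.5, 4))
  m <- mr_mode(tab, "hdl", n_boot = 150, seed = 2)
  h <- duomr:::mode_bandwidth(c(1, 1, 1, 5), 1)
  expect_lt(abs(m$estimate - 1), h)

  # all ratios identical: degenerate exact answer
  tab <- make_table(bx = c(1, 2, 4), by = 0.3 * c(1, 2, 4), sy = rep(0.1, 3))
  m <- mr_mode(tab, "hdl", n_boot = 150, seed = 2)
  expect_equal(m$estimate, 0.3)
  expect_equal(m$se, 1 / sqrt(sum(c(1, 2, 4)^2 / 0.1^2)))

  # weighting can move the chosen cluster: 2 strong SNPs at ratio 2,
  # 3 weak SNPs at ratio 0
  tab <- make_table(bx = rep(1, 5), by = c(0, 0.02, -0.02, 2, 2.02),
                    sy = c(1, 1, 1, 0.05, 0.05))
  simple <- mr_mode(tab, "hdl", weighted = FALSE, n_boot = 150, seed = 2)
  wtd <- mr_mode(tab, "hdl", weighted = TRUE, n_boot = 150, seed = 2)
  expect_lt(abs(simple$estimate), 0.5)
  expect_gt(wtd$estimate, 1.5)
})

test_that("mode estimator is consistent when the plurality cluster is valid", {
  # valid cluster holds 40% of the weight (a plurality, under half), two
  # pleiotropic clusters split the rest: the mode sticks with the valid
  # cluster while IVW is dragged off by the invalid majority weight
  set.seed(16)
  truth <- 0.1
  sy <- c(rep(0.02, 6), rep(0.025, 4), rep(0.03, 3))
  by <- c(rnorm(6, truth, 0.01), rnorm(4, 0.5, 0.01), rnorm(3, 0.8, 0.01))
  tab <- make_table(bx = rep(1, 13), by = by, sy = sy, sx = rep(0.01, 13))
  m <- mr_mode(tab, "hdl", weighted = TRUE, n_boot = 300, seed = 6)
  expect_lt(abs(m$estimate - truth), 3 * m$se)
  # IVW averages across the invalid majority weight and lands far off;
  # its random-effects SE balloons with the heterogeneity, so compare
  # point-estimate error, not its own 3-SE band
  iv <- mr_ivw(tab, "hdl")
  expect_gt(abs(iv$estimate - truth), 10 * abs(m$estimate - truth))
})

test_that("exclusion re-runs isolate influential instruments", {
  # 4 SNPs, three on ratio 0.5 and one discordant: removing the discordant
  # SNP returns the common ratio exactly
  tab <- make_table(bx = c(1, 2, 4, 1), by = c(0.5, 1, 2, 3),
                    sy = rep(0.1, 4))
  res <- exclude_and_rerun(tab, "rs4", estimators = "ivw", exposure = "hdl")
  expect_equal(res$estimate[res$snp_set == "excluded"], 0.5)

  # removing an uninfluential point barely moves the estimate
  res2 <- exclude_and_rerun(tab, "rs2", estimators = "ivw", exposure = "hdl")
  d <- abs(diff(res2$estimate))
  expect_lt(d, abs(diff(res$estimate)))

  # leave-one-out brute force ranks the planted outlier first
  set.seed(14)
  t2 <- make_table(bx = rep(1, 8), by = c(rnorm(7, 0.1, 0.01), 2),
                   sy = rep(0.05, 8))
  loo <- mr_loo(t2, "hdl")
  expect_equal(which.max(abs(loo$delta)), 8L)
  expect_gt(max(abs(loo$delta)), 3 * sort(abs(loo$delta), decreasing = TRUE)[2])

  expect_error(exclude_and_rerun(tab, "rs99", estimators = "ivw",
                                 exposure = "hdl"), "not in table")
  # exclusion leaving too few SNPs skips that estimator with a warning
  expect_warning(
    res3 <- exclude_and_rerun(tab, c("rs1", "rs2", "rs3"),
                              estimators = "weighted_median",
                              exposure = "hdl", n_boot = 100, seed = 1),
    "skipping")
  expect_equal(res3$snp_set, "original")
})

test_that("estimators are sign-flip invariant and scale equivariant", {
  set.seed(15)
  tab <- rand_table(12)
  flip <- as.data.frame(tab)
  idx <- c(2, 5, 9)
  for (col in c("beta_hdl", "beta_mat", "beta_fet")) {
    flip[[col]][idx] <- -flip[[col]][idx]
  }
  flip <- as_instrument_table(flip, "hdl")
  expect_equal(mr_ivw(flip, "hdl")$estimate, mr_ivw(tab, "hdl")$estimate,
               tolerance = 1e-12)
  wm1 <- mr_weighted_median(tab, "hdl", n_boot = 150, seed = 4)
  wm2 <- mr_weighted_median(flip, "hdl", n_boot = 150, seed = 4)
  expect_equal(wm2$estimate, wm1$estimate, tolerance = 1e-12)
  md1 <- mr_mode(tab, "hdl", n_boot = 150, seed = 4)
  md2 <- mr_mode(flip, "hdl", n_boot = 150, seed = 4)
  expect_equal(md2$estimate, md1$estimate, tolerance = 1e-12)
  # Egger needs re-orientation, after which the slope coincides
  e1 <- mr_egger(orient_positive(tab, "hdl"), "hdl")
  e2 <- mr_egger(orient_positive(flip, "hdl"), "hdl")
  expect_equal(e2$estimate, e1$estimate, tolerance = 1e-12)
  expect_equal(e2$intercept, e1$intercept, tolerance = 1e-12)

  # scale equivariance: outcome in units c times larger
  cc <- 3.7
  scaled <- as.data.frame(tab)
  scaled$beta_mat <- scaled$beta_mat * cc
  scaled$se_mat <- scaled$se_mat * cc
  scaled <- as_instrument_table(scaled, "hdl")
  expect_equal(mr_ivw(scaled, "hdl")$estimate, cc * mr_ivw(tab, "hdl")$estimate)
  expect_equal(mr_ivw(scaled, "hdl")$se, cc * mr_ivw(tab, "hdl")$se)
  ws <- mr_weighted_median(scaled, "hdl", n_boot = 150, seed = 4)
  expect_equal(ws$estimate, cc * wm1$estimate, tolerance = 1e-12)
  expect_equal(ws$se, cc * wm1$se, tolerance = 1e-10)
  ms <- mr_mode(scaled, "hdl", n_boot = 150, seed = 4)
  expect_equal(ms$estimate, cc * md1$estimate, tolerance = 1e-10)
})
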