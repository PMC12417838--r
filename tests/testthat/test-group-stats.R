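# Nonparametric statistics: Kruskal-Wallis, Dunn, Mann-Whitney, Spearman,
# infiltration stratification.

test_that("Kruskal-Wallis matches the hand-computed toy partition", {
  v <- 1:9
  g <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskal_wallis(v, g)
  # H = 12/(N(N+1)) * sum(R_j^2/n_j) - 3(N+1) = 7.2 for {1,2,3}/{4,5,6}/{7,8,9}
  expect_equal(kw$H, 7.2, tolerance = 1e-10)
  expect_equal(kw$df, 2)
  # two identical groups: H = 0, p = 1
  kw0 <- kruskal_wallis(rep(c(5, 5), 4), rep(c("a", "b"), each = 4))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p, 1)
})

test_that("Dunn post hoc agrees with direct mean-rank computation", {
  v <- 1:9
  g <- rep(c("a", "b", "c"), each = 3)
  dp <- dunn_posthoc(v, g)
  expect_equal(nrow(dp), 3)
  # oracle: mean ranks 2, 5, 8; se = sqrt((9*10/12)*(2/3)); z_ac largest
  se <- sqrt(9 * 10 / 12 * (2 / 3))
  ac <- dp[dp$group1 == "a" & dp$group2 == "c", ]
  expect_equal(ac$z, (2 - 8) / se, tolerance = 1e-10)
  expect_equal(max(abs(dp$z)), abs(ac$z))
  # adjusted p never below raw p
  expect_true(all(dp$p_adj >= dp$p))
  # identical groups: all adjusted p = 1
  dp0 <- dunn_posthoc(rep(1, 8), rep(c("a", "b"), each = 4))
  expect_true(all(dp0$p_adj == 1))
  # 4 groups yield all 6 pairs
  dp4 <- dunn_posthoc(1:12, rep(letters[1:4], each = 3))
  expect_equal(nrow(dp4), 6)
  # order invariance of the group labels
  perm <- withr::with_seed(4, sample(9))
  dpp <- dunn_posthoc(v[perm], g[perm])
  expect_equal(dpp[order(dpp$group1, dpp$group2), c("z", "p")],
               dp[order(dp$group1, dp$group2), c("z", "p")])
})

test_that("Mann-Whitney reproduces the exact enumeration case", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(mw$U %in% c(0, 9))
  expect_equal(mw$p, 0.1, tolerance = 1e-10)  # 2/C(6,3) two-sided
  expect_equal(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 1,
               tolerance = 0.05)
  # shifting one sample drives p down monotonically
  a <- withr::with_seed(5, rnorm(30))
  ps <- vapply(c(0, 1, 2, 3), function(sh)
    mann_whitney(a, a + sh)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Spearman handles the classic rank cases", {
  expect_equal(spearman_corr(1:4, c(1, 3, 2, 4))$rho, 0.8, tolerance = 1e-10)
  expect_equal(spearman_corr(1:10, exp(1:10))$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10)^3)$rho, -1)
  # monotone-transform invariance
  x <- withr::with_seed(6, rnorm(50)); y <- withr::with_seed(7, rnorm(50))
  expect_equal(spearman_corr(x, y)$rho, spearman_corr(exp(x), y)$rho)
  # degenerate inputs reported missing
  expect_true(is.na(spearman_corr(rep(1, 10), 1:10)$rho))
  expect_true(is.na(spearman_corr(1:3, 3:1)$rho))
})

test_that("omnibus test is calibrated under the null", {
  reps <- 2000
  pvals <- withr::with_seed(8, vapply(seq_len(reps), function(i) {
    kruskal_wallis(rnorm(90), rep(c("a", "b", "c"), each = 30))$p
  }, numeric(1)))
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)
  # p values uniform under the null
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.001)
})

test_that("infiltration strata and stratified correlations behave", {
  s <- stratify_infiltration(c(0, 30, 49, 50, 120))
  expect_equal(as.character(s), c("healthy", "low", "low", "high", "high"))
  expect_error(stratify_infiltration(-1), ">= 0")
  # stratified Spearman recovers a built-in negative effect
  feats <- withr::with_seed(9, data.frame(
    channel_id = sprintf("c%03d", 1:300),
    label = "close_peritumoral",
    abs_beta = rlnorm(300), stringsAsFactors = FALSE))
  bx <- generate_infiltration_table(feats, "abs_beta", -0.5,
                                    n_biopsies = 200, seed = 10)
  out <- stratify_and_correlate(bx, feats, feature_cols = "abs_beta")
  low <- out[out$stratum == "low", ]
  expect_lt(abs(low$rho - (-0.5)), 0.15)
  # a stratum with n < 4 comes back missing
  bx_small <- bx[bx$stratum == "low", ][1:20, ]
  bx_small$count[1:2] <- 0L   # healthy stratum of size 2
  out2 <- stratify_and_correlate(bx_small, feats, feature_cols = "abs_beta")
  expect_true(is.na(out2$rho[out2$stratum == "healthy"]))
})
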