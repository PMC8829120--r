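# Moderated-t differential expression engine: fits, prior, p-values, BH.

test_that("fit_two_group reproduces hand-computed pooled fits", {
  x <- rbind(c(5, 5, 5, 5),    # constant
             c(2, 2, 1, 1),    # no within-group variance
             c(3, 1, 2, 0))    # pooled variance (2 + 2) / 2 = 2
  ex <- make_expr(x)
  fit <- fit_two_group(ex, make_meta(2, 2))
  expect_equal(fit$log_fc, c(0, 1, 1))
  expect_equal(fit$s2, c(0, 0, 2))
  expect_equal(fit$df_resid, rep(2L, 3))
  expect_identical(attr(fit, "n1"), 2L)
})

test_that("groups with fewer than two samples are rejected", {
  ex <- make_expr(matrix(rnorm(9), 3))
  meta <- sample_metadata(data.frame(
    sample_id = sprintf("s%02d", 1:3), group = c("tumor", "tumor", "normal")))
  expect_error(fit_two_group(ex, meta),
               class = "mimrda_insufficient_replication_error")
})

test_that("estimate_prior handles degenerate spreads", {
  # identical variances: no spread beyond chance, infinite prior df
  pr <- estimate_prior(rep(0.7, 50), 4)
  expect_identical(pr$d0, Inf)
  expect_gt(pr$s0_sq, 0)
  # two distinct repeated values: finite d0 solving the trigamma equation
  s2 <- rep(c(0.2, 1.4), 25)
  pr2 <- estimate_prior(s2, 4)
  expect_true(is.finite(pr2$d0) && pr2$d0 > 0)
  e <- log(s2) - digamma(2) + log(2)
  evar <- stats::var(e) - trigamma(2)
  expect_lt(abs(trigamma(pr2$d0 / 2) - evar), 1e-8)
  expect_error(estimate_prior(rep(0, 50), 4),
               class = "mimrda_degenerate_data_error")
  expect_error(estimate_prior(rep(1, 5), 4),
               class = "mimrda_degenerate_data_error")
})

test_that("moderated t matches its closed form and limits", {
  fit <- data.frame(feature_id = "f", log_fc = 1, s2 = 2, df_resid = 2)
  prior <- structure(list(d0 = 2, s0_sq = 2), class = "prior_estimate")
  mt <- moderated_t(fit, prior, n1 = 2, n0 = 2)
  expect_equal(mt$s2_post, 2)
  expect_equal(mt$t_mod, 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(mt$df_total, 4)
  expect_equal(mt$p_raw, 2 * stats::pt(-1 / sqrt(2), 4), tolerance = 1e-12)
  # zero effect: t = 0, p = 1
  fit0 <- data.frame(feature_id = "f", log_fc = 0, s2 = 1, df_resid = 2)
  mt0 <- moderated_t(fit0, prior, 2, 2)
  expect_equal(mt0$t_mod, 0)
  expect_equal(mt0$p_raw, 1)
  # infinite prior df: normal-distribution limit on the prior variance
  mtI <- moderated_t(fit, structure(list(d0 = Inf, s0_sq = 2),
                                    class = "prior_estimate"), 2, 2)
  expect_equal(mtI$p_raw, 2 * stats::pnorm(-1 / sqrt(2)), tolerance = 1e-12)
  # exact separation: zero variance with nonzero effect
  sep <- data.frame(feature_id = "f", log_fc = 1, s2 = 0, df_resid = 2)
  expect_warning(mts <- moderated_t(sep, structure(
    list(d0 = 0, s0_sq = NA_real_), class = "prior_estimate"), 2, 2))
  expect_equal(mts$p_raw, 0)
})

test_that("d0 = 0 reduces the pipeline to the classical pooled t-test", {
  set.seed(101)
  ex <- make_expr(matrix(rnorm(60 * 10, 5, 1.3), 60))
  meta <- make_meta(5, 5)
  mt <- suppressMessages(de_analysis(ex, meta, ordinary_t = TRUE))
  oracle <- apply(ex$values, 1L, function(v)
    stats::t.test(v[1:5], v[6:10], var.equal = TRUE)$p.value)
  expect_equal(mt$p_raw, unname(oracle), tolerance = 1e-10)
})

test_that("the moderated pipeline agrees with an independent GLS fit (limma)", {
  library(limma)
  # heteroskedastic features so the prior degrees of freedom are finite
  set.seed(202)
  nfeat <- 400
  sigma <- sqrt(0.5 * 6 / stats::rchisq(nfeat, 6))
  vals <- matrix(stats::rnorm(nfeat * 16, 7, sigma), nfeat, 16)
  vals[1:80, 1:8] <- vals[1:80, 1:8] + 1
  ex <- make_expr(vals)
  meta <- make_meta(8, 8)
  design <- cbind(intercept = 1, tumor = as.integer(meta$group == "tumor"))
  ref <- limma::eBayes(limma::lmFit(ex$values, design))
  mine <- suppressMessages(de_analysis(ex, meta))
  expect_true(is.finite(ref$df.prior))
  expect_equal(attr(mine, "prior")$d0, ref$df.prior, tolerance = 1e-8)
  expect_equal(attr(mine, "prior")$s0_sq, ref$s2.prior, tolerance = 1e-8)
  expect_equal(mine$t_mod, unname(ref$t[, "tumor"]), tolerance = 1e-10)
  expect_equal(mine$p_raw, unname(ref$p.value[, "tumor"]), tolerance = 1e-10)
})

test_that("bh_adjust reproduces the step-up calculation and its invariants", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.37, 6)), rep(0.37, 6))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mimrda_validation_error")
  # permutation equivariance and p_adj >= p_raw
  set.seed(303)
  for (i in 1:20) {
    p <- stats::runif(sample(2:40, 1))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("select_de applies the adjusted-p threshold", {
  fits <- data.frame(feature_id = c("a", "b"), p_adj = c(0.005, 0.02))
  expect_identical(select_de(fits, 0.01), "a")
  expect_identical(select_de(fits, 0), character(0))
})

test_that("null p-values are approximately uniform", {
  set.seed(404)
  ex <- make_expr(matrix(rnorm(5000 * 12, 8, 1), 5000))
  mt <- suppressMessages(de_analysis(ex, make_meta(6, 6)))
  ks <- suppressWarnings(stats::ks.test(mt$p_raw, "punif"))
  expect_lt(unname(ks$statistic), 0.03)
  expect_true(all(mt$p_adj >= mt$p_raw))
})

test_that("planted effects are detected with high power", {
  sim <- simulate_expression(1000, 20, 20, de_fraction = 0.1,
                             effect_size = 2, sigma = 1, seed = 505)
  mt <- suppressMessages(de_analysis(sim$expr, sim$meta, alpha = 0.01))
  hits <- select_de(mt, 0.01)
  expect_gte(mean(sim$de_features %in% hits), 0.95)
})
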