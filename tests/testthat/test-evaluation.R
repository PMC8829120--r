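# Label overlap, median split, KM/log-rank, RF AUC comparison.

test_that("top-k overlap percentage follows its definition", {
  ranked <- sprintf("mir-%02d", 1:20)
  labels <- c(ranked[c(1:6, 8:10)], "mir-99")  # 9 of the top 10
  expect_equal(topk_overlap_percentage(ranked, labels, 10), 90)
  expect_equal(topk_overlap_percentage(ranked, c("x", "y"), 10), 0)
  expect_equal(topk_overlap_percentage(ranked, ranked, 20), 100)
  expect_error(topk_overlap_percentage(ranked, labels, 0),
               class = "mimrda_validation_error")
  expect_error(topk_overlap_percentage(ranked, labels, 21),
               class = "mimrda_validation_error")
  # monotone non-decreasing in the label set
  grown <- c(labels, ranked[7])
  expect_gte(topk_overlap_percentage(ranked, grown, 10),
             topk_overlap_percentage(ranked, labels, 10))
})

test_that("compare_rankings counts labeled miRNAs per method", {
  ids <- sprintf("mir-%02d", 1:30)
  labels <- ids[c(2, 5, 11, 25)]
  same <- compare_rankings(ids, ids, ids, labels, n = 10)
  expect_true(all(same == same[1]))
  all_lab <- compare_rankings(ids, rev(ids), ids, ids, n = 10)
  expect_true(all(all_lab == 10L))
  expect_error(compare_rankings(ids, ids[-1], ids, labels),
               class = "mimrda_validation_error")
})

test_that("median split sends ties to the low group", {
  s <- function(v) stats::setNames(v, sprintf("s%d", seq_along(v)))
  expect_identical(as.character(median_split(s(c(1, 2, 3, 4)))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(median_split(s(c(1, 1, 2, 2)))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(median_split(s(c(1, 1, 1, 2)))),
                   c("low", "low", "low", "high"))
  expect_error(median_split(s(rep(3, 6))),
               class = "mimrda_degenerate_split_error")
})

test_that("KM curve matches the hand product-limit calculation", {
  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # order invariance
  km2 <- km_curve(c(3, 1, 2), c(TRUE, TRUE, TRUE))
  expect_equal(km2, km)
  # censored subjects shrink the risk set without a step
  kmc <- km_curve(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(kmc$surv[kmc$time == 1], 2 / 3)
  expect_equal(kmc$surv[kmc$time == 3], 0)
  all_cens <- km_curve(c(5, 6, 7), rep(FALSE, 3))
  expect_true(all(all_cens$surv == 1))
  single <- km_curve(5, TRUE)
  expect_equal(single$surv, 0)
  # S(t) non-increasing on a larger random input
  set.seed(808)
  kmr <- km_curve(stats::rexp(200), stats::runif(200) < 0.7)
  expect_true(all(diff(kmr$surv) <= 1e-12))
  expect_error(km_curve(numeric(0), logical(0)),
               class = "mimrda_validation_error")
})

test_that("log-rank matches a hand-computed O/E example to 1e-10", {
  # high: events at 1, 3, 5; low: events at 2, 4, 6 (all observed).
  # Risk-set bookkeeping gives E_high = 67/30, V = 1091/900,
  # chi2 = (3 - 67/30)^2 / (1091/900) = 529/1091, HR = (3/(67/30))/(3/(113/30)).
  lr <- logrank_test(data.frame(time = c(1, 3, 5), event = TRUE),
                     data.frame(time = c(2, 4, 6), event = TRUE))
  expect_equal(lr$chi2, 529 / 1091, tolerance = 1e-10)
  expect_equal(lr$hr, 113 / 67, tolerance = 1e-10)
  expect_equal(lr$p, stats::pchisq(529 / 1091, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("log-rank is symmetric and null on identical groups", {
  g <- data.frame(time = c(2, 4, 7, 9), event = c(TRUE, TRUE, FALSE, TRUE))
  same <- logrank_test(g, g)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$hr, 1, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  h <- data.frame(time = c(1, 3, 5, 8), event = c(TRUE, TRUE, TRUE, FALSE))
  ab <- logrank_test(h, g)
  ba <- logrank_test(g, h)
  expect_equal(ab$chi2, ba$chi2, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$hr, 1 / ba$hr, tolerance = 1e-12)
  none <- data.frame(time = c(1, 2), event = FALSE)
  expect_error(logrank_test(none, none),
               class = "mimrda_undefined_test_error")
})

test_that("median-split survival verification wires the pieces together", {
  set.seed(909)
  n <- 40L
  expr <- make_expr(matrix(rnorm(2 * n, 8, 1), 2, n), kind = "miRNA",
                    features = c("mir-a", "mir-b"),
                    samples = sprintf("s%03d", 1:n))
  surv <- simulate_survival(n, 0.4, censor_rate = 0.1, seed = 910)
  out <- survival_verification(expr, surv, "mir-a")
  expect_identical(out$n_high + out$n_low, n)
  expect_true(out$logrank_p >= 0 && out$logrank_p <= 1)
  expect_error(survival_verification(expr, surv, "mir-zzz"),
               class = "mimrda_validation_error")
})

test_that("rf_evaluate is deterministic and validates its inputs", {
  sim <- simulate_dataset(n_mrna = 100, n_mirna = 15, n_tumor = 8,
                          n_normal = 8, mean_degree = 10, n_disease = 1,
                          seed = 77)
  feats <- rownames(sim$mirna$values)[1:4]
  a1 <- rf_evaluate(sim$mirna, sim$meta, feats, n_reps = 3, seed = 5,
                    num_trees = 100)
  a2 <- rf_evaluate(sim$mirna, sim$meta, feats, n_reps = 3, seed = 5,
                    num_trees = 100)
  expect_identical(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_error(rf_evaluate(sim$mirna, sim$meta, "mir-nope", n_reps = 1),
               class = "mimrda_validation_error")
  expect_error(rf_evaluate(sim$mirna, sim$meta, feats, folds = 10,
                           n_reps = 1),
               class = "mimrda_validation_error")
})

test_that("planted disease miRNAs classify tumor vs normal well", {
  sim <- simulate_dataset(n_mrna = 100, n_mirna = 40, n_tumor = 15,
                          n_normal = 15, mean_degree = 10, n_disease = 4,
                          seed = 88)
  aucs <- rf_evaluate(sim$mirna, sim$meta, sim$truth$disease_mirnas,
                      n_reps = 5, seed = 6, num_trees = 200)
  expect_gt(mean(aucs), 0.9)
})

test_that("compare_auc reports rank-sum evidence symmetrically", {
  same <- compare_auc(rep(0.7, 20), rep(0.7, 20))
  expect_gt(same$p_value, 0.99)
  set.seed(1010)
  top <- pmin(1, 0.95 + rnorm(100, 0, 0.01))
  rnd <- pmax(0, 0.5 + rnorm(100, 0, 0.02))
  sep <- compare_auc(top, rnd, k = 10)
  expect_lt(sep$p_value, 0.001)
  swap <- compare_auc(rnd, top)
  expect_equal(swap$p_value, sep$p_value, tolerance = 1e-12)
  expect_lt(swap$mean_top, swap$mean_random)
  expect_error(compare_auc(1:3 / 10, 1:4 / 10),
               class = "mimrda_validation_error")
})
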