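# Verification procedures: top-k overlap against curated label sets,
# three-statistic ranking comparison, Kaplan-Meier / log-rank median-split
# survival analysis, and the cross-validated random-forest AUC test.

label_ids <- function(labels) {
  if (inherits(labels, "label_set")) labels$mirna_ids
  else unique(as.character(labels))
}

#' Percentage of top-k ranked miRNAs found in a label set
#'
#' @param ranked_mirnas Character vector of miRNA identifiers, best first.
#' @param labels A [label_set()] or character vector of known
#'   disease-associated miRNAs.
#' @param k Number of top ranks to inspect (1..length of the ranking).
#' @return \code{100 * |top-k intersect labels| / k}.
#' @export
topk_overlap_percentage <- function(ranked_mirnas, labels, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 ||
      k > length(ranked_mirnas))
    mimrda_error("'k' must lie in 1..length(ranked_mirnas)",
                 "mimrda_validation_error")
  100 * length(intersect(ranked_mirnas[seq_len(k)], label_ids(labels))) / k
}

#' Labeled-miRNA counts within the top n of three rankings
#'
#' Compares the ranking by the global probability with the rankings a
#' DE-only analysis (\code{p_mirna}) or an ORA-only analysis (\code{p_nde})
#' would produce: for each, the number of label-set miRNAs among its top-n.
#'
#' @param ranked_pg,ranked_pmirna,ranked_pnde Character vectors of ranked
#'   miRNA identifiers (best first) covering the same miRNA set; see
#'   [ranked_ids()].
#' @param labels A [label_set()] or character vector.
#' @param n Depth of the comparison (default 100, capped at the ranking
#'   length).
#' @return Named integer vector with elements \code{p_g}, \code{p_mirna},
#'   \code{p_nde}.
#' @export
compare_rankings <- function(ranked_pg, ranked_pmirna, ranked_pnde, labels,
                             n = 100) {
  rankings <- list(p_g = ranked_pg, p_mirna = ranked_pmirna,
                   p_nde = ranked_pnde)
  base <- sort(unique(ranked_pg))
  for (r in rankings)
    if (!identical(sort(unique(r)), base))
      mimrda_error("the three rankings must cover the same miRNA set",
                   "mimrda_validation_error")
  n <- min(n, length(ranked_pg))
  ids <- label_ids(labels)
  vapply(rankings,
         function(r) length(intersect(r[seq_len(n)], ids)),
         integer(1))
}

#' Median split of expression values into high/low groups
#'
#' Values strictly above the median go to \code{"high"}; ties at the median
#' go to \code{"low"}.
#'
#' @param values Named numeric vector (one expression value per sample,
#'   >= 4 samples).
#' @return Factor with levels \code{c("low", "high")}, named like
#'   \code{values}.
#' @export
median_split <- function(values) {
  if (!is.numeric(values) || length(values) < 4L)
    mimrda_error("need >= 4 numeric values", "mimrda_validation_error")
  med <- stats::median(values)
  grp <- ifelse(values > med, "high", "low")
  if (length(unique(grp)) < 2L)
    mimrda_error("median split is degenerate (a group is empty)",
                 "mimrda_degenerate_split_error")
  stats::setNames(factor(grp, levels = c("low", "high")), names(values))
}

#' Kaplan-Meier product-limit curve
#'
#' @param times Non-negative follow-up times.
#' @param events Logical event indicators (censored subjects leave the risk
#'   set without a survival step).
#' @return Data frame with columns \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{surv}.
#' @export
km_curve <- function(times, events) {
  if (!length(times) || length(times) != length(events))
    mimrda_error("'times' and 'events' must be non-empty and equal length",
                 "mimrda_validation_error")
  if (any(times < 0) || anyNA(times))
    mimrda_error("'times' must be non-negative", "mimrda_validation_error")
  sf <- survival::survfit(survival::Surv(times, as.logical(events)) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, surv = sf$surv)
}

#' Log-rank test and observed/expected hazard ratio
#'
#' Standard 1-df log-rank chi-square over shared event times (hypergeometric
#' variance, so tied event times are handled), with the hazard ratio of the
#' high- vs low-expression group estimated from the log-rank
#' observed/expected event counts: \code{(O_h / E_h) / (O_l / E_l)}.
#'
#' @param high,low Data frames (or lists) with elements \code{time} and
#'   \code{event} for the two groups; both nonempty, with at least one event
#'   overall.
#' @return Object of class \code{"logrank_result"}: list with \code{chi2},
#'   \code{p}, \code{hr}, \code{n_high}, \code{n_low}, \code{obs},
#'   \code{exp} (the latter two ordered low, high).
#' @export
logrank_test <- function(high, low) {
  high <- as.data.frame(high)
  low <- as.data.frame(low)
  for (g in list(high, low))
    if (!nrow(g) || !all(c("time", "event") %in% names(g)))
      mimrda_error("both groups need nonempty time/event columns",
                   "mimrda_validation_error")
  if (sum(high$event) + sum(low$event) < 1)
    mimrda_error("log-rank test undefined with zero events",
                 "mimrda_undefined_test_error")
  df <- data.frame(
    time = c(high$time, low$time),
    event = as.logical(c(high$event, low$event)),
    group = factor(rep(c("high", "low"), c(nrow(high), nrow(low))),
                   levels = c("low", "high")))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  chi2 <- unname(sd$chisq)
  rate <- sd$obs / sd$exp  # level order: low, high
  hr <- unname(rate[2L] / rate[1L])
  structure(list(chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 hr = hr, n_high = nrow(high), n_low = nrow(low),
                 obs = unname(sd$obs), exp = unname(sd$exp)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.4g, p = %.4g, HR (high vs low) = %.4g\n",
              x$chi2, x$p, x$hr))
  invisible(x)
}

#' Median-split survival analysis of one miRNA
#'
#' Splits samples at the miRNA's median expression and runs [logrank_test()]
#' on the two groups.
#'
#' @param mirna_expr An [expression_matrix()] of miRNAs.
#' @param surv Data frame with \code{sample_id}, \code{time}, \code{event}
#'   (e.g. from [simulate_survival()] or survival-annotated metadata).
#' @param mirna_id The miRNA to analyze.
#' @return Data frame row: \code{mirna_id}, \code{hr}, \code{logrank_chi2},
#'   \code{logrank_p}, \code{n_high}, \code{n_low}.
#' @export
survival_verification <- function(mirna_expr, surv, mirna_id) {
  stopifnot(inherits(mirna_expr, "expression_matrix"))
  if (!mirna_id %in% rownames(mirna_expr$values))
    mimrda_error(sprintf("miRNA '%s' not measured", mirna_id),
                 "mimrda_validation_error")
  surv <- as.data.frame(surv)
  common <- intersect(colnames(mirna_expr$values), surv$sample_id)
  if (length(common) < 4L)
    mimrda_error("need >= 4 samples with survival data",
                 "mimrda_validation_error")
  v <- mirna_expr$values[mirna_id, common]
  grp <- median_split(stats::setNames(v, common))
  s <- surv[match(common, surv$sample_id), ]
  lr <- logrank_test(high = s[grp == "high", c("time", "event")],
                     low = s[grp == "low", c("time", "event")])
  data.frame(mirna_id = mirna_id, hr = lr$hr, logrank_chi2 = lr$chi2,
             logrank_p = lr$p, n_high = lr$n_high, n_low = lr$n_low,
             stringsAsFactors = FALSE)
}

# Rank-based AUC of out-of-fold probabilities (via pROC).
.auc <- function(y, prob) {
  as.numeric(pROC::auc(response = y, predictor = prob,
                       levels = c("normal", "tumor"), direction = "<",
                       quiet = TRUE))
}

#' Cross-validated random-forest AUC of a miRNA panel
#'
#' Per repetition: samples are split into stratified folds (default 5, i.e.
#' a 4:1 train/test ratio per fold), a probability random forest restricted
#' to \code{feature_ids} is trained on each training portion, and the AUC of
#' the pooled out-of-fold tumor probabilities is recorded. Fully seeded and
#' single-threaded, so results are reproducible.
#'
#' @param mirna_expr An [expression_matrix()] of miRNAs.
#' @param sample_labels \code{sample_metadata} (its \code{group} column is
#'   used) or a character/factor vector of \code{"tumor"}/\code{"normal"}
#'   labels aligned with the matrix columns.
#' @param feature_ids miRNAs to use as predictors (must be measured).
#' @param folds Number of cross-validation folds (default 5); every class
#'   needs at least \code{folds} samples.
#' @param n_reps Number of repetitions (default 200).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 500).
#' @return Numeric vector of \code{n_reps} AUC values.
#' @export
rf_evaluate <- function(mirna_expr, sample_labels, feature_ids, folds = 5L,
                        n_reps = 200L, seed = 1L, num_trees = 500L) {
  stopifnot(inherits(mirna_expr, "expression_matrix"))
  x <- mirna_expr$values
  missing_feat <- setdiff(feature_ids, rownames(x))
  if (length(missing_feat))
    mimrda_error(sprintf("feature(s) not measured: %s",
                         paste(missing_feat, collapse = ", ")),
                 "mimrda_validation_error")
  if (inherits(sample_labels, "sample_metadata") ||
      is.data.frame(sample_labels)) {
    meta <- validate_metadata(sample_labels)
    sample_labels <- meta$group[match(colnames(x), meta$sample_id)]
  }
  y <- factor(as.character(sample_labels), levels = c("normal", "tumor"))
  if (anyNA(y) || length(y) != ncol(x))
    mimrda_error("labels must be tumor/normal, one per sample",
                 "mimrda_validation_error")
  if (any(table(y) < folds))
    mimrda_error(sprintf("each class needs >= %d samples for %d-fold CV",
                         folds, folds),
                 "mimrda_validation_error")
  dat <- as.data.frame(t(x[feature_ids, , drop = FALSE]))
  names(dat) <- make.names(names(dat))
  n <- length(y)
  aucs <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    fold <- integer(n)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    prob <- numeric(n)
    for (f in seq_len(folds)) {
      tr <- fold != f
      rf <- ranger::ranger(x = dat[tr, , drop = FALSE], y = y[tr],
                           num.trees = num_trees, probability = TRUE,
                           num.threads = 1L,
                           seed = seed + r * 100L + f)
      prob[!tr] <- stats::predict(rf, data = dat[!tr, , drop = FALSE],
                                  num.threads = 1L)$predictions[, "tumor"]
    }
    aucs[r] <- .auc(y, prob)
  }
  aucs
}

#' Compare two AUC distributions by rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test between the AUCs of a top-ranked panel
#' and a random panel of the same size.
#'
#' @param auc_top,auc_random Equal-length numeric vectors of AUCs in
#'   \code{[0, 1]}.
#' @param k Optional panel size, recorded in the result.
#' @return Object of class \code{"auc_comparison"}: list with
#'   \code{auc_top}, \code{auc_random}, \code{mean_top}, \code{mean_random},
#'   \code{p_value}, \code{n_reps}, \code{k}.
#' @export
compare_auc <- function(auc_top, auc_random, k = NA_integer_) {
  if (length(auc_top) != length(auc_random))
    mimrda_error("AUC vectors must have equal length",
                 "mimrda_validation_error")
  if (any(c(auc_top, auc_random) < 0 | c(auc_top, auc_random) > 1))
    mimrda_error("AUC values must lie in [0, 1]", "mimrda_validation_error")
  wt <- suppressWarnings(stats::wilcox.test(auc_top, auc_random))
  p_value <- wt$p.value
  if (is.nan(p_value)) p_value <- 1  # complete ties carry no evidence
  structure(list(auc_top = auc_top, auc_random = auc_random,
                 mean_top = mean(auc_top), mean_random = mean(auc_random),
                 p_value = p_value, n_reps = length(auc_top),
                 k = k),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "AUC comparison (k = %s, %d reps): top %.3f vs random %.3f, rank-sum p = %.3g\n",
    format(x$k), x$n_reps, x$mean_top, x$mean_random, x$p_value))
  invisible(x)
}
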