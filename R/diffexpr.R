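# Two-group differential expression with empirical-Bayes variance
# moderation (Smyth 2004): per-feature pooled-variance fits, a
# method-of-moments prior on the log variances, moderated t statistics and
# Benjamini-Hochberg adjustment.

#' Per-feature two-group fit
#'
#' Computes, for each feature, the tumor-minus-normal log2 fold change and
#' the pooled within-group variance.
#'
#' @param expr An [expression_matrix()].
#' @param meta Sample metadata (columns \code{sample_id}, \code{group}) whose
#'   \code{sample_id}s cover the matrix's samples. Each group needs at least
#'   two samples.
#' @return Data frame with columns \code{feature_id}, \code{log_fc} (mean
#'   tumor minus mean normal), \code{s2} (pooled variance) and
#'   \code{df_resid} (= n1 + n2 - 2); group sizes are attached as attributes
#'   \code{n1} (tumor) and \code{n0} (normal).
#' @export
fit_two_group <- function(expr, meta) {
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- validate_metadata(meta)
  x <- expr$values
  missing_samples <- setdiff(colnames(x), meta$sample_id)
  if (length(missing_samples))
    mimrda_error(sprintf("samples absent from metadata: %s",
                         paste(missing_samples, collapse = ", ")),
                 "mimrda_metadata_error")
  grp <- meta$group[match(colnames(x), meta$sample_id)]
  n1 <- sum(grp == "tumor")
  n0 <- sum(grp == "normal")
  if (n1 < 2L || n0 < 2L)
    mimrda_error(sprintf(
      "each group needs >= 2 samples (tumor: %d, normal: %d)", n1, n0),
      "mimrda_insufficient_replication_error")
  xt <- x[, grp == "tumor", drop = FALSE]
  xn <- x[, grp == "normal", drop = FALSE]
  m1 <- rowMeans(xt)
  m0 <- rowMeans(xn)
  rss <- rowSums((xt - m1)^2) + rowSums((xn - m0)^2)
  df <- n1 + n0 - 2L
  fit <- data.frame(feature_id = rownames(x), log_fc = m1 - m0,
                    s2 = rss / df, df_resid = df,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(fit, "n1") <- n1
  attr(fit, "n0") <- n0
  fit
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
trigamma_inverse <- function(y) {
  if (any(!is.finite(y)) || any(y <= 0))
    mimrda_error("trigamma_inverse needs positive finite input",
                 "mimrda_validation_error")
  x <- 0.5 + 1 / y
  for (i in seq_len(75L)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-12) break
  }
  x
}

#' Estimate the variance prior (d0, s0^2) by moments on log variances
#'
#' Matches the mean and spread of \code{log(s2)} to the scaled-F marginal of
#' the hierarchical variance model using digamma/trigamma identities. If the
#' observed spread does not exceed the spread expected from the residual
#' degrees of freedom alone, the prior degrees of freedom are infinite and
#' \code{s0_sq} is the (geometric-mean-based) common variance.
#'
#' @param s2 Per-feature pooled variances (zero variances are excluded from
#'   moment matching, with a message).
#' @param df_resid Residual degrees of freedom, scalar or per feature.
#' @return Object of class \code{"prior_estimate"}: list with \code{d0}
#'   (prior degrees of freedom, possibly \code{Inf}) and \code{s0_sq}.
#' @export
estimate_prior <- function(s2, df_resid) {
  if (!is.numeric(s2) || !length(s2))
    mimrda_error("'s2' must be a non-empty numeric vector",
                 "mimrda_validation_error")
  df <- rep_len(as.numeric(df_resid), length(s2))
  ok <- df >= 1
  s2 <- s2[ok]
  df <- df[ok]
  if (length(s2) < 10L)
    mimrda_error("need >= 10 features with df_resid >= 1 to estimate a prior",
                 "mimrda_degenerate_data_error")
  pos <- s2 > 0
  if (!any(pos))
    mimrda_error("all residual variances are zero",
                 "mimrda_degenerate_data_error")
  if (any(!pos))
    message(sprintf(
      "estimate_prior: %d zero variance(s) excluded from moment matching",
      sum(!pos)))
  e <- log(s2[pos]) - digamma(df[pos] / 2) + log(df[pos] / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(df[pos] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "prior_estimate")
}

#' @export
print.prior_estimate <- function(x, ...) {
  cat(sprintf("variance prior: d0 = %s, s0_sq = %.6g\n",
              format(x$d0), x$s0_sq))
  invisible(x)
}

#' Moderated t statistics and p-values
#'
#' Shrinks each feature's variance toward the prior,
#' \code{s2_post = (d0 * s0_sq + df * s2) / (d0 + df)}, and tests
#' \code{log_fc} against a t distribution on \code{df + d0} degrees of
#' freedom (normal limit when \code{d0} is infinite; ordinary two-sample
#' pooled t when \code{d0 = 0}).
#'
#' @param fit Output of [fit_two_group()].
#' @param prior A \code{prior_estimate} (use \code{d0 = 0} for the ordinary
#'   t-test).
#' @param n1,n0 Group sizes; default to the attributes stored on \code{fit}.
#' @return Data frame of class \code{"moderated_fit"} with columns
#'   \code{feature_id}, \code{log_fc}, \code{s2}, \code{df_resid},
#'   \code{s2_post}, \code{t_mod}, \code{df_total}, \code{p_raw},
#'   \code{p_adj}.
#' @export
moderated_t <- function(fit, prior, n1 = attr(fit, "n1"),
                        n0 = attr(fit, "n0")) {
  if (is.null(n1) || is.null(n0))
    mimrda_error("group sizes n1/n0 are required", "mimrda_validation_error")
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  df <- fit$df_resid
  s2 <- fit$s2
  s2_post <- if (d0 == 0) {
    s2
  } else if (is.infinite(d0)) {
    rep_len(s0_sq, length(s2))
  } else {
    (d0 * s0_sq + df * s2) / (d0 + df)
  }
  df_total <- df + d0
  se <- sqrt(s2_post) * sqrt(1 / n1 + 1 / n0)
  degenerate <- se == 0 & fit$log_fc != 0
  if (any(degenerate))
    warning(sprintf(
      "%d feature(s) with zero posterior variance but nonzero log_fc: p_raw = 0",
      sum(degenerate)))
  t_mod <- ifelse(se > 0, fit$log_fc / se,
                  ifelse(fit$log_fc == 0, 0, sign(fit$log_fc) * Inf))
  p_raw <- if (any(is.infinite(df_total))) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df_total)
  }
  out <- data.frame(feature_id = fit$feature_id, log_fc = fit$log_fc,
                    s2 = s2, df_resid = df, s2_post = s2_post,
                    t_mod = t_mod, df_total = df_total, p_raw = p_raw,
                    p_adj = bh_adjust(p_raw),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "n1") <- n1
  attr(out, "n0") <- n0
  class(out) <- c("moderated_fit", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, capped at 1, input order
#' preserved).
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p))
    mimrda_error("'p' must be numeric", "mimrda_validation_error")
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    mimrda_error("p-values must lie in [0, 1]", "mimrda_validation_error")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed features
#'
#' @param fits A \code{moderated_fit} (or any data frame with
#'   \code{feature_id} and \code{p_adj}).
#' @param alpha Significance level on the BH-adjusted p-value (default 0.01).
#' @return Character vector of feature identifiers with \code{p_adj < alpha}.
#' @export
select_de <- function(fits, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    mimrda_error("'alpha' must be a single value in [0, 1]",
                 "mimrda_validation_error")
  fits$feature_id[fits$p_adj < alpha]
}

#' One-call differential expression analysis
#'
#' Runs [fit_two_group()], [estimate_prior()] and [moderated_t()] and flags
#' features with \code{p_adj < alpha}.
#'
#' @inheritParams fit_two_group
#' @param alpha BH-adjusted significance level (default 0.01).
#' @param ordinary_t If \code{TRUE}, skip variance moderation (\code{d0 = 0}),
#'   giving the classical pooled two-sample t-test.
#' @return A \code{moderated_fit} data frame with an extra logical column
#'   \code{is_de}.
#' @export
de_analysis <- function(expr, meta, alpha = 0.01, ordinary_t = FALSE) {
  fit <- fit_two_group(expr, meta)
  prior <- if (ordinary_t) {
    structure(list(d0 = 0, s0_sq = NA_real_), class = "prior_estimate")
  } else {
    estimate_prior(fit$s2, fit$df_resid)
  }
  mt <- moderated_t(fit, prior)
  mt$is_de <- mt$p_adj < alpha
  attr(mt, "alpha") <- alpha
  mt
}
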