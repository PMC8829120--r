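# Fisher-product combination of the two per-miRNA p-values into the global
# probability P_G, FDR control over P_G, and the final ranking.

#' Combine two p-values by Fisher's product
#'
#' For \code{c = p_nde * p_mirna}, returns the exact tail probability that a
#' product of two independent Uniform(0, 1) p-values falls at or below
#' \code{c}: \code{P_G = c * (1 - log(c))} (0 when \code{c = 0}, 1 when
#' \code{c = 1}). The product is computed in log space, so extreme inputs do
#' not underflow.
#'
#' @param p_nde,p_mirna Numeric vectors of p-values in \code{[0, 1]} (equal
#'   length or scalar).
#' @return The combined probability \code{P_G}, clamped to \code{[0, 1]}.
#' @export
fisher_combine <- function(p_nde, p_mirna) {
  n <- max(length(p_nde), length(p_mirna))
  p1 <- rep_len(as.numeric(p_nde), n)
  p2 <- rep_len(as.numeric(p_mirna), n)
  if (anyNA(p1) || anyNA(p2) || any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1))
    mimrda_error("p-values must lie in [0, 1]", "mimrda_validation_error")
  lc <- log(p1) + log(p2)
  p_g <- numeric(n)
  zero <- is.infinite(lc)
  if (any(zero)) {
    warning("zero Fisher product(s); P_G set to 0")
    p_g[zero] <- 0
  }
  p_g[!zero] <- exp(lc[!zero]) * (1 - lc[!zero])
  pmin(pmax(p_g, 0), 1)
}

#' Score all miRNAs: join DE evidence with target over-representation
#'
#' Joins the miRNA moderated-t results with the ORA results on
#' \code{mirna_id}, combines the raw DE p-value with \code{p_nde} into
#' \code{P_G}, applies one Benjamini-Hochberg pass over all \code{P_G}
#' values, and ranks. miRNAs absent from the ORA table are scored with
#' \code{p_nde = 1} and flagged \code{"not_in_interactions"}.
#'
#' @param mirna_fits A \code{moderated_fit} for the miRNA matrix.
#' @param ora An \code{ora_result} from [run_ora()].
#' @param prefilter_de_mirnas If \code{TRUE}, restrict scoring to miRNAs with
#'   BH-adjusted DE p-value below \code{alpha} before combining (off by
#'   default so every measured miRNA receives a rank).
#' @param alpha Significance level used by the pre-filter (default 0.01).
#' @return Data frame of class \code{"mimrda_scores"}, ordered by rank, with
#'   columns \code{mirna_id}, \code{p_mirna} (raw moderated-t p),
#'   \code{log_fc}, \code{m}, \code{x}, \code{p_nde}, \code{c}, \code{p_g},
#'   \code{p_g_fdr}, \code{rank}, \code{flags}.
#' @export
score_all <- function(mirna_fits, ora, prefilter_de_mirnas = FALSE,
                      alpha = 0.01) {
  fits <- as.data.frame(mirna_fits)
  if (!all(c("feature_id", "p_raw", "log_fc") %in% names(fits)))
    mimrda_error("'mirna_fits' must carry feature_id, p_raw and log_fc",
                 "mimrda_validation_error")
  if (prefilter_de_mirnas) fits <- fits[fits$p_adj < alpha, , drop = FALSE]
  if (!nrow(fits) || !nrow(ora))
    mimrda_error("empty join between miRNA fits and ORA results",
                 "mimrda_empty_join_error")
  idx <- match(fits$feature_id, ora$mirna_id)
  sc <- data.frame(
    mirna_id = fits$feature_id,
    p_mirna = fits$p_raw,
    log_fc = fits$log_fc,
    m = ifelse(is.na(idx), 0L, ora$m[idx]),
    x = ifelse(is.na(idx), 0L, ora$x[idx]),
    p_nde = ifelse(is.na(idx), 1, ora$p_nde[idx]),
    stringsAsFactors = FALSE)
  flags <- ifelse(is.na(idx), "not_in_interactions", ora$flags[idx])
  sc$c <- sc$p_nde * sc$p_mirna
  sc$p_g <- fisher_combine(sc$p_nde, sc$p_mirna)
  sc$p_g_fdr <- bh_adjust(sc$p_g)
  sc$flags <- flags
  rank_mirnas(sc)
}

#' Rank miRNAs by global probability
#'
#' Ascending \code{p_g}; ties broken by ascending \code{p_nde}, then
#' ascending \code{p_mirna}, then lexicographic \code{mirna_id}. The
#' \code{rank} column is assigned 1..n and rows are returned in rank order.
#'
#' @param scores Data frame with \code{p_g}, \code{p_nde}, \code{p_mirna}
#'   and \code{mirna_id}.
#' @return The reordered table, classed \code{"mimrda_scores"}.
#' @export
rank_mirnas <- function(scores) {
  o <- order(scores$p_g, scores$p_nde, scores$p_mirna, scores$mirna_id,
             method = "radix")
  scores <- scores[o, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  lead <- intersect(c("mirna_id", "p_mirna", "log_fc", "m", "x", "p_nde",
                      "c", "p_g", "p_g_fdr", "rank", "flags"),
                    names(scores))
  scores <- scores[, c(lead, setdiff(names(scores), lead)), drop = FALSE]
  class(scores) <- c("mimrda_scores", "data.frame")
  scores
}

#' Ranked miRNA identifiers under alternative statistics
#'
#' Ranking by \code{p_g} reproduces the table's own order; \code{p_mirna}
#' and \code{p_nde} give the orderings a differential-expression-only or
#' ORA-only analysis would produce (ties by \code{mirna_id}).
#'
#' @param scores A \code{mimrda_scores} table.
#' @param by One of \code{"p_g"}, \code{"p_mirna"}, \code{"p_nde"}.
#' @return Character vector of miRNA identifiers, best first.
#' @export
ranked_ids <- function(scores, by = c("p_g", "p_mirna", "p_nde")) {
  by <- match.arg(by)
  o <- switch(by,
    p_g = order(scores$p_g, scores$p_nde, scores$p_mirna, scores$mirna_id,
                method = "radix"),
    p_mirna = order(scores$p_mirna, scores$mirna_id, method = "radix"),
    p_nde = order(scores$p_nde, scores$mirna_id, method = "radix"))
  scores$mirna_id[o]
}
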