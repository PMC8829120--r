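# Target-set over-representation: for each miRNA, the upper-tail
# hypergeometric probability that at least x of its m validated targets in a
# universe of M mRNAs (k of them differentially expressed) are DE by chance.

#' Build the mRNA universe for over-representation analysis
#'
#' @param interactions An [interaction_table()].
#' @param measured_mrnas Character vector of mRNAs present in the expression
#'   matrix (required in \code{"measured_intersection"} mode).
#' @param mode \code{"measured_intersection"} (default): mRNAs that are both
#'   targeted by at least one miRNA and measured -- the sampling model then
#'   matches the data actually tested. \code{"interaction_table"}: every mRNA
#'   in the interaction table.
#' @return Object of class \code{"ora_universe"}: list with \code{mrna_ids}
#'   (sorted) and \code{mode}.
#' @export
build_universe <- function(interactions, measured_mrnas = NULL,
                           mode = c("measured_intersection",
                                    "interaction_table")) {
  mode <- match.arg(mode)
  if (!inherits(interactions, "interaction_table"))
    mimrda_error("'interactions' must be an interaction_table",
                 "mimrda_validation_error")
  if (!nrow(interactions))
    mimrda_error("interaction table is empty", "mimrda_config_error")
  ids <- sort(unique(interactions$mrna_id), method = "radix")
  if (mode == "measured_intersection") {
    if (is.null(measured_mrnas))
      mimrda_error("'measured_mrnas' required in measured_intersection mode",
                   "mimrda_config_error")
    ids <- ids[ids %in% measured_mrnas]
  }
  if (!length(ids))
    mimrda_error("resulting mRNA universe is empty", "mimrda_config_error")
  structure(list(mrna_ids = ids, mode = mode), class = "ora_universe")
}

#' @export
print.ora_universe <- function(x, ...) {
  cat(sprintf("ora_universe: M = %d mRNAs (mode: %s)\n",
              length(x$mrna_ids), x$mode))
  invisible(x)
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing \code{x} or more DE targets among \code{m}
#' targets when \code{k} of the \code{M} universe genes are DE:
#' \code{sum_{j >= x} C(m, j) C(M - m, k - j) / C(M, k)}. Exactly 1 when
#' \code{x = 0}.
#'
#' @param M Universe size.
#' @param k Number of DE genes in the universe (draws).
#' @param m Target-set size within the universe (successes).
#' @param x Observed number of DE targets.
#' @return The tail probability, in \code{(0, 1]}. Vectorized with recycling.
#' @export
hypergeom_sf <- function(M, k, m, x) {
  n <- max(length(M), length(k), length(m), length(x))
  M <- rep_len(as.numeric(M), n)
  k <- rep_len(as.numeric(k), n)
  m <- rep_len(as.numeric(m), n)
  x <- rep_len(as.numeric(x), n)
  if (anyNA(c(M, k, m, x)) || any(c(M, k, m, x) < 0) ||
      any(c(M, k, m, x) != floor(c(M, k, m, x))))
    mimrda_error("M, k, m, x must be non-negative integers",
                 "mimrda_validation_error")
  if (any(m > M) || any(k > M) || any(x > pmin(m, k)))
    mimrda_error("need x <= min(m, k), m <= M and k <= M",
                 "mimrda_validation_error")
  p <- ifelse(x <= 0, 1,
              stats::phyper(x - 1, m, M - m, k, lower.tail = FALSE))
  pmin(p, 1)
}

#' Over-representation analysis of every miRNA's target set
#'
#' @param interactions An [interaction_table()].
#' @param de_mrnas Character vector of DE mRNA identifiers (the dataset-wide
#'   DE set; its size is reported as \code{N}).
#' @param universe An [build_universe()] result.
#' @param min_targets Minimum in-universe target-set size to test (default
#'   1). miRNAs below it -- including \code{m = 0} -- get \code{p_nde = 1}
#'   and a flag instead of being dropped.
#' @param mirnas Optional character vector of miRNAs to score (e.g. all
#'   measured miRNAs); defaults to the miRNAs in the interaction table.
#'   miRNAs without table entries are flagged \code{"no_targets"}.
#' @return Data frame of class \code{"ora_result"}, ordered by
#'   \code{mirna_id}, with columns \code{mirna_id}, \code{m}, \code{x},
#'   \code{k}, \code{M}, \code{N}, \code{p_nde}, \code{flags}.
#' @export
run_ora <- function(interactions, de_mrnas, universe, min_targets = 1L,
                    mirnas = NULL) {
  if (!inherits(universe, "ora_universe"))
    mimrda_error("'universe' must come from build_universe()",
                 "mimrda_validation_error")
  if (!inherits(interactions, "interaction_table"))
    mimrda_error("'interactions' must be an interaction_table",
                 "mimrda_validation_error")
  de_mrnas <- unique(as.character(de_mrnas))
  univ <- universe$mrna_ids
  M <- length(univ)
  de_in_univ <- de_mrnas[de_mrnas %in% univ]
  k <- length(de_in_univ)
  N <- length(de_mrnas)
  mirnas <- if (is.null(mirnas)) {
    unique(interactions$mirna_id)
  } else {
    unique(as.character(mirnas))
  }
  mirnas <- sort(mirnas, method = "radix")
  keep <- interactions$mrna_id %in% univ
  targets <- split(interactions$mrna_id[keep], interactions$mirna_id[keep])
  m <- integer(length(mirnas))
  x <- integer(length(mirnas))
  idx <- match(mirnas, names(targets))
  for (i in seq_along(mirnas)) {
    if (is.na(idx[i])) next
    tg <- targets[[idx[i]]]
    m[i] <- length(tg)
    x[i] <- sum(tg %in% de_in_univ)
  }
  testable <- m >= max(1L, min_targets)
  p_nde <- rep(1, length(mirnas))
  if (any(testable))
    p_nde[testable] <- hypergeom_sf(M, k, m[testable], x[testable])
  flags <- character(length(mirnas))
  flags[m == 0L] <- "no_targets"
  flags[m > 0L & !testable] <- "below_min_targets"
  message(sprintf("run_ora: M = %d, k = %d, N = %d, %d miRNA(s) scored",
                  M, k, N, length(mirnas)))
  out <- data.frame(mirna_id = mirnas, m = m, x = x, k = k, M = M, N = N,
                    p_nde = p_nde, flags = flags,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ora_result", "data.frame")
  out
}
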