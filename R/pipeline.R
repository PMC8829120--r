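# End-to-end orchestration: read -> DE(mRNA) -> DE(miRNA) -> ORA ->
# combine -> rank -> write, with a run report echoing the stage counts.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    mimrda_error(sprintf("[%s] %s", stage, conditionMessage(e)),
                 "mimrda_stage_error")
  })
}

#' Run the full miRNA prioritization pipeline
#'
#' Computes the dataset-wide DE mRNA set (size \code{N}), per-miRNA
#' differential expression, the hypergeometric over-representation of each
#' miRNA's validated targets, combines both p-values into the global
#' probability and ranks all measured miRNAs.
#'
#' @param mrna_expr,mirna_expr [expression_matrix()] objects sharing the
#'   sample set described by \code{meta}.
#' @param meta A [sample_metadata()] table.
#' @param interactions An [interaction_table()] of validated miRNA->mRNA
#'   pairs.
#' @param alpha_mrna,alpha_mirna BH-adjusted significance levels (default
#'   0.01 each).
#' @param universe_mode Passed to [build_universe()].
#' @param min_targets Passed to [run_ora()].
#' @param prefilter_de_mirnas Passed to [score_all()].
#' @param ordinary_t Disable variance moderation (see [de_analysis()]).
#' @return Object of class \code{"mimrda_result"}: list with \code{scores}
#'   (the ranked table), \code{mrna_de}, \code{mirna_de}, \code{ora} and
#'   \code{report} (stage counts and the configuration).
#' @export
run_mimrda <- function(mrna_expr, mirna_expr, meta, interactions,
                       alpha_mrna = 0.01, alpha_mirna = 0.01,
                       universe_mode = c("measured_intersection",
                                         "interaction_table"),
                       min_targets = 1L, prefilter_de_mirnas = FALSE,
                       ordinary_t = FALSE) {
  universe_mode <- match.arg(universe_mode)
  for (a in c(alpha_mrna, alpha_mirna))
    if (!is.numeric(a) || a <= 0 || a >= 1)
      mimrda_error("significance levels must lie in (0, 1)",
                   "mimrda_config_error")
  mrna_de <- with_stage("diffexpr_mrna",
                        de_analysis(mrna_expr, meta, alpha_mrna, ordinary_t))
  de_mrnas <- select_de(mrna_de, alpha_mrna)
  mirna_de <- with_stage("diffexpr_mirna",
                         de_analysis(mirna_expr, meta, alpha_mirna,
                                     ordinary_t))
  universe <- with_stage("build_universe",
                         build_universe(interactions,
                                        rownames(mrna_expr$values),
                                        universe_mode))
  ora <- with_stage("target_ora",
                    run_ora(interactions, de_mrnas, universe, min_targets,
                            mirnas = rownames(mirna_expr$values)))
  scores <- with_stage("global_score",
                       score_all(mirna_de, ora, prefilter_de_mirnas,
                                 alpha_mirna))
  report <- list(
    n_mrna = nrow(mrna_expr$values),
    n_mirna = nrow(mirna_expr$values),
    n_samples = ncol(mrna_expr$values),
    N = length(de_mrnas),
    de_mirna_count = sum(mirna_de$is_de),
    M = length(universe$mrna_ids),
    k = ora$k[1L],
    n_scored = nrow(scores),
    config = list(alpha_mrna = alpha_mrna, alpha_mirna = alpha_mirna,
                  universe_mode = universe_mode, min_targets = min_targets,
                  prefilter_de_mirnas = prefilter_de_mirnas,
                  ordinary_t = ordinary_t))
  structure(list(scores = scores, mrna_de = mrna_de, mirna_de = mirna_de,
                 ora = ora, report = report),
            class = "mimrda_result")
}

#' @export
print.mimrda_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "mimrda_result: %d miRNAs ranked | N = %d DE mRNAs | M = %d, k = %d\n",
    r$n_scored, r$N, r$M, r$k))
  cat("top of the ranking:\n")
  print(utils::head(as.data.frame(
    x$scores[, c("mirna_id", "p_mirna", "p_nde", "p_g", "p_g_fdr",
                 "rank")]), 5L))
  invisible(x)
}

#' File-based pipeline run
#'
#' Reads the four inputs, runs [run_mimrda()] and writes
#' \code{scores.tsv} plus \code{report.json} under \code{out_dir}.
#'
#' @param mrna_path,mirna_path Expression TSVs (features x samples).
#' @param meta_path Sample metadata TSV.
#' @param interactions_path Interaction TSV.
#' @param out_dir Output directory (created if needed).
#' @param log2_transform Apply \code{log2(x + 1)} to both expression
#'   matrices on read.
#' @param ... Further arguments to [run_mimrda()].
#' @return The \code{mimrda_result}, invisibly.
#' @export
run_mimrda_files <- function(mrna_path, mirna_path, meta_path,
                             interactions_path, out_dir = ".",
                             log2_transform = FALSE, ...) {
  mrna <- read_expression(mrna_path, "mRNA", log2_transform)
  mirna <- read_expression(mirna_path, "miRNA", log2_transform)
  meta <- read_metadata(meta_path)
  interactions <- read_interactions(interactions_path)
  res <- run_mimrda(mrna, mirna, meta, interactions, ...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_scores(res$scores, file.path(out_dir, "scores.tsv"))
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
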