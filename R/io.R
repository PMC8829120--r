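# Readers/writers for the plain-text formats the pipeline consumes:
# expression TSVs (features x samples), sample metadata, validated
# miRNA->mRNA interaction pairs, label sets and the ranked score table.

#' Construct an expression matrix
#'
#' A thin validated container for a features x samples matrix of log2-scale
#' expression values. Row names are feature identifiers (mRNAs or miRNAs),
#' column names are sample identifiers; both must be unique and all values
#' finite.
#'
#' @param values Numeric matrix (features x samples) with row and column
#'   names. Values are assumed to be on the log2 scale.
#' @param feature_kind Either \code{"mRNA"} or \code{"miRNA"}.
#' @return An object of class \code{"expression_matrix"}: a list with
#'   elements \code{values} and \code{feature_kind}.
#' @export
expression_matrix <- function(values, feature_kind = c("mRNA", "miRNA")) {
  feature_kind <- match.arg(feature_kind)
  if (!is.matrix(values) || !is.numeric(values))
    mimrda_error("'values' must be a numeric matrix", "mimrda_format_error")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    mimrda_error("'values' must have feature (row) and sample (column) names",
                 "mimrda_format_error")
  if (anyDuplicated(rownames(values)))
    mimrda_error("duplicate feature identifiers", "mimrda_duplicate_id_error")
  if (anyDuplicated(colnames(values)))
    mimrda_error("duplicate sample identifiers", "mimrda_duplicate_id_error")
  if (!all(is.finite(values)))
    mimrda_error("expression values must all be finite numbers",
                 "mimrda_nonnumeric_error")
  structure(list(values = values, feature_kind = feature_kind),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d %s features x %d samples (log2 scale)\n",
              nrow(x$values), x$feature_kind, ncol(x$values)))
  invisible(x)
}

#' Feature and sample identifiers of an expression matrix
#' @param x An \code{expression_matrix}.
#' @return Character vector of identifiers.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers; the first column holds feature
#' identifiers and the remaining cells are numeric expression values.
#'
#' @inheritParams expression_matrix
#' @param path Path to a tab-separated file.
#' @param log2_transform If \code{TRUE}, apply \code{log2(x + 1)} to the
#'   values (for matrices supplied as raw counts/quantifications).
#' @return An \code{expression_matrix}.
#' @export
read_expression <- function(path, feature_kind = c("mRNA", "miRNA"),
                            log2_transform = FALSE) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path))
    mimrda_error(sprintf("file not found: %s", path),
                 "mimrda_missing_file_error")
  raw <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character"),
    error = function(e) mimrda_error(
      sprintf("cannot parse expression TSV '%s': %s", path,
              conditionMessage(e)),
      "mimrda_format_error"))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    mimrda_error(sprintf("expression TSV '%s' has no data rows/columns", path),
                 "mimrda_format_error")
  ids <- trimws(raw[[1L]])
  if (anyDuplicated(ids))
    mimrda_error(sprintf("duplicate feature identifiers in '%s': %s", path,
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")),
                 "mimrda_duplicate_id_error")
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals))
    mimrda_error(sprintf("non-numeric expression value(s) in '%s'", path),
                 "mimrda_nonnumeric_error")
  dimnames(vals) <- list(ids, trimws(colnames(raw)[-1L]))
  if (log2_transform) vals <- log2(vals + 1)
  expression_matrix(vals, feature_kind)
}

#' Construct/validate a sample metadata table
#'
#' @param df Data frame with columns \code{sample_id}, \code{group} (values
#'   \code{"tumor"} or \code{"normal"}) and, optionally, both \code{time}
#'   (non-negative survival time in days) and \code{event} (logical, death
#'   observed).
#' @return The validated data frame, classed \code{"sample_metadata"}.
#' @export
sample_metadata <- function(df) {
  if (!is.data.frame(df) || !all(c("sample_id", "group") %in% names(df)))
    mimrda_error("metadata needs columns 'sample_id' and 'group'",
                 "mimrda_format_error")
  df$sample_id <- trimws(as.character(df$sample_id))
  df$group <- trimws(as.character(df$group))
  if (anyDuplicated(df$sample_id))
    mimrda_error("duplicate sample identifiers in metadata",
                 "mimrda_duplicate_id_error")
  bad <- setdiff(unique(df$group), c("tumor", "normal"))
  if (length(bad))  # malformed rows are a hard error, never dropped
    mimrda_error(sprintf("unknown group label(s): %s",
                         paste(bad, collapse = ", ")),
                 "mimrda_metadata_error")
  has_time <- "time" %in% names(df)
  has_event <- "event" %in% names(df)
  if (has_time != has_event)
    mimrda_error("'time' and 'event' must be supplied together",
                 "mimrda_metadata_error")
  if (has_time) {
    df$time <- as.numeric(df$time)
    if (anyNA(df$time) || any(df$time < 0))
      mimrda_error("'time' must be non-negative numbers",
                   "mimrda_metadata_error")
    ev <- df$event
    if (is.character(ev)) ev <- trimws(ev)
    ev <- suppressWarnings(as.logical(as.numeric(ev)))
    if (anyNA(ev)) ev <- as.logical(df$event)
    if (anyNA(ev))
      mimrda_error("'event' must be logical or 0/1", "mimrda_metadata_error")
    df$event <- ev
  }
  class(df) <- c("sample_metadata", "data.frame")
  df
}

validate_metadata <- function(meta) {
  if (inherits(meta, "sample_metadata")) return(meta)
  sample_metadata(as.data.frame(meta))
}

#' Read a sample metadata TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{group} and optionally
#'   \code{time} and \code{event}.
#' @return A \code{sample_metadata} data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path))
    mimrda_error(sprintf("file not found: %s", path),
                 "mimrda_missing_file_error")
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) mimrda_error(
      sprintf("cannot parse metadata TSV '%s': %s", path, conditionMessage(e)),
      "mimrda_format_error"))
  sample_metadata(df)
}

#' Construct a validated miRNA->mRNA interaction table
#'
#' Set semantics: duplicate pairs are collapsed and rows are stored in a
#' canonical (miRNA, mRNA) order, so the table is independent of input order.
#'
#' @param mirna_id,mrna_id Character vectors of equal length giving validated
#'   interaction pairs.
#' @return Data frame with columns \code{mirna_id} and \code{mrna_id},
#'   classed \code{"interaction_table"}.
#' @export
interaction_table <- function(mirna_id = character(), mrna_id = character()) {
  mirna_id <- trimws(as.character(mirna_id))
  mrna_id <- trimws(as.character(mrna_id))
  if (length(mirna_id) != length(mrna_id))
    mimrda_error("'mirna_id' and 'mrna_id' must have equal length",
                 "mimrda_format_error")
  if (any(!nzchar(mirna_id)) || any(!nzchar(mrna_id)))
    mimrda_error("empty identifiers in interaction table",
                 "mimrda_format_error")
  df <- unique(data.frame(mirna_id = mirna_id, mrna_id = mrna_id,
                          stringsAsFactors = FALSE))
  df <- df[order(df$mirna_id, df$mrna_id, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interaction_table", "data.frame")
  df
}

#' Read a miRNA->mRNA interaction TSV
#'
#' Two tab-separated columns (mirna_id, mrna_id). A first line whose fields
#' look like column headers (e.g. \code{mirna_id}, \code{target}) is skipped.
#' Duplicate pairs are collapsed.
#'
#' @param path Path to the TSV.
#' @return An \code{interaction_table}.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path))
    mimrda_error(sprintf("file not found: %s", path),
                 "mimrda_missing_file_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(interaction_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    mimrda_error(sprintf(
      "interaction TSV '%s': every row must have exactly two columns", path),
      "mimrda_format_error")
  m <- matrix(trimws(unlist(parts)), ncol = 2L, byrow = TRUE)
  hdr <- tolower(m[1L, ])
  mir_tokens <- c("mirna", "mirna_id", "mir", "mir_id", "microrna")
  mrna_tokens <- c("mrna", "mrna_id", "gene", "gene_id", "target",
                   "target_id", "target_gene")
  if (hdr[1L] %in% mir_tokens || hdr[2L] %in% mrna_tokens)
    m <- m[-1L, , drop = FALSE]
  tab <- interaction_table(m[, 1L], m[, 2L])
  message(sprintf("read_interactions: %d validated pairs (%d miRNAs, %d mRNAs)",
                  nrow(tab), length(unique(tab$mirna_id)),
                  length(unique(tab$mrna_id))))
  tab
}

#' Construct a label set of known disease-associated miRNAs
#'
#' @param mirna_ids Character vector of miRNA identifiers (deduplicated).
#' @param source_name Free-text provenance label.
#' @return Object of class \code{"label_set"}.
#' @export
label_set <- function(mirna_ids, source_name = "labels") {
  ids <- unique(trimws(as.character(mirna_ids)))
  ids <- ids[nzchar(ids)]
  if (!length(ids))
    mimrda_error("label set is empty", "mimrda_validation_error")
  structure(list(mirna_ids = ids, source_name = source_name),
            class = "label_set")
}

#' Read a label file (one miRNA identifier per line)
#' @param path Path to the file.
#' @param source_name Provenance label; defaults to the file name.
#' @return A \code{label_set}.
#' @export
read_labels <- function(path, source_name = basename(path)) {
  if (!file.exists(path))
    mimrda_error(sprintf("file not found: %s", path),
                 "mimrda_missing_file_error")
  label_set(readLines(path, warn = FALSE), source_name)
}

.score_columns <- c("mirna_id", "p_mirna", "log_fc", "m", "x", "p_nde",
                    "c", "p_g", "p_g_fdr", "rank")

#' Write a ranked miRNA score table to TSV
#'
#' Rows are sorted by rank. Doubles are serialized with \code{\%.17g} so a
#' re-read reproduces them bit-exactly.
#'
#' @param scores Score table as returned by [score_all()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @seealso [read_scores()]
#' @export
write_scores <- function(scores, path) {
  missing_cols <- setdiff(.score_columns, names(scores))
  if (length(missing_cols))
    mimrda_error(sprintf("score table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "mimrda_format_error")
  out <- as.data.frame(scores)[order(scores$rank), .score_columns,
                               drop = FALSE]
  for (j in c("p_mirna", "log_fc", "p_nde", "c", "p_g", "p_g_fdr"))
    out[[j]] <- sprintf("%.17g", as.numeric(out[[j]]))
  for (j in c("m", "x", "rank"))
    out[[j]] <- sprintf("%d", as.integer(out[[j]]))
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE),
    error = function(e) mimrda_error(
      sprintf("cannot write scores to '%s': %s", path, conditionMessage(e)),
      "mimrda_write_error"))
  invisible(path)
}

#' Read back a score table written by [write_scores()]
#' @param path Path to the TSV.
#' @return Data frame with the score columns, sorted by rank.
#' @export
read_scores <- function(path) {
  if (!file.exists(path))
    mimrda_error(sprintf("file not found: %s", path),
                 "mimrda_missing_file_error")
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(.score_columns, names(df))
  if (length(missing_cols))
    mimrda_error(sprintf("score TSV lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "mimrda_format_error")
  for (j in c("p_mirna", "log_fc", "p_nde", "c", "p_g", "p_g_fdr"))
    df[[j]] <- as.numeric(df[[j]])
  for (j in c("m", "x", "rank"))
    df[[j]] <- as.integer(df[[j]])
  df[order(df$rank), , drop = FALSE]
}

#' Write an expression matrix to TSV (feature column + sample columns)
#' @param expr An \code{expression_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  out <- data.frame(feature_id = rownames(expr$values),
                    apply(expr$values, 2L, function(v) sprintf("%.17g", v)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
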