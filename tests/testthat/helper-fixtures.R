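# Small in-code fixtures shared across test files.

# Expression matrix from a plain numeric matrix with default labels.
make_expr <- function(values, kind = "mRNA",
                      features = sprintf("f%02d", seq_len(nrow(values))),
                      samples = sprintf("s%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(features, samples)
  expression_matrix(values, kind)
}

make_meta <- function(n_tumor, n_normal,
                      samples = sprintf("s%02d", seq_len(n_tumor + n_normal))) {
  sample_metadata(data.frame(
    sample_id = samples,
    group = rep(c("tumor", "normal"), c(n_tumor, n_normal)),
    stringsAsFactors = FALSE))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# probability that a uniformly drawn k-subset of {1..M} contains at least x
# elements of {1..m}. Enumerates all choose(M, k) subsets.
hyper_tail_enum <- function(M, k, m, x) {
  if (k == 0) return(as.numeric(x <= 0))
  subsets <- utils::combn(M, k)
  overlap <- colSums(subsets <= m)
  mean(overlap >= x)
}

# Brute-force BH step-up: adj_i = min over j with p_j ranked >= rank(i) of
# p_(j) * n / j, capped at 1.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(1, min((n / (i:n)) * ps[i:n]))
  out <- numeric(n)
  out[o] <- adj
  out
}
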