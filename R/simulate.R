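# Seeded generators emulating the statistical structure the method assumes:
# log2 expression with planted group effects, a bipartite miRNA->mRNA target
# network with planted enrichment for "disease" miRNAs, and exponential
# survival times with group-dependent hazard.

#' Simulate a two-group log2 expression matrix with planted effects
#'
#' Baseline per-feature means are Normal(8, 2) on the log2 scale with
#' Normal(0, sigma) noise; a planted fraction of features gains
#' \code{effect_size} in the tumor group. Fully deterministic under
#' \code{seed}.
#'
#' @param n_features Number of features.
#' @param n_tumor,n_normal Samples per group (each >= 2).
#' @param de_fraction Fraction of features planted as differentially
#'   expressed, in \code{[0, 1]}.
#' @param effect_size Log2 shift added to tumor samples of planted features.
#' @param sigma Within-group standard deviation (log2 units).
#' @param seed Integer seed.
#' @param feature_kind \code{"mRNA"} or \code{"miRNA"} (controls identifier
#'   prefixes \code{gene-}/\code{mir-}).
#' @param sample_ids Optional sample identifiers (length
#'   \code{n_tumor + n_normal}), tumor samples first.
#' @return List with \code{expr} (an [expression_matrix()]), \code{meta}
#'   (a [sample_metadata()] table) and \code{de_features} (planted feature
#'   identifiers).
#' @export
simulate_expression <- function(n_features, n_tumor, n_normal,
                                de_fraction = 0.1, effect_size = 1.5,
                                sigma = 1, seed = 1,
                                feature_kind = c("mRNA", "miRNA"),
                                sample_ids = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (n_features < 1L || n_tumor < 2L || n_normal < 2L)
    mimrda_error("need n_features >= 1 and >= 2 samples per group",
                 "mimrda_validation_error")
  if (de_fraction < 0 || de_fraction > 1 || sigma <= 0 ||
      !is.finite(effect_size))
    mimrda_error("invalid de_fraction/effect_size/sigma",
                 "mimrda_validation_error")
  set.seed(seed)
  prefix <- if (feature_kind == "miRNA") "mir-" else "gene-"
  fid <- sprintf("%s%04d", prefix, seq_len(n_features))
  n <- n_tumor + n_normal
  sid <- if (is.null(sample_ids)) sprintf("s%03d", seq_len(n)) else sample_ids
  if (length(sid) != n)
    mimrda_error("'sample_ids' must have length n_tumor + n_normal",
                 "mimrda_validation_error")
  group <- rep(c("tumor", "normal"), c(n_tumor, n_normal))
  base <- stats::rnorm(n_features, 8, 2)
  vals <- base + matrix(stats::rnorm(n_features * n, 0, sigma),
                        n_features, n)
  n_de <- round(de_fraction * n_features)
  de <- if (n_de > 0) sort(sample(fid, n_de)) else character(0)
  if (n_de > 0)
    vals[fid %in% de, group == "tumor"] <-
      vals[fid %in% de, group == "tumor"] + effect_size
  dimnames(vals) <- list(fid, sid)
  list(expr = expression_matrix(vals, feature_kind),
       meta = sample_metadata(data.frame(sample_id = sid, group = group,
                                         stringsAsFactors = FALSE)),
       de_features = de)
}

#' Simulate a bipartite miRNA->mRNA target network
#'
#' Target-set sizes are drawn from a negative binomial around
#' \code{mean_degree} (variance \code{mu + dispersion * mu^2}; zero
#' dispersion gives a constant degree) and targets are sampled without
#' replacement, so the table never contains duplicate pairs.
#'
#' @param n_mirna,n_mrna Numbers of miRNAs and mRNAs (identifiers
#'   \code{mir-0001}..., \code{gene-0001}...).
#' @param mean_degree Mean target-set size; must not exceed \code{n_mrna}.
#' @param degree_dispersion Negative-binomial dispersion (0 = constant
#'   degree).
#' @param seed Integer seed.
#' @return An [interaction_table()].
#' @export
simulate_interactions <- function(n_mirna, n_mrna, mean_degree,
                                  degree_dispersion = 0, seed = 1) {
  if (n_mirna < 1L || n_mrna < 1L || mean_degree <= 0 ||
      degree_dispersion < 0)
    mimrda_error("invalid network parameters", "mimrda_validation_error")
  if (mean_degree > n_mrna)
    mimrda_error("mean_degree cannot exceed n_mrna",
                 "mimrda_validation_error")
  set.seed(seed)
  mir <- sprintf("mir-%04d", seq_len(n_mirna))
  genes <- sprintf("gene-%04d", seq_len(n_mrna))
  deg <- if (degree_dispersion == 0) {
    rep(as.integer(round(mean_degree)), n_mirna)
  } else {
    stats::rnbinom(n_mirna, mu = mean_degree, size = 1 / degree_dispersion)
  }
  deg <- pmin(deg, n_mrna)
  pairs <- lapply(seq_len(n_mirna), function(i)
    if (deg[i] > 0) sample(genes, deg[i]) else character(0))
  interaction_table(rep(mir, deg), unlist(pairs))
}

#' Plant target-set enrichment for disease miRNAs
#'
#' Rewires each disease miRNA's target set so that a fraction
#' \code{enrichment_rho} of its targets lies in \code{de_mrnas}, preserving
#' every miRNA's degree. Rewiring only adds DE targets (a set already above
#' the requested fraction is left alone); non-disease miRNAs are untouched.
#'
#' @param interactions An [interaction_table()].
#' @param de_mrnas Character vector of DE mRNA identifiers.
#' @param disease_mirnas miRNAs to enrich (must appear in the table).
#' @param enrichment_rho Target DE fraction per disease miRNA, in
#'   \code{[0, 1]}.
#' @param seed Integer seed.
#' @return A new [interaction_table()].
#' @export
plant_disease_mirnas <- function(interactions, de_mrnas, disease_mirnas,
                                 enrichment_rho, seed = 1) {
  if (enrichment_rho < 0 || enrichment_rho > 1)
    mimrda_error("'enrichment_rho' must lie in [0, 1]",
                 "mimrda_validation_error")
  if (!inherits(interactions, "interaction_table"))
    mimrda_error("'interactions' must be an interaction_table",
                 "mimrda_validation_error")
  absent <- setdiff(disease_mirnas, interactions$mirna_id)
  if (length(absent))
    mimrda_error(sprintf("disease miRNA(s) absent from the table: %s",
                         paste(absent, collapse = ", ")),
                 "mimrda_validation_error")
  set.seed(seed)
  df <- as.data.frame(interactions)
  de_mrnas <- unique(as.character(de_mrnas))
  for (mir in sort(unique(disease_mirnas), method = "radix")) {
    rows <- which(df$mirna_id == mir)
    tg <- df$mrna_id[rows]
    want <- round(enrichment_rho * length(tg))
    is_de <- tg %in% de_mrnas
    need <- want - sum(is_de)
    if (need <= 0) next
    pool <- setdiff(de_mrnas, tg)
    if (length(pool) < need)
      mimrda_error(sprintf(
        "|de_mrnas| too small to enrich '%s' to rho = %g without duplicates",
        mir, enrichment_rho), "mimrda_validation_error")
    swap_out <- sample(which(!is_de), need)
    df$mrna_id[rows[swap_out]] <- sample(pool, need)
  }
  interaction_table(df$mirna_id, df$mrna_id)
}

#' Simulate survival times with group-dependent hazard
#'
#' Event times are exponential; the \code{"high"} (expression) group's
#' hazard is \code{hr} times the \code{"low"} group's, whose median survival
#' is \code{median_low_group}. Censoring times are Uniform(0, b) with
#' \code{b} solved so the expected censored fraction equals
#' \code{censor_rate}.
#'
#' @param n Number of subjects (split as evenly as possible into high/low).
#' @param hr Hazard ratio, high vs low (> 0).
#' @param median_low_group Median survival of the low group (days).
#' @param censor_rate Expected censored fraction, in \code{[0, 1)}.
#' @param seed Integer seed.
#' @return Data frame with columns \code{sample_id}, \code{group}
#'   (\code{"high"}/\code{"low"}), \code{time}, \code{event}.
#' @export
simulate_survival <- function(n, hr, median_low_group = 730,
                              censor_rate = 0.2, seed = 1) {
  if (n < 4L || hr <= 0 || median_low_group <= 0 ||
      censor_rate < 0 || censor_rate >= 1)
    mimrda_error("invalid survival simulation parameters",
                 "mimrda_validation_error")
  set.seed(seed)
  n_high <- ceiling(n / 2)
  group <- rep(c("high", "low"), c(n_high, n - n_high))
  rate_low <- log(2) / median_low_group
  rate <- ifelse(group == "high", hr * rate_low, rate_low)
  t_event <- stats::rexp(n, rate)
  if (censor_rate > 0) {
    # P(censored | b) = mean over subjects of (1 - exp(-rate*b)) / (rate*b),
    # decreasing in b from 1 to 0; invert for the requested rate.
    f <- function(b) mean((1 - exp(-rate * b)) / (rate * b)) - censor_rate
    upper <- median_low_group
    while (f(upper) > 0) upper <- upper * 2
    b <- stats::uniroot(f, lower = median_low_group * 1e-6, upper = upper,
                        tol = 1e-8)$root
    cens <- stats::runif(n, 0, b)
    time <- pmin(t_event, cens)
    event <- t_event <= cens
  } else {
    time <- t_event
    event <- rep(TRUE, n)
  }
  data.frame(sample_id = sprintf("s%03d", seq_len(n)), group = group,
             time = time, event = event, stringsAsFactors = FALSE)
}

# Deterministic fan-out of one master seed into per-component seeds.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% (2^31 - 1))
}

#' Simulate a complete desk-scale dataset
#'
#' Generates paired mRNA and miRNA expression matrices (same samples), a
#' target network whose planted "disease" miRNAs have target sets enriched
#' for planted DE mRNAs, and the ground truth. The defaults are the
#' desk-scale preset used throughout the package's tests: 2,000 mRNAs, 300
#' miRNAs, 30 + 30 samples, mean degree 40, 10\% DE features, effect size
#' 1.5, enrichment rho 0.4 and 20 disease miRNAs. All randomness flows from
#' the single master \code{seed}, fanned out to component seeds by fixed
#' offsets (1 = mRNA expression, 2 = miRNA expression, 3 = network,
#' 4 = disease-miRNA choice, 5 = enrichment rewiring).
#'
#' @param n_mrna,n_mirna Feature counts.
#' @param n_tumor,n_normal Samples per group.
#' @param de_fraction Planted DE fraction (both feature kinds).
#' @param effect_size Planted log2 effect (both feature kinds).
#' @param sigma Within-group standard deviation.
#' @param mean_degree,degree_dispersion Target-network degree model.
#' @param n_disease Number of disease miRNAs (drawn from the planted DE
#'   miRNAs, so \code{disease_mirnas} is a subset of \code{de_mirnas}).
#' @param enrichment_rho Planted DE-target fraction for disease miRNAs.
#' @param seed Master seed.
#' @return List with \code{mrna}, \code{mirna} (expression matrices),
#'   \code{meta}, \code{interactions} and \code{truth} (list with
#'   \code{de_mrnas}, \code{de_mirnas}, \code{disease_mirnas}, \code{seed},
#'   \code{params}).
#' @export
simulate_dataset <- function(n_mrna = 2000, n_mirna = 300, n_tumor = 30,
                             n_normal = 30, de_fraction = 0.1,
                             effect_size = 1.5, sigma = 1, mean_degree = 40,
                             degree_dispersion = 0.2, n_disease = 20,
                             enrichment_rho = 0.4, seed = 1) {
  mr <- simulate_expression(n_mrna, n_tumor, n_normal, de_fraction,
                            effect_size, sigma, derive_seed(seed, 1),
                            feature_kind = "mRNA")
  mi <- simulate_expression(n_mirna, n_tumor, n_normal, de_fraction,
                            effect_size, sigma, derive_seed(seed, 2),
                            feature_kind = "miRNA",
                            sample_ids = mr$meta$sample_id)
  net <- simulate_interactions(n_mirna, n_mrna, mean_degree,
                               degree_dispersion, derive_seed(seed, 3))
  if (n_disease > length(mi$de_features))
    mimrda_error("n_disease exceeds the number of planted DE miRNAs",
                 "mimrda_validation_error")
  set.seed(derive_seed(seed, 4))
  disease <- sort(sample(mi$de_features, n_disease))
  if (enrichment_rho > 0 && n_disease > 0)
    net <- plant_disease_mirnas(net, mr$de_features, disease,
                                enrichment_rho, derive_seed(seed, 5))
  params <- list(n_mrna = n_mrna, n_mirna = n_mirna, n_tumor = n_tumor,
                 n_normal = n_normal, de_fraction = de_fraction,
                 effect_size = effect_size, sigma = sigma,
                 mean_degree = mean_degree,
                 degree_dispersion = degree_dispersion,
                 n_disease = n_disease, enrichment_rho = enrichment_rho)
  list(mrna = mr$expr, mirna = mi$expr, meta = mr$meta,
       interactions = net,
       truth = list(de_mrnas = mr$de_features, de_mirnas = mi$de_features,
                    disease_mirnas = disease, seed = seed, params = params))
}
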