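Package: mimrda
Title: Ranking Disease-Associated miRNAs from Paired miRNA and mRNA
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes disease-associated microRNAs from paired tumor/normal
    miRNA and mRNA expression profiles. For every measured miRNA an
    empirical-Bayes moderated t-test p-value (differential expression of the
    miRNA itself) is combined, via Fisher's product, with an upper-tail
    hypergeometric p-value measuring over-representation of the miRNA's
    experimentally validated mRNA targets among differentially expressed
    mRNAs. The combined global probability is Benjamini-Hochberg adjusted and
    used to rank miRNAs. Includes seeded synthetic-data generators (expression
    matrices with planted effects, bipartite target networks with planted
    enrichment, survival times), Kaplan-Meier/log-rank verification with
    observed/expected hazard ratios, top-k label-overlap summaries, and a
    cross-validated random-forest AUC evaluation of ranked miRNA panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    ranger,
    stats,
    survival,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
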