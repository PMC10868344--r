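# Shared fixtures and independent oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

zero_missing <- c(
  biological_process = 0, cellular_compartment = 0,
  molecular_function = 0, domain = 0, motif = 0
)

fixture_universe <- function(seed, n_proteins = 300, ...) {
  generate_universe(synthetic_config(n_proteins = n_proteins, seed = seed,
                                     ...))
}

positives_from <- function(u) {
  data.frame(idA = u$edges$idA, idB = u$edges$idB,
             label = "positive", source = "curated",
             stringsAsFactors = FALSE)
}

gold_from <- function(u, scheme = "balanced", ratio = 1, seed = 1) {
  pos <- positives_from(u)
  assemble_gold_standard(
    pos, sample_negatives(pos, u$proteins, scheme, ratio, seed = seed)
  )
}

# Brute-force AUROC oracle: explicit enumeration of positive-negative
# pairs with ties counted half. Independent of the curve-based code path.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

# Rank-based AUROC for tight loops (Mann-Whitney with midranks).
fast_auc <- function(labels, scores) {
  r <- rank(scores, ties.method = "average")
  m <- sum(labels == 1)
  n <- length(labels) - m
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

# Permutation oracle for comparing two correlated ROC curves: model
# identity is flipped independently within each subject; the p-value is
# the fraction of permuted |AUC differences| at least as large as the
# observed one.
perm_roc_p <- function(labels, scoresA, scoresB, n_perm = 10000,
                       seed = 42) {
  obs <- abs(fast_auc(labels, scoresA) - fast_auc(labels, scoresB))
  set.seed(seed)
  n <- length(labels)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    sw <- stats::runif(n) < 0.5
    a <- ifelse(sw, scoresB, scoresA)
    b <- ifelse(sw, scoresA, scoresB)
    if (abs(fast_auc(labels, a) - fast_auc(labels, b)) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

mean_positive_jaccard <- function(u, facet = "biological_process",
                                  n_pairs = 1000, seed = 99) {
  set.seed(seed)
  idx <- sample.int(nrow(u$edges), min(n_pairs, nrow(u$edges)))
  mean(vapply(idx, function(i) {
    facet_similarity(u$annotations[[u$edges$idA[i]]][[facet]],
                     u$annotations[[u$edges$idB[i]]][[facet]])[1]
  }, numeric(1)))
}

mean_random_jaccard <- function(u, facet = "biological_process",
                                n_pairs = 1000, seed = 98) {
  set.seed(seed)
  a <- sample(u$proteins, n_pairs, replace = TRUE)
  b <- sample(u$proteins, n_pairs, replace = TRUE)
  keep <- a != b
  mean(vapply(which(keep), function(i) {
    facet_similarity(u$annotations[[a[i]]][[facet]],
                     u$annotations[[b[i]]][[facet]])[1]
  }, numeric(1)))
}
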