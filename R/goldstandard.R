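# Gold-standard construction: curate positive interactions from evidence
# tables, compute positive-set degrees and hub status, and sample negative
# pairs under a uniform or degree-balanced endpoint marginal.

#' Curate positive interactions from an evidence table
#'
#' Drops self-pairs, then keeps an unordered pair if at least one of its
#' evidence records has a method class outside the excluded set
#' (any-qualifying-evidence rule). This removes low-quality interactions
#' such as those supported only by spatial colocalization, which are a
#' known source of false positives.
#'
#' @param evidence data frame with columns `idA`, `idB`, `method_class`
#'   (and optionally `n_publications`).
#' @param excluded_classes method classes that never qualify a pair on
#'   their own.
#' @return canonical data frame of positive pairs: `idA`, `idB`, `label`
#'   (`"positive"`), `source` (`"curated"`).
#' @export
curate_positives <- function(evidence,
                             excluded_classes = c("colocalization",
                                                  "predicted")) {
  if (is.null(evidence) || nrow(evidence) == 0)
    input_error("'evidence' is empty")
  if (!all(c("idA", "idB", "method_class") %in% names(evidence)))
    input_error("'evidence' needs columns idA, idB, method_class")
  ev <- evidence[as.character(evidence$idA) != as.character(evidence$idB), ,
                 drop = FALSE]
  keep <- !(ev$method_class %in% excluded_classes)
  ev <- ev[keep, , drop = FALSE]
  if (nrow(ev) == 0)
    infeasible_error("no positives survive filters")
  pos <- canonicalize_pairs(ev[, c("idA", "idB")])
  data.frame(
    idA = pos$idA, idB = pos$idB,
    label = "positive", source = "curated",
    stringsAsFactors = FALSE
  )
}

#' Positive-set degree table with hub flags
#'
#' Degree is the number of positive pairs a protein takes part in. Hubs are
#' the top `ceil(hub_quantile * n)` proteins by degree, ties at the cut
#' broken lexicographically by id; with the default quantile this is the
#' "top 20% of proteins by number of interactions".
#'
#' @param positives canonical positive pairs (`idA`, `idB`).
#' @param proteome optional character vector of all protein ids; proteins
#'   absent from `positives` get degree 0 and are never hubs by tie-break
#'   unless the quantile reaches them.
#' @param hub_quantile fraction of top-degree proteins flagged as hubs,
#'   strictly in (0, 1).
#' @return data frame `protein`, `degree`, `hub`.
#' @export
degree_table <- function(positives, proteome = NULL, hub_quantile = 0.20) {
  if (is.null(positives) || nrow(positives) == 0)
    input_error("'positives' is empty")
  endpoints <- c(positives$idA, positives$idB)
  counts <- table(endpoints)
  ids <- sort(unique(c(names(counts), proteome)))
  degree <- as.integer(counts[ids])
  degree[is.na(degree)] <- 0L
  data.frame(
    protein = ids, degree = degree,
    hub = hub_flags(ids, degree, hub_quantile),
    stringsAsFactors = FALSE
  )
}

#' Fraction of pairs touching a protein subset
#'
#' Share of pairs with at least one endpoint in `protein_subset`; the
#' statistic behind the contrast between hub involvement in positives
#' versus uniformly sampled negatives.
#'
#' @param pairs data frame with `idA`, `idB`.
#' @param protein_subset character vector of protein ids.
#' @return fraction in `[0, 1]`.
#' @export
endpoint_share <- function(pairs, protein_subset) {
  if (is.null(pairs) || nrow(pairs) == 0) input_error("'pairs' is empty")
  mean(pairs$idA %in% protein_subset | pairs$idB %in% protein_subset)
}

#' Sample negative pairs under a uniform or balanced endpoint marginal
#'
#' Draws `round(ratio * |positives|)` unique unordered non-positive pairs
#' by sampling the two endpoints independently from the scheme's marginal
#' distribution and rejecting self-pairs, known positives and duplicates.
#'
#' Under `uniform`, every proteome protein has equal mass: the negative set
#' is representative of the general pair population (hubs rarely involved).
#' Under `balanced`, a protein's mass is proportional to its endpoint
#' frequency in the positive set, so negatives mirror the positives' degree
#' profile; proteins with zero positive degree have zero mass. Balanced
#' sampling is intended for training sets; evaluation sets should use
#' uniform sampling.
#'
#' @param positives canonical positive pairs.
#' @param proteome character vector of sampleable protein ids (>= 3).
#' @param scheme `"uniform"` or `"balanced"`.
#' @param ratio negatives per positive (> 0).
#' @param seed integer seed; output is deterministic given it.
#' @param forbidden optional extra pairs (data frame `idA`, `idB`) that must
#'   not be re-drawn, e.g. negatives already present in another set.
#' @return data frame `idA`, `idB`, `label` (`"negative"`), `source`
#'   (`"sampled-uniform"` or `"sampled-balanced"`). The attribute
#'   `endpoint_draws` carries the raw endpoint draw counts before
#'   rejection, i.e. the empirical endpoint marginal of the scheme.
#' @export
sample_negatives <- function(positives, proteome,
                             scheme = c("uniform", "balanced"),
                             ratio = 1, seed = 1, forbidden = NULL) {
  scheme <- match.arg(scheme)
  if (length(proteome) < 3) config_error("'proteome' must have >= 3 proteins")
  if (!is.numeric(ratio) || ratio <= 0) config_error("'ratio' must be > 0")
  n_target <- round_half_up(ratio * nrow(positives))
  pos_keys <- pair_key(positives$idA, positives$idB)
  bad_keys <- pos_keys
  if (!is.null(forbidden) && nrow(forbidden) > 0)
    bad_keys <- union(bad_keys, pair_key(forbidden$idA, forbidden$idB))

  proteome <- sort(unique(as.character(proteome)))
  if (scheme == "uniform") {
    pool <- proteome
    weights <- rep(1, length(pool))
  } else {
    counts <- table(c(positives$idA, positives$idB))
    pool <- intersect(proteome, names(counts))
    weights <- as.numeric(counts[pool])
  }
  # Feasibility: candidate pairs are pairs of positive-mass proteins that
  # are not already positive/forbidden.
  k <- length(pool)
  in_pool <- function(keys) {
    parts <- strsplit(keys, "\t", fixed = TRUE)
    vapply(parts, function(p) all(p %in% pool), logical(1))
  }
  n_available <- k * (k - 1) / 2 - sum(in_pool(bad_keys))
  if (n_target > n_available)
    infeasible_error(sprintf(
      "requested %d negatives under '%s' sampling but only %d candidate pairs exist",
      n_target, scheme, n_available
    ))

  set.seed(seed)
  drawn <- character(0)
  out_a <- character(0)
  out_b <- character(0)
  raw_draws <- stats::setNames(integer(length(pool)), pool)
  guard <- 0L
  while (length(drawn) < n_target) {
    guard <- guard + 1L
    if (guard > 10000L)
      infeasible_error("negative sampling failed to converge; pool too constrained")
    n_batch <- max(100L, 2L * (n_target - length(drawn)))
    a <- sample(pool, n_batch, replace = TRUE, prob = weights)
    b <- sample(pool, n_batch, replace = TRUE, prob = weights)
    batch_counts <- table(c(a, b))
    raw_draws[names(batch_counts)] <- raw_draws[names(batch_counts)] +
      as.integer(batch_counts)
    ok <- a != b
    a <- a[ok]; b <- b[ok]
    keys <- pair_key(a, b)
    ok <- !(keys %in% bad_keys) & !(keys %in% drawn) & !duplicated(keys)
    a <- a[ok]; b <- b[ok]; keys <- keys[ok]
    take <- seq_len(min(length(keys), n_target - length(drawn)))
    drawn <- c(drawn, keys[take])
    out_a <- c(out_a, a[take])
    out_b <- c(out_b, b[take])
  }
  neg <- canonicalize_pairs(data.frame(idA = out_a, idB = out_b,
                                       stringsAsFactors = FALSE))
  out <- data.frame(
    idA = neg$idA, idB = neg$idB,
    label = "negative", source = paste0("sampled-", scheme),
    stringsAsFactors = FALSE
  )
  # Raw endpoint draw counts (before self-pair/positive/duplicate
  # rejection): the empirical face of the scheme's endpoint marginal. The
  # realized unique pair set necessarily under-represents hubs relative to
  # this marginal, because hub-hub candidates are consumed by the positive
  # set and saturated by deduplication.
  attr(out, "endpoint_draws") <- raw_draws
  out
}

#' Assemble a gold standard from positives and negatives
#'
#' Merges the two labelled sets into one canonical table, preserving source
#' tags, and fails on any pair appearing with both labels.
#'
#' @param positives,negatives data frames with `idA`, `idB`, `label`,
#'   `source`.
#' @return merged canonical gold-standard data frame.
#' @export
assemble_gold_standard <- function(positives, negatives) {
  pos <- canonicalize_pairs(positives)
  neg <- canonicalize_pairs(negatives)
  clash <- intersect(pair_key(pos$idA, pos$idB), pair_key(neg$idA, neg$idB))
  if (length(clash) > 0)
    integrity_error(sprintf(
      "%d pair(s) labelled both positive and negative, e.g. %s",
      length(clash), gsub("\t", "-", clash[1], fixed = TRUE)
    ))
  gold <- rbind(pos, neg)
  rownames(gold) <- NULL
  gold
}
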