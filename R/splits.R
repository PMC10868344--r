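# Train / T1 / T2 partitioning with controlled protein-level overlap.
#
# Pair-level disjointness between train and test is necessary but not
# sufficient: individual proteins shared between train and test pairs
# (protein-level overlap) inflate apparent performance for models that
# memorise proteins. T1 is a balanced (50% positive by default) test set
# deliberately populated across overlap strata, built around proteins held
# out of training; T2 keeps a realistic 1% positive prevalence to measure
# generalisation where interactions are rare.

#' Split configuration
#'
#' @param t1_size number of pairs in T1.
#' @param t2_size number of pairs in T2.
#' @param heldout_protein_fraction fraction of the proteome excluded from
#'   training pairs (default 0.10).
#' @param t1_positive_fraction positive fraction of T1 (default 0.50).
#' @param t2_positive_fraction positive fraction of T2 (default 0.01,
#'   the realistic prevalence regime).
#' @param seed integer seed.
#' @return validated list of class `ppi_split_config`.
#' @export
split_config <- function(t1_size, t2_size,
                         heldout_protein_fraction = 0.10,
                         t1_positive_fraction = 0.50,
                         t2_positive_fraction = 0.01,
                         seed = 1) {
  check_count(t1_size, "t1_size")
  check_count(t2_size, "t2_size")
  check_prob(heldout_protein_fraction, "heldout_protein_fraction")
  check_prob(t1_positive_fraction, "t1_positive_fraction")
  check_prob(t2_positive_fraction, "t2_positive_fraction")
  check_count(seed, "seed", min = 0)
  structure(
    list(
      t1_size = as.integer(t1_size), t2_size = as.integer(t2_size),
      heldout_protein_fraction = heldout_protein_fraction,
      t1_positive_fraction = t1_positive_fraction,
      t2_positive_fraction = t2_positive_fraction,
      seed = as.integer(seed)
    ),
    class = "ppi_split_config"
  )
}

#' Hold out proteins from training
#'
#' Uniformly random subset of `round(fraction * n)` proteins (round half
#' up) that no training pair may touch; T1 draws on these to populate its
#' one-seen and none-seen overlap strata.
#'
#' @param proteome character vector of protein ids.
#' @param fraction fraction to hold out, strictly in (0, 1).
#' @param seed integer seed.
#' @return character vector of held-out protein ids.
#' @export
hold_out_proteins <- function(proteome, fraction, seed = 1) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1)
    config_error("'fraction' must lie strictly in (0, 1)")
  proteome <- sort(unique(as.character(proteome)))
  size <- round_half_up(fraction * length(proteome))
  if (size == 0 || size >= length(proteome))
    config_error(sprintf(
      "held-out size %d is empty or the whole proteome (n = %d)",
      size, length(proteome)
    ))
  set.seed(seed)
  sort(sample(proteome, size))
}

#' Protein-level overlap stratum of a pair
#'
#' Counts how many of a pair's endpoints occur in the realized training
#' protein set: 2 is `both-seen`, 1 `one-seen`, 0 `none-seen`.
#'
#' @param pairs data frame with `idA`, `idB` (one or more rows).
#' @param train_protein_set character vector of proteins occurring in any
#'   training pair.
#' @return character vector of strata, one per row.
#' @export
overlap_stratum <- function(pairs, train_protein_set) {
  seen <- (pairs$idA %in% train_protein_set) +
    (pairs$idB %in% train_protein_set)
  c("none-seen", "one-seen", "both-seen")[seen + 1L]
}

#' Network-topology stratum of a pair
#'
#' Classifies a pair by the hub status of its endpoints: `hub-hub`,
#' `hub-lone` or `lone-lone`.
#'
#' @param pairs data frame with `idA`, `idB`.
#' @param degrees degree table from [degree_table()] (`protein`, `hub`).
#' @return character vector of strata, one per row.
#' @export
topology_stratum <- function(pairs, degrees) {
  hub <- stats::setNames(degrees$hub, degrees$protein)
  unknown <- setdiff(unique(c(pairs$idA, pairs$idB)), degrees$protein)
  if (length(unknown) > 0)
    lookup_error(paste0("proteins missing from degree table: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  n_hub <- as.integer(hub[pairs$idA]) + as.integer(hub[pairs$idB])
  c("lone-lone", "hub-lone", "hub-hub")[n_hub + 1L]
}

# Fill T1 strata for one label: even targets across the prospective
# none-seen (2 held-out endpoints), one-seen (1) and both-seen (0) pools,
# scarcest first, capped at pool size with the overflow carried to the
# both-seen pool. Fails loudly when a needed stratum is empty or the
# overflow cannot be absorbed.
fill_t1_strata <- function(pools, want, label) {
  strata <- c("none-seen", "one-seen", "both-seen")
  even <- want %/% 3L
  for (i in 1:3) {
    if (even > 0 && length(pools[[i]]) == 0)
      infeasible_error(sprintf(
        "cannot populate T1 %s stratum: no %s pairs available",
        strata[i], label
      ))
  }
  take <- integer(3)
  take[1] <- min(even, length(pools[[1]]))
  take[2] <- min(even, length(pools[[2]]))
  take[3] <- want - take[1] - take[2]
  if (length(pools[[3]]) < take[3])
    infeasible_error(sprintf(
      "cannot fill T1 both-seen stratum for %s pairs: need %d, pool has %d",
      label, take[3], length(pools[[3]])
    ))
  unlist(lapply(1:3, function(i) {
    if (take[i] == 0) integer(0)
    else pools[[i]][sample.int(length(pools[[i]]), take[i])]
  }))
}

#' Partition a gold standard into train, T1 and T2
#'
#' T1 is drawn first, at `t1_positive_fraction`, filling the three
#' overlap-related pools (pairs with 2, 1 and 0 held-out endpoints, i.e.
#' prospective none-seen, one-seen and both-seen pairs) as evenly as the
#' pool allows -- scarcest first, remainder to the both-seen pool. T2 is
#' then drawn from the remaining pairs at `t2_positive_fraction`; its
#' negatives come from remaining uniform-sampled gold negatives, topped up
#' with freshly uniform-sampled pairs when `proteome` is supplied (balanced
#' negatives are a training device and are not used for evaluation sets).
#' Train is every remaining pair with no held-out endpoint. Remaining pairs
#' touching held-out proteins can belong to no split and are returned with
#' split `unused` so nothing is dropped silently.
#'
#' Overlap strata in the output are computed against the realized train
#' protein set; topology strata against `degrees` (computed from the gold
#' positives when not supplied).
#'
#' @param gold gold-standard data frame (`idA`, `idB`, `label`, `source`).
#' @param heldout character vector of held-out protein ids, from
#'   [hold_out_proteins()].
#' @param config a [split_config()].
#' @param proteome optional proteome for topping up T2 negatives.
#' @param degrees optional degree table for topology strata.
#' @return data frame `idA`, `idB`, `label`, `source`, `split`
#'   (`train`/`T1`/`T2`/`unused`), `overlap_stratum`, `topology_stratum`.
#' @export
make_splits <- function(gold, heldout, config, proteome = NULL,
                        degrees = NULL) {
  if (!inherits(config, "ppi_split_config"))
    config_error("'config' must be built with split_config()")
  gold <- canonicalize_pairs(gold)
  keys <- pair_key(gold$idA, gold$idB)
  n_held <- (gold$idA %in% heldout) + (gold$idB %in% heldout)
  is_pos <- gold$label == "positive"

  t1_pos_n <- round_half_up(config$t1_size * config$t1_positive_fraction)
  t1_neg_n <- config$t1_size - t1_pos_n
  t2_pos_n <- round_half_up(config$t2_size * config$t2_positive_fraction)
  t2_neg_n <- config$t2_size - t2_pos_n

  set.seed(derive_seed(config$seed, "splits"))
  t1_idx <- integer(0)
  for (lab in c("positive", "negative")) {
    want <- if (lab == "positive") t1_pos_n else t1_neg_n
    pools <- lapply(c(2L, 1L, 0L), function(h) {
      which(gold$label == lab & n_held == h)
    })
    t1_idx <- c(t1_idx, fill_t1_strata(pools, want, lab))
  }

  remaining <- setdiff(seq_along(keys), t1_idx)
  rem_pos <- remaining[is_pos[remaining]]
  if (length(rem_pos) < t2_pos_n)
    infeasible_error(sprintf(
      "cannot fill T2 positives: need %d, %d remain", t2_pos_n,
      length(rem_pos)
    ))
  t2_pos_idx <- rem_pos[sample.int(length(rem_pos), t2_pos_n)]

  rem_unif_neg <- remaining[!is_pos[remaining] &
                              gold$source[remaining] == "sampled-uniform"]
  t2_neg_idx <- rem_unif_neg[sample.int(length(rem_unif_neg),
                                        min(length(rem_unif_neg), t2_neg_n))]
  extra_neg <- NULL
  short <- t2_neg_n - length(t2_neg_idx)
  if (short > 0) {
    if (is.null(proteome))
      infeasible_error(sprintf(
        "T2 needs %d uniform negatives but only %d remain and no proteome was supplied for top-up",
        t2_neg_n, length(t2_neg_idx)
      ))
    extra_neg <- sample_negatives(
      gold[is_pos, c("idA", "idB")], proteome,
      scheme = "uniform", ratio = short / sum(is_pos),
      seed = derive_seed(config$seed, "t2_negatives"),
      forbidden = gold[, c("idA", "idB")]
    )
    extra_neg <- utils::head(extra_neg, short)
  }

  split <- rep(NA_character_, nrow(gold))
  split[t1_idx] <- "T1"
  split[c(t2_pos_idx, t2_neg_idx)] <- "T2"
  train_ok <- is.na(split) & n_held == 0L
  split[train_ok] <- "train"
  split[is.na(split)] <- "unused"

  out <- data.frame(
    idA = gold$idA, idB = gold$idB, label = gold$label,
    source = gold$source, split = split, stringsAsFactors = FALSE
  )
  if (!is.null(extra_neg) && nrow(extra_neg) > 0) {
    out <- rbind(out, data.frame(
      idA = extra_neg$idA, idB = extra_neg$idB, label = "negative",
      source = extra_neg$source, split = "T2", stringsAsFactors = FALSE
    ))
  }

  train_proteins <- unique(c(out$idA[out$split == "train"],
                             out$idB[out$split == "train"]))
  out$overlap_stratum <- overlap_stratum(out, train_proteins)
  if (is.null(degrees))
    degrees <- degree_table(gold[is_pos, , drop = FALSE],
                            proteome = unique(c(out$idA, out$idB)))
  out$topology_stratum <- topology_stratum(out, degrees)
  rownames(out) <- NULL
  out
}
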