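# Pair featurization: per-facet annotation similarity with explicit
# missingness indicators, expression rank correlation, and simple
# sequence-derived pair features. All features are symmetric in the two
# proteins by construction.

#' Annotation-overlap similarity between two term sets
#'
#' Jaccard index `|A n B| / |A u B|` when both sets are present and
#' nonempty, or the overlap coefficient `|A n B| / min(|A|, |B|)` under
#' `measure = "overlap"`. When either facet is absent the similarity is
#' imputed to 0 and the missing flag set, so models can learn missingness
#' effects through the indicator rather than a silent zero.
#'
#' @param setA,setB character vectors of terms, or `NULL` when the facet is
#'   unannotated.
#' @param measure similarity strategy, `"jaccard"` (default) or
#'   `"overlap"`.
#' @return numeric `c(similarity, missing)` with similarity in `[0, 1]` and
#'   missing in `{0, 1}`.
#' @export
facet_similarity <- function(setA, setB, measure = c("jaccard", "overlap")) {
  measure <- match.arg(measure)
  if (is.null(setA) || is.null(setB) || length(setA) == 0 ||
      length(setB) == 0)
    return(c(similarity = 0, missing = 1))
  inter <- length(intersect(setA, setB))
  denom <- switch(measure,
    jaccard = length(union(setA, setB)),
    overlap = min(length(unique(setA)), length(unique(setB)))
  )
  c(similarity = inter / denom, missing = 0)
}

#' Rank correlation of two expression profiles
#'
#' Spearman correlation when both profiles are present, of equal length
#' >= 3 and neither constant; otherwise `(0, missing = 1)`. Rank
#' correlation is preferred over Pearson for robustness to monotone
#' transformations of expression units.
#'
#' @param vecA,vecB numeric vectors or `NULL`.
#' @return numeric `c(correlation, missing)`.
#' @export
expression_correlation <- function(vecA, vecB) {
  if (is.null(vecA) || is.null(vecB))
    return(c(correlation = 0, missing = 1))
  if (length(vecA) != length(vecB))
    input_error("expression profiles differ in length")
  if (length(vecA) < 3 || stats::sd(vecA) == 0 || stats::sd(vecB) == 0)
    return(c(correlation = 0, missing = 1))
  c(correlation = stats::cor(vecA, vecB, method = "spearman"), missing = 0)
}

kmer_counts <- function(seq, k) {
  n <- nchar(seq)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  table(kmers)
}

#' Cosine similarity of k-mer count vectors
#'
#' Compares the k-mer composition of two sequences; in `[0, 1]` because
#' counts are nonnegative.
#'
#' @param seqA,seqB nonempty amino-acid strings of length >= `k`.
#' @param k k-mer length (default 3).
#' @return cosine similarity.
#' @export
kmer_cosine <- function(seqA, seqB, k = 3) {
  if (is.null(seqA) || is.null(seqB) || !nzchar(seqA) || !nzchar(seqB) ||
      nchar(seqA) < k || nchar(seqB) < k)
    input_error(sprintf("sequences must be nonempty and at least %d residues", k))
  ca <- kmer_counts(seqA, k)
  cb <- kmer_counts(seqB, k)
  shared <- intersect(names(ca), names(cb))
  if (length(shared) == 0) return(0)
  num <- sum(as.numeric(ca[shared]) * as.numeric(cb[shared]))
  num / sqrt(sum(as.numeric(ca)^2) * sum(as.numeric(cb)^2))
}

protein_motif_profile <- function(sequences) {
  locks <- vapply(MOTIF_LOCKS, function(m) grepl(m, sequences, fixed = TRUE),
                  logical(length(sequences)))
  keys <- vapply(MOTIF_KEYS, function(m) grepl(m, sequences, fixed = TRUE),
                 logical(length(sequences)))
  if (length(sequences) == 1) {
    locks <- matrix(locks, nrow = 1)
    keys <- matrix(keys, nrow = 1)
  }
  rownames(locks) <- rownames(keys) <- names(sequences)
  list(locks = locks, keys = keys)
}

shared_motif_indicator <- function(profileA_lock, profileA_key,
                                   profileB_lock, profileB_key) {
  as.numeric(any(profileA_lock & profileB_key) ||
               any(profileB_lock & profileA_key))
}

#' Build a model-ready feature table for protein pairs
#'
#' One row per pair; columns depend on the requested feature groups:
#' \describe{
#'   \item{`fg`}{per facet `sim_<facet>` (annotation similarity) and
#'     `miss_<facet>` (1 when either protein lacks the facet).}
#'   \item{`expr`}{`expr_cor` (Spearman) and `miss_expr`.}
#'   \item{`seq`}{`kmer_cos` (k-mer cosine, `k = 3` by default) and
#'     `shared_motif` (1 when the two sequences carry a complementary
#'     lock-key motif pair from the dictionary).}
#'   \item{`kmer_profile`}{one column `kp_<w>` per dipeptide `w`: the mean
#'     of the two proteins' relative k-mer frequencies. High-dimensional
#'     composition features for sequence baselines; a linear model on them
#'     learns per-protein composition scores, which is exactly the
#'     protein-memorization behaviour sequence models are prone to.}
#' }
#' All features are symmetric: `build_feature_table()` on (A,B) and (B,A)
#' gives identical rows.
#'
#' @param pairs data frame with `idA`, `idB` (extra columns ignored).
#' @param universe a `ppi_universe`, or any list with `annotations`,
#'   `expression`, `sequences` entries indexed by protein id.
#' @param features character subset of
#'   `c("fg", "expr", "seq", "kmer_profile")`.
#' @param k k-mer length for `kmer_cos`.
#' @param profile_k k-mer length for `kmer_profile` columns (default 2,
#'   giving 400 columns).
#' @param measure similarity strategy passed to [facet_similarity()].
#' @return data frame with `idA`, `idB` and the feature columns.
#' @export
build_feature_table <- function(pairs, universe, features = c("fg", "expr"),
                                k = 3, profile_k = 2,
                                measure = "jaccard") {
  features <- match.arg(features, c("fg", "expr", "seq", "kmer_profile"),
                        several.ok = TRUE)
  pairs <- canonicalize_pairs(pairs[, c("idA", "idB")])
  ids <- unique(c(pairs$idA, pairs$idB))
  known <- names(universe$annotations)
  if (is.null(known)) known <- names(universe$sequences)
  if (!is.null(universe$expression))
    known <- unique(c(known, rownames(universe$expression)))
  unknown <- setdiff(ids, known)
  if (length(unknown) > 0)
    lookup_error(paste0("unknown proteins in pairs: ",
                        paste(utils::head(unknown, 5), collapse = ", "),
                        if (length(unknown) > 5) ", ..."))
  out <- pairs
  n <- nrow(pairs)

  if ("fg" %in% features) {
    ann <- universe$annotations
    for (f in PPI_FACETS) {
      vals <- vapply(seq_len(n), function(i) {
        facet_similarity(ann[[pairs$idA[i]]][[f]], ann[[pairs$idB[i]]][[f]],
                         measure = measure)
      }, numeric(2))
      out[[paste0("sim_", f)]] <- if (n > 0) vals[1, ] else numeric(0)
      out[[paste0("miss_", f)]] <- if (n > 0) vals[2, ] else numeric(0)
    }
  }

  if ("expr" %in% features) {
    expr <- universe$expression
    vals <- vapply(seq_len(n), function(i) {
      a <- if (pairs$idA[i] %in% rownames(expr)) expr[pairs$idA[i], ] else NULL
      b <- if (pairs$idB[i] %in% rownames(expr)) expr[pairs$idB[i], ] else NULL
      expression_correlation(a, b)
    }, numeric(2))
    out$expr_cor <- if (n > 0) vals[1, ] else numeric(0)
    out$miss_expr <- if (n > 0) vals[2, ] else numeric(0)
  }

  if ("seq" %in% features) {
    seqs <- universe$sequences[ids]
    prof <- protein_motif_profile(seqs)
    out$kmer_cos <- vapply(seq_len(n), function(i) {
      kmer_cosine(seqs[[pairs$idA[i]]], seqs[[pairs$idB[i]]], k = k)
    }, numeric(1))
    if (n == 0) out$kmer_cos <- numeric(0)
    out$shared_motif <- vapply(seq_len(n), function(i) {
      shared_motif_indicator(
        prof$locks[pairs$idA[i], ], prof$keys[pairs$idA[i], ],
        prof$locks[pairs$idB[i], ], prof$keys[pairs$idB[i], ]
      )
    }, numeric(1))
    if (n == 0) out$shared_motif <- numeric(0)
  }

  if ("kmer_profile" %in% features) {
    vocab <- apply(expand.grid(rep(list(AMINO_ACIDS), profile_k),
                               stringsAsFactors = FALSE),
                   1, paste, collapse = "")
    vocab <- sort(vocab)
    freq <- matrix(0, nrow = length(ids), ncol = length(vocab),
                   dimnames = list(ids, vocab))
    for (id in ids) {
      cnt <- kmer_counts(universe$sequences[[id]], profile_k)
      freq[id, names(cnt)] <- as.numeric(cnt) / sum(cnt)
    }
    kp <- (freq[pairs$idA, , drop = FALSE] +
             freq[pairs$idB, , drop = FALSE]) / 2
    colnames(kp) <- paste0("kp_", vocab)
    out <- cbind(out, as.data.frame(kp, row.names = NULL))
  }

  rownames(out) <- NULL
  out
}
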