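# Internal helpers shared across modules: classed conditions, seed
# derivation, pair canonicalisation, rounding.

abort_ppi <- function(msg, class) {
  stop(structure(
    class = c(class, "ppibench_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error  <- function(msg) abort_ppi(msg, "ppibench_config_error")
input_error   <- function(msg) abort_ppi(msg, "ppibench_input_error")
lookup_error  <- function(msg) abort_ppi(msg, "ppibench_lookup_error")
infeasible_error <- function(msg) abort_ppi(msg, "ppibench_infeasible_error")
integrity_error  <- function(msg) abort_ppi(msg, "ppibench_integrity_error")

# Round-half-up: R's round() is round-half-even, which would make realized
# split sizes depend on parity. All fraction-by-size computations go
# through this so counts are bit-reproducible.
round_half_up <- function(x) floor(x + 0.5)

# Deterministic per-stage seed derived from a single master seed, so each
# pipeline stage is independently reproducible. Kept below 2^31 - 1.
STAGE_NAMES <- c(
  "network", "annotations", "expression", "sequences",
  "negatives", "heldout", "splits", "t2_negatives", "model", "evidence"
)

derive_seed <- function(seed, stage) {
  idx <- match(stage, STAGE_NAMES)
  if (is.na(idx)) idx <- 97L + (sum(utf8ToInt(stage)) %% 1000L)
  as.integer((as.double(seed %% 1000003L) * 1009 + 7919 * idx) %% 2147483629)
}

check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != floor(x))
    config_error(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

check_prob <- function(x, name) {
  if (any(!is.numeric(x)) || any(is.na(x)) || any(x < 0) || any(x > 1))
    config_error(sprintf("'%s' must lie in [0, 1]", name))
  invisible(x)
}

#' Canonicalize unordered protein pairs
#'
#' Reorders each pair so that `idA < idB` lexicographically and drops
#' duplicate pairs, so an unordered pair has exactly one representation
#' throughout the package.
#'
#' @param pairs data frame with character columns `idA` and `idB` (extra
#'   columns are preserved; the first occurrence wins on deduplication).
#' @param drop_self drop rows with `idA == idB`?
#' @return the canonicalized data frame.
#' @export
canonicalize_pairs <- function(pairs, drop_self = TRUE) {
  if (!all(c("idA", "idB") %in% names(pairs)))
    input_error("pairs must have columns 'idA' and 'idB'")
  a <- as.character(pairs$idA)
  b <- as.character(pairs$idB)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  pairs$idA <- a
  pairs$idB <- b
  if (drop_self) pairs <- pairs[a != b, , drop = FALSE]
  pairs <- pairs[!duplicated(pair_key(pairs$idA, pairs$idB)), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

pair_key <- function(idA, idB) paste(pmin(idA, idB), pmax(idA, idB), sep = "\t")

# Hub rule: strictly the top ceil(quantile * n) proteins by degree; ties at
# the cut broken by lexicographic id for determinism.
hub_flags <- function(ids, degrees, hub_quantile = 0.20) {
  if (length(hub_quantile) != 1 || !is.numeric(hub_quantile) ||
      is.na(hub_quantile) || hub_quantile <= 0 || hub_quantile >= 1)
    config_error("'hub_quantile' must lie strictly in (0, 1)")
  n <- length(ids)
  n_hubs <- ceiling(hub_quantile * n)
  ord <- order(-degrees, ids)
  hub <- logical(n)
  hub[ord[seq_len(min(n_hubs, n))]] <- TRUE
  hub
}
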