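# Readers and writers for the package's plain-text interchange formats:
# TSV tables for pairs / evidence / gold standards / splits / features /
# expression, long-format TSV for annotations, FASTA for sequences, JSON
# for configurations.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write / read protein pair tables
#'
#' Plain TSV with columns `idA`, `idB` plus any label/source/split columns
#' present.
#'
#' @param pairs data frame with at least `idA`, `idB`.
#' @param path file path.
#' @return the path (writer) or the data frame (reader).
#' @export
write_pairs_tsv <- function(pairs, path) write_tsv(pairs, path)

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) read_tsv(path)

#' Write / read evidence tables
#'
#' TSV columns: `idA`, `idB`, `method_class`, `n_publications`.
#'
#' @param evidence evidence data frame.
#' @param path file path.
#' @export
write_evidence_tsv <- function(evidence, path) write_tsv(evidence, path)

#' @rdname write_evidence_tsv
#' @export
read_evidence_tsv <- function(path) read_tsv(path)

#' Write / read annotations in long format
#'
#' TSV columns `protein_id`, `facet`, `term`; a protein-facet with no rows
#' is an unannotated (missing) facet.
#'
#' @param annotations named list: protein id -> named list facet -> terms.
#' @param path file path.
#' @export
write_annotations_tsv <- function(annotations, path) {
  rows <- lapply(names(annotations), function(id) {
    per <- annotations[[id]]
    facets <- names(per)[!vapply(per, is.null, logical(1))]
    if (length(facets) == 0) return(NULL)
    do.call(rbind, lapply(facets, function(f) {
      data.frame(protein_id = id, facet = f, term = per[[f]],
                 stringsAsFactors = FALSE)
    }))
  })
  write_tsv(do.call(rbind, rows), path)
}

#' @rdname write_annotations_tsv
#' @param proteins optional full protein id vector so proteins with no
#'   annotated facet at all are still represented (with all facets
#'   missing).
#' @export
read_annotations_tsv <- function(path, proteins = NULL) {
  df <- read_tsv(path)
  ids <- unique(c(df$protein_id, proteins))
  ann <- lapply(ids, function(id) {
    sub <- df[df$protein_id == id, , drop = FALSE]
    per <- lapply(PPI_FACETS, function(f) {
      terms <- sub$term[sub$facet == f]
      if (length(terms) == 0) NULL else terms
    })
    names(per) <- PPI_FACETS
    per
  })
  names(ann) <- ids
  ann
}

#' Write / read expression matrices
#'
#' TSV matrix, proteins in rows (first column `protein_id`), conditions in
#' columns.
#'
#' @param expression numeric matrix with protein ids as rownames.
#' @param path file path.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(protein_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$protein_id
  m
}

#' Write / read sequences as FASTA
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write / read configurations as JSON
#'
#' @param config a config list (e.g. [synthetic_config()]).
#' @param path file path.
#' @export
write_config_json <- function(config, path) {
  x <- unclass(config)
  # Named numeric vectors must serialize as JSON objects, not arrays.
  for (field in c("facet_vocab_sizes", "missing_rate_per_facet"))
    if (!is.null(x[[field]])) x[[field]] <- as.list(x[[field]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_synthetic_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("facet_vocab_sizes", "missing_rate_per_facet"))
    if (is.list(raw[[field]])) raw[[field]] <- unlist(raw[[field]])
  raw$seq_length_range <- as.numeric(raw$seq_length_range)
  do.call(synthetic_config, raw)
}

#' Export curve coordinates as CSV
#'
#' One row per curve point with columns `threshold`, `x`, `y` (FPR/TPR for
#' ROC, recall/precision for PR), so curves can be compared across studies
#' without re-training.
#'
#' @param curve a `ppi_curve` from [roc_curve()] or [pr_curve()].
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve$points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic universe to a directory
#'
#' Emits `positive_pairs.tsv`, `annotations.tsv`, `expression.tsv`,
#' `sequences.fasta` and `config.json`.
#'
#' @param universe a `ppi_universe`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pairs_tsv(universe$edges, file.path(dir, "positive_pairs.tsv"))
  write_annotations_tsv(universe$annotations,
                        file.path(dir, "annotations.tsv"))
  write_expression_tsv(universe$expression, file.path(dir, "expression.tsv"))
  write_fasta(universe$sequences, file.path(dir, "sequences.fasta"))
  write_config_json(universe$config, file.path(dir, "config.json"))
  invisible(dir)
}
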