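# Synthetic proteome/interactome generator. Emulates the statistical
# structure PPI benchmarks have to cope with: a scale-free positive
# network dominated by hubs, hub-inflated annotation counts, facet-wise
# annotation overlap that is predictive of interaction, controllable
# per-facet missingness, co-expression modules, and sequences carrying a
# planted lock-key motif signal.

#' Annotation facets used throughout the package
#' @export
PPI_FACETS <- c(
  "biological_process", "cellular_compartment", "molecular_function",
  "domain", "motif"
)

FACET_PREFIX <- c(
  biological_process = "BP", cellular_compartment = "CC",
  molecular_function = "MF", domain = "DM", motif = "MT"
)

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Fixed lock-key motif dictionary: 16 complementary 6-mer pairs. Arbitrary
# constants, shipped so generated universes are reproducible everywhere.
MOTIF_LOCKS <- c(
  "WKDHLC", "MFYQRE", "CPTNGA", "HLWSVK", "YDEMFR", "QGANCP", "VKTHLW",
  "RFMDYE", "NCAPQG", "LWHKVS", "EYRFMD", "GQCNAP", "SVLWHK", "DREYFM",
  "PAGQCN", "KSHVLW"
)
MOTIF_KEYS <- c(
  "ERQYFM", "KHWCLD", "GNAPTC", "VSKWHL", "MRFEYD", "CPQGNA", "WLHKTV",
  "EYDFRM", "GQPCNA", "SVKHWL", "DMEFYR", "APGNCQ", "HKSWVL", "FMRDEY",
  "NCQAPG", "LWKSVH"
)

#' Configuration of the synthetic universe generator
#'
#' Bundles and validates every knob of the generator. Defaults describe a
#' human-interactome-like benchmark at desk scale: a preferential-attachment
#' network, annotation facets with hub-inflated term counts, the per-facet
#' missingness rates observed in curated annotation databases (domains and
#' motifs unannotated for 58% and 89% of proteins respectively), modular
#' co-expression, and random amino-acid sequences with a planted
#' complementary-motif interaction signal.
#'
#' @param n_proteins number of proteins.
#' @param n_edges_per_new_node preferential-attachment parameter `m`: edges
#'   each newly added protein forms.
#' @param facet_vocab_sizes named integer vector, vocabulary size per facet
#'   (names must be `PPI_FACETS`).
#' @param base_terms_per_protein background terms drawn per facet for a
#'   non-hub protein.
#' @param hub_annotation_inflation multiplier (>= 1) on the background term
#'   count of hub proteins; models hubs being more heavily annotated.
#' @param fg_signal probability, per interacting pair and facet, that a
#'   shared term is injected into both partners (the planted
#'   functional-genomics signal).
#' @param missing_rate_per_facet named numeric vector in `[0,1]`: probability
#'   that a protein's whole facet is masked as unannotated.
#' @param expr_n_conditions number of expression conditions.
#' @param expr_module_count number of latent co-expression modules.
#' @param expr_noise_sd standard deviation of Gaussian noise around the
#'   module mean profile.
#' @param seq_length_range integer `c(min, max)` sequence length in residues.
#' @param motif_signal probability that an interacting pair receives a
#'   complementary lock-key motif pair planted in its two sequences.
#' @param species species label attached to every generated protein.
#' @param seed master seed; identical config + seed gives identical output.
#' @return an object of class `ppi_synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_proteins = 2000,
                             n_edges_per_new_node = 3,
                             facet_vocab_sizes = c(
                               biological_process = 3000,
                               cellular_compartment = 800,
                               molecular_function = 2000,
                               domain = 2500,
                               motif = 1500
                             ),
                             base_terms_per_protein = 4,
                             hub_annotation_inflation = 3,
                             fg_signal = 0.6,
                             missing_rate_per_facet = c(
                               biological_process = 0.05,
                               cellular_compartment = 0.05,
                               molecular_function = 0.10,
                               domain = 0.58,
                               motif = 0.89
                             ),
                             expr_n_conditions = 30,
                             expr_module_count = 15,
                             expr_noise_sd = 1,
                             seq_length_range = c(60, 200),
                             motif_signal = 0.5,
                             species = "synthetica",
                             seed = 1) {
  check_count(n_proteins, "n_proteins", min = 2)
  check_count(n_edges_per_new_node, "n_edges_per_new_node", min = 1)
  if (n_proteins <= n_edges_per_new_node)
    config_error("'n_proteins' must exceed 'n_edges_per_new_node'")
  if (!all(PPI_FACETS %in% names(facet_vocab_sizes)))
    config_error("'facet_vocab_sizes' must name every facet in PPI_FACETS")
  if (!all(PPI_FACETS %in% names(missing_rate_per_facet)))
    config_error("'missing_rate_per_facet' must name every facet in PPI_FACETS")
  check_prob(missing_rate_per_facet, "missing_rate_per_facet")
  check_prob(fg_signal, "fg_signal")
  check_prob(motif_signal, "motif_signal")
  check_count(base_terms_per_protein, "base_terms_per_protein")
  if (any(facet_vocab_sizes[PPI_FACETS] < base_terms_per_protein))
    config_error("'facet_vocab_sizes' must all be >= 'base_terms_per_protein'")
  if (!is.numeric(hub_annotation_inflation) || hub_annotation_inflation < 1)
    config_error("'hub_annotation_inflation' must be a multiplier >= 1")
  check_count(expr_n_conditions, "expr_n_conditions")
  check_count(expr_module_count, "expr_module_count")
  if (!is.numeric(expr_noise_sd) || expr_noise_sd < 0)
    config_error("'expr_noise_sd' must be a nonnegative real")
  if (length(seq_length_range) != 2 ||
      seq_length_range[1] > seq_length_range[2] || seq_length_range[1] < 7)
    config_error("'seq_length_range' must be c(min, max) with 7 <= min <= max")
  check_count(seed, "seed", min = 0)
  structure(
    list(
      n_proteins = as.integer(n_proteins),
      n_edges_per_new_node = as.integer(n_edges_per_new_node),
      facet_vocab_sizes = facet_vocab_sizes[PPI_FACETS],
      base_terms_per_protein = as.integer(base_terms_per_protein),
      hub_annotation_inflation = hub_annotation_inflation,
      fg_signal = fg_signal,
      missing_rate_per_facet = missing_rate_per_facet[PPI_FACETS],
      expr_n_conditions = as.integer(expr_n_conditions),
      expr_module_count = as.integer(expr_module_count),
      expr_noise_sd = expr_noise_sd,
      seq_length_range = as.integer(seq_length_range),
      motif_signal = motif_signal,
      species = species,
      seed = as.integer(seed)
    ),
    class = "ppi_synthetic_config"
  )
}

protein_ids <- function(n) sprintf("SYN%05d", seq_len(n))

#' Generate a scale-free positive-interaction network
#'
#' Grows a Barabasi-Albert preferential-attachment graph, the canonical
#' generator for the scale-free topology of PPI networks: a few highly
#' connected hubs and many lone proteins.
#'
#' @param config a [synthetic_config()].
#' @return list with `edges` (canonical data frame `idA`, `idB`) and
#'   `degrees` (data frame `protein`, `degree`, `hub`; hubs are the top 20%
#'   of proteins by degree).
#' @export
generate_network <- function(config) {
  if (!inherits(config, "ppi_synthetic_config"))
    config_error("'config' must be built with synthetic_config()")
  n <- config$n_proteins
  m <- config$n_edges_per_new_node
  ids <- protein_ids(n)
  set.seed(derive_seed(config$seed, "network"))
  g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- canonicalize_pairs(data.frame(
    idA = ids[el[, 1]], idB = ids[el[, 2]], stringsAsFactors = FALSE
  ))
  deg <- igraph::degree(g)
  degrees <- data.frame(
    protein = ids, degree = as.integer(deg),
    hub = hub_flags(ids, deg), stringsAsFactors = FALSE
  )
  list(edges = edges, degrees = degrees)
}

sample_terms <- function(facet, vocab_size, n_terms) {
  sprintf("%s%04d", FACET_PREFIX[[facet]],
          sample.int(vocab_size, min(n_terms, vocab_size)))
}

#' Generate facet-wise annotations with planted interaction signal
#'
#' Every protein draws background terms per facet; hubs draw
#' `hub_annotation_inflation` times as many (hubs are heavily studied and
#' hence heavily annotated). For each interacting pair and facet, a shared
#' term is injected into both partners with probability `fg_signal` -- the
#' planted signal that annotation overlap predicts interaction. Finally,
#' whole facets are masked per protein at the configured per-facet missing
#' rate (missingness in annotation databases is per protein and facet, not
#' per term).
#'
#' @param edges canonical positive edges (data frame `idA`, `idB`).
#' @param degrees degree table from [generate_network()] (used for hub flags).
#' @param config a [synthetic_config()].
#' @return list with `annotations` (named list: protein id -> named list
#'   facet -> character vector of terms, `NULL` when the facet is missing)
#'   and `truth` (logical matrix, pairs x facets, of injected shared terms).
#' @export
generate_annotations <- function(edges, degrees, config) {
  ids <- degrees$protein
  hub <- degrees$hub
  set.seed(derive_seed(config$seed, "annotations"))
  base <- config$base_terms_per_protein
  n_terms <- ifelse(hub, round(config$hub_annotation_inflation * base), base)

  ann <- vector("list", length(ids))
  names(ann) <- ids
  for (i in seq_along(ids)) {
    per_facet <- lapply(PPI_FACETS, function(f) {
      sample_terms(f, config$facet_vocab_sizes[[f]], n_terms[i])
    })
    names(per_facet) <- PPI_FACETS
    ann[[i]] <- per_facet
  }

  truth <- matrix(FALSE, nrow = nrow(edges), ncol = length(PPI_FACETS),
                  dimnames = list(NULL, PPI_FACETS))
  for (f in PPI_FACETS) {
    inject <- stats::runif(nrow(edges)) < config$fg_signal
    truth[, f] <- inject
    if (!any(inject)) next
    shared <- sample_terms(f, config$facet_vocab_sizes[[f]], sum(inject))
    idx <- which(inject)
    for (k in seq_along(idx)) {
      a <- edges$idA[idx[k]]; b <- edges$idB[idx[k]]
      ann[[a]][[f]] <- union(ann[[a]][[f]], shared[k])
      ann[[b]][[f]] <- union(ann[[b]][[f]], shared[k])
    }
  }

  for (f in PPI_FACETS) {
    mask <- stats::runif(length(ids)) < config$missing_rate_per_facet[[f]]
    for (i in which(mask)) ann[[i]][f] <- list(NULL)
  }
  list(annotations = ann, truth = truth)
}

#' Generate modular expression profiles
#'
#' Each protein is assigned a latent co-expression module; interacting
#' pairs are co-assigned with elevated probability (0.7). A profile is the
#' module's mean vector plus Gaussian noise of sd `expr_noise_sd`.
#'
#' @inheritParams generate_annotations
#' @return list with `expression` (matrix, proteins x conditions) and
#'   `modules` (named integer vector of latent module assignments).
#' @export
generate_expression <- function(edges, config) {
  ids <- protein_ids(config$n_proteins)
  set.seed(derive_seed(config$seed, "expression"))
  k <- config$expr_module_count
  p <- config$expr_n_conditions
  module_init <- sample.int(k, length(ids), replace = TRUE)
  names(module_init) <- ids
  # Co-assignment copies from the initial assignment (not the propagated
  # one), so modules stay local clusters around their seed protein instead
  # of flooding the whole connected network through transitive copying.
  module <- module_init
  coassign <- stats::runif(nrow(edges)) < 0.7
  for (e in which(coassign))
    module[edges$idB[e]] <- module_init[[edges$idA[e]]]
  means <- matrix(stats::rnorm(k * p), nrow = k)
  expr <- means[module, , drop = FALSE] +
    matrix(stats::rnorm(length(ids) * p, sd = config$expr_noise_sd),
           nrow = length(ids))
  rownames(expr) <- ids
  colnames(expr) <- sprintf("cond%02d", seq_len(p))
  list(expression = expr, modules = module)
}

# Write `motif` into `seq` at a random position that does not overlap any
# interval in `occupied` (previously planted motifs must survive later
# insertions). Falls back to an arbitrary position in the rare case no
# free slot is found.
insert_motif <- function(seq, motif, occupied) {
  len <- nchar(seq)
  w <- nchar(motif)
  pos <- NA_integer_
  for (try in 1:50) {
    cand <- sample.int(len - w + 1, 1)
    clash <- any(vapply(occupied, function(iv) {
      cand <= iv[2] && cand + w - 1L >= iv[1]
    }, logical(1)))
    if (!clash) { pos <- cand; break }
  }
  if (is.na(pos)) pos <- sample.int(len - w + 1, 1)
  list(
    seq = paste0(substr(seq, 1, pos - 1), motif, substr(seq, pos + w, len)),
    interval = c(pos, pos + w - 1L)
  )
}

#' Generate amino-acid sequences with a planted lock-key motif signal
#'
#' Sequences are uniform-random over the 20 canonical amino acids. Each
#' protein carries one fixed binding-interface index into the 16-entry
#' lock-key motif dictionary. For each interacting pair, with probability
#' `motif_signal`, the first partner's interface lock is written into its
#' sequence and the complementary key into the second partner's sequence
#' (each motif at most once per protein, at positions that do not overlap
#' previously planted motifs). A protein therefore carries at most one
#' lock plus a handful of keys, so motif load does not grow with degree.
#'
#' @inheritParams generate_annotations
#' @return list with `sequences` (named character vector), `truth` (integer
#'   vector: dictionary index planted per pair, 0 when none) and
#'   `interfaces` (named integer vector of per-protein interface indices).
#' @export
generate_sequences <- function(edges, config) {
  ids <- protein_ids(config$n_proteins)
  set.seed(derive_seed(config$seed, "sequences"))
  rng <- config$seq_length_range
  lens <- sample.int(rng[2] - rng[1] + 1, length(ids), replace = TRUE) +
    rng[1] - 1L
  seqs <- vapply(lens, function(l) {
    paste(sample(AMINO_ACIDS, l, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- ids
  interface <- sample.int(length(MOTIF_LOCKS), length(ids), replace = TRUE)
  names(interface) <- ids
  occupied <- stats::setNames(rep(list(list()), length(ids)), ids)

  plant_once <- function(id, motif) {
    if (!grepl(motif, seqs[[id]], fixed = TRUE)) {
      ins <- insert_motif(seqs[[id]], motif, occupied[[id]])
      seqs[id] <<- ins$seq
      occupied[[id]] <<- c(occupied[[id]], list(ins$interval))
    }
  }

  plant <- stats::runif(nrow(edges)) < config$motif_signal
  dict_idx <- integer(nrow(edges))
  for (e in which(plant)) {
    d <- interface[[edges$idA[e]]]
    dict_idx[e] <- d
    plant_once(edges$idA[e], MOTIF_LOCKS[d])
    plant_once(edges$idB[e], MOTIF_KEYS[d])
  }
  list(sequences = seqs, truth = dict_idx, interfaces = interface)
}

#' Generate a full synthetic universe
#'
#' Runs network, annotation, expression and sequence generation with
#' deterministic per-stage seeds derived from the master seed, and bundles
#' the result.
#'
#' @param config a [synthetic_config()].
#' @return object of class `ppi_universe`: list with `config`, `proteins`
#'   (ids), `species`, `edges` (positive pairs), `degrees`, `annotations`,
#'   `expression`, `sequences`, and `truth_log` (planted-signal diagnostics,
#'   not to be used as features).
#' @export
generate_universe <- function(config = synthetic_config()) {
  net <- generate_network(config)
  ann <- generate_annotations(net$edges, net$degrees, config)
  expr <- generate_expression(net$edges, config)
  seqs <- generate_sequences(net$edges, config)
  truth_log <- data.frame(
    idA = net$edges$idA, idB = net$edges$idB,
    ann$truth, motif_dict = seqs$truth,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  structure(
    list(
      config = config,
      proteins = net$degrees$protein,
      species = config$species,
      edges = net$edges,
      degrees = net$degrees,
      annotations = ann$annotations,
      expression = expr$expression,
      sequences = seqs$sequences,
      truth_log = truth_log
    ),
    class = "ppi_universe"
  )
}

#' @export
print.ppi_universe <- function(x, ...) {
  cat(sprintf(
    "<ppi_universe> %d proteins (%s), %d positive pairs, %d hubs\n",
    length(x$proteins), x$species, nrow(x$edges), sum(x$degrees$hub)
  ))
  invisible(x)
}
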