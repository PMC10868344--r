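# Reporting: render a per-model performance sheet (human-readable markdown
# plus machine-readable JSON with curve-coordinate CSVs) and orchestrate
# the full synthetic benchmark end to end under one master seed.

fmt_metric <- function(x) ifelse(is.na(x), "not-evaluable", sprintf("%.4f", x))

strata_rows <- function(df) {
  if (is.null(df)) return(NULL)
  lapply(seq_len(nrow(df)), function(i) {
    list(
      stratum = df$stratum[i], n = df$n[i], n_pos = df$n_pos[i],
      pos_fraction = df$pos_fraction[i], evaluable = df$evaluable[i],
      auroc = if (df$evaluable[i]) df$auroc[i] else NA,
      auprc = if (df$evaluable[i]) df$auprc[i] else NA
    )
  })
}

strata_md <- function(df, title) {
  if (is.null(df)) return(character(0))
  c(
    sprintf("## %s", title), "",
    "| stratum | n | % positive | AUROC | AUPRC |",
    "|---|---|---|---|---|",
    vapply(seq_len(nrow(df)), function(i) {
      sprintf("| %s | %d | %.1f | %s | %s |", df$stratum[i], df$n[i],
              100 * df$pos_fraction[i], fmt_metric(df$auroc[i]),
              fmt_metric(df$auprc[i]))
    }, character(1)),
    ""
  )
}

#' Render a performance sheet for one model on one test set
#'
#' Writes, idempotently (same inputs give byte-identical files):
#' `sheet.json` (machine-readable report), `sheet.md` (human-readable),
#' and `roc.csv` / `pr.csv` with the curve coordinates. Strata that could
#' not be evaluated (single-class) are rendered as `not-evaluable`, never
#' dropped.
#'
#' @param report a `ppi_eval_report` from [evaluate_scores()].
#' @param fit optional `ppi_fit` (for training time).
#' @param metadata named list: `model`, `dataset`, and anything else worth
#'   recording (config fingerprint, seeds).
#' @param dir output directory.
#' @return named character vector of the files written, invisibly.
#' @export
render_sheet <- function(report, fit = NULL, metadata = list(), dir) {
  if (!inherits(report, "ppi_eval_report"))
    input_error("'report' must come from evaluate_scores()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roc_path <- file.path(dir, "roc.csv")
  pr_path <- file.path(dir, "pr.csv")
  write_curve_csv(report$roc, roc_path)
  write_curve_csv(report$pr, pr_path)

  sheet <- list(
    model = metadata$model %||% "unnamed-model",
    dataset = metadata$dataset %||% "unnamed-dataset",
    metadata = metadata[setdiff(names(metadata), c("model", "dataset"))],
    n = report$n, n_pos = report$n_pos,
    pos_fraction = report$pos_fraction,
    auroc = report$auroc, auprc = report$auprc,
    by_overlap = strata_rows(report$by_overlap),
    by_topology = strata_rows(report$by_topology),
    training_walltime_s = if (!is.null(fit)) fit$walltime_s,
    resources = report$resources,
    curves = list(roc = "roc.csv", pr = "pr.csv")
  )
  json_path <- file.path(dir, "sheet.json")
  jsonlite::write_json(sheet, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)

  md <- c(
    sprintf("# Performance sheet: %s on %s", sheet$model, sheet$dataset), "",
    sprintf("- n = %d pairs (%.1f%% positive)", sheet$n,
            100 * sheet$pos_fraction),
    sprintf("- AUROC = %.4f, AUPRC = %.4f", sheet$auroc, sheet$auprc),
    if (!is.null(fit))
      sprintf("- training time: %.2f s", fit$walltime_s),
    if (!is.null(report$resources))
      sprintf("- energy: %.6f kWh, carbon: %.4f gCO2e",
              report$resources$energy_kwh, report$resources$carbon_gco2e),
    sprintf("- curve coordinates: %s, %s", roc_path, pr_path),
    "",
    strata_md(report$by_overlap, "By protein-level overlap"),
    strata_md(report$by_topology, "By network topology")
  )
  md_path <- file.path(dir, "sheet.md")
  writeLines(md, md_path)
  invisible(c(json = json_path, md = md_path, roc = roc_path, pr = pr_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benchmark configuration
#'
#' Bundles the synthetic generator, negative sampling, split and model
#' settings of one end-to-end benchmark run under a single master seed.
#'
#' @param synthetic a [synthetic_config()].
#' @param negative_ratio negatives per positive in the training gold
#'   standard.
#' @param negative_scheme sampling scheme for training negatives
#'   (`"balanced"` by default: training sets benefit from negatives that
#'   mirror the positives' degree profile).
#' @param split a [split_config()].
#' @param model a [model_spec()].
#' @param features feature groups for [build_feature_table()].
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `ppi_benchmark_config`.
#' @export
benchmark_config <- function(synthetic = synthetic_config(n_proteins = 600,
                                                          seed = 1),
                             negative_ratio = 1,
                             negative_scheme = "balanced",
                             split = split_config(t1_size = 400,
                                                  t2_size = 1000),
                             model = model_spec("logistic"),
                             features = c("fg", "expr"),
                             seed = 1) {
  structure(
    list(synthetic = synthetic, negative_ratio = negative_ratio,
         negative_scheme = negative_scheme, split = split, model = model,
         features = features, seed = as.integer(seed)),
    class = "ppi_benchmark_config"
  )
}

run_stage <- function(name, expr) {
  message(sprintf("[%s] running", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic benchmark end to end
#'
#' Executes simulate -> curate -> sample -> split -> featurize -> train ->
#' evaluate -> report with per-stage seeds derived from one master seed,
#' writes every intermediate artifact under `dir`, and finishes with a
#' manifest of files and their MD5 checksums so a rerun (or a corrupted
#' file) is detectable by comparison.
#'
#' To exercise the curation filter, the simulated evidence table contains
#' every true interaction as `binary-physical` evidence plus a 5% admixture
#' of colocalization-only decoy pairs, which curation must remove.
#'
#' @param config a [benchmark_config()].
#' @param dir output directory.
#' @return list with `universe`, `gold`, `splits`, `fit`, reports for T1
#'   and T2, and the manifest, invisibly.
#' @export
run_benchmark <- function(config = benchmark_config(), dir) {
  if (!inherits(config, "ppi_benchmark_config"))
    config_error("'config' must be built with benchmark_config()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  universe <- run_stage("simulate", {
    u <- generate_universe(config$synthetic)
    write_universe(u, file.path(dir, "universe"))
    u
  })

  evidence <- run_stage("evidence", {
    set.seed(derive_seed(config$seed, "evidence"))
    ev <- data.frame(
      idA = universe$edges$idA, idB = universe$edges$idB,
      method_class = "binary-physical", n_publications = 1L,
      stringsAsFactors = FALSE
    )
    n_decoys <- max(1L, round_half_up(0.05 * nrow(ev)))
    decoys <- sample_negatives(universe$edges, universe$proteins,
                               scheme = "uniform",
                               ratio = n_decoys / nrow(ev),
                               seed = derive_seed(config$seed, "evidence"))
    ev <- rbind(ev, data.frame(
      idA = decoys$idA, idB = decoys$idB,
      method_class = "colocalization", n_publications = 1L,
      stringsAsFactors = FALSE
    ))
    write_evidence_tsv(ev, file.path(dir, "evidence.tsv"))
    ev
  })

  gold <- run_stage("curate+sample", {
    positives <- curate_positives(evidence)
    negatives <- sample_negatives(
      positives, universe$proteins, scheme = config$negative_scheme,
      ratio = config$negative_ratio,
      seed = derive_seed(config$seed, "negatives")
    )
    g <- assemble_gold_standard(positives, negatives)
    write_pairs_tsv(g, file.path(dir, "gold_standard.tsv"))
    g
  })

  splits <- run_stage("split", {
    heldout <- hold_out_proteins(universe$proteins,
                                 config$split$heldout_protein_fraction,
                                 seed = derive_seed(config$seed, "heldout"))
    s <- make_splits(gold, heldout, config$split,
                     proteome = universe$proteins,
                     degrees = universe$degrees)
    write_pairs_tsv(s, file.path(dir, "splits.tsv"))
    s
  })

  feats <- run_stage("featurize", {
    ft <- build_feature_table(splits[, c("idA", "idB")], universe,
                              features = config$features)
    stopifnot(identical(ft$idA, splits$idA), identical(ft$idB, splits$idB))
    write_pairs_tsv(ft, file.path(dir, "features.tsv"))
    ft
  })

  fit <- run_stage("train", {
    idx <- splits$split == "train"
    fit_model(config$model, feats[idx, , drop = FALSE], splits$label[idx])
  })

  reports <- run_stage("evaluate", {
    lapply(c(T1 = "T1", T2 = "T2"), function(sp) {
      idx <- splits$split == sp
      scores <- predict_scores(fit, feats[idx, , drop = FALSE])
      res <- estimate_carbon(fit$walltime_s)
      res$walltime_s <- fit$walltime_s
      evaluate_scores(splits$label[idx], scores,
                      overlap = splits$overlap_stratum[idx],
                      topology = splits$topology_stratum[idx],
                      resources = res)
    })
  })

  run_stage("report", {
    for (sp in names(reports)) {
      render_sheet(reports[[sp]], fit,
                   metadata = list(model = config$model$family,
                                   dataset = sp,
                                   master_seed = config$seed),
                   dir = file.path(dir, paste0("sheet_", sp)))
    }
  })

  manifest <- run_stage("manifest", {
    files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
    # Sheets embed measured wall time and energy, which legitimately vary
    # between reruns; the manifest checksums only the deterministic
    # artifacts so a rerun under the same master seed is byte-comparable.
    files <- files[!basename(files) %in%
                     c("manifest.json", "sheet.json", "sheet.md")]
    m <- data.frame(
      file = substring(files, nchar(dir) + 2),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE
    )
    jsonlite::write_json(m, file.path(dir, "manifest.json"), digits = NA,
                         pretty = TRUE)
    m
  })

  invisible(list(universe = universe, gold = gold, splits = splits,
                 fit = fit, reports = reports, manifest = manifest))
}

#' Verify a benchmark output directory against its manifest
#'
#' Recomputes MD5 checksums and reports mismatching or missing files.
#'
#' @param dir benchmark output directory containing `manifest.json`.
#' @return data frame of mismatches (zero rows when everything checks out).
#' @export
verify_manifest <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  actual <- unname(tools::md5sum(file.path(dir, m$file)))
  bad <- is.na(actual) | actual != m$md5
  data.frame(file = m$file[bad],
             expected = m$md5[bad],
             actual = actual[bad],
             stringsAsFactors = FALSE)
}
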