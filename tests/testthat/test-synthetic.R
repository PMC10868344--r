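# Synthetic universe generator: topology, planted signals, missingness,
# determinism.

test_that("config validation names the offending field", {
  expect_error(synthetic_config(n_proteins = 1), "n_proteins",
               class = "ppibench_config_error")
  expect_error(synthetic_config(n_proteins = 5, n_edges_per_new_node = 5),
               "n_proteins", class = "ppibench_config_error")
  expect_error(synthetic_config(fg_signal = 1.2), "fg_signal",
               class = "ppibench_config_error")
  expect_error(synthetic_config(seq_length_range = c(50, 20)),
               "seq_length_range", class = "ppibench_config_error")
  expect_error(
    synthetic_config(missing_rate_per_facet = c(biological_process = -0.1)),
    "missing_rate_per_facet", class = "ppibench_config_error"
  )
})

test_that("tiny preferential-attachment network is the forced tree", {
  net <- generate_network(synthetic_config(n_proteins = 3,
                                           n_edges_per_new_node = 1,
                                           seed = 5))
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$degrees$degree >= 1))
})

test_that("degree distribution is heavy-tailed relative to an ER graph", {
  cfg <- synthetic_config(n_proteins = 2000, n_edges_per_new_node = 2,
                          seed = 1)
  net <- generate_network(cfg)
  hubs <- net$degrees$protein[net$degrees$hub]
  share <- endpoint_share(net$edges, hubs)
  expect_gt(share, 0.5)

  # Erdos-Renyi graph of equal density as the no-heavy-tail oracle.
  set.seed(1)
  er <- igraph::sample_gnm(2000, nrow(net$edges))
  er_deg <- igraph::degree(er)
  er_ids <- sprintf("P%04d", seq_len(2000))
  er_edges <- igraph::as_edgelist(er, names = FALSE)
  er_hubs <- er_ids[order(-er_deg)][1:400]
  er_share <- mean(er_ids[er_edges[, 1]] %in% er_hubs |
                     er_ids[er_edges[, 2]] %in% er_hubs)
  expect_gt(share, er_share)
})

test_that("identical config and seed give identical universes", {
  cfg <- synthetic_config(n_proteins = 150, seed = 17)
  expect_identical(generate_universe(cfg), generate_universe(cfg))
})

test_that("planted annotation signal separates positive from random pairs", {
  u0 <- fixture_universe(21, n_proteins = 500, fg_signal = 0,
                         missing_rate_per_facet = zero_missing)
  u9 <- fixture_universe(21, n_proteins = 500, fg_signal = 0.9,
                         missing_rate_per_facet = zero_missing)

  gap0 <- mean_positive_jaccard(u0) - mean_random_jaccard(u0)
  expect_lt(abs(gap0), 0.02)

  # One-sided comparison on the generated output at n = 1000 pairs.
  set.seed(99)
  idx <- sample.int(nrow(u9$edges), 1000)
  pos_j <- vapply(idx, function(i) {
    facet_similarity(u9$annotations[[u9$edges$idA[i]]]$biological_process,
                     u9$annotations[[u9$edges$idB[i]]]$biological_process)[1]
  }, numeric(1))
  set.seed(98)
  a <- sample(u9$proteins, 1000, replace = TRUE)
  b <- sample(u9$proteins, 1000, replace = TRUE)
  rnd_j <- vapply(which(a != b), function(i) {
    facet_similarity(u9$annotations[[a[i]]]$biological_process,
                     u9$annotations[[b[i]]]$biological_process)[1]
  }, numeric(1))
  expect_lt(stats::t.test(pos_j, rnd_j, alternative = "greater")$p.value,
            0.01)
})

test_that("positive-vs-random similarity gap is monotone in fg_signal", {
  gaps <- vapply(c(0, 0.3, 0.6, 0.9), function(fg) {
    u <- fixture_universe(31, n_proteins = 500, fg_signal = fg,
                          missing_rate_per_facet = zero_missing)
    mean_positive_jaccard(u) - mean_random_jaccard(u)
  }, numeric(1))
  expect_true(all(diff(gaps) >= -0.005))
  expect_gt(gaps[4], gaps[1])
})

test_that("facet missingness hits the configured per-protein rate", {
  u <- fixture_universe(41, n_proteins = 2000)
  frac_missing <- function(facet) {
    mean(vapply(u$annotations, function(a) is.null(a[[facet]]), logical(1)))
  }
  expect_lt(abs(frac_missing("domain") - 0.58), 0.03)
  expect_lt(abs(frac_missing("motif") - 0.89), 0.03)
})

test_that("hub proteins carry inflated annotation counts", {
  u <- fixture_universe(43, n_proteins = 400,
                        missing_rate_per_facet = zero_missing,
                        fg_signal = 0, hub_annotation_inflation = 3)
  sizes <- vapply(u$annotations, function(a) length(a$molecular_function),
                  numeric(1))
  hub <- u$degrees$hub[match(names(sizes), u$degrees$protein)]
  expect_gt(mean(sizes[hub]), 2.5 * mean(sizes[!hub]))
})

test_that("expression profiles reflect module structure and noise level", {
  cfg0 <- synthetic_config(n_proteins = 200, expr_noise_sd = 0, seed = 8)
  net <- generate_network(cfg0)
  ex <- generate_expression(net$edges, cfg0)
  same <- which(outer(ex$modules, ex$modules, "=="), arr.ind = TRUE)
  same <- same[same[, 1] < same[, 2], , drop = FALSE][1, ]
  expect_equal(
    stats::cor(ex$expression[same[1], ], ex$expression[same[2], ],
               method = "spearman"), 1
  )

  # Null |Spearman| scales as 1/sqrt(conditions - 1); 120 conditions put
  # the chance floor (~0.07) safely below the asserted bound.
  cfg_noisy <- synthetic_config(n_proteins = 200, expr_noise_sd = 100,
                                expr_n_conditions = 120, seed = 8)
  exn <- generate_expression(net$edges, cfg_noisy)
  co <- which(outer(exn$modules, exn$modules, "=="), arr.ind = TRUE)
  co <- co[co[, 1] < co[, 2], , drop = FALSE]
  set.seed(1)
  co <- co[sample.int(nrow(co), 500), , drop = FALSE]
  cors <- vapply(seq_len(nrow(co)), function(i) {
    stats::cor(exn$expression[co[i, 1], ], exn$expression[co[i, 2], ],
               method = "spearman")
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.1)
})

test_that("single-condition expression is flagged missing downstream", {
  u <- fixture_universe(44, n_proteins = 120, expr_n_conditions = 1)
  p <- u$edges[1, ]
  res <- expression_correlation(u$expression[p$idA, ], u$expression[p$idB, ])
  expect_equal(unname(res["missing"]), 1)
})

test_that("sequences use the canonical alphabet and plant lock-key motifs", {
  u1 <- fixture_universe(9, n_proteins = 150, motif_signal = 1)
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", u1$sequences)))
  carries <- vapply(seq_len(nrow(u1$edges)), function(i) {
    sa <- u1$sequences[[u1$edges$idA[i]]]
    sb <- u1$sequences[[u1$edges$idB[i]]]
    any(vapply(seq_along(ppibench:::MOTIF_LOCKS), function(d) {
      grepl(ppibench:::MOTIF_LOCKS[d], sa, fixed = TRUE) &&
        grepl(ppibench:::MOTIF_KEYS[d], sb, fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  expect_true(all(carries))

  u0 <- fixture_universe(9, n_proteins = 150, motif_signal = 0)
  expect_true(all(u0$truth_log$motif_dict == 0))
})
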