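# Gold-standard curation, degrees/hubs, endpoint shares, negative
# sampling.

ev <- function(a, b, mc) {
  data.frame(idA = a, idB = b, method_class = mc, n_publications = 1L,
             stringsAsFactors = FALSE)
}

test_that("curation drops self-pairs and low-quality-only pairs", {
  expect_error(curate_positives(ev("A", "B", "colocalization")),
               "no positives survive",
               class = "ppibench_infeasible_error")

  two <- rbind(ev("A", "B", "colocalization"), ev("B", "A", "binary-physical"))
  pos <- curate_positives(two)
  expect_equal(nrow(pos), 1)
  expect_equal(pos$idA, "A")
  expect_equal(pos$idB, "B")

  expect_error(curate_positives(ev("A", "A", "binary-physical")),
               class = "ppibench_infeasible_error")
  empty <- data.frame(idA = character(0), idB = character(0),
                      method_class = character(0))
  expect_error(curate_positives(empty), class = "ppibench_input_error")
})

test_that("degree table counts positive-set degrees and flags hubs", {
  pos <- data.frame(idA = "A", idB = "B")
  dt <- degree_table(pos)
  expect_equal(dt$degree, c(1L, 1L))
  # ceil(0.2 * 2) = 1 hub; degree tie broken lexicographically.
  expect_equal(dt$protein[dt$hub], "A")

  # Degrees [5,4,3,2,1,1,1,1,1,1] over 10 proteins: hubs = top 2.
  p <- sprintf("P%02d", 1:10)
  pos10 <- data.frame(
    idA = c(p[1], p[1], p[1], p[1], p[1], p[2], p[2], p[2], p[9]),
    idB = c(p[2], p[3], p[4], p[5], p[6], p[3], p[4], p[7], p[10])
  )
  pos10 <- rbind(pos10, data.frame(idA = p[3], idB = p[8]))
  dt10 <- degree_table(pos10)
  expect_equal(sort(dt10$degree, decreasing = TRUE),
               c(5, 4, 3, 2, 1, 1, 1, 1, 1, 1))
  expect_equal(sort(dt10$protein[dt10$hub]), c("P01", "P02"))

  expect_error(degree_table(pos[0, ]), class = "ppibench_input_error")
  expect_error(degree_table(pos, hub_quantile = 0), "hub_quantile",
               class = "ppibench_config_error")

  # Proteins absent from the positives get degree 0.
  dt0 <- degree_table(pos, proteome = c("A", "B", "C"))
  expect_equal(dt0$degree[dt0$protein == "C"], 0L)
})

test_that("endpoint share counts pairs touching the subset", {
  pairs <- data.frame(idA = c("A", "C"), idB = c("B", "D"))
  expect_equal(endpoint_share(pairs, c("A", "B", "C", "D")), 1.0)
  expect_equal(endpoint_share(pairs, character(0)), 0.0)
  expect_equal(endpoint_share(pairs, "A"), 0.5)
})

test_that("negative sampling enumerates tiny cases correctly", {
  pos <- data.frame(idA = "A", idB = "B", label = "positive",
                    source = "curated")
  # Balanced: C has zero mass and A-B is positive, so nothing can be drawn.
  expect_error(
    sample_negatives(pos, c("A", "B", "C"), "balanced", 1, seed = 1),
    class = "ppibench_infeasible_error"
  )
  # Uniform: the only candidates are A-C and B-C.
  neg <- sample_negatives(pos, c("A", "B", "C"), "uniform", 1, seed = 1)
  expect_equal(nrow(neg), 1)
  expect_true(paste(neg$idA, neg$idB) %in% c("A C", "B C"))
})

test_that("negative sampling is deterministic, canonical and collision-free", {
  u <- fixture_universe(51, n_proteins = 200)
  pos <- positives_from(u)
  n1 <- sample_negatives(pos, u$proteins, "balanced", 1, seed = 7)
  n2 <- sample_negatives(pos, u$proteins, "balanced", 1, seed = 7)
  expect_identical(n1, n2)
  expect_equal(nrow(n1), nrow(pos))
  expect_true(all(n1$idA < n1$idB))
  keys <- paste(n1$idA, n1$idB)
  expect_false(any(duplicated(keys)))
  expect_false(any(keys %in% paste(pos$idA, pos$idB)))

  # Zero-degree proteins never appear under balanced sampling.
  deg <- degree_table(pos, proteome = u$proteins)
  zero <- deg$protein[deg$degree == 0]
  expect_false(any(c(n1$idA, n1$idB) %in% zero))
})

test_that("balanced endpoint marginal tracks positive-set frequencies", {
  u <- fixture_universe(52, n_proteins = 500)
  pos <- positives_from(u)
  neg <- sample_negatives(pos, u$proteins, "balanced",
                          ratio = 10000 / nrow(pos), seed = 11)
  draws <- attr(neg, "endpoint_draws")
  pcount <- table(c(pos$idA, pos$idB))
  p <- as.vector(pcount[names(draws)]) / sum(pcount)
  tv <- 0.5 * sum(abs(draws / sum(draws) - p))
  expect_lt(tv, 0.05)
  chi <- suppressWarnings(stats::chisq.test(as.vector(draws), p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("uniform negatives involve hubs far less than positives do", {
  u <- fixture_universe(53, n_proteins = 500)
  pos <- positives_from(u)
  hubs <- u$degrees$protein[u$degrees$hub]
  negu <- sample_negatives(pos, u$proteins, "uniform", 1, seed = 3)
  negb <- sample_negatives(pos, u$proteins, "balanced", 1, seed = 3)
  share_pos <- endpoint_share(u$edges, hubs)
  share_unif <- endpoint_share(negu, hubs)
  share_bal <- endpoint_share(negb, hubs)
  expect_lt(share_unif, share_pos)
  expect_gt(share_bal, share_unif)
  expect_lt(abs(share_bal - share_pos), abs(share_unif - share_pos))
})

test_that("gold-standard assembly is canonical and clash-safe", {
  pos <- data.frame(idA = c("A", "D"), idB = c("B", "C"),
                    label = "positive", source = "curated")
  neg <- data.frame(idA = c("E", "A"), idB = c("F", "C"),
                    label = "negative", source = "sampled-uniform")
  g <- assemble_gold_standard(pos, neg)
  expect_equal(nrow(g), 4)
  expect_true(all(g$idA < g$idB))

  clash <- data.frame(idA = "B", idB = "A", label = "negative",
                      source = "sampled-uniform")
  expect_error(assemble_gold_standard(pos, clash),
               class = "ppibench_integrity_error")

  dup <- data.frame(idA = c("A", "B"), idB = c("B", "A"),
                    label = "positive", source = "curated")
  expect_equal(nrow(canonicalize_pairs(dup)), 1)
})
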