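# Evaluation: curve construction, tie conventions, DeLong test,
# stratified breakdowns, carbon model.

test_that("ROC curve endpoints, monotonicity and hand-checked AUROCs", {
  r <- roc_curve(c(0, 1), c(0.1, 0.9))
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$x[1], 0)
  expect_equal(r$points$y[1], 0)
  expect_equal(utils::tail(r$points$x, 1), 1)
  expect_equal(utils::tail(r$points$y, 1), 1)

  expect_equal(roc_curve(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  expect_equal(roc_curve(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.5))$auc, 0.75)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)),
               class = "ppibench_input_error")

  big <- roc_curve(rep(c(0, 1), 50), stats::runif(100))
  expect_true(all(diff(big$points$x) >= 0))
})

test_that("trapezoid AUROC equals brute-force pair counting with ties", {
  set.seed(123)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    labels <- stats::rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    scores <- round(stats::runif(n), 2)  # coarse grid forces ties
    expect_equal(roc_curve(labels, scores)$auc, brute_auc(labels, scores))
  }
})

test_that("average precision matches hand-checked cases", {
  lab <- c(1, rep(0, 9))
  expect_equal(pr_curve(lab, seq(1, 0.1, by = -0.1))$auc, 1.0)
  expect_equal(pr_curve(c(0, 1), c(0.9, 0.2))$auc, 0.5)
  lab2 <- c(1, 1, 0, 0, 1)
  expect_equal(pr_curve(lab2, c(0.9, 0.8, 0.7, 0.6, 0.99))$auc, 1.0)
  expect_error(pr_curve(c(0, 0), c(0.1, 0.2)),
               class = "ppibench_input_error")
  # Worked small case: positives at ranks 1 and 3 of 4.
  # AP = 1 * 1/2 + (2/3) * 1/2 = 5/6.
  expect_equal(pr_curve(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6))$auc, 5 / 6)
})

test_that("random rankings give AUPRC near prevalence", {
  set.seed(7)
  prev <- 0.1
  ap <- replicate(200, {
    labels <- stats::rbinom(1000, 1, prev)
    if (sum(labels) == 0) labels[1] <- 1
    pr_curve(labels, stats::runif(1000))$auc
  })
  expect_lt(abs(mean(ap) - prev), 0.05)
})

test_that("AUROC is prevalence-insensitive while AUPRC is not", {
  set.seed(11)
  sim <- function(n_pos, n_neg) {
    labels <- c(rep(1, n_pos), rep(0, n_neg))
    scores <- c(stats::rnorm(n_pos, 1), stats::rnorm(n_neg, 0))
    list(roc = roc_curve(labels, scores)$auc,
         pr = pr_curve(labels, scores)$auc)
  }
  balanced <- sim(500, 500)   # T1-style
  rare <- sim(20, 1980)       # T2-style
  expect_lt(abs(balanced$roc - rare$roc), 0.05)
  expect_lt(rare$pr, balanced$pr - 0.3)
})

test_that("DeLong AUROC equals the trapezoid estimate and handles ties", {
  set.seed(31)
  for (i in 1:10) {
    labels <- stats::rbinom(80, 1, 0.5)
    if (sum(labels) %in% c(0, 80)) next
    sA <- round(stats::runif(80), 1)
    sB <- round(stats::runif(80), 1)
    cmp <- compare_roc(labels, sA, sB)
    expect_equal(cmp$auc_A, roc_curve(labels, sA)$auc)
    expect_equal(cmp$auc_B, roc_curve(labels, sB)$auc)
  }
})

test_that("identical scores give p = 1; variance and p match pROC", {
  labels <- rep(c(0, 1), 25)
  s <- stats::runif(50)
  expect_equal(compare_roc(labels, s, s)$p_value, 1)

  set.seed(41)
  labels <- stats::rbinom(120, 1, 0.5)
  latent <- stats::rnorm(120) + labels
  sA <- latent + stats::rnorm(120, sd = 0.4)
  sB <- latent + stats::rnorm(120, sd = 0.4)
  ours <- compare_roc(labels, sA, sB)
  ref <- pROC::roc.test(
    pROC::roc(labels, sA, quiet = TRUE, direction = "<"),
    pROC::roc(labels, sB, quiet = TRUE, direction = "<"),
    method = "delong"
  )
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("stratified evaluation partitions rows and flags degeneracy", {
  set.seed(51)
  labels <- stats::rbinom(200, 1, 0.5)
  scores <- stats::runif(200) + 0.3 * labels
  one <- stratified_eval(labels, scores, rep("all", 200))
  expect_equal(one$auroc, roc_curve(labels, scores)$auc)
  expect_equal(one$auprc, pr_curve(labels, scores)$auc)

  strata <- rep(c("s1", "s2"), each = 100)
  two <- stratified_eval(labels, scores, strata)
  expect_equal(sum(two$n), 200)
  expect_equal(sum(two$n_pos), sum(labels))
  # Confusion counts are additive across strata at any threshold.
  thr <- 0.6
  tp_total <- sum(scores >= thr & labels == 1)
  tp_split <- sum(vapply(c("s1", "s2"), function(st) {
    idx <- strata == st
    sum(scores[idx] >= thr & labels[idx] == 1)
  }, numeric(1)))
  expect_equal(tp_split, tp_total)

  deg <- stratified_eval(c(0, 0, 1, 0), c(0.1, 0.2, 0.9, 0.4),
                         c("neg", "neg", "mix", "mix"))
  expect_false(deg$evaluable[deg$stratum == "neg"])
  expect_true(is.na(deg$auroc[deg$stratum == "neg"]))
})

test_that("carbon model reproduces hand arithmetic and is linear in PUE", {
  z <- estimate_carbon(0)
  expect_equal(z$energy_kwh, 0)
  expect_equal(z$carbon_gco2e, 0)

  r <- estimate_carbon(3600, n_cores = 1, power_per_core_W = 10,
                       usage_factor = 1, mem_GB = 0, PUE = 1,
                       carbon_intensity_gCO2e_per_kWh = 100)
  expect_equal(r$energy_kwh, 0.01)
  expect_equal(r$carbon_gco2e, 1)

  r2 <- estimate_carbon(3600, n_cores = 1, power_per_core_W = 10,
                        usage_factor = 1, mem_GB = 0, PUE = 2,
                        carbon_intensity_gCO2e_per_kWh = 100)
  expect_equal(r2$energy_kwh, 2 * r$energy_kwh)
  expect_equal(r2$carbon_gco2e, 2 * r$carbon_gco2e)

  expect_error(estimate_carbon(-1), class = "ppibench_input_error")
})
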