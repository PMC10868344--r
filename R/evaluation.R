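# Evaluation: ROC and PR curves, AUROC/AUPRC, a DeLong test for comparing
# correlated ROC curves on a shared test set, stratified breakdowns, and
# energy/carbon accounting for training runs.
#
# Conventions: AUROC uses the trapezoid rule over thresholds at distinct
# scores, which equals the probability that a random positive outscores a
# random negative with ties counted half. AUPRC is step-wise average
# precision (precision summed against recall increments, tied scores
# processed as one block) -- no linear interpolation, which would be
# optimistic.

check_binary_eval <- function(labels, scores, need_both = TRUE) {
  if (length(labels) != length(scores))
    input_error("labels and scores differ in length")
  labels <- as_binary_vector(labels)
  if (need_both && (sum(labels) == 0 || sum(labels) == length(labels)))
    input_error("both classes must be present to compute this metric")
  if (!need_both && sum(labels) == 0)
    input_error("at least one positive is required")
  labels
}

as_binary_vector <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "positive")
  if (!all(labels %in% c(0, 1))) input_error("labels must be binary")
  as.numeric(labels)
}

#' ROC curve and AUROC
#'
#' Thresholds are placed at the distinct score values; the curve starts at
#' (0, 0) and ends at (1, 1). The trapezoid AUROC equals the
#' concordant-pair probability with ties counted half.
#'
#' @param labels binary labels (or character with `"positive"`).
#' @param scores numeric scores, higher = more likely positive.
#' @return list of class `ppi_curve` with `points` (data frame
#'   `threshold`, `x` = FPR, `y` = TPR), `auc`, `kind = "ROC"`.
#' @export
roc_curve <- function(labels, scores) {
  labels <- check_binary_eval(labels, scores)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[block_end]
  fp <- block_end - tp
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  thr <- c(Inf, s[block_end])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = data.frame(threshold = thr, x = fpr, y = tpr),
         auc = auc, kind = "ROC"),
    class = "ppi_curve"
  )
}

#' Precision-recall curve and average precision
#'
#' AUPRC is average precision: the sum over ranked score blocks of
#' precision times the recall increment. Tied scores are processed as one
#' block.
#'
#' @inheritParams roc_curve
#' @return list of class `ppi_curve` with `points` (data frame
#'   `threshold`, `x` = recall, `y` = precision), `auc`, `kind = "PR"`.
#' @export
pr_curve <- function(labels, scores) {
  labels <- check_binary_eval(labels, scores, need_both = FALSE)
  n_pos <- sum(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[block_end]
  precision <- tp / block_end
  recall <- tp / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  structure(
    list(points = data.frame(threshold = s[block_end], x = recall,
                             y = precision),
         auc = ap, kind = "PR"),
    class = "ppi_curve"
  )
}

#' @export
print.ppi_curve <- function(x, ...) {
  cat(sprintf("<ppi_curve> %s, AUC = %.4f, %d points\n",
              x$kind, x$auc, nrow(x$points)))
  invisible(x)
}

delong_placements <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc)
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of the AUROCs of two models scored on the same
#' labelled test set, using DeLong's placement-value variance estimate of
#' `AUROC_A - AUROC_B` and a normal reference (two-sided). When the
#' variance estimate is zero and the AUROC difference is zero (e.g.
#' identical scores) the p-value is 1; a zero variance with a nonzero
#' difference is an error, as the test does not apply.
#'
#' @param labels shared binary labels.
#' @param scoresA,scoresB score vectors of the two models on the same rows.
#' @return list: `auc_A`, `auc_B`, `delta`, `se`, `z`, `p_value`.
#' @export
compare_roc <- function(labels, scoresA, scoresB) {
  labels <- check_binary_eval(labels, scoresA)
  if (length(scoresB) != length(labels))
    input_error("scoresB differs in length from labels")
  pa <- delong_placements(labels, scoresA)
  pb <- delong_placements(labels, scoresB)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5)
      return(list(auc_A = pa$auc, auc_B = pb$auc, delta = delta, se = 0,
                  z = 0, p_value = 1))
    input_error("degenerate variance estimate with nonzero AUROC difference; DeLong test not applicable")
  }
  se <- sqrt(var_delta)
  z <- delta / se
  list(auc_A = pa$auc, auc_B = pb$auc, delta = delta, se = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Per-stratum evaluation
#'
#' Computes AUROC and AUPRC independently within each stratum. Strata with
#' a single class are reported as not evaluable rather than dropped, so
#' the stratum table always accounts for every row.
#'
#' @param labels binary labels.
#' @param scores numeric scores.
#' @param strata character vector of stratum labels, one per row.
#' @return data frame: `stratum`, `n`, `n_pos`, `pos_fraction`,
#'   `evaluable`, `auroc`, `auprc`.
#' @export
stratified_eval <- function(labels, scores, strata) {
  labels <- as_binary_vector(labels)
  if (length(strata) != length(labels) || anyNA(strata))
    input_error("every row needs a stratum label")
  out <- lapply(sort(unique(strata)), function(st) {
    idx <- strata == st
    l <- labels[idx]
    evaluable <- sum(l) > 0 && sum(l) < length(l)
    data.frame(
      stratum = st, n = sum(idx), n_pos = sum(l),
      pos_fraction = mean(l), evaluable = evaluable,
      auroc = if (evaluable) roc_curve(l, scores[idx])$auc else NA_real_,
      auprc = if (evaluable) pr_curve(l, scores[idx])$auc else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Full evaluation report for one model on one test set
#'
#' Bundles curves, area summaries, stratified breakdowns and resource
#' figures into one object, the machine-readable counterpart of a
#' performance sheet.
#'
#' @param labels binary labels.
#' @param scores numeric scores.
#' @param overlap optional overlap-stratum labels per row.
#' @param topology optional topology-stratum labels per row.
#' @param resources optional list with `walltime_s`, `energy_kwh`,
#'   `carbon_gco2e` (e.g. from [estimate_carbon()]).
#' @return list of class `ppi_eval_report`.
#' @export
evaluate_scores <- function(labels, scores, overlap = NULL, topology = NULL,
                            resources = NULL) {
  labels <- check_binary_eval(labels, scores)
  roc <- roc_curve(labels, scores)
  pr <- pr_curve(labels, scores)
  structure(
    list(
      n = length(labels), n_pos = sum(labels),
      pos_fraction = mean(labels),
      auroc = roc$auc, auprc = pr$auc, roc = roc, pr = pr,
      by_overlap = if (!is.null(overlap))
        stratified_eval(labels, scores, overlap),
      by_topology = if (!is.null(topology))
        stratified_eval(labels, scores, topology),
      resources = resources
    ),
    class = "ppi_eval_report"
  )
}

#' @export
print.ppi_eval_report <- function(x, ...) {
  cat(sprintf(
    "<ppi_eval_report> n = %d (%.1f%% positive)  AUROC = %.4f  AUPRC = %.4f\n",
    x$n, 100 * x$pos_fraction, x$auroc, x$auprc
  ))
  invisible(x)
}

#' Training energy and carbon footprint
#'
#' Green-Algorithms-style accounting: energy is runtime times the power
#' draw of cores and memory, scaled by the data-centre power usage
#' effectiveness (PUE); carbon is energy times the grid carbon intensity.
#' Defaults are generic calculator values (PUE 1.67, world-average carbon
#' intensity 475 gCO2e/kWh), editable per site.
#'
#' @param walltime_s runtime in seconds.
#' @param n_cores cores used.
#' @param power_per_core_W power draw per core (W).
#' @param usage_factor core usage in `[0, 1]`-ish (1 = fully busy).
#' @param mem_GB memory provisioned (GB).
#' @param power_per_GB_W memory power draw (W/GB).
#' @param PUE power usage effectiveness of the facility.
#' @param carbon_intensity_gCO2e_per_kWh grid carbon intensity.
#' @return list `energy_kwh`, `carbon_gco2e`.
#' @export
estimate_carbon <- function(walltime_s, n_cores = 1, power_per_core_W = 12,
                            usage_factor = 1, mem_GB = 0,
                            power_per_GB_W = 0.3725, PUE = 1.67,
                            carbon_intensity_gCO2e_per_kWh = 475) {
  args <- c(walltime_s, n_cores, power_per_core_W, usage_factor, mem_GB,
            power_per_GB_W, PUE, carbon_intensity_gCO2e_per_kWh)
  if (any(!is.finite(args)) || any(args < 0))
    input_error("all carbon-model inputs must be nonnegative")
  energy_kwh <- (walltime_s / 3600) *
    (n_cores * power_per_core_W * usage_factor + mem_GB * power_per_GB_W) *
    PUE / 1000
  list(energy_kwh = energy_kwh,
       carbon_gco2e = energy_kwh * carbon_intensity_gCO2e_per_kWh)
}
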