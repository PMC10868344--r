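# Baseline model families behind one uniform fit/predict interface.
# The point of the benchmark is the evaluation design, not model research:
# these are reference implementations of the families practitioners
# actually use on low-dimensional similarity features (logistic regression,
# naive Bayes, random forest, gradient boosting) plus a penalized logistic
# baseline for high-dimensional k-mer composition features.

MODEL_FAMILIES <- c("logistic", "naive_bayes", "random_forest",
                    "gradient_boosting", "kmer_logistic")

#' Model specification
#'
#' @param family one of `"logistic"`, `"naive_bayes"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"kmer_logistic"`.
#' @param hyperparameters named list overriding the family defaults
#'   (`num.trees` for random forest; `nrounds`, `max_depth`, `eta` for
#'   gradient boosting; `lambda` for the ridge-penalized k-mer logistic).
#' @param seed integer seed; fitting is deterministic given it.
#' @return list of class `ppi_model_spec`.
#' @export
model_spec <- function(family = "logistic", hyperparameters = list(),
                       seed = 1) {
  if (!family %in% MODEL_FAMILIES)
    config_error(paste0("unknown model family '", family, "'; expected one of ",
                        paste(MODEL_FAMILIES, collapse = ", ")))
  defaults <- switch(family,
    random_forest = list(num.trees = 300),
    gradient_boosting = list(nrounds = 100, max_depth = 4, eta = 0.3),
    kmer_logistic = list(lambda = 0.05),
    list()
  )
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown) > 0)
    config_error(paste0("hyperparameters not recognised for family '",
                        family, "': ", paste(unknown, collapse = ", ")))
  defaults[names(hyperparameters)] <- hyperparameters
  structure(list(family = family, hyperparameters = defaults,
                 seed = as.integer(seed)),
            class = "ppi_model_spec")
}

feature_matrix <- function(features, feature_cols = NULL) {
  cols <- setdiff(names(features), c("idA", "idB", "label", "source",
                                     "split", "overlap_stratum",
                                     "topology_stratum"))
  if (!is.null(feature_cols)) {
    missing_cols <- setdiff(feature_cols, names(features))
    extra_cols <- setdiff(cols, feature_cols)
    if (length(missing_cols) > 0 || length(extra_cols) > 0)
      input_error(paste0(
        "feature columns do not match the training schema; missing: {",
        paste(missing_cols, collapse = ", "), "}; unexpected: {",
        paste(extra_cols, collapse = ", "), "}"
      ))
    cols <- feature_cols
  }
  x <- as.matrix(features[, cols, drop = FALSE])
  if (!is.numeric(x)) input_error("feature columns must be numeric")
  x
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "positive")
  if (!all(labels %in% c(0, 1))) input_error("labels must be binary")
  if (length(unique(labels)) < 2)
    input_error("training labels contain a single class")
  as.numeric(labels)
}

#' Fit a baseline PPI prediction model
#'
#' @param spec a [model_spec()].
#' @param features feature table from [build_feature_table()] (id columns
#'   are ignored for fitting).
#' @param labels binary vector, or character/factor with `"positive"` as
#'   the positive class.
#' @return object of class `ppi_fit`: the fitted handle, the training
#'   feature schema, wall-time seconds, and a coefficient table for the
#'   logistic families.
#' @export
fit_model <- function(spec, features, labels) {
  if (!inherits(spec, "ppi_model_spec"))
    config_error("'spec' must be built with model_spec()")
  y <- as_binary_labels(labels)
  if (nrow(features) != length(y))
    input_error("features and labels differ in length")
  if (nrow(features) < 10)
    input_error("need at least 10 training rows")
  x <- feature_matrix(features)
  hp <- spec$hyperparameters
  t0 <- proc.time()[["elapsed"]]
  set.seed(spec$seed)
  coef_table <- NULL
  model <- switch(spec$family,
    logistic = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      m <- stats::glm(.y ~ ., data = df, family = stats::binomial())
      sm <- summary(m)$coefficients
      coef_table <- data.frame(
        term = rownames(sm), estimate = sm[, 1], std_error = sm[, 2],
        p_value = sm[, 4], row.names = NULL, stringsAsFactors = FALSE
      )
      m
    },
    naive_bayes = e1071::naiveBayes(x, factor(y, levels = c(0, 1))),
    random_forest = ranger::ranger(
      x = x, y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = hp$num.trees, seed = spec$seed, num.threads = 1
    ),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = hp$max_depth, eta = hp$eta, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp$nrounds, verbose = 0
    ),
    kmer_logistic = {
      m <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = hp$lambda, standardize = TRUE)
      cf <- as.matrix(stats::coef(m))
      coef_table <- data.frame(term = rownames(cf), estimate = cf[, 1],
                               row.names = NULL, stringsAsFactors = FALSE)
      m
    }
  )
  walltime <- proc.time()[["elapsed"]] - t0
  structure(
    list(spec = spec, model = model, feature_cols = colnames(x),
         walltime_s = walltime, coefficients = coef_table),
    class = "ppi_fit"
  )
}

#' Predict interaction scores
#'
#' Scores are probabilities in `[0, 1]`, one per row, order-preserving
#' with the input. The feature columns must match the training schema
#' (column order is irrelevant; a mismatch raises an error listing the
#' differing columns).
#'
#' @param fit a `ppi_fit` from [fit_model()].
#' @param features feature table to score.
#' @return numeric vector of scores.
#' @export
predict_scores <- function(fit, features) {
  if (!inherits(fit, "ppi_fit")) input_error("'fit' must be a ppi_fit")
  x <- feature_matrix(features, fit$feature_cols)
  scores <- switch(fit$spec$family,
    logistic = {
      df <- as.data.frame(x, check.names = FALSE)
      as.numeric(stats::predict(fit$model, newdata = df, type = "response"))
    },
    naive_bayes = as.numeric(
      stats::predict(fit$model, x, type = "raw")[, "1"]
    ),
    random_forest = as.numeric(
      stats::predict(fit$model, data = x, num.threads = 1)$predictions[, "1"]
    ),
    gradient_boosting = as.numeric(
      stats::predict(fit$model, xgboost::xgb.DMatrix(x, nthread = 1))
    ),
    kmer_logistic = as.numeric(
      stats::predict(fit$model, newx = x, type = "response")[, 1]
    )
  )
  pmin(pmax(scores, 0), 1)
}

#' Agreement rate between two score vectors
#'
#' Fraction of rows where the thresholded decisions of two models agree;
#' the statistic behind statements like two models "making identical
#' predictions in 93% of cases".
#'
#' @param scoresA,scoresB numeric score vectors of equal length.
#' @param threshold decision threshold (default 0.5).
#' @return fraction in `[0, 1]`.
#' @export
agreement_rate <- function(scoresA, scoresB, threshold = 0.5) {
  if (length(scoresA) != length(scoresB))
    input_error("score vectors differ in length")
  mean((scoresA >= threshold) == (scoresB >= threshold))
}
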