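#' Assign lines to cross-validation folds
#'
#' Uniform random partition into `k` folds whose sizes differ by at most one,
#' reproducible from the seed. The same fold assignment object is meant to be
#' reused across every prediction task of an analysis run.
#'
#' @param lines line IDs.
#' @param k number of folds (5 in the standard protocol).
#' @param seed integer seed.
#' @return data frame (line, fold) with attributes `k` and `seed`.
#' @export
assign_folds <- function(lines, k = 5L, seed = 1L) {
  n <- length(lines)
  if (k > n) stopf("k = %d folds but only %d lines", k, n)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  out <- data.frame(line = lines, fold = fold)
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  out
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Aggregate per-fold predictive abilities into prediction accuracy
#'
#' Predictive ability is the Pearson correlation between predictions and the
#' validation BLUPs; accuracy divides the mean ability by the line-mean
#' heritability square root:
#' \deqn{r_g = \bar r_p / H_{line}.}
#' The standard error defaults to `sd(r_p) / (H_line sqrt(k))`; the
#' alternative convention dividing by `H_line * k` is available via
#' `se_method = "k"`.
#'
#' @param r_p numeric vector of per-fold predictive abilities.
#' @param H_line line-mean heritability square root (must exceed 0.05).
#' @param se_method `"sqrtk"` (default) or `"k"`.
#' @return one-row data frame: r_p_mean, r_g, se, k.
#' @export
accuracy_from_folds <- function(r_p, H_line, se_method = c("sqrtk", "k")) {
  se_method <- match.arg(se_method)
  r_p <- r_p[!is.na(r_p)]
  if (length(r_p) < 2L) stopf("need at least 2 fold abilities")
  if (!is.finite(H_line) || H_line < 0.05)
    stopf("H_line = %g too small for stable accuracy scaling", H_line)
  k <- length(r_p)
  denom <- if (se_method == "sqrtk") H_line * sqrt(k) else H_line * k
  data.frame(r_p_mean = mean(r_p), r_g = mean(r_p) / H_line,
             se = sd(r_p) / denom, k = k)
}

#' Cross-validated prediction accuracy for one task
#'
#' For each fold, trains on the remaining folds' grain-yield BLUEs (plus
#' secondary-trait BLUEs on all lines for multivariate tasks), predicts the
#' fold's lines, and correlates predictions with the validation BLUPs; fold
#' abilities are aggregated with [accuracy_from_folds()]. A fold whose model
#' fails to converge is excluded from the mean with a warning.
#'
#' @param folds fold assignment from [assign_folds()].
#' @param gy_blues training-data BLUE table for the target trait (within
#'   environment, or across environments for the across-environment task).
#' @param validation validation BLUP table (`line`, `blup`) from the target
#'   environment.
#' @param H_line heritability square root used to scale ability to accuracy.
#' @param kernel relationship matrix (ignored when `predict_fun` given).
#' @param secondary named list of secondary BLUE tables for the multivariate
#'   task, or `NULL` for univariate.
#' @param covariates,covariate_terms fixed covariates (see
#'   [multivariate_predict()]).
#' @param se_method passed to [accuracy_from_folds()].
#' @param predict_fun optional override: `function(train_blues, test_lines)`
#'   returning a data frame (line, pred); used for diagnostics.
#' @param ... passed to the predictor.
#' @return one-row data frame with accuracy results plus attribute
#'   `fold_abilities`.
#' @export
cross_validate <- function(folds, gy_blues, validation, H_line, kernel = NULL,
                           secondary = NULL, covariates = NULL,
                           covariate_terms = character(),
                           se_method = "sqrtk", predict_fun = NULL, ...) {
  k <- attr(folds, "k")
  lines_cv <- intersect(folds$line, intersect(gy_blues$line, validation$line))
  r_p <- rep(NA_real_, k)
  extra_args <- list(...)
  if (!is.null(secondary) && is.null(predict_fun) &&
      !"start" %in% names(extra_args)) {
    # warm-start fold fits from the complete-data covariance estimates;
    # each fold's REML optimum is still defined by its training records
    prefit <- tryCatch(suppressWarnings(
      multivariate_predict(gy_blues, secondary, kernel,
                           test_lines = lines_cv[1L],
                           covariates = covariates,
                           covariate_terms = covariate_terms,
                           on_nonconverge = "warn", ...)),
      error = function(e) NULL)
    if (!is.null(prefit)) {
      f0 <- attr(prefit, "fit")
      extra_args$start <- list(H = f0$H, R = f0$R)
      extra_args$em_iter <- 0L
    }
  }
  for (f in seq_len(k)) {
    test <- intersect(folds$line[folds$fold == f], lines_cv)
    if (length(test) < 3L) stopf("fold %d too small", f)
    train_blues <- gy_blues[!gy_blues$line %in% test, , drop = FALSE]
    pred <- tryCatch({
      if (!is.null(predict_fun)) predict_fun(train_blues, test)
      else if (is.null(secondary))
        univariate_predict(train_blues, kernel, test, covariates = covariates,
                           covariate_terms = covariate_terms)
      else
        do.call(multivariate_predict,
                c(list(gy_train = train_blues, secondary = secondary,
                       kernel = kernel, test_lines = test,
                       covariates = covariates,
                       covariate_terms = covariate_terms), extra_args))
    }, error = function(e) {
      warnf("fold %d failed (%s); excluded from the mean", f, conditionMessage(e))
      NULL
    })
    if (is.null(pred)) next
    v <- validation$blup[match(test, validation$line)]
    r_p[f] <- suppressWarnings(cor(pred$pred[match(test, pred$line)], v))
  }
  out <- accuracy_from_folds(r_p, H_line, se_method = se_method)
  out$n_lines <- length(lines_cv)
  out$folds_used <- sum(!is.na(r_p))
  attr(out, "fold_abilities") <- r_p
  out
}

#' Regression of accuracy gain on its drivers
#'
#' Ordinary least squares of the multivariate-minus-univariate accuracy gain
#' on the relationship-matrix kind (reference: pedigree), the environment
#' (reference: optimal), the mean heritability square root of the secondary
#' traits, and the mean absolute genetic correlation between secondary traits
#' and the target.
#'
#' @param gains data frame with columns `gain`, `kernel`, `environment`,
#'   `hbar`, `rbar`.
#' @param kernel_ref,environment_ref reference factor levels.
#' @return list with `coefficients` (estimate, p_value per term),
#'   `adj_r_squared`, and the `lm` fit.
#' @export
gain_regression <- function(gains, kernel_ref = "A", environment_ref = "optimal") {
  need <- c("gain", "kernel", "environment", "hbar", "rbar")
  if (!all(need %in% names(gains)))
    stopf("gains must have columns %s", paste(need, collapse = ", "))
  if (nrow(gains) < 8L) stopf("need at least 8 gain rows")
  d <- gains
  d$kernel <- stats::relevel(factor(d$kernel), ref = kernel_ref)
  d$environment <- stats::relevel(factor(d$environment), ref = environment_ref)
  drop_terms <- c(if (nlevels(d$kernel) < 2L) "kernel",
                  if (nlevels(d$environment) < 2L) "environment")
  terms_rhs <- setdiff(c("kernel", "environment", "hbar", "rbar"), drop_terms)
  fit <- lm(as.formula(paste("gain ~", paste(terms_rhs, collapse = " + "))), d)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit)))
    stopf("aliased terms in gain regression: %s",
          paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  list(coefficients = data.frame(term = rownames(cf), estimate = cf[, 1L],
                                 p_value = cf[, 4L], row.names = NULL),
       adj_r_squared = summary(fit)$adj.r.squared,
       fit = fit)
}
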