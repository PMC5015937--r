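#' Univariate pedigree/genomic prediction of line genetic values
#'
#' Fits `y = mu + beta * lodging + g + e` with `g ~ N(0, K sigma_g^2)` on the
#' training lines' BLUEs and predicts test-line genetic values through the
#' kernel cross-covariance.
#'
#' @param train_blues data frame (`line`, `blue`, optional `weight`).
#' @param kernel relationship matrix covering training and test lines.
#' @param test_lines line IDs to predict (may be absent from training data
#'   but must be in the kernel).
#' @param covariates optional data frame (`line`, covariate columns).
#' @param covariate_terms covariate columns entering the fixed design
#'   (training lines only; e.g. `"lodging"`).
#' @param use_weights use observation counts as residual weights.
#' @return data frame (line, pred) for `test_lines`, plus attribute `vc`.
#' @export
univariate_predict <- function(train_blues, kernel, test_lines,
                               covariates = NULL,
                               covariate_terms = character(),
                               use_weights = TRUE) {
  check_relationship(kernel)
  bad <- setdiff(test_lines, rownames(kernel))
  if (length(bad) > 0L)
    stopf("test lines absent from kernel: %s", paste(head(bad, 5L), collapse = ", "))
  d <- data.frame(line = train_blues$line, value = train_blues$blue)
  d$w <- if (use_weights && "weight" %in% names(train_blues))
    train_blues$weight else 1
  if (!is.null(covariates) && length(covariate_terms) > 0L) {
    d <- merge(d, covariates[c("line", covariate_terms)], by = "line",
               all.x = TRUE, sort = FALSE)
    for (cc in covariate_terms) d[[cc]][is.na(d[[cc]])] <- 0
  }
  spec <- model_spec("value", fixed = covariate_terms, genotype = "line",
                     weights = "w")
  fit <- reml_fit(d, spec, kernel = kernel)
  g <- fit$blups$genotype
  out <- data.frame(line = test_lines, pred = unname(g[test_lines]))
  attr(out, "vc") <- fit$vc
  out
}

#' Multivariate prediction of grain yield with secondary traits
#'
#' Secondary-trait BLUEs observed on every line (training and test) are
#' modeled jointly with grain-yield BLUEs observed on the training lines
#' only, under genetic covariance `K (x) H`; grain-yield genetic values for
#' the test lines are read off the mixed-model-equation predictions.
#' Observation counts enter the diagonal of `R` as inverse weights, so
#' three-replicate secondary BLUEs carry three times the residual precision
#' of single-replicate ones. With `dthd` supplied, days to heading is added
#' as a fixed covariate for every trait.
#'
#' @param gy_train grain-yield BLUE table for training lines (`line`, `blue`,
#'   `weight`).
#' @param secondary named list of secondary-trait BLUE tables covering every
#'   training and test line.
#' @param kernel relationship matrix.
#' @param test_lines lines whose grain yield is masked and predicted.
#' @param covariates optional data frame of per-line covariates.
#' @param covariate_terms covariate columns (e.g. `"lodging"`, `"dthd"`).
#' @param target name of the target trait (default `"GY"`).
#' @param ... passed on to [mt_reml_fit()].
#' @return data frame (line, pred) for `test_lines`; attributes `H`, `R`,
#'   `fit`.
#' @export
multivariate_predict <- function(gy_train, secondary, kernel, test_lines,
                                 covariates = NULL,
                                 covariate_terms = character(),
                                 target = "GY", ...) {
  check_relationship(kernel)
  if (length(secondary) == 0L) stopf("no secondary traits supplied; use univariate_predict")
  for (tt in names(secondary)) {
    miss <- setdiff(test_lines, secondary[[tt]]$line)
    if (length(miss) > 0L)
      stopf("secondary trait %s missing for test lines: %s", tt,
            paste(head(miss, 5L), collapse = ", "))
  }
  rec <- rbind(
    data.frame(line = gy_train$line, trait = target, value = gy_train$blue,
               weight = if ("weight" %in% names(gy_train)) gy_train$weight else 1),
    do.call(rbind, lapply(names(secondary), function(tt) {
      b <- secondary[[tt]]
      data.frame(line = b$line, trait = tt, value = b$blue,
                 weight = if ("weight" %in% names(b)) b$weight else 1)
    })))
  rec$trait <- factor(rec$trait, levels = c(target, names(secondary)))
  if (!is.null(covariates) && length(covariate_terms) > 0L) {
    rec <- merge(rec, covariates[c("line", covariate_terms)], by = "line",
                 all.x = TRUE, sort = FALSE)
    for (cc in covariate_terms) rec[[cc]][is.na(rec[[cc]])] <- 0
  }
  fixed <- if (length(covariate_terms) > 0L)
    as.formula(paste("~", paste(covariate_terms, collapse = " + ")))
  else ~1
  lines_all <- sort(unique(rec$line))
  K <- align_kernel(kernel, lines_all)
  fit <- mt_reml_fit(rec, K, fixed = fixed, weights = "weight", ...)
  pred <- conditional_predict(fit, target, test_lines)
  out <- data.frame(line = test_lines, pred = unname(pred))
  attr(out, "H") <- fit$H
  attr(out, "R") <- fit$R
  attr(out, "fit") <- fit
  out
}

#' Multivariate prediction of total genetic value assuming unrelated lines
#'
#' For the case without pedigree or genomic information: per-replicate BLUEs
#' of all traits are stacked, the kernel is the identity, a random replicate
#' effect nested within trait absorbs replicate shifts, and grain yield
#' (masked on the test lines) is predicted from the secondary traits through
#' the estimated trait covariances. Predictions are of total genetic value.
#'
#' @param per_rep_blues data frame with columns `line`, `trait`, `replicate`,
#'   `blue`, optional `weight`; grain-yield rows for test lines must be
#'   absent (they are masked automatically if present).
#' @param test_lines lines to predict.
#' @param target target trait name.
#' @param ... passed on to [mt_reml_fit()].
#' @return data frame (line, pred); attributes `H`, `R`.
#' @export
unrelated_predict <- function(per_rep_blues, test_lines, target = "GY", ...) {
  d <- per_rep_blues
  need <- c("line", "trait", "replicate", "blue")
  if (!all(need %in% names(d))) stopf("per_rep_blues needs columns %s", paste(need, collapse = ", "))
  d <- d[!(d$trait == target & d$line %in% test_lines), , drop = FALSE]
  rec <- data.frame(line = d$line, trait = d$trait, value = d$blue,
                    replicate = d$replicate,
                    weight = if ("weight" %in% names(d)) d$weight else 1)
  # residual grouping: records of the same line and replicate share a plot
  rec$unit <- paste(rec$line, rec$replicate, sep = "\r")
  lines_all <- sort(unique(c(rec$line, test_lines)))
  K <- identity_kernel(lines_all)
  nrep <- length(unique(rec$replicate))
  extra <- if (nrep >= 2L) "replicate" else NULL
  if (is.null(extra)) warnf("single replicate: replicate effect dropped")
  fit <- mt_reml_fit(rec, K, weights = "weight", extra_random = extra, ...)
  pred <- conditional_predict(fit, target, test_lines)
  out <- data.frame(line = test_lines, pred = unname(pred))
  attr(out, "H") <- fit$H
  attr(out, "R") <- fit$R
  out
}
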