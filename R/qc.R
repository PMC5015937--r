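#' Within-date repeatability of a trial slice
#'
#' Fits the plot-level model `y = mu + g + r + e` with genotype, replicate
#' and residual as independent random effects on one (trial, trait, date)
#' slice and returns
#' \deqn{r^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2 / n_{rep})}
#' with `nrep` the realized number of replicates in the slice.
#'
#' @param plots plot table (see [read_plot_table()] for columns).
#' @param trial,trait trial and trait identifying the slice.
#' @param date measurement date, or `NA` for single-measure traits.
#' @param environment optional environment to disambiguate trial IDs.
#' @return a one-row data frame: trial, trait, date, scope, r2, sigma_g2,
#'   sigma_r2, sigma_e2, ndate, nrep, n_obs, converged.
#' @export
within_date_repeatability <- function(plots, trial, trait, date = NA,
                                      environment = NULL) {
  sl <- qc_slice(plots, trial, trait, environment)
  if (!is.na(date)) sl <- sl[!is.na(sl$date) & sl$date == date, , drop = FALSE]
  sl <- sl[!is.na(sl$value), , drop = FALSE]
  nrep <- length(unique(sl$replicate))
  if (nrep < 2L) stopf("fewer than 2 replicates in slice (trial %s, trait %s)", trial, trait)
  rec <- data.frame(trial = trial, trait = trait, date = date,
                    scope = "single date", r2 = NA_real_,
                    sigma_g2 = NA_real_, sigma_r2 = NA_real_,
                    sigma_gd2 = NA_real_, sigma_e2 = NA_real_,
                    ndate = 1L, nrep = nrep, n_obs = nrow(sl), converged = FALSE)
  fit <- tryCatch(
    reml_fit(sl, model_spec("value", genotype = "line", random = "replicate")),
    error = function(e) NULL)
  if (is.null(fit)) return(rec)
  sg <- unname(fit$vc["line"]); se <- unname(fit$vc["residual"])
  rec$sigma_g2 <- sg; rec$sigma_r2 <- unname(fit$vc["replicate"])
  rec$sigma_e2 <- se
  rec$r2 <- if (sg + se / nrep <= 0) 0 else sg / (sg + se / nrep)
  rec$converged <- fit$converged
  rec
}

#' Overall repeatability of a trial slice across measurement dates
#'
#' Fits `y = mu + g + d + r(d) + gd + e` (replicate nested in date) on one
#' (trial, trait) slice spanning several dates and returns
#' \deqn{r^2_{overall} = \sigma_g^2 / (\sigma_g^2 + \sigma_{gd}^2/n_{date} +
#'       \sigma_e^2 / (n_{rep} n_{date}))}
#' with realized date and replicate counts.
#'
#' @inheritParams within_date_repeatability
#' @return a one-row data frame as in [within_date_repeatability()] with
#'   scope `"overall"` and the genotype-by-date component filled in.
#' @export
overall_repeatability <- function(plots, trial, trait, environment = NULL) {
  sl <- qc_slice(plots, trial, trait, environment)
  sl <- sl[!is.na(sl$value), , drop = FALSE]
  ndate <- length(unique(sl$date[!is.na(sl$date)]))
  if (ndate < 2L)
    stopf("single measurement date; use within_date_repeatability")
  nrep <- length(unique(sl$replicate))
  rec <- data.frame(trial = trial, trait = trait, date = NA,
                    scope = "overall", r2 = NA_real_,
                    sigma_g2 = NA_real_, sigma_r2 = NA_real_,
                    sigma_gd2 = NA_real_, sigma_e2 = NA_real_,
                    ndate = ndate, nrep = nrep, n_obs = nrow(sl),
                    converged = FALSE)
  fit <- tryCatch(
    reml_fit(sl, model_spec("value", genotype = "line",
                            random = c("date", "date:replicate", "line:date"))),
    error = function(e) NULL)
  if (is.null(fit)) return(rec)
  sg <- unname(fit$vc["line"]); se <- unname(fit$vc["residual"])
  sgd <- unname(fit$vc["line:date"]); if (is.na(sgd)) sgd <- 0
  rec$sigma_g2 <- sg; rec$sigma_gd2 <- sgd
  rec$sigma_r2 <- unname(fit$vc["date:replicate"]); rec$sigma_e2 <- se
  den <- sg + sgd / ndate + se / (nrep * ndate)
  rec$r2 <- if (den <= 0) 0 else sg / den
  rec$converged <- fit$converged
  rec
}

#' Remove outlier plots by externally Studentized residuals
#'
#' Computes marginal residuals from the slice repeatability model, their
#' variances from the fitted covariance structure, converts internally to
#' externally Studentized residuals via the leave-one-out identity, and
#' removes records with two-sided t-test p-value below `alpha`. The caller
#' refits repeatability once on the cleaned slice.
#'
#' @param sl one slice of the plot table (single trial, trait, and date for
#'   within-date screening).
#' @param random random terms of the slice model (as in the repeatability
#'   fit).
#' @param alpha two-sided p-value threshold (0.001 in the standard protocol).
#' @return list with `kept` and `removed` row subsets of `sl`.
#' @export
studentized_outlier_removal <- function(sl, random = "replicate",
                                        alpha = 0.001) {
  sl <- sl[!is.na(sl$value), , drop = FALSE]
  n <- nrow(sl)
  keep_terms <- vapply(random, function(r) {
    key <- interaction(sl[strsplit(r, ":", fixed = TRUE)[[1L]]], drop = TRUE)
    nlevels(key) > 1L
  }, logical(1L))
  random <- random[keep_terms]
  fit <- tryCatch(
    reml_fit(sl, model_spec("value", genotype = "line", random = random)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(kept = sl, removed = sl[0, , drop = FALSE]))
  # marginal covariance V from the fitted components
  V <- diag(unname(fit$vc["residual"]), n)
  for (r in c("line", random)) {
    vc_r <- unname(fit$vc[r]); if (is.na(vc_r) || vc_r <= 0) next
    key <- interaction(sl[strsplit(r, ":", fixed = TRUE)[[1L]]], drop = TRUE)
    Zr <- outer(as.integer(key), as.integer(key), "==") * 1
    V <- V + vc_r * Zr
  }
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  B <- solve(crossprod(X, Vi %*% X))
  r_marg <- sl$value - drop(X %*% B %*% crossprod(X, Vi %*% sl$value))
  # variance of marginal residuals, then internal -> external conversion
  vr <- diag(V - X %*% B %*% t(X))
  tin <- r_marg / sqrt(pmax(vr, 1e-12))
  df <- n - 1L - 1L           # residual df after mean; external loses one more
  if (df < 1L) {
    warnf("slice too small for Studentized screening; no removal")
    return(list(kept = sl, removed = sl[0, , drop = FALSE]))
  }
  text_ <- tin * sqrt(pmax((df - 1) / pmax(df - tin^2, 1e-8), 0))
  pv <- 2 * pt(-abs(text_), df = df)
  out <- pv < alpha
  list(kept = sl[!out, , drop = FALSE], removed = sl[out, , drop = FALSE])
}

#' Quality-control pipeline for plot-level longitudinal phenotypes
#'
#' Per trial and trait: screens each measurement date for outliers by
#' Studentized residuals (one remove-and-refit pass), computes within-date
#' repeatabilities and the overall repeatability; dates with within-date
#' r2 below `r2_min` are then dropped greedily (worst first) whenever
#' dropping them improves the overall repeatability; finally, whole trials
#' are removed when any trait's overall repeatability stays below `r2_min`.
#'
#' @param plots plot table.
#' @param r2_min repeatability threshold (0.01 in the standard protocol).
#' @param alpha outlier p-value threshold.
#' @return list with `plots` (cleaned table) and `report` (list: `outliers`
#'   removed records, `dates_dropped`, `trials_dropped`, `repeatability`
#'   table of before/after values).
#' @export
qc_pipeline <- function(plots, r2_min = 0.01, alpha = 0.001) {
  plots <- validate_plot_table(plots)
  plots$.row <- seq_len(nrow(plots))
  env_trials <- unique(plots[c("environment", "trial")])
  removed_all <- plots[0, , drop = FALSE]
  dates_dropped <- data.frame(environment = character(), trial = character(),
                              trait = character(), date = character(),
                              r2_date = numeric(), r2_overall_before = numeric(),
                              r2_overall_after = numeric())
  trials_dropped <- data.frame(environment = character(), trial = character(),
                               trait = character(), r2_overall = numeric())
  rep_table <- NULL
  keep_rows <- rep(TRUE, nrow(plots))

  for (k in seq_len(nrow(env_trials))) {
    env <- env_trials$environment[k]; tr <- env_trials$trial[k]
    in_trial <- plots$environment == env & plots$trial == tr
    traits <- unique(plots$trait[in_trial])
    trial_bad <- FALSE
    for (tt in traits) {
      idx <- which(in_trial & plots$trait == tt)
      sl <- plots[idx, , drop = FALSE]
      dates <- unique(sl$date[!is.na(sl$date)])
      # outlier pass per date (or whole slice for single-measure traits)
      slices <- if (length(dates) >= 1L)
        lapply(dates, function(d) sl[!is.na(sl$date) & sl$date == d, , drop = FALSE])
      else list(sl)
      for (ss in slices) {
        res <- studentized_outlier_removal(ss, alpha = alpha)
        if (nrow(res$removed) > 0L) {
          removed_all <- rbind(removed_all, res$removed)
          keep_rows[res$removed$.row] <- FALSE
        }
      }
      cur <- plots[keep_rows & in_trial & plots$trait == tt, , drop = FALSE]
      dates <- unique(cur$date[!is.na(cur$date)])
      if (length(dates) >= 2L) {
        wd <- do.call(rbind, lapply(dates, function(d)
          tryCatch(within_date_repeatability(cur, tr, tt, d, environment = env),
                   error = function(e) NULL)))
        ov <- tryCatch(overall_repeatability(cur, tr, tt, environment = env),
                       error = function(e) NULL)
        r2_before <- if (is.null(ov)) NA_real_ else ov$r2
        # greedy low-repeatability date drops, worst first
        if (!is.null(wd) && !is.null(ov)) {
          low <- wd[!is.na(wd$r2) & wd$r2 < r2_min, , drop = FALSE]
          low <- low[order(low$r2), , drop = FALSE]
          for (j in seq_len(nrow(low))) {
            d <- low$date[j]
            cand <- cur[is.na(cur$date) | cur$date != d, , drop = FALSE]
            nd_left <- length(unique(cand$date[!is.na(cand$date)]))
            ov2 <- if (nd_left >= 2L)
              tryCatch(overall_repeatability(cand, tr, tt, environment = env),
                       error = function(e) NULL)
            else tryCatch(within_date_repeatability(
              cand, tr, tt, unique(cand$date[!is.na(cand$date)]),
              environment = env), error = function(e) NULL)
            if (!is.null(ov2) && !is.na(ov2$r2) && !is.na(ov$r2) &&
                ov2$r2 >= ov$r2) {
              dates_dropped <- rbind(dates_dropped, data.frame(
                environment = env, trial = tr, trait = tt,
                date = as.character(d), r2_date = low$r2[j],
                r2_overall_before = ov$r2, r2_overall_after = ov2$r2))
              keep_rows[keep_rows & in_trial & plots$trait == tt &
                          !is.na(plots$date) & plots$date == d] <- FALSE
              cur <- cand
              ov <- ov2
            }
          }
        }
        r2_final <- if (is.null(ov)) NA_real_ else ov$r2
      } else {
        d1 <- if (length(dates) == 1L) dates else NA
        ov <- tryCatch(within_date_repeatability(cur, tr, tt, d1,
                                                 environment = env),
                       error = function(e) NULL)
        r2_before <- r2_final <- if (is.null(ov)) NA_real_ else ov$r2
      }
      rep_table <- rbind(rep_table, data.frame(
        environment = env, trial = tr, trait = tt,
        r2_overall_before = r2_before, r2_overall_after = r2_final))
      if (!is.na(r2_final) && r2_final < r2_min) {
        trial_bad <- TRUE
        trials_dropped <- rbind(trials_dropped, data.frame(
          environment = env, trial = tr, trait = tt, r2_overall = r2_final))
      }
    }
    if (trial_bad) keep_rows[in_trial] <- FALSE
  }

  out <- plots[keep_rows, , drop = FALSE]
  out$.row <- NULL
  removed_all$.row <- NULL
  list(plots = out,
       report = list(outliers = removed_all, dates_dropped = dates_dropped,
                     trials_dropped = trials_dropped,
                     repeatability = rep_table))
}

# slice helper shared by the repeatability functions
qc_slice <- function(plots, trial, trait, environment = NULL) {
  sel <- plots$trial == trial & plots$trait == trait
  if (!is.null(environment)) sel <- sel & plots$environment == environment
  sl <- plots[sel, , drop = FALSE]
  if (nrow(sl) == 0L) stopf("empty slice (trial %s, trait %s)", trial, trait)
  sl
}
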