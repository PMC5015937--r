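#' Per-environment line BLUEs for one trait
#'
#' Fits the across-trial model with genotype fixed and trial, measurement
#' date, replicate within trial and date, and incomplete block within trial,
#' date and replicate as independent random effects, and returns per-line
#' best linear unbiased estimates with observation-count weights.
#'
#' Variants: single-measure traits (no `date` values) drop the date terms;
#' `dthd_style = TRUE` (for days to heading, scored once on one replicate)
#' keeps only the trial random effect; `per_replicate` restricts to one
#' replicate's data and drops the replicate and block terms, emulating
#' selection candidates grown without replication.
#'
#' @param plots QC'd plot table.
#' @param trait,environment trait name and environment.
#' @param per_replicate `NULL`, or a replicate identifier to restrict to.
#' @param dthd_style drop date/replicate/block terms entirely.
#' @return data frame (line, blue, weight) with attributes `trait`,
#'   `environment`, `scope`, `replicate_scope`, `ndate`.
#' @export
environment_blues <- function(plots, trait, environment, per_replicate = NULL,
                              dthd_style = FALSE) {
  sl <- plots[plots$trait == trait & plots$environment == environment &
                !is.na(plots$value), , drop = FALSE]
  if (nrow(sl) == 0L) stopf("no data for trait %s in environment %s", trait, environment)
  if (!is.null(per_replicate)) {
    sl <- sl[sl$replicate == per_replicate, , drop = FALSE]
    if (nrow(sl) == 0L) stopf("replicate %s absent", per_replicate)
  }
  multi_date <- length(unique(sl$date[!is.na(sl$date)])) >= 2L
  random <- if (dthd_style) "trial"
  else if (!is.null(per_replicate)) {
    if (multi_date) c("trial", "date") else "trial"
  } else if (multi_date)
    c("trial", "date", "trial:date:replicate", "trial:date:replicate:block")
  else c("trial", "trial:replicate", "trial:replicate:block")
  bl <- line_blues_engine(sl, random)
  line <- bl$line
  wt <- as.integer(table(factor(sl$line, levels = line)))
  out <- data.frame(line = line, blue = bl$blue, weight = wt)
  attr(out, "trait") <- trait
  attr(out, "environment") <- environment
  attr(out, "scope") <- "single environment"
  attr(out, "replicate_scope") <-
    if (is.null(per_replicate)) "all replicates" else paste("replicate", per_replicate)
  attr(out, "ndate") <- max(1L, length(unique(sl$date[!is.na(sl$date)])))
  out
}

#' Across-environment line BLUEs excluding one validation environment
#'
#' Fits the BLUE model on all environments except `exclude`, adding a random
#' environment main effect and nesting all non-genotype effects within
#' environment; the genotype effect is fixed and common across environments.
#'
#' @param plots QC'd plot table with at least three environments.
#' @param trait trait name.
#' @param exclude environment designated for validation and left out.
#' @return data frame (line, blue, weight) with scope metadata.
#' @export
across_env_blues <- function(plots, trait, exclude) {
  if (!exclude %in% unique(plots$environment))
    stopf("environment '%s' not found", exclude)
  sl <- plots[plots$trait == trait & plots$environment != exclude &
                !is.na(plots$value), , drop = FALSE]
  if (length(unique(sl$environment)) < 2L)
    stopf("need at least 2 environments after excluding %s", exclude)
  multi_date <- length(unique(sl$date[!is.na(sl$date)])) >= 2L
  random <- if (multi_date)
    c("environment", "environment:trial", "environment:date",
      "environment:trial:date:replicate",
      "environment:trial:date:replicate:block")
  else c("environment", "environment:trial", "environment:trial:replicate",
         "environment:trial:replicate:block")
  bl <- line_blues_engine(sl, random)
  line <- bl$line
  wt <- as.integer(table(factor(sl$line, levels = line)))
  out <- data.frame(line = line, blue = bl$blue, weight = wt)
  attr(out, "trait") <- trait
  attr(out, "environment") <- paste("all except", exclude)
  attr(out, "scope") <- "across environments"
  attr(out, "replicate_scope") <- "all replicates"
  out
}

# Per-line BLUEs with nuisance random terms. Small line sets use the exact
# genotype-as-fixed REML fit. Large line sets (where a dense fixed design
# makes that fit slow) estimate the nuisance variance components once with
# genotype random, then solve the genotype-fixed generalized least squares
# problem through sparse mixed-model equations at those components; the
# nuisance component estimates differ only marginally between the two
# parameterizations.
line_blues_engine <- function(sl, random, fixed_threshold = 120L) {
  n_lines <- length(unique(sl$line))
  saturated <- nrow(sl) - n_lines < 10L   # genotype-fixed REML needs residual df
  if (n_lines <= fixed_threshold && !saturated) {
    fit <- reml_fit(sl, model_spec("value", genotype = "line",
                                   genotype_fixed = TRUE, random = random))
    cf <- fit$fixef
    sel <- grepl("^line", names(cf))
    return(data.frame(line = sub("^line", "", names(cf)[sel]),
                      blue = unname(cf[sel])))
  }
  fit0 <- reml_fit(sl, model_spec("value", genotype = "line",
                                  genotype_fixed = FALSE, random = random))
  se2 <- max(unname(fit0$vc["residual"]), 1e-8 * max(var(sl$value), 1e-12))
  keep <- vapply(random, function(r) {
    key <- interaction(sl[strsplit(r, ":", fixed = TRUE)[[1L]]], drop = TRUE)
    nlevels(key) > 1L
  }, logical(1L))
  random <- random[keep]
  lf <- factor(sl$line)
  X <- Matrix::sparseMatrix(i = seq_len(nrow(sl)), j = as.integer(lf),
                            x = 1, dims = c(nrow(sl), nlevels(lf)))
  Zs <- list(); lambdas <- numeric(0)
  for (r in random) {
    vr <- unname(fit0$vc[r])
    if (is.na(vr) || vr <= 1e-12 * se2) next
    key <- interaction(sl[strsplit(r, ":", fixed = TRUE)[[1L]]], drop = TRUE)
    Zs[[r]] <- Matrix::sparseMatrix(i = seq_len(nrow(sl)),
                                    j = as.integer(key), x = 1,
                                    dims = c(nrow(sl), nlevels(key)))
    lambdas <- c(lambdas, se2 / vr)
  }
  if (length(Zs) == 0L) {
    blue <- drop(Matrix::solve(Matrix::crossprod(X), Matrix::crossprod(X, sl$value)))
    return(data.frame(line = levels(lf), blue = as.numeric(blue)))
  }
  Z <- do.call(cbind, Zs)
  q <- vapply(Zs, ncol, integer(1L))
  Dpen <- Matrix::Diagonal(x = rep(lambdas, q))
  W <- cbind(X, Z)
  C <- Matrix::crossprod(W)
  idxZ <- nlevels(lf) + seq_len(sum(q))
  C[idxZ, idxZ] <- C[idxZ, idxZ] + Dpen
  sol <- Matrix::solve(C, Matrix::crossprod(W, sl$value))
  data.frame(line = levels(lf), blue = as.numeric(sol[seq_len(nlevels(lf))]))
}

#' Validation BLUPs of grain yield within one environment
#'
#' Fits the validation model with genotype as an iid random effect, trial,
#' replicate within trial and block within trial and replicate random, an
#' optional fixed lodging covariate (fit when lodging scores are present in
#' the environment), and an optional fixed days-to-heading covariate.
#' Genotype BLUPs from this model are the benchmark that cross-validated
#' predictions are correlated against.
#'
#' @param plots QC'd plot table.
#' @param environment environment name.
#' @param trait response trait (grain yield by default).
#' @param dthd_corrected add the days-to-heading fixed covariate.
#' @return data frame (line, blup) with attribute `dthd_corrected`.
#' @export
validation_blups <- function(plots, environment, trait = "GY",
                             dthd_corrected = FALSE) {
  sl <- plots[plots$trait == trait & plots$environment == environment &
                !is.na(plots$value), , drop = FALSE]
  if (nrow(sl) == 0L) stopf("no %s data in environment %s", trait, environment)
  fixed <- character()
  if ("lodging" %in% names(sl) && any(!is.na(sl$lodging) & sl$lodging != 0)) {
    sl$lodging[is.na(sl$lodging)] <- 0
    fixed <- c(fixed, "lodging")
  }
  if (dthd_corrected) {
    if (!"dthd" %in% names(sl) || all(is.na(sl$dthd)))
      stopf("DTHD correction requested but no dthd column present")
    sl <- sl[!is.na(sl$dthd), , drop = FALSE]
    fixed <- c(fixed, "dthd")
  }
  fit <- reml_fit(sl, model_spec(
    "value", fixed = fixed, genotype = "line", genotype_fixed = FALSE,
    random = c("trial", "trial:replicate", "trial:replicate:block")))
  b <- fit$blups$line
  out <- data.frame(line = names(b), blup = unname(b))
  attr(out, "trait") <- trait
  attr(out, "environment") <- environment
  attr(out, "dthd_corrected") <- dthd_corrected
  out
}

#' Square roots of broad-sense heritability from variance components
#'
#' For traits measured on several dates,
#' \deqn{H_{plot} = \sqrt{\sigma_g^2 / (\sigma_g^2 + \sigma_{gd}^2/n_{date} +
#'   \sigma_e^2/n_{date})}}
#' \deqn{H_{line} = \sqrt{\sigma_g^2 / (\sigma_g^2 + \sigma_{gd}^2/n_{date} +
#'   \sigma_e^2/(n_{rep} n_{date}))}}
#' Single-measure traits use `ndate = 1` and omit the genotype-by-date term.
#' When all components are zero both values are reported as 0 with the
#' `undefined` flag set.
#'
#' @param components named vector with `sigma_g2`, `sigma_e2` and optionally
#'   `sigma_gd2`.
#' @param ndate,nrep realized measurement-date and replicate counts.
#' @return one-row data frame: H_plot, H_line, ndate, nrep, undefined.
#' @export
heritability <- function(components, ndate, nrep) {
  sg <- unname(components["sigma_g2"])
  se <- unname(components["sigma_e2"])
  sgd <- if (ndate > 1L) unname(components["sigma_gd2"]) else 0
  if (is.na(sgd)) sgd <- 0
  if (is.na(sg) || is.na(se)) stopf("components must contain sigma_g2 and sigma_e2")
  den_plot <- sg + sgd / ndate + se / ndate
  den_line <- sg + sgd / ndate + se / (nrep * ndate)
  undefined <- den_line <= 0
  H_plot <- if (den_plot <= 0) 0 else sqrt(sg / den_plot)
  H_line <- if (den_line <= 0) 0 else sqrt(sg / den_line)
  data.frame(H_plot = H_plot, H_line = H_line, ndate = ndate, nrep = nrep,
             undefined = undefined)
}

#' Estimate heritability components and H for one trait in one environment
#'
#' Runs the BLUE model with genotype switched to random and (for multi-date
#' traits) a genotype-by-date interaction added, then converts the components
#' with [heritability()]. Optionally corrects for days to heading via a fixed
#' covariate; the lodging covariate is included whenever lodging scores are
#' present in the environment.
#'
#' @inheritParams environment_blues
#' @param dthd_corrected add the days-to-heading fixed covariate.
#' @return one-row data frame with environment, trait, components, H values.
#' @export
environment_heritability <- function(plots, trait, environment,
                                     dthd_corrected = FALSE) {
  sl <- plots[plots$trait == trait & plots$environment == environment &
                !is.na(plots$value), , drop = FALSE]
  if (nrow(sl) == 0L) stopf("no data for trait %s in environment %s", trait, environment)
  multi_date <- length(unique(sl$date[!is.na(sl$date)])) >= 2L
  ndate <- max(1L, length(unique(sl$date[!is.na(sl$date)])))
  nrep <- length(unique(sl$replicate))
  fixed <- character()
  if ("lodging" %in% names(sl) && any(!is.na(sl$lodging) & sl$lodging != 0)) {
    sl$lodging[is.na(sl$lodging)] <- 0
    fixed <- c(fixed, "lodging")
  }
  if (dthd_corrected) {
    if (!"dthd" %in% names(sl) || all(is.na(sl$dthd)))
      stopf("DTHD correction requested but no dthd column present")
    sl <- sl[!is.na(sl$dthd), , drop = FALSE]
    fixed <- c(fixed, "dthd")
  }
  random <- if (multi_date)
    c("trial", "date", "line:date", "trial:date:replicate",
      "trial:date:replicate:block")
  else c("trial", "trial:replicate", "trial:replicate:block")
  fit <- reml_fit(sl, model_spec("value", fixed = fixed, genotype = "line",
                                 genotype_fixed = FALSE, random = random))
  comp <- c(sigma_g2 = unname(fit$vc["line"]),
            sigma_gd2 = if (multi_date) unname(fit$vc["line:date"]) else 0,
            sigma_e2 = unname(fit$vc["residual"]))
  h <- heritability(comp, ndate = ndate, nrep = nrep)
  cbind(data.frame(environment = environment, trait = trait,
                   dthd_corrected = dthd_corrected,
                   sigma_g2 = comp[["sigma_g2"]],
                   sigma_gd2 = comp[["sigma_gd2"]],
                   sigma_e2 = comp[["sigma_e2"]]),
        h)
}
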