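#' Build a complete within-environment dataset from a scenario preset
#'
#' Convenience orchestration for simulation studies: simulates a population
#' and its field trials under a named scenario, builds the genomic and
#' pedigree kernels from the emitted markers and pedigree, estimates
#' three-replicate and single-replicate BLUEs for grain yield and the
#' requested secondary traits, validation BLUPs, and heritabilities.
#' Check lines are excluded from the candidate set (they are design fillers
#' repeated in every trial).
#'
#' @param env_name scenario preset name.
#' @param n_lines,n_markers population size.
#' @param seed simulation seed.
#' @param secondary_traits secondary traits to carry through (default: the
#'   grain-filling canopy temperature and both grain-filling vegetation
#'   indices, the strongest predictors in most environments).
#' @param qc run [qc_pipeline()] on the simulated plots first.
#' @param dthd_variants also compute DTHD-corrected validation BLUPs and
#'   heritabilities (needed for `cv_accuracy_table(dthd = TRUE)`).
#' @param estimate_rbar estimate the mean absolute secondary/grain-yield
#'   genetic correlations (averaged A/G) for the gain table.
#' @return list with `cfg`, `pop`, `plots`, `G`, `A`, `gy_blues`,
#'   `secondary` (3-rep BLUEs), `secondary_1rep`, `validation`, `H_line`
#'   (grain yield), `herit_secondary`, `candidates`.
#' @export
scenario_dataset <- function(env_name, n_lines = 150L, n_markers = 1000L,
                             seed = 1L,
                             secondary_traits = c("CT-GF", "GNDVI-GF",
                                                  "RNDVI-GF"),
                             qc = FALSE, dthd_variants = TRUE,
                             estimate_rbar = TRUE) {
  cfg <- scenario_presets(env_name, n_lines = n_lines, n_markers = n_markers,
                          seed = seed)
  pop <- simulate_population(cfg)
  plots <- simulate_trials(cfg, pop)
  if (qc) plots <- qc_pipeline(plots)$plots
  fm <- filter_and_impute_markers(pop$markers)
  G <- genomic_relationship(fm$markers)
  A <- pedigree_relationship(pop$pedigree, ids = rownames(G))
  cand <- intersect(pop$lines, rownames(G))

  pick <- function(b) b[b$line %in% cand, , drop = FALSE]
  gy_blues <- pick(environment_blues(plots, "GY", env_name))
  sec <- lapply(setNames(secondary_traits, secondary_traits), function(tt)
    pick(environment_blues(plots, tt, env_name)))
  sec1 <- lapply(setNames(secondary_traits, secondary_traits), function(tt)
    pick(environment_blues(plots, tt, env_name, per_replicate = 1)))
  vb <- validation_blups(plots, env_name)
  vb <- vb[vb$line %in% cand, , drop = FALSE]
  vbd <- hgd <- hsd <- NULL
  hg <- environment_heritability(plots, "GY", env_name)
  hs <- do.call(rbind, lapply(secondary_traits, function(tt)
    environment_heritability(plots, tt, env_name)))
  if (dthd_variants) {
    vbd <- validation_blups(plots, env_name, dthd_corrected = TRUE)
    vbd <- vbd[vbd$line %in% cand, , drop = FALSE]
    hgd <- environment_heritability(plots, "GY", env_name,
                                    dthd_corrected = TRUE)
    hsd <- do.call(rbind, lapply(secondary_traits, function(tt)
      environment_heritability(plots, tt, env_name, dthd_corrected = TRUE)))
  }
  # line-level days-to-heading covariate
  dthd_cov <- unique(plots[!is.na(plots$dthd), c("line", "dthd")])
  dthd_cov <- dthd_cov[!duplicated(dthd_cov$line), , drop = FALSE]
  # estimated mean |genetic correlation| of the secondaries with grain yield
  # (averaged A/G estimates), with and without the DTHD covariate
  rbar_of <- function(terms) {
    gcx <- tryCatch(genetic_correlation_matrix(
      c(sec, list(GY = gy_blues)), list(A = A, G = G),
      covariates = dthd_cov, covariate_terms = terms),
      error = function(e) NULL)
    if (is.null(gcx)) return(NA_real_)
    mean(abs(gcx$correlation["GY", names(sec)]))
  }
  list(cfg = cfg, pop = pop, plots = plots, G = G, A = A,
       gy_blues = gy_blues, secondary = sec, secondary_1rep = sec1,
       validation = vb, validation_dthd = vbd,
       H_line = hg$H_line,
       H_line_dthd = if (dthd_variants) hgd$H_line else NULL,
       herit = hg, herit_secondary = hs, herit_secondary_dthd = hsd,
       dthd_cov = dthd_cov,
       rbar_est = if (estimate_rbar) rbar_of(character()) else NA_real_,
       rbar_est_dthd = if (estimate_rbar && dthd_variants) rbar_of("dthd")
                       else NA_real_,
       candidates = cand)
}

#' Cross-validated accuracies for one environment, all model variants
#'
#' Runs five-fold cross-validation (one shared fold assignment) for the
#' univariate and multivariate predictors under the requested kernels and
#' secondary-trait replication modes, and assembles the gain-table row for
#' each scenario: accuracy gain, mean secondary-trait heritability (line or
#' plot basis depending on replication), and mean absolute genetic
#' correlation with grain yield.
#'
#' @param ds dataset from [scenario_dataset()].
#' @param kernel_kinds subset of `c("A", "G")`.
#' @param rep_modes subset of `c("3rep", "1rep")` (secondary-trait BLUEs on
#'   three replicates or one).
#' @param dthd correct for days to heading: the DTHD covariate enters every
#'   prediction model, validation uses DTHD-corrected BLUPs, and the gain
#'   covariates switch to their corrected versions.
#' @param k folds.
#' @param fold_seed seed for the shared fold assignment.
#' @param se_method passed to [accuracy_from_folds()].
#' @return data frame with one row per (kernel, model, rep_mode):
#'   r_g, se, and for multivariate rows the gain over the matching
#'   univariate model plus `hbar` and `rbar`.
#' @export
cv_accuracy_table <- function(ds, kernel_kinds = c("A", "G"),
                              rep_modes = c("1rep", "3rep"), dthd = FALSE,
                              k = 5L, fold_seed = 1L, se_method = "sqrtk") {
  folds <- assign_folds(ds$candidates, k = k, seed = fold_seed)
  env_name <- names(ds$cfg$environments)[1L]
  validation <- if (dthd) ds$validation_dthd else ds$validation
  H_line <- if (dthd) ds$H_line_dthd else ds$H_line
  hsec <- if (dthd) ds$herit_secondary_dthd else ds$herit_secondary
  rbar <- if (dthd) ds$rbar_est_dthd else ds$rbar_est
  covs <- if (dthd) ds$dthd_cov else NULL
  cterms <- if (dthd) "dthd" else character()
  out <- NULL
  for (kk in kernel_kinds) {
    K <- if (kk == "G") ds$G else ds$A
    uv <- cross_validate(folds, ds$gy_blues, validation, H_line,
                         kernel = K, se_method = se_method,
                         covariates = covs, covariate_terms = cterms)
    out <- rbind(out, data.frame(
      environment = env_name, kernel = kk, model = "UV", rep_mode = NA,
      dthd = dthd, r_g = uv$r_g, se = uv$se, gain = NA, hbar = NA,
      rbar = NA))
    for (rm in rep_modes) {
      sec <- if (rm == "3rep") ds$secondary else ds$secondary_1rep
      hb <- if (rm == "3rep") mean(hsec$H_line) else mean(hsec$H_plot)
      mv <- suppressWarnings(
        cross_validate(folds, ds$gy_blues, validation, H_line,
                       kernel = K, secondary = sec, se_method = se_method,
                       covariates = covs, covariate_terms = cterms,
                       on_nonconverge = "warn"))
      out <- rbind(out, data.frame(
        environment = env_name, kernel = kk, model = "MV", rep_mode = rm,
        dthd = dthd, r_g = mv$r_g, se = mv$se, gain = mv$r_g - uv$r_g,
        hbar = hb, rbar = rbar))
    }
  }
  out
}
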