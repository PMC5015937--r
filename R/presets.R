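# Reference tables for the five Obregon-style trial environments: square
# roots of broad-sense heritability (line-mean and single-plot bases, with
# and without correction for days to heading) and genetic correlations of
# the aerial secondary traits with grain yield. These drive the simulator's
# default targets and are exposed as reference data.

secondary_traits <- c("CT-GF", "CT-VEG", "GNDVI-GF", "GNDVI-VEG",
                      "RNDVI-GF", "RNDVI-VEG")
environment_names <- c("optimal", "drought", "severe_drought", "late_heat",
                       "early_heat")

.herit_table <- local({
  rows <- list(
    # environment, trait, line_unc, plot_unc, line_cor, plot_cor
    list("optimal", "CT-GF",     .93, .83, .92, .81),
    list("optimal", "CT-VEG",    .88, .81, .82, .74),
    list("optimal", "GNDVI-GF",  .97, .95, .95, .90),
    list("optimal", "GNDVI-VEG", .95, .93, .81, .74),
    list("optimal", "GY",        .83, .66, .83, .65),
    list("optimal", "RNDVI-GF",  .96, .93, .94, .88),
    list("optimal", "RNDVI-VEG", .94, .92, .76, .69),
    list("drought", "CT-GF",     .77, .68, .75, .66),
    list("drought", "CT-VEG",    .93, .83, .92, .83),
    list("drought", "GNDVI-GF",  .97, .94, .94, .89),
    list("drought", "GNDVI-VEG", .75, .71, .35, .31),
    list("drought", "GY",        .92, .81, .89, .75),
    list("drought", "RNDVI-GF",  .97, .94, .96, .91),
    list("drought", "RNDVI-VEG", .87, .85, .48, .44),
    list("severe_drought", "CT-GF",     .95, .86, .94, .85),
    list("severe_drought", "CT-VEG",    .79, .60, .79, .60),
    list("severe_drought", "GNDVI-GF",  .98, .95, .96, .90),
    list("severe_drought", "GNDVI-VEG", .53, .48, .00, .00),
    list("severe_drought", "GY",        .97, .91, .93, .83),
    list("severe_drought", "RNDVI-GF",  .97, .93, .95, .90),
    list("severe_drought", "RNDVI-VEG", .82, .79, .46, .42),
    list("late_heat", "CT-GF",     .81, .66, .81, .65),
    list("late_heat", "CT-VEG",    .76, .56, .75, .54),
    list("late_heat", "GNDVI-GF",  .97, .93, .96, .89),
    list("late_heat", "GNDVI-VEG", .89, .75, .76, .56),
    list("late_heat", "GY",        .96, .89, .96, .89),
    list("late_heat", "RNDVI-GF",  .87, .82, .74, .67),
    list("late_heat", "RNDVI-VEG", .95, .86, .92, .80),
    list("early_heat", "CT-GF",     .96, .88, .94, .85),
    list("early_heat", "CT-VEG",    .91, .85, .81, .71),
    list("early_heat", "GNDVI-GF",  .99, .97, .96, .91),
    list("early_heat", "GNDVI-VEG", .95, .92, .82, .76),
    list("early_heat", "GY",        .91, .78, .86, .70),
    list("early_heat", "RNDVI-GF",  .98, .96, .95, .88),
    list("early_heat", "RNDVI-VEG", .98, .96, .90, .84))
  data.frame(environment = vapply(rows, `[[`, "", 1L),
             trait = vapply(rows, `[[`, "", 2L),
             H_line = vapply(rows, `[[`, 0, 3L),
             H_plot = vapply(rows, `[[`, 0, 4L),
             H_line_dthd = vapply(rows, `[[`, 0, 5L),
             H_plot_dthd = vapply(rows, `[[`, 0, 6L))
})

.gencor_table <- local({
  m <- rbind(
    optimal          = c(-.65, -.50,  .27,  .38,  .33,  .33),
    drought          = c(-.59, -.53, -.29, -.41, -.12, -.43),
    severe_drought   = c(-.41,  .01, -.54, -.62, -.40, -.77),
    late_heat        = c(-.73, -.66,  .44, -.14,  .34,  .47),
    early_heat       = c(-.70, -.71,  .71,  .61,  .73,  .67))
  mc <- rbind(
    optimal          = c(-.63, -.49,  .24,  .44,  .33,  .35),
    drought          = c(-.59, -.51, -.06, -.23,  .03, -.42),
    severe_drought   = c(-.40,  .03, -.46, -.46, -.33, -.73),
    late_heat        = c(-.73, -.65,  .54, -.13,  .39,  .51),
    early_heat       = c(-.70, -.72,  .68,  .58,  .71,  .67))
  colnames(m) <- colnames(mc) <- secondary_traits
  list(uncorrected = m, corrected = mc)
})

.dthd_gy_cor <- c(optimal = 0.17, drought = -0.49, severe_drought = -0.71,
                  late_heat = -0.15, early_heat = 0.72)

# measurement-date counts per growth stage (vegetative, grain filling)
.stage_dates <- list(
  optimal = c(VEG = 5L, GF = 3L), drought = c(VEG = 3L, GF = 3L),
  severe_drought = c(VEG = 2L, GF = 5L), late_heat = c(VEG = 1L, GF = 2L),
  early_heat = c(VEG = 4L, GF = 3L))

#' Reference heritability and genetic-correlation tables
#'
#' The per-environment square-root heritabilities (line-mean and single-plot
#' bases, uncorrected and corrected for days to heading) and the secondary
#' trait-grain yield genetic correlations that parameterize the scenario
#' presets.
#'
#' @return `reference_heritabilities()`: data frame (environment, trait,
#'   H_line, H_plot, H_line_dthd, H_plot_dthd).
#'   `reference_genetic_correlations()`: list of two environment x trait
#'   matrices, `uncorrected` and `corrected`.
#' @export
reference_heritabilities <- function() .herit_table

#' @rdname reference_heritabilities
#' @export
reference_genetic_correlations <- function() .gencor_table

#' Simulation scenario presets for the five trial environments
#'
#' Returns a simulation configuration whose heritability targets equal the
#' named environment's reference column, whose secondary-trait-grain yield
#' genetic correlations equal its reference row (uncorrected), and whose
#' days-to-heading-grain yield correlation matches the reported
#' per-environment value. Pass several names for a multi-environment
#' configuration with a configurable between-environment genetic correlation
#' for grain yield.
#'
#' The per-environment trait correlation matrix is completed from the
#' published pairwise values with a single-factor structure (each trait
#' loads on a latent grain-yield factor by its correlation with grain
#' yield), which is positive definite by construction; a final eigenvalue
#' bend at 1e-4 is applied as a guard.
#'
#' @param names one or more of `"optimal"`, `"drought"`, `"severe_drought"`,
#'   `"late_heat"`, `"early_heat"`.
#' @param n_lines,n_markers population size (defaults match the study scale:
#'   557 candidate lines, 12,083 markers).
#' @param rho_between between-environment genetic correlation of the latent
#'   factor (multi-environment configurations).
#' @param seed simulation seed.
#' @param ... overrides for other [simulation_config()] fields.
#' @return a `sim_config` object.
#' @export
scenario_presets <- function(names, n_lines = 557L, n_markers = 12083L,
                             rho_between = 0.6, seed = 1L, ...) {
  bad <- setdiff(names, environment_names)
  if (length(bad) > 0L)
    stopf("unknown preset(s) %s; valid names: %s",
          paste(bad, collapse = ", "), paste(environment_names, collapse = ", "))
  envs <- lapply(names, function(e) {
    ht <- .herit_table[.herit_table$environment == e, ]
    r_gy <- vapply(ht$trait, function(tn)
      if (tn == "GY") 1 else .gencor_table$uncorrected[e, tn], numeric(1L))
    list(name = e,
         traits = data.frame(
           trait = ht$trait,
           H_line = ht$H_line, H_plot = ht$H_plot,
           r_gy = unname(r_gy)),
         ndates = .stage_dates[[e]],
         dthd_r_gy = unname(.dthd_gy_cor[e]),
         lodging = identical(e, "optimal"))
  })
  names(envs) <- names
  simulation_config(environments = envs, n_lines = n_lines,
                    n_markers = n_markers, rho_between = rho_between,
                    seed = seed, ...)
}

#' Construct and validate a simulation configuration
#'
#' Field-trial layout defaults follow the study design: trials of 30 entries
#' (28 unique lines plus 2 repeated checks), 3 replicates, 6 incomplete
#' blocks of 5 plots. Genetic variance is 1 per trait (correlation scale);
#' nuisance variances are expressed in the same units.
#'
#' @param environments list of per-environment specifications (see
#'   [scenario_presets()]).
#' @param n_lines,n_markers population dimensions (candidate lines, before
#'   adding the 2 checks).
#' @param n_founders founder pool size for the crossing scheme.
#' @param selfing_gens selfing generations after the cross (F5-equivalent
#'   inbreeding by default).
#' @param rho_between between-environment latent-factor correlation.
#' @param dthd_h single-plot heritability square root for days to heading.
#' @param var_trial,var_date,var_rep,var_block nuisance variance components.
#' @param gd_frac fallback genotype-by-date variance as a fraction of the
#'   genetic variance, used when the plot-basis target is absent.
#' @param marker_missing missing-call rate injected into the emitted marker
#'   matrix (truths use the complete matrix).
#' @param lodging_beta plot grain-yield penalty per lodging score unit.
#' @param trait_means named trait intercepts (defaults supplied).
#' @param seed integer seed.
#' @return validated `sim_config` list.
#' @export
simulation_config <- function(environments, n_lines = 557L, n_markers = 12083L,
                              n_founders = 40L, selfing_gens = 4L,
                              rho_between = 0.6, dthd_h = 0.9,
                              var_trial = 0.5, var_date = 0.5,
                              var_rep = 0.2, var_block = 0.1,
                              gd_frac = 0.25, marker_missing = 0.02,
                              lodging_beta = 0.3, trait_means = NULL,
                              seed = 1L) {
  if (is.null(trait_means))
    trait_means <- c("CT-GF" = 28, "CT-VEG" = 24, "GNDVI-GF" = 0.7,
                     "GNDVI-VEG" = 0.6, "RNDVI-GF" = 0.75, "RNDVI-VEG" = 0.65,
                     GY = 6, DTHD = 80)
  names(environments) <- vapply(environments, `[[`, "", "name")
  cfg <- list(environments = environments, n_lines = as.integer(n_lines),
              n_markers = as.integer(n_markers),
              n_founders = as.integer(n_founders),
              selfing_gens = as.integer(selfing_gens),
              rho_between = rho_between, dthd_h = dthd_h,
              var_trial = var_trial, var_date = var_date, var_rep = var_rep,
              var_block = var_block, gd_frac = gd_frac,
              marker_missing = marker_missing, lodging_beta = lodging_beta,
              trait_means = trait_means,
              entries_per_trial = 30L, unique_per_trial = 28L,
              n_rep = 3L, n_block = 6L, block_size = 5L, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$entries_per_trial != cfg$n_block * cfg$block_size)
    stopf("entries per trial must equal blocks x block size")
  for (env in cfg$environments) {
    tr <- env$traits
    if (any(tr$H_line <= 0 | tr$H_line > 1))
      stopf("heritability targets must lie in (0, 1] (environment %s)", env$name)
    if (any(abs(tr$r_gy) > 1) || abs(env$dthd_r_gy) > 1)
      stopf("genetic correlations must lie in [-1, 1] (environment %s)", env$name)
  }
  Sg <- config_genetic_covariance(cfg)
  ev <- eigen(Sg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stopf("configured genetic covariance is not positive definite after bending")
  invisible(cfg)
}

# Full genetic covariance over (environment x trait) cells, single-factor
# completion of the pairwise targets; returns a PD correlation-scale matrix
# with dimnames "<env>|<trait>".
config_genetic_covariance <- function(cfg) {
  envs <- cfg$environments
  cells <- unlist(lapply(envs, function(e)
    paste(e$name, c(e$traits$trait, "DTHD"), sep = "|")))
  loading <- unlist(lapply(envs, function(e) c(e$traits$r_gy, e$dthd_r_gy)))
  env_of <- unlist(lapply(envs, function(e)
    rep(e$name, nrow(e$traits) + 1L)))
  ne <- length(envs)
  Phi <- matrix(cfg$rho_between, ne, ne); diag(Phi) <- 1
  dimnames(Phi) <- list(names(envs), names(envs))
  Lam <- matrix(0, length(cells), ne, dimnames = list(cells, names(envs)))
  Lam[cbind(seq_along(cells), match(env_of, names(envs)))] <- loading
  Sg <- Lam %*% Phi %*% t(Lam) + diag(pmax(1 - loading^2, 1e-4))
  dimnames(Sg) <- list(cells, cells)
  bend_pd(Sg, 1e-4)
}
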