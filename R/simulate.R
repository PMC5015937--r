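#' Simulate a breeding population: markers, pedigree, and true genetic values
#'
#' Founders are inbred with per-marker allele frequencies drawn from
#' Uniform(0.05, 0.95). Each candidate line descends from a biparental cross
#' between two random founders followed by `selfing_gens` generations of
#' selfing (markers segregate independently), giving mostly-inbred lines and
#' a pedigree recording the crossing and selfing chain. Two repeated check
#' lines are simulated the same way and flagged.
#'
#' True genetic values for every (environment, trait) cell follow the
#' scaled marker-effect model: marker effects are drawn with row covariance
#' equal to the configured genetic covariance divided by the VanRaden
#' denominator, so that genetic values have covariance `G (x) Sigma` across
#' lines and cells, with per-line genetic variance approximately 1 per trait.
#' Missing calls are injected into the emitted marker matrix only; truths
#' use the complete matrix. Deterministic given `config$seed`.
#'
#' @param config a `sim_config` from [simulation_config()] or
#'   [scenario_presets()].
#' @return list with `markers` (calls with missing values), `pedigree`,
#'   `truth` (data frame line, environment, trait, g), `lines`,
#'   `check_lines`, and `genetic_covariance` (the configured cell
#'   covariance).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_markers
  nf <- config$n_founders
  n <- config$n_lines + 2L   # two checks
  p <- runif(m, 0.05, 0.95)
  founders <- matrix(2 * rbinom(nf * m, 1L, rep(p, each = nf)) - 1, nf, m)
  founder_ids <- sprintf("FND%03d", seq_len(nf))
  rownames(founders) <- founder_ids

  ids <- c(sprintf("L%04d", seq_len(config$n_lines)), "CHECK1", "CHECK2")
  calls <- matrix(0, n, m, dimnames = list(ids, NULL))
  ped <- vector("list", n + 1L)
  ped[[1L]] <- data.frame(line = founder_ids, parent1 = NA_character_,
                          parent2 = NA_character_)
  for (i in seq_len(n)) {
    par <- sample.int(nf, 2L)
    f1 <- ifelse(founders[par[1L], ] == founders[par[2L], ],
                 founders[par[1L], ], 0)
    g <- f1
    for (s in seq_len(config$selfing_gens)) {
      het <- g == 0
      if (any(het)) {
        u <- runif(sum(het))
        g[het] <- ifelse(u < 0.25, -1, ifelse(u < 0.5, 1, 0))
      }
    }
    calls[i, ] <- g
    chain_ids <- c(paste0(ids[i], "_F1"),
                   if (config$selfing_gens > 1L)
                     paste0(ids[i], "_S", seq_len(config$selfing_gens - 1L)),
                   ids[i])
    ped[[i + 1L]] <- data.frame(
      line = chain_ids,
      parent1 = c(founder_ids[par[1L]], chain_ids[-length(chain_ids)]),
      parent2 = c(founder_ids[par[2L]], chain_ids[-length(chain_ids)]))
  }
  pedigree <- do.call(rbind, ped)

  # true genetic values: marker-effect model with configured cell covariance
  Sg <- config_genetic_covariance(config)
  pj <- (colMeans(calls) + 1) / 2
  poly <- pj > 1e-9 & pj < 1 - 1e-9
  denom <- 2 * sum(pj[poly] * (1 - pj[poly]))
  Z <- sweep(calls[, poly, drop = FALSE], 2L, colMeans(calls[, poly, drop = FALSE]))
  B <- matrix(rnorm(sum(poly) * ncol(Sg)), sum(poly)) %*% chol(Sg) / sqrt(denom)
  A <- Z %*% B
  # normalize to unit per-line genetic variance: inbred populations have
  # VanRaden diagonals near 1 + F, which would inflate every cell variance
  mean_diag <- mean(rowSums(Z^2)) / denom
  A <- A / sqrt(mean_diag)
  cells <- colnames(Sg)
  parts <- strsplit(cells, "|", fixed = TRUE)
  truth <- data.frame(
    line = rep(ids, times = length(cells)),
    environment = rep(vapply(parts, `[[`, "", 1L), each = n),
    trait = rep(vapply(parts, `[[`, "", 2L), each = n),
    g = as.vector(A))

  markers <- calls
  if (config$marker_missing > 0) {
    nmiss <- round(config$marker_missing * length(markers))
    markers[sample.int(length(markers), nmiss)] <- NA
  }
  list(markers = markers, pedigree = pedigree, truth = truth,
       lines = ids[seq_len(config$n_lines)], check_lines = c("CHECK1", "CHECK2"),
       genetic_covariance = Sg)
}

#' Simulate multi-environment trial plot data from true genetic values
#'
#' Lines are grouped into trials of `unique_per_trial` candidates plus the
#' two checks, laid out in replicates and incomplete blocks; secondary
#' traits are measured on the configured number of dates per growth stage,
#' grain yield once, and days to heading once on the first replicate.
#' Trial, date, replicate-within-date, block, genotype-by-date, and residual
#' effects are added with variances solved so the realized plot- and
#' line-basis heritabilities match the configured targets given the date
#' counts; when the two targets are jointly infeasible the
#' genotype-by-date component is clamped at zero and the line-basis target
#' kept. Days to heading is written both as trait rows and as a per-line
#' covariate column; lodging scores are generated in environments flagged
#' for lodging and subtract from grain yield.
#'
#' @param config a `sim_config`.
#' @param pop population from [simulate_population()].
#' @return a plot table data frame (line, environment, trial, replicate,
#'   block, date, trait, value, lodging, dthd).
#' @export
simulate_trials <- function(config, pop) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  ids <- pop$lines
  checks <- pop$check_lines
  n_trial <- ceiling(length(ids) / config$unique_per_trial)
  truth <- pop$truth

  out <- vector("list", 0L)
  for (env in config$environments) {
    ename <- env$name
    assign_ids <- sample(ids)
    trial_of <- split(assign_ids,
                      rep(seq_len(n_trial), each = config$unique_per_trial,
                          length.out = length(assign_ids)))
    # lodging susceptibility per line (used only when env$lodging)
    all_ids <- c(ids, checks)
    lsus <- if (isTRUE(env$lodging))
      setNames(rbinom(length(all_ids), 1L, 0.25) * runif(length(all_ids), 0.3, 1),
               all_ids)
    else setNames(rep(0, length(all_ids)), all_ids)

    gval <- function(trait) {
      tv <- truth$g[truth$environment == ename & truth$trait == trait]
      setNames(tv, truth$line[truth$environment == ename & truth$trait == trait])
    }

    trait_rows <- env$traits
    env_out <- vector("list", 0L)
    for (tix in seq_len(nrow(trait_rows) + 1L)) {
      is_dthd <- tix > nrow(trait_rows)
      trait <- if (is_dthd) "DTHD" else trait_rows$trait[tix]
      g <- gval(trait)
      stage <- if (grepl("-VEG$", trait)) "VEG"
               else if (grepl("-GF$", trait)) "GF" else NA
      ndate <- if (is.na(stage)) 1L else max(1L, env$ndates[[stage]])
      dates <- if (is.na(stage)) NA_character_
               else paste0(substr(stage, 1L, 1L), seq_len(ndate))
      nrep_t <- if (is_dthd) 1L else config$n_rep

      # solve variance components for the heritability targets
      sg <- 1
      if (is_dthd) {
        se <- sg * (1 / config$dthd_h^2 - 1); sgd <- 0
      } else if (ndate > 1L) {
        Aq <- sg * (1 / trait_rows$H_plot[tix]^2 - 1)
        Bq <- sg * (1 / trait_rows$H_line[tix]^2 - 1)
        se <- (Aq - Bq) * ndate * config$n_rep / (config$n_rep - 1)
        sgd <- ndate * Aq - se
        if (sgd < 0) { sgd <- 0; se <- Bq * config$n_rep * ndate }
      } else {
        se <- config$n_rep * sg * (1 / trait_rows$H_line[tix]^2 - 1)
        sgd <- 0
      }

      mu <- unname(config$trait_means[trait])
      if (is.na(mu)) mu <- 0
      for (tr in seq_len(n_trial)) {
        entry_ids <- c(trial_of[[tr]], checks)
        trial_eff <- rnorm(1L, 0, sqrt(config$var_trial))
        gd <- if (ndate > 1L)
          matrix(rnorm(length(entry_ids) * ndate, 0, sqrt(sgd)),
                 length(entry_ids), ndate, dimnames = list(entry_ids, NULL))
        else matrix(0, length(entry_ids), 1L, dimnames = list(entry_ids, NULL))
        for (d in seq_len(ndate)) {
          date_eff <- if (ndate > 1L) rnorm(1L, 0, sqrt(config$var_date)) else 0
          for (rp in seq_len(nrep_t)) {
            rep_eff <- rnorm(1L, 0, sqrt(config$var_rep))
            blocks <- rep(seq_len(config$n_block), each = config$block_size)
            layout <- sample(entry_ids)
            if (length(layout) < length(blocks)) blocks <- blocks[seq_along(layout)]
            block_eff <- rnorm(config$n_block, 0, sqrt(config$var_block))
            lodge <- if (isTRUE(env$lodging))
              pmin(5L, rbinom(length(layout), 5L, lsus[layout] * 0.5))
            else rep(0L, length(layout))
            val <- mu + trial_eff + date_eff + rep_eff + block_eff[blocks] +
              g[layout] + gd[layout, d] + rnorm(length(layout), 0, sqrt(se))
            if (trait == "GY") val <- val - config$lodging_beta * lodge
            env_out[[length(env_out) + 1L]] <- data.frame(
              line = layout, environment = ename,
              trial = sprintf("%s_T%02d", ename, tr), replicate = rp,
              block = blocks, date = dates[d], trait = trait, value = val,
              lodging = lodge)
          }
        }
      }
    }
    env_df <- do.call(rbind, env_out)
    # per-line measured DTHD (single plot, first replicate) as covariate
    dt <- env_df[env_df$trait == "DTHD", c("line", "value")]
    dthd_map <- setNames(dt$value, dt$line)
    env_df$dthd <- unname(dthd_map[env_df$line])
    out[[length(out) + 1L]] <- env_df
  }
  plots <- do.call(rbind, out)
  rownames(plots) <- NULL
  plots
}
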