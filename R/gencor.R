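#' Genetic correlation matrix among traits from multi-trait REML
#'
#' Stacks per-trait line BLUEs into the multi-trait model with genetic
#' covariance `K (x) H` and unstructured `H`, `R`, fits by REML for each
#' supplied kernel, converts `H` to a correlation matrix, and (by default)
#' averages the per-kernel correlation estimates elementwise. Traits whose
#' genetic variance collapses to the boundary have their correlations
#' reported as 0 and flagged undefined.
#'
#' If the joint fit over all traits fails to converge the function falls
#' back to pairwise bivariate fits, flagged in the output.
#'
#' @param blues_list named list of per-trait BLUE tables (`line`, `blue`,
#'   `weight` columns), one per trait.
#' @param kernels a single relationship matrix or a named list of them
#'   (e.g. `list(A = A, G = G)`).
#' @param covariates optional data frame (`line` plus covariate columns,
#'   e.g. `lodging`, `dthd`) merged into every trait's fixed design.
#' @param covariate_terms character vector naming which covariate columns
#'   enter the fixed design.
#' @param average elementwise-average the per-kernel estimates.
#' @param use_weights use the BLUE observation counts as residual weights.
#' @return list with `correlation` (averaged matrix), `per_kernel` (list of
#'   matrices), `H` per kernel, `undefined` logical matrix, `pairwise_fallback`
#'   flag.
#' @export
genetic_correlation_matrix <- function(blues_list, kernels,
                                       covariates = NULL,
                                       covariate_terms = character(),
                                       average = TRUE, use_weights = TRUE) {
  if (is.matrix(kernels)) kernels <- list(K = kernels)
  traits <- names(blues_list)
  if (is.null(traits) || any(traits == ""))
    stopf("blues_list must be a named list of per-trait BLUE tables")
  rec <- do.call(rbind, lapply(traits, function(tt) {
    b <- blues_list[[tt]]
    data.frame(line = b$line, trait = tt, value = b$blue,
               weight = if ("weight" %in% names(b)) b$weight else 1)
  }))
  if (!is.null(covariates) && length(covariate_terms) > 0L) {
    rec <- merge(rec, covariates[c("line", covariate_terms)], by = "line",
                 all.x = TRUE, sort = FALSE)
    for (cc in covariate_terms) rec[[cc]][is.na(rec[[cc]])] <- 0
  }
  fixed <- if (length(covariate_terms) > 0L)
    as.formula(paste("~", paste(covariate_terms, collapse = " + ")))
  else ~1

  common <- sort(Reduce(intersect, lapply(blues_list, function(b) b$line)))
  per_cor <- list(); per_H <- list()
  fallback <- FALSE
  for (kn in names(kernels)) {
    K <- align_kernel(kernels[[kn]], common)
    rk <- rec[rec$line %in% common, , drop = FALSE]
    fit <- tryCatch(
      mt_reml_fit(rk, K, fixed = fixed,
                  weights = if (use_weights) "weight" else NULL),
      error = function(e) NULL)
    if (is.null(fit)) {
      fallback <- TRUE
      H <- matrix(NA_real_, length(traits), length(traits),
                  dimnames = list(traits, traits))
      for (a in seq_along(traits)) {
        H[a, a] <- 0
        for (b in seq_along(traits)) if (b > a) {
          f2 <- tryCatch(
            mt_reml_fit(rk[rk$trait %in% traits[c(a, b)], , drop = FALSE], K,
                        fixed = fixed,
                        weights = if (use_weights) "weight" else NULL,
                        on_nonconverge = "warn"),
            error = function(e) NULL)
          if (!is.null(f2)) {
            H[a, a] <- f2$H[traits[a], traits[a]]
            H[b, b] <- f2$H[traits[b], traits[b]]
            H[a, b] <- H[b, a] <- f2$H[traits[a], traits[b]]
          }
        }
      }
    } else H <- fit$H
    per_H[[kn]] <- H
    per_cor[[kn]] <- cov_to_cor_safe(H)$cor
  }
  undefined <- cov_to_cor_safe(per_H[[1L]])$undefined
  avg <- Reduce(`+`, per_cor) / length(per_cor)
  diag(avg) <- 1
  list(correlation = if (average) avg else per_cor[[1L]],
       per_kernel = per_cor, H = per_H, undefined = undefined,
       pairwise_fallback = fallback)
}

# covariance -> correlation with zero-variance traits reported as 0 + flag
cov_to_cor_safe <- function(H, tol_frac = 1e-6) {
  d <- diag(H)
  tiny <- d <= tol_frac * max(d, .Machine$double.eps)
  s <- sqrt(pmax(d, .Machine$double.eps))
  C <- H / outer(s, s)
  C[tiny, ] <- 0; C[, tiny] <- 0
  diag(C) <- ifelse(tiny, 0, 1)
  C <- pmin(pmax(C, -1), 1)
  und <- outer(tiny, tiny, "|")
  dimnames(C) <- dimnames(H); dimnames(und) <- dimnames(H)
  list(cor = C, undefined = und)
}
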