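#' Multi-trait REML with Kronecker-structured genetic covariance
#'
#' Fits the multivariate mixed model
#' \deqn{y = X b + Z a + e, \quad a \sim N(0, K \otimes H), \quad
#'       e \sim N(0, I \otimes R)}
#' where `K` is a line relationship kernel (pedigree, genomic, or identity),
#' `H` is the unstructured trait-by-trait genetic covariance and `R` the
#' unstructured residual covariance. Records carry optional weights: the
#' residual variance of a record with weight `w` is `R[t,t]/w`, and residual
#' covariances between traits on the same unit scale by `1/sqrt(w_1 w_2)`
#' (weights enter the diagonal of `R`).
#'
#' Missing responses are simply absent rows of the stacked observation vector
#' (never zero-filled); genetic values are predicted for every line-by-trait
#' cell, including masked ones, through the mixed-model equations. Estimation
#' runs a fixed number of EM iterations for stability, then switches to
#' average-information updates with step halving; `H` and `R` are kept
#' positive definite by eigenvalue bending after each update.
#'
#' A fast path is used automatically when the data are complete (every kernel
#' line observed once for every trait, per-trait-constant weights, no extra
#' random term): a single eigendecomposition of `K` rotates the model into
#' independent per-line blocks.
#'
#' @param records data frame with columns `line`, `trait`, `value`, optional
#'   `weight`, optional `unit` (residual-covariance grouping, default the
#'   line), an optional extra-random grouping column, and any covariates used
#'   in `fixed`.
#' @param kernel relationship matrix whose rownames cover all record lines;
#'   lines present in the kernel but not in `records` receive predictions.
#' @param fixed one-sided formula applied to every trait (default `~ 1`), or
#'   a named list of per-trait formulas.
#' @param weights name of the weight column, or `NULL` for unweighted.
#' @param extra_random name of a column defining an additional independent
#'   random intercept nested within trait (one shared variance), or `NULL`.
#' @param constrain `"unstructured"` (default) or `"diagonal"` to force `H`
#'   and `R` diagonal.
#' @param em_iter number of EM warm-start iterations.
#' @param max_iter total iteration cap.
#' @param tol_ll,tol_par convergence tolerances on the restricted
#'   log-likelihood change and the maximum relative parameter change.
#' @param on_nonconverge `"error"` (default) or `"warn"`.
#' @param start optional list with `H` and `R` starting matrices (defaults:
#'   half the phenotypic covariance each).
#' @return an object of class `mt_fit`: list with `traits`, `lines`, `H`,
#'   `R`, `extra_vc`, `fixef` (per trait), `predictions` (lines x traits
#'   matrix of genetic values for all cells), `loglik`, `trace`, `converged`.
#' @export
mt_reml_fit <- function(records, kernel, fixed = ~1, weights = NULL,
                        extra_random = NULL,
                        constrain = c("unstructured", "diagonal"),
                        em_iter = 20L, max_iter = 200L,
                        tol_ll = 1e-6, tol_par = 1e-5,
                        on_nonconverge = c("error", "warn"),
                        start = NULL) {
  constrain <- match.arg(constrain)
  on_nonconverge <- match.arg(on_nonconverge)
  check_relationship(kernel)
  records <- as.data.frame(records)
  if (!all(c("line", "trait", "value") %in% names(records)))
    stopf("records must have columns line, trait, value")
  records <- records[!is.na(records$value), , drop = FALSE]
  if (nrow(records) == 0L) stopf("no observed records")
  lines <- rownames(kernel)
  bad <- setdiff(unique(as.character(records$line)), lines)
  if (length(bad) > 0L)
    stopf("record lines absent from kernel: %s", paste(head(bad, 5L), collapse = ", "))
  traits <- if (is.factor(records$trait)) levels(droplevels(records$trait))
            else unique(as.character(records$trait))
  tt <- length(traits)
  if (tt < 2L && is.null(extra_random))
    stopf("mt_reml_fit needs at least 2 traits")

  i_idx <- match(as.character(records$line), lines)
  t_idx <- match(as.character(records$trait), traits)
  y <- as.numeric(records$value)
  w <- if (!is.null(weights)) as.numeric(records[[weights]]) else rep(1, length(y))
  if (any(!is.finite(w)) || any(w <= 0)) stopf("weights must be positive")
  unit <- if ("unit" %in% names(records)) as.character(records$unit)
          else as.character(records$line)

  # per-trait fixed designs, assembled block-diagonally
  fml_list <- if (inherits(fixed, "formula"))
    setNames(rep(list(fixed), tt), traits) else fixed
  if (!all(traits %in% names(fml_list)))
    stopf("fixed must be one formula or a named list covering all traits")
  Xt <- vector("list", tt)
  for (s in seq_len(tt)) {
    rs <- records[t_idx == s, , drop = FALSE]
    Xs <- model.matrix(fml_list[[traits[s]]], rs)
    if (qr(Xs)$rank < ncol(Xs))
      stopf("singular fixed design for trait %s", traits[s])
    Xt[[s]] <- Xs
  }
  p_t <- vapply(Xt, ncol, integer(1L))
  p_tot <- sum(p_t)
  X <- matrix(0, length(y), p_tot)
  off <- c(0L, cumsum(p_t))
  for (s in seq_len(tt))
    X[t_idx == s, (off[s] + 1L):off[s + 1L]] <- Xt[[s]]
  attr(X, "p_t") <- p_t

  # starting values: half the phenotypic covariance each (per design)
  Ybar <- matrix(NA_real_, length(lines), tt)
  agg <- tapply(y, list(i_idx, t_idx), mean)
  Ybar[as.integer(rownames(agg)), as.integer(colnames(agg))] <- agg
  Sph <- suppressWarnings(cov(Ybar, use = "pairwise.complete.obs"))
  dv <- diag(Sph)
  dv[!is.finite(dv) | dv <= 0] <- stats::median(dv[is.finite(dv) & dv > 0],
                                               na.rm = TRUE)
  if (!is.finite(dv[1L])) dv[] <- 1
  diag(Sph) <- dv
  Sph[!is.finite(Sph)] <- 0
  Sph <- bend_pd(Sph, 1e-4)
  H0 <- R0 <- sanitize_cov(0.5 * Sph, 0.98)
  if (!is.null(start)) {
    # warm start (e.g. cross-validation folds started from the full-data
    # fit); the REML optimum is defined by the data alone
    H0 <- sanitize_cov(unname(start$H), 0.9995)
    R0 <- sanitize_cov(unname(start$R), 0.98)
  }
  attr(H0, "changed") <- attr(R0, "changed") <- NULL
  if (constrain == "diagonal") { H0 <- diag(diag(H0), tt); R0 <- diag(diag(R0), tt) }

  complete_ok <- is.null(extra_random) &&
    identical(unit, as.character(records$line)) &&
    nrow(records) == length(lines) * tt &&
    !anyDuplicated(paste(i_idx, t_idx)) &&
    all(vapply(seq_len(tt), function(s) {
      ws <- w[t_idx == s]; diff(range(ws)) < 1e-12
    }, logical(1L)))

  eng <- if (complete_ok) mt_engine_complete else mt_engine_general
  res <- eng(y = y, X = X, i_idx = i_idx, t_idx = t_idx, w = w, unit = unit,
             extra = if (is.null(extra_random)) NULL
                     else paste(records$trait, records[[extra_random]], sep = "\r"),
             K = unclass(kernel), H0 = H0, R0 = R0, constrain = constrain,
             em_iter = em_iter, max_iter = max_iter,
             tol_ll = tol_ll, tol_par = tol_par)

  if (!res$converged) {
    msg <- sprintf("multi-trait REML did not converge in %d iterations (last |dLL| = %.3g)",
                   max_iter, res$last_dll)
    if (on_nonconverge == "error") {
      cond <- simpleError(msg)
      cond$trace <- res$trace
      stop(cond)
    }
    warnf("%s", msg)
  }

  dimnames(res$H) <- dimnames(res$R) <- list(traits, traits)
  dimnames(res$predictions) <- list(lines, traits)
  fixef <- vector("list", tt)
  for (s in seq_len(tt))
    fixef[[s]] <- setNames(res$beta[(off[s] + 1L):off[s + 1L]],
                           colnames(Xt[[s]]))
  names(fixef) <- traits
  structure(list(traits = traits, lines = lines, H = res$H, R = res$R,
                 extra_vc = res$extra_vc, fixef = fixef,
                 predictions = res$predictions, loglik = res$loglik,
                 trace = res$trace, converged = res$converged,
                 engine = if (complete_ok) "rotated" else "general"),
            class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  cat("Multi-trait REML fit (", x$engine, " engine, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  cat("Traits:", paste(x$traits, collapse = ", "), "\n")
  cat("Restricted log-likelihood:", format(x$loglik, digits = 8), "\n")
  cat("Genetic covariance H:\n"); print(round(x$H, 4))
  cat("Residual covariance R:\n"); print(round(x$R, 4))
  invisible(x)
}

#' Extract predicted genetic values from a multi-trait fit
#'
#' Returns the fitted genetic values for the requested line-by-trait cells.
#' Masked cells (lines with no observation for the trait) carry predictions
#' borrowed from kernel relatives and genetically correlated traits through
#' the mixed-model equations; this is deterministic given the fit.
#'
#' @param fit an `mt_fit` object.
#' @param trait trait name.
#' @param lines line IDs (default: all kernel lines).
#' @return named numeric vector of genetic-value predictions.
#' @export
conditional_predict <- function(fit, trait, lines = fit$lines) {
  stopifnot(inherits(fit, "mt_fit"))
  if (!trait %in% fit$traits)
    stopf("unknown trait '%s' (fit has: %s)", trait, paste(fit$traits, collapse = ", "))
  bad <- setdiff(lines, fit$lines)
  if (length(bad) > 0L)
    stopf("unknown lines: %s", paste(head(bad, 5L), collapse = ", "))
  setNames(fit$predictions[lines, trait], lines)
}

# ---- shared parameter bookkeeping --------------------------------------

# Keep a covariance matrix inside a well-conditioned parameter space:
# eigenvalue bending plus a cap on off-diagonal correlations. Residual
# correlations approaching +-1 create degenerate likelihood spikes (a
# residual contrast that the latent genetic values can interpolate exactly),
# so R is held at |r| <= 0.98; H correlations may legitimately approach 1
# and are capped just inside the boundary.
sanitize_cov <- function(M, max_cor) {
  M0 <- M
  M <- bend_pd(M)
  if (nrow(M) > 1L) {
    s <- sqrt(pmax(diag(M), .Machine$double.eps))
    C <- M / outer(s, s)
    off <- row(C) != col(C)
    if (any(abs(C[off]) > max_cor)) {
      C[off] <- pmin(pmax(C[off], -max_cor), max_cor)
      M <- outer(s, s) * C
      M <- bend_pd(M)
    }
  }
  attr(M, "changed") <- max(abs(M - M0)) > 1e-10 * (mean(diag(M)) + 1e-300)
  M
}

mt_param_pairs <- function(tt, constrain) {
  if (constrain == "diagonal") cbind(seq_len(tt), seq_len(tt))
  else {
    idx <- which(upper.tri(matrix(0, tt, tt), diag = TRUE), arr.ind = TRUE)
    cbind(idx[, "row"], idx[, "col"])
  }
}

mt_theta_get <- function(H, R, extra_vc, pairs) {
  c(H[pairs], R[pairs], extra_vc)
}

mt_theta_set <- function(theta, tt, pairs, has_extra, constrain) {
  np <- nrow(pairs)
  H <- matrix(0, tt, tt); R <- matrix(0, tt, tt)
  H[pairs] <- theta[seq_len(np)];        H[pairs[, 2:1, drop = FALSE]] <- theta[seq_len(np)]
  R[pairs] <- theta[np + seq_len(np)];   R[pairs[, 2:1, drop = FALSE]] <- theta[np + seq_len(np)]
  Hb <- sanitize_cov(H, 0.9995); Rb <- sanitize_cov(R, 0.98)
  bent <- attr(Hb, "changed") || attr(Rb, "changed")
  H <- Hb; R <- Rb
  attr(H, "changed") <- NULL; attr(R, "changed") <- NULL
  if (constrain == "diagonal") { H <- diag(diag(H), tt); R <- diag(diag(R), tt) }
  extra_vc <- if (has_extra) max(theta[2 * np + 1L], 1e-10 * mean(diag(R))) else NULL
  list(H = H, R = R, extra_vc = extra_vc, bent = bent)
}

# ---- general engine: dense V over observed cells -----------------------

mt_engine_general <- function(y, X, i_idx, t_idx, w, unit, extra, K, H0, R0,
                              constrain, em_iter, max_iter, tol_ll, tol_par) {
  n_obs <- length(y)
  n <- nrow(K)
  tt <- nrow(H0)
  sw <- sqrt(w)
  Kobs <- K[i_idx, i_idx, drop = FALSE]

  # same-unit residual pairs (includes o1 == o2)
  uf <- factor(unit)
  by_unit <- split(seq_len(n_obs), uf)
  pr1 <- pr2 <- integer(0)
  for (oo in by_unit) {
    g <- expand.grid(o1 = oo, o2 = oo)
    pr1 <- c(pr1, g$o1); pr2 <- c(pr2, g$o2)
  }
  pr_s <- 1 / (sw[pr1] * sw[pr2])
  n_units <- length(by_unit)

  has_extra <- !is.null(extra)
  if (has_extra) {
    ef <- factor(extra)
    Emat <- matrix(0, n_obs, nlevels(ef))
    Emat[cbind(seq_len(n_obs), as.integer(ef))] <- 1
    EEt <- tcrossprod(Emat)
    n_groups <- nlevels(ef)
    extra_vc <- 0.1 * mean(diag(R0))
  } else { extra_vc <- NULL }

  pairs <- mt_param_pairs(tt, constrain)
  np <- nrow(pairs)
  H <- H0; R <- R0

  build_V <- function(H, R, extra_vc) {
    V <- Kobs * H[t_idx, t_idx]
    V[cbind(pr1, pr2)] <- V[cbind(pr1, pr2)] + R[cbind(t_idx[pr1], t_idx[pr2])] * pr_s
    if (has_extra) V <- V + extra_vc * EEt
    V
  }

  eval_state <- function(H, R, extra_vc) {
    V <- build_V(H, R, extra_vc)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    dcv <- diag(cV)
    if (!all(is.finite(dcv)) || min(dcv) < 1e-8 * max(dcv)) return(NULL)
    Vinv <- chol2inv(cV)
    VX <- Vinv %*% X
    XtVX <- crossprod(X, VX)
    cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cXtVX)) return(NULL)
    B <- chol2inv(cXtVX)
    P <- Vinv - VX %*% B %*% t(VX)
    q <- drop(P %*% y)
    quad <- sum(y * q)
    if (quad < -1e-8 * sum(y^2)) return(NULL)   # P must be PSD; cancellation
    ll <- -0.5 * (2 * sum(log(dcv)) + 2 * sum(log(diag(cXtVX))) + quad)
    if (!is.finite(ll)) return(NULL)
    beta <- drop(B %*% crossprod(VX, y))
    list(P = P, q = q, ll = ll, beta = beta)
  }

  trace_mats <- function(P) {
    TK <- TR <- matrix(0, tt, tt)
    for (a in seq_len(tt)) for (b in a:tt) {
      oa <- which(t_idx == a); ob <- which(t_idx == b)
      TK[a, b] <- TK[b, a] <- sum(P[oa, ob, drop = FALSE] * Kobs[oa, ob, drop = FALSE])
    }
    sel <- P[cbind(pr1, pr2)] * pr_s
    for (a in seq_len(tt)) for (b in a:tt) {
      m <- (t_idx[pr1] == a & t_idx[pr2] == b)
      if (a != b) m <- m | (t_idx[pr1] == b & t_idx[pr2] == a)
      v <- sum(sel[m]); if (a != b) v <- v / 2
      TR[a, b] <- TR[b, a] <- v
    }
    TU <- if (has_extra) sum(P * EEt) else NULL
    list(TK = TK, TR = TR, TU = TU)
  }

  scatter <- function(q, idx_row, idx_col, nr, nc) {
    M <- matrix(0, nr, nc)
    for (k in seq_along(q)) M[idx_row[k], idx_col[k]] <- M[idx_row[k], idx_col[k]] + q[k]
    M
  }

  st <- eval_state(H, R, extra_vc)
  if (is.null(st)) stopf("initial covariance matrices are not positive definite")
  trace_ll <- st$ll
  converged <- FALSE
  last_dll <- Inf
  iter <- 0L
  dll_window <- numeric(0)
  u_idx <- as.integer(uf)

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    Q <- scatter(st$q, i_idx, t_idx, n, tt)
    Qe <- scatter(st$q / sw, u_idx, t_idx, n_units, tt)
    tm <- trace_mats(st$P)

    if (iter <= em_iter) {
      KQ <- K %*% Q
      Hn <- H + (H %*% (crossprod(Q, KQ) - tm$TK) %*% H) / n
      Rn <- R + (R %*% (crossprod(Qe) - tm$TR) %*% R) / n_units
      Hn <- sanitize_cov(Hn, 0.9995); Rn <- sanitize_cov(Rn, 0.98)
      if (constrain == "diagonal") { Hn <- diag(diag(Hn), tt); Rn <- diag(diag(Rn), tt) }
      en <- if (has_extra) {
        qe <- drop(crossprod(Emat, st$q))
        max(extra_vc + extra_vc^2 * (sum(qe^2) - tm$TU) / n_groups,
            1e-10 * mean(diag(Rn)))
      } else NULL
      st2 <- eval_state(Hn, Rn, en)
      if (!is.null(st2)) {
        last_dll <- st2$ll - st$ll
        H <- Hn; R <- Rn; extra_vc <- en; st <- st2
        trace_ll <- c(trace_ll, st$ll)
      }
      next
    }

    # average-information step
    KQo <- (K %*% Q)[i_idx, , drop = FALSE]     # n_obs x tt
    Qeo <- Qe[u_idx, , drop = FALSE] / sw       # scaled unit scatter per obs
    n_par <- 2L * np + as.integer(has_extra)
    Umat <- matrix(0, n_obs, n_par)
    score <- numeric(n_par)
    for (k in seq_len(np)) {
      a <- pairs[k, 1L]; b <- pairs[k, 2L]
      u <- numeric(n_obs)
      u[t_idx == a] <- u[t_idx == a] + KQo[t_idx == a, b]
      if (a != b) u[t_idx == b] <- u[t_idx == b] + KQo[t_idx == b, a]
      Umat[, k] <- u
      mult <- if (a == b) 1 else 2
      score[k] <- -0.5 * (mult * tm$TK[a, b] - sum(st$q * u))
      u2 <- numeric(n_obs)
      u2[t_idx == a] <- u2[t_idx == a] + Qeo[t_idx == a, b]
      if (a != b) u2[t_idx == b] <- u2[t_idx == b] + Qeo[t_idx == b, a]
      Umat[, np + k] <- u2
      score[np + k] <- -0.5 * (mult * tm$TR[a, b] - sum(st$q * u2))
    }
    if (has_extra) {
      u3 <- drop(EEt %*% st$q)
      Umat[, n_par] <- u3
      score[n_par] <- -0.5 * (tm$TU - sum(st$q * u3))
    }
    PU <- st$P %*% Umat
    AI <- 0.5 * crossprod(Umat, PU)
    AI <- AI + diag(1e-8 * max(diag(AI)), n_par)
    # parameters pinned at the zero-variance boundary are frozen: including
    # them makes the AI system ill-conditioned and stalls every direction
    scale <- mean(diag(H)) + mean(diag(R))
    pinH <- diag(H) < 1e-6 * scale
    pinR <- diag(R) < 1e-6 * scale
    active <- c(!(pinH[pairs[, 1L]] | pinH[pairs[, 2L]]),
                !(pinR[pairs[, 1L]] | pinR[pairs[, 2L]]),
                if (has_extra) TRUE)
    delta <- rep(0, n_par)
    delta[active] <- tryCatch(solve(AI[active, active, drop = FALSE],
                                    score[active]),
                              error = function(e) NA_real_)
    if (anyNA(delta)) delta <- NULL
    improved <- FALSE
    if (!is.null(delta)) {
      theta0 <- mt_theta_get(H, R, extra_vc, pairs)
      step <- 1
      for (h in 1:12) {
        cand <- mt_theta_set(theta0 + step * delta, tt, pairs, has_extra, constrain)
        st2 <- eval_state(cand$H, cand$R, cand$extra_vc)
        if (!is.null(st2) && st2$ll >= st$ll - 1e-10) {
          dpar <- max(abs(c(cand$H - H, cand$R - R)) /
                        (mean(diag(H)) + mean(diag(R)) + 1e-12))
          last_dll <- st2$ll - st$ll
          H <- cand$H; R <- cand$R; extra_vc <- cand$extra_vc; st <- st2
          trace_ll <- c(trace_ll, st$ll)
          improved <- TRUE
          if (abs(last_dll) < tol_ll && dpar < tol_par) converged <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!improved) {
      # fall back to one EM update; if that stalls too, declare convergence
      KQ <- K %*% Q
      Hn <- sanitize_cov(H + (H %*% (crossprod(Q, KQ) - tm$TK) %*% H) / n, 0.9995)
      Rn <- sanitize_cov(R + (R %*% (crossprod(Qe) - tm$TR) %*% R) / n_units, 0.98)
      if (constrain == "diagonal") { Hn <- diag(diag(Hn), tt); Rn <- diag(diag(Rn), tt) }
      st2 <- eval_state(Hn, Rn, extra_vc)
      if (!is.null(st2) && st2$ll >= st$ll - 1e-10) {
        last_dll <- st2$ll - st$ll
        H <- Hn; R <- Rn; st <- st2
        trace_ll <- c(trace_ll, st$ll)
        if (abs(last_dll) < tol_ll) converged <- TRUE
      } else converged <- abs(last_dll) < tol_ll
    }
    # flat-ridge guard: when the last 12 post-EM iterations jointly gained
    # almost nothing, the remaining crawl along a weakly identified H/R
    # ridge cannot move the estimates meaningfully
    if (iter > em_iter) {
      dll_window <- c(dll_window, abs(last_dll))
      if (length(dll_window) > 12L) dll_window <- dll_window[-1L]
      if (length(dll_window) == 12L && sum(dll_window) < 0.015)
        converged <- TRUE
    }
    if (converged) break
  }

  Q <- scatter(st$q, i_idx, t_idx, n, tt)
  preds <- (K %*% Q) %*% H
  list(H = H, R = R, extra_vc = extra_vc, beta = st$beta,
       predictions = preds, loglik = st$ll, trace = trace_ll,
       converged = converged, last_dll = last_dll)
}

# ---- rotated engine for complete balanced data -------------------------

mt_engine_complete <- function(y, X, i_idx, t_idx, w, unit, extra, K, H0, R0,
                               constrain, em_iter, max_iter, tol_ll, tol_par) {
  n <- nrow(K)
  tt <- nrow(H0)
  # per-trait weight (constant within trait); absorb into R
  wt <- vapply(seq_len(tt), function(s) w[t_idx == s][1L], numeric(1L))
  swt <- sqrt(wt)
  eK <- eigen((K + t(K)) / 2, symmetric = TRUE)
  U <- eK$vectors
  dvals <- pmax(eK$values, 0)

  Y <- matrix(0, n, tt)
  Y[cbind(i_idx, t_idx)] <- y
  Yr <- crossprod(U, Y)                         # rotated responses, n x tt

  # X arrived block-diagonal over obs with per-trait column counts in p_t;
  # recover per-trait blocks in kernel line order and rotate
  p_t <- attr(X, "p_t")
  off <- c(0L, cumsum(p_t))
  p_tot <- sum(p_t)
  Xr <- vector("list", tt)
  for (s in seq_len(tt)) {
    rows <- which(t_idx == s)
    cols <- (off[s] + 1L):off[s + 1L]
    Xs <- matrix(0, n, length(cols))
    Xs[i_idx[rows], ] <- X[rows, cols, drop = FALSE]
    Xr[[s]] <- crossprod(U, Xs)
  }

  pairs <- mt_param_pairs(tt, constrain)
  np <- nrow(pairs)
  H <- H0
  Rw <- diag(1 / swt) %*% R0 %*% diag(1 / swt)   # estimate weighted residual cov

  eval_state <- function(H, Rw) {
    Vinv <- array(0, c(tt, tt, n))
    ldV <- 0
    for (i in seq_len(n)) {
      M <- dvals[i] * H + Rw
      cM <- tryCatch(chol(M), error = function(e) NULL)
      if (is.null(cM)) return(NULL)
      dcm <- diag(cM)
      if (!all(is.finite(dcm)) || min(dcm) < 1e-10 * max(dcm)) return(NULL)
      ldV <- ldV + 2 * sum(log(dcm))
      Vinv[, , i] <- chol2inv(cM)
    }
    XtVX <- matrix(0, p_tot, p_tot)
    rhs <- numeric(p_tot)
    for (s in seq_len(tt)) for (s2 in seq_len(tt)) {
      v <- Vinv[s, s2, ]
      blk <- crossprod(Xr[[s]], v * Xr[[s2]])
      XtVX[(off[s] + 1L):off[s + 1L], (off[s2] + 1L):off[s2 + 1L]] <-
        XtVX[(off[s] + 1L):off[s + 1L], (off[s2] + 1L):off[s2 + 1L]] + blk
      rhs[(off[s] + 1L):off[s + 1L]] <-
        rhs[(off[s] + 1L):off[s + 1L]] + crossprod(Xr[[s]], v * Yr[, s2])
    }
    cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cXtVX)) return(NULL)
    beta <- backsolve(cXtVX, forwardsolve(t(cXtVX), rhs))
    Rm <- Yr
    for (s in seq_len(tt))
      Rm[, s] <- Rm[, s] - Xr[[s]] %*% beta[(off[s] + 1L):off[s + 1L]]
    Qm <- matrix(0, n, tt)                       # q_i = Vinv_i r_i
    for (s in seq_len(tt))
      for (s2 in seq_len(tt)) Qm[, s] <- Qm[, s] + Vinv[s, s2, ] * Rm[, s2]
    ll <- -0.5 * (ldV + 2 * sum(log(diag(cXtVX))) + sum(Rm * Qm))
    if (!is.finite(ll)) return(NULL)
    # diagonal t x t blocks of P: P_ii = Vinv_i - A_i B A_i',  A_i = Vinv_i Xb_i
    B <- chol2inv(cXtVX)
    Pd <- Vinv
    A <- array(0, c(tt, p_tot, n))
    for (s in seq_len(tt)) for (s2 in seq_len(tt)) {
      cols <- (off[s2] + 1L):off[s2 + 1L]
      A[s, cols, ] <- A[s, cols, ] + t(Vinv[s, s2, ] * Xr[[s2]])
    }
    for (i in seq_len(n)) {
      Ai <- matrix(A[, , i], tt, p_tot)
      Pd[, , i] <- Pd[, , i] - Ai %*% B %*% t(Ai)
    }
    list(Vinv = Vinv, Pd = Pd, Qm = Qm, A = A, B = B, beta = beta, ll = ll)
  }

  st <- eval_state(H, Rw)
  if (is.null(st)) stopf("initial covariance matrices are not positive definite")
  trace_ll <- st$ll
  converged <- FALSE
  last_dll <- Inf
  iter <- 0L
  dll_window <- numeric(0)

  tmats <- function(st) {
    TK <- matrix(0, tt, tt); TR <- matrix(0, tt, tt)
    for (a in seq_len(tt)) for (b in seq_len(tt)) {
      TK[a, b] <- sum(st$Pd[a, b, ] * dvals)
      TR[a, b] <- sum(st$Pd[a, b, ])
    }
    list(TK = TK, TR = TR)
  }

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) break
    tm <- tmats(st)
    QtDQ <- crossprod(st$Qm, dvals * st$Qm)
    QtQ <- crossprod(st$Qm)

    if (iter <= em_iter) {
      Hn <- sanitize_cov(H + (H %*% (QtDQ - tm$TK) %*% H) / n, 0.9995)
      Rn <- sanitize_cov(Rw + (Rw %*% (QtQ - tm$TR) %*% Rw) / n, 0.98)
      if (constrain == "diagonal") { Hn <- diag(diag(Hn), tt); Rn <- diag(diag(Rn), tt) }
      st2 <- eval_state(Hn, Rn)
      if (!is.null(st2)) {
        last_dll <- st2$ll - st$ll
        H <- Hn; Rw <- Rn; st <- st2
        trace_ll <- c(trace_ll, st$ll)
      }
      next
    }

    n_par <- 2L * np
    score <- numeric(n_par)
    Uarr <- array(0, c(n, tt, n_par))            # u vectors per parameter
    for (k in seq_len(np)) {
      a <- pairs[k, 1L]; b <- pairs[k, 2L]
      mult <- if (a == b) 1 else 2
      ua <- matrix(0, n, tt)
      ua[, a] <- dvals * st$Qm[, b]
      if (a != b) ua[, b] <- ua[, b] + dvals * st$Qm[, a]
      Uarr[, , k] <- ua
      score[k] <- -0.5 * (mult * tm$TK[a, b] - sum(st$Qm * ua))
      ub <- matrix(0, n, tt)
      ub[, a] <- st$Qm[, b]
      if (a != b) ub[, b] <- ub[, b] + st$Qm[, a]
      Uarr[, , np + k] <- ub
      score[np + k] <- -0.5 * (mult * tm$TR[a, b] - sum(st$Qm * ub))
    }
    # P u = Vinv u - A B (sum_i A_i' u_i)
    PU <- array(0, c(n, tt, n_par))
    for (k in seq_len(n_par)) {
      uk <- matrix(Uarr[, , k], n, tt)
      s1 <- matrix(0, n, tt)
      for (s in seq_len(tt)) for (s2 in seq_len(tt))
        s1[, s] <- s1[, s] + st$Vinv[s, s2, ] * uk[, s2]
      Atu <- numeric(p_tot)
      for (s in seq_len(tt)) for (j in seq_len(p_tot))
        Atu[j] <- Atu[j] + sum(st$A[s, j, ] * uk[, s])
      Bv <- st$B %*% Atu
      for (s in seq_len(tt)) for (j in seq_len(p_tot))
        s1[, s] <- s1[, s] - st$A[s, j, ] * Bv[j]
      PU[, , k] <- s1
    }
    AI <- matrix(0, n_par, n_par)
    for (k in seq_len(n_par)) for (l in k:n_par)
      AI[k, l] <- AI[l, k] <- 0.5 * sum(Uarr[, , k] * PU[, , l])
    AI <- AI + diag(1e-8 * max(diag(AI)), n_par)
    scale <- mean(diag(H)) + mean(diag(Rw))
    pinH <- diag(H) < 1e-6 * scale
    pinR <- diag(Rw) < 1e-6 * scale
    active <- c(!(pinH[pairs[, 1L]] | pinH[pairs[, 2L]]),
                !(pinR[pairs[, 1L]] | pinR[pairs[, 2L]]))
    delta <- rep(0, n_par)
    delta[active] <- tryCatch(solve(AI[active, active, drop = FALSE],
                                    score[active]),
                              error = function(e) NA_real_)
    if (anyNA(delta)) delta <- NULL
    improved <- FALSE
    if (!is.null(delta)) {
      theta0 <- mt_theta_get(H, Rw, NULL, pairs)
      step <- 1
      for (h in 1:12) {
        cand <- mt_theta_set(theta0 + step * delta, tt, pairs, FALSE, constrain)
        st2 <- eval_state(cand$H, cand$R)
        if (!is.null(st2) && st2$ll >= st$ll - 1e-10) {
          dpar <- max(abs(c(cand$H - H, cand$R - Rw)) /
                        (mean(diag(H)) + mean(diag(Rw)) + 1e-12))
          last_dll <- st2$ll - st$ll
          H <- cand$H; Rw <- cand$R; st <- st2
          trace_ll <- c(trace_ll, st$ll)
          improved <- TRUE
          if (abs(last_dll) < tol_ll && dpar < tol_par) converged <- TRUE
          break
        }
        step <- step / 2
      }
    }
    if (!improved) {
      Hn <- sanitize_cov(H + (H %*% (QtDQ - tm$TK) %*% H) / n, 0.9995)
      Rn <- sanitize_cov(Rw + (Rw %*% (QtQ - tm$TR) %*% Rw) / n, 0.98)
      if (constrain == "diagonal") { Hn <- diag(diag(Hn), tt); Rn <- diag(diag(Rn), tt) }
      st2 <- eval_state(Hn, Rn)
      if (!is.null(st2) && st2$ll >= st$ll - 1e-10) {
        last_dll <- st2$ll - st$ll
        H <- Hn; Rw <- Rn; st <- st2
        trace_ll <- c(trace_ll, st$ll)
        if (abs(last_dll) < tol_ll) converged <- TRUE
      } else converged <- abs(last_dll) < tol_ll
    }
    # flat-ridge guard: when the last 12 post-EM iterations jointly gained
    # almost nothing, the remaining crawl along a weakly identified H/R
    # ridge cannot move the estimates meaningfully
    if (iter > em_iter) {
      dll_window <- c(dll_window, abs(last_dll))
      if (length(dll_window) > 12L) dll_window <- dll_window[-1L]
      if (length(dll_window) == 12L && sum(dll_window) < 0.015)
        converged <- TRUE
    }
    if (converged) break
  }

  preds <- U %*% (dvals * st$Qm) %*% H
  R_out <- diag(swt) %*% Rw %*% diag(swt)
  list(H = H, R = R_out, extra_vc = NULL, beta = st$beta,
       predictions = preds, loglik = st$ll, trace = trace_ll,
       converged = converged, last_dll = last_dll)
}
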