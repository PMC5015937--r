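#' Specify a univariate mixed model
#'
#' Lightweight container describing a single-trait mixed model: the response
#' column, fixed-effect terms (covariates, or the genotype factor itself when
#' estimating BLUEs), independent random terms (nesting expressed with `:`,
#' e.g. `"trial:date:replicate"`), an optional kernel-structured genotype
#' term, and an optional per-record weight column. Per-record residual
#' variance is `sigma_e^2 / w_i` when weights are supplied.
#'
#' @param response name of the response column.
#' @param fixed character vector of fixed-effect terms (may include factor
#'   terms such as `"line"` for genotype-as-fixed); intercept always included
#'   unless a `0 + factor` coding is requested via `genotype_fixed`.
#' @param random character vector of independent random intercept terms.
#' @param genotype name of the genotype column when it enters the model
#'   (fixed or kernel-structured random), or `NULL`.
#' @param genotype_fixed logical; `TRUE` fits genotype as fixed with cell-means
#'   coding (`0 + genotype`) so coefficients are per-line BLUEs.
#' @param weights optional name of a weight column.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, fixed = character(), random = character(),
                       genotype = NULL, genotype_fixed = FALSE,
                       weights = NULL) {
  structure(list(response = response, fixed = fixed, random = random,
                 genotype = genotype, genotype_fixed = genotype_fixed,
                 weights = weights),
            class = "model_spec")
}

#' Fit a univariate mixed model by REML
#'
#' Two regimes share this surface:
#' \itemize{
#'   \item independent random factors only (repeatability, BLUE and BLUP
#'     models): delegated to \code{lme4::lmer}; variance components are
#'     constrained nonnegative by the fitter's boundary handling;
#'   \item one kernel-structured genotype term plus residual (the GBLUP
#'     model): an exact two-component REML fit via a single eigendecomposition
#'     of the (weight-transformed) kernel and one-dimensional profile
#'     optimization of the variance ratio.
#' }
#'
#' @param data data frame with all columns named in `spec`.
#' @param spec a [model_spec()].
#' @param kernel optional relationship matrix for the genotype term; its
#'   rownames must cover all genotype levels in `data`. When supplied, `random`
#'   terms are not allowed (use the multi-trait engine for that combination).
#' @return list with elements `vc` (named variance components including
#'   `"residual"`), `fixef` (named fixed-effect estimates), `blups` (list per
#'   random term; for the kernel term, predictions for every kernel line),
#'   `loglik`, `converged`, and `fit` (the underlying lme4 fit, when used).
#' @export
reml_fit <- function(data, spec, kernel = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  data <- as.data.frame(data)
  data <- data[!is.na(data[[spec$response]]), , drop = FALSE]
  if (!is.null(kernel)) {
    if (length(spec$random) > 0L)
      stopf("kernel term cannot be combined with extra random terms in reml_fit; use mt_reml_fit")
    return(reml_fit_kernel(data, spec, kernel))
  }
  # genotype-random models with no other random terms get the exact
  # eigendecomposition path (identity kernel): one-dimensional profile REML
  if (!is.null(spec$genotype) && !spec$genotype_fixed &&
      length(spec$random) == 0L) {
    ids <- unique(as.character(data[[spec$genotype]]))
    K <- diag(length(ids))
    dimnames(K) <- list(ids, ids)
    fit <- reml_fit_kernel(data, spec, K)
    names(fit$vc) <- c(spec$genotype, "residual")
    fit$blups <- setNames(fit$blups, spec$genotype)
    return(fit)
  }
  reml_fit_lmer(data, spec)
}

reml_fit_lmer <- function(data, spec) {
  fx <- spec$fixed
  if (!is.null(spec$genotype) && spec$genotype_fixed)
    fx <- c(if (spec$genotype_fixed) paste0("0 + ", spec$genotype), fx)
  else if (!is.null(spec$genotype) && !spec$genotype_fixed)
    spec$random <- c(spec$genotype, spec$random)
  rhs_fixed <- if (length(fx) > 0L) paste(fx, collapse = " + ") else "1"
  w <- if (!is.null(spec$weights)) data[[spec$weights]] else NULL
  if (!is.null(w) && any(w <= 0)) stopf("weights must be positive")

  # drop random terms with a single level (inestimable)
  keep <- vapply(spec$random, function(r) {
    key <- interaction(data[strsplit(r, ":", fixed = TRUE)[[1L]]], drop = TRUE)
    nlevels(key) > 1L
  }, logical(1L))
  random <- spec$random[keep]

  if (length(random) == 0L) {
    fml <- as.formula(paste(spec$response, "~", rhs_fixed))
    fit <- if (is.null(w)) lm(fml, data = data) else lm(fml, data = data, weights = w)
    beta <- coef(fit)
    if (anyNA(beta))
      stopf("singular fixed design; aliased columns: %s",
            paste(names(beta)[is.na(beta)], collapse = ", "))
    return(list(vc = c(residual = summary(fit)$sigma^2), fixef = beta,
                blups = list(), loglik = as.numeric(logLik(fit)),
                converged = TRUE, fit = fit))
  }

  rhs <- paste(c(rhs_fixed, paste0("(1 | ", random, ")")), collapse = " + ")
  fml <- as.formula(paste(spec$response, "~", rhs))
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE,
                            optCtrl = list(xtol_abs = 1e-12, ftol_abs = 1e-14))
  fit <- suppressMessages(
    lme4::lmer(fml, data = data, weights = w, REML = TRUE, control = ctrl))
  vcl <- lme4::VarCorr(fit)
  vc <- vapply(vcl, function(m) m[1L, 1L], numeric(1L))
  vc <- c(vc, residual = attr(vcl, "sc")^2)
  beta <- lme4::fixef(fit)
  if (anyNA(beta))
    stopf("singular fixed design; aliased columns: %s",
          paste(names(beta)[is.na(beta)], collapse = ", "))
  blups <- lapply(lme4::ranef(fit), function(df) setNames(df[[1L]], rownames(df)))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  list(vc = vc, fixef = beta, blups = blups,
       loglik = as.numeric(logLik(fit)), converged = conv, fit = fit)
}

# Exact REML for y = X beta + Z g + e, g ~ N(0, K sg2), e ~ N(0, se2 W^-1).
# Eigendecompose W^(1/2) Z K Z' W^(1/2) once; profile the restricted
# likelihood over the ratio delta = se2/sg2.
reml_fit_kernel <- function(data, spec, kernel) {
  check_relationship(kernel)
  gcol <- spec$genotype
  if (is.null(gcol)) stopf("kernel supplied but spec has no genotype term")
  ids <- as.character(data[[gcol]])
  missing_ids <- setdiff(ids, rownames(kernel))
  if (length(missing_ids) > 0L)
    stopf("genotypes absent from kernel: %s", paste(head(missing_ids, 5L), collapse = ", "))
  y <- data[[spec$response]]
  n <- length(y)
  rhs_fixed <- if (length(spec$fixed) > 0L) paste(spec$fixed, collapse = " + ") else "1"
  X <- model.matrix(as.formula(paste("~", rhs_fixed)), data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("singular fixed design; aliased columns: %s",
          paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  w <- if (!is.null(spec$weights)) data[[spec$weights]] else rep(1, n)
  if (any(w <= 0)) stopf("weights must be positive")
  sw <- sqrt(w)

  Kobs <- kernel[ids, ids, drop = FALSE]
  M <- sw * t(sw * t(Kobs))          # W^(1/2) Z K Z' W^(1/2)
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  U <- eM$vectors
  lam <- pmax(eM$values, 0)
  ys <- crossprod(U, sw * y)
  Xs <- crossprod(U, sw * X)
  p <- ncol(X)

  restricted_ll <- function(log_delta) {
    delta <- exp(log_delta)
    d <- lam + delta                      # V = sg2 * diag(d) in rotated basis
    XtVX <- crossprod(Xs / d, Xs)
    cXtVX <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(cXtVX)) return(-Inf)
    beta <- backsolve(cXtVX, forwardsolve(t(cXtVX), crossprod(Xs / d, ys)))
    r <- ys - Xs %*% beta
    quad <- sum(r^2 / d)
    sg2 <- quad / (n - p)
    -0.5 * ((n - p) * log(sg2) + sum(log(d)) + 2 * sum(log(diag(cXtVX))) +
              (n - p))
  }
  opt <- optimize(restricted_ll, interval = c(-18, 18), maximum = TRUE,
                  tol = 1e-9)
  # guard the boundaries
  cand <- c(opt$maximum, -18, 18)
  lls <- vapply(cand, restricted_ll, numeric(1L))
  log_delta <- cand[which.max(lls)]
  # parabolic polish: Brent's tolerance leaves the stationary point a little
  # off, which matters for closed-form equivalence checks
  if (abs(log_delta) < 17.5) {
    for (h in c(1e-3, 1e-5)) {
      f0 <- restricted_ll(log_delta)
      fp <- restricted_ll(log_delta + h)
      fm <- restricted_ll(log_delta - h)
      denom2 <- fp - 2 * f0 + fm
      if (is.finite(denom2) && denom2 < 0) {
        step <- 0.5 * h * (fm - fp) / denom2
        if (abs(step) < 10 * h && restricted_ll(log_delta + step) >= f0)
          log_delta <- log_delta + step
      }
    }
  }
  delta <- exp(log_delta)
  d <- lam + delta
  XtVX <- crossprod(Xs / d, Xs)
  beta <- solve(XtVX, crossprod(Xs / d, ys))
  r <- ys - Xs %*% beta
  sg2 <- sum(r^2 / d) / (n - p)
  se2 <- sg2 * delta
  # BLUPs for every kernel line: g_hat = sg2 * K[. , obs] W^(1/2) U d^-1 r / sg2
  vr <- U %*% (r / d)                 # = (V/sg2)^-1 (y - X beta) in W^(1/2) basis
  ghat <- drop(kernel[, ids, drop = FALSE] %*% (sw * vr))
  names(ghat) <- rownames(kernel)
  beta <- drop(beta); names(beta) <- colnames(X)
  list(vc = c(genetic = sg2, residual = se2), fixef = beta,
       blups = list(genotype = ghat), loglik = max(lls), converged = TRUE,
       fit = NULL)
}
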