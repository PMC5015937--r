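test_that("univariate REML on balanced one-way data matches ANOVA estimators", {
  for (seed in 1:3) {
    d <- fixture_oneway(n_g = 30, n_rep = 3, sg2 = 2, se2 = 1, seed = seed)
    fit <- reml_fit(d, model_spec("value", genotype = "line"))
    av <- anova(lm(value ~ line, d))
    msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
    expect_lt(abs(fit$vc[["line"]] - max(0, (msb - msw) / 3)), 1e-8)
    expect_lt(abs(fit$vc[["residual"]] - msw), 1e-8)
  }
})

test_that("genotype-fixed model without random terms is ordinary least squares", {
  d <- fixture_oneway(n_g = 10, n_rep = 2, seed = 2)
  fit <- reml_fit(d, model_spec("value", genotype = "line",
                                genotype_fixed = TRUE))
  ols <- coef(lm(value ~ 0 + line, d))
  expect_equal(fit$fixef, ols)
})

test_that("identity-kernel BLUPs equal the closed-form shrinkage", {
  d <- fixture_oneway(n_g = 25, n_rep = 3, seed = 3)
  K <- diag(25)
  dimnames(K) <- list(unique(d$line), unique(d$line))
  fit <- reml_fit(d, model_spec("value", genotype = "line"), kernel = K)
  sg <- fit$vc[["genetic"]]; se <- fit$vc[["residual"]]
  ybar <- tapply(d$value, d$line, mean)
  shrink <- sg / (sg + se / 3)
  cf <- shrink * (ybar - mean(d$value))
  expect_lt(max(abs(fit$blups$genotype[names(ybar)] - cf)), 1e-5)
})

test_that("weighted kernel REML matches an independent dense-algebra oracle", {
  n <- 60
  K <- fixture_kernel(n, seed = 4, n_founders = 8)
  ids <- rownames(K)
  set.seed(44)
  ek <- eigen(K, symmetric = TRUE)
  g <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(n))
  w <- sample(c(1, 2, 3), n, replace = TRUE)
  y <- drop(g) + rnorm(n, sd = sqrt(0.8 / w))
  d <- data.frame(line = ids, value = y, w = w)
  fit <- reml_fit(d, model_spec("value", genotype = "line", weights = "w"),
                  kernel = K)
  # oracle: dense restricted likelihood, residual variance se2/w per record
  X <- matrix(1, n, 1)
  rll <- function(sg2, se2) {
    if (!is.finite(sg2) || !is.finite(se2)) return(-1e10)
    V <- sg2 * K + diag(se2 / w)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(-1e10)
    Vi <- chol2inv(cV)
    XtVX <- crossprod(X, Vi %*% X)
    P <- Vi - (Vi %*% X) %*% solve(XtVX, t(X) %*% Vi)
    -0.5 * (2 * sum(log(diag(cV))) + log(XtVX[1, 1]) + sum(y * (P %*% y)))
  }
  o <- optim(c(log(1), log(0.8)),
             function(p) -rll(exp(p[1]), exp(p[2])), method = "Nelder-Mead",
             control = list(reltol = 1e-14, maxit = 5000))
  expect_lt(abs(fit$vc[["genetic"]] - exp(o$par[1])), 1e-3)
  expect_lt(abs(fit$vc[["residual"]] - exp(o$par[2])), 1e-3)
  # and the fit's restricted likelihood is no worse than the oracle's optimum
  expect_gte(rll(fit$vc[["genetic"]], fit$vc[["residual"]]), -o$value - 1e-6)
  # oracle BLUPs at the oracle's own optimum
  sg2 <- exp(o$par[1]); se2 <- exp(o$par[2])
  V <- sg2 * K + diag(se2 / w)
  Vi <- solve(V)
  b <- sum(Vi %*% y) / sum(Vi)
  gor <- drop(sg2 * K %*% Vi %*% (y - b))
  expect_lt(max(abs(fit$blups$genotype[ids] - gor)), 1e-3)
})

test_that("singular fixed designs fail with the aliased column named", {
  d <- fixture_oneway(n_g = 6, n_rep = 2, seed = 5)
  d$dup <- 1  # constant column aliased with intercept
  expect_error(
    reml_fit(d, model_spec("value", fixed = c("dup"), genotype = "line"),
             kernel = {
               K <- diag(6); dimnames(K) <- list(unique(d$line), unique(d$line)); K
             }),
    "aliased|singular")
})

test_that("multi-trait engines agree between rotated and general paths", {
  K <- fixture_kernel(40, seed = 6)
  H <- rbind(c(1, .6), c(.6, 1)); R <- rbind(c(.5, .1), c(.1, .5))
  fx <- fixture_mt_records(K, H, R, seed = 6)
  f1 <- mt_reml_fit(fx$records, K, max_iter = 300, on_nonconverge = "warn")
  expect_identical(f1$engine, "rotated")
  # an extra kernel line with no records forces the general engine while
  # leaving the observed-cell model unchanged
  K2 <- rbind(cbind(K, 0), 0); K2[41, 41] <- 1
  ids2 <- c(rownames(K), "EXTRA")
  dimnames(K2) <- list(ids2, ids2)
  f2 <- mt_reml_fit(fx$records, K2, max_iter = 300, on_nonconverge = "warn")
  expect_identical(f2$engine, "general")
  expect_lt(max(abs(f1$H - f2$H)), 0.02)
  expect_lt(max(abs(f1$R - f2$R)), 0.02)
  expect_lt(max(abs(f1$predictions - f2$predictions[1:40, ])), 0.05)
})

test_that("restricted log-likelihood is non-decreasing across EM iterations", {
  K <- fixture_kernel(20, seed = 7)
  H <- rbind(c(1, .7), c(.7, 1)); R <- rbind(c(.4, 0), c(0, .6))
  fx <- fixture_mt_records(K, H, R, seed = 7)
  f <- suppressWarnings(
    mt_reml_fit(fx$records, K, em_iter = 60L, max_iter = 60L,
                on_nonconverge = "warn"))
  expect_true(all(diff(f$trace) > -1e-8))
})

test_that("diagonal-constrained multi-trait fit reduces to univariate fits", {
  K <- fixture_kernel(30, seed = 8)
  H <- diag(c(1, 1.3)); R <- diag(c(.5, .7))
  fx <- fixture_mt_records(K, H, R, seed = 8)
  fm <- mt_reml_fit(fx$records, K, constrain = "diagonal",
                    em_iter = 30L, max_iter = 800L, on_nonconverge = "warn")
  for (tt in c("GY", "SEC")) {
    rec_t <- fx$records[fx$records$trait == tt, ]
    d <- data.frame(line = rec_t$line, value = rec_t$value)
    fu <- reml_fit(d, model_spec("value", genotype = "line"), kernel = K)
    expect_lt(max(abs(fm$predictions[, tt] -
                        fu$blups$genotype[rownames(K)])), 2e-3)
  }
})

test_that("masked-cell predictions equal joint-normal conditioning (oracle)", {
  for (seed in 1:3) {
    K <- fixture_kernel(10, seed = seed + 10)
    H <- rbind(c(1, -.6), c(-.6, .9)); R <- rbind(c(.5, .1), c(.1, .4))
    fx <- fixture_mt_records(K, H, R, seed = seed)
    rec <- fx$records
    rec$value[rec$trait == "GY" & rec$line %in% rownames(K)[1:3]] <- NA
    f <- mt_reml_fit(rec, K, max_iter = 300, on_nonconverge = "warn")
    oc <- oracle_conditional(f, rec, K)
    expect_lt(max(abs(oc - f$predictions)), 1e-8)
  }
})

test_that("a constant trait collapses its genetic variance to the boundary", {
  K <- fixture_kernel(20, seed = 9)
  H <- rbind(c(1, 0), c(0, 1)); R <- rbind(c(.5, 0), c(0, .5))
  fx <- fixture_mt_records(K, H, R, seed = 9)
  rec <- fx$records
  rec$value[rec$trait == "SEC"] <- 3.14
  f <- mt_reml_fit(rec, K, max_iter = 300, on_nonconverge = "warn")
  expect_lt(f$H["SEC", "SEC"], 1e-3 * f$H["GY", "GY"])
  cc <- genetic_correlation_matrix(
    list(GY = data.frame(line = rownames(K),
                         blue = rec$value[rec$trait == "GY"], weight = 1),
         SEC = data.frame(line = rownames(K), blue = 3.14, weight = 1)),
    list(K = K))
  expect_true(cc$undefined["GY", "SEC"])
  expect_equal(cc$correlation["GY", "SEC"], 0)
})

test_that("conditional_predict is a deterministic lookup with prior-mean default", {
  ids <- sprintf("L%03d", 1:15)
  K <- identity_kernel_test(ids)
  H <- rbind(c(1, .8), c(.8, 1)); R <- rbind(c(.3, 0), c(0, .3))
  fx <- fixture_mt_records(K, H, R, seed = 12)
  rec <- fx$records
  rec$value[rec$line == ids[1] & rec$trait == "GY"] <- NA   # masked, has SEC
  rec$value[rec$line == ids[2]] <- NA                       # fully masked
  f <- mt_reml_fit(rec, K, max_iter = 300, on_nonconverge = "warn")
  # fully unobserved line with identity kernel: prior mean 0
  expect_equal(unname(conditional_predict(f, "GY", ids[2])), 0, tolerance = 1e-10)
  # observed cell: matches the stored prediction
  expect_equal(unname(conditional_predict(f, "SEC", ids[3])),
               unname(f$predictions[ids[3], "SEC"]))
  # masked GY with observed secondary, K = I: bivariate conditional-normal
  ysec <- rec$value[rec$line == ids[1] & rec$trait == "SEC"]
  bsec <- f$fixef$SEC[["(Intercept)"]]
  hand <- f$H["GY", "SEC"] / (f$H["SEC", "SEC"] + f$R["SEC", "SEC"]) *
    (ysec - bsec)
  expect_lt(abs(conditional_predict(f, "GY", ids[1]) - hand), 1e-6)
  expect_error(conditional_predict(f, "NOPE", ids[1]), "unknown trait")
  expect_error(conditional_predict(f, "GY", "ZZZ"), "unknown lines")
})

test_that("multi-trait parameter recovery at moderate scale", {
  # scaled-down replicate study: 2 traits, genomic kernel, known h2 and r_g
  reps <- 6
  est <- matrix(NA_real_, reps, 3)
  for (r in seq_len(reps)) {
    K <- fixture_kernel(250, seed = 100 + r, n_markers = 2000)
    K <- K / mean(diag(K))   # unit per-line genetic variance at H = 1
    H <- rbind(c(1, .7), c(.7, 1))
    R <- rbind(c(1 / .6 - 1, 0), c(0, 1 / .9 - 1))  # h2 = .6, .9
    fx <- fixture_mt_records(K, H, R, seed = 100 + r)
    f <- mt_reml_fit(fx$records, K, max_iter = 300, on_nonconverge = "warn")
    h2 <- diag(f$H) / (diag(f$H) + diag(f$R))
    est[r, ] <- c(h2, f$H[1, 2] / sqrt(f$H[1, 1] * f$H[2, 2]))
  }
  m <- colMeans(est)
  expect_lt(abs(m[1] - 0.6), 0.07)
  expect_lt(abs(m[2] - 0.9), 0.07)
  expect_lt(abs(m[3] - 0.7), 0.07)
})
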