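test_that("fold assignment is balanced, deterministic, and partition-valid", {
  f <- assign_folds(sprintf("L%02d", 1:10), k = 5, seed = 3)
  expect_equal(unname(table(f$fold)), rep(2L, 5), ignore_attr = TRUE)
  f2 <- assign_folds(sprintf("L%02d", 1:10), k = 5, seed = 3)
  expect_identical(f, f2)
  lines557 <- sprintf("L%04d", 1:557)
  f3 <- assign_folds(lines557, k = 5, seed = 9)
  sz <- table(f3$fold)
  expect_equal(sum(sz), 557)
  expect_lte(max(sz) - min(sz), 1)
  expect_setequal(f3$line, lines557)
  expect_error(assign_folds(c("a", "b"), k = 5, seed = 1), "folds")
})

test_that("accuracy aggregation follows the heritability-scaled formula", {
  rp <- c(0.4, 0.5, 0.6, 0.5, 0.5)
  a <- accuracy_from_folds(rp, H_line = 0.9)
  expect_equal(a$r_p_mean, 0.5)
  expect_equal(a$r_g, 0.5 / 0.9)
  expect_equal(a$se, sd(rp) / (0.9 * sqrt(5)))
  a2 <- accuracy_from_folds(rp, H_line = 0.9, se_method = "k")
  expect_equal(a2$se, sd(rp) / (0.9 * 5))
  expect_equal(accuracy_from_folds(rep(0.5, 5), 0.9)$se, 0)
  expect_error(accuracy_from_folds(rp, H_line = 0.01), "H_line")
  expect_error(accuracy_from_folds(0.5, H_line = 0.9), "at least 2")
})

test_that("oracle and null predictors bracket cross-validated accuracy", {
  set.seed(41)
  ids <- sprintf("L%03d", 1:100)
  v <- data.frame(line = ids, blup = rnorm(100))
  gy <- data.frame(line = ids, blue = rnorm(100), weight = 3)
  folds <- assign_folds(ids, k = 5, seed = 7)
  # oracle injection: predictions equal the validation BLUPs
  res <- cross_validate(folds, gy, v, H_line = 0.8,
                        predict_fun = function(train, test)
                          data.frame(line = test,
                                     pred = v$blup[match(test, v$line)]))
  expect_equal(attr(res, "fold_abilities"), rep(1, 5), tolerance = 1e-12)
  expect_equal(res$r_g, 1 / 0.8)
  # pure-noise predictor averages to zero accuracy
  rg <- replicate(50, {
    cross_validate(folds, gy, v, H_line = 0.8,
                   predict_fun = function(train, test)
                     data.frame(line = test, pred = rnorm(length(test))))$r_g
  })
  expect_lt(abs(mean(rg)), 0.05)
})

test_that("gain regression recovers noiseless coefficients and degenerates
           safely", {
  set.seed(42)
  gains <- expand.grid(kernel = c("A", "G"),
                       environment = c("optimal", "drought", "severe_drought",
                                       "late_heat", "early_heat"),
                       rep_mode = c("1rep", "3rep"))
  gains$hbar <- runif(nrow(gains), 0.6, 0.95)
  gains$rbar <- runif(nrow(gains), 0.2, 0.7)
  gains$gain <- 0.1 + 1.1 * gains$hbar + 0.57 * gains$rbar
  g <- gain_regression(gains)
  cf <- setNames(g$coefficients$estimate, g$coefficients$term)
  expect_lt(abs(cf[["hbar"]] - 1.1), 1e-8)
  expect_lt(abs(cf[["rbar"]] - 0.57), 1e-8)
  expect_lt(abs(cf[["(Intercept)"]] - 0.1), 1e-8)
  expect_lt(abs(cf[["kernelG"]]), 1e-8)
  expect_gt(g$adj_r_squared, 0.9999)

  # gain unrelated to every predictor: slopes collapse and the adjusted r2
  # is non-positive (constant gain makes r2 0/0, so add negligible noise)
  set.seed(5)
  gains2 <- gains; gains2$gain <- 0.3 + rnorm(nrow(gains), sd = 0.01)
  g2 <- gain_regression(gains2)
  expect_lt(max(abs(g2$coefficients$estimate[-1])), 0.05)
  expect_lte(g2$adj_r_squared, 0)

  # OLS oracle on noisy rows
  gains3 <- gains
  gains3$gain <- gains$gain + rnorm(nrow(gains), sd = 0.05)
  g3 <- gain_regression(gains3)
  X <- model.matrix(~ kernel + environment + hbar + rbar,
                    transform(gains3,
                              kernel = relevel(factor(kernel), "A"),
                              environment = relevel(factor(environment),
                                                    "optimal")))
  beta <- solve(crossprod(X), crossprod(X, gains3$gain))
  expect_lt(max(abs(g3$coefficients$estimate - drop(beta))), 1e-10)
})

test_that("cross-validation with real predictors: multivariate with an
           informative secondary trait beats univariate", {
  set.seed(43)
  K <- fixture_kernel(120, seed = 43)
  K <- K / mean(diag(K))
  ids <- rownames(K)
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  z <- matrix(rnorm(240), 120)
  g <- drop(L %*% z[, 1])
  gs <- drop(L %*% (0.75 * z[, 1] + sqrt(1 - 0.75^2) * z[, 2]))
  gy <- data.frame(line = ids, blue = g + rnorm(120, sd = 0.5), weight = 3)
  sec <- list(SEC = data.frame(line = ids, blue = gs + rnorm(120, sd = 0.3),
                               weight = 3))
  v <- data.frame(line = ids, blup = g + rnorm(120, sd = 0.3))
  folds <- assign_folds(ids, k = 5, seed = 17)
  uv <- cross_validate(folds, gy, v, H_line = 0.9, kernel = K)
  mv <- suppressWarnings(
    cross_validate(folds, gy, v, H_line = 0.9, kernel = K, secondary = sec,
                   on_nonconverge = "warn"))
  expect_gt(mv$r_g, uv$r_g)
  expect_equal(uv$k, 5)
})

test_that("within-environment accuracy exceeds across-environment accuracy
           when environments are imperfectly genetically correlated", {
  res <- t(sapply(1:5, function(s) {
    cfg <- scenario_presets(c("optimal", "drought", "early_heat"),
                            n_lines = 80, n_markers = 500, rho_between = 0.5,
                            seed = 400 + s)
    pop <- simulate_population(cfg)
    plots <- simulate_trials(cfg, pop)
    G <- genomic_relationship(filter_and_impute_markers(pop$markers)$markers)
    cand <- pop$lines
    env <- "early_heat"
    gy_w <- environment_blues(plots, "GY", env)
    gy_w <- gy_w[gy_w$line %in% cand, ]
    gy_a <- across_env_blues(plots, "GY", exclude = env)
    gy_a <- gy_a[gy_a$line %in% cand, ]
    vb <- validation_blups(plots, env); vb <- vb[vb$line %in% cand, ]
    hl <- environment_heritability(plots, "GY", env)$H_line
    folds <- assign_folds(cand, k = 5, seed = 400 + s)
    c(within = cross_validate(folds, gy_w, vb, hl, kernel = G)$r_g,
      across = cross_validate(folds, gy_a, vb, hl, kernel = G)$r_g)
  }))
  expect_gt(mean(res[, "within"]), mean(res[, "across"]))
})
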