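# balanced two-trial environment with known additive genotype values
make_env <- function(n_lines = 40, sg2 = 1, se2 = 0.5, ndate = 1, seed = 1,
                     env = "E1", trait = "GY", env_shift = 0, g = NULL,
                     trial_eff = c(0.5, -0.5)) {
  set.seed(seed)
  lines <- sprintf("G%03d", seq_len(n_lines))
  if (is.null(g)) g <- rnorm(n_lines, sd = sqrt(sg2))
  per_trial <- ceiling(n_lines / 2)
  trial_of <- rep(1:2, each = per_trial, length.out = n_lines)
  out <- NULL
  for (d in seq_len(ndate)) {
    for (r in 1:3) {
      out <- rbind(out, data.frame(
        line = lines, environment = env, trial = paste0(env, "_T", trial_of),
        replicate = r, block = rep(rep(1:4, each = 5), length.out = n_lines),
        date = if (ndate > 1) paste0("D", d) else NA_character_,
        trait = trait,
        value = env_shift + trial_eff[trial_of] + g +
          rnorm(n_lines, sd = sqrt(se2))))
    }
  }
  attr(out, "g") <- setNames(g, lines)
  out
}

test_that("noiseless balanced BLUEs recover true genotype deviations", {
  # no trial effects: lines sit in disjoint trials, so a trial effect would
  # be confounded with genotype contrasts in a noise-free fixture
  pl <- make_env(se2 = 0, seed = 1, trial_eff = c(0, 0))
  b <- environment_blues(pl, "GY", "E1")
  g <- attr(pl, "g")[b$line]
  expect_lt(max(abs((b$blue - mean(b$blue)) - (g - mean(g)))), 1e-8)
  expect_true(all(b$weight == 3))
})

test_that("per-replicate BLUEs use one third of the records with unit weight", {
  pl <- make_env(seed = 2, ndate = 2)
  b1 <- environment_blues(pl, "GY", "E1", per_replicate = 1)
  expect_true(all(b1$weight == 2))   # one record per date on that replicate
  pl1 <- make_env(seed = 2)
  b2 <- environment_blues(pl1, "GY", "E1", per_replicate = 1)
  expect_true(all(b2$weight == 1))
})

test_that("BLUEs equal direct generalized least squares on an unbalanced
           fixture", {
  pl <- make_env(n_lines = 20, seed = 3)
  pl <- pl[-c(5, 23), ]               # delete two plots
  b <- environment_blues(pl, "GY", "E1")
  # independent GLS at the same REML components (exact genotype-fixed fit)
  fit <- reml_fit(pl, model_spec("value", genotype = "line",
                                 genotype_fixed = TRUE,
                                 random = c("trial", "trial:replicate",
                                            "trial:replicate:block")))
  vc <- fit$vc
  n <- nrow(pl)
  V <- diag(unname(vc["residual"]), n)
  for (r in c("trial", "trial:replicate", "trial:replicate:block")) {
    if (is.na(vc[r]) || vc[r] <= 0) next
    key <- interaction(pl[strsplit(r, ":", fixed = TRUE)[[1]]], drop = TRUE)
    V <- V + unname(vc[r]) * outer(as.integer(key), as.integer(key), "==")
  }
  X <- model.matrix(~ 0 + line, pl)
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% pl$value))
  expect_lt(max(abs(b$blue - drop(beta))), 1e-6)
})

test_that("across-environment BLUEs ignore environment shifts and G-by-E-free
           structure reduces to the within-environment answer", {
  g <- rnorm(30, sd = 1)
  p1 <- make_env(n_lines = 30, se2 = 0.2, seed = 4, env = "E1", g = g)
  p2 <- make_env(n_lines = 30, se2 = 0.2, seed = 5, env = "E2", g = g,
                 env_shift = 10)
  p3 <- make_env(n_lines = 30, se2 = 0.2, seed = 6, env = "E3", g = g,
                 env_shift = -10)
  pl <- rbind(p1, p2, p3)
  b <- across_env_blues(pl, "GY", exclude = "E3")
  expect_equal(attr(b, "environment"), "all except E3")
  # environment shifts must not leak into genotype contrasts
  p2b <- make_env(n_lines = 30, se2 = 0.2, seed = 5, env = "E2", g = g,
                  env_shift = 0)
  b2 <- across_env_blues(rbind(p1, p2b, p3), "GY", exclude = "E3")
  expect_lt(max(abs((b$blue - mean(b$blue)) - (b2$blue - mean(b2$blue)))), 1e-6)
  expect_error(across_env_blues(pl, "GY", exclude = "E9"), "not found")
})

test_that("validation BLUPs shrink line means by the balanced factor and
           respect covariates", {
  pl <- make_env(n_lines = 40, sg2 = 1.5, se2 = 0.9, seed = 7,
                 trial_eff = c(0, 0))
  vb <- validation_blups(pl, "E1")
  expect_lt(abs(mean(vb$blup)), 1e-8)
  # zero lodging column leaves the fit untouched
  pl2 <- pl; pl2$lodging <- 0
  vb2 <- validation_blups(pl2, "E1")
  expect_equal(vb$blup, vb2$blup, tolerance = 1e-8)
  # DTHD column perfectly collinear with the genetic signal wipes the BLUPs
  pl3 <- pl; pl3$dthd <- attr(pl, "g")[pl$line]
  vb3 <- validation_blups(pl3, "E1", dthd_corrected = TRUE)
  expect_lt(sd(vb3$blup), 0.25 * sd(vb$blup))
  expect_error(validation_blups(pl, "E1", dthd_corrected = TRUE), "dthd")
})

test_that("heritability formulas, boundaries, and the line >= plot invariant", {
  h <- heritability(c(sigma_g2 = 1, sigma_e2 = 1), ndate = 1, nrep = 1)
  expect_equal(h$H_plot, sqrt(0.5))
  expect_equal(h$H_line, sqrt(0.5))
  h2 <- heritability(c(sigma_g2 = 1, sigma_gd2 = 1, sigma_e2 = 1),
                     ndate = 2, nrep = 3)
  expect_equal(h2$H_line, sqrt(0.6))
  expect_equal(h2$H_plot, sqrt(0.5))
  h3 <- heritability(c(sigma_g2 = 0, sigma_e2 = 1), ndate = 1, nrep = 3)
  expect_equal(h3$H_plot, 0)
  expect_equal(h3$H_line, 0)
  # property: H_line >= H_plot, equality iff nrep = 1
  for (s in 1:25) {
    set.seed(s)
    comp <- c(sigma_g2 = runif(1, 0, 2), sigma_gd2 = runif(1, 0, 1),
              sigma_e2 = runif(1, 0.1, 2))
    nd <- sample(1:5, 1); nr <- sample(1:3, 1)
    hh <- heritability(comp, ndate = nd, nrep = nr)
    expect_gte(hh$H_line, hh$H_plot - 1e-12)
    if (nr == 1) expect_equal(hh$H_line, hh$H_plot)
  }
})

test_that("genetic correlations hit the perfect and null limits and average
           symmetrically across kernels", {
  K <- fixture_kernel(120, seed = 21)
  ids <- rownames(K)
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  set.seed(21)
  a <- drop(L %*% rnorm(120))
  mk_blues <- function(y) data.frame(line = ids, blue = y, weight = 3)
  # identical genetic values -> correlation near 1
  b1 <- mk_blues(a + rnorm(120, sd = 0.3))
  b2 <- mk_blues(a + rnorm(120, sd = 0.3))
  gc1 <- genetic_correlation_matrix(list(T1 = b1, T2 = b2), list(G = K))
  expect_gt(gc1$correlation["T1", "T2"], 0.95)
  # independent genetic values -> small correlation most of the time
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    a1 <- drop(L %*% rnorm(120)); a2 <- drop(L %*% rnorm(120))
    gc0 <- genetic_correlation_matrix(
      list(T1 = mk_blues(a1 + rnorm(120, sd = 0.3)),
           T2 = mk_blues(a2 + rnorm(120, sd = 0.3))), list(G = K))
    if (abs(gc0$correlation["T1", "T2"]) < 0.25) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # A/G averaging stays symmetric with unit diagonal
  A <- K; A[upper.tri(A)] <- A[upper.tri(A)] * 0.95
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  dimnames(A) <- dimnames(K)
  gc2 <- genetic_correlation_matrix(list(T1 = b1, T2 = b2),
                                    list(A = A, G = K))
  expect_equal(gc2$correlation, t(gc2$correlation))
  expect_equal(unname(diag(gc2$correlation)), c(1, 1))
})
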