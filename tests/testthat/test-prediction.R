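test_that("identity kernels carry no information to unseen test lines", {
  ids <- sprintf("L%03d", 1:30)
  K <- identity_kernel_test(ids)
  set.seed(31)
  train <- data.frame(line = ids[1:20], blue = rnorm(20), weight = 3)
  p <- univariate_predict(train, K, test_lines = ids[21:30])
  expect_lt(max(abs(p$pred)), 1e-8)
  expect_error(univariate_predict(train, K, test_lines = "NOPE"), "absent")
})

test_that("a test line duplicated in the kernel inherits its twin's BLUP", {
  K0 <- fixture_kernel(25, seed = 32)
  ids <- rownames(K0)
  dup <- "DUP"
  K <- rbind(cbind(K0, K0[, 1]), c(K0[1, ], K0[1, 1]))
  dimnames(K) <- list(c(ids, dup), c(ids, dup))
  set.seed(32)
  ek <- eigen(K0, symmetric = TRUE)
  g <- drop(ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(25)))
  train <- data.frame(line = ids, blue = g + rnorm(25, sd = 0.4), weight = 3)
  p <- univariate_predict(train, K, test_lines = dup)
  ptrain <- univariate_predict(train, K, test_lines = ids[1])
  expect_lt(abs(p$pred - ptrain$pred), 1e-8)
})

test_that("univariate accuracy increases with heritability", {
  set.seed(33)
  acc <- sapply(c(0.2, 0.5, 0.8), function(h2) {
    r <- replicate(12, {
      seed <- sample.int(1e6, 1)
      K <- fixture_kernel(120, seed = seed)
      K <- K / mean(diag(K))
      ids <- rownames(K)
      ek <- eigen(K, symmetric = TRUE)
      g <- drop(ek$vectors %*% (sqrt(pmax(ek$values, 0)) * rnorm(120)))
      y <- g + rnorm(120, sd = sqrt(1 / h2 - 1))
      train <- data.frame(line = ids[1:90], blue = y[1:90], weight = 1)
      p <- univariate_predict(train, K, test_lines = ids[91:120])
      cor(p$pred, g[91:120])
    })
    mean(r)
  })
  expect_gt(acc[1], 0)
  expect_true(all(diff(acc) > 0))
})

test_that("an almost-noiseless secondary proxy drives test predictions even
           without relatedness", {
  ids <- sprintf("L%03d", 1:60)
  K <- identity_kernel_test(ids)
  set.seed(34)
  g <- rnorm(60)
  gy <- data.frame(line = ids[1:40], blue = g[1:40] + rnorm(40, sd = 0.3),
                   weight = 3)
  sec <- list(PROXY = data.frame(line = ids, blue = g + rnorm(60, sd = 0.1),
                                 weight = 3))
  p <- multivariate_predict(gy, sec, K, test_lines = ids[41:60],
                            on_nonconverge = "warn")
  expect_gt(cor(p$pred, g[41:60]), 0.9)
  # missing secondary coverage is an error naming the lines
  sec_bad <- list(PROXY = sec$PROXY[1:50, ])
  expect_error(multivariate_predict(gy, sec_bad, K, test_lines = ids[41:60]),
               "missing for test lines")
})

test_that("uninformative secondary traits neither help nor hurt accuracy", {
  set.seed(35)
  diffs <- replicate(10, {
    seed <- sample.int(1e6, 1)
    K <- fixture_kernel(100, seed = seed)
    K <- K / mean(diag(K))
    ids <- rownames(K)
    ek <- eigen(K, symmetric = TRUE)
    L <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
    g <- drop(L %*% rnorm(100))
    g2 <- drop(L %*% rnorm(100))      # independent genetic values
    gy <- data.frame(line = ids[1:75], blue = g[1:75] + rnorm(75, sd = 0.5),
                     weight = 3)
    sec <- list(SEC = data.frame(line = ids, blue = g2 + rnorm(100, sd = 0.5),
                                 weight = 3))
    test <- ids[76:100]
    pm <- tryCatch(
      multivariate_predict(gy, sec, K, test_lines = test,
                           on_nonconverge = "warn"),
      error = function(e) NULL)
    pu <- univariate_predict(gy, K, test_lines = test)
    if (is.null(pm)) NA else cor(pm$pred, g[76:100]) - cor(pu$pred, g[76:100])
  })
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.05)
})

test_that("unrelated-lines prediction uses secondary traits and is robust to
           replicate shifts", {
  set.seed(36)
  n <- 60
  ids <- sprintf("L%03d", 1:n)
  g <- rnorm(n)
  gsec <- 0.8 * g + sqrt(1 - 0.64) * rnorm(n)   # r_g = 0.8 proxy
  mk <- function(shift = c(0, 0, 0)) {
    out <- NULL
    for (r in 1:3) {
      out <- rbind(out,
        data.frame(line = ids, trait = "GY", replicate = r,
                   blue = g + shift[r] + rnorm(n, sd = 0.4), weight = 1),
        data.frame(line = ids, trait = "SEC", replicate = r,
                   blue = gsec + shift[r] + rnorm(n, sd = 0.4), weight = 1))
    }
    out
  }
  set.seed(37); d0 <- mk()
  test <- ids[46:60]
  p0 <- unrelated_predict(d0, test_lines = test, on_nonconverge = "warn")
  expect_gt(cor(p0$pred, g[46:60]), 0.3)
  # same noise realization, constant replicate shifts added
  set.seed(37); d1 <- mk(shift = c(5, -5, 2))
  p1 <- unrelated_predict(d1, test_lines = test, on_nonconverge = "warn")
  expect_gt(cor(p0$pred, p1$pred), 0.98)

  # no secondary signal, no relatedness: predictions collapse to prior mean
  d2 <- d0[d0$trait == "GY", ]
  p2 <- unrelated_predict(d2, test_lines = test, on_nonconverge = "warn")
  expect_lt(max(abs(p2$pred)), 1e-6)
})

test_that("predictions are invariant to a constant shift of training values", {
  K <- fixture_kernel(40, seed = 38)
  ids <- rownames(K)
  set.seed(38)
  y <- rnorm(40)
  train <- data.frame(line = ids[1:30], blue = y[1:30], weight = 3)
  train2 <- train; train2$blue <- train2$blue + 100
  p1 <- univariate_predict(train, K, test_lines = ids[31:40])
  p2 <- univariate_predict(train2, K, test_lines = ids[31:40])
  expect_lt(max(abs(p1$pred - p2$pred)), 1e-6)
})

test_that("without relationship information, secondary traits still deliver
           most of the kernel model's accuracy", {
  # head-to-head at reduced scale: two high-heritability secondaries with
  # |r_g| = 0.7; the unrelated model's ceiling is the multiple-R of the
  # target on the secondaries, slightly below the kernel model's
  res <- t(sapply(1:8, function(s) {
    K <- fixture_kernel(80, seed = 600 + s, n_founders = 10)
    K <- K / mean(diag(K))
    ids <- rownames(K)
    set.seed(600 + s)
    ek <- eigen(K, symmetric = TRUE)
    L <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
    z <- matrix(rnorm(3 * 80), 80)
    g <- drop(L %*% z[, 1])
    gs1 <- drop(L %*% (0.7 * z[, 1] + sqrt(1 - 0.49) * z[, 2]))
    gs2 <- drop(L %*% (0.7 * z[, 1] + sqrt(1 - 0.49) * z[, 3]))
    per <- NULL
    for (r in 1:3) per <- rbind(per,
      data.frame(line = ids, trait = "GY", replicate = r,
                 blue = g + rnorm(80, sd = 0.5), weight = 1),
      data.frame(line = ids, trait = "S1", replicate = r,
                 blue = gs1 + rnorm(80, sd = 0.3), weight = 1),
      data.frame(line = ids, trait = "S2", replicate = r,
                 blue = gs2 + rnorm(80, sd = 0.3), weight = 1))
    test <- ids[61:80]
    pu <- suppressWarnings(
      unrelated_predict(per, test_lines = test, on_nonconverge = "warn"))
    agg <- aggregate(blue ~ line + trait, per, mean)
    mk <- function(tt) data.frame(line = agg$line[agg$trait == tt],
                                  blue = agg$blue[agg$trait == tt], weight = 3)
    pm <- suppressWarnings(
      multivariate_predict(mk("GY")[!mk("GY")$line %in% test, ],
                           list(S1 = mk("S1"), S2 = mk("S2")), K, test,
                           on_nonconverge = "warn"))
    c(unrel = cor(pu$pred, g[61:80]), kernel = cor(pm$pred, g[61:80]))
  }))
  expect_gt(mean(res[, "unrel"]), 0.6)
  expect_gt(mean(res[, "unrel"]) - mean(res[, "kernel"]), -0.2)
})
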