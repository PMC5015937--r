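# Shared fixture builders. Everything is generated in code under fixed seeds;
# no data files are stored.

identity_kernel_test <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}

# structured PSD kernel: inbred lines derived from crosses among a small
# founder pool, so relatedness varies across pairs (an unstructured kernel
# would make genetic and residual variances nearly unidentifiable)
fixture_kernel <- function(n, seed = 1, n_markers = 1000, n_founders = 12) {
  set.seed(seed)
  p <- runif(n_markers, 0.05, 0.95)
  fnd <- matrix(2 * rbinom(n_founders * n_markers, 1L, rep(p, each = n_founders)) - 1,
                n_founders, n_markers)
  M <- matrix(0, n, n_markers, dimnames = list(sprintf("L%03d", seq_len(n)), NULL))
  for (i in seq_len(n)) {
    par <- sample.int(n_founders, 2L)
    pick <- runif(n_markers) < 0.5
    M[i, ] <- ifelse(pick, fnd[par[1L], ], fnd[par[2L], ])
  }
  genomic_relationship(M)
}

# line-level two-trait records drawn from the K (x) H model
fixture_mt_records <- function(K, H, R, seed = 1, traits = c("GY", "SEC")) {
  set.seed(seed)
  n <- nrow(K)
  tt <- nrow(H)
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% (sqrt(pmax(ek$values, 0)) * t(ek$vectors))
  a <- L %*% matrix(rnorm(n * tt), n) %*% chol(H)
  e <- matrix(rnorm(n * tt), n) %*% chol(R)
  Y <- a + e
  list(records = data.frame(line = rep(rownames(K), tt),
                            trait = rep(traits, each = n),
                            value = c(Y)),
       genetic = a, Y = Y)
}

# small balanced single-trait trial: g lines x r reps, optional extras
fixture_oneway <- function(n_g = 30, n_rep = 3, sg2 = 2, se2 = 1, seed = 1) {
  set.seed(seed)
  g <- rnorm(n_g, sd = sqrt(sg2))
  d <- expand.grid(line = sprintf("G%02d", seq_len(n_g)),
                   replicate = seq_len(n_rep))
  d$value <- g[as.integer(factor(d$line))] + rnorm(nrow(d), sd = sqrt(se2))
  d$true_g <- g[as.integer(factor(d$line))]
  d
}

# small simulated scenario via the package generator
fixture_scenario <- function(env = "early_heat", n_lines = 100,
                             n_markers = 400, seed = 1, ...) {
  cfg <- scenario_presets(env, n_lines = n_lines, n_markers = n_markers,
                          seed = seed, ...)
  pop <- simulate_population(cfg)
  plots <- simulate_trials(cfg, pop)
  list(cfg = cfg, pop = pop, plots = plots)
}

# direct joint-normal conditioning oracle for multi-trait predictions:
# builds the full covariance over all (line, trait) cells at the fitted
# H and R, conditions on the observed cells, and returns E[a | y_obs]
oracle_conditional <- function(fit, records, K) {
  ids <- fit$lines; tts <- fit$traits
  obs <- records[!is.na(records$value), , drop = FALSE]
  i <- match(as.character(obs$line), ids)
  t <- match(as.character(obs$trait), tts)
  n <- length(ids)
  Sig <- kronecker(fit$H, K)          # cell (i,t) at index (t-1)*n + i
  ci <- (t - 1L) * n + i
  w <- if ("weight" %in% names(obs)) obs$weight else rep(1, nrow(obs))
  same_line <- outer(as.character(obs$line), as.character(obs$line), "==")
  V <- Sig[ci, ci] + fit$R[t, t] * same_line / sqrt(outer(w, w))
  X <- matrix(0, nrow(obs), length(tts))
  X[cbind(seq_len(nrow(obs)), t)] <- 1
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% obs$value))
  r <- obs$value - X %*% beta
  matrix(Sig[, ci] %*% (Vi %*% r), n, length(tts))
}
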