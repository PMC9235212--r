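# small deterministic fit problem: y with genuine genetic signal
make_problem <- function(n, m, h2 = 0.6, seed = 13) {
  p <- panel_tiny(n, m, seed = seed)
  ca <- select_causal(p, NULL, "average", max(5, m %/% 5), seed = seed + 1)
  tr <- simulate_phenotypes(p, ca, h2 = h2, seed = seed + 2)
  list(panel = p, y = tr$phenotype, G = grm_gcta(standardize_dosage(p)))
}

test_that("REML matches a brute-force restricted-likelihood grid at n = 20", {
  pb <- make_problem(20, 60, h2 = 0.6, seed = 41)
  fit <- reml_fit(pb$y, pb$G)
  # 60 x 60 grid over both variance components
  vy <- var(pb$y)
  grid <- seq(0.02, 1.6, length.out = 60) * vy
  best <- -Inf
  best_th <- NULL
  for (a in grid) {
    for (b in grid) {
      ll <- oracle_restricted_logL(pb$y, list(pb$G$values), c(a, b))
      if (ll > best) {
        best <- ll
        best_th <- c(a, b)
      }
    }
  }
  # the fit's maximum must match the oracle's definition of the likelihood...
  ll_fit <- oracle_restricted_logL(pb$y, list(pb$G$values),
                                   c(fit$sigma2_g, fit$sigma2_e))
  expect_equal(ll_fit, fit$logL, tolerance = 1e-8)
  # ...and dominate every grid point
  expect_gte(fit$logL, best - 1e-8)
  # the grid argmax lies within one grid cell of the fitted optimum
  res <- diff(grid)[1]
  expect_lt(abs(best_th[1] - fit$sigma2_g), res + 1e-12)
  expect_lt(abs(best_th[2] - fit$sigma2_e), res + 1e-12)
})

test_that("multi-component REML maximizes the oracle likelihood", {
  p <- panel_tiny(60, 80, seed = 51)
  pr <- ld_profile(p, compute_weights = FALSE, n_groups = 2)
  gs <- stratified_grms(p, pr$ld_level)
  ca <- select_causal(p, NULL, "average", 20, seed = 3)
  y <- simulate_phenotypes(p, ca, h2 = 0.7, seed = 4)$phenotype
  fit <- reml_fit(y, gs)
  Gl <- lapply(gs, `[[`, "values")
  theta_hat <- c(fit$sigma2_g, fit$sigma2_e)
  expect_equal(oracle_restricted_logL(y, Gl, theta_hat), fit$logL,
               tolerance = 1e-8)
  # local maximum: nudging any unpinned component down/up lowers the oracle
  for (t in seq_along(theta_hat)) {
    for (f in c(0.9, 1.1)) {
      th <- theta_hat
      th[t] <- th[t] * f
      if (th[t] <= 0) next
      expect_lte(oracle_restricted_logL(y, Gl, th), fit$logL + 1e-6)
    }
  }
})

test_that("eigen and dense REML engines agree pointwise", {
  pb <- make_problem(50, 80, seed = 23)
  y <- unname(pb$y)
  eng_e <- ldhet:::reml_engine_eigen(y, grm_eigen(pb$G))
  eng_d <- ldhet:::reml_engine_dense(y, list(pb$G$values))
  for (theta in list(c(0.5, 0.5), c(0.1, 0.9), c(1.3, 0.2))) {
    a <- eng_e(theta)
    b <- eng_d(theta)
    expect_equal(a$logL, b$logL, tolerance = 1e-8)
    expect_equal(a$yPGPy, b$yPGPy, tolerance = 1e-8)
    expect_equal(a$trPG, b$trPG, tolerance = 1e-8)
    expect_equal(a$AI, b$AI, tolerance = 1e-8)
    expect_equal(a$mu, b$mu, tolerance = 1e-10)
  }
})

test_that("REML is invariant to permuting individuals", {
  pb <- make_problem(60, 90, seed = 17)
  fit <- reml_fit(pb$y, pb$G)
  set.seed(1)
  perm <- sample(60)
  Gp <- ldhet:::new_grm(pb$G$values[perm, perm], pb$G$n_snps,
                        pb$G$ids[perm], "uniform")
  fitp <- reml_fit(pb$y[perm], Gp)
  expect_equal(fitp$logL, fit$logL, tolerance = 1e-8)
  expect_equal(fitp$h2, fit$h2, tolerance = 1e-8)
  expect_equal(fitp$sigma2_g, fit$sigma2_g, tolerance = 1e-8)
})

test_that("scaling the GRM rescales the variance component only", {
  pb <- make_problem(60, 90, seed = 29)
  fit <- reml_fit(pb$y, pb$G)
  G2 <- ldhet:::new_grm(4 * pb$G$values, pb$G$n_snps, pb$G$ids, "uniform")
  fit2 <- reml_fit(pb$y, G2)
  expect_equal(unname(fit2$sigma2_g), unname(fit$sigma2_g) / 4,
               tolerance = 1e-3)
  expect_equal(fit2$sigma2_e, fit$sigma2_e, tolerance = 1e-3)
  expect_equal(fit2$logL, fit$logL, tolerance = 1e-6)
})

test_that("likelihood never decreases after the EM burn-in", {
  pb <- make_problem(80, 120, seed = 31)
  fit <- reml_fit(pb$y, pb$G)
  expect_true(fit$converged)
  post <- fit$logL_trace[-seq_len(4)]
  expect_true(all(diff(post) >= -1e-8))
})

test_that("pure-noise phenotypes give a near-zero heritability", {
  p <- panel_tiny(200, 150, seed = 37)
  y <- with(list(), {
    set.seed(99)
    rnorm(200)
  })
  names(y) <- p$ids
  fit <- reml_fit(y, grm_gcta(standardize_dosage(p)))
  expect_lt(fit$h2, 0.25)
})

test_that("AIC and enrichment follow their closed forms", {
  fake <- list(logL = 0, n_components = 1)
  expect_equal(aic(fake), 4)
  fake5 <- list(logL = -10, n_components = 5)
  expect_equal(aic(fake5), 32)
  # the single-GRM model is nested in the stratified one
  # (theta_t = sigma2_g * N_t / N reproduces it), so logL_5 >= logL_1
  p <- panel_tiny(80, 100, seed = 43)
  pr <- ld_profile(p, compute_weights = FALSE)
  gs <- stratified_grms(p, pr$ld_level)
  ca <- select_causal(p, NULL, "average", 20, seed = 5)
  y <- simulate_phenotypes(p, ca, h2 = 0.6, seed = 6)$phenotype
  f1 <- reml_fit(y, grm_gcta(standardize_dosage(p)))
  f5 <- reml_fit(y, gs)
  expect_gte(f5$logL, f1$logL - 1e-5)
  # enrichment arithmetic on a fabricated fit
  ff <- list(n_components = 2, sigma2_g = c(a = 3, b = 1))
  en <- heritability_enrichment(ff, c(10, 30))
  expect_equal(en$share, c(0.75, 0.25))
  expect_equal(en$enrichment, c(0.75 / 0.25, 0.25 / 0.75))
  expect_error(heritability_enrichment(list(n_components = 1), 5),
               "at least two")
})

test_that("GBLUP matches the mixed-model-equation oracle at n = 5", {
  p <- panel_tiny(5, 60, seed = 47)
  G <- grm_gcta(standardize_dosage(p))
  # centered genotypes make G singular (G 1 = 0); blend with the identity so
  # the MME form (which needs G^-1) is defined. GBLUP and the MME are
  # equivalent for any invertible PSD covariance.
  G <- ldhet:::new_grm(0.9 * G$values + 0.1 * diag(5), G$n_snps, G$ids,
                       "uniform")
  set.seed(7)
  y <- rnorm(5) + 0.5
  names(y) <- p$ids
  train <- p$ids[1:4]
  val <- p$ids[5]
  s2g <- 0.7
  s2e <- 0.4
  # GLS intercept on the training block
  Vtt <- s2g * G$values[1:4, 1:4] + diag(s2e, 4)
  mu <- sum(solve(Vtt, y[1:4])) / sum(solve(Vtt, rep(1, 4)))
  fit <- list(sigma2_g = s2g, sigma2_e = s2e, mu = mu, n_components = 1)
  pred <- gblup_predict(fit, G, y[train], train, val)
  # Henderson MME: [X'X  X'Z; Z'X  Z'Z + G^-1 lambda] [b; u] = [X'y; Z'y]
  Z <- diag(5)[1:4, ]
  X <- matrix(1, 4, 1)
  lam <- s2e / s2g
  lhs <- rbind(cbind(crossprod(X), t(X) %*% Z),
               cbind(t(Z) %*% X, crossprod(Z) + solve(G$values) * lam))
  rhs <- c(crossprod(X, y[1:4]), crossprod(Z, y[1:4]))
  sol <- solve(lhs, rhs)
  expect_equal(unname(pred$gebv), unname(sol[6]), tolerance = 1e-8)
  expect_equal(unname(mu), unname(sol[1]), tolerance = 1e-8)
})

test_that("GBLUP reports accuracy against a named reference", {
  p <- panel_tiny(100, 150, seed = 53)
  ca <- select_causal(p, NULL, "average", 30, seed = 8)
  tr <- simulate_phenotypes(p, ca, h2 = 0.9, seed = 9)
  G <- grm_gcta(standardize_dosage(p))
  train <- p$ids[1:90]
  val <- p$ids[91:100]
  fit <- reml_fit(tr$phenotype[train], subset_grm(G, train))
  pred <- gblup_predict(fit, G, tr$phenotype[train], train, val,
                        reference = tr$tbv)
  expect_equal(unname(pred$accuracy),
               cor(unname(pred$gebv), unname(tr$tbv[val])))
  expect_gt(pred$accuracy, 0.3)   # strong signal, LD-rich small genome
  expect_error(gblup_predict(fit, G, tr$phenotype[train], train, "nobody"),
               "missing")
})

test_that("reml_fit validates its inputs", {
  pb <- make_problem(30, 40, seed = 59)
  expect_error(reml_fit(pb$y[1:10], pb$G), "missing|length")
  y2 <- unname(pb$y)[1:29]
  expect_error(reml_fit(y2, pb$G), "length")
  eg <- grm_eigen(pb$G)
  expect_error(reml_fit(pb$y, list(eg, eg)), "single-component")
  # standard errors are produced
  fit <- reml_fit(pb$y, pb$G)
  expect_length(fit$se_sigma2, 2)
  expect_true(is.finite(fit$se_h2))
})
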