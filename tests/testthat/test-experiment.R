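test_that("scenario grids enumerate tagging classes and heritabilities", {
  sc <- sim_scenarios()
  expect_equal(sc$tagging_class,
               c("very_weak", "weak", "average", "strong", "very_strong"))
  expect_equal(sc$h2, rep(0.8, 5))
  sc2 <- sim_scenarios(c("weak", "strong"), h2 = c(0.5, 0.8))
  expect_equal(nrow(sc2), 4)
  expect_setequal(sc2$tagging_class, c("weak", "strong"))
})

test_that("model GRM sets follow the four specifications", {
  p <- subset_panel(panel_small(), snps = 1:200)
  pr <- ld_profile(p)
  mg <- build_model_grms(p, pr)
  expect_named(mg, c("GCTA", "LDAK", "GCTA-LDS", "LDAK-LDS"))
  expect_length(mg$GCTA, 1)
  expect_length(mg$`GCTA-LDS`, 5)
  expect_equal(mg$GCTA[[1]]$weighting, "uniform")
  expect_equal(mg$LDAK[[1]]$weighting, "ldak")
  X <- standardize_dosage(p)
  expect_equal(mg$LDAK[[1]]$values, grm_ldak(X, pr$w_star)$values)
  expect_error(build_model_grms(p, NULL, c("GCTA", "LDAK")), "profile")
})

test_that("the simulation grid is deterministic with exact bookkeeping", {
  p <- fixture("panel_grid",
               simulate_genotypes(120, 400, n_chromosomes = 2,
                                  chrom_length = 5e6, seed = 77))
  sc <- sim_scenarios(c("weak", "average"))
  res <- run_simulation_grid(p, sc, models = "GCTA", n_replicates = 3,
                             n_causal = 30, seed = 101)
  expect_equal(nrow(res), 2 * 3 * 1)
  expect_setequal(res$tagging_class, c("weak", "average"))
  expect_true(all(c("accuracy", "h2_hat", "aic", "logL", "converged",
                    "error") %in% names(res)))
  expect_true(all(is.na(res$error)))
  expect_true(all(abs(res$accuracy) <= 1))
  expect_true(all(res$h2_hat >= 0 & res$h2_hat <= 1))
  res2 <- run_simulation_grid(p, sc, models = "GCTA", n_replicates = 3,
                              n_causal = 30, seed = 101)
  expect_identical(res, res2)
  res3 <- run_simulation_grid(p, sc, models = "GCTA", n_replicates = 3,
                              n_causal = 30, seed = 102)
  expect_false(identical(res$accuracy, res3$accuracy))
})

test_that("deregression standardizes then divides by reliability", {
  ebv <- data.frame(id = c("a", "b", "c"), value = c(1, 2, 3),
                    reliability = c(0.5, 0.8, 1))
  d <- deregress(ebv)
  expect_equal(d$value, c(-1 / 0.5, 0, 1))
  # homogeneous reliability r2: dEBV = standardized EBV / r2
  ebv2 <- data.frame(id = letters[1:5], value = rnorm(5), reliability = 0.8)
  d2 <- deregress(ebv2)
  expect_equal(d2$value, as.numeric(scale(ebv2$value)) / 0.8)
  # heterogeneous reliabilities inflate the variance above 1
  expect_gt(var(d$value), 1)
  expect_error(deregress(data.frame(id = "a", value = 1, reliability = 0)),
               "positive")
  expect_error(deregress(data.frame(id = "a", value = 1, reliability = 1.2)),
               "exceed")
})

test_that("model comparison reproduces textbook paired t-tests", {
  set.seed(202)
  R <- 12
  base <- rnorm(R, 0.5, 0.05)
  res <- data.frame(
    model = rep(c("A", "B", "C"), each = R),
    replicate = rep(1:R, 3),
    accuracy = c(base, base + rnorm(R, 0.08, 0.02), base + rnorm(R, 0, 0.01)))
  cmp <- compare_models(res, "accuracy")
  expect_s3_class(cmp, "comparison_report")
  expect_equal(cmp$summary$model, c("A", "B", "C"))
  # oracle ANOVA p from the textbook F statistic
  wide <- matrix(res$accuracy, R, 3)
  gm <- mean(wide)
  ssb <- R * sum((colMeans(wide) - gm)^2)
  ssw <- sum(sweep(wide, 2, colMeans(wide))^2)
  Fstat <- (ssb / 2) / (ssw / (3 * R - 3))
  expect_equal(cmp$anova_p, pf(Fstat, 2, 3 * R - 3, lower.tail = FALSE),
               tolerance = 1e-10)
  # oracle paired t for the A-B pair, Bonferroni over 3 pairs
  d <- wide[, 1] - wide[, 2]
  tstat <- mean(d) / (sd(d) / sqrt(R))
  p_ab <- 2 * pt(-abs(tstat), R - 1)
  row_ab <- cmp$pairwise[cmp$pairwise$model1 == "A" &
                           cmp$pairwise$model2 == "B", ]
  expect_equal(row_ab$p, p_ab, tolerance = 1e-10)
  expect_equal(row_ab$p_adj, min(1, p_ab * 3), tolerance = 1e-10)
  expect_equal(row_ab$mean_diff, mean(d))
})

test_that("model comparison handles degenerate inputs", {
  R <- 6
  set.seed(404)
  a <- rnorm(R)
  same <- data.frame(model = rep(c("A", "B"), each = R),
                     replicate = rep(1:R, 2), accuracy = c(a, a))
  cmp <- compare_models(same, "accuracy")
  expect_equal(cmp$anova_p, 1)
  expect_null(cmp$pairwise)
  shift <- data.frame(model = rep(c("A", "B"), each = R),
                      replicate = rep(1:R, 2), accuracy = c(a, a + 5))
  cmp2 <- compare_models(shift, "accuracy")
  pw <- cmp2$pairwise
  expect_true(pw$degenerate[1])
  expect_equal(pw$p[1], 0)
  expect_equal(as.character(pw$code[1]), "***")
  expect_error(compare_models(same[same$model == "A", ], "accuracy"),
               "two models")
  expect_error(compare_models(same[-1, ], "accuracy"), "paired")
})

test_that("cross-validation is reproducible and detects real signal", {
  p <- fixture("panel_grid",
               simulate_genotypes(120, 400, n_chromosomes = 2,
                                  chrom_length = 5e6, seed = 77))
  G <- grm_gcta(standardize_dosage(p))
  ca <- select_causal(p, NULL, "average", 40, seed = 11)
  tr <- simulate_phenotypes(p, ca, h2 = 0.9, seed = 12)
  cv <- cross_validate(G, tr$phenotype, n_folds = 5, n_repeats = 2, seed = 3)
  expect_equal(nrow(cv), 10)
  expect_identical(cv, cross_validate(G, tr$phenotype, n_folds = 5,
                                      n_repeats = 2, seed = 3))
  # predicting the phenotype: accuracy bounded by sqrt(h2) but well above 0
  expect_gt(mean(cv$accuracy), 0.2)
  # pure noise: accuracy near zero on average
  set.seed(13)
  noise <- setNames(rnorm(120), p$ids)
  cvn <- cross_validate(G, noise, n_folds = 5, n_repeats = 2, seed = 3)
  expect_lt(abs(mean(cvn$accuracy)), 0.2)
  expect_error(cross_validate(G, tr$phenotype, n_folds = 60), "fewer than 3")
})

test_that("density comparison is exactly paired across densities", {
  p <- fixture("panel_grid",
               simulate_genotypes(120, 400, n_chromosomes = 2,
                                  chrom_length = 5e6, seed = 77))
  res <- density_comparison(p, medium_count = 200, tagging_class = "weak",
                            models = "GCTA", n_replicates = 3,
                            n_causal = 20, seed = 31)
  expect_equal(nrow(res), 2 * 3)
  expect_setequal(res$density, c("high", "medium"))
  # paired: same replicate uses the same seed in both densities
  wide <- split(res, res$density)
  expect_equal(wide$high$seed, wide$medium$seed)
  expect_true(all(is.na(res$error)))
  # degenerate case: medium == high gives identical results per replicate
  res2 <- density_comparison(p, medium_count = 400, tagging_class = "weak",
                             models = "GCTA", n_replicates = 2,
                             n_causal = 20, seed = 31)
  w2 <- split(res2, res2$density)
  expect_equal(w2$high$accuracy, w2$medium$accuracy, tolerance = 1e-10)
  expect_equal(w2$high$h2_hat, w2$medium$h2_hat, tolerance = 1e-10)
  expect_error(density_comparison(p, 500), "larger")
})
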