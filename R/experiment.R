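#' Scenario grid constructor
#'
#' @param tagging_class character vector of tagging classes for the causal
#'   variants (`"very_weak"`, `"weak"`, `"average"`, `"strong"`,
#'   `"very_strong"`).
#' @param h2 heritabilities to simulate (default 0.8).
#' @return data.frame with one row per (tagging_class, h2) combination.
#' @export
sim_scenarios <- function(tagging_class = c("very_weak", "weak", "average",
                                            "strong", "very_strong"),
                          h2 = 0.8) {
  out <- expand.grid(tagging_class = tagging_class, h2 = h2,
                     stringsAsFactors = FALSE)
  out[order(match(out$tagging_class, tagging_class)), , drop = FALSE]
}

#' Build the GRM sets of the four model specifications
#'
#' `GCTA`: one uniformly weighted GRM on all SNPs. `LDAK`: one LD-weighted
#' GRM. `GCTA-LDS` / `LDAK-LDS`: one GRM per LD level, uniformly or LD
#' weighted.
#'
#' @param panel a [genotype_panel()].
#' @param profile an [ld_profile()] of the panel (required for all models but
#'   `GCTA`).
#' @param models character subset of
#'   `c("GCTA", "LDAK", "GCTA-LDS", "LDAK-LDS")`.
#' @return named list; each element is the list of `grm` objects of one model.
#' @export
build_model_grms <- function(panel, profile = NULL,
                             models = c("GCTA", "LDAK", "GCTA-LDS",
                                        "LDAK-LDS")) {
  models <- match.arg(models, several.ok = TRUE)
  need_profile <- any(models != "GCTA")
  if (need_profile && is.null(profile)) stop("profile required for ", paste(
    setdiff(models, "GCTA"), collapse = ", "))
  X <- standardize_dosage(panel)
  out <- list()
  for (mod in models) {
    out[[mod]] <- switch(mod,
      "GCTA" = list(grm_gcta(X)),
      "LDAK" = list(grm_ldak(X, profile$w_star)),
      "GCTA-LDS" = stratified_grms(panel, profile$ld_level, "uniform"),
      "LDAK-LDS" = stratified_grms(panel, profile$ld_level, "ldak",
                                   weights = profile$w))
  }
  out
}

# One replicate of the simulate / split / fit / predict pipeline for a set of
# prepared model GRMs. Returns one row per model.
run_replicate <- function(panel, classes, model_grms, tagging_class, h2,
                          n_causal, train_fraction, rep_seed,
                          causal_pool_panel = NULL) {
  causal <- select_causal(panel, classes, tagging_class, n_causal,
                          seed = rep_seed)
  trait <- simulate_phenotypes(panel, causal, h2 = h2,
                               seed = derive_seed(rep_seed, 1))
  ids <- panel$ids
  n <- length(ids)
  n_val <- max(1, round((1 - train_fraction) * n))
  val_ids <- with_seed(derive_seed(rep_seed, 2), sample(ids, n_val))
  train_ids <- setdiff(ids, val_ids)
  rows <- lapply(names(model_grms), function(mod) {
    res <- tryCatch({
      grms <- model_grms[[mod]]
      fit <- reml_fit(trait$phenotype[train_ids],
                      lapply(grms, subset_grm, ids = train_ids))
      pred <- gblup_predict(fit, grms, trait$phenotype[train_ids],
                            train_ids, val_ids, reference = trait$tbv)
      list(accuracy = pred$accuracy, h2_hat = fit$h2,
           h2_levels = list(unname(fit$h2_components)),
           aic = fit$aic, logL = fit$logL, converged = fit$converged,
           error = NA_character_)
    }, error = function(e) {
      list(accuracy = NA_real_, h2_hat = NA_real_, h2_levels = list(NULL),
           aic = NA_real_, logL = NA_real_, converged = FALSE,
           error = conditionMessage(e))
    })
    data.frame(model = mod, accuracy = res$accuracy, h2_hat = res$h2_hat,
               aic = res$aic, logL = res$logL, converged = res$converged,
               error = res$error, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run a replicated simulation grid
#'
#' For each scenario and replicate: draw causal variants from the scenario's
#' tagging class, simulate the trait, randomly split individuals into
#' training and validation sets, fit each model's REML on the training set
#' (variance components are re-estimated within every split), predict the
#' validation individuals by GBLUP and record the accuracy against the true
#' genetic values, the heritability estimate and the AIC. Genotypes are
#' simulated (or supplied) once and reused across replicates; all seeds are
#' derived deterministically from `seed`.
#'
#' @param panel a [genotype_panel()].
#' @param scenarios data.frame from [sim_scenarios()].
#' @param models model specifications, see [build_model_grms()].
#' @param n_replicates replicates per scenario (default 30).
#' @param n_causal causal variants per trait (default 100).
#' @param train_fraction fraction of individuals used for training
#'   (default 0.9).
#' @param profile optional precomputed [ld_profile()].
#' @param n_groups LD levels for the stratified models (default 5).
#' @param seed master seed.
#' @return data.frame with one row per (scenario, model, replicate):
#'   `tagging_class`, `h2_true`, `model`, `replicate`, `seed`, `accuracy`,
#'   `h2_hat`, `aic`, `logL`, `converged`, `error`.
#' @export
run_simulation_grid <- function(panel, scenarios = sim_scenarios(),
                                models = c("GCTA", "LDAK", "GCTA-LDS",
                                           "LDAK-LDS"),
                                n_replicates = 30, n_causal = 100,
                                train_fraction = 0.9, profile = NULL,
                                n_groups = 5, seed = 1) {
  models <- match.arg(models, several.ok = TRUE)
  need_weights <- any(grepl("LDAK", models))
  need_profile <- any(models != "GCTA") ||
    any(scenarios$tagging_class != "average")
  if (need_profile && is.null(profile)) {
    profile <- ld_profile(panel, n_groups = n_groups,
                          compute_weights = need_weights)
  }
  classes <- if (is.null(profile)) NULL else
    classify_tagging(panel, profile$ld_score)
  model_grms <- build_model_grms(panel, profile, models)
  out <- list()
  for (si in seq_len(nrow(scenarios))) {
    cls <- scenarios$tagging_class[si]
    h2 <- scenarios$h2[si]
    for (r in seq_len(n_replicates)) {
      rep_seed <- derive_seed(seed, si, r)
      rows <- run_replicate(panel, classes, model_grms, cls, h2, n_causal,
                            train_fraction, rep_seed)
      rows <- cbind(data.frame(tagging_class = cls, h2_true = h2,
                               replicate = r, seed = rep_seed,
                               stringsAsFactors = FALSE), rows)
      out[[length(out) + 1]] <- rows
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Repeated k-fold cross-validation of one model specification
#'
#' Repeats a random (stratification-free) fold assignment `n_repeats` times;
#' in each fold the variance components are re-estimated by REML on the
#' training folds and the held-out individuals are predicted by GBLUP. The
#' accuracy is the Pearson correlation of GEBV and the held-out phenotypes.
#'
#' @param grms list of `grm` objects of one model specification.
#' @param y named phenotype vector covering the GRM ids.
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 10).
#' @param seed integer seed; fold assignments are reproducible.
#' @return data.frame with columns `rep`, `fold`, `accuracy`.
#' @export
cross_validate <- function(grms, y, n_folds = 10, n_repeats = 10, seed = 1) {
  if (inherits(grms, "grm")) grms <- list(grms)
  ids <- grms[[1]]$ids
  n <- length(ids)
  if (n < n_folds) stop("fewer individuals than folds")
  if (floor(n / n_folds) < 3) stop("folds would contain fewer than 3 individuals")
  y <- if (!is.null(names(y))) y[ids] else stats::setNames(y, ids)
  out <- list()
  for (r in seq_len(n_repeats)) {
    folds <- with_seed(derive_seed(seed, r),
                       sample(rep(seq_len(n_folds), length.out = n)))
    for (f in seq_len(n_folds)) {
      val_ids <- ids[folds == f]
      train_ids <- ids[folds != f]
      fit <- reml_fit(y[train_ids], lapply(grms, subset_grm, ids = train_ids))
      pred <- gblup_predict(fit, grms, y[train_ids], train_ids, val_ids,
                            reference = y, reference_kind = "phenotype")
      out[[length(out) + 1]] <- data.frame(rep = r, fold = f,
                                           accuracy = pred$accuracy)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deregress estimated breeding values
#'
#' EBV are standardized to mean 0 and variance 1 across individuals, then
#' divided by their reliability: `dEBV_i = g_i / r_i^2`. Heterogeneous
#' reliabilities inflate the variance of the deregressed values relative to
#' the standardized EBV.
#'
#' @param ebv data.frame with columns `id`, `value` (EBV) and `reliability`
#'   in `(0, 1]`.
#' @return data.frame with columns `id`, `value` (deregressed EBV).
#' @export
deregress <- function(ebv) {
  stopifnot(all(c("id", "value", "reliability") %in% names(ebv)))
  r2 <- ebv$reliability
  if (any(r2 <= 0)) stop("reliability must be positive")
  if (any(r2 > 1)) stop("reliability must not exceed 1")
  g <- as.numeric(scale(ebv$value))
  data.frame(id = as.character(ebv$id), value = g / r2,
             stringsAsFactors = FALSE)
}

#' Compare models on a replicate metric
#'
#' One-way ANOVA across models; when the ANOVA rejects at the 0.05 level,
#' all pairwise paired t-tests are run (replicates are paired through shared
#' seeds) with Bonferroni-adjusted p-values and the usual significance codes
#' (`*`, `**`, `***` at 0.05 / 0.01 / 0.001). A pair whose differences have
#' zero variance is flagged degenerate and reported with a p-value of 0 (or
#' 1 when the metric vectors are identical).
#'
#' @param results replicate table from [run_simulation_grid()] (a single
#'   scenario) or any data.frame with columns `model`, `replicate` and the
#'   metric.
#' @param metric one of `"accuracy"`, `"h2_hat"`, `"aic"` (or any numeric
#'   column name).
#' @return object of class `comparison_report`: list with `metric`,
#'   `summary` (per-model mean/sd), `anova_p`, `pairwise` (data.frame, `NULL`
#'   when the ANOVA does not reject).
#' @export
compare_models <- function(results, metric = c("accuracy", "h2_hat", "aic")) {
  metric <- if (length(metric) > 1) match.arg(metric) else metric
  stopifnot(metric %in% names(results),
            all(c("model", "replicate") %in% names(results)))
  models <- unique(results$model)
  if (length(models) < 2) stop("need at least two models")
  wide <- stats::reshape(
    results[, c("model", "replicate", metric)],
    idvar = "replicate", timevar = "model", direction = "wide")
  wide <- wide[, -1, drop = FALSE]
  colnames(wide) <- sub(paste0("^", metric, "\\."), "", colnames(wide))
  wide <- as.matrix(wide[, models, drop = FALSE])
  if (anyNA(wide)) stop("replicates are not paired across models")
  R <- nrow(wide)
  if (R < 3) stop("need at least three replicates")
  summ <- data.frame(model = models,
                     mean = colMeans(wide),
                     sd = apply(wide, 2, stats::sd), row.names = NULL)
  grand <- mean(wide)
  ssb <- R * sum((colMeans(wide) - grand)^2)
  anova_p <- if (ssb == 0) 1 else {
    df <- data.frame(value = as.vector(wide),
                     model = factor(rep(models, each = R)))
    summary(stats::aov(value ~ model, data = df))[[1]][["Pr(>F)"]][1]
  }
  pairwise <- NULL
  if (!is.na(anova_p) && anova_p < 0.05) {
    prs <- utils::combn(models, 2)
    C <- ncol(prs)
    pw <- lapply(seq_len(C), function(i) {
      a <- wide[, prs[1, i]]
      b <- wide[, prs[2, i]]
      d <- a - b
      degenerate <- stats::sd(d) == 0
      p <- if (degenerate) {
        if (mean(d) == 0) 1 else 0
      } else {
        stats::t.test(a, b, paired = TRUE)$p.value
      }
      data.frame(model1 = prs[1, i], model2 = prs[2, i],
                 mean_diff = mean(d), p = p, degenerate = degenerate,
                 stringsAsFactors = FALSE)
    })
    pairwise <- do.call(rbind, pw)
    pairwise$p_adj <- pmin(1, pairwise$p * C)
    pairwise$code <- cut(pairwise$p_adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                         labels = c("***", "**", "*", "ns"))
  }
  structure(list(metric = metric, summary = summ, anova_p = anova_p,
                 pairwise = pairwise, n_replicates = R),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report on %s over %d paired replicates\n",
              x$metric, x$n_replicates))
  print(x$summary, row.names = FALSE, digits = 4)
  cat(sprintf("one-way ANOVA p = %.4g\n", x$anova_p))
  if (is.null(x$pairwise)) {
    cat("no pairwise tests run (ANOVA not significant at 0.05)\n")
  } else {
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

# Downdate one model's GRM list by the causal SNP columns (removing the
# causal variants from the panel without rebuilding the matrices).
exclude_causal_grms <- function(grms, X, causal, profile = NULL) {
  lapply(grms, function(g) {
    if (length(grms) == 1) {
      idx <- causal
    } else {
      lvl <- as.integer(sub("^ld_level ", "", g$label))
      idx <- causal[profile$ld_level[causal] == lvl]
    }
    if (length(idx) == 0) return(g)
    if (g$weighting == "uniform") {
      grm_exclude(g, X[, idx, drop = FALSE])
    } else {
      # weights as used inside the matrix: rescaled within the SNP subset
      if (length(grms) == 1) {
        wc <- profile$w_star[idx]
      } else {
        lvl <- as.integer(sub("^ld_level ", "", g$label))
        grp <- which(profile$ld_level == lvl)
        w_grp <- profile$w[grp] * length(grp) / sum(profile$w[grp])
        wc <- w_grp[match(idx, grp)]
      }
      grm_exclude(g, X[, idx, drop = FALSE], wc)
    }
  })
}

#' Compare marker densities on the same simulated traits
#'
#' Builds a medium-density panel by even thinning of the high-density panel,
#' then evaluates each model on both panels against the same simulated traits.
#' Per replicate, the causal variants are drawn from the requested tagging
#' class (defined on the high-density panel), the trait is simulated, and the
#' causal variants are removed from both panels (by exact GRM downdating for
#' uniform weighting; LDAK weights of the remaining SNPs are rescaled) before
#' fitting and prediction, so that prediction must work through linked
#' markers only.
#'
#' @param panel the high-density [genotype_panel()].
#' @param medium_count SNP count of the medium-density panel.
#' @param tagging_class tagging class of the causal variants (default
#'   `"weak"`).
#' @param models model specifications (default `"GCTA"`).
#' @param n_replicates paired replicates (default 30).
#' @param h2,n_causal,train_fraction trait and split settings.
#' @param n_groups LD levels for stratified models.
#' @param seed master seed.
#' @return data.frame with one row per (density, model, replicate), paired by
#'   `replicate` across densities; columns as in [run_simulation_grid()] plus
#'   `density`.
#' @export
density_comparison <- function(panel, medium_count, tagging_class = "weak",
                               models = "GCTA", n_replicates = 30, h2 = 0.8,
                               n_causal = 100, train_fraction = 0.9,
                               n_groups = 5, seed = 1) {
  if (medium_count > n_snps(panel)) {
    stop("medium panel larger than the high-density panel")
  }
  models <- match.arg(models, c("GCTA", "LDAK", "GCTA-LDS", "LDAK-LDS"),
                      several.ok = TRUE)
  need_weights <- any(grepl("LDAK", models))
  medium <- build_medium_panel(panel, medium_count)
  panels <- list(high = panel, medium = medium)
  profiles <- lapply(panels, ld_profile, n_groups = n_groups,
                     compute_weights = need_weights)
  Xs <- lapply(panels, standardize_dosage)
  base_grms <- mapply(function(p, pr) build_model_grms(p, pr, models),
                      panels, profiles, SIMPLIFY = FALSE)
  classes <- classify_tagging(panel, profiles$high$ld_score)
  ids <- panel$ids
  n <- length(ids)
  out <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- derive_seed(seed, r)
    causal <- select_causal(panel, classes, tagging_class, n_causal,
                            seed = rep_seed)
    trait <- simulate_phenotypes(panel, causal, h2 = h2,
                                 seed = derive_seed(rep_seed, 1))
    n_val <- max(1, round((1 - train_fraction) * n))
    val_ids <- with_seed(derive_seed(rep_seed, 2), sample(ids, n_val))
    train_ids <- setdiff(ids, val_ids)
    causal_ids <- panel$map$snp_id[causal]
    for (dens in names(panels)) {
      cidx <- match(causal_ids, panels[[dens]]$map$snp_id)
      cidx <- cidx[!is.na(cidx)]
      for (mod in models) {
        grms <- exclude_causal_grms(base_grms[[dens]][[mod]], Xs[[dens]],
                                    cidx, profiles[[dens]])
        row <- tryCatch({
          fit <- reml_fit(trait$phenotype[train_ids],
                          lapply(grms, subset_grm, ids = train_ids))
          pred <- gblup_predict(fit, grms, trait$phenotype[train_ids],
                                train_ids, val_ids, reference = trait$tbv)
          data.frame(accuracy = pred$accuracy, h2_hat = fit$h2,
                     aic = fit$aic, converged = fit$converged,
                     error = NA_character_, stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(accuracy = NA_real_, h2_hat = NA_real_, aic = NA_real_,
                     converged = FALSE, error = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
        out[[length(out) + 1]] <- cbind(
          data.frame(density = dens, model = mod, tagging_class = tagging_class,
                     h2_true = h2, replicate = r, seed = rep_seed,
                     stringsAsFactors = FALSE), row)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
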