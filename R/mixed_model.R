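#' Precompute the eigendecomposition of a GRM
#'
#' For single-component REML the model can be rotated into the eigenbasis of
#' the GRM, making every REML iteration O(n) instead of O(n^3). Use this when
#' fitting many traits against the same GRM.
#'
#' @param grm a `grm` object.
#' @return object of class `grm_eigen` accepted by [reml_fit()].
#' @export
grm_eigen <- function(grm) {
  ev <- eigen(grm$values, symmetric = TRUE)
  structure(list(U = ev$vectors, d = ev$values, ids = grm$ids,
                 n_snps = grm$n_snps, weighting = grm$weighting,
                 label = grm$label), class = "grm_eigen")
}

# --- REML engines -----------------------------------------------------------
# Each engine maps theta = (sigma2_g_1..T, sigma2_e) to the restricted
# log-likelihood with an intercept-only fixed effect, the data parts of the
# score (y'PGPy), the traces tr(PG), and the average-information matrix.

reml_engine_dense <- function(y, Gs) {
  n <- length(y)
  T_ <- length(Gs)
  ones <- rep(1, n)
  function(theta) {
    V <- diag(theta[T_ + 1], n)
    for (t in seq_len(T_)) V <- V + theta[t] * Gs[[t]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Vi <- chol2inv(R)
    u <- rowSums(Vi)                      # Vi %*% 1
    xvx <- sum(u)
    mu <- sum(u * y) / xvx
    Py <- drop(Vi %*% y) - u * mu
    logL <- -0.5 * (2 * sum(log(diag(R))) + log(xvx) + sum(y * Py))
    P <- Vi - tcrossprod(u) / xvx
    q <- vector("list", T_ + 1)
    yPGPy <- trPG <- numeric(T_ + 1)
    for (t in seq_len(T_)) {
      q[[t]] <- drop(Gs[[t]] %*% Py)
      yPGPy[t] <- sum(Py * q[[t]])
      trPG[t] <- sum(P * Gs[[t]])
    }
    q[[T_ + 1]] <- Py
    yPGPy[T_ + 1] <- sum(Py^2)
    trPG[T_ + 1] <- sum(diag(P))
    Pq <- lapply(q, function(v) drop(P %*% v))
    AI <- matrix(0, T_ + 1, T_ + 1)
    for (t in seq_len(T_ + 1)) {
      for (s in t:(T_ + 1)) {
        AI[t, s] <- AI[s, t] <- 0.5 * sum(q[[t]] * Pq[[s]])
      }
    }
    list(logL = logL, yPGPy = yPGPy, trPG = trPG, AI = AI, mu = mu)
  }
}

reml_engine_eigen <- function(y, eg) {
  uy <- drop(crossprod(eg$U, y))
  u1 <- drop(crossprod(eg$U, rep(1, length(y))))
  d <- eg$d
  function(theta) {
    v <- theta[1] * d + theta[2]
    if (any(v <= 0)) return(NULL)
    iv <- 1 / v
    xvx <- sum(u1^2 * iv)
    mu <- sum(u1 * uy * iv) / xvx
    Py <- uy * iv - u1 * iv * mu        # rotated coordinates
    logL <- -0.5 * (sum(log(v)) + log(xvx) + sum(uy * Py))
    q <- list(d * Py, Py)
    yPGPy <- c(sum(d * Py^2), sum(Py^2))
    trPG <- c(sum(d * iv) - sum(u1^2 * iv^2 * d) / xvx,
              sum(iv) - sum(u1^2 * iv^2) / xvx)
    applyP <- function(x) x * iv - u1 * iv * (sum(u1 * x * iv) / xvx)
    Pq <- lapply(q, applyP)
    AI <- matrix(0, 2, 2)
    for (t in 1:2) {
      for (s in t:2) AI[t, s] <- AI[s, t] <- 0.5 * sum(q[[t]] * Pq[[s]])
    }
    list(logL = logL, yPGPy = yPGPy, trPG = trPG, AI = AI, mu = mu)
  }
}

#' Restricted maximum-likelihood fit of a (multi-)GRM mixed model
#'
#' Fits `y = mu + sum_t g_t + e` with `g_t ~ N(0, G_t sigma2_g_t)` and
#' `e ~ N(0, I sigma2_e)` by REML: 4 EM-REML burn-in iterations followed by
#' average-information (AI) updates until the restricted log-likelihood
#' changes by less than `tol`. An AI step that would decrease the restricted
#' likelihood is replaced by an EM step, so the likelihood never decreases
#' after burn-in. Variance components whose update goes negative are pinned
#' to the boundary `1e-8 * var(y)`.
#'
#' With a single GRM (or a [grm_eigen()] decomposition) an exact
#' eigenrotation fast path is used; results are identical to the dense path.
#'
#' @param y named numeric vector of phenotypes, or aligned with the GRM ids.
#' @param grms a `grm`, `grm_eigen`, or list of `grm` objects sharing ids.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the change in restricted log-likelihood
#'   (default 1e-6).
#' @param n_em EM burn-in iterations (default 4).
#' @return object of class `variance_fit`: component variances `sigma2_g`,
#'   residual `sigma2_e`, intercept `mu`, restricted `logL` (and `logL_trace`),
#'   `aic`, per-component and total heritability (`h2_components`, `h2`),
#'   standard errors from the inverse AI matrix (`se_sigma2`, `se_h2` by the
#'   delta method), `iterations`, `converged`.
#' @export
reml_fit <- function(y, grms, max_iter = 100, tol = 1e-6, n_em = 4) {
  if (inherits(grms, "grm") || inherits(grms, "grm_eigen")) grms <- list(grms)
  T_ <- length(grms)
  ids <- grms[[1]]$ids
  for (g in grms) {
    if (!identical(g$ids, ids)) stop("GRMs do not share individual ids")
  }
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y))) stop("phenotype missing for some GRM ids")
    y <- y[ids]
  }
  n <- length(y)
  if (n != length(ids)) stop("phenotype length does not match GRM ids")
  if (n < T_ + 2) stop("too few individuals for the number of components")
  use_eigen <- T_ == 1
  engine <- if (use_eigen) {
    eg <- if (inherits(grms[[1]], "grm_eigen")) grms[[1]] else
      grm_eigen(grms[[1]])
    reml_engine_eigen(y, eg)
  } else {
    if (any(vapply(grms, inherits, logical(1), "grm_eigen"))) {
      stop("grm_eigen inputs are only supported for single-component fits")
    }
    reml_engine_dense(y, lapply(grms, `[[`, "values"))
  }
  vy <- stats::var(y)
  bound <- 1e-8 * vy
  theta <- c(rep(vy / 2 / T_, T_), vy / 2)
  ev <- engine(theta)
  if (is.null(ev)) stop("singular V at starting values")
  trace <- ev$logL
  converged <- FALSE
  iter <- 0
  em_step <- function(theta, ev) {
    pmax(theta + theta^2 / n * (ev$yPGPy - ev$trPG), bound)
  }
  while (iter < max_iter) {
    iter <- iter + 1
    if (iter <= n_em) {
      theta_new <- em_step(theta, ev)
      ev_new <- engine(theta_new)
    } else {
      score <- 0.5 * (ev$yPGPy - ev$trPG)
      # components pinned at the boundary with a negative score are held
      # there and dropped from the AI system (it is singular otherwise)
      active <- theta > bound * 1.001 | score > 0
      delta <- rep(0, length(theta))
      step <- tryCatch(
        solve(ev$AI[active, active, drop = FALSE], score[active]),
        error = function(e) NULL)
      if (is.null(step)) {
        theta_new <- em_step(theta, ev)
      } else {
        delta[active] <- step
        theta_new <- pmax(theta + delta, bound)
      }
      ev_new <- engine(theta_new)
      if (is.null(ev_new) || ev_new$logL < ev$logL - 1e-10) {
        theta_new <- em_step(theta, ev)   # fall back to guaranteed-ascent EM
        ev_new <- engine(theta_new)
      }
    }
    if (is.null(ev_new)) break
    dl <- ev_new$logL - ev$logL
    theta <- theta_new
    ev <- ev_new
    trace <- c(trace, ev$logL)
    if (iter > n_em && abs(dl) < tol) {
      converged <- TRUE
      break
    }
  }
  sg <- theta[seq_len(T_)]
  se2 <- theta[T_ + 1]
  tot <- sum(sg) + se2
  labels <- vapply(grms, function(g) {
    if (is.na(g$label)) "genetic" else g$label
  }, character(1))
  if (anyDuplicated(labels)) labels <- paste0(labels, "_", seq_len(T_))
  names(sg) <- labels
  covm <- tryCatch(solve(ev$AI), error = function(e) NULL)
  se_sigma2 <- if (is.null(covm)) rep(NA_real_, T_ + 1) else
    sqrt(pmax(diag(covm), 0))
  # delta method for total h2 = sum(sg) / tot
  se_h2 <- if (is.null(covm)) NA_real_ else {
    grad <- c(rep(se2 / tot^2, T_), -sum(sg) / tot^2)
    sqrt(max(drop(t(grad) %*% covm %*% grad), 0))
  }
  fit <- structure(list(
    sigma2_g = sg, sigma2_e = se2, mu = ev$mu,
    logL = ev$logL, logL_trace = trace,
    h2 = sum(sg) / tot, h2_components = sg / tot,
    se_sigma2 = se_sigma2, se_h2 = se_h2,
    iterations = iter, converged = converged,
    n = n, n_components = T_, ids = ids
  ), class = "variance_fit")
  fit$aic <- aic(fit)
  fit
}

#' @export
print.variance_fit <- function(x, ...) {
  cat(sprintf(
    "variance_fit: %d component(s), n = %d, %s after %d iterations\n",
    x$n_components, x$n,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  comp <- data.frame(component = c(names(x$sigma2_g), "residual"),
                     variance = c(unname(x$sigma2_g), x$sigma2_e),
                     se = x$se_sigma2,
                     h2 = c(unname(x$h2_components), NA))
  print(comp, row.names = FALSE, digits = 4)
  cat(sprintf("total h2 = %.4f (se %.4f), logL = %.4f, AIC = %.4f\n",
              x$h2, x$se_h2, x$logL, x$aic))
  invisible(x)
}

#' Akaike information criterion of a REML fit
#'
#' `AIC = -2 logL + 2 k` on the restricted log-likelihood with
#' `k = T + 1` variance parameters (the intercept is absorbed by REML). Only
#' AIC differences between models fitted to the same data are meaningful.
#'
#' @param fit a [reml_fit()] result.
#' @return numeric AIC.
#' @export
aic <- function(fit) {
  -2 * fit$logL + 2 * (fit$n_components + 1)
}

#' Heritability enrichment per LD group
#'
#' A group's share of the total genetic variance divided by its share of the
#' SNPs; 1 means the group contributes proportionally to its size.
#'
#' @param fit a multi-component [reml_fit()] result.
#' @param snps_per_group SNP counts of the groups, aligned with the fit
#'   components.
#' @return data.frame with columns `component`, `n_snps`, `share`,
#'   `enrichment`.
#' @export
heritability_enrichment <- function(fit, snps_per_group) {
  T_ <- fit$n_components
  if (T_ < 2) stop("enrichment requires at least two components")
  stopifnot(length(snps_per_group) == T_)
  sg <- fit$sigma2_g
  if (sum(sg) <= 0) stop("all genetic variances are zero")
  share <- sg / sum(sg)
  frac <- snps_per_group / sum(snps_per_group)
  data.frame(component = names(sg), n_snps = snps_per_group,
             share = unname(share), enrichment = unname(share / frac),
             row.names = NULL)
}

#' GBLUP prediction of validation individuals
#'
#' Given variance components estimated on the training individuals, predicts
#' genomic breeding values of the validation individuals as
#' `GEBV = C_vt V_tt^{-1} (y_train - mu)` with
#' `V_tt = sum_t G_t[train,train] sigma2_g_t + I sigma2_e` and
#' `C_vt = sum_t G_t[val,train] sigma2_g_t`.
#'
#' @param fit a [reml_fit()] result estimated on the training individuals.
#' @param grms list of `grm` objects covering training and validation
#'   individuals (same components, in fit order).
#' @param y_train named phenotypes of the training individuals.
#' @param train_ids,validation_ids character id vectors.
#' @param reference optional named reference values (true genetic values or
#'   deregressed EBV) used to compute the validation accuracy.
#' @param reference_kind label stored with the accuracy (default
#'   `"true_genetic_value"`).
#' @return object of class `prediction_result`: list with `gebv` (named),
#'   `accuracy` (Pearson correlation, `NA` without a reference),
#'   `reference_kind`.
#' @export
gblup_predict <- function(fit, grms, y_train, train_ids, validation_ids,
                          reference = NULL,
                          reference_kind = "true_genetic_value") {
  if (inherits(grms, "grm")) grms <- list(grms)
  if (length(grms) != fit$n_components) {
    stop("number of GRMs does not match the fit components")
  }
  all_ids <- grms[[1]]$ids
  if (!all(c(train_ids, validation_ids) %in% all_ids)) {
    stop("individual id missing from GRM")
  }
  tr <- match(train_ids, all_ids)
  va <- match(validation_ids, all_ids)
  nt <- length(tr)
  Vtt <- diag(fit$sigma2_e, nt)
  Cvt <- matrix(0, length(va), nt)
  for (t in seq_along(grms)) {
    Vtt <- Vtt + fit$sigma2_g[t] * grms[[t]]$values[tr, tr]
    Cvt <- Cvt + fit$sigma2_g[t] * grms[[t]]$values[va, tr, drop = FALSE]
  }
  yt <- if (!is.null(names(y_train))) y_train[train_ids] else y_train
  gebv <- drop(Cvt %*% solve(Vtt, yt - fit$mu))
  names(gebv) <- validation_ids
  accuracy <- NA_real_
  if (!is.null(reference)) {
    ref <- if (!is.null(names(reference))) reference[validation_ids] else
      reference
    accuracy <- stats::cor(gebv, ref)
  }
  structure(list(gebv = gebv, accuracy = accuracy,
                 reference_kind = reference_kind),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("prediction_result: %d validation individuals, accuracy %s (%s)\n",
              length(x$gebv),
              ifelse(is.na(x$accuracy), "NA", sprintf("%.4f", x$accuracy)),
              x$reference_kind))
  invisible(x)
}
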