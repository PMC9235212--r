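#' Standardize a dosage matrix
#'
#' Column-standardizes the (mean-imputed) dosages as
#' `x_ij = (m_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))` with `p_j` the allele
#' frequency computed on the same individuals; columns therefore have mean
#' (approximately) zero and unit variance under Hardy-Weinberg sampling.
#'
#' @param panel a [genotype_panel()].
#' @return numeric n x m matrix with individual/snp dimnames.
#' @export
standardize_dosage <- function(panel) {
  d <- imputed_dosage(panel)
  p <- colMeans(d) / 2
  if (any(p <= 0 | p >= 1)) stop("monomorphic SNP: standardization undefined")
  X <- sweep(d, 2, 2 * p)
  sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
}

new_grm <- function(values, n_snps, ids, weighting, label = NA_character_) {
  dimnames(values) <- list(ids, ids)
  structure(list(values = values, n_snps = n_snps, ids = ids,
                 weighting = weighting, label = label), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, built from %d SNPs (%s weighting%s)\n",
              length(x$ids), x$n_snps, x$weighting,
              if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

#' Classical (uniformly weighted) genomic relationship matrix
#'
#' `G = X X' / N` on the standardized genotype matrix `X`, `N` the SNP count.
#'
#' @param X standardized matrix from [standardize_dosage()], or a
#'   [genotype_panel()] (standardized internally).
#' @param label optional SNP-subset label stored on the result.
#' @return object of class `grm`.
#' @export
grm_gcta <- function(X, label = NA_character_) {
  if (inherits(X, "genotype_panel")) X <- standardize_dosage(X)
  N <- ncol(X)
  if (N == 0) stop("no SNPs")
  new_grm(tcrossprod(X) / N, N, rownames(X), "uniform", label)
}

#' LD-weighted genomic relationship matrix
#'
#' `G = X W X' / N` with `W = diag(w_star)`, the scaled LD weights
#' (`sum(w_star) = N`) from [ldak_weights()].
#'
#' @param X standardized matrix from [standardize_dosage()].
#' @param w_star non-negative per-SNP scaled weights, `length(w_star) ==
#'   ncol(X)`.
#' @param label optional SNP-subset label.
#' @return object of class `grm`.
#' @export
grm_ldak <- function(X, w_star, label = NA_character_) {
  if (inherits(X, "genotype_panel")) X <- standardize_dosage(X)
  N <- ncol(X)
  if (N == 0) stop("no SNPs")
  if (length(w_star) != N) stop("weight vector length mismatch")
  if (any(w_star < 0)) stop("negative LD weight")
  Xw <- sweep(X, 2, sqrt(w_star), "*")
  new_grm(tcrossprod(Xw) / N, N, rownames(X), "ldak", label)
}

#' One GRM per LD level
#'
#' Builds the per-group GRMs of the LD-stratified multi-component model:
#' SNPs in each level form their own GRM with its own SNP count `N_t`. With
#' `weighting = "ldak"` the supplied weights are re-scaled within each group
#' so that they sum to `N_t`, keeping the expected scale of every component
#' matrix comparable.
#'
#' @param panel a [genotype_panel()].
#' @param levels integer group labels from [ld_stratify()] (one per SNP).
#' @param weighting `"uniform"` or `"ldak"`.
#' @param weights raw or scaled LD weights, required for `"ldak"`.
#' @return named list of `grm` objects, one per level in sorted label order.
#' @export
stratified_grms <- function(panel, levels, weighting = c("uniform", "ldak"),
                            weights = NULL) {
  weighting <- match.arg(weighting)
  stopifnot(length(levels) == n_snps(panel))
  X <- standardize_dosage(panel)
  labs <- sort(unique(levels))
  out <- lapply(labs, function(t) {
    idx <- which(levels == t)
    if (length(idx) == 0) stop("empty LD group ", t)
    Xt <- X[, idx, drop = FALSE]
    if (weighting == "uniform") {
      grm_gcta(Xt, label = paste0("ld_level ", t))
    } else {
      if (is.null(weights)) stop("weights required for ldak weighting")
      wt <- weights[idx] * length(idx) / sum(weights[idx])
      grm_ldak(Xt, wt, label = paste0("ld_level ", t))
    }
  })
  names(out) <- paste0("level", labs)
  out
}

#' Write / read a GRM in GCTA binary format
#'
#' `prefix.grm.bin` holds the lower triangle (including the diagonal) row by
#' row as 4-byte floats, `prefix.grm.N.bin` the per-pair SNP counts, and
#' `prefix.grm.id` the individual ids (family and within-family id columns).
#'
#' @param grm a `grm` object.
#' @param prefix output path prefix.
#' @return `prefix` invisibly ([write_grm_gcta()]); a `grm`
#'   ([read_grm_gcta()]).
#' @export
write_grm_gcta <- function(grm, prefix) {
  n <- length(grm$ids)
  lower <- grm$values[lower.tri(grm$values, diag = TRUE)]
  # lower.tri is column-major; GCTA stores row-major lower triangle, which
  # for a symmetric matrix equals the column-major upper triangle.
  upper <- t(grm$values)[lower.tri(grm$values, diag = TRUE)]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(upper), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$n_snps), n * (n + 1) / 2), con, size = 4)
  close(con)
  utils::write.table(data.frame(grm$ids, grm$ids),
                     paste0(prefix, ".grm.id"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(prefix)
}

#' @rdname write_grm_gcta
#' @export
read_grm_gcta <- function(prefix) {
  ids <- utils::read.table(paste0(prefix, ".grm.id"),
                           stringsAsFactors = FALSE)[[2]]
  n <- length(ids)
  np <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), what = "numeric", n = np,
                  size = 4)
  nsnp <- readBin(paste0(prefix, ".grm.N.bin"), what = "numeric", n = np,
                  size = 4)
  G <- matrix(0, n, n)
  G[lower.tri(G, diag = TRUE)] <- vals
  G <- t(G)
  G[lower.tri(G, diag = TRUE)] <- vals
  new_grm(G, as.integer(round(nsnp[1])), as.character(ids), "uniform")
}

#' Subset a GRM to a set of individuals
#'
#' @param grm a `grm` object.
#' @param ids character ids or integer indices of individuals to keep.
#' @return a `grm` over the requested individuals.
#' @export
subset_grm <- function(grm, ids) {
  if (is.character(ids)) {
    idx <- match(ids, grm$ids)
    if (anyNA(idx)) stop("individual id missing from GRM")
  } else {
    idx <- ids
  }
  new_grm(grm$values[idx, idx, drop = FALSE], grm$n_snps, grm$ids[idx],
          grm$weighting, grm$label)
}

# Remove a set of SNP columns from an existing GRM by downdating:
# G' = (N G - Xc Wc Xc') * s / (N - k), exact for uniform weighting
# (Wc = I, s = 1); for LDAK weighting the remaining weights are rescaled by
# s = (N - k) / (N - sum(wc)) so they again sum to the SNP count.
grm_exclude <- function(grm, Xc, wc = NULL) {
  k <- ncol(Xc)
  if (k == 0) return(grm)
  N <- grm$n_snps
  if (is.null(wc)) {
    vals <- (N * grm$values - tcrossprod(Xc)) / (N - k)
  } else {
    s <- (N - k) / (N - sum(wc))
    vals <- s * (N * grm$values -
                   tcrossprod(sweep(Xc, 2, sqrt(wc), "*"))) / (N - k)
  }
  new_grm(vals, N - k, grm$ids, grm$weighting, grm$label)
}
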