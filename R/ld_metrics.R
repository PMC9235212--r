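#' Pairwise LD between two SNPs
#'
#' Squared Pearson correlation of the (mean-imputed) dosage vectors of SNPs
#' `j` and `k`.
#'
#' @param panel a [genotype_panel()].
#' @param j,k SNP column indices.
#' @return r-squared in `[0, 1]`.
#' @export
pairwise_r2 <- function(panel, j, k) {
  idx <- sort(unique(c(j, k)))
  d <- imputed_dosage(subset_panel(panel, snps = idx))
  x <- d[, match(j, idx)]
  y <- d[, match(k, idx)]
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero-variance SNP")
  stats::cor(x, y)^2
}

# Per-chromosome list of SNP column indices, in map order.
chrom_index <- function(panel) {
  split(seq_len(n_snps(panel)), panel$map$chr)
}

# Column-standardized, mean-imputed dosage block; errors on monomorphic SNPs.
scaled_block <- function(panel, idx) {
  d <- imputed_dosage(subset_panel(panel, snps = idx))
  sds <- apply(d, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance SNP; run qc_filter first")
  scale(d)
}

# Closed-interval window bounds on sorted positions: for each j the indices
# [lo_j, hi_j] with |pos_k - pos_j| <= half.
window_bounds <- function(pos, half) {
  lo <- findInterval(pos - half - 0.5, pos) + 1L
  hi <- findInterval(pos + half + 0.5, pos)
  list(lo = lo, hi = hi)
}

#' Per-SNP LD score
#'
#' For SNP j, the sum of r-squared with all SNPs on the same chromosome whose
#' position lies within the window of length `window_bp` centered on j
#' (self pair included, so every score is at least 1). Windows never cross
#' chromosomes.
#'
#' @param panel a [genotype_panel()].
#' @param window_bp window length in bp (default 10 Mb).
#' @return numeric vector of LD scores, named by snp id.
#' @export
snp_ld_score <- function(panel, window_bp = 1e7) {
  n <- n_individuals(panel)
  out <- numeric(n_snps(panel))
  for (idx in chrom_index(panel)) {
    X <- scaled_block(panel, idx)
    C <- crossprod(X) / (n - 1)
    wb <- window_bounds(panel$map$pos[idx], window_bp / 2)
    out[idx] <- vapply(seq_along(idx), function(j) {
      sum(C[wb$lo[j]:wb$hi[j], j]^2)
    }, numeric(1))
  }
  names(out) <- panel$map$snp_id
  out
}

#' Regional mean LD score by sliding segments
#'
#' Segments of length `segment_bp` advance by `step_bp` along each chromosome
#' starting at the first SNP position; each segment's value is the mean LD
#' score of the SNPs it contains (closed interval), and each SNP's regional
#' score is the mean over all segments containing it. A SNP is always inside
#' at least one segment, so every SNP receives a value.
#'
#' @param panel a [genotype_panel()].
#' @param ld_scores per-SNP LD scores from [snp_ld_score()].
#' @param segment_bp segment length in bp (default 100 kb).
#' @param step_bp step between segment starts in bp (default 50 kb).
#' @return numeric vector of regional scores, named by snp id.
#' @export
regional_mean_ld_score <- function(panel, ld_scores, segment_bp = 1e5,
                                   step_bp = 5e4) {
  stopifnot(segment_bp > 0, step_bp > 0,
            length(ld_scores) == n_snps(panel))
  acc <- numeric(n_snps(panel))
  cnt <- numeric(n_snps(panel))
  for (idx in chrom_index(panel)) {
    pos <- panel$map$pos[idx]
    starts <- seq(min(pos), max(pos), by = step_bp)
    for (s in starts) {
      lo <- findInterval(s - 0.5, pos) + 1L
      hi <- findInterval(s + segment_bp + 0.5, pos)
      if (hi < lo) next
      seg <- idx[lo:hi]
      mval <- mean(ld_scores[seg])
      acc[seg] <- acc[seg] + mval
      cnt[seg] <- cnt[seg] + 1
    }
  }
  out <- ifelse(cnt > 0, acc / pmax(cnt, 1), ld_scores)
  names(out) <- panel$map$snp_id
  out
}

#' Stratify SNPs into LD-level groups
#'
#' Sorts SNPs by regional score in decreasing order and assigns contiguous
#' blocks of (almost) equal size to groups `1` (very high LD) through
#' `n_groups` (very low LD). When the SNP count is not divisible, the larger
#' groups sit at the high-LD end; ties in score are broken by original SNP
#' order, so the partition is deterministic.
#'
#' @param regional_scores per-SNP regional mean LD scores.
#' @param n_groups number of groups (default 5).
#' @return integer vector of group labels in `1..n_groups`.
#' @export
ld_stratify <- function(regional_scores, n_groups = 5) {
  m <- length(regional_scores)
  stopifnot(n_groups >= 2, m >= n_groups)
  sizes <- rep(m %/% n_groups, n_groups)
  rem <- m %% n_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  ord <- order(regional_scores, decreasing = TRUE)
  lev <- integer(m)
  lev[ord] <- rep(seq_len(n_groups), times = sizes)
  names(lev) <- names(regional_scores)
  lev
}

# Banded r-squared matrix of one chromosome block (dgCMatrix, symmetric
# content stored fully): entries r2_jk for |pos_j - pos_k| <= window_bp / 2.
r2_band <- function(X, pos, window_bp) {
  n <- nrow(X)
  mc <- ncol(X)
  C <- crossprod(X) / (n - 1)
  wb <- window_bounds(pos, window_bp / 2)
  lens <- wb$hi - wb$lo + 1L
  cols <- rep.int(seq_len(mc), lens)
  rows <- unlist(lapply(seq_len(mc), function(j) wb$lo[j]:wb$hi[j]),
                 use.names = FALSE)
  vals <- C[cbind(rows, cols)]^2
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(mc, mc))
}

#' LD (LDAK-style) SNP weights
#'
#' Solves, independently per chromosome, the non-negative least-squares
#' tagging system `min_w sum_j (1 - sum_k r2_jk w_k)^2` over `w >= 0`, where
#' the inner sum runs over the SNPs within `window_bp` of SNP j (self pair
#' included). The solution down-weights SNPs in high-LD regions so that each
#' SNP's weighted replicate tagging is close to 1. A small ridge penalty
#' `lambda * ||w||^2` selects the minimum-norm solution when the system is
#' degenerate (e.g. duplicated SNPs). Scaled weights satisfy
#' `sum(w_star) = N`, the panel SNP count.
#'
#' @param panel a [genotype_panel()].
#' @param window_bp weighting window in bp (default 1 Mb).
#' @param lambda ridge tie-break penalty (default 1e-4).
#' @param tol coordinate-descent convergence tolerance on the largest weight
#'   update (default 1e-7).
#' @param max_sweeps maximum coordinate-descent sweeps (default 100000).
#' @return list with `w` (raw weights), `w_star` (scaled to sum to the SNP
#'   count), `converged`, `sweeps`.
#' @export
ldak_weights <- function(panel, window_bp = 1e6, lambda = 1e-4, tol = 1e-7,
                         max_sweeps = 100000) {
  m <- n_snps(panel)
  w <- numeric(m)
  converged <- TRUE
  sweeps <- 0L
  for (idx in chrom_index(panel)) {
    X <- scaled_block(panel, idx)
    A <- r2_band(X, panel$map$pos[idx], window_bp)
    # ridge continuation: solve with decreasing penalties, warm-starting each
    # stage, so that near-degenerate systems (e.g. duplicated SNPs) reach the
    # minimum-norm solution of the final penalty quickly
    lambdas <- unique(c(pmax(c(1e-1, 1e-2, 1e-3), lambda), lambda))
    wj <- numeric(0)
    total_sweeps <- 0L
    for (lam in lambdas) {
      # intermediate stages only warm-start the next one: a loose tolerance
      # suffices there; the final stage applies the requested tolerance
      stage_tol <- if (lam == lambda) tol else max(tol, 1e-4)
      sol <- nnls_cd_sparse(A@i, A@p, A@x, length(idx),
                            rep(1, length(idx)), lam, stage_tol,
                            max_sweeps - total_sweeps, wj)
      total_sweeps <- total_sweeps + sol$sweeps
      wj <- sol$w
    }
    if (!sol$converged) {
      stop("NNLS weight solver did not converge within ", max_sweeps,
           " sweeps on chromosome ", panel$map$chr[idx[1]],
           "; increase max_sweeps or tol")
    }
    w[idx] <- wj
    converged <- converged && sol$converged
    sweeps <- max(sweeps, total_sweeps)
  }
  names(w) <- panel$map$snp_id
  list(w = w, w_star = w * m / sum(w), converged = converged, sweeps = sweeps)
}

#' Replicate tagging of SNPs
#'
#' `tagging_j = sum_k r2_jk * weight_k` over the SNPs within `window_bp` of
#' SNP j (self pair included). With unit weights this measures how many times
#' a SNP's signal is repeatedly counted in an unweighted GRM (minimum 1);
#' after LD weighting with the raw [ldak_weights()] it is close to 1 for
#' every SNP.
#'
#' @param panel a [genotype_panel()].
#' @param weights per-SNP weights; default all ones (unweighted tagging).
#' @param window_bp tagging window in bp (default 1 Mb).
#' @return numeric vector of tagging levels, named by snp id.
#' @export
replicate_tagging <- function(panel, weights = NULL, window_bp = 1e6) {
  m <- n_snps(panel)
  if (is.null(weights)) weights <- rep(1, m)
  if (length(weights) != m) stop("weight vector length mismatch")
  out <- numeric(m)
  for (idx in chrom_index(panel)) {
    X <- scaled_block(panel, idx)
    A <- r2_band(X, panel$map$pos[idx], window_bp)
    out[idx] <- as.numeric(A %*% weights[idx])
  }
  names(out) <- panel$map$snp_id
  out
}

#' Full LD profile of a panel
#'
#' Convenience wrapper computing, in one pass: per-SNP 10-Mb LD scores,
#' regional mean LD scores on 100-kb sliding segments, the LD-level
#' stratification, LD weights and replicate tagging (unweighted and
#' weighted).
#'
#' @param panel a [genotype_panel()].
#' @param score_window_bp LD-score window (default 10 Mb).
#' @param segment_bp,step_bp regional-score segment length and step.
#' @param n_groups number of LD levels (default 5).
#' @param weight_window_bp weighting/tagging window (default 1 Mb).
#' @param compute_weights solve the NNLS weights (default `TRUE`).
#' @return object of class `ld_profile`: data.frame with columns `snp_id`,
#'   `chr`, `pos`, `ld_score`, `regional_score`, `ld_level`, and when
#'   weights are computed, `w`, `w_star`, `tagging`, `tagging_weighted`.
#' @export
ld_profile <- function(panel, score_window_bp = 1e7, segment_bp = 1e5,
                       step_bp = 5e4, n_groups = 5, weight_window_bp = 1e6,
                       compute_weights = TRUE) {
  sc <- snp_ld_score(panel, score_window_bp)
  reg <- regional_mean_ld_score(panel, sc, segment_bp, step_bp)
  lev <- ld_stratify(reg, n_groups)
  out <- data.frame(snp_id = panel$map$snp_id, chr = panel$map$chr,
                    pos = panel$map$pos, ld_score = sc, regional_score = reg,
                    ld_level = lev, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (compute_weights) {
    wt <- ldak_weights(panel, weight_window_bp)
    out$w <- wt$w
    out$w_star <- wt$w_star
    out$tagging <- replicate_tagging(panel, NULL, weight_window_bp)
    out$tagging_weighted <- replicate_tagging(panel, wt$w, weight_window_bp)
  }
  class(out) <- c("ld_profile", "data.frame")
  out
}
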