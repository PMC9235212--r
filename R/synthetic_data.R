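#' Simulate a genotype panel with heterogeneous regional LD
#'
#' Generates diploid dosages from a haplotype-block model. Each chromosome is
#' partitioned into blocks whose lengths are drawn uniformly from
#' `block_length_range`; within a block, haplotype alleles follow a latent
#' first-order Gaussian autoregression whose adjacent-SNP correlation is drawn
#' once per block from `within_block_corr_range`, and the chain restarts
#' (correlation 0) at block boundaries. Two independent haplotypes are summed
#' per individual. Allele frequencies are drawn uniformly from `maf_range`;
#' SNP positions are distinct uniform draws, sorted within chromosome.
#'
#' The per-block correlation is drawn from a Beta(`s`, `s`) distribution
#' rescaled to `within_block_corr_range`, with
#' `s = within_block_corr_shape`. Shapes below 1 are U-shaped, concentrating
#' blocks at the weakly and strongly correlated extremes; this produces the
#' severalfold variation of the regional mean LD score along the genome that
#' is the experimental variable this package studies. At the default
#' settings the ratio of the 90th to the 10th percentile of the regional
#' mean LD score is at least 3 for panels of around 1000 individuals and
#' 10000 SNPs.
#'
#' @param n_individuals number of individuals.
#' @param n_snps total number of SNPs (split as evenly as possible across
#'   chromosomes).
#' @param n_chromosomes number of chromosomes (default 3).
#' @param chrom_length chromosome length in bp (default 40 Mb).
#' @param block_length_range bp range for block lengths (default 100 kb-2 Mb).
#' @param within_block_corr_range range in `[0, 1)` for the per-block latent
#'   adjacent-SNP correlation (default `c(0.1, 0.999)`).
#' @param within_block_corr_shape Beta shape for the per-block correlation
#'   draw within `within_block_corr_range`; 1 is uniform, values below 1 are
#'   U-shaped (default 0.35).
#' @param maf_range range of allele frequencies (default `c(0.01, 0.5)`).
#' @param seed integer seed; the same seed yields a bit-identical panel.
#' @return a [genotype_panel()].
#' @export
simulate_genotypes <- function(n_individuals, n_snps, n_chromosomes = 3,
                               chrom_length = 4e7,
                               block_length_range = c(1e5, 2e6),
                               within_block_corr_range = c(0.1, 0.999),
                               within_block_corr_shape = 0.35,
                               maf_range = c(0.01, 0.5), seed = 1) {
  stopifnot(n_individuals >= 2, n_snps >= 1, n_chromosomes >= 1,
            chrom_length >= 1,
            length(block_length_range) == 2,
            all(block_length_range > 0),
            length(within_block_corr_range) == 2,
            all(within_block_corr_range >= 0),
            all(within_block_corr_range < 1),
            within_block_corr_shape > 0,
            all(maf_range > 0), all(maf_range < 1))
  per_chr <- rep(n_snps %/% n_chromosomes, n_chromosomes)
  extra <- n_snps %% n_chromosomes
  if (extra > 0) per_chr[seq_len(extra)] <- per_chr[seq_len(extra)] + 1
  if (any(per_chr > chrom_length)) {
    stop("chromosome too short to place distinct SNP positions")
  }
  n <- n_individuals
  with_seed(seed, {
    dosage <- matrix(0, nrow = n, ncol = n_snps)
    chr_lab <- integer(n_snps)
    pos_all <- integer(n_snps)
    col0 <- 0L
    for (ch in seq_len(n_chromosomes)) {
      mc <- per_chr[ch]
      if (mc == 0) next
      pos <- sort(sample.int(chrom_length, mc))
      # block boundaries: cumulative lengths until the chromosome is covered
      bl <- numeric(0)
      while (sum(bl) < chrom_length) {
        bl <- c(bl, stats::runif(16, block_length_range[1],
                                 block_length_range[2]))
      }
      edges <- cumsum(bl)
      block <- findInterval(pos - 1, c(0, edges), rightmost.closed = FALSE)
      rho_block <- within_block_corr_range[1] +
        diff(within_block_corr_range) *
          stats::qbeta(stats::runif(length(edges) + 1),
                       within_block_corr_shape, within_block_corr_shape)
      f <- stats::runif(mc, maf_range[1], maf_range[2])
      z1 <- stats::rnorm(n)
      z2 <- stats::rnorm(n)
      for (j in seq_len(mc)) {
        new_block <- j == 1 || block[j] != block[j - 1]
        rho <- if (new_block) 0 else rho_block[block[j]]
        for (try in seq_len(50)) {
          e1 <- stats::rnorm(n)
          e2 <- stats::rnorm(n)
          c1 <- rho * z1 + sqrt(1 - rho^2) * e1
          c2 <- rho * z2 + sqrt(1 - rho^2) * e2
          thr <- stats::qnorm(f[j])
          dj <- as.numeric(c1 < thr) + as.numeric(c2 < thr)
          if (stats::var(dj) > 0) break
        }
        z1 <- c1
        z2 <- c2
        dosage[, col0 + j] <- dj
      }
      chr_lab[col0 + seq_len(mc)] <- ch
      pos_all[col0 + seq_len(mc)] <- pos
      col0 <- col0 + mc
    }
    map <- data.frame(snp_id = sprintf("snp_%d_%d", chr_lab,
                                       seq_len(n_snps)),
                      chr = chr_lab, pos = pos_all,
                      stringsAsFactors = FALSE)
    genotype_panel(dosage, map)
  })
}

#' Classify SNPs by tagging level
#'
#' Uses per-SNP LD scores (sum of r-squared over a 10-Mb window, see
#' [snp_ld_score()]) to define overlapping quantile classes: the bottom 20%
#' and 40% of scores are the very weakly and weakly tagged SNPs, the top 40%
#' and 20% the strongly and very strongly tagged SNPs; `average` denotes the
#' whole genome. Ties are broken by (score, chromosome, position) order so
#' class sizes always equal the quantile counts.
#'
#' @param panel a [genotype_panel()].
#' @param ld_scores numeric vector of per-SNP LD scores aligned with the panel
#'   map.
#' @return object of class `tagging_classes`: list with `members` (named list
#'   of SNP index vectors) and `ld_scores`.
#' @export
classify_tagging <- function(panel, ld_scores) {
  m <- n_snps(panel)
  stopifnot(length(ld_scores) == m)
  if (m < 5) stop("need at least 5 SNPs to form tagging quantiles")
  ord <- order(ld_scores, panel$map$chr, panel$map$pos)
  k20 <- floor(0.2 * m)
  k40 <- floor(0.4 * m)
  members <- list(
    very_weak = sort(ord[seq_len(k20)]),
    weak = sort(ord[seq_len(k40)]),
    average = seq_len(m),
    strong = sort(ord[seq(m - k40 + 1, m)]),
    very_strong = sort(ord[seq(m - k20 + 1, m)])
  )
  structure(list(members = members, ld_scores = ld_scores),
            class = "tagging_classes")
}

#' Members of a tagging class
#' @param classes a [classify_tagging()] result.
#' @param class one of `"very_weak"`, `"weak"`, `"average"`, `"strong"`,
#'   `"very_strong"`.
#' @return integer vector of SNP indices.
#' @export
tagging_members <- function(classes, class) {
  stopifnot(inherits(classes, "tagging_classes"))
  cls <- match.arg(class, names(classes$members))
  classes$members[[cls]]
}

#' Select causal variants from a tagging class
#'
#' Samples `m` SNP indices uniformly without replacement from the requested
#' tagging class (the whole panel for `"average"`).
#'
#' @param panel a [genotype_panel()].
#' @param classes a [classify_tagging()] result, or `NULL` when
#'   `class = "average"`.
#' @param class tagging class to sample from.
#' @param m number of causal variants (default 100).
#' @param seed integer seed.
#' @return sorted integer vector of causal SNP indices.
#' @export
select_causal <- function(panel, classes = NULL, class = "average", m = 100,
                          seed = 1) {
  pool <- if (class == "average" && is.null(classes)) {
    seq_len(n_snps(panel))
  } else {
    tagging_members(classes, class)
  }
  if (m > length(pool)) {
    stop(sprintf("requested %d causal variants from a class of %d SNPs",
                 m, length(pool)))
  }
  with_seed(seed, sort(sample(pool, m)))
}

#' Simulate a quantitative trait from causal variants
#'
#' Allele substitution effects follow the equal-contribution scheme
#' `a_i = (2 p_i (1 - p_i))^(-1/2) * delta_g / sqrt(m)` with
#' `delta_g = sqrt(var_p * h2)`, so every causal variant contributes exactly
#' `delta_g^2 / m` to the genetic variance (the assumption built into the
#' standardized GRM). Environmental effects are drawn from
#' `N(0, (1 - h2) * var_p)` and the phenotype is the sum of the causal-variant
#' effects and the environmental effect.
#'
#' By default each effect is multiplied by an independent random sign, which
#' leaves the per-variant variance contributions unchanged but avoids
#' inflation of `var(tbv)` when causal variants are in mutual LD; set
#' `positive_effects = TRUE` for strictly positive effects.
#'
#' @param panel a [genotype_panel()].
#' @param causal integer vector of causal SNP indices.
#' @param h2 heritability in `(0, 1]` (default 0.8).
#' @param var_p phenotypic variance (default 1).
#' @param seed integer seed.
#' @param positive_effects keep all effects positive (default `FALSE`).
#' @return object of class `simulated_trait`: list with `phenotype`, `tbv`,
#'   `env` (all named by individual id), `causal`, `effects`, `h2`, `var_p`.
#' @export
simulate_phenotypes <- function(panel, causal, h2 = 0.8, var_p = 1, seed = 1,
                                positive_effects = FALSE) {
  stopifnot(h2 > 0, h2 <= 1, var_p > 0, length(causal) >= 1)
  m <- length(causal)
  p <- allele_freq(panel)[causal]
  if (any(p <= 0 | p >= 1)) stop("causal SNP is monomorphic")
  delta_g <- sqrt(var_p * h2)
  a <- (2 * p * (1 - p))^(-1 / 2) * delta_g / sqrt(m)
  with_seed(seed, {
    if (!positive_effects) {
      a <- a * sample(c(-1, 1), m, replace = TRUE)
    }
    d <- imputed_dosage(subset_panel(panel, snps = causal))
    tbv <- drop(d %*% a)
    e <- stats::rnorm(n_individuals(panel), 0, sqrt((1 - h2) * var_p))
    y <- tbv + e
    names(y) <- names(tbv) <- names(e) <- panel$ids
    structure(list(phenotype = y, tbv = tbv, env = e, causal = causal,
                   effects = a, h2 = h2, var_p = var_p),
              class = "simulated_trait")
  })
}

#' Build a medium-density panel by even SNP thinning
#'
#' Selects `target_count` SNPs at evenly spaced index ranks within each
#' chromosome, with per-chromosome counts proportional to chromosome SNP
#' counts (largest-remainder allocation); order is preserved.
#'
#' @param panel a [genotype_panel()].
#' @param target_count number of SNPs to retain.
#' @return a [genotype_panel()].
#' @export
build_medium_panel <- function(panel, target_count) {
  m <- n_snps(panel)
  stopifnot(target_count > 0, target_count <= m)
  chrs <- unique(panel$map$chr)
  mc <- vapply(chrs, function(ch) sum(panel$map$chr == ch), integer(1))
  exact <- target_count * mc / m
  kc <- floor(exact)
  rem <- target_count - sum(kc)
  if (rem > 0) {
    frac_ord <- order(exact - kc, decreasing = TRUE)
    kc[frac_ord[seq_len(rem)]] <- kc[frac_ord[seq_len(rem)]] + 1
  }
  keep <- integer(0)
  for (i in seq_along(chrs)) {
    if (kc[i] == 0) next
    idx <- which(panel$map$chr == chrs[i])
    stride <- floor(mc[i] / kc[i])
    keep <- c(keep, idx[1 + stride * (seq_len(kc[i]) - 1)])
  }
  subset_panel(panel, snps = sort(keep))
}

#' Remove causal variants from a panel
#'
#' @param panel a [genotype_panel()].
#' @param causal integer vector of SNP indices to drop; may be empty.
#' @return a [genotype_panel()] without the causal columns.
#' @export
drop_causal <- function(panel, causal) {
  if (length(causal) == 0) return(panel)
  m <- n_snps(panel)
  causal <- as.integer(causal)
  if (any(causal < 1 | causal > m)) stop("causal index out of range")
  subset_panel(panel, snps = setdiff(seq_len(m), causal))
}
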