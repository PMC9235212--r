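# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# Subset individuals, then keep the first `m` SNPs still polymorphic.
polymorphic_subset <- function(panel, individuals, m) {
  p <- subset_panel(panel, individuals = individuals)
  ok <- which(apply(p$dosage, 2, stats::var) > 0)
  subset_panel(p, snps = ok[seq_len(m)])
}

# Small panel for fast unit tests: 2 chromosomes, mixed LD.
panel_small <- function() {
  fixture("panel_small",
          simulate_genotypes(200, 600, n_chromosomes = 2, chrom_length = 8e6,
                             seed = 11))
}

# Tiny low-LD panel for REML/GBLUP oracle tests.
panel_tiny <- function(n, m, seed) {
  simulate_genotypes(n, m, n_chromosomes = 1, chrom_length = 1e7,
                     within_block_corr_range = c(0, 0.3), seed = seed)
}

# Study-scale panel and LD profile shared by the acceptance-criteria tests.
panel_study <- function() {
  fixture("panel_study", simulate_genotypes(1000, 10000, seed = 20260101))
}

profile_study <- function() {
  fixture("profile_study", ld_profile(panel_study()))
}

classes_study <- function() {
  fixture("classes_study",
          classify_tagging(panel_study(), profile_study()$ld_score))
}

eigen_study <- function() {
  fixture("eigen_study",
          grm_eigen(grm_gcta(standardize_dosage(panel_study()))))
}

strat_grms_study <- function() {
  fixture("strat_grms_study",
          stratified_grms(panel_study(), profile_study()$ld_level))
}

# Independent restricted log-likelihood (REML) oracle: intercept-only fixed
# effect, V = sum_t theta_t G_t + theta_e I, profiled directly from the
# textbook formula. Used to cross-check the iterative fitter.
oracle_restricted_logL <- function(y, G_list, theta) {
  n <- length(y)
  T_ <- length(G_list)
  V <- diag(theta[T_ + 1], n)
  for (t in seq_len(T_)) V <- V + theta[t] * G_list[[t]]
  Vi <- solve(V)
  X <- matrix(1, n, 1)
  XVX <- drop(t(X) %*% Vi %*% X)
  P <- Vi - (Vi %*% X %*% t(X) %*% Vi) / XVX
  -0.5 * (determinant(V)$modulus[1] + log(XVX) + drop(t(y) %*% P %*% y))
}
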