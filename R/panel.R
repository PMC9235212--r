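#' Construct a genotype panel
#'
#' A `genotype_panel` holds a diploid dosage matrix (individuals x SNPs, entries
#' 0/1/2 or `NA`) together with the SNP map (chromosome, base-pair position,
#' alleles). Positions must be strictly increasing within each chromosome.
#'
#' @param dosage numeric matrix, individuals in rows and SNPs in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param map data.frame with columns `snp_id`, `chr` (integer chromosome
#'   label), `pos` (1-based bp position) and optionally `a1`, `a2` (allele
#'   codes; default `"A"`/`"B"`).
#' @param ids character vector of individual ids; defaults to the dosage row
#'   names or `ind1..indn`.
#' @return An object of class `genotype_panel`: a list with elements `dosage`,
#'   `map`, `ids`.
#' @export
genotype_panel <- function(dosage, map, ids = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(ids)) {
    ids <- rownames(dosage)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(dosage)))
  }
  stopifnot(is.data.frame(map), nrow(map) == ncol(dosage))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (is.null(map$snp_id)) map$snp_id <- paste0("snp", seq_len(nrow(map)))
  if (is.null(map$a1)) map$a1 <- "A"
  if (is.null(map$a2)) map$a2 <- "B"
  map$snp_id <- as.character(map$snp_id)
  map$chr <- as.integer(map$chr)
  map$pos <- as.integer(map$pos)
  rownames(map) <- NULL
  rownames(dosage) <- ids
  colnames(dosage) <- map$snp_id
  panel <- structure(list(dosage = dosage, map = map, ids = as.character(ids)),
                     class = "genotype_panel")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  d <- panel$dosage
  ok <- is.na(d) | d == 0 | d == 1 | d == 2
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or NA")
  if (anyDuplicated(panel$ids)) stop("individual ids must be unique")
  if (anyDuplicated(panel$map$snp_id)) stop("snp ids must be unique")
  for (ch in unique(panel$map$chr)) {
    p <- panel$map$pos[panel$map$chr == ch]
    if (any(diff(p) <= 0)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs, %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chr))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing rate %.4f, bp span per chromosome %s\n", miss,
              paste(tapply(x$map$pos, x$map$chr, function(p) max(p) - min(p)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Number of individuals / SNPs in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_individuals <- function(panel) nrow(panel$dosage)

#' @rdname n_individuals
#' @export
n_snps <- function(panel) ncol(panel$dosage)

#' Allele frequencies of a panel
#'
#' Frequency of the counted (A1) allele at each SNP, computed on non-missing
#' dosages: `mean(dosage)/2`.
#'
#' @param panel a `genotype_panel`.
#' @return numeric vector of length `n_snps(panel)`, named by snp id.
#' @export
allele_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}

#' Subset a panel by SNP or individual index
#'
#' @param panel a `genotype_panel`.
#' @param snps integer/logical index of SNPs to keep (in map order).
#' @param individuals integer/logical/character index of individuals to keep.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, snps = NULL, individuals = NULL) {
  d <- panel$dosage
  map <- panel$map
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    map <- map[snps, , drop = FALSE]
    rownames(map) <- NULL
  }
  ids <- panel$ids
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, ids)
    d <- d[individuals, , drop = FALSE]
    ids <- ids[individuals]
  }
  genotype_panel(d, map, ids)
}

#' Mean-impute missing dosages
#'
#' Replaces missing entries of SNP j with `2*p_j`, the dosage mean on the
#' non-missing individuals; the convention used for all downstream LD and GRM
#' computation.
#'
#' @param panel a `genotype_panel`.
#' @return numeric matrix of imputed dosages (not a panel: imputed values are
#'   fractional).
#' @export
imputed_dosage <- function(panel) {
  d <- panel$dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministically mix a master seed with stream indices; result < 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in idx) {
    x <- (x * 48271 + as.double(i) * 7919 + 1) %% 2147483647
  }
  as.integer(x)
}
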