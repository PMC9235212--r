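#' Read a PLINK 1 binary genotype file set
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` (SNP-major v1 BED, magic
#' bytes `0x6c 0x1b 0x01`). Dosages count the BIM A1 allele: the 2-bit codes
#' 00/10/11 decode to dosage 2/1/0 and 01 to missing.
#'
#' @param prefix path prefix (without extension).
#' @return a [genotype_panel()].
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop("missing PLINK file: ", f)
  }
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chr", "snp_id", "cm", "pos",
                                            "a1", "a2"))
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("bad magic bytes: not a PLINK 1 .bed file")
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bps <- ceiling(n / 4)                      # bytes per SNP
  if (length(raw) - 3 != bps * m) {
    stop(sprintf(".bed payload is %d bytes; expected %d for %d individuals x %d SNPs",
                 length(raw) - 3, bps * m, n, m))
  }
  payload <- as.integer(raw[-(1:3)])
  codes <- matrix(NA_integer_, nrow = 4 * bps, ncol = m)
  for (s in 0:3) {
    codes[seq(s + 1, 4 * bps, by = 4), ] <-
      bitwAnd(bitwShiftR(matrix(payload, nrow = bps), 2 * s), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  lut <- c(2, NA, 1, 0)
  dosage <- matrix(lut[codes + 1L], nrow = n, ncol = m)
  map <- data.frame(snp_id = as.character(bim_df$snp_id),
                    chr = as.integer(bim_df$chr),
                    pos = as.integer(bim_df$pos),
                    a1 = as.character(bim_df$a1),
                    a2 = as.character(bim_df$a2),
                    stringsAsFactors = FALSE)
  genotype_panel(dosage, map, ids = as.character(fam_df[[2]]))
}

#' Write a genotype panel as a PLINK 1 binary file set
#'
#' @param panel a [genotype_panel()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  validate_panel(panel)
  n <- n_individuals(panel)
  m <- n_snps(panel)
  fam <- data.frame(fid = panel$ids, iid = panel$ids, pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(chr = panel$map$chr, snp_id = panel$map$snp_id, cm = 0,
                    pos = panel$map$pos, a1 = panel$map$a1, a2 = panel$map$a2)
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # dosage (of A1) -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code_lut <- c(3L, 2L, 0L)
  codes <- matrix(1L, nrow = 4 * ceiling(n / 4), ncol = m)
  d <- panel$dosage
  cd <- matrix(code_lut[d + 1L], nrow = n, ncol = m)
  cd[is.na(cd)] <- 1L
  codes[seq_len(n), ] <- cd
  bps <- ceiling(n / 4)
  bytes <- matrix(0L, nrow = bps, ncol = m)
  for (s in 0:3) {
    bytes <- bytes + bitwShiftL(codes[seq(s + 1, 4 * bps, by = 4), ,
                                      drop = FALSE], 2 * s)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson 1-df chi-square on observed vs expected genotype counts under the
#' allele frequency estimated from the same counts.
#'
#' @param n0,n1,n2 counts of individuals with dosage 0, 1, 2.
#' @return list with `statistic` and `p_value`.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(list(statistic = NA_real_, p_value = 1))
  p <- (2 * n2 + n1) / (2 * n)       # frequency of the counted allele
  q <- 1 - p
  e <- n * c(q^2, 2 * p * q, p^2)
  o <- c(n0, n1, n2)
  if (any(e == 0)) return(list(statistic = 0, p_value = 1))  # monomorphic
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Quality-control filter for a genotype panel
#'
#' Removes SNPs with minor allele frequency below `maf_min`, genotype call
#' rate below `callrate_min`, Hardy-Weinberg chi-square p-value below
#' `hwe_p_min`, or that are monomorphic (standardization is undefined at
#' p in {0,1}, so monomorphic SNPs are removed even when the MAF filter is
#' disabled with `maf_min = 0`).
#'
#' @param panel a [genotype_panel()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param callrate_min minimum genotype call rate (default 0.9).
#' @param hwe_p_min minimum HWE p-value (default 1e-6).
#' @return list of class `qc_result` with elements `panel` (retained SNPs) and
#'   `report` (counts removed per criterion).
#' @export
qc_filter <- function(panel, maf_min = 0.01, callrate_min = 0.9,
                      hwe_p_min = 1e-6) {
  if (n_snps(panel) == 0) stop("empty panel")
  d <- panel$dosage
  n <- nrow(d)
  callrate <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    hwe_test(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 2, na.rm = TRUE))$p_value
  }, numeric(1))
  fail_call <- callrate < callrate_min
  fail_maf <- maf < maf_min
  fail_mono <- maf == 0
  fail_hwe <- hwe_p < hwe_p_min
  keep <- !(fail_call | fail_maf | fail_mono | fail_hwe)
  if (!any(keep)) stop("QC removed all SNPs")
  report <- list(n_input = ncol(d),
                 n_retained = sum(keep),
                 removed_callrate = sum(fail_call),
                 removed_maf = sum(fail_maf & !fail_call),
                 removed_monomorphic = sum(fail_mono & !fail_call & !fail_maf),
                 removed_hwe = sum(fail_hwe & !fail_call & !fail_maf &
                                     !fail_mono),
                 thresholds = c(maf_min = maf_min, callrate_min = callrate_min,
                                hwe_p_min = hwe_p_min))
  out <- subset_panel(panel, snps = which(keep))
  structure(list(panel = out, report = report), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("QC: %d of %d SNPs retained\n", r$n_retained, r$n_input))
  cat(sprintf("  removed: call rate %d, MAF %d, monomorphic %d, HWE %d\n",
              r$removed_callrate, r$removed_maf, r$removed_monomorphic,
              r$removed_hwe))
  invisible(x)
}

#' Read / write a phenotype table
#'
#' Whitespace-delimited text with columns `id`, `value` and optionally
#' `reliability`; lines starting with `#` are treated as header/comments.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `value` and, when present,
#'   `reliability`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("id", "value")
  if (ncol(df) >= 3) names(df)[3] <- "reliability"
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) stop("duplicate individual ids in phenotype table")
  df
}

#' @rdname read_phenotypes
#' @param df data.frame with columns `id`, `value` and optionally
#'   `reliability`.
#' @export
write_phenotypes <- function(df, path) {
  cols <- intersect(c("id", "value", "reliability"), names(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(cols, collapse = " ")), con)
  utils::write.table(df[, cols], con, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
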