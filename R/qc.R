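#' Genotype matrix container
#'
#' Holds an animals x markers genotype matrix coded -1/0/1 (with `NA` for
#' missing calls), its marker map, animal ids, and per-marker allele
#' frequencies.  The frequency slot `freq` is the frequency of the allele
#' counted positively by the -1/0/1 coding; `maf()` of a marker is
#' `min(freq, 1 - freq)`.
#'
#' @param genotypes Numeric or integer matrix, animals in rows, markers in
#'   columns, values in -1/0/1 or `NA`.
#' @param map Data frame with columns `marker`, `chrom`, `pos` (and
#'   optionally `genic`), one row per genotype column.
#' @param ids Animal identifiers (defaults to row names or 1..n).
#' @return Object of class `genotype_matrix`: list with elements
#'   `genotypes`, `map`, `ids`, `freq`.
#' @export
genotype_matrix <- function(genotypes, map, ids = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(map), all(c("marker", "chrom", "pos") %in% names(map)),
            nrow(map) == ncol(genotypes))
  if (anyDuplicated(map$marker)) stop("marker names must be unique")
  rng <- range(genotypes, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1 || rng[2] > 1))
    stop("genotype codes must lie in [-1, 1] (-1/0/1 coding, mean-imputed values allowed)")
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(genotypes))) rownames(genotypes)
           else seq_len(nrow(genotypes))
  }
  stopifnot(length(ids) == nrow(genotypes))
  colnames(genotypes) <- map$marker
  freq <- colMeans(genotypes + 1, na.rm = TRUE) / 2
  structure(list(genotypes = genotypes, map = map, ids = ids, freq = freq),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$genotypes), "animals x",
      ncol(x$genotypes), "markers on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing rate %.3f, median MAF %.3f\n", miss,
              stats::median(pmin(x$freq, 1 - x$freq), na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Per-marker call rate, allele frequency and Hardy-Weinberg statistics
#'
#' Call rate is the fraction of non-missing genotypes; MAF is the minor
#' allele frequency computed from non-missing genotypes only; the HWE test is
#' the 1-df chi-square goodness of fit of observed genotype counts to
#' Hardy-Weinberg expectations at the sample allele frequency.  Markers with
#' no calls at all get call rate 0 and `NA` frequency/HWE values.
#'
#' @param genotypes A [genotype_matrix()].
#' @return Data frame (class `qc_stats`) with columns `marker`, `chrom`,
#'   `pos`, `call_rate`, `maf`, `hwe_chisq`, `hwe_p`.
#' @export
compute_marker_stats <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- genotypes$genotypes
  if (nrow(g) < 1) stop("at least one animal is required")
  n_obs <- colSums(!is.na(g))
  call_rate <- n_obs / nrow(g)
  # allele frequency from all non-missing entries (mean-imputed dosages
  # contribute their expectation, so QC after imputation sees the same f);
  # HWE genotype counts use hard -1/0/1 calls only
  f <- ifelse(n_obs > 0, colMeans(g + 1, na.rm = TRUE) / 2, NA_real_)
  maf <- pmin(f, 1 - f)
  n_aa <- colSums(g == -1, na.rm = TRUE)
  n_ab <- colSums(g == 0, na.rm = TRUE)
  n_bb <- colSums(g == 1, na.rm = TRUE)
  hwe <- mapply(function(a, h, b) {
    if (a + h + b == 0) return(c(NA_real_, NA_real_))
    unlist(hwe_test(c(a, h, b)))
  }, n_aa, n_ab, n_bb)
  out <- data.frame(marker = genotypes$map$marker,
                    chrom = genotypes$map$chrom,
                    pos = genotypes$map$pos,
                    call_rate = call_rate, maf = maf,
                    hwe_chisq = hwe[1, ], hwe_p = hwe[2, ])
  rownames(out) <- NULL
  class(out) <- c("qc_stats", class(out))
  out
}

#' Hardy-Weinberg chi-square test from genotype counts
#'
#' One-degree-of-freedom goodness-of-fit statistic comparing observed
#' genotype counts `(n_aa, n_ab, n_bb)` to the Hardy-Weinberg expectations at
#' the sample allele frequency.  Monomorphic markers return statistic 0 and
#' p-value 1 by convention.
#'
#' @param counts Integer vector of length 3: homozygote, heterozygote,
#'   other-homozygote counts.
#' @return List with `statistic` and `p.value`.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be at least 1")
  f <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (f <= 0 || f >= 1) return(list(statistic = 0, p.value = 1))
  e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  stat <- sum((counts - e)^2 / e)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Filter markers by call rate, MAF and Hardy-Weinberg equilibrium
#'
#' Applies the three filters to the unfiltered per-marker statistics, in the
#' order call rate, MAF, HWE; a marker failing several criteria is attributed
#' to the first.  Surviving markers keep their original map order and any
#' remaining missing genotypes are imputed (marker mean by default, which
#' preserves the allele frequency; zero-fill optionally).
#'
#' @param genotypes A [genotype_matrix()].
#' @param call_rate_min Minimum call rate; markers strictly below are removed.
#' @param maf_min Minimum minor allele frequency; markers strictly below (or
#'   with undefined MAF) are removed.
#' @param hwe_alpha Markers with HWE p-value strictly below this level are
#'   removed.
#' @param impute Missing-genotype fill for survivors: `"mean"` or `"zero"`.
#' @return List of class `qc_result` with elements `genotypes` (filtered
#'   `genotype_matrix`, imputed, numeric codes), `report` (per-marker
#'   data frame with `pass` and `fail_reason`), `per_chromosome` (surviving
#'   marker counts), and the thresholds used.
#' @export
apply_filters <- function(genotypes, call_rate_min = 0.90, maf_min = 0.05,
                          hwe_alpha = 1e-6, impute = c("mean", "zero")) {
  impute <- match.arg(impute)
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            maf_min >= 0, maf_min <= 0.5, hwe_alpha >= 0, hwe_alpha <= 1)
  stats_df <- compute_marker_stats(genotypes)
  reason <- rep(NA_character_, nrow(stats_df))
  fail_cr <- stats_df$call_rate < call_rate_min
  fail_maf <- is.na(stats_df$maf) | stats_df$maf < maf_min
  fail_hwe <- !is.na(stats_df$hwe_p) & stats_df$hwe_p < hwe_alpha
  reason[fail_hwe] <- "hwe"
  reason[fail_maf] <- "maf"
  reason[fail_cr] <- "call_rate"   # first-failing-reason wins
  keep <- is.na(reason)
  if (!any(keep)) stop("all markers removed by QC filters: empty panel")
  g <- genotypes$genotypes[, keep, drop = FALSE]
  if (anyNA(g)) {
    fill <- if (impute == "mean") colMeans(g, na.rm = TRUE) else rep(0, ncol(g))
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- fill[idx[, 2]]
  }
  filtered <- genotype_matrix(g, genotypes$map[keep, , drop = FALSE],
                              ids = genotypes$ids)
  report <- cbind(stats_df,
                  pass = keep,
                  fail_reason = ifelse(keep, "", reason))
  per_chrom <- as.data.frame(table(chrom = filtered$map$chrom),
                             responseName = "n_markers")
  per_chrom$chrom <- as.integer(as.character(per_chrom$chrom))
  structure(list(genotypes = filtered, report = report,
                 per_chromosome = per_chrom,
                 thresholds = list(call_rate_min = call_rate_min,
                                   maf_min = maf_min, hwe_alpha = hwe_alpha,
                                   impute = impute)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  rem <- table(factor(x$report$fail_reason[!x$report$pass],
                      levels = c("call_rate", "maf", "hwe")))
  cat("marker QC:", sum(x$report$pass), "of", nrow(x$report),
      "markers retained\n  removed:",
      paste(names(rem), rem, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
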