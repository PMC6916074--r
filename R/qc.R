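# Variant quality control: exact Hardy-Weinberg test, MAF/call-rate filters,
# and stratification principal components.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts no more probable than
#' the observed one under random mating (plain exact tail, no mid-p
#' adjustment). Monomorphic SNPs have a single attainable configuration and
#' return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return Two-sided exact p-value in `(0, 1]`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (length(counts) != 3L || any(counts < 0) || any(counts != floor(counts)))
    stop_param("counts", "must be three non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("empty genotype data: all genotype counts are zero",
                  call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)        # monomorphic
  # attainable heterozygote counts share parity with the allele count
  h_max <- min(nA, na)
  h <- seq(h_max %% 2, h_max, by = 2)
  # log P(h | n, nA) up to the common normalizing constant:
  # P ~ n! 2^h / (nAA! h! naa!)
  lp <- h * log(2) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_Aa, h)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

genotype_counts <- function(dosage_col) {
  c(n_AA = sum(dosage_col == 2L, na.rm = TRUE),
    n_Aa = sum(dosage_col == 1L, na.rm = TRUE),
    n_aa = sum(dosage_col == 0L, na.rm = TRUE))
}

#' Variant quality control filter
#'
#' Retains exactly the SNPs with minor allele frequency strictly greater than
#' `maf_min`, exact Hardy-Weinberg p-value strictly greater than `hwe_p_min`
#' (computed on complete genotypes), and genotype call rate strictly greater
#' than `call_rate_min`. A SNP may fail several criteria and is tallied under
#' each; `n_pass` plus the number of SNPs failing at least one criterion
#' equals the input count.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min,hwe_p_min,call_rate_min thresholds (strict inequalities).
#' @param keep_ids if `TRUE`, per-criterion failing variant-id lists are
#'   attached to the report.
#' @return A list with `panel` (the filtered [genotype_panel()]) and `report`
#'   (class `qc_report`).
#' @export
qc_filter <- function(panel, maf_min = 0.01, hwe_p_min = 1e-3,
                      call_rate_min = 0.95, keep_ids = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- ncol(panel$dosage)
  if (m == 0L || length(panel$sample_id) == 0L)
    stop("empty genotype panel", call. = FALSE)
  check_prob(maf_min, "maf_min", hi_open = TRUE)
  check_prob(hwe_p_min, "hwe_p_min", hi_open = TRUE)
  check_prob(call_rate_min, "call_rate_min")

  n <- nrow(panel$dosage)
  call_rate <- colMeans(!is.na(panel$dosage))
  freq <- colMeans(panel$dosage, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  maf <- pmin(freq, 1 - freq)
  hwe_p <- vapply(seq_len(m), function(j) {
    cc <- genotype_counts(panel$dosage[, j])
    if (sum(cc) == 0) return(1)
    hwe_test(cc[1], cc[2], cc[3])
  }, numeric(1))

  fail_maf <- maf <= maf_min
  fail_hwe <- hwe_p <= hwe_p_min
  fail_call <- call_rate <= call_rate_min
  pass <- !(fail_maf | fail_hwe | fail_call)

  report <- structure(list(
    n_input_variants = m,
    n_fail_hwe = sum(fail_hwe),
    n_fail_maf = sum(fail_maf),
    n_fail_callrate = sum(fail_call),
    n_pass = sum(pass),
    thresholds = c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                   call_rate_min = call_rate_min)),
    class = "qc_report")
  if (keep_ids) {
    ids <- panel$variants$variant_id
    report$fail_hwe_ids <- ids[fail_hwe]
    report$fail_maf_ids <- ids[fail_maf]
    report$fail_callrate_ids <- ids[fail_call]
  }
  list(panel = subset_panel(panel, variants = which(pass)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "qc_report: %d variants in, %d pass (fail MAF %d, HWE %d, call rate %d)\n",
    x$n_input_variants, x$n_pass, x$n_fail_maf, x$n_fail_hwe,
    x$n_fail_callrate))
  invisible(x)
}

#' Stratification principal components
#'
#' Principal components of the column-standardized, mean-imputed dosage
#' matrix, in the EIGENSTRAT spirit. Constant dosage columns are dropped
#' before standardization. Component signs are fixed deterministically: the
#' loading of largest magnitude on each component is made positive, so scores
#' are reproducible across runs and platforms.
#'
#' @param panel a [genotype_panel()].
#' @param k number of components, `< min(n_samples, n_snps)`.
#' @return Sample-by-`k` score matrix with columns `PC1..PCk`, ordered by
#'   decreasing eigenvalue. The eigenvalues are attached as attribute
#'   `"eigenvalues"`.
#' @export
compute_pcs <- function(panel, k = 2L) {
  stopifnot(inherits(panel, "genotype_panel"))
  k <- check_count(k, "k", 1L)
  X <- impute_dosage_means(panel$dosage)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all dosage columns are constant; PCA undefined",
                       call. = FALSE)
  X <- scale(X[, keep, drop = FALSE])
  if (k >= min(dim(X)))
    stop_param("k", "must be smaller than min(n_samples, n_snps)")
  # eigendecompose the sample-side cross-product (cheaper than a full SVD
  # when SNPs outnumber samples, the usual case)
  ee <- eigen(tcrossprod(X), symmetric = TRUE)
  d <- sqrt(pmax(ee$values[seq_len(k)], 0))
  u <- ee$vectors[, seq_len(k), drop = FALSE]
  v <- crossprod(X, u)                  # loadings (up to scaling by 1/d)
  # sign convention: largest-|loading| entry of each component > 0
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) u[, j] <- -u[, j]
  }
  scores <- u %*% diag(d, k, k)
  dimnames(scores) <- list(panel$sample_id, paste0("PC", seq_len(k)))
  attr(scores, "eigenvalues") <- d^2 / (nrow(X) - 1)
  scores
}
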