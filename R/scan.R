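# Trait transforms, the per-trait linear association scan, genomic-control
# diagnostics, and reduction to LDSC-ready summary statistics.

#' Log-transform selected traits
#'
#' Replaces the listed traits by their natural logarithm and updates the
#' per-trait transform flags, the standard normalization for right-skewed
#' biochemical measurements.
#'
#' @param pheno a `phenotype_panel`.
#' @param log_traits trait names to transform.
#' @param offset optional value added before taking logs (for traits with
#'   zeros); default 0, in which case non-positive values are an error.
#' @return The transformed `phenotype_panel`.
#' @export
transform_traits <- function(pheno, log_traits, offset = 0) {
  stopifnot(inherits(pheno, "phenotype_panel"))
  bad <- setdiff(log_traits, pheno$trait_names)
  if (length(bad))
    stop_param("log_traits", paste("unknown traits:", paste(bad, collapse = ", ")))
  for (tr in log_traits) {
    v <- pheno$traits[, tr] + offset
    if (any(v <= 0, na.rm = TRUE)) {
      i <- which(v <= 0)[1]
      stop(sprintf(
        "trait %s has non-positive value at sample %s; cannot log-transform without an offset",
        tr, pheno$sample_id[i]), call. = FALSE)
    }
    pheno$traits[, tr] <- log(v)
    pheno$transform[tr] <- "log"
  }
  pheno
}

#' Per-trait association scan
#'
#' For each SNP, ordinary least squares of the (transformed) trait on dosage
#' plus covariates plus an intercept. Two-sided p-values come from the t
#' distribution with `n_used - p_covariates - 2` degrees of freedom. Missing
#' dosages are mean-imputed within each SNP's regression (keeping n stable);
#' samples with a missing phenotype or covariate are dropped for that trait.
#' SNPs with zero dosage variance among used samples are reported with
#' `beta = 0`, `p = 1` and flagged degenerate.
#'
#' Computation uses the Frisch-Waugh-Lovell decomposition: phenotype and
#' dosages are residualized on the covariates once, so the per-SNP fit is a
#' single simple regression, algebraically identical to the full OLS fit.
#'
#' @param panel a [genotype_panel()] (samples aligned with `pheno`).
#' @param pheno a `phenotype_panel`.
#' @param covariates sample-level covariate matrix or data frame (for the
#'   standard adjustment, two stratification PCs plus age: see
#'   [compute_pcs()]); `NULL` for an intercept-only model.
#' @param traits trait names to scan; default all.
#' @return A named list of `assoc_scan` objects, one per trait, each with
#'   fields `trait`, `results` (per-SNP data frame), `lambda_gc` and
#'   `covariate_names`.
#' @export
run_scan <- function(panel, pheno, covariates = NULL, traits = NULL) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(pheno, "phenotype_panel"))
  if (!identical(panel$sample_id, pheno$sample_id))
    stop("panel and pheno samples are not aligned", call. = FALSE)
  traits <- traits %||% pheno$trait_names
  bad <- setdiff(traits, pheno$trait_names)
  if (length(bad))
    stop_param("traits", paste("unknown traits:", paste(bad, collapse = ", ")))

  n <- length(panel$sample_id)
  C <- if (is.null(covariates)) matrix(1, n, 1) else {
    cv <- as.matrix(as.data.frame(covariates))
    if (nrow(cv) != n) stop_param("covariates", "row count must match samples")
    cbind(`(intercept)` = 1, cv)
  }
  if (anyNA(C)) stop_param("covariates", "must be complete (no NA)")
  cov_names <- setdiff(colnames(C), "(intercept)")
  p_cov <- ncol(C) - 1L

  G <- impute_dosage_means(panel$dosage)
  n_geno <- colSums(!is.na(panel$dosage))
  qrC <- qr(C)
  G_res_full <- qr.resid(qrC, G)

  scan_one <- function(y) {
    use <- is.finite(y)
    if (all(use)) {
      y_res <- qr.resid(qrC, y)
      G_res <- G_res_full
      n_used <- n
    } else {
      qrS <- qr(C[use, , drop = FALSE])
      y_res <- qr.resid(qrS, y[use])
      G_res <- qr.resid(qrS, G[use, , drop = FALSE])
      n_used <- sum(use)
    }
    df <- n_used - p_cov - 2L
    if (df < 1L)
      stop("fewer usable samples than model parameters", call. = FALSE)
    xx <- colSums(G_res^2)
    xy <- as.numeric(crossprod(G_res, y_res))
    yy <- sum(y_res^2)
    degen <- xx < n_used * 1e-12
    beta <- ifelse(degen, 0, xy / ifelse(degen, 1, xx))
    rss <- pmax(yy - beta * xy, 0)
    se <- ifelse(degen, NA_real_, sqrt(rss / df / ifelse(degen, 1, xx)))
    t_stat <- ifelse(degen, NA_real_, beta / se)
    p <- ifelse(degen, 1, 2 * stats::pt(-abs(t_stat), df))
    p <- pmax(p, .Machine$double.xmin)
    data.frame(variant_id = panel$variants$variant_id,
               chrom = panel$variants$chrom,
               pos = panel$variants$pos,
               A1 = panel$variants$A1,
               A2 = panel$variants$A2,
               n_used = n_used,
               n_geno = n_geno,
               beta = beta, se = se, t_stat = t_stat, p = p,
               degenerate = degen,
               stringsAsFactors = FALSE)
  }

  out <- lapply(traits, function(tr) {
    res <- scan_one(pheno$traits[, tr])
    sc <- structure(list(trait = tr, results = res,
                         covariate_names = cov_names),
                    class = "assoc_scan")
    sc$lambda_gc <- lambda_gc(sc)
    sc
  })
  names(out) <- traits
  out
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("assoc_scan: trait %s, %d SNPs, lambda_gc = %.3f\n",
              x$trait, nrow(x$results), x$lambda_gc))
  invisible(x)
}

#' Genomic-control inflation factor
#'
#' The median association chi-square (the squared t statistic, treated as a
#' 1-df chi-square) divided by the null median `qchisq(0.5, 1) = 0.45494`.
#' Values near 1 indicate adequate control of confounding; degenerate SNPs
#' are excluded.
#'
#' @param scan an `assoc_scan`.
#' @return The inflation factor, a positive real.
#' @export
lambda_gc <- function(scan) {
  stopifnot(inherits(scan, "assoc_scan"))
  t2 <- scan$results$t_stat[!scan$results$degenerate]^2
  t2 <- t2[is.finite(t2)]
  if (!length(t2)) stop("no non-degenerate SNPs in scan", call. = FALSE)
  stats::median(t2) / stats::qchisq(0.5, df = 1)
}

#' Reduce an association scan to LDSC summary statistics
#'
#' Z is the Wald statistic `beta/se`, signed with respect to allele A1; N is
#' the per-SNP sample size. Degenerate SNPs are dropped (the count is kept as
#' attribute `"n_dropped"`).
#'
#' @param scan an `assoc_scan`.
#' @return A `sumstats` data frame with columns `SNP`, `A1`, `A2`, `N`, `Z`
#'   and attributes `trait` and `n_dropped`.
#' @export
to_sumstats <- function(scan) {
  stopifnot(inherits(scan, "assoc_scan"))
  r <- scan$results
  keep <- !r$degenerate & is.finite(r$t_stat)
  ss <- data.frame(SNP = r$variant_id[keep],
                   A1 = r$A1[keep], A2 = r$A2[keep],
                   N = r$n_used[keep], Z = r$t_stat[keep],
                   stringsAsFactors = FALSE)
  attr(ss, "trait") <- scan$trait
  attr(ss, "n_dropped") <- sum(!keep)
  class(ss) <- c("sumstats", "data.frame")
  ss
}
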