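# LD score computation and univariate / cross-trait LD score regression.
#
# The regression model: for a polygenic trait with heritability h2 spread
# over M SNPs, the expected association chi-square at SNP j is
#   E[chi2_j] = 1 + N * h2 * l_j / M
# where l_j is the LD score (sum of squared correlations with all SNPs in a
# window, including itself). Confounding inflates the intercept, not the
# slope. For two traits, E[Z1_j * Z2_j] = sqrt(N1*N2) * rho_g * l_j / M plus
# an intercept absorbing sample overlap; the genetic correlation is
# rg = rho_g / sqrt(h2_1 * h2_2).

#' LD scores from a reference genotype panel
#'
#' For each SNP, the sum of squared dosage correlations with all SNPs on the
#' same chromosome within `window_kb`, including itself (so every score is at
#' least 1). With `bias_correct`, each off-diagonal r-squared is replaced by
#' the approximately unbiased `r2 - (1 - r2)/(n - 2)`; the self term stays
#' exactly 1. Missing dosages are mean-imputed.
#'
#' @param reference a QC'd [genotype_panel()] with sorted positions.
#' @param window_kb window half-width in kb (default 1000).
#' @param bias_correct apply the finite-sample r-squared correction.
#' @param chunk_size SNPs per block in the windowed cross-product
#'   computation (performance only).
#' @return An `ld_score_table` data frame: `variant_id`, `L2`, `maf`,
#'   `n_ref`, ordered as the panel.
#' @export
ld_scores <- function(reference, window_kb = 1000, bias_correct = TRUE,
                      chunk_size = 256L) {
  stopifnot(inherits(reference, "genotype_panel"))
  n <- length(reference$sample_id)
  if (bias_correct && n < 3)
    stop("bias correction needs at least 3 reference samples", call. = FALSE)
  if (window_kb < 0) stop_param("window_kb", "must be non-negative")
  window_bp <- window_kb * 1000

  v <- reference$variants
  m <- nrow(v)
  L2 <- rep(1, m)                      # exact self term
  freq <- colMeans(reference$dosage, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)

  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]
    X <- impute_dosage_means(reference$dosage[, idx, drop = FALSE])
    sds <- apply(X, 2, stats::sd)
    ok <- sds > 0
    Xs <- X
    Xs[, ok] <- scale(X[, ok, drop = FALSE])
    Xs[, !ok] <- 0                     # monomorphic: correlates with nothing
    mc <- length(idx)
    for (a in seq(1L, mc, by = chunk_size)) {
      b <- min(a + chunk_size - 1L, mc)
      lo <- findInterval(pos[a] - window_bp - 0.5, pos) + 1L
      hi <- findInterval(pos[b] + window_bp, pos)
      R <- crossprod(Xs[, a:b, drop = FALSE],
                     Xs[, lo:hi, drop = FALSE]) / (n - 1)
      r2 <- R^2
      if (bias_correct) r2 <- r2 - (1 - r2) / (n - 2)
      # keep only pairs within the window, excluding self
      dp <- abs(outer(pos[a:b], pos[lo:hi], `-`))
      r2[dp > window_bp] <- 0
      self <- cbind(seq_len(b - a + 1L), (a:b) - lo + 1L)
      r2[self] <- 0
      L2[idx[a:b]] <- L2[idx[a:b]] + rowSums(r2)
    }
  }
  out <- data.frame(variant_id = v$variant_id, L2 = L2, maf = maf,
                    n_ref = n, stringsAsFactors = FALSE)
  class(out) <- c("ld_score_table", "data.frame")
  out
}

# two-parameter weighted least squares: returns c(intercept, slope) and the
# per-block weighted moment sums needed for the delete-one-block jackknife
wls_blocks <- function(x, y, w, blocks) {
  sums <- function(sel) c(sw = sum(w[sel]), swx = sum(w[sel] * x[sel]),
                          swx2 = sum(w[sel] * x[sel]^2),
                          swy = sum(w[sel] * y[sel]),
                          swxy = sum(w[sel] * x[sel] * y[sel]))
  per_block <- t(vapply(split(seq_along(x), blocks), sums, numeric(5)))
  total <- colSums(per_block)
  fit <- function(s) {
    det <- s["sw"] * s["swx2"] - s["swx"]^2
    if (abs(det) < .Machine$double.eps * max(1, s["swx2"]))
      stop("zero variance in LD scores; regression undefined", call. = FALSE)
    slope <- (s["sw"] * s["swxy"] - s["swx"] * s["swy"]) / det
    intercept <- (s["swy"] - slope * s["swx"]) / s["sw"]
    c(intercept = unname(intercept), slope = unname(slope))
  }
  list(full = fit(total),
       leave_one_out = t(apply(per_block, 1, function(b) fit(total - b))))
}

# contiguous equal-count blocks over m SNPs
jackknife_blocks <- function(m, n_blocks) {
  sort(rep_len(seq_len(n_blocks), m))
}

merge_sumstats_ld <- function(ss, ld) {
  i <- match(ld$variant_id, ss$SNP)
  keep <- !is.na(i)
  data.frame(SNP = ld$variant_id[keep], L2 = ld$L2[keep],
             N = ss$N[i[keep]], Z = ss$Z[i[keep]],
             stringsAsFactors = FALSE)
}

#' Univariate LD score regression
#'
#' Weighted least squares of the per-SNP chi-square on the LD score with a
#' free intercept and weights `1/max(l, 1)`; the heritability is recovered
#' from the slope as `slope * M / mean(N)`. Standard errors come from a
#' delete-one block jackknife over contiguous SNP blocks.
#'
#' @param ss a `sumstats` table (see [to_sumstats()]).
#' @param ld an [ld_scores()] table.
#' @param n_blocks jackknife block count (default 20).
#' @return An `h2_estimate` list: `h2`, `se_h2`, `intercept`,
#'   `se_intercept`, `M`, `mean_chi2`, `n_blocks`.
#' @export
h2_regression <- function(ss, ld, n_blocks = 20L) {
  n_blocks <- check_count(n_blocks, "n_blocks", 2L)
  d <- merge_sumstats_ld(ss, ld)
  M <- nrow(d)
  if (M < 2L * n_blocks)
    stop(sprintf("need at least %d SNPs shared between sumstats and LD scores",
                 2L * n_blocks), call. = FALSE)
  chi2 <- d$Z^2
  w <- 1 / pmax(d$L2, 1)
  blocks <- jackknife_blocks(M, n_blocks)
  wb <- wls_blocks(d$L2, chi2, w, blocks)
  Nbar <- mean(d$N)
  h2_hat <- wb$full["slope"] * M / Nbar
  h2_jack <- wb$leave_one_out[, "slope"] * M / Nbar
  int_jack <- wb$leave_one_out[, "intercept"]
  jk_se <- function(v) sqrt((n_blocks - 1) / n_blocks * sum((v - mean(v))^2))
  structure(list(h2 = unname(h2_hat),
                 se_h2 = jk_se(h2_jack),
                 intercept = unname(wb$full["intercept"]),
                 se_intercept = jk_se(int_jack),
                 M = M, mean_chi2 = mean(chi2), n_blocks = n_blocks),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2_estimate: h2 = %.4f (se %.4f), intercept = %.4f (se %.4f), M = %d\n",
              x$h2, x$se_h2, x$intercept, x$se_intercept, x$M))
  invisible(x)
}

# align ss2 alleles to ss1 over shared SNPs: flip Z2 when A1/A2 are swapped,
# drop SNPs whose allele pairs do not match either way
align_sumstats <- function(ss1, ss2) {
  i <- match(ss1$SNP, ss2$SNP)
  keep <- !is.na(i)
  a <- ss1[keep, , drop = FALSE]
  b <- ss2[i[keep], , drop = FALSE]
  same <- a$A1 == b$A1 & a$A2 == b$A2
  flipped <- a$A1 == b$A2 & a$A2 == b$A1
  b$Z[flipped] <- -b$Z[flipped]
  ok <- same | flipped
  list(ss1 = a[ok, , drop = FALSE], ss2 = b[ok, , drop = FALSE],
       n_dropped = sum(!ok))
}

#' Cross-trait LD score regression
#'
#' Regression of the per-SNP Z-score product on the LD score with a free
#' intercept (absorbing sample overlap and shared confounding), weights
#' `1/max(l, 1)`. The genetic covariance comes from the slope; the genetic
#' correlation divides it by the geometric mean of the two univariate
#' heritability estimates, both fit on the same SNPs. The standard error of
#' the full ratio comes from a delete-one block jackknife (all three
#' regressions recomputed per block); the p-value is the two-sided normal
#' approximation. A trait regressed on itself gives rg = 1 exactly.
#'
#' @param ss1,ss2 `sumstats` tables; alleles are aligned by flipping Z signs
#'   at A1/A2-swapped SNPs and dropping mismatches.
#' @param ld an [ld_scores()] table.
#' @param n_blocks jackknife block count.
#' @return An `rg_estimate` list: `rho_g`, `rg`, `se_rg`, `p_rg`,
#'   `cross_intercept`, `h2_1`, `h2_2`, `M`, `defined` (FALSE when either
#'   heritability estimate is non-positive, which flags the pair for
#'   outlier removal).
#' @export
rg_estimate <- function(ss1, ss2, ld, n_blocks = 20L) {
  n_blocks <- check_count(n_blocks, "n_blocks", 2L)
  al <- align_sumstats(ss1, ss2)
  i <- match(ld$variant_id, al$ss1$SNP)
  keep <- !is.na(i)
  M <- sum(keep)
  if (M < 2L * n_blocks)
    stop(sprintf("need at least %d shared SNPs", 2L * n_blocks), call. = FALSE)
  l2 <- ld$L2[keep]
  z1 <- al$ss1$Z[i[keep]]; n1 <- al$ss1$N[i[keep]]
  z2 <- al$ss2$Z[i[keep]]; n2 <- al$ss2$N[i[keep]]
  w <- 1 / pmax(l2, 1)
  blocks <- jackknife_blocks(M, n_blocks)

  f11 <- wls_blocks(l2, z1^2, w, blocks)
  f22 <- wls_blocks(l2, z2^2, w, blocks)
  f12 <- wls_blocks(l2, z1 * z2, w, blocks)
  N1 <- mean(n1); N2 <- mean(n2)

  rg_from <- function(s1, s2, s12) {
    h2_1 <- s1 * M / N1
    h2_2 <- s2 * M / N2
    rho <- s12 * M / sqrt(N1 * N2)
    if (h2_1 <= 0 || h2_2 <= 0) return(c(rho, NA_real_, h2_1, h2_2))
    c(rho, rho / sqrt(h2_1 * h2_2), h2_1, h2_2)
  }
  full <- rg_from(f11$full["slope"], f22$full["slope"], f12$full["slope"])
  rg_jack <- vapply(seq_len(n_blocks), function(b)
    rg_from(f11$leave_one_out[b, "slope"], f22$leave_one_out[b, "slope"],
            f12$leave_one_out[b, "slope"])[2], numeric(1))

  defined <- is.finite(full[2])
  rg_ok <- rg_jack[is.finite(rg_jack)]
  se <- if (defined && length(rg_ok) >= 2) {
    B <- length(rg_ok)
    sqrt((B - 1) / B * sum((rg_ok - mean(rg_ok))^2))
  } else NA_real_
  p <- if (defined && is.finite(se) && se > 0)
    max(2 * stats::pnorm(-abs(full[2] / se)), .Machine$double.xmin)
  else if (defined && identical(se, 0)) .Machine$double.xmin
  else NA_real_

  structure(list(rho_g = unname(full[1]), rg = unname(full[2]),
                 se_rg = se, p_rg = p,
                 cross_intercept = unname(f12$full["intercept"]),
                 h2_1 = unname(full[3]), h2_2 = unname(full[4]),
                 M = M, n_blocks = n_blocks, defined = defined,
                 n_dropped_alleles = al$n_dropped),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("rg_estimate: rg = %s (se %s, p = %s), rho_g = %.4f, M = %d\n",
              format(x$rg, digits = 4), format(x$se_rg, digits = 3),
              format(x$p_rg, digits = 3), x$rho_g, x$M))
  invisible(x)
}

#' Genetic-correlation matrix over all trait pairs
#'
#' Evaluates [rg_estimate()] for every unordered pair. Pairs with an
#' undefined rg (non-positive heritability) or `|rg|` above `rg_abs_max` are
#' flagged as outliers and excluded from the significant pair set, which
#' collects the remaining pairs with p strictly below `p_max`.
#'
#' @param ss_list named list of `sumstats` tables (>= 2 traits).
#' @param ld an [ld_scores()] table.
#' @param p_max significance threshold for the pair set.
#' @param rg_abs_max outlier threshold on `|rg|` (default 1.25).
#' @param n_blocks jackknife block count.
#' @return A list with `rg` (class `rg_matrix`: matrices `rg`, `se`, `p`,
#'   logical `outlier`; long-format `pairs` data frame covering every
#'   evaluated pair) and `pairs` (a [pair_set()] with provenance `"ldsc"`).
#' @export
rg_matrix <- function(ss_list, ld, p_max = 0.05, rg_abs_max = 1.25,
                      n_blocks = 20L) {
  nm <- names(ss_list)
  if (is.null(nm) || length(nm) < 2L)
    stop_param("ss_list", "must be a named list of >= 2 sumstats tables")
  T <- length(nm)
  Rg <- Se <- P <- matrix(NA_real_, T, T, dimnames = list(nm, nm))
  Out <- matrix(FALSE, T, T, dimnames = list(nm, nm))
  rows <- list()
  for (i in seq_len(T - 1)) for (j in (i + 1):T) {
    est <- rg_estimate(ss_list[[i]], ss_list[[j]], ld, n_blocks = n_blocks)
    outlier <- !est$defined || (is.finite(est$rg) && abs(est$rg) > rg_abs_max)
    Rg[i, j] <- Rg[j, i] <- est$rg
    Se[i, j] <- Se[j, i] <- est$se_rg
    P[i, j] <- P[j, i] <- est$p_rg
    Out[i, j] <- Out[j, i] <- outlier
    rows[[length(rows) + 1L]] <- data.frame(
      trait1 = nm[i], trait2 = nm[j], rg = est$rg, se = est$se_rg,
      p = est$p_rg, rho_g = est$rho_g, cross_intercept = est$cross_intercept,
      outlier = outlier, stringsAsFactors = FALSE)
  }
  pairs_df <- do.call(rbind, rows)
  sig <- pairs_df[!pairs_df$outlier & is.finite(pairs_df$p) &
                    pairs_df$p < p_max, , drop = FALSE]
  ps <- if (nrow(sig))
    pair_set(sig$trait1, sig$trait2, provenance = "ldsc", traits = nm,
             thresholds = c(p_max = p_max, rg_abs_max = rg_abs_max))
  else pair_set(character(0), character(0), provenance = "ldsc", traits = nm,
                thresholds = c(p_max = p_max, rg_abs_max = rg_abs_max))
  rg_obj <- structure(list(trait_names = nm, rg = Rg, se = Se, p = P,
                           outlier = Out, pairs = pairs_df),
                      class = "rg_matrix")
  list(rg = rg_obj, pairs = ps)
}

#' @export
print.rg_matrix <- function(x, ...) {
  cat(sprintf("rg_matrix: %d traits, %d pairs evaluated, %d outliers\n",
              length(x$trait_names), nrow(x$pairs), sum(x$pairs$outlier)))
  invisible(x)
}
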