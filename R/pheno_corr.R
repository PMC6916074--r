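# Phenotypic correlation matrix, thresholded pair calling, and trait
# clustering.

#' Trait-trait correlation matrix
#'
#' Pairwise-complete Pearson or Spearman correlations with two-sided p-values
#' from the t transform of r. Spearman ranks each trait first (average ranks
#' for ties), i.e. the Pearson correlation between rank variables. Constant
#' traits have undefined correlations, reported as `NA` rather than
#' fabricated.
#'
#' @param pheno a `phenotype_panel` (typically after [transform_traits()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `correlation_matrix` with fields `trait_names`,
#'   `r`, `p`, `n` (pairwise complete counts) and `method`.
#' @export
correlation_matrix <- function(pheno, method = c("pearson", "spearman")) {
  stopifnot(inherits(pheno, "phenotype_panel"))
  method <- match.arg(method)
  Y <- pheno$traits
  if (method == "spearman")
    Y <- apply(Y, 2, function(v) { r <- rep(NA_real_, length(v))
      r[!is.na(v)] <- rank(v[!is.na(v)]); r })
  nm <- colnames(Y)
  obs <- !is.na(Y)
  n <- crossprod(obs)
  if (any(n[upper.tri(n)] < 3))
    stop("fewer than 3 complete observations for some trait pair", call. = FALSE)
  r <- suppressWarnings(stats::cor(Y, use = "pairwise.complete.obs"))
  sdv <- apply(Y, 2, stats::sd, na.rm = TRUE)
  const <- !is.finite(sdv) | sdv == 0
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  diag(r)[!const] <- 1
  # two-sided p from t = r * sqrt((n-2)/(1-r^2))
  r_clip <- pmin(pmax(r, -1), 1)
  tt <- r_clip * sqrt(pmax(n - 2, 0) / pmax(1 - r_clip^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = pmax(n - 2, 1))
  p <- pmax(p, .Machine$double.xmin)   # exact +/-1 maps below representable p
  diag(p) <- NA_real_
  dimnames(r) <- dimnames(p) <- dimnames(n) <- list(nm, nm)
  structure(list(trait_names = nm, r = r, p = p, n = n, method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d traits (%s)\n",
              length(x$trait_names), x$method))
  invisible(x)
}

#' Construct a set of unordered trait pairs
#'
#' @param trait1,trait2 endpoint vectors (self-pairs rejected; duplicates
#'   collapsed after canonical ordering).
#' @param provenance label of the evidence source (`"pearson"`, `"jaccard"`,
#'   `"ldsc"`, ...).
#' @param traits the full trait namespace the pairs are drawn from.
#' @param thresholds named numeric vector recording the thresholds used.
#' @return A `pair_set` data frame with columns `trait1`, `trait2`.
#' @export
pair_set <- function(trait1, trait2, provenance = "unknown",
                     traits = NULL, thresholds = NULL) {
  if (any(trait1 == trait2)) stop_param("pairs", "self-pairs not allowed")
  df <- unique(canonical_pairs(as.character(trait1), as.character(trait2)))
  df <- df[order(df$trait1, df$trait2), , drop = FALSE]
  rownames(df) <- NULL
  traits <- sort(unique(c(traits, df$trait1, df$trait2)))
  structure(df, provenance = provenance, traits = traits,
            thresholds = thresholds, class = c("pair_set", "data.frame"))
}

#' Call significantly correlated trait pairs
#'
#' Pairs with `|r|` strictly greater than `r_abs_min` and p strictly smaller
#' than `p_max` (a correlation of exactly `r_abs_min` is excluded).
#'
#' @param cm a [correlation_matrix()].
#' @param r_abs_min,p_max thresholds (strict).
#' @return A [pair_set()] with provenance `"pearson"` (or `"spearman"`).
#' @export
significant_pairs <- function(cm, r_abs_min = 0.3, p_max = 0.01) {
  stopifnot(inherits(cm, "correlation_matrix"))
  nm <- cm$trait_names
  idx <- which(upper.tri(cm$r) & !is.na(cm$r) &
                 abs(cm$r) > r_abs_min & cm$p < p_max, arr.ind = TRUE)
  pair_set(nm[idx[, 1]], nm[idx[, 2]], provenance = cm$method,
           traits = nm,
           thresholds = c(r_abs_min = r_abs_min, p_max = p_max))
}

#' Cluster traits from their correlation matrix
#'
#' Agglomerative clustering with complete linkage on the distance
#' `d = 1 - r`, cut into `k` groups. Traits are ordered alphabetically before
#' clustering so the partition does not depend on input order.
#'
#' @param cm a [correlation_matrix()].
#' @param k number of groups.
#' @return Named integer vector of group labels; the dendrogram is attached
#'   as attribute `"hclust"`.
#' @export
cluster_traits <- function(cm, k = 2L) {
  stopifnot(inherits(cm, "correlation_matrix"))
  k <- check_count(k, "k", 1L)
  ord <- order(cm$trait_names)
  r <- cm$r[ord, ord]
  if (anyNA(r))
    stop("correlation matrix has missing entries; impute or drop the ",
         "affected traits before clustering", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  grp <- stats::cutree(hc, k = k)
  out <- grp[cm$trait_names]
  attr(out, "hclust") <- hc
  out
}
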