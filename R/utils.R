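#' @keywords internal
"_PACKAGE"

# shared internal helpers -----------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(param, msg) {
  stop(sprintf("invalid `%s`: %s", param, msg), call. = FALSE)
}

check_count <- function(x, param, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    stop_param(param, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_prob <- function(x, param, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok)
    stop_param(param, sprintf("must be in %s%g, %g%s",
                              if (lo_open) "(" else "[", lo, hi,
                              if (hi_open) ")" else "]"))
  as.numeric(x)
}

# symmetric PSD square root via eigendecomposition; tolerates tiny negative
# eigenvalues from finite precision, rejects genuinely non-PSD input
psd_sqrt <- function(S, param = "matrix", tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-10)
    stop_param(param, "must be a symmetric square matrix")
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop_param(param, "must be positive semidefinite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

check_corr_matrix <- function(S, param) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop_param(param, "must be a square matrix")
  if (max(abs(diag(S) - 1)) > 1e-10)
    stop_param(param, "must have a unit diagonal")
  if (max(abs(S - t(S))) > 1e-10)
    stop_param(param, "must be symmetric")
  if (any(abs(S) > 1 + 1e-10))
    stop_param(param, "entries must lie in [-1, 1]")
  invisible(S)
}

# column means ignoring NA, with NA columns mapped to 0
col_means_safe <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  mu[!is.finite(mu)] <- 0
  mu
}

# replace missing dosages by the per-SNP mean dosage (computed on observed calls)
impute_dosage_means <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- col_means_safe(X)
    idx <- which(is.na(X))
    X[idx] <- mu[(idx - 1L) %/% nrow(X) + 1L]
  }
  X
}

# canonical unordered pair representation: trait1 < trait2 lexicographically
canonical_pairs <- function(a, b) {
  swap <- a > b
  t1 <- ifelse(swap, b, a)
  t2 <- ifelse(swap, a, b)
  data.frame(trait1 = t1, trait2 = t2, stringsAsFactors = FALSE)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
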