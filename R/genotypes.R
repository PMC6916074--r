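# Genotype panel container and the LD-blocked genotype simulator.

#' Construct a genotype panel
#'
#' A genotype panel holds a sample-by-variant matrix of additive allele
#' dosages (counts of allele A1 in 0/1/2, `NA` for missing calls) together
#' with variant coordinates and alleles.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based bp), `A1`, `A2`. Positions must be strictly increasing within
#'   each chromosome and variant ids unique.
#' @param dosage integer matrix, samples in rows, variants in columns;
#'   values in `{0, 1, 2, NA}`.
#' @param population optional integer vector of subpopulation labels
#'   (simulation ground truth).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sample_id, variants, dosage, population = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop_param("sample_id", "must be unique")
  need <- c("variant_id", "chrom", "pos", "A1", "A2")
  if (!all(need %in% names(variants)))
    stop_param("variants", paste("must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(variants$variant_id))
    stop_param("variants", "variant_id must be unique")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0))
      stop_param("variants", sprintf(
        "positions must be strictly increasing within chromosome %s", ch))
  }
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(sample_id) || ncol(dosage) != nrow(variants))
    stop_param("dosage", "dimensions must match sample_id x variants")
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop_param("dosage", "values must be 0, 1, 2 or NA")
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(sample_id, variants$variant_id)
  rownames(variants) <- NULL
  structure(list(sample_id = sample_id, variants = variants,
                 dosage = dosage, population = population),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants (%d chromosome%s)\n",
              length(x$sample_id), nrow(x$variants),
              length(unique(x$variants$chrom)),
              if (length(unique(x$variants$chrom)) == 1L) "" else "s"))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing call rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Simulate an LD-blocked genotype panel
#'
#' Draws diploid genotypes from a latent-Gaussian copula: within each block
#' of `block_size` consecutive SNPs the per-haplotype latent variables follow
#' a first-order autoregression, so adjacent SNPs have latent correlation
#' equal to the block's autoregressive parameter and the correlation decays
#' geometrically with lag (Markov-style LD); blocks are mutually
#' independent. When `within_block_r` is a length-2 range, each block draws
#' its own parameter uniformly from it, giving the heterogeneous LD-score
#' distribution real genomes show (and that LD score regression needs for
#' leverage); a scalar gives every block the same LD strength.
#' Each haplotype is thresholded at its allele
#' frequency, so marginal genotype frequencies satisfy Hardy-Weinberg
#' proportions exactly. Realized genotype (dosage) correlations are somewhat
#' attenuated relative to `within_block_r` by the thresholding, as usual for
#' discretized Gaussian copulas.
#'
#' Optionally a fraction of samples forms a second subpopulation whose allele
#' frequencies are shifted by `strat_shift` (random direction per SNP),
#' inducing principal-component structure.
#'
#' @param n_samples,n_snps cohort dimensions.
#' @param block_size SNPs per LD block (the last block may be short).
#' @param within_block_r latent correlation between adjacent SNPs of a
#'   block, in `[0, 1)`: a scalar (same for every block) or a length-2
#'   range from which per-block values are drawn uniformly.
#' @param maf_range interval in `(0, 0.5]`; per-SNP allele-A1 frequencies are
#'   drawn uniformly from it.
#' @param missing_rate per-call missing probability, in `[0, 0.2)`.
#' @param strat_fraction fraction of samples in the shifted subpopulation.
#' @param strat_shift magnitude of the subpopulation allele-frequency shift.
#' @param spacing_bp distance between consecutive SNP positions.
#' @param n_chrom number of chromosomes to spread the blocks across.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return A [genotype_panel()] whose `population` field records the
#'   subpopulation assignment (1 or 2).
#' @export
simulate_genotypes <- function(n_samples, n_snps, block_size = 50L,
                               within_block_r = c(0.7, 0.995),
                               maf_range = c(0.05, 0.5),
                               missing_rate = 0, strat_fraction = 0,
                               strat_shift = 0.1, spacing_bp = 1000L,
                               n_chrom = 1L, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", 2L)
  n_snps <- check_count(n_snps, "n_snps", 1L)
  block_size <- check_count(block_size, "block_size", 1L)
  if (!length(within_block_r) %in% 1:2 || !is.numeric(within_block_r) ||
      any(!is.finite(within_block_r)) || any(within_block_r < 0) ||
      any(within_block_r >= 1) || is.unsorted(within_block_r))
    stop_param("within_block_r", "must be a scalar or sorted range in [0, 1)")
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop_param("maf_range", "must be an interval within (0, 0.5]")
  missing_rate <- check_prob(missing_rate, "missing_rate", hi = 0.2, hi_open = TRUE)
  strat_fraction <- check_prob(strat_fraction, "strat_fraction")
  strat_shift <- check_prob(strat_shift, "strat_shift", hi = 0.5)
  n_chrom <- check_count(n_chrom, "n_chrom", 1L)
  set.seed(check_count(seed, "seed", min = 0L))

  maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  n_blocks <- ceiling(n_snps / block_size)
  block <- rep(seq_len(n_blocks), each = block_size)[seq_len(n_snps)]

  # chromosomes split at block boundaries so LD never crosses a chromosome
  n_chrom <- min(n_chrom, n_blocks)
  chrom_of_block <- if (n_chrom == 1L) rep(1L, n_blocks) else
    as.integer(cut(seq_len(n_blocks), n_chrom, labels = FALSE))
  chrom <- chrom_of_block[block]
  pos <- integer(n_snps)
  for (ch in seq_len(n_chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- seq_along(idx) * as.integer(spacing_bp)
  }

  pop <- rep(1L, n_samples)
  if (strat_fraction > 0) {
    n2 <- round(strat_fraction * n_samples)
    pop[sample.int(n_samples, n2)] <- 2L
  }
  p1 <- maf
  shift_dir <- sample(c(-1, 1), n_snps, replace = TRUE)
  p2 <- pmin(pmax(maf + strat_shift * shift_dir, 0.01), 0.99)

  thr1 <- stats::qnorm(p1)
  thr2 <- stats::qnorm(p2)
  thr_mat <- matrix(thr1, n_samples, n_snps, byrow = TRUE)
  if (any(pop == 2L))
    thr_mat[pop == 2L, ] <- matrix(thr2, sum(pop == 2L), n_snps, byrow = TRUE)

  dosage <- matrix(0L, n_samples, n_snps)
  rho_block <- if (length(within_block_r) == 1L)
    rep(within_block_r, n_blocks)
  else stats::runif(n_blocks, within_block_r[1], within_block_r[2])
  # the AR recursion runs over within-block position, vectorized across all
  # blocks at once (blocks are contiguous index ranges of width block_size)
  block_starts <- (seq_len(n_blocks) - 1L) * block_size + 1L
  any_ld <- any(rho_block > 0)
  for (h in 1:2) {
    Z <- matrix(stats::rnorm(n_samples * n_snps), n_samples, n_snps)
    if (any_ld) for (w in seq_len(block_size)[-1L]) {
      idx <- block_starts + (w - 1L)
      idx <- idx[idx <= n_snps]
      if (!length(idx)) break
      rho_i <- rep(rho_block[block[idx]], each = n_samples)
      Z[, idx] <- rho_i * Z[, idx - 1L, drop = FALSE] +
        sqrt(1 - rho_i^2) * Z[, idx, drop = FALSE]
    }
    dosage <- dosage + (Z < thr_mat)
  }
  storage.mode(dosage) <- "integer"
  if (missing_rate > 0) {
    miss <- which(stats::runif(length(dosage)) < missing_rate)
    dosage[miss] <- NA_integer_
  }

  variants <- data.frame(
    variant_id = sprintf("rs%07d", seq_len(n_snps)),
    chrom = as.character(chrom),
    pos = pos,
    A1 = "A", A2 = "G",
    maf = maf,
    block = block,
    ld_rho = rho_block[block],
    stringsAsFactors = FALSE)
  genotype_panel(sprintf("S%05d", seq_len(n_samples)), variants, dosage,
                 population = pop)
}

#' Subset a genotype panel by variant or sample
#'
#' @param panel a [genotype_panel()].
#' @param variants logical/integer/character index into the variants.
#' @param samples logical/integer/character index into the samples.
#' @return The subset `genotype_panel`.
#' @export
subset_panel <- function(panel, variants = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  vi <- variants %||% seq_len(nrow(panel$variants))
  si <- samples %||% seq_along(panel$sample_id)
  if (is.character(vi)) vi <- match(vi, panel$variants$variant_id)
  if (is.character(si)) si <- match(si, panel$sample_id)
  genotype_panel(panel$sample_id[si],
                 panel$variants[vi, , drop = FALSE],
                 panel$dosage[si, vi, drop = FALSE],
                 population = panel$population[si])
}

# allele frequency of A1 from observed dosages
panel_freq <- function(panel) {
  colMeans(panel$dosage, na.rm = TRUE) / 2
}
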