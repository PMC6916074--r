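# Sparse pleiotropic effect architectures and trait simulation.

#' Simulate a shared sparse genetic architecture
#'
#' Selects `n_causal` causal SNPs uniformly without replacement and draws one
#' effect vector per causal SNP from a zero-mean multivariate normal whose
#' trait-by-trait correlation equals `genetic_corr`. Effects follow the
#' standard additive-genetic model in which each causal SNP explains equal
#' variance on the standardized-genotype scale: the stored per-allele effect
#' of SNP k is scaled by `1/sd(dosage_k)`. Effect columns are then rescaled
#' so that the realized variance of each trait's genetic value (dosages times
#' effects, on this panel) equals its target heritability, anticipating
#' traits standardized to unit total variance. Rescaling columns leaves the
#' genetic correlations untouched.
#'
#' @param panel a [genotype_panel()].
#' @param n_traits number of traits.
#' @param n_causal number of causal SNPs (`<=` number of SNPs in the panel).
#' @param h2 per-trait heritability targets in `[0, 1]`.
#' @param genetic_corr trait-by-trait genetic correlation matrix (symmetric,
#'   unit diagonal, positive semidefinite).
#' @param trait_names optional trait names; default `trait01`, `trait02`, ...
#' @param seed integer seed.
#' @return An object of class `effect_architecture` with fields `causal_snps`
#'   (variant ids), `effects` (causal-SNP x trait matrix, per-allele effects in
#'   standardized-trait units), `h2`, `genetic_corr`, `trait_names`.
#' @export
simulate_architecture <- function(panel, n_traits, n_causal,
                                  h2 = rep(0.5, n_traits),
                                  genetic_corr = diag(n_traits),
                                  trait_names = NULL, seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_traits <- check_count(n_traits, "n_traits", 1L)
  n_causal <- check_count(n_causal, "n_causal", 1L)
  m <- nrow(panel$variants)
  if (n_causal > m) stop_param("n_causal", "exceeds the number of SNPs in the panel")
  if (length(h2) == 1L) h2 <- rep(h2, n_traits)
  if (length(h2) != n_traits || any(h2 < 0 | h2 > 1))
    stop_param("h2", "must give one value in [0, 1] per trait")
  check_corr_matrix(genetic_corr, "genetic_corr")
  if (nrow(genetic_corr) != n_traits)
    stop_param("genetic_corr", "dimension must equal n_traits")
  S <- psd_sqrt(genetic_corr, "genetic_corr")
  trait_names <- trait_names %||% sprintf("trait%02d", seq_len(n_traits))
  if (length(trait_names) != n_traits || anyDuplicated(trait_names))
    stop_param("trait_names", "must be unique and of length n_traits")
  set.seed(check_count(seed, "seed", 0L))

  causal_idx <- sort(sample.int(m, n_causal))
  B <- matrix(stats::rnorm(n_causal * n_traits), n_causal, n_traits) %*% S

  X <- impute_dosage_means(panel$dosage[, causal_idx, drop = FALSE])
  xsd <- apply(X, 2, stats::sd)
  if (any(xsd == 0) && any(h2 > 0))
    xsd[xsd == 0] <- Inf                # monomorphic causal SNP: zero effect
  B <- B / xsd
  G <- X %*% B
  gv <- apply(G, 2, stats::var)
  for (t in seq_len(n_traits)) {
    if (h2[t] == 0) {
      B[, t] <- 0
    } else {
      if (gv[t] <= 0)
        stop("cannot scale effects for a trait with zero realized genetic variance",
             call. = FALSE)
      B[, t] <- B[, t] * sqrt(h2[t] / gv[t])
    }
  }
  dimnames(B) <- list(panel$variants$variant_id[causal_idx], trait_names)
  structure(list(causal_snps = panel$variants$variant_id[causal_idx],
                 effects = B, h2 = h2, genetic_corr = genetic_corr,
                 trait_names = trait_names),
            class = "effect_architecture")
}

#' @export
print.effect_architecture <- function(x, ...) {
  cat(sprintf("effect_architecture: %d causal SNPs x %d traits, h2 = [%s]\n",
              length(x$causal_snps), length(x$trait_names),
              paste(format(x$h2, digits = 2), collapse = ", ")))
  invisible(x)
}

# variance of the discrete uniform age distribution on 20..69
AGE_VAR <- (50^2 - 1) / 12

#' Simulate phenotypes from a genotype panel and an architecture
#'
#' Each trait is the sum of its genetic value (dosages times effects, with
#' missing dosages mean-imputed), a linear age effect, and multivariate-normal
#' environmental noise with correlation `env_corr`, scaled so total variance is
#' approximately 1 per trait. Ages are drawn uniformly on 20-69 years. Traits
#' named in `lognormal` are exponentiated after construction to emulate
#' right-skewed biochemical measurements that call for a log transform.
#'
#' @param panel a [genotype_panel()].
#' @param arch an [simulate_architecture()] result.
#' @param env_corr environmental correlation matrix (n_traits x n_traits).
#' @param age_effects per-trait linear age slopes (standardized-trait units
#'   per year); with ages spanning 50 years, slopes around 0.01-0.05 give
#'   realistic age contributions.
#' @param lognormal character vector of trait names to exponentiate.
#' @param seed integer seed.
#' @return An object of class `phenotype_panel` with fields `sample_id`,
#'   `traits` (sample x trait matrix), `covariates` (data frame with `age`),
#'   `transform` (per-trait flag, `"none"` or `"log"`), `genetic_value`
#'   (ground-truth genetic values) and `lognormal` (which traits were
#'   exponentiated).
#' @export
simulate_traits <- function(panel, arch, env_corr = NULL,
                            age_effects = NULL, lognormal = character(0),
                            seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(arch, "effect_architecture"))
  n_traits <- length(arch$trait_names)
  env_corr <- env_corr %||% diag(n_traits)
  check_corr_matrix(env_corr, "env_corr")
  if (nrow(env_corr) != n_traits)
    stop_param("env_corr", "dimension must match the architecture's trait count")
  age_effects <- age_effects %||% rep(0, n_traits)
  if (length(age_effects) == 1L) age_effects <- rep(age_effects, n_traits)
  if (length(age_effects) != n_traits)
    stop_param("age_effects", "must give one slope per trait")
  if (!all(lognormal %in% arch$trait_names))
    stop_param("lognormal", "names not among the architecture's traits")
  missing_causal <- setdiff(arch$causal_snps, panel$variants$variant_id)
  if (length(missing_causal))
    stop_param("arch", "causal SNPs absent from the panel")
  set.seed(check_count(seed, "seed", 0L))

  n <- length(panel$sample_id)
  age <- sample(20:69, n, replace = TRUE)

  X <- impute_dosage_means(
    panel$dosage[, arch$causal_snps, drop = FALSE])
  G <- X %*% arch$effects

  env_var <- 1 - arch$h2 - age_effects^2 * AGE_VAR
  if (any(env_var < 0))
    stop("h2 plus the age-effect variance exceeds 1 for some trait; ",
         "reduce `age_effects` or heritability", call. = FALSE)
  E <- matrix(stats::rnorm(n * n_traits), n, n_traits) %*%
    psd_sqrt(env_corr, "env_corr")
  E <- sweep(E, 2, sqrt(env_var), `*`)

  Y <- G + outer(age, age_effects) + E
  colnames(Y) <- arch$trait_names
  for (tr in lognormal) Y[, tr] <- exp(Y[, tr])
  rownames(Y) <- panel$sample_id

  structure(list(sample_id = panel$sample_id,
                 trait_names = arch$trait_names,
                 traits = Y,
                 covariates = data.frame(age = age,
                                         row.names = panel$sample_id),
                 transform = stats::setNames(rep("none", n_traits),
                                             arch$trait_names),
                 genetic_value = G,
                 lognormal = lognormal),
            class = "phenotype_panel")
}

#' Construct a phenotype panel from raw components
#'
#' @param traits sample x trait numeric matrix with column names.
#' @param covariates data frame of per-sample covariates (must include `age`
#'   for the default association-scan adjustment).
#' @param sample_id sample identifiers; default the row names of `traits`.
#' @param transform per-trait transform flags (`"none"` or `"log"`).
#' @return A `phenotype_panel`.
#' @export
phenotype_panel <- function(traits, covariates, sample_id = rownames(traits),
                            transform = NULL) {
  traits <- as.matrix(traits)
  if (is.null(colnames(traits))) stop_param("traits", "must have column names")
  if (is.null(sample_id)) sample_id <- sprintf("S%05d", seq_len(nrow(traits)))
  transform <- transform %||%
    stats::setNames(rep("none", ncol(traits)), colnames(traits))
  if (!all(colnames(traits) %in% names(transform)))
    stop_param("transform", "must be defined for every trait")
  structure(list(sample_id = as.character(sample_id),
                 trait_names = colnames(traits),
                 traits = traits,
                 covariates = as.data.frame(covariates),
                 transform = transform[colnames(traits)],
                 genetic_value = NULL,
                 lognormal = character(0)),
            class = "phenotype_panel")
}

#' @export
print.phenotype_panel <- function(x, ...) {
  cat(sprintf("phenotype_panel: %d samples x %d traits (%d log-flagged)\n",
              length(x$sample_id), length(x$trait_names),
              sum(x$transform == "log")))
  invisible(x)
}
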