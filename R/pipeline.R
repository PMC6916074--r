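# End-to-end pipeline driver: simulate (optional) -> QC -> PCs -> scans ->
# sumstats -> phenotypic correlation -> MCI -> LDSC -> integration ->
# pleiotropy -> catalogue join, with a provenance manifest.

#' Default pipeline configuration
#'
#' A small synthetic-cohort configuration exercising every stage. Fields can
#' be overridden; `run_pipeline()` also accepts the path of a YAML file with
#' the same structure.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_samples = 500L, n_snps = 5000L, block_size = 50L,
      within_block_r = c(0.7, 0.995), maf_range = c(0.05, 0.5), missing_rate = 0.01,
      strat_fraction = 0.3, strat_shift = 0.05, n_chrom = 2L,
      n_traits = 8L, n_causal = 1000L, h2 = 0.5,
      genetic_corr = NULL,              # identity unless supplied
      env_corr = NULL,
      age_effects = 0.02,
      n_genes = 300L, mean_degree = 4,
      catalogue_frac = 0.05, catalogue_n_phenotypes = 20L),
    qc = list(maf_min = 0.01, hwe_p_min = 1e-3, call_rate_min = 0.95),
    pca = list(k = 2L),
    pheno_corr = list(method = "pearson", r_abs_min = 0.3, p_max = 0.01,
                      k_clusters = 2L),
    mci = list(p_threshold = 1e-3, window = 10000L, mci_min = 0.6),
    ldsc = list(window_kb = 100, n_blocks = 20L, p_max = 0.05,
                rg_abs_max = 1.25),
    integration = list(tier1_min = 21L, tier2_min = 16L, tier3_min = 11L),
    pleiotropy = list(p_threshold = 1e-3, min_traits = 3L),
    catalogue = list(cat_p_max = 1e-8, min_traits = 2L))
}

modify_list <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      modify_list(base[[nm]], override[[nm]]) else override[[nm]]
  }
  base
}

stage_failed <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
       call. = FALSE)
}

#' Run the full trait-network pipeline
#'
#' Executes simulation (unless genotype/phenotype inputs are supplied in the
#' config), variant QC, stratification PCs, per-trait association scans,
#' summary-statistic reduction, phenotypic correlation, MCI over the PPI
#' network, LD score regression, integration into the trait network with hub
#' tiers, pleiotropy tallies and the catalogue join. Intermediate artifacts
#' are written as TSV/JSON under `out_dir` (when given) together with a run
#' manifest recording the seed, thresholds and completed stages. The run is
#' a pure function of the configuration, so an identical config reproduces
#' byte-identical outputs.
#'
#' @param config configuration list as from [default_config()] (partial
#'   overrides are merged over the defaults), or the path of a YAML file.
#' @param out_dir optional output directory for artifacts.
#' @return A list bundle with every intermediate object and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- modify_list(default_config(), config)
  seed <- check_count(cfg$seed, "seed", 0L)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  emit <- function(name, writer, obj) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
  }
  stages <- character(0)
  bundle <- list(config = cfg)

  # --- simulate -------------------------------------------------------------
  sim <- cfg$simulate
  n_traits <- sim$n_traits
  gcorr <- sim$genetic_corr %||% diag(n_traits)
  ecorr <- sim$env_corr %||% diag(n_traits)
  tryCatch({
    panel <- simulate_genotypes(
      sim$n_samples, sim$n_snps, block_size = sim$block_size,
      within_block_r = sim$within_block_r, maf_range = sim$maf_range,
      missing_rate = sim$missing_rate, strat_fraction = sim$strat_fraction,
      strat_shift = sim$strat_shift, n_chrom = sim$n_chrom, seed = seed)
    arch <- simulate_architecture(
      panel, n_traits = n_traits, n_causal = sim$n_causal, h2 = sim$h2,
      genetic_corr = gcorr, seed = seed + 1L)
    pheno <- simulate_traits(
      panel, arch, env_corr = ecorr, age_effects = sim$age_effects,
      seed = seed + 2L)
    ann <- simulate_gene_map_and_ppi(panel, n_genes = sim$n_genes,
                                     mean_degree = sim$mean_degree,
                                     seed = seed + 3L)
    catalogue <- simulate_catalogue(panel$variants$variant_id,
                                    n_phenotypes = sim$catalogue_n_phenotypes,
                                    frac_annotated = sim$catalogue_frac,
                                    seed = seed + 4L)
    stages <- c(stages, "simulate")
  }, error = function(e) stage_failed("simulate", e))
  emit("genotypes.tsv", write_dosage_tsv, panel)
  emit("phenotypes.tsv", write_phenotype_tsv, pheno)
  emit("gene_map.bed", write_gene_map_bed, ann$gene_map)
  emit("ppi.tsv", write_ppi_tsv, ann$ppi)
  emit("catalogue.tsv", function(o, p) write_tsv(o, p), catalogue)
  bundle$panel_raw <- panel
  bundle$arch <- arch
  bundle$pheno <- pheno
  bundle$gene_map <- ann$gene_map
  bundle$ppi <- ann$ppi
  bundle$catalogue <- catalogue

  # --- qc -------------------------------------------------------------------
  tryCatch({
    qc <- qc_filter(panel, maf_min = cfg$qc$maf_min,
                    hwe_p_min = cfg$qc$hwe_p_min,
                    call_rate_min = cfg$qc$call_rate_min)
    stages <- c(stages, "qc")
  }, error = function(e) stage_failed("qc", e))
  panel_qc <- qc$panel
  emit("qc_report.json", function(o, p)
    jsonlite::write_json(unclass(o), p, auto_unbox = TRUE, digits = NA),
    qc$report)
  bundle$panel <- panel_qc
  bundle$qc_report <- qc$report

  # --- pca ------------------------------------------------------------------
  tryCatch({
    pcs <- compute_pcs(panel_qc, k = cfg$pca$k)
    stages <- c(stages, "pca")
  }, error = function(e) stage_failed("pca", e))
  emit("pcs.tsv", function(o, p)
    write_tsv(data.frame(sample_id = rownames(o), o), p), pcs)
  bundle$pcs <- pcs

  # --- scan -----------------------------------------------------------------
  tryCatch({
    pheno_t <- if (length(pheno$lognormal))
      transform_traits(pheno, pheno$lognormal) else pheno
    covars <- cbind(pcs, age = pheno_t$covariates$age)
    scans <- run_scan(panel_qc, pheno_t, covariates = covars)
    stages <- c(stages, "scan")
  }, error = function(e) stage_failed("scan", e))
  if (!is.null(out_dir)) for (tr in names(scans))
    write_tsv(scans[[tr]]$results, file.path(out_dir, paste0("scan_", tr, ".tsv")))
  bundle$pheno_transformed <- pheno_t
  bundle$scans <- scans
  bundle$lambda_gc <- vapply(scans, `[[`, numeric(1), "lambda_gc")

  # --- sumstats -------------------------------------------------------------
  tryCatch({
    ss_list <- lapply(scans, to_sumstats)
    stages <- c(stages, "sumstats")
  }, error = function(e) stage_failed("sumstats", e))
  if (!is.null(out_dir)) for (tr in names(ss_list))
    write_sumstats_tsv(ss_list[[tr]], file.path(out_dir, paste0("sumstats_", tr, ".tsv")))
  bundle$sumstats <- ss_list

  # --- pheno_corr -----------------------------------------------------------
  tryCatch({
    cm <- correlation_matrix(pheno_t, method = cfg$pheno_corr$method)
    pearson_pairs <- significant_pairs(cm, r_abs_min = cfg$pheno_corr$r_abs_min,
                                       p_max = cfg$pheno_corr$p_max)
    clusters <- cluster_traits(cm, k = cfg$pheno_corr$k_clusters)
    stages <- c(stages, "pheno_corr")
  }, error = function(e) stage_failed("pheno_corr", e))
  emit("pheno_corr.tsv", function(o, p) {
    up <- which(upper.tri(o$r), arr.ind = TRUE)
    write_tsv(data.frame(trait1 = o$trait_names[up[, 1]],
                         trait2 = o$trait_names[up[, 2]],
                         r = o$r[up], p = o$p[up], n = o$n[up]), p)
  }, cm)
  bundle$pheno_corr <- cm
  bundle$pearson_pairs <- pearson_pairs
  bundle$clusters <- clusters

  # --- mci ------------------------------------------------------------------
  tryCatch({
    tgs <- trait_gene_sets(scans, bundle$gene_map,
                           p_threshold = cfg$mci$p_threshold,
                           window = cfg$mci$window)
    tgs_ppi <- restrict_to_interactome(tgs, bundle$ppi)
    mm <- mci_matrix(tgs_ppi, bundle$ppi, mci_min = cfg$mci$mci_min)
    nstats <- node_stats(bundle$ppi,
                         nodes = unique(unlist(tgs_ppi, use.names = FALSE)))
    stages <- c(stages, "mci")
  }, error = function(e) stage_failed("mci", e))
  emit("trait_genes.tsv", function(o, p) {
    long <- do.call(rbind, lapply(names(o), function(tr)
      if (length(o[[tr]])) data.frame(trait = tr, gene_id = o[[tr]])))
    write_tsv(long %||% data.frame(trait = character(0),
                                   gene_id = character(0)), p)
  }, tgs_ppi)
  emit("mci.tsv", function(o, p) {
    up <- which(upper.tri(o$m), arr.ind = TRUE)
    write_tsv(data.frame(trait1 = o$trait_names[up[, 1]],
                         trait2 = o$trait_names[up[, 2]],
                         mci = o$m[up],
                         intersection = o$components[, , 1][up],
                         cross_1to2 = o$components[, , 2][up],
                         cross_2to1 = o$components[, , 3][up],
                         union = o$components[, , 4][up]), p)
  }, mm$mci)
  emit("node_stats.tsv", function(o, p) write_tsv(o, p), nstats)
  bundle$trait_genes <- tgs_ppi
  bundle$mci <- mm$mci
  bundle$jaccard_pairs <- mm$pairs
  bundle$node_stats <- nstats

  # --- ldsc -----------------------------------------------------------------
  tryCatch({
    ld <- ld_scores(panel_qc, window_kb = cfg$ldsc$window_kb)
    rgm <- rg_matrix(ss_list, ld, p_max = cfg$ldsc$p_max,
                     rg_abs_max = cfg$ldsc$rg_abs_max,
                     n_blocks = cfg$ldsc$n_blocks)
    stages <- c(stages, "ldsc")
  }, error = function(e) stage_failed("ldsc", e))
  emit("ldscore.tsv", function(o, p) write_tsv(o, p), ld)
  emit("rg.tsv", function(o, p) write_tsv(o$pairs, p), rgm$rg)
  bundle$ld_scores <- ld
  bundle$rg <- rgm$rg
  bundle$ldsc_pairs <- rgm$pairs

  # --- integrate ------------------------------------------------------------
  tryCatch({
    intg <- integrate_pairs(pearson_pairs, bundle$jaccard_pairs,
                            bundle$ldsc_pairs)
    tiers <- hub_tiers(intg$network, tier1_min = cfg$integration$tier1_min,
                       tier2_min = cfg$integration$tier2_min,
                       tier3_min = cfg$integration$tier3_min)
    stages <- c(stages, "integrate")
  }, error = function(e) stage_failed("integrate", e))
  emit("network_edges.tsv", function(o, p) write_tsv(o$edges, p), intg$network)
  emit("venn.json", function(o, p)
    jsonlite::write_json(unclass(o), p, auto_unbox = TRUE, digits = NA),
    intg$venn)
  bundle$network <- intg$network
  bundle$venn <- intg$venn
  bundle$hub_tiers <- tiers

  # --- pleiotropy -----------------------------------------------------------
  tryCatch({
    pleio <- snp_pleiotropy(scans, p_threshold = cfg$pleiotropy$p_threshold,
                            min_traits = cfg$pleiotropy$min_traits)
    tgs_fine <- trait_gene_sets(scans, bundle$gene_map,
                                p_threshold = cfg$pleiotropy$p_threshold,
                                window = cfg$mci$window)
    gene_pleio <- gene_pleiotropy(tgs_fine,
                                  min_traits = cfg$pleiotropy$min_traits,
                                  ppi = bundle$ppi)
    stages <- c(stages, "pleiotropy")
  }, error = function(e) stage_failed("pleiotropy", e))
  emit("pleiotropy_snp.tsv", function(o, p) write_tsv(o, p), pleio)
  emit("pleiotropy_gene.tsv", function(o, p) write_tsv(o, p), gene_pleio)
  bundle$snp_pleiotropy <- pleio
  bundle$gene_pleiotropy <- gene_pleio

  # --- catalogue_join -------------------------------------------------------
  tryCatch({
    cat_join <- catalogue_join(pleio, bundle$catalogue,
                               cat_p_max = cfg$catalogue$cat_p_max,
                               min_traits = cfg$catalogue$min_traits)
    stages <- c(stages, "catalogue_join")
  }, error = function(e) stage_failed("catalogue_join", e))
  emit("catalogue_join.tsv", function(o, p) write_tsv(o, p), cat_join)
  bundle$catalogue_join <- cat_join

  manifest <- list(
    package = "phenonet",
    version = as.character(utils::packageVersion("phenonet")),
    seed = seed,
    stages = stages,
    thresholds = list(qc = cfg$qc, pheno_corr = cfg$pheno_corr[1:3],
                      mci = cfg$mci, ldsc = cfg$ldsc,
                      pleiotropy = cfg$pleiotropy, catalogue = cfg$catalogue))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  invisible(bundle)
}
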