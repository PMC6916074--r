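# Fusion of the three evidence pair sets into a trait network, hub tiers,
# pleiotropy tallies and the catalogue cross-reference.

#' Integrate the three evidence pair sets into a trait network
#'
#' An edge is drawn for every pair in the union of the phenotypic-correlation,
#' MCI and LDSC pair sets; per-edge logical flags record which methods called
#' it. Venn counts (per-method totals, pairwise intersections inclusive of
#' the triple, triple intersection, union) are computed exactly and satisfy
#' inclusion-exclusion.
#'
#' @param pearson,jaccard,ldsc [pair_set()] objects over the same trait
#'   namespace (a mismatch in the recorded namespaces is an error naming the
#'   offending traits).
#' @return A list with `network` (class `trait_network`: `traits`, `edges`
#'   data frame with columns `trait1`, `trait2`, `pearson`, `jaccard`,
#'   `ldsc`; named `degree` vector) and `venn` (class `venn_counts`).
#' @export
integrate_pairs <- function(pearson, jaccard, ldsc) {
  sets <- list(pearson = pearson, jaccard = jaccard, ldsc = ldsc)
  namespaces <- lapply(sets, attr, "traits")
  traits <- sort(unique(unlist(namespaces)))
  for (nm in names(sets)) {
    ns <- namespaces[[nm]]
    if (!is.null(ns) && length(setdiff(traits, ns)))
      stop(sprintf("trait-name mismatch: %s set lacks traits %s",
                   nm, paste(setdiff(traits, ns), collapse = ", ")),
           call. = FALSE)
  }
  keys <- lapply(sets, function(s)
    if (nrow(s)) pair_key(s$trait1, s$trait2) else character(0))
  all_keys <- sort(unique(unlist(keys)))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  member <- matrix(member, ncol = 3,
                   dimnames = list(NULL, c("pearson", "jaccard", "ldsc")))
  parts <- do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  edges <- data.frame(trait1 = if (length(all_keys)) parts[, 1] else character(0),
                      trait2 = if (length(all_keys)) parts[, 2] else character(0),
                      pearson = member[, "pearson"],
                      jaccard = member[, "jaccard"],
                      ldsc = member[, "ldsc"],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$trait1, edges$trait2), , drop = FALSE]
  rownames(edges) <- NULL

  degree <- stats::setNames(rep(0L, length(traits)), traits)
  if (nrow(edges)) {
    tab <- table(c(edges$trait1, edges$trait2))
    degree[names(tab)] <- as.integer(tab)
  }
  venn <- structure(list(
    totals = colSums(member),
    pairwise = c(pearson_jaccard = sum(member[, 1] & member[, 2]),
                 pearson_ldsc = sum(member[, 1] & member[, 3]),
                 jaccard_ldsc = sum(member[, 2] & member[, 3])),
    triple = sum(member[, 1] & member[, 2] & member[, 3]),
    union = nrow(edges)), class = "venn_counts")
  net <- structure(list(traits = traits, edges = edges, degree = degree),
                   class = "trait_network")
  list(network = net, venn = venn)
}

#' @export
print.trait_network <- function(x, ...) {
  cat(sprintf("trait_network: %d traits, %d edges\n",
              length(x$traits), nrow(x$edges)))
  invisible(x)
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf(
    "venn_counts: totals %s; pairwise %s; triple %d; union %d\n",
    paste(x$totals, collapse = "/"), paste(x$pairwise, collapse = "/"),
    x$triple, x$union))
  invisible(x)
}

#' Assign hub tiers from node degree
#'
#' Tier 1 for degree at least `tier1_min` (connected to more than 20
#' traits), tier 2 for degrees between `tier2_min` and `tier1_min - 1`
#' (more than 15, up to 20), tier 3 between `tier3_min` and `tier2_min - 1`
#' (more than 10), otherwise `"none"`. Every node gets exactly one label.
#'
#' @param net a `trait_network` (or a named degree vector).
#' @param tier1_min,tier2_min,tier3_min lower degree bounds of the tiers.
#' @return Named character vector of tiers (`"1"`, `"2"`, `"3"`, `"none"`).
#' @export
hub_tiers <- function(net, tier1_min = 21L, tier2_min = 16L, tier3_min = 11L) {
  degree <- if (inherits(net, "trait_network")) net$degree else net
  if (!(tier3_min <= tier2_min && tier2_min <= tier1_min))
    stop_param("tier bounds", "must be ordered tier3_min <= tier2_min <= tier1_min")
  tier <- ifelse(degree >= tier1_min, "1",
                 ifelse(degree >= tier2_min, "2",
                        ifelse(degree >= tier3_min, "3", "none")))
  stats::setNames(tier, names(degree))
}

#' SNP-level pleiotropy table
#'
#' For every SNP, collects the traits whose scan p-value is strictly below
#' `p_threshold`, filters to SNPs hitting at least `min_traits` traits, and
#' sorts by descending trait count then variant id.
#'
#' @param scans named list of `assoc_scan` objects over a shared SNP panel.
#' @param p_threshold per-trait inclusion threshold.
#' @param min_traits minimum number of traits for a SNP to be reported.
#' @return Data frame `variant_id`, `trait_count`, `traits` (comma-joined),
#'   with attributes `p_threshold` and `min_traits`.
#' @export
snp_pleiotropy <- function(scans, p_threshold = 1e-3, min_traits = 3L) {
  min_traits <- check_count(min_traits, "min_traits", 1L)
  ids <- scans[[1]]$results$variant_id
  for (s in scans)
    if (!identical(s$results$variant_id, ids))
      stop("scans do not share the same SNP panel", call. = FALSE)
  hit <- vapply(scans, function(s)
    s$results$p < p_threshold & !s$results$degenerate, logical(length(ids)))
  hit <- matrix(hit, nrow = length(ids),
                dimnames = list(NULL, vapply(scans, `[[`, "", "trait")))
  count <- rowSums(hit)
  keep <- which(count >= min_traits)
  traits_str <- vapply(keep, function(i)
    paste(colnames(hit)[hit[i, ]], collapse = ","), character(1))
  out <- data.frame(variant_id = ids[keep],
                    trait_count = as.integer(count[keep]),
                    traits = traits_str, stringsAsFactors = FALSE)
  out <- out[order(-out$trait_count, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "p_threshold") <- p_threshold
  attr(out, "min_traits") <- min_traits
  out
}

#' Gene-level pleiotropy table
#'
#' Counts, for every gene, the traits whose gene set (built at the stated
#' scan threshold) contains it; filters to at least `min_traits`, and joins
#' the PPI degree when a network is supplied.
#'
#' @param tgs a [trait_gene_sets()].
#' @param min_traits minimum trait count.
#' @param ppi optional [ppi_network()] for the degree column.
#' @return Data frame `gene_id`, `trait_count` (and `ppi_degree` when `ppi`
#'   is given), sorted by descending count then gene id.
#' @export
gene_pleiotropy <- function(tgs, min_traits = 3L, ppi = NULL) {
  min_traits <- check_count(min_traits, "min_traits", 1L)
  all_genes <- unlist(lapply(tgs, as.character), use.names = FALSE)
  if (!length(all_genes))
    return(data.frame(gene_id = character(0), trait_count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(unlist(lapply(tgs, function(s) unique(as.character(s)))))
  out <- data.frame(gene_id = names(tab), trait_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$trait_count >= min_traits, , drop = FALSE]
  if (!is.null(ppi)) {
    stopifnot(inherits(ppi, "ppi_network"))
    deg <- stats::setNames(rep(0L, length(ppi$nodes)), ppi$nodes)
    tab2 <- table(c(ppi$edges$from, ppi$edges$to))
    deg[names(tab2)] <- as.integer(tab2)
    out$ppi_degree <- ifelse(out$gene_id %in% names(deg),
                             deg[out$gene_id], NA_integer_)
  }
  out <- out[order(-out$trait_count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_traits") <- min_traits
  out
}

#' Cross-reference pleiotropic SNPs against a catalogue table
#'
#' Intersects SNPs associated with at least `min_traits` traits in the
#' pipeline with catalogue records whose reported p is strictly below
#' `cat_p_max`.
#'
#' @param pleio a [snp_pleiotropy()] table.
#' @param cat catalogue data frame (`variant_id`, `phenotype`, `p`).
#' @param cat_p_max catalogue significance threshold.
#' @param min_traits minimum in-pipeline trait count.
#' @return Data frame `variant_id`, `trait_count`, `traits`,
#'   `catalogue_phenotypes` (comma-joined), `catalogue_min_p`.
#' @export
catalogue_join <- function(pleio, cat, cat_p_max = 1e-8, min_traits = 2L) {
  min_traits <- check_count(min_traits, "min_traits", 1L)
  p_sel <- pleio[pleio$trait_count >= min_traits, , drop = FALSE]
  c_sel <- cat[cat$p < cat_p_max, , drop = FALSE]
  keep <- p_sel$variant_id %in% c_sel$variant_id
  out <- p_sel[keep, , drop = FALSE]
  if (nrow(out)) {
    out$catalogue_phenotypes <- vapply(out$variant_id, function(id)
      paste(sort(unique(c_sel$phenotype[c_sel$variant_id == id])),
            collapse = ","), character(1))
    out$catalogue_min_p <- vapply(out$variant_id, function(id)
      min(c_sel$p[c_sel$variant_id == id]), numeric(1))
  } else {
    out$catalogue_phenotypes <- character(0)
    out$catalogue_min_p <- numeric(0)
  }
  rownames(out) <- NULL
  out
}
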