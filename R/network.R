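# SNP-to-gene mapping, interactome restriction, the molecular comorbidity
# index (MCI), and node topology statistics.

#' Map trait-associated SNPs to genes
#'
#' A gene is included when at least one SNP with scan p strictly below
#' `p_threshold` lies within the gene body extended by `window` bp on both
#' sides. Gene intervals follow the BED convention (0-based half-open), SNP
#' positions are 1-based; the conversion is handled internally, so a SNP at
#' 1-based position 101 falls inside the BED interval `[100, 200)`.
#'
#' @param scan an `assoc_scan`.
#' @param gene_map data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (BED convention).
#' @param p_threshold inclusion threshold on the scan p-value (strict).
#' @param window bp extension on both sides of each gene (default 10 kb).
#' @return Character vector of gene ids, with attributes `p_threshold`,
#'   `window` and `trait`.
#' @export
map_snps_to_genes <- function(scan, gene_map, p_threshold = 1e-3,
                              window = 10000L) {
  stopifnot(inherits(scan, "assoc_scan"))
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(gene_map)))
    stop_param("gene_map", paste("must have columns", paste(need, collapse = ", ")))
  if (any(gene_map$start >= gene_map$end))
    stop_param("gene_map", "start must be < end")
  r <- scan$results
  unmatched <- setdiff(unique(r$chrom), unique(gene_map$chrom))
  if (length(unmatched))
    stop(sprintf("chromosome name mismatch: %s absent from gene map",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  hits <- r[r$p < p_threshold & !r$degenerate, , drop = FALSE]
  genes <- character(0)
  if (nrow(hits)) {
    snp_gr <- GenomicRanges::GRanges(hits$chrom,
                                     IRanges::IRanges(hits$pos, width = 1))
    # BED [start, end) 0-based, +/- window -> 1-based closed
    gene_gr <- GenomicRanges::GRanges(
      gene_map$chrom,
      IRanges::IRanges(pmax(gene_map$start - window + 1L, 1L),
                       gene_map$end + window))
    ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
    genes <- sort(unique(gene_map$gene_id[S4Vectors::subjectHits(ov)]))
  }
  structure(genes, p_threshold = p_threshold, window = window,
            trait = scan$trait)
}

#' Build per-trait gene sets from all scans
#'
#' @param scans named list of `assoc_scan` objects.
#' @inheritParams map_snps_to_genes
#' @return Named list of gene-id vectors (class `trait_gene_sets`) with
#'   attributes `p_threshold` and `window`.
#' @export
trait_gene_sets <- function(scans, gene_map, p_threshold = 1e-3,
                            window = 10000L) {
  sets <- lapply(scans, map_snps_to_genes, gene_map = gene_map,
                 p_threshold = p_threshold, window = window)
  names(sets) <- vapply(scans, function(s) s$trait, character(1))
  structure(sets, p_threshold = p_threshold, window = window,
            class = "trait_gene_sets")
}

#' Restrict trait gene sets to the interactome
#'
#' Intersects each trait's gene set with the PPI node set, mirroring the loss
#' of genes without curated interactions; the per-trait dropped counts are
#' attached as attribute `"n_dropped"`.
#'
#' @param tgs a [trait_gene_sets()] (or plain named list of gene-id vectors).
#' @param ppi a [ppi_network()].
#' @return The restricted `trait_gene_sets`.
#' @export
restrict_to_interactome <- function(tgs, ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  out <- lapply(tgs, function(s) intersect(as.character(s), ppi$nodes))
  attributes(out) <- attributes(tgs)
  names(out) <- names(tgs)
  attr(out, "n_dropped") <- vapply(seq_along(tgs), function(i)
    length(tgs[[i]]) - length(out[[i]]), integer(1))
  out
}

# genes in `from` with at least one PPI neighbour in `to`
cross_interactors <- function(from, to, edges) {
  hit <- (edges$from %in% from & edges$to %in% to) |
    (edges$to %in% from & edges$from %in% to)
  e <- edges[hit, , drop = FALSE]
  intersect(from, c(e$from, e$to))
}

#' Molecular comorbidity index for two gene sets
#'
#' A Jaccard-style index augmented with direct PPI cross-interactors: the
#' numerator is the size of the union of the set intersection, the genes of
#' set 1 directly interacting with set 2, and the genes of set 2 directly
#' interacting with set 1; the denominator is the size of the set union.
#' With an edgeless PPI this reduces exactly to the Jaccard index, and adding
#' PPI edges can only increase it. Symmetric by construction, in `[0, 1]`.
#'
#' @param set1,set2 gene-id vectors.
#' @param ppi a [ppi_network()].
#' @return The index, or `NA` when both sets are empty (undefined).
#' @export
mci <- function(set1, set2, ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  set1 <- unique(as.character(set1))
  set2 <- unique(as.character(set2))
  denom <- union(set1, set2)
  if (!length(denom)) return(NA_real_)
  num <- union(intersect(set1, set2),
               union(cross_interactors(set1, set2, ppi$edges),
                     cross_interactors(set2, set1, ppi$edges)))
  length(num) / length(denom)
}

#' MCI matrix over all trait pairs
#'
#' Full symmetric matrix of pairwise [mci()] values plus the pair set with
#' MCI strictly over `mci_min`. The diagonal is 1 for traits with a non-empty
#' gene set and `NA` otherwise; pairs where both sets are empty are `NA` and
#' tallied in the coverage attribute `"n_undefined_pairs"`. Per-pair
#' component counts (intersection, the two cross-interactor sets, union) are
#' attached as the `components` field.
#'
#' @param tgs a [trait_gene_sets()] (typically interactome-restricted).
#' @param ppi a [ppi_network()].
#' @param mci_min pair-calling threshold (strict; a value of exactly
#'   `mci_min` is excluded).
#' @return A list with `mci` (class `mci_matrix`: fields `trait_names`, `m`,
#'   `components`) and `pairs` (a [pair_set()] with provenance `"jaccard"`).
#' @export
mci_matrix <- function(tgs, ppi, mci_min = 0.6) {
  stopifnot(inherits(ppi, "ppi_network"))
  nm <- names(tgs)
  if (length(nm) < 2L) stop_param("tgs", "needs at least 2 traits")
  T <- length(nm)
  M <- matrix(NA_real_, T, T, dimnames = list(nm, nm))
  comp <- array(NA_integer_, dim = c(T, T, 4),
                dimnames = list(nm, nm,
                                c("intersection", "cross_1to2",
                                  "cross_2to1", "union")))
  for (i in seq_len(T)) {
    if (length(tgs[[i]])) M[i, i] <- 1
    for (j in seq_len(T)[-seq_len(i)]) {
      s1 <- unique(as.character(tgs[[i]]))
      s2 <- unique(as.character(tgs[[j]]))
      M[i, j] <- M[j, i] <- mci(s1, s2, ppi)
      comp[i, j, ] <- comp[j, i, c(1, 3, 2, 4)] <- c(
        length(intersect(s1, s2)),
        length(cross_interactors(s1, s2, ppi$edges)),
        length(cross_interactors(s2, s1, ppi$edges)),
        length(union(s1, s2)))
    }
  }
  up <- upper.tri(M)
  sel <- which(up & !is.na(M) & M > mci_min, arr.ind = TRUE)
  pairs <- pair_set(nm[sel[, 1]], nm[sel[, 2]], provenance = "jaccard",
                    traits = nm, thresholds = c(mci_min = mci_min))
  mm <- structure(list(trait_names = nm, m = M, components = comp),
                  class = "mci_matrix")
  attr(mm, "n_undefined_pairs") <- sum(up & is.na(M))
  list(mci = mm, pairs = pairs)
}

#' @export
print.mci_matrix <- function(x, ...) {
  cat(sprintf("mci_matrix: %d traits, %d undefined pairs\n",
              length(x$trait_names), attr(x, "n_undefined_pairs") %||% 0L))
  invisible(x)
}

#' Node topology statistics on an induced PPI subgraph
#'
#' On the subgraph induced by `nodes`: degree; local clustering coefficient
#' (`2*triangles / (deg*(deg-1))`, 0 for degree below 2); topological
#' coefficient (the average, over nodes sharing at least one neighbour, of
#' the shared-neighbour count plus 1 if adjacent, divided by the node's
#' degree; 0 for degree below 2); and closeness centrality computed within
#' each connected component as `(reachable - 1) / sum(distances)`.
#'
#' @param ppi a [ppi_network()].
#' @param nodes subset of nodes to induce; default all.
#' @return Data frame with columns `gene`, `degree`, `clustering`,
#'   `topological`, `closeness`.
#' @export
node_stats <- function(ppi, nodes = NULL) {
  stopifnot(inherits(ppi, "ppi_network"))
  nodes <- nodes %||% ppi$nodes
  bad <- setdiff(nodes, ppi$nodes)
  if (length(bad)) stop_param("nodes", "must be a subset of the PPI node set")
  g <- igraph::induced_subgraph(ppi_igraph(ppi), vids = as.character(nodes))
  nm <- igraph::V(g)$name
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[deg < 2] <- 0

  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  Sh <- A %*% A                       # shared-neighbour counts
  J <- Sh + A                         # +1 when also adjacent
  topo <- vapply(seq_along(nm), function(i) {
    if (deg[i] < 2) return(0)
    sh <- Sh[i, ]
    partners <- which(sh > 0)
    partners <- partners[partners != i]
    if (!length(partners)) return(0)
    mean(J[i, partners]) / deg[i]
  }, numeric(1))

  D <- igraph::distances(g)
  clo <- vapply(seq_along(nm), function(i) {
    d <- D[i, ]
    d <- d[is.finite(d) & d > 0]
    if (!length(d)) return(0)
    length(d) / sum(d)
  }, numeric(1))

  data.frame(gene = nm, degree = as.integer(deg), clustering = cc,
             topological = topo, closeness = clo,
             stringsAsFactors = FALSE, row.names = NULL)
}
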