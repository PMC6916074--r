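# Synthetic gene maps, PPI networks and catalogue tables.

#' Construct a PPI network
#'
#' Undirected simple graph over gene/protein identifiers. Self-loops and
#' duplicate edges are rejected; the node set may extend beyond edge
#' endpoints (singletons).
#'
#' @param edges data frame (or two-column matrix) of endpoints.
#' @param nodes optional node identifiers; defaults to the edge endpoints.
#' @return An object of class `ppi_network` with fields `nodes` and `edges`.
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop_param("edges", "needs two endpoint columns")
  edges <- data.frame(from = as.character(edges[[1]]),
                      to = as.character(edges[[2]]),
                      stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) stop_param("edges", "self-loops not allowed")
  key <- pair_key(edges$from, edges$to)
  if (anyDuplicated(key)) stop_param("edges", "duplicate edges not allowed")
  nodes <- sort(unique(c(as.character(nodes), edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

ppi_igraph <- function(ppi) {
  stopifnot(inherits(ppi, "ppi_network"))
  igraph::graph_from_data_frame(ppi$edges, directed = FALSE,
                                vertices = data.frame(name = ppi$nodes))
}

#' Simulate a gene map tiling the panel and a scale-free PPI network
#'
#' Genes tile each chromosome as non-overlapping 0-based half-open intervals
#' that jointly cover every SNP position (a partition of the covered span, so
#' with window 0 each SNP maps to exactly one gene). The PPI graph is grown by
#' preferential attachment over the gene identifiers, giving the heavy-tailed
#' degree distribution typical of curated interactomes; gene ids are assigned
#' to graph nodes in random order so genomic position and connectivity are
#' independent.
#'
#' @param panel a [genotype_panel()].
#' @param n_genes number of genes (>= 2).
#' @param mean_degree target mean PPI degree (> 0); realized mean degree is
#'   `2*round(mean_degree/2)` up to preferential-attachment edge rounding.
#' @param seed integer seed.
#' @return A list with `gene_map` (data frame `gene_id`, `chrom`, `start`,
#'   `end` in BED convention) and `ppi` (a [ppi_network()]).
#' @export
simulate_gene_map_and_ppi <- function(panel, n_genes, mean_degree = 4,
                                      seed = 1L) {
  stopifnot(inherits(panel, "genotype_panel"))
  n_genes <- check_count(n_genes, "n_genes", 2L)
  if (!is.numeric(mean_degree) || length(mean_degree) != 1L || mean_degree <= 0)
    stop_param("mean_degree", "must be a positive number")
  set.seed(check_count(seed, "seed", 0L))

  v <- panel$variants
  chroms <- unique(v$chrom)
  snps_per_chrom <- table(factor(v$chrom, levels = chroms))
  # allocate genes proportionally to SNP counts, at least one per chromosome
  alloc <- pmax(1L, round(n_genes * as.numeric(snps_per_chrom) / nrow(v)))
  while (sum(alloc) != n_genes) {
    i <- which.max(alloc)
    alloc[i] <- alloc[i] + sign(n_genes - sum(alloc))
  }

  maps <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    pos <- v$pos[v$chrom == chroms[ci]]
    k <- alloc[ci]
    # breakpoints at midpoints between consecutive SNPs; 0-based half-open
    # tiles [0, b1), [b1, b2), ..., [b_{k-1}, max_pos] cover every position
    if (k > 1L) {
      if (length(pos) < k)
        stop_param("n_genes", sprintf(
          "chromosome %s has fewer SNPs than allocated genes", chroms[ci]))
      mids <- floor((pos[-1] + pos[-length(pos)]) / 2)
      breaks <- sort(sample(mids, k - 1L))
    } else breaks <- integer(0)
    start0 <- c(0L, as.integer(breaks))
    end0 <- c(as.integer(breaks), max(pos))
    maps[[ci]] <- data.frame(chrom = chroms[ci], start = start0, end = end0,
                             stringsAsFactors = FALSE)
  }
  gene_map <- do.call(rbind, maps)
  gene_map <- data.frame(gene_id = sprintf("gene%04d", seq_len(nrow(gene_map))),
                         gene_map, stringsAsFactors = FALSE)

  m_pa <- max(1L, round(mean_degree / 2))
  g <- igraph::sample_pa(n_genes, m = m_pa, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  perm <- sample(gene_map$gene_id)      # decouple degree from genomic order
  edges <- unique(canonical_pairs(perm[el[, 1]], perm[el[, 2]]))
  ppi <- ppi_network(edges, nodes = gene_map$gene_id)
  list(gene_map = gene_map, ppi = ppi)
}

#' Simulate a catalogue of externally reported SNP-phenotype associations
#'
#' A random fraction of the supplied SNPs receives 1 to 3 phenotype records
#' with association p-values drawn log-uniformly over `[1e-30, 1e-4]`,
#' emulating a genome-wide association catalogue extract.
#'
#' @param snps character vector of variant ids.
#' @param n_phenotypes size of the phenotype label pool.
#' @param frac_annotated fraction of SNPs annotated, in `[0, 1]`.
#' @param seed integer seed.
#' @return Data frame with columns `variant_id`, `phenotype`, `p`.
#' @export
simulate_catalogue <- function(snps, n_phenotypes = 20L, frac_annotated = 0.1,
                               seed = 1L) {
  n_phenotypes <- check_count(n_phenotypes, "n_phenotypes", 1L)
  frac_annotated <- check_prob(frac_annotated, "frac_annotated")
  set.seed(check_count(seed, "seed", 0L))
  snps <- as.character(snps)
  n_sel <- round(frac_annotated * length(snps))
  if (n_sel == 0L)
    return(data.frame(variant_id = character(0), phenotype = character(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  sel <- sample(snps, n_sel)
  reps <- sample(1:3, n_sel, replace = TRUE)
  id <- rep(sel, reps)
  data.frame(
    variant_id = id,
    phenotype = sprintf("phenotype_%02d",
                        sample.int(n_phenotypes, length(id), replace = TRUE)),
    p = 10^stats::runif(length(id), -30, -4),
    stringsAsFactors = FALSE)
}
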