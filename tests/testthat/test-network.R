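# SNP-to-gene mapping, interactome restriction, the molecular comorbidity
# index, and node topology statistics.

fake_scan <- function(df, trait = "t1") {
  res <- data.frame(variant_id = sprintf("v%03d", seq_len(nrow(df))),
                    chrom = df$chrom, pos = df$pos, A1 = "A", A2 = "G",
                    n_used = 100L, n_geno = 100L, beta = 0.1, se = 0.05,
                    t_stat = 2, p = df$p, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  structure(list(trait = trait, results = res, lambda_gc = 1,
                 covariate_names = character(0)), class = "assoc_scan")
}

test_that("SNP-gene overlap handles the 0-based/1-based conversion", {
  gm <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                   start = c(100L, 200L), end = c(200L, 300L))
  # 1-based 101 is 0-based 100: inside gA only; 1-based 200 inside gA
  # (0-based 199 < 200); 1-based 201 inside gB
  sc <- fake_scan(data.frame(chrom = "1", pos = c(101L, 200L, 201L),
                             p = c(1e-5, 0.5, 1e-5)))
  genes <- map_snps_to_genes(sc, gm, p_threshold = 1e-3, window = 0)
  expect_identical(as.character(genes), c("gA", "gB"))
  # window extension pulls a nearby gene in
  sc2 <- fake_scan(data.frame(chrom = "1", pos = 95L, p = 1e-5))
  expect_length(map_snps_to_genes(sc2, gm, window = 0), 0)
  expect_identical(as.character(map_snps_to_genes(sc2, gm, window = 10)), "gA")
})

test_that("no significant SNPs gives an empty set; threshold 1 saturates", {
  gm <- data.frame(gene_id = "gA", chrom = "1", start = 0L, end = 10000L)
  sc <- fake_scan(data.frame(chrom = "1", pos = c(10L, 20L), p = c(0.5, 0.9)))
  expect_length(map_snps_to_genes(sc, gm, p_threshold = 1e-3), 0)
  expect_identical(as.character(map_snps_to_genes(sc, gm, p_threshold = 1.0)),
                   "gA")
})

test_that("chromosome mismatches raise a named error", {
  gm <- data.frame(gene_id = "gA", chrom = "1", start = 0L, end = 1000L)
  sc <- fake_scan(data.frame(chrom = c("1", "7"), pos = c(10L, 10L),
                             p = c(0.1, 0.1)))
  expect_error(map_snps_to_genes(sc, gm), "7")
})

test_that("interactome restriction intersects with the node set", {
  tgs <- structure(list(t1 = c("a", "b", "x"), t2 = c("b", "y")),
                   class = "trait_gene_sets")
  ppi <- ppi_network(data.frame(from = "a", to = "b"), nodes = c("a", "b"))
  out <- restrict_to_interactome(tgs, ppi)
  expect_identical(out$t1, c("a", "b"))
  expect_identical(out$t2, "b")
  expect_equal(attr(out, "n_dropped"), c(1L, 1L))
  empty <- restrict_to_interactome(tgs, ppi_network(
    data.frame(from = character(0), to = character(0)), nodes = "zz"))
  expect_length(empty$t1, 0)
})

test_that("MCI matches its hand-worked examples", {
  no_edges <- ppi_network(data.frame(from = character(0), to = character(0)),
                          nodes = letters[1:6])
  # identical sets: numerator contains the whole union
  expect_equal(mci(c("a", "b", "c"), c("a", "b", "c"), no_edges), 1)
  # disjoint sets with no interactions
  expect_equal(mci(c("a", "b"), c("c", "d"), no_edges), 0)
  # one cross edge makes every member of the union count
  e_ac <- ppi_network(data.frame(from = "a", to = "c"),
                      nodes = letters[1:4])
  expect_equal(mci(c("a", "b"), c("b", "c"), e_ac), 1)
  # both sets empty: undefined
  expect_true(is.na(mci(character(0), character(0), no_edges)))
})

test_that("MCI agrees with exhaustive enumeration on random instances", {
  set.seed(81)
  universe <- sprintf("g%02d", 1:12)
  for (i in 1:300) {
    ppi <- random_ppi(12, runif(1, 0, 0.4), seed = 8000 + i)
    s1 <- sample(universe, sample(0:6, 1))
    s2 <- sample(universe, sample(1:6, 1))
    expect_equal(mci(s1, s2, ppi), oracle_mci(s1, s2, ppi$edges),
                 tolerance = 1e-12)
  }
})

test_that("MCI is symmetric, bounded, Jaccard-degenerate and edge-monotone", {
  set.seed(82)
  universe <- sprintf("g%02d", 1:10)
  for (i in 1:100) {
    ppi <- random_ppi(10, runif(1, 0, 0.5), seed = 9000 + i)
    s1 <- sample(universe, sample(1:5, 1))
    s2 <- sample(universe, sample(1:5, 1))
    v <- mci(s1, s2, ppi)
    expect_equal(v, mci(s2, s1, ppi), tolerance = 1e-12)
    expect_gte(v, 0); expect_lte(v, 1)
    # edgeless PPI reduces exactly to the Jaccard index
    jac <- length(intersect(s1, s2)) / length(union(s1, s2))
    expect_equal(mci(s1, s2, ppi_network(
      data.frame(from = character(0), to = character(0)),
      nodes = universe)), jac, tolerance = 1e-12)
    # adding one edge never decreases the index
    missing_pairs <- setdiff(pair_key(rep(universe, each = 10),
                                      rep(universe, 10)),
                             c(pair_key(ppi$edges$from, ppi$edges$to),
                               pair_key(universe, universe)))
    if (length(missing_pairs)) {
      add <- strsplit(sample(missing_pairs, 1), "\r", fixed = TRUE)[[1]]
      ppi2 <- ppi_network(rbind(ppi$edges,
                                data.frame(from = add[1], to = add[2])),
                          nodes = universe)
      expect_gte(mci(s1, s2, ppi2), v - 1e-12)
    }
  }
})

test_that("mci_matrix equals elementwise mci and calls pairs strictly", {
  set.seed(83)
  ppi <- random_ppi(15, 0.2, seed = 84)
  tgs <- structure(lapply(1:5, function(i) sample(ppi$nodes, sample(2:8, 1))),
                   class = "trait_gene_sets")
  names(tgs) <- sprintf("t%d", 1:5)
  out <- mci_matrix(tgs, ppi, mci_min = 0.6)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(out$mci$m[i, j], mci(tgs[[i]], tgs[[j]], ppi),
                 tolerance = 1e-12)
  expect_equal(unname(diag(out$mci$m)), rep(1, 5))
  called <- pair_key(out$pairs$trait1, out$pairs$trait2)
  for (i in 1:4) for (j in (i + 1):5) {
    k <- pair_key(names(tgs)[i], names(tgs)[j])
    expect_equal(k %in% called, out$mci$m[i, j] > 0.6)
  }
})

test_that("MCI of exactly the threshold is excluded from the pair set", {
  # two sets with Jaccard exactly 0.6 on an edgeless PPI: 3 shared of 5
  ppi <- ppi_network(data.frame(from = character(0), to = character(0)),
                     nodes = letters[1:7])
  tgs <- structure(list(t1 = c("a", "b", "c", "d"), t2 = c("b", "c", "d", "e")),
                   class = "trait_gene_sets")
  out <- mci_matrix(tgs, ppi, mci_min = 0.6)
  expect_equal(out$mci$m[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(nrow(out$pairs), 0)
})

test_that("node statistics match closed forms on canonical graphs", {
  # triangle: degree 2, clustering 1, closeness 1
  tri <- ppi_network(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")))
  ns <- node_stats(tri)
  expect_equal(ns$degree, rep(2L, 3))
  expect_equal(ns$clustering, rep(1, 3))
  expect_equal(ns$closeness, rep(1, 3))
  # star S4: centre degree 4, clustering 0
  star <- ppi_network(data.frame(from = "hub", to = paste0("s", 1:4)))
  ns2 <- node_stats(star)
  hub <- ns2[ns2$gene == "hub", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$clustering, 0)
  # leaves have degree 1 -> clustering and topological coefficient 0
  expect_true(all(ns2$clustering[ns2$gene != "hub"] == 0))
  expect_true(all(ns2$topological[ns2$gene != "hub"] == 0))
})

test_that("node statistics match brute force on random graphs", {
  for (i in 1:10) {
    ppi <- random_ppi(10, 0.3, seed = 8500 + i)
    got <- node_stats(ppi)
    want <- oracle_node_stats(ppi$nodes, ppi$edges)
    got <- got[order(got$gene), ]; want <- want[order(want$gene), ]
    expect_equal(got$degree, want$degree)
    expect_equal(got$clustering, want$clustering, tolerance = 1e-12)
    expect_equal(got$topological, want$topological, tolerance = 1e-12)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
  }
})

test_that("node_stats restricts to the induced subgraph", {
  ppi <- ppi_network(data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
  ns <- node_stats(ppi, nodes = c("a", "b", "d"))
  expect_setequal(ns$gene, c("a", "b", "d"))
  # edge c is gone, so d is isolated in the induced subgraph
  expect_equal(ns$degree[ns$gene == "d"], 0L)
  expect_error(node_stats(ppi, nodes = "zzz"), "subset")
})
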