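# Independent oracles used to check the package's implementations.
# These are deliberately naive (explicit formulas, nested loops, exhaustive
# enumeration) and share no code with the implementation paths they verify.

# OLS by explicit normal equations: y ~ [1, covars, x]; returns the
# coefficient, SE, t and two-sided p for x.
oracle_ols <- function(y, x, covars = NULL) {
  X <- cbind(1, covars, x)
  XtX <- t(X) %*% X
  bhat <- solve(XtX, t(X) %*% y)
  res <- y - X %*% bhat
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  j <- ncol(X)
  beta <- bhat[j]
  se <- sqrt(covb[j, j])
  tt <- beta / se
  list(beta = beta, se = se, t = tt, p = 2 * pt(-abs(tt), df), df = df)
}

# MCI by exhaustive elementwise enumeration over the Methods-style formula
oracle_mci <- function(set1, set2, edges) {
  set1 <- unique(set1); set2 <- unique(set2)
  denom <- unique(c(set1, set2))
  if (length(denom) == 0) return(NA_real_)
  adj <- function(a, b) {
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  }
  numerator <- character(0)
  for (g in denom) {
    in1 <- g %in% set1; in2 <- g %in% set2
    if (in1 && in2) { numerator <- c(numerator, g); next }
    if (in1 && any(vapply(set2, function(h) adj(g, h), logical(1))))
      numerator <- c(numerator, g)
    if (in2 && any(vapply(set1, function(h) adj(g, h), logical(1))))
      numerator <- c(numerator, g)
  }
  length(unique(numerator)) / length(denom)
}

# brute-force node statistics on an edge list (undirected simple graph)
oracle_node_stats <- function(nodes, edges) {
  nbrs <- function(v) unique(c(edges$to[edges$from == v],
                               edges$from[edges$to == v]))
  adj <- function(a, b) b %in% nbrs(a)
  # BFS shortest paths
  dist_from <- function(v) {
    d <- setNames(rep(Inf, length(nodes)), nodes)
    d[v] <- 0
    frontier <- v
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) for (w in nbrs(u)) if (is.infinite(d[w])) {
        d[w] <- d[u] + 1
        nxt <- c(nxt, w)
      }
      frontier <- unique(nxt)
    }
    d
  }
  out <- data.frame(gene = nodes, degree = NA_integer_, clustering = NA_real_,
                    topological = NA_real_, closeness = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    nv <- nbrs(v)
    k <- length(nv)
    out$degree[i] <- k
    if (k < 2) out$clustering[i] <- 0 else {
      tri <- 0
      for (a in seq_len(k - 1)) for (b in (a + 1):k)
        if (adj(nv[a], nv[b])) tri <- tri + 1
      out$clustering[i] <- 2 * tri / (k * (k - 1))
    }
    if (k < 2) out$topological[i] <- 0 else {
      js <- c()
      for (m in setdiff(nodes, v)) {
        shared <- length(intersect(nv, nbrs(m)))
        if (shared > 0) js <- c(js, shared + as.integer(adj(v, m)))
      }
      out$topological[i] <- if (length(js)) mean(js) / k else 0
    }
    d <- dist_from(v)
    d <- d[is.finite(d) & d > 0]
    out$closeness[i] <- if (length(d)) length(d) / sum(d) else 0
  }
  out
}

# random PPI fixture
random_ppi <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("g%02d", seq_len(n_nodes))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p_edge
  ppi_network(data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                         stringsAsFactors = FALSE), nodes = nodes)
}

# small deterministic genotype panel built by hand
tiny_panel <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  genotype_panel(
    sprintf("s%02d", seq_len(nrow(dosage))),
    data.frame(variant_id = sprintf("v%03d", seq_len(m)),
               chrom = chrom %||% rep("1", m),
               pos = pos %||% (seq_len(m) * 1000L),
               A1 = "A", A2 = "G", stringsAsFactors = FALSE),
    dosage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

traits30 <- sprintf("T%02d", 1:30)

# build three pair sets over `traits` with prescribed Venn-region sizes, by
# walking the enumeration of all unordered pairs
sets_with_venn <- function(traits, triple, pj_only, pl_only, jl_only,
                           p_only, j_only, l_only) {
  all_pairs <- t(combn(traits, 2))
  take <- function(n, from) seq_len(n) + from
  at <- 0
  reg <- list(triple = take(triple, at)); at <- at + triple
  reg$pj <- take(pj_only, at); at <- at + pj_only
  reg$pl <- take(pl_only, at); at <- at + pl_only
  reg$jl <- take(jl_only, at); at <- at + jl_only
  reg$p <- take(p_only, at); at <- at + p_only
  reg$j <- take(j_only, at); at <- at + j_only
  reg$l <- take(l_only, at); at <- at + l_only
  stopifnot(at <= nrow(all_pairs))
  mk <- function(rows, prov) pair_set(all_pairs[rows, 1], all_pairs[rows, 2],
                                      provenance = prov, traits = traits)
  list(pearson = mk(c(reg$triple, reg$pj, reg$pl, reg$p), "pearson"),
       jaccard = mk(c(reg$triple, reg$pj, reg$jl, reg$j), "jaccard"),
       ldsc = mk(c(reg$triple, reg$pl, reg$jl, reg$l), "ldsc"))
}
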