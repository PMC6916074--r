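# LD scores and LD score regression: definitional contracts and small-scale
# statistical behaviour (full-scale parameter recovery lives in the
# acceptance suite).

test_that("window 0 gives the self term only", {
  p <- simulate_genotypes(100, 50, block_size = 10, seed = 61)
  ld <- ld_scores(p, window_kb = 0)
  expect_equal(ld$L2, rep(1, 50))
})

test_that("a duplicated SNP column doubles the LD score", {
  set.seed(62)
  d <- rbinom(200, 2, 0.4)
  other <- rbinom(200, 2, 0.3)
  # two identical columns adjacent; a third SNP far outside the window
  p <- tiny_panel(cbind(d, d, other), pos = c(1000L, 2000L, 900000L))
  ld <- ld_scores(p, window_kb = 10)
  expect_equal(ld$L2[1:2], c(2, 2), tolerance = 1e-9)
  expect_equal(ld$L2[3], 1)
})

test_that("independent SNPs have mean LD score near 1 after bias correction", {
  means <- vapply(1:10, function(s) {
    p <- simulate_genotypes(150, 200, block_size = 10, within_block_r = 0,
                            seed = 62 + s)
    mean(ld_scores(p, window_kb = 50)$L2)
  }, numeric(1))
  expect_lt(abs(mean(means) - 1), 0.02)
  # without correction, each of ~100 window neighbours adds ~1/(n-1)
  p <- simulate_genotypes(150, 200, block_size = 10, within_block_r = 0,
                          seed = 99)
  raw <- ld_scores(p, window_kb = 50, bias_correct = FALSE)
  expect_gt(mean(raw$L2), 1.3)
})

test_that("LD scores respect the window and chromosome boundaries", {
  p <- simulate_genotypes(300, 200, block_size = 50, n_chrom = 2,
                          within_block_r = 0.95, seed = 64)
  ld_narrow <- ld_scores(p, window_kb = 5)
  ld_wide <- ld_scores(p, window_kb = 100)
  expect_true(all(ld_wide$L2 - ld_narrow$L2 > -1e-6))
  expect_gt(mean(ld_wide$L2), mean(ld_narrow$L2))
})

test_that("bias correction requires 3 reference samples", {
  p <- tiny_panel(matrix(c(0L, 1L, 2L, 1L), 2, 2))
  expect_error(ld_scores(p), "3 reference samples")
})

test_that("constant chi-square gives slope 0 and intercept 1", {
  p <- simulate_genotypes(200, 300, block_size = 20, seed = 65)
  ld <- ld_scores(p, window_kb = 50)
  ss <- data.frame(SNP = ld$variant_id, A1 = "A", A2 = "G",
                   N = 200L, Z = 1)
  class(ss) <- c("sumstats", "data.frame")
  h <- h2_regression(ss, ld)
  expect_equal(h$h2, 0, tolerance = 1e-10)
  expect_equal(h$intercept, 1, tolerance = 1e-10)
  expect_equal(h$se_h2, 0, tolerance = 1e-10)
})

test_that("a trait regressed on itself has rg exactly 1", {
  p <- simulate_genotypes(500, 600, block_size = 20, seed = 66)
  a <- simulate_architecture(p, 1, 600, h2 = 0.4, seed = 67)
  ph <- simulate_traits(p, a, seed = 68)
  ss <- to_sumstats(run_scan(p, ph)[[1]])
  ld <- ld_scores(p, window_kb = 50)
  r <- rg_estimate(ss, ss, ld)
  expect_equal(r$rg, 1, tolerance = 1e-12)
  expect_equal(r$rho_g, r$h2_1, tolerance = 1e-12)
})

test_that("allele alignment flips swapped Z and negates rg", {
  p <- simulate_genotypes(500, 600, block_size = 20, seed = 69)
  a <- simulate_architecture(p, 2, 600, h2 = c(0.4, 0.4),
                             genetic_corr = matrix(c(1, .8, .8, 1), 2),
                             seed = 70)
  ph <- simulate_traits(p, a, seed = 71)
  ss <- lapply(run_scan(p, ph), to_sumstats)
  ld <- ld_scores(p, window_kb = 50)
  r0 <- rg_estimate(ss[[1]], ss[[2]], ld)
  # swap the allele labels (and the Z sign) of the second trait: the
  # estimate must be invariant because alignment flips it back
  ss_sw <- ss[[2]]
  ss_sw$A1 <- ss[[2]]$A2; ss_sw$A2 <- ss[[2]]$A1; ss_sw$Z <- -ss[[2]]$Z
  r_sw <- rg_estimate(ss[[1]], ss_sw, ld)
  expect_equal(r_sw$rg, r0$rg, tolerance = 1e-12)
  # mismatched allele pairs are dropped
  ss_bad <- ss[[2]]
  ss_bad$A1[1:10] <- "T"
  r_bad <- rg_estimate(ss[[1]], ss_bad, ld)
  expect_equal(r_bad$n_dropped_alleles, 10)
  expect_equal(r_bad$M, r0$M - 10)
})

test_that("rg symmetry holds to numerical tolerance", {
  p <- simulate_genotypes(400, 400, block_size = 20, seed = 72)
  a <- simulate_architecture(p, 2, 400, h2 = c(0.5, 0.5),
                             genetic_corr = matrix(c(1, .5, .5, 1), 2),
                             seed = 73)
  ph <- simulate_traits(p, a, seed = 74)
  ss <- lapply(run_scan(p, ph), to_sumstats)
  ld <- ld_scores(p, window_kb = 50)
  r12 <- rg_estimate(ss[[1]], ss[[2]], ld)
  r21 <- rg_estimate(ss[[2]], ss[[1]], ld)
  expect_equal(r12$rg, r21$rg, tolerance = 1e-10)
  expect_equal(r12$se_rg, r21$se_rg, tolerance = 1e-10)
})

test_that("rg_matrix evaluates all unordered pairs and flags outliers", {
  p <- simulate_genotypes(300, 400, block_size = 20, seed = 75)
  # 4 traits: two heritable and correlated, two pure noise (h2 = 0, whose
  # rg is undefined and must be flagged, feeding outlier removal)
  gc4 <- diag(4); gc4[1, 2] <- gc4[2, 1] <- 0.8
  a <- simulate_architecture(p, 4, 400, h2 = c(0.5, 0.5, 0, 0),
                             genetic_corr = gc4, seed = 76)
  ph <- simulate_traits(p, a, seed = 77)
  ss <- lapply(run_scan(p, ph), to_sumstats)
  ld <- ld_scores(p, window_kb = 50)
  out <- rg_matrix(ss, ld, n_blocks = 10)
  expect_equal(nrow(out$rg$pairs), choose(4, 2))
  expect_true(all(out$rg$pairs$outlier[
    out$rg$pairs$trait1 %in% c("trait03", "trait04") |
      out$rg$pairs$trait2 %in% c("trait03", "trait04")] |
      is.finite(out$rg$pairs$rg[
        out$rg$pairs$trait1 %in% c("trait03", "trait04") |
          out$rg$pairs$trait2 %in% c("trait03", "trait04")])))
  # the significant set never contains an outlier pair
  if (nrow(out$pairs))
    expect_true(all(!out$rg$pairs$outlier[
      pair_key(out$rg$pairs$trait1, out$rg$pairs$trait2) %in%
        pair_key(out$pairs$trait1, out$pairs$trait2)]))
  # symmetry of the matrices where defined
  expect_equal(out$rg$rg, t(out$rg$rg), tolerance = 1e-10)
})

test_that("too few shared SNPs for the jackknife is an error", {
  p <- simulate_genotypes(100, 30, block_size = 10, seed = 78)
  ld <- ld_scores(p, window_kb = 10)
  ss <- data.frame(SNP = ld$variant_id, A1 = "A", A2 = "G", N = 100L,
                   Z = rnorm(30))
  class(ss) <- c("sumstats", "data.frame")
  expect_error(h2_regression(ss, ld, n_blocks = 20), "at least")
})
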