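# Association scan: OLS oracle equivalence, calibration, diagnostics,
# and sumstats reduction.

scan_fixture <- function(seed = 31, n = 400, m = 300) {
  p <- simulate_genotypes(n, m, block_size = 20, seed = seed)
  a <- simulate_architecture(p, 2, n_causal = max(10, m %/% 10),
                             h2 = c(0, 0), seed = seed + 1)
  ph <- simulate_traits(p, a, seed = seed + 2)
  list(panel = p, pheno = ph)
}

test_that("scan matches the explicit normal-equations oracle", {
  # many small random instances, covariate-adjusted, compared at 1e-10
  set.seed(32)
  for (rep in 1:20) {
    n <- sample(15:50, 1)
    m <- sample(3:8, 1)
    d <- matrix(rbinom(n * m, 2, runif(1, 0.2, 0.5)), n, m)
    if (any(apply(d, 2, var) == 0)) next
    p <- tiny_panel(d)
    covars <- cbind(c1 = rnorm(n), age = sample(20:69, n, TRUE))
    y <- rnorm(n)
    ph <- phenotype_panel(matrix(y, dimnames = list(NULL, "y")),
                          covariates = data.frame(age = covars[, "age"]),
                          sample_id = p$sample_id)
    sc <- run_scan(p, ph, covariates = covars)[["y"]]
    for (j in seq_len(m)) {
      o <- oracle_ols(y, d[, j], covars)
      expect_equal(sc$results$beta[j], o$beta, tolerance = 1e-10)
      expect_equal(sc$results$se[j], o$se, tolerance = 1e-10)
      expect_equal(sc$results$p[j], o$p, tolerance = 1e-10)
    }
  }
})

test_that("missing dosages are mean-imputed within the regression", {
  set.seed(33)
  n <- 40
  d <- rbinom(n, 2, 0.4)
  d_na <- d; d_na[c(3, 17)] <- NA
  p <- tiny_panel(matrix(d_na))
  y <- rnorm(n)
  ph <- phenotype_panel(matrix(y, dimnames = list(NULL, "y")),
                        covariates = data.frame(age = rep(30, n)),
                        sample_id = p$sample_id)
  sc <- run_scan(p, ph)[["y"]]
  x_imp <- d_na; x_imp[is.na(x_imp)] <- mean(d_na, na.rm = TRUE)
  o <- oracle_ols(y, x_imp)
  expect_equal(sc$results$beta[1], o$beta, tolerance = 1e-12)
  expect_equal(sc$results$n_geno[1], n - 2)
})

test_that("null scans give uniform p-values and nominal type-I error", {
  fx <- scan_fixture()
  sc <- run_scan(fx$panel, fx$pheno,
                 covariates = data.frame(age = fx$pheno$covariates$age))
  pv <- unlist(lapply(sc, function(s) s$results$p))
  frac05 <- mean(pv < 0.05)
  expect_lt(abs(frac05 - 0.05), 0.02)
  # pooled KS against uniform (LD makes SNPs dependent; tolerance is loose)
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("a strongly causal SNP reaches genome-wide significance", {
  set.seed(34)
  p <- simulate_genotypes(2000, 50, block_size = 5, seed = 35)
  x <- impute_dosage <- p$dosage[, 25]
  g <- scale(x) * sqrt(0.05)            # one SNP explaining 5% of variance
  y <- as.numeric(g + rnorm(2000, sd = sqrt(0.95)))
  ph <- phenotype_panel(matrix(y, dimnames = list(NULL, "y")),
                        covariates = data.frame(age = rep(40, 2000)),
                        sample_id = p$sample_id)
  sc <- run_scan(p, ph)[["y"]]
  expect_lt(sc$results$p[25], 1e-8)
})

test_that("degenerate SNPs are flagged with beta 0 and p 1", {
  n <- 30
  d <- cbind(rep(1L, n), rbinom(n, 2, 0.4))
  p <- tiny_panel(d)
  set.seed(36)
  ph <- phenotype_panel(matrix(rnorm(n), dimnames = list(NULL, "y")),
                        covariates = data.frame(age = rep(30, n)),
                        sample_id = p$sample_id)
  sc <- run_scan(p, ph)[["y"]]
  expect_true(sc$results$degenerate[1])
  expect_equal(sc$results$beta[1], 0)
  expect_equal(sc$results$p[1], 1)
  expect_false(sc$results$degenerate[2])
})

test_that("lambda_gc is 1 when every chi-square equals the null median", {
  n <- 60
  sc <- list(trait = "x",
             results = data.frame(
               t_stat = rep(sqrt(qchisq(0.5, 1)), n),
               degenerate = FALSE),
             covariate_names = character(0))
  class(sc) <- "assoc_scan"
  expect_equal(lambda_gc(sc), 1, tolerance = 1e-12)
})

test_that("PC adjustment deflates stratification-driven lambda", {
  p <- simulate_genotypes(500, 2000, block_size = 20, strat_fraction = 0.5,
                          strat_shift = 0.15, within_block_r = 0, seed = 37)
  a <- simulate_architecture(p, 1, 10, h2 = 0, seed = 38)
  ph <- simulate_traits(p, a, seed = 39)
  # confounded trait: shift the mean of one subpopulation
  ph$traits[, 1] <- ph$traits[, 1] + 0.5 * (p$population == 2)
  pcs <- compute_pcs(p, 2)
  sc_raw <- run_scan(p, ph)[[1]]
  sc_adj <- run_scan(p, ph, covariates = pcs)[[1]]
  expect_gt(sc_raw$lambda_gc, sc_adj$lambda_gc)
  expect_lt(abs(sc_adj$lambda_gc - 1), 0.1)
})

test_that("sumstats carry Z = beta/se with the A1 sign convention", {
  fx <- scan_fixture(seed = 41, n = 100, m = 20)
  sc <- run_scan(fx$panel, fx$pheno)[[1]]
  ss <- to_sumstats(sc)
  expect_equal(ss$Z, sc$results$t_stat[!sc$results$degenerate])
  expect_equal(ss$N, sc$results$n_used[!sc$results$degenerate])
  # flipping A1/A2 labels flips the dosage and so negates Z
  p2 <- fx$panel
  p2$dosage <- 2L - p2$dosage
  tmp <- p2$variants$A1; p2$variants$A1 <- p2$variants$A2; p2$variants$A2 <- tmp
  sc2 <- run_scan(p2, fx$pheno)[[1]]
  ss2 <- to_sumstats(sc2)
  expect_equal(ss2$Z, -ss$Z, tolerance = 1e-10)
})

test_that("sumstats survive a TSV round trip", {
  fx <- scan_fixture(seed = 42, n = 80, m = 15)
  ss <- to_sumstats(run_scan(fx$panel, fx$pheno)[[1]])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats_tsv(ss, path)
  back <- read_sumstats_tsv(path, trait = attr(ss, "trait"))
  for (col in c("SNP", "A1", "A2", "N", "Z"))
    expect_equal(back[[col]], ss[[col]], tolerance = 1e-12)
})

test_that("transform_traits applies natural logs and flags errors", {
  y <- cbind(a = c(exp(1), exp(2)), b = c(1, 2))
  ph <- phenotype_panel(y, covariates = data.frame(age = c(30, 40)))
  tr <- transform_traits(ph, "a")
  expect_equal(unname(tr$traits[, "a"]), c(1, 2))
  expect_equal(unname(tr$traits[, "b"]), c(1, 2))
  expect_identical(unname(tr$transform), c("log", "none"))
  expect_identical(transform_traits(ph, character(0)), ph)
  ph$traits[1, "a"] <- -1
  expect_error(transform_traits(ph, "a"), "non-positive")
})
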