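make_scan_inputs <- function(seed = 26, n_per = 10, snps = 100) {
  cfg <- sim_config(n_animals_per_breed = n_per, n_chromosomes = 2,
                    n_snps_per_chrom = snps, seed = seed)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  grm <- build_grm(g)
  fit <- suppressWarnings(reml_fit(ph$records$y, NULL, grm, max_iter = 200))
  Z <- sweep(g$calls, 2, 2 * grm$allele_freqs)
  list(cfg = cfg, g = g, ph = ph, grm = grm, fit = fit, Z = Z)
}

test_that("back-solved effects interpolate the GEBVs (Z u = a_hat)", {
  s <- make_scan_inputs(seed = 26, n_per = 10, snps = 100)
  eff <- suppressWarnings(
    backsolve_snp_effects(s$Z, s$fit$gebv, p = s$grm$allele_freqs))
  expect_lt(max(abs(s$Z %*% eff$u_hat - s$fit$gebv)), 1e-8)
  # zero GEBVs give zero effects
  eff0 <- suppressWarnings(backsolve_snp_effects(s$Z, rep(0, 20)))
  expect_equal(max(abs(eff0$u_hat)), 0)
})

test_that("back-solved effects equal ridge/SNP-BLUP solutions", {
  # GEBVs built from G = ZZ'/k (no blending) so the equivalence is exact:
  # u_ridge = Z'(ZZ' + lam I)^{-1} y  vs  backsolve of a_hat = BLUP
  s <- make_scan_inputs(seed = 27, n_per = 15, snps = 150)
  grm0 <- build_grm(s$g, blend_eps = 0)
  y <- s$ph$records$y
  yc <- y - mean(y)
  k <- grm0$scale_k
  sa <- 500; se <- 750
  # GBLUP with intercept-free centered model for an exact algebraic check
  G <- grm0$matrix
  gebv <- sa * G %*% solve(sa * G + se * diag(30), yc)
  eff <- suppressWarnings(backsolve_snp_effects(s$Z, drop(gebv)))
  # independent ridge oracle with matched shrinkage lambda = k * se / sa
  u_ridge <- drop(crossprod(s$Z, solve(tcrossprod(s$Z) +
                                         (k * se / sa) * diag(30), yc)))
  expect_lt(max(abs(eff$u_hat - u_ridge)) / max(abs(u_ridge)), 1e-6)
})

test_that("per-SNP variance is u^2 * 2p(1-p) exactly", {
  eff <- structure(list(snp_ids = c("a", "b", "c"),
                        u_hat = c(1, 2, 0), p = c(0.5, 0.1, 0.3),
                        var_i = NULL, D = rep(1, 3)),
                   class = "snp_effects")
  out <- per_snp_variance(eff)
  expect_equal(out$var_i, c(0.5, 0.72, 0))
  eff$p <- c(0.5, 1, 0.3)
  expect_error(per_snp_variance(eff), "strictly in")
  eff$p <- NULL
  expect_error(per_snp_variance(eff), "missing")
})

test_that("a single self-normalized window explains 100% of its variance", {
  set.seed(28)
  Z <- scale(matrix(rbinom(100, 2, 0.4), 20, 5), scale = FALSE)
  colnames(Z) <- paste0("s", 1:5)
  u <- rnorm(5)
  a <- drop(Z %*% u)
  eff <- structure(list(snp_ids = colnames(Z), u_hat = u,
                        p = rep(0.4, 5), var_i = NULL, D = rep(1, 5)),
                   class = "snp_effects")
  map <- data.frame(snp_id = colnames(Z), chrom = "1",
                    pos_bp = as.integer(1:5 * 1000))
  wt <- window_scan(Z, eff, map, sigma2_a = var(a))
  expect_equal(nrow(wt), 1)
  expect_equal(wt$pct_of_total, 100, tolerance = 1e-10)
  expect_true(wt$significant)
})

test_that("distinct-window variances add up for orthogonal genotype columns", {
  # construct Z with exactly orthogonal columns so between-window
  # covariances vanish and variance decomposes additively
  set.seed(33)
  n <- 16
  # orthonormal columns inside the centered subspace: columns are both
  # mutually orthogonal and mean-zero, so empirical covariances vanish
  Z <- qr.Q(qr(scale(matrix(rnorm(n * 10), n, 10), scale = FALSE)))[, 1:10]
  colnames(Z) <- paste0("s", 1:10)
  u <- rnorm(10)
  eff <- structure(list(snp_ids = colnames(Z), u_hat = u, p = rep(0.3, 10),
                        var_i = NULL, D = rep(1, 10)),
                   class = "snp_effects")
  map <- data.frame(snp_id = colnames(Z), chrom = "1",
                    pos_bp = as.integer(1:10 * 100))
  a_tot <- drop(Z %*% u)
  wt <- window_scan(Z, eff, map, sigma2_a = 1, window_size = 5,
                    scheme = "distinct")
  expect_equal(nrow(wt), 2)
  expect_equal(sum(wt$var_window), var(a_tot), tolerance = 1e-10)
})

test_that("chromosomes shorter than a window are skipped with a warning", {
  set.seed(29)
  Z <- scale(matrix(rbinom(140, 2, 0.3), 20, 7), scale = FALSE)
  colnames(Z) <- paste0("s", 1:7)
  eff <- structure(list(snp_ids = colnames(Z), u_hat = rnorm(7),
                        p = rep(0.3, 7), var_i = NULL, D = rep(1, 7)),
                   class = "snp_effects")
  map <- data.frame(snp_id = colnames(Z), chrom = c(rep("1", 5), "2", "2"),
                    pos_bp = as.integer(c(1:5, 1:2) * 1000))
  expect_warning(wt <- window_scan(Z, eff, map, sigma2_a = 1), "chromosome 2")
  expect_equal(unique(wt$chrom), "1")
})

test_that("window percentages are invariant to rescaling the phenotype", {
  s <- make_scan_inputs(seed = 30)
  c_scale <- 7.3
  fit1 <- solve_gblup(s$ph$records$y, NULL, s$grm, 400, 900)
  fit2 <- solve_gblup(s$ph$records$y * c_scale, NULL, s$grm,
                      400 * c_scale^2, 900 * c_scale^2)
  e1 <- suppressWarnings(backsolve_snp_effects(s$Z, fit1$gebv,
                                               p = s$grm$allele_freqs))
  e2 <- suppressWarnings(backsolve_snp_effects(s$Z, fit2$gebv,
                                               p = s$grm$allele_freqs))
  w1 <- window_scan(s$Z, e1, s$g$map, sigma2_a = 400)
  w2 <- window_scan(s$Z, e2, s$g$map, sigma2_a = 400 * c_scale^2)
  expect_equal(w1$pct_of_total, w2$pct_of_total, tolerance = 1e-8)
})

test_that("window significance grows with planted QTL effect size", {
  # hold genotypes and residual noise fixed while the QTL effect scales,
  # so the QTL window's share of variance must be non-decreasing
  cfg <- sim_config(n_animals_per_breed = 30, n_chromosomes = 1,
                    n_snps_per_chrom = 100, n_qtl_windows = 1,
                    qtl_effect_sd = 1, seed = 31)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  grm <- build_grm(g)
  Z <- sweep(g$calls, 2, 2 * grm$allele_freqs)
  g1 <- ph$truth$true_breeding_values
  set.seed(310)
  e_fixed <- rnorm(60, 0, sd(g1))
  q <- ph$truth$qtl_windows
  pct_at <- vapply(c(0.5, 2, 8), function(es) {
    y <- es * g1 + e_fixed
    sa <- var(es * g1)
    fit <- solve_gblup(y, NULL, grm, sa, var(e_fixed))
    eff <- suppressWarnings(backsolve_snp_effects(Z, fit$gebv,
                                                  p = grm$allele_freqs))
    wt <- window_scan(Z, eff, g$map, sa)
    max(wt$pct_of_total[wt$start_idx >= q$start_idx - 4 &
                          wt$start_idx <= q$start_idx + 4])
  }, numeric(1))
  expect_true(all(diff(pct_at) > -1e-8))
})

test_that("gene annotation assigns overlaps and respects BED boundaries", {
  wt <- structure(data.frame(
    chrom = c("1", "2"), start_idx = c(1L, 6L), end_idx = c(5L, 10L),
    bp_start = c(1000L, 500L), bp_end = c(5000L, 900L),
    var_window = 1, pct_of_total = 1, var_snp_sum = 1,
    significant = TRUE, genes = NA_character_, stringsAsFactors = FALSE),
    class = c("window_table", "data.frame"),
    scheme = "distinct", window_size = 5, threshold = 0.1, sigma2_a = 1)
  # BED-style (0-based half-open): geneA inside window 1; geneB abuts
  # window 1's end exactly (start = bp_end) -> not assigned; geneC on an
  # unmatched chromosome -> warning
  genes <- data.frame(chrom = c("1", "1", "3"),
                      start = c(2000L, 5000L, 100L),
                      end = c(3000L, 6000L, 200L),
                      gene_id = c("geneA", "geneB", "geneC"),
                      stringsAsFactors = FALSE)
  expect_warning(out <- annotate_windows(wt, genes), "2")
  expect_equal(out$genes, c("geneA", NA))
})

test_that("annotation via a BED file matches hand-worked overlaps", {
  bed <- file.path(withr::local_tempdir(), "genes.bed")
  writeLines(c("1\t1500\t2500\tg1\t0\t+",
               "1\t4999\t7000\tg2\t0\t-",
               "2\t100\t200\tg3\t0\t+"), bed)
  wt <- structure(data.frame(
    chrom = "1", start_idx = 1L, end_idx = 5L,
    bp_start = 1000L, bp_end = 5000L, var_window = 1, pct_of_total = 1,
    var_snp_sum = 1, significant = TRUE, genes = NA_character_,
    stringsAsFactors = FALSE),
    class = c("window_table", "data.frame"),
    scheme = "distinct", window_size = 5, threshold = 0.1, sigma2_a = 1)
  out <- annotate_windows(wt, bed)
  # g1 fully inside; g2 starts at 1-based 5000 = window end -> overlaps by
  # one base; g3 on another chromosome
  expect_equal(out$genes, "g1,g2")
})

test_that("Manhattan positions increase across concatenated chromosomes", {
  s <- make_scan_inputs(seed = 32)
  eff <- suppressWarnings(backsolve_snp_effects(s$Z, s$fit$gebv,
                                                p = s$grm$allele_freqs))
  wt <- window_scan(s$Z, eff, s$g$map, sigma2_a = s$fit$sigma2_a)
  mt <- manhattan_table(wt)
  expect_equal(nrow(mt), nrow(wt))
  expect_true(all(diff(mt$cum_pos) > 0))
  # single window: cumulative position equals its own midpoint
  w1 <- wt[1, , drop = FALSE]
  attr(w1, "scheme") <- "sliding"; class(w1) <- class(wt)
  m1 <- manhattan_table(w1)
  expect_equal(m1$cum_pos, (w1$bp_start + w1$bp_end) / 2)
})
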