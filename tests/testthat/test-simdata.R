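test_that("sim_config validates its fields by name", {
  expect_error(sim_config(n_animals_per_breed = 0), "n_animals_per_breed")
  expect_error(sim_config(h2_target = 1), "h2_target")
  expect_error(sim_config(h2_target = 0), "h2_target")
  expect_error(sim_config(ld_rho = 1), "ld_rho")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(dirichlet_concentration = -1),
               "dirichlet_concentration")
})

test_that("independent markers at frequency 0.5 give mean dose near 1", {
  cfg <- sim_config(n_animals_per_breed = 250, n_chromosomes = 1,
                    n_snps_per_chrom = 2000, ld_rho = 0,
                    maf_range = c(0.5, 0.5), seed = 11)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$calls %in% 0:2))
  # overall allele-frequency mean within 3 SE of 0.5
  p_hat <- mean(allele_freq(g))
  se <- sqrt(0.5 * 0.5 / (2 * 500)) / sqrt(2000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
  expect_equal(mean(colMeans(g$calls)), 1, tolerance = 0.01)
})

test_that("adjacent-marker correlation decays with lag (Markov LD)", {
  cfg <- sim_config(n_animals_per_breed = 150, n_chromosomes = 1,
                    n_snps_per_chrom = 500, ld_rho = 0.9, seed = 12)
  g <- simulate_genotypes(cfg)
  m <- ncol(g$calls)
  lag_cor <- function(l) {
    mean(vapply(seq_len(m - l), function(j)
      stats::cor(g$calls[, j], g$calls[, j + l]), numeric(1)), na.rm = TRUE)
  }
  expect_gt(lag_cor(1), lag_cor(10))
  expect_gt(lag_cor(1), 0.3)
})

test_that("realized allele frequencies converge to drawn ones at large n", {
  cfg <- sim_config(n_animals_per_breed = 1000, n_chromosomes = 1,
                    n_snps_per_chrom = 200, ld_rho = 0.2, seed = 13)
  g <- simulate_genotypes(cfg)
  p <- allele_freq(g)
  # drawn frequencies are uniform on maf_range; realized ones must track
  # them marker by marker within binomial noise at n = 2000 animals
  set.seed(cfg$seed)
  drawn <- stats::runif(200, cfg$maf_range[1], cfg$maf_range[2])
  se <- sqrt(drawn * (1 - drawn) / (2 * 2000))
  expect_gt(mean(abs(p - drawn) < 4 * se), 0.95)
})

test_that("genotype, phenotype and ASV simulation are seed-deterministic", {
  cfg <- tiny_cfg(seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  p1 <- simulate_phenotypes(g1, cfg)
  p2 <- simulate_phenotypes(g2, cfg)
  expect_identical(p1, p2)
  a1 <- simulate_asv_table(cfg)
  a2 <- simulate_asv_table(cfg)
  expect_identical(a1, a2)
})

test_that("zero QTL variance raises the unreachable-h2 error", {
  cfg <- tiny_cfg(qtl_effect_sd = 0)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_phenotypes(g, cfg), "unreachable")
})

test_that("phenotype generator hits its heritability target on average", {
  reps <- 30
  h2 <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_animals_per_breed = 100, n_chromosomes = 2,
                      n_snps_per_chrom = 100, n_qtl_windows = 4,
                      h2_target = 0.4, seed = 500 + r)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    # realized h2: genetic variance over total variance of the focal trait
    # within the generator's own definition
    e <- ph$records$y - ph$truth$true_breeding_values -
      ifelse(ph$records$breed == "ZA", cfg$breed_effect, 0)
    var(ph$truth$true_breeding_values) /
      (var(ph$truth$true_breeding_values) + var(e))
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.4), 0.02)
})

test_that("record columns track the reference group means", {
  cfg <- sim_config(n_animals_per_breed = 200, n_chromosomes = 1,
                    n_snps_per_chrom = 60, seed = 21)
  g <- simulate_genotypes(cfg)
  rec <- simulate_phenotypes(g, cfg)$records
  ref <- breed_reference_means()
  sh <- rec[rec$breed == "SH", ]
  # group mean DMI within 3 SE of the SH target (SE at the simulated n)
  sd_dmi <- ref$dmi_g_per_mbw_se[1] * sqrt(10)
  se <- sd_dmi / sqrt(nrow(sh))
  expect_lt(abs(mean(sh$dmi_g_per_mbw) - ref$dmi_g_per_mbw[1]), 3 * se)
  expect_lt(abs(mean(sh$bw_kg) - ref$bw_kg[1]),
            3 * ref$bw_kg_se[1] * sqrt(10) / sqrt(nrow(sh)))
})

test_that("QTL truth lies on the simulated map with positive variance", {
  cfg <- tiny_cfg(seed = 3)
  g <- simulate_genotypes(cfg)
  tr <- simulate_phenotypes(g, cfg)$truth
  expect_true(all(tr$qtl_windows$end_idx <= ncol(g$calls)))
  expect_true(all(g$map$chrom[tr$qtl_windows$start_idx] ==
                    g$map$chrom[tr$qtl_windows$end_idx]))
  expect_gt(var(tr$true_breeding_values), 0)
  expect_equal(tr$true_h2, cfg$h2_target, tolerance = 1e-10)
})

test_that("null ASV simulation gives equal expected group abundances", {
  cfg <- sim_config(n_animals_per_breed = 30, asv_n_taxa = 40,
                    asv_depth_mean = 20000, seed = 31)
  tab <- simulate_asv_table(cfg)
  prop <- tab$counts / rowSums(tab$counts)
  d <- colMeans(prop[tab$group == "SH", ]) -
    colMeans(prop[tab$group == "ZA", ])
  pooled_se <- apply(prop, 2, sd) * sqrt(2 / 30)
  expect_gt(mean(abs(d) < 4 * pooled_se), 0.95)
})

test_that("a planted log2FC = 2 taxon shifts abundance by ~4-fold", {
  # Monte-Carlo over replicates against the generator's own definition:
  # expected group-mean abundances are pi1 and pi1*4 renormalized, so the
  # ratio of abundances pooled over replicates is sum(pi1*4/norm)/sum(pi1)
  reps <- 60
  idx <- 5
  obs <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(n_animals_per_breed = 10, asv_n_taxa = 50,
                      asv_depth_mean = 50000,
                      asv_effect_taxa = list(c(idx, 2)), seed = 700 + r)
    tab <- simulate_asv_table(cfg)
    prop <- tab$counts / rowSums(tab$counts)
    c(za = mean(prop[tab$group == "ZA", idx]),
      sh = mean(prop[tab$group == "SH", idx]))
  }, numeric(2))
  theo <- vapply(seq_len(reps), function(r) {
    set.seed(699 + r + 2L + 1L)  # cfg seed + 2 is the ASV stream
    base <- stats::rlnorm(50, 0, 1.5)
    pi1 <- base / sum(base)
    c(za = pi1[idx] * 4 / (1 + 3 * pi1[idx]), sh = pi1[idx])
  }, numeric(2))
  ratio_obs <- mean(obs["za", ]) / mean(obs["sh", ])
  ratio_theo <- mean(theo["za", ]) / mean(theo["sh", ])
  expect_lt(abs(ratio_obs - ratio_theo) / ratio_theo, 0.15)
  # the fold change is 4 deflated by renormalization (never amplified)
  expect_gt(ratio_obs, 2.5)
  expect_lt(ratio_obs, 4 * 1.05)
})

test_that("effect taxon index out of range is rejected", {
  cfg <- tiny_cfg(asv_n_taxa = 10, asv_effect_taxa = list(c(11, 1)))
  expect_error(simulate_asv_table(cfg), "out of range")
})
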