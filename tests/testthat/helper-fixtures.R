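# small configurations reused across tests
tiny_cfg <- function(seed = 1L, ...) {
  args <- list(n_animals_per_breed = 10, n_chromosomes = 2,
               n_snps_per_chrom = 50, n_qtl_windows = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# hand-worked 5-animal x 6-SNP QC fixture (order-dependent by design):
#   snpA/snpB share (chrom, pos)        -> both removed as duplicates
#   an1-an3 miss snpC -> call rate 3/4  -> the three animals removed
#   snpC is then complete in an4/an5    -> survives the SNP call-rate step
#   snpD monomorphic (MAF 0)            -> removed by MAF
#   snpC, snpE, snpF                    -> pass (3 survivors)
qc_fixture <- function() {
  calls <- rbind(
    c(0, 2, NA, 2, 1, 0),
    c(1, 1, NA, 2, 0, 1),
    c(2, 0, NA, 2, 1, 2),
    c(0, 1,  1, 2, 2, 1),
    c(1, 2,  0, 2, 1, 0)
  )
  colnames(calls) <- paste0("snp", LETTERS[1:6])
  rownames(calls) <- paste0("an", 1:5)
  map <- data.frame(
    snp_id = colnames(calls),
    chrom = c("1", "1", "1", "1", "2", "2"),
    pos_bp = c(100L, 100L, 200L, 300L, 100L, 200L)
  )
  genotype_matrix(calls, map)
}

# independent brute-force exact HWE oracle: factorial products in double
# precision (valid for n <= 50), same tie tolerance as the implementation
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n1 <- 2 * n_AA + n_Aa
  minor <- min(n1, 2 * n - n1)
  hets <- seq(minor %% 2, minor, by = 2)
  prob <- vapply(hets, function(h) {
    homr <- (minor - h) / 2
    homc <- n - h - homr
    factorial(n) / (factorial(homr) * factorial(h) * factorial(homc)) * 2^h
  }, numeric(1))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# independent restricted-likelihood evaluator for the animal model,
# written directly from the REML definition (dense algebra, no rotation)
reml_ll_dense <- function(sigma2_a, sigma2_e, y, X, G) {
  V <- sigma2_a * G + sigma2_e * diag(length(y))
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  -0.5 * (determinant(V, logarithm = TRUE)$modulus +
            determinant(XVX, logarithm = TRUE)$modulus +
            drop(t(y) %*% P %*% y))
}
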