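#' Simulation configuration for the two-breed goat study emulator
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study design the pipeline targets: two breed groups
#' of 10 lactating goats, a medium-density SNP panel scaled down from ~60K
#' markers, a moderately heritable focal trait, and rumen ASV tables with a
#' handful of differentially abundant taxa.
#'
#' @param n_animals_per_breed Animals per breed group (default 10).
#' @param n_chromosomes Number of autosomes to simulate.
#' @param n_snps_per_chrom Markers per chromosome.
#' @param ld_rho First-order dependence between adjacent markers on a
#'   haplotype, in `[0, 1)`. 0 gives independent markers.
#' @param maf_range Interval within `(0, 0.5]` from which per-SNP minor
#'   allele frequencies are drawn uniformly.
#' @param n_qtl_windows Number of 5-SNP windows that carry trait effects.
#' @param qtl_effect_sd SD of per-allele QTL effects, in trait units.
#' @param h2_target Narrow-sense heritability of the focal trait, in (0,1).
#' @param breed_effect Additive shift of the focal trait in the second
#'   breed, trait units.
#' @param seed Integer seed; all randomness flows from it.
#' @param missing_rate Fraction of genotype calls set missing (default 0;
#'   used to exercise QC).
#' @param asv_n_taxa Number of taxa in simulated ASV tables.
#' @param asv_depth_mean Mean per-sample library size (Poisson).
#' @param asv_effect_taxa List of `c(taxon_index, log2_fold_change)` pairs;
#'   the named taxa differ between groups by that fold change.
#' @param dirichlet_concentration Dirichlet concentration governing
#'   sample-to-sample compositional overdispersion (larger = tighter).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_animals_per_breed = 10,
                       n_chromosomes = 5,
                       n_snps_per_chrom = 200,
                       ld_rho = 0.3,
                       maf_range = c(0.05, 0.5),
                       n_qtl_windows = 3,
                       qtl_effect_sd = 30,
                       h2_target = 0.3,
                       breed_effect = 185,
                       seed = 1L,
                       missing_rate = 0,
                       asv_n_taxa = 100,
                       asv_depth_mean = 50000,
                       asv_effect_taxa = list(),
                       dirichlet_concentration = 50) {
  cfg <- list(
    n_animals_per_breed = n_animals_per_breed,
    n_chromosomes = n_chromosomes,
    n_snps_per_chrom = n_snps_per_chrom,
    ld_rho = ld_rho,
    maf_range = maf_range,
    n_qtl_windows = n_qtl_windows,
    qtl_effect_sd = qtl_effect_sd,
    h2_target = h2_target,
    breed_effect = breed_effect,
    seed = as.integer(seed),
    missing_rate = missing_rate,
    asv_n_taxa = asv_n_taxa,
    asv_depth_mean = asv_depth_mean,
    asv_effect_taxa = asv_effect_taxa,
    dirichlet_concentration = dirichlet_concentration
  )
  for (f in c("n_animals_per_breed", "n_chromosomes", "n_snps_per_chrom",
              "n_qtl_windows", "asv_n_taxa", "asv_depth_mean")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1)
      stop("sim_config: '", f, "' must be a count >= 1", call. = FALSE)
  }
  if (!is.numeric(cfg$ld_rho) || cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("sim_config: 'ld_rho' must lie in [0, 1)", call. = FALSE)
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] <= 0 ||
      cfg$maf_range[2] > 0.5 || cfg$maf_range[1] > cfg$maf_range[2])
    stop("sim_config: 'maf_range' must be an interval within (0, 0.5]",
         call. = FALSE)
  if (!is.numeric(cfg$h2_target) || cfg$h2_target <= 0 || cfg$h2_target >= 1)
    stop("sim_config: 'h2_target' must be strictly inside (0, 1)",
         call. = FALSE)
  if (cfg$qtl_effect_sd < 0)
    stop("sim_config: 'qtl_effect_sd' must be >= 0", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("sim_config: 'missing_rate' must lie in [0, 1)", call. = FALSE)
  if (cfg$dirichlet_concentration <= 0)
    stop("sim_config: 'dirichlet_concentration' must be > 0", call. = FALSE)
  for (e in cfg$asv_effect_taxa) {
    if (length(e) != 2L || e[1] < 1 || e[1] != round(e[1]))
      stop("sim_config: 'asv_effect_taxa' entries must be ",
           "(taxon index, log2 fold change) pairs", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Reference group means emulated by the simulator
#'
#' Published-style group means (and standard errors, n = 10 per group) for
#' the two breed groups used as the simulator's phenotype targets: body
#' weight, dry-matter intake per metabolic weight, daily milk yield, milk
#' composition, and rumen propionate. These are the defaults around which
#' [simulate_phenotypes()] draws per-animal records, and the inputs at
#' which the trait formulas are evaluated in the worked examples.
#'
#' @return A data.frame with one row per breed (`SH`, `ZA`) and columns
#'   `<trait>` and `<trait>_se` for bw_kg, dmi_g_per_mbw, milk_ml_day,
#'   fat_pct, protein_pct, lactose_pct, propionate_mM.
#' @export
breed_reference_means <- function() {
  data.frame(
    breed = c("SH", "ZA"),
    bw_kg = c(40.6, 25.3),            bw_kg_se = c(1.39, 1.57),
    dmi_g_per_mbw = c(110.30, 136.13), dmi_g_per_mbw_se = c(1.32, 3.26),
    milk_ml_day = c(1241, 1427.77),   milk_ml_day_se = c(103.18, 106.18),
    fat_pct = c(2.62, 2.52),          fat_pct_se = c(0.22, 0.23),
    protein_pct = c(2.29, 2.55),      protein_pct_se = c(0.058, 0.07),
    lactose_pct = c(4.16, 4.24),      lactose_pct_se = c(0.11, 0.039),
    propionate_mM = c(13.41, 17.49),  propionate_mM_se = c(1.32, 1.10),
    stringsAsFactors = FALSE
  )
}

#' Simulate a biallelic genotype matrix with first-order LD
#'
#' Haplotypes are generated as a first-order Markov chain along each
#' chromosome via a thresholded AR(1) Gaussian latent process: adjacent
#' markers on a haplotype have latent correlation `ld_rho`, and each marker
#' segregates at an allele frequency drawn uniformly from `maf_range`.
#' The two haplotypes of an animal are summed into a {0,1,2} dose counting
#' copies of the A1 allele. Marker positions are laid out every 50 kb.
#'
#' Draws consumed, in order: per-chromosome allele frequencies, then the
#' latent Gaussian haplotype field, then (if `missing_rate > 0`) the
#' missingness mask.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `genotype_matrix`: list with `calls`
#'   (animals x SNPs integer matrix, NA = missing) and `map` (data.frame
#'   snp_id, chrom, pos_bp, a1, a2).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- 2L * cfg$n_animals_per_breed
  m_chrom <- cfg$n_snps_per_chrom
  n_hap <- 2L * n
  calls_list <- vector("list", cfg$n_chromosomes)
  map_list <- vector("list", cfg$n_chromosomes)
  for (ch in seq_len(cfg$n_chromosomes)) {
    p <- stats::runif(m_chrom, cfg$maf_range[1], cfg$maf_range[2])
    # latent AR(1) field: rows = haplotypes, columns = markers
    z <- matrix(0, n_hap, m_chrom)
    z[, 1] <- stats::rnorm(n_hap)
    if (m_chrom > 1L) {
      innov_sd <- sqrt(1 - cfg$ld_rho^2)
      for (j in 2:m_chrom) {
        z[, j] <- cfg$ld_rho * z[, j - 1] + innov_sd * stats::rnorm(n_hap)
      }
    }
    thresh <- stats::qnorm(p)
    hap <- sweep(z, 2, thresh, `<`) * 1L
    calls <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
      hap[seq(2, n_hap, by = 2), , drop = FALSE]
    snp_id <- sprintf("chr%d_snp%d", ch, seq_len(m_chrom))
    colnames(calls) <- snp_id
    calls_list[[ch]] <- calls
    map_list[[ch]] <- data.frame(
      snp_id = snp_id,
      chrom = as.character(ch),
      pos_bp = 50000L * seq_len(m_chrom),
      a1 = "A", a2 = "B",
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(cbind, calls_list)
  storage.mode(calls) <- "integer"
  rownames(calls) <- sprintf("animal_%02d", seq_len(n))
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                   nrow(calls), ncol(calls))
    calls[miss] <- NA_integer_
  }
  genotype_matrix(calls, do.call(rbind, map_list))
}

#' Simulate phenotype records and the associated genetic truth
#'
#' Places `n_qtl_windows` non-overlapping 5-SNP windows of additive QTL
#' effects on the simulated map, builds true breeding values `g = Z beta`
#' from centered doses, and scales the residual variance so the realized
#' heritability `Var(g) / (Var(g) + sigma2_e)` equals `h2_target`. The
#' focal trait is `y = mean + breed_effect * I(breed 2) + g + e`. Daily
#' milk yield carries the same breeding values (plus its own residual at
#' the target h2) so that derived feed-efficiency traits inherit the
#' genetic architecture; the remaining record columns are drawn around the
#' supplied group means.
#'
#' @param geno A `genotype_matrix` from [simulate_genotypes()]; animals
#'   must equal `2 * n_animals_per_breed`, first half breed 1.
#' @param cfg A [sim_config()].
#' @param group_means Data frame in the shape of [breed_reference_means()].
#' @return List with `records` (one row per animal: animal_id, breed,
#'   bw_kg, dmi_g_per_mbw, milk_ml_day, fat_pct, protein_pct, lactose_pct,
#'   propionate_mM, y) and `truth` (class `sim_truth`: qtl_windows,
#'   true_snp_effects, true_breeding_values, sigma2_e, true_h2).
#' @export
simulate_phenotypes <- function(geno, cfg,
                                group_means = breed_reference_means()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geno, "genotype_matrix"))
  n <- nrow(geno$calls)
  if (n != 2L * cfg$n_animals_per_breed)
    stop("simulate_phenotypes: genotype matrix has ", n,
         " animals; expected 2 * n_animals_per_breed = ",
         2L * cfg$n_animals_per_breed, call. = FALSE)
  set.seed(cfg$seed + 1L)
  m <- ncol(geno$calls)
  win <- 5L
  # eligible window starts: whole windows within one chromosome
  starts <- unlist(lapply(split(seq_len(m), geno$map$chrom), function(idx) {
    if (length(idx) < win) return(integer(0))
    idx[seq_len(length(idx) - win + 1L)]
  }), use.names = FALSE)
  if (cfg$n_qtl_windows > 0 && length(starts) == 0L)
    stop("simulate_phenotypes: no chromosome long enough for a 5-SNP QTL window",
         call. = FALSE)
  beta <- numeric(m)
  qtl <- data.frame(chrom = character(0), start_idx = integer(0),
                    end_idx = integer(0), stringsAsFactors = FALSE)
  if (cfg$n_qtl_windows > 0) {
    chosen <- integer(0)
    avail <- starts
    for (k in seq_len(cfg$n_qtl_windows)) {
      if (length(avail) == 0L)
        stop("simulate_phenotypes: cannot place ", cfg$n_qtl_windows,
             " non-overlapping QTL windows", call. = FALSE)
      s <- if (length(avail) == 1L) avail else sample(avail, 1L)
      chosen <- c(chosen, s)
      avail <- setdiff(avail, (s - win + 1L):(s + win - 1L))
    }
    chosen <- sort(chosen)
    for (s in chosen) {
      idx <- s:(s + win - 1L)
      beta[idx] <- stats::rnorm(win, 0, cfg$qtl_effect_sd)
    }
    qtl <- data.frame(chrom = geno$map$chrom[chosen],
                      start_idx = chosen, end_idx = chosen + win - 1L,
                      stringsAsFactors = FALSE)
  }
  calls <- geno$calls
  if (anyNA(calls)) {
    # truth is defined on the complete genotypes; fill by column mean dose
    mu <- colMeans(calls, na.rm = TRUE)
    nas <- which(is.na(calls), arr.ind = TRUE)
    calls[nas] <- mu[nas[, 2]]
  }
  Z <- scale(calls, center = TRUE, scale = FALSE)
  g <- drop(Z %*% beta)
  var_g <- stats::var(g)
  if (var_g <= 0)
    stop("simulate_phenotypes: h2_target unreachable, realized genetic ",
         "variance is zero (no QTL variance)", call. = FALSE)
  sigma2_e <- var_g * (1 - cfg$h2_target) / cfg$h2_target
  breed <- rep(group_means$breed, each = cfg$n_animals_per_breed)
  e <- stats::rnorm(n, 0, sqrt(sigma2_e))
  y <- mean(group_means$milk_ml_day) +
    cfg$breed_effect * (breed == group_means$breed[2]) + g + e
  draw <- function(col) {
    mu <- group_means[[col]][match(breed, group_means$breed)]
    sdv <- group_means[[paste0(col, "_se")]][match(breed, group_means$breed)] *
      sqrt(cfg$n_animals_per_breed)
    stats::rnorm(n, mu, sdv)
  }
  bw <- pmax(draw("bw_kg"), 5)
  dmi <- pmax(draw("dmi_g_per_mbw"), 10)
  milk_mu <- group_means$milk_ml_day[match(breed, group_means$breed)]
  e_milk <- stats::rnorm(n, 0, sqrt(sigma2_e))
  milk <- pmax(milk_mu + g + e_milk, 0)
  records <- data.frame(
    animal_id = rownames(geno$calls),
    breed = breed,
    bw_kg = bw,
    dmi_g_per_mbw = dmi,
    milk_ml_day = milk,
    fat_pct = pmax(draw("fat_pct"), 0.1),
    protein_pct = pmax(draw("protein_pct"), 0.1),
    lactose_pct = pmax(draw("lactose_pct"), 0.1),
    propionate_mM = pmax(draw("propionate_mM"), 1),
    y = y,
    stringsAsFactors = FALSE
  )
  truth <- structure(list(
    qtl_windows = qtl,
    true_snp_effects = beta,
    true_breeding_values = g,
    sigma2_e = sigma2_e,
    true_h2 = var_g / (var_g + sigma2_e)
  ), class = "sim_truth")
  list(records = records, truth = truth)
}

#' Simulate a two-group ASV count table
#'
#' Base taxon abundances follow a lognormal rank-abundance curve shared by
#' both groups; taxa listed in `asv_effect_taxa` are multiplied by
#' `2^log2fc` in the second group (compositions renormalized). Per-sample
#' compositions are drawn from a Dirichlet with the group composition as
#' mean and `dirichlet_concentration` total mass; counts are multinomial
#' at a Poisson library size around `asv_depth_mean`.
#'
#' Draws consumed, in order: base abundances, taxonomy assignment, then
#' per-sample (depth, Dirichlet, multinomial) in sample order.
#'
#' @param cfg A [sim_config()].
#' @return An [asv_table()] with `2 * n_animals_per_breed` samples.
#' @export
simulate_asv_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$asv_n_taxa < 2)
    stop("simulate_asv_table: 'asv_n_taxa' must be >= 2", call. = FALSE)
  for (e in cfg$asv_effect_taxa) {
    if (e[1] > cfg$asv_n_taxa)
      stop("simulate_asv_table: effect taxon index ", e[1],
           " out of range (asv_n_taxa = ", cfg$asv_n_taxa, ")",
           call. = FALSE)
  }
  set.seed(cfg$seed + 2L)
  t_n <- cfg$asv_n_taxa
  base <- stats::rlnorm(t_n, meanlog = 0, sdlog = 1.5)
  pi1 <- base / sum(base)
  pi2 <- pi1
  for (e in cfg$asv_effect_taxa) pi2[e[1]] <- pi2[e[1]] * 2^e[2]
  pi2 <- pi2 / sum(pi2)
  phyla <- c("Bacteroidota", "Firmicutes", "Fibrobacterota", "Spirochaetota",
             "Verrucomicrobiota", "Cyanobacteria", "Desulfobacterota",
             "Planctomycetota")
  phy <- sample(phyla, t_n, replace = TRUE,
                prob = c(0.45, 0.3, 0.05, 0.05, 0.05, 0.04, 0.03, 0.03))
  fam <- paste0(phy, "_fam", sample.int(4, t_n, replace = TRUE))
  gen <- paste0("Genus_", seq_len(t_n))
  # a fraction of taxa are unresolved at genus rank
  gen[stats::runif(t_n) < 0.1] <- ""
  taxonomy <- paste(phy, fam, gen, sep = ";")
  n_per <- cfg$n_animals_per_breed
  n <- 2L * n_per
  group <- rep(c("SH", "ZA"), each = n_per)
  counts <- matrix(0L, n, t_n)
  conc <- cfg$dirichlet_concentration
  for (i in seq_len(n)) {
    pig <- if (group[i] == "SH") pi1 else pi2
    depth <- stats::rpois(1, cfg$asv_depth_mean)
    gam <- stats::rgamma(t_n, shape = conc * pig, rate = 1)
    if (sum(gam) == 0) gam <- pig
    counts[i, ] <- stats::rmultinom(1, depth, gam / sum(gam))[, 1]
  }
  rownames(counts) <- sprintf("%s_%02d", group, rep(seq_len(n_per), 2))
  colnames(counts) <- sprintf("ASV_%03d", seq_len(t_n))
  asv_table(counts, taxonomy, group)
}

#' Simulate a synthetic gene annotation matching a marker map
#'
#' Lays `genes_per_chrom` uniformly spread gene intervals along each
#' simulated chromosome so windows from the genome scan can be annotated.
#'
#' @param map Marker map data.frame (snp_id, chrom, pos_bp).
#' @param genes_per_chrom Genes per chromosome.
#' @param gene_length Gene span in bp.
#' @param seed Integer seed.
#' @return A `GRanges` of gene intervals with a `gene_id` column.
#' @export
simulate_gene_annotation <- function(map, genes_per_chrom = 20,
                                     gene_length = 30000, seed = 1L) {
  set.seed(as.integer(seed) + 3L)
  out <- lapply(split(map, map$chrom), function(mp) {
    span <- range(mp$pos_bp)
    start <- sort(round(stats::runif(genes_per_chrom, span[1], span[2])))
    data.frame(chrom = mp$chrom[1], start = start,
               end = start + gene_length,
               gene_id = sprintf("GENE_%s_%03d", mp$chrom[1],
                                 seq_len(genes_per_chrom)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  GenomicRanges::GRanges(
    seqnames = out$chrom,
    ranges = IRanges::IRanges(start = out$start, end = out$end),
    gene_id = out$gene_id
  )
}
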