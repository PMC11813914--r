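#' Pipeline configuration
#'
#' Validates the end-to-end run configuration. Either simulated inputs
#' (`sim` = a [sim_config()]) or file paths (`phenotypes`, `calls`,
#' `calls_map` TSVs as read by [read_calls_tsv()]) must be given;
#' `annotation` (BED/GFF3 path or GRanges) and `asv` inputs are optional.
#'
#' @param out_dir Output directory for this run.
#' @param traits Traits to scan, a subset of
#'   `c("gross_fe", "adjusted_fe", "milk_ne", "fe_lactation")` (default:
#'   all four).
#' @param sim A [sim_config()] for fully simulated inputs, or NULL.
#' @param phenotypes,calls,calls_map Input TSV paths when not simulating.
#' @param annotation Gene annotation path or GRanges (optional).
#' @param qc Named list of QC threshold overrides passed to [apply_qc()].
#' @param window_size,scheme,threshold Window-scan settings.
#' @param fixed Fixed effects: `"mean"` (intercept only, default) or
#'   `"breed"` (intercept + breed).
#' @param variances Optional `c(sigma2_a, sigma2_e)` to bypass REML.
#' @param seed Integer seed.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            traits = c("gross_fe", "adjusted_fe",
                                       "milk_ne", "fe_lactation"),
                            sim = sim_config(),
                            phenotypes = NULL, calls = NULL,
                            calls_map = NULL, annotation = NULL,
                            qc = list(), window_size = 5,
                            scheme = "sliding", threshold = 0.1,
                            fixed = c("mean", "breed"),
                            variances = NULL, seed = 1L) {
  fixed <- match.arg(fixed)
  allowed <- c("gross_fe", "adjusted_fe", "milk_ne", "fe_lactation")
  if (!length(traits) || !all(traits %in% allowed))
    stop("pipeline_config: traits must come from {",
         paste(allowed, collapse = ", "), "}", call. = FALSE)
  if (is.null(sim)) {
    for (f in c("phenotypes", "calls", "calls_map")) {
      v <- get(f)
      if (is.null(v) || !file.exists(v))
        stop("pipeline_config: input file for '", f,
             "' missing or does not exist", call. = FALSE)
    }
  }
  if (!is.null(variances) && (length(variances) != 2 || any(variances <= 0)))
    stop("pipeline_config: 'variances' must be two positive numbers",
         call. = FALSE)
  structure(list(out_dir = out_dir, traits = traits, sim = sim,
                 phenotypes = phenotypes, calls = calls,
                 calls_map = calls_map, annotation = annotation,
                 qc = qc, window_size = window_size, scheme = scheme,
                 threshold = threshold, fixed = fixed,
                 variances = variances, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[setdiff(names(cfg), "out_dir")], f)
  unname(tools::md5sum(f))
}

write_stage_tsv <- function(x, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end: obtain inputs (simulate or read),
#' derive feed-efficiency traits and group summaries, apply genotype QC,
#' build the GRM, fit GBLUP per trait (EM-REML unless variance components
#' are supplied), back-solve SNP effects, run the windowed variance scan,
#' annotate significant windows, and analyze the ASV table (diversity,
#' Bray-Curtis PCoA, two-group taxon comparison). Every table is written
#' under `out_dir` with a config-hash header comment, and a JSON manifest
#' records versions, config hash, seed, and per-stage record counts. On
#' any stage failure a `FAILED` marker file is left next to the partial
#' outputs and the error is re-raised.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  manifest <- list(
    package = "goatfe",
    version = as.character(utils::packageVersion("goatfe")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = hash, seed = cfg$seed,
    traits = cfg$traits, stages = list(), outputs = character(0)
  )
  fail_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  out <- function(name) file.path(cfg$out_dir, name)
  emit <- function(x, name) {
    write_stage_tsv(x, out(name), hash)
    manifest$outputs <<- c(manifest$outputs, name)
  }
  tryCatch({
    # --- inputs -----------------------------------------------------------
    if (!is.null(cfg$sim)) {
      sim <- cfg$sim
      sim$seed <- cfg$seed
      geno <- simulate_genotypes(sim)
      ph <- simulate_phenotypes(geno, sim)
      records <- ph$records
      asv <- simulate_asv_table(sim)
      genes <- if (!is.null(cfg$annotation)) cfg$annotation
      else simulate_gene_annotation(geno$map, seed = cfg$seed)
    } else {
      records <- utils::read.table(cfg$phenotypes, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
      geno <- read_calls_tsv(cfg$calls, cfg$calls_map)
      asv <- NULL
      genes <- cfg$annotation
    }
    manifest$stages$inputs <- list(animals = nrow(records),
                                   snps = ncol(geno$calls))
    # --- traits -----------------------------------------------------------
    traits_tab <- derive_traits(records)
    if (!is.null(records$y)) traits_tab$y <- records$y
    emit(traits_tab, "traits.tsv")
    if (length(unique(traits_tab$breed)) == 2) {
      emit(group_summary(traits_tab), "trait_group_summary.tsv")
    }
    manifest$stages$traits <- list(animals = nrow(traits_tab))
    # --- QC ---------------------------------------------------------------
    qc_args <- c(list(geno = geno), cfg$qc)
    qcres <- do.call(apply_qc, qc_args)
    geno_qc <- qcres$geno
    qcrep <- qcres$report
    repl <- unclass(qcrep)
    cnt <- setdiff(names(repl), "thresholds")
    emit(data.frame(metric = cnt, count = unlist(repl[cnt])),
         "qc_report.tsv")
    manifest$stages$qc <- repl[c("n_input_snps", "n_pass")]
    # --- GRM --------------------------------------------------------------
    grm <- build_grm(geno_qc)
    traits_tab <- traits_tab[match(rownames(geno_qc$calls),
                                   traits_tab$animal_id), ]
    X <- if (cfg$fixed == "breed" &&
             length(unique(traits_tab$breed)) > 1) {
      stats::model.matrix(~breed, traits_tab)
    } else NULL
    Z <- sweep(geno_qc$calls, 2, 2 * grm$allele_freqs)
    # --- per-trait GBLUP + window scan ------------------------------------
    for (tr in cfg$traits) {
      y <- traits_tab[[tr]]
      fit <- if (!is.null(cfg$variances)) {
        solve_gblup(y, X, grm, cfg$variances[1], cfg$variances[2])
      } else {
        reml_fit(y, X, grm)
      }
      emit(data.frame(animal_id = names(fit$gebv), gebv = fit$gebv),
           paste0("gebv_", tr, ".tsv"))
      emit(data.frame(sigma2_a = fit$sigma2_a, sigma2_e = fit$sigma2_e,
                      h2 = fit$h2, converged = fit$converged,
                      n_iter = fit$n_iter),
           paste0("fit_", tr, ".tsv"))
      eff <- backsolve_snp_effects(Z, fit$gebv, p = grm$allele_freqs)
      eff <- per_snp_variance(eff)
      wt <- window_scan(Z, eff, geno_qc$map, fit$sigma2_a,
                        window_size = cfg$window_size,
                        scheme = cfg$scheme, threshold = cfg$threshold)
      if (!is.null(genes)) {
        wt <- annotate_windows(wt, genes)
      } else {
        warning("run_pipeline: no gene annotation; windows left unannotated",
                call. = FALSE)
      }
      wt_out <- as.data.frame(wt)
      wt_out$trait <- tr
      emit(wt_out, paste0("windows_", tr, ".tsv"))
      sig <- wt_out[wt_out$significant,
                    c("chrom", "bp_start", "bp_end", "genes", "trait",
                      "pct_of_total")]
      emit(sig, paste0("windows_significant_", tr, ".tsv"))
      emit(manhattan_table(wt), paste0("manhattan_", tr, ".tsv"))
      manifest$stages[[paste0("scan_", tr)]] <-
        list(windows = nrow(wt_out), significant = sum(wt_out$significant),
             scheme = cfg$scheme, window_size = cfg$window_size)
    }
    # --- ecology ----------------------------------------------------------
    if (!is.null(asv)) {
      emit(alpha_diversity(asv), "asv_alpha_diversity.tsv")
      d <- bray_curtis(asv)
      emit(data.frame(sample_id = rownames(d), d), "asv_bray_curtis.tsv")
      pc <- pcoa(d)
      emit(data.frame(sample_id = rownames(pc$coordinates),
                      pc$coordinates,
                      group = asv$group), "asv_pcoa.tsv")
      emit(compare_groups(asv, level = "genus"), "asv_genus_comparison.tsv")
      emit(compare_groups(asv, level = "phylum"),
           "asv_phylum_comparison.tsv")
      manifest$stages$ecol <- list(samples = nrow(asv$counts),
                                   taxa = ncol(asv$counts))
    }
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    writeLines(conditionMessage(e), fail_marker)
    stop(e)
  })
}
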