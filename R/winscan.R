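#' Back-solve SNP effects from genomic breeding values
#'
#' Recovers per-marker effects from GEBVs via
#' `u = D Z' (Z D Z')^{-1} a_hat`, where `Z` is the centered genotype
#' matrix (animals x SNPs), `D` a diagonal SNP weight matrix (identity by
#' default), and `a_hat` the GEBV vector. When `Z D Z'` is nonsingular the
#' identity `Z u = a_hat` holds exactly; if it is rank deficient a
#' Moore-Penrose pseudo-inverse is used with a warning.
#'
#' @param Z Centered genotype matrix, animals x SNPs.
#' @param gebv GEBV vector `a_hat`, length = animals.
#' @param p Per-SNP allele frequencies (needed later for
#'   [per_snp_variance()]; optional here).
#' @param D Diagonal weight vector, length = SNPs (default all 1).
#' @return Object of class `snp_effects`: `snp_ids`, `u_hat`, `p`,
#'   `var_i` (NULL until [per_snp_variance()]), `D`.
#' @export
backsolve_snp_effects <- function(Z, gebv, p = NULL, D = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z); m <- ncol(Z)
  if (length(gebv) != n)
    stop("backsolve_snp_effects: gebv length ", length(gebv),
         " does not match ", n, " animals in Z", call. = FALSE)
  if (is.null(D)) D <- rep(1, m)
  if (length(D) != m)
    stop("backsolve_snp_effects: D length must equal the number of SNPs",
         call. = FALSE)
  ZD <- sweep(Z, 2, D, `*`)
  K <- tcrossprod(ZD, Z)          # Z D Z'
  alpha <- tryCatch(solve(K, gebv), error = function(e) NULL)
  if (is.null(alpha) || qr(K)$rank < n) {
    warning("backsolve_snp_effects: Z D Z' is rank deficient; ",
            "using a Moore-Penrose pseudo-inverse", call. = FALSE)
    alpha <- drop(MASS::ginv(K) %*% gebv)
  }
  u <- D * drop(crossprod(Z, alpha))
  structure(list(
    snp_ids = colnames(Z), u_hat = u, p = p, var_i = NULL, D = D
  ), class = "snp_effects")
}

#' Per-SNP genetic variance from back-solved effects
#'
#' Marker-wise variance `var_i = u^2 * 2 p (1 - p)`, the variance a SNP at
#' frequency `p` with effect `u` contributes under Hardy-Weinberg and
#' linkage equilibrium.
#'
#' @param effects A `snp_effects` with allele frequencies `p` set.
#' @return The same object with `var_i` filled in.
#' @export
per_snp_variance <- function(effects) {
  stopifnot(inherits(effects, "snp_effects"))
  p <- effects$p
  if (is.null(p) || length(p) != length(effects$u_hat))
    stop("per_snp_variance: allele frequencies missing or of wrong length",
         call. = FALSE)
  if (any(p <= 0) || any(p >= 1))
    stop("per_snp_variance: allele frequencies must lie strictly in (0, 1)",
         call. = FALSE)
  effects$var_i <- effects$u_hat^2 * 2 * p * (1 - p)
  effects
}

#' Windowed genome scan of genetic variance
#'
#' For each window of `window_size` adjacent SNPs on a chromosome, the
#' window genomic value of every animal is `a_w = Z[, w] %*% u[w]`, and the
#' window's share of genetic variance is `100 * Var(a_w) / sigma2_a`,
#' where `Var` is the empirical variance across animals and `sigma2_a`
#' the total additive variance. Windows are `sliding` (step 1, the
#' default) or `distinct` (non-overlapping); trailing SNPs that cannot
#' fill a window are dropped, and chromosomes shorter than one window are
#' skipped with a warning. The sum of within-window per-SNP variances
#' `u^2 2p(1-p)` is also reported, but significance is defined on the
#' empirical window variance.
#'
#' @param Z Centered genotype matrix, animals x SNPs, in map order.
#' @param effects A `snp_effects` (after [per_snp_variance()] if `p` was
#'   supplied).
#' @param map Marker map data.frame (snp_id, chrom, pos_bp) sorted by
#'   (chrom, pos_bp).
#' @param sigma2_a Total additive genetic variance (> 0).
#' @param window_size SNPs per window (default 5).
#' @param scheme `"sliding"` or `"distinct"`.
#' @param threshold Significance threshold on the percentage of total
#'   genetic variance (default 0.1, i.e. windows explaining > 0.1%).
#' @return Data frame of class `window_table`: chrom, start_idx, end_idx,
#'   bp_start, bp_end, var_window, pct_of_total, var_snp_sum,
#'   significant; attributes `scheme`, `window_size`, `threshold`,
#'   `sigma2_a`.
#' @export
window_scan <- function(Z, effects, map, sigma2_a, window_size = 5,
                        scheme = c("sliding", "distinct"), threshold = 0.1) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(effects, "snp_effects"))
  if (sigma2_a <= 0)
    stop("window_scan: sigma2_a must be positive", call. = FALSE)
  Z <- as.matrix(Z)
  m <- ncol(Z)
  if (m != nrow(map) || m != length(effects$u_hat))
    stop("window_scan: Z, map and effects disagree on the number of SNPs",
         call. = FALSE)
  u <- effects$u_hat
  rows <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (any(diff(map$pos_bp[idx]) < 0))
      stop("window_scan: map not sorted by position on chromosome ", ch,
           call. = FALSE)
    if (length(idx) < window_size) {
      warning("window_scan: chromosome ", ch, " has fewer than ",
              window_size, " SNPs; skipped", call. = FALSE)
      next
    }
    starts <- if (scheme == "sliding") {
      seq_len(length(idx) - window_size + 1L)
    } else {
      seq(1L, length(idx) - window_size + 1L, by = window_size)
    }
    for (s in starts) {
      w <- idx[s:(s + window_size - 1L)]
      a_w <- drop(Z[, w, drop = FALSE] %*% u[w])
      vw <- stats::var(a_w)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start_idx = w[1], end_idx = w[window_size],
        bp_start = map$pos_bp[w[1]], bp_end = map$pos_bp[w[window_size]],
        var_window = vw,
        pct_of_total = 100 * vw / sigma2_a,
        var_snp_sum = if (is.null(effects$var_i)) NA_real_ else
          sum(effects$var_i[w]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    stop("window_scan: no chromosome long enough for a window", call. = FALSE)
  wt <- do.call(rbind, rows)
  wt$significant <- wt$pct_of_total > threshold
  wt$genes <- NA_character_
  attr(wt, "scheme") <- scheme
  attr(wt, "window_size") <- window_size
  attr(wt, "threshold") <- threshold
  attr(wt, "sigma2_a") <- sigma2_a
  class(wt) <- c("window_table", "data.frame")
  wt
}

#' Annotate scan windows with overlapping genes
#'
#' Assigns to each window every gene whose interval overlaps the window's
#' bp span by at least one base. Gene annotations may be a `GRanges`, a
#' path to a BED or GFF3 file (imported with rtracklayer; BED's 0-based
#' half-open starts become 1-based closed intervals, so a gene starting
#' exactly at a window's end coordinate does not overlap it), or a
#' BED-like data.frame (chrom, start, end, gene_id; 0-based half-open).
#'
#' @param wt A `window_table`.
#' @param genes Gene annotation (see above). The gene label is taken from
#'   a `gene_id`, `name`, or `ID` column, in that order.
#' @return The `window_table` with its `genes` column filled
#'   (comma-separated labels, NA where no gene overlaps). Unmatched
#'   chromosome names trigger a warning listing them.
#' @export
annotate_windows <- function(wt, genes) {
  stopifnot(inherits(wt, "window_table"))
  if (is.character(genes) && length(genes) == 1L) {
    genes <- rtracklayer::import(genes)
  } else if (is.data.frame(genes)) {
    genes <- GenomicRanges::GRanges(
      seqnames = as.character(genes$chrom),
      ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      gene_id = genes$gene_id
    )
  }
  if (!methods::is(genes, "GRanges"))
    stop("annotate_windows: 'genes' must be a GRanges, data.frame, or path",
         call. = FALSE)
  md <- S4Vectors::mcols(genes)
  lab <- if ("gene_id" %in% names(md)) md$gene_id
  else if ("name" %in% names(md)) md$name
  else if ("ID" %in% names(md)) md$ID
  else as.character(seq_along(genes))
  unmatched <- setdiff(unique(wt$chrom),
                       unique(as.character(GenomicRanges::seqnames(genes))))
  if (length(unmatched))
    warning("annotate_windows: window chromosome(s) absent from the ",
            "annotation: ", paste(unmatched, collapse = ", "),
            call. = FALSE)
  wgr <- GenomicRanges::GRanges(
    seqnames = wt$chrom,
    ranges = IRanges::IRanges(start = wt$bp_start, end = wt$bp_end)
  )
  hits <- suppressWarnings(GenomicRanges::findOverlaps(wgr, genes))
  gl <- rep(NA_character_, nrow(wt))
  if (length(hits)) {
    by_win <- split(lab[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits))
    gl[as.integer(names(by_win))] <-
      vapply(by_win, paste, character(1), collapse = ",")
  }
  wt$genes <- gl
  wt
}

#' Plot-ready Manhattan table of window variance percentages
#'
#' Concatenates chromosomes along a cumulative coordinate and emits one
#' row per window with its genome-wide midpoint position and percentage
#' of genetic variance (the scan statistic itself is plotted; no window
#' p-values are defined).
#'
#' @param wt A `window_table`.
#' @return Data frame: chrom, bp_mid, cum_pos, pct_of_total, significant.
#' @export
manhattan_table <- function(wt) {
  stopifnot(inherits(wt, "window_table"))
  if (!nrow(wt)) stop("manhattan_table: empty window table", call. = FALSE)
  chroms <- unique(wt$chrom)
  spans <- vapply(chroms, function(ch) max(wt$bp_end[wt$chrom == ch]),
                  numeric(1))
  offsets <- c(0, cumsum(spans))[seq_along(chroms)]
  names(offsets) <- chroms
  mid <- (wt$bp_start + wt$bp_end) / 2
  data.frame(
    chrom = wt$chrom,
    bp_mid = mid,
    cum_pos = offsets[wt$chrom] + mid,
    pct_of_total = wt$pct_of_total,
    significant = wt$significant,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
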