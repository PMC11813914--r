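#' Construct an ASV count table
#'
#' @param counts Samples x taxa matrix of non-negative integer counts;
#'   row names are sample ids, column names taxon ids.
#' @param taxonomy Character vector of semicolon-delimited rank strings,
#'   one per taxon (e.g. `"Bacteroidota;Prevotellaceae;Prevotella"`).
#' @param group Group label per sample.
#' @param rank_names Names of the ranks encoded in `taxonomy`, outermost
#'   first (default phylum, family, genus — the granularity of the
#'   simulator).
#' @return Object of class `asv_table`: `counts`, `taxonomy` (data.frame
#'   of ranks), `group`.
#' @export
asv_table <- function(counts, taxonomy, group,
                      rank_names = c("phylum", "family", "genus")) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("asv_table: counts must be non-negative integers", call. = FALSE)
  if (any(rowSums(counts) == 0))
    stop("asv_table: every sample needs at least one positive count",
         call. = FALSE)
  if (length(taxonomy) != ncol(counts))
    stop("asv_table: one taxonomy string per taxon required", call. = FALSE)
  if (length(group) != nrow(counts))
    stop("asv_table: one group label per sample required", call. = FALSE)
  parts <- strsplit(taxonomy, ";", fixed = TRUE)
  tax <- as.data.frame(do.call(rbind, lapply(parts, function(x) {
    length(x) <- length(rank_names)
    x
  })), stringsAsFactors = FALSE)
  names(tax) <- rank_names
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("sample_%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("taxon_%03d", seq_len(ncol(counts)))
  structure(list(counts = counts, taxonomy = tax,
                 group = as.character(group)),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("asv_table:", nrow(x$counts), "samples x", ncol(x$counts),
      "taxa; groups:", paste(unique(x$group), collapse = ", "), "\n")
  invisible(x)
}

#' Per-sample alpha diversity
#'
#' Observed richness, Chao1 (bias-corrected by default:
#' `S + F1(F1-1)/(2(F2+1))` with F1/F2 the singleton/doubleton counts;
#' the classic `S + F1^2/(2 F2)` by flag), Shannon entropy in natural
#' log, and inverse Simpson `1/sum(p^2)`. With no singletons Chao1 equals
#' the observed richness.
#'
#' @param tab An `asv_table`, or a samples x taxa count matrix.
#' @param chao1_classic Use the classic Chao1 estimator (undefined when
#'   F2 = 0) instead of the bias-corrected form.
#' @return Data frame: sample_id, group (if known), observed, chao1,
#'   shannon, inv_simpson.
#' @export
alpha_diversity <- function(tab, chao1_classic = FALSE) {
  counts <- if (inherits(tab, "asv_table")) tab$counts else as.matrix(tab)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("sample_%02d", seq_len(nrow(counts)))
  if (any(rowSums(counts) == 0))
    stop("alpha_diversity: all-zero sample", call. = FALSE)
  one <- function(x) {
    x <- x[x > 0]
    s <- length(x)
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao <- if (chao1_classic) {
      if (f2 == 0 && f1 > 0) Inf else if (f2 == 0) s
      else s + f1^2 / (2 * f2)
    } else {
      s + f1 * (f1 - 1) / (2 * (f2 + 1))
    }
    p <- x / sum(x)
    c(observed = s, chao1 = chao, shannon = -sum(p * log(p)),
      inv_simpson = 1 / sum(p^2))
  }
  res <- base::t(apply(counts, 1, one))
  out <- data.frame(sample_id = rownames(counts), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (inherits(tab, "asv_table")) out <- cbind(out[1], group = tab$group,
                                             out[-1])
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x - y| / sum(x + y)`, computed on per-sample
#' proportions when `normalize = TRUE` (the default, so unequal library
#' sizes do not masquerade as community differences) or on raw counts
#' otherwise.
#'
#' @param tab An `asv_table` or samples x taxa matrix (>= 2 samples).
#' @param normalize Convert rows to proportions first.
#' @return Symmetric samples x samples matrix with zero diagonal,
#'   entries in `[0, 1]`.
#' @export
bray_curtis <- function(tab, normalize = TRUE) {
  x <- if (inherits(tab, "asv_table")) tab$counts else as.matrix(tab)
  if (nrow(x) < 2)
    stop("bray_curtis: need at least 2 samples", call. = FALSE)
  if (normalize) x <- x / rowSums(x)
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- sum(abs(x[i, ] - x[j, ]))
      den <- sum(x[i, ] + x[j, ])
      d[i, j] <- d[j, i] <- if (den == 0) 0 else num / den
    }
  }
  d
}

#' Principal coordinate analysis of a dissimilarity matrix
#'
#' Gower double-centering `B = -1/2 J D^2 J` (J the centering matrix)
#' followed by an eigendecomposition; coordinates are eigenvectors scaled
#' by the square root of their (positive) eigenvalues. Negative
#' eigenvalues — possible because Bray-Curtis is not Euclidean — are
#' reported untouched; the proportion explained is relative to the sum of
#' positive eigenvalues.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param n_axes Number of coordinate axes to return (default 2).
#' @return Object of class `pcoa_result`: `coordinates` (samples x axes),
#'   `eigenvalues` (all), `prop_explained` (per returned axis),
#'   `distance` (the input).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - base::t(d))) > 1e-8)
    stop("pcoa: input must be a square symmetric matrix", call. = FALSE)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  eg <- eigen((B + base::t(B)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12 & eg$values > 0
  n_axes <- min(n_axes, sum(pos))
  coords <- eg$vectors[, which(pos)[seq_len(n_axes)], drop = FALSE] %*%
    diag(sqrt(eg$values[which(pos)[seq_len(n_axes)]]), n_axes)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(
    coordinates = coords,
    eigenvalues = eg$values,
    prop_explained = eg$values[which(pos)[seq_len(n_axes)]] /
      sum(eg$values[pos]),
    distance = d
  ), class = "pcoa_result")
}

#' Aggregate an ASV table to a taxonomic rank as relative abundances
#'
#' Taxa unresolved at the requested rank fall into an
#' `"<last assigned rank>_unclass"` bucket (or `"unclassified"` when
#' nothing is assigned).
#'
#' @param tab An `asv_table`.
#' @param level Rank name present in the table's taxonomy.
#' @return Samples x aggregated-taxa matrix of relative abundances in
#'   percent (rows sum to 100).
#' @export
aggregate_rank <- function(tab, level = "genus") {
  stopifnot(inherits(tab, "asv_table"))
  if (!level %in% names(tab$taxonomy))
    stop("aggregate_rank: rank '", level, "' not in taxonomy (has: ",
         paste(names(tab$taxonomy), collapse = ", "), ")", call. = FALSE)
  ranks <- names(tab$taxonomy)
  li <- match(level, ranks)
  lab <- tab$taxonomy[[level]]
  for (i in which(is.na(lab) | lab == "")) {
    parent <- rev(unlist(tab$taxonomy[i, seq_len(li)]))
    parent <- parent[!is.na(parent) & parent != ""]
    lab[i] <- if (length(parent)) paste0(parent[1], "_unclass")
    else "unclassified"
  }
  prop <- 100 * tab$counts / rowSums(tab$counts)
  base::t(rowsum(base::t(prop), lab))
}

#' Two-group comparison of taxon relative abundances
#'
#' Aggregates to the requested rank, expresses abundances in percent, and
#' compares the two groups taxon by taxon with an unpaired t-test
#' (pooled variance by default, Welch by flag), optionally on arcsine-
#' square-root or log transformed proportions. Benjamini-Hochberg q-values
#' are added when `fdr = TRUE`.
#'
#' @param tab An `asv_table` with exactly two groups, >= 2 samples each.
#' @param level Taxonomic rank to aggregate to.
#' @param fdr Add BH-adjusted q-values.
#' @param welch Use Welch's t-test.
#' @param transform `"none"` (default), `"arcsine"` (on proportions), or
#'   `"log"` (log10 of abundance + half the smallest nonzero value).
#' @return Data frame, one row per aggregated taxon: group means and SEs
#'   (percent, untransformed scale), t statistic, p-value, and q-value.
#' @export
compare_groups <- function(tab, level = "genus", fdr = TRUE, welch = FALSE,
                           transform = c("none", "arcsine", "log")) {
  stopifnot(inherits(tab, "asv_table"))
  transform <- match.arg(transform)
  g <- factor(tab$group)
  if (nlevels(g) != 2)
    stop("compare_groups: exactly two groups required", call. = FALSE)
  if (any(table(g) < 2))
    stop("compare_groups: each group needs >= 2 samples", call. = FALSE)
  abund <- aggregate_rank(tab, level)
  lv <- levels(g)
  tx <- switch(transform,
               none = abund,
               arcsine = asin(sqrt(pmin(abund / 100, 1))),
               log = {
                 eps <- min(abund[abund > 0]) / 2
                 log10(abund + eps)
               })
  rows <- lapply(colnames(abund), function(taxon) {
    x <- abund[g == lv[1], taxon]; y <- abund[g == lv[2], taxon]
    xt <- tx[g == lv[1], taxon]; yt <- tx[g == lv[2], taxon]
    if (stats::var(xt) == 0 && stats::var(yt) == 0) {
      tt <- list(statistic = NA_real_,
                 p.value = if (mean(xt) == mean(yt)) 1 else NA_real_)
    } else {
      tt <- stats::t.test(xt, yt, var.equal = !welch)
    }
    data.frame(taxon = taxon,
               mean_1 = mean(x), se_1 = stats::sd(x) / sqrt(length(x)),
               mean_2 = mean(y), se_2 = stats::sd(y) / sqrt(length(y)),
               t = unname(tt$statistic), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- c(paste0("mean_", lv[1]), paste0("se_", lv[1]),
                       paste0("mean_", lv[2]), paste0("se_", lv[2]))
  if (fdr) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
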