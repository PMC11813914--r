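#' Build the genomic relationship matrix (VanRaden scaling)
#'
#' `Z = M - 2p` (doses centered at twice the observed allele frequency),
#' `G = Z Z' / k` with `k = 2 * sum(p_j (1 - p_j))`, then blended with the
#' identity, `(1 - eps) G + eps I`, so G is invertible even with few
#' markers or duplicated genotypes. With every phenotyped animal
#' genotyped and no pedigree, the single-step H matrix reduces to this G,
#' which is the case this pipeline implements.
#'
#' @param geno Post-QC `genotype_matrix` (no missing calls) or a plain
#'   dose matrix.
#' @param blend_eps Identity blending weight in `[0, 1)` (default 0.01).
#' @return Object of class `grm`: `matrix` (animals x animals), `scale_k`,
#'   `allele_freqs`, `blend_eps`.
#' @export
build_grm <- function(geno, blend_eps = 0.01) {
  calls <- if (inherits(geno, "genotype_matrix")) geno$calls else as.matrix(geno)
  if (nrow(calls) < 2 || ncol(calls) < 1)
    stop("build_grm: need at least 2 animals and 1 SNP", call. = FALSE)
  if (anyNA(calls))
    stop("build_grm: missing calls present; run apply_qc() first",
         call. = FALSE)
  p <- colMeans(calls) / 2
  k <- 2 * sum(p * (1 - p))
  if (k <= 0)
    stop("build_grm: zero scale 2*sum(p(1-p)); all SNPs are monomorphic",
         call. = FALSE)
  Z <- sweep(calls, 2, 2 * p)
  G <- tcrossprod(Z) / k
  if (blend_eps > 0)
    G <- (1 - blend_eps) * G + blend_eps * diag(nrow(G))
  dimnames(G) <- list(rownames(calls), rownames(calls))
  structure(list(matrix = G, scale_k = k, allele_freqs = p,
                 blend_eps = blend_eps), class = "grm")
}

# restricted log-likelihood of (sigma2_a, sigma2_e) in the eigen-rotated
# animal model; d = eigenvalues of G, yt/Xt = rotated data
reml_loglik_rotated <- function(sigma2_a, sigma2_e, d, yt, Xt) {
  v <- sigma2_a * d + sigma2_e
  if (any(v <= 0)) return(-Inf)
  w <- 1 / v
  XtW <- Xt * w
  xwx <- crossprod(Xt, XtW)
  b <- solve(xwx, crossprod(XtW, yt))
  r <- yt - Xt %*% b
  -0.5 * (sum(log(v)) + determinant(xwx, logarithm = TRUE)$modulus +
            sum(w * r^2))
}

#' EM-REML variance components for the GBLUP animal model
#'
#' Fits `y = X b + a + e`, `a ~ N(0, G sigma2_a)`, `e ~ N(0, I sigma2_e)`
#' by EM-REML. The model is rotated into the eigenbasis of G once, after
#' which each EM update costs O(n); the restricted log-likelihood is
#' tracked and is non-decreasing across iterations (an EM guarantee).
#'
#' @param y Phenotype vector, one record per genotyped animal.
#' @param X Fixed-effect design matrix (default: intercept only); must
#'   have full column rank.
#' @param grm A `grm` from [build_grm()].
#' @param max_iter Iteration cap (default 1000).
#' @param tol Convergence tolerance on the relative change of both
#'   variance components (default 1e-6).
#' @param start Optional starting values `c(sigma2_a, sigma2_e)`.
#' @return Object of class `gblup_fit`: `sigma2_a`, `sigma2_e`, `h2`,
#'   `fixed_effects`, `gebv`, `converged`, `n_iter`, `loglik` (trace).
#'   A warning is raised (and `converged = FALSE`) if the cap is hit.
#' @export
reml_fit <- function(y, X = NULL, grm, max_iter = 1000, tol = 1e-6,
                     start = NULL) {
  stopifnot(inherits(grm, "grm"))
  n <- length(y)
  if (n != nrow(grm$matrix))
    stop("reml_fit: y length ", n, " does not match GRM order ",
         nrow(grm$matrix), call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X))
    stop("reml_fit: fixed-effect design is rank deficient", call. = FALSE)
  eg <- eigen(grm$matrix, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  vy <- stats::var(y)
  if (is.null(start)) start <- c(0.5 * vy, 0.5 * vy)
  sa <- start[1]; se <- start[2]
  p_rank <- ncol(X)
  ll <- numeric(0)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    v <- sa * d + se
    w <- 1 / v
    XtW <- Xt * w
    xwx <- crossprod(Xt, XtW)
    xwx_inv <- solve(xwx)
    b <- xwx_inv %*% crossprod(XtW, yt)
    r <- drop(yt - Xt %*% b)
    Py <- w * r
    # tr(P) and tr(P D) via the rotated projection
    trP <- sum(w) - sum(xwx_inv * crossprod(Xt * w, Xt * w))
    trPD <- sum(w * d) - sum(xwx_inv * crossprod(Xt * w, Xt * (w * d)))
    ll <- c(ll, -0.5 * (sum(log(v)) +
                          determinant(xwx, logarithm = TRUE)$modulus +
                          sum(Py * r)))
    sa_new <- sa + (sa^2 / n) * (sum(d * Py^2) - trPD)
    se_new <- se + (se^2 / n) * (sum(Py^2) - trP)
    sa_new <- max(sa_new, 1e-10 * vy)
    se_new <- max(se_new, 1e-10 * vy)
    rel <- max(abs(sa_new - sa) / (abs(sa) + 1e-12),
               abs(se_new - se) / (abs(se) + 1e-12))
    sa <- sa_new; se <- se_new
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("reml_fit: EM-REML did not converge in ", max_iter,
            " iterations", call. = FALSE)
  # BLUP/BLUE at the final variance components
  v <- sa * d + se
  w <- 1 / v
  XtW <- Xt * w
  xwx <- crossprod(Xt, XtW)
  b <- solve(xwx, crossprod(XtW, yt))
  r <- drop(yt - Xt %*% b)
  gebv <- drop(U %*% (sa * d * w * r))
  names(gebv) <- rownames(grm$matrix)
  structure(list(
    sigma2_a = sa, sigma2_e = se, h2 = sa / (sa + se),
    fixed_effects = drop(b), gebv = gebv,
    converged = converged, n_iter = it, loglik = ll
  ), class = "gblup_fit")
}

#' Solve the GBLUP mixed-model equations at given variance components
#'
#' Builds and solves the Henderson mixed-model equations for
#' `y = X b + a + e` with `a ~ N(0, G sigma2_a)`:
#' `[X'X, X'; X, I + G^{-1} lambda] [b; a] = [X'y; y]`,
#' `lambda = sigma2_e / sigma2_a`. The solution residual of the MME
#' system is checked to be below `1e-8` relative to the right-hand side.
#'
#' @param y Phenotype vector.
#' @param X Fixed-effect design (default intercept).
#' @param grm A `grm`.
#' @param sigma2_a,sigma2_e Variance components (> 0), e.g. from
#'   [reml_fit()].
#' @return A `gblup_fit` with `fixed_effects` and `gebv` (no likelihood
#'   trace).
#' @export
solve_gblup <- function(y, X = NULL, grm, sigma2_a, sigma2_e) {
  stopifnot(inherits(grm, "grm"))
  if (sigma2_a <= 0 || sigma2_e <= 0)
    stop("solve_gblup: variance components must be positive", call. = FALSE)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  G <- grm$matrix
  Ginv <- tryCatch(solve(G), error = function(e)
    stop("solve_gblup: G is singular; rebuild with a larger blend_eps",
         call. = FALSE))
  lambda <- sigma2_e / sigma2_a
  p <- ncol(X)
  M <- rbind(cbind(crossprod(X), t(X)),
             cbind(X, diag(n) + Ginv * lambda))
  rhs <- c(crossprod(X, y), y)
  sol <- tryCatch(solve(M, rhs), error = function(e)
    stop("solve_gblup: singular MME coefficient matrix; increase blend_eps",
         call. = FALSE))
  resid <- M %*% sol - rhs
  if (sqrt(sum(resid^2)) / max(1, sqrt(sum(rhs^2))) > 1e-8)
    stop("solve_gblup: MME solution residual exceeds 1e-8", call. = FALSE)
  b <- sol[seq_len(p)]
  a <- sol[-seq_len(p)]
  names(a) <- rownames(G)
  structure(list(
    sigma2_a = sigma2_a, sigma2_e = sigma2_e,
    h2 = sigma2_a / (sigma2_a + sigma2_e),
    fixed_effects = b, gebv = a, converged = TRUE, n_iter = 0L,
    loglik = numeric(0)
  ), class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit: sigma2_a =", signif(x$sigma2_a, 4),
      " sigma2_e =", signif(x$sigma2_e, 4),
      " h2 =", signif(x$h2, 3),
      if (length(x$loglik)) paste0(" (", x$n_iter, " EM iterations",
                                   if (!x$converged) ", NOT converged", ")")
      else "", "\n")
  invisible(x)
}
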