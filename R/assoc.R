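#' Loiselle marker-based kinship matrix
#'
#' Pairwise coancestry from biallelic dosages using the Loiselle et al.
#' (1995) estimator: for lines i, j with per-locus allele frequencies
#' `p_il = dosage/2` and panel mean frequency `p_l`,
#' `f_ij = (sum_l (p_il - p_l)(p_jl - p_l) + sum_l p_l (1 - p_l) / (n_l - 1))
#'         / sum_l p_l (1 - p_l)`,
#' where `n_l` is the number of lines scored at locus l; the second
#' numerator term is the small-sample bias correction. Missing dosages are
#' mean-imputed per SNP before the cross-products are formed. Negative
#' estimates (less related than random pairs) are retained by default.
#'
#' @param g a [genotype_matrix()].
#' @param clamp_negative set negative off-diagonal estimates to zero.
#' @return symmetric lines x lines numeric matrix of class `matrix` with
#'   attribute `estimator = "loiselle"`.
#' @export
loiselle_kinship <- function(g, clamp_negative = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosage
  if (nrow(d) < 2L) stop("need at least 2 lines")
  n_l <- colSums(!is.na(d))
  pbar <- colMeans(d, na.rm = TRUE) / 2
  poly <- pbar > 0 & pbar < 1
  if (!any(poly)) stop("no polymorphic SNPs")
  d <- d[, poly, drop = FALSE]
  n_l <- n_l[poly]
  pbar <- pbar[poly]
  # mean imputation leaves the locus frequency unchanged
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * pbar[j]
  dev <- sweep(d / 2, 2L, pbar)
  denom <- sum(pbar * (1 - pbar))
  bias <- sum(pbar * (1 - pbar) / pmax(n_l - 1L, 1L))
  kin <- (tcrossprod(dev) + bias) / denom
  if (clamp_negative) {
    diag_save <- diag(kin)
    kin[kin < 0] <- 0
    diag(kin) <- diag_save
  }
  dimnames(kin) <- list(rownames(g$dosage), rownames(g$dosage))
  attr(kin, "estimator") <- "loiselle"
  kin
}

#' Genotype principal components as population-structure covariates
#'
#' The leading principal components of the mean-imputed, centered dosage
#' matrix, the standard fixed-effect stand-in for ancestry membership
#' proportions.
#'
#' @param g a [genotype_matrix()].
#' @param q number of components (0 gives a zero-column matrix: intercept
#'   only downstream).
#' @return lines x q matrix of PC scores (columns `PC1..PCq`).
#' @export
structure_pcs <- function(g, q = 3L) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (q < 0) stop("q must be >= 0")
  if (q >= nrow(g$dosage)) stop("q must be smaller than the number of lines")
  d <- g$dosage
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  if (q == 0L)
    return(matrix(0, nrow(d), 0L, dimnames = list(rownames(d), NULL)))
  pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(q), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(q))
  rownames(sc) <- rownames(g$dosage)
  sc
}

# Floor the eigenvalues of a kinship matrix at `floor` so the mixed model's
# covariance is positive semi-definite; reports the applied shift.
psd_eigen <- function(K, floor = 1e-8) {
  ek <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(ek$values) < floor) {
    message(sprintf("kinship eigenvalues floored at %g (min was %.3g)",
                    floor, min(ek$values)))
    ek$values <- pmax(ek$values, floor)
  }
  ek
}

# REML log-likelihood profile in the rotated basis, up to an additive
# constant: lambda = sigma_g^2 / sigma_e^2.
reml_profile <- function(log_lambda, d, yt, Xt) {
  lambda <- exp(log_lambda)
  v <- lambda * d + 1
  w <- 1 / v
  XtW <- Xt * w
  XtWX <- crossprod(Xt, XtW)
  beta <- solve(XtWX, crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  n <- length(yt); q <- ncol(Xt)
  s2 <- sum(w * r^2) / (n - q)
  -0.5 * ((n - q) * log(s2) + sum(log(v)) + determinant(XtWX)$modulus[1])
}

#' Fit the null mixed linear model by eigendecomposition REML
#'
#' Model: `y = X b + u + e` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)`. The kinship matrix is eigendecomposed once; the
#' restricted likelihood is then a one-dimensional function of the variance
#' ratio `lambda = sigma_g^2 / sigma_e^2`, profiled over `log(lambda)` by
#' golden-section search after a coarse grid. Narrow-sense heritability is
#' `h^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2) = lambda / (1 + lambda)`.
#'
#' @param y numeric trait vector, one value per line.
#' @param cov lines x q fixed-effect covariate matrix (e.g.
#'   [structure_pcs()]); an intercept is always added.
#' @param K kinship matrix (PSD enforced by eigenvalue flooring).
#' @param lambda_range log10 search bounds for the variance ratio.
#' @return An object of class `variance_components`: `sigma_g`, `sigma_e`,
#'   `h2`, `loglik` (restricted, up to constant), `lambda`, plus the rotated
#'   quantities reused by [scan_snps()].
#' @export
fit_null_mlm <- function(y, cov = NULL, K, lambda_range = c(-6, 6)) {
  y <- as.numeric(y)
  n <- length(y)
  if (any(!is.finite(y))) stop("y must be finite (drop missing lines first)")
  if (stats::sd(y) == 0) stop("y is constant")
  if (is.null(cov)) cov <- matrix(0, n, 0L)
  stopifnot(nrow(K) == n, nrow(cov) == n)
  X <- cbind(`(Intercept)` = 1, cov)
  if (qr(X)$rank < ncol(X)) stop("covariates are rank deficient with intercept")
  ek <- psd_eigen(K)
  U <- ek$vectors; d <- ek$values
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  # coarse grid then local refinement on log(lambda)
  grid <- seq(lambda_range[1] * log(10), lambda_range[2] * log(10), length.out = 61)
  ll <- vapply(grid, reml_profile, 0, d = d, yt = yt, Xt = Xt)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(reml_profile, c(lo, hi), d = d, yt = yt, Xt = Xt,
                         maximum = TRUE, tol = 1e-8)
  lambda <- exp(opt$maximum)
  v <- lambda * d + 1
  w <- 1 / v
  XtW <- Xt * w
  beta <- solve(crossprod(Xt, XtW), crossprod(XtW, yt))
  r <- yt - Xt %*% beta
  sigma_e <- sum(w * r^2) / (n - ncol(X))
  sigma_g <- lambda * sigma_e
  structure(list(sigma_g = sigma_g, sigma_e = sigma_e,
                 h2 = lambda / (1 + lambda), lambda = lambda,
                 loglik = opt$objective, beta = drop(beta),
                 U = U, d = d, X = X, y = y),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components: sigma_g^2 = %.4g, sigma_e^2 = %.4g, h2 = %.3f\n",
              x$sigma_g, x$sigma_e, x$h2))
  invisible(x)
}

#' Mixed-model association scan over all SNPs
#'
#' P3D strategy: the variance components estimated once on the null model
#' are reused for every SNP, so each test is a generalized least squares
#' regression of the trait on covariates plus one SNP under the fixed
#' covariance `sigma_g^2 K + sigma_e^2 I`, with a Wald/F test on the SNP
#' coefficient. SNPs below the minor-allele-frequency floor are excluded
#' before testing, as are SNPs constant across lines. Lines missing a SNP
#' call are excluded pairwise for that SNP's test.
#'
#' @param vc a fitted [fit_null_mlm()] null model.
#' @param g a [genotype_matrix()] over the same lines, same order.
#' @param maf_min minor-allele-frequency floor; SNPs with MAF >= the floor
#'   are kept (default 0.05).
#' @param fdr_alphas two significance levels applied to BH-adjusted
#'   p-values (default conservative 0.001 and generous 0.05).
#' @return An object of class `gwas_result`: data.frame `snp`, `chrom`,
#'   `pos`, `maf`, `effect`, `se`, `p`, `fdr_p`, `sig001`, `sig05` (flag
#'   names follow the default alphas), with attributes `n_excluded_maf`,
#'   `n_excluded_constant`, `fdr_alphas`.
#' @export
scan_snps <- function(vc, g, maf_min = 0.05, fdr_alphas = c(0.001, 0.05)) {
  stopifnot(inherits(vc, "variance_components"), inherits(g, "genotype_matrix"))
  n <- length(vc$y)
  stopifnot(nrow(g$dosage) == n)
  maf <- minor_allele_freq(g)
  keep_maf <- maf >= maf_min - 1e-12
  const <- apply(g$dosage, 2L, function(col) {
    col <- col[!is.na(col)]
    length(unique(col)) < 2L
  })
  keep <- keep_maf & !const
  n_ex_maf <- sum(!keep_maf)
  n_ex_const <- sum(const & keep_maf)
  idx <- which(keep)
  # rotated, whitened null quantities (complete-data fast path)
  w <- 1 / (vc$lambda * vc$d + 1)
  sw <- sqrt(w)
  yt <- drop(crossprod(vc$U, vc$y)) * sw
  Xt <- crossprod(vc$U, vc$X) * sw
  qrX <- qr(Xt)
  yr <- qr.resid(qrX, yt)
  out <- vector("list", length(idx))
  V <- NULL  # dense covariance, built lazily for SNPs with missing lines
  for (jj in seq_along(idx)) {
    j <- idx[jj]
    snp <- g$dosage[, j]
    if (anyNA(snp)) {
      ok <- !is.na(snp)
      if (is.null(V))
        V <- vc$sigma_g * (vc$U %*% (vc$d * t(vc$U))) + vc$sigma_e * diag(n)
      fit <- gls_wald(vc$y[ok], cbind(vc$X[ok, , drop = FALSE], snp[ok]),
                      V[ok, ok, drop = FALSE])
    } else {
      gt <- drop(crossprod(vc$U, snp)) * sw
      gr <- qr.resid(qrX, gt)
      gg <- sum(gr^2)
      beta <- sum(gr * yr) / gg
      rss <- sum(yr^2) - beta^2 * gg
      df <- n - ncol(Xt) - 1L
      se <- sqrt(rss / df / gg)
      tval <- beta / se
      fit <- list(effect = beta, se = se,
                  p = 2 * stats::pt(-abs(tval), df))
    }
    out[[jj]] <- data.frame(snp = colnames(g$dosage)[j], chrom = g$chrom[j],
                            pos = g$pos[j], maf = maf[j],
                            effect = fit$effect, se = fit$se, p = fit$p,
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(snp = character(), chrom = integer(), pos = numeric(),
               maf = numeric(), effect = numeric(), se = numeric(),
               p = numeric(), stringsAsFactors = FALSE)
  res$fdr_p <- bh_adjust(res$p)
  res$sig001 <- res$fdr_p < fdr_alphas[1]
  res$sig05 <- res$fdr_p < fdr_alphas[2]
  rownames(res) <- NULL
  structure(res, class = c("gwas_result", "data.frame"),
            n_excluded_maf = n_ex_maf, n_excluded_constant = n_ex_const,
            fdr_alphas = fdr_alphas)
}

# Dense GLS with a Wald/F t-test on the last column of X.
gls_wald <- function(y, X, V) {
  L <- chol(V)
  yw <- backsolve(L, y, transpose = TRUE)
  Xw <- backsolve(L, X, transpose = TRUE)
  qrx <- qr(Xw)
  beta <- qr.coef(qrx, yw)
  r <- yw - Xw %*% beta
  df <- length(y) - ncol(X)
  s2 <- sum(r^2) / df
  XtX_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(s2 * XtX_inv[ncol(X), ncol(X)])
  tval <- beta[ncol(X)] / se
  list(effect = beta[ncol(X)], se = se, p = 2 * stats::pt(-abs(tval), df))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), after validating the
#' inputs lie in the unit interval.
#'
#' @param pvals numeric vector of raw p-values.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Significant SNP sets at the two declared FDR levels
#'
#' @param res a [scan_snps()] result.
#' @return named list of character vectors of SNP ids, one per alpha; the
#'   conservative set is always a subset of the generous one.
#' @export
significant_sets <- function(res) {
  alphas <- attr(res, "fdr_alphas")
  if (is.null(alphas)) alphas <- c(0.001, 0.05)
  out <- lapply(alphas, function(a) res$snp[res$fdr_p < a])
  names(out) <- as.character(alphas)
  out
}

#' Overlap between two significant SNP sets
#'
#' Used to check that module-level hits are echoed by single-feature scans
#' (and vice versa).
#'
#' @param setA,setB character vectors of SNP ids.
#' @return list with `n_a`, `n_b`, `n_shared`, `shared` (sorted ids).
#' @export
concordance <- function(setA, setB) {
  shared <- sort(intersect(setA, setB))
  list(n_a = length(setA), n_b = length(setB),
       n_shared = length(shared), shared = shared)
}

#' Export Manhattan-plot data
#'
#' @param res a [scan_snps()] result.
#' @param path optional output TSV path.
#' @return data.frame `snp`, `chrom`, `pos`, `neg_log10_p` sorted by
#'   (chrom, pos), with attribute `thresholds` giving the
#'   `-log10` FDR cut lines; written to `path` when given.
#' @export
manhattan_export <- function(res, path = NULL) {
  df <- data.frame(snp = res$snp, chrom = res$chrom, pos = res$pos,
                   neg_log10_p = -log10(res$p), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  alphas <- attr(res, "fdr_alphas")
  if (is.null(alphas)) alphas <- c(0.001, 0.05)
  attr(df, "thresholds") <- stats::setNames(-log10(alphas), as.character(alphas))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Write a GWAS result table as TSV
#'
#' @param res a [scan_snps()] result.
#' @param path output path.
#' @export
write_gwas <- function(res, path) {
  utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
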