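#' Column scaling for feature matrices
#'
#' `autoscale()` centers each feature and divides by its sample standard
#' deviation (n - 1 denominator), giving every feature equal weight in the
#' correlation network regardless of its ion-count magnitude — this damps the
#' dominance of dynamic, high-concentration metabolites. `pareto_scale()`
#' divides the centered values by the square root of the standard deviation
#' instead, a gentler compression conventional for PCA of metabolomics data.
#'
#' Zero-variance features carry no correlation information and cannot be
#' scaled; they are dropped with a warning.
#'
#' @param x a [feature_table()] or a numeric samples x features matrix.
#' @return A numeric matrix of the same shape (minus dropped columns) with
#'   attribute `scaling` set to `"autoscale"` or `"pareto"`, and attribute
#'   `dropped` listing removed zero-variance feature ids.
#' @export
autoscale <- function(x) scale_columns(x, "autoscale")

#' @rdname autoscale
#' @export
pareto_scale <- function(x) scale_columns(x, "pareto")

scale_columns <- function(x, method) {
  mat <- if (inherits(x, "feature_table")) x$intensities else as.matrix(x)
  if (nrow(mat) < 2L) stop("scaling needs at least 2 samples")
  if (any(!is.finite(mat))) stop("matrix must be complete and finite")
  s <- apply(mat, 2L, stats::sd)
  dropped <- colnames(mat)[s == 0]
  if (length(dropped)) {
    warning(sprintf("dropping %d zero-variance feature(s): %s",
                    length(dropped),
                    paste(utils::head(dropped, 5), collapse = ", ")))
    mat <- mat[, s > 0, drop = FALSE]
    s <- s[s > 0]
  }
  centered <- sweep(mat, 2L, colMeans(mat))
  out <- sweep(centered, 2L, if (method == "autoscale") s else sqrt(s), "/")
  attr(out, "scaling") <- method
  attr(out, "dropped") <- dropped
  out
}

#' PCA variance-fraction summary
#'
#' A quality-control view of a scaled matrix: the fraction of total variance
#' carried by each of the leading principal components. Diverse germplasm
#' panels typically show a flat spectrum (a few tens of percent in the first
#' two or three components).
#'
#' @param sm scaled matrix from [autoscale()] or [pareto_scale()].
#' @param ncomp number of leading components to report.
#' @return data.frame with columns `pc`, `variance_fraction`,
#'   `cumulative_fraction`.
#' @export
pca_summary <- function(sm, ncomp = 5L) {
  if (ncomp < 1L) stop("ncomp must be >= 1")
  ncomp <- min(ncomp, nrow(sm) - 1L, ncol(sm))
  p <- stats::prcomp(sm, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  data.frame(pc = seq_len(ncomp),
             variance_fraction = frac[seq_len(ncomp)],
             cumulative_fraction = cumsum(frac)[seq_len(ncomp)])
}
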