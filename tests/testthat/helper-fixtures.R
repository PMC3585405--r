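# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Mid-sized simulated cohort reused across network/GWAS/stepwise tests.
test_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- sim_config(n_lines = 200L, n_snps = 300L, n_features = 600L,
                      module_sizes = c(120L, 80L, 60L, 40L, 30L, 20L, 15L, 10L),
                      seed = 7L)
    co <- sim_cohort(cfg)
    co$cfg <- cfg
    co$sm <- autoscale(co$feature_table)
    co$net <- build_network(co$sm, beta = 6)
    co$partition <- detect_modules(co$net)
    co$me <- module_eigenvalues(co$sm, co$partition)
    .fixture_env$cohort <- co
  }
  .fixture_env$cohort
}

# True module labels ("bg" for background) aligned to a cohort's features.
true_module_labels <- function(co) {
  lab <- rep("bg", ncol(co$sm))
  names(lab) <- colnames(co$sm)
  for (m in names(co$truth$module_features))
    lab[co$truth$module_features[[m]]] <- m
  lab
}

# Tiny feature table with hand-set intensities.
toy_feature_table <- function(mat, rts = NULL, mzs = NULL, channel = "MS") {
  p <- ncol(mat)
  if (is.null(mzs)) mzs <- seq(100, by = 10, length.out = p)
  if (is.null(rts)) rts <- seq(60, by = 1, length.out = p)
  colnames(mat) <- sprintf("%.3f_%.2f", mzs, rts)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("s%d", seq_len(nrow(mat)))
  feature_table(mat, channel = channel)
}

# Two vectors with an exact Pearson correlation r (n = 4 construction).
vectors_with_cor <- function(r) {
  x <- c(1, -1, 1, -1)
  z <- c(1, 1, -1, -1)
  y <- r * x + sqrt(1 - r^2) * z
  cbind(x = x, y = y)
}
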