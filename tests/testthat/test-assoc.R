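# Independent hand evaluation of the Loiselle coancestry estimator on
# explicit per-line allele frequencies (dosage / 2).
loiselle_oracle <- function(dosage) {
  p <- dosage / 2
  pbar <- colMeans(p)
  keep <- pbar > 0 & pbar < 1
  p <- p[, keep, drop = FALSE]; pbar <- pbar[keep]
  n <- nrow(dosage)
  denom <- sum(pbar * (1 - pbar))
  bias <- sum(pbar * (1 - pbar) / (n - 1))
  k <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    k[i, j] <- (sum((p[i, ] - pbar) * (p[j, ] - pbar)) + bias) / denom
  k
}

test_that("Loiselle kinship matches the hand-arithmetic oracle", {
  dos <- matrix(c(0, 2, 2,
                  2, 0, 2), 3, 2,
                dimnames = list(c("l1", "l2", "l3"), c("S1_1", "S1_2")))
  g <- genotype_matrix(dos)
  K <- loiselle_kinship(g)
  expect_equal(unname(unclass(K))[1:3, 1:3], loiselle_oracle(dos),
               tolerance = 1e-12)
  expect_equal(K, t(K))
})

test_that("identical lines attain the maximal pairwise kinship", {
  dos <- rbind(l1 = c(0, 2, 0, 2, 2),
               l2 = c(0, 2, 0, 2, 2),
               l3 = c(2, 0, 2, 0, 2),
               l4 = c(2, 0, 0, 2, 0))
  colnames(dos) <- paste0("S1_", 1:5)
  K <- loiselle_kinship(genotype_matrix(dos))
  off <- K; diag(off) <- -Inf
  expect_equal(K["l1", "l2"], max(off))
  expect_equal(K["l1", "l2"], K["l1", "l1"])  # ties with self-comparison

  # permuting line order permutes rows and columns identically
  perm <- c(3, 1, 4, 2)
  K2 <- loiselle_kinship(genotype_matrix(dos[perm, ]))
  expect_equal(unclass(K2), unclass(K)[perm, perm], ignore_attr = TRUE)
  expect_error(loiselle_kinship(genotype_matrix(
    matrix(2, 2, 2, dimnames = list(NULL, c("S1_1", "S1_2"))))),
    "polymorphic")
})

test_that("genotype PCs separate simulated subpopulations", {
  cfg <- sim_config(n_lines = 120, n_snps = 400, n_subpops = 2, fst = 0.3,
                    seed = 31)
  geno <- sim_genotypes(cfg)
  pcs <- structure_pcs(geno$genotypes, q = 3)
  r <- cor(pcs[, 1], geno$truth$subpop)
  expect_gt(abs(r), 0.9)
  # orthogonality of scores
  cp <- crossprod(pcs)
  expect_true(all(abs(cp[upper.tri(cp)]) < 1e-6))
  expect_equal(ncol(structure_pcs(geno$genotypes, q = 0)), 0L)
  expect_error(structure_pcs(geno$genotypes, q = 200), "smaller")
})

test_that("null model REML is scale equivariant", {
  co <- test_cohort()
  K <- loiselle_kinship(co$genotypes)
  y <- co$me$scores[1, ]
  vc1 <- fit_null_mlm(y, K = K)
  vc2 <- fit_null_mlm(2 * y, K = K)
  expect_equal(vc2$sigma_g, 4 * vc1$sigma_g, tolerance = 1e-4)
  expect_equal(vc2$sigma_e, 4 * vc1$sigma_e, tolerance = 1e-4)
  expect_equal(vc2$h2, vc1$h2, tolerance = 1e-6)
  expect_error(fit_null_mlm(rep(1, nrow(K)), K = K), "constant")
})

test_that("scan enforces the MAF floor inclusively", {
  set.seed(41)
  n <- 100
  dos <- cbind(
    S1_1 = c(rep(2, 4), rep(0, n - 4)),   # MAF 0.04: excluded
    S1_2 = c(rep(2, 5), rep(0, n - 5)),   # MAF exactly 0.05: retained
    S1_3 = sample(c(0, 2), n, replace = TRUE),
    S1_4 = rep(2, n))                     # constant: excluded
  rownames(dos) <- sprintf("l%03d", 1:n)
  g <- genotype_matrix(dos)
  K <- diag(n); dimnames(K) <- list(rownames(dos), rownames(dos))
  vc <- fit_null_mlm(rnorm(n), K = K)
  res <- scan_snps(vc, g, maf_min = 0.05)
  expect_false("S1_1" %in% res$snp)
  expect_true("S1_2" %in% res$snp)
  expect_false("S1_4" %in% res$snp)
  expect_equal(attr(res, "n_excluded_maf"), 2L)  # S1_1 and constant S1_4
})

test_that("with identity kinship the scan reduces to ordinary regression", {
  set.seed(42)
  n <- 60
  dos <- sapply(1:10, function(i) sample(c(0, 2), n, replace = TRUE))
  colnames(dos) <- paste0("S1_", 1:10)
  rownames(dos) <- sprintf("l%02d", 1:n)
  g <- genotype_matrix(dos)
  y <- rnorm(n) + 0.5 * dos[, 3]
  K <- diag(n); dimnames(K) <- list(rownames(dos), rownames(dos))
  vc <- fit_null_mlm(y, K = K)
  res <- scan_snps(vc, g, maf_min = 0)
  # oracle: per-SNP OLS F-test (V proportional to I makes GLS = OLS)
  for (j in seq_len(10)) {
    ols <- summary(lm(y ~ dos[, j]))$coefficients
    row <- res[res$snp == paste0("S1_", j), ]
    expect_equal(row$p, ols[2, 4], tolerance = 1e-8)
    expect_equal(row$effect, ols[2, 1], tolerance = 1e-8)
  }
})

test_that("p-values are invariant to line order and missing calls are handled", {
  co <- test_cohort()
  g <- co$genotypes
  K <- loiselle_kinship(g)
  pcs <- structure_pcs(g, 2)
  y <- co$me$scores[2, ]
  vc <- fit_null_mlm(y, pcs, K)
  res <- scan_snps(vc, g)

  perm <- sample(nrow(g$dosage))
  gp <- genotype_matrix(g$dosage[perm, ], chrom = g$chrom, pos = g$pos)
  Kp <- loiselle_kinship(gp)
  vcp <- fit_null_mlm(y[perm], pcs[perm, ], Kp)
  resp <- scan_snps(vcp, gp)
  expect_equal(resp$p, res$p, tolerance = 1e-6)

  # sprinkle missing calls into a few SNPs: pairwise-complete path
  dos_na <- g$dosage
  set.seed(77)
  for (j in 1:3) dos_na[sample(nrow(dos_na), 5), j] <- NA
  gna <- genotype_matrix(dos_na, chrom = g$chrom, pos = g$pos)
  resna <- scan_snps(vc, gna)
  expect_true(all(is.finite(resna$p)))
  # untouched SNPs keep their p-values
  same <- setdiff(res$snp, colnames(g$dosage)[1:3])
  expect_equal(resna$p[match(same, resna$snp)], res$p[match(same, res$snp)],
               tolerance = 1e-10)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.17), 0.17)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.02, 0.5, 0.9)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("significance sets are nested and concordance counts overlap", {
  res <- structure(
    data.frame(snp = c("s1", "s2", "s3"), chrom = 1, pos = 1:3, maf = 0.3,
               effect = 1, se = 1, p = c(1e-6, 0.002, 0.2),
               fdr_p = c(0.0005, 0.01, 0.3),
               sig001 = c(TRUE, FALSE, FALSE), sig05 = c(TRUE, TRUE, FALSE)),
    class = c("gwas_result", "data.frame"), fdr_alphas = c(0.001, 0.05))
  sets <- significant_sets(res)
  expect_equal(sets[["0.001"]], "s1")
  expect_equal(sets[["0.05"]], c("s1", "s2"))
  expect_true(all(sets[["0.001"]] %in% sets[["0.05"]]))

  cc <- concordance(c("s1", "s2", "s3"), c("s2", "s3", "s4"))
  expect_equal(cc$n_shared, 2L)
  expect_equal(cc$shared, c("s2", "s3"))
  expect_equal(concordance(c("a"), c("b"))$n_shared, 0L)
})

test_that("manhattan export is sorted with threshold metadata", {
  res <- structure(
    data.frame(snp = c("s1", "s2"), chrom = c(2L, 1L), pos = c(5, 9),
               maf = 0.3, effect = 1, se = 1, p = c(0.001, 0.01),
               fdr_p = c(0.01, 0.05), sig001 = FALSE, sig05 = TRUE),
    class = c("gwas_result", "data.frame"), fdr_alphas = c(0.001, 0.05))
  mh <- manhattan_export(res)
  expect_equal(mh$chrom, c(1L, 2L))
  expect_equal(mh$neg_log10_p[2], 3)  # -log10(0.001)
  expect_equal(unname(attr(mh, "thresholds")["0.001"]), 3)
  expect_equal(nrow(mh), nrow(res))
  empty <- res[0, ]
  attr(empty, "fdr_alphas") <- c(0.001, 0.05)
  expect_equal(nrow(manhattan_export(empty)), 0L)
})

test_that("module eigenvalue GWAS beats the median member feature at the QTL", {
  co <- test_cohort()
  K <- loiselle_kinship(co$genotypes)
  pcs <- structure_pcs(co$genotypes, 3)
  causal <- co$truth$causal
  # module 1's features are the turquoise module (largest)
  mod_feats <- co$truth$module_features$latent1
  vc_me <- fit_null_mlm(co$me$scores["turquoise", ], pcs, K)
  res_me <- scan_snps(vc_me, co$genotypes)
  lp_me <- -log10(res_me$p[res_me$snp == causal$snp[1]])
  set.seed(99)
  feats <- sample(mod_feats, 15)
  lp_single <- vapply(feats, function(f) {
    vc <- fit_null_mlm(co$sm[, f], pcs, K)
    res <- scan_snps(vc, co$genotypes)
    -log10(res$p[res$snp == causal$snp[1]])
  }, 0)
  expect_gt(lp_me, median(lp_single))

  # concordance: with a strong module QTL, the causal SNP is significant in
  # both the eigenvalue scan and a single-member-feature scan
  cfg <- sim_config(n_lines = 200, n_snps = 200, n_features = 40,
                    module_sizes = 30L, loading_range = c(0.85, 0.95),
                    noise_sd = 0.4,
                    qtl = data.frame(module = 1, effect = 1.0), seed = 45)
  cs <- sim_cohort(cfg)
  sm <- autoscale(cs$feature_table)
  Ks <- loiselle_kinship(cs$genotypes)
  pcss <- structure_pcs(cs$genotypes, 3)
  parts <- detect_modules(build_network(sm, beta = 6), min_module_size = 10)
  mes <- module_eigenvalues(sm, parts)
  res_mod <- scan_snps(fit_null_mlm(mes$scores[1, ], pcss, Ks), cs$genotypes)
  feat <- cs$truth$module_features$latent1[
    which.max(cs$truth$loadings[1:30])]
  res_one <- scan_snps(fit_null_mlm(sm[, feat], pcss, Ks), cs$genotypes)
  cc <- concordance(significant_sets(res_mod)[["0.05"]],
                    significant_sets(res_one)[["0.05"]])
  expect_true(cs$truth$causal$snp[1] %in% cc$shared)
})
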