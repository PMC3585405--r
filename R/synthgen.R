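#' Simulation configuration for a synthetic association cohort
#'
#' Bundles every knob of the generator with defaults emulating a diverse
#' inbred panel profiled by non-targeted LC-MS: a couple of hundred lines
#' drawn from a few differentiated subpopulations, a few hundred genotyped
#' SNPs, a metabolome of thousands of features organized in latent
#' correlation modules, module-level QTLs, and a moderately heritable
#' polygenic phenotype.
#'
#' @param n_lines number of inbred lines (default 200).
#' @param n_snps number of biallelic SNPs (default 500).
#' @param n_subpops number of subpopulations (default 3).
#' @param fst differentiation of subpopulation allele frequencies from the
#'   ancestral pool, in (0, 1) (default 0.2).
#' @param het_rate residual heterozygosity of the inbred lines (default 0:
#'   dosages are 0/2).
#' @param module_sizes integer vector of latent-module sizes (default 8
#'   modules from 200 down to 10 features).
#' @param n_features total feature count including unstructured background
#'   (default 2000).
#' @param loading_range per-feature factor loadings are drawn uniformly
#'   from this interval (default c(0.7, 0.9)).
#' @param noise_sd SD of per-feature noise around the loaded latent
#'   (default 0.6).
#' @param qtl data.frame with columns `module` (latent index) and `effect`
#'   (added per dosage unit); causal SNPs are picked deterministically from
#'   the seed among common SNPs. Default: one QTL of effect 0.5 on each of
#'   the first three modules.
#' @param pheno_weights weights of the module latents in the genetic part
#'   of the phenotype (recycled/truncated to the module count).
#' @param h2 target phenotype heritability (default 0.5).
#' @param mz_range,rt_range ranges for synthetic feature m/z (Da) and
#'   retention time (s), matching a typical small-molecule acquisition.
#' @param seed mandatory RNG seed; stages use fixed offsets from it so each
#'   is independently reproducible.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 200L, n_snps = 500L, n_subpops = 3L,
                       fst = 0.2, het_rate = 0,
                       module_sizes = c(200L, 120L, 80L, 60L, 40L, 25L, 15L, 10L),
                       n_features = 2000L,
                       loading_range = c(0.7, 0.9), noise_sd = 0.6,
                       qtl = data.frame(module = 1:3, effect = 0.5),
                       pheno_weights = c(1, 1),
                       h2 = 0.5,
                       mz_range = c(50, 1200), rt_range = c(0, 720),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  qtl <- as.data.frame(qtl)  # YAML configs deliver plain lists
  stopifnot(n_lines > 1, n_snps > 0, n_subpops > 0,
            fst > 0, fst < 1, all(module_sizes > 0),
            sum(module_sizes) <= n_features,
            loading_range[1] > 0, loading_range[2] <= 1,
            h2 >= 0, h2 <= 1)
  if (nrow(qtl) && !all(qtl$module %in% seq_along(module_sizes)))
    stop("qtl$module refers to a module beyond length(module_sizes)")
  structure(list(n_lines = as.integer(n_lines), n_snps = as.integer(n_snps),
                 n_subpops = as.integer(n_subpops), fst = fst,
                 het_rate = het_rate, module_sizes = as.integer(module_sizes),
                 n_features = as.integer(n_features),
                 loading_range = loading_range, noise_sd = noise_sd,
                 qtl = qtl, pheno_weights = pheno_weights, h2 = h2,
                 mz_range = mz_range, rt_range = rt_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate structured inbred genotypes (Balding-Nichols model)
#'
#' Ancestral allele frequencies are uniform on (0.1, 0.9); each
#' subpopulation's frequency is drawn from the Beta distribution with
#' parameters `p (1 - Fst) / Fst` and `(1 - p)(1 - Fst) / Fst`, so Fst
#' controls differentiation. Lines are assigned to subpopulations
#' round-robin and, being inbred, carry dosage 0 or 2 (a configurable
#' residual heterozygosity adds dosage-1 calls).
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]) and `truth` (list
#'   with `subpop`, `p_anc`, `p_subpop`).
#' @export
sim_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p_anc <- stats::runif(cfg$n_snps, 0.1, 0.9)
  a <- (1 - cfg$fst) / cfg$fst
  p_sub <- sapply(seq_len(cfg$n_subpops), function(s)
    stats::rbeta(cfg$n_snps, p_anc * a, (1 - p_anc) * a))
  subpop <- rep_len(seq_len(cfg$n_subpops), cfg$n_lines)
  dosage <- matrix(0, cfg$n_lines, cfg$n_snps)
  for (i in seq_len(cfg$n_lines)) {
    p <- p_sub[, subpop[i]]
    het <- stats::runif(cfg$n_snps) < cfg$het_rate
    dosage[i, ] <- ifelse(het, 1, 2 * stats::rbinom(cfg$n_snps, 1L, p))
  }
  chrom <- rep_len(1:10, cfg$n_snps)
  pos <- stats::ave(seq_len(cfg$n_snps), chrom, FUN = seq_along) * 100000L
  colnames(dosage) <- paste0("S", chrom, "_", pos)
  rownames(dosage) <- sprintf("line%03d", seq_len(cfg$n_lines))
  names(subpop) <- rownames(dosage)
  list(genotypes = genotype_matrix(dosage, chrom = chrom, pos = pos),
       truth = list(subpop = subpop, p_anc = p_anc, p_subpop = p_sub))
}

#' Simulate a module-structured metabolome from genotypes
#'
#' Each latent module value per line is the sum of its QTL effects times
#' dosage plus standard normal noise; each member feature is its module's
#' latent times a per-feature loading plus Gaussian noise; background
#' features are pure noise. Standardized values are mapped affinely to
#' positive ion-count-like intensities (1000 + 100 z, floored at 0), which
#' preserves every correlation. Features receive plausible m/z and
#' retention times and `"<mz>_<rt>"` ids.
#'
#' @param genotypes a [genotype_matrix()] (from [sim_genotypes()]).
#' @param cfg a [sim_config()].
#' @return list with `feature_table` (low collision energy) and `truth`
#'   (list with `latents` lines x modules, `module_features` named list of
#'   feature ids, `causal` data.frame snp/module/effect, `loadings`).
#' @export
sim_metabolome <- function(genotypes, cfg) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(genotypes$dosage)
  n_mod <- length(cfg$module_sizes)
  maf <- minor_allele_freq(genotypes)
  common <- which(maf >= 0.2 & maf <= 0.45)
  qtl <- cfg$qtl
  causal <- NULL
  latents <- matrix(stats::rnorm(n * n_mod), n, n_mod)
  if (nrow(qtl)) {
    picks <- sample(common, nrow(qtl))
    causal <- data.frame(snp = colnames(genotypes$dosage)[picks],
                         module = qtl$module, effect = qtl$effect,
                         stringsAsFactors = FALSE)
    for (r in seq_len(nrow(qtl)))
      latents[, qtl$module[r]] <- latents[, qtl$module[r]] +
        qtl$effect[r] * genotypes$dosage[, picks[r]]
  }
  z <- matrix(stats::rnorm(n * cfg$n_features, sd = cfg$noise_sd),
              n, cfg$n_features)
  loadings <- numeric(cfg$n_features)
  col <- 1L
  module_cols <- vector("list", n_mod)
  for (m in seq_len(n_mod)) {
    idx <- col:(col + cfg$module_sizes[m] - 1L)
    loadings[idx] <- stats::runif(length(idx), cfg$loading_range[1],
                                  cfg$loading_range[2])
    z[, idx] <- z[, idx] + outer(scale_vec(latents[, m]), loadings[idx])
    module_cols[[m]] <- idx
    col <- col + cfg$module_sizes[m]
  }
  # background features stay N(0, noise_sd) -> rescale to unit-ish spread
  if (col <= cfg$n_features)
    z[, col:cfg$n_features] <- matrix(
      stats::rnorm(n * (cfg$n_features - col + 1L)), n,
      cfg$n_features - col + 1L)
  mz <- stats::runif(cfg$n_features, cfg$mz_range[1], cfg$mz_range[2])
  rt <- stats::runif(cfg$n_features, cfg$rt_range[1], cfg$rt_range[2])
  ids <- sprintf("%.4f_%.2f", mz, rt)
  while (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    mz[dup] <- mz[dup] + 0.0001
    ids <- sprintf("%.4f_%.2f", mz, rt)
  }
  intensities <- pmax(1000 + 100 * z, 0)
  dimnames(intensities) <- list(rownames(genotypes$dosage), ids)
  rownames(latents) <- rownames(genotypes$dosage)
  colnames(latents) <- paste0("latent", seq_len(n_mod))
  list(feature_table = feature_table(intensities, channel = "MS"),
       truth = list(latents = latents,
                    module_features = stats::setNames(
                      lapply(module_cols, function(i) ids[i]),
                      colnames(latents)),
                    causal = causal, loadings = loadings))
}

scale_vec <- function(x) (x - mean(x)) / stats::sd(x)

#' Simulate a polygenic phenotype from module latents
#'
#' The genetic value is a weighted sum of the module latents; i.i.d.
#' Gaussian noise is added with variance chosen from the realized genetic
#' variance so the in-sample variance ratio equals the target heritability
#' in expectation. `h2 = 1` gives a deterministic phenotype, `h2 = 0` pure
#' noise.
#'
#' @param latents lines x modules latent matrix (from [sim_metabolome()]
#'   truth).
#' @param cfg a [sim_config()].
#' @return list with `phenotype` (data.frame `line`, `trait`), `h2`
#'   (target), `genetic` (the genetic values).
#' @export
sim_phenotype <- function(latents, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  w <- rep(0, ncol(latents))
  w[seq_along(cfg$pheno_weights)] <- cfg$pheno_weights
  g <- drop(latents %*% w)
  n <- length(g)
  if (cfg$h2 == 0) {
    y <- stats::rnorm(n)
  } else if (cfg$h2 == 1) {
    y <- g
  } else {
    ve <- stats::var(g) * (1 - cfg$h2) / cfg$h2
    y <- g + stats::rnorm(n, sd = sqrt(ve))
  }
  list(phenotype = data.frame(line = rownames(latents), trait = y,
                              stringsAsFactors = FALSE),
       h2 = cfg$h2, genetic = stats::setNames(g, rownames(latents)))
}

#' Simulate a full cohort
#'
#' Convenience wrapper chaining [sim_genotypes()], [sim_metabolome()] and
#' [sim_phenotype()]; the combined truth record is returned alongside the
#' observables.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes`, `feature_table`, `phenotype`, `truth`.
#' @export
sim_cohort <- function(cfg) {
  geno <- sim_genotypes(cfg)
  met <- sim_metabolome(geno$genotypes, cfg)
  phe <- sim_phenotype(met$truth$latents, cfg)
  list(genotypes = geno$genotypes, feature_table = met$feature_table,
       phenotype = phe$phenotype,
       truth = c(geno$truth, met$truth,
                 list(h2 = phe$h2, genetic = phe$genetic)))
}

#' Default compound definitions for the spectra fixture
#'
#' Two synthetic compounds modelled on familiar maize-kernel cases: a
#' tyramine-like small molecule (singly charged, fragments at 138.09 and
#' 121.06) and a zein-peptide-like species observed as doubly and triply
#' charged isotope clusters (monoisotopic m/z 786.910 and 524.943).
#'
#' @return list of compound definitions consumed by
#'   [sim_spectra_fixture()].
#' @export
default_compounds <- function() {
  list(
    list(name = "tyramine_like", rt = 70.421,
         clusters = list(list(mono_mz = 138.0913, z = 1L, n_iso = 2L)),
         fragments = data.frame(mz = c(138.0913, 121.0648),
                                rel = c(999, 700))),
    list(name = "zein_peptide_like", rt = 226.57,
         clusters = list(list(mono_mz = 786.910, z = 2L, n_iso = 3L),
                         list(mono_mz = 524.943, z = 3L, n_iso = 3L)),
         fragments = data.frame(mz = c(886.467, 756.424, 625.345, 498.289),
                                rel = c(999, 650, 420, 300))))
}

#' Simulate a paired low/high collision-energy spectra fixture
#'
#' Emulates alternating-energy acquisition: each compound contributes its
#' precursor isotope cluster(s) (spacing 1.003355/z) to the low-energy
#' channel and correlated fragment features to the high-energy channel,
#' all within +/- 0.5 s of the compound's retention time. Per-sample
#' compound abundances are log-normal; per-feature multiplicative noise is
#' small, so fragments correlate strongly with their precursor.
#' Uncorrelated background features are added to both channels.
#'
#' @param compounds list of compound definitions (see
#'   [default_compounds()]).
#' @param n_samples number of samples (default 60; with fewer than ~40
#'   samples, chance correlations above 0.5 between unrelated features stop
#'   being rare, which defeats the correlational filter the fixture is
#'   meant to exercise).
#' @param noise_cv multiplicative noise coefficient of variation
#'   (default 0.05).
#' @param n_background uncorrelated decoy features per channel
#'   (default 10).
#' @param seed RNG seed.
#' @return list with `low_ce` and `high_ce` [feature_table()]s, and
#'   `targets`: per compound, the low-channel feature id of its first
#'   monoisotopic peak.
#' @export
sim_spectra_fixture <- function(compounds = default_compounds(),
                                n_samples = 60L, noise_cv = 0.05,
                                n_background = 10L, seed = 1L) {
  set.seed(seed)
  samples <- sprintf("s%02d", seq_len(n_samples))
  low <- list(); high <- list(); targets <- character()
  noisy <- function(abund, rel)
    pmax(abund * rel * (1 + noise_cv * stats::rnorm(length(abund))), 0)
  iso_rel <- c(999, 580, 240, 90)
  for (cmp in compounds) {
    abund <- exp(stats::rnorm(n_samples))
    first <- TRUE
    for (cl in cmp$clusters) {
      for (k in seq_len(cl$n_iso)) {
        mz <- cl$mono_mz + (k - 1L) *
          MASS_CONSTANTS[["isotope_spacing"]] / cl$z
        id <- sprintf("%.4f_%.2f", mz, cmp$rt)
        low[[id]] <- noisy(abund, iso_rel[k])
        if (first) { targets[cmp$name] <- id; first <- FALSE }
      }
    }
    for (r in seq_len(nrow(cmp$fragments))) {
      rt <- cmp$rt + stats::runif(1, -0.5, 0.5)
      id <- sprintf("%.4f_%.2f", cmp$fragments$mz[r], rt)
      high[[id]] <- noisy(abund, cmp$fragments$rel[r])
    }
  }
  rts <- vapply(compounds, `[[`, 0, "rt")
  for (b in seq_len(n_background)) {
    mz <- stats::runif(1, 50, 1200)
    rt <- stats::runif(1, 0, 720)
    # half the decoys co-elute with a compound but do not co-vary
    if (b %% 2L == 0L) rt <- rts[1L + b %% length(rts)] + stats::runif(1, -1, 1)
    id <- sprintf("%.4f_%.2f", mz, rt)
    low[[id]] <- exp(stats::rnorm(n_samples)) * 500
    id2 <- sprintf("%.4f_%.2f", mz + 0.01, rt)
    high[[id2]] <- exp(stats::rnorm(n_samples)) * 500
  }
  as_ft <- function(lst, channel) {
    mat <- do.call(cbind, lst)
    rownames(mat) <- samples
    feature_table(mat, channel = channel)
  }
  list(low_ce = as_ft(low, "MS"), high_ce = as_ft(high, "MSE"),
       targets = targets)
}
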