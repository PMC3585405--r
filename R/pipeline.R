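#' Default run configuration
#'
#' Returns the full configuration list with every stage's defaults: the
#' conventional retention-time window (2 s), correlational-filter threshold
#' (0.5), minor-allele-frequency floor (0.05), two-level FDR (0.001 and
#' 0.05) and pruning multipliers (1, 4, 6). User-supplied values (a list or
#' a YAML file) are merged over these defaults; everything lands in the run
#' manifest so a run is auditable.
#'
#' @param config named list or path to a YAML file with overrides.
#' @return configuration list.
#' @export
default_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- list(
    out_dir = "eigenmet_run",
    seed = 1L,
    paths = list(feature_table = NULL, genotypes = NULL, phenotype = NULL,
                 eigenvalues = NULL, low_ce = NULL, high_ce = NULL,
                 q_file = NULL),
    scaling = "autoscale",
    network = list(beta = "auto", min_module_size = 10L, cut_height = 0.99,
                   dissimilarity = "tom", prune_k = c(1, 4, 6)),
    gwas = list(maf_min = 0.05, q_pcs = 3L, fdr_alphas = c(0.001, 0.05)),
    spectra = list(window = 2, r_min = 0.5, targets = NULL),
    stepwise = list(p_enter = 0.05, p_leave = 0.10),
    simulate = list())
  modifyList(base, config)
}

write_manifest <- function(config, stage, inputs = character(), out_dir) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("eigenmet")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), "paths")],
                   input_hashes = hashes,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Run the simulation stage
#'
#' Generates a synthetic cohort with [sim_cohort()] and writes the same file
#' formats the readers consume (feature table CSV, genotype CSV, phenotype
#' TSV) plus a truth JSON, so the rest of the pipeline can be exercised
#' end-to-end without external data.
#'
#' @param config see [default_config()]; `config$simulate` holds
#'   [sim_config()] arguments (the seed defaults to `config$seed`).
#' @return invisibly, the output directory.
#' @export
run_simulate <- function(config = list()) {
  config <- default_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  args <- config$simulate
  if (is.null(args$seed)) args$seed <- config$seed
  cfg <- do.call(sim_config, args)
  cohort <- sim_cohort(cfg)
  write_feature_table(cohort$feature_table, file.path(out, "features.csv"))
  write_genotypes(cohort$genotypes, file.path(out, "genotypes.csv"))
  utils::write.table(cohort$phenotype, file.path(out, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$latents <- NULL  # matrices go to their own TSV
  utils::write.table(
    data.frame(line = rownames(cohort$truth$latents), cohort$truth$latents),
    file.path(out, "truth_latents.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(truth, file.path(out, "truth.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  write_manifest(config, "simulate", out_dir = out)
  invisible(out)
}

#' Run the network stage
#'
#' Reads the feature table, autoscales it, picks (or accepts) the soft
#' threshold, builds the unsigned network, detects modules, computes module
#' eigenvalues, prunes at each configured SD multiplier and writes module
#' assignments, the eigenvalue matrix, the pruning summary and
#' Cytoscape-loadable edge/node exports.
#'
#' @param config see [default_config()]; requires
#'   `config$paths$feature_table`.
#' @return invisibly, a list with the partition, eigenvalues and prunings.
#' @export
run_network <- function(config = list()) {
  config <- default_config(config)
  ftp <- config$paths$feature_table
  if (is.null(ftp) || !file.exists(ftp))
    stop("network stage needs paths$feature_table (run simulate first, or point to your data)")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ft <- read_feature_table(ftp)
  sm <- if (identical(config$scaling, "pareto")) pareto_scale(ft) else autoscale(ft)
  nw <- config$network
  beta <- if (identical(nw$beta, "auto")) pick_soft_threshold(sm)$beta else nw$beta
  net <- build_network(sm, beta = beta)
  part <- detect_modules(net, min_module_size = nw$min_module_size,
                         cut_height = nw$cut_height,
                         dissimilarity = nw$dissimilarity)
  me <- module_eigenvalues(sm, part)
  prunings <- lapply(nw$prune_k, function(k) prune_at_sd(net, k))
  utils::write.table(
    data.frame(feature = names(part$labels), module = unname(part$labels)),
    file.path(out, "modules.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_eigenvalues(me, file.path(out, "eigenvalues.tsv"))
  utils::write.table(network_summary(part, prunings),
                     file.path(out, "network_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (p in prunings)
    export_edges(p, file.path(out, sprintf("network_k%g", p$k)), part)
  write_manifest(config, "network", inputs = ftp, out_dir = out)
  invisible(list(beta = beta, partition = part, eigenvalues = me,
                 prunings = prunings))
}

#' Read back an eigenvalue matrix written by [write_eigenvalues()]
#'
#' @param path TSV path (modules x lines).
#' @return numeric matrix, modules in rows.
#' @export
read_eigenvalues <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Run the GWAS stage
#'
#' Computes the Loiselle kinship and structure covariates (genotype PCs, or
#' an externally supplied membership matrix), then for every module
#' eigenvalue fits the null mixed model and scans all SNPs under P3D,
#' writing one result TSV per module plus a summary of significant counts
#' and heritabilities.
#'
#' @param config see [default_config()]; requires `paths$eigenvalues` and
#'   `paths$genotypes`.
#' @return invisibly, a named list of [scan_snps()] results.
#' @export
run_gwas <- function(config = list()) {
  config <- default_config(config)
  evp <- config$paths$eigenvalues
  gp <- config$paths$genotypes
  if (is.null(evp) || !file.exists(evp))
    stop("gwas stage needs paths$eigenvalues (run the network stage first)")
  if (is.null(gp) || !file.exists(gp))
    stop("gwas stage needs paths$genotypes")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  me <- read_eigenvalues(evp)
  g <- read_genotypes(gp)
  common <- intersect(colnames(me), rownames(g$dosage))
  if (!length(common)) stop("no lines shared between eigenvalues and genotypes")
  me <- me[, common, drop = FALSE]
  g <- genotype_matrix(g$dosage[common, , drop = FALSE],
                       chrom = g$chrom, pos = g$pos)
  K <- loiselle_kinship(g)
  cov <- if (!is.null(config$paths$q_file)) {
    q <- utils::read.table(config$paths$q_file, header = TRUE, row.names = 1L)
    as.matrix(q[common, , drop = FALSE])
  } else structure_pcs(g, q = config$gwas$q_pcs)
  results <- list()
  summ <- list()
  for (mod in rownames(me)) {
    vc <- fit_null_mlm(me[mod, ], cov = cov, K = K)
    res <- scan_snps(vc, g, maf_min = config$gwas$maf_min,
                     fdr_alphas = config$gwas$fdr_alphas)
    write_gwas(res, file.path(out, paste0("gwas_", mod, ".tsv")))
    results[[mod]] <- res
    sets <- significant_sets(res)
    summ[[mod]] <- data.frame(module = mod, h2 = vc$h2,
                              n_snps_tested = nrow(res),
                              n_sig_conservative = length(sets[[1L]]),
                              n_sig_generous = length(sets[[2L]]))
  }
  utils::write.table(do.call(rbind, summ), file.path(out, "gwas_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config, "gwas", inputs = c(evp, gp), out_dir = out)
  invisible(results)
}

#' Run the spectral annotation stage
#'
#' Reconstructs MS and idMS/MS spectra for each target feature from the
#' paired collision-energy channels and exports them as one msp library.
#'
#' @param config see [default_config()]; requires `paths$low_ce`,
#'   `paths$high_ce` and `spectra$targets` (feature ids).
#' @return invisibly, the list of reconstructed spectra.
#' @export
run_annotate <- function(config = list()) {
  config <- default_config(config)
  lp <- config$paths$low_ce; hp <- config$paths$high_ce
  targets <- config$spectra$targets
  if (is.null(lp) || is.null(hp) || !file.exists(lp) || !file.exists(hp))
    stop("annotate stage needs paths$low_ce and paths$high_ce feature tables")
  if (!length(targets)) stop("annotate stage needs spectra$targets feature ids")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  low <- read_feature_table(lp, channel = "MS")
  high <- read_feature_table(hp, channel = "MSE")
  specs <- list()
  for (tg in targets) {
    rec <- reconstruct_idmsms(tg, low, high, window = config$spectra$window,
                              r_min = config$spectra$r_min)
    specs <- c(specs, list(rec$ms, rec$idmsms))
  }
  write_msp(specs, file.path(out, "spectra.msp"))
  write_manifest(config, "annotate", inputs = c(lp, hp), out_dir = out)
  invisible(specs)
}

#' Run the stepwise phenotype-regression stage
#'
#' Regresses the phenotype on the module eigenvalues by mixed stepwise
#' selection and writes the partial-SS ANOVA table and selection history.
#'
#' @param config see [default_config()]; requires `paths$eigenvalues` and
#'   `paths$phenotype` (TSV with columns `line`, `trait`).
#' @return invisibly, the [stepwise_select()] model.
#' @export
run_stepfit <- function(config = list()) {
  config <- default_config(config)
  evp <- config$paths$eigenvalues
  php <- config$paths$phenotype
  if (is.null(evp) || !file.exists(evp))
    stop("stepfit stage needs paths$eigenvalues (run the network stage first)")
  if (is.null(php) || !file.exists(php))
    stop("stepfit stage needs paths$phenotype")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  me <- read_eigenvalues(evp)
  ph <- utils::read.table(php, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  y <- ph[[2L]][match(colnames(me), ph[[1L]])]
  model <- stepwise_select(y, t(me), p_enter = config$stepwise$p_enter,
                           p_leave = config$stepwise$p_leave)
  utils::write.table(model$history, file.path(out, "stepwise_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(model$terms))
    write_anova(partial_anova(model), file.path(out, "stepwise_anova.tsv"))
  write_manifest(config, "stepfit", inputs = c(evp, php), out_dir = out)
  invisible(model)
}

#' Run the whole pipeline on one configuration
#'
#' `simulate` (when `config$simulate` is non-empty or no input paths are
#' given), then `network`, `gwas` and `stepfit`, wiring each stage's outputs
#' into the next stage's inputs under `config$out_dir`. Reruns with the same
#' configuration and seed reproduce identical outputs.
#'
#' @param config see [default_config()].
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config = list()) {
  config <- default_config(config)
  out <- config$out_dir
  if (is.null(config$paths$feature_table)) {
    run_simulate(config)
    config$paths$feature_table <- file.path(out, "features.csv")
    config$paths$genotypes <- file.path(out, "genotypes.csv")
    config$paths$phenotype <- file.path(out, "phenotype.tsv")
  }
  run_network(config)
  config$paths$eigenvalues <- file.path(out, "eigenvalues.tsv")
  if (!is.null(config$paths$genotypes)) run_gwas(config)
  if (!is.null(config$paths$phenotype)) run_stepfit(config)
  if (!is.null(config$paths$low_ce)) run_annotate(config)
  invisible(out)
}
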