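#' Build a weighted unsigned correlation network
#'
#' Edge weights are `|cor(i, j)|^beta`: the absolute Pearson correlation
#' between feature profiles raised to a soft-thresholding power. Taking the
#' absolute value makes the network unsigned, so positively and negatively
#' co-varying features (e.g. substrate/product pairs) can fall in one module;
#' the power de-emphasises weak correlations without a hard cutoff.
#'
#' @param sm autoscaled samples x features matrix (see [autoscale()]); at
#'   least 3 samples, no zero-variance columns.
#' @param beta soft-thresholding power, >= 1. See [pick_soft_threshold()].
#' @return An object of class `corr_network`: list with `adjacency`
#'   (features x features, diagonal zero), `beta`, `mode = "unsigned"`.
#' @export
build_network <- function(sm, beta = 6) {
  sm <- as.matrix(sm)
  if (nrow(sm) < 3L) stop("need at least 3 samples to correlate features")
  if (beta < 1) stop("beta must be >= 1")
  s <- apply(sm, 2L, stats::sd)
  if (any(s == 0)) stop("zero-variance feature(s) must be dropped before network construction")
  a <- abs(stats::cor(sm))^beta
  diag(a) <- 0
  structure(list(adjacency = a, beta = beta, mode = "unsigned"),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network: %d nodes, unsigned, beta = %g\n",
              ncol(x$adjacency), x$beta))
  invisible(x)
}

#' Choose a soft-thresholding power by the scale-free topology criterion
#'
#' For each candidate power the unsigned adjacency is built and the fit of
#' the node connectivity distribution to a power law is measured: log10 of
#' the binned connectivity frequency is regressed on log10 of the mean bin
#' connectivity, and the fit index is R^2 signed by the slope (a positive
#' slope, i.e. connectivity increasing in frequency, counts as 0). The
#' smallest power reaching `rsq_min` is selected; if none does, a
#' conventional fallback is used.
#'
#' @param sm autoscaled matrix.
#' @param candidate_betas powers to try.
#' @param rsq_min scale-free fit threshold (default 0.8).
#' @param fallback power used when no candidate fits (default 6).
#' @param nbins connectivity histogram bins.
#' @return list with `beta` (selected power), `selected_by`
#'   (`"scale_free_fit"` or `"fallback"`) and `fit_table`
#'   (data.frame of beta, rsq, mean_connectivity, median_connectivity).
#' @export
pick_soft_threshold <- function(sm, candidate_betas = 1:20, rsq_min = 0.8,
                                fallback = 6, nbins = 10L) {
  r <- abs(stats::cor(as.matrix(sm)))
  diag(r) <- 0
  rows <- lapply(candidate_betas, function(beta) {
    a <- r^beta
    k <- rowSums(a)
    data.frame(beta = beta, rsq = scale_free_rsq(k, nbins = nbins),
               mean_connectivity = mean(k),
               median_connectivity = stats::median(k))
  })
  tab <- do.call(rbind, rows)
  hit <- which(tab$rsq >= rsq_min)
  if (length(hit)) {
    list(beta = tab$beta[hit[1L]], selected_by = "scale_free_fit", fit_table = tab)
  } else {
    list(beta = fallback, selected_by = "fallback", fit_table = tab)
  }
}

# Signed scale-free fit index of a connectivity vector.
scale_free_rsq <- function(k, nbins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(0)
  cuts <- cut(k, breaks = nbins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3L) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2L]
  if (is.na(slope) || slope >= 0) 0 else r2
}

#' Topological overlap similarity of an adjacency matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where
#' `l_ij = sum_u a_iu a_uj` and `k_i` is node connectivity. Shared
#' neighbourhoods reinforce direct edges, which stabilises clustering
#' against single noisy correlations.
#'
#' @param adjacency symmetric matrix, unit-interval weights, zero diagonal.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom
}

# Size-ordered module label palette (largest module first), following the
# convention of labelling co-expression modules by colour names.
module_color_palette <- function(n) {
  base <- c("turquoise", "blue", "brown", "yellow", "green", "red", "black",
            "pink", "magenta", "purple", "greenyellow", "tan", "salmon",
            "cyan", "midnightblue", "lightcyan", "grey60", "lightgreen",
            "lightyellow", "royalblue", "darkred", "darkgreen",
            "darkturquoise", "darkgrey", "orange", "darkorange", "white",
            "skyblue", "saddlebrown", "steelblue", "paleturquoise", "violet",
            "darkolivegreen", "darkmagenta", "sienna", "yellowgreen",
            "skyblue3", "plum1", "plum2", "orangered4", "mediumpurple",
            "lightsteelblue", "lightcyan1", "ivory", "floralwhite",
            "darkslateblue", "coral", "brown4", "bisque", "salmon4")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, paste0("module", seq.int(length(base) + 1L, n)))
}

#' Detect network modules by hierarchical clustering
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM` (or `1 - adjacency`), with a static tree cut. Clusters smaller
#' than `min_module_size` are left unassigned (`"grey"`). Modules are
#' labelled with colour names in strictly decreasing size order (largest =
#' `"turquoise"`); ties are broken by the lexicographically smallest member
#' id, so labels are deterministic.
#'
#' @param net a [build_network()] result.
#' @param min_module_size smallest cluster kept as a module (default 10).
#' @param cut_height static cut height on the dissimilarity dendrogram.
#'   Unsigned TOM dissimilarities of soft-thresholded networks concentrate
#'   just below 1 (unrelated features sit at ~0.999 even when co-regulated
#'   groups merge around 0.9-0.97), so the default cut is 0.99; lower it
#'   only for nearly noise-free data.
#' @param dissimilarity `"tom"` (default) or `"adjacency"`.
#' @return An object of class `module_partition`: list with `labels` (named
#'   character vector node -> colour, `"grey"` = unassigned), `sizes` (named
#'   integer vector, non-grey, decreasing), `params`.
#' @export
detect_modules <- function(net, min_module_size = 10L, cut_height = 0.99,
                           dissimilarity = c("tom", "adjacency")) {
  stopifnot(inherits(net, "corr_network"))
  dissimilarity <- match.arg(dissimilarity)
  if (min_module_size < 2L) stop("min_module_size must be >= 2")
  sim <- if (dissimilarity == "tom") tom_similarity(net$adjacency) else {
    s <- net$adjacency; diag(s) <- 1; s
  }
  nodes <- colnames(net$adjacency)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  names(cl) <- nodes
  tab <- table(cl)
  keep <- names(tab)[tab >= min_module_size]
  # deterministic size order; ties by smallest member id
  ord <- order(-tab[keep],
               vapply(keep, function(g) min(nodes[cl == g]), ""))
  keep <- keep[ord]
  labels <- stats::setNames(rep("grey", length(nodes)), nodes)
  cols <- module_color_palette(length(keep))
  for (i in seq_along(keep)) labels[cl == keep[i]] <- cols[i]
  sizes <- stats::setNames(as.integer(tab[keep]), cols)
  structure(list(labels = labels, sizes = sizes,
                 params = list(min_module_size = min_module_size,
                               cut_height = cut_height,
                               dissimilarity = dissimilarity)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d nodes, %d modules (+%d grey)\n",
              length(x$labels), length(x$sizes), sum(x$labels == "grey")))
  if (length(x$sizes)) print(x$sizes)
  invisible(x)
}

#' Module eigenvalues (first principal component per module)
#'
#' For each module the first principal component of the member submatrix is
#' computed by singular value decomposition and the per-sample scores are
#' rescaled to unit sample variance. The score sign is fixed by requiring a
#' non-negative correlation with the mean member profile, so "more of the
#' module" always means a larger eigenvalue. The proportion of member
#' variance explained by the component is reported.
#'
#' @param sm autoscaled samples x features matrix (the same one the network
#'   was built from).
#' @param partition a [detect_modules()] result (grey nodes are skipped).
#' @return An object of class `module_eigenvalues`: list with `scores`
#'   (modules x samples matrix, unit variance rows), `pve` (named numeric),
#'   `members` (named list of feature ids).
#' @export
module_eigenvalues <- function(sm, partition) {
  stopifnot(inherits(partition, "module_partition"))
  sm <- as.matrix(sm)
  mods <- names(partition$sizes)
  if (!length(mods)) stop("partition has no non-grey modules")
  scores <- matrix(NA_real_, nrow = length(mods), ncol = nrow(sm),
                   dimnames = list(mods, rownames(sm)))
  pve <- stats::setNames(numeric(length(mods)), mods)
  members <- stats::setNames(vector("list", length(mods)), mods)
  for (m in mods) {
    ids <- names(partition$labels)[partition$labels == m]
    if (!length(ids)) stop("module of size 0: ", m)
    x <- sm[, ids, drop = FALSE]
    sv <- svd(x, nu = 1L, nv = 0L)
    sc <- sv$u[, 1L] * sv$d[1L]
    if (stats::sd(sc) == 0) stop("degenerate module eigenvalue for ", m)
    sc <- sc / stats::sd(sc)
    mean_profile <- rowMeans(x)
    if (stats::sd(mean_profile) > 0 && stats::cor(sc, mean_profile) < 0) sc <- -sc
    scores[m, ] <- sc
    pve[m] <- sv$d[1L]^2 / sum(sv$d^2)
    members[[m]] <- ids
  }
  structure(list(scores = scores, pve = pve, members = members),
            class = "module_eigenvalues")
}

#' @export
print.module_eigenvalues <- function(x, ...) {
  cat(sprintf("module_eigenvalues: %d modules x %d samples\n",
              nrow(x$scores), ncol(x$scores)))
  print(round(x$pve, 3))
  invisible(x)
}

#' Prune a network at a connectivity-SD threshold
#'
#' Retains only node pairs whose edge weight strictly exceeds
#' `mean + k * SD` of all off-diagonal weights — "connectivity between
#' nodes" is the pairwise edge weight, and the statistics are computed over
#' every node pair of the full network. Nodes left without any retained edge
#' are removed. Connected components of the retained graph are reported:
#' pruning can split a module into several components.
#'
#' @param net a [build_network()] result.
#' @param k SD multiplier (conventionally 1, 4 or 6).
#' @return An object of class `pruned_network`: list with `edges`
#'   (data.frame `from`, `to`, `weight`), `k`, `threshold`, `nodes`
#'   (retained ids), `component` (named integer vector over retained nodes),
#'   `n_total` (node count before pruning).
#' @export
prune_at_sd <- function(net, k) {
  stopifnot(inherits(net, "corr_network"))
  a <- net$adjacency
  nodes <- colnames(a)
  w <- a[upper.tri(a)]
  thr <- mean(w) + k * stats::sd(w)
  idx <- which(upper.tri(a) & a > thr, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1L]], to = nodes[idx[, 2L]],
                      weight = a[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  retained <- sort(unique(c(edges$from, edges$to)))
  structure(list(edges = edges, k = k, threshold = thr, nodes = retained,
                 component = graph_components(retained, edges),
                 n_total = length(nodes)),
            class = "pruned_network")
}

# Connected components by union-find on the retained edge list.
graph_components <- function(nodes, edges) {
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(match(edges$from[e], nodes))
    rj <- find(match(edges$to[e], nodes))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(nodes), find, 0L)
  stats::setNames(match(roots, unique(roots)), nodes)
}

#' @export
print.pruned_network <- function(x, ...) {
  cat(sprintf(
    "pruned_network: k = %g, threshold %.4g; %d/%d nodes, %d edges, %d components\n",
    x$k, x$threshold, length(x$nodes), x$n_total, nrow(x$edges),
    if (length(x$component)) max(x$component) else 0L))
  invisible(x)
}

#' Node/edge/module accounting across pruning thresholds
#'
#' @param partition a [detect_modules()] result for the unpruned network.
#' @param pruned_list list of [prune_at_sd()] results (one per k).
#' @return data.frame with one row per k: retained nodes, percent of
#'   detected features (1 decimal), edges, modules still represented, and
#'   connected components.
#' @export
network_summary <- function(partition, pruned_list) {
  stopifnot(inherits(partition, "module_partition"))
  rows <- lapply(pruned_list, function(p) {
    stopifnot(inherits(p, "pruned_network"))
    mods <- unique(partition$labels[p$nodes])
    data.frame(k = p$k,
               nodes = length(p$nodes),
               pct_of_detected = round(100 * length(p$nodes) / length(partition$labels), 1),
               edges = nrow(p$edges),
               modules = length(setdiff(mods, "grey")),
               components = if (length(p$component)) max(p$component) else 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a pruned network for external graph viewers
#'
#' Writes three files sharing `path_prefix`: `<prefix>.sif` (tab-separated
#' source / interaction / target, interaction `"cor"`), `<prefix>_edges.tsv`
#' (source, target, weight to 6 decimals) and `<prefix>_nodes.tsv` (node,
#' module colour) — the layout Cytoscape-style tools import directly.
#'
#' @param pruned a [prune_at_sd()] result.
#' @param path_prefix output path prefix.
#' @param partition optional [detect_modules()] result supplying node colours.
#' @return invisibly, the three file paths.
#' @export
export_edges <- function(pruned, path_prefix, partition = NULL) {
  stopifnot(inherits(pruned, "pruned_network"))
  sif <- paste0(path_prefix, ".sif")
  etsv <- paste0(path_prefix, "_edges.tsv")
  ntsv <- paste0(path_prefix, "_nodes.tsv")
  e <- pruned$edges
  writeLines(c("source\tinteraction\ttarget",
               if (nrow(e)) paste(e$from, "cor", e$to, sep = "\t")), sif)
  writeLines(c("source\ttarget\tweight",
               if (nrow(e)) paste(e$from, e$to, sprintf("%.6f", e$weight), sep = "\t")),
             etsv)
  labs <- if (is.null(partition)) stats::setNames(rep(NA_character_, length(pruned$nodes)),
                                                  pruned$nodes)
          else partition$labels[pruned$nodes]
  writeLines(c("node\tmodule",
               if (length(pruned$nodes)) paste(pruned$nodes, labs, sep = "\t")), ntsv)
  invisible(c(sif, etsv, ntsv))
}

#' Read back an exported edge table
#'
#' @param path an `_edges.tsv` file written by [export_edges()].
#' @return data.frame `from`, `to`, `weight`.
#' @export
read_edges <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  data.frame(from = df$source, to = df$target, weight = as.numeric(df$weight),
             stringsAsFactors = FALSE)
}

#' Guilt-by-association annotation propagation
#'
#' Identified features lend their annotation to co-module neighbours: each
#' unannotated node in a module containing at least one annotated node
#' receives every such label, scored by the retained edge weight to the
#' annotated node (0 when pruning severed the pair). Candidates are ranked
#' by score within each node.
#'
#' @param partition a [detect_modules()] result.
#' @param pruned a [prune_at_sd()] result providing the retained edges.
#' @param known named character vector: feature id -> identity label.
#' @return data.frame `node`, `label` (`"<identity>-associated"`), `source`
#'   (the annotated feature), `score`; ordered by node then decreasing score.
#' @export
annotate_by_association <- function(partition, pruned, known) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(pruned, "pruned_network"), length(known) >= 1L)
  labs <- partition$labels
  ew <- pruned$edges
  edge_weight <- function(a, b) {
    hit <- (ew$from == a & ew$to == b) | (ew$from == b & ew$to == a)
    if (any(hit)) max(ew$weight[hit]) else 0
  }
  out <- list()
  for (src in names(known)) {
    mod <- labs[[src]]
    if (is.na(mod) || mod == "grey") next
    targets <- setdiff(names(labs)[labs == mod], names(known))
    for (tg in targets)
      out[[length(out) + 1L]] <- data.frame(
        node = tg, label = paste0(known[[src]], "-associated"),
        source = src, score = edge_weight(src, tg),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(node = character(), label = character(),
                      source = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$node, -res$score, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write module eigenvalue scores as TSV (modules x lines)
#'
#' @param me a [module_eigenvalues()] result.
#' @param path output path.
#' @export
write_eigenvalues <- function(me, path) {
  df <- data.frame(module = rownames(me$scores), me$scores,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
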