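test_that("unsigned adjacency weights follow |r|^beta", {
  # identical and orthogonal profiles
  x <- c(1, 2, 3, 4)
  m <- cbind(x, x, c(1, -1, -1, 1))  # third column orthogonal to x
  colnames(m) <- c("1.0_1.0", "2.0_2.0", "3.0_3.0")
  net <- build_network(scale(m), beta = 4)
  expect_equal(net$adjacency[1, 2], 1, tolerance = 1e-12)
  expect_equal(net$adjacency[1, 3], 0, tolerance = 1e-12)

  # r = -0.5 at beta 2 gives weight 0.25
  v <- vectors_with_cor(-0.5)
  colnames(v) <- c("1.0_1.0", "2.0_2.0")
  net2 <- build_network(v, beta = 2)
  expect_equal(net2$adjacency[1, 2], 0.25, tolerance = 1e-12)

  expect_error(build_network(v, beta = 0.5), "beta")
  expect_error(build_network(cbind(v, `9.0_9.0` = rep(1, 4)), beta = 2),
               "zero-variance")
})

test_that("soft-threshold selection is deterministic and sane", {
  co <- test_cohort()
  sub <- co$sm[, 1:300]
  pick1 <- pick_soft_threshold(sub, candidate_betas = c(1, 2, 4, 6, 8))
  pick2 <- pick_soft_threshold(sub, candidate_betas = c(1, 2, 4, 6, 8))
  expect_identical(pick1, pick2)
  expect_gte(pick1$beta, 1)
  expect_equal(nrow(pick1$fit_table), 5L)
  expect_true(all(diff(pick1$fit_table$mean_connectivity) <= 0))

  # all-correlated single-module data computes without error
  set.seed(1)
  latent <- rnorm(50)
  onemod <- sapply(1:20, function(i) latent + rnorm(50, sd = 0.1))
  colnames(onemod) <- sprintf("%d.0_1.0", 1:20)
  expect_silent(pick_soft_threshold(autoscale(onemod)))
})

test_that("module detection recovers planted blocks and greys out noise", {
  set.seed(21)
  n <- 60
  lat1 <- rnorm(n); lat2 <- rnorm(n)
  block <- function(lat, k) sapply(seq_len(k), function(i) lat + rnorm(n, sd = 0.3))
  m <- cbind(block(lat1, 10), block(lat2, 10))
  colnames(m) <- sprintf("%d.0_1.0", 1:20)
  net <- build_network(autoscale(m), beta = 6)
  part <- detect_modules(net, min_module_size = 5)
  expect_equal(length(part$sizes), 2L)
  expect_setequal(names(part$sizes), c("turquoise", "blue"))
  # block-perfect partition
  expect_equal(length(unique(part$labels[1:10])), 1L)
  expect_equal(length(unique(part$labels[11:20])), 1L)
  expect_false(part$labels[1] == part$labels[11])

  # pure noise at n = 200 samples: nothing reaches min size 10
  set.seed(22)
  noise <- matrix(rnorm(200 * 40), 200, 40,
                  dimnames = list(NULL, sprintf("%d.0_1.0", 1:40)))
  pnoise <- detect_modules(build_network(noise, beta = 6), min_module_size = 10)
  expect_true(all(pnoise$labels == "grey"))

  # permutation of sample rows leaves labels unchanged
  perm <- sample(nrow(m))
  part_perm <- detect_modules(build_network(autoscale(m[perm, ]), beta = 6),
                              min_module_size = 5)
  expect_identical(part$labels, part_perm$labels)

  # unsigned symmetry: negating a column changes nothing
  m2 <- m; m2[, 3] <- -m2[, 3]
  net_neg <- build_network(autoscale(m2), beta = 6)
  expect_equal(net_neg$adjacency, net$adjacency, tolerance = 1e-12)
  expect_identical(detect_modules(net_neg, min_module_size = 5)$labels,
                   part$labels)
  expect_error(detect_modules(net, min_module_size = 1), "min_module_size")
})

test_that("module eigenvalues equal first-PC scores from an SVD oracle", {
  co <- test_cohort()
  me <- co$me
  expect_true(all(abs(apply(me$scores, 1, sd) - 1) < 1e-10))
  for (m in rownames(me$scores)[1:3]) {
    x <- co$sm[, me$members[[m]], drop = FALSE]
    # independent oracle: prcomp scores on the member submatrix
    oracle <- prcomp(x, center = FALSE, scale. = FALSE)$x[, 1]
    oracle <- oracle / sd(oracle)
    dev <- min(max(abs(me$scores[m, ] - oracle)),
               max(abs(me$scores[m, ] + oracle)))
    expect_lt(dev, 1e-8)
    # sign convention: non-negative correlation with the member mean
    expect_gte(cor(me$scores[m, ], rowMeans(x)), 0)
  }
})

test_that("degenerate modules give exact eigenvalues", {
  set.seed(5)
  x <- rnorm(30)
  m <- cbind(a = x, b = x, c = x, d = rnorm(30))
  colnames(m) <- sprintf("%d.0_1.0", 1:4)
  sm <- autoscale(m)
  part <- structure(list(
    labels = setNames(c("turquoise", "turquoise", "turquoise", "blue"),
                      colnames(sm)),
    sizes = c(turquoise = 3L, blue = 1L), params = list()),
    class = "module_partition")
  me <- module_eigenvalues(sm, part)
  # m identical features: eigenvalue is the shared profile, PVE = 1
  expect_equal(unname(me$scores["turquoise", ]), unname(sm[, 1]),
               tolerance = 1e-10)
  expect_equal(unname(me$pve["turquoise"]), 1, tolerance = 1e-12)
  # single-feature module: the feature's autoscaled column, PVE = 1
  expect_equal(unname(me$scores["blue", ]), unname(sm[, 4]), tolerance = 1e-10)
  expect_equal(unname(me$pve["blue"]), 1, tolerance = 1e-12)
})

test_that("SD pruning applies the strict mean + k*SD rule", {
  # 5-node toy with hand-computable threshold
  w <- c(1.0, 0.9, 0.8, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  a <- matrix(0, 5, 5, dimnames = list(paste0("n", 1:5), paste0("n", 1:5)))
  a[upper.tri(a)] <- w
  a <- a + t(a)
  net <- structure(list(adjacency = a, beta = 1, mode = "unsigned"),
                   class = "corr_network")
  # hand arithmetic: mean = 0.34, sd = 0.38930..., t = 0.72930...
  thr <- mean(w) + 1 * sd(w)
  p <- prune_at_sd(net, 1)
  expect_equal(p$threshold, thr, tolerance = 1e-12)
  expect_equal(sort(p$edges$weight), c(0.8, 0.9, 1.0))

  # equal weights: SD 0, strict inequality leaves nothing
  aeq <- matrix(0.5, 4, 4, dimnames = list(paste0("n", 1:4), paste0("n", 1:4)))
  diag(aeq) <- 0
  neteq <- structure(list(adjacency = aeq, beta = 1, mode = "unsigned"),
                     class = "corr_network")
  expect_equal(nrow(prune_at_sd(neteq, 0)$edges), 0L)

  # k low enough that t < min weight keeps the complete graph
  p_all <- prune_at_sd(net, -2)
  expect_equal(nrow(p_all$edges), 10L)

  # nestedness on a real network
  co <- test_cohort()
  ps <- lapply(c(1, 4, 6), function(k) prune_at_sd(co$net, k))
  key <- function(p) paste(p$edges$from, p$edges$to)
  expect_true(all(key(ps[[3]]) %in% key(ps[[2]])))
  expect_true(all(key(ps[[2]]) %in% key(ps[[1]])))
  summ <- network_summary(co$partition, ps)
  expect_true(all(diff(summ$nodes) <= 0))
  expect_equal(summ$pct_of_detected,
               round(100 * summ$nodes / length(co$partition$labels), 1))
})

test_that("network summary percentages match the retained fraction", {
  part <- structure(list(labels = setNames(rep("turquoise", 10),
                                           paste0("n", 1:10)),
                         sizes = c(turquoise = 10L), params = list()),
                    class = "module_partition")
  full <- structure(list(edges = data.frame(from = "n1", to = "n2", weight = 1),
                         k = 0, threshold = 0, nodes = paste0("n", 1:10),
                         component = setNames(rep(1L, 10), paste0("n", 1:10)),
                         n_total = 10L),
                    class = "pruned_network")
  expect_equal(network_summary(part, list(full))$pct_of_detected, 100.0)
})

test_that("edge export writes SIF + TSV and roundtrips", {
  edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                      weight = c(0.912345678, 0.5, 0.25))
  p <- structure(list(edges = edges, k = 1, threshold = 0.1,
                      nodes = c("a", "b", "c"),
                      component = setNames(rep(1L, 3), c("a", "b", "c")),
                      n_total = 3L),
                 class = "pruned_network")
  prefix <- file.path(withr::local_tempdir(), "net")
  export_edges(p, prefix)
  sif <- readLines(paste0(prefix, ".sif"))
  expect_equal(length(sif), 4L)  # header + 3 edges
  etab <- readLines(paste0(prefix, "_edges.tsv"))
  expect_match(etab[2], "0\\.912346$")  # 6 decimals
  back <- read_edges(paste0(prefix, "_edges.tsv"))
  expect_equal(paste(back$from, back$to), paste(edges$from, edges$to))
  expect_equal(back$weight, round(edges$weight, 6))

  empty <- structure(list(edges = edges[0, ], k = 6, threshold = 0.9,
                          nodes = character(),
                          component = setNames(integer(), character()),
                          n_total = 3L),
                     class = "pruned_network")
  export_edges(empty, paste0(prefix, "_empty"))
  expect_equal(length(readLines(paste0(prefix, "_empty.sif"))), 1L)
})

test_that("guilt-by-association propagates module annotations by edge weight", {
  labels <- setNames(c("orange", "orange", "orange", "grey"),
                     c("A", "B", "C", "D"))
  part <- structure(list(labels = labels, sizes = c(orange = 3L),
                         params = list()),
                    class = "module_partition")
  pruned <- structure(list(
    edges = data.frame(from = "A", to = "B", weight = 0.9),
    k = 4, threshold = 0.5, nodes = c("A", "B"),
    component = setNames(c(1L, 1L), c("A", "B")), n_total = 4L),
    class = "pruned_network")
  ann <- annotate_by_association(part, pruned, c(A = "tyramine"))
  expect_equal(ann$label[ann$node == "B"], "tyramine-associated")
  expect_equal(ann$score[ann$node == "B"], 0.9)
  # C shares the module but lost its edge: propagated with score 0
  expect_equal(ann$score[ann$node == "C"], 0)
  expect_false("D" %in% ann$node)

  # two annotated nodes in one module both propagate, ranked by weight
  pruned2 <- structure(list(
    edges = data.frame(from = c("A", "B"), to = c("C", "C"),
                       weight = c(0.4, 0.8)),
    k = 4, threshold = 0.5, nodes = c("A", "B", "C"),
    component = setNames(rep(1L, 3), c("A", "B", "C")), n_total = 4L),
    class = "pruned_network")
  ann2 <- annotate_by_association(part, pruned2,
                                  c(A = "tyramine", B = "coumaroyl-tyramine"))
  cc <- ann2[ann2$node == "C", ]
  expect_equal(nrow(cc), 2L)
  expect_equal(cc$score, c(0.8, 0.4))  # ranked by weight
  expect_equal(cc$source, c("B", "A"))
})
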