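test_that("electrode reduction partitions the torso into balanced patches", {
  a <- small_atlas()
  lay <- reduce_electrodes(a, 64, rng_seed = 1)
  sizes <- table(lay$patch)
  expect_length(sizes, 64)
  expect_equal(sum(sizes), nrow(a$torso$verts))        # partition
  expect_lte(max(sizes) - min(sizes), 2)               # size-balanced
  expect_true(all(lay$patch[lay$representatives] == seq_len(64)))
  # identity layout when every node is its own patch
  small <- matrix(rnorm(30), 10, 3)
  id <- reduce_electrodes(small, 10, 1)
  expect_setequal(id$representatives, 1:10)
  # deterministic patches, seeded representatives
  lay2 <- reduce_electrodes(a, 64, rng_seed = 2)
  expect_identical(lay$patch, lay2$patch)
  expect_false(identical(lay$representatives, lay2$representatives))
  expect_error(reduce_electrodes(small, 11, 1), "more patches")
})

test_that("Ward clustering separates well-separated blobs and cuts nest", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40 * 5, 0), ncol = 5),
             matrix(rnorm(35 * 5, 8), ncol = 5))
  truth <- rep(1:2, c(40, 35))
  cl <- ward_cluster(X, 2:10)
  k2 <- cl$labels[, "K2"]
  expect_equal(length(unique(k2)), 2)
  expect_true(all(table(k2, truth) %in% c(0, 35, 40)))  # perfect split
  # the clusters of each cut partition the samples (sizes sum to the total)
  for (j in seq_len(ncol(cl$labels))) {
    sizes <- tabulate(cl$labels[, j])
    expect_equal(sum(sizes), 75)
    expect_equal(length(sizes), cl$k_range[j])
  }
  # Ward merge heights are non-decreasing
  expect_true(all(diff(cl$tree$height) >= -1e-9))
  # cutting at K+1 splits exactly one cluster of the K cut
  for (j in 1:(ncol(cl$labels) - 1)) {
    tab <- table(cl$labels[, j], cl$labels[, j + 1])
    expect_equal(sum(rowSums(tab > 0) == 2), 1)
    expect_equal(sum(rowSums(tab > 0) == 1), nrow(tab) - 1)
  }
  expect_error(ward_cluster(X[1:5, ], 2:10), "fewer samples")
})

test_that("cluster labels map onto foci with correct persistence", {
  manifest <- data.frame(
    focus = rep(c("LA1", "LA2", "RA1"), each = 5),
    excluded = FALSE)
  labels <- c(rep(1, 5), rep(2, 5), c(2, 2, 2, 3, 3))
  sets <- induce_atrial_clusters(labels, manifest)
  expect_equal(sets$LA1, 1)
  expect_equal(sets$RA1, c(2, 3))
  K <- 4
  pers <- vapply(sets, length, 1) / K
  expect_true(all(pers >= 1 / K & pers <= 1))
  expect_equal(pers[["RA1"]], 2 / K)
  # focus with zero surviving runs is dropped with a warning
  manifest$excluded[11:15] <- TRUE
  expect_warning(induce_atrial_clusters(labels[1:10], manifest,
                                        c("LA1", "LA2", "RA1")),
                 "omitted")
})

# a 19-node path graph: every contiguous label set is connected
path_graph <- function(ids) {
  k <- length(ids)
  adj <- matrix(FALSE, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  structure(list(adjacency = adj, areas = rep(10, k), ids = ids),
            class = "ectopic_graph")
}

test_that("validation metrics reproduce the worked examples", {
  ids <- paste0("F", 1:19)
  g <- path_graph(ids)
  # one of 19 foci lands in two clusters -> OR = 5.26%
  sets <- setNames(as.list(rep(1, 19)), ids)
  sets <- lapply(seq_along(sets), function(i) if (i <= 10) 1 else 2)
  names(sets) <- ids
  sets$F5 <- c(1, 2)
  m <- compute_metrics(sets, g, K = 10)
  expect_equal(m$or, 100 * 1 / 19, tolerance = 1e-9)
  expect_equal(round(m$or, 2), 5.26)
  # a two-focus class with no connecting edge -> both isolated -> CR 89.4%
  sets2 <- setNames(as.list(c(2, rep(1, 17), 2)), ids)
  m2 <- compute_metrics(sets2, g, K = 6)
  expect_equal(m2$cr, 100 * 17 / 19, tolerance = 1e-9)  # 89.47...%
  expect_lt(m2$cr_cluster, 100)
  # all-singleton, all-connected labeling: OR 0, CR 100 at any K
  sets3 <- setNames(lapply(1:19, function(i) if (i <= 9) 1 else 2), ids)
  m3 <- compute_metrics(sets3, g, K = 2)
  expect_equal(m3$or, 0)
  expect_equal(m3$cr, 100)
  expect_equal(m3$cr_cluster, 100)
  # double counting of multiply-labeled foci in the region areas
  expect_equal(m$mean_area, mean(c(10 * 10, 10 * 10)))  # F5 counted twice
})

test_that("chi-square selection finds planted informative electrodes", {
  set.seed(11)
  n <- 120
  y <- rep(1:3, each = 40)
  X <- matrix(rnorm(n * 40, sd = 0.3), n, 40)
  X[, 1:4] <- X[, 1:4] + matrix(y, n, 4) * 1.5   # features 1..4 encode class
  sel <- chi2_select(X, y, 4)
  expect_setequal(sel, 1:4)
  # constant feature scores zero and ranks last
  X2 <- cbind(X, 5)
  sc <- attr(chi2_select(X2, y, 2), "scores")
  expect_equal(sc[41], 0)
  # permutation invariance up to the tie rule
  perm <- sample(ncol(X))
  sel_p <- chi2_select(X[, perm], y, 4)
  expect_setequal(perm[sel_p], 1:4)
  # identity when N equals the feature count, nesting across N
  expect_setequal(chi2_select(X, y, 40), 1:40)
  expect_true(all(chi2_select(X, y, 8) %in% chi2_select(X, y, 16)))
  expect_error(chi2_select(X, rep(1, n), 4), "two classes")
  expect_error(chi2_select(X, y, 99), "exceeds")
})

test_that("stratified SVM cross-validation: separable data and chance floor", {
  set.seed(21)
  n <- 96
  y <- rep(1:4, each = 24)
  X <- matrix(rnorm(n * 10, sd = 0.25), n, 10) + outer(y, rep(1, 10)) * 2
  out <- classify_cv(X, y, folds = 4, rng_seed = 3)
  expect_equal(out$accuracy, 1.0)
  # shuffled labels drop to the 1/K chance floor
  ysh <- sample(y)
  Xn <- matrix(rnorm(n * 10), n, 10)
  base <- classify_cv(Xn, ysh, folds = 4, rng_seed = 3)
  sigma3 <- 3 * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(base$accuracy - 0.25), sigma3 + 0.05)
  expect_error(classify_cv(X, rep(1, n), 4, 1), "two classes")
})

test_that("stratified folds preserve class proportions", {
  y <- factor(rep(c("a", "b", "c"), c(40, 24, 8)))
  f <- fibrofocal:::stratified_folds(y, 4, rng_seed = 5)
  for (k in 1:4) {
    expect_equal(sum(y[f == k] == "a"), 10)
    expect_equal(sum(y[f == k] == "b"), 6)
    expect_equal(sum(y[f == k] == "c"), 2)
  }
  expect_warning(fibrofocal:::stratified_folds(factor(rep(1:2, c(3, 9))),
                                               4, 1),
                 "fewer members")
})

test_that("ectopic graph tiles the surface and bounds patch geometry", {
  a <- small_atlas()
  g <- ectopic_graph(a)
  expect_equal(dim(g$adjacency), c(19, 19))
  expect_true(isSymmetric(g$adjacency))
  expect_false(any(diag(g$adjacency)))
  reach <- !is.na(g$patch)
  expect_gt(mean(reach), 0.95)            # patches tile the surface
  expect_equal(sum(g$areas),
               sum(a$vert_area[reach]), tolerance = 1e-9)
  # every focus owns its own patch
  fv <- a$foci$vertex[a$foci$primary]
  expect_equal(g$patch[fv], seq_len(19))
})
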