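# ---- Steps 2-5: electrode reduction, clustering, validation, selection,
#      classification ----

#' Reduce the torso node set to representative electrode patches
#'
#' Partitions the torso nodes into `P` spatially contiguous, size-balanced
#' patches by recursive bisection along the widest coordinate axis, then
#' selects one random representative node per patch (the patching is
#' deterministic; only the representative draw is seeded).
#'
#' @param torso_verts Torso node coordinates (n x 3) or an `atrial_atlas`.
#' @param P Number of patches (electrodes).
#' @param rng_seed Integer seed for representative sampling.
#' @return Object of class `electrode_layout`: `patch` (per-node patch id),
#'   `representatives` (node index per patch), `P`.
#' @export
reduce_electrodes <- function(torso_verts, P = 256, rng_seed = 1) {
  if (inherits(torso_verts, "atrial_atlas"))
    torso_verts <- torso_verts$torso$verts
  n <- nrow(torso_verts)
  if (P > n) stop("more patches than torso nodes")
  patch <- integer(n)
  # recursive bisection with proportional split sizes
  rec <- function(idx, p, base) {
    if (p == 1) { patch[idx] <<- base; return(invisible()) }
    p1 <- floor(p / 2); p2 <- p - p1
    rng <- apply(torso_verts[idx, , drop = FALSE], 2,
                 function(x) diff(range(x)))
    ax <- which.max(rng)
    o <- idx[order(torso_verts[idx, ax])]
    k <- round(length(o) * p1 / p)
    rec(o[seq_len(k)], p1, base)
    rec(o[(k + 1):length(o)], p2, base + p1)
  }
  rec(seq_len(n), P, 1L)
  reps <- with_seed(rng_seed,
                    vapply(seq_len(P), function(p) {
                      m <- which(patch == p)
                      if (length(m) == 1) m else sample(m, 1)
                    }, integer(1)))
  structure(list(patch = patch, representatives = reps, P = P,
                 rng_seed = rng_seed),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("electrode_layout: %d patches over %d nodes (mean %.1f nodes/patch)\n",
              x$P, length(x$patch), length(x$patch) / x$P))
  invisible(x)
}

#' Ward agglomerative clustering of BSPiM features
#'
#' Hierarchical clustering with Ward's variance-minimization linkage on
#' Euclidean distances; sample labels for every K in `k_range` are cuts of
#' the same tree.
#'
#' @param features Runs x electrodes matrix.
#' @param k_range Cluster counts (default 2..10).
#' @return Object of class `clustering_result`: `labels` (runs x K matrix,
#'   one column per K), `tree` (the `hclust` object), `k_range`.
#' @export
ward_cluster <- function(features, k_range = 2:10) {
  if (anyNA(features)) stop("features contain missing values")
  if (nrow(features) < max(k_range))
    stop("fewer samples than the largest requested K")
  tree <- hclust(dist(features), method = "ward.D2")
  labels <- sapply(k_range, function(k) cutree(tree, k))
  colnames(labels) <- paste0("K", k_range)
  structure(list(labels = labels, tree = tree, k_range = k_range),
            class = "clustering_result")
}

#' @export
#' @importFrom graphics abline axis legend lines matplot
plot.clustering_result <- function(x, ...) {
  plot(x$tree, labels = FALSE, hang = -1,
       main = "Ward clustering of BSPiMs", xlab = "", sub = "",
       ylab = "merge distance", ...)
  ks <- sort(unique(pmin(max(x$k_range), c(2, 4, 6, 10))))
  h <- rev(x$tree$height)
  for (k in ks) abline(h = mean(h[c(k - 1, k)]), lty = 3, col = "grey50")
  invisible(x)
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: %d samples, Ward tree cut at K = %s\n",
              nrow(x$labels), paste(range(x$k_range), collapse = "..")))
  invisible(x)
}

#' Ectopic adjacency graph of the foci
#'
#' Associates to each focus the geodesic-Voronoi patch of atlas vertices
#' closer (by fast-marching distance) to it than to any other focus; two
#' foci are connected by an edge if their patches share a border.  Patch
#' areas are vertex-area sums (cm^2).
#'
#' @param atlas An `atrial_atlas`.
#' @param foci_ids Focus ids forming the graph nodes (default: the primary
#'   subset).
#' @return Object of class `ectopic_graph`: `adjacency` (logical matrix),
#'   `areas` (cm^2), `patch` (per-vertex nearest focus index), `ids`.
#' @export
ectopic_graph <- function(atlas, foci_ids = NULL) {
  ids <- foci_ids %||% atlas$foci$id[atlas$foci$primary]
  vi <- atlas$foci$vertex[match(ids, atlas$foci$id)]
  nv <- nrow(atlas$verts)
  slow <- ifelse(atlas$speed > 0, 1, Inf)  # unit slowness -> distance (mm)
  D <- vapply(vi, function(s)
    cpp_fmm(atlas$verts * 10, atlas$faces - 1L, slow,
            atlas$extra_edges - 1L, s - 1L, 0), numeric(nv))
  D[is.na(D)] <- Inf
  patch <- max.col(-D, ties.method = "first")
  patch[!is.finite(apply(D, 1, min))] <- NA_integer_
  k <- length(ids)
  adjm <- matrix(FALSE, k, k, dimnames = list(ids, ids))
  e <- rbind(atlas$faces[, 1:2], atlas$faces[, 2:3],
             atlas$faces[, c(3, 1)], atlas$extra_edges)
  pa <- patch[e[, 1]]; pb <- patch[e[, 2]]
  ok <- !is.na(pa) & !is.na(pb) & pa != pb
  for (i in which(ok)) {
    adjm[pa[i], pb[i]] <- TRUE
    adjm[pb[i], pa[i]] <- TRUE
  }
  areas <- vapply(seq_len(k), function(p)
    sum(atlas$vert_area[which(patch == p)]), numeric(1))
  structure(list(adjacency = adjm, areas = areas, patch = patch, ids = ids),
            class = "ectopic_graph")
}

#' @export
print.ectopic_graph <- function(x, ...) {
  cat(sprintf("ectopic_graph: %d foci, %d edges, patch areas %.1f +/- %.1f cm^2\n",
              length(x$ids), sum(x$adjacency) / 2, mean(x$areas),
              sd(x$areas)))
  invisible(x)
}

#' Map BSPiM cluster labels onto the ectopic foci
#'
#' Every run's cluster label is assigned to the focus that produced it; a
#' focus accumulates the set of labels of its runs.
#'
#' @param labels Per-run cluster labels (one K).
#' @param manifest Run manifest (`focus` per run, excluded runs removed).
#' @param ids Focus id universe (order defines the output).
#' @return Named list of sorted unique label sets per focus; foci with no
#'   surviving runs are dropped with a warning.
#' @export
induce_atrial_clusters <- function(labels, manifest, ids = NULL) {
  keep <- !manifest$excluded
  runs <- manifest$focus[keep]
  stopifnot(length(labels) == length(runs))
  ids <- ids %||% unique(runs)
  missing <- setdiff(ids, runs)
  if (length(missing)) {
    warning("foci with no surviving runs omitted: ",
            paste(missing, collapse = ", "))
    ids <- setdiff(ids, missing)
  }
  sets <- lapply(ids, function(f) sort(unique(labels[runs == f])))
  names(sets) <- ids
  sets
}

# connected components of a logical adjacency matrix restricted to `nodes`
graph_components <- function(adjm, nodes) {
  comp <- rep(NA_integer_, length(nodes))
  names(comp) <- nodes
  cid <- 0L
  for (s in nodes) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    q <- s; comp[s] <- cid
    while (length(q)) {
      v <- q[[1]]; q <- q[-1]
      nb <- nodes[adjm[v, nodes] & is.na(comp[nodes])]
      comp[nb] <- cid
      q <- c(q, nb)
    }
  }
  comp
}

#' Cluster validation metrics on the atria
#'
#' Persistence of a focus is `|label set| / K` (1/K is best).  OR
#' (overlapped regions) is the percentage of foci appearing in more than one
#' cluster.  CR (connection ratio) counts isolated foci: a focus of a
#' multi-member class with no same-class neighbour on the ectopic graph is
#' isolated, and CR is the percentage of non-isolated class memberships
#' (the node-based reading whose worked example is 17/19 = 89.4% when a
#' two-focus class is disconnected).  Two stricter variants are reported as
#' well: `cr_largest` (members inside the largest connected component of
#' their class subgraph) and `cr_cluster` (percentage of classes whose whole
#' subgraph is connected).  Mean region area sums patch areas per cluster
#' with double counting of multiply-labeled foci.
#'
#' @param labelsets From [induce_atrial_clusters()].
#' @param graph An [ectopic_graph()].
#' @param K Number of clusters.
#' @return Object of class `cluster_metrics`: `persistence`, `or`, `cr`,
#'   `cr_largest`, `cr_cluster`, `mean_area`, `sd_area`, `K`.
#' @export
compute_metrics <- function(labelsets, graph, K) {
  stopifnot(length(labelsets) > 0)
  ids <- names(labelsets)
  persistence <- vapply(labelsets, length, numeric(1)) / K
  or <- 100 * mean(vapply(labelsets, length, numeric(1)) > 1)
  classes <- sort(unique(unlist(labelsets)))
  n_noniso <- 0; n_big <- 0; n_tot <- 0; n_classes_conn <- 0
  for (cl in classes) {
    members <- ids[vapply(labelsets, function(s) cl %in% s, logical(1))]
    if (length(members) == 1) {
      n_noniso <- n_noniso + 1; n_big <- n_big + 1; n_tot <- n_tot + 1
      n_classes_conn <- n_classes_conn + 1
      next
    }
    sub <- graph$adjacency[members, members, drop = FALSE]
    n_noniso <- n_noniso + sum(rowSums(sub) > 0)
    comp <- graph_components(graph$adjacency, members)
    big <- max(table(comp))
    n_big <- n_big + big
    n_tot <- n_tot + length(members)
    if (big == length(members)) n_classes_conn <- n_classes_conn + 1
  }
  cr <- 100 * n_noniso / n_tot
  cr_largest <- 100 * n_big / n_tot
  cr_cluster <- 100 * n_classes_conn / length(classes)
  area_by_class <- vapply(classes, function(cl) {
    members <- ids[vapply(labelsets, function(s) cl %in% s, logical(1))]
    sum(graph$areas[match(members, graph$ids)])
  }, numeric(1))
  structure(list(persistence = persistence, or = or, cr = cr,
                 cr_largest = cr_largest, cr_cluster = cr_cluster,
                 mean_area = mean(area_by_class),
                 sd_area = sd(area_by_class), K = K),
            class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf("K = %d: area %.0f +/- %.0f cm^2, OR %.2f%%, CR %.1f%%\n",
              x$K, x$mean_area, x$sd_area, x$or, x$cr))
  invisible(x)
}

#' Chi-square feature (electrode) ranking and selection
#'
#' Scores each feature's dependence on the class labels with the chi-square
#' statistic on per-class sums of the feature rescaled to \[0, 1\]
#' (non-negativity requirement), and keeps the `N` best.  A single global
#' ranking is used for every `N`, so larger selected sets always contain
#' smaller ones; ties break toward the lower feature index.
#'
#' @param features Runs x electrodes matrix.
#' @param labels Class label per run.
#' @param N Number of features to keep.
#' @return Integer feature indices (best first); attribute `scores` has the
#'   full ranking statistic.
#' @export
chi2_select <- function(features, labels, N) {
  if (length(unique(labels)) < 2)
    stop("chi-square selection needs at least two classes")
  if (N > ncol(features)) stop("N exceeds the feature count")
  rng <- apply(features, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  X <- sweep(sweep(features, 2, rng[1, ]), 2, span, "/")
  cls <- split(seq_len(nrow(X)), labels)
  tot <- colSums(X)
  chi2 <- numeric(ncol(X))
  for (g in cls) {
    obs <- colSums(X[g, , drop = FALSE])
    expd <- tot * length(g) / nrow(X)
    ok <- expd > 0
    chi2[ok] <- chi2[ok] + (obs[ok] - expd[ok])^2 / expd[ok]
  }
  o <- order(-chi2, seq_along(chi2))
  structure(o[seq_len(N)], scores = chi2)
}

# seeded stratified fold assignment; classes smaller than `folds` are
# spread over the first folds (with a warning)
stratified_folds <- function(labels, folds, rng_seed) {
  fold <- integer(length(labels))
  small <- FALSE
  with_seed(rng_seed, {
    for (cl in unique(labels)) {
      m <- which(labels == cl)
      if (length(m) < folds) small <- TRUE
      m <- if (length(m) > 1) sample(m) else m
      fold[m] <- rep_len(seq_len(folds), length(m))
    }
  })
  if (small)
    warning("some classes have fewer members than folds; ",
            "they are spread over a subset of folds")
  fold
}

#' RBF-SVM classification with stratified cross-validation
#'
#' 4-fold stratified cross-validation (75%/25% train/test per fold, each
#' fold preserving class proportions) of a radial-basis-kernel support
#' vector machine.  The regularization cost and kernel width are tuned by an
#' inner 3-fold grid search on each training split.
#'
#' @param features Runs x electrodes matrix.
#' @param labels Class label per run.
#' @param folds Outer folds.
#' @param rng_seed Integer seed (fold shuffling).
#' @param cost_grid,gamma_scale Hyperparameter grids; `gamma_scale`
#'   multiplies the `1/ncol(features)` default.
#' @return List with `accuracy` (mean test accuracy), `fold_accuracy`,
#'   `best_params`.
#' @export
classify_cv <- function(features, labels, folds = 4, rng_seed = 1,
                        cost_grid = c(1, 10, 100),
                        gamma_scale = c(0.5, 1, 2)) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("classification needs at least two classes")
  fold <- stratified_folds(labels, folds, rng_seed)
  g0 <- 1 / ncol(features)
  acc <- numeric(folds)
  best <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    if (nlevels(droplevels(labels[tr])) < 2) { acc[f] <- NA; next }
    # inner grid search
    inner <- stratified_folds(labels[tr], 3, rng_seed + f)
    grid <- expand.grid(cost = cost_grid, gamma = g0 * gamma_scale)
    gscore <- vapply(seq_len(nrow(grid)), function(gi) {
      s <- vapply(1:3, function(k) {
        itr <- inner != k
        if (nlevels(droplevels(labels[tr][itr])) < 2) return(NA_real_)
        m <- e1071::svm(features[tr, , drop = FALSE][itr, , drop = FALSE],
                        droplevels(labels[tr][itr]), kernel = "radial",
                        cost = grid$cost[gi], gamma = grid$gamma[gi],
                        scale = FALSE)
        mean(predict(m, features[tr, , drop = FALSE][!itr, , drop = FALSE])
             == labels[tr][!itr])
      }, numeric(1))
      mean(s, na.rm = TRUE)
    }, numeric(1))
    gi <- which.max(gscore)
    m <- e1071::svm(features[tr, , drop = FALSE], droplevels(labels[tr]),
                    kernel = "radial", cost = grid$cost[gi],
                    gamma = grid$gamma[gi], scale = FALSE)
    acc[f] <- mean(predict(m, features[te, , drop = FALSE]) == labels[te])
    best[[f]] <- grid[gi, ]
  }
  list(accuracy = mean(acc, na.rm = TRUE), fold_accuracy = acc,
       best_params = best)
}

#' Run the full localization pipeline on an activation dataset
#'
#' Electrode reduction is assumed done (features are at the reduced
#' electrode set).  For each K: Ward clustering, label induction on the
#' foci, validation metrics; for each (K, N): chi-square electrode selection
#' and stratified-CV SVM accuracy.
#'
#' @param features Runs x electrodes BSPiM matrix.
#' @param manifest Run manifest of the dataset.
#' @param graph An [ectopic_graph()] over the dataset's foci.
#' @param k_range Cluster counts.
#' @param n_list Feature counts for selection/classification.
#' @param rng_seed Integer seed.
#' @param folds Outer CV folds.
#' @return Object of class `pipeline_result`: `metrics` (data frame per K),
#'   `accuracy` (data frame per K x N), `clustering`, `labelsets` per K.
#' @export
run_full_pipeline <- function(features, manifest, graph, k_range = 2:10,
                              n_list = c(2, 4, 8, 16, 32, 64, 128, 256),
                              rng_seed = 1, folds = 4) {
  n_list <- n_list[n_list <= ncol(features)]
  cl <- ward_cluster(features, k_range)
  metrics <- NULL
  accuracy <- NULL
  labelsets <- list()
  for (j in seq_along(k_range)) {
    K <- k_range[j]
    lab <- cl$labels[, j]
    ls <- induce_atrial_clusters(lab, manifest, graph$ids)
    labelsets[[paste0("K", K)]] <- ls
    mt <- compute_metrics(ls, graph, K)
    metrics <- rbind(metrics, data.frame(
      K = K, mean_area = mt$mean_area, sd_area = mt$sd_area,
      or = mt$or, cr = mt$cr, cr_largest = mt$cr_largest,
      cr_cluster = mt$cr_cluster))
    for (N in n_list) {
      selected <- chi2_select(features, lab, N)
      cv <- classify_cv(features[, selected, drop = FALSE], lab,
                        folds = folds, rng_seed = rng_seed + K)
      accuracy <- rbind(accuracy, data.frame(K = K, N = N,
                                             ca = cv$accuracy))
    }
  }
  structure(list(metrics = metrics, accuracy = accuracy,
                 clustering = cl, labelsets = labelsets),
            class = "pipeline_result")
}

#' @export
plot.pipeline_result <- function(x, ..., target = 0.9) {
  if (is.null(x$accuracy)) stop("no accuracy table in this result")
  tab <- stats::reshape(x$accuracy, idvar = "N", timevar = "K",
                        direction = "wide")
  matplot(tab$N, tab[, -1], type = "b", log = "x", pch = 19, lty = 1,
          xlab = "number of electrodes (N)",
          ylab = "classification accuracy", ylim = c(0, 1), ...)
  abline(h = target, lty = 2)
  legend("bottomright", legend = paste0("K=", unique(x$accuracy$K)),
         col = seq_along(unique(x$accuracy$K)), pch = 19, bty = "n")
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$accuracy)) {
    ca <- x$accuracy[x$accuracy$N == max(x$accuracy$N), ]
    cat(sprintf("CA at N = %d: %s\n", max(x$accuracy$N),
                paste(sprintf("K%d %.2f", ca$K, ca$ca), collapse = "  ")))
  }
  invisible(x)
}
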