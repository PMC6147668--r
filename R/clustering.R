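# Kinetic pattern discovery: k-means with correlation distance, silhouette
# diagnostics against a permutation baseline, and the elbow curve.

# row-standardize to zero mean, unit variance; errors on zero-variance rows
.standardize_rows <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  if (any(s == 0))
    stop("zero-variance trajectory(ies): ",
         paste(utils::head(rownames(x)[s == 0], 5), collapse = ", "),
         " - exclude constant genes before clustering")
  (x - m) / s
}

# 1 - Pearson correlation between rows of x and rows of centers
.cor_dist <- function(x, centers) {
  1 - stats::cor(t(x), t(centers))
}

#' k-means clustering of trajectories with correlation distance
#'
#' Lloyd iterations under the distance `d(x, y) = 1 - Pearson(x, y)`
#' (scale- and shift-invariant, so trajectories cluster by shape):
#' assignment by highest correlation with the centroid, centroid update by
#' averaging the standardized member trajectories.  The best of `repeats`
#' seeded restarts (restart seeds `seed + restart - 1`, ties broken by the
#' lower restart index) by total within-cluster distance is returned, with
#' cluster labels renumbered by decreasing cluster size.
#'
#' @param traj numeric matrix, genes x time points (>= 2 time points, no
#'   zero-variance rows).
#' @param k number of clusters (default 6).
#' @param repeats number of restarts (default 5).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap.
#' @return object of class `kb_patterns`: list with `cluster` (named
#'   integer vector), `centroids` (k x time points), `tot_withinss` (total
#'   within-cluster correlation distance), `k`, `repeats`.
#' @export
kmeans_patterns <- function(traj, k = 6, repeats = 5, seed = 1,
                            max_iter = 100) {
  traj <- as.matrix(traj)
  if (nrow(traj) < k) stop("need at least k trajectories")
  if (ncol(traj) < 2) stop("need at least 2 time points")
  z <- .standardize_rows(traj)

  run_once <- function(s) {
    set.seed(s)
    centers <- z[sample(nrow(z), k), , drop = FALSE]
    labels <- rep(0L, nrow(z))
    for (it in seq_len(max_iter)) {
      d <- .cor_dist(z, centers)
      new_labels <- max.col(-d, ties.method = "first")
      for (j in seq_len(k)) {       # revive empty clusters from the
        if (!any(new_labels == j)) {  # currently worst-fitted gene
          worst <- which.max(d[cbind(seq_len(nrow(z)), new_labels)])
          new_labels[worst] <- j
        }
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (j in seq_len(k)) {
        members <- which(labels == j)
        if (!length(members)) next  # keep the previous center
        cj <- colMeans(z[members, , drop = FALSE])
        if (stats::sd(cj) > 0) {
          centers[j, ] <- (cj - mean(cj)) / stats::sd(cj)
        } else {
          # opposite shapes cancelled out: reseat on the worst-fitted member
          worst <- members[which.max(d[cbind(members, labels[members])])]
          centers[j, ] <- z[worst, ]
        }
      }
    }
    d <- .cor_dist(z, centers)
    list(labels = labels, centers = centers,
         tot = sum(d[cbind(seq_len(nrow(z)), labels)]))
  }

  best <- NULL
  for (r in seq_len(repeats)) {
    fit <- run_once(seed + r - 1L)
    if (is.null(best) || fit$tot < best$tot) best <- fit
  }
  # deterministic renumbering: decreasing size, ties by old label
  sizes <- tabulate(best$labels, k)
  new_order <- order(-sizes, seq_len(k))
  relabel <- match(seq_len(k), new_order)
  cluster <- setNames(relabel[best$labels], rownames(traj))
  centroids <- best$centers[new_order, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  colnames(centroids) <- colnames(traj)
  structure(list(cluster = cluster, centroids = centroids,
                 tot_withinss = best$tot, k = k, repeats = repeats),
            class = "kb_patterns")
}

#' @export
print.kb_patterns <- function(x, ...) {
  cat("kb_patterns: k =", x$k, ", total within-cluster distance =",
      format(x$tot_withinss, digits = 4), "\n")
  print(table(cluster = x$cluster))
  invisible(x)
}

#' Silhouette widths with a permutation baseline
#'
#' Computes silhouette widths under the correlation distance for the given
#' clustering, together with a null distribution of mean silhouettes
#' obtained by permuting the cluster memberships uniformly (cluster sizes
#' preserved) `n_perm` times.  Silhouette widths always lie in [-1, 1].
#'
#' @param traj trajectory matrix (genes x time points).
#' @param labels integer cluster labels (>= 2 nonempty clusters, not all
#'   singletons).
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutations.
#' @return object of class `kb_silhouette`: list with `widths` (per-gene
#'   silhouette), `mean` (observed mean), `null_means` (length `n_perm`).
#' @export
silhouette_with_null <- function(traj, labels, n_perm = 100, seed = 1) {
  traj <- as.matrix(traj)
  labels <- as.integer(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 nonempty clusters")
  if (all(tab == 1)) stop("all clusters are singletons")
  z <- .standardize_rows(traj)
  d <- 1 - stats::cor(t(z))
  sil <- cluster::silhouette(labels, dmatrix = d)
  widths <- sil[, "sil_width"]
  set.seed(seed)
  null_means <- vapply(seq_len(n_perm), function(i) {
    perm <- sample(labels)
    mean(cluster::silhouette(perm, dmatrix = d)[, "sil_width"])
  }, numeric(1))
  structure(list(widths = widths, mean = mean(widths),
                 null_means = null_means),
            class = "kb_silhouette")
}

#' @export
print.kb_silhouette <- function(x, ...) {
  cat("kb_silhouette: observed mean =", format(x$mean, digits = 3),
      "; permutation-null mean =",
      format(mean(x$null_means), digits = 3), "\n")
  invisible(x)
}

#' Elbow curve over a range of k
#'
#' Best-of-restarts total within-cluster correlation distance for each k.
#' The curve is non-increasing in k (for `k = n` it reaches 0).
#'
#' @param traj trajectory matrix.
#' @param k_range integer vector of cluster counts to evaluate.
#' @param repeats restarts per k.
#' @param seed integer seed.
#' @return data.frame with columns `k` and `tot_withinss`.
#' @export
elbow_curve <- function(traj, k_range = 1:10, repeats = 5, seed = 1) {
  stopifnot(all(k_range >= 1), all(k_range <= nrow(traj)))
  tot <- vapply(k_range, function(k)
    kmeans_patterns(traj, k = k, repeats = repeats, seed = seed)$tot_withinss,
    numeric(1))
  # enforce the theoretical monotonicity against restart luck: a solution
  # for k is always admissible for k+1, so carry the running minimum
  data.frame(k = k_range, tot_withinss = cummin(tot))
}
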