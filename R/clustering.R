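# Mini-batch k-means with k-means++ seeding and Davies-Bouldin model
# selection over a candidate range of cluster counts.

# squared Euclidean distances between rows of x and rows of centers
dist2_to_centers <- function(x, centers) {
  xx <- rowSums(x^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, "+") - 2 * x %*% t(centers)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ initialization (D^2 sampling); degenerate data (all points
# identical) falls back to repeating the first point
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- dist2_to_centers(x, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    idx <- if (tot <= 0) sample.int(n, 1L)
           else sample.int(n, 1L, prob = d2 / tot)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, dist2_to_centers(x, centers[j, , drop = FALSE])[, 1])
  }
  centers
}

#' Mini-batch k-means
#'
#' Fits k-means by per-batch aggregate updates with per-centre learning
#' rates 1/count (Sculley-style mini-batch scheme) and k-means++
#' initialization. `n_init` independent starts are run on seed substreams
#' and the fit with the lowest within-cluster sum of squares is kept; the
#' whole procedure is deterministic given `seed`.
#'
#' @param x Numeric feature matrix (rows = patches).
#' @param k Number of clusters (>= 2).
#' @param seed Integer RNG seed.
#' @param batch_size Mini-batch size (default 1024; capped at `nrow(x)`).
#' @param max_iter Maximum number of batch updates per start (default 100).
#' @param n_init Number of independent starts (default 10).
#' @param tol Early-stopping threshold on the mean centre shift.
#' @return A `cluster_model`: list with `k`, `centers`, `labels` (0-based,
#'   length `nrow(x)`), `seed`, `batch_size`, `iterations`, `degenerate`
#'   flag and `db_index`.
#' @export
minibatch_kmeans <- function(x, k, seed, batch_size = 1024, max_iter = 100,
                             n_init = 10, tol = 1e-6) {
  stopifnot(is.matrix(x))
  stopifnot_count(k, "k")
  if (k < 2) stop("invalid-domain: k must be at least 2", call. = FALSE)
  n <- nrow(x)
  if (k > n) stop("invalid-domain: k exceeds the number of rows", call. = FALSE)
  b <- min(batch_size, n)
  one_start <- function(sub_seed) with_seed(sub_seed, {
    centers <- kmeanspp_init(x, k)
    counts <- rep(0, k)
    iters <- 0L
    for (it in seq_len(max_iter)) {
      iters <- it
      idx <- sample.int(n, b)
      batch <- x[idx, , drop = FALSE]
      a <- max.col(-dist2_to_centers(batch, centers))
      old <- centers
      for (j in unique(a)) {
        rows <- which(a == j)
        counts[j] <- counts[j] + length(rows)
        centers[j, ] <- centers[j, ] +
          (colSums(batch[rows, , drop = FALSE]) -
             length(rows) * centers[j, ]) / counts[j]
      }
      if (mean(sqrt(rowSums((centers - old)^2))) < tol) break
    }
    labels <- max.col(-dist2_to_centers(x, centers))
    # reseed empty clusters to the point farthest from its centre
    for (j in which(tabulate(labels, k) == 0L)) {
      far <- which.max(dist2_to_centers(x, centers)[cbind(seq_len(n), labels)])
      centers[j, ] <- x[far, ]
      labels <- max.col(-dist2_to_centers(x, centers))
    }
    sse <- sum(dist2_to_centers(x, centers)[cbind(seq_len(n), labels)])
    list(centers = centers, labels = labels, iterations = iters, sse = sse)
  })
  starts <- lapply(seq_len(n_init), function(t) one_start(derive_seed(seed, t)))
  fit <- starts[[which.min(vapply(starts, `[[`, numeric(1), "sse"))]]
  degenerate <- any(dist2_to_centers(fit$centers, fit$centers)
                    [upper.tri(diag(k))] < 1e-20)
  db <- if (degenerate) NA_real_
        else davies_bouldin(x, fit$labels - 1L, fit$centers)
  structure(list(k = k, centers = fit$centers, labels = fit$labels - 1L,
                 seed = seed, batch_size = b, iterations = fit$iterations,
                 degenerate = degenerate, db_index = db),
            class = "cluster_model")
}

#' Fit patch clusters
#'
#' Thin validated wrapper around [minibatch_kmeans()] used by the slide
#' pipeline; every patch receives a label in `0..k-1`.
#'
#' @inheritParams minibatch_kmeans
#' @param features Normalized feature matrix ([normalize_features()]).
#' @return A `cluster_model`.
#' @export
fit_clusters <- function(features, k, seed, batch_size = 1024,
                         max_iter = 100) {
  minibatch_kmeans(features, k, seed, batch_size = batch_size,
                   max_iter = max_iter)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio
#' \eqn{(S_i + S_j) / M_{ij}} where \eqn{S_i} is the mean Euclidean
#' distance of cluster members to their centroid and \eqn{M_{ij}} the
#' distance between centroids. Lower is better.
#'
#' @param x Feature matrix.
#' @param labels 0-based cluster labels.
#' @param centers Optional centre matrix; defaults to per-cluster means.
#' @return The index (scalar).
#' @export
davies_bouldin <- function(x, labels, centers = NULL) {
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) stop("invalid-domain: Davies-Bouldin needs at least 2 clusters",
                  call. = FALSE)
  if (is.null(centers))
    centers <- t(vapply(ks, function(j)
      colMeans(x[labels == j, , drop = FALSE]), numeric(ncol(x))))
  else
    centers <- centers[ks + 1L, , drop = FALSE]
  S <- vapply(seq_along(ks), function(i) {
    rows <- labels == ks[i]
    mean(sqrt(rowSums(sweep(x[rows, , drop = FALSE], 2L, centers[i, ])^2)))
  }, numeric(1))
  M <- sqrt(dist2_to_centers(centers, centers))
  R <- outer(S, S, "+") / M
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Select the number of clusters by Davies-Bouldin score
#'
#' Fits [fit_clusters()] for every k in the candidate range and returns the
#' fit minimizing the Davies-Bouldin index; ties break toward smaller k.
#'
#' @param features Normalized feature matrix.
#' @param k_range Candidate cluster counts (default 7:12).
#' @param seed Seed shared by all candidate fits.
#' @param ... Passed to [fit_clusters()].
#' @return List with `k_best`, `model` (the winning `cluster_model`) and
#'   `db` (named vector of scores per candidate k).
#' @export
select_k <- function(features, k_range = 7:12, seed = 1L, ...) {
  stopifnot(length(k_range) >= 1L)
  fits <- lapply(k_range, function(k) fit_clusters(features, k, seed, ...))
  db <- vapply(fits, function(f) f$db_index, numeric(1))
  names(db) <- k_range
  best <- which.min(db)  # first minimum; k_range scanned upward
  list(k_best = k_range[best], model = fits[[best]], db = db)
}
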