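# Independent oracles used to cross-check package computations. These are
# deliberately written as direct enumerations/loops, not via the code paths
# they audit.

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mwu_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(a, b) {
    sum(vapply(a, function(v) sum(v > b) + 0.5 * sum(v == b), numeric(1)))
  }
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Davies-Bouldin by the direct textbook formula, plain loops
db_oracle <- function(x, labels) {
  ks <- sort(unique(labels))
  cent <- list(); S <- numeric(length(ks))
  for (i in seq_along(ks)) {
    rows <- x[labels == ks[i], , drop = FALSE]
    cent[[i]] <- colMeans(rows)
    s <- 0
    for (r in seq_len(nrow(rows)))
      s <- s + sqrt(sum((rows[r, ] - cent[[i]])^2))
    S[i] <- s / nrow(rows)
  }
  total <- 0
  for (i in seq_along(ks)) {
    worst <- -Inf
    for (j in seq_along(ks)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (S[i] + S[j]) / M)
    }
    total <- total + worst
  }
  total / length(ks)
}

# O(n^2) nearest-reference-distance oracle with explicit loops
nearest_dist_oracle <- function(cells, ref_marker = "CK") {
  ref <- which(cells[[ref_marker]])
  out <- rep(NA_real_, nrow(cells))
  for (i in seq_len(nrow(cells))) {
    best <- Inf
    for (j in ref) {
      if (j == i) next
      d <- sqrt((cells$x_um[i] - cells$x_um[j])^2 +
                  (cells$y_um[i] - cells$y_um[j])^2)
      if (d < best) best <- d
    }
    out[i] <- if (is.finite(best)) best else NA_real_
  }
  out
}

# mixture-separated Gaussian blobs for clustering tests
make_blobs <- function(k, n_per, dim = 5, sep = 10, sd = 1, seed = 1) {
  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s); expr
  }
  withr_seed(seed, {
    centers <- matrix(stats::rnorm(k * dim), k)
    centers <- sep * centers / sqrt(rowSums(centers^2))
    x <- do.call(rbind, lapply(seq_len(k), function(j)
      sweep(matrix(stats::rnorm(n_per * dim, sd = sd), n_per), 2L,
            centers[j, ], "+")))
    list(x = x, labels = rep(seq_len(k) - 1L, each = n_per))
  })
}

# small uniform RGB tile helper
uniform_tile <- function(value, size = 64) {
  array(value, c(size, size, 3L))
}

# random marker-positive cell table
make_cells <- function(n, markers = c("CK", "PDL1", "CD68"), seed = 1) {
  set.seed(seed)
  df <- data.frame(x_um = runif(n, 0, 500), y_um = runif(n, 0, 500))
  for (m in markers) df[[m]] <- runif(n) < 0.4
  df
}
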