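# Cluster-proportion association with confirmed response:
# Mann-Whitney U per cluster, Benjamini-Hochberg across clusters.

#' Two-sided Mann-Whitney U test
#'
#' Wrapper with the package's conventions: the exact null is used when both
#' groups have at most `exact_max` observations and no ties; otherwise the
#' normal approximation with tie and continuity corrections. A comparison
#' of two identical constant samples has U = n1*n2/2 and p = 1.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest per-group size for the exact null (default 8).
#' @return List with `statistic` (U for `x`), `p.value` and `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p.value = 1,
                method = "degenerate (all values tied)"))
  ties <- any(duplicated(c(x, y)))
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Independent Benjamini-Hochberg step-up (reference form)
#'
#' Direct step-up implementation used for auditing; the pipeline itself
#' calls [stats::p.adjust()].
#'
#' @param p Vector of p-values.
#' @return Adjusted q-values in the input order.
#' @export
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Associate clusters with confirmed response
#'
#' For each cluster, compares its per-slide proportions between responders
#' and non-responders with a two-sided Mann-Whitney U test, adjusts across
#' the k clusters with Benjamini-Hochberg, and reports the direction of the
#' median difference (responders minus non-responders).
#'
#' @param profiles A numeric matrix (slides x clusters), or a list of
#'   [slide_profile()] objects.
#' @param response Logical (or 0/1) vector: `TRUE` for confirmed
#'   responders, one entry per slide.
#' @return Data frame with one row per cluster: `cluster` (0-based index),
#'   `p_value`, `q_value`, `direction` and `median_responder`,
#'   `median_nonresponder`.
#' @export
associate_clusters <- function(profiles, response) {
  v <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  response <- as.logical(response)
  stopifnot(length(response) == nrow(v), !anyNA(response))
  if (sum(response) < 2 || sum(!response) < 2)
    stop("single-group: need at least 2 slides per response group",
         call. = FALSE)
  k <- ncol(v)
  res <- lapply(seq_len(k), function(c) {
    r <- v[response, c]; nr <- v[!response, c]
    ht <- mann_whitney_u(r, nr)
    data.frame(cluster = c - 1L,
               p_value = ht$p.value,
               median_responder = stats::median(r),
               median_nonresponder = stats::median(nr))
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- sign(out$median_responder - out$median_nonresponder)
  out[, c("cluster", "p_value", "q_value", "direction",
          "median_responder", "median_nonresponder")]
}
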