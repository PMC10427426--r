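# Exact binomial machinery for single-arm phase 2 designs and the trial's
# response-rate estimates with exact confidence intervals.

#' Upper binomial tail probability
#'
#' Computes \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, p)} via the
#' numerically stable regularized incomplete beta function underlying
#' [stats::pbinom()].
#'
#' @param k Number of successes (0 to n + 1 allowed; k = n + 1 gives 0).
#' @param n Number of trials.
#' @param p Success probability.
#' @return The tail probability \eqn{P(X \ge k)}.
#' @examples
#' binom_tail_ge(2, 3, 0.5)  # 0.5
#' @export
binom_tail_ge <- function(k, n, p) {
  stopifnot_count(k, "k")
  stopifnot_count(n, "n")
  stopifnot_prob(p, "p")
  if (k > n + 1) stop("invalid-domain: k may not exceed n + 1", call. = FALSE)
  if (k == 0) return(1)
  if (k == n + 1) return(0)
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Specify an exact single-arm design hypothesis
#'
#' @param p0 Unacceptable response probability.
#' @param p1 Target response probability (must exceed `p0`).
#' @param alpha One-sided type-I error.
#' @param power Required power.
#' @return A `design_spec` object.
#' @export
design_spec <- function(p0, p1, alpha, power) {
  stopifnot_prob(p0, "p0"); stopifnot_prob(p1, "p1")
  stopifnot_prob(alpha, "alpha"); stopifnot_prob(power, "power")
  if (p0 >= p1) stop("invalid-domain: p0 must be smaller than p1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("invalid-domain: alpha and power must lie strictly in (0, 1)", call. = FALSE)
  structure(list(p0 = p0, p1 = p1, alpha = alpha, power = power),
            class = "design_spec")
}

#' Exact single-stage (A'Hern) design search
#'
#' Finds the smallest sample size `n` admitting a response threshold `r` with
#' \eqn{P(X \ge r \mid n, p_0) \le \alpha} and
#' \eqn{P(X \ge r \mid n, p_1) \ge power}; at that `n`, `r` is the smallest
#' threshold meeting the type-I condition.
#'
#' @param spec A [design_spec()], or `p0` given all four scalars.
#' @param p1,alpha,power Scalars, used when `spec` is numeric.
#' @param n_max Search ceiling for `n` (default 1000).
#' @return A `design_result` list with elements `n`, `r`, and the attained
#'   `alpha` and `power`.
#' @examples
#' ahern_design(design_spec(0.30, 0.45, 0.05, 0.80))  # n = 67, r = 27
#' @export
ahern_design <- function(spec, p1 = NULL, alpha = NULL, power = NULL,
                         n_max = 1000) {
  if (!inherits(spec, "design_spec"))
    spec <- design_spec(spec, p1, alpha, power)
  for (n in seq_len(n_max)) {
    # smallest r whose p0-tail clears alpha; scan downward from n
    r_ok <- NA_integer_
    for (r in n:1) {
      if (binom_tail_ge(r, n, spec$p0) <= spec$alpha) r_ok <- r else break
    }
    if (is.na(r_ok)) next
    if (binom_tail_ge(r_ok, n, spec$p1) >= spec$power) {
      return(structure(
        list(n = n, r = r_ok,
             alpha_attained = binom_tail_ge(r_ok, n, spec$p0),
             power_attained = binom_tail_ge(r_ok, n, spec$p1),
             spec = spec),
        class = "design_result"))
    }
  }
  stop("search-bound: no design found with n <= ", n_max, call. = FALSE)
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf(
    "Exact single-stage design: n = %d, promising if >= %d responses\n",
    x$n, x$r))
  cat(sprintf("  attained one-sided alpha = %.4f, power = %.4f\n",
              x$alpha_attained, x$power_attained))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval by beta-quantile inversion of the binomial test:
#' the lower bound is the `(1 - level)/2` beta quantile with shape
#' `(k, n - k + 1)`, the upper the `(1 + level)/2` quantile with shape
#' `(k + 1, n - k)`; `k = 0` forces `lo = 0` and `k = n` forces `hi = 1`.
#'
#' @param k Successes.
#' @param n Trials.
#' @param level Two-sided confidence level (default 0.95).
#' @return A `binomial_ci` list with `k`, `n`, `level`, `estimate`, `lo`, `hi`.
#' @examples
#' clopper_pearson(3, 10)  # 6.7% to 65.2%
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot_count(k, "k"); stopifnot_count(n, "n")
  stopifnot_prob(level, "level")
  if (n < 1) stop("invalid-domain: n must be at least 1", call. = FALSE)
  if (k > n) stop("invalid-domain: k may not exceed n", call. = FALSE)
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  structure(list(k = k, n = n, level = level, estimate = k / n,
                 lo = lo, hi = hi),
            class = "binomial_ci")
}

#' @export
print.binomial_ci <- function(x, ...) {
  cat(sprintf("%d/%d (%s%%, %d%% CI %s-%s)\n", x$k, x$n,
              format_pct(x$estimate), round(100 * x$level),
              format_pct(x$lo), format_pct(x$hi)))
  invisible(x)
}

#' Confirmed objective response rate with exact interval
#'
#' Counts records with a confirmed complete or partial response over all
#' records of the cohort; non-evaluable patients stay in the denominator
#' (full-analysis-set logic).
#'
#' @param records Data frame of response records with columns `patient_id`,
#'   `cohort`, `best_response` (CR/PR/SD/PD/NE), `confirmed` (logical), and
#'   optionally `best_change_pct`.
#' @param cohort Cohort identifier to subset on; `NULL` uses all records.
#' @param level Confidence level for the exact interval.
#' @return A list with `estimate`, `n`, `k` and `ci` (a [clopper_pearson()]).
#' @export
confirmed_orr <- function(records, cohort = NULL, level = 0.95) {
  stopifnot(is.data.frame(records))
  need <- c("patient_id", "cohort", "best_response", "confirmed")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(cohort)) records <- records[records$cohort %in% cohort, , drop = FALSE]
  if (nrow(records) == 0L) stop("empty-cohort: no records selected", call. = FALSE)
  bad <- records$confirmed & !records$best_response %in% c("CR", "PR")
  if (any(bad, na.rm = TRUE))
    stop("invalid records: confirmed response outside {CR, PR}", call. = FALSE)
  k <- sum(records$confirmed & records$best_response %in% c("CR", "PR"),
           na.rm = TRUE)
  n <- nrow(records)
  list(estimate = k / n, k = k, n = n, ci = clopper_pearson(k, n, level))
}

#' Define a two-stage decision rule
#'
#' @param n1 Stage-1 size.
#' @param s1_min Minimal stage-1 successes required to continue.
#' @param n_total Final sample size.
#' @param r_final Final threshold declaring the regimen promising.
#' @return A `two_stage_rule` object.
#' @export
two_stage_rule <- function(n1, s1_min, n_total, r_final) {
  stopifnot_count(n1, "n1"); stopifnot_count(s1_min, "s1_min")
  stopifnot_count(n_total, "n_total"); stopifnot_count(r_final, "r_final")
  if (n1 >= n_total) stop("invalid-domain: n1 must be below n_total", call. = FALSE)
  if (s1_min > n1) stop("invalid-domain: s1_min may not exceed n1", call. = FALSE)
  if (r_final > n_total) stop("invalid-domain: r_final may not exceed n_total",
                              call. = FALSE)
  structure(list(n1 = n1, s1_min = s1_min, n_total = n_total,
                 r_final = r_final),
            class = "two_stage_rule")
}

#' Evaluate a two-stage rule
#'
#' Stage 1 stops for futility when fewer than `s1_min` successes are seen
#' among the first `n1` patients. Past the interim, the decision is
#' `"continue"` until a final success count is supplied, then `"promising"`
#' iff the final count reaches `r_final`.
#'
#' @param rule A [two_stage_rule()].
#' @param stage1_successes Successes among the first `n1` patients.
#' @param final_successes Final success count, or `NULL` at the interim look.
#' @param final_analysis Set `TRUE` to demand a final decision; an absent
#'   `final_successes` is then an error rather than `"continue"`.
#' @return One of `"stop_futility"`, `"continue"`, `"promising"`,
#'   `"not_promising"`.
#' @export
evaluate_two_stage <- function(rule, stage1_successes, final_successes = NULL,
                               final_analysis = !is.null(final_successes)) {
  stopifnot(inherits(rule, "two_stage_rule"))
  stopifnot_count(stage1_successes, "stage1_successes")
  if (stage1_successes > rule$n1)
    stop("invalid-domain: stage1_successes exceeds n1", call. = FALSE)
  if (stage1_successes < rule$s1_min) return("stop_futility")
  if (is.null(final_successes)) {
    if (final_analysis)
      stop("missing-final: stage 1 passed but no final success count supplied",
           call. = FALSE)
    return("continue")
  }
  stopifnot_count(final_successes, "final_successes")
  if (final_successes > rule$n_total)
    stop("invalid-domain: final_successes exceeds n_total", call. = FALSE)
  if (final_successes >= rule$r_final) "promising" else "not_promising"
}
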