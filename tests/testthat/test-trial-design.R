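# Exact binomial design machinery and response-rate intervals.

test_that("binomial upper tail matches direct enumeration", {
  expect_equal(binom_tail_ge(0, 10, 0.3), 1)
  expect_equal(binom_tail_ge(11, 10, 0.3), 0)
  # enumerate all 8 outcomes of 3 fair coin flips
  outcomes <- expand.grid(rep(list(0:1), 3))
  expect_equal(binom_tail_ge(2, 3, 0.5), mean(rowSums(outcomes) >= 2))
  # random spot-checks against summed density
  for (case in list(c(3, 12, 0.25), c(7, 9, 0.8), c(1, 30, 0.05))) {
    direct <- sum(dbinom(case[1]:case[2], case[2], case[3]))
    expect_equal(binom_tail_ge(case[1], case[2], case[3]), direct,
                 tolerance = 1e-12)
  }
  expect_error(binom_tail_ge(-1, 10, 0.5), "invalid-domain")
  expect_error(binom_tail_ge(2, 10, 1.5), "invalid-domain")
})

test_that("single-stage design search reproduces the trial designs", {
  d1 <- ahern_design(design_spec(0.30, 0.45, 0.05, 0.80))
  expect_equal(c(d1$n, d1$r), c(67, 27))
  d2 <- ahern_design(design_spec(0.20, 0.40, 0.05, 0.85))
  expect_equal(c(d2$n, d2$r), c(40, 13))
})

test_that("design search agrees with exhaustive scan on a small design", {
  spec <- design_spec(0.05, 0.95, 0.20, 0.50)
  # brute force: first (n, r) by scanning all n, r in 1..20
  brute <- NULL
  for (n in 1:20) {
    for (r in 1:n) {
      ok0 <- sum(dbinom(r:n, n, spec$p0)) <= spec$alpha
      ok1 <- sum(dbinom(r:n, n, spec$p1)) >= spec$power
      if (ok0 && ok1) { brute <- c(n, r); break }
    }
    if (!is.null(brute)) break
  }
  d <- ahern_design(spec)
  expect_equal(c(d$n, d$r), brute)
})

test_that("found designs satisfy both tails and are minimal in n", {
  for (pars in list(c(0.30, 0.45, 0.05, 0.80), c(0.20, 0.40, 0.05, 0.85))) {
    spec <- design_spec(pars[1], pars[2], pars[3], pars[4])
    d <- ahern_design(spec)
    expect_lte(binom_tail_ge(d$r, d$n, spec$p0), spec$alpha)
    expect_gte(binom_tail_ge(d$r, d$n, spec$p1), spec$power)
    for (n in seq_len(d$n - 1)) {
      any_ok <- any(vapply(seq_len(n), function(r)
        binom_tail_ge(r, n, spec$p0) <= spec$alpha &&
          binom_tail_ge(r, n, spec$p1) >= spec$power, logical(1)))
      expect_false(any_ok)
    }
  }
  expect_error(ahern_design(design_spec(0.299, 0.30, 0.01, 0.99),
                            n_max = 50), "search-bound")
})

test_that("exact interval reproduces printed trial intervals", {
  cases <- list(
    list(3, 10, c(6.7, 65.2)), list(0, 5, c(0, 52.2)),
    list(48, 68, c(58.3, 81.0)), list(27, 72, c(26.4, 49.7)),
    list(11, 37, c(15.9, 47.0)))
  for (cs in cases) {
    ci <- clopper_pearson(cs[[1]], cs[[2]])
    expect_equal(round(100 * ci$lo, 1), cs[[3]][1])
    expect_equal(round(100 * ci$hi, 1), cs[[3]][2])
  }
  expect_equal(clopper_pearson(0, 5)$lo, 0)
  expect_equal(clopper_pearson(5, 5)$hi, 1)
  expect_error(clopper_pearson(6, 5), "invalid-domain")
})

test_that("exact interval agrees with grid inversion of the binomial test", {
  grid <- seq(0, 1, by = 1e-4)
  for (n in c(5, 12, 25)) {
    # vectorized over the p grid, looped over k
    for (k in 0:n) {
      ci <- clopper_pearson(k, n, 0.95)
      lo_grid <- if (k == 0) 0 else
        grid[min(which(pbinom(k - 1, n, grid, lower.tail = FALSE) > 0.025))]
      hi_grid <- if (k == n) 1 else
        grid[max(which(pbinom(k, n, grid) > 0.025))]
      expect_lt(abs(ci$lo - lo_grid), 1e-3)
      expect_lt(abs(ci$hi - hi_grid), 1e-3)
    }
  }
})

test_that("interval bounds are monotone and narrow with n", {
  los <- vapply(0:20, function(k) clopper_pearson(k, 20)$lo, numeric(1))
  expect_true(all(diff(los) > 0))
  widths <- vapply(c(10, 20, 40, 80, 160), function(n) {
    ci <- clopper_pearson(round(0.3 * n), n)
    ci$hi - ci$lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("exact interval achieves nominal coverage (conservative)", {
  set.seed(42)
  ks <- rbinom(2000, 30, 0.3)
  lo <- ifelse(ks == 0, 0, qbeta(0.025, ks, 30 - ks + 1))
  hi <- ifelse(ks == 30, 1, qbeta(0.975, ks + 1, 30 - ks))
  expect_gte(mean(lo <= 0.3 & 0.3 <= hi), 0.95)
})

test_that("confirmed ORR counts confirmed CR/PR over the full cohort", {
  rec <- data.frame(
    patient_id = sprintf("p%02d", 1:72), cohort = 2,
    best_response = c(rep("PR", 25), rep("CR", 2), rep("SD", 30),
                      rep("PD", 10), rep("NE", 5)),
    confirmed = c(rep(TRUE, 27), rep(FALSE, 45)))
  orr <- confirmed_orr(rec, cohort = 2)
  expect_equal(orr$estimate, 27 / 72)
  expect_equal(round(100 * orr$ci$lo, 1), 26.4)
  expect_equal(round(100 * orr$ci$hi, 1), 49.7)

  none <- data.frame(patient_id = 1:10, cohort = 1,
                     best_response = "PD", confirmed = FALSE)
  expect_equal(confirmed_orr(none, 1)$estimate, 0)
  expect_equal(confirmed_orr(none, 1)$ci$lo, 0)
  expect_error(confirmed_orr(none, 99), "empty-cohort")
  bad <- data.frame(patient_id = 1, cohort = 1,
                    best_response = "SD", confirmed = TRUE)
  expect_error(confirmed_orr(bad, 1), "confirmed")
})

test_that("two-stage rule decisions follow the thresholds", {
  rule <- two_stage_rule(16, 5, 40, 13)
  expect_equal(evaluate_two_stage(rule, 4), "stop_futility")
  expect_equal(evaluate_two_stage(rule, 5, 13), "promising")
  expect_equal(evaluate_two_stage(rule, 16, 12), "not_promising")
  expect_equal(evaluate_two_stage(rule, 5), "continue")
  expect_error(evaluate_two_stage(rule, 5, final_analysis = TRUE),
               "missing-final")
  expect_error(evaluate_two_stage(rule, 17), "invalid-domain")
})

test_that("percent formatting drops trailing zero decimals", {
  expect_equal(format_pct(0.47), "47")
  expect_equal(format_pct(0.706), "70.6")
  expect_equal(format_pct(0.81), "81")
  expect_equal(format_pct(0.8095), "81")  # rounds half away from zero
})
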