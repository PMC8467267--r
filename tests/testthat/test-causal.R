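test_that("relative risk is the ratio of exposed to reference risk", {
  expect_equal(risk_ratio(0.30, 0.10), 3.0)
  expect_equal(round(risk_ratio(0.27, 0.13), 1), 2.1)
  for (p in c(0.01, 0.4, 1)) expect_equal(risk_ratio(p, p), 1.0)
  expect_error(risk_ratio(0.2, 0), class = "cc_undefined_ratio")
  expect_error(risk_ratio(1.2, 0.5), class = "cc_domain_error")
})

test_that("attributable risk follows (RR-1)/RR and flags protection", {
  expect_equal(round(as.numeric(attributable_risk(3.0))), 67)
  expect_equal(round(as.numeric(attributable_risk(1.5))), 33)
  expect_equal(as.numeric(attributable_risk(1.0)), 0)
  expect_true(attr(attributable_risk(0.8), "protective"))
  expect_lt(as.numeric(attributable_risk(0.8)), 0)
  expect_error(attributable_risk(0), class = "cc_domain_error")
  expect_error(attributable_risk(-2), class = "cc_domain_error")
})

test_that("the two attributable-risk routes agree to 1e-12", {
  set.seed(8)
  p1 <- runif(200, 0.001, 1)
  p0 <- runif(200, 0.001, 1)
  expect_equal(as.numeric(attributable_risk_from_probs(p1, p0)),
               as.numeric(attributable_risk(risk_ratio(p1, p0))),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(attributable_risk_from_probs(0.27, 0.13))), 52)
  expect_equal(as.numeric(attributable_risk_from_probs(0.10, 0.01)), 90)
  expect_equal(as.numeric(attributable_risk_from_probs(0.3, 0.3)), 0)
  expect_error(attributable_risk_from_probs(0, 0.1), class = "cc_domain_error")
})

test_that("attributable risk is strictly increasing in the relative risk", {
  rr <- sort(c(exp(seq(log(0.05), log(50), length.out = 300)), 2))
  ar <- as.numeric(attributable_risk(rr))
  expect_true(all(diff(ar) > 0))
})

test_that("absolute risk difference is a plain difference", {
  expect_equal(absolute_risk_difference(0.30, 0.10), 0.20)
  expect_equal(absolute_risk_difference(10 / 1e7, 1 / 1e7), 9 / 1e7)
  expect_equal(absolute_risk_difference(0.5, 0.5), 0)
  expect_error(absolute_risk_difference(1.5, 0.1), class = "cc_domain_error")
})

test_that("significance assessment handles both methods and degeneracy", {
  a <- risk_estimate(0.3, se_logit = 0.2)
  expect_false(assess_significance(a, a, "wald_difference")$significant)
  expect_false(assess_significance(a, a, "ci_overlap")$significant)

  same_p <- assess_significance(risk_estimate(0.3, 0), risk_estimate(0.3, 0))
  expect_true(same_p$degenerate)
  expect_false(same_p$significant)
  diff_p <- assess_significance(risk_estimate(0.4, 0), risk_estimate(0.3, 0))
  expect_true(diff_p$significant)

  # wide, overlapping intervals: heuristic says not significant
  e1 <- risk_estimate(0.66, se_logit = 0.5)
  e0 <- risk_estimate(0.78, se_logit = 0.4)
  expect_false(assess_significance(e1, e0, "ci_overlap")$significant)
  # tight, disjoint intervals: both methods agree
  t1 <- risk_estimate(0.30, se_logit = 0.05)
  t0 <- risk_estimate(0.10, se_logit = 0.05)
  expect_true(assess_significance(t1, t0, "ci_overlap")$significant)
  expect_true(assess_significance(t1, t0, "wald_difference")$significant)
  # positive covariance shrinks the variance of the difference
  z_indep <- assess_significance(t1, t0, "wald_difference")$statistic
  z_cov <- assess_significance(t1, t0, "wald_difference",
                               cov_p = 2e-5)$statistic
  expect_gt(abs(z_cov), abs(z_indep))
})

test_that("a strong significant effect passes the gate with absolute-risk apportionment", {
  fit <- stub_fit(p1 = 0.30, p0 = 0.10)
  case <- case_spec(delta_v_mph = 25, body_type = "car")
  q <- suppressWarnings(quantify_case(fit, case))
  expect_equal(q$rr, 3.0, tolerance = 1e-10)
  expect_equal(round(q$ar_percent), 67)
  expect_true(q$wald$significant)
  expect_true(q$gate_passed)
  expect_equal(q$apportionment, 0.20, tolerance = 1e-10)
  # product-defect framing apportions the attributable fraction instead
  qpd <- suppressWarnings(quantify_case(fit, case, framing = "product_defect"))
  expect_equal(qpd$apportionment, q$ar_percent / 100, tolerance = 1e-12)
})

test_that("a sub-threshold ratio fails the gate even when significant", {
  fit <- stub_fit(p1 = 0.15, p0 = 0.10)
  q <- suppressWarnings(quantify_case(fit, case_spec(delta_v_mph = 25)))
  expect_equal(q$rr, 1.5, tolerance = 1e-10)
  expect_equal(round(q$ar_percent), 33)
  expect_false(q$gate_passed)
  expect_equal(q$apportionment, 0)
  expect_match(q$narrative, "more-probable-than-not")
})

test_that("a protective configuration is surfaced, not clamped", {
  fit <- stub_fit(p1 = 0.66, p0 = 0.78, se2 = 0.5)
  q <- suppressWarnings(quantify_case(fit, case_spec(delta_v_mph = 25)))
  expect_true(q$protective)
  expect_lt(q$rr, 1)
  expect_false(q$gate_passed)
  expect_equal(q$apportionment, 0)
  expect_true(q$survivable_regardless)
  expect_match(q$narrative, "regardless of seat belt use")
})

test_that("quantify_case refuses a non-converged fit", {
  fit <- stub_fit(0.3, 0.1)
  fit$converged <- FALSE
  expect_error(quantify_case(fit, case_spec(delta_v_mph = 25)),
               class = "cc_domain_error")
})

test_that("apportionment never exceeds the unbelted risk (random sweep)", {
  set.seed(14)
  for (i in 1:30) {
    p0 <- runif(1, 0.01, 0.6)
    p1 <- runif(1, 0.01, 0.9)
    fit <- stub_fit(p1, p0)
    q <- suppressWarnings(quantify_case(fit, case_spec(delta_v_mph = 25)))
    expect_lte(q$apportionment, q$p_unbelted$p + 1e-12)
    if (!q$gate_passed) expect_equal(q$apportionment, 0)
    if (q$gate_passed) expect_gt(q$rr, 2)
  }
})
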