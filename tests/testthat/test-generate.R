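params_small <- function(n = 4000, ...) generator_params(n_population = n, seed = 9, ...)

test_that("delta V draws are reproducible, right-skewed, sparse in the tail", {
  p <- params_small()
  expect_identical(sample_delta_v(p, 1), sample_delta_v(p, 1))
  x <- sample_delta_v(p, 1e5)
  expect_true(all(x > 0))
  expect_gt(mean(x) , median(x))  # right skew
  # empirical mode (kernel density peak) near the configured mode
  d <- density(x)
  expect_lt(abs(d$x[which.max(d$y)] - p$delta_v_mode), 2)
  # sparse upper tail, consistent with the configured distribution's integral
  expect_lt(mean(x >= 56), 0.02)
  g <- crashcausal:::gamma_from_mode(p$delta_v_mode, p$delta_v_spread)
  tail_true <- pgamma(56, g$shape, scale = g$scale, lower.tail = FALSE)
  expect_lt(abs(mean(x >= 56) - tail_true), 3 * sqrt(tail_true / 1e5))
})

test_that("true risk is the inverse-logit of the mechanism", {
  p <- generator_params(beta0 = -0.143 * 30, beta_dv = 0.143,
                        beta_unbelted = 0, beta_dv_unbelted = 0)
  expect_equal(true_risk(p, 30, "used"), 0.5)             # logit = 0
  expect_equal(true_risk(p, 40, "used"), true_risk(p, 40, "not_used"))
  expect_gt(true_risk(p, 60, "used"), true_risk(p, 30, "used"))
  p2 <- generator_params()
  expect_gt(true_risk(p2, 20, "not_used"), true_risk(p2, 20, "used"))
})

test_that("simulated deaths match the closed-form risk within binomial error", {
  p <- generator_params(n_population = 3e4, seed = 21)
  pop <- generate_population(p)
  df <- as.data.frame(pop$records)
  bins <- cut(df$delta_v_mph, c(0, 10, 20, 30, 45, Inf))
  for (b in levels(bins)) {
    idx <- which(bins == b)
    if (length(idx) < 50) next
    expected <- mean(pop$truth$true_risk[idx])
    observed <- mean(df$died_30day[idx])
    mc_se <- sqrt(expected * (1 - expected) / length(idx))
    expect_lt(abs(observed - expected), 3.5 * mc_se + 1e-12,
              label = sprintf("death rate in delta V bin %s", b))
  }
})

test_that("a positive belt effect shows up as excess unbelted death rates", {
  p <- generator_params(n_population = 3e4, seed = 22,
                        beta_unbelted = 1.5, beta_dv_unbelted = 0)
  pop <- generate_population(p)
  df <- as.data.frame(pop$records)
  df$belt_actual <- pop$truth$belt_actual
  mid <- df$delta_v_mph > 10 & df$delta_v_mph < 40
  r1 <- mean(df$died_30day[mid & df$belt_actual == "not_used"])
  r0 <- mean(df$died_30day[mid & df$belt_actual == "used"])
  expect_gt(r1, r0)
})

test_that("a fixed seed gives byte-identical CSV output on two runs", {
  p <- params_small()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_records(simulate_crash_sample(p)$sample, f1)
  write_records(simulate_crash_sample(p)$sample, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("zero severity bias gives an equal-probability design", {
  p <- params_small(sampling_severity_bias = 0, sampling_fraction = 0.25)
  des <- assign_survey_design(generate_population(p), p)
  expect_true(all(abs(des$inclusion_prob - 0.25) < 1e-12))
  expect_true(all(abs(des$sample$weight - 4) < 1e-12))
})

test_that("weighted sample totals estimate the population size unbiasedly", {
  p <- params_small(n = 2000)
  pop <- generate_population(p)
  totals <- vapply(1:200, function(r) {
    pr <- p; pr$seed <- p$seed + 1000L + r
    sum(assign_survey_design(pop, pr)$sample$weight)
  }, 0)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - p$n_population), 2 * se)
})

test_that("severity bias oversamples severe crashes; PSUs nest in strata", {
  p <- params_small(sampling_severity_bias = 1.5)
  pop <- generate_population(p)
  des <- assign_survey_design(pop, p)
  dv <- pop$records$delta_v_mph
  expect_gt(mean(des$inclusion_prob[dv > 40]), mean(des$inclusion_prob[dv < 10]))
  map <- unique(as.data.frame(des$sample)[, c("stratum", "psu")])
  expect_equal(anyDuplicated(map$psu), 0L)
  expect_equal(length(des$design$strata), p$n_strata)
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(p_unbelted = 0), class = "cc_domain_error")
  expect_error(generator_params(delta_v_mode = -1), class = "cc_domain_error")
  expect_error(generator_params(sampling_severity_bias = -1),
               class = "cc_domain_error")
  expect_error(sample_delta_v(generator_params(), 0), class = "cc_domain_error")
})
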