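test_that("equal-weight fits match the independent ML oracle to 1e-6", {
  for (seed in c(11, 12, 13)) {
    recs <- make_logit_data(n = 180, seed = seed)
    fit <- suppressWarnings(
      fit_weighted_logistic(recs, model_spec(interaction_dv_belt = FALSE),
                            design = "independent"))
    df <- crashcausal:::prepare_model_frame(recs, model_spec())
    oracle <- glm(.outcome ~ delta_v_mph + unbelted + airbag,
                  family = binomial(), data = df)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$coefficients - coef(oracle))), 1e-6)
  }
})

test_that("duplicating every record at half weight leaves coefficients unchanged", {
  recs <- make_logit_data(n = 120, seed = 31)
  fit1 <- suppressWarnings(
    fit_weighted_logistic(recs, model_spec(interaction_dv_belt = FALSE),
                          design = "independent"))
  doubled <- as.data.frame(recs)[rep(seq_len(nrow(recs)), 2), ]
  doubled$weight <- 0.5
  doubled$record_id <- sprintf("D%04d", seq_len(nrow(doubled)))
  doubled$psu <- sprintf("S01-P%04d", seq_len(nrow(doubled)))
  rownames(doubled) <- NULL
  fit2 <- suppressWarnings(
    fit_weighted_logistic(crash_records(doubled),
                          model_spec(interaction_dv_belt = FALSE),
                          design = "independent"))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
})

test_that("sandwich variance approximates model-based variance under equal weights", {
  recs <- make_logit_data(n = 4000, seed = 41)
  fit <- suppressWarnings(
    fit_weighted_logistic(recs, model_spec(interaction_dv_belt = FALSE),
                          design = "independent"))
  ratio <- diag(fit$covariance) / diag(fit$covariance_model)
  expect_true(all(ratio > 0.75 & ratio < 1.25))
})

test_that("complete separation fails informatively naming the term", {
  recs <- make_logit_data(n = 80, seed = 51)
  recs$died_30day <- recs$belt_used == "not_used"   # perfectly separated
  expect_error(
    suppressWarnings(fit_weighted_logistic(
      recs, model_spec(interaction_dv_belt = FALSE, include_airbag = FALSE),
      design = "independent")),
    "unbelted", class = "cc_separation_error")
})

test_that("degenerate cohorts are refused with domain errors", {
  recs <- make_logit_data(n = 50, seed = 61)
  all_belted <- recs; all_belted$belt_used <- "used"
  expect_error(fit_weighted_logistic(crash_records(as.data.frame(all_belted))),
               class = "cc_domain_error")
  no_deaths <- recs; no_deaths$died_30day <- FALSE
  expect_error(fit_weighted_logistic(crash_records(as.data.frame(no_deaths))),
               class = "cc_domain_error")
})

test_that("single-PSU strata trigger the centred-variance fallback warning", {
  recs <- make_logit_data(n = 200, seed = 71)
  df <- as.data.frame(recs)
  df$stratum <- c("S01", rep(c("S02", "S03"), length.out = 199))
  df$psu <- c("S01-P01", paste0(df$stratum[-1], "-P",
                                rep_len(1:4, 199)))
  expect_warning(fit_weighted_logistic(crash_records(df)),
                 class = "cc_single_psu")
})

test_that("risk predictions respect the logistic midpoint and CI geometry", {
  recs <- make_logit_data(n = 200, seed = 81)
  fit <- suppressWarnings(fit_weighted_logistic(
    recs, model_spec(interaction_dv_belt = FALSE), design = "independent"))
  # profile at which the fitted linear predictor is zero -> p = 0.5
  b <- fit$coefficients
  dv0 <- -(b[["(Intercept)"]]) / b[["delta_v_mph"]]
  est <- suppressWarnings(predict_risk(
    fit, list(delta_v_mph = dv0, belt_used = "used",
              airbag_deployed = "not_deployed")))
  expect_equal(est$p, 0.5, tolerance = 1e-10)
  expect_true(est$ci_low <= est$p && est$p <= est$ci_high)

  # zero covariance -> degenerate CI at the point estimate
  fit0 <- fit
  fit0$covariance <- 0 * fit0$covariance
  est0 <- predict_risk(fit0, list(delta_v_mph = 20, belt_used = "used"))
  expect_equal(est0$ci_low, est0$p)
  expect_equal(est0$ci_high, est0$p)

  # logit-scale CI maps monotonically to probability scale
  est2 <- predict_risk(fit, data.frame(delta_v_mph = c(10, 20, 30),
                                       belt_used = "used",
                                       airbag_deployed = "not_deployed"))
  expect_true(all(est2$ci_low <= est2$p & est2$p <= est2$ci_high))
  expect_true(all(est2$ci_low >= 0 & est2$ci_high <= 1))

  # extrapolation outside the fitted delta V range warns
  expect_warning(predict_risk(fit, list(delta_v_mph = 500, belt_used = "used")),
                 class = "cc_extrapolation")
})

test_that("predictions at the truth scale agree with the generator oracle", {
  p <- generator_params(n_population = 6e4, seed = 91)
  sim <- simulate_crash_sample(p)
  s <- sim$sample
  s <- crash_records(as.data.frame(s)[s$belt_used != "unknown" &
                                        s$airbag_deployed != "unknown", ])
  fit <- suppressWarnings(fit_weighted_logistic(s))
  for (belt in c("used", "not_used")) {
    est <- suppressWarnings(predict_risk(
      fit, list(delta_v_mph = 40, belt_used = belt,
                airbag_deployed = "deployed")))
    truth <- true_risk(p, 40, belt, "deployed")
    se_p <- est$se_logit * est$p * (1 - est$p)
    expect_lt(abs(est$p - truth), 3 * se_p + 0.02)
  }
})

test_that("risk curves have the right cardinality and monotone shape", {
  recs <- make_logit_data(n = 300, seed = 95)
  fit <- suppressWarnings(fit_weighted_logistic(
    recs, model_spec(interaction_dv_belt = FALSE), design = "independent"))
  curve <- risk_curve(fit, profile_base = list(airbag_deployed = "deployed"),
                      delta_v_grid = 30:80)
  expect_equal(nrow(curve), 102L)
  for (state in c("used", "not_used")) {
    pp <- curve$p[curve$belt_state == state]
    if (fit$coefficients[["delta_v_mph"]] >= 0)
      expect_true(all(diff(pp) >= -1e-12))
  }
  # null belt effect: forcing the belt terms to zero collapses the two curves
  fit_null <- fit
  fit_null$coefficients[["unbelted"]] <- 0
  c0 <- risk_curve(fit_null, profile_base = list(airbag_deployed = "deployed"),
                   delta_v_grid = seq(30, 60, 5))
  expect_equal(c0$p[c0$belt_state == "used"], c0$p[c0$belt_state == "not_used"])
  expect_error(risk_curve(fit, delta_v_grid = numeric(0)),
               class = "cc_domain_error")
  expect_error(risk_curve(fit, delta_v_grid = c(50, 30)),
               class = "cc_domain_error")
})
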