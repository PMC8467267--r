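# Shared fixtures, built in code.

# A small hand-specified record table covering the categorical levels.
make_records <- function(n = 10, seed = 101) {
  set.seed(seed)
  crash_records(data.frame(
    record_id = sprintf("R%03d", seq_len(n)),
    year = sample(2001:2015, n, replace = TRUE),
    delta_v_mph = round(runif(n, 5, 60), 2),
    pdof_deg = round(runif(n, 250, 350), 1),
    belt_used = sample(c("used", "not_used"), n, replace = TRUE),
    airbag_deployed = sample(c("deployed", "not_deployed"), n, replace = TRUE),
    rollover = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.1, .9)),
    ejected = FALSE,
    role = "driver",
    body_type = sample(c("car", "pickup"), n, replace = TRUE),
    model_year = sample(1998:2014, n, replace = TRUE),
    died_30day = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.2, .8)),
    injury_codes = replicate(n, {
      k <- sample(0:3, 1)
      paste(sprintf("%06d%d", sample(0:999999, k), sample(1:6, k, TRUE)),
            collapse = ";")
    }),
    weight = round(runif(n, 1, 50), 3),
    stratum = sprintf("S%02d", rep_len(1:3, n)),
    psu = sprintf("S%02d-P%02d", rep_len(1:3, n), rep_len(1:2, n)),
    stringsAsFactors = FALSE
  ))
}

# Equal-weight Bernoulli data with a logistic mechanism, for fitter oracles.
make_logit_data <- function(n = 150, seed = 11, beta = c(-1, 0.08, 0.9),
                            with_airbag = TRUE) {
  set.seed(seed)
  dv <- runif(n, 5, 50)
  unbelted <- rbinom(n, 1, 0.4)
  airbag <- rbinom(n, 1, 0.3)
  eta <- beta[1] + beta[2] * dv + beta[3] * unbelted +
    if (with_airbag) -0.4 * airbag else 0
  y <- rbinom(n, 1, plogis(eta))
  crash_records(data.frame(
    record_id = sprintf("L%04d", seq_len(n)),
    year = 2010L, delta_v_mph = dv, pdof_deg = 300,
    belt_used = ifelse(unbelted == 1, "not_used", "used"),
    airbag_deployed = ifelse(airbag == 1, "deployed", "not_deployed"),
    rollover = FALSE, ejected = FALSE, role = "driver",
    body_type = "car", model_year = 2005L,
    died_30day = y == 1, injury_codes = "",
    weight = 1, stratum = "S01",
    psu = sprintf("S01-P%04d", seq_len(n)),  # one PSU per record
    stringsAsFactors = FALSE
  ))
}
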