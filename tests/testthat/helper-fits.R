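# A fitted_risk_model with chosen coefficients (delta V slope 0.05, no
# interaction) so predicted risks at dv = 25 hit exact targets; the
# covariance scale controls whether differences register as significant.
stub_fit <- function(p1, p0, dv = 25, se2 = 1e-4) {
  recs <- make_logit_data(n = 60, seed = 3)
  fit <- suppressWarnings(fit_weighted_logistic(
    recs, model_spec(interaction_dv_belt = FALSE, include_airbag = FALSE),
    design = "independent"))
  b_dv <- 0.05
  b0 <- qlogis(p0) - b_dv * dv
  fit$coefficients <- c("(Intercept)" = b0, delta_v_mph = b_dv,
                        unbelted = qlogis(p1) - qlogis(p0))
  fit$covariance <- diag(se2, 3)
  dimnames(fit$covariance) <- list(names(fit$coefficients),
                                   names(fit$coefficients))
  fit$delta_v_range <- c(0, 100)
  fit
}
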