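# The medicolegal decision calculus: relative risk, attributable risk,
# absolute risk difference, significance, the >50% "more probable than not"
# gate, and the two-stage apportionment of the claimant's contributory share.

#' Relative risk (risk ratio)
#'
#' Ratio of the outcome probability in the exposed (unbelted) group to the
#' unexposed (belted) group.
#'
#' @param p1 risk in the exposed group.
#' @param p0 risk in the unexposed (reference) group; must be positive.
#' @return `p1 / p0`.
#' @examples
#' risk_ratio(0.30, 0.10)  # 3
#' @export
risk_ratio <- function(p1, p0) {
  if (any(p1 < 0 | p1 > 1 | p0 < 0 | p0 > 1))
    stop_domain("risks must lie in [0, 1]")
  if (any(p0 == 0))
    stop_ratio("risk ratio undefined: reference risk is 0")
  p1 / p0
}

#' Attributable risk from a relative risk
#'
#' The fraction of the exposed group's risk attributable to the exposure,
#' `(RR - 1) / RR * 100` percent. Negative (flagged protective) when RR < 1.
#' AR exceeds 50% exactly when RR exceeds 2.0 — the algebraic form of the
#' "more probable than not" threshold.
#'
#' @param rr relative risk, > 0.
#' @return attributable risk in percent (attribute `protective` when RR < 1).
#' @examples
#' attributable_risk(3.0)  # 66.7 -> prints as 67%
#' attributable_risk(1.5)  # 33.3
#' @export
attributable_risk <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop_domain("relative risk must be a positive finite number")
  structure((rr - 1) / rr * 100, protective = any(rr < 1))
}

#' Attributable risk directly from two risks
#'
#' `(p1 - p0) / p1 * 100` percent: identical to
#' `attributable_risk(risk_ratio(p1, p0))` whenever `p0 > 0`, but defined
#' also for `p0 = 0`.
#'
#' @param p1 exposed-group risk, > 0.
#' @param p0 unexposed-group risk.
#' @return attributable risk in percent.
#' @examples
#' attributable_risk_from_probs(0.27, 0.13)  # 51.9 -> prints as 52%
#' @export
attributable_risk_from_probs <- function(p1, p0) {
  if (any(p1 <= 0)) stop_domain("exposed risk p1 must be positive")
  if (any(p0 < 0 | p0 > 1 | p1 > 1)) stop_domain("risks must lie in [0, 1]")
  structure((p1 - p0) / p1 * 100, protective = any(p0 > p1))
}

#' Absolute risk difference
#'
#' `p1 - p0`: once causation passes the legal gate, this is the quantity that
#' apportions the claimant's contributory share, because the claimant's
#' exposed population is everyone in the crash, survivors included.
#'
#' @param p1,p0 risks in \[0, 1\].
#' @return `p1 - p0`.
#' @examples
#' absolute_risk_difference(0.30, 0.10)  # 0.20
#' @export
absolute_risk_difference <- function(p1, p0) {
  if (any(p1 < 0 | p1 > 1 | p0 < 0 | p0 > 1))
    stop_domain("risks must lie in [0, 1]")
  p1 - p0
}

#' Test whether two risk estimates differ significantly
#'
#' Two methods are computed. `wald_difference` (the formal test, default): a
#' z statistic for the probability-scale difference via the delta method,
#' `z = (p1 - p0) / sqrt(se1^2 + se0^2 - 2 cov)`, two-sided at `alpha`. When
#' both estimates come from one fitted model they are correlated; pass their
#' probability-scale covariance via `cov_p` (as [quantify_case()] does) for a
#' correctly sized test — the default `cov_p = 0` treats them as independent.
#' `ci_overlap` (the conservative field heuristic): significant only when the
#' two 95% confidence intervals are disjoint.
#'
#' @param e1,e0 `risk_estimate` rows (exposed and reference).
#' @param method `"wald_difference"` or `"ci_overlap"`.
#' @param alpha two-sided level for the Wald test.
#' @param cov_p probability-scale covariance between the two estimates.
#' @return list: `significant`, `method`, `statistic`, `p_value`,
#'   `ci_disjoint`, `degenerate`.
#' @export
assess_significance <- function(e1, e0,
                                method = c("wald_difference", "ci_overlap"),
                                alpha = 0.05, cov_p = 0) {
  method <- match.arg(method)
  se1 <- e1$se_logit * e1$p * (1 - e1$p)  # delta method, logit -> probability
  se0 <- e0$se_logit * e0$p * (1 - e0$p)
  diff <- e1$p - e0$p
  var_diff <- se1^2 + se0^2 - 2 * cov_p
  degenerate <- FALSE
  if (var_diff <= 0) {
    if (abs(diff) < .Machine$double.eps^0.5) {
      z <- 0; pval <- 1; degenerate <- TRUE
    } else {
      z <- sign(diff) * Inf; pval <- 0
    }
  } else {
    z <- diff / sqrt(var_diff)
    pval <- 2 * stats::pnorm(-abs(z))
  }
  disjoint <- e1$ci_low > e0$ci_high || e0$ci_low > e1$ci_high
  significant <- if (method == "wald_difference") pval < alpha else disjoint
  list(significant = significant, method = method, statistic = z,
       p_value = pval, ci_disjoint = disjoint, degenerate = degenerate)
}

#' The litigated occupant's crash profile
#'
#' Bundles the facts of the subject crash that the analysis conditions on:
#' occupant role, actual belt state, airbag deployment, reconstructed delta V
#' and PDOF, vehicle, the outcome at issue, and the cohort window used to
#' match the crash.
#'
#' @param role occupant role.
#' @param belt_used_actual the claimant's actual belt state.
#' @param airbag_deployed airbag deployment status.
#' @param delta_v_mph reconstructed delta V (mph), > 0.
#' @param pdof principal direction of force (clock text or degrees).
#' @param body_type vehicle body type.
#' @param model_year vehicle model year.
#' @param peak_acceleration_g optional, informational peak acceleration.
#' @param outcome the binary event at issue.
#' @param cohort a [cohort_spec()] matching the crash.
#' @return a list of class `case_spec`.
#' @export
case_spec <- function(role = "driver",
                      belt_used_actual = c("not_used", "used"),
                      airbag_deployed = "deployed",
                      delta_v_mph,
                      pdof = "10:30",
                      body_type = "pickup",
                      model_year = 2005L,
                      peak_acceleration_g = NULL,
                      outcome = c("death_30day", "max_ais_ge_k"),
                      cohort = cohort_spec()) {
  belt_used_actual <- match.arg(belt_used_actual)
  outcome <- match.arg(outcome)
  if (!is.numeric(delta_v_mph) || length(delta_v_mph) != 1L || delta_v_mph <= 0)
    stop_domain("case delta_v_mph must be a single positive value")
  structure(list(role = role, belt_used_actual = belt_used_actual,
                 airbag_deployed = airbag_deployed,
                 delta_v_mph = delta_v_mph, pdof = as_pdof(pdof),
                 body_type = body_type, model_year = as.integer(model_year),
                 peak_acceleration_g = peak_acceleration_g,
                 outcome = outcome, cohort = cohort),
            class = "case_spec")
}

#' Quantify causation and apportionment for a litigated case
#'
#' The two-stage decision: first, is there statistically reliable evidence
#' that the attributable risk of belt non-use exceeds 50% (relative risk
#' above 2.0) — the "more probable than not" gate; second, if and only if the
#' gate is passed, the contributory share is quantified. Under the default
#' contributory-negligence framing that share is the absolute risk difference
#' (the exposed population is everyone in the crash); under the
#' product-defect framing (e.g. a failed belt latch, where cause and effect
#' are proximate) it is the attributable fraction itself.
#'
#' The gate is strict at both thresholds (AR = 50% or RR = 2.0 exactly fails)
#' and is assessed at the point estimate, with the confidence intervals
#' reported alongside. An apparently protective belt non-use (RR < 1) is
#' surfaced, not clamped; when the death risk exceeds 50% for both belt
#' states the narrative records that the outcome was more probable than not
#' regardless of belt use (the survivability conclusion).
#'
#' @param fit a converged `fitted_risk_model`.
#' @param case a [case_spec()].
#' @param framing `"contributory_negligence"` (default) or
#'   `"product_defect"`.
#' @param significance_method governing method for the gate (default the
#'   formal Wald difference test; the CI-overlap heuristic is always reported
#'   alongside).
#' @param alpha two-sided significance level.
#' @return an object of class `causal_quantification`.
#' @export
quantify_case <- function(fit, case,
                          framing = c("contributory_negligence",
                                      "product_defect"),
                          significance_method = c("wald_difference",
                                                  "ci_overlap"),
                          alpha = 0.05) {
  framing <- match.arg(framing)
  significance_method <- match.arg(significance_method)
  if (!inherits(fit, "fitted_risk_model") || !isTRUE(fit$converged))
    stop_domain("quantify_case requires a converged fitted_risk_model")
  nd <- data.frame(delta_v_mph = case$delta_v_mph,
                   belt_used = c("not_used", "used"),
                   airbag_deployed = case$airbag_deployed,
                   body_type = case$body_type,
                   model_year = case$model_year,
                   stringsAsFactors = FALSE)
  est <- predict_risk(fit, nd)
  e1 <- est[1L, , drop = FALSE]  # unbelted (actual scenario)
  e0 <- est[2L, , drop = FALSE]  # belted (counterfactual)
  cov_eta <- attr(est, "cov_eta")[1L, 2L]
  cov_p <- cov_eta * e1$p * (1 - e1$p) * e0$p * (1 - e0$p)

  rr <- risk_ratio(e1$p, e0$p)
  ar <- as.numeric(attributable_risk(rr))
  abs_diff <- absolute_risk_difference(e1$p, e0$p)
  wald <- assess_significance(e1, e0, "wald_difference", alpha, cov_p = cov_p)
  overlap <- assess_significance(e1, e0, "ci_overlap", alpha)
  governing <- if (significance_method == "wald_difference") wald else overlap
  significant <- governing$significant
  gate_passed <- ar > 50 && significant
  protective <- rr < 1
  apportionment <- if (!gate_passed) 0
    else if (framing == "contributory_negligence") abs_diff
    else ar / 100
  both_over_half <- min(e1$p, e0$p) > 0.5

  narrative <- c(
    sprintf(paste0("At a delta V of %.1f mph, the modelled risk of the ",
                   "outcome is %.1f%% unbelted (95%% CI %.1f-%.1f%%) and ",
                   "%.1f%% belted (95%% CI %.1f-%.1f%%)."),
            case$delta_v_mph, 100 * e1$p, 100 * e1$ci_low, 100 * e1$ci_high,
            100 * e0$p, 100 * e0$ci_low, 100 * e0$ci_high),
    sprintf("Relative risk %.1f; attributable risk %.0f%%; absolute risk difference %.1f percentage points.",
            rr, ar, 100 * abs_diff),
    sprintf("Wald difference test: z = %.2f, p = %.3f (%ssignificant at alpha = %.2f); 95%% CIs %s.",
            wald$statistic, wald$p_value,
            if (wald$significant) "" else "not ", alpha,
            if (overlap$ci_disjoint) "disjoint" else "overlap"),
    if (protective)
      "Belt non-use appears protective at this profile (RR < 1); this finding is surfaced, not clamped."
    else NULL,
    if (gate_passed)
      sprintf("Gate PASSED: attributable risk exceeds 50%% with statistical support; contributory share quantified as %s = %.3f.",
              if (framing == "contributory_negligence")
                "the absolute risk difference" else "the attributable fraction",
              apportionment)
    else
      "Gate FAILED: non-use not proven causal at the more-probable-than-not standard; apportionment 0.",
    if (both_over_half)
      "Risk exceeds 50% for both belt states: the outcome was more probable than not regardless of seat belt use."
    else NULL
  )

  structure(list(
    p_unbelted = e1, p_belted = e0, rr = rr, ar_percent = ar,
    abs_diff = abs_diff,
    significant = significant, significance_method = significance_method,
    wald = wald, ci_overlap = overlap,
    gate_passed = gate_passed, protective = protective,
    survivable_regardless = both_over_half,
    apportionment = apportionment, framing = framing,
    case = case, narrative = paste(narrative, collapse = "\n")
  ), class = "causal_quantification")
}

#' @export
print.causal_quantification <- function(x, ...) {
  cat("Causal quantification of seat belt non-use\n")
  cat(sprintf("  framing: %s; significance method: %s\n",
              x$framing, x$significance_method))
  cat(x$narrative, "\n")
  invisible(x)
}
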