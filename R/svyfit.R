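# Design-based (pseudo-maximum-likelihood) logistic regression.
#
# Point estimates maximise the sampling-weighted binomial log-likelihood by
# Newton-Raphson; the weights are treated strictly as sampling weights, never
# frequency weights, so all uncertainty comes from the Taylor-linearized
# (sandwich) variance with PSU-level clustering within strata under the
# with-replacement approximation. This is the standard design-based treatment
# for stratified multistage crash samples.

#' Specification of the death-risk model
#'
#' Declares the terms of the weighted logistic model. Delta V (continuous,
#' per mph) and the belt non-use indicator are always present — they are the
#' two variables of interest. A delta V x belt interaction is included by
#' default: it allows the belted and unbelted risk curves to cross, a pattern
#' seen in very severe frontal crashes that a main-effects-only model cannot
#' produce. Airbag deployment, vehicle body type, (banded) model year, and a
#' quadratic delta V term are optional adjustments.
#'
#' @param outcome `"death_30day"` (the `died_30day` field) or
#'   `"max_ais_ge_k"` (maximum known AIS at or above `ais_threshold`).
#' @param interaction_dv_belt include the delta V x belt-non-use term?
#' @param include_airbag adjust for airbag deployment?
#' @param include_body_type adjust for vehicle body type (categorical)?
#' @param include_model_year adjust for vehicle model year (centred at 2005)?
#' @param quadratic_delta_v add a quadratic delta V term on the logit scale?
#' @param ais_threshold AIS cut point for the injury outcome (3 = serious).
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(outcome = c("death_30day", "max_ais_ge_k"),
                       interaction_dv_belt = TRUE,
                       include_airbag = TRUE,
                       include_body_type = FALSE,
                       include_model_year = FALSE,
                       quadratic_delta_v = FALSE,
                       ais_threshold = 3L) {
  outcome <- match.arg(outcome)
  structure(list(outcome = outcome,
                 interaction_dv_belt = interaction_dv_belt,
                 include_airbag = include_airbag,
                 include_body_type = include_body_type,
                 include_model_year = include_model_year,
                 quadratic_delta_v = quadratic_delta_v,
                 ais_threshold = as.integer(ais_threshold)),
            class = "model_spec")
}

model_formula <- function(spec) {
  rhs <- c("delta_v_mph", "unbelted")
  if (spec$quadratic_delta_v)   rhs <- c(rhs, "I(delta_v_mph^2)")
  if (spec$interaction_dv_belt) rhs <- c(rhs, "delta_v_mph:unbelted")
  if (spec$include_airbag)      rhs <- c(rhs, "airbag")
  if (spec$include_body_type)   rhs <- c(rhs, "body_type")
  if (spec$include_model_year)  rhs <- c(rhs, "I(model_year - 2005)")
  stats::as.formula(paste(".outcome ~", paste(rhs, collapse = " + ")),
                    env = baseenv())
}

outcome_vector <- function(records, spec) {
  if (spec$outcome == "death_30day") return(as.numeric(records$died_30day))
  vapply(records$injury_codes, function(cell)
    as.numeric(max_ais(parse_injury_codes(cell)) >= spec$ais_threshold),
    numeric(1), USE.NAMES = FALSE)
}

prepare_model_frame <- function(records, spec) {
  df <- as.data.frame(records)
  df$.outcome <- outcome_vector(df, spec)
  df$unbelted <- as.numeric(df$belt_used == "not_used")
  df$airbag <- as.numeric(df$airbag_deployed == "deployed")
  df$body_type <- factor(df$body_type)
  df
}

#' Fit the survey-weighted logistic death-risk model
#'
#' Maximises the sampling-weighted binomial log-likelihood by Newton-Raphson
#' (convergence when the maximum relative coefficient change falls below
#' `tol`, default 1e-8, within `max_iter` iterations; a 1e-8 ridge is added
#' if the weighted information is singular). The covariance of the
#' coefficients is the Taylor-linearized sandwich estimator: weighted score
#' contributions are totalled per PSU and their between-PSU variance pooled
#' within strata with the with-replacement small-sample factor
#' `n_h / (n_h - 1)`. A stratum containing a single PSU is variance-degenerate
#' and contributes its PSU total centred at the grand mean of PSU totals, with
#' a warning. Rows with missing delta V are excluded from the fit and counted
#' in the returned `n_missing_delta_v`.
#'
#' @param cohort a `crash_records` table containing both outcome classes and
#'   both belt states.
#' @param spec a [model_spec()].
#' @param design a [survey_design()]; defaults to the design implied by the
#'   cohort's `stratum`/`psu` columns. Pass `design = "independent"` to treat
#'   every record as its own PSU in one stratum (no clustering).
#' @param tol,max_iter Newton-Raphson convergence controls.
#' @return an object of class `fitted_risk_model`: `coefficients`,
#'   `covariance` (sandwich), `covariance_model` (inverse information),
#'   `design`, `converged`, `n_used`, `weighted_n`, `n_missing_delta_v`, plus
#'   the internals needed by [predict_risk()].
#' @export
fit_weighted_logistic <- function(cohort, spec = model_spec(), design = NULL,
                                  tol = 1e-8, max_iter = 100L) {
  df <- prepare_model_frame(cohort, spec)
  miss_dv <- is.na(df$delta_v_mph)
  n_missing_delta_v <- sum(miss_dv)
  df <- df[!miss_dv, , drop = FALSE]
  if (nrow(df) == 0L) stop_domain("no rows with known delta V to fit")
  if (length(unique(df$.outcome)) < 2L)
    stop_domain("cohort must contain both outcome classes")
  if (length(unique(df$unbelted)) < 2L)
    stop_domain("cohort must contain both belted and unbelted occupants")

  fml <- model_formula(spec)
  mf <- stats::model.frame(fml, data = df)
  X <- stats::model.matrix(fml, mf)
  y <- stats::model.response(mf)
  w <- df$weight
  p <- ncol(X)

  # Newton-Raphson on the weighted log-likelihood, intercept warm start
  beta <- numeric(p)
  wy <- sum(w * y) / sum(w)
  beta[1L] <- stats::qlogis(min(max(wy, 1e-6), 1 - 1e-6))
  converged <- FALSE
  ridged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    irls_w <- w * mu * (1 - mu)
    info <- crossprod(X, X * irls_w)
    score <- crossprod(X, w * (y - mu))
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      ridged <- TRUE
      step <- solve(info + diag(1e-8, p), score)
    }
    beta_new <- beta + drop(step)
    if (any(!is.finite(beta_new)))
      stop_separation("fit diverged: non-finite coefficients")
    # relative change, with an absolute floor so coefficients that are
    # genuinely zero do not stall the criterion at machine noise
    rel <- max(abs(beta_new - beta) / pmax(abs(beta_new), 0.01))
    beta <- beta_new
    if (max(abs(beta)) > 100) {
      worst <- colnames(X)[which.max(abs(beta))]
      stop_separation(sprintf(
        "apparent complete separation on term '%s' (coefficient diverging)",
        worst))
    }
    if (rel < tol || max(abs(step)) < 1e-12) { converged <- TRUE; break }
  }
  if (ridged)
    warn_cc("singular weighted information; 1e-8 ridge applied",
            "cc_ridge_fallback")
  names(beta) <- colnames(X)
  # converged onto a saturated boundary: fitted probabilities numerically 0/1
  mu_chk <- stats::plogis(drop(X %*% beta))
  if (any(mu_chk < 1e-12 | mu_chk > 1 - 1e-12)) {
    worst <- colnames(X)[which.max(abs(beta))]
    stop_separation(sprintf(
      "apparent complete separation on term '%s' (fitted probabilities at 0/1)",
      worst))
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(X, X * (w * mu * (1 - mu)))
  Ainv <- tryCatch(solve(info), error = function(e) solve(info + diag(1e-8, p)))

  # Taylor linearization: score totals per PSU, pooled within strata
  if (identical(design, "independent")) {
    stratum <- rep("ALL", nrow(df)); psu <- as.character(seq_len(nrow(df)))
  } else {
    stratum <- df$stratum; psu <- df$psu
    if (is.null(design)) design <- survey_design(stratum, psu)
  }
  U <- X * (w * (y - mu))
  Z <- rowsum(U, group = psu, reorder = FALSE)
  psu_stratum <- stratum[!duplicated(psu)]
  names(psu_stratum) <- psu[!duplicated(psu)]
  psu_stratum <- psu_stratum[rownames(Z)]
  B <- matrix(0, p, p)
  grand <- colMeans(Z)
  single_psu <- character(0)
  for (h in unique(psu_stratum)) {
    Zh <- Z[psu_stratum == h, , drop = FALSE]
    nh <- nrow(Zh)
    if (nh == 1L) {
      single_psu <- c(single_psu, h)
      d <- Zh[1L, ] - grand
      B <- B + tcrossprod(d)
    } else {
      Zc <- sweep(Zh, 2L, colMeans(Zh))
      B <- B + (nh / (nh - 1)) * crossprod(Zc)
    }
  }
  if (length(single_psu) > 0L)
    warn_cc(sprintf(
      "%d single-PSU stratum(s): variance centred at the grand PSU mean (%s)",
      length(single_psu), paste(single_psu, collapse = ", ")),
      "cc_single_psu")
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(beta), names(beta))

  structure(list(
    coefficients = beta,
    covariance = V,
    covariance_model = Ainv,
    design = if (identical(design, "independent")) NULL else design,
    converged = converged,
    iterations = iter,
    n_used = nrow(df),
    weighted_n = sum(w),
    n_missing_delta_v = n_missing_delta_v,
    spec = spec,
    formula = fml,
    terms = stats::delete.response(stats::terms(mf)),
    xlevels = stats::.getXlevels(stats::terms(mf), mf),
    delta_v_range = range(df$delta_v_mph),
    loglik = sum(w * (y * log(pmax(mu, 1e-300)) +
                        (1 - y) * log(pmax(1 - mu, 1e-300))))
  ), class = "fitted_risk_model")
}

#' @export
print.fitted_risk_model <- function(x, ...) {
  cat(sprintf(
    "Survey-weighted logistic risk model (%s)\n  n = %d (weighted %.1f), %s in %d iterations\n",
    x$spec$outcome, x$n_used, x$weighted_n,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(coef = x$coefficients, se = se,
                    z = x$coefficients / se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.fitted_risk_model <- function(object, ...) object$coefficients

#' @export
vcov.fitted_risk_model <- function(object, ...) object$covariance

#' Construct a risk estimate directly
#'
#' A probability with its logit-scale standard error and a delta-method 95%
#' confidence interval. Used when feeding externally obtained risks (e.g. a
#' published two-group comparison) into the causal calculus; model-based
#' estimates come from [predict_risk()].
#'
#' @param p probability of the outcome.
#' @param se_logit standard error on the logit scale (0 = no uncertainty).
#' @param level confidence level.
#' @return a one-row data frame of class `risk_estimate`.
#' @export
risk_estimate <- function(p, se_logit = 0, level = 0.95) {
  if (any(p < 0 | p > 1)) stop_domain("p must lie in [0, 1]")
  if (any(se_logit < 0)) stop_domain("se_logit must be >= 0")
  z <- stats::qnorm(1 - (1 - level) / 2)
  eta <- stats::qlogis(pmin(pmax(p, 1e-15), 1 - 1e-15))
  lo <- ifelse(se_logit == 0, p, stats::plogis(eta - z * se_logit))
  hi <- ifelse(se_logit == 0, p, stats::plogis(eta + z * se_logit))
  structure(data.frame(p = p, se_logit = se_logit, ci_low = lo, ci_high = hi),
            class = c("risk_estimate", "data.frame"))
}

profile_to_frame <- function(profile) {
  if (is.data.frame(profile)) return(profile)
  as.data.frame(profile[!vapply(profile, is.null, logical(1))],
                stringsAsFactors = FALSE)
}

#' Predict outcome risk at covariate profiles
#'
#' Evaluates the fitted model at one or more covariate profiles. The estimate
#' is the inverse-logit of the linear predictor; the confidence interval is
#' computed on the logit scale by the delta method and then transformed, so
#' it always lies inside \[0, 1\] and brackets the point estimate. Profiles
#' whose delta V lies outside the fitted range trigger an extrapolation
#' warning. The full covariance matrix of the linear predictors across the
#' supplied profiles is attached as attribute `"cov_eta"` (needed for a valid
#' test of a difference between two profiles from the same fit).
#'
#' @param fit a `fitted_risk_model`.
#' @param profile data frame (or named list) of profiles with the fields the
#'   model uses: `delta_v_mph`, `belt_used`, and as applicable
#'   `airbag_deployed`, `body_type`, `model_year`.
#' @param level confidence level (default 0.95; the 95% normal quantile
#'   1.959964 is used on the logit scale).
#' @return a `risk_estimate` data frame, one row per profile.
#' @export
predict_risk <- function(fit, profile, level = 0.95) {
  nd <- profile_to_frame(profile)
  if (!"delta_v_mph" %in% names(nd))
    stop_domain("profile must supply delta_v_mph")
  if (!"belt_used" %in% names(nd))
    stop_domain("profile must supply belt_used")
  nd$unbelted <- as.numeric(nd$belt_used == "not_used")
  nd$airbag <- if ("airbag_deployed" %in% names(nd))
    as.numeric(nd$airbag_deployed == "deployed") else 0
  if (length(fit$xlevels) > 0L && "body_type" %in% names(nd))
    nd$body_type <- factor(nd$body_type, levels = fit$xlevels$body_type)
  mf <- stats::model.frame(fit$terms, nd, xlev = fit$xlevels)
  X <- stats::model.matrix(fit$terms, mf)
  eta <- drop(X %*% fit$coefficients)
  cov_eta <- X %*% fit$covariance %*% t(X)
  se <- sqrt(pmax(diag(cov_eta), 0))
  if (any(nd$delta_v_mph < fit$delta_v_range[1L] |
          nd$delta_v_mph > fit$delta_v_range[2L]))
    warn_cc(sprintf(
      "profile delta V outside the fitted range [%.1f, %.1f] mph: extrapolating",
      fit$delta_v_range[1L], fit$delta_v_range[2L]), "cc_extrapolation")
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- structure(data.frame(
    p = stats::plogis(eta),
    se_logit = se,
    ci_low = stats::plogis(eta - z * se),
    ci_high = stats::plogis(eta + z * se)
  ), class = c("risk_estimate", "data.frame"))
  attr(out, "cov_eta") <- cov_eta
  out
}

#' Death-risk curve over delta V for belted and unbelted occupants
#'
#' Evaluates [predict_risk()] on a delta V grid for each belt state, holding
#' the remaining profile fields fixed — the plotting-ready table behind a
#' belted-vs-unbelted risk figure with its 95% confidence band.
#'
#' @param fit a `fitted_risk_model`.
#' @param profile_base named list of the non-belt profile fields
#'   (`airbag_deployed`, `body_type`, `model_year` as the model requires).
#' @param delta_v_grid ascending numeric grid of delta V values (mph).
#' @param belt_states belt states to trace.
#' @return data frame: `delta_v_mph`, `belt_state`, `p`, `ci_low`, `ci_high`.
#' @export
risk_curve <- function(fit, profile_base = list(airbag_deployed = "deployed"),
                       delta_v_grid = 30:80,
                       belt_states = c("used", "not_used")) {
  if (length(delta_v_grid) == 0L) stop_domain("delta V grid must be nonempty")
  if (is.unsorted(delta_v_grid))
    stop_domain("delta V grid must be ascending")
  grids <- expand.grid(delta_v_mph = delta_v_grid, belt_state = belt_states,
                       stringsAsFactors = FALSE)
  nd <- data.frame(delta_v_mph = grids$delta_v_mph,
                   belt_used = grids$belt_state,
                   stringsAsFactors = FALSE)
  for (fld in names(profile_base)) nd[[fld]] <- profile_base[[fld]]
  est <- suppressWarnings(predict_risk(fit, nd))
  data.frame(delta_v_mph = grids$delta_v_mph, belt_state = grids$belt_state,
             p = est$p, ci_low = est$ci_low, ci_high = est$ci_high,
             stringsAsFactors = FALSE)
}
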