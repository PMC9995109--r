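#' Drift diffusion model variant specifications
#'
#' The six DDM variants differ in which trial-level regressors enter which
#' diffusion parameter:
#'
#' * `ddm1` — drift from z-scored magnitude and delay differences through a
#'   sigmoidal saturation link; free starting bias with a delay-difference
#'   covariate; drug effects on every included parameter.
#' * `ddm2` — as `ddm1` but the starting bias is fixed at 0.5.
#' * `ddm3` — no attribute terms in the drift (the drift is identically 0 and
#'   choices are carried by the bias); free bias with delay-difference
#'   covariate.
#' * `ddm4` — as `ddm1` but the bias covariate is the delay *sum* (overall
#'   proximity) instead of the delay difference.
#' * `ddm5` — drift from the difference of hyperbolically discounted
#'   subjective values (raw magnitudes/delays; discount weight a free,
#'   non-negative parameter), sigmoidal link; bias as in `ddm1`.
#' * `ddm6` — relative-starting-time model: attribute onsets are asynchronous
#'   by `t_diff` seconds (positive = delay evidence starts earlier), giving an
#'   RT-dependent effective drift; bias intercept only.
#'
#' In the within-subject design every included parameter carries a drug shift
#' (`*_drug` coefficient, multiplying a 0/1 drug code); in the between-subject
#' design drug effects are instead carried by separate group-level means per
#' dose group, and the `*_drug` coefficients are dropped.
#'
#' @param name one of `"ddm1"` ... `"ddm6"`.
#' @param linear_link ablation switch: if `TRUE` the sigmoidal saturation is
#'   removed and the drift is the linear predictor itself (no `v_max`
#'   parameters). Provided for link-function comparisons; the saturating
#'   link fits intertemporal choice data far better.
#' @return an object of class `ddm_variant`.
#' @export
ddm_variant <- function(name = c("ddm1", "ddm2", "ddm3", "ddm4", "ddm5",
                                 "ddm6"), linear_link = FALSE) {
  name <- match.arg(name)
  spec <- switch(name,
    ddm1 = list(drift_mode = "attribute_difference", drift_attributes = TRUE,
                bias = "free", bias_covariate = "delay_diff",
                tau_diff = FALSE),
    ddm2 = list(drift_mode = "attribute_difference", drift_attributes = TRUE,
                bias = "fixed", bias_covariate = NULL, tau_diff = FALSE),
    ddm3 = list(drift_mode = "attribute_difference", drift_attributes = FALSE,
                bias = "free", bias_covariate = "delay_diff",
                tau_diff = FALSE),
    ddm4 = list(drift_mode = "attribute_difference", drift_attributes = TRUE,
                bias = "free", bias_covariate = "delay_sum",
                tau_diff = FALSE),
    ddm5 = list(drift_mode = "discounted_value", drift_attributes = FALSE,
                bias = "free", bias_covariate = "delay_diff",
                tau_diff = FALSE),
    ddm6 = list(drift_mode = "time_varying", drift_attributes = TRUE,
                bias = "free", bias_covariate = NULL, tau_diff = TRUE))
  structure(c(list(variant_id = name, linear_link = linear_link), spec),
            class = "ddm_variant")
}

#' @export
print.ddm_variant <- function(x, ...) {
  cat("DDM variant ", x$variant_id, ": drift mode = ", x$drift_mode,
      ", bias = ", x$bias,
      if (!is.null(x$bias_covariate)) paste0(" (+ ", x$bias_covariate, ")"),
      if (x$tau_diff) ", asynchronous attribute onsets (t_diff)", "\n",
      sep = "")
  invisible(x)
}

#' Free parameters of a variant
#'
#' Names of the individual-/group-level coefficients a variant estimates,
#' with their block membership (`drift`, `bias`, `scale`) used by the
#' blockwise sampler.
#'
#' @param variant a [ddm_variant()] object or variant name.
#' @param study_design `"within"` (drug-shift coefficients included) or
#'   `"between"` (drug effects via separate group means).
#' @return data.frame with columns `name` and `block`.
#' @export
variant_params <- function(variant, study_design = c("within", "between")) {
  study_design <- match.arg(study_design)
  if (is.character(variant)) variant <- ddm_variant(variant)
  p <- character(0)
  b <- character(0)
  add <- function(nms, blk) {
    p <<- c(p, nms)
    b <<- c(b, rep(blk, length(nms)))
  }
  if (variant$drift_mode == "discounted_value") {
    add(c("k_disc", "k_disc_drug"), "drift")
  } else if (variant$drift_attributes) {
    add(c("v_mag", "v_mag_drug", "v_delay", "v_delay_drug"), "drift")
  }
  if (!isTRUE(variant$linear_link)) add(c("v_max", "v_max_drug"), "drift")
  if (variant$tau_diff) add(c("t_diff", "t_diff_drug"), "scale")
  if (variant$bias == "free") {
    add(c("z_int", "z_drug"), "bias")
    if (!is.null(variant$bias_covariate)) {
      nm <- if (variant$bias_covariate == "delay_sum") "z_dsum" else "z_delay"
      add(c(nm, paste0(nm, "_drug")), "bias")
    }
  }
  add(c("a_int", "a_drug", "t_int", "t_drug"), "scale")
  out <- data.frame(name = p, block = b, stringsAsFactors = FALSE)
  if (study_design == "between") {
    out <- out[!grepl("_drug$", out$name), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Linear attribute-difference drift regression
#'
#' Unbounded drift \eqn{v' = \beta_{mag} M_{diff} + \beta_{mag,drug} (Drug
#' \times M_{diff}) + \beta_{delay} D_{diff} + \beta_{delay,drug} (Drug \times
#' D_{diff})} on z-scored attribute differences.
#'
#' @param magnitude_diff,delay_diff z-scored attribute differences.
#' @param drug 0/1 drug code.
#' @param coefs named coefficients (`v_mag`, `v_mag_drug`, `v_delay`,
#'   `v_delay_drug`; absent names count as 0).
#' @return unbounded drift `v'`.
#' @export
drift_linear <- function(magnitude_diff, delay_diff, drug, coefs) {
  cf <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  (cf("v_mag") + drug * cf("v_mag_drug")) * magnitude_diff +
    (cf("v_delay") + drug * cf("v_delay_drug")) * delay_diff
}

#' Sigmoidal drift link
#'
#' Maps the unbounded drift onto `(-v_max, v_max)` via
#' \eqn{v = v_{max} (2 / (1 + e^{-v'}) - 1) = v_{max} \tanh(v'/2)}: odd,
#' strictly increasing, saturating at \eqn{\pm v_{max}}.
#'
#' @param v_prime unbounded drift.
#' @param v_max saturation bound (> 0).
#' @return bounded drift `v`, `|v| < v_max`.
#' @export
sigmoid_link <- function(v_prime, v_max) {
  if (any(v_max <= 0)) stop("effective v_max must be > 0")
  v_max * tanh(v_prime / 2)
}

#' Starting-bias regression
#'
#' Identity-scale linear predictor for the relative starting point:
#' \eqn{\zeta = \beta_0 + \beta_{drug} Drug + \beta_{cov} X + \beta_{cov,drug}
#' (Drug \times X)} with `X` the z-scored delay difference (or delay sum).
#' Values are not transformed; during estimation, coefficient draws pushing
#' any trial's \eqn{\zeta} outside (0.02, 0.98) are rejected, which preserves
#' the direct interpretability of the coefficients.
#'
#' @param covariate z-scored bias covariate (ignored when the variant has
#'   none).
#' @param drug 0/1 drug code.
#' @param coefs named coefficients (`z_int`, `z_drug`, and `z_delay`/`z_dsum`
#'   with drug shifts).
#' @param variant a [ddm_variant()]; for a fixed-bias variant the result is
#'   0.5 everywhere.
#' @return relative starting point \eqn{\zeta} per trial.
#' @export
bias_regression <- function(covariate, drug, coefs, variant = ddm_variant()) {
  if (is.character(variant)) variant <- ddm_variant(variant)
  n <- max(length(covariate), length(drug))
  if (variant$bias == "fixed") return(rep(0.5, n))
  cf <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  z <- cf("z_int") + drug * cf("z_drug")
  if (!is.null(variant$bias_covariate)) {
    nm <- if (variant$bias_covariate == "delay_sum") "z_dsum" else "z_delay"
    z <- z + (cf(nm) + drug * cf(paste0(nm, "_drug"))) * covariate
  }
  rep_len(z, n)
}

#' Threshold and non-decision time regressions
#'
#' \eqn{a = \beta_{a,0} + \beta_{a,drug} Drug} and \eqn{\tau = \beta_{\tau,0}
#' + \beta_{\tau,drug} Drug}; both are constrained positive during
#' estimation by rejection.
#'
#' @param drug 0/1 drug code.
#' @param coefs named coefficients (`a_int`, `a_drug`, `t_int`, `t_drug`).
#' @return list with components `a` and `tau`.
#' @export
threshold_and_ndt <- function(drug, coefs) {
  cf <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  list(a = cf("a_int") + drug * cf("a_drug"),
       tau = cf("t_int") + drug * cf("t_drug"))
}

#' Discounted-value drift
#'
#' Unbounded drift as the difference of hyperbolically discounted subjective
#' values, \eqn{v' = LL_{mag}/(1 + k_d LL_{delay}) - SS_{mag}/(1 + k_d
#' SS_{delay})}, on raw (unstandardized) magnitudes and delays.
#'
#' @param ll_magnitude,ll_delay,ss_magnitude,ss_delay raw option attributes.
#' @param k_disc effective hyperbolic discount weight (>= 0, per day).
#' @return unbounded drift `v'`.
#' @export
drift_discounted_value <- function(ll_magnitude, ll_delay, ss_magnitude,
                                   ss_delay, k_disc) {
  if (any(k_disc < 0)) stop("discount weight must be >= 0")
  ll_magnitude / (1 + k_disc * ll_delay) -
    ss_magnitude / (1 + k_disc * ss_delay)
}

#' Time-varying drift with asynchronous attribute onsets
#'
#' In the relative-starting-time model, accumulation of one attribute begins
#' `|tau_diff|` seconds before the other (delay first when `tau_diff > 0`,
#' magnitude first when `tau_diff < 0`). The effective drift for a trial with
#' decision time `rt - tau` is the duration-weighted average of the
#' early-attribute-only drift over the first `|tau_diff|` seconds and the
#' full two-attribute drift over the remainder; when the decision falls
#' entirely within the asynchrony window, only the early attribute drives it.
#'
#' @param m_term magnitude contribution to the drift (per trial).
#' @param d_term delay contribution to the drift (per trial).
#' @param tau_diff onset asynchrony in seconds (positive = delay earlier).
#' @param rt observed response time (seconds).
#' @param tau non-decision time (seconds); requires `rt > tau`.
#' @return effective unbounded drift `v'` per trial.
#' @export
drift_time_varying <- function(m_term, d_term, tau_diff, rt, tau) {
  dt <- rt - tau
  if (any(dt <= 0)) stop("drift_time_varying requires rt > tau")
  n <- max(length(m_term), length(d_term), length(tau_diff), length(dt))
  m_term <- rep_len(m_term, n); d_term <- rep_len(d_term, n)
  tau_diff <- rep_len(tau_diff, n); dt <- rep_len(dt, n)
  early <- ifelse(tau_diff >= 0, d_term, m_term)
  both <- m_term + d_term
  gap <- pmin(abs(tau_diff), dt)
  (gap * early + (dt - gap) * both) / dt
}

# Map an individual's coefficient vector onto trial-level Wiener parameters.
# Returns list(v, a, z, tau, ok); ok = FALSE signals an inadmissible draw
# (non-positive a/tau/v_max, negative discount weight, bias outside
# (0.02, 0.98), or rt <= tau) that the sampler must reject.
.map_trials_core <- function(coefs, trials, variant) {
  cf <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else 0
  drug <- trials$drug_code
  linear <- isTRUE(variant$linear_link)
  vmax <- if (linear) 1 else cf("v_max") + drug * cf("v_max_drug")
  sc <- threshold_and_ndt(drug, coefs)
  a <- rep_len(sc$a, nrow(trials))
  tau <- rep_len(sc$tau, nrow(trials))
  if (variant$bias == "fixed") {
    z <- rep(0.5, nrow(trials))
  } else {
    cov <- if (is.null(variant$bias_covariate)) 0 else
      trials[[variant$bias_covariate]]
    z <- bias_regression(cov, drug, coefs, variant)
  }
  ok <- all(vmax > 0) && all(a > 0) && all(tau >= 0) &&
    all(z > 0.02 & z < 0.98) && all(trials$rt > tau)
  if (!ok) return(list(ok = FALSE))
  vprime <- switch(variant$drift_mode,
    attribute_difference =
      if (variant$drift_attributes) {
        drift_linear(trials$magnitude_diff, trials$delay_diff, drug, coefs)
      } else rep(0, nrow(trials)),
    discounted_value = {
      kd <- cf("k_disc") + drug * cf("k_disc_drug")
      if (any(kd < 0)) return(list(ok = FALSE))
      drift_discounted_value(trials$ll_magnitude, trials$ll_delay,
                             trials$ss_magnitude, trials$ss_delay, kd)
    },
    time_varying = {
      m_term <- (cf("v_mag") + drug * cf("v_mag_drug")) * trials$magnitude_diff
      d_term <- (cf("v_delay") + drug * cf("v_delay_drug")) *
        trials$delay_diff
      td <- cf("t_diff") + drug * cf("t_diff_drug")
      drift_time_varying(m_term, d_term, rep_len(td, nrow(trials)),
                         trials$rt, tau)
    })
  v <- if (linear) rep_len(vprime, nrow(trials)) else
    sigmoid_link(vprime, vmax)
  list(v = v, a = a, z = z, tau = tau, ok = TRUE)
}

# Build a variant-specialized participant log-likelihood closure for the
# sampler hot path: integer-indexed coefficient access, plain-vector trial
# covariates (tr: list with mdiff, ddiff, dsum, drug, rt, choice, llm, lld,
# ssm, ssd, n). Must agree with .map_trials_core + cpp_wfpt_loglik exactly
# (property-tested).
.make_fast_loglik <- function(variant, pn) {
  ix <- function(nm) {
    i <- match(nm, pn)
    if (is.na(i)) 0L else i
  }
  i_vmag <- ix("v_mag"); i_vmagd <- ix("v_mag_drug")
  i_vdel <- ix("v_delay"); i_vdeld <- ix("v_delay_drug")
  i_vmax <- ix("v_max"); i_vmaxd <- ix("v_max_drug")
  i_zint <- ix("z_int"); i_zdrug <- ix("z_drug")
  use_dsum <- identical(variant$bias_covariate, "delay_sum")
  i_zc <- ix(if (use_dsum) "z_dsum" else "z_delay")
  i_zcd <- ix(if (use_dsum) "z_dsum_drug" else "z_delay_drug")
  has_zc <- !is.null(variant$bias_covariate) && i_zc > 0L
  i_aint <- ix("a_int"); i_adrug <- ix("a_drug")
  i_tint <- ix("t_int"); i_tdrug <- ix("t_drug")
  i_k <- ix("k_disc"); i_kd <- ix("k_disc_drug")
  i_td <- ix("t_diff"); i_tdd <- ix("t_diff_drug")
  gv <- function(b, i) if (i > 0L) b[i] else 0
  mode <- variant$drift_mode
  attrs <- variant$drift_attributes
  bias_free <- variant$bias == "free"
  linear <- isTRUE(variant$linear_link)
  function(b, tr) {
    drug <- tr$drug
    vmax <- if (linear) 1 else gv(b, i_vmax) + drug * gv(b, i_vmaxd)
    a <- gv(b, i_aint) + drug * gv(b, i_adrug)
    tau <- gv(b, i_tint) + drug * gv(b, i_tdrug)
    if (any(vmax <= 0) || any(a <= 0) || any(tau < 0) ||
        any(tr$rt <= tau)) return(-Inf)
    if (bias_free) {
      z <- gv(b, i_zint) + drug * gv(b, i_zdrug)
      if (has_zc) {
        zc <- if (use_dsum) tr$dsum else tr$ddiff
        z <- z + (b[i_zc] + drug * gv(b, i_zcd)) * zc
      }
      if (any(z <= 0.02) || any(z >= 0.98)) return(-Inf)
    } else {
      z <- 0.5
    }
    vp <- if (mode == "discounted_value") {
      kd <- gv(b, i_k) + drug * gv(b, i_kd)
      if (any(kd < 0)) return(-Inf)
      tr$llm / (1 + kd * tr$lld) - tr$ssm / (1 + kd * tr$ssd)
    } else if (mode == "time_varying") {
      m_term <- (gv(b, i_vmag) + drug * gv(b, i_vmagd)) * tr$mdiff
      d_term <- (gv(b, i_vdel) + drug * gv(b, i_vdeld)) * tr$ddiff
      td <- gv(b, i_td) + drug * gv(b, i_tdd)
      dt <- tr$rt - tau
      n <- tr$n
      td <- rep_len(td, n)
      early <- ifelse(td >= 0, d_term, m_term)
      gap <- pmin(abs(td), dt)
      (gap * early + (dt - gap) * (m_term + d_term)) / dt
    } else if (attrs) {
      (gv(b, i_vmag) + drug * gv(b, i_vmagd)) * tr$mdiff +
        (gv(b, i_vdel) + drug * gv(b, i_vdeld)) * tr$ddiff
    } else {
      0
    }
    v <- if (linear) vp else vmax * tanh(vp / 2)
    n <- tr$n
    cpp_wfpt_loglik(tr$rt, tr$choice, rep_len(v, n), rep_len(a, n),
                    rep_len(z, n), rep_len(tau, n))
  }
}

#' Map coefficients onto trial-level diffusion parameters
#'
#' Composes the variant's drift, bias, threshold and non-decision-time
#' regressions to produce one set of Wiener parameters per trial. For the
#' time-varying variant (`ddm6`) the effective drift depends on each trial's
#' observed RT; the first-passage density is then evaluated at that
#' trial-specific drift (an approximation inherited from the
#' relative-starting-time approach).
#'
#' @param coefs named numeric vector of coefficients (see [variant_params()]).
#' @param data standardized trials ([standardize_attributes()] output, or any
#'   data.frame with the needed columns).
#' @param variant a [ddm_variant()] or variant name.
#' @return data.frame with columns `v`, `a`, `z`, `tau` (one row per trial).
#' @export
map_trials <- function(coefs, data, variant = ddm_variant()) {
  if (is.character(variant)) variant <- ddm_variant(variant)
  m <- .map_trials_core(coefs, data, variant)
  if (!m$ok) {
    stop("coefficients map to inadmissible diffusion parameters ",
         "(need a > 0, tau >= 0 and < rt, v_max > 0, k >= 0, ",
         "bias in (0.02, 0.98))")
  }
  data.frame(v = m$v, a = m$a, z = m$z, tau = m$tau)
}

#' Variant inclusion matrix
#'
#' Logical matrix recording which regressor enters which diffusion parameter
#' in each variant (rows: parameter/regressor, columns: `ddm1` ... `ddm6`).
#' Useful for programmatic conformance checks.
#'
#' @return logical matrix.
#' @export
variant_matrix <- function() {
  vs <- paste0("ddm", 1:6)
  rows <- c("drift:delay_diff", "drift:magnitude_diff", "drift:v_max",
            "threshold:intercept", "bias:intercept", "bias:delay_diff",
            "bias:delay_sum", "ndt:intercept", "ndt:tau_diff")
  m <- matrix(FALSE, length(rows), length(vs), dimnames = list(rows, vs))
  for (v in vs) {
    sp <- ddm_variant(v)
    m["drift:delay_diff", v] <- sp$drift_attributes ||
      sp$drift_mode == "discounted_value"
    m["drift:magnitude_diff", v] <- sp$drift_attributes
    m["drift:v_max", v] <- TRUE
    m["threshold:intercept", v] <- TRUE
    m["bias:intercept", v] <- sp$bias == "free"
    m["bias:delay_diff", v] <- identical(sp$bias_covariate, "delay_diff")
    m["bias:delay_sum", v] <- identical(sp$bias_covariate, "delay_sum")
    m["ndt:intercept", v] <- TRUE
    m["ndt:tau_diff", v] <- sp$tau_diff
  }
  m
}
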