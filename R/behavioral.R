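#' Hyperbolic subjective value
#'
#' \eqn{SV = magnitude / (1 + k \cdot delay)}: the standard hyperbolic
#' discount function (delay in days, k per day).
#'
#' @param magnitude reward magnitude (currency units).
#' @param delay delay in days (>= 0).
#' @param k hyperbolic discount rate (>= 0).
#' @return discounted subjective value.
#' @export
hyperbolic_sv <- function(magnitude, delay, k) {
  if (any(k < 0)) stop("k must be >= 0")
  if (any(delay < 0)) stop("delay must be >= 0")
  magnitude / (1 + k * delay)
}

#' Softmax probability of choosing the larger-later option
#'
#' \eqn{P(LL) = 1 / (1 + e^{-\beta_{temp} (SV_{LL} - SV_{SS})})}.
#'
#' @param sv_ll,sv_ss subjective values of the LL and SS options.
#' @param beta_temp inverse temperature (>= 0).
#' @return choice probability in (0, 1).
#' @export
softmax_ll_probability <- function(sv_ll, sv_ss, beta_temp) {
  if (any(beta_temp < 0)) stop("beta_temp must be >= 0")
  stats::plogis(beta_temp * (sv_ll - sv_ss))
}

.jags_inits <- function(chains, seed) {
  seeds <- if (is.null(seed)) sample.int(2^31 - 2, chains) else
    seed + seq_len(chains)
  lapply(seeds, function(s) {
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s)
  })
}

.jags_run <- function(model_string, data, monitor, chains, burn, keep,
                      seed, inits_extra = NULL) {
  inits <- .jags_inits(chains, seed)
  if (!is.null(inits_extra)) {
    inits <- lapply(inits, function(i) c(i, inits_extra))
  }
  m <- rjags::jags.model(textConnection(model_string), data = data,
                         inits = inits, n.chains = chains, n.adapt = 500,
                         quiet = TRUE)
  stats::update(m, burn, progress.bar = "none")
  rjags::coda.samples(m, monitor, n.iter = keep, progress.bar = "none")
}

#' Fit the hyperbolic discounting model per participant and session
#'
#' Estimates the discount rate k and softmax inverse temperature
#' \eqn{\beta_{temp}} separately for every participant-session cell by MCMC
#' (JAGS), on the log scale with weakly informative normal priors
#' (defaults: log k ~ N(-3, 2), log beta ~ N(-1, 2)). Cells with fewer than
#' `min_trials` trials are skipped; cells without choice variation are
#' fitted but flagged (their posterior is prior-dominated on one side).
#'
#' @param data an `itc_data` (or any data.frame with the trial columns).
#' @param chains,iter,warmup MCMC settings (defaults: 2 chains x 4000
#'   iterations, 2000 burn-in).
#' @param prior_logk,prior_logbeta length-2 vectors (mean, sd) of the log-
#'   scale normal priors.
#' @param min_trials minimum trials per cell (default 5).
#' @param seed optional RNG seed.
#' @return data.frame of class `discounting_fit`: one row per participant-
#'   session with posterior means `k`, `beta_temp`, `log_k`, `log_beta`,
#'   posterior SDs, and a `flagged` indicator for degenerate cells.
#' @export
fit_discounting <- function(data, chains = 2, iter = 4000, warmup = 2000,
                            prior_logk = c(-3, 2), prior_logbeta = c(-1, 2),
                            min_trials = 5, seed = NULL) {
  df <- as.data.frame(data)
  stopifnot(all(c("participant_id", "session_id", "choice") %in% names(df)))
  if (!is.null(seed)) set.seed(seed)
  model <- "
  model {
    for (t in 1:N) {
      svll[t] <- llm[t] / (1 + k * lld[t])
      svss[t] <- ssm[t] / (1 + k * ssd[t])
      choice[t] ~ dbern(ilogit(beta * (svll[t] - svss[t])))
    }
    k <- exp(logk)
    beta <- exp(logbeta)
    logk ~ dnorm(mu_lk, pow(sd_lk, -2))
    logbeta ~ dnorm(mu_lb, pow(sd_lb, -2))
  }"
  cells <- unique(df[c("participant_id", "session_id")])
  out <- NULL
  for (r in seq_len(nrow(cells))) {
    sel <- df$participant_id == cells$participant_id[r] &
      df$session_id == cells$session_id[r]
    tr <- df[sel, , drop = FALSE]
    if (nrow(tr) < min_trials) next
    jd <- list(N = nrow(tr), choice = tr$choice, llm = tr$ll_magnitude,
               lld = tr$ll_delay, ssm = tr$ss_magnitude, ssd = tr$ss_delay,
               mu_lk = prior_logk[1], sd_lk = prior_logk[2],
               mu_lb = prior_logbeta[1], sd_lb = prior_logbeta[2])
    s <- .jags_run(model, jd, c("logk", "logbeta"), chains,
                   burn = warmup, keep = iter - warmup,
                   seed = if (is.null(seed)) NULL else seed + r)
    draws <- as.matrix(do.call(rbind, s))
    no_var <- length(unique(tr$choice)) < 2
    out <- rbind(out, data.frame(
      participant_id = cells$participant_id[r],
      session_id = cells$session_id[r],
      drug = if ("drug" %in% names(tr)) as.character(tr$drug[1]) else NA,
      n_trials = nrow(tr),
      log_k = mean(draws[, "logk"]), sd_log_k = stats::sd(draws[, "logk"]),
      log_beta = mean(draws[, "logbeta"]),
      sd_log_beta = stats::sd(draws[, "logbeta"]),
      k = mean(exp(draws[, "logk"])),
      beta_temp = mean(exp(draws[, "logbeta"])),
      flagged = no_var || stats::sd(draws[, "logk"]) > 1.5,
      stringsAsFactors = FALSE))
  }
  class(out) <- c("discounting_fit", "data.frame")
  out
}

#' Robust Bayesian t-test
#'
#' Posterior of a mean difference under a robust t model: each group is
#' modeled as Student-t distributed with its own mean and scale and a shared
#' normality parameter \eqn{\nu} (exponential-plus-one prior, mean 30), with
#' vague data-scaled priors on means and scales. `paired = TRUE` fits the
#' one-sample version to the differences `x - y`.
#'
#' @param x,y numeric samples (n >= 3 per group; equal length when paired).
#' @param paired fit difference scores instead of two groups.
#' @param chains,iter,warmup MCMC settings.
#' @param mass HDI mass (default 0.95).
#' @param seed optional RNG seed.
#' @return list with `mean`, `hdi`, and the posterior `draws` of the mean
#'   difference (x minus y).
#' @export
bayesian_ttest <- function(x, y, paired = FALSE, chains = 2, iter = 5000,
                           warmup = 1000, mass = 0.95, seed = NULL) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  if (paired) {
    if (length(x) != length(y)) stop("paired test requires equal lengths")
    d <- x - y
    model <- "
    model {
      for (i in 1:n) { d[i] ~ dt(mu, pow(sigma, -2), nu) }
      mu ~ dnorm(m0, pow(s0 * 1000, -2))
      sigma ~ dunif(s0 / 1000, s0 * 1000)
      nu <- numinus1 + 1
      numinus1 ~ dexp(1 / 29)
    }"
    s0 <- max(stats::sd(d), 1e-6)
    jd <- list(n = length(d), d = d, m0 = mean(d), s0 = s0)
    s <- .jags_run(model, jd, "mu", chains, warmup, iter - warmup, seed)
    draws <- as.numeric(as.matrix(do.call(rbind, s)))
  } else {
    model <- "
    model {
      for (i in 1:n1) { x[i] ~ dt(mu1, pow(sigma1, -2), nu) }
      for (j in 1:n2) { y[j] ~ dt(mu2, pow(sigma2, -2), nu) }
      mu1 ~ dnorm(m0, pow(s0 * 1000, -2))
      mu2 ~ dnorm(m0, pow(s0 * 1000, -2))
      sigma1 ~ dunif(s0 / 1000, s0 * 1000)
      sigma2 ~ dunif(s0 / 1000, s0 * 1000)
      nu <- numinus1 + 1
      numinus1 ~ dexp(1 / 29)
    }"
    s0 <- max(stats::sd(c(x, y)), 1e-6)
    jd <- list(n1 = length(x), n2 = length(y), x = x, y = y,
               m0 = mean(c(x, y)), s0 = s0)
    s <- .jags_run(model, jd, c("mu1", "mu2"), chains, warmup, iter - warmup,
                   seed)
    m <- as.matrix(do.call(rbind, s))
    draws <- m[, "mu1"] - m[, "mu2"]
  }
  list(mean = mean(draws), hdi = compute_hdi(draws, mass), draws = draws)
}

# build the MGLM fixed-effects design matrix
.mglm_design <- function(data, outcome = c("choice", "rt"),
                         trial_index = FALSE) {
  outcome <- match.arg(outcome)
  df <- as.data.frame(data)
  drug <- if (attr(data, "study_design") == "within") df$drug_code else {
    dn <- suppressWarnings(as.numeric(as.character(df$drug)))
    if (anyNA(dn)) as.numeric(factor(df$drug)) - 1 else
      as.numeric(scale(dn))
  }
  X <- cbind(Intercept = 1, Drug = drug, Delay_diff = df$delay_diff,
             Magnitude_diff = df$magnitude_diff,
             `Drug:Delay_diff` = drug * df$delay_diff,
             `Drug:Magnitude_diff` = drug * df$magnitude_diff,
             `Delay_diff:Magnitude_diff` = df$delay_diff * df$magnitude_diff,
             `Drug:Delay_diff:Magnitude_diff` =
               drug * df$delay_diff * df$magnitude_diff)
  if (outcome == "rt") {
    X <- cbind(X, Choice = df$choice,
               Magnitude_sum = df$magnitude_sum)
  }
  if (trial_index) {
    tz <- as.numeric(scale(df$trial_index))
    X <- cbind(X, Trial = tz, `Drug:Trial` = drug * tz)
  }
  X
}

.mglm_jags <- function(X, y, pid, family, chains, iter, warmup, seed) {
  K <- ncol(X)
  P <- length(unique(pid))
  lik <- if (family == "binomial") {
    "y[n] ~ dbern(ilogit(eta[n]))"
  } else {
    "y[n] ~ dnorm(eta[n], pow(sigma_e, -2))"
  }
  extra <- if (family == "gaussian") "sigma_e ~ dunif(0, 10)" else ""
  model <- sprintf("
  model {
    for (n in 1:N) {
      eta[n] <- inprod(X[n, ], beta[]) + inprod(X[n, ], u[pid[n], ])
      %s
    }
    for (j in 1:K) { beta[j] ~ dnorm(0, pow(5, -2)) }
    for (i in 1:P) {
      for (j in 1:K) { u[i, j] ~ dnorm(0, pow(sigma_u[j], -2)) }
    }
    for (j in 1:K) { sigma_u[j] ~ dnorm(0, 1) T(0, ) }
    %s
  }", lik, extra)
  jd <- list(N = nrow(X), K = K, P = P, X = X, y = y,
             pid = as.integer(factor(pid)))
  s <- .jags_run(model, jd, "beta", chains, warmup, iter - warmup, seed)
  draws <- as.matrix(do.call(rbind, s))
  colnames(draws) <- colnames(X)
  tab <- data.frame(
    predictor = colnames(X),
    mean = colMeans(draws),
    sem = apply(draws, 2, stats::sd),
    hdi_lower = apply(draws, 2, function(d) compute_hdi(d)[1]),
    hdi_upper = apply(draws, 2, function(d) compute_hdi(d)[2]),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, draws = draws, family = family),
            class = "mglm_fit")
}

#' @export
print.mglm_fit <- function(x, ...) {
  cat("Bayesian mixed-effects ",
      if (x$family == "binomial") "logistic" else "linear",
      " regression (participant random intercepts + slopes)\n", sep = "")
  tab <- x$coefficients
  tab[-1] <- round(tab[-1], 3)
  print(tab)
  invisible(x)
}

#' Model-free Bayesian mixed logistic regression of choices
#'
#' Regresses LL-vs-SS choices on Drug, the z-scored magnitude and delay
#' differences and all their interactions (optionally plus a z-scored trial
#' index and its drug interaction), with participant-level random intercepts
#' and random slopes for every predictor. Fixed effects have Normal(0, 5)
#' priors, random-effect SDs half-Normal(0, 1) priors; fitted by MCMC
#' (JAGS).
#'
#' @param data standardized `itc_data`.
#' @param trial_index include the trial-number predictor.
#' @param chains,iter,warmup MCMC settings.
#' @param seed optional RNG seed.
#' @return object of class `mglm_fit` with a coefficient table (posterior
#'   mean, SEM, 95% HDI) and the fixed-effect draws.
#' @export
fit_choice_mglm <- function(data, trial_index = FALSE, chains = 2,
                            iter = 3000, warmup = 1000, seed = NULL) {
  stopifnot(inherits(data, "itc_data"))
  if (is.null(attr(data, "standardization"))) {
    data <- standardize_attributes(data)
  }
  X <- .mglm_design(data, "choice", trial_index)
  .mglm_jags(X, as.integer(data$choice), data$participant_id, "binomial",
             chains, iter, warmup, seed)
}

#' Bayesian mixed linear regression of log decision times
#'
#' Same fixed- and random-effects structure as [fit_choice_mglm()], applied
#' to log-transformed response times, with additional predictors for the
#' chosen option (SS vs LL) and the z-scored magnitude sum.
#'
#' @inheritParams fit_choice_mglm
#' @return an `mglm_fit`.
#' @export
fit_rt_mglm <- function(data, trial_index = FALSE, chains = 2, iter = 3000,
                        warmup = 1000, seed = NULL) {
  stopifnot(inherits(data, "itc_data"), all(data$rt > 0))
  if (is.null(attr(data, "standardization"))) {
    data <- standardize_attributes(data)
  }
  X <- .mglm_design(data, "rt", trial_index)
  .mglm_jags(X, log(data$rt), data$participant_id, "gaussian",
             chains, iter, warmup, seed)
}
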