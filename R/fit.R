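#' Hierarchical prior specification
#'
#' Group-level effects have standard normal priors (mean 0, SD
#' `group_mean_sd`); each group-level standard deviation \eqn{\lambda}
#' (one per effect) has a Gamma prior with the given shape and rate
#' (default Gamma(1, 1): mean 1, weakly informative on the scale of
#' standardized coefficients).
#'
#' @param group_mean_sd prior SD of group-level means (default 1).
#' @param lambda_shape,lambda_rate Gamma hyperparameters for the
#'   between-participant SDs (> 0).
#' @return an object of class `ddm_prior`.
#' @export
ddm_prior <- function(group_mean_sd = 1, lambda_shape = 1, lambda_rate = 1) {
  stopifnot(group_mean_sd > 0, lambda_shape > 0, lambda_rate > 0)
  structure(list(group_mean_sd = group_mean_sd, lambda_shape = lambda_shape,
                 lambda_rate = lambda_rate), class = "ddm_prior")
}

# plain-vector covariate bundle for the sampler hot path
.trial_bundle <- function(df) {
  list(mdiff = if (is.null(df$magnitude_diff)) numeric(nrow(df)) else
         as.numeric(df$magnitude_diff),
       ddiff = if (is.null(df$delay_diff)) numeric(nrow(df)) else
         as.numeric(df$delay_diff),
       dsum = if (is.null(df$delay_sum)) numeric(nrow(df)) else
         as.numeric(df$delay_sum),
       drug = if (is.null(df$drug_code)) numeric(nrow(df)) else
         as.numeric(df$drug_code),
       rt = as.numeric(df$rt), choice = as.integer(df$choice),
       llm = as.numeric(df$ll_magnitude), lld = as.numeric(df$ll_delay),
       ssm = as.numeric(df$ss_magnitude), ssd = as.numeric(df$ss_delay),
       n = nrow(df))
}

.sorted_groups <- function(drug) {
  u <- unique(as.character(drug))
  if (is.factor(drug)) return(levels(drug)[levels(drug) %in% u])
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' Fit a hierarchical Bayesian drift diffusion model
#'
#' Estimates all coefficients of a DDM variant by blockwise adaptive
#' Metropolis-within-Gibbs sampling over the exact Wiener first-passage
#' likelihood. Individual-level coefficients for participant *i* are normally
#' distributed around the group-level mean with an effect-specific SD
#' \eqn{\lambda} (between-subject designs: around the participant's own dose
#' group's mean, with \eqn{\lambda} shared across groups). Group means have
#' conjugate Gibbs updates; \eqn{\lambda}s are updated by log-scale random
#' walk; individual coefficient blocks (drift, bias, threshold/NDT) are
#' updated jointly per participant with proposal scales adapted during
#' warmup. Positivity and admissibility constraints (threshold, non-decision
#' time, drift saturation bound, discount weight, bias inside (0.02, 0.98))
#' are enforced by rejection so coefficients keep their natural scale.
#'
#' The deviance (-2 log-likelihood) is tracked for every retained draw, so
#' [compute_dic()] needs no re-computation; convergence is assessed by
#' rank-normalized split R-hat (pass: all below 1.01) on group-level draws.
#'
#' @param data an `itc_data` dataset; trimmed and standardized data are
#'   expected ([trim_rts()], [standardize_attributes()]); attributes are
#'   standardized automatically (with a message) when missing.
#' @param variant a [ddm_variant()] or its name (`"ddm1"` ... `"ddm6"`).
#' @param prior a [ddm_prior()].
#' @param chains number of MCMC chains (default 2).
#' @param iter total iterations per chain (default 20,000).
#' @param warmup adaptation iterations discarded from the front (default
#'   `iter / 2`).
#' @param thin keep every `thin`-th post-warmup draw (default 5).
#' @param seed RNG seed; chains receive derived seeds and are jittered
#'   independently.
#' @param full_scale if `TRUE`, use the full-scale settings (2 x 500,000
#'   iterations, 450,000 warmup, thin 5 for within-subject data; 2 x 100,000
#'   / 50,000 / thin 5 for between-subject data). Expect hours of runtime.
#' @param store_individual keep the individual-level draws (needed only for
#'   draw-resolved posterior predictive checks; posterior means are always
#'   kept).
#' @param progress print a progress line per 1000 iterations.
#' @return an object of class `ddm_fit`; see [summary.ddm_fit()],
#'   [coef.ddm_fit()], [compute_dic()], [posterior_predictive_check()].
#' @export
fit_ddm <- function(data, variant = "ddm1", prior = ddm_prior(), chains = 2,
                    iter = 20000, warmup = NULL, thin = 5, seed = NULL,
                    full_scale = FALSE, store_individual = FALSE,
                    progress = FALSE) {
  stopifnot(inherits(data, "itc_data"))
  if (is.character(variant)) variant <- ddm_variant(variant)
  design <- attr(data, "study_design")
  if (is.null(attr(data, "standardization"))) {
    message("fit_ddm: standardizing attribute regressors (pooled z-scores)")
    data <- standardize_attributes(data)
  }
  if (full_scale) {
    iter <- if (design == "within") 500000L else 100000L
    warmup <- if (design == "within") 450000L else 50000L
    thin <- 5L
  }
  if (is.null(warmup)) warmup <- floor(iter / 2)
  stopifnot(iter > warmup, warmup >= 10, thin >= 1, chains >= 1)
  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(2^31 - 2, chains)

  pt <- variant_params(variant, design)
  pn <- pt$name
  npar <- length(pn)
  blocks <- split(seq_len(npar), pt$block)

  pid <- factor(data$participant_id, levels = unique(data$participant_id))
  P <- nlevels(pid)
  glev <- if (design == "between") .sorted_groups(data$drug) else "all"
  G <- length(glev)
  gidx <- if (design == "between") {
    match(tapply(as.character(data$drug), pid, function(d) d[1])[levels(pid)],
          glev)
  } else rep(1L, P)

  trials_list <- lapply(split(seq_len(nrow(data)), pid), function(ix) {
    .trial_bundle(as.data.frame(data)[ix, , drop = FALSE])
  })
  llfun <- .make_fast_loglik(variant, pn)

  nkeep <- floor((iter - warmup) / thin)
  mu_names <- if (G > 1) {
    as.vector(outer(pn, glev, function(a, g) paste(a, g, sep = ":")))
  } else pn

  run_chain <- function(ch) {
    set.seed(chain_seeds[ch])
    # --- initialization (group means at reference values, jittered) ---
    mu <- matrix(0, npar, G, dimnames = list(pn, glev))
    if ("v_max" %in% pn) mu["v_max", ] <- 1
    if ("z_int" %in% pn) mu["z_int", ] <- 0.5
    if ("a_int" %in% pn) mu["a_int", ] <- 2
    if ("t_int" %in% pn) mu["t_int", ] <- 0.5 * min(data$rt)
    if ("k_disc" %in% pn) mu["k_disc", ] <- 0.01
    mu <- mu + matrix(stats::rnorm(npar * G, 0, 0.05), npar, G)
    if ("v_max" %in% pn) mu["v_max", ] <- pmax(mu["v_max", ], 0.3)
    if ("k_disc" %in% pn) mu["k_disc", ] <- pmax(mu["k_disc", ], 1e-3)
    lam <- rep(1, npar)
    names(lam) <- pn

    b <- matrix(0, P, npar, dimnames = list(NULL, pn))
    ll <- numeric(P)
    for (i in seq_len(P)) {
      bi <- mu[, gidx[i]]
      if ("t_int" %in% pn) bi["t_int"] <- 0.45 * min(trials_list[[i]]$rt)
      jit <- stats::rnorm(npar, 0, 0.01)
      jit[grepl("^k_disc", pn)] <- 0
      cand <- bi + jit
      if (!is.finite(llfun(cand, trials_list[[i]]))) {
        cand <- bi  # re-initialize without jitter
        if (!is.finite(llfun(cand, trials_list[[i]]))) {
          stop("likelihood is -Inf at initialization for participant ",
               levels(pid)[i], "; check RT support and variant")
        }
        message("fit_ddm: re-initialized participant ", levels(pid)[i],
                " at unjittered start values")
      }
      b[i, ] <- cand
      ll[i] <- llfun(cand, trials_list[[i]])
    }

    # blockwise proposal machinery: per participant and block a Cholesky
    # factor of the running posterior covariance (adaptive Metropolis) plus
    # a log step-size tuned to ~30% acceptance
    psd0 <- rep(0.1, npar)
    psd0[grepl("^z_", pn)] <- 0.02
    psd0[pn %in% c("t_int", "t_drug", "t_diff", "t_diff_drug")] <- 0.05
    psd0[grepl("^k_disc", pn)] <- 0.01
    cholL <- lapply(seq_len(P), function(i) {
      lapply(blocks, function(ids) diag(psd0[ids], length(ids)))
    })
    ls <- matrix(0, P, length(blocks))
    for (bl in seq_along(blocks)) {
      ls[, bl] <- log(2.38 / sqrt(length(blocks[[bl]])))
    }
    lsl <- rep(log(0.25), npar)  # lambda proposal log-scales
    # multivariate Welford accumulators (per participant) for the
    # covariance refreshment
    wn <- 0L
    wmean <- matrix(0, P, npar)
    wm2 <- lapply(seq_len(P), function(i) matrix(0, npar, npar))

    mu_draws <- matrix(NA_real_, nkeep, npar * G,
                       dimnames = list(NULL, mu_names))
    lam_draws <- matrix(NA_real_, nkeep, npar, dimnames = list(NULL, pn))
    dev_draws <- numeric(nkeep)
    ind_draws <- if (store_individual) array(NA_real_, c(nkeep, P, npar))
                 else NULL
    ind_sum <- matrix(0, P, npar, dimnames = list(NULL, pn))
    kept <- 0L
    pm_sd <- prior$group_mean_sd

    rnorm_ <- stats::rnorm
    runif_ <- stats::runif
    lshape <- prior$lambda_shape
    lrate <- prior$lambda_rate
    mu_g <- t(mu[, gidx, drop = FALSE])  # P x npar view of each member's mean

    for (t in seq_len(iter)) {
      gam <- if (t <= warmup) min(0.05, 3 / sqrt(t)) else 0
      # individual-level blocks (adaptive random-walk Metropolis)
      for (i in seq_len(P)) {
        tr <- trials_list[[i]]
        g <- gidx[i]
        for (bl in seq_along(blocks)) {
          ids <- blocks[[bl]]
          prop <- b[i, ]
          prop[ids] <- prop[ids] +
            exp(ls[i, bl]) * drop(cholL[[i]][[bl]] %*% rnorm_(length(ids)))
          llp <- llfun(prop, tr)
          acc <- FALSE
          if (is.finite(llp)) {
            dev_new <- (prop[ids] - mu[ids, g]) / lam[ids]
            dev_old <- (b[i, ids] - mu[ids, g]) / lam[ids]
            lacc <- llp - ll[i] -
              0.5 * (sum(dev_new * dev_new) - sum(dev_old * dev_old))
            acc <- log(runif_(1)) < lacc
          }
          if (acc) {
            b[i, ] <- prop
            ll[i] <- llp
          }
          if (gam > 0) ls[i, bl] <- ls[i, bl] + gam * ((acc * 1) - 0.3)
        }
      }
      # group-level means: conjugate normal updates
      for (g in seq_len(G)) {
        members <- which(gidx == g)
        nG <- length(members)
        sb <- if (nG == 1) b[members, ] else colSums(b[members, , drop = FALSE])
        post_prec <- 1 / pm_sd^2 + nG / lam^2
        post_mean <- (sb / lam^2) / post_prec
        mu[, g] <- rnorm_(npar, post_mean, sqrt(1 / post_prec))
      }
      mu_g <- t(mu[, gidx, drop = FALSE])
      # lambda: log-scale random walk with Gamma(shape, rate) prior on the SD
      lam_prop <- lam * exp(exp(lsl) * rnorm_(npar))
      for (k in seq_len(npar)) {
        lam_new <- lam_prop[k]
        ss <- sum((b[, k] - mu_g[, k])^2)
        lp_new <- (lshape - 1) * log(lam_new) - lrate * lam_new -
          P * log(lam_new) - ss / (2 * lam_new^2)
        lp_old <- (lshape - 1) * log(lam[k]) - lrate * lam[k] -
          P * log(lam[k]) - ss / (2 * lam[k]^2)
        acc <- log(runif_(1)) < lp_new - lp_old + log(lam_new / lam[k])
        if (acc) lam[k] <- lam_new
        if (gam > 0) lsl[k] <- lsl[k] + gam * ((acc * 1) - 0.44)
      }
      # proposal-covariance refreshment from the running posterior scatter
      if (t <= warmup && t > 100) {
        wn <- wn + 1L
        for (i in seq_len(P)) {
          d <- b[i, ] - wmean[i, ]
          wmean[i, ] <- wmean[i, ] + d / wn
          wm2[[i]] <- wm2[[i]] + tcrossprod(d, b[i, ] - wmean[i, ])
        }
        if (wn > 200 && t %% 250 == 0) {
          for (i in seq_len(P)) {
            for (bl in seq_along(blocks)) {
              ids <- blocks[[bl]]
              Sig <- wm2[[i]][ids, ids, drop = FALSE] / (wn - 1)
              diag(Sig) <- diag(Sig) + 1e-8
              L <- tryCatch(t(chol(Sig)),
                            error = function(e)
                              diag(pmax(sqrt(diag(Sig)), 1e-4),
                                   length(ids)))
              cholL[[i]][[bl]] <- L
            }
          }
        }
      }
      if (t > warmup && (t - warmup) %% thin == 0) {
        kept <- kept + 1L
        mu_draws[kept, ] <- as.vector(mu)
        lam_draws[kept, ] <- lam
        dev_draws[kept] <- -2 * sum(ll)
        ind_sum <- ind_sum + b
        if (store_individual) ind_draws[kept, , ] <- b
      }
      if (progress && t %% 1000 == 0) {
        message("chain ", ch, ": iteration ", t, "/", iter)
      }
    }
    list(mu = mu_draws, lambda = lam_draws, deviance = dev_draws,
         ind_mean = ind_sum / kept, ind = ind_draws)
  }

  res <- lapply(seq_len(chains), run_chain)

  rh <- rep(NA_real_, npar * G + npar)
  names(rh) <- c(mu_names, paste0("lambda_", pn))
  if (chains >= 2 || nkeep >= 4) {
    for (j in seq_len(npar * G)) {
      rh[j] <- rhat(sapply(res, function(r) r$mu[, j]))
    }
    for (j in seq_len(npar)) {
      rh[npar * G + j] <- rhat(sapply(res, function(r) r$lambda[, j]))
    }
  }
  converged <- all(rh < 1.01, na.rm = TRUE)
  if (!converged) {
    warning("fit_ddm: max split R-hat ", round(max(rh, na.rm = TRUE), 3),
            " >= 1.01; treat estimates with caution", call. = FALSE)
  }

  ind_mean <- Reduce(`+`, lapply(res, `[[`, "ind_mean")) / chains
  structure(list(
    variant = variant, study_design = design, prior = prior, data = data,
    param_table = pt, groups = glev, group_index = gidx,
    participants = levels(pid),
    mcmc = list(chains = chains, iter = iter, warmup = warmup, thin = thin,
                seed = seed, chain_seeds = chain_seeds, nkeep = nkeep),
    draws = list(mu = lapply(res, `[[`, "mu"),
                 lambda = lapply(res, `[[`, "lambda"),
                 deviance = lapply(res, `[[`, "deviance"),
                 ind = lapply(res, `[[`, "ind")),
    ind_mean = ind_mean, rhat = rh, converged = converged
  ), class = "ddm_fit")
}

# pooled draws of one group-level column across chains
.mu_draws <- function(fit, column) {
  unlist(lapply(fit$draws$mu, function(m) m[, column]), use.names = FALSE)
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("Hierarchical Bayesian DDM fit (", x$variant$variant_id, ", ",
      x$study_design, "-subject)\n", sep = "")
  cat("  ", length(x$participants), " participants, ", nrow(x$data),
      " trials; ", x$mcmc$chains, " chains x ", x$mcmc$iter,
      " iterations (warmup ", x$mcmc$warmup, ", thin ", x$mcmc$thin, ")\n",
      sep = "")
  cat("  convergence: max split R-hat = ",
      round(max(x$rhat, na.rm = TRUE), 4),
      if (x$converged) " (all < 1.01)" else " (NOT converged)", "\n",
      sep = "")
  cat("Group-level posterior means:\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Summarize a hierarchical DDM fit
#'
#' Posterior summary of all group-level effects and between-participant SDs:
#' posterior mean, SD of the posterior (the SEM of the group-level mean),
#' 95% HDI bounds, split R-hat and effective sample size.
#'
#' @param object a `ddm_fit`.
#' @param mass HDI mass (default 0.95).
#' @param ... unused.
#' @return data.frame, one row per parameter.
#' @export
summary.ddm_fit <- function(object, mass = 0.95, ...) {
  cols <- colnames(object$draws$mu[[1]])
  lcols <- colnames(object$draws$lambda[[1]])
  all_names <- c(cols, paste0("lambda_", lcols))
  get_draws <- function(j) {
    if (j <= length(cols)) .mu_draws(object, cols[j])
    else unlist(lapply(object$draws$lambda,
                       function(m) m[, j - length(cols)]), use.names = FALSE)
  }
  ess <- function(j) {
    ml <- coda::mcmc.list(lapply(
      if (j <= length(cols)) lapply(object$draws$mu, function(m) m[, j])
      else lapply(object$draws$lambda, function(m) m[, j - length(cols)]),
      coda::mcmc))
    as.numeric(coda::effectiveSize(ml))
  }
  out <- data.frame(parameter = all_names, mean = NA_real_, sem = NA_real_,
                    hdi_lower = NA_real_, hdi_upper = NA_real_,
                    rhat = unname(object$rhat[all_names]), ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(all_names)) {
    d <- get_draws(j)
    h <- compute_hdi(d, mass)
    out$mean[j] <- mean(d)
    out$sem[j] <- stats::sd(d)
    out$hdi_lower[j] <- h[1]
    out$hdi_upper[j] <- h[2]
    out$ess[j] <- ess(j)
  }
  out
}

#' Extract posterior-mean coefficients
#'
#' @param object a `ddm_fit`.
#' @param level `"group"` for group-level posterior means (named vector),
#'   `"individual"` for the participants x coefficients matrix of
#'   individual-level posterior means.
#' @param ... unused.
#' @export
coef.ddm_fit <- function(object, level = c("group", "individual"), ...) {
  level <- match.arg(level)
  if (level == "individual") {
    m <- object$ind_mean
    rownames(m) <- object$participants
    return(m)
  }
  cols <- colnames(object$draws$mu[[1]])
  vapply(cols, function(cl) mean(.mu_draws(object, cl)), numeric(1))
}

#' Posterior predictive simulation from a fitted DDM
#'
#' Regenerates every trial's (choice, rt) from the individual-level
#' posterior-mean coefficients (each simulated trial inherits its real
#' trial's covariates).
#'
#' @param object a `ddm_fit`.
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a list of `nsim` data.frames with columns `choice` and `rt`, in
#'   the row order of the fitted dataset.
#' @export
simulate.ddm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  wp <- .fit_trial_params(object)
  sim <- cpp_rwfpt(wp$v, wp$a, wp$z, wp$tau, as.integer(nsim))
  # cpp_rwfpt is parameter-row-major: nsim consecutive draws per trial
  lapply(seq_len(nsim), function(s) {
    sel <- seq(s, by = nsim, length.out = nrow(wp))
    data.frame(choice = sim$choice[sel], rt = sim$rt[sel])
  })
}

# trial-level Wiener parameters at the individual posterior means
.fit_trial_params <- function(fit, ind = NULL) {
  data <- fit$data
  if (is.null(ind)) ind <- fit$ind_mean
  pid <- factor(data$participant_id, levels = fit$participants)
  out <- data.frame(v = numeric(nrow(data)), a = NA_real_, z = NA_real_,
                    tau = NA_real_)
  keep_cols <- intersect(
    c("magnitude_diff", "delay_diff", "delay_sum", "drug_code", "rt",
      "choice", "ll_magnitude", "ll_delay", "ss_magnitude", "ss_delay"),
    names(data))
  for (i in seq_along(fit$participants)) {
    ix <- which(pid == fit$participants[i])
    tr <- as.data.frame(data)[ix, keep_cols, drop = FALSE]
    m <- .map_trials_core(ind[i, ], tr, fit$variant)
    if (!m$ok) {
      stop("posterior-mean coefficients are inadmissible for participant ",
           fit$participants[i])
    }
    out$v[ix] <- m$v
    out$a[ix] <- rep_len(m$a, length(ix))
    out$z[ix] <- rep_len(m$z, length(ix))
    out$tau[ix] <- rep_len(m$tau, length(ix))
  }
  out
}

#' Predicted choice probabilities
#'
#' Closed-form probability of choosing the larger-later option per trial,
#' evaluated at the individual-level posterior-mean coefficients.
#'
#' @param object a `ddm_fit`.
#' @param ... unused.
#' @return numeric vector of P(LL) per trial of the fitted dataset.
#' @export
predict.ddm_fit <- function(object, ...) {
  wp <- .fit_trial_params(object)
  upper_choice_probability(wp$v, wp$a, wp$z)
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D} with \eqn{p_D = \bar D - D(\bar\theta)}: mean
#' posterior deviance plus the effective number of parameters, where
#' \eqn{D(\bar\theta)} is the deviance at the posterior mean of the
#' individual-level coefficients. Lower is better.
#'
#' @param fit a `ddm_fit`, or a numeric vector of posterior deviance draws.
#' @param deviance_at_mean when `fit` is a numeric vector: the deviance
#'   evaluated at the posterior mean of the parameters.
#' @return list with components `DIC`, `Dbar`, `Dhat`, `pD`.
#' @export
compute_dic <- function(fit, deviance_at_mean = NULL) {
  if (is.numeric(fit)) {
    stopifnot(!is.null(deviance_at_mean))
    Dbar <- mean(fit)
    Dhat <- deviance_at_mean
  } else {
    stopifnot(inherits(fit, "ddm_fit"))
    Dbar <- mean(unlist(fit$draws$deviance))
    wp <- .fit_trial_params(fit)
    llhat <- cpp_wfpt_loglik(fit$data$rt, as.integer(fit$data$choice),
                             wp$v, wp$a, wp$z, wp$tau)
    if (!is.finite(llhat)) {
      stop("likelihood undefined at the posterior mean; cannot compute DIC")
    }
    Dhat <- -2 * llhat
  }
  pD <- Dbar - Dhat
  list(DIC = Dbar + pD, Dbar = Dbar, Dhat = Dhat, pD = pD)
}

#' Posterior contrast between two dose groups
#'
#' Elementwise difference of the posterior draws of one group-level effect
#' between two between-subject groups, with mean and HDI — the group-
#' difference test for between-subject designs.
#'
#' @param fit a `ddm_fit` of a between-subject dataset.
#' @param effect coefficient name (e.g. `"v_mag"`).
#' @param groups length-2 character vector of group labels
#'   (`groups[1] - groups[2]`).
#' @param mass HDI mass.
#' @return list with `mean`, `hdi`, and the difference `draws`.
#' @export
contrast_conditions <- function(fit, effect, groups, mass = 0.95) {
  stopifnot(inherits(fit, "ddm_fit"), length(groups) == 2)
  if (length(fit$groups) < 2) {
    stop("contrast_conditions requires a between-subject fit with >= 2 groups")
  }
  cols <- paste(effect, groups, sep = ":")
  have <- colnames(fit$draws$mu[[1]])
  if (!all(cols %in% have)) {
    stop("unknown effect/group combination: ",
         paste(setdiff(cols, have), collapse = ", "))
  }
  d <- .mu_draws(fit, cols[1]) - .mu_draws(fit, cols[2])
  list(mean = mean(d), hdi = compute_hdi(d, mass), draws = d)
}

#' Serialize posterior summaries
#'
#' Writes the group-level posterior summary ([summary.ddm_fit()] layout:
#' per-effect mean, SEM, HDI bounds, diagnostics) as JSON or CSV.
#'
#' @param fit a `ddm_fit`.
#' @param path output path; format chosen by extension (`.json` or `.csv`).
#' @param draws_path optional path for the full group-level draws
#'   (chain-stacked CSV: one column per effect plus a `chain` column).
#' @export
write_posterior_summary <- function(fit, path, draws_path = NULL) {
  s <- summary(fit)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(s, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  } else {
    utils::write.csv(s, path, row.names = FALSE)
  }
  if (!is.null(draws_path)) {
    dr <- do.call(rbind, lapply(seq_along(fit$draws$mu), function(ch) {
      cbind(as.data.frame(fit$draws$mu[[ch]]),
            as.data.frame(fit$draws$lambda[[ch]]) |>
              stats::setNames(paste0("lambda_",
                                     colnames(fit$draws$lambda[[ch]]))),
            chain = ch)
    }))
    utils::write.csv(dr, draws_path, row.names = FALSE)
  }
  invisible(path)
}
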