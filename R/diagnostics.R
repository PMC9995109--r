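#' Posterior predictive check with quantile binning
#'
#' Simulates `n_sims` replicate datasets from a fitted model (each simulated
#' trial inherits the covariates of its real trial; choices and RTs are
#' regenerated from the individual-level posterior-mean coefficients, or from
#' random posterior draws when `use = "draws"` and individual draws were
#' stored), bins trials into quantiles of the magnitude difference and, in a
#' second binning, of the delay difference, and compares observed and
#' simulated mean RTs per bin and drug condition.
#'
#' Bins are sample-quantile bins on the pooled trials: trials are sorted by
#' the binning attribute (ties broken by trial order, a stable sort) and cut
#' into `n_bins` near-equal groups (sizes differ by at most 1), so the
#' binning partitions the retained trials exactly.
#'
#' The model-fit score is the mean over all (attribute x bin x condition)
#' cells of the squared difference between the observed mean RT and the
#' simulation-averaged mean RT; smaller is better.
#'
#' @param fit a `ddm_fit`.
#' @param n_sims number of simulated datasets (default 1000).
#' @param n_bins number of quantile bins (default 5, quintiles).
#' @param use `"individual_mean"` (default) or `"draws"` (requires
#'   `store_individual = TRUE` at fit time).
#' @param seed optional RNG seed.
#' @return object of class `ddm_ppc`: list with `cells` (long data.frame:
#'   attribute, bin, condition, n, observed, simulated, envelope bounds) and
#'   `score`.
#' @export
posterior_predictive_check <- function(fit, n_sims = 1000, n_bins = 5,
                                       use = c("individual_mean", "draws"),
                                       seed = NULL) {
  stopifnot(inherits(fit, "ddm_fit"), n_sims >= 1)
  use <- match.arg(use)
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data
  n <- nrow(data)
  cond <- if (fit$study_design == "within") {
    ifelse(data$drug_code > 0, "drug", "reference")
  } else as.character(data$drug)

  # simulated RT matrix: trials x sims
  if (use == "individual_mean") {
    wp <- .fit_trial_params(fit)
    sim <- cpp_rwfpt(wp$v, wp$a, wp$z, wp$tau, as.integer(n_sims))
    rt_sim <- matrix(sim$rt, nrow = n, ncol = n_sims, byrow = TRUE)
  } else {
    if (is.null(fit$draws$ind[[1]])) {
      stop("draw-resolved PPC requires store_individual = TRUE at fit time")
    }
    rt_sim <- matrix(NA_real_, n, n_sims)
    nk <- dim(fit$draws$ind[[1]])[1]
    for (s in seq_len(n_sims)) {
      ch <- sample(length(fit$draws$ind), 1)
      it <- sample(nk, 1)
      ind <- fit$draws$ind[[ch]][it, , , drop = TRUE]
      dimnames(ind) <- list(NULL, fit$param_table$name)
      wp <- .fit_trial_params(fit, ind = ind)
      sim <- cpp_rwfpt(wp$v, wp$a, wp$z, wp$tau, 1L)
      rt_sim[, s] <- sim$rt
    }
  }

  quantile_bins <- function(x) {
    ord <- order(x, seq_along(x))  # stable tie-break on trial order
    bin <- integer(length(x))
    bin[ord] <- ceiling(seq_along(ord) * n_bins / length(ord))
    bin
  }
  cells <- NULL
  for (attr_name in c("magnitude_diff", "delay_diff")) {
    bin <- quantile_bins(data[[attr_name]])
    for (cd in unique(cond)) {
      for (bb in seq_len(n_bins)) {
        sel <- bin == bb & cond == cd
        if (!any(sel)) next
        sim_means <- colMeans(rt_sim[sel, , drop = FALSE])
        cells <- rbind(cells, data.frame(
          attribute = attr_name, bin = bb, condition = cd, n = sum(sel),
          observed = mean(data$rt[sel]), simulated = mean(sim_means),
          sim_lower = unname(stats::quantile(sim_means, 0.025)),
          sim_upper = unname(stats::quantile(sim_means, 0.975)),
          stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(cells = cells,
                 score = mean((cells$observed - cells$simulated)^2),
                 n_sims = n_sims, n_bins = n_bins, use = use),
            class = "ddm_ppc")
}

#' @export
print.ddm_ppc <- function(x, ...) {
  cat("Posterior predictive check (", x$n_sims, " simulations, ",
      x$n_bins, " bins)\n", sep = "")
  cat("  observed-vs-simulated mean-RT squared-difference score: ",
      round(x$score, 4), "\n", sep = "")
  inside <- with(x$cells, observed >= sim_lower & observed <= sim_upper)
  cat("  observed bin means inside the simulated 95% envelope: ",
      sum(inside), "/", nrow(x$cells), "\n", sep = "")
  invisible(x)
}

#' Parameter recovery analysis
#'
#' Simulates `n_datasets` full datasets from the fitted model's group-level
#' posterior means and between-participant SDs (reusing the fitted dataset's
#' design: same participants, covariates and conditions), refits the same
#' variant to each, and reports, for every group-level effect, whether the
#' refit posterior mean lies inside the original fit's 95% HDI.
#'
#' @param fit a `ddm_fit`.
#' @param n_datasets number of simulated datasets (default 10; 0 returns an
#'   empty report).
#' @param seed optional RNG seed (the report is deterministic given the
#'   seed).
#' @param chains,iter,warmup,thin MCMC settings for the refits (defaults:
#'   the original fit's settings).
#' @return object of class `ddm_recovery`: list with `recovered` (logical
#'   matrix, datasets x parameters), `refit_means`, `original_hdi`, `truth`.
#' @export
parameter_recovery <- function(fit, n_datasets = 10, seed = NULL,
                               chains = NULL, iter = NULL, warmup = NULL,
                               thin = NULL) {
  stopifnot(inherits(fit, "ddm_fit"))
  if (!is.null(seed)) set.seed(seed)
  chains <- chains %||% fit$mcmc$chains
  iter <- iter %||% fit$mcmc$iter
  warmup <- warmup %||% fit$mcmc$warmup
  thin <- thin %||% fit$mcmc$thin
  cols <- colnames(fit$draws$mu[[1]])
  hdi <- t(vapply(cols, function(cl) compute_hdi(.mu_draws(fit, cl)),
                  numeric(2)))
  truth <- coef(fit)
  lam_mean <- colMeans(do.call(rbind, fit$draws$lambda))
  recovered <- matrix(NA, n_datasets, length(cols),
                      dimnames = list(NULL, cols))
  refit_means <- matrix(NA_real_, n_datasets, length(cols),
                        dimnames = list(NULL, cols))
  if (n_datasets == 0) {
    return(structure(list(recovered = recovered, refit_means = refit_means,
                          original_hdi = hdi, truth = truth),
                     class = "ddm_recovery"))
  }
  pn <- fit$param_table$name
  seeds <- sample.int(2^31 - 2, n_datasets)
  for (d in seq_len(n_datasets)) {
    simdat <- .regenerate_dataset(fit, lam_mean, seed = seeds[d])
    refit <- fit_ddm(simdat, variant = fit$variant, prior = fit$prior,
                     chains = chains, iter = iter, warmup = warmup,
                     thin = thin, seed = seeds[d])
    rm <- coef(refit)
    refit_means[d, ] <- rm[cols]
    recovered[d, ] <- rm[cols] >= hdi[, 1] & rm[cols] <= hdi[, 2]
  }
  structure(list(recovered = recovered, refit_means = refit_means,
                 original_hdi = hdi, truth = truth),
            class = "ddm_recovery")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulate a dataset from a fit's group-level posterior means, reusing the
# fitted design (covariates, conditions, participants)
.regenerate_dataset <- function(fit, lam_mean, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data <- fit$data
  pn <- fit$param_table$name
  mu_hat <- coef(fit)
  pid <- factor(data$participant_id, levels = fit$participants)
  keep_cols <- intersect(
    c("magnitude_diff", "delay_diff", "delay_sum", "drug_code", "rt",
      "choice", "ll_magnitude", "ll_delay", "ss_magnitude", "ss_delay"),
    names(data))
  out <- as.data.frame(data)
  for (i in seq_along(fit$participants)) {
    ix <- which(pid == fit$participants[i])
    tr <- as.data.frame(data)[ix, keep_cols, drop = FALSE]
    tr$rt <- rep(Inf, nrow(tr))
    g <- fit$group_index[i]
    mu_i <- if (length(fit$groups) > 1) {
      mu_hat[paste(pn, fit$groups[g], sep = ":")]
    } else mu_hat[pn]
    for (attempt in seq_len(1000)) {
      bi <- stats::rnorm(length(pn), mu_i, lam_mean[pn])
      names(bi) <- pn
      m <- .map_trials_core(bi, tr, fit$variant)
      if (m$ok) break
      if (attempt == 1000) stop("no admissible coefficients for recovery sim")
    }
    sim <- cpp_rwfpt(as.numeric(m$v), rep_len(as.numeric(m$a), nrow(tr)),
                     rep_len(as.numeric(m$z), nrow(tr)),
                     rep_len(as.numeric(m$tau), nrow(tr)), 1L)
    out$choice[ix] <- sim$choice
    out$rt[ix] <- sim$rt
  }
  newdat <- itc_data(out, study_design = fit$study_design)
  attr(newdat, "standardization") <- attr(data, "standardization")
  newdat
}

#' @export
print.ddm_recovery <- function(x, ...) {
  nd <- nrow(x$recovered)
  cat("Parameter recovery report (", nd, " simulated datasets)\n", sep = "")
  if (nd > 0 && !all(is.na(x$recovered))) {
    frac <- colMeans(x$recovered)
    cat("  fraction of refits inside the original 95% HDI, per parameter:\n")
    print(round(frac, 2))
  } else {
    cat("  (empty report)\n")
  }
  invisible(x)
}

#' Apply drug shifts to a coefficient set
#'
#' Collapses each `*_drug` shift into its base coefficient (the drug-
#' condition effective coefficients) and drops the shift terms.
#'
#' @param coefs named coefficient vector with `*_drug` entries.
#' @return named vector of effective coefficients under the drug condition.
#' @export
apply_drug_effects <- function(coefs) {
  base <- names(coefs)[!grepl("_drug$", names(coefs))]
  out <- coefs[base]
  for (nm in base) {
    # intercept-style parameters (z_int, a_int, t_int) name their shift
    # after the parameter family: z_drug, a_drug, t_drug
    shift <- paste0(sub("_int$", "", nm), "_drug")
    if (shift %in% names(coefs)) out[nm] <- out[nm] + coefs[[shift]]
  }
  out
}

#' Choice-probability surface over the attribute plane
#'
#' Computes P(choose LL) on a grid of standardized magnitude-difference x
#' delay-difference values under two coefficient sets (e.g. placebo and
#' drug), via the closed-form absorption probability (and optionally by
#' simulation), together with their difference — the surface showing where
#' in attribute space a manipulation increases or decreases LL choices.
#'
#' @param coefs_a,coefs_b effective coefficient vectors for the two
#'   conditions (see [apply_drug_effects()]); evaluated with a drug code of
#'   0, i.e. each set fully describes its condition.
#' @param magnitude_diff,delay_diff grid values (standardized units).
#' @param variant a [ddm_variant()] or name (attribute-difference variants).
#' @param n_sims if > 0, also estimate each cell's P(LL) from `n_sims`
#'   simulated trials.
#' @param seed optional RNG seed (used when `n_sims > 0`).
#' @return long data.frame: one row per grid cell with `p_ll_a`, `p_ll_b`,
#'   `difference` (b - a) and, if simulated, `p_sim_a`, `p_sim_b`.
#' @export
choice_probability_surface <- function(coefs_a, coefs_b,
                                       magnitude_diff = seq(-2, 2, 0.25),
                                       delay_diff = seq(-2, 2, 0.25),
                                       variant = "ddm1", n_sims = 0,
                                       seed = NULL) {
  if (is.character(variant)) variant <- ddm_variant(variant)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(magnitude_diff = magnitude_diff,
                      delay_diff = delay_diff)
  grid$delay_sum <- 0
  grid$drug_code <- 0
  grid$rt <- Inf
  p <- list()
  for (side in c("a", "b")) {
    coefs <- if (side == "a") coefs_a else coefs_b
    m <- .map_trials_core(coefs, grid, variant)
    if (!m$ok) stop("coefficient set '", side, "' maps outside the ",
                    "admissible region on this grid")
    p[[side]] <- upper_choice_probability(m$v, rep_len(m$a, nrow(grid)),
                                          rep_len(m$z, nrow(grid)))
    if (n_sims > 0) {
      sim <- cpp_rwfpt(as.numeric(m$v), rep_len(as.numeric(m$a), nrow(grid)),
                       rep_len(as.numeric(m$z), nrow(grid)),
                       rep_len(as.numeric(m$tau), nrow(grid)),
                       as.integer(n_sims))
      p[[paste0("sim_", side)]] <-
        rowMeans(matrix(sim$choice, nrow(grid), n_sims, byrow = TRUE))
    }
  }
  out <- data.frame(grid[c("magnitude_diff", "delay_diff")],
                    p_ll_a = p$a, p_ll_b = p$b, difference = p$b - p$a)
  if (n_sims > 0) {
    out$p_sim_a <- p$sim_a
    out$p_sim_b <- p$sim_b
  }
  out
}

#' Prior-predictive admissibility rate
#'
#' Samples group-level effects from their priors, individual coefficients
#' around them, and maps them onto a dataset's trials, reporting the
#' fraction of draws that land in the admissible diffusion-parameter region
#' (the sampler's rejection rule). A sanity check that the priors and the
#' constraint region are compatible.
#'
#' @param data standardized `itc_data`.
#' @param variant a [ddm_variant()] or name.
#' @param prior a [ddm_prior()].
#' @param n number of prior draws.
#' @param seed optional RNG seed.
#' @return admissible fraction in `[0, 1]` (also reported via `message`).
#' @export
prior_predictive_check <- function(data, variant = "ddm1",
                                   prior = ddm_prior(), n = 1000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(variant)) variant <- ddm_variant(variant)
  design <- attr(data, "study_design")
  pn <- variant_params(variant, design)$name
  pid <- data$participant_id == data$participant_id[1]
  tr <- as.data.frame(data)[pid, , drop = FALSE]
  ok <- logical(n)
  for (s in seq_len(n)) {
    mu <- stats::rnorm(length(pn), 0, prior$group_mean_sd)
    lam <- stats::rgamma(length(pn), prior$lambda_shape, prior$lambda_rate)
    bi <- stats::rnorm(length(pn), mu, lam)
    names(bi) <- pn
    ok[s] <- isTRUE(.map_trials_core(bi, tr, variant)$ok)
  }
  rate <- mean(ok)
  message("prior predictive admissibility: ", round(100 * rate, 1),
          "% of ", n, " draws")
  rate
}
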