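#' Task templates for the two pharmacological study designs
#'
#' Describes the stimulus structure of the two intertemporal-choice tasks the
#' package emulates:
#'
#' * `"d2"` — within-subject D2-antagonist design: 56 participants x 2
#'   sessions (placebo / amisulpride), 20 trials per session; SS option
#'   magnitude 5-250 currency units at 0-30 days, LL option 15-300 units at
#'   3-90 days, sampled uniformly (whole units / whole days) subject to
#'   LL magnitude > SS magnitude and LL delay > SS delay.
#' * `"d1"` — between-subject D1-agonist design: 120 participants in four
#'   dose groups (0, 6, 15, 30 mg), one session of 54 trials; SS magnitude
#'   0-16 in steps of 2 at delay 0, LL fixed at 16 units with delay level
#'   0-180 days, full factorial (each SS magnitude x LL delay combination
#'   exactly once) in randomized order.
#'
#' @param study `"d2"` or `"d1"`.
#' @param n_participants,n_trials optional overrides of the study's
#'   participant count and trials per session.
#' @return an object of class `task_template`.
#' @export
task_template <- function(study = c("d2", "d1"), n_participants = NULL,
                          n_trials = NULL) {
  study <- match.arg(study)
  tpl <- if (study == "d2") {
    list(study = "d2", design = "within",
         ss_magnitude = c(5, 250), ss_delay = c(0, 30),
         ll_magnitude = c(15, 300), ll_delay = c(3, 90),
         n_trials = 20, n_participants = 56, n_sessions = 2,
         drug_labels = c("placebo", "amisulpride"))
  } else {
    list(study = "d1", design = "between",
         ss_magnitude = seq(0, 16, by = 2), ss_delay = 0,
         ll_magnitude = 16, ll_delay = c(0, 7, 30, 60, 90, 180),
         n_trials = 54, n_participants = 120, n_sessions = 1,
         drug_labels = c("0", "6", "15", "30"))
  }
  if (!is.null(n_participants)) tpl$n_participants <- n_participants
  if (!is.null(n_trials)) tpl$n_trials <- n_trials
  structure(tpl, class = "task_template")
}

#' Generate a task design (trials without choices or response times)
#'
#' Samples the option attributes for every participant and session of a
#' template. Within-subject templates randomize the drug/placebo session
#' order per participant; between-subject templates assign participants to
#' dose groups in equal blocks.
#'
#' @param template a [task_template()].
#' @param seed optional RNG seed (same seed, same design).
#' @return data.frame of trials with columns `participant_id`, `session_id`,
#'   `drug`, `ss_magnitude`, `ss_delay`, `ll_magnitude`, `ll_delay`,
#'   `trial_index`.
#' @export
generate_design <- function(template = task_template("d2"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(template, "task_template"))
  rows <- list()
  if (template$study == "d2") {
    for (p in seq_len(template$n_participants)) {
      order_drug <- sample(template$drug_labels)
      for (s in seq_len(template$n_sessions)) {
        n <- template$n_trials
        ssm <- ssd <- llm <- lld <- numeric(n)
        for (t in seq_len(n)) {
          repeat {
            m1 <- sample(template$ss_magnitude[1]:template$ss_magnitude[2], 1)
            m2 <- sample(template$ll_magnitude[1]:template$ll_magnitude[2], 1)
            d1 <- sample(template$ss_delay[1]:template$ss_delay[2], 1)
            d2 <- sample(template$ll_delay[1]:template$ll_delay[2], 1)
            if (m2 > m1 && d2 > d1) break
          }
          ssm[t] <- m1; llm[t] <- m2; ssd[t] <- d1; lld[t] <- d2
        }
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = sprintf("p%02d", p), session_id = s,
          drug = order_drug[s], ss_magnitude = ssm, ss_delay = ssd,
          ll_magnitude = llm, ll_delay = lld, trial_index = seq_len(n),
          stringsAsFactors = FALSE)
      }
    }
  } else {
    cells <- expand.grid(ss_magnitude = template$ss_magnitude,
                         ll_delay = template$ll_delay)
    groups <- rep(template$drug_labels,
                  length.out = template$n_participants)
    for (p in seq_len(template$n_participants)) {
      ord <- sample(nrow(cells))
      # replicate the factorial to honor a trial-count override
      ord <- rep(ord, length.out = template$n_trials)
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = sprintf("p%03d", p), session_id = 1,
        drug = groups[p], ss_magnitude = cells$ss_magnitude[ord],
        ss_delay = 0, ll_magnitude = template$ll_magnitude,
        ll_delay = cells$ll_delay[ord],
        trial_index = seq_len(template$n_trials), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reference group-level coefficients for the synthetic generator
#'
#' Group-level posterior-mean coefficients of the winning attribute-
#' difference model fitted to the within-subject D2 dataset, used as the
#' generator's default ground truth: magnitude and delay drift weights (and
#' their drug shifts), the drift saturation bound, starting-bias intercept
#' and delay-difference slope, decision threshold and non-decision time.
#'
#' For the between-subject D1 design (`study = "d1"`), the placebo-group
#' posterior means of the same model fitted to that study are returned
#' (between-subject naming, no drug-shift terms).
#'
#' @param study `"d2"` (within-subject defaults) or `"d1"`.
#' @return named numeric vector of coefficients.
#' @export
reference_coefs <- function(study = c("d2", "d1")) {
  study <- match.arg(study)
  if (study == "d2") {
    c(v_mag = 2.41, v_mag_drug = 0.81, v_delay = -1.13, v_delay_drug = -0.30,
      v_max = 0.80, v_max_drug = 0.00,
      z_int = 0.57, z_drug = -0.04, z_delay = -0.02, z_delay_drug = 0.02,
      a_int = 3.96, a_drug = 0.17, t_int = 1.48, t_drug = -0.10)
  } else {
    c(v_mag = 0.86, v_delay = -0.42, v_max = 1.72,
      z_int = 0.59, z_delay = 0.00, a_int = 2.82, t_int = 0.85)
  }
}

#' Default between-participant SDs for the synthetic generator
#'
#' Heterogeneity SDs (\eqn{\lambda}) used when generating individual
#' coefficients. Chosen so that essentially all simulated individuals stay
#' inside the admissible parameter region (positive threshold, saturation
#' bound and non-decision time; bias within (0.02, 0.98)) while giving
#' between-participant spread comparable to the group-level effect sizes.
#'
#' @return named numeric vector covering all coefficient names used by the
#'   six variants.
#' @export
reference_lambda <- function() {
  c(v_mag = 1.0, v_mag_drug = 0.5, v_delay = 0.5, v_delay_drug = 0.3,
    v_max = 0.2, v_max_drug = 0.1,
    z_int = 0.05, z_drug = 0.03, z_delay = 0.01, z_delay_drug = 0.01,
    z_dsum = 0.01, z_dsum_drug = 0.01,
    a_int = 0.6, a_drug = 0.3, t_int = 0.3, t_drug = 0.1,
    k_disc = 0.01, k_disc_drug = 0.005, t_diff = 0.1, t_diff_drug = 0.05)
}

# add standardized regressor columns to a design/trial frame
.add_design_columns <- function(df, design, drug_reference) {
  df$magnitude_diff_raw <- df$ll_magnitude - df$ss_magnitude
  df$delay_diff_raw <- df$ll_delay - df$ss_delay
  df$magnitude_sum_raw <- df$ll_magnitude + df$ss_magnitude
  df$delay_sum_raw <- df$ll_delay + df$ss_delay
  for (nm in c("magnitude_diff", "delay_diff", "magnitude_sum",
               "delay_sum")) {
    r <- df[[paste0(nm, "_raw")]]
    df[[nm]] <- (r - mean(r)) / stats::sd(r)
  }
  df$drug_code <- if (design == "within") {
    as.numeric(as.character(df$drug) != drug_reference)
  } else 0
  df
}

#' Generate a full synthetic behavioral dataset from a DDM variant
#'
#' Draws individual-level coefficients around the group-level truth
#' (\eqn{b_i \sim N(\mu, \lambda)}, resampled into the admissible region),
#' maps every design trial onto Wiener parameters through the variant, and
#' simulates choices and response times with the exact first-passage
#' sampler. The ground truth is returned alongside the data, so parameter
#' recovery can be scored.
#'
#' For between-subject templates, `true_coefs` may be a list of per-group
#' coefficient vectors (names = dose labels); a single vector is recycled to
#' all groups.
#'
#' @param template a [task_template()].
#' @param true_coefs group-level coefficients (default [reference_coefs()]).
#' @param lambda between-participant SDs (default [reference_lambda()];
#'   use 0 for identical participants).
#' @param variant a [ddm_variant()] or name; the time-varying variant is not
#'   supported as a generator (its drift is conditioned on the realized RT).
#' @param seed optional RNG seed.
#' @return list of class `synthetic_itc` with elements `data` (an
#'   [itc_data()] with standardized regressors), and `truth`
#'   (`coefs`, `lambda`, matrix `individual` of the coefficients actually
#'   drawn).
#' @export
generate_dataset <- function(template = task_template("d2"),
                             true_coefs = reference_coefs(),
                             lambda = reference_lambda(),
                             variant = "ddm1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(variant)) variant <- ddm_variant(variant)
  if (variant$drift_mode == "time_varying") {
    stop("generate_dataset does not support the time-varying variant; ",
         "its drift is defined conditionally on the observed RT")
  }
  design <- generate_design(template)
  pn <- variant_params(variant, template$design)$name
  design <- .add_design_columns(design, template$design,
                                template$drug_labels[1])
  if (!is.list(true_coefs)) {
    true_coefs <- stats::setNames(
      rep(list(true_coefs), length(template$drug_labels)),
      template$drug_labels)
  }
  lam <- rep(0, length(pn))
  names(lam) <- pn
  if (length(lambda) == 1 && is.null(names(lambda))) {
    lam[] <- lambda
  } else {
    lam[intersect(pn, names(lambda))] <-
      lambda[intersect(pn, names(lambda))]
  }

  pids <- unique(design$participant_id)
  ind <- matrix(NA_real_, length(pids), length(pn),
                dimnames = list(pids, pn))
  out <- design
  out$choice <- NA_real_
  out$rt <- NA_real_
  for (i in seq_along(pids)) {
    ix <- which(design$participant_id == pids[i])
    tr <- design[ix, , drop = FALSE]
    grp <- if (template$design == "between") as.character(tr$drug[1]) else
      names(true_coefs)[1]
    mu_i <- true_coefs[[grp]]
    mu_vec <- stats::setNames(numeric(length(pn)), pn)
    mu_vec[intersect(pn, names(mu_i))] <- mu_i[intersect(pn, names(mu_i))]
    tr$rt <- rep(Inf, nrow(tr))  # rt unknown yet; only used by ddm6 mapping
    for (attempt in seq_len(1000)) {
      bi <- stats::rnorm(length(pn), mu_vec, lam)
      names(bi) <- pn
      m <- .map_trials_core(bi, tr, variant)
      if (m$ok) break
      if (attempt == 1000) {
        stop("could not draw admissible individual coefficients; ",
             "check true_coefs/lambda")
      }
    }
    ind[i, ] <- bi
    sim <- cpp_rwfpt(as.numeric(m$v), rep_len(as.numeric(m$a), nrow(tr)),
                     rep_len(as.numeric(m$z), nrow(tr)),
                     rep_len(as.numeric(m$tau), nrow(tr)), 1L)
    out$choice[ix] <- sim$choice
    out$rt[ix] <- sim$rt
  }
  dat <- itc_data(out, study_design = template$design)
  attr(dat, "standardization") <- list(drug_reference =
                                         template$drug_labels[1])
  structure(list(data = dat,
                 truth = list(coefs = true_coefs, lambda = lam,
                              individual = ind, variant = variant)),
            class = "synthetic_itc")
}

#' @export
print.synthetic_itc <- function(x, ...) {
  cat("Synthetic dataset (", x$truth$variant$variant_id, " generator)\n",
      sep = "")
  print(x$data)
  invisible(x)
}

#' Generate choices from the hyperbolic-discounting softmax model
#'
#' Bernoulli choices with P(LL) given by the softmax of hyperbolically
#' discounted subjective values; no response times are generated (the
#' discounting model is a choice-only model).
#'
#' @param template a [task_template()].
#' @param k hyperbolic discount rate (per day, >= 0).
#' @param beta_temp softmax inverse temperature (>= 0).
#' @param seed optional RNG seed.
#' @return data.frame of design trials plus `p_ll` (generating probability)
#'   and `choice`.
#' @export
generate_discounting_dataset <- function(template = task_template("d2"),
                                         k = 0.05, beta_temp = 0.5,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(k >= 0, beta_temp >= 0)
  design <- generate_design(template)
  sv_ll <- hyperbolic_sv(design$ll_magnitude, design$ll_delay, k)
  sv_ss <- hyperbolic_sv(design$ss_magnitude, design$ss_delay, k)
  design$p_ll <- softmax_ll_probability(sv_ll, sv_ss, beta_temp)
  design$choice <- stats::rbinom(nrow(design), 1, design$p_ll)
  design
}
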