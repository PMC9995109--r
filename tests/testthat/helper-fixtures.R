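# Shared fixtures: small synthetic datasets and reduced MCMC settings used
# across test files. Everything is generated in code at test time.

small_d2 <- function(n_participants = 6, n_trials = 30, seed = 7, ...) {
  generate_dataset(task_template("d2", n_participants = n_participants,
                                 n_trials = n_trials),
                   seed = seed, ...)
}

quick_fit <- function(data, variant = "ddm1", iter = 2000, warmup = 1000,
                      seed = 1, ...) {
  suppressWarnings(fit_ddm(data, variant, chains = 2, iter = iter,
                           warmup = warmup, thin = 2, seed = seed, ...))
}

# hand-built 20-trial frame satisfying all invariants
tiny_trials <- function(n = 20) {
  set.seed(42)
  data.frame(
    participant_id = rep(c("a", "b"), each = n / 2),
    session_id = rep(1:2, n / 2),
    drug = rep(c("placebo", "amisulpride"), n / 2),
    ss_magnitude = sample(5:100, n, TRUE),
    ss_delay = sample(0:10, n, TRUE),
    ll_magnitude = sample(101:300, n, TRUE),
    ll_delay = sample(11:90, n, TRUE),
    choice = sample(0:1, n, TRUE),
    rt = round(runif(n, 1, 6), 3),
    stringsAsFactors = FALSE)
}

# 200-trial design identifying both discounting parameters: half the trials
# from the magnitude-rich within-subject task (varying delays on both
# options identify k) and half from the small-magnitude factorial task
# (near-indifference cells identify beta) — the role the original adaptive
# stimulus selection played. Replicate estimates are averaged to keep the
# check's Monte-Carlo noise below the tolerance being asserted.
recovery_battery <- function(seed, k = 0.05, beta_temp = 0.5) {
  d2 <- generate_discounting_dataset(
    task_template("d2", n_participants = 1, n_trials = 100),
    k = k, beta_temp = beta_temp, seed = seed)
  d2 <- d2[d2$session_id == 1, ]
  d1 <- generate_discounting_dataset(
    task_template("d1", n_participants = 1, n_trials = 100),
    k = k, beta_temp = beta_temp, seed = seed + 50)
  d1$participant_id <- d2$participant_id[1]
  d1$session_id <- 1
  cols <- c("participant_id", "session_id", "ss_magnitude", "ss_delay",
            "ll_magnitude", "ll_delay", "choice")
  rbind(d2[cols], d1[cols])
}
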