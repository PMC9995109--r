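# Synthetic task generators: design structure, reproducibility, and the
# statistical signatures of generated behavior.

test_that("the factorial between-subject design presents each combination
           exactly once per participant", {
  des <- generate_design(task_template("d1", n_participants = 4), seed = 1)
  for (p in unique(des$participant_id)) {
    sub <- des[des$participant_id == p, ]
    expect_equal(nrow(sub), 54)
    combos <- paste(sub$ss_magnitude, sub$ll_delay)
    expect_equal(length(unique(combos)), 54)
    expect_setequal(unique(sub$ss_magnitude), seq(0, 16, 2))
    expect_true(all(sub$ll_magnitude == 16))
  }
  # equal dose-group sizes
  grp <- table(tapply(des$drug, des$participant_id, `[`, 1))
  expect_true(all(grp == 1))
})

test_that("within-subject designs stay inside the stated attribute ranges
           with the strict dominance constraints", {
  des <- generate_design(task_template("d2", n_participants = 10), seed = 2)
  expect_equal(nrow(des), 10 * 2 * 20)
  expect_true(all(des$ss_magnitude >= 5 & des$ss_magnitude <= 250))
  expect_true(all(des$ll_magnitude >= 15 & des$ll_magnitude <= 300))
  expect_true(all(des$ss_delay >= 0 & des$ss_delay <= 30))
  expect_true(all(des$ll_delay >= 3 & des$ll_delay <= 90))
  expect_true(all(des$ll_magnitude > des$ss_magnitude))
  expect_true(all(des$ll_delay > des$ss_delay))
  expect_true(all(des$ss_magnitude == round(des$ss_magnitude)))
  # each participant sees both conditions, one per session
  cond <- tapply(des$drug, des$participant_id,
                 function(d) length(unique(d)))
  expect_true(all(cond == 2))
})

test_that("generation is reproducible given the seed", {
  d1 <- generate_design(task_template("d2", n_participants = 3), seed = 5)
  d2 <- generate_design(task_template("d2", n_participants = 3), seed = 5)
  expect_identical(d1, d2)
  s1 <- small_d2(n_participants = 3, n_trials = 10, seed = 6)
  s2 <- small_d2(n_participants = 3, n_trials = 10, seed = 6)
  expect_identical(s1$data$rt, s2$data$rt)
  expect_identical(s1$data$choice, s2$data$choice)
})

test_that("synthetic datasets pass the data-model validation unchanged", {
  syn <- small_d2(n_participants = 5, n_trials = 20, seed = 7)
  revalidated <- itc_data(as.data.frame(syn$data), "within")
  expect_equal(nrow(revalidated), nrow(syn$data))
  expect_true(all(syn$data$rt > 0))
})

test_that("zero heterogeneity makes all participants share the generating
           coefficients", {
  syn <- generate_dataset(task_template("d2", n_participants = 4,
                                        n_trials = 10),
                          lambda = 0, seed = 8)
  ind <- syn$truth$individual
  expect_true(all(apply(ind, 2, function(x) max(x) - min(x)) == 0))
})

test_that("a driftless unbiased generator yields an even choice split", {
  cf <- reference_coefs()
  cf[c("v_mag", "v_mag_drug", "v_delay", "v_delay_drug")] <- 0
  cf[c("z_int", "z_drug", "z_delay", "z_delay_drug")] <- c(0.5, 0, 0, 0)
  syn <- generate_dataset(task_template("d2", n_participants = 12,
                                        n_trials = 60),
                          true_coefs = cf, lambda = 0, seed = 9)
  p <- mean(syn$data$choice)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / nrow(syn$data)))
})

test_that("under the reference coefficients LL choices rise across
           magnitude-difference quintiles", {
  syn <- generate_dataset(task_template("d2", n_participants = 30,
                                        n_trials = 60),
                          lambda = 0, seed = 10)
  d <- syn$data
  q <- cut(d$magnitude_diff,
           breaks = stats::quantile(d$magnitude_diff, seq(0, 1, 0.2)),
           include.lowest = TRUE, labels = FALSE)
  frac <- tapply(d$choice, q, mean)
  expect_gt(frac[5], frac[1] + 0.2)
  expect_true(all(diff(frac) > -0.05))  # monotone up to binomial noise
})

test_that("discounting generator: temperature zero gives coin-flip choices,
           large k makes discounted dominance decisive", {
  tpl <- task_template("d2", n_participants = 5, n_trials = 40)
  d0 <- generate_discounting_dataset(tpl, k = 0.05, beta_temp = 0,
                                     seed = 11)
  expect_true(all(d0$p_ll == 0.5))
  expect_lt(abs(mean(d0$choice) - 0.5), 3 * sqrt(0.25 / nrow(d0)))
  # strong discounting + steep softmax: choices follow the sign of the
  # discounted-value difference computed in closed form
  dk <- generate_discounting_dataset(tpl, k = 5, beta_temp = 50, seed = 12)
  sv_ll <- hyperbolic_sv(dk$ll_magnitude, dk$ll_delay, 5)
  sv_ss <- hyperbolic_sv(dk$ss_magnitude, dk$ss_delay, 5)
  decisive <- abs(sv_ll - sv_ss) > 0.2
  expect_true(all(dk$choice[decisive] == as.integer(sv_ll > sv_ss)[decisive]))
  d1 <- generate_discounting_dataset(tpl, seed = 13)
  d2 <- generate_discounting_dataset(tpl, seed = 13)
  expect_identical(d1$choice, d2$choice)
})

test_that("time-varying variant is rejected as a generator", {
  expect_error(generate_dataset(task_template("d2", n_participants = 2,
                                              n_trials = 5),
                                variant = "ddm6", seed = 1),
               "time-varying")
})
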