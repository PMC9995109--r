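# Variant layer: the inclusion matrix, the parameter-mapping regressions and
# their published-coefficient spot values, and agreement between the fast
# sampler likelihood and the reference mapping.

test_that("the variant inclusion matrix reproduces the published structure", {
  m <- variant_matrix()
  expected <- rbind(
    "drift:delay_diff"     = c(T, T, F, T, T, T),
    "drift:magnitude_diff" = c(T, T, F, T, F, T),
    "drift:v_max"          = c(T, T, T, T, T, T),
    "threshold:intercept"  = c(T, T, T, T, T, T),
    "bias:intercept"       = c(T, F, T, T, T, T),
    "bias:delay_diff"      = c(T, F, T, F, T, F),
    "bias:delay_sum"       = c(F, F, F, T, F, F),
    "ndt:intercept"        = c(T, T, T, T, T, T),
    "ndt:tau_diff"         = c(F, F, F, F, F, T))
  colnames(expected) <- paste0("ddm", 1:6)
  expect_identical(m, expected)
  # drug shifts exist for every included parameter in the within design
  # (the bias intercept's shift is the drug main effect, named z_drug)
  for (vn in paste0("ddm", 1:6)) {
    pn <- variant_params(vn, "within")$name
    base <- pn[!grepl("_drug$", pn)]
    # intercept-style parameters name their shift X_drug, not X_int_drug
    shifts <- paste0(sub("_int$", "", base), "_drug")
    expect_setequal(shifts, pn[grepl("_drug$", pn)])
    expect_false(any(grepl("_drug$",
                           variant_params(vn, "between")$name)))
  }
})

test_that("linear drift regression reproduces coefficient arithmetic", {
  cf <- c(v_mag = 2.41, v_delay = -1.13, v_mag_drug = 0.81,
          v_delay_drug = -0.30)
  expect_equal(drift_linear(0, 0, 0, cf), 0)
  expect_equal(drift_linear(1, 0, 0, cf), 2.41)
  expect_equal(drift_linear(1, 1, 0, cf), 2.41 - 1.13)
  expect_equal(drift_linear(1, 1, 1, cf), 2.41 + 0.81 - 1.13 - 0.30)
  expect_equal(drift_linear(0, 0, 0, numeric(0)), 0)
})

test_that("sigmoidal link: midpoint, saturation, odd symmetry, bound", {
  expect_identical(sigmoid_link(0, 0.8), 0)
  expect_equal(sigmoid_link(50, 0.8), 0.8, tolerance = 1e-12)
  expect_equal(sigmoid_link(-50, 0.8), -0.8, tolerance = 1e-12)
  expect_equal(sigmoid_link(2.41, 0.80), 0.80 * tanh(1.205),
               tolerance = 1e-12)
  vp <- seq(-6, 6, 0.1)
  y <- sigmoid_link(vp, 1.3)
  expect_equal(y, -sigmoid_link(-vp, 1.3), tolerance = 1e-12)  # odd
  expect_true(all(abs(y) < 1.3))                               # bounded
  expect_true(all(diff(y) > 0))                                # monotone
  expect_error(sigmoid_link(1, 0), "v_max")
})

test_that("bias regression reproduces published starting-bias values", {
  cf <- c(z_int = 0.57, z_drug = -0.04, z_delay = -0.02,
          z_delay_drug = 0.02)
  v1 <- ddm_variant("ddm1")
  expect_equal(bias_regression(0, 0, cf, v1), 0.57)
  expect_equal(bias_regression(0, 1, cf, v1), 0.53)
  expect_equal(bias_regression(1, 0, cf, v1), 0.55)  # +1 SD delay_diff
  # fixed-bias variant pins the starting point at 0.5
  expect_equal(bias_regression(2, 1, cf, ddm_variant("ddm2")), 0.5)
})

test_that("threshold and non-decision-time regressions", {
  cf <- c(a_int = 3.96, a_drug = 0.17, t_int = 1.48, t_drug = -0.10)
  p0 <- threshold_and_ndt(0, cf)
  p1 <- threshold_and_ndt(1, cf)
  expect_equal(p0$a, 3.96)
  expect_equal(p0$tau, 1.48)
  expect_equal(p1$a, 4.13)
  expect_equal(p1$tau, 1.38)
})

test_that("discounted-value drift: no-discounting limit and arithmetic", {
  expect_equal(drift_discounted_value(250, 60, 100, 0, 0), 150)
  expect_equal(drift_discounted_value(250, 60, 100, 0, 0.1),
               250 / 7 - 100, tolerance = 1e-12)
  expect_equal(drift_discounted_value(80, 30, 80, 30, 0.05), 0)
  expect_error(drift_discounted_value(250, 60, 100, 0, -0.1), ">= 0")
})

test_that("discounted-value drift weakly decreases in k when the SS option
           is immediate", {
  # with a delayed SS option the value *difference* need not be monotone in
  # k (the SS term can decay faster); for an immediate SS it always is
  ks <- seq(0, 0.5, 0.02)
  for (pair in list(c(250, 60, 100), c(16, 30, 8), c(120, 10, 110))) {
    vp <- drift_discounted_value(pair[1], pair[2], pair[3], 0, ks)
    expect_true(all(diff(vp) <= 1e-12))
  }
})

test_that("time-varying drift: synchronous, early-only, and duration-weighted
           branches", {
  expect_equal(drift_time_varying(2, -1, 0, 2, 0.5), 1)  # tau_diff = 0
  # decision ends inside the asynchrony window: early attribute only
  expect_equal(drift_time_varying(2, -1, 0.5, 0.8, 0.5), -1)
  expect_equal(drift_time_varying(2, -1, -0.5, 0.8, 0.5), 2)
  # tau_diff = +0.5, decision time 1.0: (0.5 * D + 0.5 * (M + D)) / 1.0
  expect_equal(drift_time_varying(2, -1, 0.5, 1.5, 0.5),
               (0.5 * -1 + 0.5 * 1) / 1.0)
  expect_error(drift_time_varying(1, 1, 0.2, 0.4, 0.5), "rt > tau")
})

test_that("map_trials composes the variant equations per trial", {
  tr <- data.frame(magnitude_diff = c(0, 2, -2), delay_diff = c(0, 1, -1),
                   delay_sum = c(0, 1, 2), drug_code = c(0, 1, 0),
                   rt = c(3, 4, 5))
  cf <- reference_coefs()
  wp <- map_trials(cf, tr, "ddm1")
  # covariate-free placebo trial: v = 0, z = intercept, a and tau intercepts
  expect_equal(wp$v[1], 0)
  expect_equal(wp$z[1], 0.57)
  expect_equal(wp$a[1], 3.96)
  expect_equal(wp$tau[1], 1.48)
  # large positive magnitude difference saturates near +v_max
  tr_big <- data.frame(magnitude_diff = 4, delay_diff = 0, delay_sum = 0,
                       drug_code = 0, rt = 3)
  expect_gt(map_trials(cf, tr_big, "ddm1")$v, 0.99 * 0.80)
  # fixed-bias variant: z = 0.5 everywhere
  cf2 <- cf[variant_params("ddm2")$name]
  expect_equal(map_trials(cf2, tr, "ddm2")$z, rep(0.5, 3))
  # attribute-free drift: v = 0 for every trial
  cf3 <- cf[variant_params("ddm3")$name]
  expect_equal(map_trials(cf3, tr, "ddm3")$v, rep(0, 3))
  # inadmissible parameters are rejected
  cfbad <- cf
  cfbad["a_int"] <- -1
  expect_error(map_trials(cfbad, tr, "ddm1"), "inadmissible")
})

test_that("linear-link ablation removes the saturation bound", {
  v_lin <- ddm_variant("ddm1", linear_link = TRUE)
  expect_false("v_max" %in% variant_params(v_lin)$name)
  tr <- data.frame(magnitude_diff = c(1, 3), delay_diff = 0, delay_sum = 0,
                   drug_code = 0, rt = 5)
  cf <- reference_coefs()
  cf <- cf[setdiff(names(cf), c("v_max", "v_max_drug"))]
  wp <- map_trials(cf, tr, v_lin)
  expect_equal(wp$v, c(2.41, 7.23))  # unbounded: v = v' itself
  wp_sig <- map_trials(reference_coefs(), tr, "ddm1")
  expect_true(all(abs(wp_sig$v) < 0.80))
})

test_that("fast sampler likelihood agrees exactly with the reference mapping
           for every variant", {
  syn <- small_d2(n_participants = 2, n_trials = 25, seed = 3)
  d <- as.data.frame(syn$data)
  tr <- d[d$participant_id == d$participant_id[1], ]
  trb <- itcddm:::.trial_bundle(tr)
  set.seed(99)
  for (vn in paste0("ddm", 1:6)) {
    v <- ddm_variant(vn)
    pn <- variant_params(v, "within")$name
    f <- itcddm:::.make_fast_loglik(v, pn)
    for (r in 1:25) {
      b <- stats::setNames(stats::rnorm(length(pn), 0, 0.4), pn)
      b["v_max"] <- abs(b["v_max"]) + 0.2
      b["a_int"] <- abs(b["a_int"]) + 1.5
      b["t_int"] <- runif(1, 0, 1)
      if ("z_int" %in% pn) b["z_int"] <- runif(1, 0.3, 0.7)
      if ("k_disc" %in% pn) b[c("k_disc", "k_disc_drug")] <- c(abs(b["k_disc"]) / 10, 0)
      m <- itcddm:::.map_trials_core(b, tr, v)
      ref <- if (!m$ok) -Inf else
        wiener_loglik(tr$rt, tr$choice, m$v, rep_len(m$a, nrow(tr)),
                      rep_len(m$z, nrow(tr)), rep_len(m$tau, nrow(tr)))
      expect_equal(f(b, trb), ref, tolerance = 1e-12)
    }
  }
})
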