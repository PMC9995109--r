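# Hierarchical inference: HDI and R-hat utilities, DIC arithmetic, group
# contrasts, and sampler behavior on small synthetic datasets.

test_that("compute_hdi: degenerate, uniform and normal reference cases", {
  expect_equal(compute_hdi(rep(3.2, 500)), c(3.2, 3.2))
  set.seed(1)
  u <- runif(1e6)
  h <- compute_hdi(u)
  expect_equal(h[2] - h[1], 0.95, tolerance = 0.01)
  z <- rnorm(1e6)
  hz <- compute_hdi(z)
  expect_equal(hz, c(-1.96, 1.96), tolerance = 0.02, ignore_attr = TRUE)
  expect_error(compute_hdi(numeric(0)), "no finite draws")
})

test_that("hdi is the shortest interval for a skewed sample", {
  set.seed(2)
  x <- rexp(2e5)
  h <- compute_hdi(x, 0.9)
  # for an exponential the 90% HDI starts at 0
  expect_lt(h[1], 0.02)
  expect_equal(h[2], stats::qexp(0.9), tolerance = 0.03)
})

test_that("rank-normalized split R-hat separates mixed from unmixed chains", {
  set.seed(3)
  good <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(rhat(good), 1.01)
  bad <- cbind(rnorm(2000), rnorm(2000) + 3)
  expect_gt(rhat(bad), 1.5)
  # a within-chain trend is caught by splitting
  drift <- cbind(seq(0, 1, length.out = 2000) + rnorm(2000, 0, 0.1),
                 seq(0, 1, length.out = 2000) + rnorm(2000, 0, 0.1))
  expect_gt(rhat(drift), 1.1)
})

test_that("DIC arithmetic on toy deviance draws", {
  r <- compute_dic(c(10, 12), deviance_at_mean = 10)
  expect_equal(r$Dbar, 11)
  expect_equal(r$pD, 1)
  expect_equal(r$DIC, 12)
  # constant deviance: no effective parameters
  r2 <- compute_dic(rep(44.4, 50), deviance_at_mean = 44.4)
  expect_equal(r2$pD, 0)
  expect_equal(r2$DIC, 44.4)
})

test_that("posterior contrasts: identical groups give zero, shifted normals
           their mean difference", {
  set.seed(4)
  x <- rnorm(5000)
  fake <- structure(list(
    draws = list(mu = list(cbind("v_mag:a" = x, "v_mag:b" = x,
                                 "v_mag:c" = x + 1))),
    groups = c("a", "b", "c")), class = "ddm_fit")
  same <- contrast_conditions(fake, "v_mag", c("a", "b"))
  expect_true(all(same$draws == 0))
  diff1 <- contrast_conditions(fake, "v_mag", c("a", "c"))
  expect_equal(diff1$mean, -1, tolerance = 1e-12)
  expect_error(contrast_conditions(fake, "nope", c("a", "b")), "unknown")
})

test_that("the sampler recovers strongly identified group-level parameters on
           a small within-subject dataset", {
  lam <- reference_lambda()
  lam[] <- 0.15
  syn <- generate_dataset(task_template("d2", n_participants = 10,
                                        n_trials = 60),
                          lambda = lam, seed = 51)
  fit <- quick_fit(syn$data, iter = 6000, warmup = 3000, seed = 52)
  s <- summary(fit)
  truth <- reference_coefs()
  # scale-type parameters (bias, threshold, non-decision time) are sharply
  # identified even at this size
  for (par in c("z_int", "a_int", "t_int")) {
    row <- s[s$parameter == par, ]
    expect_lt(abs(row$mean - truth[par]), max(0.35, 4 * row$sem))
  }
  # drift weights shrink toward the prior at 10 participants (saturation
  # limits per-trial information); signs and rough magnitude must recover
  expect_gt(s$mean[s$parameter == "v_mag"], 0.8)
  expect_lt(s$mean[s$parameter == "v_delay"], -0.4)
  expect_true(all(is.finite(unlist(fit$draws$deviance))))
  # deviance-based DIC is computable and finite
  expect_true(is.finite(compute_dic(fit)$DIC))
})

test_that("posterior means are stable across chain seeds within Monte-Carlo
           error", {
  syn <- small_d2(n_participants = 5, n_trials = 30, seed = 61)
  f1 <- quick_fit(syn$data, iter = 4000, warmup = 2000, seed = 100)
  f2 <- quick_fit(syn$data, iter = 4000, warmup = 2000, seed = 200)
  s1 <- summary(f1)
  s2 <- summary(f2)
  for (par in c("v_mag", "z_int", "a_int", "t_int")) {
    r1 <- s1[s1$parameter == par, ]
    r2 <- s2[s2$parameter == par, ]
    mcse <- sqrt(r1$sem^2 / max(r1$ess, 4) + r2$sem^2 / max(r2$ess, 4))
    expect_lt(abs(r1$mean - r2$mean), max(3 * mcse, 0.5 * r1$sem))
  }
})

test_that("between-subject fits estimate separate group means and expose
           contrasts", {
  syn <- generate_dataset(task_template("d1", n_participants = 8),
                          true_coefs = reference_coefs("d1"), seed = 71)
  fit <- quick_fit(syn$data, iter = 3000, warmup = 1500, seed = 72)
  cols <- colnames(fit$draws$mu[[1]])
  pn <- variant_params("ddm1", "between")$name
  expect_setequal(cols, as.vector(outer(pn, c("0", "6", "15", "30"),
                                        paste, sep = ":")))
  ct <- contrast_conditions(fit, "v_mag", c("6", "0"))
  expect_true(ct$hdi[1] <= ct$mean && ct$mean <= ct$hdi[2])
  expect_length(ct$draws, 2 * fit$mcmc$nkeep)
})

test_that("fit summaries carry HDIs, R-hat and effective sample sizes", {
  syn <- small_d2(n_participants = 4, n_trials = 25, seed = 81)
  fit <- quick_fit(syn$data, iter = 1500, warmup = 600, seed = 82)
  s <- summary(fit)
  expect_true(all(c("mean", "sem", "hdi_lower", "hdi_upper", "rhat",
                    "ess") %in% names(s)))
  expect_true(all(s$hdi_lower <= s$mean & s$mean <= s$hdi_upper))
  expect_true(all(s$ess > 0))
  expect_equal(nrow(s), 2 * nrow(fit$param_table))
  # coef methods
  expect_length(coef(fit), nrow(fit$param_table))
  im <- coef(fit, level = "individual")
  expect_equal(dim(im), c(4, nrow(fit$param_table)))
  # posterior predictive simulate() returns one frame per replicate
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(nrow(sims[[1]]), nrow(syn$data))
  expect_true(all(sims[[1]]$rt > 0))
  # predicted choice probabilities are proper probabilities
  p <- predict(fit)
  expect_true(all(p > 0 & p < 1))
  # posterior summary serialization round-trips through JSON
  path <- tempfile(fileext = ".json")
  write_posterior_summary(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$mean, s$mean, tolerance = 1e-9)
})
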