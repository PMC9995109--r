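# Wiener first-passage engine: density normalization, closed-form absorption
# probabilities, simulator agreement, and an independent Euler-Maruyama
# oracle.

upper_mass <- function(v, a, z, rel.tol = 1e-10) {
  stats::integrate(function(t) wfpt_density(t, 1, v, a, z, 0),
                   0, Inf, rel.tol = rel.tol)$value
}
lower_mass <- function(v, a, z, rel.tol = 1e-10) {
  stats::integrate(function(t) wfpt_density(t, 0, v, a, z, 0),
                   0, Inf, rel.tol = rel.tol)$value
}

test_that("density mass equals the closed-form absorption probabilities", {
  for (v in c(-2, 0, 1)) {
    for (a in c(0.5, 2, 4)) {
      for (z in c(0.2, 0.5, 0.8)) {
        up <- upper_mass(v, a, z)
        lo <- lower_mass(v, a, z)
        expect_equal(up + lo, 1, tolerance = 1e-6)
        expect_equal(up, upper_choice_probability(v, a, z),
                     tolerance = 1e-6)
      }
    }
  }
  # v = 1, a = 2, z = 0.5: absorption probability ~ 0.8808
  expect_equal(upper_choice_probability(1, 2, 0.5),
               (1 - exp(-2)) / (1 - exp(-4)), tolerance = 1e-12)
  expect_equal(upper_choice_probability(1, 2, 0.5), 0.8808, tolerance = 1e-4)
})

test_that("choice probability limits: zero drift gives z, strong drift 1", {
  expect_identical(upper_choice_probability(0, 2, 0.37), 0.37)
  expect_equal(upper_choice_probability(100, 2, 0.5), 1, tolerance = 1e-12)
  expect_lt(upper_choice_probability(-100, 2, 0.5), 1e-30)
})

test_that("reflection symmetry: upper density equals mirrored lower", {
  ts <- c(0.05, 0.3, 1, 3, 10)
  for (v in c(-1.5, 0.4)) {
    for (z in c(0.3, 0.6)) {
      expect_equal(wfpt_density(ts, 1, v, 2.5, z, 0),
                   wfpt_density(ts, 0, -v, 2.5, 1 - z, 0),
                   tolerance = 1e-10)
    }
  }
})

test_that("density is zero at or before the non-decision time, never negative", {
  expect_identical(wfpt_density(c(0.1, 0.3), 1, 1, 2, 0.5, tau = 0.3),
                   c(0, 0))
  tt <- seq(0.01, 20, length.out = 500)
  expect_true(all(wfpt_density(tt, 1, -2, 3, 0.7, 0) >= 0))
  expect_error(wfpt_density(1, 1, 1, -1, 0.5, 0), "must be > 0")
  expect_error(wfpt_density(1, 1, 1, 2, 1.2, 0), "\\(0, 1\\)")
  expect_error(wfpt_density(1, 1, 1, 2, 0.5, -1), ">= 0")
})

test_that("simulator matches the closed-form choice probability and
           zero-drift mean first-passage time", {
  set.seed(1)
  n <- 50000
  s <- simulate_wiener(v = 1, a = 2, z = 0.5, tau = 0.3, nrep = n)
  p <- upper_choice_probability(1, 2, 0.5)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(s$choice) - p), 3 * se)
  expect_true(all(s$rt > 0.3))

  s0 <- simulate_wiener(v = 0, a = 2, z = 0.5, tau = 0, nrep = n)
  # zero-drift mean decision time: a^2 z (1 - z) = 1.0 s
  expect_lt(abs(mean(s0$rt) - 1.0) - 3 * stats::sd(s0$rt) / sqrt(n), 0)

  set.seed(9)
  sbig <- simulate_wiener(v = 50, a = 2, z = 0.5, nrep = 10000)
  expect_gte(mean(sbig$choice), 0.999)
})

test_that("simulation is reproducible given the RNG state", {
  set.seed(123)
  s1 <- simulate_wiener(v = c(0.5, -1), a = 2, z = 0.4, tau = 0.2, nrep = 5)
  set.seed(123)
  s2 <- simulate_wiener(v = c(0.5, -1), a = 2, z = 0.4, tau = 0.2, nrep = 5)
  expect_identical(s1, s2)
})

test_that("simulated RT distribution matches the density (inverse-CDF vs
           numerically integrated CDF)", {
  for (par in list(c(v = 1, a = 2, z = 0.5), c(v = -0.5, a = 3, z = 0.3),
                   c(v = 0, a = 1, z = 0.6))) {
    set.seed(11)
    n <- 20000
    s <- simulate_wiener(par["v"], par["a"], par["z"], nrep = n)
    up <- s$rt[s$choice == 1]
    pu <- upper_choice_probability(par["v"], par["a"], par["z"])
    # conditional CDF of the upper-boundary decision time on a grid
    grid <- seq(1e-4, max(up) * 1.05, length.out = 4000)
    dens <- wfpt_density(grid, 1, par["v"], par["a"], par["z"], 0)
    cdf <- cumsum(c(0, diff(grid) * (dens[-1] + dens[-length(dens)]) / 2))
    cdf_fun <- stats::approxfun(grid, pmin(cdf / pu, 1), yleft = 0,
                                yright = 1)
    ks <- suppressWarnings(stats::ks.test(up, cdf_fun))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("simulator agrees with an independent Euler-Maruyama oracle", {
  # brute-force path simulation, dt = 1e-3, as an implementation-independent
  # reference for choice fraction and RT quantiles
  set.seed(5)
  v <- 1; a <- 2; z <- 0.5
  n <- 8000
  dt <- 1e-3
  x <- rep(z * a, n)
  t_hit <- rep(NA_real_, n)
  hit_up <- rep(NA, n)
  alive <- seq_len(n)
  step <- 0L
  while (length(alive) && step < 60000L) {
    step <- step + 1L
    x[alive] <- x[alive] + v * dt + sqrt(dt) * stats::rnorm(length(alive))
    done_up <- alive[x[alive] >= a]
    done_lo <- alive[x[alive] <= 0]
    t_hit[c(done_up, done_lo)] <- step * dt
    hit_up[done_up] <- TRUE
    hit_up[done_lo] <- FALSE
    alive <- setdiff(alive, c(done_up, done_lo))
  }
  keep <- !is.na(hit_up)
  set.seed(6)
  s <- simulate_wiener(v, a, z, nrep = n)
  p_em <- mean(hit_up[keep])
  p_pkg <- mean(s$choice)
  expect_lt(abs(p_em - p_pkg), 4 * sqrt(0.11 / n) * sqrt(2))
  q_em <- stats::quantile(t_hit[keep & hit_up], c(0.25, 0.5, 0.75))
  q_pkg <- stats::quantile(s$rt[s$choice == 1], c(0.25, 0.5, 0.75))
  expect_equal(unname(q_em), unname(q_pkg), tolerance = 0.08)
})

test_that("dataset log-likelihood is the sum of trial log densities", {
  set.seed(2)
  rt <- runif(10, 0.5, 3)
  ch <- sample(0:1, 10, TRUE)
  v <- rnorm(10); a <- runif(10, 1, 3); z <- runif(10, 0.3, 0.7)
  ll <- wiener_loglik(rt, ch, v, a, z, 0.1)
  brute <- sum(log(wfpt_density(rt, ch, v, a, z, 0.1)))
  expect_equal(ll, brute, tolerance = 1e-12)
  # single trial: identity
  expect_equal(wiener_loglik(rt[1], ch[1], v[1], a[1], z[1], 0.1),
               log(wfpt_density(rt[1], ch[1], v[1], a[1], z[1], 0.1)))
  # support violation: any rt <= tau gives -Inf
  expect_identical(wiener_loglik(c(1, 0.05), c(1, 0), 1, 2, 0.5, 0.1), -Inf)
  expect_error(wiener_loglik(rt, ch[1:5], v, a, z, 0.1), "equal length")
})
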