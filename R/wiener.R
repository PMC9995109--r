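#' @useDynLib itcddm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.check_wiener <- function(v, a, z, tau) {
  if (anyNA(c(v, a, z, tau))) stop("Wiener parameters must not contain NA")
  if (any(a <= 0)) stop("boundary separation 'a' must be > 0")
  if (any(z <= 0 | z >= 1)) stop("relative starting point 'z' must lie in (0, 1)")
  if (any(tau < 0)) stop("non-decision time 'tau' must be >= 0")
  invisible(TRUE)
}

.recycle <- function(n, ...) {
  args <- list(...)
  lens <- vapply(args, length, 1L)
  if (any(lens != 1L & lens != n)) {
    stop("parameter vectors must have length 1 or length ", n)
  }
  lapply(args, rep_len, n)
}

#' Wiener first-passage time density
#'
#' Defective density of the first passage through the upper (`choice = 1`) or
#' lower (`choice = 0`) boundary of a two-boundary Wiener diffusion with unit
#' diffusion coefficient, evaluated at response time `rt` (the density is in
#' decision time `rt - tau`; it is 0 for `rt <= tau`). The upper boundary
#' is conventionally the larger-later (LL) option, so positive drift favours
#' LL choices. The density uses a small-time/large-time dual series with
#' automatic switching; truncation error is below 1e-10 on the standardized
#' density scale.
#'
#' @param rt response time(s) in seconds.
#' @param choice 1 for the upper boundary, 0 for the lower boundary.
#' @param v drift rate (signed; evidence units per second).
#' @param a boundary separation (> 0).
#' @param z relative starting point in (0, 1); 0.5 is unbiased.
#' @param tau non-decision time in seconds (>= 0).
#' @param log if `TRUE`, return the log density.
#' @return numeric vector of (log) densities, one per trial.
#' @examples
#' # unbiased, driftless diffusion: each boundary absorbs half the mass
#' integrate(function(t) wfpt_density(t, 1, v = 0, a = 2, z = 0.5, tau = 0),
#'           0, Inf)
#' @export
wfpt_density <- function(rt, choice, v, a, z, tau = 0, log = FALSE) {
  .check_wiener(v, a, z, tau)
  if (!all(choice %in% c(0, 1))) stop("'choice' must be 0 or 1")
  n <- max(length(rt), length(choice), length(v), length(a), length(z),
           length(tau))
  p <- .recycle(n, rt = rt, choice = choice, v = v, a = a, z = z, tau = tau)
  cpp_dwfpt(as.numeric(p$rt), as.integer(p$choice), as.numeric(p$v),
            as.numeric(p$a), as.numeric(p$z), as.numeric(p$tau), log)
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form probability that the diffusion is absorbed at the upper (LL)
#' boundary, \eqn{(1 - e^{-2 v a z}) / (1 - e^{-2 v a})}, with the zero-drift
#' limit \eqn{z} taken analytically.
#'
#' @inheritParams wfpt_density
#' @return numeric vector of probabilities.
#' @examples
#' upper_choice_probability(v = 1, a = 2, z = 0.5)  # ~0.8808
#' @export
upper_choice_probability <- function(v, a, z) {
  .check_wiener(v, a, z, 0)
  n <- max(length(v), length(a), length(z))
  p <- .recycle(n, v = v, a = a, z = z)
  cpp_pupper(as.numeric(p$v), as.numeric(p$a), as.numeric(p$z))
}

#' Simulate choices and response times from the Wiener diffusion
#'
#' Exact-in-distribution sampler: the absorbing boundary is drawn from the
#' closed-form absorption probability and the hitting time by inversion of the
#' numerically integrated conditional first-passage density (trapezoid rule
#' with a step adapted to the diffusion time scale, at most 0.02 s). Repeated
#' draws from the same parameter row share one integration sweep, so
#' posterior-predictive style simulation (`nrep` large) is fast.
#'
#' @inheritParams wfpt_density
#' @param nrep number of (choice, rt) draws per parameter row.
#' @return a data.frame with columns `choice` (1 = upper/LL) and `rt`
#'   (seconds, `> tau`); rows are ordered parameter-row-major
#'   (`nrep` consecutive draws per parameter row).
#' @examples
#' set.seed(1)
#' sim <- simulate_wiener(v = 1, a = 2, z = 0.5, tau = 0.3, nrep = 1000)
#' mean(sim$choice)  # close to upper_choice_probability(1, 2, 0.5)
#' @export
simulate_wiener <- function(v, a, z, tau = 0, nrep = 1) {
  .check_wiener(v, a, z, tau)
  n <- max(length(v), length(a), length(z), length(tau))
  p <- .recycle(n, v = v, a = a, z = z, tau = tau)
  res <- cpp_rwfpt(as.numeric(p$v), as.numeric(p$a), as.numeric(p$z),
                   as.numeric(p$tau), as.integer(nrep))
  data.frame(choice = res$choice, rt = res$rt)
}

#' Joint log-likelihood of a set of trials
#'
#' Sum of log first-passage densities over trials, one parameter set per
#' trial. Returns `-Inf` if any trial has `rt <= tau` (zero density).
#'
#' @inheritParams wfpt_density
#' @return a single log-likelihood value.
#' @export
wiener_loglik <- function(rt, choice, v, a, z, tau = 0) {
  .check_wiener(v, a, z, tau)
  if (!all(choice %in% c(0, 1))) stop("'choice' must be 0 or 1")
  n <- length(rt)
  if (length(choice) != n) stop("'rt' and 'choice' must have equal length")
  p <- .recycle(n, v = v, a = a, z = z, tau = tau)
  cpp_wfpt_loglik(as.numeric(rt), as.integer(choice), as.numeric(p$v),
                  as.numeric(p$a), as.numeric(p$z), as.numeric(p$tau))
}
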