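#' Highest-density interval
#'
#' Shortest interval containing a given mass of a sample, computed by the
#' sorted sliding-window method.
#'
#' @param x numeric vector of posterior draws (>= 100 recommended).
#' @param mass probability mass the interval must contain (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' compute_hdi(rnorm(1e4))  # about c(-1.96, 1.96)
#' @export
compute_hdi <- function(x, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("no finite draws")
  k <- max(1L, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

# classic potential-scale-reduction factor on an iterations x chains matrix
.rhat_basic <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  W <- mean(apply(m, 2, stats::var))
  B <- n * stats::var(colMeans(m))
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Rank-normalized split R-hat
#'
#' Gelman-Rubin convergence diagnostic with chain splitting and rank
#' normalization, taking the maximum of the bulk statistic and the
#' tail-sensitive statistic on folded draws. Values below 1.01 indicate
#' convergence.
#'
#' @param m matrix of draws, iterations in rows, chains in columns.
#' @return a single R-hat value.
#' @export
rhat <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m) %/% 2L
  if (n < 2) return(NA_real_)
  split <- cbind(m[1:n, , drop = FALSE], m[(n + 1):(2 * n), , drop = FALSE])
  znorm <- function(s) {
    r <- matrix(rank(s, ties.method = "average"), nrow(s), ncol(s))
    matrix(stats::qnorm((r - 3 / 8) / (length(s) + 1 / 4)), nrow(s), ncol(s))
  }
  bulk <- .rhat_basic(znorm(split))
  folded <- .rhat_basic(znorm(abs(split - stats::median(split))))
  max(bulk, folded, na.rm = TRUE)
}
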