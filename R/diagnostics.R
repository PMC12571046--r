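# Convergence diagnostics: split R-hat and rank-normalised bulk ESS.

split_chains <- function(x) {
  # x: iterations x chains; returns iterations/2 x (2*chains)
  n <- nrow(x)
  half <- floor(n / 2)
  cbind(x[seq_len(half), , drop = FALSE],
        x[seq(n - half + 1, n), , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x))
}

#' Split R-hat for a single parameter
#'
#' Potential scale reduction computed on rank-normalised split chains;
#' values near 1 indicate between- and within-chain agreement.
#'
#' @param x matrix of posterior draws, iterations x chains.
#' @return scalar R-hat (NA for constant draws).
#' @export
rhat <- function(x) {
  x <- split_chains(as.matrix(x))
  if (stats::sd(as.vector(x)) < 1e-12) return(NA_real_)
  x <- rank_normalize(x)
  m <- ncol(x); n <- nrow(x)
  means <- colMeans(x)
  vars <- apply(x, 2, stats::var)
  B <- n * stats::var(means)
  W <- mean(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bulk effective sample size for a single parameter
#'
#' Rank-normalised ESS following the combined-chain autocorrelation
#' estimator with Geyer's initial monotone positive sequence.
#'
#' @param x matrix of posterior draws, iterations x chains.
#' @return scalar effective sample size.
#' @export
ess_bulk <- function(x) {
  x <- split_chains(as.matrix(x))
  if (stats::sd(as.vector(x)) < 1e-12) return(NA_real_)
  x <- rank_normalize(x)
  m <- ncol(x); n <- nrow(x)
  lag_max <- min(n - 2, 1000)
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = lag_max, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  w_var <- mean(apply(x, 2, stats::var))
  means <- colMeans(x)
  var_plus <- w_var * (n - 1) / n + stats::var(means)
  rho <- 1 - (w_var - mean_acov) / var_plus  # rho[k] is lag k-1
  # Geyer: tau = -1 + 2 * sum of initial monotone positive lag pairs
  pair_sum <- 0
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    pair_sum <- pair_sum + pair
    prev_pair <- pair
    t <- t + 2
  }
  tau <- max(-1 + 2 * pair_sum, 1e-3)
  max(min(m * n / tau, m * n), 1)
}
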