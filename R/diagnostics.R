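#' Shortest 95% highest-density interval
#'
#' Computes the shortest contiguous interval containing a given fraction of
#' the (pooled) posterior draws: sort the draws and slide a window of
#' \code{ceiling(prob * n)} draws, keeping the narrowest.
#'
#' @param x numeric vector of posterior draws.
#' @param prob probability mass the interval must contain.
#' @return Named numeric vector \code{c(lower, upper)}.
#' @export
#' @examples
#' hdi(rnorm(1e4))     # roughly c(-1.96, 1.96)
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) stop("no finite draws", call. = FALSE)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin shrink factor computed on split chains: each chain is halved
#' so that non-stationarity within a chain also inflates the statistic.
#' Values near 1 indicate convergence; the conventional pass criterion here
#' is R-hat < 1.1.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return The split R-hat (scalar).
#' @export
split_rhat <- function(draws) {
  draws <- .split_chains(as.matrix(draws))
  n <- nrow(draws)
  if (n < 4) return(NA_real_)
  means <- colMeans(draws)
  vars <- apply(draws, 2, stats::var)
  w <- mean(vars)
  b <- n * stats::var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-adjusted number of independent draws, computed across
#' split chains with Geyer's initial monotone positive sequence truncation.
#' Strong autocorrelation drives the ESS far below the raw draw count; the
#' conventional pass criterion here is ESS > 1000.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return Effective sample size (scalar).
#' @export
ess <- function(draws) {
  draws <- .split_chains(as.matrix(draws))
  n <- nrow(draws)
  m <- ncol(draws)
  if (n < 4) return(NA_real_)
  chain_vars <- apply(draws, 2, stats::var)
  w <- mean(chain_vars)
  var_plus <- (n - 1) / n * w + stats::var(colMeans(draws))
  if (var_plus == 0) return(NA_real_)
  # combined autocorrelation estimate (BDA3): rho_t = 1 - (W - mean_j s_j^2 rho_jt) / var_plus
  acfs <- apply(draws, 2, function(ch)
    stats::acf(ch, lag.max = n - 2, plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (w - colMeans(t(acfs) * chain_vars)) / var_plus
  # Geyer: sum consecutive pairs while positive and monotone decreasing
  max_pairs <- floor((length(rho) - 1) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    tau <- tau + 2 * pair
    prev <- pair
  }
  m * n / tau
}

.split_chains <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[seq.int(n - half + 1, n), , drop = FALSE])
}

#' Convergence diagnostics for a fitted model
#'
#' Per-parameter split R-hat and effective sample size over the retained
#' chains, with a pass flag at the conventional thresholds R-hat < 1.1 and
#' ESS > 1000.
#'
#' @param fit an \code{"av_fit"} object from [fit_av_model()], or a list of
#'   draw matrices (iterations x chains) named by parameter.
#' @param rhat_max,ess_min pass thresholds.
#' @return Data frame with columns \code{parameter}, \code{rhat},
#'   \code{ess}; attribute \code{"pass"} holds the overall flag, also
#'   stored in column attributes printed by [summary.av_fit()].
#' @export
diagnose <- function(fit, rhat_max = 1.1, ess_min = 1000) {
  mats <- if (inherits(fit, "av_fit")) .draw_matrices(fit) else fit
  if (length(mats) == 0) stop("no parameters to diagnose", call. = FALSE)
  if (ncol(as.matrix(mats[[1]])) < 2)
    stop("convergence diagnostics require at least 2 chains", call. = FALSE)
  out <- data.frame(parameter = names(mats),
                    rhat = vapply(mats, split_rhat, numeric(1)),
                    ess = vapply(mats, ess, numeric(1)),
                    row.names = NULL)
  attr(out, "pass") <- all(out$rhat < rhat_max, na.rm = TRUE) &&
    all(out$ess > ess_min, na.rm = TRUE)
  out
}
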