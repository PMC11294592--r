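#' MCMC convergence diagnostics (split R-hat, effective sample size)
#'
#' Computes the split potential-scale-reduction statistic and an
#' autocorrelation-based effective sample size for each parameter from
#' per-chain post-warmup draws. Each chain is split in half, so R-hat also
#' detects within-chain drift. Chains with zero variance yield an undefined
#' (`NA`) R-hat rather than an error.
#'
#' @param draws Either a 3-D array `iterations x chains x parameters`
#'   (dimnames on the third margin name the parameters) or a matrix
#'   `iterations x chains` for a single parameter.
#' @return A data.frame with columns `param`, `rhat`, `ess`, plus the draws
#'   themselves attached as attribute `"traceplot"` (an
#'   iterations x chains x parameters array ready for plotting).
#' @export
compute_diagnostics <- function(draws) {
  if (is.matrix(draws)) {
    draws <- array(draws, dim = c(nrow(draws), ncol(draws), 1),
                   dimnames = list(NULL, colnames(draws), "param"))
  }
  stopifnot(length(dim(draws)) == 3)
  n_iter <- dim(draws)[1]
  n_chain <- dim(draws)[2]
  if (n_chain < 2) stop("at least 2 chains are required", call. = FALSE)
  if (n_iter < 4) stop("at least 4 post-warmup draws per chain are required",
                       call. = FALSE)
  pn <- dimnames(draws)[[3]] %||% paste0("param", seq_len(dim(draws)[3]))
  out <- data.frame(param = pn,
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (p in seq_along(pn)) {
    m <- draws[, , p, drop = TRUE]
    m <- matrix(m, nrow = n_iter)
    out$rhat[p] <- split_rhat(m)
    out$ess[p] <- ess_mean(m)
  }
  attr(out, "traceplot") <- draws
  out
}

#' @rdname compute_diagnostics
#' @param chains Matrix of draws, `iterations x chains`.
#' @export
split_rhat <- function(chains) {
  n <- nrow(chains)
  half <- n %/% 2L
  # split each chain into halves -> 2 * n_chain half-chains of length half
  halves <- cbind(chains[seq_len(half), , drop = FALSE],
                  chains[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(halves)
  nh <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- nh * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)  # undefined for flat chains
  var_plus <- (nh - 1) / nh * W + B / nh
  sqrt(var_plus / W)
}

## Effective sample size for the mean: M*N / (1 + 2 * sum(rho_t)), with
## chain-averaged autocorrelations truncated by Geyer's initial monotone
## positive sequence.
ess_mean <- function(chains) {
  n <- nrow(chains)
  m <- ncol(chains)
  vars <- apply(chains, 2, var)
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- n * var(colMeans(chains))
  var_plus <- (n - 1) / n * W + B / n
  max_lag <- min(n - 2L, 1000L)
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(chains[, j], lag.max = max_lag, plot = FALSE,
             type = "covariance", demean = TRUE)
    as.numeric(a$acf)
  })
  acov <- matrix(acov, ncol = m)
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / var_plus
  # Geyer: sum consecutive pairs while positive and non-increasing
  n_pairs <- length(rho) %/% 2L
  s <- 0
  prev <- Inf
  for (k in seq_len(n_pairs)) {
    pair <- rho[2 * k - 1] + rho[2 * k]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}
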