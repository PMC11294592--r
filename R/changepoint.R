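#' Priors for the negative-binomial changepoint model
#'
#' The filing rate in each month is negative-binomial; one (mean,
#' dispersion) pair governs the months before the changepoint and another
#' the months at and after it. The four positive parameters get exponential
#' priors (weakly informative, positive support) with the stated means; the
#' changepoint month gets a discrete uniform prior over all interior
#' candidates.
#'
#' @param mu_prior_mean Prior mean of the early and late monthly filing
#'   rates (default 10).
#' @param phi_prior_mean Prior mean of the early and late dispersions
#'   (default 1).
#' @return A `changepoint_priors` object.
#' @export
changepoint_priors <- function(mu_prior_mean = 10, phi_prior_mean = 1) {
  stopifnot(is.numeric(mu_prior_mean), mu_prior_mean > 0,
            is.numeric(phi_prior_mean), phi_prior_mean > 0)
  structure(list(mu_prior_mean = mu_prior_mean,
                 phi_prior_mean = phi_prior_mean),
            class = "changepoint_priors")
}

#' MCMC sampler settings for the changepoint model
#'
#' @param iterations Iterations per chain, warmup included (default 2000;
#'   at least 100 so the diagnostics are defined).
#' @param chains Number of independent chains (default 4).
#' @param warmup_fraction Fraction of each chain discarded as warmup
#'   (default 0.5).
#' @param target_accept Acceptance-rate target in (0,1), kept for interface
#'   compatibility with gradient samplers' `adapt_delta`; the slice-sampling
#'   kernel used here is rejection-free, so the value is recorded in the
#'   result but tunes nothing.
#' @param seed Integer RNG seed.
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(iterations = 2000, chains = 4,
                           warmup_fraction = 0.5, target_accept = 0.95,
                           seed = 1L) {
  stopifnot(iterations >= 100, chains >= 1,
            warmup_fraction > 0, warmup_fraction < 1,
            target_accept > 0, target_accept < 1)
  structure(list(iterations = as.integer(iterations),
                 chains = as.integer(chains),
                 warmup_fraction = warmup_fraction,
                 target_accept = target_accept,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

CP_PARAMS <- c("mu_early", "mu_late", "phi_early", "phi_late")

## Candidate changepoints are 1-based indices of the first month governed by
## the late regime: t = 2..n, so both segments are non-empty and there are
## n - 1 candidates.
cp_candidates <- function(n) seq.int(2L, n)

#' Log joint density of the changepoint model
#'
#' Sum of NB2 log-pmfs (early parameters for months before `tau`, late
#' parameters at and after), plus the exponential log prior densities and
#' the log of the uniform changepoint prior.
#'
#' @param series A [monthly_counts()] series.
#' @param tau Candidate changepoint: 1-based index of the first "late"
#'   month, in `2..length(series)`.
#' @param params Numeric vector `c(mu_early, mu_late, phi_early, phi_late)`,
#'   all positive.
#' @param priors A [changepoint_priors()] object.
#' @return The log joint density (a scalar).
#' @export
log_joint <- function(series, tau, params,
                      priors = changepoint_priors()) {
  y <- series$counts
  n <- length(y)
  if (length(tau) != 1 || tau < 2 || tau > n) {
    stop("tau must be a single index in 2..", n, call. = FALSE)
  }
  params <- as.numeric(params)
  if (length(params) != 4 || any(params <= 0)) {
    stop("params must be 4 positive values (mu_early, mu_late, phi_early, phi_late)",
         call. = FALSE)
  }
  ll <- sum(nb_log_pmf(y[seq_len(tau - 1L)], params[1], params[3])) +
    sum(nb_log_pmf(y[tau:n], params[2], params[4]))
  lp <- dexp(params[1], 1 / priors$mu_prior_mean, log = TRUE) +
    dexp(params[2], 1 / priors$mu_prior_mean, log = TRUE) +
    dexp(params[3], 1 / priors$phi_prior_mean, log = TRUE) +
    dexp(params[4], 1 / priors$phi_prior_mean, log = TRUE)
  ll + lp - log(n - 1)
}

new_changepoint_posterior <- function(series, tau_probs, method,
                                      draws = NULL, diagnostics = NULL,
                                      converged = NA, extra = list()) {
  n <- length(series$counts)
  months <- series_months(series)
  names(tau_probs) <- months[cp_candidates(n)]
  map_index <- cp_candidates(n)[which.max(tau_probs)]
  structure(c(list(taxon = series$taxon,
                   start_month = series$start_month,
                   n_months = n,
                   tau_probs = tau_probs,
                   map_index = map_index,
                   map_month = months[map_index],
                   method = method,
                   draws = draws,
                   diagnostics = diagnostics,
                   converged = converged),
              extra),
            class = "changepoint_posterior")
}

#' @export
print.changepoint_posterior <- function(x, ...) {
  cat(sprintf("<changepoint_posterior (%s)%s: %d months from %s>\n",
              x$method,
              if (is.na(x$taxon)) "" else paste0(" '", x$taxon, "'"),
              x$n_months, x$start_month))
  cat(sprintf("  MAP changepoint: %s (P = %.3f)\n",
              x$map_month, max(x$tau_probs)))
  if (!is.null(x$diagnostics)) {
    rh <- x$diagnostics$rhat
    cat(sprintf("  max split R-hat: %s; converged: %s\n",
                if (all(is.na(rh))) "undefined" else
                  sprintf("%.4f", max(rh, na.rm = TRUE)),
                x$converged))
  }
  invisible(x)
}

#' Exact changepoint posterior by quadrature (oracle)
#'
#' Brute-force reference posterior for short series: for each candidate
#' month the four continuous parameters are integrated out numerically on a
#' prior-quantile midpoint grid (the early and late blocks factorize, so
#' only two 2-D integrals per candidate are needed), and the candidate
#' probabilities are normalized. Intended as ground truth for validating
#' the MCMC sampler; refuses series longer than 120 months.
#'
#' @param series A [monthly_counts()] series (length 4..120).
#' @param priors A [changepoint_priors()] object.
#' @param grid List with `n_mu` and `n_phi` quadrature points per dimension
#'   (defaults 64 each).
#' @return A `changepoint_posterior` with `method = "exact"`.
#' @export
exact_changepoint_posterior <- function(series,
                                        priors = changepoint_priors(),
                                        grid = list(n_mu = 64, n_phi = 64)) {
  y <- series$counts
  n <- length(y)
  if (n > 120) {
    stop("exact oracle is limited to series of at most 120 months (got ",
         n, ")", call. = FALSE)
  }
  if (n < 4) stop("series too short for changepoint inference", call. = FALSE)
  n_mu <- as.integer(grid$n_mu %||% 64)
  n_phi <- as.integer(grid$n_phi %||% 64)
  stopifnot(n_mu >= 4, n_phi >= 4)
  # prior-quantile midpoints: integrating f wrt the prior becomes a plain
  # average of f over these points
  mu_pts <- stats::qexp((seq_len(n_mu) - 0.5) / n_mu,
                        rate = 1 / priors$mu_prior_mean)
  phi_pts <- stats::qexp((seq_len(n_phi) - 0.5) / n_phi,
                         rate = 1 / priors$phi_prior_mean)
  gg <- expand.grid(mu = mu_pts, phi = phi_pts)
  blocks <- cp_grid_blocks_cpp(y, gg$mu, gg$phi)
  # log of the prior-averaged early/late block likelihoods per candidate
  lse_col <- function(M) apply(M, 2, function(col) {
    m <- max(col); m + log(mean(exp(col - m)))
  })
  logA <- lse_col(blocks$prefix)  # candidate t=2..n uses prefix column t-1
  logB <- lse_col(blocks$suffix)
  lp <- logA + logB
  tau_probs <- exp(lp - max(lp))
  tau_probs <- tau_probs / sum(tau_probs)
  new_changepoint_posterior(series, tau_probs, method = "exact",
                            extra = list(priors = priors, grid = grid))
}

## Univariate slice sampler step (Neal 2003, stepping-out + shrinkage).
slice_update <- function(x0, f0, f, w = 1, max_steps = 50L) {
  logy <- f0 - rexp(1)
  u <- runif(1)
  L <- x0 - w * u
  R <- L + w
  k <- max_steps
  while (k > 0 && f(L) > logy) { L <- L - w; k <- k - 1L }
  k <- max_steps
  while (k > 0 && f(R) > logy) { R <- R + w; k <- k - 1L }
  repeat {
    x1 <- runif(1, L, R)
    f1 <- f(x1)
    if (f1 >= logy) return(list(x = x1, f = f1))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

#' Sample the changepoint posterior by MCMC
#'
#' Runs seeded MCMC over the four continuous parameters (on the log scale,
#' univariate slice sampling within Gibbs) with the discrete changepoint
#' marginalized out of the likelihood by log-sum-exp over every interior
#' candidate month. The reported per-month changepoint probabilities are
#' Rao-Blackwellized: the posterior mean over draws of the conditional
#' distribution P(changepoint | parameters, counts).
#'
#' @param series A [monthly_counts()] series (length >= 4).
#' @param priors A [changepoint_priors()] object.
#' @param config A [sampler_config()] object.
#' @return A `changepoint_posterior` with `method = "mcmc"`: per-candidate
#'   probabilities, post-warmup parameter draws (iterations x chains x 4
#'   array, traceplot-ready), split R-hat / effective-sample-size
#'   diagnostics, and a `converged` flag (all split R-hat < 1.01).
#' @export
sample_changepoint_posterior <- function(series,
                                         priors = changepoint_priors(),
                                         config = sampler_config()) {
  y <- series$counts
  n <- length(y)
  if (n < 4) stop("series too short for changepoint inference", call. = FALSE)
  stopifnot(inherits(priors, "changepoint_priors"),
            inherits(config, "sampler_config"))
  n_warm <- max(1L, floor(config$iterations * config$warmup_fraction))
  n_keep <- config$iterations - n_warm
  if (n_keep < 2) stop("too few post-warmup iterations", call. = FALSE)

  yi <- as.integer(y)
  logpost <- function(theta) cp_logpost_cpp(yi, theta, priors$mu_prior_mean,
                                            priors$phi_prior_mean)

  set.seed(config$seed)
  draws <- array(NA_real_, dim = c(n_keep, config$chains, 4),
                 dimnames = list(NULL, paste0("chain", seq_len(config$chains)),
                                 CP_PARAMS))
  tau_acc <- numeric(n - 1)
  half <- max(2L, n %/% 2L)
  base_init <- log(pmax(c(mean(y[seq_len(half)]), mean(y[(half + 1L):n]),
                          priors$phi_prior_mean, priors$phi_prior_mean), 0.25))
  for (ch in seq_len(config$chains)) {
    theta <- base_init + rnorm(4, 0, 0.5)  # overdispersed chain starts
    f_cur <- logpost(theta)
    if (!is.finite(f_cur)) {
      stop("non-finite log density at initialization; check the series",
           call. = FALSE)
    }
    for (it in seq_len(config$iterations)) {
      for (j in 1:4) {
        f_j <- function(v) {
          th <- theta; th[j] <- v; logpost(th)
        }
        upd <- slice_update(theta[j], f_cur, f_j, w = 1)
        theta[j] <- upd$x
        f_cur <- upd$f
      }
      if (it > n_warm) {
        k <- it - n_warm
        draws[k, ch, ] <- exp(theta)
        tau_acc <- tau_acc + cp_tau_probs_cpp(yi, theta)
      }
    }
  }
  tau_probs <- tau_acc / (n_keep * config$chains)
  tau_probs <- tau_probs / sum(tau_probs)
  diag <- compute_diagnostics(draws)
  converged <- all(is.finite(diag$rhat)) && all(diag$rhat < 1.01)
  if (!converged) {
    warning("changepoint sampler flagged as non-converged (split R-hat >= 1.01)",
            call. = FALSE)
  }
  new_changepoint_posterior(series, tau_probs, method = "mcmc",
                            draws = draws, diagnostics = diag,
                            converged = converged,
                            extra = list(priors = priors, config = config,
                                         n_warmup = n_warm))
}

#' Recursive changepoint segmentation
#'
#' Fits the single-changepoint model, then splits the series at the MAP
#' changepoint and fits each half, breadth-first, until `max_segments` fits
#' have been made, a segment is shorter than `min_segment_length` (or its
#' parent shorter than twice that, in which case no split is attempted), or
#' a segment's posterior is too diffuse (maximum candidate probability
#' below twice the uniform value), which drops the segment as
#' changepoint-free.
#'
#' @inheritParams sample_changepoint_posterior
#' @param max_segments Maximum number of changepoint fits (>= 1).
#' @param min_segment_length Minimum months per fitted segment (default 12).
#' @return List of `changepoint_posterior` objects in time order (fits
#'   whose posterior was diffuse are not returned; if every fit was
#'   diffuse, the single full-series fit is).
#' @export
segment_changepoints <- function(series, priors = changepoint_priors(),
                                 config = sampler_config(),
                                 max_segments = 3L,
                                 min_segment_length = 12L) {
  stopifnot(max_segments >= 1, min_segment_length >= 4)
  queue <- list(list(s = series, id = 1L))
  fits <- list()
  budget <- as.integer(max_segments)
  while (length(queue) && budget > 0L) {
    item <- queue[[1]]
    queue <- queue[-1]
    s <- item$s
    n <- length(s$counts)
    if (n < max(4L, min_segment_length)) next
    cfg <- config
    cfg$seed <- (config$seed + 977L * item$id) %% .Machine$integer.max
    cfg <- do.call(sampler_config, cfg[names(formals(sampler_config))])
    fit <- sample_changepoint_posterior(s, priors, cfg)
    budget <- budget - 1L
    if (max(fit$tau_probs) < 2 / length(fit$tau_probs)) next  # no changepoint
    fits[[length(fits) + 1L]] <- fit
    if (n >= 2L * min_segment_length) {
      split_at <- fit$map_index
      months <- series_months(s)
      if (split_at - 1L >= min_segment_length) {
        queue[[length(queue) + 1L]] <- list(
          s = monthly_counts(s$counts[seq_len(split_at - 1L)],
                             s$start_month, s$taxon),
          id = 2L * item$id)
      }
      if (n - split_at + 1L >= min_segment_length) {
        queue[[length(queue) + 1L]] <- list(
          s = monthly_counts(s$counts[split_at:n], months[split_at],
                             s$taxon),
          id = 2L * item$id + 1L)
      }
    }
  }
  if (!length(fits)) {
    # every fitted posterior was diffuse: report the full-series fit anyway
    fits <- list(sample_changepoint_posterior(series, priors, config))
  }
  fits[order(vapply(fits, function(f) ym_index(f$start_month), integer(1)))]
}
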