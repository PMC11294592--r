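#' Negative-binomial log-pmf (mean/dispersion form)
#'
#' Log probability mass of the NB2 parameterization with mean `mu` and
#' dispersion `phi`, variance `mu + mu^2/phi`. This is the emission
#' distribution of the changepoint model; as `phi -> Inf` it approaches the
#' Poisson(`mu`) pmf.
#'
#' @param y Non-negative integer count(s).
#' @param mu Positive mean.
#' @param phi Positive dispersion (smaller = more overdispersed).
#' @param log If `FALSE`, return the probability instead of its log.
#' @return Numeric vector of log-probabilities (finite for valid inputs).
#' @examples
#' nb_log_pmf(0, mu = 1, phi = 1)  # log(1/2)
#' @export
nb_log_pmf <- function(y, mu, phi, log = TRUE) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(!is.finite(phi)) || any(phi <= 0)) stop("phi must be > 0", call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) {
    stop("y must be non-negative integer(s)", call. = FALSE)
  }
  out <- dnbinom(y, size = phi, mu = mu, log = TRUE)
  if (log) out else exp(out)
}
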