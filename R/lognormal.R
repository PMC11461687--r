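#' Log-normal parameters from first two moments
#'
#' Clinic service times are modelled as log-normal. Given a target mean `m`
#' (minutes) and variance `v` (minutes squared), the parameters of the
#' underlying normal are obtained by moment inversion:
#' \deqn{\sigma^2 = \log(1 + v / m^2), \qquad \mu = \log(m) - \sigma^2 / 2.}
#' The mapping is a bijection on \{m > 0, v >= 0\}; `v = 0` degenerates to a
#' point mass at `m` (`sdlog = 0`).
#'
#' @param mean target mean, minutes; must be positive.
#' @param variance target variance, minutes^2; must be non-negative.
#' @return an object of class `lognormal_params`: a list with elements
#'   `mean`, `variance`, `meanlog`, `sdlog`.
#' @seealso [fit_lognormal_moments()], [sample_lognormal()]
#' @export
#' @examples
#' p <- lognormal_from_moments(11.62, 185.52)
#' p$meanlog; p$sdlog
lognormal_from_moments <- function(mean, variance) {
  if (!is.numeric(mean) || length(mean) != 1 || is.na(mean) || mean <= 0)
    stop_cf("log-normal mean must be a single positive number, got %s",
            deparse(mean))
  if (!is.numeric(variance) || length(variance) != 1 || is.na(variance) ||
      variance < 0)
    stop_cf("log-normal variance must be a single non-negative number, got %s",
            deparse(variance))
  s2 <- log(1 + variance / mean^2)
  structure(
    list(mean = mean, variance = variance,
         meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2)),
    class = "lognormal_params"
  )
}

#' Fit a log-normal distribution to duration samples by moment matching
#'
#' Computes the sample mean and (unbiased) sample variance of the provided
#' positive durations and inverts them to log-normal parameters via
#' [lognormal_from_moments()]. Degenerate samples (all equal) yield
#' `sdlog = 0` and `meanlog = log(mean)`.
#'
#' @param samples numeric vector of at least two positive durations (minutes).
#' @return an object of class `lognormal_params`.
#' @export
#' @examples
#' fit_lognormal_moments(c(5, 5, 5))
fit_lognormal_moments <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 2)
    stop_cf("need at least 2 duration samples, got %d", length(samples))
  bad <- which(samples <= 0 | is.na(samples))
  if (length(bad))
    stop_cf("duration samples must be positive; offending value %s at index %d",
            format(samples[bad[1]]), bad[1])
  lognormal_from_moments(mean(samples), stats::var(samples))
}

#' Draw from a fitted log-normal duration distribution
#'
#' @param n number of draws.
#' @param params a `lognormal_params` object.
#' @return numeric vector of `n` continuous (un-rounded) durations in minutes.
#' @export
sample_lognormal <- function(n, params) {
  stopifnot(inherits(params, "lognormal_params"))
  if (params$sdlog == 0) return(rep(params$mean, n))
  stats::rlnorm(n, params$meanlog, params$sdlog)
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf(
    "log-normal durations: mean %.4g min, variance %.4g min^2 (meanlog %.4g, sdlog %.4g)\n",
    x$mean, x$variance, x$meanlog, x$sdlog))
  invisible(x)
}
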