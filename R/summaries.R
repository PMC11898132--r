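#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws; ties are broken by the lowest left endpoint.
#'
#' @param samples Numeric draws (at least 20).
#' @param mass Posterior mass, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  x <- sort(samples)
  n <- length(x)
  if (n < 20) stop("need at least 20 draws for an HPD interval")
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  width <- x[seq.int(m, n)] - x[seq.int(1L, n - m + 1L)]
  i <- which.min(width)            # which.min takes the first = lowest left end
  c(x[i], x[i + m - 1L])
}

#' Posterior probability of exceeding a cutoff
#'
#' Fraction of draws strictly greater than `cutoff` (the "P" column of the
#' genetic-parameter tables, default cutoff 0.10 for heritability).
#'
#' @param samples Numeric draws.
#' @param cutoff Exceedance cutoff, default 0.10.
#' @export
prob_exceeds <- function(samples, cutoff = 0.10) {
  stopifnot(length(samples) > 0)
  mean(samples > cutoff)
}

#' Lower credible limit
#'
#' The value k such that the posterior mass above k is `mass`: the
#' `(1 - mass)` empirical quantile with type-7 interpolation (the "k" column
#' of the genetic-parameter tables).
#'
#' @param samples Numeric draws.
#' @param mass Posterior mass above the limit, default 0.95.
#' @export
lower_credible_limit <- function(samples, mass = 0.95) {
  stopifnot(length(samples) > 0)
  unname(stats::quantile(samples, probs = 1 - mass, type = 7))
}

#' Effective sample size of a chain
#'
#' Autocorrelation-based ESS: `n * var(x) / s0`, where `s0` is the spectral
#' density at frequency zero estimated from an AR fit (order chosen by AIC),
#' the standard single-chain estimator. An i.i.d. chain scores close to its
#' length.
#'
#' @param samples Numeric draws.
#' @export
effective_sample_size <- function(samples) {
  n <- length(samples)
  v <- stats::var(samples)
  if (n < 10 || v == 0) return(as.numeric(n))
  fit <- stats::ar(samples, aic = TRUE, order.max = min(50, n - 1L))
  s0 <- if (length(fit$ar) == 0) v else fit$var.pred / (1 - sum(fit$ar))^2
  if (!is.finite(s0) || s0 <= 0) return(as.numeric(n))
  min(as.numeric(n), n * v / s0)
}

#' Scalar posterior summary
#'
#' Posterior mean, 95% HPD interval, exceedance probability, lower credible
#' limit and effective sample size of a vector of draws.
#'
#' @param samples Numeric draws.
#' @param cutoff Cutoff for [prob_exceeds()].
#' @param mass Mass for the HPD interval and [lower_credible_limit()].
#' @return A one-row data.frame with columns `mean`, `hpd_low`, `hpd_high`,
#'   `p_exceed`, `k_limit`, `ess`.
#' @export
scalar_summary <- function(samples, cutoff = 0.10, mass = 0.95) {
  hpd <- hpd_interval(samples, mass)
  data.frame(mean = mean(samples), hpd_low = hpd[1L], hpd_high = hpd[2L],
             p_exceed = prob_exceeds(samples, cutoff),
             k_limit = lower_credible_limit(samples, mass),
             ess = effective_sample_size(samples))
}

#' Summarize derived quantities over a chain
#'
#' Applies `derived` to every retained draw (never to the posterior-mean
#' draw) and summarizes each resulting quantity with [scalar_summary()].
#' `derived` receives a list with elements `G`, `P`, `sigma2e` (and `tau`)
#' for one draw and must return a named numeric vector.
#'
#' @param chain A `litter_chain` from [run_chain()].
#' @param derived Function of one draw returning a named numeric vector.
#' @param cutoff,mass Passed to [scalar_summary()].
#' @return data.frame with one row per derived quantity (row order of the
#'   first draw's names) plus a `quantity` column.
#' @export
summarize_chain <- function(chain, derived, cutoff = 0.10, mass = 0.95) {
  stopifnot(inherits(chain, "litter_chain"), chain$n_draws > 0)
  q <- chain$basis$order + 1L
  vals <- vapply(seq_len(chain$n_draws), function(j) {
    derived(list(G = matrix(chain$draws$G[j, ], q, q),
                 P = matrix(chain$draws$P[j, ], q, q),
                 sigma2e = chain$draws$sigma2e[j, ],
                 tau = chain$tau))
  }, FUN.VALUE = derived(list(G = matrix(chain$draws$G[1, ], q, q),
                              P = matrix(chain$draws$P[1, ], q, q),
                              sigma2e = chain$draws$sigma2e[1, ],
                              tau = chain$tau)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list("value", NULL))
  out <- do.call(rbind, lapply(seq_len(nrow(vals)), function(i)
    scalar_summary(vals[i, ], cutoff, mass)))
  out <- cbind(quantity = rownames(vals), out)
  rownames(out) <- NULL
  out
}
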