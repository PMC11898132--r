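#' Trajectory variance at a parity
#'
#' Variance of a random-regression function at time t: `phi_t' M phi_t`,
#' where M is the coefficient covariance matrix and `phi_t` the basis row.
#'
#' @param M Symmetric PSD coefficient covariance.
#' @param phi_t Basis row (numeric vector of length `ncol(M)`).
#' @export
variance_at <- function(M, phi_t) {
  if (length(phi_t) != ncol(M) || nrow(M) != ncol(M))
    stop("dimension mismatch between basis row and covariance matrix")
  drop(crossprod(phi_t, M %*% phi_t))
}

#' Heritability on the liability scale
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_p + sigma2_e)` at one parity.
#'
#' @param sigma2_a,sigma2_p,sigma2_e Additive genetic, permanent-environment
#'   and residual variances (all >= 0, not all zero). Vectorized.
#' @export
heritability_at <- function(sigma2_a, sigma2_p, sigma2_e) {
  tot <- sigma2_a + sigma2_p + sigma2_e
  if (any(tot <= 0)) stop("zero total variance")
  sigma2_a / tot
}

#' Permanent-environment fraction of phenotypic variance
#'
#' `c2 = sigma2_p / (sigma2_a + sigma2_p + sigma2_e)` at one parity.
#'
#' @inheritParams heritability_at
#' @export
pe_fraction_at <- function(sigma2_a, sigma2_p, sigma2_e) {
  tot <- sigma2_a + sigma2_p + sigma2_e
  if (any(tot <= 0)) stop("zero total variance")
  sigma2_p / tot
}

#' Genetic correlation between two parities
#'
#' `rg(t, s) = phi_t' G phi_s / sqrt((phi_t' G phi_t)(phi_s' G phi_s))`.
#' Returns `NA` when either parity has zero genetic variance.
#'
#' @param G Genetic coefficient covariance.
#' @param phi_t,phi_s Basis rows of the two parities.
#' @export
genetic_correlation <- function(G, phi_t, phi_s) {
  vt <- variance_at(G, phi_t)
  vs <- variance_at(G, phi_s)
  if (vt <= 0 || vs <= 0) return(NA_real_)
  drop(crossprod(phi_t, G %*% phi_s)) / sqrt(vt * vs)
}

#' Phenotypic correlation between two parities
#'
#' Phenotypic covariance across parities has genetic and
#' permanent-environment components only; residuals are independent across
#' parities and contribute to the diagonal variances alone:
#' `rp(t, s) = (phi_t'G phi_s + phi_t'P phi_s) / sqrt(vp(t) vp(s))` with
#' `vp(t) = phi_t'G phi_t + phi_t'P phi_t + sigma2_e(class(t))`.
#'
#' @param G,P Genetic and permanent-environment coefficient covariances.
#' @param sigma2_e Residual variances per class.
#' @param phi_t,phi_s Basis rows.
#' @param class_t,class_s Residual classes of the two parities.
#' @export
phenotypic_correlation <- function(G, P, sigma2_e, phi_t, phi_s,
                                   class_t, class_s) {
  vt <- variance_at(G, phi_t) + variance_at(P, phi_t) + sigma2_e[class_t]
  vs <- variance_at(G, phi_s) + variance_at(P, phi_s) + sigma2_e[class_s]
  if (vt <= 0 || vs <= 0) return(NA_real_)
  cv <- drop(crossprod(phi_t, G %*% phi_s)) + drop(crossprod(phi_t, P %*% phi_s))
  cv / sqrt(vt * vs)
}

#' Per-parity genetic parameters from one draw
#'
#' Converts one draw of (G, P, residual-class variances) into per-parity
#' variances, heritability, permanent-environment fraction and the 6x6
#' genetic and phenotypic correlation matrices.
#'
#' @param G,P Coefficient covariance matrices.
#' @param sigma2_e Residual variances per class.
#' @param basis A `trajectory_basis`.
#' @param class_map Residual class of each parity (integer vector over
#'   `basis$t_min..basis$t_max`), e.g. `assign_residual_class(1:6, line)`.
#' @return List of class `trajectory_params` with vectors `sigma2_a`,
#'   `sigma2_p`, `sigma2_e`, `h2`, `c2` (named by parity) and matrices `rg`,
#'   `rp`.
#' @export
trajectory_params <- function(G, P, sigma2_e, basis, class_map) {
  ts <- basis$t_min:basis$t_max
  nt <- length(ts)
  stopifnot(length(class_map) == nt)
  va <- vapply(seq_len(nt), function(i) variance_at(G, basis$phi[i, ]), 0)
  vp <- vapply(seq_len(nt), function(i) variance_at(P, basis$phi[i, ]), 0)
  ve <- sigma2_e[class_map]
  rg <- diag(1, nt)
  rp <- diag(1, nt)
  for (i in seq_len(nt)) for (j in seq_len(nt)) {
    if (i == j) next
    rg[i, j] <- genetic_correlation(G, basis$phi[i, ], basis$phi[j, ])
    rp[i, j] <- phenotypic_correlation(G, P, sigma2_e, basis$phi[i, ],
                                       basis$phi[j, ], class_map[i], class_map[j])
  }
  dimnames(rg) <- dimnames(rp) <- list(ts, ts)
  structure(list(sigma2_a = stats::setNames(va, ts),
                 sigma2_p = stats::setNames(vp, ts),
                 sigma2_e = stats::setNames(ve, ts),
                 h2 = stats::setNames(heritability_at(va, vp, ve), ts),
                 c2 = stats::setNames(pe_fraction_at(va, vp, ve), ts),
                 rg = rg, rp = rp),
            class = "trajectory_params")
}

flatten_trajectory_params <- function(tp) {
  ts <- names(tp$h2)
  nt <- length(ts)
  pairs <- which(upper.tri(tp$rg), arr.ind = TRUE)
  c(stats::setNames(tp$sigma2_a, paste0("sigma2_a.", ts)),
    stats::setNames(tp$sigma2_p, paste0("sigma2_p.", ts)),
    stats::setNames(tp$sigma2_e, paste0("sigma2_e.", ts)),
    stats::setNames(tp$h2, paste0("h2.", ts)),
    stats::setNames(tp$c2, paste0("c2.", ts)),
    stats::setNames(tp$rg[pairs],
                    paste0("rg.", ts[pairs[, 1]], ".", ts[pairs[, 2]])),
    stats::setNames(tp$rp[pairs],
                    paste0("rp.", ts[pairs[, 1]], ".", ts[pairs[, 2]])))
}

#' Posterior summaries of the genetic-parameter trajectories
#'
#' Computes [trajectory_params()] for every retained draw of a chain and
#' summarizes each entry (per-parity variances, h2, c2, and all pairwise
#' genetic and phenotypic correlations) with posterior mean, 95% HPD
#' interval, exceedance probability and lower credible limit.
#'
#' @param chain A `litter_chain`.
#' @param class_map Residual class per parity; defaults to the chain's
#'   line-specific map.
#' @param cutoff Exceedance cutoff (applied to every quantity; only
#'   meaningful for h2, where the conventional value is 0.10).
#' @return data.frame with columns `quantity`, `mean`, `hpd_low`,
#'   `hpd_high`, `p_exceed`, `k_limit`, `ess`.
#' @export
trajectory_summary <- function(chain, class_map = NULL, cutoff = 0.10) {
  stopifnot(inherits(chain, "litter_chain"))
  if (is.null(class_map))
    class_map <- if (!is.null(chain$class_map)) chain$class_map
                 else assign_residual_class(chain$basis$t_min:chain$basis$t_max,
                                            chain$line)
  summarize_chain(chain, function(draw)
    flatten_trajectory_params(
      trajectory_params(draw$G, draw$P, draw$sigma2e, chain$basis, class_map)),
    cutoff = cutoff)
}

#' Genetic-parameter table for one line
#'
#' Lays a [trajectory_summary()] out like the published per-parity tables:
#' one row per parity with posterior means of the variance components, h2
#' with its HPD interval, exceedance probability P and lower limit k, and
#' c2. For a repeatability chain the table has a single row.
#'
#' @param chain A `litter_chain`.
#' @param digits Rounding for display columns (full precision is retained in
#'   the `trajectory_summary` output); default 2 to mirror published tables.
#' @return data.frame with columns `parity`, `sigma2_a`, `sigma2_p`,
#'   `sigma2_e`, `h2`, `hpd_low`, `hpd_high`, `P`, `k`, `c2`.
#' @export
parameter_table <- function(chain, digits = 2) {
  ts <- chain$basis$t_min:chain$basis$t_max
  s <- trajectory_summary(chain)
  repeatability <- chain$config$model == "repeatability"
  rows <- if (repeatability) ts[1L] else ts
  out <- do.call(rbind, lapply(rows, function(t) {
    g <- function(qn) s[s$quantity == paste0(qn, ".", t), ]
    h <- g("h2")
    data.frame(parity = if (repeatability) NA_integer_ else t,
               sigma2_a = g("sigma2_a")$mean, sigma2_p = g("sigma2_p")$mean,
               sigma2_e = g("sigma2_e")$mean, h2 = h$mean,
               hpd_low = h$hpd_low, hpd_high = h$hpd_high,
               P = h$p_exceed, k = h$k_limit, c2 = g("c2")$mean)
  }))
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) round(x, digits + 2))
  attr(out, "display_digits") <- digits
  out
}

#' Correlation table for one line
#'
#' Posterior-mean correlations laid out like the published matrices:
#' genetic correlations above the diagonal, phenotypic below.
#'
#' @param chain A `litter_chain` (random-regression model).
#' @return Square numeric matrix with parities as dimnames.
#' @export
correlation_table <- function(chain) {
  s <- trajectory_summary(chain)
  ts <- chain$basis$t_min:chain$basis$t_max
  nt <- length(ts)
  out <- diag(1, nt)
  dimnames(out) <- list(ts, ts)
  for (i in seq_len(nt - 1)) for (j in seq.int(i + 1, nt)) {
    out[i, j] <- s$mean[s$quantity == paste0("rg.", ts[i], ".", ts[j])]
    out[j, i] <- s$mean[s$quantity == paste0("rp.", ts[i], ".", ts[j])]
  }
  out
}
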