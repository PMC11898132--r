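#' Truncated normal draws by inversion
#'
#' Draws from a normal distribution truncated to `(lower, upper)` using the
#' inverse-CDF method, which stays well-behaved in extreme tails (no
#' rejection loops).
#'
#' @param n Number of draws.
#' @param mean,sd Normal parameters (recycled).
#' @param lower,upper Truncation bounds (recycled; may be infinite).
#' @export
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  .rtnorm_cpp(as.integer(n), as.double(mean), as.double(sd),
              as.double(lower), as.double(upper))
}

#' Inverse-Wishart draw
#'
#' Samples from IW(`df`, `scale`) (density proportional to
#' `|X|^-(df+q+1)/2 exp(-tr(scale X^-1)/2)`) via the Bartlett decomposition,
#' using R's RNG stream.
#'
#' @param df Degrees of freedom, must exceed `ncol(scale) - 1`.
#' @param scale Symmetric positive definite scale matrix.
#' @return A symmetric positive definite matrix of the same dimension.
#' @export
riwish <- function(df, scale) {
  q <- ncol(scale)
  stopifnot(nrow(scale) == q, df > q - 1)
  Sinv <- chol2inv(chol(scale))
  L <- t(chol(Sinv))                       # Wishart(df, Sinv) via Bartlett
  A <- matrix(0, q, q)
  diag(A) <- sqrt(stats::rchisq(q, df - seq_len(q) + 1))
  if (q > 1) A[lower.tri(A)] <- stats::rnorm(q * (q - 1) / 2)
  LA <- L %*% A
  W <- LA %*% t(LA)
  out <- chol2inv(chol(W))
  (out + t(out)) / 2
}

#' Gibbs update of the genetic coefficient covariance
#'
#' Draws G from its inverse-Wishart full conditional given the current
#' additive coefficients: scale = Sa + prior scale, df = n_animals + prior
#' df, with `Sa[i, j] = a_i' A^-1 a_j` over coefficient vectors. With zero
#' animals this is a draw from the prior. Non-positive-definite draws are
#' resampled with a warning.
#'
#' @param a_mat Matrix of additive coefficients, `q x n_animals`.
#' @param a_inverse Sparse A-inverse over the same animals.
#' @param prior List with `df` and `scale` (`q x q`).
#' @export
sample_genetic_cov <- function(a_mat, a_inverse, prior) {
  q <- nrow(a_mat)
  n <- ncol(a_mat)
  S <- if (n > 0) {
    At <- t(a_mat)
    crossprod(At, as.matrix(a_inverse %*% At))
  } else matrix(0, q, q)
  draw_cov(n + prior$df, S + prior$scale, q)
}

#' Gibbs update of the permanent-environment covariance
#'
#' As [sample_genetic_cov()] with the identity relationship:
#' `Sp = p p'`, df = n_ewes + prior df.
#'
#' @param p_mat Matrix of PE coefficients, `q x n_ewes`.
#' @param prior List with `df` and `scale`.
#' @export
sample_pe_cov <- function(p_mat, prior) {
  q <- nrow(p_mat)
  n <- ncol(p_mat)
  S <- if (n > 0) tcrossprod(p_mat) else matrix(0, q, q)
  draw_cov(n + prior$df, S + prior$scale, q)
}

draw_cov <- function(df, scale, q) {
  if (df <= q - 1)
    stop("posterior degrees of freedom too small (", df,
         "); use a proper prior for this data size")
  for (try in 1:10) {
    out <- riwish(df, scale)
    ev <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > 0) return(out)
    warning("non-positive-definite covariance draw; resampling")
  }
  stop("could not draw a positive definite covariance matrix")
}

#' Gibbs update of a residual variance
#'
#' Scaled inverse-chi-square draw: `(sse + df0 * s02) / rchisq(n + df0)`.
#' The flat prior corresponds to `df0 = -2`, `s02 = 0`. A class with zero
#' records returns a prior draw with a warning.
#'
#' @param sse Residual sum of squares of the class.
#' @param n Number of records in the class.
#' @param prior List with `df` and `s2`.
#' @export
sample_residual_var <- function(sse, n, prior) {
  if (n == 0) {
    warning("residual class with zero records; drawing from the prior")
    if (prior$df <= 0) stop("flat residual prior is improper with no records")
    return(prior$df * prior$s2 / stats::rchisq(1, prior$df))
  }
  dfp <- n + prior$df
  if (dfp <= 0) stop("non-positive residual posterior degrees of freedom")
  (sse + prior$df * prior$s2) / stats::rchisq(1, dfp)
}

#' Sampler configuration
#'
#' Collects the Gibbs chain settings and priors. Defaults mirror a
#' full-length production run (500,000 samples, 100,000 burn-in, thinning
#' 100, giving 4,000 retained draws); tests and examples use much shorter
#' chains.
#'
#' @param n_iter Total iterations.
#' @param burn_in Burn-in iterations (discarded).
#' @param thin Keep one sample every `thin` iterations.
#' @param order Legendre order for the random-regression model.
#' @param model `"random_regression"` or `"repeatability"` (intercept-only
#'   random effects with a raw constant covariate).
#' @param prior `"weak"` for minimally-informative proper priors
#'   (inverse-Wishart df = q + 2, scale = 0.1 I; scaled inv-chi-square
#'   df = 4, s2 = 1) or `"flat"` for the improper flat priors
#'   (covariances: df = -(q+1), scale 0; residuals: df = -2).
#' @param fixed_prior_var Gaussian prior variance on each fixed effect;
#'   `Inf` (default) means flat. A finite value keeps the location
#'   identified when design columns are collinear.
#' @param store_effects Retain fixed and additive effect draws (memory
#'   permitting); running means are always kept.
#' @param seed Optional integer; if given, `set.seed(seed)` is called at the
#'   start of the chain.
#' @export
model_config <- function(n_iter = 500000, burn_in = 100000, thin = 100,
                         order = 2, model = c("random_regression", "repeatability"),
                         prior = c("weak", "flat"), fixed_prior_var = Inf,
                         store_effects = FALSE, seed = NULL) {
  model <- match.arg(model)
  prior <- match.arg(prior)
  stopifnot(burn_in < n_iter, thin >= 1, order >= 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), order = as.integer(order),
                 model = model, prior = prior,
                 fixed_prior_var = fixed_prior_var,
                 store_effects = store_effects, seed = seed),
            class = "model_config")
}

chain_priors <- function(config, q) {
  if (config$prior == "weak") {
    list(g = list(df = q + 2, scale = diag(0.1, q)),
         p = list(df = q + 2, scale = diag(0.1, q)),
         resid = list(df = 4, s2 = 1))
  } else {
    list(g = list(df = -(q + 1), scale = matrix(0, q, q)),
         p = list(df = -(q + 1), scale = matrix(0, q, q)),
         resid = list(df = -2, s2 = 0))
  }
}

# Index representation of the model consumed by the compiled sweep.
prepare_model_data <- function(records, pedigree, basis, a_inverse) {
  nrec <- nrow(records)
  q <- basis$order + 1L
  months <- sort(unique(records$month_level))
  month_col <- match(records$month_level, months) - 1L  # 0 = reference level
  anim_idx <- match(records$ewe, pedigree$ped$id)
  if (anyNA(anim_idx))
    stop("ewes with records but absent from pedigree: ",
         paste(unique(records$ewe[is.na(anim_idx)]), collapse = ", "))
  ewe_ids <- unique(records$ewe)
  ewe_idx <- match(records$ewe, ewe_ids)
  group_ptr <- function(idx, n) {
    ord <- order(idx)
    cnt <- tabulate(idx, nbins = n)
    list(ptr = c(0L, cumsum(cnt)), idx = as.integer(ord - 1L))
  }
  ga <- group_ptr(anim_idx, pedigree$n)
  ge <- group_ptr(ewe_idx, length(ewe_ids))
  list(nrec = nrec, q = q,
       year_col = as.integer(records$year_level),
       month_col = as.integer(month_col),
       n_year = max(records$year_level),
       n_month_col = length(months) - 1L,
       anim_idx = anim_idx, ewe_idx = ewe_idx, ewe_ids = ewe_ids,
       ewe_anim = match(ewe_ids, pedigree$ped$id),
       par_idx = as.integer(records$parity - basis$t_min + 1L),
       cls_idx = as.integer(records$residual_class),
       cat_idx = as.integer(records$category),
       phi_t = t(basis$phi),                       # q x n_parity
       Ap = a_inverse@p, Ai = a_inverse@i, Ax = a_inverse@x,
       arec = ga, erec = ge)
}

#' Fit the threshold model by Gibbs sampling
#'
#' Runs the liability-augmented Gibbs sampler for the threshold
#' random-regression (or repeatability) animal model. Identifiability: the
#' first threshold is fixed at 0; with three categories the second threshold
#' is fixed at 1 and all residual-class variances are free; with two
#' categories the class-1 residual variance is fixed at 1.
#'
#' @param records A `parity_records` data.frame (see [read_records()]).
#' @param pedigree A `litter_pedigree` containing every recorded ewe.
#' @param config A [model_config()].
#' @param a_inverse Optional precomputed sparse A-inverse (built from the
#'   pedigree otherwise).
#' @param checkpoint_path,checkpoint_every Optional: serialize sampler state
#'   (including the RNG state) every `checkpoint_every` iterations so an
#'   interrupted run resumes bit-identically.
#' @param resume Path to a checkpoint written by a previous call; the chain
#'   continues from its exact state.
#' @param verbose Print progress.
#' @return A `litter_chain`: retained draws of G, P, residual variances and
#'   per-draw deviance, posterior-mean linear predictor, thresholds, basis,
#'   and the configuration echo.
#' @export
run_chain <- function(records, pedigree, config = model_config(),
                      a_inverse = NULL, checkpoint_path = NULL,
                      checkpoint_every = NULL, resume = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "model_config"))
  line <- attr(records, "line")
  n_cat <- if (identical(line, "conventional")) 2L else 3L
  basis <- if (config$model == "repeatability") repeatability_basis()
           else build_basis(config$order)
  # the repeatability model has a single residual variance (no parity classes)
  if (config$model == "repeatability") records$residual_class <- 1L
  class_map <- if (config$model == "repeatability") rep(1L, 6)
               else assign_residual_class(basis$t_min:basis$t_max, line)
  q <- basis$order + 1L
  if (is.null(a_inverse)) a_inverse <- build_a_inverse(pedigree)
  dat <- prepare_model_data(records, pedigree, basis, a_inverse)
  tau <- if (n_cat == 3L) c(-Inf, 0, 1, Inf) else c(-Inf, 0, Inf)
  priors <- chain_priors(config, q)
  classes <- sort(unique(dat$cls_idx))
  # Binary data identify only eta/sigma within a residual class: freeing the
  # class scales leaves a flat ridge the sampler random-walks along, so every
  # class is anchored at 1 (the standard binary threshold-model constraint).
  # With 3 categories the two fixed thresholds pin the scale and all classes
  # are estimable.
  fixed_class <- if (n_cat == 2L) 1:3 else integer(0)
  free_classes <- setdiff(classes, fixed_class)

  if (!is.null(resume)) {
    ck <- readRDS(resume)
    st <- ck$state
    assign(".Random.seed", ck$random_seed, envir = globalenv())
    it0 <- ck$iter
    keep <- ck$keep
    acc <- ck$acc
  } else {
    if (!is.null(config$seed)) set.seed(config$seed)
    mid <- c(-0.5, 0.5, 1.5)[dat$cat_idx]
    if (n_cat == 2L) mid <- c(-0.5, 0.5)[dat$cat_idx]
    # l and e are mutated in place by the compiled sweep: they must not
    # share memory with each other or anything else
    st <- list(l = mid + 0, e = mid + 0,
               b = numeric(dat$n_year + dat$n_month_col + q),
               a = matrix(0, q, pedigree$n),
               p = matrix(0, q, length(dat$ewe_ids)),
               G = diag(0.1, q), P = diag(0.1, q),
               sig2e = rep(1, 3))
    it0 <- 0L
    n_keep <- (config$n_iter - config$burn_in) %/% config$thin
    keep <- list(G = matrix(NA_real_, n_keep, q * q),
                 P = matrix(NA_real_, n_keep, q * q),
                 sigma2e = matrix(NA_real_, n_keep, 3),
                 deviance = rep(NA_real_, n_keep),
                 b = if (config$store_effects)
                       matrix(NA_real_, n_keep, length(st$b)),
                 a = if (config$store_effects)
                       matrix(NA_real_, n_keep, q * pedigree$n),
                 idx = rep(NA_integer_, n_keep))
    acc <- list(eta = numeric(dat$nrec), b = numeric(length(st$b)),
                a = matrix(0, q, pedigree$n), n = 0L, kept = 0L)
  }

  fixed_prec <- if (is.finite(config$fixed_prior_var))
    1 / config$fixed_prior_var else 0
  cls_n <- tabulate(dat$cls_idx, nbins = 3)
  # scratch buffers filled in place by the compiled sweep
  Sa <- matrix(0, q, q)
  Sp <- matrix(0, q, q)
  sse <- numeric(3)

  for (it in seq.int(it0 + 1L, config$n_iter)) {
    Ginv <- chol2inv(chol(st$G))
    Pinv <- chol2inv(chol(st$P))
    .gibbs_sweep_cpp(st$l, st$e, st$b, st$a, st$p,
                     dat$year_col, dat$month_col, dat$anim_idx, dat$ewe_idx,
                     dat$par_idx, dat$cls_idx, dat$cat_idx, dat$phi_t,
                     Ginv, Pinv, st$sig2e, tau,
                     dat$Ap, dat$Ai, dat$Ax,
                     dat$arec$ptr, dat$arec$idx, dat$erec$ptr, dat$erec$idx,
                     dat$ewe_anim, dat$n_year, dat$n_month_col, fixed_prec,
                     TRUE, Sa, Sp, sse)
    for (k in free_classes)
      st$sig2e[k] <- sample_residual_var(sse[k], cls_n[k], priors$resid)
    st$G <- draw_cov(pedigree$n + priors$g$df, Sa + priors$g$scale, q)
    st$P <- draw_cov(length(dat$ewe_ids) + priors$p$df, Sp + priors$p$scale, q)

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      j <- acc$kept + 1L
      keep$G[j, ] <- as.vector(st$G)
      keep$P[j, ] <- as.vector(st$P)
      keep$sigma2e[j, ] <- st$sig2e
      eta <- st$l - st$e
      keep$deviance[j] <- category_deviance(eta, dat$cat_idx, dat$cls_idx,
                                            st$sig2e, tau)
      if (config$store_effects) {
        keep$b[j, ] <- st$b
        keep$a[j, ] <- as.vector(st$a)
      }
      keep$idx[j] <- it
      acc$eta <- acc$eta + eta
      acc$b <- acc$b + st$b
      acc$a <- acc$a + st$a
      acc$n <- acc$n + 1L
      acc$kept <- j
    }
    if (!is.null(checkpoint_path) && !is.null(checkpoint_every) &&
        it %% checkpoint_every == 0L) {
      saveRDS(list(state = st, iter = it, keep = keep, acc = acc,
                   random_seed = get(".Random.seed", envir = globalenv())),
              checkpoint_path)
    }
    if (verbose && it %% 1000L == 0L)
      message("iteration ", it, " / ", config$n_iter)
  }

  structure(list(draws = keep, n_draws = acc$kept,
                 eta_mean = acc$eta / max(acc$n, 1L),
                 b_mean = acc$b / max(acc$n, 1L),
                 a_mean = acc$a / max(acc$n, 1L),
                 tau = tau, n_categories = n_cat, basis = basis, line = line,
                 class_map = class_map,
                 classes_present = classes, free_classes = free_classes,
                 n_animals = pedigree$n, n_ewes = length(dat$ewe_ids),
                 ewe_ids = dat$ewe_ids,
                 sigma2e_mean = colMeans(keep$sigma2e[seq_len(acc$kept), , drop = FALSE]),
                 cat_idx = dat$cat_idx, cls_idx = dat$cls_idx,
                 config = config),
            class = "litter_chain")
}

# -2 log-likelihood of the observed categories given the linear predictor
# and residual scales (ordered-probit likelihood).
category_deviance <- function(eta, cat_idx, cls_idx, sig2e, tau) {
  sd <- sqrt(sig2e[cls_idx])
  lo <- tau[cat_idx]
  hi <- tau[cat_idx + 1L]
  pr <- stats::pnorm((hi - eta) / sd) - stats::pnorm((lo - eta) / sd)
  -2 * sum(log(pmax(pr, 1e-300)))
}

#' @export
print.litter_chain <- function(x, ...) {
  cat("<litter_chain> ", x$config$model, " model, ", x$n_draws,
      " retained draws (n_iter = ", x$config$n_iter, ", burn-in = ",
      x$config$burn_in, ", thin = ", x$config$thin, ")\n", sep = "")
  cat("  ", x$n_animals, " animals, ", x$n_ewes, " recorded ewes, ",
      x$n_categories, " categories\n", sep = "")
  invisible(x)
}
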