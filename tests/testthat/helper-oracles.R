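# Independent oracles and small fixture builders used across the suite.

# Brute-force tabular relationship matrix A by the recursive a(i,j) rules.
# Independent of the package's Henderson/Meuwissen-Luo code paths.
tabular_A <- function(pedigree) {
  s <- pedigree$ped$sire_idx
  d <- pedigree$ped$dam_idx
  n <- pedigree$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      aij <- 0
      if (s[i] > 0L) aij <- aij + 0.5 * A[j, s[i]]
      if (d[i] > 0L) aij <- aij + 0.5 * A[j, d[i]]
      A[i, j] <- A[j, i] <- aij
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}

# Random valid pedigree of n animals: parents always drawn among earlier
# animals (or unknown), so the structure is acyclic by construction.
random_pedigree <- function(n, seed, p_founder = 0.3) {
  set.seed(seed)
  sire <- dam <- rep(NA_character_, n)
  ids <- sprintf("A%03d", seq_len(n))
  for (i in 3:n) {
    if (stats::runif(1) > p_founder) {
      pick <- sample.int(i - 1L, 2L)
      sire[i] <- ids[pick[1L]]
      dam[i] <- ids[pick[2L]]
    }
  }
  new_litter_pedigree(data.frame(id = ids, sire = sire, dam = dam,
                                 stringsAsFactors = FALSE))
}

# Five-animal pedigree with two recorded generations, used by sampler tests.
toy_pedigree <- function() {
  new_litter_pedigree(data.frame(
    id = c("s1", "d1", "d2", "e1", "e2"),
    sire = c(NA, NA, NA, "s1", "s1"),
    dam = c(NA, NA, NA, "d1", "d2"),
    sex = c("male", "female", "female", "female", "female"),
    stringsAsFactors = FALSE))
}

toy_records <- function(line = "conventional") {
  make_records(
    ewe = c("e1", "e1", "e1", "e2", "e2", "d1", "d1", "d2", "d2", "d2"),
    year_level = c(1, 1, 2, 2, 2, 1, 1, 2, 1, 2),
    month_level = c(1, 2, 1, 3, 1, 2, 1, 1, 3, 2),
    parity = c(1, 2, 3, 1, 2, 1, 2, 1, 2, 3),
    litter_size = c(1, 2, 1, 1, 1, 2, 1, 1, 1, 2),
    line = line)
}

# Simulated dataset small enough for fast chain tests.
sim_small <- function(line = "conventional", n_ewes = 120, seed = 42) {
  sc <- make_paper_like_scenario(line, n_ewes = n_ewes)
  set.seed(seed)
  ped <- simulate_pedigree(sc)
  a <- simulate_breeding_values(ped, sc$true_G)
  sim <- simulate_records(ped, a, sc)
  list(scenario = sc, pedigree = ped, a = a, records = sim$records,
       truth = sim$truth)
}

# Direct sparse mixed-model-equations solve: the oracle for the Gibbs
# location updates under fixed variances and fixed liabilities.
mme_solution <- function(design, ainv, G, P, sigma2e, l, fixed_prior_var) {
  w <- 1 / sigma2e[design$residual_class_of]
  W <- cbind(design$X, design$Z, design$W)
  nb <- ncol(design$X)
  n_ewe <- length(design$ewe_ids)
  prior <- Matrix::bdiag(
    Matrix::Diagonal(nb, 1 / fixed_prior_var),
    kronecker(ainv, solve(G)),
    kronecker(Matrix::Diagonal(n_ewe), solve(P)))
  C <- Matrix::crossprod(W, Matrix::Diagonal(x = w) %*% W) + prior
  as.vector(Matrix::solve(C, Matrix::crossprod(W, w * l)))
}

# Drive raw location sweeps (no liability update, fixed variances).
location_sweeps <- function(records, pedigree, basis, ainv, G, P, sigma2e,
                            l, n_iter, fixed_prior_var, n_cat = 2,
                            collect = c("mean", "batches")) {
  collect <- match.arg(collect)
  dat <- litterRRM:::prepare_model_data(records, pedigree, basis, ainv)
  q <- basis$order + 1L
  tau <- if (n_cat == 3) c(-Inf, 0, 1, Inf) else c(-Inf, 0, Inf)
  st <- list(l = l + 0, e = l + 0, b = numeric(dat$n_year + dat$n_month_col + q),
             a = matrix(0, q, pedigree$n),
             p = matrix(0, q, length(dat$ewe_ids)))
  Ginv <- solve(G); Pinv <- solve(P)
  Sa <- matrix(0, q, q); Sp <- matrix(0, q, q); sse <- numeric(3)
  np <- length(st$b) + length(st$a) + length(st$p)
  nbatch <- 40L
  bsize <- n_iter %/% nbatch
  bm <- matrix(0, nbatch, np)
  for (bt in seq_len(nbatch)) {
    acc <- numeric(np)
    for (it in seq_len(bsize)) {
      litterRRM:::.gibbs_sweep_cpp(st$l, st$e, st$b, st$a, st$p,
        dat$year_col, dat$month_col, dat$anim_idx, dat$ewe_idx,
        dat$par_idx, dat$cls_idx, dat$cat_idx, dat$phi_t,
        Ginv, Pinv, sigma2e, tau, dat$Ap, dat$Ai, dat$Ax,
        dat$arec$ptr, dat$arec$idx, dat$erec$ptr, dat$erec$idx, dat$ewe_anim,
        dat$n_year, dat$n_month_col, 1 / fixed_prior_var, FALSE, Sa, Sp, sse)
      acc <- acc + c(st$b, as.vector(st$a), as.vector(st$p))
    }
    bm[bt, ] <- acc / bsize
  }
  if (collect == "mean") colMeans(bm) else bm
}

# Printed per-parity variance components (both lines, both models) used by
# the ratio-identity checks: sigma2_a, sigma2_p, sigma2_e, h2, c2.
published_parameters <- function() {
  prolific <- data.frame(
    model = c("repeatability", rep("rrm", 6)),
    parity = c(NA, 1:6),
    sigma2_a = c(0.060, 0.060, 0.065, 0.104, 0.119, 0.130, 0.231),
    sigma2_p = c(0.043, 0.582, 0.219, 0.110, 0.076, 0.085, 0.251),
    sigma2_e = c(0.306, 0.769, 0.735, 0.735, 0.735, 0.794, 0.794),
    h2 = c(0.14, 0.04, 0.06, 0.11, 0.13, 0.13, 0.18),
    c2 = c(0.10, 0.41, 0.21, 0.12, 0.08, 0.08, 0.20))
  conventional <- data.frame(
    model = c("repeatability", rep("rrm", 6)),
    parity = c(NA, 1:6),
    sigma2_a = c(0.223, 0.822, 0.338, 0.387, 0.422, 0.526, 1.406),
    sigma2_p = c(0.273, 1.768, 0.577, 0.635, 0.738, 0.656, 1.130),
    sigma2_e = c(1.003, 1.003, 1.066, 1.003, 1.003, 1.003, 1.066),
    h2 = c(0.15, 0.23, 0.17, 0.19, 0.20, 0.24, 0.39),
    c2 = c(0.18, 0.49, 0.29, 0.31, 0.34, 0.30, 0.31))
  list(prolific = prolific, conventional = conventional)
}
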