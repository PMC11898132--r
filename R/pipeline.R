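#' Fit the full pipeline from data files
#'
#' Reads the pedigree and records files, runs the Gibbs sampler, and writes
#' (optionally) a per-parity genetic-parameter report, a correlation-matrix
#' report (genetic above the diagonal, phenotypic below), a full-precision
#' draws file and a JSON run manifest.
#'
#' @param pedigree_file,records_file Delimited text inputs (see
#'   [read_pedigree()] and [read_records()]).
#' @param line `"prolific"` or `"conventional"`.
#' @param config A [model_config()].
#' @param out_dir Optional output directory for the reports and manifest.
#' @param ... Passed on to [run_chain()] (checkpointing, verbosity).
#' @return List with `chain`, `parameters` (the per-parity table),
#'   `correlations` (matrix, `NULL` for a repeatability fit), `summary`
#'   (full [trajectory_summary()]), and output `paths` when `out_dir` is
#'   given.
#' @export
fit_litter_rrm <- function(pedigree_file, records_file,
                           line = c("prolific", "conventional"),
                           config = model_config(), out_dir = NULL, ...) {
  line <- match.arg(line)
  ped <- read_pedigree(pedigree_file)
  rec <- read_records(records_file, line = line, pedigree = ped)
  chain <- run_chain(rec, ped, config, ...)
  params <- parameter_table(chain)
  corr <- if (config$model == "random_regression") correlation_table(chain)
  summ <- trajectory_summary(chain)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(parameters = file.path(out_dir, "parameter_table.tsv"),
                  correlations = file.path(out_dir, "correlation_table.tsv"),
                  summary = file.path(out_dir, "trajectory_summary.tsv"),
                  draws = file.path(out_dir, "draws.tsv"),
                  manifest = file.path(out_dir, "manifest.json"))
    utils::write.table(params, paths$parameters, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(corr))
      utils::write.table(round(corr, 4), paths$correlations, sep = "\t",
                         quote = FALSE, col.names = NA)
    utils::write.table(summ, paths$summary, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_draws(chain, paths$draws)
    manifest <- list(seed = config$seed, line = line,
                     model = config$model, order = config$order,
                     n_iter = config$n_iter, burn_in = config$burn_in,
                     thin = config$thin, prior = config$prior,
                     n_draws = chain$n_draws,
                     inputs = list(pedigree = pedigree_file,
                                   records = records_file),
                     input_digests = as.list(
                       tools::md5sum(c(pedigree_file, records_file))),
                     package_version = as.character(
                       utils::packageVersion("litterRRM")))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  list(chain = chain, parameters = params, correlations = corr,
       summary = summ, paths = paths)
}

# one row per retained draw: flattened G, P, residual variances, deviance
write_draws <- function(chain, path) {
  q <- chain$basis$order + 1L
  nm <- outer(seq_len(q), seq_len(q), function(i, j) paste0(i, j))
  out <- data.frame(iteration = chain$draws$idx[seq_len(chain$n_draws)],
                    chain$draws$G[seq_len(chain$n_draws), , drop = FALSE],
                    chain$draws$P[seq_len(chain$n_draws), , drop = FALSE],
                    chain$draws$sigma2e[seq_len(chain$n_draws), , drop = FALSE],
                    deviance = chain$draws$deviance[seq_len(chain$n_draws)])
  names(out) <- c("iteration", paste0("G", as.vector(nm)),
                  paste0("P", as.vector(nm)), paste0("sigma2e", 1:3),
                  "deviance")
  write_full_precision(out, path)
}

#' Deviance-based model comparison across polynomial orders
#'
#' Fits the random-regression model at each requested Legendre order and
#' reports DIC (primary criterion) and a plug-in AIC analogue (deviance at
#' the posterior mean of the linear predictor and residual scales, plus two
#' per estimated dispersion parameter). The order minimizing DIC is
#' flagged. A failed fit is recorded and the comparison continues.
#'
#' @param records A `parity_records` data.frame.
#' @param pedigree A `litter_pedigree`.
#' @param orders Integer vector of Legendre orders (>= 2 entries).
#' @param config Base [model_config()]; its `order` field is overridden.
#' @return data.frame with columns `order`, `dbar`, `dhat`, `p_d`, `dic`,
#'   `aic`, `n_params`, `best`, `error`.
#' @export
compare_orders <- function(records, pedigree, orders,
                           config = model_config()) {
  stopifnot(length(orders) >= 2)
  ainv <- build_a_inverse(pedigree)
  rows <- lapply(orders, function(k) {
    cfg <- config
    cfg$order <- as.integer(k)
    res <- tryCatch({
      chain <- run_chain(records, pedigree, cfg, a_inverse = ainv)
      nd <- chain$n_draws
      dbar <- mean(chain$draws$deviance[seq_len(nd)])
      dhat <- category_deviance(chain$eta_mean, chain$cat_idx, chain$cls_idx,
                                chain$sigma2e_mean, chain$tau)
      q <- k + 1
      npar <- q * (q + 1) + length(chain$free_classes)  # G, P, free residuals
      data.frame(order = k, dbar = dbar, dhat = dhat, p_d = dbar - dhat,
                 dic = dbar + (dbar - dhat), aic = dhat + 2 * npar,
                 n_params = npar, error = NA_character_)
    }, error = function(e)
      data.frame(order = k, dbar = NA, dhat = NA, p_d = NA, dic = NA,
                 aic = NA, n_params = NA, error = conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  out$best <- !is.na(out$dic) & out$dic == min(out$dic, na.rm = TRUE)
  out
}
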