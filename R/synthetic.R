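#' Define a simulation scenario
#'
#' Collects everything the generator needs: pedigree shape (discrete
#' generations bred through rotating ram families), true covariance
#' matrices of the random-regression coefficients, per-class residual
#' variances, thresholds, fixed effects, fixed-regression coefficients and
#' sequential parity-retention probabilities.
#'
#' @param n_founder_ewes Founder ewes (generation 0), spread over families.
#' @param n_generations Discrete offspring generations.
#' @param ewes_per_generation Recorded females retained per generation.
#' @param n_families Ram families (one sire per family per generation).
#' @param true_G,true_P True coefficient covariances (`q x q`, PSD).
#' @param true_resid True residual variances for classes 1..3.
#' @param thresholds Liability thresholds (c(0) binary, c(0, 1) 3-category).
#' @param year_sd SD of the once-per-year lambing-year effects.
#' @param month_effects Fixed month-of-lambing effects (Sep, Oct, Nov).
#' @param beta Fixed-regression coefficients on the normalized Legendre
#'   basis.
#' @param parity_retention Probability a ewe recorded at parity t records
#'   parity t+1 (length 5, entries in (0, 1]).
#' @param line Category coding and residual-class map to apply.
#' @param year_spacing Calendar years between generation cohorts.
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_founder_ewes = 60, n_generations = 5,
                                ewes_per_generation = 50, n_families = 7,
                                true_G, true_P, true_resid,
                                thresholds = c(0, 1), year_sd = 0.3,
                                month_effects = c(0, -0.05, -0.1), beta,
                                parity_retention = rep(0.7, 5),
                                line = c("prolific", "conventional"),
                                year_spacing = 2) {
  line <- match.arg(line)
  q <- ncol(true_G)
  stopifnot(nrow(true_G) == q, identical(dim(true_P), dim(true_G)),
            length(true_resid) == 3, length(beta) == q,
            length(parity_retention) == 5,
            all(parity_retention > 0), all(parity_retention <= 1))
  n_cat <- length(thresholds) + 1L
  stopifnot(n_cat == if (line == "prolific") 3L else 2L)
  structure(list(n_founder_ewes = n_founder_ewes,
                 n_generations = n_generations,
                 ewes_per_generation = ewes_per_generation,
                 n_families = n_families, true_G = true_G, true_P = true_P,
                 true_resid = true_resid, thresholds = thresholds,
                 year_sd = year_sd, month_effects = month_effects,
                 beta = beta, parity_retention = parity_retention,
                 line = line, n_categories = n_cat,
                 year_spacing = year_spacing),
            class = "simulation_scenario")
}

#' Ready-made scenario sized like one of the study lines
#'
#' Returns a scenario shaped like the named line: number of recorded ewes,
#' mean lambings per ewe (~2.8 prolific, ~3.0 conventional), three lambing
#' months, and order-2 true covariance matrices of published magnitude
#' (projections of plausible per-parity variance trajectories onto the
#' normalized Legendre basis, so they are PSD by construction).
#'
#' @param line `"prolific"` (3 categories, ~992 ewes) or `"conventional"`
#'   (2 categories, ~857 ewes).
#' @param n_ewes Override the total number of recorded ewes (e.g. scaled-
#'   down recovery studies); pedigree depth is kept, cohort size adjusts.
#' @return A `simulation_scenario`.
#' @export
make_paper_like_scenario <- function(line = c("prolific", "conventional"),
                                     n_ewes = NULL) {
  line <- match.arg(line)
  if (line == "prolific") {
    G <- matrix(c(0.1701, 0.0333, -0.0036,
                  0.0333, 0.0293, 0.0052,
                  -0.0036, 0.0052, 0.0073), 3, 3, byrow = TRUE)
    P <- matrix(c(0.1777, -0.0449, 0.0297,
                  -0.0449, 0.0945, -0.0197,
                  0.0297, -0.0197, 0.0315), 3, 3, byrow = TRUE)
    resid <- c(0.769, 0.735, 0.794)
    beta <- c(0.0673, 0.1884, -0.1041)
    thresholds <- c(0, 1)
    retention <- c(0.72, 0.58, 0.65, 0.70, 0.85)
    n_gen <- 8L
    spacing <- 3
    if (is.null(n_ewes)) n_ewes <- 992L
  } else {
    G <- matrix(c(0.7201, 0.0860, 0.0788,
                  0.0860, 0.2090, 0.0295,
                  0.0788, 0.0295, 0.0654), 3, 3, byrow = TRUE)
    P <- matrix(c(0.9149, -0.0439, 0.0244,
                  -0.0439, 0.3350, -0.0371,
                  0.0244, -0.0371, 0.1153), 3, 3, byrow = TRUE)
    resid <- c(1.0, 1.066, 1.003)
    beta <- c(-3.3842, -0.3459, -0.4163)
    thresholds <- 0
    retention <- c(0.66, 0.79, 0.70, 0.65, 0.85)
    n_gen <- 7L
    spacing <- 2
    if (is.null(n_ewes)) n_ewes <- 857L
  }
  simulation_scenario(
    n_founder_ewes = max(14L, round(n_ewes / n_gen / 2)),
    n_generations = n_gen,
    ewes_per_generation = max(7L, round(n_ewes / n_gen)),
    true_G = G, true_P = P, true_resid = resid, thresholds = thresholds,
    beta = beta, parity_retention = retention, line = line,
    year_spacing = spacing)
}

#' Simulate a family-rotation pedigree
#'
#' Breeds `n_generations` discrete generations through `n_families` ram
#' families: one sire per family per generation, and dams born in family f
#' are mated in family f+1 (rotation), which limits inbreeding relative to
#' mating within the birth family.
#'
#' @param scenario A `simulation_scenario`.
#' @param rotate Disable to keep dams in their birth family (control used
#'   to demonstrate the inbreeding effect of rotation).
#' @return A `litter_pedigree`. The data frame carries extra columns
#'   `generation` and `family`.
#' @export
simulate_pedigree <- function(scenario, rotate = TRUE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  nf <- scenario$n_families
  ids <- character(0); sires <- character(0); dams <- character(0)
  sex <- character(0); gen <- integer(0); fam <- integer(0)
  # founders: one ram per family plus the founder ewes
  ram_ids <- sprintf("R0_%02d", seq_len(nf))
  ewe_ids <- sprintf("E0_%03d", seq_len(scenario$n_founder_ewes))
  ids <- c(ram_ids, ewe_ids)
  sires <- dams <- rep(NA_character_, length(ids))
  sex <- c(rep("male", nf), rep("female", scenario$n_founder_ewes))
  gen <- rep(0L, length(ids))
  fam <- c(seq_len(nf), (seq_along(ewe_ids) - 1L) %% nf + 1L)
  cur_rams <- ram_ids                      # index = family
  cur_ewes <- ewe_ids
  cur_ewe_fam <- fam[-seq_len(nf)]
  for (g in seq_len(scenario$n_generations)) {
    mate_fam <- if (rotate) cur_ewe_fam %% nf + 1L else cur_ewe_fam
    n_off <- scenario$ewes_per_generation + nf
    if (length(cur_ewes) == 0L || any(tabulate(mate_fam, nf) == 0L))
      stop("infeasible pedigree shape: a family has no dams in generation ", g)
    off_fam <- (seq_len(n_off) - 1L) %% nf + 1L
    off_dam <- vapply(off_fam, function(f) {
      cand <- cur_ewes[mate_fam == f]
      cand[sample.int(length(cand), 1L)]
    }, "")
    off_sire <- cur_rams[off_fam]
    off_sex <- c(rep("male", nf), rep("female", n_off - nf))
    off_ids <- sprintf("%s%d_%03d", ifelse(off_sex == "male", "R", "E"),
                       g, seq_len(n_off))
    ids <- c(ids, off_ids); sires <- c(sires, off_sire)
    dams <- c(dams, off_dam); sex <- c(sex, off_sex)
    gen <- c(gen, rep(g, n_off)); fam <- c(fam, off_fam)
    cur_rams <- off_ids[seq_len(nf)]        # one replacement ram per family
    cur_ewes <- off_ids[off_sex == "female"]
    cur_ewe_fam <- off_fam[off_sex == "female"]
  }
  ped <- data.frame(id = ids, sire = sires, dam = dams, sex = sex,
                    birth_year = 2000L + gen * scenario$year_spacing,
                    stringsAsFactors = FALSE)
  out <- new_litter_pedigree(ped)
  ord <- match(out$ped$id, ids)
  out$ped$generation <- gen[ord]
  out$ped$family <- fam[ord]
  out
}

#' Simulate additive-genetic coefficient vectors down a pedigree
#'
#' Founders draw their coefficients from MVN(0, G); descendants take the
#' parent average plus a Mendelian-sampling deviation with covariance
#' `d_i * G`, where `d_i` is the inbreeding-adjusted Mendelian-sampling
#' variance (0.5 - 0.25(F_s + F_d) with both parents known).
#'
#' @param pedigree A `litter_pedigree`.
#' @param true_G True coefficient covariance.
#' @return `n x q` matrix of coefficients, rownames = animal ids.
#' @export
simulate_breeding_values <- function(pedigree, true_G) {
  q <- ncol(true_G)
  n <- pedigree$n
  F <- compute_inbreeding(pedigree)
  s <- pedigree$ped$sire_idx
  d <- pedigree$ped$dam_idx
  ev <- eigen(true_G, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)  # G may be singular
  a <- matrix(0, n, q)
  for (i in seq_len(n)) {
    di <- if (s[i] > 0L && d[i] > 0L) 0.5 - 0.25 * (F[s[i]] + F[d[i]])
          else if (s[i] > 0L) 0.75 - 0.25 * F[s[i]]
          else if (d[i] > 0L) 0.75 - 0.25 * F[d[i]]
          else 1
    pa <- numeric(q)
    if (s[i] > 0L) pa <- pa + 0.5 * a[s[i], ]
    if (d[i] > 0L) pa <- pa + 0.5 * a[d[i], ]
    a[i, ] <- pa + sqrt(di) * drop(L %*% stats::rnorm(q))
  }
  rownames(a) <- pedigree$ped$id
  a
}

#' Simulate litter-size records from the threshold trajectory model
#'
#' Every non-founder female becomes a recorded ewe. Each draws
#' permanent-environment coefficients from MVN(0, P), records parity 1 in
#' the year after her birth cohort, and survives to each next parity by an
#' independent retention draw. The liability of a record is
#' year + month + phi' beta + phi' a + phi' p + e, with e drawn from the
#' parity class's residual variance; the observed category follows from the
#' thresholds and litter size is decoded as the category's minimal count.
#'
#' @param pedigree A `litter_pedigree` from [simulate_pedigree()].
#' @param a Breeding-value matrix from [simulate_breeding_values()].
#' @param scenario The `simulation_scenario`.
#' @return List with `records` (a `parity_records` data.frame) and `truth`
#'   (per-record decomposition of every liability, the PE coefficient
#'   matrix, year and month effects) sufficient to reconstruct each
#'   liability exactly.
#' @export
simulate_records <- function(pedigree, a, scenario) {
  basis <- build_basis(ncol(scenario$true_G) - 1L)
  phi <- basis$phi
  ewes <- which(pedigree$ped$sex == "female" & pedigree$ped$generation > 0L)
  n_ewes <- length(ewes)
  q <- ncol(scenario$true_P)
  ev <- eigen(scenario$true_P, symmetric = TRUE)
  Lp <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q)
  pmat <- t(Lp %*% matrix(stats::rnorm(q * n_ewes), q, n_ewes))
  rownames(pmat) <- pedigree$ped$id[ewes]

  years <- sort(unique(as.vector(
    outer(pedigree$ped$birth_year[ewes] + 1L, 0:5, "+"))))
  year_eff <- stats::setNames(stats::rnorm(length(years), 0, scenario$year_sd),
                              years)
  month_eff <- scenario$month_effects
  rows <- vector("list", n_ewes)
  for (j in seq_len(n_ewes)) {
    i <- ewes[j]
    last <- 1L
    while (last < 6L && stats::runif(1) <= scenario$parity_retention[last])
      last <- last + 1L
    ts <- seq_len(last)
    month <- sample.int(3L, last, replace = TRUE, prob = c(0.4, 0.35, 0.25))
    year <- pedigree$ped$birth_year[i] + 1L + (ts - 1L)
    cls <- assign_residual_class(ts, scenario$line)
    e <- stats::rnorm(last, 0, sqrt(scenario$true_resid[cls]))
    fx <- drop(phi[ts, , drop = FALSE] %*% scenario$beta)
    gen <- drop(phi[ts, , drop = FALSE] %*% a[pedigree$ped$id[i], ])
    pe <- drop(phi[ts, , drop = FALSE] %*% pmat[j, ])
    ye <- year_eff[as.character(year)]
    systematic <- ye + month_eff[month] + fx + gen + pe
    liab <- systematic + e   # single rounding: liability reconstructs bitwise
    cat <- findInterval(liab, scenario$thresholds) + 1L
    rows[[j]] <- data.frame(ewe = pedigree$ped$id[i], year = year,
                            month = c(9L, 10L, 11L)[month], parity = ts,
                            litter_size = cat,  # minimal count per category
                            liability = liab, systematic = unname(systematic),
                            year_effect = unname(ye),
                            month_effect = month_eff[month],
                            fixed_regression = fx, genetic = gen,
                            permanent_env = pe, residual = e,
                            stringsAsFactors = FALSE)
  }
  truth_rec <- do.call(rbind, rows)
  rownames(truth_rec) <- NULL
  rec <- make_records(ewe = truth_rec$ewe,
                      year_level = as.integer(factor(truth_rec$year)),
                      month_level = match(truth_rec$month, c(9L, 10L, 11L)),
                      parity = truth_rec$parity,
                      litter_size = truth_rec$litter_size,
                      line = scenario$line)
  list(records = rec,
       truth = list(records = truth_rec, p = pmat,
                    year_effects = year_eff,
                    month_effects = month_eff, scenario = scenario))
}

#' Simulate and write a complete dataset
#'
#' Runs the full generator under one seed and writes the pedigree and
#' records files in the dialects the readers consume, plus tab-delimited
#' truth files (full precision, so every liability can be reconstructed
#' exactly from its components) and a JSON run manifest.
#'
#' @param scenario A `simulation_scenario`.
#' @param dir Output directory (created if needed).
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @return Invisibly, a list with the `pedigree`, `records`, `truth` and the
#'   file paths written.
#' @export
simulate_dataset <- function(scenario, dir, seed = 1L) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- simulate_pedigree(scenario)
  a <- simulate_breeding_values(ped, scenario$true_G)
  sim <- simulate_records(ped, a, scenario)
  paths <- list(pedigree = file.path(dir, "pedigree.tsv"),
                records = file.path(dir, "records.tsv"),
                truth_records = file.path(dir, "truth_records.tsv"),
                truth_bv = file.path(dir, "truth_breeding_values.tsv"),
                truth_pe = file.path(dir, "truth_permanent_env.tsv"),
                truth_years = file.path(dir, "truth_year_effects.tsv"),
                manifest = file.path(dir, "manifest.json"))
  pd <- ped$ped
  pd$sire[is.na(pd$sire)] <- "0"
  pd$dam[is.na(pd$dam)] <- "0"
  utils::write.table(pd[, c("id", "sire", "dam", "sex", "birth_year")],
                     paths$pedigree, sep = "\t", quote = FALSE,
                     row.names = FALSE,
                     col.names = c("animal", "sire", "dam", "sex", "birth_year"))
  utils::write.table(sim$truth$records[, c("ewe", "year", "month", "parity",
                                           "litter_size")],
                     paths$records, sep = "\t", quote = FALSE, row.names = FALSE)
  write_full_precision(sim$truth$records, paths$truth_records)
  bv <- data.frame(id = rownames(a), a, check.names = FALSE)
  names(bv)[-1] <- paste0("a", seq_len(ncol(a)) - 1L)
  write_full_precision(bv, paths$truth_bv)
  pe <- data.frame(ewe = rownames(sim$truth$p), sim$truth$p, check.names = FALSE)
  names(pe)[-1] <- paste0("p", seq_len(ncol(sim$truth$p)) - 1L)
  write_full_precision(pe, paths$truth_pe)
  ye <- data.frame(year = names(sim$truth$year_effects),
                   effect = unname(sim$truth$year_effects))
  write_full_precision(ye, paths$truth_years)
  manifest <- list(seed = seed, line = scenario$line,
                   n_animals = ped$n, n_records = nrow(sim$records),
                   n_ewes = length(unique(sim$records$ewe)),
                   scenario = scenario[c("n_founder_ewes", "n_generations",
                                         "ewes_per_generation", "n_families",
                                         "true_resid", "thresholds", "year_sd",
                                         "month_effects", "beta",
                                         "parity_retention", "line")],
                   true_G = scenario$true_G, true_P = scenario$true_P,
                   files = lapply(paths[1:6], basename),
                   digests = as.list(tools::md5sum(unlist(paths[1:6]))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(pedigree = ped, records = sim$records, truth = sim$truth,
                 paths = paths))
}

# full-precision text so liabilities reconstruct bitwise from components
write_full_precision <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
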