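mini_scenario <- function(line = "conventional", n_gen = 0, ...) {
  q <- 3
  simulation_scenario(
    n_founder_ewes = 14, n_generations = n_gen, ewes_per_generation = 10,
    true_G = diag(0.2, q), true_P = diag(0.1, q),
    true_resid = c(1, 1, 1),
    thresholds = if (line == "conventional") 0 else c(0, 1),
    beta = c(0, 0, 0), line = line, ...)
}

test_that("a zero-generation scenario yields founders only, all non-inbred", {
  sc <- mini_scenario()
  set.seed(1)
  ped <- simulate_pedigree(sc)
  expect_equal(ped$n, 21L)                    # 7 rams + 14 founder ewes
  expect_true(all(ped$ped$sire_idx == 0L))
  expect_equal(unname(compute_inbreeding(ped)), rep(0, 21))
})

test_that("family rotation prevents full-sib matings and lowers inbreeding", {
  sc <- make_paper_like_scenario("conventional", n_ewes = 150)
  set.seed(7)
  ped <- simulate_pedigree(sc, rotate = TRUE)
  pd <- ped$ped
  # no mating pair (sire, dam) of any animal shares both parents
  for (g in 2:max(pd$generation)) {
    off <- pd[pd$generation == g, ]
    sires <- pd[match(off$sire, pd$id), ]
    dams <- pd[match(off$dam, pd$id), ]
    fullsib <- !is.na(sires$sire) & !is.na(dams$sire) &
      sires$sire == dams$sire & sires$dam == dams$dam
    expect_false(any(fullsib))
  }
  set.seed(7)
  ped_no <- simulate_pedigree(sc, rotate = FALSE)
  expect_lt(mean(compute_inbreeding(ped)), mean(compute_inbreeding(ped_no)))
})

test_that("breeding values follow the pedigree covariance structure", {
  set.seed(2)
  q <- 3
  G0 <- matrix(c(0.4, 0.15, 0.05, 0.15, 0.3, 0.1, 0.05, 0.1, 0.25), q, q)
  # founder draws: empirical covariance within 10% at n = 5000
  founders <- new_litter_pedigree(data.frame(id = sprintf("f%04d", 1:5000),
                                             sire = NA_character_,
                                             dam = NA_character_))
  a <- simulate_breeding_values(founders, G0)
  emp <- stats::cov(a)
  expect_true(all(abs(diag(emp) - diag(G0)) / diag(G0) < 0.1))
  # zero G gives zero coefficients
  a0 <- simulate_breeding_values(founders, matrix(0, q, q))
  expect_true(all(a0 == 0))
})

test_that("replicated breeding values reproduce the Kronecker covariance A x G", {
  set.seed(3)
  ped <- new_litter_pedigree(data.frame(
    id = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j"),
    sire = c(NA, NA, NA, "a", "a", "d", "d", "f", "f", "h"),
    dam = c(NA, NA, NA, "b", "c", "e", "c", "g", "e", "i")))
  G0 <- matrix(c(0.5, 0.2, 0.2, 0.4), 2, 2)
  reps <- 2000
  draws <- vapply(seq_len(reps),
                  function(i) as.vector(t(simulate_breeding_values(ped, G0))),
                  numeric(2 * 10))
  emp <- stats::cov(t(draws))
  truth <- kronecker(tabular_A(ped), G0)
  # 15% relative on sizeable entries, Monte-Carlo floor on the small ones
  expect_true(all(abs(emp - truth) < pmax(0.15 * abs(truth), 0.045)))
})

test_that("record categories match the closed-form normal mass at the simulated means", {
  sc <- make_paper_like_scenario("prolific", n_ewes = 3600)
  set.seed(4)
  ped <- simulate_pedigree(sc)
  a <- simulate_breeding_values(ped, sc$true_G)
  sim <- simulate_records(ped, a, sc)
  tr <- sim$truth$records
  expect_gt(nrow(tr), 1e4 * 0.9)
  cm <- assign_residual_class(1:6, "prolific")
  for (t in 1:6) {
    sub <- tr[tr$parity == t, ]
    m <- sub$systematic
    sd_e <- sqrt(sc$true_resid[cm[t]])
    p1_hat <- mean(stats::pnorm((0 - m) / sd_e))
    p3_hat <- mean(1 - stats::pnorm((1 - m) / sd_e))
    expect_lt(abs(mean(sub$litter_size == 1) - p1_hat), 0.02)
    expect_lt(abs(mean(sub$litter_size == 3) - p3_hat), 0.02)
  }
})

test_that("degenerate scenarios produce the expected categories", {
  sc <- mini_scenario("conventional", n_gen = 3)
  sc$thresholds <- 1e10                      # bracketing: everything category 1
  set.seed(5)
  ped <- simulate_pedigree(sc)
  a <- simulate_breeding_values(ped, sc$true_G)
  sim <- simulate_records(ped, a, sc)
  expect_true(all(sim$records$category == 1L))

  # no genetics, no effects, threshold 0: a balanced binary split
  sc2 <- make_paper_like_scenario("conventional", n_ewes = 3400)
  sc2$true_G <- matrix(0, 3, 3); sc2$true_P <- matrix(0, 3, 3)
  sc2$beta <- c(0, 0, 0); sc2$year_sd <- 0
  sc2$month_effects <- c(0, 0, 0)
  sc2$true_resid <- c(1, 1, 1)
  set.seed(6)
  ped2 <- simulate_pedigree(sc2)
  a2 <- simulate_breeding_values(ped2, sc2$true_G)
  sim2 <- simulate_records(ped2, a2, sc2)
  expect_gt(nrow(sim2$records), 1e4 * 0.9)
  expect_lt(abs(mean(sim2$records$category == 1L) - 0.5), 0.02)
})

test_that("paper-like scenarios carry each line's documented shape", {
  pro <- make_paper_like_scenario("prolific")
  expect_equal(pro$n_categories, 3L)
  expect_equal(assign_residual_class(1:6, pro$line), c(1L, 2L, 2L, 2L, 3L, 3L))
  con <- make_paper_like_scenario("conventional")
  expect_equal(con$n_categories, 2L)
  expect_equal(assign_residual_class(1:6, con$line), c(1L, 2L, 3L, 3L, 3L, 2L))
  # record count close to the prolific line's size under default retention
  set.seed(8)
  ped <- simulate_pedigree(pro)
  a <- simulate_breeding_values(ped, pro$true_G)
  sim <- simulate_records(ped, a, pro)
  expect_equal(nrow(sim$records), 2751, tolerance = 0.15)
  expect_equal(nrow(sim$records) / length(unique(sim$records$ewe)), 2.77,
               tolerance = 0.15)
})

test_that("the truth file reconstructs every liability exactly", {
  sc <- make_paper_like_scenario("conventional", n_ewes = 60)
  dir <- tempfile("ds")
  out <- simulate_dataset(sc, dir, seed = 9)
  tr <- out$truth$records
  # in memory: liability is bitwise systematic + residual
  expect_identical(tr$liability, tr$systematic + tr$residual)
  recon <- tr$year_effect + tr$month_effect + tr$fixed_regression +
    tr$genetic + tr$permanent_env
  expect_equal(tr$systematic, recon, tolerance = 1e-12)
  # from the full-precision text file: bitwise round trip
  disk <- utils::read.table(out$paths$truth_records, header = TRUE, sep = "\t")
  expect_identical(disk$liability, tr$liability)
  expect_identical(disk$residual, tr$residual)
  expect_identical(disk$liability, disk$systematic + disk$residual)
  # files parse with the package's own readers
  ped <- read_pedigree(out$paths$pedigree)
  rec <- read_records(out$paths$records, "conventional", pedigree = ped)
  expect_equal(nrow(rec), nrow(out$records))
  # reproducibility: same seed, same digests
  out2 <- simulate_dataset(sc, tempfile("ds2"), seed = 9)
  for (f in c("pedigree", "records", "truth_records"))
    expect_identical(unname(tools::md5sum(out$paths[[f]])),
                     unname(tools::md5sum(out2$paths[[f]])))
})
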