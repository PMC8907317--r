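test_that("no-drift limit keeps population frequencies at the ancestral value", {
  cfg <- sim_config(sizes = c(A = 20L, B = 20L), n_loci = 400L,
                    drift = c(A = 0.002, B = 0.002), clades = list(),
                    clade_drift = numeric(0), fixed_pairs = numeric(0),
                    target_fst = NULL, missing_rate = 0)
  ft <- sample_reference_frequencies(cfg, 1)
  expect_lt(mean(abs(ft$freq["A", ] - ft$freq["B", ])), 0.03)
  pan <- sample_genotypes(ft, cfg$sizes, 2)
  fst <- pairwise_fst_matrix(pan, c("A", "B"))$fst["A", "B"]
  expect_lt(abs(fst), 0.02)
})

test_that("exact fixation yields per-locus theta of exactly 1", {
  cfg <- sim_config(sizes = c(A = 10L, B = 10L), n_loci = 20L,
                    drift = c(A = 0.3, B = 0.3), clades = list(),
                    clade_drift = numeric(0),
                    fixed_pairs = c("A:B" = 0.5),
                    target_fst = NULL, missing_rate = 0,
                    fixation = "exact")
  ft <- sample_reference_frequencies(cfg, 3)
  forced <- !is.na(attr(ft, "fixed_for"))
  expect_gt(sum(forced), 0)
  pan <- sample_genotypes(ft, cfg$sizes, 4)
  st <- per_locus_fst(pan, "A", "B")
  expect_true(all(st$theta[forced] == 1))
  expect_true(all(st$fixed[forced]))
})

test_that("binomial sampling at p = 0.5 gives the HWE heterozygote rate", {
  ft <- freq_table(matrix(0.5, 1, 100, dimnames = list("A", NULL)))
  pan <- sample_genotypes(ft, c(A = 100L), 11)
  expect_equal(mean(pan$calls == 1L), 0.5, tolerance = 0.03)
  ft1 <- freq_table(matrix(1, 1, 50, dimnames = list("A", NULL)))
  expect_true(all(sample_genotypes(ft1, c(A = 5L), 1)$calls == 2L))
})

test_that("seeded simulation is reproducible", {
  cfg <- small_config()
  expect_identical(simulate_panel(cfg, 9)$panel$calls,
                   simulate_panel(cfg, 9)$panel$calls)
  pan <- simulate_panel(cfg, 9)$panel
  expect_identical(inject_missingness(pan, 0.1, 4)$calls,
                   inject_missingness(pan, 0.1, 4)$calls)
})

test_that("missingness injection hits the requested rate", {
  cfg <- small_config(n_loci = 500L)
  pan <- simulate_panel(cfg, 2)$panel
  expect_identical(inject_missingness(pan, 0, 1)$calls, pan$calls)
  with_na <- inject_missingness(pan, 0.05, 1)
  expect_lt(abs(mean(is.na(with_na$calls)) - 0.05), 0.01)
})

test_that("a half-missing sample fails the downstream call-rate filter", {
  cfg <- small_config(n_loci = 200L)
  pan <- simulate_panel(cfg, 3)$panel
  calls <- pan$calls
  calls[1, seq(1, 200, by = 2)] <- NA   # sample 1 at 50% call rate
  pan2 <- genotype_panel(calls, pan$samples, pan$loci)
  res <- filter_individual_callrate(pan2, 0.90)
  expect_true(pan$samples$id[1] %in% res$report$id)
})

test_that("simulated panels are in Hardy-Weinberg equilibrium (F_IS ~ 0)", {
  cfg <- sim_config(n_loci = 300L, missing_rate = 0)
  pan <- simulate_panel(cfg, 21)$panel
  ds <- diversity_summary(pan, n_perm = 500L, seed = 2)
  # permutation P at alpha = 0.01, each population
  expect_true(all(ds$Fis_P > 0.01))
})

test_that("replicate simulation recovers its inputs in the limits", {
  pan <- toy_panel(matrix(1L, 20, 50))
  clean <- simulate_replicates(pan, 3, seed = 1)
  expect_true(all(clean$calls == 1L))
  ado <- simulate_replicates(pan, 3, ado_rate = 0.05, seed = 2)
  hom_frac <- mean(ado$calls != 1L, na.rm = TRUE)
  expect_lt(abs(hom_frac - 0.05), 0.01)
  dead <- simulate_replicates(pan, 3, fail_rate = 1 - 1e-12, seed = 3)
  expect_true(all(is.na(dead$calls)))
})

test_that("calibration reproduces the reference FST matrix entry-wise", {
  cfg <- sim_config()
  cal <- suppressWarnings(calibrate_drift(cfg, seed = 5))
  # verify on a fresh, larger panel so the check is independent of the
  # calibration iterations themselves
  big <- cal$config
  big$n_loci <- 5000L
  big$missing_rate <- 0
  sim <- simulate_panel(big, 6)
  realized <- pairwise_fst_matrix(sim$panel, names(cfg$sizes))$fst
  expect_lt(max(abs(realized - canid_target_fst())), 0.05)
})

test_that("two-population symmetric target calibrates to equal drift", {
  tgt <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  cfg <- sim_config(sizes = c(A = 25L, B = 25L), n_loci = 400L,
                    drift = c(A = 0.4, B = 0.4), clades = list(),
                    clade_drift = numeric(0), fixed_pairs = numeric(0),
                    target_fst = tgt, missing_rate = 0)
  cal <- suppressWarnings(calibrate_drift(cfg, seed = 8, n_loci_cal = 2000))
  expect_lt(abs(cal$realized["A", "B"] - 0.5), 0.05)
  # a symmetric start keeps the solver on the symmetric solution
  expect_lt(abs(cal$drift[["A"]] - cal$drift[["B"]]), 0.1)
})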