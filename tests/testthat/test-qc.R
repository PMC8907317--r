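test_that("individual call-rate filter keeps the boundary, locus filter drops it", {
  # 3 samples at call rates 0.85 / 0.90 / 0.95 over 20 loci
  calls <- matrix(1L, 3, 20)
  calls[1, 1:3] <- NA
  calls[2, 1:2] <- NA
  calls[3, 1] <- NA
  pan <- toy_panel(calls)
  res <- filter_individual_callrate(pan, 0.90)
  expect_equal(res$report$id, "s01")
  expect_equal(n_samples(res$panel), 2)

  # loci at call rate 0.9 (exactly) are removed: strict > threshold
  calls2 <- matrix(1L, 10, 3)
  calls2[1, 1] <- NA          # locus 1 at 0.9 exactly
  calls2[1:2, 2] <- NA        # locus 2 at 0.8
  pan2 <- toy_panel(calls2)
  res2 <- filter_locus_callrate(pan2, 0.90)
  expect_setequal(res2$report$id, c("L001", "L002"))
  expect_equal(n_loci(res2$panel), 1)
})

test_that("call-rate filters error when nothing survives and are idempotent", {
  all_bad <- toy_panel(matrix(NA_integer_, 3, 4))
  expect_error(filter_individual_callrate(all_bad), "all samples")
  cfg <- small_config()
  pan <- inject_missingness(simulate_panel(cfg, 1)$panel, 0.05, 2)
  once <- filter_individual_callrate(pan, 0.9)
  twice <- filter_individual_callrate(once$panel, 0.9)
  expect_equal(nrow(twice$report), 0)
  expect_identical(twice$panel$calls, once$panel$calls)
})

test_that("LD pruning removes exactly one of each duplicated locus pair", {
  set.seed(14)
  base <- panel_from_freqs(matrix(runif(30, 0.3, 0.7), 1, 30,
                                  dimnames = list("A", NULL)),
                           c(A = 40L), seed = 4)
  # interleave each locus with an exact copy on the same chromosome
  calls <- base$calls[, rep(1:30, each = 2)]
  loci <- base$loci[rep(1:30, each = 2), ]
  loci$id <- sprintf("L%03d", 1:60)
  loci$chrom <- rep(1:2, each = 30)
  loci$pos <- stats::ave(seq_len(60), loci$chrom, FUN = seq_along) * 1000L
  pan <- genotype_panel(calls, base$samples, loci)
  res <- ld_prune(pan, 0.5, 50)
  expect_equal(n_loci(res$panel), 30)
  expect_true(all(res$report$r2 > 0.999))
  # no retained within-window pair exceeds the threshold (exhaustive re-scan)
  m <- res$panel$calls
  ch <- res$panel$loci$chrom
  for (i in seq_len(ncol(m) - 1)) for (j in seq(i + 1, ncol(m))) {
    if (ch[i] != ch[j] || j - i >= 50) next
    r <- suppressWarnings(cor(m[, i], m[, j], use = "pairwise.complete.obs"))
    if (!is.na(r)) expect_lte(r^2, 0.5 + 1e-12)
  }
})

test_that("independent loci survive pruning untouched", {
  pan <- panel_from_freqs(matrix(0.5, 1, 40, dimnames = list("A", NULL)),
                          c(A = 60L), seed = 6)
  res <- ld_prune(pan)
  expect_equal(nrow(res$report), 0)
  expect_equal(n_loci(res$panel), 40)
})

test_that("purity screen removes planted F1s but keeps pure references", {
  cfg <- sim_config(n_loci = 150L)
  sim <- simulate_panel(cfg, 15)
  freqs <- sim$freqs
  f1 <- simulate_f1(freqs, "WIT", "D", n = 2, seed = 3)
  # mislabel the hybrids as Italian wolves
  f1$samples$group <- "WIT"
  f1$samples$id <- c("hyb1", "hyb2")
  pan <- bind_samples(sim$panel, f1)
  res <- purity_screen(pan, seed = 5)
  expect_true(all(c("hyb1", "hyb2") %in% res$report$id))
  # at most a stray pure reference dips under the strict 0.95 screen
  expect_lte(sum(sim$panel$samples$id %in% res$report$id), 2)
  # removed hybrids carried q near 0.5, far below the wolf threshold
  expect_true(all(res$report$own_q[res$report$id %in% c("hyb1", "hyb2")] < 0.7))
})

test_that("dogs are screened at their own, laxer threshold", {
  cfg <- sim_config(n_loci = 150L)
  sim <- simulate_panel(cfg, 18)
  f1 <- simulate_f1(sim$freqs, "WIT", "D", n = 4, seed = 9)
  f1$samples$id <- sprintf("adm%d", 1:4)
  # two mislabelled as dogs, two as Italian wolves; with a dog threshold
  # below 0.5 the admixed dogs pass while the admixed wolves fail
  f1$samples$group <- c("D", "D", "WIT", "WIT")
  pan <- bind_samples(sim$panel, f1)
  res <- purity_screen(pan, wild_q_min = 0.8, dog_q_min = 0.3, seed = 2)
  expect_setequal(res$report$id, c("adm3", "adm4"))
})

test_that("the qc pipeline applies stages in canonical order", {
  cfg <- sim_config(n_loci = 120L)
  pan <- inject_missingness(simulate_panel(cfg, 16)$panel, 0.02, 17)
  res <- run_qc(pan, purity = FALSE)
  expect_named(res$reports,
               c("individual_callrate", "locus_callrate", "ld_prune"))
  # re-applying any stage changes nothing
  again <- filter_locus_callrate(res$panel, 0.90)
  expect_equal(nrow(again$report), 0)
})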