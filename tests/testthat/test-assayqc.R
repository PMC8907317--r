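rep_set <- function(mat3) {
  # mat3: samples x loci x replicates integer array
  d <- dim(mat3)
  structure(list(
    calls = array(as.integer(mat3), d,
                  dimnames = list(sprintf("s%d", seq_len(d[1])),
                                  sprintf("L%d", seq_len(d[2])), NULL)),
    samples = data.frame(id = sprintf("s%d", seq_len(d[1])),
                         group = "A", source = "invasive"),
    loci = data.frame(id = sprintf("L%d", seq_len(d[2])), chrom = 1L,
                      pos = seq_len(d[2]), ref = "A", alt = "G",
                      category = NA_character_),
    truth = NULL), class = "replicate_set")
}

cell <- function(...) {
  v <- c(...)
  rep_set(array(v, c(1, 1, length(v))))
}

test_that("consensus follows the replicate-agreement rules", {
  expect_equal(consensus_genotype(cell(1, 1, 1))$consensus[1, 1], 1L)
  # het + dropout homozygote over two replicates reads as het
  expect_equal(consensus_genotype(cell(1, 0))$consensus[1, 1], 1L)
  # conflicting homozygotes are irreconcilable
  res <- consensus_genotype(cell(0, 2))
  expect_true(is.na(res$consensus[1, 1]))
  expect_true(res$conflict[1, 1])
  # a lone het among three successes is outvoted by agreeing homozygotes
  expect_equal(consensus_genotype(cell(1, 0, 0))$consensus[1, 1], 0L)
  # confirmed het wins over a single dropout
  expect_equal(consensus_genotype(cell(1, 1, 0))$consensus[1, 1], 1L)
  # single successful replicate is provisional
  res1 <- consensus_genotype(cell(2, NA, NA))
  expect_equal(res1$consensus[1, 1], 2L)
  expect_true(res1$provisional[1, 1])
  # all failed stays missing
  expect_true(is.na(consensus_genotype(cell(NA, NA))$consensus[1, 1]))
})

test_that("majority rule takes the modal call with het winning ties", {
  expect_equal(consensus_genotype(cell(0, 0, 1), "majority")$consensus[1, 1], 0L)
  expect_equal(consensus_genotype(cell(0, 1), "majority")$consensus[1, 1], 1L)
  expect_true(is.na(consensus_genotype(cell(0, 2), "majority")$consensus[1, 1]))
})

test_that("consensus is idempotent", {
  pan <- toy_panel(matrix(sample(0:2, 200, TRUE), 10, 20))
  rs <- simulate_replicates(pan, 3, ado_rate = 0.1, fa_rate = 0.02,
                            fail_rate = 0.1, seed = 3)
  cons <- consensus_genotype(rs)$consensus
  again <- rep_set(array(rep(cons, 3), c(10, 20, 3)))
  expect_equal(unname(consensus_genotype(again)$consensus), unname(cons))
})

test_that("error-free replicates give AS 1 and zero error rates", {
  pan <- toy_panel(matrix(sample(0:2, 300, TRUE), 15, 20))
  rs <- simulate_replicates(pan, 3, seed = 1)
  er <- error_rates(rs)
  expect_equal(unname(er$summary["AS"]), 1)
  expect_equal(unname(er$summary["ADO"]), 0)
  expect_equal(unname(er$summary["FA"]), 0)
  expect_equal(consensus_genotype(rs)$consensus[, ], pan$calls[, ])
})

test_that("injected ADO and FA rates are recovered within one point", {
  # ADO on an all-heterozygous truth
  het <- toy_panel(matrix(1L, 40, 100))
  rs <- simulate_replicates(het, 3, ado_rate = 0.05, seed = 2)
  er <- error_rates(rs)
  expect_lt(abs(er$summary[["ADO"]] - 0.05), 0.01)
  # FA on homozygous truth (10^4 cells)
  hom <- toy_panel(matrix(rep(c(0L, 2L), each = 50), 100, 100))
  rs2 <- simulate_replicates(hom, 3, fa_rate = 0.05, seed = 4)
  er2 <- error_rates(rs2)
  expect_lt(abs(er2$summary[["FA"]] - 0.05), 0.01)
  # one failed replicate in 200 attempts
  ok <- toy_panel(matrix(0L, 1, 10))
  rs3 <- simulate_replicates(ok, 2, seed = 5)
  rs3$calls[1, 1, 1] <- NA
  expect_equal(unname(error_rates(rs3)$summary["AS"]), 19 / 20)
})

test_that("blank samples yield zero amplification success", {
  pan <- toy_panel(matrix(0L, 2, 10))
  rs <- simulate_replicates(pan, 3, seed = 6)
  rs$calls[2, , ] <- NA    # blank control
  er <- error_rates(rs)
  expect_equal(er$per_sample$AS[2], 0)
  expect_equal(er$per_sample$AS[1], 1)
})

test_that("concordance counts mismatching co-called cells", {
  pan <- toy_panel(matrix(sample(0:2, 178, TRUE), 1, 178))
  cons <- pan$calls
  expect_equal(concordance(cons, pan)$overall, 0)
  cons2 <- cons
  cons2[1, 1] <- (cons2[1, 1] + 1L) %% 3L
  expect_equal(concordance(cons2, pan)$overall, 1 / 178)
  bad <- pan
  colnames(cons2) <- paste0("other", seq_len(ncol(cons2)))
  expect_error(concordance(cons2, pan), "no shared loci")
})

test_that("consensus from error-free replicates matches truth end to end", {
  cfg <- small_config(n_loci = 60L)
  pan <- simulate_panel(cfg, 8)$panel
  rs <- simulate_replicates(pan, 3, seed = 9)
  cons <- consensus_genotype(rs)$consensus
  expect_equal(concordance(cons, pan)$overall, 0)
})

test_that("PCoA separates groups and centres its coordinates", {
  pan <- fixed_two_pop_panel(5, 30)
  res <- pcoa(pan)
  expect_equal(unname(colMeans(res$coords)), c(0, 0), tolerance = 1e-6)
  ax1 <- res$coords[, 1]
  expect_true(all(ax1[1:5] * ax1[6:10] < 0))  # groups on opposite sides
  # identical samples land on identical coordinates
  pan2 <- toy_panel(rbind(c(0L, 2L, 1L), c(0L, 2L, 1L), c(2L, 0L, 1L)))
  res2 <- pcoa(pan2)
  expect_equal(res2$coords[1, ], res2$coords[2, ], tolerance = 1e-6)
})

test_that("hybrids fall between parental centroids in PCoA space", {
  cfg <- sim_config(n_loci = 150L, missing_rate = 0)
  sim <- simulate_panel(cfg, 23)
  freqs <- sim$freqs
  f1 <- simulate_f1(freqs, "J", "WIT", n = 5, seed = 2)
  pan <- bind_samples(sim$panel, f1)
  res <- pcoa(pan)
  grp <- pan$samples$group
  c_j <- colMeans(res$coords[grp == "J", , drop = FALSE])
  c_w <- colMeans(res$coords[grp == "WIT", , drop = FALSE])
  c_h <- colMeans(res$coords[grp == "J-WIT", , drop = FALSE])
  # the hybrid centroid projects inside the parental segment on axis 1-2
  t_h <- sum((c_h - c_j) * (c_w - c_j)) / sum((c_w - c_j)^2)
  expect_gt(t_h, 0.25)
  expect_lt(t_h, 0.75)
})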