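test_that("closed forms at p = 0.5 are reproduced", {
  # 10 diploids, forced to exact frequency 0.5 with half heterozygotes
  g <- c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 1L)  # p = 0.5, Ho = 0.6
  pan <- toy_panel(matrix(g, ncol = 1))
  ds <- diversity_summary(pan, n_perm = 0)
  expect_equal(ds$PIC, 1 - 0.5 - 2 * 0.25 * 0.25)   # 0.375
  expect_equal(ds$Ae, 2)
  expect_equal(ds$uHe, (20 / 19) * 0.5)
  expect_equal(ds$Ho, 0.6)
  expect_equal(ds$PID, 0.375)
  expect_equal(ds$PID_sibs, 0.59375)
})

test_that("PID matches exhaustive genotype-pair enumeration on 3-locus toys", {
  set.seed(7)
  for (rep in 1:10) {
    p <- runif(3, 0.05, 0.95)
    ft <- freq_table(matrix(p, 1, 3, dimnames = list("A", NULL)))
    pan <- sample_genotypes(ft, c(A = 400L), seed = rep)
    est <- pid(pan, "A")
    phat <- colMeans(pan$calls) / 2
    expect_equal(unname(est["pid"]), prod(vapply(phat, pid_oracle_locus, 0)),
                 tolerance = 1e-12)
    expect_equal(unname(est["pid_sibs"]),
                 prod(vapply(phat, pidsibs_oracle_locus, 0)),
                 tolerance = 1e-12)
  }
})

test_that("PID obeys the product rule and monotone decrease in loci", {
  p <- rep(0.5, 6)
  ft <- freq_table(matrix(p, 1, 6, dimnames = list("A", NULL)))
  pan <- toy_panel(matrix(1L, 4, 6))   # every locus het -> p = 0.5 exactly
  expect_equal(unname(pid(pan, "A")["pid"]), 0.375^6)
  set.seed(1)
  pan2 <- panel_from_freqs(matrix(runif(8, 0.2, 0.8), 1, 8,
                                  dimnames = list("A", NULL)),
                           c(A = 50L), seed = 2)
  vals <- vapply(1:8, function(k) unname(pid(pan2[, 1:k], "A")["pid"]), 0)
  expect_true(all(diff(vals) < 0))
})

test_that("PIDsibs >= PID for any allele frequencies", {
  set.seed(11)
  p <- runif(200)
  q <- 1 - p
  s2 <- p^2 + q^2; s4 <- p^4 + q^4
  pid_l <- s4 + (2 * p * q)^2
  sib_l <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  expect_true(all(sib_l >= pid_l))
})

test_that("uHe exceeds He at finite n and converges with n", {
  p <- 0.3
  he <- 2 * p * (1 - p)
  for (n in c(5, 50, 5000)) {
    uhe <- (2 * n / (2 * n - 1)) * he
    expect_gt(uhe, he)
  }
  expect_equal((2 * 5000 / (2 * 5000 - 1)) * he, he, tolerance = 3e-4)
})

test_that("rarefaction at full depth returns the observed allele count", {
  # equal sample depth everywhere: g = N so Ar = Ao exactly
  pan <- toy_panel(matrix(c(0L, 1L, 2L, 1L, 0L, 0L, 2L, 2L), 4, 2),
                   groups = rep("A", 4))
  ds <- diversity_summary(pan, n_perm = 0)
  expect_equal(ds$Ar, ds$Ao, tolerance = 1e-12)
})

test_that("private alleles are counted once per population", {
  # locus 1: alt allele only in A; locus 2: shared
  calls <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 1L), c(0L, 1L))
  pan <- toy_panel(calls, groups = c("A", "A", "B", "B"))
  ds <- diversity_summary(pan, n_perm = 0)
  expect_equal(ds$Np[ds$population == "A"], 1)
  expect_equal(ds$Np[ds$population == "B"], 0)
})

test_that("AMOVA components match the hand-computed toy", {
  # group 1: dosages 0, 1; group 2: 2, 1 (single locus)
  pan <- toy_panel(matrix(c(0L, 1L, 2L, 1L), 4, 1),
                   groups = c("g1", "g1", "g2", "g2"))
  res <- amova(pan, n_perm = 0)
  expect_equal(res$ss[["among"]], 1)
  expect_equal(res$ss[["within"]], 1)
  expect_equal(res$sigma_among, 0.25)
  expect_equal(res$sigma_within, 0.5)
  expect_equal(res$phi_pt, 1 / 3)
})

test_that("AMOVA reaches the degenerate limits", {
  fixed <- fixed_two_pop_panel(6, 10)
  expect_equal(amova(fixed, n_perm = 0)$phi_pt, 1)
  null_pan <- panel_from_freqs(matrix(0.5, 2, 50,
                                      dimnames = list(c("A", "B"), NULL)),
                               c(A = 20L, B = 20L), seed = 4)
  res <- amova(null_pan, n_perm = 99, seed = 1)
  expect_lt(res$phi_pt, 0.05)
  expect_gt(res$p_value, 0.05)
  expect_error(amova(null_pan, groups = "A"), "2 groups")
})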