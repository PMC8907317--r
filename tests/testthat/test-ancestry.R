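test_that("supervised q hits the vertices and the symmetric point", {
  P <- rbind(A = rep(0.999, 20), B = rep(0.001, 20))
  ft <- freq_table(P)
  # individual carrying only A's alleles
  pure <- toy_panel(matrix(2L, 1, 20))
  qa <- supervised_q(pure, ft)$Q
  expect_gt(qa[1, "A"], 0.999)
  # heterozygous at every locus fixed between A and B
  het <- toy_panel(matrix(1L, 1, 20))
  qh <- supervised_q(het, ft)$Q
  expect_equal(unname(qh[1, ]), c(0.5, 0.5), tolerance = 1e-6)
  expect_error(supervised_q(toy_panel(matrix(NA_integer_, 1, 20)), ft),
               "no genotyped loci")
})

test_that("supervised q agrees with a simplex grid search on small toys", {
  set.seed(3)
  loglik_at <- function(q, g, P) {
    x <- pmin(pmax(colSums(q * P), 1e-9), 1 - 1e-9)
    sum(g * log(x) + (2 - g) * log1p(-x), na.rm = TRUE)
  }
  for (rep in 1:5) {
    P <- rbind(A = runif(5, 0.05, 0.95), B = runif(5, 0.05, 0.95))
    g <- sample(0:2, 5, replace = TRUE)
    est <- supervised_q(matrix(g, 1), freq_table(P), tol = 1e-12,
                        max_iter = 50000)$Q
    grid <- seq(0, 1, length.out = 2001)
    ll <- vapply(grid, function(a) loglik_at(c(a, 1 - a), g, P), 0)
    q_star <- grid[which.max(ll)]
    expect_equal(unname(est[1, "A"]), q_star, tolerance = 1e-3)
  }
  # 3-cluster toy against a coarse simplex grid
  P3 <- rbind(A = runif(6, 0.05, 0.95), B = runif(6, 0.05, 0.95),
              C = runif(6, 0.05, 0.95))
  g3 <- sample(0:2, 6, replace = TRUE)
  est3 <- supervised_q(matrix(g3, 1), freq_table(P3), tol = 1e-12,
                       max_iter = 50000)$Q
  step <- 0.01
  bestll <- -Inf; bestq <- NULL
  for (a in seq(0, 1, step)) for (b in seq(0, 1 - a, step)) {
    llv <- loglik_at(c(a, b, 1 - a - b), g3, P3)
    if (llv > bestll) { bestll <- llv; bestq <- c(a, b, 1 - a - b) }
  }
  expect_lt(max(abs(est3[1, ] - bestq)), 0.011)
})

test_that("EM log-likelihood is monotone and rows sum to one", {
  cfg <- small_config(n_loci = 80L)
  pan <- simulate_panel(cfg, 12)$panel
  fit <- admixture(pan, K = 2, n_runs = 2, seed = 5)
  expect_true(all(diff(fit$trace) >= -1e-6))
  expect_equal(unname(rowSums(fit$Q)), rep(1, n_samples(pan)),
               tolerance = 1e-6)
  expect_true(all(fit$Q >= 0 & fit$Q <= 1))
})

test_that("K = 1 equals the closed-form binomial likelihood", {
  pan <- toy_panel(matrix(c(0L, 1L, 2L, 1L, 0L, 2L), 3, 2))
  fit <- admixture(pan, K = 1)
  p <- colMeans(pan$calls) / 2
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  ll <- sum(pan$calls * log(p)[col(pan$calls)] +
              (2 - pan$calls) * log(1 - p)[col(pan$calls)])
  expect_equal(fit$loglik, ll, tolerance = 1e-9)
  expect_true(all(fit$Q == 1))
})

test_that("fully separated populations are assigned near-perfectly at K = 2", {
  pan <- fixed_two_pop_panel(12, 30)
  fit <- admixture(pan, K = 2, n_runs = 3, seed = 2)
  own <- apply(group_mean_q(fit$Q, pan$samples$group), 1, max)
  expect_true(all(own >= 0.999))
})

test_that("choose_k finds the number of simulated populations", {
  pan2 <- fixed_two_pop_panel(10, 25)
  scan2 <- admixture_scan(pan2, k_max = 4, n_runs = 2, seed = 4)
  expect_equal(choose_k(scan2), 2)
  # single population: flat scan
  pan1 <- panel_from_freqs(matrix(0.5, 1, 60, dimnames = list("A", NULL)),
                           c(A = 30L), seed = 3)
  scan1 <- admixture_scan(pan1, k_max = 3, n_runs = 2, seed = 5)
  expect_warning(k1 <- choose_k(scan1), "flat")
  expect_equal(k1, 1)
})

test_that("align_runs undoes label permutations and averages", {
  set.seed(8)
  Q <- matrix(rgamma(30 * 3, 1), 30, 3)
  Q <- Q / rowSums(Q)
  colnames(Q) <- paste0("C", 1:3)
  permuted <- Q[, c(3, 1, 2)]
  res <- align_runs(list(Q, permuted))
  expect_equal(unname(res$Q), unname(Q), tolerance = 1e-12)
  expect_lt(res$max_dev, 1e-12)
  # already-aligned runs average arithmetically
  res2 <- align_runs(list(Q, Q * 0.5 + 0.5 / 3))
  expect_equal(unname(res2$Q), unname((Q + (Q * 0.5 + 0.5 / 3)) / 2),
               tolerance = 1e-12)
  expect_error(align_runs(list(Q, Q[1:10, ])), "inconsistent")
})

test_that("hybrid classification follows the interval rules", {
  expect_equal(classify_hybrid(c(0.99, 0.01, 0, 0, 0))$label, "parental")
  expect_equal(classify_hybrid(c(0.5, 0.5, 0, 0, 0))$label, "F1-like")
  expect_equal(classify_hybrid(c(0.75, 0.25, 0, 0, 0))$label, "BC1-like")
  expect_equal(classify_hybrid(c(0.94, 0.02, 0.02, 0.01, 0.01))$label,
               "admixed-other")
  top <- classify_hybrid(c(A = 0.3, B = 0.6, C = 0.1))$top
  expect_equal(names(top), c("B", "A"))
})

test_that("F1 and BC1 ancestry is recovered by supervised assignment", {
  cfg <- sim_config(n_loci = 192L, missing_rate = 0)
  sim <- simulate_panel(cfg, 31)
  freqs <- sim$freqs
  f1 <- simulate_f1(freqs, "WIT", "D", n = 40, seed = 1)
  qf1 <- supervised_q(f1, freqs)$Q
  expect_equal(mean(qf1[, "WIT"]), 0.5, tolerance = 0.02)
  expect_equal(mean(qf1[, "D"]), 0.5, tolerance = 0.02)
  bc <- simulate_backcross(f1, freqs, "WIT", n = 40, seed = 2)
  qbc <- supervised_q(bc, freqs)$Q
  expect_equal(mean(qbc[, "WIT"]), 0.75, tolerance = 0.03)
})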