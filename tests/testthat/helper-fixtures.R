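# Small in-code fixtures shared across test files.

# hand-specified panel: 2 groups, explicit dosages
toy_panel <- function(calls, groups = NULL, chrom = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); L <- ncol(calls)
  if (is.null(groups)) groups <- rep("A", n)
  if (is.null(chrom)) chrom <- rep_len(1:38, L)
  genotype_panel(
    calls,
    samples = data.frame(id = sprintf("s%02d", seq_len(n)), group = groups),
    loci = data.frame(id = sprintf("L%03d", seq_len(L)), chrom = chrom,
                      pos = stats::ave(seq_len(L), chrom, FUN = seq_along) * 1000L,
                      ref = "A", alt = "G")
  )
}

# two populations fixed for alternate alleles at every locus
fixed_two_pop_panel <- function(n_per = 10L, L = 20L) {
  toy_panel(rbind(matrix(0L, n_per, L), matrix(2L, n_per, L)),
            groups = rep(c("A", "B"), each = n_per))
}

# panel drawn from explicit per-population frequencies under HWE
panel_from_freqs <- function(freq, sizes, seed = 1L) {
  ft <- freq_table(freq)
  sample_genotypes(ft, sizes, seed)
}

# small two-population simulation config (no clades)
small_config <- function(n_loci = 100L, fst_target = NULL, ...) {
  sim_config(sizes = c(A = 15L, B = 15L), n_loci = n_loci,
             drift = c(A = 0.3, B = 0.3), clades = list(),
             clade_drift = numeric(0),
             fixed_pairs = c("A:B" = 0.1),
             target_fst = fst_target, missing_rate = 0, ...)
}

# brute-force Weir-Cockerham variance components for ONE locus, two
# populations, from genotype vectors (textbook formulas, independent of
# the package implementation)
wc_oracle <- function(g1, g2) {
  gl <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  n <- vapply(gl, length, 0)
  p <- vapply(gl, function(g) sum(g) / (2 * length(g)), 0)
  h <- vapply(gl, function(g) mean(g == 1), 0)
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# exhaustive enumeration oracle for PID over one biallelic locus
pid_oracle_locus <- function(p) {
  gp <- c(p^2, 2 * p * (1 - p), (1 - p)^2)   # alt-hom, het, ref-hom
  sum(gp^2)
}

# exhaustive sib-pair enumeration oracle for PIDsibs over one locus:
# enumerate parental genotype pairs under HWE, then the probability two
# sibs share a genotype given the parents
pidsibs_oracle_locus <- function(p) {
  alleles <- c(1, 0)
  probs <- c(p, 1 - p)
  tot <- 0
  for (m1 in 1:2) for (m2 in 1:2) for (f1 in 1:2) for (f2 in 1:2) {
    w <- probs[m1] * probs[m2] * probs[f1] * probs[f2]
    # child genotypes: one maternal, one paternal allele, each 50/50
    kids <- c(alleles[m1] + alleles[f1], alleles[m1] + alleles[f2],
              alleles[m2] + alleles[f1], alleles[m2] + alleles[f2])
    share <- 0
    for (g in 0:2) share <- share + mean(kids == g)^2
    tot <- tot + w * share
  }
  tot
}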