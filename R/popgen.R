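#' Per-population diversity summary
#'
#' Computes, for each population, the descriptive diversity statistics of
#' a reduced SNP panel: sample size N, mean genotyping success GL (%),
#' percentages of polymorphic and monomorphic loci (PL, ML), mean
#' observed and effective allele numbers (A_O, A_E), rarefied allelic
#' richness (A_R), private alleles (N_P), polymorphic information content
#' (PIC), observed and unbiased expected heterozygosity (H_O, uH_E), the
#' inbreeding coefficient F_IS = 1 - H_O/H_E with a within-population
#' allele-permutation P-value, and the probabilities of identity among
#' unrelated individuals and among full sibs.
#'
#' Per-locus definitions (p = alternate-allele frequency in the
#' population, n = genotyped individuals): H_O = observed heterozygote
#' fraction; H_E = 2p(1-p); uH_E = (2n/(2n-1)) H_E; A_E = 1 / (p^2 +
#' (1-p)^2); PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2; A_R =
#' sum over alleles of 1 - choose(N - N_i, g) / choose(N, g), rarefied to
#' the smallest allele-copy count g across populations and loci. A
#' private allele is observed in exactly one population.
#'
#' @param panel A `genotype_panel`.
#' @param groups Populations to summarise (default all).
#' @param n_perm Permutations for the F_IS test (default 10000; the
#'   reported P is the fraction of permuted F_IS values at least as large
#'   as the observed).
#' @param seed Seed for the permutation test.
#' @return A data frame with one row per population.
#' @export
diversity_summary <- function(panel, groups = NULL, n_perm = 10000L,
                              seed = 1L) {
  if (is.null(groups)) groups <- unique(panel$samples$group)
  ft <- allele_freqs(panel, groups)
  # global rarefaction depth: smallest allele-copy count anywhere
  g_min <- min(ft$n[ft$n > 0])
  # which populations carry each allele (for private-allele counts)
  has_ref <- ft$freq < 1 & !is.na(ft$freq)
  has_alt <- ft$freq > 0 & !is.na(ft$freq)
  priv_ref <- colSums(has_ref, na.rm = TRUE) == 1
  priv_alt <- colSums(has_alt, na.rm = TRUE) == 1
  set.seed(seed)
  rows <- lapply(groups, function(gr) {
    m <- panel$calls[panel$samples$group == gr, , drop = FALSE]
    n <- colSums(!is.na(m))
    ok <- n > 0
    p <- ft$freq[gr, ]
    q <- 1 - p
    poly <- ok & p > 0 & p < 1
    ho_l <- colSums(m == 1L, na.rm = TRUE)[ok] / n[ok]
    he_l <- (2 * p * q)[ok]
    uhe_l <- (2 * n / (2 * n - 1))[ok] * he_l
    ao_l <- (has_ref[gr, ] + has_alt[gr, ])[ok]
    ae_l <- 1 / (p^2 + q^2)[ok]
    pic_l <- (1 - (p^2 + q^2) - 2 * p^2 * q^2)[ok]
    # rarefied allele counts
    N <- ft$n[gr, ok]
    Nalt <- round(p[ok] * N)
    ar_l <- ar_term(N - Nalt, N, g_min) + ar_term(Nalt, N, g_min)
    np <- sum(priv_ref & has_ref[gr, ], na.rm = TRUE) +
      sum(priv_alt & has_alt[gr, ], na.rm = TRUE)
    fis_obs <- 1 - mean(ho_l) / mean(he_l)
    # permutation: shuffle allele copies among individuals within the
    # population, locus by locus, and recompute F_IS
    pval <- NA_real_
    if (n_perm > 0) {
      # allele copies per locus, missing dropped
      copies <- lapply(which(ok), function(l) {
        g <- m[!is.na(m[, l]), l]
        c(as.integer(g >= 1L), as.integer(g == 2L))
      })
      he_mean <- mean(he_l)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        hp <- vapply(copies, function(cp) {
          cp <- sample(cp)
          k <- length(cp) %/% 2
          mean(cp[seq_len(k)] != cp[k + seq_len(k)])
        }, 0)
        if (1 - mean(hp) / he_mean >= fis_obs) hits <- hits + 1L
      }
      pval <- hits / n_perm
    }
    pid <- pid_from_freq(p[ok])
    data.frame(population = gr,
               N = sum(panel$samples$group == gr),
               GL = 100 * mean(rowMeans(!is.na(m))),
               PL = 100 * mean(poly[ok]),
               ML = 100 * (1 - mean(poly[ok])),
               Ao = mean(ao_l), Ae = mean(ae_l), Ar = mean(ar_l),
               Np = np, PIC = mean(pic_l),
               Ho = mean(ho_l), uHe = mean(uhe_l),
               Fis = fis_obs, Fis_P = pval,
               PID = pid["pid"], PID_sibs = pid["pid_sibs"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# rarefaction term: expected presence of an allele with count x out of N
# copies in a subsample of g copies
ar_term <- function(x, N, g) {
  ifelse(x <= 0, 0, 1 - exp(lchoose(N - x, g) - lchoose(N, g)))
}

# multilocus PID and PIDsibs from a vector of per-locus frequencies
pid_from_freq <- function(p) {
  p <- p[!is.na(p)]
  q <- 1 - p
  s2 <- p^2 + q^2
  s4 <- p^4 + q^4
  pid_l <- s4 + (2 * p * q)^2
  sib_l <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
  c(pid = prod(pid_l), pid_sibs = prod(sib_l))
}

#' Probability of identity within a population
#'
#' Multilocus probability that two unrelated individuals (`PID`), or two
#' full siblings (`PID_sibs`), drawn from the population share an
#' identical multilocus genotype, assuming Hardy-Weinberg proportions and
#' independent loci. Per-locus values are multiplied across loci; loci
#' with no data in the group are excluded.
#'
#' @param panel A `genotype_panel`.
#' @param group Population label.
#' @return Named vector `c(pid, pid_sibs)`.
#' @export
pid <- function(panel, group) {
  stopifnot(sum(panel$samples$group == group) >= 2)
  ft <- allele_freqs(panel, group)
  p <- ft$freq[group, ]
  if (anyNA(p))
    message(sum(is.na(p)), " loci with no data in ", group, " excluded")
  pid_from_freq(p)
}

#' Two-level analysis of molecular variance
#'
#' Partitions the total variance of squared Euclidean dosage distances
#' into among-population and within-population components and reports
#' PhiPT, the among-group proportion, with a permutation P-value
#' (individuals permuted among groups). Missing calls are mean-imputed
#' per locus before distances are computed.
#'
#' @param panel A `genotype_panel`.
#' @param groups Populations to include (default all).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `sigma_among`, `sigma_within`, `phi_pt`, `p_value`,
#'   `ss` (sums of squares), `df`.
#' @export
amova <- function(panel, groups = NULL, n_perm = 999L, seed = 1L) {
  if (is.null(groups)) groups <- unique(panel$samples$group)
  if (length(groups) < 2) stop("AMOVA needs at least 2 groups")
  sel <- panel$samples$group %in% groups
  m <- panel$calls[sel, , drop = FALSE]
  lab <- panel$samples$group[sel]
  for (j in seq_len(ncol(m))) {
    mj <- m[, j]
    if (anyNA(mj)) mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
    m[, j] <- mj
  }
  d2 <- as.matrix(stats::dist(m))^2
  phi_of <- function(lab) {
    N <- length(lab)
    ss_t <- sum(d2[upper.tri(d2)]) / N
    ss_w <- 0
    for (gr in unique(lab)) {
      i <- which(lab == gr)
      ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    ss_a <- ss_t - ss_w
    g <- length(unique(lab))
    df_a <- g - 1
    df_w <- N - g
    ms_a <- ss_a / df_a
    ms_w <- ss_w / df_w
    ns <- table(lab)
    n0 <- (N - sum(ns^2) / N) / df_a
    s_a <- max((ms_a - ms_w) / n0, 0)
    c(phi = s_a / (s_a + ms_w), s_a = s_a, s_w = ms_w,
      ss_a = ss_a, ss_w = ss_w, df_a = df_a, df_w = df_w)
  }
  obs <- phi_of(lab)
  set.seed(seed)
  pval <- NA_real_
  if (n_perm > 0) {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      if (phi_of(sample(lab))["phi"] >= obs["phi"]) hits <- hits + 1L
    }
    pval <- (hits + 1) / (n_perm + 1)
  }
  list(sigma_among = unname(obs["s_a"]), sigma_within = unname(obs["s_w"]),
       phi_pt = unname(obs["phi"]), p_value = pval,
       ss = c(among = unname(obs["ss_a"]), within = unname(obs["ss_w"])),
       df = c(among = unname(obs["df_a"]), within = unname(obs["df_w"])))
}
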