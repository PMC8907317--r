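#' Weir-Cockerham variance components per locus
#'
#' Computes the 1984 Weir-Cockerham variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) for every locus, from genotype dosages of two or more
#' populations. Per-locus theta is a/(a+b+c); the multi-locus estimator is
#' the ratio of sums.
#'
#' @param panel A `genotype_panel`.
#' @param groups Character vector of group labels to use (>= 2).
#' @return A data frame with one row per locus: `id`, `a`, `b`, `c`,
#'   `theta` (NA where the locus is monomorphic across all groups, i.e.
#'   a+b+c = 0).
#' @keywords internal
wc_components <- function(panel, groups) {
  stopifnot(length(groups) >= 2)
  r <- length(groups)
  L <- n_loci(panel)
  nmat <- matrix(0, r, L)    # individuals typed
  pmat <- matrix(0, r, L)    # sample alt frequency
  hmat <- matrix(0, r, L)    # observed het proportion
  for (k in seq_len(r)) {
    m <- panel$calls[panel$samples$group == groups[k], , drop = FALSE]
    nk <- colSums(!is.na(m))
    nmat[k, ] <- nk
    pmat[k, ] <- colSums(m, na.rm = TRUE) / (2 * nk)
    hmat[k, ] <- colSums(m == 1L, na.rm = TRUE) / nk
  }
  nbar <- colMeans(nmat)
  rn <- r * nbar
  nc <- (rn - colSums(nmat^2) / rn) / (r - 1)
  pbar <- colSums(nmat * pmat) / rn
  s2 <- colSums(nmat * (pmat - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(nmat * hmat) / rn
  pq <- pbar * (1 - pbar)
  a <- (nbar / nc) *
    (s2 - (pq - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pq - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(abs(tot) < .Machine$double.eps^0.5, NA_real_, a / tot)
  data.frame(id = panel$loci$id, a = a, b = b, c = cc, theta = theta,
             stringsAsFactors = FALSE)
}

#' Per-locus pairwise FST between two groups
#'
#' Weir-Cockerham theta for every locus between two populations, with a
#' fixed-difference flag where the two sample frequencies are exactly 0
#' and 1. Loci monomorphic in both groups have undefined theta and are
#' reported as 0 with `monomorphic = TRUE`.
#'
#' @param panel A `genotype_panel`.
#' @param group_a,group_b Group labels present in the panel (each with at
#'   least 2 genotyped individuals).
#' @return A data frame: `id`, `chrom`, `pos`, `theta` (raw estimate, may
#'   be slightly negative), `theta_rank` (clamped to [0, 1] for ranking),
#'   `fixed` (logical), `monomorphic` (logical), `freq_a`, `freq_b`.
#' @export
per_locus_fst <- function(panel, group_a, group_b) {
  for (g in c(group_a, group_b))
    if (sum(panel$samples$group == g) < 2)
      stop("group ", g, " has fewer than 2 individuals")
  comp <- wc_components(panel, c(group_a, group_b))
  ft <- allele_freqs(panel, c(group_a, group_b))
  pa <- ft$freq[group_a, ]
  pb <- ft$freq[group_b, ]
  fixed <- !is.na(pa) & !is.na(pb) &
    ((pa == 0 & pb == 1) | (pa == 1 & pb == 0))
  mono <- is.na(comp$theta)
  theta <- ifelse(mono, 0, comp$theta)
  data.frame(id = panel$loci$id,
             chrom = panel$loci$chrom,
             pos = panel$loci$pos,
             theta = theta,
             theta_rank = pmin(pmax(theta, 0), 1),
             fixed = fixed,
             monomorphic = mono,
             freq_a = pa, freq_b = pb,
             stringsAsFactors = FALSE)
}

#' Multi-locus pairwise FST matrix with permutation P-values
#'
#' Ratio-of-sums Weir-Cockerham theta for every pair of populations.
#' Significance is assessed by permuting individuals between the two
#' groups of each pair and recomputing theta.
#'
#' @param panel A `genotype_panel`.
#' @param groups Group labels (default: all, in order of appearance).
#' @param n_perm Number of permutations per pair (0 to skip the test;
#'   the convention of the source workflow is >= 9999).
#' @param seed Optional integer seed for the permutations.
#' @return A list with `fst` (symmetric matrix of theta), `p`
#'   (permutation P-values, `NA` on the diagonal and when `n_perm = 0`).
#' @export
pairwise_fst_matrix <- function(panel, groups = NULL, n_perm = 0, seed = NULL) {
  if (is.null(groups)) groups <- unique(panel$samples$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (!is.null(seed)) set.seed(seed)
  K <- length(groups)
  fst <- matrix(0, K, K, dimnames = list(groups, groups))
  pval <- matrix(NA_real_, K, K, dimnames = list(groups, groups))
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    sel <- panel$samples$group %in% groups[c(i, j)]
    sub <- panel[sel, ]
    obs <- multilocus_theta(sub$calls, sub$samples$group, groups[c(i, j)])
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      lab <- sub$samples$group
      hits <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(lab)
        if (multilocus_theta(sub$calls, perm, groups[c(i, j)]) >= obs)
          hits <- hits + 1L
      }
      pval[i, j] <- pval[j, i] <- (hits + 1) / (n_perm + 1)
    }
  }
  list(fst = fst, p = pval)
}

# ratio-of-sums W-C theta on a dosage matrix given group labels
multilocus_theta <- function(calls, labels, groups) {
  fake <- structure(list(calls = calls,
                         samples = data.frame(id = rownames(calls) %||%
                                                as.character(seq_len(nrow(calls))),
                                              group = labels,
                                              stringsAsFactors = FALSE),
                         loci = data.frame(id = colnames(calls) %||%
                                             as.character(seq_len(ncol(calls))),
                                           stringsAsFactors = FALSE)),
                    class = "genotype_panel")
  comp <- wc_components(fake, groups)
  keep <- is.finite(comp$a) & is.finite(comp$b) & is.finite(comp$c)
  sum(comp$a[keep]) / sum(comp$a[keep] + comp$b[keep] + comp$c[keep])
}

#' Gene-flow estimates from an FST matrix
#'
#' Converts pairwise FST values to island-model effective migrant numbers,
#' Nm = (1 - FST) / (4 FST).
#'
#' @param fst Symmetric matrix of pairwise FST values in (0, 1).
#' @param digits Decimals to round the reported values to (default 3,
#'   matching the conventional presentation; use `NULL` for no rounding).
#' @return Matrix of Nm estimates with the same dimnames; entries with
#'   FST = 0 are `NA` with a warning, the diagonal is `NA`.
#' @examples
#' nm_from_fst(matrix(c(0, 0.677, 0.677, 0), 2, 2))
#' @export
nm_from_fst <- function(fst, digits = 3) {
  fst <- as.matrix(fst)
  nm <- (1 - fst) / (4 * fst)
  zero <- fst == 0 & row(fst) != col(fst)
  if (any(zero)) {
    warning("FST = 0 yields infinite Nm; reported as NA")
    nm[zero] <- NA_real_
  }
  diag(nm) <- NA_real_
  if (!is.null(digits)) nm <- round(nm, digits)
  nm
}
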