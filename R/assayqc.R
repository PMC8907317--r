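#' Consensus genotypes from replicate calls
#'
#' Reconstructs one genotype per sample and locus from 2-3 replicate
#' amplifications. Under the default `"confirmed_het"` rule a
#' heterozygote is accepted when it is observed in at least two
#' replicates, or observed once when no more than two replicates
#' succeeded (with 2 replicates a het + homozygote pair is read as a
#' heterozygote with one allelic dropout); otherwise the successful
#' homozygote calls must agree, and conflicting homozygotes (0 vs 2)
#' yield a missing consensus. The `"majority"` rule takes the most
#' frequent call, ties going to the heterozygote. Cells whose consensus
#' rests on a single successful replicate are flagged provisional.
#'
#' @param replicates A `replicate_set`.
#' @param rule `"confirmed_het"` (default) or `"majority"`.
#' @return List with `consensus` (samples x loci dosage matrix, `NA`
#'   where no replicate succeeded or homozygotes conflict), `provisional`
#'   (logical matrix), `conflict` (logical matrix).
#' @export
consensus_genotype <- function(replicates,
                               rule = c("confirmed_het", "majority")) {
  rule <- match.arg(rule)
  calls <- replicates$calls
  d <- dim(calls)
  n0 <- apply(calls == 0L, c(1, 2), sum, na.rm = TRUE)
  n1 <- apply(calls == 1L, c(1, 2), sum, na.rm = TRUE)
  n2 <- apply(calls == 2L, c(1, 2), sum, na.rm = TRUE)
  nsucc <- n0 + n1 + n2
  cons <- matrix(NA_integer_, d[1], d[2],
                 dimnames = dimnames(calls)[1:2])
  conflict <- matrix(FALSE, d[1], d[2])
  if (rule == "confirmed_het") {
    het <- n1 >= 2 | (n1 == 1 & nsucc <= 2)
    cons[het] <- 1L
    hom_zone <- !het & nsucc > 0
    both <- hom_zone & n0 > 0 & n2 > 0
    conflict[both] <- TRUE
    cons[hom_zone & !both & n0 > 0] <- 0L
    cons[hom_zone & !both & n2 > 0 & n0 == 0] <- 2L
    # residual: only a single unconfirmed het among >= 3 successes and no
    # homozygote at all (e.g. {1, NA, NA} cannot happen here; {1} handled
    # above) -> call the het
    lone <- hom_zone & !both & n0 == 0 & n2 == 0 & n1 > 0
    cons[lone] <- 1L
  } else {
    top <- pmax(n0, n1, n2)
    het_wins <- top > 0 & n1 == top            # het takes ties
    cons[het_wins] <- 1L
    cons[top > 0 & !het_wins & n0 == top & n2 < top] <- 0L
    cons[top > 0 & !het_wins & n2 == top & n0 < top] <- 2L
    conflict <- top > 0 & !het_wins & n0 == top & n2 == top
    cons[conflict] <- NA_integer_
  }
  list(consensus = cons, provisional = nsucc == 1, conflict = conflict)
}

#' Amplification-success and genotyping-error rates
#'
#' Computes, per locus, per sample and panel-wide: AS (fraction of
#' replicate amplifications that succeeded), ADO (fraction of successful
#' replicates at heterozygous-consensus cells showing a homozygote, the
#' per-positive-reaction allelic-dropout convention) and FA (fraction of
#' successful replicates showing an allele absent from the consensus).
#'
#' @param replicates A `replicate_set`.
#' @param consensus Result of [consensus_genotype()] (or a dosage matrix).
#' @return List with `summary` (named vector AS/ADO/FA), `per_locus`,
#'   `per_sample` data frames.
#' @export
error_rates <- function(replicates, consensus = consensus_genotype(replicates)) {
  cons <- if (is.list(consensus)) consensus$consensus else consensus
  calls <- replicates$calls
  R <- dim(calls)[3]
  succ <- !is.na(calls)
  cons_r <- array(rep(cons, R), dim(calls))
  het_cell <- !is.na(cons_r) & cons_r == 1L
  ado_ev <- succ & het_cell & calls != 1L
  fa_ev <- succ & !is.na(cons_r) &
    ((cons_r == 0L & calls >= 1L) | (cons_r == 2L & calls <= 1L))
  called <- succ & !is.na(cons_r)
  rate <- function(ev, den) ifelse(den > 0, ev / den, NA_real_)
  per_locus <- data.frame(
    id = replicates$loci$id,
    AS = apply(succ, 2, mean),
    ADO = rate(apply(ado_ev, 2, sum), apply(succ & het_cell, 2, sum)),
    FA = rate(apply(fa_ev, 2, sum), apply(called, 2, sum)),
    stringsAsFactors = FALSE)
  per_sample <- data.frame(
    id = replicates$samples$id,
    AS = apply(succ, 1, mean),
    ADO = rate(apply(ado_ev, 1, sum), apply(succ & het_cell, 1, sum)),
    FA = rate(apply(fa_ev, 1, sum), apply(called, 1, sum)),
    stringsAsFactors = FALSE)
  n_het <- sum(succ & het_cell)
  summary <- c(AS = mean(succ),
               ADO = if (n_het > 0) sum(ado_ev) / n_het else NA_real_,
               FA = if (sum(called) > 0) sum(fa_ev) / sum(called)
                    else NA_real_)
  list(summary = summary, per_locus = per_locus, per_sample = per_sample)
}

#' Concordance between consensus and reference genotypes
#'
#' Mismatch rate over cells called in both matrices, per sample and
#' overall, matched by sample and locus id.
#'
#' @param consensus Samples x loci dosage matrix (dimnames required), or
#'   the result of [consensus_genotype()].
#' @param reference A `genotype_panel` or dosage matrix with dimnames.
#' @return List with `overall` mismatch rate and `per_sample` data frame
#'   (`id`, `compared`, `mismatch`, `rate`).
#' @export
concordance <- function(consensus, reference) {
  cons <- if (is.list(consensus)) consensus$consensus else consensus
  ref <- if (inherits(reference, "genotype_panel")) reference$calls
         else as.matrix(reference)
  sh_s <- intersect(rownames(cons), rownames(ref))
  sh_l <- intersect(colnames(cons), colnames(ref))
  if (length(sh_l) == 0) stop("no shared loci between consensus and reference")
  if (length(sh_s) == 0) stop("no shared samples between consensus and reference")
  a <- cons[sh_s, sh_l, drop = FALSE]
  b <- ref[sh_s, sh_l, drop = FALSE]
  both <- !is.na(a) & !is.na(b)
  mism <- both & a != b
  per_sample <- data.frame(id = sh_s,
                           compared = rowSums(both),
                           mismatch = rowSums(mism),
                           rate = ifelse(rowSums(both) > 0,
                                         rowSums(mism) / rowSums(both),
                                         NA_real_),
                           stringsAsFactors = FALSE)
  list(overall = sum(mism) / max(sum(both), 1), per_sample = per_sample)
}

#' Principal coordinates analysis on allele-sharing distances
#'
#' Classical multidimensional scaling of the pairwise allele-sharing
#' distance (1 minus the proportion of shared alleles, averaged over
#' co-typed loci).
#'
#' @param x A `genotype_panel` or dosage matrix.
#' @param k Number of axes (default 2).
#' @return List with `coords` (n x k, column means zero), `eig`
#'   (eigenvalues), `dist` (the distance matrix).
#' @export
pcoa <- function(x, k = 2L) {
  m <- if (inherits(x, "genotype_panel")) x$calls else as.matrix(x)
  if (nrow(m) < 3) stop("PCoA needs at least 3 samples")
  d <- allele_sharing_dist(m)
  k_eff <- min(k, nrow(m) - 1)
  fit <- stats::cmdscale(d, k = k_eff, eig = TRUE)
  if (ncol(fit$points) < k)
    warning("degenerate distance matrix: only ", ncol(fit$points),
            " axes available")
  list(coords = fit$points, eig = fit$eig, dist = d)
}

# mean per-locus allele-sharing distance: |g1 - g2| / 2 over co-typed loci
allele_sharing_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    both <- !is.na(m[i, ]) & !is.na(m[j, ])
    d[i, j] <- d[j, i] <-
      if (any(both)) mean(abs(m[i, both] - m[j, both])) / 2 else NA_real_
  }
  stats::as.dist(d)
}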