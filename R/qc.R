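#' Call-rate filters
#'
#' `filter_individual_callrate()` removes samples whose fraction of
#' non-missing calls is below `min_rate` (boundary retained: a sample at
#' exactly the threshold passes). `filter_locus_callrate()` removes loci
#' whose call rate is not strictly above `min_rate` (boundary removed),
#' matching the strict per-SNP screening convention of the source
#' workflow.
#'
#' @param panel A `genotype_panel`.
#' @param min_rate Call-rate threshold (default 0.90 for both filters).
#' @return List with `panel` (filtered) and `report` (data frame of
#'   removals with the call rate that triggered each).
#' @export
filter_individual_callrate <- function(panel, min_rate = 0.90) {
  stopifnot(n_samples(panel) > 0)
  rate <- rowMeans(!is.na(panel$calls))
  drop <- rate < min_rate
  if (all(drop)) stop("all samples fail the call-rate filter")
  list(panel = panel[!drop, ],
       report = data.frame(id = panel$samples$id[drop],
                           call_rate = rate[drop],
                           stringsAsFactors = FALSE))
}

#' @rdname filter_individual_callrate
#' @export
filter_locus_callrate <- function(panel, min_rate = 0.90) {
  stopifnot(n_loci(panel) > 0)
  rate <- colMeans(!is.na(panel$calls))
  drop <- rate <= min_rate           # strict: "> min_rate" is kept
  if (all(drop)) stop("all loci fail the call-rate filter")
  list(panel = panel[, !drop],
       report = data.frame(id = panel$loci$id[drop],
                           call_rate = rate[drop],
                           stringsAsFactors = FALSE))
}

#' Linkage-disequilibrium pruning
#'
#' Deterministic left-to-right sweep within sliding windows per
#' chromosome: for every retained pair of loci closer than `window`
#' positions in the (chromosome, position)-sorted order whose squared
#' Pearson correlation of dosages exceeds `r2_threshold`, the locus with
#' the lower minor-allele frequency is removed (ties: the later locus).
#' r-squared is computed on pairwise-complete observations.
#'
#' @param panel A `genotype_panel` (loci are sorted internally).
#' @param r2_threshold Squared-correlation threshold (default 0.5).
#' @param window Window size in loci (default 50).
#' @return List with `panel` (pruned, loci in sorted order) and `report`
#'   (data frame: removed locus, the partner that triggered removal, r2).
#' @export
ld_prune <- function(panel, r2_threshold = 0.5, window = 50L) {
  ord <- order(panel$loci$chrom, panel$loci$pos)
  panel <- panel[, ord]
  L <- n_loci(panel)
  maf <- pmin(colMeans(panel$calls, na.rm = TRUE) / 2,
              1 - colMeans(panel$calls, na.rm = TRUE) / 2)
  keep <- rep(TRUE, L)
  removed <- character(0)
  partner <- character(0)
  r2s <- numeric(0)
  chrom <- panel$loci$chrom
  for (j in seq_len(L)) {
    if (!keep[j]) next
    lo <- max(1, j - window + 1L)
    for (i in seq(lo, j - 1L)[seq_len(max(0, j - lo))]) {
      if (!keep[i] || !keep[j]) next
      if (chrom[i] != chrom[j]) next
      r <- suppressWarnings(
        stats::cor(panel$calls[, i], panel$calls[, j],
                   use = "pairwise.complete.obs"))
      if (is.na(r) || r * r <= r2_threshold) next
      # drop the less informative locus; ties drop the later one
      drop <- if (maf[i] < maf[j]) i else j
      keep[drop] <- FALSE
      removed <- c(removed, panel$loci$id[drop])
      partner <- c(partner, panel$loci$id[if (drop == i) j else i])
      r2s <- c(r2s, r * r)
      if (drop == j) break
    }
  }
  list(panel = panel[, keep],
       report = data.frame(id = removed, partner = partner, r2 = r2s,
                           stringsAsFactors = FALSE))
}

#' Purity screening of reference individuals
#'
#' Re-runs two-population admixture assignments, as in reference-panel
#' curation: each wolf population against dogs, each wolf population
#' against jackals, and dogs against jackals, all at K = 2. The runs are
#' unsupervised but initialised from the group labels, repeated with
#' `n_seeds` seeds and averaged. An individual is excluded when its mean
#' membership in its own group's cluster falls below its threshold
#' (wolves and jackals 0.95, dogs 0.90, reflecting the higher
#' within-group variability of dogs).
#'
#' @param panel A `genotype_panel`.
#' @param wild_q_min Own-cluster threshold for wolves and jackals.
#' @param dog_q_min Own-cluster threshold for dogs.
#' @param dog_group,jackal_group Group labels of dogs and jackals.
#' @param wolf_groups Wolf group labels (default: all other groups).
#' @param n_seeds Seeds averaged per pairwise run (default 3).
#' @param seed Base seed.
#' @return List with `panel` (screened), `report` (data frame: id, group,
#'   minimum own-cluster q across that individual's pairwise runs), and
#'   `q_table` (all per-individual own-cluster q values).
#' @export
purity_screen <- function(panel, wild_q_min = 0.95, dog_q_min = 0.90,
                          dog_group = "D", jackal_group = "J",
                          wolf_groups = NULL, n_seeds = 3L, seed = 1L) {
  groups <- unique(panel$samples$group)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(wolf_groups))
    wolf_groups <- setdiff(groups, c(dog_group, jackal_group))
  comparisons <- c(lapply(intersect(wolf_groups, groups),
                          function(w) c(w, dog_group)),
                   lapply(intersect(wolf_groups, groups),
                          function(w) c(w, jackal_group)),
                   list(c(dog_group, jackal_group)))
  comparisons <- Filter(function(p) all(p %in% groups), comparisons)
  own_q <- rep(NA_real_, n_samples(panel))
  for (cmp in comparisons) {
    sel <- which(panel$samples$group %in% cmp)
    sub <- panel[sel, ]
    qs <- matrix(0, length(sel), 2)
    for (s in seq_len(n_seeds)) {
      fit <- admixture_labeled(sub, cmp, seed = seed + 7L * s)
      qs <- qs + fit / n_seeds
    }
    own <- ifelse(sub$samples$group == cmp[1], qs[, 1], qs[, 2])
    own_q[sel] <- pmin(own_q[sel], own, na.rm = TRUE)
  }
  thr <- ifelse(panel$samples$group == dog_group, dog_q_min, wild_q_min)
  drop <- !is.na(own_q) & own_q < thr
  kept <- panel[!drop, ]
  surv <- table(kept$samples$group)
  if (any(surv < 2))
    stop("group with fewer than 2 individuals after purity screen: ",
         paste(names(surv)[surv < 2], collapse = ", "))
  list(panel = kept,
       report = data.frame(id = panel$samples$id[drop],
                           group = panel$samples$group[drop],
                           own_q = own_q[drop], stringsAsFactors = FALSE),
       q_table = data.frame(id = panel$samples$id,
                            group = panel$samples$group,
                            own_q = own_q, stringsAsFactors = FALSE))
}

# unsupervised K = 2 admixture initialised from the group labels;
# returns the Q matrix with column 1 = first label's cluster
admixture_labeled <- function(panel, labels, seed) {
  set.seed(seed)
  n <- n_samples(panel)
  Q0 <- matrix(0.1, n, 2)
  Q0[cbind(seq_len(n), match(panel$samples$group, labels))] <- 0.9
  Q0 <- Q0 + matrix(stats::runif(2 * n, 0, 0.05), n, 2)
  Q0 <- Q0 / rowSums(Q0)
  P0 <- vapply(labels, function(g)
    colMeans(panel$calls[panel$samples$group == g, , drop = FALSE],
             na.rm = TRUE) / 2, numeric(n_loci(panel)))
  fit <- admixture_em(panel$calls, Q0, clamp_freq(t(P0)))
  # keep column 1 aligned with labels[1] (labels may swap during EM)
  m1 <- mean(fit$Q[panel$samples$group == labels[1], 1])
  m2 <- mean(fit$Q[panel$samples$group == labels[1], 2])
  if (m2 > m1) fit$Q[, 2:1] else fit$Q
}

#' Run the full QC pipeline in canonical order
#'
#' Applies, in order: individual call-rate filter, locus call-rate
#' filter, LD pruning, and (optionally) the purity screen.
#'
#' @param panel A `genotype_panel`.
#' @param min_ind_callrate,min_locus_callrate,r2_threshold,window,
#'   wild_q_min,dog_q_min Stage thresholds, see the stage functions.
#' @param purity Run the purity screen (default TRUE; needs the dog and
#'   jackal group labels to be present or given).
#' @param ... Passed to [purity_screen()].
#' @return List with `panel` and `reports` (one entry per stage).
#' @export
run_qc <- function(panel, min_ind_callrate = 0.90,
                   min_locus_callrate = 0.90, r2_threshold = 0.5,
                   window = 50L, purity = TRUE, ...) {
  s1 <- filter_individual_callrate(panel, min_ind_callrate)
  s2 <- filter_locus_callrate(s1$panel, min_locus_callrate)
  s3 <- ld_prune(s2$panel, r2_threshold, window)
  reports <- list(individual_callrate = s1$report,
                  locus_callrate = s2$report,
                  ld_prune = s3$report)
  out <- s3$panel
  if (purity) {
    s4 <- purity_screen(out, ...)
    reports$purity <- s4$report
    out <- s4$panel
  }
  list(panel = out, reports = reports)
}
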