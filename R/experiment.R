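#' Hybrid-detection power experiment on a calibrated synthetic panel
#'
#' Runs the full validation workflow: calibrate the simulator to the
#' reference FST matrix, draw the five reference populations, estimate
#' their allele frequencies, simulate 10 F1 offspring for every pairwise
#' cross and 10 BC1 offspring for every backcross type, fit the
#' unsupervised admixture model at K = 5 with several aligned and
#' averaged replicate runs, match clusters to the reference groups, and
#' summarise the membership proportions of parental groups and hybrid
#' classes.
#'
#' @param seed Integer seed driving every stochastic step.
#' @param config A [sim_config()] (default: the packaged five-population
#'   study configuration).
#' @param calibrate Calibrate drift before simulating (default TRUE).
#' @param n_runs Aligned admixture runs (default 5).
#' @param n_per_cross Offspring per cross type (default 10).
#' @return A list:
#'   \describe{
#'     \item{panel}{parental `genotype_panel`}
#'     \item{full_panel}{parentals + simulated hybrids}
#'     \item{hybrid_groups}{cross bookkeeping from
#'       [build_validation_set()]}
#'     \item{Q}{consensus membership matrix (columns named by matched
#'       reference group)}
#'     \item{run_dev}{mean absolute across-run deviation after alignment}
#'     \item{parental_Q}{per-group mean own-cluster membership}
#'     \item{f1_table, bc1_table}{per-cross summaries (mean membership
#'       toward each parent / the backcross parent, with 5th and 95th
#'       percentiles)}
#'     \item{f1_grand_mean}{grand mean F1 membership toward the two
#'       parental clusters}
#'     \item{bc1_grand_mean}{grand mean BC1 membership toward the
#'       backcross parent}
#'     \item{min_parental_Q}{minimum per-group mean own-cluster
#'       membership}
#'     \item{config}{the (calibrated) configuration used}
#'   }
#' @export
hybrid_power_experiment <- function(seed = 1L, config = sim_config(),
                                    calibrate = TRUE, n_runs = 5L,
                                    n_per_cross = 10L) {
  if (calibrate) {
    cal <- suppressWarnings(calibrate_drift(config, seed = seed))
    config <- cal$config
  }
  sim <- simulate_panel(config, seed + 1L)
  panel <- sim$panel
  freqs <- allele_freqs(panel)
  crosses <- standard_crosses(wolves = config$clades$wolf,
                              dog = "D", jackal = "J")
  vs <- build_validation_set(panel, freqs, crosses,
                             n_per_cross = n_per_cross, seed = seed + 2L)
  runs <- lapply(seq_len(n_runs), function(r)
    admixture(vs$panel, K = length(config$sizes), n_runs = 1L,
              seed = seed + 31L * r, init = "kmeans")$Q)
  ali <- align_runs(runs)
  Q <- ali$Q
  groups <- vs$panel$samples$group
  pops <- names(config$sizes)
  parental <- groups %in% pops
  map <- match_clusters(Q[parental, , drop = FALSE], groups[parental],
                        levels = pops)
  colnames(Q)[map] <- names(map)
  gq <- group_mean_q(Q[parental, , drop = FALSE], groups[parental])
  parental_Q <- gq[cbind(pops, pops)]
  names(parental_Q) <- pops

  hg <- vs$hybrid_groups
  pct <- function(v) stats::quantile(v, c(0.05, 0.95), names = FALSE)
  f1 <- hg[hg$type == "F1", , drop = FALSE]
  f1_rows <- lapply(seq_len(nrow(f1)), function(i) {
    qs <- Q[groups == f1$label[i], , drop = FALSE]
    qa <- qs[, f1$parent_a[i]]
    qb <- qs[, f1$parent_b[i]]
    data.frame(label = f1$label[i], n = nrow(qs),
               mean_parent_a = mean(qa), mean_parent_b = mean(qb),
               q05_a = pct(qa)[1], q95_a = pct(qa)[2],
               q05_b = pct(qb)[1], q95_b = pct(qb)[2],
               stringsAsFactors = FALSE)
  })
  f1_table <- do.call(rbind, f1_rows)
  bc <- hg[hg$type == "BC1", , drop = FALSE]
  bc_rows <- lapply(seq_len(nrow(bc)), function(i) {
    qs <- Q[groups == bc$label[i], , drop = FALSE]
    qb <- qs[, bc$backcross_parent[i]]
    other <- setdiff(c(bc$parent_a[i], bc$parent_b[i]),
                     bc$backcross_parent[i])
    data.frame(label = bc$label[i], n = nrow(qs),
               mean_backcross = mean(qb),
               mean_other = mean(qs[, other]),
               q05 = pct(qb)[1], q95 = pct(qb)[2],
               stringsAsFactors = FALSE)
  })
  bc1_table <- do.call(rbind, bc_rows)

  list(panel = panel, full_panel = vs$panel, hybrid_groups = hg, Q = Q,
       run_dev = ali$mean_dev, parental_Q = parental_Q,
       f1_table = f1_table, bc1_table = bc1_table,
       f1_grand_mean = mean(c(f1_table$mean_parent_a,
                              f1_table$mean_parent_b)),
       bc1_grand_mean = mean(bc1_table$mean_backcross),
       min_parental_Q = min(parental_Q),
       config = config)
}

#' Cluster-number recovery experiment
#'
#' On a synthetic parental panel: K-means/BIC scan (1..`k_max`) and the
#' admixture log-likelihood scan with the rate-of-increase rule.
#'
#' @param panel Parental `genotype_panel` (e.g. from
#'   [hybrid_power_experiment()] or [simulate_panel()]).
#' @param k_max Largest K scanned (default 10).
#' @param n_runs Restarts per K in the likelihood scan (default 3).
#' @param seed Integer seed.
#' @return List with `bic` (the [kmeans_bic()] result), `scan` (the
#'   likelihood scan), `k_bic`, `k_loglik`.
#' @export
cluster_number_experiment <- function(panel, k_max = 10L, n_runs = 3L,
                                      seed = 1L) {
  bic <- kmeans_bic(panel, k_max = k_max, seed = seed)
  scan <- admixture_scan(panel, k_max = k_max, n_runs = n_runs,
                         seed = seed + 77L)
  list(bic = bic, scan = scan, k_bic = bic$best_k,
       k_loglik = choose_k(scan))
}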