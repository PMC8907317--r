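#' Supervised ancestry estimation with fixed parental frequencies
#'
#' Maximum-likelihood estimation of each individual's admixture vector q
#' over K parental populations whose allele frequencies are known and held
#' fixed. The likelihood is the standard admixture model: each of the two
#' allele copies at a locus comes from cluster k with probability q_k and
#' is then the alternate allele with probability p_kl. q is fitted by EM
#' on the simplex; missing genotypes are skipped.
#'
#' @param panel A `genotype_panel` (or dosage matrix with loci in columns
#'   matching `freqs`).
#' @param freqs A `freq_table` of parental allele frequencies (K >= 2
#'   rows) sharing the panel's loci.
#' @param tol Stop when the per-individual log-likelihood improves by less
#'   than this (default 1e-7).
#' @param max_iter Iteration cap per individual batch.
#' @return An `ancestry_result`: list with `Q` (n x K matrix, rows sum to
#'   1), `loglik` (per-individual), `K`, `clusters` (cluster names).
#' @export
supervised_q <- function(panel, freqs, tol = 1e-7, max_iter = 2000L) {
  calls <- if (inherits(panel, "genotype_panel")) panel$calls else as.matrix(panel)
  P <- freqs$freq
  if (ncol(calls) != ncol(P)) stop("panel and frequency table differ in loci")
  K <- nrow(P)
  if (K < 2) stop("need at least 2 parental populations")
  if (any(rowSums(!is.na(calls)) == 0))
    stop("individual with no genotyped loci: ",
         paste(rownames(calls)[rowSums(!is.na(calls)) == 0], collapse = ", "))
  P <- clamp_freq(P)
  n <- nrow(calls)
  Q <- matrix(1 / K, n, K, dimnames = list(rownames(calls), rownames(P)))
  fit <- admixture_em(calls, Q, P, update_p = FALSE, tol = tol,
                      max_iter = max_iter)
  structure(list(Q = fit$Q, loglik = fit$loglik_i, K = K,
                 clusters = rownames(P)),
            class = "ancestry_result")
}

clamp_freq <- function(P, eps = 1e-6) pmin(pmax(P, eps), 1 - eps)

# Block EM for the admixture likelihood
#   l(i) = sum_l [ g_il log x_il + (2 - g_il) log(1 - x_il) ],
#   x = Q %*% P, optionally updating the cluster frequencies P.
# Returns Q, P, total log-likelihood trace, per-individual log-likelihood.
admixture_em <- function(calls, Q, P, update_p = TRUE, tol = 1e-7,
                         max_iter = 2000L) {
  obs <- !is.na(calls)
  g <- calls
  g[!obs] <- 0L
  gc2 <- 2L - g
  gc2[!obs] <- 0L
  nloc2 <- 2 * rowSums(obs)
  # x is kept strictly inside (0, 1); row sums of Q drift from 1 by a few
  # ulp per iteration, which would otherwise push x past 1 at near-fixed loci
  xsafe <- function(Q, P) pmin(pmax(Q %*% P, 1e-9), 1 - 1e-9)
  ll_of <- function(x) {
    rowSums((g * log(x) + gc2 * log1p(-x)) * obs)
  }
  trace <- numeric(0)
  ll_i <- ll_of(xsafe(Q, P))
  ll <- sum(ll_i)
  for (it in seq_len(max_iter)) {
    x <- xsafe(Q, P)
    # expected allele-copy counts per cluster
    ga <- (g / x) * obs          # alt copies scale
    gb <- (gc2 / (1 - x)) * obs  # ref copies scale
    # A_ik = sum_l q_ik p_kl ga_il ; B_ik = sum_l q_ik (1-p_kl) gb_il
    A <- Q * (ga %*% t(P))
    B <- Q * (gb %*% t(1 - P))
    Qn <- (A + B) / nloc2
    if (update_p) {
      # per-locus expected allele copies attributed to each cluster
      alt_k <- (t(Q) %*% ga) * P        # K x L: sum_i q_ik ga_il * p_kl
      tot_k <- alt_k + (t(Q) %*% gb) * (1 - P)
      Pn <- clamp_freq(alt_k / pmax(tot_k, .Machine$double.xmin))
    } else Pn <- P
    Qn <- Qn / rowSums(Qn)
    ll_new_i <- ll_of(xsafe(Qn, Pn))
    ll_new <- sum(ll_new_i)
    trace <- c(trace, ll_new)
    Q <- Qn
    P <- Pn
    ll_i <- ll_new_i
    if (ll_new - ll < tol * max(1, abs(ll_new))) { ll <- ll_new; break }
    ll <- ll_new
  }
  list(Q = Q, P = P, loglik = ll, loglik_i = ll_i, trace = trace,
       iterations = length(trace))
}

#' Unsupervised maximum-likelihood admixture model
#'
#' Fits the admixture model (individual ancestry vectors Q and cluster
#' allele frequencies P) by block EM with random restarts, keeping the
#' best run. This is the maximum-likelihood counterpart of Bayesian
#' admixture clustering with independent cluster frequencies: the
#' inference target (individual membership proportions q) is the same,
#' with the mean best log-likelihood across restarts standing in for the
#' posterior-probability curve used to choose the number of clusters.
#'
#' @param panel A `genotype_panel`.
#' @param K Number of clusters (>= 1).
#' @param n_runs Random restarts (default 5).
#' @param seed Integer seed.
#' @param tol,max_iter EM convergence controls.
#' @param init `"random"` starts from random memberships and perturbed
#'   pooled frequencies; `"kmeans"` seeds each restart from a K-means
#'   partition of the top principal components (jittered per restart), a
#'   standard way to keep EM out of poor local optima on strongly
#'   structured data.
#' @return An object of class `admixture_fit`: list with `Q`, `P`,
#'   `loglik` (best run), `run_loglik` (all runs), `K`, `n_runs`, `seed`,
#'   `trace` (log-likelihood trace of the best run), `panel_ids`.
#' @examples
#' cfg <- sim_config(sizes = c(A = 10, B = 10), n_loci = 50,
#'                   drift = c(A = 0.5, B = 0.5), clades = list(),
#'                   clade_drift = numeric(0), fixed_pairs = c("A:B" = 0.2),
#'                   target_fst = NULL)
#' pan <- simulate_panel(cfg, 1)$panel
#' fit <- admixture(pan, K = 2, n_runs = 2, seed = 1)
#' head(coef(fit))
#' @export
admixture <- function(panel, K, n_runs = 5L, seed = 1L, tol = 1e-7,
                      max_iter = 2000L, init = c("random", "kmeans")) {
  init <- match.arg(init)
  stopifnot(K >= 1)
  calls <- panel$calls
  if (nrow(calls) < K) stop("panel has fewer individuals than clusters")
  if (K == 1) {
    # closed form: binomial likelihood at the pooled frequencies
    p <- clamp_freq(matrix(colMeans(calls, na.rm = TRUE) / 2, 1,
                           ncol(calls)))
    obs <- !is.na(calls)
    g <- calls; g[!obs] <- 0L
    ll <- sum((g * log(p[col(g)]) +
                 (2 - g) * log1p(-p[col(g)])) * obs)
    fit <- list(Q = matrix(1, nrow(calls), 1,
                           dimnames = list(rownames(calls), "C1")),
                P = p, loglik = ll, run_loglik = rep(ll, n_runs),
                K = 1L, n_runs = n_runs, seed = seed, trace = ll,
                panel_ids = panel$samples$id)
    return(structure(fit, class = "admixture_fit"))
  }
  pcs <- NULL
  if (init == "kmeans") {
    m <- impute_mean(calls)
    pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    pcs <- pc$x[, seq_len(min(20L, sum(pc$sdev > 1e-9))), drop = FALSE]
  }
  best <- NULL
  run_ll <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seed + 1000L * (r - 1L))
    base_p <- colMeans(calls, na.rm = TRUE) / 2
    use_kmeans <- init == "kmeans" &&
      nrow(unique(round(pcs, 8))) >= K
    for (attempt in 1:3) {
      if (use_kmeans) {
        km <- stats::kmeans(pcs, K, nstart = 5, iter.max = 100)
        Q0 <- matrix(0.05 / (K - 1), nrow(calls), K)
        Q0[cbind(seq_len(nrow(calls)), km$cluster)] <- 0.95
        jit <- matrix(stats::rgamma(nrow(calls) * K, 2), nrow(calls), K)
        Q0 <- 0.9 * Q0 + 0.1 * jit / rowSums(jit)
        P0 <- t(vapply(seq_len(K), function(k)
          colMeans(calls[km$cluster == k, , drop = FALSE], na.rm = TRUE) / 2,
          numeric(ncol(calls))))
        P0[is.na(P0)] <- matrix(rep(base_p, each = K), K)[is.na(P0)]
      } else {
        Q0 <- matrix(stats::rgamma(nrow(calls) * K, 1), nrow(calls), K)
        Q0 <- Q0 / rowSums(Q0)
        P0 <- matrix(stats::rbeta(K * ncol(calls),
                                  1 + 20 * rep(base_p, each = K),
                                  1 + 20 * rep(1 - base_p, each = K)),
                     K, ncol(calls))
      }
      fit <- admixture_em(calls, Q0, clamp_freq(P0), update_p = TRUE,
                          tol = tol, max_iter = max_iter)
      sizes <- colSums(fit$Q)
      if (all(sizes > 0.5)) break
      if (attempt == 3) warning("empty cluster after 3 restarts (K = ", K, ")")
    }
    run_ll[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  rownames(best$Q) <- rownames(calls)
  colnames(best$Q) <- paste0("C", seq_len(K))
  structure(list(Q = best$Q, P = best$P, loglik = best$loglik,
                 run_loglik = run_ll, K = K, n_runs = n_runs, seed = seed,
                 trace = best$trace, loglik_i = best$loglik_i,
                 panel_ids = panel$samples$id),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("admixture_fit: K =", x$K, ", n =", nrow(x$Q), "individuals\n")
  cat("best log-likelihood:", format(x$loglik), "over", x$n_runs, "runs",
      sprintf("(sd %.3g)\n", stats::sd(x$run_loglik)))
  invisible(x)
}

#' @export
logLik.admixture_fit <- function(object, ...) {
  structure(object$loglik,
            df = nrow(object$Q) * (object$K - 1) +
              object$K * ncol(object$P),
            class = "logLik")
}

#' @export
coef.admixture_fit <- function(object, ...) object$Q

#' Project new genotypes onto a fitted admixture model
#'
#' Supervised estimation of admixture vectors for new individuals using
#' the fitted cluster allele frequencies.
#'
#' @param object An `admixture_fit`.
#' @param newdata A `genotype_panel` with the same loci.
#' @param ... Ignored.
#' @return Matrix of membership proportions (rows sum to 1).
#' @export
predict.admixture_fit <- function(object, newdata, ...) {
  ft <- freq_table(object$P)
  colnames(ft$freq) <- NULL
  res <- supervised_q(newdata, ft)
  colnames(res$Q) <- colnames(object$Q)
  res$Q
}

#' @export
summary.admixture_fit <- function(object, groups = NULL, ...) {
  out <- list(K = object$K, loglik = object$loglik,
              run_sd = stats::sd(object$run_loglik))
  if (!is.null(groups)) out$group_Q <- group_mean_q(object$Q, groups)
  class(out) <- "summary.admixture_fit"
  out
}

#' @export
print.summary.admixture_fit <- function(x, ...) {
  cat("K =", x$K, " best logLik =", format(x$loglik),
      " run sd =", format(x$run_sd), "\n")
  if (!is.null(x$group_Q)) {
    cat("group mean Q:\n")
    print(round(x$group_Q, 3))
  }
  invisible(x)
}

#' Group-mean membership matrix
#'
#' @param Q Individuals x clusters membership matrix.
#' @param groups Group label per individual.
#' @return Groups x clusters matrix of mean membership.
#' @export
group_mean_q <- function(Q, groups) {
  t(vapply(split(seq_len(nrow(Q)), groups),
           function(i) colMeans(Q[i, , drop = FALSE]),
           numeric(ncol(Q))))
}

#' Match clusters to reference groups
#'
#' Greedy one-to-one assignment of cluster columns to the groups whose
#' members load on them most strongly.
#'
#' @param Q Membership matrix.
#' @param groups Group label per individual (same length as rows of
#'   `Q`); only groups to be matched need occur.
#' @param levels Optional group order; defaults to order of appearance.
#' @return Named integer vector: for each group, the matched cluster
#'   column index.
#' @export
match_clusters <- function(Q, groups, levels = unique(groups)) {
  gm <- group_mean_q(Q, factor(groups, levels = levels))
  gm <- gm[levels, , drop = FALSE]
  K <- ncol(Q)
  assign <- integer(length(levels))
  names(assign) <- levels
  taken <- rep(FALSE, K)
  for (step in seq_along(levels)) {
    # greedy: highest remaining (group, cluster) cell
    best <- -Inf; bi <- bj <- 0
    for (i in seq_along(levels)) {
      if (assign[i] != 0) next
      for (j in seq_len(K)) {
        if (taken[j]) next
        if (gm[i, j] > best) { best <- gm[i, j]; bi <- i; bj <- j }
      }
    }
    if (bi == 0) break
    assign[bi] <- bj
    taken[bj] <- TRUE
    if (all(assign != 0)) break
  }
  assign
}

#' Scan the number of clusters with the likelihood rate-of-increase rule
#'
#' Fits the admixture model for K = 1..`k_max` and records the best
#' log-likelihood per K. [choose_k()] picks the K after which the
#' log-likelihood stops increasing substantially.
#'
#' @param panel A `genotype_panel`.
#' @param k_max Largest K scanned (>= 3).
#' @param n_runs Restarts per K.
#' @param seed Integer seed.
#' @param init Initialisation passed to [admixture()]; the K-means start
#'   (default) keeps per-K best likelihoods from being depressed by poor
#'   local optima, which would distort the rate-of-increase rule.
#' @param ... Passed to [admixture()].
#' @return A `cluster_scan` data frame: `K`, `loglik` (best),
#'   `loglik_mean`, `loglik_sd` across runs.
#' @export
admixture_scan <- function(panel, k_max = 10L, n_runs = 5L, seed = 1L,
                           init = "kmeans", ...) {
  stopifnot(k_max >= 3)
  rows <- lapply(seq_len(k_max), function(k) {
    fit <- admixture(panel, K = k, n_runs = n_runs,
                     seed = seed + 131L * k, init = init, ...)
    data.frame(K = k, loglik = fit$loglik,
               loglik_mean = mean(fit$run_loglik),
               loglik_sd = stats::sd(fit$run_loglik))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_scan", "data.frame")
  out
}

#' Choose the number of clusters from a likelihood scan
#'
#' Implements the rate-of-increase rule: the chosen K is the last one
#' whose log-likelihood gain over K-1 is still substantial. The plateau
#' starts at the first K whose gain falls below `plateau_frac` of the
#' largest gain seen so far (an anchor that stays robust when the
#' post-plateau gains fluctuate around a small constant); the K just
#' before the plateau is returned.
#'
#' @param scan A `cluster_scan` from [admixture_scan()] (or any data
#'   frame with columns `K` and `loglik` covering K = 1..Kmax).
#' @param plateau_frac Gain fraction below which the curve counts as flat
#'   (default 0.05).
#' @return The chosen K. A scan that is flat from the start returns 1
#'   with a warning; a scan that never flattens returns the largest K
#'   with a warning.
#' @export
choose_k <- function(scan, plateau_frac = 0.05) {
  scan <- scan[order(scan$K), ]
  ll <- scan$loglik
  k <- scan$K
  d <- pmax(diff(ll), 0)
  total <- ll[length(ll)] - ll[1]
  # overfitting-scale gains: a homogeneous panel still gains a few
  # percent of |logLik| from extra clusters, so "flat" is judged against
  # the baseline likelihood magnitude
  if (!is.finite(total) || total <= 0.10 * abs(ll[1])) {
    warning("log-likelihood scan is flat; returning K = 1")
    return(1L)
  }
  for (i in seq_along(d)) {
    if (i == 1) next
    if (d[i] < plateau_frac * max(d[seq_len(i - 1)]))
      return(k[i])                       # last K before the plateau
  }
  warning("log-likelihood increases to the end of the scan; returning Kmax")
  k[length(k)]
}

#' Align replicate admixture runs and average them
#'
#' Cluster labels are arbitrary in each run; each run's columns are
#' permuted to best match the first run (exhaustive over permutations up
#' to K = 7, greedy above) and the aligned matrices are averaged.
#'
#' @param runs List of Q matrices with identical dimensions.
#' @return List with `Q` (consensus, element-wise mean), `max_dev`
#'   (largest absolute deviation of any aligned run from the consensus),
#'   `mean_dev` (mean absolute deviation).
#' @export
align_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  dims <- vapply(runs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("runs have inconsistent dimensions")
  K <- ncol(runs[[1]])
  ref <- runs[[1]]
  aligned <- vector("list", length(runs))
  aligned[[1]] <- ref
  for (r in seq_along(runs)[-1]) {
    Qr <- runs[[r]]
    score <- t(ref) %*% Qr          # similarity of ref col i to run col j
    perm <- best_permutation(score)
    aligned[[r]] <- Qr[, perm, drop = FALSE]
    colnames(aligned[[r]]) <- colnames(ref)
  }
  consensus <- Reduce(`+`, aligned) / length(aligned)
  devs <- vapply(aligned, function(a) max(abs(a - consensus)), 0)
  mean_devs <- vapply(aligned, function(a) mean(abs(a - consensus)), 0)
  list(Q = consensus, max_dev = max(devs), mean_dev = mean(mean_devs))
}

# maximum-trace column assignment: returns perm with score[i, perm[i]] summed
best_permutation <- function(score) {
  K <- ncol(score)
  if (K <= 7) {
    perms <- permutations(K)
    vals <- apply(perms, 1, function(p) sum(score[cbind(seq_len(K), p)]))
    perms[which.max(vals), ]
  } else {
    # greedy fallback for large K
    perm <- integer(K)
    taken <- rep(FALSE, K)
    for (i in order(-apply(score, 1, max))) {
      j <- which.max(ifelse(taken, -Inf, score[i, ]))
      perm[i] <- j
      taken[j] <- TRUE
    }
    perm
  }
}

permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Classify an individual from its admixture vector
#'
#' Deterministic interval rules over the sorted membership vector:
#' parental if the top cluster reaches `parental_min`; F1-like if the two
#' top clusters both lie in the F1 window; BC1-like if the top cluster
#' lies in the backcross window with a substantial second cluster;
#' admixed-other otherwise.
#'
#' @param q Membership vector (sums to 1).
#' @param parental_min Parental threshold (default 0.95).
#' @param f1_window Two-sided window for both F1 parental memberships
#'   (default `c(0.40, 0.60)`).
#' @param bc1_window Window for the major cluster of a first backcross
#'   (default `c(0.65, 0.90)`).
#' @param minor_min Minimum second-cluster membership for BC1
#'   (default 0.10).
#' @return List with `label` (one of `"parental"`, `"F1-like"`,
#'   `"BC1-like"`, `"admixed-other"`) and `top` (named top-two
#'   memberships).
#' @export
classify_hybrid <- function(q, parental_min = 0.95,
                            f1_window = c(0.40, 0.60),
                            bc1_window = c(0.65, 0.90),
                            minor_min = 0.10) {
  stopifnot(abs(sum(q) - 1) < 1e-6)
  ord <- order(q, decreasing = TRUE)
  top <- q[ord[1:2]]
  if (is.null(names(q))) names(top) <- paste0("C", ord[1:2])
  label <-
    if (top[1] >= parental_min) "parental"
    else if (top[1] >= f1_window[1] && top[1] <= f1_window[2] &&
             top[2] >= f1_window[1] && top[2] <= f1_window[2]) "F1-like"
    else if (top[1] >= bc1_window[1] && top[1] <= bc1_window[2] &&
             top[2] >= minor_min) "BC1-like"
    else "admixed-other"
  list(label = label, top = top)
}
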