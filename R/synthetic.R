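#' Published pairwise FST reference matrix for the five canid groups
#'
#' Pairwise Weir-Cockerham FST among golden jackals (J), domestic dogs (D),
#' Dinaric (WDIN), Iberian (WIB) and Italian (WIT) wolves, estimated from a
#' 192-SNP ancestry-informative panel. Used as the default calibration
#' target of the genotype simulator.
#'
#' @return Symmetric 5 x 5 numeric matrix with zero diagonal.
#' @export
canid_target_fst <- function() {
  pops <- c("J", "D", "WDIN", "WIB", "WIT")
  m <- matrix(0, 5, 5, dimnames = list(pops, pops))
  m["J", "D"] <- 0.677
  m["J", "WDIN"] <- 0.734
  m["J", "WIB"] <- 0.781
  m["J", "WIT"] <- 0.884
  m["D", "WDIN"] <- 0.640
  m["D", "WIB"] <- 0.648
  m["D", "WIT"] <- 0.695
  m["WDIN", "WIB"] <- 0.493
  m["WDIN", "WIT"] <- 0.741
  m["WIB", "WIT"] <- 0.813
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Simulation configuration for multi-population AIM panels
#'
#' Describes the synthetic study system: five canid groups (21 jackals,
#' 52 dogs, 30 Dinaric, 25 Iberian and 30 Italian wolves by default) typed
#' at an AIM-grade SNP panel spread over 38 autosomes. Population allele
#' frequencies follow a hierarchical Balding-Nichols model: every locus has
#' an ancestral frequency, the three wolf populations share an additional
#' wolf-clade drift branch, and each population drifts further with its own
#' coefficient. A configurable fraction of loci per population pair is
#' forced to a (near-)fixed allele-frequency difference, emulating the
#' diagnostic fixed-difference AIMs of real reduced panels.
#'
#' @param sizes Named integer vector of group sizes (>= 2 each).
#' @param n_loci Number of loci.
#' @param n_chrom Number of autosomes loci are spread over (round-robin).
#' @param drift Named per-population drift coefficients F in (0, 1).
#' @param clades Named list of clades sharing an extra drift branch.
#' @param clade_drift Named drift coefficients of the clade branches.
#' @param fixed_pairs Named numeric vector of per-pair fractions of loci
#'   forced to a fixed difference. A name `"A:B"` lets the more
#'   differentiated member (larger mean target FST) carry the derived
#'   allele; `"A>B"` forces population B to carry it.
#' @param target_fst Symmetric target FST matrix used by
#'   [calibrate_drift()] and by the side-assignment rule at forced loci.
#' @param missing_rate Probability that any call is missing.
#' @param fixation `"near"` clamps forced loci to `near_clamp` vs
#'   `1 - near_clamp`; `"exact"` uses 1 vs 0.
#' @param near_clamp Allele frequency of the anchored side at near-fixed
#'   forced loci (default 0.998, i.e. a locus that looks fixed in
#'   reference samples of a few dozen individuals while still carrying a
#'   small minor-allele rate in the population).
#' @param anc_range Range of the uniform ancestral-frequency distribution.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(sizes = c(J = 21L, D = 52L, WDIN = 30L, WIB = 25L, WIT = 30L),
                       n_loci = 192L,
                       n_chrom = 38L,
                       drift = c(J = 0.82, D = 0.02, WDIN = 0.02,
                                 WIB = 0.19, WIT = 0.74),
                       clades = list(wolf = c("WDIN", "WIB", "WIT")),
                       clade_drift = c(wolf = 0.39),
                       fixed_pairs = c("WIT>D" = 0.17, "WIT>J" = 0.05,
                                       "WDIN>WIB" = 0.035, "WIB>WDIN" = 0.035,
                                       "WDIN>WIT" = 0.05, "WIB>WIT" = 0.085,
                                       "WIT>WDIN" = 0.015, "WIT>WIB" = 0.015),
                       target_fst = canid_target_fst(),
                       missing_rate = 0.003,
                       fixation = c("near", "exact"),
                       near_clamp = 0.998,
                       anc_range = c(0.05, 0.95)) {
  fixation <- match.arg(fixation)
  stopifnot(near_clamp >= 0.98, near_clamp <= 1)
  pops <- names(sizes)
  stopifnot(!is.null(pops), all(sizes >= 2), n_loci >= 1,
            all(drift > 0), all(drift < 1),
            missing_rate >= 0, missing_rate < 1)
  if (!setequal(names(drift), pops))
    stop("drift must be named with the population names")
  if (!is.null(target_fst)) {
    stopifnot(isTRUE(all.equal(target_fst, t(target_fst))),
              all(diag(target_fst) == 0))
  }
  if (length(fixed_pairs)) {
    if (any(fixed_pairs < 0) || sum(fixed_pairs) > 1)
      stop("fixed-pair fractions must be >= 0 and sum to at most 1")
    for (nm in names(fixed_pairs)) {
      ab <- strsplit(nm, "[:>]")[[1]]
      if (length(ab) != 2 || !all(ab %in% pops))
        stop("bad fixed-pair name: ", nm)
    }
  }
  structure(list(sizes = sizes, n_loci = as.integer(n_loci),
                 n_chrom = as.integer(n_chrom), drift = drift,
                 clades = clades, clade_drift = clade_drift,
                 fixed_pairs = fixed_pairs, target_fst = target_fst,
                 missing_rate = missing_rate, fixation = fixation,
                 near_clamp = near_clamp, anc_range = anc_range),
            class = "sim_config")
}

# Beta draw with mean p and variance F p (1 - p) (Balding-Nichols).
rbn <- function(n, p, f) {
  a <- p * (1 - f) / f
  b <- (1 - p) * (1 - f) / f
  stats::rbeta(n, a, b)
}

# The member of a forced pair that carries the derived (opposite) allele
# at that pair's diagnostic loci: the more differentiated of the two
# populations overall (larger mean target FST, falling back on total
# drift).  The other member and all remaining populations stay around the
# anchored ancestral side, so a diagnostic locus for one pair reads as
# "allele fixed in the outlier population" and barely perturbs other
# pairs.
forced_outlier <- function(pair, config) {
  score <- outlier_scores(config)
  pair[which.max(score[pair])]
}

# "A:B" -> auto outlier by score; "A>B" -> B carries the derived allele
parse_forced_pair <- function(nm, config) {
  if (grepl(">", nm, fixed = TRUE)) {
    ab <- strsplit(nm, ">", fixed = TRUE)[[1]]
    list(members = ab, outlier = ab[2])
  } else {
    ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
    list(members = ab, outlier = forced_outlier(ab, config))
  }
}

outlier_scores <- function(config) {
  pops <- names(config$sizes)
  if (!is.null(config$target_fst)) {
    s <- vapply(pops, function(p)
      mean(config$target_fst[p, setdiff(pops, p)]), 0)
  } else {
    s <- total_drift(config)
  }
  s
}

# accumulated drift of each population from the root (clade branch
# compounding with the population branch)
total_drift <- function(config) {
  pops <- names(config$sizes)
  cl_of <- pop_clades(config)
  vapply(pops, function(p) {
    cl <- cl_of[[p]]
    if (!is.na(cl)) {
      fc <- config$clade_drift[[cl]]
      fc + config$drift[[p]] * (1 - fc)
    } else config$drift[[p]]
  }, 0)
}

pop_clades <- function(config) {
  pops <- names(config$sizes)
  out <- rep(NA_character_, length(pops))
  names(out) <- pops
  for (cl in names(config$clades)) out[config$clades[[cl]]] <- cl
  out
}

#' Draw per-population reference allele frequencies
#'
#' Samples the ancestral frequency of every locus uniformly on
#' `config$anc_range`, applies the shared clade drift branch and the
#' per-population Balding-Nichols drift, then forces the configured
#' fraction of loci per population pair to a (near-)fixed difference.
#' A forced locus is anchored: its ancestral frequency is set to one
#' extreme, the pair member with the larger overall differentiation (the
#' "outlier") carries the opposite extreme, and every other population
#' drifts normally around the anchored ancestral value. Diagnostic loci
#' for one pair therefore read as "allele fixed in the outlier" and barely
#' perturb the differentiation of the remaining pairs.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A `freq_table` with one row per population. The attribute
#'   `fixed_for` is a character vector (length `n_loci`) naming the pair a
#'   locus was forced for, `NA` elsewhere.
#' @export
sample_reference_frequencies <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pops <- names(config$sizes)
  L <- config$n_loci
  anc <- stats::runif(L, config$anc_range[1], config$anc_range[2])

  # allocate forced fixed-difference loci and anchor their ancestral side
  hi <- if (config$fixation == "exact") 1 else config$near_clamp
  lo <- 1 - hi
  counts <- round(config$fixed_pairs * L)
  if (sum(counts) > L) stop("infeasible config: forced fractions exceed 1")
  fixed_for <- rep(NA_character_, L)
  forced <- vector("list", length(counts))
  names(forced) <- names(counts)
  if (sum(counts) > 0) {
    slots <- sample.int(L, sum(counts))
    at <- 0L
    for (nm in names(counts)) {
      if (counts[[nm]] == 0) next
      idx <- slots[(at + 1L):(at + counts[[nm]])]
      at <- at + counts[[nm]]
      fixed_for[idx] <- nm
      side_hi <- stats::runif(length(idx)) < 0.5
      forced[[nm]] <- list(idx = idx, side_hi = side_hi)
      anc[idx] <- ifelse(side_hi, min(hi, 0.998), max(lo, 0.002))
    }
  }

  # clade-branch frequencies, then per-population drift
  parent <- matrix(rep(anc, each = length(pops)), length(pops), L,
                   dimnames = list(pops, NULL))
  for (cl in names(config$clades)) {
    pc <- rbn(L, anc, config$clade_drift[[cl]])
    for (p in config$clades[[cl]]) parent[p, ] <- pc
  }
  freq <- matrix(NA_real_, length(pops), L, dimnames = list(pops, NULL))
  for (p in pops) freq[p, ] <- rbn(L, parent[p, ], config$drift[[p]])

  # the outlier member carries the derived extreme, the other member the
  # anchored ancestral extreme
  for (nm in names(counts)) {
    if (is.null(forced[[nm]])) next
    pp <- parse_forced_pair(nm, config)
    out <- pp$outlier
    other <- setdiff(pp$members, out)
    idx <- forced[[nm]]$idx
    side_hi <- forced[[nm]]$side_hi
    freq[other, idx] <- ifelse(side_hi, hi, lo)
    freq[out, idx] <- ifelse(side_hi, lo, hi)
  }
  loci <- locus_map(L, config$n_chrom)
  loci$category <- fixed_for
  colnames(freq) <- loci$id
  ft <- freq_table(freq,
                   n = matrix(Inf, length(pops), L,
                              dimnames = list(pops, loci$id)),
                   loci = loci)
  attr(ft, "fixed_for") <- fixed_for
  ft
}

# round-robin assignment of loci to chromosomes with increasing positions
locus_map <- function(L, n_chrom) {
  chrom <- rep_len(seq_len(n_chrom), L)
  pos <- integer(L)
  for (ch in seq_len(n_chrom)) {
    k <- sum(chrom == ch)
    pos[chrom == ch] <- seq_len(k) * 100000L
  }
  data.frame(id = sprintf("snp%04d", seq_len(L)),
             chrom = chrom, pos = pos, ref = "A", alt = "G",
             category = NA_character_, stringsAsFactors = FALSE)
}

#' Sample diploid genotypes from reference frequencies
#'
#' Each individual's dosage at each locus is Binomial(2, p) for its
#' population's allele frequency p, independent across loci
#' (Hardy-Weinberg equilibrium, no linkage).
#'
#' @param freqs A `freq_table` (populations x loci).
#' @param sizes Named integer vector of individuals per population; names
#'   must match the rows of `freqs`.
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated sample ids.
#' @return A `genotype_panel`.
#' @export
sample_genotypes <- function(freqs, sizes, seed, id_prefix = "ind") {
  stopifnot(inherits(freqs, "freq_table"),
            all(names(sizes) %in% rownames(freqs$freq)))
  set.seed(seed)
  L <- ncol(freqs$freq)
  n <- sum(sizes)
  calls <- matrix(NA_integer_, n, L)
  groups <- rep(names(sizes), sizes)
  at <- 0L
  for (g in names(sizes)) {
    k <- sizes[[g]]
    p <- freqs$freq[g, ]
    calls[(at + 1L):(at + k), ] <-
      matrix(stats::rbinom(k * L, 2L, rep(p, each = k)), k, L)
    at <- at + k
  }
  samples <- data.frame(id = sprintf("%s%03d", id_prefix, seq_len(n)),
                        group = groups, source = "invasive",
                        stringsAsFactors = FALSE)
  genotype_panel(calls, samples, freqs$loci)
}

#' Inject missing calls
#'
#' Sets each call missing independently with the given probability.
#'
#' @param panel A `genotype_panel`.
#' @param rate Missingness probability in [0, 1).
#' @param seed Integer seed.
#' @return The panel with missing calls injected.
#' @export
inject_missingness <- function(panel, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  set.seed(seed)
  calls <- panel$calls
  calls[stats::runif(length(calls)) < rate] <- NA_integer_
  genotype_panel(calls, panel$samples, panel$loci)
}

#' Simulate one complete synthetic panel
#'
#' Convenience wrapper: draws reference frequencies, samples genotypes and
#' injects missingness, all from one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list with `panel` (`genotype_panel`) and `freqs`
#'   (`freq_table` of the true population frequencies).
#' @export
simulate_panel <- function(config, seed) {
  freqs <- sample_reference_frequencies(config, seed)
  panel <- sample_genotypes(freqs, config$sizes, seed + 1L)
  panel <- inject_missingness(panel, config$missing_rate, seed + 2L)
  list(panel = panel, freqs = freqs)
}

#' Expected pairwise FST of a simulation configuration
#'
#' Closed-form large-sample expectation of the multi-locus Weir-Cockerham
#' theta between every pair of populations under the hierarchical
#' Balding-Nichols model of [sample_reference_frequencies()], including the
#' contribution of forced fixed-difference loci (their side-assignment rule
#' determines which third-party pairs they differentiate). Used as the
#' deterministic objective of [calibrate_drift()].
#'
#' @param config A [sim_config()].
#' @return Symmetric matrix of expected pairwise theta.
#' @export
expected_fst_matrix <- function(config) {
  pops <- names(config$sizes)
  pop_clade <- pop_clades(config)
  ctot <- total_drift(config)
  # ancestral heterozygosity integral E[p(1-p)] for p ~ U(anc_range)
  a0 <- config$anc_range[1]; b0 <- config$anc_range[2]
  mu <- (a0 + b0) / 2
  vu <- (b0 - a0)^2 / 12
  vbar <- mu * (1 - mu) - vu

  hi <- if (config$fixation == "exact") 1 else config$near_clamp
  anchor <- min(hi, 0.998)                   # anchored ancestral side
  anc_v <- anchor * (1 - anchor)

  # continuous locus weights keep the expectation smooth in the fractions
  counts <- config$fixed_pairs * config$n_loci
  n_base <- config$n_loci - sum(counts)

  # per-class population means and variances (class = one forced pair)
  keys <- names(counts)[counts > 0]
  scores <- outlier_scores(config)
  cls_m <- matrix(anchor, length(keys), length(pops),
                  dimnames = list(keys, pops))
  cls_v <- matrix(rep(ctot * anc_v, each = length(keys)),
                  length(keys), length(pops), dimnames = list(keys, pops))
  for (nm in keys) {
    pp <- parse_forced_pair(nm, config)
    cls_m[nm, pp$members] <- hi
    cls_m[nm, pp$outlier] <- 1 - hi
    cls_v[nm, pp$members] <- 0
  }

  fst <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_len(length(pops) - 1)) for (j in seq(i + 1, length(pops))) {
    a <- pops[i]; b <- pops[j]
    rho <- if (!is.na(pop_clade[[a]]) &&
               identical(pop_clade[[a]], pop_clade[[b]]))
      config$clade_drift[[pop_clade[[a]]]] else 0
    # baseline loci
    d2 <- (ctot[[a]] + ctot[[b]] - 2 * rho) * vbar
    pq <- vbar * (1 - (ctot[[a]] + ctot[[b]] + 2 * rho) / 4)
    num <- n_base * d2 / 2
    den <- n_base * (pq + d2 / 4)
    if (length(keys)) {
      # forced loci: members sit at the two extremes, the rest drift
      # around the anchored ancestral extreme
      va <- cls_v[, a]; vb <- cls_v[, b]
      covf <- ifelse(va > 0 & vb > 0, rho * anc_v, 0)
      d2f <- (cls_m[, a] - cls_m[, b])^2 + va + vb - 2 * covf
      mbar <- (cls_m[, a] + cls_m[, b]) / 2
      pqf <- mbar * (1 - mbar) - (va + vb + 2 * covf) / 4
      num <- num + sum(counts[keys] * d2f / 2)
      den <- den + sum(counts[keys] * (pqf + d2f / 4))
    }
    fst[i, j] <- fst[j, i] <- num / den
  }
  fst
}

#' Calibrate the simulator to a target FST matrix
#'
#' Iteratively adjusts the per-population (and clade-branch) drift
#' coefficients, and optionally the per-pair fixed-difference fractions,
#' until the realized multi-locus pairwise Weir-Cockerham FST of simulated
#' panels matches the target matrix entry-wise within the tolerance.
#' Calibration panels use a larger locus count than the production panel
#' so the realized matrix is estimated with little noise.
#'
#' @param config A [sim_config()].
#' @param target Symmetric target matrix (default `config$target_fst`).
#' @param seed Integer seed.
#' @param tol Entry-wise tolerance on the realized matrix (default 0.05).
#' @param max_iter Maximum calibration iterations (default 50).
#' @param n_loci_cal Locus count of the internal calibration panels.
#' @param adjust_fixed Also tune the per-pair forced fractions (default
#'   TRUE; drift-only updates cannot fit targets that violate the additive
#'   pair structure of the drift model).
#' @param design_pairs Named fractions held constant during calibration.
#'   The default (`NULL`) keeps every configured fraction fixed: the
#'   per-pair share of diagnostic loci is a design property of an AIM
#'   panel that a mean-FST target cannot identify (a drift-heavy and a
#'   diagnostic-locus-heavy panel can have identical mean FST but very
#'   different per-locus informativeness), so panel composition is pinned
#'   and only the drift coefficients plus any unconfigured directional
#'   classes move. Pass an empty numeric to free everything.
#' @return A list of class `drift_calibration`: `config` (calibrated copy),
#'   `drift`, `clade_drift`, `fixed_pairs`, `realized` (FST matrix of the
#'   final calibration panel), `iterations`, `converged`. Warns and returns
#'   the best configuration found if the tolerance is not reached.
#' @export
calibrate_drift <- function(config, target = config$target_fst, seed,
                            tol = 0.05, max_iter = 50L, n_loci_cal = 2000L,
                            adjust_fixed = TRUE, design_pairs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  off <- target[upper.tri(target)]
  if (any(off <= 0 | off >= 1)) stop("target FST entries must lie in (0, 1)")
  pops <- names(config$sizes)
  pairs <- t(utils::combn(pops, 2))
  npair <- nrow(pairs)
  nd <- length(pops)
  ncd <- length(config$clade_drift)

  # directional parameter space: for each pair, one knob per choice of
  # which member carries the derived allele
  dir_key <- c(paste0(pairs[, 1], ">", pairs[, 2]),
               paste0(pairs[, 2], ">", pairs[, 1]))
  canon_key <- function(nm) {
    pp <- parse_forced_pair(nm, config)
    paste0(setdiff(pp$members, pp$outlier), ">", pp$outlier)
  }
  canon_fracs <- function(fp) {
    f <- setNames(numeric(length(dir_key)), dir_key)
    for (nm in names(fp)) f[canon_key(nm)] <- f[canon_key(nm)] + fp[[nm]]
    f
  }
  if (is.null(design_pairs)) design_pairs <- config$fixed_pairs
  design_pairs <- canon_fracs(design_pairs)
  design_pairs <- design_pairs[design_pairs > 0]
  kept_key <- names(design_pairs)
  free_key <- if (adjust_fixed) setdiff(dir_key, kept_key) else character(0)
  nfree <- length(free_key)

  set_params <- function(cfg, drifts, free_fr) {
    cfg$drift[pops] <- pmin(pmax(drifts[seq_len(nd)], 0.005), 0.98)
    if (ncd) cfg$clade_drift[] <- pmin(pmax(drifts[nd + seq_len(ncd)], 0.005), 0.98)
    f <- canon_fracs(cfg$fixed_pairs)
    f[kept_key] <- design_pairs[kept_key]
    if (nfree) f[free_key] <- pmin(pmax(free_fr, 0), 0.6)
    if (sum(f) > 0.9) {
      scale <- (0.9 - sum(f[kept_key])) / max(sum(f[free_key]), 1e-9)
      f[free_key] <- f[free_key] * max(scale, 0)
    }
    cfg$fixed_pairs <- f[f > 1e-4]
    cfg
  }
  realized_fst <- function(cfg, sim_seed) {
    cfg$n_loci <- as.integer(n_loci_cal)
    cfg$missing_rate <- 0
    sim <- simulate_panel(cfg, sim_seed)
    pairwise_fst_matrix(sim$panel, pops)$fst
  }

  # fully vectorised expected pairwise theta, precomputed over the
  # directional class table (equivalent to expected_fst_matrix but cheap
  # enough for a quasi-Newton objective)
  hi <- if (config$fixation == "exact") 1 else config$near_clamp
  anchor <- min(hi, 0.998)
  anc_v <- anchor * (1 - anchor)
  a0 <- config$anc_range[1]; b0 <- config$anc_range[2]
  vbar <- (a0 + b0) / 2 * (1 - (a0 + b0) / 2) - (b0 - a0)^2 / 12
  clade_names <- names(config$clade_drift)
  cl_of <- pop_clades(config)
  cl_idx <- setNames(match(cl_of, clade_names, nomatch = 0L), pops)
  scl <- apply(pairs, 1, function(p)
    if (cl_idx[[p[1]]] > 0 && cl_idx[[p[1]]] == cl_idx[[p[2]]])
      cl_idx[[p[1]]] else 0L)
  nkey <- length(dir_key)
  M <- matrix(anchor, nkey, nd, dimnames = list(dir_key, pops))
  nonmem <- matrix(TRUE, nkey, nd, dimnames = list(dir_key, pops))
  for (k in seq_len(nkey)) {
    ab <- strsplit(dir_key[k], ">", fixed = TRUE)[[1]]
    M[k, ab[1]] <- hi
    M[k, ab[2]] <- 1 - hi
    nonmem[k, ab] <- FALSE
  }
  expected_pairs_fast <- function(drift, claded, fr) {
    ctot <- ifelse(cl_idx > 0,
                   claded[pmax(cl_idx, 1)] + drift * (1 - claded[pmax(cl_idx, 1)]),
                   drift)
    counts <- fr * config$n_loci
    n_base <- config$n_loci - sum(counts)
    V <- nonmem * rep(ctot * anc_v, each = nkey)
    out <- numeric(npair)
    for (r in seq_len(npair)) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      rho <- if (scl[r] > 0) claded[scl[r]] else 0
      d2 <- (ctot[[a]] + ctot[[b]] - 2 * rho) * vbar
      pq <- vbar * (1 - (ctot[[a]] + ctot[[b]] + 2 * rho) / 4)
      num <- n_base * d2 / 2
      den <- n_base * (pq + d2 / 4)
      va <- V[, a]; vb <- V[, b]
      covf <- (nonmem[, a] & nonmem[, b] & scl[r] > 0) * rho * anc_v
      d2f <- (M[, a] - M[, b])^2 + va + vb - 2 * covf
      mb <- (M[, a] + M[, b]) / 2
      pqf <- mb * (1 - mb) - (va + vb + 2 * covf) / 4
      num <- num + sum(counts * d2f) / 2
      den <- den + sum(counts * (pqf + d2f / 4))
      out[r] <- num / den
    }
    out
  }

  # inner solver: quasi-Newton minimisation of the squared misfit on
  # logit-transformed parameters so the bounds never clamp a step; a
  # structured second start guards against poor basins
  frac_from_x <- function(x) {
    f <- setNames(numeric(nkey), dir_key)
    f[kept_key] <- design_pairs[kept_key]
    if (nfree) f[free_key] <- 0.6 * stats::plogis(x[nd + ncd + seq_len(nfree)])
    if (sum(f) > 0.9) {
      scale <- (0.9 - sum(f[kept_key])) / max(sum(f[free_key]), 1e-9)
      f[free_key] <- f[free_key] * max(scale, 0)
    }
    f
  }
  to_x <- function(cfg) {
    dr <- pmin(pmax(c(cfg$drift[pops], cfg$clade_drift), 0.006), 0.974)
    fr <- pmin(pmax(canon_fracs(cfg$fixed_pairs)[free_key], 1e-5), 0.599)
    c(stats::qlogis((dr - 0.005) / 0.97),
      if (nfree) stats::qlogis(fr / 0.6))
  }
  from_x <- function(x) {
    dr <- 0.005 + 0.97 * stats::plogis(x[seq_len(nd + ncd)])
    f <- frac_from_x(x)
    set_params(config, dr, f[free_key])
  }
  fit_expected <- function(cfg, tgt) {
    tv <- tgt[pairs]
    sse <- function(x) {
      dr <- 0.005 + 0.97 * stats::plogis(x[seq_len(nd + ncd)])
      ex <- expected_pairs_fast(dr[seq_len(nd)], dr[nd + seq_len(ncd)],
                                frac_from_x(x))
      sum((ex - tv)^2)
    }
    row_mean <- vapply(pops, function(p)
      mean(tgt[p, setdiff(pops, p)]), 0)
    s2 <- cfg
    s2$drift[pops] <- pmin(pmax(row_mean, 0.1), 0.9)
    fp2 <- canon_fracs(cfg$fixed_pairs)
    fp2[free_key] <- 0.02
    s2$fixed_pairs <- fp2
    starts <- list(to_x(cfg), to_x(s2))
    best_x <- NULL
    best_v <- Inf
    for (x0 in starts) {
      o <- stats::optim(x0, sse, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-10))
      if (o$value < best_v) { best_v <- o$value; best_x <- o$par }
    }
    from_x(best_x)
  }

  best <- NULL
  best_err <- Inf
  cfg <- config
  inner_tol <- 0.8 * tol     # headroom for noise at production locus counts
  eff_target <- target       # shifted to absorb model-vs-simulation bias
  it <- 0L
  repeat {
    it <- it + 1L
    cfg <- fit_expected(cfg, eff_target)
    # average two simulated panels so the bias estimate is not chasing
    # single-panel sampling noise
    realized <- (realized_fst(cfg, seed + 1013L * it) +
                   realized_fst(cfg, seed + 1013L * it + 499L)) / 2
    err <- realized[pairs] - target[pairs]
    worst <- max(abs(err))
    if (worst < best_err) {
      best_err <- worst
      best <- list(cfg = cfg, realized = realized, iter = it)
    }
    if (worst <= inner_tol || it >= max(6L, max_iter %/% 8L)) break
    eff_target[pairs] <- pmin(pmax(eff_target[pairs] - 0.7 * err, 0.02), 0.98)
    eff_target[pairs[, 2:1]] <- eff_target[pairs]
  }
  converged <- best_err <= inner_tol
  if (!converged)
    warning(sprintf(
      "calibration did not reach tolerance %.3f (best max error %.3f); returning best found",
      tol, best_err))
  out <- best$cfg
  structure(list(config = out, drift = out$drift,
                 clade_drift = out$clade_drift,
                 fixed_pairs = out$fixed_pairs,
                 realized = best$realized,
                 iterations = it, converged = converged),
            class = "drift_calibration")
}

#' @export
print.drift_calibration <- function(x, ...) {
  cat("drift_calibration:", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("drift:", paste(sprintf("%s=%.3f", names(x$drift), x$drift),
                      collapse = ", "), "\n")
  if (length(x$fixed_pairs))
    cat("fixed pairs:", paste(sprintf("%s=%.3f", names(x$fixed_pairs),
                                      x$fixed_pairs), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate replicate genotyping of a panel
#'
#' Emulates microfluidic re-genotyping of every sample: each replicate of
#' each call fails with probability `fail_rate`; a heterozygous truth drops
#' one random allele (appearing homozygous) with probability `ado_rate`;
#' any surviving call substitutes one allele with the wrong one with
#' probability `fa_rate`.
#'
#' @param panel A `genotype_panel` holding the true genotypes.
#' @param n_replicates Replicates per sample (2-3 in typical assays).
#' @param ado_rate,fa_rate,fail_rate Error and failure probabilities in
#'   [0, 1).
#' @param seed Integer seed.
#' @return A `replicate_set`: list with `calls` (samples x loci x
#'   replicates integer array, `NA` = failed), `samples`, `loci`, `truth`.
#' @export
simulate_replicates <- function(panel, n_replicates = 3L, ado_rate = 0,
                                fa_rate = 0, fail_rate = 0, seed) {
  stopifnot(ado_rate >= 0, ado_rate < 1, fa_rate >= 0, fa_rate < 1,
            fail_rate >= 0, fail_rate < 1)
  set.seed(seed)
  n <- n_samples(panel); L <- n_loci(panel)
  calls <- array(NA_integer_, c(n, L, n_replicates),
                 dimnames = list(panel$samples$id, panel$loci$id, NULL))
  for (r in seq_len(n_replicates)) {
    g <- panel$calls
    het <- !is.na(g) & g == 1L
    drop <- het & (stats::runif(n * L) < ado_rate)
    g[drop] <- ifelse(stats::runif(sum(drop)) < 0.5, 0L, 2L)
    fa <- !is.na(g) & (stats::runif(n * L) < fa_rate)
    if (any(fa)) {
      cur <- g[fa]
      # replace one random allele copy with the other allele type
      g[fa] <- ifelse(cur == 0L, 1L,
                      ifelse(cur == 2L, 1L,
                             ifelse(stats::runif(length(cur)) < 0.5, 0L, 2L)))
    }
    g[stats::runif(n * L) < fail_rate] <- NA_integer_
    calls[, , r] <- g
  }
  structure(list(calls = calls, samples = panel$samples, loci = panel$loci,
                 truth = panel$calls),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  d <- dim(x$calls)
  cat("replicate_set:", d[1], "samples x", d[2], "loci x", d[3],
      "replicates\n")
  invisible(x)
}

#' Long-format conversion for replicate sets
#'
#' @param x A `replicate_set`.
#' @return Data frame with columns `sample`, `locus`, `replicate`, `call`
#'   (NA = failed amplification).
#' @export
replicate_long <- function(x) {
  stopifnot(inherits(x, "replicate_set"))
  d <- dim(x$calls)
  data.frame(
    sample = rep(x$samples$id, times = d[2] * d[3]),
    locus = rep(rep(x$loci$id, each = d[1]), times = d[3]),
    replicate = rep(seq_len(d[3]), each = d[1] * d[2]),
    call = as.vector(x$calls),
    stringsAsFactors = FALSE
  )
}
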