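#' Simulate first-generation hybrids from parental allele frequencies
#'
#' HybridLab-style cross: each F1 offspring receives, at every locus, one
#' allele drawn Bernoulli(p_A) from parent population A's frequency and
#' one drawn Bernoulli(p_B) from parent population B's, independently
#' across loci. Loci with a missing frequency in either parent are
#' dropped with a warning.
#'
#' @param freqs A `freq_table` of parental population frequencies.
#' @param parent_a,parent_b Row names of the two parent populations.
#' @param n Number of offspring (default 10).
#' @param seed Integer seed.
#' @param label Group label of the offspring (default `"A-B"`).
#' @return A `genotype_panel` of simulated F1 individuals.
#' @export
simulate_f1 <- function(freqs, parent_a, parent_b, n = 10L, seed,
                        label = paste0(parent_a, "-", parent_b)) {
  stopifnot(inherits(freqs, "freq_table"),
            all(c(parent_a, parent_b) %in% rownames(freqs$freq)))
  pa <- freqs$freq[parent_a, ]
  pb <- freqs$freq[parent_b, ]
  keep <- !is.na(pa) & !is.na(pb)
  if (!all(keep)) {
    warning(sum(!keep), " loci missing a parental frequency dropped from cross ",
            label)
  }
  set.seed(seed)
  L <- sum(keep)
  g1 <- matrix(stats::rbinom(n * L, 1L, rep(pa[keep], each = n)), n, L)
  g2 <- matrix(stats::rbinom(n * L, 1L, rep(pb[keep], each = n)), n, L)
  calls <- g1 + g2
  samples <- data.frame(id = sprintf("%s_F1_%02d", label, seq_len(n)),
                        group = label, source = "invasive",
                        stringsAsFactors = FALSE)
  genotype_panel(calls, samples, freqs$loci[keep, , drop = FALSE])
}

#' Simulate first-generation backcrosses
#'
#' Each BC1 offspring receives one allele drawn from the allele frequency
#' of the simulated F1 pool at that locus (the population-frequency
#' approach of HybridLab) and one drawn Bernoulli(p) from the backcross
#' parent population's frequency.
#'
#' @param f1_panel A nonempty `genotype_panel` of F1 individuals.
#' @param freqs Parental `freq_table`.
#' @param backcross_parent Row name of the backcross parent population.
#' @param n Number of offspring (default 10).
#' @param seed Integer seed.
#' @param label Group label of the offspring.
#' @return A `genotype_panel` of simulated BC1 individuals.
#' @export
simulate_backcross <- function(f1_panel, freqs, backcross_parent, n = 10L,
                               seed,
                               label = paste0(unique(f1_panel$samples$group)[1],
                                              "-", backcross_parent)) {
  if (n_samples(f1_panel) == 0) stop("empty F1 pool")
  stopifnot(backcross_parent %in% rownames(freqs$freq))
  ids <- match(f1_panel$loci$id, freqs$loci$id)
  if (anyNA(ids)) stop("F1 panel loci missing from the frequency table")
  p_f1 <- colMeans(f1_panel$calls, na.rm = TRUE) / 2
  p_bc <- freqs$freq[backcross_parent, ids]
  keep <- !is.na(p_f1) & !is.na(p_bc)
  if (!all(keep))
    warning(sum(!keep), " loci without both pool and parental frequencies ",
            "dropped from backcross ", label)
  set.seed(seed)
  L <- sum(keep)
  g1 <- matrix(stats::rbinom(n * L, 1L, rep(p_f1[keep], each = n)), n, L)
  g2 <- matrix(stats::rbinom(n * L, 1L, rep(p_bc[keep], each = n)), n, L)
  samples <- data.frame(id = sprintf("%s_BC1_%02d", label, seq_len(n)),
                        group = label, source = "invasive",
                        stringsAsFactors = FALSE)
  genotype_panel(g1 + g2, samples, f1_panel$loci[keep, , drop = FALSE])
}

#' Standard cross list for a set of reference groups
#'
#' All pairwise F1 crosses, plus the BC1 types of the reference workflow:
#' wolf x wolf and jackal x wolf crosses are backcrossed to both parents,
#' dog x wolf crosses only to the wolf parent, and the dog x jackal cross
#' to the jackal — backcrosses go to the wild parental populations.
#'
#' @param wolves Wolf group labels.
#' @param dog,jackal Dog and jackal group labels.
#' @return List with `f1` (two-column matrix of parent pairs) and `bc1`
#'   (three-column matrix: parent A, parent B, backcross parent).
#' @export
standard_crosses <- function(wolves = c("WDIN", "WIB", "WIT"), dog = "D",
                             jackal = "J") {
  groups <- c(jackal, dog, wolves)
  f1 <- t(utils::combn(groups, 2))
  bc1 <- matrix(character(0), 0, 3)
  add <- function(a, b, to) rbind(bc1, c(a, b, to))
  for (i in seq_along(wolves)) {
    for (j in seq_along(wolves)) {
      if (i < j) {
        bc1 <- add(wolves[i], wolves[j], wolves[i])
        bc1 <- add(wolves[i], wolves[j], wolves[j])
      }
    }
    bc1 <- add(jackal, wolves[i], wolves[i])
    bc1 <- add(jackal, wolves[i], jackal)
    bc1 <- add(dog, wolves[i], wolves[i])
  }
  bc1 <- add(dog, jackal, jackal)
  colnames(f1) <- c("parent_a", "parent_b")
  colnames(bc1) <- c("parent_a", "parent_b", "backcross_parent")
  list(f1 = f1, bc1 = bc1)
}

#' Build a hybrid validation panel
#'
#' Concatenates the parental panel with simulated F1 and BC1 individuals
#' for each requested cross, labelled by cross id (`"A-B"` for F1,
#' `"A-B-C"` for a backcross of the A x B cross to parent C).
#'
#' @param panel Parental `genotype_panel`.
#' @param freqs Parental `freq_table` (typically estimated from `panel`
#'   via [allele_freqs()] after QC).
#' @param crosses A cross list as from [standard_crosses()]; an empty
#'   list leaves the panel unchanged.
#' @param n_per_cross Offspring per cross (default 10).
#' @param seed Integer seed.
#' @return List with `panel` (parentals + hybrids), `hybrid_groups`
#'   (data frame: cross label, type F1/BC1, parents, backcross parent).
#' @export
build_validation_set <- function(panel, freqs, crosses, n_per_cross = 10L,
                                 seed = 1L) {
  groups <- unique(panel$samples$group)
  out <- panel
  info <- data.frame(label = character(0), type = character(0),
                     parent_a = character(0), parent_b = character(0),
                     backcross_parent = character(0),
                     stringsAsFactors = FALSE)
  f1_cache <- list()
  if (!is.null(crosses$f1) && nrow(crosses$f1)) {
    for (r in seq_len(nrow(crosses$f1))) {
      ab <- crosses$f1[r, ]
      if (!all(ab %in% groups)) stop("unknown group in cross: ",
                                     paste(ab, collapse = " x "))
      lab <- paste(ab, collapse = "-")
      f1 <- simulate_f1(freqs, ab[1], ab[2], n = n_per_cross,
                        seed = seed + 11L * r, label = lab)
      f1_cache[[lab]] <- f1
      out <- bind_samples(out, f1)
      info <- rbind(info, data.frame(label = lab, type = "F1",
                                     parent_a = ab[1], parent_b = ab[2],
                                     backcross_parent = NA_character_,
                                     stringsAsFactors = FALSE))
    }
  }
  if (!is.null(crosses$bc1) && nrow(crosses$bc1)) {
    for (r in seq_len(nrow(crosses$bc1))) {
      abc <- crosses$bc1[r, ]
      if (!all(abc %in% groups)) stop("unknown group in cross: ",
                                      paste(abc, collapse = " x "))
      f1lab <- paste(abc[1:2], collapse = "-")
      f1 <- f1_cache[[f1lab]]
      if (is.null(f1)) {
        f1 <- simulate_f1(freqs, abc[1], abc[2], n = n_per_cross,
                          seed = seed + 101L * r, label = f1lab)
        f1_cache[[f1lab]] <- f1
      }
      lab <- paste(abc, collapse = "-")
      bc <- simulate_backcross(f1, freqs, abc[3], n = n_per_cross,
                               seed = seed + 211L * r, label = lab)
      out <- bind_samples(out, bc)
      info <- rbind(info, data.frame(label = lab, type = "BC1",
                                     parent_a = abc[1], parent_b = abc[2],
                                     backcross_parent = abc[3],
                                     stringsAsFactors = FALSE))
    }
  }
  list(panel = out, hybrid_groups = info)
}
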