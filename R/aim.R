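#' Per-locus FST for every population pair
#'
#' Convenience wrapper running [per_locus_fst()] for all pairs of the
#' given groups.
#'
#' @param panel A `genotype_panel`.
#' @param groups Group labels (default all).
#' @return Named list of per-pair data frames, keys `"A:B"`.
#' @export
pairwise_locus_stats <- function(panel, groups = NULL) {
  if (is.null(groups)) groups <- unique(panel$samples$group)
  prs <- utils::combn(groups, 2)
  out <- lapply(seq_len(ncol(prs)), function(i)
    per_locus_fst(panel, prs[1, i], prs[2, i]))
  names(out) <- paste0(prs[1, ], ":", prs[2, ])
  out
}

#' Candidate AIM pools per population pair
#'
#' For each pair, loci with FST at or above `fst_min` are ranked by
#' descending FST (ties by chromosome, position, id) and the top `top_n`
#' are taken under an even-chromosome rule: loci are picked round-robin
#' across chromosomes in within-chromosome rank order, so no chromosome
#' dominates the pool. Pairs with fewer than `top_n` qualifying loci
#' return them all with a warning.
#'
#' @param stats List of per-pair locus statistics from
#'   [pairwise_locus_stats()].
#' @param fst_min Minimum (rank-clamped) FST (default 0.90).
#' @param top_n Pool size per pair (default 45).
#' @return Named list of data frames (subset of the input rows, in
#'   selection order). Each pool carries the attribute `qualifying`: the
#'   ids of every locus that met the FST threshold for that pair, before
#'   the top-`top_n` cut (used by the shared categories of
#'   [prioritize_panel()]).
#' @export
candidate_pool <- function(stats, fst_min = 0.90, top_n = 45L) {
  lapply_named(stats, function(df, key) {
    qual <- df[df$theta_rank >= fst_min, , drop = FALSE]
    if (nrow(qual) == 0) {
      warning("no loci reach FST ", fst_min, " for pair ", key)
      attr(qual, "qualifying") <- character(0)
      return(qual)
    }
    ord <- order(-qual$theta_rank, qual$chrom, qual$pos, qual$id)
    qual <- qual[ord, , drop = FALSE]
    if (nrow(qual) <= top_n) {
      if (nrow(qual) < top_n)
        warning("only ", nrow(qual), " of ", top_n,
                " qualifying loci for pair ", key)
      attr(qual, "qualifying") <- qual$id
      return(qual)
    }
    # round-robin across chromosomes by within-chromosome rank
    qids <- qual$id
    qual$.rank <- stats::ave(seq_len(nrow(qual)), qual$chrom,
                             FUN = seq_along)
    ord2 <- order(qual$.rank, qual$chrom)
    picked <- qual[ord2, , drop = FALSE][seq_len(top_n), ]
    picked$.rank <- NULL
    attr(picked, "qualifying") <- qids
    picked
  })
}

lapply_named <- function(x, f) {
  out <- lapply(names(x), function(k) f(x[[k]], k))
  names(out) <- names(x)
  out
}

#' Default selection-category quotas
#'
#' The reduced-panel prioritisation ladder: (a) wolf-jackal discriminant
#' loci, (b) loci shared by all wolf-wolf pair pools, (c) Italian-Iberian,
#' (d) Italian-Dinaric, (e) dog-Italian, (f) dog-Iberian, (g) dog-Dinaric,
#' and (h) loci shared by all dog-wolf pools.
#'
#' @return Named integer vector of quotas (a-h).
#' @export
default_category_quota <- function() {
  c(a = 15L, b = 37L, c = 23L, d = 2L, e = 13L, f = 2L, g = 3L, h = 10L)
}

#' Prioritise candidate pools into a reduced panel
#'
#' Fills the selection categories in ladder order with their quotas,
#' skipping loci already selected (first category wins). Category (a)
#' draws from the jackal-wolf pools (best FST first); (b) takes pooled
#' loci that qualified for all three wolf-wolf comparisons; (c)-(g) draw
#' from single pair pools; (h) takes pooled loci that qualified for all
#' three dog-wolf comparisons.
#' Unreachable quotas are filled as far as the pools allow, with a
#' warning.
#'
#' @param candidates Named list from [candidate_pool()].
#' @param quota Named quotas as from [default_category_quota()].
#' @param wolves,dog,jackal Group labels.
#' @return A `panel_selection` data frame: `id`, `category`, `pair`,
#'   `theta`, with attribute `counts` (per-category totals).
#' @export
prioritize_panel <- function(candidates, quota = default_category_quota(),
                             wolves = c("WDIN", "WIB", "WIT"), dog = "D",
                             jackal = "J") {
  key_of <- function(a, b) {
    k1 <- paste0(a, ":", b); k2 <- paste0(b, ":", a)
    if (k1 %in% names(candidates)) k1 else k2
  }
  pool <- function(...) {
    keys <- c(...)
    rows <- do.call(rbind, lapply(keys, function(k) {
      df <- candidates[[k]]
      if (is.null(df) || nrow(df) == 0) return(NULL)
      data.frame(id = df$id, pair = k, theta = df$theta,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) return(rows)
    rows[order(-rows$theta, rows$id), , drop = FALSE]
  }
  intersect_pool <- function(keys) {
    # loci meeting the threshold in every listed comparison, drawn from
    # whatever pools they entered
    common <- Reduce(intersect, lapply(keys, function(k) {
      q <- attr(candidates[[k]], "qualifying")
      if (is.null(q)) candidates[[k]]$id else q
    }))
    rows <- pool(keys)
    rows <- rows[rows$id %in% common, , drop = FALSE]
    rows[!duplicated(rows$id), , drop = FALSE]
  }
  wolf_pairs <- utils::combn(wolves, 2)
  wolf_keys <- vapply(seq_len(ncol(wolf_pairs)), function(i)
    key_of(wolf_pairs[1, i], wolf_pairs[2, i]), "")
  dogwolf_keys <- vapply(wolves, function(w) key_of(dog, w), "")
  sources <- list(
    a = pool(vapply(wolves, function(w) key_of(jackal, w), "")),
    b = intersect_pool(wolf_keys),
    c = pool(key_of("WIT", "WIB")),
    d = pool(key_of("WIT", "WDIN")),
    e = pool(key_of(dog, "WIT")),
    f = pool(key_of(dog, "WIB")),
    g = pool(key_of(dog, "WDIN")),
    h = intersect_pool(dogwolf_keys)
  )
  chosen <- character(0)
  rows <- NULL
  for (cat in names(quota)) {
    src <- sources[[cat]]
    if (!is.null(src)) src <- src[!duplicated(src$id), , drop = FALSE]
    avail <- if (is.null(src)) NULL else
      src[!(src$id %in% chosen), , drop = FALSE]
    take <- min(quota[[cat]], if (is.null(avail)) 0L else nrow(avail))
    if (take < quota[[cat]])
      warning("category ", cat, ": quota ", quota[[cat]],
              " but only ", take, " loci available")
    if (take > 0) {
      sel <- avail[seq_len(take), , drop = FALSE]
      sel$category <- cat
      rows <- rbind(rows, sel)
      chosen <- c(chosen, sel$id)
    }
  }
  if (is.null(rows))
    rows <- data.frame(id = character(0), pair = character(0),
                       theta = numeric(0), category = character(0),
                       stringsAsFactors = FALSE)
  rows <- rows[, c("id", "category", "pair", "theta")]
  attr(rows, "counts") <- table(factor(rows$category, levels = names(quota)))
  class(rows) <- c("panel_selection", "data.frame")
  rows
}

#' Compose the final panel
#'
#' Unions the prioritised selection with force-included phenotypic loci
#' and a prior reference panel, deduplicating (first listing wins; any
#' overlap is recorded).
#'
#' @param selection A `panel_selection` from [prioritize_panel()].
#' @param phenotypic_ids Locus ids force-included regardless of filters
#'   (they must exist in `all_loci`).
#' @param prior_panel_ids Locus ids of a previously published panel.
#' @param all_loci Locus table of the source data (as in a
#'   `genotype_panel`); used to validate the phenotypic ids.
#' @return A `panel_selection` with categories `"phenotypic"` and
#'   `"prior"` appended; attribute `overlap` lists ids dropped as
#'   duplicates.
#' @export
compose_final_panel <- function(selection, phenotypic_ids = character(0),
                                prior_panel_ids = character(0),
                                all_loci = NULL) {
  if (!is.null(all_loci)) {
    missing_ph <- setdiff(phenotypic_ids, all_loci$id)
    if (length(missing_ph))
      stop("phenotypic locus absent from source data: ",
           paste(missing_ph, collapse = ", "))
  }
  rows <- as.data.frame(selection)
  overlap <- character(0)
  add <- function(rows, ids, cat) {
    dup <- ids %in% rows$id
    overlap <<- c(overlap, ids[dup])
    if (any(!dup))
      rows <- rbind(rows, data.frame(id = ids[!dup], category = cat,
                                     pair = NA_character_,
                                     theta = NA_real_,
                                     stringsAsFactors = FALSE))
    rows
  }
  rows <- add(rows, phenotypic_ids, "phenotypic")
  rows <- add(rows, prior_panel_ids, "prior")
  attr(rows, "counts") <- table(rows$category)
  attr(rows, "overlap") <- overlap
  class(rows) <- c("panel_selection", "data.frame")
  rows
}

#' @export
print.panel_selection <- function(x, ...) {
  cat("panel_selection:", nrow(x), "loci\n")
  print(attr(x, "counts"))
  invisible(x)
}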