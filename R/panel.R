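#' Genotype panel container
#'
#' A `genotype_panel` bundles a biallelic dosage matrix with its sample and
#' locus metadata. It is the common currency of the package: the simulator
#' produces one, the QC filters and the marker-selection ladder subset it,
#' and the assignment and diversity statistics consume it.
#'
#' @param calls Integer matrix of alternate-allele dosages, samples in rows
#'   and loci in columns. Allowed values are 0, 1, 2 and `NA` (missing).
#' @param samples Data frame with one row per sample: columns `id`
#'   (unique character), `group` (population label) and optionally `source`
#'   (`"invasive"` or `"noninvasive"`; defaults to `"invasive"`).
#' @param loci Data frame with one row per locus: columns `id` (unique
#'   character), `chrom` (integer autosome 1-38), `pos` (1-based bp
#'   position), `ref` and `alt` (single-character alleles) and optionally
#'   `category` (selection tag, defaults to `NA`).
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `calls`, `samples`, `loci`.
#' @examples
#' p <- genotype_panel(
#'   calls = rbind(a = c(0L, 1L), b = c(2L, NA)),
#'   samples = data.frame(id = c("a", "b"), group = c("W", "D")),
#'   loci = data.frame(id = c("L1", "L2"), chrom = c(1L, 2L),
#'                     pos = c(100L, 200L), ref = "A", alt = "G")
#' )
#' n_samples(p)
#' @export
genotype_panel <- function(calls, samples, loci) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  if (is.null(samples$source)) samples$source <- "invasive"
  if (is.null(loci$category)) loci$category <- NA_character_
  stopifnot(
    all(c("id", "group") %in% names(samples)),
    all(c("id", "chrom", "pos", "ref", "alt") %in% names(loci))
  )
  samples$id <- as.character(samples$id)
  loci$id <- as.character(loci$id)
  if (nrow(calls) != nrow(samples))
    stop("calls has ", nrow(calls), " rows but samples has ", nrow(samples))
  if (ncol(calls) != nrow(loci))
    stop("calls has ", ncol(calls), " columns but loci has ", nrow(loci))
  if (anyDuplicated(samples$id))
    stop("duplicated sample id: ",
         paste(unique(samples$id[duplicated(samples$id)]), collapse = ", "))
  if (anyDuplicated(loci$id))
    stop("duplicated locus id: ",
         paste(unique(loci$id[duplicated(loci$id)]), collapse = ", "))
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(!is.na(loci$chrom) & (loci$chrom < 1 | loci$chrom > 38)))
    stop("chrom must be an autosome in 1..38")
  dimnames(calls) <- list(samples$id, loci$id)
  structure(list(calls = calls, samples = samples, loci = loci),
            class = "genotype_panel")
}

#' @rdname genotype_panel
#' @param x,panel A `genotype_panel`.
#' @export
n_samples <- function(x) nrow(x$calls)

#' @rdname genotype_panel
#' @export
n_loci <- function(x) ncol(x$calls)

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", n_samples(x), "samples x", n_loci(x), "loci\n")
  gr <- table(x$samples$group)
  cat("groups:", paste(sprintf("%s (%d)", names(gr), gr), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param x A `genotype_panel`.
#' @param i Sample index (integer, logical, or sample ids).
#' @param j Locus index (integer, logical, or locus ids).
#' @param ... Ignored.
#' @return A `genotype_panel` restricted to the selected samples and loci.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_loci(x))
  if (is.character(i)) i <- match(i, x$samples$id)
  if (is.character(j)) j <- match(j, x$loci$id)
  genotype_panel(x$calls[i, j, drop = FALSE],
                 x$samples[i, , drop = FALSE],
                 x$loci[j, , drop = FALSE])
}

#' Combine panels over samples
#'
#' Row-binds two panels that share an identical locus table.
#' @param a,b `genotype_panel` objects with identical loci.
#' @return A `genotype_panel` with the samples of `a` followed by those of `b`.
#' @export
bind_samples <- function(a, b) {
  if (!identical(a$loci$id, b$loci$id))
    stop("panels do not share the same locus set")
  genotype_panel(rbind(a$calls, b$calls),
                 rbind(a$samples, b$samples),
                 a$loci)
}

#' Per-population allele frequencies
#'
#' Estimates the alternate-allele frequency of every locus in every
#' population of the panel, together with the number of allele copies the
#' estimate is based on (twice the number of non-missing genotypes).
#'
#' @param panel A `genotype_panel`.
#' @param groups Optional character vector of group labels to include
#'   (default: all groups present, in order of first appearance).
#' @return A `freq_table`: list with `freq` (populations x loci matrix of
#'   alternate-allele frequencies, `NaN` where a population has no data) and
#'   `n` (matrix of allele-copy counts), plus the locus table as `loci`.
#' @export
allele_freqs <- function(panel, groups = NULL) {
  if (is.null(groups)) groups <- unique(panel$samples$group)
  freq <- matrix(NA_real_, length(groups), n_loci(panel),
                 dimnames = list(groups, panel$loci$id))
  n <- matrix(0L, length(groups), n_loci(panel),
              dimnames = list(groups, panel$loci$id))
  for (g in groups) {
    m <- panel$calls[panel$samples$group == g, , drop = FALSE]
    typed <- colSums(!is.na(m))
    n[g, ] <- 2L * typed
    freq[g, ] <- colSums(m, na.rm = TRUE) / (2 * typed)
  }
  freq_table(freq, n, panel$loci)
}

#' @rdname allele_freqs
#' @param freq Populations x loci matrix of alternate-allele frequencies.
#' @param n Matrix of allele-copy counts matching `freq`.
#' @param loci Locus table (as in [genotype_panel()]).
#' @export
freq_table <- function(freq, n = NULL, loci = NULL) {
  freq <- as.matrix(freq)
  if (is.null(n)) n <- matrix(Inf, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  if (is.null(loci))
    loci <- data.frame(id = colnames(freq) %||% paste0("L", seq_len(ncol(freq))),
                       chrom = rep_len(1:38, ncol(freq)),
                       pos = seq_len(ncol(freq)) * 1000L,
                       ref = "A", alt = "G",
                       category = NA_character_,
                       stringsAsFactors = FALSE)
  if (is.null(colnames(freq))) colnames(freq) <- loci$id
  ok <- is.na(freq) | (freq >= 0 & freq <= 1)
  if (!all(ok)) stop("allele frequencies must lie in [0, 1]")
  structure(list(freq = freq, n = as.matrix(n), loci = loci),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", nrow(x$freq), "populations x", ncol(x$freq), "loci\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
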