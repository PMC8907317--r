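#' Read genotypes from PLINK-text or VCF
#'
#' Reads a biallelic diploid genotype matrix into a [genotype_panel()].
#' Dosages are counted against the alternate allele. PLINK-text input is a
#' `.ped`/`.map` pair where the map file carries two extra columns with the
#' reference and alternate allele of each locus (six columns in all:
#' chromosome, id, genetic distance, position, ref, alt); group labels are
#' taken from the family column of the ped file. VCF input (4.2, `GT`
#' field) takes group labels from a sidecar sample table (tab-separated,
#' columns `id` and `group`).
#'
#' @param path For `"plink"`, the basename of the `.ped`/`.map` pair (or
#'   the path of either file); for `"vcf"`, the VCF file.
#' @param format `"plink"` or `"vcf"`.
#' @param sample_table Path of the sidecar sample table (VCF only;
#'   optional, default assigns every sample the group `"unknown"`).
#' @return A `genotype_panel`.
#' @export
read_genotypes <- function(path, format = c("plink", "vcf"),
                           sample_table = NULL) {
  format <- match.arg(format)
  if (format == "plink") read_plink(path) else read_vcf(path, sample_table)
}

read_plink <- function(path) {
  base <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(base, ".ped")
  map_path <- paste0(base, ".map")
  for (f in c(ped_path, map_path))
    if (!file.exists(f)) stop("file not found: ", f)
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "ref", "alt"))
  loci <- data.frame(id = as.character(map$id), chrom = map$chrom,
                     pos = map$pos, ref = map$ref, alt = map$alt,
                     category = NA_character_, stringsAsFactors = FALSE)
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  L <- nrow(map)
  if (ncol(ped) != 6 + 2 * L)
    stop("ped file has ", ncol(ped), " columns; expected ", 6 + 2 * L)
  ids <- ped[[2]]
  if (anyDuplicated(ids))
    stop("duplicated sample id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(L) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(L), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(ped), L)
  for (l in seq_len(L)) {
    ref <- map$ref[l]; alt <- map$alt[l]
    ok <- a1[, l] != "0" & a2[, l] != "0"
    known <- c(ref, alt)
    bad <- ok & (!(a1[, l] %in% known) | !(a2[, l] %in% known))
    if (any(bad))
      stop("allele not matching ref/alt at locus ", map$id[l],
           " for sample ", ids[which(bad)[1]])
    calls[ok, l] <- (a1[ok, l] == alt) + (a2[ok, l] == alt)
  }
  samples <- data.frame(id = ids, group = ped[[1]], source = "invasive",
                        stringsAsFactors = FALSE)
  genotype_panel(calls, samples, loci)
}

read_vcf <- function(path, sample_table = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multiallelic record not supported: ",
         fix[which(multi)[1], "ID"], " at ",
         fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"])
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- sub("\\|", "/", gt)
  dosev <- ifelse(gt == "0/0", 0L,
           ifelse(gt == "0/1" | gt == "1/0", 1L,
           ifelse(gt == "1/1", 2L, NA_integer_)))
  dose <- t(dosev)
  ids <- colnames(gt)
  if (anyDuplicated(ids))
    stop("duplicated sample id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  groups <- rep("unknown", length(ids))
  if (!is.null(sample_table)) {
    st <- utils::read.table(sample_table, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    groups <- st$group[match(ids, st$id)]
    if (anyNA(groups))
      stop("sample table is missing ids: ",
           paste(ids[is.na(groups)], collapse = ", "))
  }
  loci <- data.frame(id = ifelse(fix[, "ID"] == "." | is.na(fix[, "ID"]),
                                 paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                 fix[, "ID"]),
                     chrom = as.integer(fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     category = NA_character_, stringsAsFactors = FALSE)
  samples <- data.frame(id = ids, group = groups, source = "invasive",
                        stringsAsFactors = FALSE)
  genotype_panel(dose, samples, loci)
}

#' Write genotypes to PLINK-text, VCF or Structure format
#'
#' PLINK-text writes a `.ped`/`.map` pair (map with ref/alt allele
#' columns, missing calls as `0 0`). VCF writes a minimal VCF 4.2 with a
#' `GT` field (missing as `./.`) plus a sidecar `<path>.samples.tsv` with
#' the group labels. Structure format writes two rows per individual, one
#' allele column per locus, alleles coded 1 (ref) and 2 (alt), missing as
#' -9, with a locus-id header row.
#'
#' @param panel A `genotype_panel`.
#' @param path Output basename (plink) or file path (vcf, structure).
#' @param format `"plink"`, `"vcf"` or `"structure"`.
#' @return The main file path written, invisibly.
#' @export
write_genotypes <- function(panel, path,
                            format = c("plink", "vcf", "structure")) {
  format <- match.arg(format)
  switch(format,
         plink = write_plink(panel, path),
         vcf = write_vcf(panel, path),
         structure = write_structure(panel, path))
}

write_plink <- function(panel, path) {
  base <- sub("\\.(ped|map)$", "", path)
  map <- data.frame(chrom = panel$loci$chrom, id = panel$loci$id, cm = 0,
                    pos = panel$loci$pos, ref = panel$loci$ref,
                    alt = panel$loci$alt)
  utils::write.table(map, paste0(base, ".map"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- n_samples(panel); L <- n_loci(panel)
  al <- matrix("0", n, 2 * L)
  for (l in seq_len(L)) {
    g <- panel$calls[, l]
    ref <- panel$loci$ref[l]; alt <- panel$loci$alt[l]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, alt, ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, alt, ref))
    al[, 2 * l - 1] <- a1
    al[, 2 * l] <- a2
  }
  ped <- cbind(panel$samples$group, panel$samples$id, "0", "0", "0", "-9", al)
  utils::write.table(ped, paste0(base, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(paste0(base, ".ped"))
}

write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", panel$samples$id),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (l in seq_len(n_loci(panel))) {
    g <- panel$calls[, l]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(panel$loci$chrom[l], panel$loci$pos[l],
                       panel$loci$id[l], panel$loci$ref[l],
                       panel$loci$alt[l], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  st <- data.frame(id = panel$samples$id, group = panel$samples$group)
  utils::write.table(st, paste0(path, ".samples.tsv"), quote = FALSE,
                     row.names = FALSE, sep = "\t")
  invisible(path)
}

write_structure <- function(panel, path) {
  groups <- panel$samples$group
  gnum <- as.integer(factor(groups, levels = unique(groups)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(panel$loci$id, collapse = "\t"), con)
  for (i in seq_len(n_samples(panel))) {
    g <- panel$calls[i, ]
    # allele codes: 1 = ref, 2 = alt, -9 = missing
    row1 <- ifelse(is.na(g), -9L, ifelse(g >= 1L, 2L, 1L))
    row2 <- ifelse(is.na(g), -9L, ifelse(g == 2L, 2L, 1L))
    writeLines(paste(c(panel$samples$id[i], gnum[i], row1), collapse = "\t"),
               con)
    writeLines(paste(c(panel$samples$id[i], gnum[i], row2), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read genotypes from the two-row Structure format
#'
#' Parses the format written by [write_genotypes()] with
#' `format = "structure"`: a locus-id header row, then two rows per
#' individual (id, numeric group code, one allele code per locus; 1 =
#' reference, 2 = alternate, -9 = missing).
#'
#' @param path File path.
#' @param loci Optional locus table (as in [genotype_panel()]); a minimal
#'   one is reconstructed from the header when absent.
#' @return A `genotype_panel` (groups are the numeric codes as character).
#' @export
read_structure <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (length(body) %% 2 != 0)
    stop("structure file must have two rows per individual")
  n <- length(body) %/% 2
  L <- length(ids)
  calls <- matrix(NA_integer_, n, L)
  sample_id <- character(n)
  group <- character(n)
  for (i in seq_len(n)) {
    r1 <- body[[2 * i - 1]]
    r2 <- body[[2 * i]]
    if (r1[1] != r2[1])
      stop("paired rows disagree on sample id: ", r1[1], " vs ", r2[1])
    sample_id[i] <- r1[1]
    group[i] <- r1[2]
    a1 <- as.integer(r1[-(1:2)])
    a2 <- as.integer(r2[-(1:2)])
    ok <- a1 != -9L & a2 != -9L
    calls[i, ok] <- (a1[ok] == 2L) + (a2[ok] == 2L)
  }
  loci <- data.frame(id = ids, chrom = rep_len(1:38, L),
                     pos = seq_len(L) * 1000L, ref = "A", alt = "G",
                     category = NA_character_, stringsAsFactors = FALSE)
  genotype_panel(calls, data.frame(id = sample_id, group = group,
                                   source = "invasive",
                                   stringsAsFactors = FALSE), loci)
}

#' Read and write replicate-genotyping tables
#'
#' Long-format tab-separated tables with columns `sample`, `locus`,
#' `replicate`, `call` (dosage 0/1/2, empty = failed amplification).
#'
#' @param x A `replicate_set`.
#' @param path File path.
#' @param samples,loci Optional sample/locus tables (as in
#'   [genotype_panel()]) attached to the result; reconstructed minimally
#'   from the file when absent.
#' @return `write_replicates` returns `path` invisibly; `read_replicates`
#'   returns a `replicate_set` (without truth genotypes).
#' @export
write_replicates <- function(x, path) {
  utils::write.table(replicate_long(x), path, quote = FALSE, sep = "\t",
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_replicates
#' @export
read_replicates <- function(path, samples = NULL, loci = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  sid <- unique(d$sample)
  lid <- unique(d$locus)
  reps <- sort(unique(d$replicate))
  calls <- array(NA_integer_, c(length(sid), length(lid), length(reps)),
                 dimnames = list(sid, lid, NULL))
  calls[cbind(match(d$sample, sid), match(d$locus, lid),
              match(d$replicate, reps))] <- d$call
  if (is.null(samples))
    samples <- data.frame(id = sid, group = "unknown", source = "invasive",
                          stringsAsFactors = FALSE)
  if (is.null(loci))
    loci <- data.frame(id = lid, chrom = 1L, pos = seq_along(lid),
                       ref = "A", alt = "G", category = NA_character_,
                       stringsAsFactors = FALSE)
  structure(list(calls = calls, samples = samples, loci = loci,
                 truth = NULL),
            class = "replicate_set")
}
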