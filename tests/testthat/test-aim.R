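# build a candidate-stats structure directly (bypassing simulation) so
# quota arithmetic is fully controlled
fake_stats <- function(ids, thetas, chrom = NULL, fixed = FALSE) {
  n <- length(ids)
  if (is.null(chrom)) chrom <- rep_len(1:38, n)
  data.frame(id = ids, chrom = chrom, pos = seq_len(n) * 100L,
             theta = thetas, theta_rank = pmin(pmax(thetas, 0), 1),
             fixed = rep_len(fixed, n), monomorphic = FALSE,
             freq_a = 1, freq_b = 0, stringsAsFactors = FALSE)
}

test_that("candidate pools honour the FST threshold and warn on shortage", {
  st <- list("A:B" = fake_stats(paste0("L", 1:5),
                                c(0.95, 0.89, 0.92, 0.5, 0.91)))
  expect_warning(pool <- candidate_pool(st, fst_min = 0.90, top_n = 45),
                 "only 3 of 45")
  expect_setequal(pool[["A:B"]]$id, c("L1", "L3", "L5"))
  expect_false("L2" %in% pool[["A:B"]]$id)   # 0.89 excluded at 0.90
})

test_that("round-robin chromosome spread covers every chromosome", {
  # 76 qualifying loci, 2 per chromosome over 38 chromosomes
  ids <- paste0("L", 1:76)
  st <- list("A:B" = fake_stats(ids, runif(76, 0.9, 1),
                                chrom = rep(1:38, each = 2)))
  pool <- candidate_pool(st, top_n = 45)[["A:B"]]
  expect_equal(nrow(pool), 45)
  expect_setequal(unique(pool$chrom), 1:38)   # at least one per chromosome
})

test_that("prioritisation fills quotas in order with first-category-wins dedupe", {
  set.seed(20)
  pairs <- c("J:D", "J:WDIN", "J:WIB", "J:WIT", "D:WDIN", "D:WIB", "D:WIT",
             "WDIN:WIB", "WDIN:WIT", "WIB:WIT")
  st <- list()
  for (p in pairs) {
    ids <- paste0(gsub(":", "_", p), "_", 1:60)
    st[[p]] <- fake_stats(ids, runif(60, 0.95, 1))
  }
  # wolf-wolf shared loci: top-ranked in the Dinaric pools, qualifying but
  # below the top-45 cut in the Italian-Iberian pool (whose own loci rank
  # highest there)
  common_wolf <- paste0("wolfcommon_", 1:40)
  for (p in c("WDIN:WIB", "WDIN:WIT")) {
    st[[p]]$id[1:40] <- common_wolf
    st[[p]]$theta[1:40] <- st[[p]]$theta_rank[1:40] <- 0.995
  }
  st[["WIB:WIT"]] <- fake_stats(c(paste0("WIB_WIT_", 1:60), common_wolf),
                                c(runif(60, 0.97, 1), rep(0.93, 40)))
  # dog-wolf shared loci: qualify everywhere at moderate rank so the
  # single-pair categories pick their own top loci first
  common_dog <- paste0("dogcommon_", 1:12)
  for (p in c("D:WDIN", "D:WIB", "D:WIT")) {
    st[[p]] <- fake_stats(c(paste0(gsub(":", "_", p), "_", 1:33), common_dog),
                          c(runif(33, 0.97, 1), rep(0.94, 12)))
  }
  # one locus shared between a jackal pool and the dog-WIT pool
  shared <- st[["J:WDIN"]]$id[1]
  st[["D:WIT"]]$id[1] <- shared
  pool <- candidate_pool(st, top_n = 45)
  sel <- prioritize_panel(pool)
  cnt <- attr(sel, "counts")
  expect_equal(as.vector(cnt[c("a", "b", "c", "d", "e", "f", "g", "h")]),
               c(15L, 37L, 23L, 2L, 13L, 2L, 3L, 10L))
  expect_equal(nrow(sel), 105)
  expect_false(anyDuplicated(sel$id) > 0)
  # the shared locus appears once at most, under the earlier category
  expect_lte(sum(sel$id == shared), 1)
})

test_that("unreachable quotas fill what exists and warn", {
  pairs <- c("J:D", "J:WDIN", "J:WIB", "J:WIT", "D:WDIN", "D:WIB", "D:WIT",
             "WDIN:WIB", "WDIN:WIT", "WIB:WIT")
  st <- list()
  for (p in pairs)
    st[[p]] <- fake_stats(paste0(gsub(":", "_", p), "_", 1:50),
                          runif(50, 0.9, 1))
  # no common loci at all: categories (b) and (h) are empty
  pool <- candidate_pool(st, top_n = 45)
  ws <- capture_warnings(sel <- prioritize_panel(pool))
  expect_match(ws, "category b", all = FALSE)
  expect_match(ws, "category h", all = FALSE)
  expect_equal(nrow(sel), 105 - 37 - 10)
})

test_that("final panel composition unions with dedupe and forced phenotypics", {
  sel <- data.frame(id = paste0("s", 1:105), category = "a",
                    pair = "J:D", theta = 0.95, stringsAsFactors = FALSE)
  class(sel) <- c("panel_selection", "data.frame")
  loci <- data.frame(id = c(paste0("s", 1:105), paste0("ph", 1:3),
                            paste0("pr", 1:84)),
                     chrom = 1L, pos = 1L, ref = "A", alt = "G")
  final <- compose_final_panel(sel, paste0("ph", 1:3), paste0("pr", 1:84),
                               all_loci = loci)
  expect_equal(nrow(final), 192)
  # one overlapping prior locus drops the total by one
  final2 <- compose_final_panel(sel, paste0("ph", 1:3),
                                c("s1", paste0("pr", 1:83)), all_loci = loci)
  expect_equal(nrow(final2), 191)
  expect_equal(attr(final2, "overlap"), "s1")
  # empty prior panel
  final3 <- compose_final_panel(sel, paste0("ph", 1:3), character(0), loci)
  expect_equal(nrow(final3), 108)
  expect_error(compose_final_panel(sel, "missing_locus", character(0), loci),
               "absent")
})

test_that("planted fixed differences dominate their categories on synthetic data", {
  cfg <- sim_config(n_loci = 192L, missing_rate = 0)
  sim <- simulate_panel(cfg, 55)
  stats <- pairwise_locus_stats(sim$panel)
  fixed_for <- attr(sim$freqs, "fixed_for")
  # loci forced for the Italian-vs-dog contrast should top that pool
  pool <- suppressWarnings(candidate_pool(stats, fst_min = 0.9, top_n = 45))
  key <- intersect(c("D:WIT", "WIT:D"), names(pool))[1]
  planted <- sim$panel$loci$id[!is.na(fixed_for) & fixed_for == "WIT>D"]
  expect_gt(mean(planted %in% pool[[key]]$id), 0.6)
  # every selected locus passes the threshold for at least one pair
  sel <- suppressWarnings(prioritize_panel(pool))
  any_high <- Reduce(`|`, lapply(stats, function(df) df$theta_rank >= 0.9))
  high_ids <- stats[[1]]$id[any_high]
  expect_true(all(sel$id %in% high_ids))
})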