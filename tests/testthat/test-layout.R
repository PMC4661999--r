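toy_maps <- function(len = 100000, id = "m1") {
  setNames(list(restriction_map(id, "E", rep(10000, len / 10000),
                                "optical")), id)
}

test_that("empty candidate sets give an empty placement set", {
  maps <- toy_maps()
  ps <- tiling_two_tier(list(), list(), c(a = 50000), maps, align_params())
  expect_equal(nrow(ps$placements), 0)
  expect_equal(ps$coverage_fraction, 0)
  expect_equal(ps$unplaced_primary, character(0))
})

test_that("greedy acceptance keeps the cheaper of two clashing candidates", {
  maps <- toy_maps()
  als <- list(fake_alignment("cheap", "m1", 10000, 60000, cost = 5),
              fake_alignment("dear", "m1", 15000, 65000, cost = 9))
  cl <- c(cheap = 50000, dear = 50000)
  ps <- tiling_two_tier(als, list(), cl, maps, align_params())
  expect_equal(ps$placements$contig_id, "cheap")
  expect_true("dear" %in% ps$unplaced_primary)
})

test_that("contigs below the length threshold are excluded from tier 1", {
  maps <- toy_maps()
  als <- list(fake_alignment("short", "m1", 10000, 49999, cost = 0,
                             query_bp = 39999))
  ps <- tiling_two_tier(als, list(), c(short = 39999), maps, align_params())
  expect_equal(nrow(ps$placements), 0)
  expect_equal(ps$unplaced_primary, "short")
  # at 40000 the same contig is accepted
  als2 <- list(fake_alignment("ok", "m1", 10000, 50000, cost = 0,
                              query_bp = 40000))
  ps2 <- tiling_two_tier(als2, list(), c(ok = 40000), maps, align_params())
  expect_equal(ps2$placements$contig_id, "ok")
})

test_that("near-tied multi-location placements set the multi flag", {
  maps <- toy_maps(200000)
  als <- list(fake_alignment("rep", "m1", 0, 40000, cost = 2),
              fake_alignment("rep", "m1", 40000, 80000, cost = 2.1),
              fake_alignment("other", "m1", 100000, 160000, cost = 50))
  cl <- c(rep = 40000, other = 60000)
  ps <- tiling_two_tier(als, list(), cl, maps, align_params())
  rep_rows <- ps$placements[ps$placements$contig_id == "rep", ]
  expect_equal(nrow(rep_rows), 2)
  expect_true(all(rep_rows$multi_flag))
  expect_false(any(ps$placements$multi_flag[
    ps$placements$contig_id == "other"]))
})

test_that("aligned contigs missing from contig_lengths raise an error", {
  maps <- toy_maps()
  als <- list(fake_alignment("ghost", "m1", 0, 50000, cost = 1))
  expect_error(tiling_two_tier(als, list(), c(other = 1000), maps,
                               align_params()),
               "absent from contig_lengths")
})

test_that("tier 2 fills only sufficiently large uncovered gaps", {
  maps <- toy_maps(200000)
  p1 <- list(fake_alignment("big1", "m1", 0, 80000, cost = 1),
             fake_alignment("big2", "m1", 150000, 200000, cost = 1))
  s1 <- list(fake_alignment("fill", "m1", 90000, 140000, cost = 3),
             fake_alignment("spill", "m1", 60000, 120000, cost = 2))
  cl <- c(big1 = 80000, big2 = 50000, fill = 50000, spill = 60000)
  ps <- tiling_two_tier(p1, s1, cl, maps, align_params())
  sec <- ps$placements[ps$placements$tier == "secondary", ]
  # "spill" overlaps the covered region by far more than the tolerance
  expect_equal(sec$contig_id, "fill")
  expect_gt(ps$coverage_fraction, ps$coverage_fraction_tier1)
})

fake_placement_set <- function(placements, map_lengths, aux = list(),
                               unplaced = character(0)) {
  structure(list(placements = placements, alignments = list(), aux = aux,
                 unplaced_primary = unplaced, map_lengths = map_lengths),
            class = "placement_set")
}

test_that("a single full-span placement reproduces its contig", {
  set.seed(61)
  ctg <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
               collapse = "")
  asm <- Biostrings::DNAStringSet(c(c1 = ctg))
  maps <- setNames(list(restriction_map("m1", "E", c(20000, 30000),
                                        "optical")), "m1")
  pl <- data.frame(map_id = "m1", start = 0, end = 50000, contig_id = "c1",
                   tier = "primary", orientation = "forward", cost = 1,
                   p_value = 0.01, multi_flag = FALSE,
                   stringsAsFactors = FALSE)
  out <- build_consensus(fake_placement_set(pl, c(m1 = 50000)), asm,
                         NULL, maps)
  expect_equal(as.character(out$consensus[["m1"]]), ctg)
  expect_equal(out$report$per_map$bp_from_primary, 50000)
  expect_equal(out$report$per_map$gap_n_bp_remaining, 0)
})

test_that("inter-placement map gaps emit exactly that many Ns", {
  set.seed(62)
  a <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
             collapse = "")
  asm <- Biostrings::DNAStringSet(c(c1 = a, c2 = b))
  maps <- setNames(list(restriction_map("m1", "E", rep(10000, 4) + 125,
                                        "optical")), "m1")
  maplen <- map_length(maps$m1)
  pl <- data.frame(map_id = "m1", start = c(0, 20500),
                   end = c(20000, 40500), contig_id = c("c1", "c2"),
                   tier = "primary", orientation = "forward", cost = 1,
                   p_value = 0.01, multi_flag = FALSE,
                   stringsAsFactors = FALSE)
  out <- build_consensus(fake_placement_set(pl, c(m1 = maplen)), asm,
                         NULL, maps)
  s <- as.character(out$consensus[["m1"]])
  runs <- gregexpr("N+", s)[[1L]]
  expect_equal(attr(runs, "match.length")[1L], 500)
  expect_equal(out$report$per_map$gap_n_bp_remaining, 500)
  # a reverse-orientation placement contributes its reverse complement
  pl$orientation[2] <- "reverse"
  out2 <- build_consensus(fake_placement_set(pl, c(m1 = maplen)), asm,
                          NULL, maps)
  expect_equal(substr(as.character(out2$consensus[["m1"]]), 20501, 40500),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(b))))
})

test_that("ambiguous runs are replaced from covering secondary alignments", {
  set.seed(63)
  truth <- paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
                 collapse = "")
  primary <- truth
  substr(primary, 20001, 21000) <- strrep("N", 1000)
  asm_p <- Biostrings::DNAStringSet(c(p1 = primary))
  asm_s <- Biostrings::DNAStringSet(c(s1 = substr(truth, 10001, 40000)))
  maps <- setNames(list(restriction_map("m1", "E", c(30000, 30000),
                                        "optical")), "m1")
  pl <- data.frame(map_id = "m1", start = 0, end = 60000, contig_id = "p1",
                   tier = "primary", orientation = "forward", cost = 1,
                   p_value = 0.01, multi_flag = FALSE,
                   stringsAsFactors = FALSE)
  aux <- list(fake_alignment("s1", "m1", 10000, 40000, cost = 2,
                             query_bp = 30000))
  out <- build_consensus(fake_placement_set(pl, c(m1 = 60000), aux = aux),
                         asm_p, asm_s, maps)
  expect_equal(out$report$per_map$ambiguous_bp_total, 1000)
  expect_equal(out$report$per_map$ambiguous_bp_replaced, 1000)
  s <- as.character(out$consensus[["m1"]])
  expect_false(grepl("N", s))
  expect_equal(s, truth)
})

test_that("unplaced primary contigs are appended as unplaced records", {
  asm <- Biostrings::DNAStringSet(c(c1 = "ACGTACGTAC", lost = "GGGGCCCC"))
  maps <- setNames(list(restriction_map("m1", "E", 10, "optical")), "m1")
  pl <- data.frame(map_id = "m1", start = 0, end = 10, contig_id = "c1",
                   tier = "primary", orientation = "forward", cost = 1,
                   p_value = 0.01, multi_flag = FALSE,
                   stringsAsFactors = FALSE)
  out <- build_consensus(fake_placement_set(pl, c(m1 = 10),
                                            unplaced = "lost"),
                         asm, NULL, maps)
  expect_true("unplaced_lost" %in% names(out$consensus))
  expect_equal(out$report$unplaced_appended, 1)
})

test_that("completion stats report ratios and flag the degenerate case", {
  rep1 <- structure(list(per_map = data.frame(
    map_id = "m1", length = 100000, bp_from_primary = 70000,
    bp_from_secondary_new = 20000, ambiguous_bp_total = 5000,
    ambiguous_bp_replaced = 4000, gap_n_bp_remaining = 10000),
    unplaced_appended = 0L), class = "consensus_report")
  cs <- completion_stats(rep1)
  expect_equal(cs$new_sequence_bp, 20000)
  expect_equal(cs$replacement_ratio, 0.8)
  expect_equal(cs$new_sequence_frac, 0.2)

  rep2 <- rep1
  rep2$per_map$ambiguous_bp_total <- 0
  rep2$per_map$ambiguous_bp_replaced <- 0
  expect_true(is.na(completion_stats(rep2)$replacement_ratio))
})

test_that("provenance tiles the consensus and traces every non-gap base", {
  set.seed(64)
  cfg <- sim_config(chrom_lengths = 300000, seed = 8,
                    optical = list(sigma_rel = 0, p_miss = 0,
                                   false_cut_per_bp = 0, d_min = 0),
                    tiling = list(mean_contig = 70000, min_contig = 40000))
  tr <- simulate_genome(cfg)
  asm <- fragment_assembly(tr, cfg)
  maps <- simulate_optical_maps(tr, get_enzyme("HindIII"))
  p <- align_params(seed = 2, perm_reps = 29)
  als <- align_contigs(digest_all(asm$seqs, get_enzyme("HindIII")), maps, p)
  ps <- tiling_two_tier(als, list(), contig_lengths(asm$seqs), maps, p)
  out <- build_consensus(ps, asm$seqs, NULL, maps)
  prov <- out$provenance[out$provenance$map_id == "chr1", ]
  prov <- prov[order(prov$cons_start), ]
  # contiguous tiling of the consensus
  expect_equal(prov$cons_start, c(0, head(prov$cons_end, -1)))
  expect_equal(max(prov$cons_end), nchar(as.character(out$consensus[["chr1"]])))
  # each non-gap interval reproduces the claimed contig slice
  cons <- as.character(out$consensus[["chr1"]])
  for (i in which(prov$source != "gap")) {
    ctg <- as.character(asm$seqs[[prov$contig_id[i]]])
    piece <- substr(cons, prov$cons_start[i] + 1, prov$cons_end[i])
    span <- prov$cons_end[i] - prov$cons_start[i]
    if (prov$orientation[i] == "forward") {
      expect_equal(piece, substr(ctg, prov$contig_start[i] + 1,
                                 prov$contig_start[i] + span))
    }
  }
})
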