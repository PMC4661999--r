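test_that("simulated chromosomes honour the length contract exactly", {
  cfg <- sim_config(chrom_lengths = c(500000, 300000), seed = 2)
  tr <- simulate_genome(cfg)
  expect_equal(unname(Biostrings::width(tr$seqs)), c(500000, 300000))
  expect_equal(names(tr$seqs), c("chr1", "chr2"))
})

test_that("identity-1 repeat copies are identical strings", {
  cfg <- sim_config(chrom_lengths = 500000, seed = 4,
                    repeats = list(list(length = 40000, copies = 2,
                                        identity = 1.0, chrom = 1,
                                        start = 200000)))
  tr <- simulate_genome(cfg)
  ann <- tr$repeats
  s <- as.character(tr$seqs[["chr1"]])
  c1 <- substr(s, ann$start[1] + 1, ann$end[1])
  c2 <- substr(s, ann$start[2] + 1, ann$end[2])
  expect_identical(c1, c2)
  # identity < 1 diverges the second copy at roughly the stated rate
  cfg2 <- sim_config(chrom_lengths = 500000, seed = 4,
                     repeats = list(list(length = 40000, copies = 2,
                                         identity = 0.95, chrom = 1,
                                         start = 200000)))
  tr2 <- simulate_genome(cfg2)
  s2 <- as.character(tr2$seqs[["chr1"]])
  d1 <- substr(s2, 200001, 240000)
  d2 <- substr(s2, 240001, 280000)
  mism <- sum(strsplit(d1, "")[[1]] != strsplit(d2, "")[[1]])
  expect_gt(mism, 0.03 * 40000)
  expect_lt(mism, 0.07 * 40000)
})

test_that("the generator is reproducible per seed", {
  cfg <- sim_config(chrom_lengths = 200000, seed = 12)
  expect_identical(as.character(simulate_genome(cfg)$seqs),
                   as.character(simulate_genome(cfg)$seqs))
  tr <- simulate_genome(cfg)
  a1 <- fragment_assembly(tr, cfg)
  a2 <- fragment_assembly(tr, cfg)
  expect_identical(as.character(a1$seqs), as.character(a2$seqs))
  expect_identical(a1$truth_table, a2$truth_table)
  m1 <- simulate_optical_maps(tr, get_enzyme("HindIII"))
  m2 <- simulate_optical_maps(tr, get_enzyme("HindIII"))
  expect_identical(lapply(m1, `[[`, "fragments"),
                   lapply(m2, `[[`, "fragments"))
  r1 <- simulate_read_pairs(tr, a1$truth_table, cfg$reads)
  r2 <- simulate_read_pairs(tr, a1$truth_table, cfg$reads)
  expect_identical(r1, r2)
  # and the SAM byte stream is identical too
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(r1, contig_lengths(a1$seqs), f1)
  write_sam(r2, contig_lengths(a1$seqs), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("error-free tilings concatenate back to the truth", {
  cfg <- sim_config(chrom_lengths = c(300000, 200000), seed = 5,
                    tiling = list(mean_contig = 60000, min_contig = 30000))
  tr <- simulate_genome(cfg)
  asm <- fragment_assembly(tr, cfg)
  tt <- asm$truth_table
  for (ch in names(tr$seqs)) {
    rows <- tt[tt$chrom == ch & !tt$ghost, ]
    rows <- rows[order(rows$t_start), ]
    expect_equal(rows$t_start, c(0, head(rows$t_end, -1)))
    rec <- paste(vapply(rows$contig_id, function(cid)
      as.character(asm$seqs[[cid]]), character(1)), collapse = "")
    expect_identical(rec, as.character(tr$seqs[[ch]]))
  }
})

test_that("collapse and n_run errors keep exact length accounting", {
  cfg <- sim_config(chrom_lengths = 600000, seed = 6,
                    repeats = list(list(length = 40000, copies = 2,
                                        identity = 1.0, chrom = 1,
                                        start = 250000)),
                    errors = list(list(type = "collapse_repeat",
                                       repeat_id = 1),
                                  list(type = "n_run", chrom = 1,
                                       start = 100000, length = 1000)))
  tr <- simulate_genome(cfg)
  asm <- fragment_assembly(tr, cfg)
  expect_equal(sum(Biostrings::width(asm$seqs)),
               sum(Biostrings::width(tr$seqs)) - 40000)
  expect_equal(sum(Biostrings::letterFrequency(asm$seqs, "N")), 1000)
  # the ghost row maps the removed copy onto the kept one
  gh <- asm$truth_table[asm$truth_table$ghost, ]
  expect_equal(nrow(gh), 1)
  expect_equal(gh$t_end - gh$t_start, 40000)
  cfg_bad <- cfg
  cfg_bad$errors <- list(list(type = "collapse_repeat", repeat_id = 99))
  expect_error(fragment_assembly(tr, cfg_bad), "absent repeat")
})

test_that("zero-noise optical maps equal the in silico digest", {
  cfg <- sim_config(chrom_lengths = c(250000, 150000), seed = 7,
                    optical = list(sigma_rel = 0, p_miss = 0,
                                   false_cut_per_bp = 0, d_min = 0))
  tr <- simulate_genome(cfg)
  enz <- get_enzyme("HindIII")
  maps <- simulate_optical_maps(tr, enz)
  dg <- digest_all(tr$seqs, enz)
  expect_identical(lapply(maps, `[[`, "fragments"),
                   lapply(dg, `[[`, "fragments"))
  expect_true(all(vapply(maps, `[[`, character(1), "source") == "optical"))
})

test_that("p_miss = 1 collapses each map to a single fragment", {
  cfg <- sim_config(chrom_lengths = c(250000, 150000), seed = 7,
                    optical = list(sigma_rel = 0, p_miss = 1,
                                   false_cut_per_bp = 0, d_min = 0))
  tr <- simulate_genome(cfg)
  maps <- simulate_optical_maps(tr, get_enzyme("HindIII"))
  expect_equal(vapply(maps, function(m) length(m$fragments), integer(1)),
               c(chr1 = 1L, chr2 = 1L))
  expect_equal(unname(vapply(maps, map_length, numeric(1))),
               c(250000, 150000))
})

test_that("desorption merges short fragments into the following one", {
  cfg <- sim_config(chrom_lengths = 400000, seed = 8,
                    optical = list(sigma_rel = 0.02, p_miss = 0.05,
                                   false_cut_per_bp = 1e-5, d_min = 2500))
  tr <- simulate_genome(cfg)
  maps <- simulate_optical_maps(tr, get_enzyme("HindIII"))
  expect_true(all(maps$chr1$fragments >= 2500))
  # total length conserved up to sizing noise
  expect_equal(map_length(maps$chr1), 400000, tolerance = 0.02)
})

test_that("pair counts follow the coverage expectation", {
  cfg <- sim_config(chrom_lengths = 1000000, seed = 10,
                    tiling = list(mean_contig = 250000,
                                  min_contig = 100000),
                    reads = list(read_len = 100, mu = 3000, sd = 300,
                                 coverage = 30))
  tr <- simulate_genome(cfg)
  asm <- fragment_assembly(tr, cfg)
  aln <- simulate_read_pairs(tr, asm$truth_table, cfg$reads)
  n_pairs <- length(unique(aln$qname))
  expected <- 30 * 1000000 / (2 * 100)
  expect_lt(abs(n_pairs - expected), 3 * sqrt(expected))
  expect_error(simulate_read_pairs(tr, asm$truth_table,
                                   list(read_len = 900000, mu = 3000,
                                        sd = 300, coverage = 1)),
               "read length exceeds")
})

test_that("anomalous-insert fraction matches the normal tail closed form", {
  cfg <- sim_config(chrom_lengths = 1000000, seed = 11,
                    tiling = list(mean_contig = 500000,
                                  min_contig = 200000),
                    reads = list(read_len = 100, mu = 3000, sd = 300,
                                 coverage = 20))
  tr <- simulate_genome(cfg)
  asm <- fragment_assembly(tr, cfg)
  aln <- simulate_read_pairs(tr, asm$truth_table, cfg$reads)
  # use the true simulation parameters: the check isolates the pair model
  ins <- aln$isize[aln$isize > 0 & aln$mrnm == aln$rname]
  z <- (ins - 3000) / 300
  phat <- mean(abs(z) > 3)
  p0 <- 2 * pnorm(-3)
  n <- length(ins)
  expect_lt(abs(phat - p0), 3.5 * sqrt(p0 * (1 - p0) / n))
})

test_that("relocated segments land on another contig and tag the table", {
  cfg <- sim_config(chrom_lengths = c(400000, 300000), seed = 13,
                    errors = list(list(type = "relocate", chrom = 1,
                                       start = 150000, length = 50000,
                                       dest_chrom = 2)),
                    tiling = list(mean_contig = 100000,
                                  min_contig = 50000))
  tr <- simulate_genome(cfg)
  asm <- fragment_assembly(tr, cfg)
  tt <- asm$truth_table
  rl <- tt[tt$tag == "relocate", ]
  expect_equal(nrow(rl), 1)
  expect_equal(rl$chrom, "chr1")
  home <- tt[tt$chrom == "chr2" & tt$tag == "", "contig_id"]
  expect_true(rl$contig_id %in% home)
  expect_equal(sum(Biostrings::width(asm$seqs)),
               sum(Biostrings::width(tr$seqs)))
  # the relocated sequence is carried verbatim at its new offset
  seg <- substr(as.character(tr$seqs[["chr1"]]), 150001, 200000)
  carried <- substr(as.character(asm$seqs[[rl$contig_id]]),
                    rl$c_start + 1, rl$c_start + 50000)
  expect_identical(carried, seg)
})
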