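# End-to-end pipeline wrapper and the packaged synthetic study conditions.

#' Run the optical-map finishing pipeline
#'
#' Digests both assemblies, aligns every contig against every optical map
#' (with permutation significance), performs two-tier placement and builds
#' the per-map consensus.
#'
#' @param primary_asm,secondary_asm named `DNAStringSet`s (the secondary may
#'   be `NULL`).
#' @param maps named list of optical `restriction_map`s.
#' @param enzyme an `rmap_enzyme`.
#' @param params an [align_params()] object.
#' @return a list with `placements` (a `placement_set`), `consensus`,
#'   `provenance`, `report` and `completion` (see [completion_stats()]).
#' @export
run_map_finishing <- function(primary_asm, secondary_asm = NULL, maps,
                              enzyme, params = align_params()) {
  als1 <- align_contigs(digest_all(primary_asm, enzyme), maps, params)
  als2 <- if (is.null(secondary_asm)) list() else
    align_contigs(digest_all(secondary_asm, enzyme), maps, params)
  cl <- c(contig_lengths(primary_asm),
          if (is.null(secondary_asm)) NULL else
            contig_lengths(secondary_asm))
  ps <- tiling_two_tier(als1, als2, cl, maps, params,
                        primary_ids = names(primary_asm))
  cons <- build_consensus(ps, primary_asm, secondary_asm, maps)
  list(placements = ps, consensus = cons$consensus,
       provenance = cons$provenance, report = cons$report,
       completion = completion_stats(cons$report))
}

#' Synthetic finishing study at chromosome scale
#'
#' Simulates the packaged study conditions -- a 5 Mbp, 3-chromosome truth
#' genome carrying one collapsed 40 kbp tandem repeat, 600 kbp of truth
#' sequence absent from the primary assembly (three dropped segments, so
#' recoverable only from the secondary assembly), and 50 kbp of injected
#' N-runs -- then runs the full finishing pipeline against noisy optical
#' maps and measures how well it reconstructs the truth.
#'
#' @param seed integer seed driving every stage.
#' @return a list with the fitted objects (`placements`, `report`) and the
#'   headline measurements: total placement `coverage` (and
#'   `coverage_tier1`), `multi_loci_hit` (number of true repeat loci covered
#'   by multi-flagged placements of the collapsed contig, out of 2),
#'   `consensus_len_err_pct` (per-chromosome percent error of consensus
#'   length vs truth), `replaced_frac` (ambiguous bp replaced / injected),
#'   `secondary_new_bp` and `n_unplaced`.
#' @export
run_finishing_study <- function(seed = 1L) {
  seed <- as.integer(seed)
  cfg <- sim_config(
    chrom_lengths = c(2200000, 1700000, 1100000), seed = seed,
    repeats = list(list(length = 40000, copies = 2, identity = 1.0,
                        chrom = 1, start = 800000)),
    errors = list(
      list(type = "collapse_repeat", repeat_id = 1),
      list(type = "n_run", chrom = 1, start = 200000, length = 10000),
      list(type = "n_run", chrom = 1, start = 1500000, length = 10000),
      list(type = "n_run", chrom = 2, start = 400000, length = 10000),
      list(type = "n_run", chrom = 2, start = 1200000, length = 10000),
      list(type = "n_run", chrom = 3, start = 500000, length = 10000),
      list(type = "drop", chrom = 1, start = 1800000, length = 200000),
      list(type = "drop", chrom = 2, start = 700000, length = 200000),
      list(type = "drop", chrom = 3, start = 100000, length = 200000)))
  truth <- simulate_genome(cfg)
  primary <- fragment_assembly(truth, cfg)
  cfg2 <- sim_config(chrom_lengths = cfg$chrom_lengths, seed = seed,
                     tiling = list(mean_contig = 60000,
                                   min_contig = 30000))
  secondary <- fragment_assembly(truth, cfg2, prefix = "hg",
                                 seed = seed + 77L)
  enzyme <- get_enzyme("HindIII")
  maps <- simulate_optical_maps(truth, enzyme)
  params <- align_params(seed = seed + 11L)
  fit <- run_map_finishing(primary$seqs, secondary$seqs, maps, enzyme,
                           params)

  # did the collapsed-repeat contig land on both true repeat loci?
  tt <- primary$truth_table
  rep_ctg <- tt$contig_id[tt$tag == "collapse_repeat" & !tt$ghost][1L]
  pl <- fit$placements$placements
  rep_pl <- pl[pl$contig_id == rep_ctg & pl$multi_flag, , drop = FALSE]
  ann <- truth$repeats
  loci_hit <- sum(vapply(seq_len(nrow(ann)), function(i) {
    any(rep_pl$map_id == ann$chrom[i] &
          rep_pl$start < ann$end[i] & rep_pl$end > ann$start[i])
  }, logical(1)))

  pm <- fit$report$per_map
  truth_len <- setNames(as.numeric(Biostrings::width(truth$seqs)),
                        names(truth$seqs))
  len_err <- 100 * abs(pm$length - truth_len[pm$map_id]) /
    truth_len[pm$map_id]
  injected_n <- 50000
  list(truth = truth, placements = fit$placements, report = fit$report,
       completion = fit$completion,
       coverage = fit$placements$coverage_fraction,
       coverage_tier1 = fit$placements$coverage_fraction_tier1,
       multi_loci_hit = loci_hit,
       collapsed_contig = rep_ctg,
       consensus_len_err_pct = setNames(len_err, pm$map_id),
       replaced_frac = sum(pm$ambiguous_bp_replaced) / injected_n,
       injected_ambiguous_bp = injected_n,
       secondary_new_bp = sum(pm$bp_from_secondary_new),
       n_unplaced = length(fit$placements$unplaced_primary))
}

#' One collapsed-repeat detection replicate
#'
#' Simulates a 300 kbp chromosome with a two-copy 30 kbp tandem repeat,
#' derives a collapsed assembly and an error-free assembly of the same
#' truth, maps simulated read pairs against both, and calls features.
#'
#' @param seed integer seed.
#' @param coverage read-pair coverage.
#' @return a named logical/numeric vector: `detected` (a HIGH_COV or
#'   COMPRESSED_REPEAT feature intersects the collapsed interval), `fewer`
#'   (the error-free assembly accumulates fewer total features),
#'   `n_collapsed` / `n_errorfree` (total feature counts).
#' @export
frc_collapse_replicate <- function(seed, coverage = 20) {
  cfg <- sim_config(
    chrom_lengths = 300000, seed = as.integer(seed),
    repeats = list(list(length = 30000, copies = 2, identity = 1.0,
                        chrom = 1, start = 120000)),
    errors = list(list(type = "collapse_repeat", repeat_id = 1)),
    tiling = list(mean_contig = 80000, min_contig = 40000),
    reads = list(read_len = 100, mu = 3000, sd = 300,
                 coverage = coverage))
  truth <- simulate_genome(cfg)
  collapsed <- fragment_assembly(truth, cfg)
  cfg0 <- cfg; cfg0$errors <- list()
  errorfree <- fragment_assembly(truth, cfg0, seed = cfg$seed + 10L)

  eval_one <- function(asm) {
    aln <- simulate_read_pairs(truth, asm$truth_table, cfg$reads)
    st <- estimate_insert_stats(aln)
    call_features(aln, contig_lengths(asm$seqs), st)
  }
  fb <- eval_one(collapsed)
  fg <- eval_one(errorfree)
  tt <- collapsed$truth_table
  rep_row <- tt[tt$tag == "collapse_repeat" & !tt$ghost &
                  tt$c_start == 0, ][1L, ]
  rep_len <- rep_row$t_end - rep_row$t_start
  hits <- fb$features[fb$features$contig_id == rep_row$contig_id &
                        fb$features$kind %in% c("HIGH_COV",
                                                "COMPRESSED_REPEAT"), ,
                      drop = FALSE]
  detected <- any(hits$start < rep_len & hits$end > 0)
  n_bad <- sum(fb$per_contig$n_features)
  n_good <- sum(fg$per_contig$n_features)
  c(detected = detected, fewer = n_good < n_bad,
    n_collapsed = n_bad, n_errorfree = n_good)
}
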