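# merged covered intervals (matrix with columns start, end) from placement
# intervals on one map
.merge_intervals <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) me <- max(me, end[i]) else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(outs, ms), end = c(oute, me))
}

.covered_bp <- function(iv) if (nrow(iv) == 0L) 0 else sum(iv[, 2] - iv[, 1])

# complement of covered intervals within [0, len]
.uncovered_intervals <- function(iv, len) {
  if (nrow(iv) == 0L) return(cbind(start = 0, end = len))
  s <- c(0, iv[, 2]); e <- c(iv[, 1], len)
  keep <- e > s
  cbind(start = s[keep], end = e[keep])
}

# bp of [s, e) falling outside the interval set iv
.bp_outside <- function(s, e, iv) {
  inside <- 0
  for (k in seq_len(nrow(iv)))
    inside <- inside + .interval_overlap(s, e, iv[k, 1], iv[k, 2])
  (e - s) - inside
}

#' Two-tier contig placement on optical maps
#'
#' Implements the primary/secondary placement strategy: the maps are first
#' covered with primary-assembly contigs passing the length, fragment-count
#' and significance gates, accepted greedily by ascending alignment cost per
#' query fragment with bounded overlap; remaining uncovered map intervals of at least `min_gap` bp
#' are then filled with secondary-assembly contigs.  A contig may be accepted
#' at several non-overlapping locations when the extra placements cost nearly
#' as little as its best one (`rel_cost_tie` relative plus
#' `cost_tie_scale * sqrt(n_frags)` absolute slack) -- the signature of a
#' collapsed repeat, marked with `multi_flag`.
#'
#' Secondary alignments that pass the significance gate but overlap primary
#' placements are retained as auxiliary evidence (`aux`): they are the donors
#' used by [build_consensus()] to replace ambiguous sequence inside primary
#' contigs.
#'
#' @param primary_alignments,secondary_alignments lists of `map_alignment`
#'   objects carrying p-values (see [align_contigs()]).
#' @param contig_lengths named vector of contig lengths (bp) covering every
#'   aligned contig id.
#' @param maps named list of optical `restriction_map`s being tiled.
#' @param params an [align_params()] object.
#' @param overlap_tol,min_gap,rel_cost_tie override the corresponding
#'   defaults in `params`.
#' @param primary_ids ids of all primary contigs (placed or not); defaults to
#'   the ids seen among `primary_alignments`.
#' @return an object of class `placement_set`.
#' @export
tiling_two_tier <- function(primary_alignments, secondary_alignments,
                            contig_lengths, maps, params = align_params(),
                            overlap_tol = params$overlap_tol,
                            min_gap = params$min_gap,
                            rel_cost_tie = params$rel_cost_tie,
                            primary_ids = NULL) {
  map_lens <- vapply(maps, map_length, numeric(1))
  cand_df <- function(alignments, tier) {
    if (length(alignments) == 0L) return(NULL)
    ids <- vapply(alignments, `[[`, character(1), "query_id")
    missing <- setdiff(unique(ids), names(contig_lengths))
    if (length(missing) > 0L)
      stop("aligned contig(s) absent from contig_lengths: ",
           paste(missing, collapse = ", "))
    data.frame(contig_id = ids,
               map_id = vapply(alignments, `[[`, character(1), "ref_id"),
               start = vapply(alignments, `[[`, numeric(1), "ref_start_bp"),
               end = vapply(alignments, `[[`, numeric(1), "ref_end_bp"),
               orientation = vapply(alignments, `[[`, character(1),
                                    "orientation"),
               cost = vapply(alignments, `[[`, numeric(1), "cost"),
               p_value = vapply(alignments, `[[`, numeric(1), "p_value"),
               n_frags = vapply(alignments, `[[`, integer(1),
                                "n_query_frags"),
               length = unname(contig_lengths[ids]), tier = tier,
               idx = seq_along(alignments), stringsAsFactors = FALSE)
  }
  p1 <- cand_df(primary_alignments, "primary")
  p2 <- cand_df(secondary_alignments, "secondary")
  if (is.null(primary_ids))
    primary_ids <- if (is.null(p1)) character(0) else unique(p1$contig_id)

  accepted <- list()   # rows of the placement table
  acc_aln <- list()
  accept_greedy <- function(cands, alignments, tier, restrict = NULL) {
    # restrict: per-map interval set candidates must (mostly) fall into
    if (is.null(cands) || nrow(cands) == 0L) return(invisible(NULL))
    # rank candidates by cost per query fragment: absolute cost grows with
    # contig size, which would let short spurious hits pre-empt long
    # well-supported placements
    cands <- cands[order(cands$cost / cands$n_frags, cands$start), ,
                   drop = FALSE]
    best_cost <- tapply(cands$cost, cands$contig_id, min)
    for (r in seq_len(nrow(cands))) {
      row <- cands[r, ]
      if (!row$map_id %in% names(map_lens)) next
      if (!is.null(restrict)) {
        iv <- restrict[[row$map_id]]
        if (.bp_outside(row$start, row$end, iv) >
            overlap_tol * (row$end - row$start)) next
      }
      ok <- TRUE
      already <- FALSE
      for (a in accepted) {
        if (a$map_id != row$map_id) next
        ov <- .interval_overlap(row$start, row$end, a$start, a$end)
        tol <- overlap_tol * min(row$end - row$start, a$end - a$start)
        if (ov > tol) { ok <- FALSE; break }
      }
      if (!ok) next
      prior <- vapply(accepted, function(a)
        identical(a$contig_id, row$contig_id), logical(1))
      if (any(prior)) {
        tie <- best_cost[[row$contig_id]] * (1 + rel_cost_tie) +
          params$cost_tie_scale * sqrt(row$n_frags)
        if (row$cost > tie + 1e-9) next
        already <- TRUE
      }
      pl <- list(map_id = row$map_id, start = row$start, end = row$end,
                 contig_id = row$contig_id, tier = tier,
                 orientation = row$orientation, cost = row$cost,
                 p_value = row$p_value, n_frags = row$n_frags,
                 multi_flag = FALSE)
      accepted[[length(accepted) + 1L]] <<- pl
      acc_aln[[length(acc_aln) + 1L]] <<- alignments[[row$idx]]
      if (already) {
        for (i in seq_along(accepted))
          if (identical(accepted[[i]]$contig_id, row$contig_id))
            accepted[[i]]$multi_flag <<- TRUE
      }
    }
    invisible(NULL)
  }

  # tier 1: primary contigs passing length, fragment and significance gates
  if (!is.null(p1)) {
    t1 <- p1[!is.na(p1$p_value) & p1$p_value <= params$p_max &
               p1$length >= params$min_contig_len &
               p1$n_frags >= params$min_fragments, , drop = FALSE]
    accept_greedy(t1, primary_alignments, "primary")
  }
  cov1 <- lapply(names(map_lens), function(mid) {
    rows <- Filter(function(a) a$map_id == mid && a$tier == "primary",
                   accepted)
    .merge_intervals(vapply(rows, `[[`, numeric(1), "start"),
                     vapply(rows, `[[`, numeric(1), "end"))
  })
  names(cov1) <- names(map_lens)
  covered_tier1 <- vapply(cov1, .covered_bp, numeric(1))

  # tier 2: secondary contigs filling uncovered gaps of at least min_gap
  aux <- list()
  if (!is.null(p2)) {
    gaps <- lapply(names(map_lens), function(mid) {
      un <- .uncovered_intervals(cov1[[mid]], map_lens[[mid]])
      un[un[, 2] - un[, 1] >= min_gap, , drop = FALSE]
    })
    names(gaps) <- names(map_lens)
    t2 <- p2[!is.na(p2$p_value) & p2$p_value <= params$p_max &
               p2$n_frags >= params$min_fragments, , drop = FALSE]
    accept_greedy(t2, secondary_alignments, "secondary", restrict = gaps)
    aux <- secondary_alignments[t2$idx]
  }

  pl_df <- if (length(accepted) == 0L) {
    data.frame(map_id = character(0), start = numeric(0), end = numeric(0),
               contig_id = character(0), tier = character(0),
               orientation = character(0), cost = numeric(0),
               p_value = numeric(0), n_frags = integer(0),
               multi_flag = logical(0), stringsAsFactors = FALSE)
  } else do.call(rbind, lapply(accepted, function(a)
    as.data.frame(a, stringsAsFactors = FALSE)))

  cov_all <- lapply(names(map_lens), function(mid) {
    rows <- pl_df[pl_df$map_id == mid, , drop = FALSE]
    .covered_bp(.merge_intervals(rows$start, rows$end))
  })
  coverage <- data.frame(
    map_id = names(map_lens), map_bp = unname(map_lens),
    covered_tier1 = unname(covered_tier1),
    covered_total = unlist(cov_all),
    frac_tier1 = unname(covered_tier1 / map_lens),
    frac_total = unlist(cov_all) / unname(map_lens),
    stringsAsFactors = FALSE)

  placed_primary <- unique(pl_df$contig_id[pl_df$tier == "primary"])
  structure(list(
    placements = pl_df, alignments = acc_aln, aux = aux,
    unplaced_primary = setdiff(primary_ids, placed_primary),
    map_lengths = map_lens, coverage = coverage,
    coverage_fraction = sum(coverage$covered_total) / sum(map_lens),
    coverage_fraction_tier1 = sum(coverage$covered_tier1) / sum(map_lens),
    params = params), class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat(sprintf(
    "placement set: %d placements on %d maps, coverage %.1f%% (tier 1: %.1f%%)\n",
    nrow(x$placements), length(x$map_lengths), 100 * x$coverage_fraction,
    100 * x$coverage_fraction_tier1))
  cat(sprintf("  unplaced primary contigs: %d; auxiliary secondary hits: %d\n",
              length(x$unplaced_primary), length(x$aux)))
  invisible(x)
}

#' Write a placement table as BED-like TSV
#' @param placements a `placement_set`.
#' @param path output path.
#' @export
write_placements <- function(placements, path) {
  df <- placements$placements
  out <- data.frame(map_id = df$map_id, start = round(df$start),
                    end = round(df$end), contig_id = df$contig_id,
                    cost = df$cost,
                    strand = ifelse(df$orientation == "reverse", "-", "+"),
                    tier = df$tier, multi_flag = df$multi_flag)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# transfer a reference (map) bp position to a 0-based contig coordinate via
# the alignment's anchors; orientation handled by the caller's use of
# aligned-query coordinates
.map_to_query_bp <- function(alignment, ref_bp) {
  a <- alignment$anchors
  approx(a[, "ref_bp"], a[, "q_bp"], xout = ref_bp, rule = 2)$y
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Build per-map consensus sequences from placements
#'
#' Placements on each map are laid out in map order; overlaps between
#' consecutive placements are resolved by trimming the higher-cost placement,
#' and inter-placement gaps (as measured on the optical map, the spatial
#' ruler) are emitted as runs of N of exactly the gap length, including
#' leading/trailing uncovered map ends.  Runs of ambiguous characters inside
#' primary placements are replaced with sequence from auxiliary secondary
#' alignments covering the same map interval, with coordinates transferred by
#' linear interpolation between matched cut positions.  Primary contigs with
#' no accepted placement are appended as separate `unplaced_` records.
#'
#' @param placements a `placement_set` from [tiling_two_tier()].
#' @param primary_asm,secondary_asm named `DNAStringSet`s resolving every
#'   placed contig id.
#' @param maps named list of the optical `restriction_map`s that were tiled.
#' @return a list with elements `consensus` (a `DNAStringSet`: one record per
#'   map plus unplaced records), `provenance` (a `data.frame` tracing every
#'   consensus interval to its source), and `report` (a `consensus_report`).
#' @export
build_consensus <- function(placements, primary_asm, secondary_asm = NULL,
                            maps) {
  pl <- placements$placements
  get_seq <- function(contig_id, tier) {
    src <- if (tier == "primary") primary_asm else secondary_asm
    if (is.null(src) || !contig_id %in% names(src))
      stop("cannot resolve placed contig '", contig_id, "'")
    as.character(src[[contig_id]])
  }
  aux <- placements$aux
  aux_by_map <- split(aux, vapply(aux, `[[`, character(1), "ref_id"))

  cons <- character(0)
  prov <- list()
  rep_rows <- list()
  for (mid in names(placements$map_lengths)) {
    maplen <- placements$map_lengths[[mid]]
    rows <- pl[pl$map_id == mid, , drop = FALSE]
    rows <- rows[order(rows$start, rows$cost), , drop = FALSE]
    n <- nrow(rows)
    relcost <- rows$cost / pmax(if (is.null(rows$n_frags)) 1 else
      rows$n_frags, 1)
    head_trim <- numeric(n); tail_trim <- numeric(n)
    eff_start <- rows$start; eff_end <- rows$end
    if (n > 1L) for (i in 2L:n) {
      o <- eff_end[i - 1L] - eff_start[i]
      if (o > 0) {
        if (relcost[i] >= relcost[i - 1L]) {
          head_trim[i] <- head_trim[i] + o
          eff_start[i] <- eff_start[i] + o
        } else {
          tail_trim[i - 1L] <- tail_trim[i - 1L] + o
          eff_end[i - 1L] <- eff_end[i - 1L] - o
        }
      }
    }
    pieces <- character(0)
    map_cursor <- 0; cons_pos <- 0
    gap_n <- 0; bp_primary <- 0; bp_secondary <- 0
    amb_total <- 0; amb_replaced <- 0
    for (i in seq_len(n)) {
      s <- get_seq(rows$contig_id[i], rows$tier[i])
      L <- nchar(s)
      if (head_trim[i] + tail_trim[i] >= L)
        stop("placement of '", rows$contig_id[i],
             "' exceeds its contig length after trimming")
      if (rows$orientation[i] == "reverse") s <- .revcomp_chr(s)
      s <- substr(s, head_trim[i] + 1L, L - tail_trim[i])
      emit_len <- nchar(s)
      gap <- eff_start[i] - map_cursor
      if (gap > 0.5) {
        g <- round(gap)
        pieces <- c(pieces, strrep("N", g))
        prov[[length(prov) + 1L]] <- data.frame(
          map_id = mid, cons_start = cons_pos, cons_end = cons_pos + g,
          source = "gap", contig_id = NA_character_, contig_start = NA_real_,
          orientation = NA_character_, tier = NA_character_,
          stringsAsFactors = FALSE)
        cons_pos <- cons_pos + g
        gap_n <- gap_n + g
      }
      # ambiguity replacement from auxiliary secondary alignments
      if (rows$tier[i] == "primary" && emit_len > 0L) {
        runs <- gregexpr("[^ACGT]+", s)[[1L]]
        if (runs[1L] != -1L) {
          rlens <- attr(runs, "match.length")
          amb_total <- amb_total + sum(rlens)
          donors <- aux_by_map[[mid]]
          if (!is.null(donors) && length(donors) > 0L) {
            for (k in seq_along(runs)) {
              a <- runs[k]; b <- a + rlens[k] - 1L
              m1 <- eff_start[i] + (a - 1); m2 <- eff_start[i] + b
              for (d in donors) {
                c1 <- max(m1, d$ref_start_bp); c2 <- min(m2, d$ref_end_bp)
                if (c2 - c1 < 1) next
                sub_len <- round(c2 - c1)
                q1 <- round(.map_to_query_bp(d, c1))
                dseq <- get_seq(d$query_id, "secondary")
                qtot <- nchar(dseq)
                q1 <- max(0, min(q1, qtot - sub_len))
                patch <- if (d$orientation == "reverse") {
                  .revcomp_chr(substr(dseq, qtot - q1 - sub_len + 1L,
                                      qtot - q1))
                } else substr(dseq, q1 + 1L, q1 + sub_len)
                if (nchar(patch) != sub_len || grepl("[^ACGT]", patch)) next
                o1 <- round(c1 - m1)
                tgt_a <- a + o1; tgt_b <- min(b, tgt_a + sub_len - 1L)
                patch <- substr(patch, 1L, tgt_b - tgt_a + 1L)
                before <- substr(s, tgt_a, tgt_b)
                n_amb <- sum(strsplit(before, "")[[1L]] %in%
                               setdiff(IUPAC_CHARS, c("A", "C", "G", "T")))
                substr(s, tgt_a, tgt_b) <- patch
                amb_replaced <- amb_replaced + n_amb
              }
            }
          }
        }
      }
      pieces <- c(pieces, s)
      prov[[length(prov) + 1L]] <- data.frame(
        map_id = mid, cons_start = cons_pos, cons_end = cons_pos + emit_len,
        source = rows$tier[i], contig_id = rows$contig_id[i],
        contig_start = if (rows$orientation[i] == "reverse") tail_trim[i]
                       else head_trim[i],
        orientation = rows$orientation[i], tier = rows$tier[i],
        stringsAsFactors = FALSE)
      cons_pos <- cons_pos + emit_len
      if (rows$tier[i] == "primary") bp_primary <- bp_primary + emit_len
      else bp_secondary <- bp_secondary + emit_len
      map_cursor <- eff_end[i]
    }
    if (maplen - map_cursor > 0.5) {
      g <- round(maplen - map_cursor)
      pieces <- c(pieces, strrep("N", g))
      prov[[length(prov) + 1L]] <- data.frame(
        map_id = mid, cons_start = cons_pos, cons_end = cons_pos + g,
        source = "gap", contig_id = NA_character_, contig_start = NA_real_,
        orientation = NA_character_, tier = NA_character_,
        stringsAsFactors = FALSE)
      cons_pos <- cons_pos + g
      gap_n <- gap_n + g
    }
    cons[[mid]] <- paste(pieces, collapse = "")
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      map_id = mid, length = nchar(cons[[mid]]),
      bp_from_primary = bp_primary, bp_from_secondary_new = bp_secondary,
      ambiguous_bp_total = amb_total, ambiguous_bp_replaced = amb_replaced,
      gap_n_bp_remaining = gap_n, stringsAsFactors = FALSE)
  }
  # unplaced primary contigs appended as 'unknown' sequence records
  unplaced <- placements$unplaced_primary
  unplaced <- unplaced[unplaced %in% names(primary_asm)]
  for (uid in unplaced)
    cons[[paste0("unplaced_", uid)]] <- as.character(primary_asm[[uid]])

  per_map <- do.call(rbind, rep_rows)
  report <- structure(list(per_map = per_map,
                           unplaced_appended = length(unplaced)),
                      class = "consensus_report")
  list(consensus = Biostrings::DNAStringSet(cons),
       provenance = do.call(rbind, prov), report = report)
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("consensus report:\n")
  print(x$per_map, row.names = FALSE)
  cat(sprintf("unplaced primary contigs appended: %d\n", x$unplaced_appended))
  invisible(x)
}

#' Completion accounting from a consensus report
#'
#' Summarises how much the secondary (long-read) assembly contributed: new
#' sequence in intervals the primary assembly could not cover, and the share
#' of ambiguous primary sequence (gaps and ambiguous base calls) that could
#' be replaced.
#'
#' @param report a `consensus_report` from [build_consensus()].
#' @return a one-row `data.frame`; the replacement ratio is `NA` when there
#'   was no ambiguous sequence to replace.
#' @export
completion_stats <- function(report) {
  pm <- report$per_map
  total <- sum(pm$length)
  new_bp <- sum(pm$bp_from_secondary_new)
  amb_tot <- sum(pm$ambiguous_bp_total)
  amb_rep <- sum(pm$ambiguous_bp_replaced)
  data.frame(consensus_bp = total,
             new_sequence_bp = new_bp,
             new_sequence_frac = new_bp / total,
             ambiguous_bp_total = amb_tot,
             ambiguous_bp_replaced = amb_rep,
             replacement_ratio = if (amb_tot > 0) amb_rep / amb_tot
                                 else NA_real_,
             gap_n_bp = sum(pm$gap_n_bp_remaining))
}
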