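#' Alignment and placement parameters
#'
#' All tunable constants of the placement stage live here.  The sizing error
#' model is relative: an observed optical fragment of true size s has standard
#' deviation `sigma_rel * s`.  Each missed or extra cut inside an alignment
#' block costs `cut_penalty`.  Contigs enter tier-1 placement only when they
#' are at least `min_contig_len` bp long *and* carry at least `min_fragments`
#' restriction fragments; both gates must pass, since short contigs carry too
#' few in silico cuts to be placed reliably.
#'
#' @param sigma_rel relative sizing error of optical fragments (default 0.05).
#' @param cut_penalty cost per missed/extra cut within a block (default 3).
#' @param delta_max maximum fragments merged per block on either side
#'   (default 5).
#' @param min_fragments minimum query fragments to attempt placement
#'   (default 8).
#' @param min_contig_len minimum contig length in bp for tier-1 placement
#'   (default 40000).
#' @param perm_reps permutation replicates for empirical placement
#'   significance (default 99).
#' @param p_max maximum acceptable empirical p-value (default 0.05).
#' @param rel_cost_tie relative cost slack under which additional
#'   non-overlapping placements of the same contig are accepted (default 0.1).
#' @param cost_tie_scale absolute cost slack for near-tied placements, scaled
#'   by `sqrt(n query fragments)`; accounts for the stochastic spread of the
#'   sizing cost between genuinely equivalent placements (default 3).
#' @param overlap_tol tolerated overlap between accepted placements, as a
#'   fraction of the shorter interval (default 0.1).
#' @param min_gap minimum uncovered map interval (bp) considered for tier-2
#'   gap filling (default 10000).
#' @param seed RNG seed used by the permutation test and other stochastic
#'   steps (default `NULL`: leave the RNG state alone).
#' @return an object of class `align_params`.
#' @export
align_params <- function(sigma_rel = 0.05, cut_penalty = 3, delta_max = 5L,
                         min_fragments = 8L, min_contig_len = 40000,
                         perm_reps = 99L, p_max = 0.05, rel_cost_tie = 0.1,
                         cost_tie_scale = 3, overlap_tol = 0.1,
                         min_gap = 10000, seed = NULL) {
  stopifnot(sigma_rel > 0, delta_max >= 1, perm_reps >= 0, cut_penalty >= 0)
  structure(list(sigma_rel = sigma_rel, cut_penalty = cut_penalty,
                 delta_max = as.integer(delta_max),
                 min_fragments = as.integer(min_fragments),
                 min_contig_len = min_contig_len,
                 perm_reps = as.integer(perm_reps), p_max = p_max,
                 rel_cost_tie = rel_cost_tie, cost_tie_scale = cost_tie_scale,
                 overlap_tol = overlap_tol, min_gap = min_gap, seed = seed),
            class = "align_params")
}

# traceback one alignment ending at reference fragment `end_j` from the DP
# traceback matrices; returns a blocks data.frame (1-based inclusive fragment
# index ranges, in aligned-query order)
.traceback_blocks <- function(ta, tb, m, end_j) {
  qs <- integer(0); qe <- integer(0); rs <- integer(0); re <- integer(0)
  i <- m; j <- end_j
  while (i > 0L) {
    a <- ta[i + 1L, j + 1L]; b <- tb[i + 1L, j + 1L]
    if (a == 0L) return(NULL)   # unreachable state
    qs <- c(i - a + 1L, qs); qe <- c(i, qe)
    rs <- c(j - b + 1L, rs); re <- c(j, re)
    i <- i - a; j <- j - b
  }
  data.frame(q_start = qs, q_end = qe, r_start = rs, r_end = re)
}

# build a map_alignment object from a traceback
.make_alignment <- function(query, reference, qfrag, blocks, cost,
                            orientation) {
  refcum <- c(0, cumsum(reference$fragments))
  qcum <- c(0, cumsum(qfrag))
  K <- nrow(blocks)
  qtot <- sum(qfrag)
  maplen <- refcum[length(refcum)]
  if (K == 1L) {
    ref_start <- refcum[blocks$r_start[1L]]
    ref_end <- min(ref_start + qtot, maplen)
  } else {
    ref_start <- refcum[blocks$r_end[1L] + 1L] - qcum[blocks$q_end[1L] + 1L]
    ref_end <- refcum[blocks$r_start[K]] +
      (qcum[blocks$q_end[K] + 1L] - qcum[blocks$q_start[K]])
    ref_start <- max(0, ref_start)
    ref_end <- min(maplen, ref_end)
  }
  # anchors: matched cut positions (block boundaries) plus the interpolated
  # placement ends, as (reference bp, aligned-query bp) pairs
  anchors <- cbind(ref_bp = ref_start, q_bp = 0)
  if (K > 1L)
    anchors <- rbind(anchors,
                     cbind(ref_bp = refcum[blocks$r_end[-K] + 1L],
                           q_bp = qcum[blocks$q_end[-K] + 1L]))
  anchors <- rbind(anchors, cbind(ref_bp = ref_end, q_bp = qtot))
  structure(list(query_id = query$id, ref_id = reference$id,
                 orientation = orientation, blocks = blocks, cost = cost,
                 ref_start_bp = ref_start, ref_end_bp = ref_end,
                 anchors = anchors, query_bp = qtot,
                 n_query_frags = length(qfrag), p_value = NA_real_),
            class = "map_alignment")
}

#' @export
print.map_alignment <- function(x, ...) {
  cat(sprintf(
    "alignment %s -> %s [%s]: ref %.0f-%.0f bp, %d blocks, cost %.3f, p %s\n",
    x$query_id, x$ref_id, x$orientation, x$ref_start_bp, x$ref_end_bp,
    nrow(x$blocks), x$cost,
    if (is.na(x$p_value)) "NA" else format(x$p_value)))
  invisible(x)
}

.interval_overlap <- function(s1, e1, s2, e2) {
  max(0, min(e1, e2) - max(s1, s2))
}

#' Fitting alignment of a restriction map against a reference map
#'
#' Places the whole query (an in silico contig digest) inside a free window of
#' the reference (an optical chromosome map) by dynamic programming over
#' block decompositions; see [align_params()] for the scoring model.  The two
#' terminal query fragments are boundary fragments (contig ends are not cut
#' sites) and are matched one-sidedly.  Both orientations are evaluated (the
#' reverse orientation aligns the reversed query fragment list) and the
#' lower-cost one is reported; exact ties go to the smaller reference start,
#' then forward before reverse.
#'
#' @param query,reference `restriction_map` objects.
#' @param params an [align_params()] object.
#' @param all_hits if `TRUE`, return every near-optimal, mutually
#'   non-overlapping placement (cost within
#'   `best * (1 + rel_cost_tie) + cost_tie_scale * sqrt(n_frags)`), which is
#'   how a collapsed repeat shows up as a multi-location placement.  If
#'   `FALSE`, return only the best placement.
#' @param orientations orientations to evaluate.
#' @return a `map_alignment` (or list of them when `all_hits = TRUE`), or
#'   `NULL` when the query has fewer than 2 fragments (no placement is
#'   possible: there is no internal cut to anchor).
#' @export
align_rmap <- function(query, reference, params = align_params(),
                       all_hits = FALSE,
                       orientations = c("forward", "reverse")) {
  qf <- query$fragments
  if (length(qf) < 2L) return(NULL)
  cands <- list()
  for (ori in orientations) {
    qo <- if (ori == "reverse") rev(qf) else qf
    dp <- .rmap_fit_dp(qo, reference$fragments, params$sigma_rel,
                       params$cut_penalty, params$delta_max)
    costs <- dp$cost_by_end
    finite <- which(is.finite(costs))
    if (length(finite) == 0L) next
    for (j in finite) {
      cands[[length(cands) + 1L]] <-
        list(ori = ori, j = j, cost = costs[j], dp = dp, qo = qo)
    }
  }
  if (length(cands) == 0L) return(NULL)
  costs <- vapply(cands, `[[`, numeric(1), "cost")
  best <- min(costs)
  cap <- if (all_hits) {
    best * (1 + params$rel_cost_tie) +
      params$cost_tie_scale * sqrt(length(qf))
  } else best
  keep <- which(costs <= cap + 1e-9)
  # deterministic order: cost, then smaller reference end, forward first
  ord <- keep[order(costs[keep],
                    vapply(cands[keep], `[[`, numeric(1), "j"),
                    vapply(cands[keep], function(c) c$ori != "forward",
                           logical(1)))]
  m <- length(qf)
  hits <- list()
  for (idx in ord) {
    cd <- cands[[idx]]
    blocks <- .traceback_blocks(cd$dp$ta, cd$dp$tb, m, cd$j)
    if (is.null(blocks)) next
    al <- .make_alignment(query, reference, cd$qo, blocks, cd$cost, cd$ori)
    clash <- FALSE
    for (h in hits) {
      ov <- .interval_overlap(al$ref_start_bp, al$ref_end_bp,
                              h$ref_start_bp, h$ref_end_bp)
      span <- min(al$ref_end_bp - al$ref_start_bp,
                  h$ref_end_bp - h$ref_start_bp)
      if (span <= 0 || ov > 0.5 * span) { clash <- TRUE; break }
    }
    if (clash) next
    hits[[length(hits) + 1L]] <- al
    if (!all_hits) break
  }
  if (length(hits) == 0L) return(NULL)
  if (all_hits) hits else {
    # among equal-cost best hits prefer smaller ref_start, forward first
    bests <- hits[vapply(hits, `[[`, numeric(1), "cost") <= best + 1e-9]
    ord2 <- order(vapply(bests, `[[`, numeric(1), "ref_start_bp"),
                  vapply(bests, function(h) h$orientation != "forward",
                         logical(1)))
    bests[[ord2[1L]]]
  }
}

#' Empirical placement significance by reference permutation
#'
#' Permutes the reference fragment order `perm_reps` times, realigns the query
#' (in the observed orientation), and reports the add-one empirical p-value
#' `(1 + #(permuted cost <= observed cost)) / (perm_reps + 1)`.
#'
#' @param query,reference `restriction_map` objects.
#' @param observed the observed `map_alignment`.
#' @param params an [align_params()] object; `perm_reps` must be >= 1.
#' @return empirical p-value in `[1/(perm_reps+1), 1]`.
#' @export
alignment_significance <- function(query, reference, observed,
                                   params = align_params()) {
  if (params$perm_reps < 1L) stop("perm_reps must be >= 1")
  qo <- if (observed$orientation == "reverse") rev(query$fragments) else
    query$fragments
  hits <- 0L
  for (rep in seq_len(params$perm_reps)) {
    rp <- sample(reference$fragments)
    dp <- .rmap_fit_dp(qo, rp, params$sigma_rel, params$cut_penalty,
                       params$delta_max)
    if (min(dp$cost_by_end) <= observed$cost + 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (params$perm_reps + 1)
}

#' Align a set of contig digests against a set of optical maps
#'
#' Pipeline convenience wrapper: aligns every query with at least
#' `min_fragments` fragments against every reference, collects near-optimal
#' multi-location hits, and attaches permutation p-values to hits passing a
#' cheap cost screen (`cost / n_fragments <= cost_per_frag_max`; hopeless
#' alignments keep `p_value = NA` and are never accepted downstream).
#'
#' @param queries named list of in silico `restriction_map`s (contig digests).
#' @param references named list of optical `restriction_map`s.
#' @param params an [align_params()] object; `params$seed`, when set, seeds
#'   the permutation RNG.
#' @param compute_p attach permutation p-values.
#' @param cost_per_frag_max screen for the permutation test.
#' @return a list of `map_alignment` objects.
#' @export
align_contigs <- function(queries, references, params = align_params(),
                          compute_p = TRUE, cost_per_frag_max = 10) {
  if (!is.null(params$seed)) set.seed(params$seed)
  out <- list()
  for (q in queries) {
    if (length(q$fragments) < params$min_fragments) next
    qhits <- list()
    refs <- list()
    for (ref in references) {
      hits <- align_rmap(q, ref, params, all_hits = TRUE)
      for (al in hits) {
        qhits[[length(qhits) + 1L]] <- al
        refs[[length(refs) + 1L]] <- ref
      }
    }
    if (length(qhits) == 0L) next
    # permutation significance only for hits inside the multi-placement cost
    # cap of this contig's best hit: nothing beyond it is ever acceptable
    costs <- vapply(qhits, `[[`, numeric(1), "cost")
    cap <- min(costs) * (1 + params$rel_cost_tie) +
      params$cost_tie_scale * sqrt(length(q$fragments))
    for (i in seq_along(qhits)) {
      al <- qhits[[i]]
      if (compute_p && params$perm_reps >= 1L && costs[i] <= cap + 1e-9 &&
          al$cost / al$n_query_frags <= cost_per_frag_max) {
        al$p_value <- alignment_significance(q, refs[[i]], al, params)
      }
      out[[length(out) + 1L]] <- al
    }
  }
  out
}

#' Summarise a list of alignments as a data frame
#'
#' @param alignments list of `map_alignment` objects.
#' @return a `data.frame` with one row per alignment.
#' @export
alignments_table <- function(alignments) {
  if (length(alignments) == 0L)
    return(data.frame(query_id = character(0), ref_id = character(0),
                      orientation = character(0), ref_start = numeric(0),
                      ref_end = numeric(0), cost = numeric(0),
                      p_value = numeric(0), n_query_frags = integer(0),
                      query_bp = numeric(0), blocks = character(0)))
  do.call(rbind, lapply(alignments, function(a) {
    b <- a$blocks
    data.frame(query_id = a$query_id, ref_id = a$ref_id,
               orientation = a$orientation, ref_start = a$ref_start_bp,
               ref_end = a$ref_end_bp, cost = a$cost, p_value = a$p_value,
               n_query_frags = a$n_query_frags, query_bp = a$query_bp,
               blocks = paste(sprintf("q%d-q%d:r%d-r%d", b$q_start - 1L,
                                      b$q_end - 1L, b$r_start - 1L,
                                      b$r_end - 1L), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

#' Write an alignment table as TSV
#' @param alignments list of `map_alignment` objects.
#' @param path output path.
#' @export
write_alignments <- function(alignments, path) {
  write.table(alignments_table(alignments), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect redundant optical maps
#'
#' In a haploid reconstruction, smaller chromosome maps that merely duplicate
#' content of larger ones (e.g. recombinant variants) should be set aside.  A
#' map M is flagged redundant when either (a) the fraction of M's placed
#' length whose contigs also hold accepted placements on larger maps reaches
#' `min_shared`, or (b) a fitting alignment of M's own fragment list against a
#' larger map spans at least `min_shared` of M with permutation p-value at
#' most `params$p_max`.  Maps are ranked by total length (descending) before
#' the "larger" relation is applied.
#'
#' @param maps named list of optical `restriction_map`s.
#' @param placements a `placement_set` from [tiling_two_tier()], or `NULL` to
#'   use criterion (b) only.
#' @param min_shared shared fraction threshold (default 0.8).
#' @param params an [align_params()] object.
#' @return a `data.frame` with columns `map_id`, `redundant`,
#'   `shared_fraction`, `via`, `evidence` (semicolon-joined supporting contig
#'   or map ids).
#' @export
map_to_map_redundancy <- function(maps, placements = NULL, min_shared = 0.8,
                                  params = align_params()) {
  lens <- vapply(maps, map_length, numeric(1))
  ord <- order(lens, decreasing = TRUE)
  maps <- maps[ord]; lens <- lens[ord]
  pl <- if (!is.null(placements)) placements$placements else NULL
  res <- data.frame(map_id = names(maps), redundant = FALSE,
                    shared_fraction = 0, via = "", evidence = "",
                    stringsAsFactors = FALSE)
  for (k in seq_along(maps)) {
    if (k == 1L) next
    mid <- names(maps)[k]
    earlier <- names(maps)[seq_len(k - 1L)]
    # (a) placement sharing with larger maps
    if (!is.null(pl) && any(pl$map_id == mid)) {
      mine <- pl[pl$map_id == mid, , drop = FALSE]
      earlier_contigs <- unique(pl$contig_id[pl$map_id %in% earlier])
      shared <- mine$contig_id %in% earlier_contigs
      frac <- sum((mine$end - mine$start)[shared]) /
        sum(mine$end - mine$start)
      res$shared_fraction[k] <- frac
      if (is.finite(frac) && frac >= min_shared) {
        res$redundant[k] <- TRUE
        res$via[k] <- "placements"
        res$evidence[k] <- paste(unique(mine$contig_id[shared]),
                                 collapse = ";")
        next
      }
    }
    # (b) whole-map fitting alignment against each larger map; the covered
    # fraction counts only blocks whose sizing agrees within 3 sigma, since
    # a fitting alignment always spans the query end to end
    if (params$perm_reps >= 1L) for (big in earlier) {
      al <- align_rmap(maps[[mid]], maps[[big]], params)
      if (is.null(al)) next
      qo <- if (al$orientation == "reverse") rev(maps[[mid]]$fragments) else
        maps[[mid]]$fragments
      rf <- maps[[big]]$fragments
      b <- al$blocks
      good_bp <- 0
      for (i in seq_len(nrow(b))) {
        sq <- sum(qo[b$q_start[i]:b$q_end[i]])
        sr <- sum(rf[b$r_start[i]:b$r_end[i]])
        terminal <- i == 1L || i == nrow(b)
        fits <- abs(sq - sr) <= 3 * params$sigma_rel * sr ||
          (terminal && sq <= sr * (1 + 3 * params$sigma_rel))
        if (fits) good_bp <- good_bp + sq
      }
      covered <- good_bp / sum(qo)
      if (covered < min_shared) next
      p <- alignment_significance(maps[[mid]], maps[[big]], al, params)
      if (p > params$p_max) next
      res$redundant[k] <- TRUE
      res$shared_fraction[k] <- max(res$shared_fraction[k], min(1, covered))
      res$via[k] <- "map_alignment"
      res$evidence[k] <- big
      break
    }
  }
  res
}
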