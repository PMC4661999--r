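# Synthetic-data generator: truth genomes with near-identical repeats,
# derived assemblies carrying controlled mis-assemblies (collapsed repeats,
# relocations, N-runs, dropped segments), optical maps with sizing noise and
# missed/false cuts, and read-pair alignments mapped through a truth table.

#' Simulation configuration
#'
#' @param chrom_lengths chromosome lengths in bp.
#' @param gc GC content of the random background sequence.
#' @param repeats list of repeat specs, each a list with `length` (bp),
#'   `copies`, `identity` (fraction, 1 = identical copies), `chrom`
#'   (index), and optionally `start` (0-based position of the first copy;
#'   random when `NULL`).  Copies are laid out in tandem.
#' @param errors list of mis-assembly specs applied to the derived assembly:
#'   `list(type = "collapse_repeat", repeat_id =)`,
#'   `list(type = "relocate", chrom =, start =, length =, dest_chrom =)`,
#'   `list(type = "n_run", chrom =, start =, length =)`,
#'   `list(type = "drop", chrom =, start =, length =)`.
#' @param snp_rate substitution rate applied to assembly contigs.
#' @param tiling contig tiling of the derived assembly: `mean_contig` and
#'   `min_contig` (bp).
#' @param optical optical-map noise model: `sigma_rel` (relative sizing
#'   error), `p_miss` (per-cut miss probability), `false_cut_per_bp`
#'   (Poisson rate of spurious cuts), `d_min` (desorption limit: fragments
#'   below it merge into their neighbour).
#' @param reads read-pair model: `read_len`, insert `mu` and `sd` (bp),
#'   `coverage`.
#' @param seed RNG seed; every simulator stage is reproducible per seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(2200000, 1700000, 1100000),
                       gc = 0.40, repeats = list(), errors = list(),
                       snp_rate = 0,
                       tiling = list(mean_contig = 250000,
                                     min_contig = 50000),
                       optical = list(sigma_rel = 0.03, p_miss = 0.05,
                                      false_cut_per_bp = 5e-7,
                                      d_min = 2000),
                       reads = list(read_len = 100, mu = 3000, sd = 300,
                                    coverage = 30),
                       seed = 1L) {
  stopifnot(all(chrom_lengths >= 1), gc > 0, gc < 1,
            optical$p_miss >= 0, optical$p_miss <= 1,
            optical$sigma_rel >= 0, snp_rate >= 0, snp_rate <= 1)
  if (length(repeats) > 0L) {
    maxrep <- max(vapply(repeats, `[[`, numeric(1), "length"))
    if (any(chrom_lengths < 10 * maxrep))
      stop("chromosome lengths must be at least 10x the longest repeat")
    for (r in repeats)
      if (r$chrom > length(chrom_lengths)) stop("repeat on absent chromosome")
  }
  structure(list(chrom_lengths = chrom_lengths, gc = gc, repeats = repeats,
                 errors = errors, snp_rate = snp_rate, tiling = tiling,
                 optical = optical, reads = reads, seed = as.integer(seed)),
            class = "sim_config")
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.mutate_string <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "")[[1L]]
  hit <- which(runif(length(ch)) < rate & ch %in% c("A", "C", "G", "T"))
  for (i in hit)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Simulate a truth genome
#'
#' Generates random chromosomes at the configured GC content and plants
#' tandem repeat arrays whose copies share the configured identity.
#'
#' @param config a [sim_config()].
#' @return a list with `seqs` (named `DNAStringSet`, chromosomes `chr1`,
#'   `chr2`, ...), `repeats` (annotation data.frame with 0-based half-open
#'   copy coordinates) and the echoed `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  n <- length(config$chrom_lengths)
  seqs <- vapply(config$chrom_lengths, .random_dna, character(1),
                 gc = config$gc)
  names(seqs) <- paste0("chr", seq_len(n))
  ann <- list()
  for (k in seq_along(config$repeats)) {
    r <- config$repeats[[k]]
    if (r$length > config$chrom_lengths[r$chrom])
      stop("repeat longer than its chromosome")
    total <- r$length * r$copies
    L <- config$chrom_lengths[r$chrom]
    start <- if (!is.null(r$start)) r$start else
      floor(runif(1, 0.25 * L, 0.75 * L - total))
    if (start < 0 || start + total > L)
      stop("repeat array does not fit its chromosome")
    unit <- .random_dna(r$length, config$gc)
    for (cp in seq_len(r$copies)) {
      s <- start + (cp - 1L) * r$length
      copy <- if (cp == 1L) unit else .mutate_string(unit, 1 - r$identity)
      substr(seqs[r$chrom], s + 1L, s + r$length) <- copy
      ann[[length(ann) + 1L]] <- data.frame(
        repeat_id = k, chrom = names(seqs)[r$chrom], copy = cp,
        start = s, end = s + r$length, stringsAsFactors = FALSE)
    }
  }
  list(seqs = Biostrings::DNAStringSet(seqs),
       repeats = if (length(ann) > 0L) do.call(rbind, ann) else
         data.frame(repeat_id = integer(0), chrom = character(0),
                    copy = integer(0), start = numeric(0), end = numeric(0)),
       config = config)
}

# subdivide a free zone [s, e) into tiles of roughly mean_contig bp
.zone_tiles <- function(s, e, mean_contig, min_contig) {
  len <- e - s
  if (len <= 0) return(NULL)
  k <- max(1L, round(len / mean_contig))
  while (k > 1L && len / k < min_contig) k <- k - 1L
  cuts <- s + round(seq_len(k - 1L) / k * len +
                      runif(k - 1L, -0.15, 0.15) * len / k)
  cuts <- sort(pmin(pmax(cuts, s + min_contig), e - min_contig))
  bounds <- unique(c(s, cuts, e))
  cbind(start = bounds[-length(bounds)], end = bounds[-1L])
}

#' Derive a (possibly mis-assembled) assembly from a truth genome
#'
#' Contigs tile the truth chromosomes at random breakpoints around the
#' configured mean contig size.  Configured errors are injected and every
#' truth-to-contig mapping is recorded in a truth table:
#' `collapse_repeat` replaces a two-copy repeat region by a single-copy
#' contig (the removed copy keeps a ghost mapping onto the kept copy, which
#' is what makes reads pile up there); `relocate` moves a segment onto the
#' end of a contig of another chromosome; `n_run` overwrites a segment with
#' N; `drop` removes a segment from the assembly entirely.
#'
#' @param truth result of [simulate_genome()].
#' @param config a [sim_config()]; `config$errors` and `config$tiling` drive
#'   this stage.
#' @param prefix contig id prefix.
#' @param seed RNG seed for the tiling (defaults to `config$seed + 1`).
#' @return a list with `seqs` (contig `DNAStringSet`) and `truth_table`
#'   (data.frame: chrom, t_start, t_end, contig_id, c_start, orientation,
#'   tag, ghost; coordinates 0-based half-open).
#' @export
fragment_assembly <- function(truth, config, prefix = "ctg",
                              seed = config$seed + 1L) {
  set.seed(seed)
  chroms <- names(truth$seqs)
  errors <- config$errors
  # resolve special zones per chromosome
  specials <- lapply(chroms, function(x) NULL)
  names(specials) <- chroms
  add_special <- function(chrom, start, end, type, extra = NULL) {
    specials[[chrom]] <<- rbind(specials[[chrom]],
                                data.frame(start = start, end = end,
                                           type = type,
                                           dest = if (is.null(extra)) NA
                                                  else extra,
                                           stringsAsFactors = FALSE))
  }
  n_runs <- list()
  for (e in errors) {
    if (e$type == "collapse_repeat") {
      ra <- truth$repeats[truth$repeats$repeat_id == e$repeat_id, ,
                          drop = FALSE]
      if (nrow(ra) < 2L) stop("collapse_repeat refers to an absent repeat")
      add_special(ra$chrom[1L], min(ra$start), max(ra$end), "collapse",
                  extra = as.character(e$repeat_id))
    } else if (e$type == "relocate") {
      add_special(paste0("chr", e$chrom), e$start, e$start + e$length,
                  "relocate", extra = paste0("chr", e$dest_chrom))
    } else if (e$type == "drop") {
      add_special(paste0("chr", e$chrom), e$start, e$start + e$length,
                  "drop")
    } else if (e$type == "n_run") {
      n_runs[[length(n_runs) + 1L]] <-
        data.frame(chrom = paste0("chr", e$chrom), start = e$start,
                   end = e$start + e$length, stringsAsFactors = FALSE)
    } else stop("unknown error type '", e$type, "'")
  }

  rows <- list()
  reloc_rows <- list()
  ctg_i <- 0L
  first_ctg <- setNames(rep(NA_character_, length(chroms)), chroms)
  for (chrom in chroms) {
    L <- length(truth$seqs[[chrom]])
    sp <- specials[[chrom]]
    if (!is.null(sp)) {
      sp <- sp[order(sp$start), , drop = FALSE]
      if (any(sp$start[-1L] < sp$end[-nrow(sp)]))
        stop("overlapping error intervals on ", chrom)
    }
    bounds <- c(0, if (!is.null(sp)) c(sp$start, sp$end), L)
    bounds <- sort(unique(bounds))
    for (z in seq_len(length(bounds) - 1L)) {
      zs <- bounds[z]; ze <- bounds[z + 1L]
      typ <- "free"
      dest <- NA
      if (!is.null(sp)) {
        hit <- which(sp$start == zs & sp$end == ze)
        if (length(hit) == 1L) { typ <- sp$type[hit]; dest <- sp$dest[hit] }
      }
      if (typ == "drop") {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, t_start = zs, t_end = ze,
          contig_id = NA_character_, c_start = NA_real_, orientation = "+",
          tag = "drop", ghost = FALSE, stringsAsFactors = FALSE)
      } else if (typ == "collapse") {
        ra <- truth$repeats[truth$repeats$repeat_id == as.integer(dest), ,
                            drop = FALSE]
        ctg_i <- ctg_i + 1L
        cid <- sprintf("%s_%03d", prefix, ctg_i)
        if (is.na(first_ctg[[chrom]])) first_ctg[[chrom]] <- cid
        kept_end <- ra$end[1L]       # keep the first copy only
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, t_start = zs, t_end = kept_end, contig_id = cid,
          c_start = 0, orientation = "+", tag = "collapse_repeat",
          ghost = FALSE, stringsAsFactors = FALSE)
        # removed copies map back onto the kept copy (ghost rows)
        for (cp in 2:nrow(ra)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, t_start = ra$start[cp], t_end = ra$end[cp],
            contig_id = cid, c_start = ra$start[1L] - zs,
            orientation = "+", tag = "collapse_repeat", ghost = TRUE,
            stringsAsFactors = FALSE)
        }
        if (ze > max(ra$end)) {   # trailing non-repeat part of the zone
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, t_start = max(ra$end), t_end = ze,
            contig_id = cid, c_start = kept_end - zs, orientation = "+",
            tag = "collapse_repeat", ghost = FALSE, stringsAsFactors = FALSE)
        }
      } else if (typ == "relocate") {
        reloc_rows[[length(reloc_rows) + 1L]] <-
          list(chrom = chrom, t_start = zs, t_end = ze, dest = dest)
      } else {
        tiles <- .zone_tiles(zs, ze, config$tiling$mean_contig,
                             config$tiling$min_contig)
        for (t in seq_len(nrow(tiles))) {
          ctg_i <- ctg_i + 1L
          cid <- sprintf("%s_%03d", prefix, ctg_i)
          if (is.na(first_ctg[[chrom]])) first_ctg[[chrom]] <- cid
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, t_start = tiles[t, 1L], t_end = tiles[t, 2L],
            contig_id = cid, c_start = 0, orientation = "+", tag = "",
            ghost = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  tt <- do.call(rbind, rows)

  # attach relocated segments to the end of the first contig of dest_chrom
  for (rl in reloc_rows) {
    if (is.na(first_ctg[[rl$dest]]))
      stop("relocation destination ", rl$dest, " has no contig")
    tt <- rbind(tt, data.frame(
      chrom = rl$chrom, t_start = rl$t_start, t_end = rl$t_end,
      contig_id = first_ctg[[rl$dest]], c_start = NA_real_,
      orientation = "+", tag = "relocate", ghost = FALSE,
      stringsAsFactors = FALSE))
  }

  # split n_run intervals out of the contig segments they overlap (an
  # n_run may straddle a tiling breakpoint)
  for (nr in n_runs) {
    hits <- which(tt$chrom == nr$chrom & tt$t_start < nr$end &
                    tt$t_end > nr$start & !tt$ghost &
                    !is.na(tt$contig_id) & tt$tag %in% c("", "collapse_repeat"))
    if (length(hits) == 0L)
      stop("n_run interval does not overlap any contig segment")
    parts <- list()
    for (h in hits) {
      row <- tt[h, ]
      a <- max(row$t_start, nr$start); b <- min(row$t_end, nr$end)
      if (a > row$t_start)
        parts[[length(parts) + 1L]] <- transform(row, t_end = a)
      parts[[length(parts) + 1L]] <- transform(row, t_start = a, t_end = b,
                                               tag = "n_run")
      if (b < row$t_end)
        parts[[length(parts) + 1L]] <- transform(row, t_start = b)
    }
    tt <- rbind(tt[-hits, ], do.call(rbind, parts))
  }
  tt <- tt[order(tt$chrom, tt$t_start, tt$ghost), , drop = FALSE]
  rownames(tt) <- NULL

  # assign contig offsets in emission order and materialise sequences
  ctg_ids <- unique(tt$contig_id[!is.na(tt$contig_id)])
  seqs <- character(0)
  for (cid in ctg_ids) {
    idx <- which(tt$contig_id == cid & !tt$ghost)
    # emission order: truth order within the home chromosome, relocated
    # segments last
    idx <- idx[order(tt$tag[idx] == "relocate", tt$t_start[idx])]
    off <- 0
    pieces <- character(0)
    for (i in idx) {
      len <- tt$t_end[i] - tt$t_start[i]
      tt$c_start[i] <- off
      pieces <- c(pieces, if (tt$tag[i] == "n_run") strrep("N", len) else
        substr(as.character(truth$seqs[[tt$chrom[i]]]),
               tt$t_start[i] + 1L, tt$t_end[i]))
      off <- off + len
    }
    seqs[[cid]] <- paste(pieces, collapse = "")
  }
  if (config$snp_rate > 0)
    seqs <- vapply(seqs, .mutate_string, character(1),
                   rate = config$snp_rate)
  list(seqs = Biostrings::DNAStringSet(seqs), truth_table = tt)
}

#' Simulate optical maps from a truth genome
#'
#' Starts from the in silico digest of each chromosome and applies the
#' optical measurement model: truncated-normal relative sizing noise on each
#' fragment, missed interior cuts (merging neighbours), spurious cuts as a
#' Poisson process along the molecule, and a desorption limit below which
#' fragments merge into the following fragment (the last merges backward).
#'
#' @param truth result of [simulate_genome()].
#' @param enzyme an `rmap_enzyme`.
#' @param optical the optical noise model (see [sim_config()]).
#' @param seed RNG seed (defaults to `config$seed + 2`).
#' @return a named list of optical `restriction_map`s, one per chromosome.
#' @export
simulate_optical_maps <- function(truth, enzyme,
                                  optical = truth$config$optical,
                                  seed = truth$config$seed + 2L) {
  set.seed(seed)
  maps <- list()
  for (chrom in names(truth$seqs)) {
    f <- digest(truth$seqs[[chrom]], enzyme, id = chrom)$fragments
    n <- length(f)
    if (optical$sigma_rel > 0) {
      eps <- rnorm(n, 0, optical$sigma_rel)
      eps <- pmax(pmin(eps, 3 * optical$sigma_rel), -3 * optical$sigma_rel)
      f <- f * (1 + eps)
    }
    total <- sum(f)
    cuts <- cumsum(f)[-n]
    if (n > 1L && optical$p_miss > 0)
      cuts <- cuts[runif(n - 1L) >= optical$p_miss]
    if (optical$false_cut_per_bp > 0) {
      nf <- rpois(1L, optical$false_cut_per_bp * total)
      if (nf > 0L) cuts <- sort(c(cuts, runif(nf, 0, total)))
    }
    f <- diff(c(0, sort(cuts), total))
    if (optical$d_min > 0 && length(f) > 1L) {
      repeat {
        small <- which(f < optical$d_min)
        if (length(small) == 0L || length(f) == 1L) break
        i <- small[1L]
        if (i < length(f)) {            # merge into the following fragment
          f[i + 1L] <- f[i + 1L] + f[i]
        } else f[i - 1L] <- f[i - 1L] + f[i]   # last merges backward
        f <- f[-i]
      }
    }
    f <- round_half_up(f)
    f[f < 1] <- 1
    maps[[chrom]] <- restriction_map(chrom, enzyme$name, f,
                                     source = "optical")
  }
  maps
}

#' Simulate read-pair alignments against a derived assembly
#'
#' Pairs are sampled uniformly on the truth genome with normal insert sizes;
#' each mate's truth interval is transferred to contig coordinates through
#' the truth table.  Pairs straddling collapse or relocation boundaries
#' naturally become anomalous (mate on another contig, wrong distance or
#' orientation); mates landing in N-runs or dropped segments are unmapped.
#'
#' @param truth result of [simulate_genome()].
#' @param truth_table the truth table from [fragment_assembly()].
#' @param reads the read model (see [sim_config()]).
#' @param seed RNG seed (defaults to `config$seed + 3`).
#' @return a coordinate-sorted `pair_alignments` data.frame.
#' @export
simulate_read_pairs <- function(truth, truth_table,
                                reads = truth$config$reads,
                                seed = truth$config$seed + 3L) {
  set.seed(seed)
  tt <- truth_table
  real <- !tt$ghost & !is.na(tt$contig_id)
  ctg_len <- tapply((tt$t_end - tt$t_start)[real], tt$contig_id[real], sum)
  if (reads$read_len > min(ctg_len))
    stop("read length exceeds the shortest contig")
  rl <- reads$read_len
  chrlen <- setNames(Biostrings::width(truth$seqs), names(truth$seqs))
  total <- sum(chrlen)
  n_pairs <- rpois(1L, reads$coverage * total / (2 * rl))
  chrom <- sample(names(chrlen), n_pairs, replace = TRUE,
                  prob = chrlen / total)
  ins <- pmax(round(rnorm(n_pairs, reads$mu, reads$sd)), 2L * rl)
  smax <- chrlen[chrom] - ins
  ok <- smax >= 0
  chrom <- chrom[ok]; ins <- ins[ok]; smax <- smax[ok]
  s <- floor(runif(length(ins), 0, smax + 1))

  # per-chromosome mapping tables sorted by truth start
  maps <- lapply(split(seq_len(nrow(tt)), tt$chrom), function(i)
    tt[i, ][order(tt$t_start[i]), , drop = FALSE])

  transfer <- function(chrom, start0, width) {
    ctg <- character(length(start0)); cpos <- integer(length(start0))
    wid <- integer(length(start0)); flip <- logical(length(start0))
    for (ch in unique(chrom)) {
      mt <- maps[[ch]]   # rows partition the chromosome (ghosts included)
      sel <- which(chrom == ch)
      ri <- findInterval(start0[sel], mt$t_start)
      ctg_r <- mt$contig_id[ri]
      tag_r <- mt$tag[ri]
      unmapped <- is.na(ctg_r) | tag_r %in% c("n_run", "drop")
      wds <- pmin(width, mt$t_end[ri] - start0[sel])
      fwd <- mt$orientation[ri] != "-"
      cp <- ifelse(fwd, mt$c_start[ri] + (start0[sel] - mt$t_start[ri]),
                   mt$c_start[ri] + (mt$t_end[ri] - (start0[sel] + wds)))
      ctg[sel] <- ifelse(unmapped, NA_character_, ctg_r)
      cpos[sel] <- ifelse(unmapped, NA_integer_, as.integer(cp))
      wid[sel] <- as.integer(wds)
      flip[sel] <- !fwd
    }
    list(ctg = ctg, pos0 = cpos, width = wid, flip = flip)
  }

  m1 <- transfer(chrom, s, rl)
  m2 <- transfer(chrom, s + ins - rl, rl)
  str1 <- ifelse(m1$flip, "-", "+")
  str2 <- ifelse(m2$flip, "+", "-")
  keep <- !is.na(m1$ctg) | !is.na(m2$ctg)
  qname <- sprintf("pair_%07d", seq_along(chrom))

  mk <- function(ma, sa, mb, sb, first) {
    mapped <- !is.na(ma$ctg)
    same <- mapped & !is.na(mb$ctg) & ma$ctg == mb$ctg
    posa <- ma$pos0 + 1L
    posb <- mb$pos0 + 1L
    isize <- ifelse(same,
                    ifelse(posa <= posb,
                           (posb + mb$width - posa),
                           -(posa + ma$width - posb)), 0L)
    flag <- 1L +
      ifelse(same & ((sa == "+" & sb == "-" & posa <= posb) |
                       (sa == "-" & sb == "+" & posb <= posa)), 2L, 0L) +
      ifelse(is.na(mb$ctg), 8L, 0L) +
      ifelse(sa == "-", 16L, 0L) +
      ifelse(!is.na(mb$ctg) & sb == "-", 32L, 0L) +
      ifelse(first, 64L, 128L)
    data.frame(qname = qname, flag = flag, rname = ma$ctg, pos = posa,
               width = ma$width, strand = sa,
               mrnm = mb$ctg, mpos = posb,
               isize = isize, mate_mapped = !is.na(mb$ctg),
               mate_strand = sb, stringsAsFactors = FALSE)[mapped & keep, ,
                                                           drop = FALSE]
  }
  out <- rbind(mk(m1, str1, m2, str2, TRUE), mk(m2, str2, m1, str1, FALSE))
  out <- out[order(out$rname, out$pos, out$qname), , drop = FALSE]
  rownames(out) <- NULL
  .as_pair_alignments(out)
}

#' Contig lengths of an assembly
#' @param seqs a `DNAStringSet`.
#' @return named numeric vector of lengths.
#' @export
contig_lengths <- function(seqs) {
  setNames(as.numeric(Biostrings::width(seqs)), names(seqs))
}
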