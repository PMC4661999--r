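# Read-pair alignment handling and feature-response-curve evaluation.
#
# Alignments are carried as a plain data.frame (class "pair_alignments") with
# one row per mapped read: qname, flag, rname, pos (1-based), width, strand,
# mrnm, mpos, isize, mate_mapped, mate_strand.  They can come from the
# simulator or from a coordinate-sorted SAM/BAM file.

.cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1L]]
    toks <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", toks))
    op <- sub("^[0-9]+", "", toks)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

.as_pair_alignments <- function(df) {
  df$rname <- as.character(df$rname)
  df$mrnm <- as.character(df$mrnm)
  if (is.null(df$strand)) df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L,
                                              "-", "+")
  if (is.null(df$mate_strand))
    df$mate_strand <- ifelse(bitwAnd(df$flag, 32L) > 0L, "-", "+")
  if (is.null(df$mate_mapped))
    df$mate_mapped <- bitwAnd(df$flag, 8L) == 0L & !is.na(df$mrnm)
  class(df) <- c("pair_alignments", "data.frame")
  df
}

#' Read pair alignments from a coordinate-sorted SAM/BAM file
#'
#' Name-sorted input is rejected: feature calling scans contigs in coordinate
#' order.  SAM input is converted through `Rsamtools::asBam()`.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return a `pair_alignments` data.frame, one row per mapped read.
#' @export
read_alignments <- function(path) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  if (is_sam) {
    hd <- readLines(path, n = 50L)
    so <- grep("^@HD", hd, value = TRUE)
    if (length(so) > 0L && grepl("SO:queryname", so[1L]))
      stop("name-sorted input; a coordinate-sorted SAM/BAM is required")
    bam <- Rsamtools::asBam(path, destination = tempfile(),
                            indexDestination = FALSE, overwrite = TRUE)
  } else {
    bam <- path
    hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$text
    hd <- hdr[names(hdr) == "@HD"]
    if (length(hd) > 0L && any(grepl("SO:queryname", unlist(hd))))
      stop("name-sorted input; a coordinate-sorted SAM/BAM is required")
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "mrnm", "mpos", "isize"))
  x <- Rsamtools::scanBam(bam, param = p)[[1L]]
  keep <- !is.na(x$pos)
  df <- data.frame(qname = x$qname[keep], flag = x$flag[keep],
                   rname = as.character(x$rname[keep]), pos = x$pos[keep],
                   width = .cigar_ref_width(x$cigar[keep]),
                   mrnm = as.character(x$mrnm[keep]), mpos = x$mpos[keep],
                   isize = x$isize[keep], stringsAsFactors = FALSE)
  df <- df[order(df$rname, df$pos), , drop = FALSE]
  .as_pair_alignments(df)
}

#' Write pair alignments as a coordinate-sorted SAM file
#'
#' @param aln a `pair_alignments` data.frame.
#' @param contig_lengths named vector of reference contig lengths.
#' @param path output path (`.sam`).
#' @export
write_sam <- function(aln, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  aln <- aln[order(match(aln$rname, names(contig_lengths)), aln$pos), ,
             drop = FALSE]
  rnext <- ifelse(!aln$mate_mapped, "*",
                  ifelse(aln$mrnm == aln$rname, "=", aln$mrnm))
  pnext <- ifelse(aln$mate_mapped, aln$mpos, 0L)
  writeLines(paste(aln$qname, aln$flag, aln$rname, aln$pos, 60L,
                   sprintf("%dM", aln$width), rnext, pnext, aln$isize,
                   "*", "*", sep = "\t"), con)
  invisible(path)
}

#' Robust insert-size statistics
#'
#' Estimates the insert-size mean and standard deviation from properly
#' oriented (forward-reverse, same-contig) pairs.  Estimation is a two-stage
#' robust procedure: a median / 1.4826*MAD screen first discards inserts more
#' than `trim_z` robust standard deviations from the median, then the mean
#' and (truncation-corrected) standard deviation are computed on the retained
#' inserts.  The screen gives outlier resistance; the second stage restores
#' full efficiency for the final estimates.
#'
#' @param aln a `pair_alignments` data.frame.
#' @param min_pairs minimum number of qualifying pairs (default 1000).
#' @param trim_z robust-z cutoff of the screening stage (default 3.5).
#' @return an object of class `insert_stats` with fields `mu`, `sd`,
#'   `n_pairs`.
#' @export
estimate_insert_stats <- function(aln, min_pairs = 1000L, trim_z = 3.5) {
  a <- .classify_reads(aln, stats = NULL, z_bound = Inf)
  ins <- a$isize[a$fr_pair & a$isize > 0]
  if (length(ins) == 0L) stop("no properly oriented same-contig pairs")
  if (length(ins) < min_pairs)
    stop("only ", length(ins), " qualifying pairs; need >= ", min_pairs)
  med <- median(ins)
  madv <- mad(ins)
  keep <- if (madv > 0) ins[abs(ins - med) <= trim_z * madv] else ins
  # correct the sd for truncation at +/- trim_z sigma of a normal
  cfac <- 1 - 2 * trim_z * stats::dnorm(trim_z) / (2 * pnorm(trim_z) - 1)
  structure(list(mu = mean(keep), sd = sd(keep) / sqrt(cfac),
                 n_pairs = length(ins)),
            class = "insert_stats")
}

#' @export
print.insert_stats <- function(x, ...) {
  cat(sprintf("insert size: mu %.1f bp, sd %.1f bp (%d pairs)\n",
              x$mu, x$sd, x$n_pairs))
  invisible(x)
}

# per-read anomaly classification; stats may be NULL when only orientation
# classes are needed
.classify_reads <- function(aln, stats, z_bound) {
  a <- .as_pair_alignments(as.data.frame(aln))
  a$singleton <- !a$mate_mapped
  a$same_contig <- a$mate_mapped & !is.na(a$mrnm) & a$mrnm == a$rname
  a$diff_contig <- a$mate_mapped & !is.na(a$mrnm) & a$mrnm != a$rname
  fr <- a$same_contig &
    ((a$strand == "+" & a$mate_strand == "-" & a$pos <= a$mpos) |
       (a$strand == "-" & a$mate_strand == "+" & a$mpos <= a$pos))
  a$fr_pair <- fr
  a$wrong_orient <- a$same_contig & !fr
  if (!is.null(stats)) {
    z <- (abs(a$isize) - stats$mu) / stats$sd
    a$wrong_dist <- a$fr_pair & abs(z) > z_bound
  } else a$wrong_dist <- rep(FALSE, nrow(a))
  a$anomalous <- a$singleton | a$diff_contig | a$wrong_orient | a$wrong_dist
  a
}

#' Feature-calling parameters
#'
#' @param window sliding window size in bp (default 1000).
#' @param step window step in bp (default 200).
#' @param low_mult,high_mult low/high coverage thresholds as multiples of the
#'   global median per-base coverage (defaults 0.5 and 2).
#' @param theta minimum anomalous-read proportion for a window to be flagged
#'   (default 0.4).
#' @param z_bound insert-size z-score bound beyond which a pair has the wrong
#'   distance (default 3).
#' @param min_support minimum supporting reads per emitted feature
#'   (default 5).
#' @param min_len minimum feature length in bp (default: the window size).
#' @param edge_exclude margin at contig ends (bp) exempt from low-coverage
#'   calls: within about one insert length of a sequence terminus only one
#'   mate of a pair can start, so the uniform-coverage expectation does not
#'   hold there (default 5000).
#' @return a list of class `frc_params`.
#' @export
frc_params <- function(window = 1000L, step = 200L, low_mult = 0.5,
                       high_mult = 2, theta = 0.4, z_bound = 3,
                       min_support = 5L, min_len = NULL,
                       edge_exclude = 5000L) {
  structure(list(window = as.integer(window), step = as.integer(step),
                 low_mult = low_mult, high_mult = high_mult, theta = theta,
                 z_bound = z_bound, min_support = as.integer(min_support),
                 min_len = if (is.null(min_len)) as.integer(window)
                           else as.integer(min_len),
                 edge_exclude = as.integer(edge_exclude)),
            class = "frc_params")
}

# count, for each window [s, s+w) (0-based starts), the elements of the
# sorted 0-based position vector P falling inside
.win_counts <- function(P, starts, w) {
  findInterval(starts + w - 0.5, P) - findInterval(starts - 0.5, P)
}

# weighted median of Rle-style (values, lengths)
.weighted_median <- function(values, lengths) {
  o <- order(values)
  values <- values[o]; lengths <- lengths[o]
  cum <- cumsum(as.numeric(lengths))
  values[which(cum >= cum[length(cum)] / 2)[1L]]
}

#' Call mis-assembly features from read-pair alignments
#'
#' Scans each contig with sliding windows and flags: `LOW_COV` / `HIGH_COV`
#' where the window mean per-base coverage falls below `low_mult` (or above
#' `high_mult`) times the global median per-base coverage; `WRONG_DIST` /
#' `WRONG_ORIENT` where the proportion of same-contig pairs with an
#' anomalous insert (|z| > `z_bound`) or a non-FR orientation reaches
#' `theta`; `SINGLETON` where the proportion of reads whose mate is unmapped
#' reaches `theta`; and `COMPRESSED_REPEAT` as a `HIGH_COV` region in which
#' the proportion of reads whose mate maps to a different contig or is
#' otherwise anomalous reaches `theta`.  Adjacent flagged windows are merged;
#' features shorter than `min_len` or with fewer than `min_support`
#' supporting reads are dropped.
#'
#' @param aln a `pair_alignments` data.frame (or SAM/BAM path).
#' @param contig_lengths named vector of contig lengths; every aligned contig
#'   must be present.
#' @param stats an [estimate_insert_stats()] result.
#' @param params an [frc_params()] object.
#' @return a list with `features` (data.frame: contig_id, start, end --
#'   0-based half-open -- kind, support) and `per_contig` (data.frame of
#'   per-contig tallies and mean coverage).
#' @export
call_features <- function(aln, contig_lengths, stats,
                          params = frc_params()) {
  if (is.character(aln)) aln <- read_alignments(aln)
  a <- .classify_reads(aln, stats, params$z_bound)
  stray <- setdiff(unique(a$rname), names(contig_lengths))
  if (length(stray) > 0L)
    stop("contig(s) in alignments absent from assembly: ",
         paste(stray, collapse = ", "))
  w <- params$window; stp <- params$step

  by_ctg <- split(seq_len(nrow(a)), a$rname)
  # global median per-base coverage over all contigs
  vals <- numeric(0); lens <- numeric(0); mean_cov <- numeric(0)
  cov_list <- list()
  for (ctg in names(contig_lengths)) {
    L <- contig_lengths[[ctg]]
    idx <- by_ctg[[ctg]]
    cv <- if (is.null(idx)) S4Vectors::Rle(0L, L) else
      IRanges::coverage(IRanges::IRanges(a$pos[idx],
                                         width = pmin(a$width[idx],
                                                      L - a$pos[idx] + 1L)),
                        width = L)
    cov_list[[ctg]] <- cv
    vals <- c(vals, S4Vectors::runValue(cv))
    lens <- c(lens, S4Vectors::runLength(cv))
    mean_cov[[ctg]] <- sum(as.numeric(S4Vectors::runValue(cv)) *
                             S4Vectors::runLength(cv)) / L
  }
  gmed <- .weighted_median(vals, lens)

  feats <- list()
  kinds <- c("LOW_COV", "HIGH_COV", "COMPRESSED_REPEAT", "WRONG_DIST",
             "WRONG_ORIENT", "SINGLETON")
  for (ctg in names(contig_lengths)) {
    L <- contig_lengths[[ctg]]
    if (L < w) next
    starts <- seq(0L, L - w, by = stp)
    cum <- c(0, cumsum(as.numeric(cov_list[[ctg]])))
    win_cov <- (cum[starts + w + 1L] - cum[starts + 1L]) / w
    idx <- by_ctg[[ctg]]
    sub <- if (is.null(idx)) a[0L, ] else a[idx, , drop = FALSE]
    P <- sort(sub$pos - 1L)
    n_all <- .win_counts(P, starts, w)
    cnt <- function(cond) .win_counts(sort(sub$pos[cond] - 1L), starts, w)
    n_same <- cnt(sub$same_contig)
    n_fr <- cnt(sub$fr_pair)
    n_wd <- cnt(sub$wrong_dist)
    n_wo <- cnt(sub$wrong_orient)
    n_sg <- cnt(sub$singleton)
    prop <- function(num, den) ifelse(den > 0, num / den, 0)

    interior <- starts >= params$edge_exclude &
      (starts + w) <= (L - params$edge_exclude)
    flag_sets <- list(
      LOW_COV = win_cov < params$low_mult * gmed & interior,
      HIGH_COV = win_cov > params$high_mult * gmed,
      WRONG_DIST = prop(n_wd, n_fr) >= params$theta & n_wd > 0,
      WRONG_ORIENT = prop(n_wo, n_same) >= params$theta & n_wo > 0,
      SINGLETON = prop(n_sg, n_all) >= params$theta & n_sg > 0)
    support_pos <- list(
      LOW_COV = P, HIGH_COV = P,
      WRONG_DIST = sort(sub$pos[sub$wrong_dist] - 1L),
      WRONG_ORIENT = sort(sub$pos[sub$wrong_orient] - 1L),
      SINGLETON = sort(sub$pos[sub$singleton] - 1L))
    anom_pos <- sort(sub$pos[sub$anomalous] - 1L)

    for (kind in names(flag_sets)) {
      fl <- flag_sets[[kind]]
      if (!any(fl)) next
      ir <- IRanges::reduce(IRanges::IRanges(starts[fl] + 1L, width = w))
      for (k in seq_along(ir)) {
        s0 <- IRanges::start(ir)[k] - 1L
        e0 <- IRanges::end(ir)[k]
        if (e0 - s0 < params$min_len) next
        sup <- .win_counts(support_pos[[kind]], s0, e0 - s0)
        if (sup < params$min_support) next
        feats[[length(feats) + 1L]] <- data.frame(
          contig_id = ctg, start = s0, end = e0, kind = kind,
          support = sup, stringsAsFactors = FALSE)
        if (kind == "HIGH_COV") {
          n_reg <- .win_counts(P, s0, e0 - s0)
          n_anom <- .win_counts(anom_pos, s0, e0 - s0)
          if (n_reg > 0 && n_anom / n_reg >= params$theta &&
              n_anom >= params$min_support) {
            feats[[length(feats) + 1L]] <- data.frame(
              contig_id = ctg, start = s0, end = e0,
              kind = "COMPRESSED_REPEAT", support = n_anom,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  features <- if (length(feats) == 0L) {
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), kind = character(0), support = integer(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, feats)

  per_contig <- data.frame(contig_id = names(contig_lengths),
                           length = unname(contig_lengths),
                           mean_cov = unname(mean_cov[names(contig_lengths)]),
                           stringsAsFactors = FALSE)
  for (kind in kinds)
    per_contig[[kind]] <- vapply(per_contig$contig_id, function(cid)
      sum(features$kind == kind & features$contig_id == cid), numeric(1))
  per_contig$n_features <- rowSums(per_contig[, kinds, drop = FALSE])
  list(features = features, per_contig = per_contig,
       global_median_coverage = gmed)
}

#' Feature-response curve
#'
#' Contigs are taken in order of decreasing length (ties by id; set
#' `order_by = "density"` for the alternative feature-density ordering) and
#' the feature count is accumulated against the cumulative genome fraction
#' covered.  Per-kind sub-curves are computed identically on single-kind
#' counts.
#'
#' @param per_contig the `per_contig` table from [call_features()] (columns
#'   `contig_id`, `length`, `n_features` and one column per feature kind).
#' @param G estimated genome size in bp; must be at least the longest contig.
#' @param normalize divide the cumulative feature count by the number of
#'   contigs.
#' @param order_by contig ordering of the curve.
#' @return an object of class `frc_curve` with `points` (x = cumulative
#'   features, y = cumulative length / G) and `by_kind` sub-curves.
#' @export
frc_curve <- function(per_contig, G, normalize = FALSE,
                      order_by = c("length", "density")) {
  order_by <- match.arg(order_by)
  if (G < max(per_contig$length))
    stop("estimated genome size G is smaller than the longest contig")
  pc <- per_contig
  o <- if (order_by == "length") {
    order(-pc$length, pc$contig_id)
  } else order(pc$n_features / pc$length, pc$contig_id)
  pc <- pc[o, , drop = FALSE]
  div <- if (normalize) nrow(pc) else 1
  pts <- data.frame(contig_id = pc$contig_id,
                    x = cumsum(pc$n_features) / div,
                    y = cumsum(pc$length) / G, stringsAsFactors = FALSE)
  kinds <- setdiff(colnames(pc),
                   c("contig_id", "length", "mean_cov", "n_features"))
  by_kind <- lapply(kinds, function(kind)
    data.frame(contig_id = pc$contig_id, x = cumsum(pc[[kind]]) / div,
               y = cumsum(pc$length) / G, stringsAsFactors = FALSE))
  names(by_kind) <- kinds
  structure(list(points = pts, by_kind = by_kind, G = G,
                 normalize = normalize, order_by = order_by),
            class = "frc_curve")
}

#' @export
print.frc_curve <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf(
    "feature-response curve: %d contigs, %.3g features%s, final coverage %.3f of G = %.0f bp\n",
    n, x$points$x[n], if (x$normalize) " (normalised per contig)" else "",
    x$points$y[n], x$G))
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, ..., col = "steelblue", lwd = 2,
                           xlab = "cumulative features",
                           ylab = "genome fraction covered") {
  graphics::plot(c(0, x$points$x), c(0, x$points$y), type = "s", col = col,
                 lwd = lwd, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write called features as BED
#' @param features the `features` table from [call_features()].
#' @param path output path.
#' @export
write_features_bed <- function(features, path) {
  write.table(features[, c("contig_id", "start", "end", "kind", "support")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a feature-response curve as TSV
#' @param curve an `frc_curve`.
#' @param path output path.
#' @export
write_frc_tsv <- function(curve, path) {
  tot <- cbind(kind = "TOTAL", curve$points)
  sub <- do.call(rbind, lapply(names(curve$by_kind), function(k)
    cbind(kind = k, curve$by_kind[[k]])))
  write.table(rbind(tot, sub), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
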