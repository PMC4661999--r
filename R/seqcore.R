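IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V")

#' Read a FASTA file of DNA sequences
#'
#' Reads sequences into a [Biostrings::DNAStringSet], uppercasing residues and
#' validating the alphabet.  Record ids are the first whitespace-delimited
#' token of each header and must be unique.  RNA (`U`) and any character
#' outside the IUPAC DNA alphabet are rejected with the offending position.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(ids == "")) stop("empty FASTA record id")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(x))
  if (any(nchar(seqs) == 0L))
    stop("zero-length sequence for record ", ids[nchar(seqs) == 0L][1L])
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    ch <- substr(seqs[i], bad[i], bad[i])
    extra <- if (ch == "U") " (RNA is not accepted)" else ""
    stop(sprintf("record '%s': invalid character '%s' at position %d%s",
                 ids[i], ch, bad[i], extra))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Assembly contiguity metrics
#'
#' Computes scaffold counts, total lengths (with and without a minimum-length
#' filter) and Nq statistics.  Nq is the length of the smallest scaffold in
#' the minimal set of largest scaffolds whose summed length reaches q% of the
#' total assembly length; quantile statistics are computed over *all*
#' scaffolds, while the `min_len` filter affects only the filtered count and
#' filtered total length columns.
#'
#' @param lengths integer vector of scaffold lengths in bp (all >= 1).
#' @param min_len minimum scaffold length for the filtered count/total.
#' @param quantiles percentages in (0, 100] for the Nq statistics.
#' @return an object of class `contiguity_metrics`.
#' @export
contiguity_metrics <- function(lengths, min_len = 0, quantiles = c(50, 80)) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L) stop("empty length set")
  if (any(!is.finite(lengths)) || any(lengths < 1))
    stop("all scaffold lengths must be >= 1")
  if (any(quantiles <= 0 | quantiles > 100))
    stop("quantiles must lie in (0, 100]")
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  cs <- cumsum(s)
  nq <- vapply(quantiles, function(q) s[which(cs >= q / 100 * total)[1L]],
               numeric(1))
  names(nq) <- paste0("N", quantiles)
  keep <- lengths >= min_len
  structure(list(
    n_scaffolds = length(lengths),
    n_scaffolds_over_min = sum(keep),
    nq = nq,
    n50 = unname(nq[match("N50", names(nq))]),
    n80 = unname(nq[match("N80", names(nq))]),
    max_scaffold = s[1L],
    total_length = total,
    total_length_over_min = sum(lengths[keep]),
    min_len_filter = min_len
  ), class = "contiguity_metrics")
}

#' @export
print.contiguity_metrics <- function(x, ...) {
  cat("Contiguity metrics (min length filter ", x$min_len_filter, " bp)\n",
      sep = "")
  cat(sprintf("  scaffolds: %d (%d over filter)\n",
              x$n_scaffolds, x$n_scaffolds_over_min))
  for (nm in names(x$nq)) cat(sprintf("  %s: %.0f\n", nm, x$nq[[nm]]))
  cat(sprintf("  longest: %.0f\n  total: %.0f (%.0f over filter)\n",
              x$max_scaffold, x$total_length, x$total_length_over_min))
  invisible(x)
}

#' Tabulate contiguity metrics for one or more assemblies
#'
#' Produces one row per assembly with the conventional column order:
#' name, number of scaffolds, number of scaffolds passing the length filter,
#' N50, N80, longest scaffold, assembly length, filtered assembly length.
#'
#' @param metrics a named list of `contiguity_metrics` objects.
#' @return a `data.frame`.
#' @export
metrics_table <- function(metrics) {
  if (inherits(metrics, "contiguity_metrics")) metrics <- list(assembly = metrics)
  do.call(rbind, lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(name = nm, n_scaffolds = m$n_scaffolds,
               n_scaffolds_over_min = m$n_scaffolds_over_min,
               n50 = m$n50, n80 = m$n80, max_scaffold = m$max_scaffold,
               total_length = m$total_length,
               total_length_over_min = m$total_length_over_min,
               stringsAsFactors = FALSE)
  }))
}

#' K-mer abundance histogram
#'
#' Exact k-mer counting; k-mers containing any character outside {A,C,G,T}
#' are skipped.  With `canonical = TRUE` each k-mer is identified with the
#' lexicographic minimum of itself and its reverse complement.
#'
#' @param seqs a `DNAStringSet` or character vector of sequences.
#' @param k k-mer size (>= 1).
#' @param canonical collapse a k-mer with its reverse complement.
#' @return a `data.frame` with columns `multiplicity` (occurrence count) and
#'   `n_kmers` (number of distinct k-mers with that count), sorted by
#'   multiplicity.
#' @export
kmer_histogram <- function(seqs, k, canonical = TRUE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  seqs <- as.character(seqs)
  kmers <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L)
    return(data.frame(multiplicity = integer(0), n_kmers = integer(0)))
  if (canonical) {
    u <- unique(kmers)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(u)))
    canon <- ifelse(u <= rc, u, rc)
    kmers <- canon[match(kmers, u)]
  }
  counts <- table(kmers)
  h <- table(as.integer(counts))
  data.frame(multiplicity = as.integer(names(h)), n_kmers = as.integer(h))
}
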