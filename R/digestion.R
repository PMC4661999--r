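#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (IUPAC DNA, length >= 4).
#' @param cut_offset cut position in bases from the start of the recognition
#'   sequence, in `[0, nchar(recognition)]`.
#' @return an object of class `rmap_enzyme`.
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("recognition sequence must be >= 4 bases")
  if (grepl(sprintf("[^%s]", paste(IUPAC_CHARS, collapse = "")), recognition))
    stop("recognition sequence contains non-IUPAC characters")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset out of range")
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "rmap_enzyme")
}

# Built-in enzyme table; cut offsets are measured from the 5' end of the
# recognition sequence on the scanned strand.
BUILTIN_ENZYMES <- list(
  HindIII = c("AAGCTT", 1L),
  EcoRI   = c("GAATTC", 1L),
  BamHI   = c("GGATCC", 1L),
  NcoI    = c("CCATGG", 1L),
  XbaI    = c("TCTAGA", 1L),
  SpeI    = c("ACTAGT", 1L),
  BglII   = c("AGATCT", 1L),
  NheI    = c("GCTAGC", 1L),
  KpnI    = c("GGTACC", 5L),
  SmaI    = c("CCCGGG", 3L),
  EcoRV   = c("GATATC", 3L),
  PvuII   = c("CAGCTG", 3L),
  HinfI   = c("GANTC", 1L)
)

#' Look up a built-in enzyme by name
#'
#' @param name enzyme name (case sensitive), e.g. `"HindIII"`.
#' @param extra optional named list of additional enzymes, each a
#'   `c(recognition, cut_offset)` pair, overriding or extending the built-in
#'   table.
#' @return an `rmap_enzyme`.
#' @export
get_enzyme <- function(name, extra = NULL) {
  tab <- BUILTIN_ENZYMES
  if (!is.null(extra)) tab[names(extra)] <- extra
  if (!name %in% names(tab))
    stop("unknown enzyme '", name, "'; known: ",
         paste(names(tab), collapse = ", "))
  e <- tab[[name]]
  restriction_enzyme(name, e[[1L]], as.integer(e[[2L]]))
}

#' @export
print.rmap_enzyme <- function(x, ...) {
  cat(sprintf("%s: %s, cut after base %d\n", x$name, x$recognition,
              x$cut_offset))
  invisible(x)
}

is_palindromic <- function(recognition) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(recognition)))
  identical(recognition, rc)
}

#' Find restriction cut sites in a sequence
#'
#' Returns 0-based cut positions: the cut falls immediately before the
#' returned position.  IUPAC codes in the recognition sequence expand to their
#' base sets; any ambiguity (including N) in the *sequence* matches nothing,
#' so runs of Ns in assembly gaps never create spurious cuts.  Palindromic
#' recognition sequences are scanned once; otherwise both strands are scanned
#' and each strand's cut offset applied.  Cuts at position 0 or at the
#' sequence end do not create fragment boundaries and are dropped.
#'
#' @param seq a `DNAString` or single character string.
#' @param enzyme an `rmap_enzyme`.
#' @return strictly increasing integer vector of cut positions in
#'   `[1, nchar(seq) - 1]`.
#' @export
find_cut_sites <- function(seq, enzyme) {
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  L <- length(seq)
  if (L < 1L) stop("empty sequence")
  scan1 <- function(pattern, offset) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern), seq,
                                     fixed = c(pattern = FALSE, subject = TRUE))
    st <- Biostrings::start(hits) - 1L   # 0-based recognition start
    st + offset
  }
  cuts <- scan1(enzyme$recognition, enzyme$cut_offset)
  if (!is_palindromic(enzyme$recognition)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(enzyme$recognition)))
    w <- nchar(enzyme$recognition)
    # occurrence of the reverse-complement pattern at 0-based position p means
    # the enzyme binds the minus strand; its cut sits at p + (w - cut_offset)
    cuts <- c(cuts, scan1(rc, w - enzyme$cut_offset))
  }
  cuts <- sort(unique(cuts))
  cuts[cuts >= 1L & cuts <= L - 1L]
}

#' Construct a restriction map
#'
#' The ordered-fragment-length representation shared by in silico digests and
#' optical maps.
#'
#' @param id map identifier.
#' @param enzyme_name name of the digesting enzyme.
#' @param fragments integer fragment lengths in bp (all >= 1).
#' @param source `"in_silico"` or `"optical"`.
#' @return an object of class `restriction_map`.
#' @export
restriction_map <- function(id, enzyme_name, fragments,
                            source = c("in_silico", "optical")) {
  source <- match.arg(source)
  fragments <- as.numeric(fragments)
  if (length(fragments) == 0L || any(fragments < 1))
    stop("fragments must be a non-empty vector of lengths >= 1")
  structure(list(id = id, enzyme_name = enzyme_name,
                 fragments = fragments, source = source, circular = FALSE),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat(sprintf("restriction map '%s' (%s, %s): %d fragments, %.0f bp\n",
              x$id, x$enzyme_name, x$source, length(x$fragments),
              sum(x$fragments)))
  invisible(x)
}

#' Total length of a restriction map
#' @param map a `restriction_map`.
#' @return total map length in bp.
#' @export
map_length <- function(map) sum(map$fragments)

#' In silico digestion of a sequence
#'
#' @param seq a `DNAString`/character sequence, or a single-record
#'   `DNAStringSet`.
#' @param enzyme an `rmap_enzyme`.
#' @param id map id; defaults to the record name when available.
#' @return a `restriction_map` with `source = "in_silico"` whose fragments sum
#'   to the sequence length.
#' @export
digest <- function(seq, enzyme, id = NULL) {
  if (inherits(seq, "DNAStringSet")) {
    if (length(seq) != 1L) stop("digest() expects a single sequence")
    if (is.null(id)) id <- names(seq)
    seq <- seq[[1L]]
  }
  if (is.character(seq)) seq <- Biostrings::DNAString(toupper(seq))
  if (is.null(id)) id <- "seq"
  cuts <- find_cut_sites(seq, enzyme)
  frags <- diff(c(0, cuts, length(seq)))
  restriction_map(id, enzyme$name, frags[frags > 0], source = "in_silico")
}

#' Digest every record of an assembly
#'
#' @param seqs a named `DNAStringSet`.
#' @param enzyme an `rmap_enzyme`.
#' @return a named list of `restriction_map` objects, one per record.
#' @export
digest_all <- function(seqs, enzyme) {
  maps <- lapply(seq_along(seqs),
                 function(i) digest(seqs[[i]], enzyme, id = names(seqs)[i]))
  names(maps) <- names(seqs)
  maps
}

round_half_up <- function(x) floor(x + 0.5)

#' Read optical maps from the map TSV dialect
#'
#' Dialect: one header line per map, `>` + map id, a tab, the enzyme name;
#' the following line holds tab-separated fragment sizes in kbp with three
#' decimals.  Sizes are converted to bp by round-half-up(kbp * 1000).
#'
#' @param path input path.
#' @return a named list of `restriction_map` objects with
#'   `source = "optical"`.
#' @export
read_optical_maps <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) %in% integer(0)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no map headers in ", path)
  maps <- list()
  for (h in heads) {
    hdr <- strsplit(sub("^>", "", lines[h]), "\t", fixed = TRUE)[[1L]]
    if (length(hdr) != 2L)
      stop("malformed map header at line ", h, ": expected id<TAB>enzyme")
    if (h + 1L > length(lines) || grepl("^>", lines[h + 1L]))
      stop("missing fragment line for map '", hdr[1L], "' at line ", h + 1L)
    toks <- strsplit(lines[h + 1L], "\t", fixed = TRUE)[[1L]]
    toks <- toks[toks != ""]
    if (length(toks) == 0L)
      stop("empty fragment line at line ", h + 1L)
    kbp <- suppressWarnings(as.numeric(toks))
    if (any(is.na(kbp)))
      stop("non-numeric fragment '", toks[is.na(kbp)][1L], "' at line ", h + 1L)
    bp <- round_half_up(kbp * 1000)
    if (any(bp <= 0))
      stop("non-positive fragment at line ", h + 1L)
    maps[[hdr[1L]]] <- restriction_map(hdr[1L], hdr[2L], bp, source = "optical")
  }
  maps
}

#' Write optical maps in the map TSV dialect
#'
#' Fragment sizes are written in kbp with exactly three decimals.
#'
#' @param maps a list of `restriction_map` objects.
#' @param path output path.
#' @export
write_optical_maps <- function(maps, path) {
  if (inherits(maps, "restriction_map")) maps <- list(maps)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in maps) {
    writeLines(sprintf(">%s\t%s", m$id, m$enzyme_name), con)
    writeLines(paste(sprintf("%.3f", m$fragments / 1000), collapse = "\t"), con)
  }
  invisible(path)
}
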