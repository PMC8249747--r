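## IUPAC degenerate motif search and palindrome detection, supporting
## binding-box analyses (e.g. the ATACnnGTAT palindrome at the centre of a
## DNase-I-protected promoter region) and footprint-interval bookkeeping.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

validate_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1L]], IUPAC_CODES)
  if (length(bad) > 0L)
    stop("invalid IUPAC character(s): ", paste(unique(bad), collapse = ", "))
  pattern
}

#' Search a sequence for an IUPAC degenerate motif
#'
#' Exact degenerate matching (each pattern letter matched against its
#' IUPAC base set); all overlapping matches are reported. Minus-strand
#' hits (matches of the reverse complement) are reported in plus-strand
#' coordinates. Lower-case pattern letters are accepted and upper-cased.
#'
#' @param seq A DNA sequence over `{A,C,G,T}` (character scalar or
#'   [Biostrings::DNAString]).
#' @param pattern IUPAC pattern string.
#' @param both_strands Also search the minus strand (default `TRUE`).
#' @return A `data.frame` with columns `start` (0-based), `end`, `strand`,
#'   sorted by `start`; attribute `width` holds the pattern length.
#' @export
iupac_search <- function(seq, pattern, both_strands = TRUE) {
  pattern <- validate_iupac(pattern)
  subject <- Biostrings::DNAString(toupper(as.character(seq)))
  w <- nchar(pattern)
  fwd <- Biostrings::matchPattern(pattern, subject, fixed = FALSE)
  hits <- data.frame(start = Biostrings::start(fwd) - 1L,
                     strand = rep("+", length(fwd)),
                     stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern)))
    rev <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
    rhits <- data.frame(start = Biostrings::start(rev) - 1L,
                        strand = rep("-", length(rev)),
                        stringsAsFactors = FALSE)
    # a palindromic pattern matches both strands at the same position;
    # report each position/strand pair once
    hits <- rbind(hits, rhits)
  }
  hits$end <- hits$start + w
  hits <- hits[order(hits$start, hits$strand), c("start", "end", "strand")]
  rownames(hits) <- NULL
  attr(hits, "width") <- w
  hits
}

#' Is an IUPAC pattern a reverse-complement palindrome?
#'
#' True when the pattern equals its IUPAC reverse complement (`N` maps to
#' `N`, `R` to `Y`, and so on), i.e. the motif reads the same on both
#' strands — the shape expected of a site bound by a homodimeric factor.
#'
#' @param pattern IUPAC pattern string.
#' @return Logical scalar.
#' @export
is_revcomp_palindrome <- function(pattern) {
  pattern <- validate_iupac(pattern)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  identical(pattern, rc)
}

#' A DNase-I footprint interval
#'
#' @param start,end Protected interval, 0-based half-open.
#' @param hypersensitive_sites Optional positions (bp) of DNase-I
#'   hypersensitive sites, all within `[start, end)`.
#' @return A `footprint_interval` list with `start`, `end`,
#'   `protected_len` and `hypersensitive_sites`.
#' @export
footprint_interval <- function(start, end, hypersensitive_sites = integer()) {
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("footprint start must be <= end")
  hs <- as.integer(hypersensitive_sites)
  if (any(hs < start | hs >= end))
    stop("hypersensitive sites must lie within the footprint")
  structure(list(start = start, end = end, protected_len = end - start,
                 hypersensitive_sites = hs),
            class = "footprint_interval")
}

#' Test motif hits against a footprint interval
#'
#' For each hit, whether it lies fully inside the protected interval, and
#' the offset of the hit centre from the footprint centre (0 means the
#' motif sits exactly at the middle of the protected region).
#'
#' @param fp A [footprint_interval()].
#' @param hits Output of [iupac_search()] (coordinates in the same frame
#'   as the footprint).
#' @return A `data.frame`: `start`, `end`, `strand`, `inside`,
#'   `center_offset`.
#' @export
footprint_overlap <- function(fp, hits) {
  stopifnot(inherits(fp, "footprint_interval"))
  if (nrow(hits) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), inside = logical(),
                      center_offset = numeric(), stringsAsFactors = FALSE))
  inside <- hits$start >= fp$start & hits$end <= fp$end
  center_offset <- (hits$start + hits$end) / 2 - (fp$start + fp$end) / 2
  data.frame(start = hits$start, end = hits$end, strand = hits$strand,
             inside = inside, center_offset = center_offset,
             stringsAsFactors = FALSE)
}

#' Export motif hits as BED
#'
#' @param hits Output of [iupac_search()].
#' @param genome_id Sequence name.
#' @param name Motif name for the BED name column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(hits, genome_id, name, path) {
  writeLines(c("# BED6: IUPAC motif hits",
               sprintf("%s\t%d\t%d\t%s\t0\t%s", genome_id, hits$start,
                       hits$end, name, hits$strand)), path)
  invisible(path)
}
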