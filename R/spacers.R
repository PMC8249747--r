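## Intergenic spacers between adjacent transcription units, with the
## orientation class that decides which promoters face the spacer.

#' Derive intergenic spacers between adjacent transcription units
#'
#' One spacer is emitted per adjacent unit pair separated by a gap of at
#' least 1 bp; abutting or overlapping units yield no spacer. The
#' orientation class is read off the flanking strands:
#' \describe{
#'   \item{divergent}{left unit on `-`, right unit on `+`: two back-to-back
#'     promoters face the spacer, so one binding site can control both.}
#'   \item{convergent}{left on `+`, right on `-`: no promoter faces the
#'     spacer.}
#'   \item{tandem}{both units on the same strand: one promoter faces it.}
#' }
#' On circular genomes the origin-spanning pair yields one wrapped spacer
#' whose `end` exceeds the genome length (`end - length` is the unwrapped
#' endpoint).
#'
#' @param ann A [genome_annotation()].
#' @return A `data.frame` with columns `left_unit`, `right_unit`, `start`,
#'   `end` (0-based half-open), `orientation`, `wraps`.
#' @export
compute_spacers <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  u <- ann$units[order(ann$units$start, ann$units$end), , drop = FALSE]
  n <- nrow(u)
  out <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      gap_start <- u$end[i]; gap_end <- u$start[i + 1L]
      if (gap_end - gap_start >= 1L)
        out[[length(out) + 1L]] <- spacer_row(u$unit_id[i], u$unit_id[i + 1L],
                                              gap_start, gap_end,
                                              u$strand[i], u$strand[i + 1L],
                                              wraps = FALSE)
    }
  }
  if (ann$circular && n >= 1L) {
    # wrap pair: last unit -> first unit across the origin
    gap <- ann$length - u$end[n] + u$start[1L]
    if (n >= 2L && gap >= 1L) {
      out[[length(out) + 1L]] <- spacer_row(u$unit_id[n], u$unit_id[1L],
                                            u$end[n], u$start[1L] + ann$length,
                                            u$strand[n], u$strand[1L],
                                            wraps = TRUE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(left_unit = character(), right_unit = character(),
                      start = integer(), end = integer(),
                      orientation = character(), wraps = logical(),
                      stringsAsFactors = FALSE))
  sp <- do.call(rbind, out)
  rownames(sp) <- NULL
  sp
}

spacer_row <- function(left, right, start, end, lstrand, rstrand, wraps) {
  orientation <- if (lstrand == "-" && rstrand == "+") "divergent"
  else if (lstrand == "+" && rstrand == "-") "convergent"
  else "tandem"
  data.frame(left_unit = left, right_unit = right,
             start = as.integer(start), end = as.integer(end),
             orientation = orientation, wraps = wraps,
             stringsAsFactors = FALSE)
}

#' Locate the spacer containing a genomic position
#'
#' @param spacers Output of [compute_spacers()].
#' @param pos 0-based position.
#' @param genome_len Genome length (needed to test wrapped spacers).
#' @return Integer row index into `spacers`, or `NA` if the position lies in
#'   no spacer.
#' @export
spacer_at <- function(spacers, pos, genome_len) {
  if (nrow(spacers) == 0L) return(NA_integer_)
  hit <- which((pos >= spacers$start & pos < spacers$end) |
                 (spacers$wraps & pos + genome_len >= spacers$start &
                    pos + genome_len < spacers$end))
  if (length(hit) == 0L) NA_integer_ else hit[[1L]]
}

#' Export spacers as BED6
#'
#' Wrapped spacers are split at the origin into two BED lines sharing a
#' name. Scores are 0; the strand column is `.` (spacers are unstranded).
#'
#' @param spacers Output of [compute_spacers()].
#' @param ann The [genome_annotation()] the spacers came from.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spacers_bed <- function(spacers, ann, path) {
  lines <- c("# BED6: intergenic spacers (0-based half-open)",
             sprintf('track name="%s_spacers"', ann$genome_id))
  for (i in seq_len(nrow(spacers))) {
    name <- paste0(spacers$left_unit[i], "|", spacers$right_unit[i], "|",
                   spacers$orientation[i])
    if (spacers$wraps[i]) {
      lines <- c(lines,
        bed6_line(ann$genome_id, spacers$start[i], ann$length, name),
        bed6_line(ann$genome_id, 0L, spacers$end[i] - ann$length, name))
    } else {
      lines <- c(lines,
        bed6_line(ann$genome_id, spacers$start[i], spacers$end[i], name))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

bed6_line <- function(chrom, start, end, name, score = 0, strand = ".") {
  sprintf("%s\t%d\t%d\t%s\t%s\t%s", chrom, start, end, name,
          format(score, trim = TRUE), strand)
}
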