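## Peak calling by the consecutive-elevated-probe criterion: a binding peak
## is a maximal run of probes whose log2 sample/reference ratio clears a
## threshold, kept only when the run is long enough. With ~300-bp selected
## fragments on a 105-bp tiling, a genuine binding site elevates a run of
## about six consecutive probes, which is the validity criterion this
## module implements.

#' Peak-calling configuration
#'
#' @param log2_threshold Minimum per-probe log2(sample/reference) for a
#'   probe to count as elevated (default 1.0, i.e. 2-fold).
#' @param min_run Minimum run length in probes (default 6, the
#'   consecutive-probe validity criterion at 105-bp spacing).
#' @param merge_gap Number of sub-threshold probes tolerated inside a run
#'   (default 0, no bridging).
#' @return A `peak_call_config` list.
#' @export
peak_call_config <- function(log2_threshold = 1.0, min_run = 6L,
                             merge_gap = 0L) {
  if (min_run < 1L) stop("min_run must be >= 1")
  if (!is.finite(log2_threshold)) stop("log2_threshold must be finite")
  if (merge_gap < 0L) stop("merge_gap must be >= 0")
  structure(list(log2_threshold = log2_threshold,
                 min_run = as.integer(min_run),
                 merge_gap = as.integer(merge_gap)),
            class = "peak_call_config")
}

#' Call peaks from a tiling-array signal
#'
#' Finds maximal runs of probes with `log2_ratio >= log2_threshold`,
#' allowing up to `merge_gap` consecutive sub-threshold probes inside a run
#' (run boundaries are always elevated probes); runs spanning fewer than
#' `min_run` probes are discarded. Each peak records the union of its
#' member probe coordinates, the summit (centre of the maximum-ratio
#' probe), the maximum log2 ratio, and a `level` label: `"high"` when
#' `max_log2 >= 2 * log2_threshold`, else `"minor"`.
#'
#' @param signal An [hybridize()] signal.
#' @param probes The matching [design_probes()] design.
#' @param cfg A [peak_call_config()].
#' @return A `data.frame` of peaks sorted by genomic position: `peak_id`,
#'   `start`, `end`, `summit`, `max_log2`, `n_probes`, `level`.
#' @export
call_peaks <- function(signal, probes, cfg = peak_call_config()) {
  if (nrow(signal) != nrow(probes))
    stop("signal has ", nrow(signal), " probes but design has ", nrow(probes))
  above <- which(signal$log2_ratio >= cfg$log2_threshold)
  empty <- data.frame(peak_id = character(), start = integer(),
                      end = integer(), summit = integer(),
                      max_log2 = numeric(), n_probes = integer(),
                      level = character(), stringsAsFactors = FALSE)
  if (length(above) == 0L) return(empty)
  grp <- cumsum(c(1L, diff(above) > cfg$merge_gap + 1L))
  first <- tapply(above, grp, min)
  last <- tapply(above, grp, max)
  n_probes <- as.integer(last - first + 1L)
  keep <- n_probes >= cfg$min_run
  if (!any(keep)) return(empty)
  first <- first[keep]; last <- last[keep]; n_probes <- n_probes[keep]
  rows <- lapply(seq_along(first), function(i) {
    idx <- first[i]:last[i]
    mx <- idx[which.max(signal$log2_ratio[idx])]
    data.frame(start = probes$start[first[i]], end = probes$end[last[i]],
               summit = as.integer(probes$start[mx] +
                                     (probes$end[mx] - probes$start[mx]) %/% 2L),
               max_log2 = max(signal$log2_ratio[idx]),
               n_probes = n_probes[i], stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, rows)
  peaks <- peaks[order(peaks$start), , drop = FALSE]
  peaks <- cbind(peak_id = sprintf("peak%03d", seq_len(nrow(peaks))), peaks,
                 stringsAsFactors = FALSE)
  peaks$level <- ifelse(peaks$max_log2 >= 2 * cfg$log2_threshold,
                        "high", "minor")
  rownames(peaks) <- NULL
  peaks
}

#' Rank peaks by binding level
#'
#' Sorted descending by `max_log2`; ties broken by genomic position
#' (lower coordinate first).
#'
#' @param peaks Output of [call_peaks()].
#' @return The reordered peak `data.frame`.
#' @export
rank_peaks <- function(peaks) {
  peaks <- peaks[order(-peaks$max_log2, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Write peaks as BED6 plus a TSV with call details
#'
#' The BED score column carries `max_log2`; the TSV adds `n_probes`,
#' `summit` and `level`.
#'
#' @param peaks Output of [call_peaks()].
#' @param genome_id Sequence name.
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, `NULL`.
#' @export
write_peaks <- function(peaks, genome_id, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    writeLines(c(
      "# BED6: called binding peaks; score = max log2 ratio",
      sprintf("%s\t%d\t%d\t%s\t%s\t.", genome_id, peaks$start, peaks$end,
              peaks$peak_id, formatC(peaks$max_log2, format = "g", digits = 6))),
      bed_path)
  }
  if (!is.null(tsv_path)) {
    writeLines(c(
      "# TSV: peak calls",
      "peak_id\tstart\tend\tsummit\tmax_log2\tn_probes\tlevel",
      sprintf("%s\t%d\t%d\t%d\t%s\t%d\t%s", peaks$peak_id, peaks$start,
              peaks$end, peaks$summit,
              formatC(peaks$max_log2, format = "g", digits = 6),
              peaks$n_probes, peaks$level)), tsv_path)
  }
  invisible(NULL)
}
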