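## Tiling-array model: probe design at fixed spacing and conversion of a
## selected fragment pool into per-probe two-channel ratio signals.

#' Design tiling probes at fixed spacing
#'
#' Probe `i` starts at `i * spacing` for
#' `i = 0 .. floor((genome_len - probe_len) / spacing)`; the last probe
#' lies fully inside the genome and probes never wrap the origin. The
#' defaults (60-bp probes every 105 bp) are the geometry of the tiling
#' array being emulated.
#'
#' @param genome_len Genome length, bp.
#' @param probe_len Probe length, bp (default 60).
#' @param spacing Probe start-to-start interval, bp (default 105).
#' @return A `probe_design`: `data.frame(probe_id, start, end)` with
#'   attributes `probe_len`, `spacing`, `genome_len`.
#' @export
design_probes <- function(genome_len, probe_len = 60L, spacing = 105L) {
  genome_len <- as.integer(genome_len)
  probe_len <- as.integer(probe_len); spacing <- as.integer(spacing)
  if (genome_len < probe_len)
    stop("genome_len (", genome_len, ") is shorter than one probe")
  if (probe_len > spacing || spacing > genome_len)
    stop("need probe_len <= spacing <= genome_len")
  starts <- seq.int(0L, genome_len - probe_len, by = spacing)
  probes <- data.frame(probe_id = sprintf("p%06d", seq_along(starts)),
                       start = starts, end = starts + probe_len,
                       stringsAsFactors = FALSE)
  attr(probes, "probe_len") <- probe_len
  attr(probes, "spacing") <- spacing
  attr(probes, "genome_len") <- genome_len
  class(probes) <- c("probe_design", "data.frame")
  probes
}

## Split (possibly origin-wrapping) fragments into linear segments, keeping
## the originating fragment index.
fragment_segments <- function(pool, genome_len) {
  wraps <- pool$end > genome_len
  seg_start <- c(pool$start, rep(0L, sum(wraps)))
  seg_end <- c(ifelse(wraps, genome_len, pool$end), pool$end[wraps] - genome_len)
  frag <- c(seq_len(nrow(pool)), which(wraps))
  list(start = as.integer(seg_start), end = as.integer(seg_end), frag = frag)
}

## Per-probe intensity: sum over fragments overlapping the probe of
## weight * overlap_bp / fragment_len.
probe_intensities <- function(pool, probes, genome_len) {
  seg <- fragment_segments(pool, genome_len)
  frag_len <- pool$end - pool$start
  q <- IRanges::IRanges(probes$start + 1L, probes$end)
  s <- IRanges::IRanges(seg$start + 1L, seg$end)
  hits <- IRanges::findOverlaps(q, s)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(probes$end[qh], seg$end[sh]) - pmax(probes$start[qh], seg$start[sh])
  fi <- seg$frag[sh]
  contrib <- pool$weight[fi] * ov / frag_len[fi]
  out <- numeric(nrow(probes))
  agg <- rowsum(contrib, qh)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Hybridize sample and reference pools to a probe design
#'
#' Per-probe intensity is the overlap-weighted fragment mass:
#' `sum(weight * overlap_bp / fragment_len)` over fragments overlapping the
#' probe. The reported ratio is
#' `(sample + eps) / (reference + eps)` with `eps = 1e-9`, multiplied by
#' lognormal noise `exp(N(0, noise_sd^2))`. The sample channel is the
#' post-selection pool and the reference channel the initial (cycle-0)
#' library; dye names are metadata and do not change the semantics.
#'
#' @param pool Post-selection fragment pool (sample channel).
#' @param ref_pool Cycle-0 library (reference channel).
#' @param probes A [design_probes()] design.
#' @param noise_sd SD of the multiplicative lognormal noise (0 = noiseless).
#' @param seed Integer seed for the noise draw, or `NULL`.
#' @return An `array_signal`: `data.frame(probe_id, ratio, log2_ratio)`
#'   with attribute `noise_sd`.
#' @export
hybridize <- function(pool, ref_pool, probes, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(probes, "probe_design"))
  if (nrow(pool) == 0L || nrow(ref_pool) == 0L) stop("empty fragment pool")
  L <- attr(probes, "genome_len")
  eps <- 1e-9
  s <- probe_intensities(pool, probes, L)
  r <- probe_intensities(ref_pool, probes, L)
  ratio <- (s + eps) / (r + eps)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ratio <- ratio * exp(rnorm(length(ratio), 0, noise_sd))
  }
  sig <- data.frame(probe_id = probes$probe_id, ratio = ratio,
                    log2_ratio = log2(ratio), stringsAsFactors = FALSE)
  attr(sig, "noise_sd") <- noise_sd
  class(sig) <- c("array_signal", "data.frame")
  sig
}

#' Write an array signal as bedGraph (log2 ratio) or TSV
#'
#' @param signal An [hybridize()] signal.
#' @param probes The matching probe design.
#' @param genome_id Sequence name.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_signal_bedgraph <- function(signal, probes, genome_id, path) {
  stopifnot(nrow(signal) == nrow(probes))
  writeLines(c(
    "# bedGraph: per-probe log2(sample/reference) ratio",
    sprintf('track type=bedGraph name="%s_log2_ratio"', genome_id),
    sprintf("%s\t%d\t%d\t%s", genome_id, probes$start, probes$end,
            formatC(signal$log2_ratio, format = "g", digits = 8))), path)
  invisible(path)
}

#' @rdname write_signal_bedgraph
#' @export
write_signal_tsv <- function(signal, probes, path) {
  stopifnot(nrow(signal) == nrow(probes))
  lines <- c("# TSV: probe_id, ratio, log2_ratio",
             "probe_id\tratio\tlog2_ratio",
             sprintf("%s\t%s\t%s", signal$probe_id,
                     formatC(signal$ratio, format = "g", digits = 8),
                     formatC(signal$log2_ratio, format = "g", digits = 8)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a probe design as BED
#'
#' @param probes A [design_probes()] design.
#' @param genome_id Sequence name.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_probes_bed <- function(probes, genome_id, path) {
  writeLines(c("# BED: tiling probe design (0-based half-open)",
               sprintf("%s\t%d\t%d\t%s", genome_id, probes$start,
                       probes$end, probes$probe_id)), path)
  invisible(path)
}
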