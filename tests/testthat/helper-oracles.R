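# Independent brute-force oracles used to cross-check the implementation.
# Each is written as a direct transcription of the definition (explicit
# scans and double loops), deliberately sharing no code with the package.

# Maximal runs of elevated probes: position-by-position scan.
brute_force_peaks <- function(log2_ratio, threshold, min_run, merge_gap = 0L) {
  n <- length(log2_ratio)
  above <- log2_ratio >= threshold
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    j <- i
    last_above <- i
    while (j < n) {
      nxt <- j + 1L
      if (above[nxt]) { j <- nxt; last_above <- nxt; next }
      # look ahead: can a gap of <= merge_gap be bridged?
      k <- nxt
      gap <- 0L
      while (k <= n && !above[k] && gap < merge_gap) { k <- k + 1L; gap <- gap + 1L }
      if (k <= n && above[k]) { j <- k; last_above <- k } else break
    }
    runs[[length(runs) + 1L]] <- c(first = i, last = last_above)
    i <- last_above + 1L
  }
  runs <- Filter(function(r) r["last"] - r["first"] + 1L >= min_run, runs)
  if (length(runs) == 0L)
    return(data.frame(first = integer(), last = integer()))
  data.frame(first = vapply(runs, `[[`, integer(1), "first"),
             last = vapply(runs, `[[`, integer(1), "last"))
}

# IUPAC matching tables written out by hand.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", D = "H", H = "D", V = "B", N = "N")

brute_revcomp <- function(s) {
  paste(rev(COMPLEMENT[strsplit(s, "")[[1L]]]), collapse = "")
}

# Position-by-position degenerate comparison on both strands.
brute_iupac <- function(seq, pattern, both_strands = TRUE) {
  sq <- strsplit(toupper(seq), "")[[1L]]
  scan1 <- function(pat, strand) {
    pc <- strsplit(pat, "")[[1L]]
    w <- length(pc)
    hits <- integer()
    for (i in seq_len(length(sq) - w + 1L)) {
      ok <- TRUE
      for (j in seq_len(w)) {
        if (!(sq[i + j - 1L] %in% IUPAC_SETS[[pc[j]]])) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, i - 1L)
    }
    if (length(hits) == 0L)
      return(data.frame(start = integer(), strand = character()))
    data.frame(start = hits, strand = strand, stringsAsFactors = FALSE)
  }
  out <- scan1(toupper(pattern), "+")
  if (both_strands)
    out <- rbind(out, scan1(brute_revcomp(toupper(pattern)), "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-probe intensities by an explicit fragment x probe double loop,
# unrolling wrapped fragments by hand.
brute_intensity <- function(pool, probes, genome_len) {
  out <- numeric(nrow(probes))
  for (p in seq_len(nrow(probes))) {
    ps <- probes$start[p]; pe <- probes$end[p]
    acc <- 0
    for (f in seq_len(nrow(pool))) {
      fs <- pool$start[f]; fe <- pool$end[f]
      len <- fe - fs
      pieces <- if (fe > genome_len)
        list(c(fs, genome_len), c(0L, fe - genome_len)) else list(c(fs, fe))
      for (pc in pieces) {
        ov <- min(pe, pc[2L]) - max(ps, pc[1L])
        if (ov > 0) acc <- acc + pool$weight[f] * ov / len
      }
    }
    out[p] <- acc
  }
  out
}

# All-pairs adjacency scan for intergenic spacers on a circular genome.
brute_spacers <- function(ann) {
  u <- ann$units[order(ann$units$start), , drop = FALSE]
  n <- nrow(u)
  rows <- list()
  orient <- function(ls, rs) {
    if (ls == "-" && rs == "+") "divergent"
    else if (ls == "+" && rs == "-") "convergent" else "tandem"
  }
  for (i in seq_len(n)) {
    j <- if (i < n) i + 1L else 1L
    if (i == n && !ann$circular) break
    gap <- if (i < n) u$start[j] - u$end[i]
    else ann$length - u$end[i] + u$start[j]
    if (gap >= 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        left_unit = u$unit_id[i], right_unit = u$unit_id[j],
        len = gap, orientation = orient(u$strand[i], u$strand[j]),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Small hand-built annotation: four units exercising every spacer
# orientation. Layout (0-based):
#   uA: gA  -  [   0,  500)  \
#   uB: gB  +  [ 700, 1200)   > divergent spacer 500..700
#   uC: gC  +  [1400, 1900)   > tandem spacers 1200..1400, and
#   uD: gD  -  [2100, 2600)   > convergent spacer 1900..2100
# circular wrap spacer 2600..3000(+0): uD(-) -> uA(-) tandem.
fixture_annotation <- function(circular = TRUE) {
  genome_annotation(
    "fix", 3000L,
    data.frame(gene_id = c("gA", "gB", "gC", "gD"),
               start = c(0L, 700L, 1400L, 2100L),
               end = c(500L, 1200L, 1900L, 2600L),
               strand = c("-", "+", "+", "-"),
               stringsAsFactors = FALSE),
    circular = circular)
}
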