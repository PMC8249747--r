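## The in-silico gSELEX engine: affinity landscape, fragment library,
## multiplicative selection cycles, and clone sampling (the cloning-
## sequencing readout).

#' Describe a transcription factor's affinity landscape
#'
#' A TF is modelled as a set of point binding sites with dimensionless
#' strengths over a uniform background affinity. Alternative site lists
#' keyed by effector state express conditional binding (e.g. an
#' unphosphorylated response regulator binding one site versus its
#' acetyl-phosphate-treated form binding many).
#'
#' @param tf_id Character TF name.
#' @param sites Either a `data.frame` with columns `position` (bp, 0-based)
#'   and `strength` (>= 0), or a named list of such data frames, one per
#'   effector state.
#' @param background Background bind score of any fragment (> 0).
#' @return An object of class `affinity_model` with elements `tf_id`,
#'   `background`, `states` (named list of site tables).
#' @export
affinity_model <- function(tf_id, sites, background = 1) {
  stopifnot(is.character(tf_id), length(tf_id) == 1L)
  if (!is.numeric(background) || background <= 0)
    stop("background must be > 0")
  if (is.data.frame(sites)) sites <- list(apo = sites)
  if (is.null(names(sites)) || any(names(sites) == ""))
    stop("site lists must be named by effector state")
  sites <- lapply(sites, function(s) {
    s <- as.data.frame(s)
    stopifnot(all(c("position", "strength") %in% names(s)))
    if (any(!is.finite(s$strength)) || any(s$strength < 0))
      stop("site strengths must be finite and >= 0")
    s$position <- as.integer(s$position)
    s
  })
  structure(list(tf_id = tf_id, background = background, states = sites),
            class = "affinity_model")
}

#' Parameters of the fragment library and selection
#'
#' @param fragment_mean_len Mean fragment length, bp (default 300, the
#'   sonication-scale segment length of the screen being emulated).
#' @param fragment_len_sd SD of fragment length, bp (default 50).
#' @param library_size Number of fragments drawn.
#' @param cycles Number of selection cycles, 1-10 (default 4; screens of
#'   this kind run three to six cycles).
#' @param seed Integer seed, or `NULL` to draw from the current RNG state.
#' @return A `selex_params` list.
#' @export
selex_params <- function(fragment_mean_len = 300L, fragment_len_sd = 50L,
                         library_size = 10000L, cycles = 4L, seed = NULL) {
  if (cycles < 1L || cycles > 10L) stop("cycles must be in [1, 10]")
  if (library_size < 1L) stop("library_size must be >= 1")
  structure(list(fragment_mean_len = as.integer(fragment_mean_len),
                 fragment_len_sd = as.numeric(fragment_len_sd),
                 library_size = as.integer(library_size),
                 cycles = as.integer(cycles), seed = seed),
            class = "selex_params")
}

#' Draw a random fragment library from a genome
#'
#' Fragment start positions are uniform on the circle; lengths are normal
#' (`fragment_mean_len`, `fragment_len_sd`) truncated to
#' `[100, 2 * fragment_mean_len]`. Fragments may wrap the origin, in which
#' case `end` exceeds the genome length. Initial weights are uniform and
#' sum to 1.
#'
#' @param ann A [genome_annotation()].
#' @param params A [selex_params()].
#' @return A `fragment_pool`: `data.frame(start, end, weight)` with
#'   attribute `genome_len`.
#' @export
make_fragment_library <- function(ann, params = selex_params()) {
  stopifnot(inherits(ann, "genome_annotation"))
  if (params$fragment_mean_len < 1L) stop("fragment_mean_len must be >= 1")
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$library_size
  start <- as.integer(floor(runif(n, 0, ann$length)))
  len <- rnorm(n, params$fragment_mean_len, params$fragment_len_sd)
  len <- as.integer(round(pmin(pmax(len, 100), 2 * params$fragment_mean_len)))
  pool <- data.frame(start = start, end = start + len, weight = rep(1 / n, n))
  attr(pool, "genome_len") <- ann$length
  class(pool) <- c("fragment_pool", "data.frame")
  pool
}

#' Bind score of every fragment under an affinity model
#'
#' Additive over covered sites: `background + sum(strength)` of sites whose
#' point position lies inside the fragment (modulo the circular wrap).
#'
#' @param pool A fragment pool.
#' @param aff An [affinity_model()].
#' @param state Effector state selecting the site list.
#' @return Numeric vector of bind scores, one per fragment.
#' @export
bind_scores <- function(pool, aff, state = "apo") {
  sites <- aff$states[[state]]
  if (is.null(sites)) stop("unknown effector state: ", state)
  L <- attr(pool, "genome_len")
  b <- rep(aff$background, nrow(pool))
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    covered <- (pool$start <= p & pool$end > p) |
      (pool$start <= p + L & pool$end > p + L)   # wrapped fragments
    b[covered] <- b[covered] + sites$strength[i]
  }
  b
}

#' One multiplicative selection cycle
#'
#' Each fragment's weight is multiplied by its bind score and the pool is
#' renormalised; the fragment set itself is unchanged. With a background-
#' only model every bind score is equal, so selection is the identity.
#'
#' @inheritParams bind_scores
#' @return The reweighted, renormalised fragment pool.
#' @export
selection_cycle <- function(pool, aff, state = "apo") {
  b <- bind_scores(pool, aff, state)
  w <- pool$weight * b
  tot <- sum(w)
  if (tot == 0) stop("degenerate affinity model: all bind scores are zero")
  pool$weight <- w / tot
  pool
}

#' Run repeated selection cycles
#'
#' Iterates [selection_cycle()] and records, per cycle, the total weight
#' share of fragments covering each site (the enrichment trace, stored in
#' attribute `"trace"` of the result).
#'
#' @inheritParams bind_scores
#' @param cycles Number of cycles (>= 1).
#' @return The final fragment pool, with attribute `trace`: a `data.frame`
#'   with columns `cycle`, `site`, `share`.
#' @export
run_selex <- function(pool, aff, cycles, state = "apo") {
  if (cycles < 1L) stop("cycles must be >= 1")
  sites <- aff$states[[state]]
  trace <- vector("list", cycles)
  for (k in seq_len(cycles)) {
    pool <- selection_cycle(pool, aff, state)
    trace[[k]] <- data.frame(
      cycle = k,
      site = seq_len(nrow(sites)),
      share = vapply(seq_len(nrow(sites)), function(i)
        site_weight_share(pool, sites$position[i]), numeric(1)))
  }
  attr(pool, "trace") <- if (nrow(sites) > 0L) do.call(rbind, trace)
  else data.frame(cycle = integer(), site = integer(), share = numeric())
  pool
}

site_weight_share <- function(pool, position) {
  L <- attr(pool, "genome_len")
  covered <- (pool$start <= position & pool$end > position) |
    (pool$start <= position + L & pool$end > position + L)
  sum(pool$weight[covered])
}

#' Sample sequenced clones from a selected pool (cloning readout)
#'
#' Draws `n` clones multinomially, proportional to fragment weights —
#' the in-silico analogue of cloning and sequencing individual selected
#' fragments instead of hybridising the pool to an array.
#'
#' @param pool A fragment pool.
#' @param n Number of clones (>= 1).
#' @param seed Integer seed, or `NULL`.
#' @return A list with `clones` (`data.frame(start, end)`, one row per
#'   clone) and `tally` (`data.frame(start, end, count)`, counts per
#'   distinct fragment, summing to `n`).
#' @export
sample_clones <- function(pool, n, seed = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
  clones <- data.frame(start = pool$start[idx], end = pool$end[idx])
  tab <- table(idx)
  ui <- as.integer(names(tab))
  tally <- data.frame(start = pool$start[ui], end = pool$end[ui],
                      count = as.integer(tab))
  tally <- tally[order(-tally$count, tally$start), , drop = FALSE]
  rownames(tally) <- NULL
  list(clones = clones, tally = tally)
}

#' Count clones carrying a given locus
#'
#' @param clones `data.frame(start, end)` as from [sample_clones()].
#' @param position 0-based genomic position of the locus.
#' @param genome_len Genome length (for wrapped clones).
#' @return Integer count of clones covering the position.
#' @export
clones_at_locus <- function(clones, position, genome_len) {
  sum((clones$start <= position & clones$end > position) |
        (clones$start <= position + genome_len &
           clones$end > position + genome_len))
}

#' Export a fragment pool as BED with weights in the score column
#'
#' Wrapped fragments are split at the origin into two lines sharing a name.
#'
#' @param pool A fragment pool.
#' @param genome_id Sequence name for the BED chrom column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pool_bed <- function(pool, genome_id, path) {
  L <- attr(pool, "genome_len")
  n <- nrow(pool)
  name <- sprintf("frag%06d", seq_len(n))
  sc <- formatC(pool$weight, format = "g", digits = 10)
  wraps <- pool$end > L
  body <- character(0)
  plain <- !wraps
  body <- c(body, sprintf("%s\t%d\t%d\t%s\t%s\t.", genome_id,
                          pool$start[plain], pool$end[plain],
                          name[plain], sc[plain]))
  if (any(wraps)) {
    body <- c(body,
      sprintf("%s\t%d\t%d\t%s\t%s\t.", genome_id, pool$start[wraps], L,
              name[wraps], sc[wraps]),
      sprintf("%s\t%d\t%d\t%s\t%s\t.", genome_id, 0L, pool$end[wraps] - L,
              name[wraps], sc[wraps]))
  }
  writeLines(c("# BED6: gSELEX fragment pool; score column = pool weight",
               body), path)
  invisible(path)
}
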