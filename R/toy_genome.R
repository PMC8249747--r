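## Synthetic circular genome generator: named transcription units separated
## by intergenic spacers, with strand patterns guaranteeing at least one
## divergent (and for larger genomes one tandem) spacer.

#' Default geometry for the toy-genome generator
#'
#' Lengths are in bp. Units hold 1-3 genes of 600-1200 bp separated by
#' short intra-operon gaps; inter-unit spacers are 150-400 bp, comfortably
#' holding a promoter region and a binding site.
#'
#' @return A named list understood by [generate_toy_genome()].
#' @export
toy_geometry <- function() {
  list(genes_per_unit = c(1L, 3L),
       gene_len = c(600L, 1200L),
       intra_gap = c(20L, 60L),
       spacer_len = c(150L, 400L))
}

#' Generate a random annotated circular toy genome
#'
#' Lays `n_units` transcription units around a circle, each followed by an
#' intergenic spacer, with uniform random sequence. Strands are random
#' except for a fixed leading pattern that guarantees at least one divergent
#' spacer (and, for `n_units >= 5`, at least one tandem spacer), so every
#' generated genome exercises the promoter-orientation logic downstream.
#' The first gene of `tf_unit` (when given) is marked `kind = "TF_gene"`.
#'
#' @param n_units Number of transcription units (>= 2).
#' @param spacer_geometry Geometry list as from [toy_geometry()]; ranges are
#'   sampled uniformly.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param tf_unit Optional unit index whose first gene becomes the TF gene.
#' @param emit_seq Generate the random genome sequence (set `FALSE` to skip
#'   the sequence for large coordinate-only simulations).
#' @return A [genome_annotation()] (circular), with sequence attached when
#'   `emit_seq = TRUE`.
#' @export
generate_toy_genome <- function(n_units, spacer_geometry = toy_geometry(),
                                seed = NULL, tf_unit = NULL,
                                emit_seq = TRUE) {
  if (n_units < 2L) stop("n_units must be >= 2")
  geo <- utils::modifyList(toy_geometry(), spacer_geometry)
  if (geo$gene_len[1L] < 1L || geo$spacer_len[1L] < 1L)
    stop("geometry cannot fit a genome: lengths must be positive")
  if (!is.null(seed)) set.seed(seed)

  strands <- sample(c("+", "-"), n_units, replace = TRUE)
  if (n_units == 2L) {
    strands[1:2] <- c("-", "+")            # divergent interior spacer
    div_left <- 1L
  } else {
    strands[2:3] <- c("-", "+")            # divergent spacer between 2 and 3
    div_left <- 2L
    if (n_units >= 5L) strands[4:5] <- c("+", "+")  # tandem spacer 4|5
  }

  runif_int <- function(n, range) {
    if (range[1L] == range[2L]) rep(range[1L], n)
    else as.integer(floor(runif(n, range[1L], range[2L] + 1L)))
  }

  pos <- 0L
  gene_rows <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    k <- runif_int(1L, geo$genes_per_unit)
    lens <- runif_int(k, geo$gene_len)
    gaps <- if (k > 1L) runif_int(k - 1L, geo$intra_gap) else integer()
    starts <- pos + cumsum(c(0L, lens[-k] + gaps))
    ends <- starts + lens
    ids <- sprintf("g%03d_%d", i, seq_len(k))
    kind <- rep("ORF", k)
    if (!is.null(tf_unit) && i == tf_unit) { kind[1L] <- "TF_gene"; ids[1L] <- "tf" }
    # operon members are listed 5'->3'; coordinates are laid left-to-right
    gene_rows[[i]] <- data.frame(
      gene_id = ids, start = starts, end = ends, strand = strands[i],
      kind = kind, unit_id = sprintf("unit%03d", i), stringsAsFactors = FALSE)
    # the guaranteed divergent spacer is kept wide enough (>= 250 bp) to
    # host a promoter-proximal site clear of both flanking genes
    sp_range <- if (i == div_left)
      c(max(250L, geo$spacer_len[1L]), max(250L, geo$spacer_len[2L]))
    else geo$spacer_len
    pos <- ends[k] + runif_int(1L, sp_range)
  }
  genome_len <- pos   # trailing spacer wraps to unit 1 at the origin
  genes <- do.call(rbind, gene_rows)

  seq <- NULL
  if (emit_seq)
    seq <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
                 collapse = "")
  genome_annotation("toygen", genome_len, genes, circular = TRUE, seq = seq)
}

#' Pick spacers suitable for planting binding sites
#'
#' Returns spacers whose orientation puts at least one promoter on the
#' spacer (divergent or tandem) and whose length leaves the planted site
#' clear of the flanking genes. `n` spacers are picked evenly around the
#' genome (deterministically, no RNG) so planted sites are well separated.
#'
#' @param spacers Output of [compute_spacers()].
#' @param n Number of spacers wanted.
#' @param min_len Minimal spacer length in bp.
#' @param orientations Admissible orientation classes.
#' @return Subset of `spacers` rows (n rows), with a `site_pos` column at
#'   the spacer midpoint.
#' @export
eligible_site_spacers <- function(spacers, n, min_len = 250L,
                                  orientations = c("divergent", "tandem")) {
  el <- spacers[!spacers$wraps &
                  spacers$orientation %in% orientations &
                  (spacers$end - spacers$start) >= min_len, , drop = FALSE]
  if (nrow(el) < n)
    stop("only ", nrow(el), " eligible spacers for ", n, " sites; ",
         "increase n_units or relax the geometry")
  idx <- unique(as.integer(round(seq(1L, nrow(el), length.out = n))))
  while (length(idx) < n)   # dense case: fill from unused rows
    idx <- union(idx, setdiff(seq_len(nrow(el)), idx)[1L])
  el <- el[sort(idx[seq_len(n)]), , drop = FALSE]
  el$site_pos <- as.integer((el$start + el$end) %/% 2L)
  rownames(el) <- NULL
  el
}
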