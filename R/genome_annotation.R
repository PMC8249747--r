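## Annotated circular genome: gene features grouped into transcription units.
## Internal coordinates are 0-based half-open throughout; GFF3 I/O converts
## to/from the 1-based inclusive dialect.

#' Construct a genome annotation
#'
#' Bundles a (possibly circular) genome of known length with its gene
#' features and the transcription units they belong to. Genes carrying the
#' same `unit_id` form one unit (an operon transcribed from a single
#' promoter); genes without an explicit unit form singleton units.
#'
#' @param genome_id Character scalar naming the sequence.
#' @param length Genome length in bp (positive integer).
#' @param genes A `data.frame` with columns `gene_id`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), optional `kind`
#'   (`"ORF"`, `"TF_gene"`, `"prophage"`, `"sRNA"`; default `"ORF"`) and
#'   optional `unit_id` (operon membership; `NA` means singleton).
#' @param circular Logical; is the genome circular?
#' @param seq Optional genome sequence (a [Biostrings::DNAString] or
#'   character scalar of length `length`).
#'
#' @return An object of class `genome_annotation`: a list with elements
#'   `genome_id`, `length`, `circular`, `genes` (the validated gene table,
#'   sorted by `start`, with `unit_id` filled in) and `units` (one row per
#'   transcription unit: `unit_id`, `strand`, `start`, `end`,
#'   `promoter_pos`, `members` list-column).
#' @export
genome_annotation <- function(genome_id, length, genes, circular = TRUE,
                              seq = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  length <- as.integer(length)
  if (is.na(length) || length <= 0L)
    stop("genome length must be a positive integer")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("genes must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in annotation")
  if (is.null(genes$kind)) genes$kind <- "ORF"
  if (is.null(genes$unit_id)) genes$unit_id <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start >= genes$end))
    stop("gene start must be < end (0-based half-open)")
  if (any(genes$start < 0L) || any(genes$end > length))
    stop("gene coordinates outside [0, genome length); features may not span the origin")
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  # singleton units for genes without an operon tag
  miss <- is.na(genes$unit_id) | genes$unit_id == ""
  genes$unit_id[miss] <- paste0("u_", genes$gene_id[miss])
  # same-strand overlap is tolerated (warn), as real annotations contain it
  ov <- same_strand_overlaps(genes)
  if (ov > 0L)
    warning(ov, " overlapping same-strand gene pair(s) kept as-is")
  units <- build_units(genes)
  ann <- structure(
    list(genome_id = genome_id, length = length, circular = isTRUE(circular),
         genes = genes, units = units,
         seq = if (!is.null(seq)) Biostrings::DNAString(seq) else NULL),
    class = "genome_annotation")
  if (!is.null(ann$seq) && length(ann$seq) != ann$length)
    stop("sequence length (", length(ann$seq),
         ") does not match declared genome length (", ann$length, ")")
  ann
}

same_strand_overlaps <- function(genes) {
  n <- 0L
  for (s in c("+", "-")) {
    g <- genes[genes$strand == s, , drop = FALSE]
    if (nrow(g) < 2L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(g$start + 1L, g$end),
      drop.self = TRUE, drop.redundant = TRUE)
    n <- n + length(hits)
  }
  n
}

build_units <- function(genes) {
  ids <- unique(genes$unit_id)
  rows <- lapply(ids, function(u) {
    g <- genes[genes$unit_id == u, , drop = FALSE]
    if (length(unique(g$strand)) != 1L)
      stop("unit ", u, " mixes strands; operon members must share a strand")
    strand <- g$strand[[1L]]
    start <- min(g$start); end <- max(g$end)
    data.frame(unit_id = u, strand = strand,
               start = start, end = end,
               promoter_pos = if (strand == "+") start else end,
               stringsAsFactors = FALSE)
  })
  units <- do.call(rbind, rows)
  units$members <- I(lapply(ids, function(u) genes$gene_id[genes$unit_id == u]))
  units <- units[order(units$start, units$end), , drop = FALSE]
  rownames(units) <- NULL
  units
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", x$genome_id,
      sprintf("(%d bp, %s)", x$length,
              if (x$circular) "circular" else "linear"), "\n")
  cat("  ", nrow(x$genes), "genes in", nrow(x$units), "transcription units;",
      if (is.null(x$seq)) "no sequence" else "sequence attached", "\n")
  invisible(x)
}

#' Read an annotated genome from GFF3 (and optionally FASTA)
#'
#' Parses gene features from a GFF3 file and groups them into transcription
#' units by an explicit `operon` attribute (genes lacking the attribute
#' become singleton units; no operon prediction is attempted). Genome length
#' is taken from the FASTA sequence when given, otherwise from the
#' `##sequence-region` pragma.
#'
#' @param gff3_path Path to a GFF3 file with `gene` features.
#' @param fasta_path Optional path to the genome FASTA.
#' @param circular Logical; treat the genome as circular (default `TRUE`).
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(gff3_path, fasta_path = NULL, circular = TRUE) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0L) stop("no gene features in ", gff3_path)
  genome_id <- as.character(GenomicRanges::seqnames(gr))[[1L]]
  seq <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seq <- ss[[1L]]
    len <- length(seq)
  } else {
    len <- sequence_region_length(gff3_path, genome_id)
    if (is.na(len))
      stop("genome length unavailable: no FASTA and no ##sequence-region pragma")
  }
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) stop("every gene feature needs an ID attribute")
  operon <- if ("operon" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$operon) else rep(NA_character_, length(gr))
  kind <- if ("kind" %in% names(S4Vectors::mcols(gr)))
    as.character(gr$kind) else rep("ORF", length(gr))
  kind[is.na(kind)] <- "ORF"
  genes <- data.frame(
    gene_id = as.character(ids),
    start = GenomicRanges::start(gr) - 1L,  # GFF3 is 1-based inclusive
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    kind = kind, unit_id = operon,
    stringsAsFactors = FALSE)
  genome_annotation(genome_id, len, genes, circular = circular, seq = seq)
}

sequence_region_length <- function(gff3_path, genome_id) {
  for (line in readLines(gff3_path, n = 50L)) {
    if (startsWith(line, "##sequence-region")) {
      f <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(f) >= 4L && f[[2L]] == genome_id)
        return(as.integer(f[[4L]]))
    }
  }
  NA_integer_
}

#' Write a genome annotation to GFF3 (and optionally FASTA)
#'
#' Emits standard GFF3, 1-based inclusive, with the transcription-unit
#' membership in an `operon` attribute and the gene kind in a `kind`
#' attribute, plus the `##sequence-region` pragma so the file is
#' self-describing. Output is deterministic (no timestamps).
#'
#' @param ann A [genome_annotation()].
#' @param gff3_path Output GFF3 path.
#' @param fasta_path Optional output FASTA path (requires `ann$seq`).
#' @return Invisibly, `gff3_path`.
#' @export
write_annotation <- function(ann, gff3_path, fasta_path = NULL) {
  stopifnot(inherits(ann, "genome_annotation"))
  g <- ann$genes
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", ann$genome_id, ann$length),
    sprintf("%s\tgselexchip\tgene\t%d\t%d\t.\t%s\t.\tID=%s;kind=%s;operon=%s",
            ann$genome_id, g$start + 1L, g$end, g$strand, g$gene_id,
            g$kind, g$unit_id))
  writeLines(lines, gff3_path)
  if (!is.null(fasta_path)) {
    if (is.null(ann$seq)) stop("annotation carries no sequence")
    ss <- Biostrings::DNAStringSet(ann$seq)
    names(ss) <- ann$genome_id
    Biostrings::writeXStringSet(ss, fasta_path, width = 70L)
  }
  invisible(gff3_path)
}
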