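## Peak-to-target annotation. The peak summit decides the genomic context:
## a summit inside a gene is an intragenic (presumed non-specific) call; a
## summit in an intergenic spacer nominates the transcription unit(s) whose
## promoter faces the spacer. A divergent spacer carries two back-to-back
## promoters, so one site there can control both flanking units.

#' Assign one peak to its genomic context and candidate targets
#'
#' Context rules, decided by the summit position:
#' \itemize{
#'   \item inside a gene: `ORF_internal`, no target units;
#'   \item divergent spacer: both flanking units are targets;
#'   \item tandem spacer: the unit whose promoter side abuts the spacer
#'     (the downstream-facing unit) is the single target;
#'   \item convergent spacer: no promoter faces the spacer, no targets;
#'   \item a gap between genes of the same unit: treated as unit-internal,
#'     reported as `ORF_internal` with the unit label.
#' }
#'
#' @param peak One row of a [call_peaks()] table (or a list with `peak_id`
#'   and `summit`).
#' @param ann A [genome_annotation()].
#' @param spacers Optionally, precomputed [compute_spacers()] output.
#' @return A one-row `data.frame`: `peak_id`, `context`,
#'   `spacer_orientation`, `target_units` (comma-joined), `label`.
#' @export
assign_target <- function(peak, ann, spacers = compute_spacers(ann)) {
  pos <- as.integer(peak$summit)
  if (pos < 0L || pos >= ann$length) stop("peak summit outside the genome")
  g <- ann$genes
  gi <- which(g$start <= pos & g$end > pos)
  if (length(gi) > 0L) {
    gene <- g$gene_id[gi[[1L]]]
    return(target_row(peak$peak_id, "ORF_internal", NA_character_,
                      character(), paste0("ORF (", gene, ")")))
  }
  si <- spacer_at(spacers, pos, ann$length)
  if (!is.na(si)) {
    sp <- spacers[si, ]
    pair_label <- paste0("spacer (", sp$left_unit, "/", sp$right_unit, ")")
    targets <- switch(sp$orientation,
      divergent = c(sp$left_unit, sp$right_unit),
      convergent = character(),
      tandem = {
        # same-strand pair: on "+" the right unit's 5' end abuts the
        # spacer; on "-" the left unit's 5' end does
        lstrand <- ann$units$strand[ann$units$unit_id == sp$left_unit]
        if (lstrand == "+") sp$right_unit else sp$left_unit
      })
    return(target_row(peak$peak_id, "spacer", sp$orientation, targets,
                      pair_label))
  }
  # not in a gene, not in an inter-unit spacer: an intra-unit gap
  ui <- which(ann$units$start <= pos & ann$units$end > pos)
  if (length(ui) == 0L) stop("summit in unannotated gap with no flanking units")
  target_row(peak$peak_id, "ORF_internal", NA_character_, character(),
             paste0("ORF (", ann$units$unit_id[ui[[1L]]], ")"))
}

target_row <- function(peak_id, context, orientation, targets, label) {
  data.frame(peak_id = peak_id, context = context,
             spacer_orientation = orientation,
             target_units = paste(targets, collapse = ","),
             label = label, stringsAsFactors = FALSE)
}

#' Assign all peaks of one run to targets
#'
#' @param peaks A [call_peaks()] table.
#' @param ann A [genome_annotation()].
#' @param spacers Optionally, precomputed spacers.
#' @return A `data.frame` with one target call per peak (columns of
#'   [assign_target()] plus the peak `level`).
#' @export
assign_targets <- function(peaks, ann, spacers = compute_spacers(ann)) {
  if (nrow(peaks) == 0L)
    return(data.frame(peak_id = character(), context = character(),
                      spacer_orientation = character(),
                      target_units = character(), label = character(),
                      level = character(), stringsAsFactors = FALSE))
  calls <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i)
    assign_target(peaks[i, ], ann, spacers)))
  calls$level <- peaks$level
  calls
}

#' Count distinct regulatory targets of one TF run
#'
#' By default a divergent unit pair regulated from one shared spacer counts
#' as a single regulatory locus (the bookkeeping used for single-target
#' factors controlling both flanks of one bidirectional spacer); set
#' `collapse_divergent = FALSE` to count individual transcription units
#' instead. Intragenic calls carry no targets and never contribute.
#'
#' @param calls Output of [assign_targets()] for one TF/effector-state run.
#' @param restrict_level Optional level filter (e.g. `"high"` to count
#'   only high-level peaks, the default bookkeeping being that minor peaks
#'   are presumed non-specific).
#' @param collapse_divergent Count a divergent pair as one locus
#'   (default `TRUE`).
#' @return Integer count of distinct regulatory targets.
#' @export
count_distinct_targets <- function(calls, restrict_level = "high",
                                   collapse_divergent = TRUE) {
  if (nrow(calls) == 0L) return(0L)
  if (!is.null(restrict_level))
    calls <- calls[calls$level %in% restrict_level, , drop = FALSE]
  calls <- calls[calls$target_units != "", , drop = FALSE]
  if (nrow(calls) == 0L) return(0L)
  units <- strsplit(calls$target_units, ",", fixed = TRUE)
  if (collapse_divergent) {
    keys <- vapply(units, function(u) paste(sort(u), collapse = "|"),
                   character(1))
  } else {
    keys <- unlist(units)
  }
  length(unique(keys))
}

#' Distinct target units (uncollapsed) of one run
#'
#' @inheritParams count_distinct_targets
#' @return Character vector of unit ids.
#' @export
target_unit_ids <- function(calls, restrict_level = "high") {
  if (nrow(calls) == 0L) return(character())
  if (!is.null(restrict_level))
    calls <- calls[calls$level %in% restrict_level, , drop = FALSE]
  unique(unlist(strsplit(calls$target_units[calls$target_units != ""],
                         ",", fixed = TRUE)))
}

#' Write / read the target report TSV
#'
#' Labels and unit lists round-trip exactly through this format.
#'
#' @param calls Output of [assign_targets()].
#' @param path TSV path.
#' @return `write_targets_tsv`: invisibly, `path`; `read_targets_tsv`: the
#'   calls `data.frame`.
#' @export
write_targets_tsv <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# TSV: peak target calls", con)
  write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_targets_tsv
#' @export
read_targets_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             na.strings = "NA", colClasses = "character")
}
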