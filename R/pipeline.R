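## End-to-end orchestration: genome -> fragment library -> selection ->
## array -> peaks -> targets -> classification, as one seeded, configured
## run emitting a reproducible report bundle.

#' Build a pipeline configuration
#'
#' A run is driven by one config and one seed; all stochastic stages draw
#' from the single seeded generator in a fixed order (genome, library,
#' then per-state hybridization noise), so re-running a config reproduces
#' every output byte for byte.
#'
#' Binding sites per effector state are given either as explicit
#' `data.frame(position, strength)` tables, or as specs
#' `list(n_sites =, strength =)` resolved against the generated genome by
#' planting sites at the midpoints of evenly spaced promoter-bearing
#' (divergent or tandem) spacers; the TF gene is then the promoter-facing
#' unit of the first planted spacer.
#'
#' @param tf_id TF name used in reports.
#' @param n_units Toy-genome size (ignored when `gff3` is given).
#' @param geometry Toy-genome geometry, see [toy_geometry()].
#' @param gff3,fasta Optional paths to a real annotation instead of a
#'   generated genome.
#' @param sites Named list (one entry per effector state) of site tables
#'   or site specs (see Details).
#' @param background Background bind score (default 1).
#' @param selex A [selex_params()] (its `seed` field is ignored; the
#'   pipeline seed rules).
#' @param probe_len,spacing Probe geometry, see [design_probes()].
#' @param noise_sd Hybridization noise SD (default 0.1).
#' @param peaks A [peak_call_config()].
#' @param thresholds A [classification_thresholds()].
#' @param seed Integer seed for the whole run.
#' @param emit_seq Attach a random genome sequence (default `FALSE`; turn
#'   on when the FASTA output is wanted).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tf_id = "toyTF", n_units = 20L,
                            geometry = toy_geometry(),
                            gff3 = NULL, fasta = NULL,
                            sites = list(apo = list(n_sites = 1L, strength = 9)),
                            background = 1,
                            selex = selex_params(),
                            probe_len = 60L, spacing = 105L,
                            noise_sd = 0.1,
                            peaks = peak_call_config(),
                            thresholds = classification_thresholds(),
                            seed = 1L, emit_seq = FALSE) {
  stopifnot(length(names(sites)) == length(sites), !is.null(names(sites)))
  structure(list(tf_id = tf_id, n_units = as.integer(n_units),
                 geometry = geometry, gff3 = gff3, fasta = fasta,
                 sites = sites, background = background, selex = selex,
                 probe_len = as.integer(probe_len),
                 spacing = as.integer(spacing),
                 noise_sd = noise_sd, peaks = peaks,
                 thresholds = thresholds, seed = as.integer(seed),
                 emit_seq = isTRUE(emit_seq)),
            class = "pipeline_config")
}

resolve_sites <- function(cfg, ann, spacers) {
  lapply(cfg$sites, function(s) {
    if (is.data.frame(s)) return(s)
    orientations <- if (!is.null(s$orientations)) s$orientations
    else c("divergent", "tandem")
    el <- eligible_site_spacers(spacers, s$n_sites,
                                orientations = orientations)
    data.frame(position = el$site_pos,
               strength = rep(s$strength, nrow(el)))
  })
}

## The TF gene is the 5'-most gene of the promoter-facing unit of the
## first planted spacer (right unit of a divergent spacer).
mark_tf_gene <- function(ann, spacers, first_site_pos) {
  si <- spacer_at(spacers, first_site_pos, ann$length)
  if (is.na(si)) return(list(ann = ann, tf_gene = NA_character_))
  sp <- spacers[si, ]
  unit_id <- if (sp$orientation == "divergent") sp$right_unit
  else {
    lstrand <- ann$units$strand[ann$units$unit_id == sp$left_unit]
    if (lstrand == "+") sp$right_unit else sp$left_unit
  }
  g <- ann$genes
  member <- which(g$unit_id == unit_id)
  strand <- g$strand[member[1L]]
  five_prime <- if (strand == "+") member[which.min(g$start[member])]
  else member[which.max(g$end[member])]
  ann$genes$kind[five_prime] <- "TF_gene"
  list(ann = ann, tf_gene = g$gene_id[five_prime])
}

#' Run the full screen-and-classify pipeline
#'
#' Executes every stage under one seed and, when `output_dir` is given,
#' writes the report bundle: genome GFF3 (and FASTA when the sequence is
#' attached), spacer BED, probe BED, per-state signal bedGraph + TSV,
#' peaks BED + TSV, target TSV, a classification JSON, and a run manifest
#' (config, seed, package version). Re-running the same config reproduces
#' the bundle byte for byte.
#'
#' @param cfg A [pipeline_config()].
#' @param output_dir Directory for the report bundle, or `NULL` to skip
#'   file output.
#' @param quiet Suppress stage logging to stderr.
#' @return A list: `ann`, `spacers`, `probes`, `tf_gene`, per-state
#'   `states` (each with `signal`, `peaks`, `calls`, `n_targets`,
#'   `group`), `conditional` (from [classify_conditional()]), `org`
#'   (from [classify_gene_org()]), and `classification` (the summary
#'   written to JSON).
#' @export
run_pipeline <- function(cfg, output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  log_stage <- function(...) if (!quiet) message("[gselexchip] ", ...)
  t0 <- proc.time()[["elapsed"]]
  set.seed(cfg$seed)

  log_stage("genome")
  ann <- if (!is.null(cfg$gff3)) {
    read_annotation(cfg$gff3, cfg$fasta)
  } else {
    generate_toy_genome(cfg$n_units, cfg$geometry, seed = NULL,
                        emit_seq = cfg$emit_seq)
  }
  spacers <- compute_spacers(ann)

  sites <- resolve_sites(cfg, ann, spacers)
  aff <- affinity_model(cfg$tf_id, sites, background = cfg$background)
  marked <- mark_tf_gene(ann, spacers, sites[[1L]]$position[1L])
  ann <- marked$ann; tf_gene <- marked$tf_gene

  log_stage("fragment library (", cfg$selex$library_size, " fragments)")
  params <- cfg$selex; params$seed <- NULL
  pool0 <- make_fragment_library(ann, params)
  probes <- design_probes(ann$length, cfg$probe_len, cfg$spacing)

  states <- list()
  for (state in names(sites)) {
    log_stage("state ", state, ": ", cfg$selex$cycles, " selection cycles")
    pool <- run_selex(pool0, aff, cfg$selex$cycles, state = state)
    signal <- hybridize(pool, pool0, probes, noise_sd = cfg$noise_sd,
                        seed = NULL)
    pks <- call_peaks(signal, probes, cfg$peaks)
    calls <- assign_targets(pks, ann, spacers)
    n_targets <- count_distinct_targets(calls)
    group <- classify_tf(n_targets, n_sites = nrow(sites[[state]]),
                         th = cfg$thresholds)
    states[[state]] <- list(pool = pool, signal = signal, peaks = pks,
                            calls = calls, n_targets = n_targets,
                            group = group)
  }

  runs <- data.frame(
    effector_state = names(states),
    n_targets = vapply(states, `[[`, integer(1), "n_targets"),
    group = vapply(states, `[[`, character(1), "group"),
    stringsAsFactors = FALSE)
  conditional <- classify_conditional(runs)
  all_targets <- unique(unlist(lapply(states, function(s)
    target_unit_ids(s$calls))))
  org <- if (!is.na(tf_gene))
    classify_gene_org(tf_gene, all_targets, ann)
  else list(tf_id = NA_character_, org = NA_character_, evidence = NA)

  classification <- list(
    tf_id = cfg$tf_id, seed = cfg$seed, tf_gene = tf_gene,
    states = runs, conditional_st = conditional$conditional_st,
    st_state = conditional$st_state, org = org$org,
    org_evidence = as.character(org$evidence))

  if (!is.null(output_dir))
    write_bundle(cfg, ann, spacers, probes, states, classification,
                 output_dir)
  log_stage(sprintf("done in %.1f s", proc.time()[["elapsed"]] - t0))
  invisible(list(ann = ann, spacers = spacers, probes = probes,
                 tf_gene = tf_gene, states = states,
                 conditional = conditional, org = org,
                 classification = classification))
}

write_bundle <- function(cfg, ann, spacers, probes, states, classification,
                         output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, paste0(...))
  write_annotation(ann, p("genome.gff3"),
                   fasta_path = if (!is.null(ann$seq)) p("genome.fasta"))
  write_spacers_bed(spacers, ann, p("spacers.bed"))
  write_probes_bed(probes, ann$genome_id, p("probes.bed"))
  for (state in names(states)) {
    s <- states[[state]]
    write_signal_bedgraph(s$signal, probes, ann$genome_id,
                          p("signal_", state, ".bedGraph"))
    write_signal_tsv(s$signal, probes, p("signal_", state, ".tsv"))
    write_peaks(s$peaks, ann$genome_id, p("peaks_", state, ".bed"),
                p("peaks_", state, ".tsv"))
    write_targets_tsv(s$calls, p("targets_", state, ".tsv"))
  }
  jsonlite::write_json(classification, p("classification.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  manifest <- list(config = manifest_config(cfg), seed = cfg$seed,
                   package = "gselexchip",
                   version = as.character(utils::packageVersion("gselexchip")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(output_dir)
}

## Config as plain lists so the manifest JSON round-trips losslessly.
manifest_config <- function(cfg) {
  c <- unclass(cfg)
  c$selex <- unclass(c$selex)
  c$peaks <- unclass(c$peaks)
  c$thresholds <- unclass(c$thresholds)
  c
}
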