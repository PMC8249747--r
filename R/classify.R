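## Classification of TFs by regulon size into the four-group hierarchy
## (single-target, local, global, nucleoid-associated), the conditional
## single-target call across effector states, and the type-A/type-B
## TF-gene/target-gene organization call.

#' Thresholds of the regulon-size classification
#'
#' The published bands are "1 to several" targets for single-target
#' factors, 10-50 for local TFs, more than 100 for global regulators and
#' on the order of 1,000 binding sites for nucleoid-associated regulators.
#' "Several" is fixed at 3 by default; counts falling in the gaps between
#' bands (4-9, 51-99) are labelled `intermediate` rather than forced into
#' a band.
#'
#' @param st_max Upper bound of the single-target band (default 3).
#' @param local_min,local_max Local-TF band (defaults 10, 50).
#' @param global_min Lower bound of the global band (default 100).
#' @param nap_min Binding-site count from which a factor is treated as
#'   nucleoid-associated (default 500).
#' @return A `classification_thresholds` list.
#' @export
classification_thresholds <- function(st_max = 3L, local_min = 10L,
                                      local_max = 50L, global_min = 100L,
                                      nap_min = 500L) {
  if (!(st_max < local_min && local_min <= local_max &&
          local_max < global_min && global_min <= nap_min))
    stop("need st_max < local_min <= local_max < global_min <= nap_min")
  structure(list(st_max = as.integer(st_max), local_min = as.integer(local_min),
                 local_max = as.integer(local_max),
                 global_min = as.integer(global_min),
                 nap_min = as.integer(nap_min)),
            class = "classification_thresholds")
}

#' Classify one TF run by target count
#'
#' Nucleoid-associated status is keyed on the binding-site count
#' (`n_sites`), not the regulated-unit count, since for such factors the
#' published numbers are total binding sites. Otherwise the regulated-unit
#' count decides the band; counts in the unclaimed gaps yield
#' `intermediate`, and zero targets yields `none`.
#'
#' @param n_targets Number of distinct regulatory targets (>= 0).
#' @param n_sites Number of binding sites (defaults to `n_targets`).
#' @param th A [classification_thresholds()].
#' @return Character scalar: one of `"none"`, `"ST"`, `"intermediate"`,
#'   `"local"`, `"global"`, `"NAP"`.
#' @export
classify_tf <- function(n_targets, n_sites = n_targets,
                        th = classification_thresholds()) {
  if (n_targets < 0 || n_sites < 0) stop("counts must be non-negative")
  if (n_sites >= th$nap_min) return("NAP")
  if (n_targets == 0) return("none")
  if (n_targets <= th$st_max) return("ST")
  if (n_targets >= th$global_min) return("global")
  if (n_targets >= th$local_min && n_targets <= th$local_max) return("local")
  "intermediate"
}

#' Combine per-effector-state runs into a conditional classification
#'
#' A factor that is single-target in exactly one effector state and not in
#' another is a conditional single-target TF (e.g. the unmodified form
#' binding one locus while the phosphorylated form binds many, or an
#' effector-bound form binding one locus while the apo form binds many).
#'
#' @param runs A `data.frame` with columns `effector_state`, `n_targets`,
#'   `group` (one row per state of one TF).
#' @return A list: `conditional_st` flag, `st_state` (the single-target
#'   state, or `NA`), and the input `runs`. With a single state the run is
#'   passed through with `conditional_st = FALSE`.
#' @export
classify_conditional <- function(runs) {
  stopifnot(all(c("effector_state", "n_targets", "group") %in% names(runs)))
  is_st <- runs$group == "ST"
  conditional <- nrow(runs) >= 2L && sum(is_st) == 1L && any(!is_st)
  list(conditional_st = conditional,
       st_state = if (any(is_st)) runs$effector_state[which(is_st)[1L]]
       else NA_character_,
       runs = runs)
}

#' Classify TF-gene/target-gene organization as type-A or type-B
#'
#' Type-A: the TF gene and its regulatory targets form an adjacent set —
#' the TF gene's unit is itself a target, or shares an intergenic spacer
#' with (equivalently, is next to in genome order) a target unit. Type-B:
#' the TF gene lies away from all its targets; the minimal separation (bp
#' between the TF unit and the nearest target unit, around the circle) is
#' recorded as evidence.
#'
#' @param tf_gene Gene id of the TF gene.
#' @param target_units Character vector of target unit ids.
#' @param ann A [genome_annotation()].
#' @return A list: `tf_id`, `org` (`"type_A"`/`"type_B"`), `evidence`
#'   (adjacency relation for type-A, separation bp for type-B).
#' @export
classify_gene_org <- function(tf_gene, target_units, ann) {
  gi <- match(tf_gene, ann$genes$gene_id)
  if (is.na(gi)) stop("TF gene ", tf_gene, " absent from annotation")
  if (!all(target_units %in% ann$units$unit_id))
    stop("target unit(s) absent from annotation: ",
         paste(setdiff(target_units, ann$units$unit_id), collapse = ", "))
  tf_unit <- ann$genes$unit_id[gi]
  if (length(target_units) == 0L)
    return(list(tf_id = tf_gene, org = "type_B", evidence = NA))
  if (tf_unit %in% target_units)
    return(list(tf_id = tf_gene, org = "type_A",
                evidence = paste0("member_of:", tf_unit)))
  u <- ann$units[order(ann$units$start, ann$units$end), , drop = FALSE]
  n <- nrow(u)
  i <- match(tf_unit, u$unit_id)
  neigh <- if (ann$circular) {
    u$unit_id[c((i - 2L) %% n + 1L, i %% n + 1L)]
  } else {
    u$unit_id[c(i - 1L, i + 1L)[c(i - 1L, i + 1L) >= 1L &
                                  c(i - 1L, i + 1L) <= n]]
  }
  adj <- intersect(neigh, target_units)
  if (length(adj) > 0L)
    return(list(tf_id = tf_gene, org = "type_A",
                evidence = paste0("adjacent_to:", adj[[1L]])))
  # type-B: minimal gap between unit intervals, around the circle
  ti <- match(target_units, u$unit_id)
  gap <- vapply(ti, function(j) unit_gap(u, i, j, ann$length, ann$circular),
                numeric(1))
  list(tf_id = tf_gene, org = "type_B", evidence = min(gap))
}

unit_gap <- function(u, i, j, L, circular) {
  d1 <- u$start[j] - u$end[i]   # gap going right from i to j
  d2 <- u$start[i] - u$end[j]   # gap going right from j to i
  if (circular) {
    # shorter way around the circle
    max(min(d1 %% L, d2 %% L), 0)
  } else {
    # on a line exactly one direction is meaningful (the other is negative)
    max(d1, d2, 0)
  }
}
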