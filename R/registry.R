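## The packaged registry of published single-target TFs of E. coli K-12,
## shipped as a plain TSV mirroring the printed table, and its summary
## counts.

#' Load the packaged single-target TF registry
#'
#' The registry transcribes the printed single-target TF list: version 1
#' holds the 13 earlier factors, version 2 the 11 newly reported ones.
#' Rows carried only for completeness (present in the printed table but
#' not in the in-text name lists, from which the totals derive) have
#' `in_counts = FALSE` and are excluded by the summary counts.
#'
#' @param include_discrepancies Keep `in_counts = FALSE` rows (default
#'   `TRUE`; they stay flagged either way).
#' @return A `data.frame` with columns `tf_name`, `alternative_name`,
#'   `family`, `org`, `effector`, `function_desc`, `target_operons`,
#'   `version`, `in_counts`, `notes`.
#' @export
load_registry <- function(include_discrepancies = TRUE) {
  path <- system.file("extdata", "sttf_registry.tsv", package = "gselexchip",
                      mustWork = TRUE)
  reg <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = c(version = "integer",
                                   in_counts = "logical"))
  if (anyDuplicated(reg$tf_name))
    stop("duplicate tf_name in registry")
  if (!all(reg$version %in% c(1L, 2L)))
    stop("registry version must be 1 or 2")
  if (!all(reg$org %in% c("type_A", "type_B")))
    stop("registry org must be type_A or type_B")
  if (!include_discrepancies) reg <- reg[reg$in_counts, , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Summary counts of the single-target TF registry
#'
#' Counts include only `in_counts` rows (the in-text name lists).
#'
#' @param registry Optionally, a preloaded [load_registry()] table.
#' @return A list: `total`, `by_version` (named counts for versions 1 and
#'   2), `by_org` (`type_A`, `type_B`), and `version_org` (2x2 table of
#'   counts).
#' @export
registry_report <- function(registry = load_registry()) {
  reg <- registry[registry$in_counts, , drop = FALSE]
  list(total = nrow(reg),
       by_version = c(`1` = sum(reg$version == 1L),
                      `2` = sum(reg$version == 2L)),
       by_org = c(type_A = sum(reg$org == "type_A"),
                  type_B = sum(reg$org == "type_B")),
       version_org = table(version = reg$version, org = reg$org))
}
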