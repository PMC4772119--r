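#' Run the full detection pipeline on files
#'
#' Reads a FASTA file and its annotation table, attaches annotations,
#' detects one TMD per record, and optionally writes the result table.
#' Per-stage record counts are reported as messages.
#'
#' @param fasta Path to the input FASTA.
#' @param annotations Path to the annotation TSV (`id`, `group`,
#'   `topology`).
#' @param output Optional path for the output TSV (see
#'   [write_tmd_table()]).
#' @param config A [tmd_config()].
#' @param lenient Passed to [attach_annotations()] and [detect_tmds()]:
#'   unannotated or UNKNOWN-topology records are flagged and skipped
#'   instead of raising an error.
#' @param quiet Suppress the per-stage count messages.
#' @return The `tmd_table`, invisibly when `output` is given.
#' @export
run_scan <- function(fasta, annotations, output = NULL,
                     config = tmd_config(), lenient = FALSE, quiet = FALSE) {
  records <- read_fasta(fasta)
  if (!quiet) message("read ", nrow(records), " sequence record(s)")
  ann <- read_annotations(annotations)
  records <- attach_annotations(records, ann, strict = !lenient)
  tab <- detect_tmds(records, config = config, lenient = lenient)
  counts <- attr(tab, "counts")
  if (!quiet) {
    message("detected spans: ", counts[["detected"]],
            "; no TMD: ", counts[["no_tmd"]],
            "; unknown topology: ", counts[["unknown_topology"]])
  }
  if (!is.null(output)) {
    write_tmd_table(tab, output)
    if (!quiet) message("wrote ", output)
    return(invisible(tab))
  }
  tab
}

#' Compare two groups in a TMD table
#'
#' Pulls the detected TMD lengths of two group labels from a `tmd_table`
#' (or a path to one) and runs [compare_groups()]: group summaries, Welch
#' two-tailed t-test, and directed plus symmetric KLDM. Optionally writes
#' the report as JSON.
#'
#' @param tmd A `tmd_table`, a data.frame with `group` and `length`
#'   columns, or a path to a table written by [write_tmd_table()].
#' @param group_a,group_b Group labels to compare.
#' @param config A [tmd_config()] (supplies the KLDM log base).
#' @param output Optional path for a JSON report.
#' @return A `tmd_comparison`.
#' @export
run_compare <- function(tmd, group_a, group_b, config = tmd_config(),
                        output = NULL) {
  if (is.character(tmd) && length(tmd) == 1L) tmd <- read_tmd_table(tmd)
  stopifnot(is.data.frame(tmd), all(c("group", "length") %in% names(tmd)))
  ok <- if ("flags" %in% names(tmd)) tmd$flags == "" else !is.na(tmd$length)
  available <- sort(unique(tmd$group[ok]))
  for (g in c(group_a, group_b)) {
    if (!(g %in% available)) {
      stop("unknown group label '", g, "'; available groups: ",
           paste(available, collapse = ", "), call. = FALSE)
    }
  }
  cmp <- compare_groups(tmd$length[ok & tmd$group == group_a],
                        tmd$length[ok & tmd$group == group_b],
                        labels = c(group_a, group_b),
                        log_base = config$kldm_log_base)
  if (!is.null(output)) {
    report <- list(
      groups = lapply(cmp$groups, function(s) {
        list(n = s$n, mean = s$mean, sd = s$sd, mode = s$mode)
      }),
      t_stat = cmp$t_stat, p_value = cmp$p_value,
      kldm_xy = cmp$kldm_xy, kldm_yx = cmp$kldm_yx, kldm_sym = cmp$kldm_sym,
      trimmed_support = cmp$trimmed_support)
    jsonlite::write_json(report, output, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  cmp
}
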