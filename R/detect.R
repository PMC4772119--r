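#' Rough scan: locate the most hydrophobic window
#'
#' Slides a fixed window along the sequence and returns the one with the
#' highest summed hydropathy, irrespective of how many hydrophilic
#' residues it contains. Ties (within 1e-9, which also absorbs
#' floating-point noise between equal-content windows) are broken towards
#' the smallest start, so the scan is deterministic.
#'
#' @param sequence Amino-acid string.
#' @param scale A `hydropathy_scale`.
#' @param window Window size; default 18.
#' @return list with `core_start`, `core_end` (1-based, inclusive).
#' @export
rough_scan <- function(sequence, scale, window = 18L) {
  window <- as.integer(window)
  n <- nchar(sequence)
  if (n < window) {
    stop(sprintf("sequence length (%d) is shorter than the scan window (%d)",
                 n, window), call. = FALSE)
  }
  s <- residue_scores(sequence, scale)
  cs <- c(0, cumsum(s))
  sums <- cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]
  start <- which(sums >= max(sums) - 1e-9)[1L]
  list(core_start = start, core_end = start + window - 1L)
}

#' Attach flanking residues to a core window
#'
#' Extends the rough-scan core by up to `max_flank` residues on each side
#' (truncated at the sequence ends) to form the candidate region that edge
#' refinement operates on. With the defaults (window 18, flank 8) the
#' candidate is 18-34 residues long, and at least 26 whenever a full flank
#' exists on one side.
#'
#' @param core list with `core_start`, `core_end` from [rough_scan()].
#' @param sequence The sequence the core was found in.
#' @param max_flank Maximum flank per side; default 8.
#' @return list with `core_start`, `core_end`, `cand_start`, `cand_end`,
#'   `flank_left`, `flank_right`.
#' @export
attach_flanks <- function(core, sequence, max_flank = 8L) {
  n <- nchar(sequence)
  max_flank <- as.integer(max_flank)
  stopifnot(core$core_start >= 1L, core$core_end <= n,
            core$core_start <= core$core_end)
  fl <- min(max_flank, core$core_start - 1L)
  fr <- min(max_flank, n - core$core_end)
  list(core_start = core$core_start, core_end = core$core_end,
       cand_start = core$core_start - fl, cand_end = core$core_end + fr,
       flank_left = fl, flank_right = fr)
}

# Burial test: position i holds a hydrophilic residue that may be kept at a
# span edge only if at least `burial` contiguous hydrophobic residues sit
# immediately on BOTH sides, all inside the candidate region. Charged
# residues are never buried-eligible (handled by the caller).
is_buried <- function(i, hmask, cand_start, cand_end, burial) {
  if (i - burial < cand_start || i + burial > cand_end) return(FALSE)
  all(hmask[(i - burial):(i - 1L)]) && all(hmask[(i + 1L):(i + burial)])
}

#' Refine the edges of a candidate TMD region
#'
#' Two-phase deterministic procedure on the candidate region (core plus
#' flanks):
#'
#' 1. **Expand** — from each core edge, extend outward (never past the
#'    flank budget) while the next residue is hydrophobic, or is an
#'    uncharged hydrophilic residue buried under the 3+3 rule (at least
#'    `burial` contiguous hydrophobic residues immediately on both sides,
#'    within the candidate).
#' 2. **Contract** — at each edge, repeatedly drop the terminal residue
#'    while it is hydrophilic and not buried. Charged residues
#'    (D, E, K, R, H by default) are never buried-eligible, so they are
#'    always chopped from an edge. Hydrophilic residues in the interior of
#'    the span are retained.
#'
#' On exit every terminal residue is hydrophobic or a buried uncharged
#' hydrophilic. If the candidate contains no hydrophobic residue at all the
#' span empties; this is reported as a no-TMD result (`no_tmd = TRUE`),
#' not an error.
#'
#' @param candidate list from [attach_flanks()].
#' @param sequence The full sequence.
#' @param scale A `hydropathy_scale`.
#' @param burial Minimum contiguous hydrophobic bracket per side; default 3.
#' @param charged Residues excluded from the buried exception.
#' @param expand_first Run the expansion phase before contraction
#'   (default); the reverse order is available for sensitivity checks.
#' @return list of class `tmd_span` with `start`, `end`, `length`, the
#'   candidate/core bookkeeping, and `no_tmd`.
#' @export
refine_edges <- function(candidate, sequence, scale, burial = 3L,
                         charged = CHARGED_RESIDUES, expand_first = TRUE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  scores <- residue_scores(sequence, scale)
  hmask <- scores > scale$hydrophobic_threshold
  cmask <- chars %in% charged
  cs <- candidate$cand_start
  ce <- candidate$cand_end
  burial <- as.integer(burial)

  admissible <- function(i) {
    hmask[i] || (!cmask[i] && is_buried(i, hmask, cs, ce, burial))
  }
  expand <- function(start, end) {
    while (start - 1L >= cs && admissible(start - 1L)) start <- start - 1L
    while (end + 1L <= ce && admissible(end + 1L)) end <- end + 1L
    list(start = start, end = end)
  }
  contract <- function(start, end) {
    while (start <= end && !hmask[start] &&
           (cmask[start] || !is_buried(start, hmask, cs, ce, burial))) {
      start <- start + 1L
    }
    while (end >= start && !hmask[end] &&
           (cmask[end] || !is_buried(end, hmask, cs, ce, burial))) {
      end <- end - 1L
    }
    list(start = start, end = end)
  }

  span <- list(start = candidate$core_start, end = candidate$core_end)
  if (expand_first) {
    span <- expand(span$start, span$end)
    span <- contract(span$start, span$end)
  } else {
    span <- contract(span$start, span$end)
    if (span$start <= span$end) span <- expand(span$start, span$end)
  }

  no_tmd <- span$start > span$end
  structure(list(start = if (no_tmd) NA_integer_ else span$start,
                 end = if (no_tmd) NA_integer_ else span$end,
                 length = if (no_tmd) NA_integer_ else span$end - span$start + 1L,
                 core_start = candidate$core_start,
                 core_end = candidate$core_end,
                 cand_start = cs, cand_end = ce,
                 flank_left = candidate$flank_left,
                 flank_right = candidate$flank_right,
                 no_tmd = no_tmd),
            class = "tmd_span")
}

reverse_string <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Orient a refined span from the cytosolic to the exoplasmic side
#'
#' Position 1 of the oriented sequence is the cytosolic-most residue of the
#' refined span: for `N_CYTO` topology (N terminus in the cytosol) the span
#' is kept in sequence order; for `C_CYTO` it is reversed. The returned
#' `oriented_context` continues past the span through the exoplasmic side
#' of the protein, which aligned profile computations use to locate the
#' membrane/aqueous transition.
#'
#' @param span A `tmd_span` from [refine_edges()].
#' @param sequence The full sequence.
#' @param topology `"N_CYTO"` or `"C_CYTO"`; `"UNKNOWN"` is an error.
#' @return list with `oriented_sequence` (span residues only),
#'   `oriented_context`, `length`, and the span coordinates.
#' @export
orient_span <- function(span, sequence, topology) {
  topology <- match_topology(topology)
  if (topology == "UNKNOWN") {
    stop("cannot orient a span with UNKNOWN topology; supply N_CYTO or C_CYTO",
         call. = FALSE)
  }
  if (isTRUE(span$no_tmd)) {
    return(list(oriented_sequence = "", oriented_context = "",
                length = NA_integer_, start = NA_integer_, end = NA_integer_))
  }
  seg <- substr(sequence, span$start, span$end)
  if (topology == "N_CYTO") {
    list(oriented_sequence = seg,
         oriented_context = substr(sequence, span$start, nchar(sequence)),
         length = span$length, start = span$start, end = span$end)
  } else {
    list(oriented_sequence = reverse_string(seg),
         oriented_context = reverse_string(substr(sequence, 1L, span$end)),
         length = span$length, start = span$start, end = span$end)
  }
}

#' Detect the TMD of a single sequence
#'
#' Composition of [rough_scan()], [attach_flanks()], [refine_edges()] and
#' [orient_span()]; fully deterministic.
#'
#' @param sequence Amino-acid string.
#' @param topology `"N_CYTO"` or `"C_CYTO"`.
#' @param config A [tmd_config()].
#' @return list with the refined span, oriented sequences, `length`,
#'   `candidate_sequence` (TMD plus flanks, used for redundancy
#'   clustering), and `no_tmd`.
#' @export
detect_tmd <- function(sequence, topology, config = tmd_config()) {
  scale <- get_scale(config$scale,
                     hydrophobic_threshold = config$hydrophobic_threshold)
  core <- rough_scan(sequence, scale, window = config$window)
  cand <- attach_flanks(core, sequence, max_flank = config$max_flank)
  span <- refine_edges(cand, sequence, scale, burial = config$burial,
                       charged = config$charged,
                       expand_first = config$expand_first)
  ori <- orient_span(span, sequence, topology)
  c(span[c("start", "end", "length", "core_start", "core_end",
           "cand_start", "cand_end", "flank_left", "flank_right", "no_tmd")],
    ori[c("oriented_sequence", "oriented_context")],
    list(candidate_sequence = substr(sequence, span$cand_start, span$cand_end),
         scale = config$scale))
}

#' Detect TMDs for a set of annotated records
#'
#' @param records A protein record set with topology annotations.
#' @param config A [tmd_config()].
#' @param lenient When FALSE (default), a record with UNKNOWN topology is
#'   an error; when TRUE such records are kept with flag
#'   `unknown_topology` and excluded from downstream statistics, with a
#'   warning giving the count.
#' @return A `tmd_table`: a data.frame with one row per input record and
#'   columns `id`, `group`, `start`, `end`, `length`, `oriented_sequence`,
#'   `scale`, `flags`, plus bookkeeping columns (`oriented_context`,
#'   `candidate_sequence`, core/candidate coordinates) used by profile and
#'   clustering functions. Records in which no hydrophobic residue
#'   survives refinement carry flag `no_tmd`.
#' @examples
#' sim <- generate_group(5, length_mean = 22, length_sd = 3, seed = 1,
#'                       group = "demo")
#' tab <- detect_tmds(sim$records)
#' tab[, c("id", "start", "end", "length")]
#' @export
detect_tmds <- function(records, config = tmd_config(), lenient = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  unknown <- records$topology == "UNKNOWN"
  if (any(unknown) && !lenient) {
    stop("record(s) with UNKNOWN topology: ",
         paste(records$id[unknown], collapse = ", "),
         " (use lenient = TRUE to skip them)", call. = FALSE)
  }
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    if (unknown[i]) {
      rows[[i]] <- data.frame(
        id = records$id[i], group = records$group[i],
        start = NA_integer_, end = NA_integer_, length = NA_integer_,
        oriented_sequence = "", scale = config$scale,
        flags = "unknown_topology", oriented_context = "",
        candidate_sequence = "", core_start = NA_integer_,
        core_end = NA_integer_, cand_start = NA_integer_,
        cand_end = NA_integer_, flank_left = NA_integer_,
        flank_right = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    d <- detect_tmd(records$sequence[i], records$topology[i], config)
    rows[[i]] <- data.frame(
      id = records$id[i], group = records$group[i],
      start = d$start, end = d$end, length = d$length,
      oriented_sequence = d$oriented_sequence, scale = d$scale,
      flags = if (d$no_tmd) "no_tmd" else "",
      oriented_context = d$oriented_context,
      candidate_sequence = d$candidate_sequence,
      core_start = d$core_start, core_end = d$core_end,
      cand_start = d$cand_start, cand_end = d$cand_end,
      flank_left = d$flank_left, flank_right = d$flank_right,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  n_skip <- sum(unknown)
  n_none <- sum(out$flags == "no_tmd")
  if (n_skip > 0L) {
    warning(n_skip, " record(s) skipped for UNKNOWN topology", call. = FALSE)
  }
  attr(out, "config") <- config
  attr(out, "counts") <- c(input = nrow(records), detected = nrow(records) -
                             n_skip - n_none, no_tmd = n_none,
                           unknown_topology = n_skip)
  class(out) <- c("tmd_table", "data.frame")
  out
}

#' @export
print.tmd_table <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("TMD table: %d record(s), %d with a detected span (scale %s)\n",
              counts[["input"]], counts[["detected"]], x$scale[1L]))
  print.data.frame(utils::head(
    x[, c("id", "group", "start", "end", "length", "oriented_sequence",
          "flags")], 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more row(s)\n")
  invisible(x)
}

#' @export
summary.tmd_table <- function(object, ...) {
  ok <- object$flags == ""
  lens <- object$length[ok]
  groups <- split(lens, object$group[ok])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    s <- group_summary(groups[[g]])
    data.frame(group = g, n = s$n, mean = round(s$mean, 2),
               sd = round(s$sd, 2), mode = s$mode)
  }))
  out
}

#' @export
plot.tmd_table <- function(x, ...) {
  ok <- x$flags == ""
  d <- length_distribution(x$length[ok])
  plot(d, ...)
}

#' Write a TMD table to TSV
#'
#' Writes the canonical eight columns
#' `id, group, start, end, length, oriented_sequence, scale, flags`
#' in that order (tab-separated, with header).
#'
#' @param x A `tmd_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tmd_table <- function(x, path) {
  cols <- c("id", "group", "start", "end", "length", "oriented_sequence",
            "scale", "flags")
  utils::write.table(as.data.frame(x)[cols], file = path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TMD table written by [write_tmd_table()]
#'
#' @param path Path to the TSV file.
#' @return A `tmd_table` (without the in-memory bookkeeping columns).
#' @export
read_tmd_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  tab$flags[is.na(tab$flags)] <- ""
  tab$oriented_sequence[is.na(tab$oriented_sequence)] <- ""
  attr(tab, "counts") <- c(input = nrow(tab),
                           detected = sum(tab$flags == ""),
                           no_tmd = sum(tab$flags == "no_tmd"),
                           unknown_topology = sum(tab$flags == "unknown_topology"))
  class(tab) <- c("tmd_table", "data.frame")
  tab
}
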