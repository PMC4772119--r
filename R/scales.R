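# Amino-acid alphabet used throughout: the 20 standard residues plus X
# (unknown), which scores 0 on every scale and classifies as hydrophilic.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# Residues treated as charged during edge refinement (never eligible for
# the buried-hydrophilic exception). H is included; override via tmd_config().
CHARGED_RESIDUES <- c("D", "E", "K", "R", "H")

#' Hydropathy scales
#'
#' Returns one of the two bundled hydropathy scales as a `hydropathy_scale`
#' object. Both are oriented so that hydrophobic residues score positive,
#' which makes windowed profiles cross zero at the aqueous/membrane
#' transition:
#'
#' * `"GES"` — the Goldman-Engelman-Steitz transfer free-energy scale
#'   (kcal/mol), thermodynamically derived.
#' * `"KD"` — the Kyte-Doolittle hydropathy index.
#'
#' The unknown residue X scores 0 and is therefore classified hydrophilic
#' under the default threshold of 0 (a score must be strictly greater than
#' the threshold to count as hydrophobic).
#'
#' The tables are shipped as versioned plain-text files under
#' `system.file("extdata/scales", package = "tmdscan")` and can be
#' overridden by supplying a custom `values` vector.
#'
#' @param name `"GES"` or `"KD"`.
#' @param hydrophobic_threshold Score above which a residue is classified
#'   hydrophobic. Default 0.
#' @param values Optional named numeric vector (21 entries, the 20 standard
#'   residues plus `X`) replacing the bundled values.
#' @return An object of class `hydropathy_scale`: a list with elements
#'   `name`, `values` (named numeric, 21 entries), `units`, and
#'   `hydrophobic_threshold`.
#' @examples
#' ges <- get_scale("GES")
#' ges$values[["L"]]
#' is_hydrophobic(ges, "D")
#' @export
get_scale <- function(name, hydrophobic_threshold = 0, values = NULL) {
  supported <- c(GES = "ges_v1.tsv", KD = "kd_v1.tsv")
  if (!is.character(name) || length(name) != 1L || !(name %in% names(supported))) {
    stop("unknown hydropathy scale ", deparse(substitute(name)),
         "; supported scales: ", paste(names(supported), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(values)) {
    path <- system.file("extdata", "scales", supported[[name]],
                        package = "tmdscan", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    values <- stats::setNames(tab$score, tab$residue)
  }
  new_hydropathy_scale(name = name, values = values,
                       units = if (name == "GES") "kcal/mol" else "index",
                       hydrophobic_threshold = hydrophobic_threshold)
}

new_hydropathy_scale <- function(name, values, units, hydrophobic_threshold) {
  values <- unlist(values)
  if (length(values) != 21L || !setequal(names(values), AA_ALPHABET)) {
    stop("a hydropathy scale needs exactly the 20 standard residues plus X; got: ",
         paste(sort(names(values)), collapse = ""), call. = FALSE)
  }
  structure(list(name = name,
                 values = values[AA_ALPHABET],
                 units = units,
                 hydrophobic_threshold = hydrophobic_threshold),
            class = "hydropathy_scale")
}

#' @export
print.hydropathy_scale <- function(x, ...) {
  cat(sprintf("Hydropathy scale %s (%s), hydrophobic threshold > %g\n",
              x$name, x$units, x$hydrophobic_threshold))
  print(round(sort(x$values, decreasing = TRUE), 2))
  invisible(x)
}

# Per-residue scores for a sequence string; errors on letters outside the
# alphabet so refinement never sees an undefined hydrophobicity class.
residue_scores <- function(sequence, scale) {
  stopifnot(inherits(scale, "hydropathy_scale"))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("sequence contains residues outside the supported alphabet (",
         paste(bad, collapse = ", "),
         "); allowed: 20 standard residues plus X", call. = FALSE)
  }
  unname(scale$values[chars])
}

#' Classify a residue as hydrophobic
#'
#' A residue is hydrophobic when its scale score is strictly greater than
#' the scale's `hydrophobic_threshold` (default 0). X scores 0 on both
#' bundled scales and is therefore hydrophilic.
#'
#' @param scale A `hydropathy_scale` from [get_scale()].
#' @param residue Single-letter residue code(s); vectorised.
#' @return Logical vector.
#' @export
is_hydrophobic <- function(scale, residue) {
  stopifnot(inherits(scale, "hydropathy_scale"))
  bad <- setdiff(unique(residue), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop("residue(s) not in alphabet: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(scale$values[residue] > scale$hydrophobic_threshold)
}

#' Windowed hydropathy profile of a sequence
#'
#' Score at position `i` is the arithmetic mean of the scale values of
#' residues `i .. i + window - 1` (left-anchored window), so the profile
#' has `nchar(sequence) - window + 1` positions.
#'
#' @param sequence Amino-acid string (uppercase, standard alphabet + X).
#' @param scale A `hydropathy_scale`.
#' @param window Window size in residues; default 18, the rough-scan
#'   window used for TMD detection.
#' @return An object of class `hydropathy_profile`: a data.frame with
#'   columns `position` (1-based start of the window) and `score`, with
#'   attributes `window` and `scale`.
#' @examples
#' p <- windowed_profile(strrep("L", 20), get_scale("GES"), window = 18)
#' p$score  # constant: every window averages leucines only
#' @export
windowed_profile <- function(sequence, scale, window = 18L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  n <- nchar(sequence)
  if (n < window) {
    stop(sprintf("sequence length (%d) is shorter than the window (%d)",
                 n, window), call. = FALSE)
  }
  s <- residue_scores(sequence, scale)
  cs <- c(0, cumsum(s))
  scores <- (cs[(window + 1L):(n + 1L)] - cs[1L:(n - window + 1L)]) / window
  structure(data.frame(position = seq_len(n - window + 1L), score = scores),
            window = window, scale = scale$name,
            class = c("hydropathy_profile", "data.frame"))
}
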