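resolve_scale <- function(scale, tmd = NULL) {
  if (inherits(scale, "hydropathy_scale")) return(scale)
  if (is.null(scale)) {
    scale <- if (!is.null(tmd) && "scale" %in% names(tmd)) tmd$scale[1L] else "GES"
  }
  get_scale(scale)
}

#' Mean hydropathy profile of aligned TMDs
#'
#' Records are aligned at position 1 = the cytosolic end of the refined
#' span (the orientation produced by detection). At each aligned position
#' the windowed hydropathy scores of all records covering that position are
#' averaged, and the coverage (number of contributing records) is reported.
#' The profile is computed on each record's `oriented_context` (span plus
#' the downstream exoplasmic residues) so the mean curve crosses the zero
#' threshold where the membrane ends, which is what the mode-length reading
#' ([profile_mode_length()]) measures.
#'
#' The default window is 1 (per-residue scores): averaging across records
#' already smooths the curve, and a left-anchored multi-residue window
#' shifts the apparent membrane boundary inward by roughly
#' `window * d / (h + d)` positions (h, d = typical hydrophobic and
#' hydrophilic score magnitudes), biasing the mode-length reading.
#'
#' @param tmd A `tmd_table`; rows with flags are ignored.
#' @param scale Scale name or `hydropathy_scale`; defaults to the scale the
#'   table was computed with.
#' @param window Smoothing window; default 1.
#' @return Object of class `tmd_profile`: data.frame with columns
#'   `position`, `mean_score`, `coverage`.
#' @export
mean_hydropathy_profile <- function(tmd, scale = NULL, window = 1L) {
  scale <- resolve_scale(scale, tmd)
  window <- as.integer(window)
  seqs <- tmd$oriented_context
  if (is.null(seqs)) seqs <- tmd$oriented_sequence
  seqs <- seqs[tmd$flags == ""]
  seqs <- seqs[nchar(seqs) >= window]
  if (length(seqs) == 0L) {
    stop("no usable records for a hydropathy profile", call. = FALSE)
  }
  maxp <- max(nchar(seqs)) - window + 1L
  total <- numeric(maxp)
  cover <- integer(maxp)
  for (s in seqs) {
    p <- windowed_profile(s, scale, window)$score
    idx <- seq_along(p)
    total[idx] <- total[idx] + p
    cover[idx] <- cover[idx] + 1L
  }
  structure(data.frame(position = seq_len(maxp), mean_score = total / cover,
                       coverage = cover),
            window = window, scale = scale$name,
            class = c("tmd_profile", "data.frame"))
}

#' @export
plot.tmd_profile <- function(x, xlab = "position (1 = cytosolic end)",
                             ylab = NULL, ...) {
  if (is.null(ylab)) {
    ylab <- sprintf("mean hydropathy (%s)", attr(x, "scale"))
  }
  plot(x$position, x$mean_score, type = "l", xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Mode TMD length read from a mean hydropathy profile
#'
#' The number of consecutive positions, starting at position 1 (the
#' cytosolic end), at which the mean profile is above the hydrophobic
#' threshold (0). On sets dominated by one span length this reading equals
#' the mode of the length distribution rather than its mean: the crossing
#' point of the averaged curve reflects the dominant sub-population, not
#' the outliers. An all-negative profile gives 0.
#'
#' @param profile A `tmd_profile` from [mean_hydropathy_profile()].
#' @param threshold Crossing threshold; default 0.
#' @return Integer length.
#' @export
profile_mode_length <- function(profile, threshold = 0) {
  pos <- profile$mean_score > threshold
  if (length(pos) == 0L || !pos[1L]) return(0L)
  rle(pos)$lengths[1L]
}

#' Per-position residue composition of aligned TMDs
#'
#' At each aligned position (1 = cytosolic end of the refined span) the
#' frequency of every residue among the records covering that position,
#' together with the aggregate hydrophobic-class frequency. Frequencies at
#' each position sum to 1 over covering records. Computed on the refined
#' span only.
#'
#' @param tmd A `tmd_table`; rows with flags are ignored.
#' @param scale Scale used for the hydrophobic classification; defaults to
#'   the table's scale.
#' @return list with `freq` (positions x 21 residue matrix),
#'   `hydrophobic` (per-position hydrophobic-class frequency), and
#'   `coverage`.
#' @export
abundance_profile <- function(tmd, scale = NULL) {
  scale <- resolve_scale(scale, tmd)
  seqs <- tmd$oriented_sequence[tmd$flags == ""]
  if (length(seqs) == 0L) stop("no usable records", call. = FALSE)
  maxp <- max(nchar(seqs))
  freq <- matrix(0, nrow = maxp, ncol = length(AA_ALPHABET),
                 dimnames = list(NULL, AA_ALPHABET))
  cover <- integer(maxp)
  for (s in seqs) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in seq_along(chars)) freq[p, chars[p]] <- freq[p, chars[p]] + 1
    cover[seq_along(chars)] <- cover[seq_along(chars)] + 1L
  }
  freq <- freq / cover
  hydro <- as.vector(freq %*% as.numeric(is_hydrophobic(scale, AA_ALPHABET)))
  list(freq = freq, hydrophobic = hydro, coverage = cover)
}

#' Write a profile (hydropathy or abundance) as a TSV matrix
#'
#' @param x A `tmd_profile` data.frame or the list returned by
#'   [abundance_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  if (is.data.frame(x)) {
    utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    out <- data.frame(position = seq_along(x$coverage), x$freq,
                      hydrophobic = x$hydrophobic, coverage = x$coverage,
                      check.names = FALSE)
    utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
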