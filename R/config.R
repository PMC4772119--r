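#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline in one place so
#' sensitivity analyses are scriptable. Defaults are the method's
#' canonical settings:
#'
#' * `scale = "GES"` — thermodynamic scale used for detection; `"KD"`
#'   available as a scale-independence check.
#' * `window = 18` residues — rough-scan window.
#' * `max_flank = 8` residues per side, giving a candidate region of
#'   18–34 residues (26 minimum whenever one full flank is available).
#' * `hydrophobic_threshold = 0` — profile zero-crossing convention.
#' * `burial = 3` — a hydrophilic residue at a span edge is retained only
#'   when bracketed by at least this many contiguous hydrophobic residues
#'   on each side.
#' * `charged = c("D","E","K","R","H")` — residues never eligible for the
#'   buried exception.
#' * `identity_threshold = 0.30` — redundancy clustering cut-off.
#' * `kldm_log_base = exp(1)` — natural log in KL divergences.
#' * `expand_first = TRUE` — refinement order (expand, then contract).
#'
#' @param scale,window,max_flank,hydrophobic_threshold,burial,charged
#'   Detection parameters, see above.
#' @param identity_threshold,kldm_log_base,expand_first Other parameters,
#'   see above.
#' @param seed Optional integer seed for the synthetic generator.
#' @return A list of class `tmd_config`.
#' @export
tmd_config <- function(scale = "GES", window = 18L, max_flank = 8L,
                       hydrophobic_threshold = 0, burial = 3L,
                       charged = CHARGED_RESIDUES,
                       identity_threshold = 0.30,
                       kldm_log_base = exp(1),
                       expand_first = TRUE,
                       seed = NULL) {
  window <- as.integer(window)
  max_flank <- as.integer(max_flank)
  burial <- as.integer(burial)
  if (window < 1L || max_flank < 0L || burial < 1L ||
      identity_threshold < 0 || identity_threshold > 1 || kldm_log_base <= 1) {
    stop("invalid configuration value(s): window >= 1, max_flank >= 0, ",
         "burial >= 1, identity_threshold in [0,1], kldm_log_base > 1",
         call. = FALSE)
  }
  structure(list(scale = scale, window = window, max_flank = max_flank,
                 hydrophobic_threshold = hydrophobic_threshold,
                 burial = burial, charged = charged,
                 identity_threshold = identity_threshold,
                 kldm_log_base = kldm_log_base,
                 expand_first = expand_first, seed = seed),
            class = "tmd_config")
}

#' @export
print.tmd_config <- function(x, ...) {
  cat("TMD analysis configuration:\n")
  for (k in setdiff(names(x), "charged")) {
    cat(sprintf("  %-21s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  }
  cat(sprintf("  %-21s %s\n", "charged", paste(x$charged, collapse = "")))
  invisible(x)
}
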