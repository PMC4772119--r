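#' Summary statistics of a group of TMD lengths
#'
#' Mean, sample (n-1) standard deviation, size, and mode of a vector of
#' integer TMD lengths. With a single observation the standard deviation is
#' reported as `NA` (absent). Report formatting rounds to 2 decimals;
#' the returned values are full precision.
#'
#' @param lengths Integer TMD lengths, n >= 1.
#' @return list with `mean`, `sd`, `n`, `mode`.
#' @examples
#' group_summary(c(30, 28, 30, 25))  # mean 28.25, sd 2.36
#' @export
group_summary <- function(lengths) {
  lengths <- check_lengths(lengths)
  list(mean = mean(lengths),
       sd = if (length(lengths) > 1L) stats::sd(lengths) else NA_real_,
       n = length(lengths),
       mode = distribution_mode(lengths))
}

check_lengths <- function(lengths) {
  lengths <- lengths[!is.na(lengths)]
  if (length(lengths) == 0L) stop("empty length vector", call. = FALSE)
  if (any(lengths != round(lengths)) || any(lengths < 1)) {
    stop("TMD lengths must be positive integers", call. = FALSE)
  }
  as.integer(lengths)
}

distribution_mode <- function(lengths) {
  counts <- table(lengths)
  # ties broken towards the smallest length
  as.integer(names(counts)[which.max(counts)])
}

#' Integer histogram of TMD lengths
#'
#' @param lengths Integer TMD lengths, n >= 1.
#' @return Object of class `length_distribution`: list with `counts`
#'   (named integer vector over observed lengths), `prob` (counts/n), `n`,
#'   `mean`, `sd` (`NA` when n = 1), and `mode` (most frequent length,
#'   ties towards the smallest).
#' @export
length_distribution <- function(lengths) {
  lengths <- check_lengths(lengths)
  tab <- table(lengths)
  counts <- stats::setNames(as.integer(tab), names(tab))
  s <- group_summary(lengths)
  structure(list(counts = counts, prob = counts / s$n, n = s$n,
                 mean = s$mean, sd = s$sd, mode = s$mode),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  sd_txt <- if (is.na(x$sd)) "sd absent (n = 1)" else sprintf("sd %.2f", x$sd)
  cat(sprintf("TMD length distribution: n = %d, mean %.2f, %s, mode %d\n",
              x$n, x$mean, sd_txt, x$mode))
  print(x$counts)
  invisible(x)
}

#' @export
plot.length_distribution <- function(x, xlab = "TMD length (residues)",
                                     ylab = "frequency", ...) {
  support <- as.integer(names(x$counts))
  full <- seq(min(support), max(support))
  y <- stats::setNames(numeric(length(full)), full)
  y[names(x$prob)] <- x$prob
  graphics::barplot(y, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Welch's two-sample t-test for TMD lengths
#'
#' Two-tailed heteroscedastic (unequal-variance) t-test, computed by
#' [stats::t.test()] with Welch-Satterthwaite degrees of freedom. The
#' degenerate case where both samples are constant with equal means is
#' reported as t = 0, p = 1 with a flag instead of an error; constant
#' samples with different means are rejected (no finite statistic exists).
#'
#' @param x,y Numeric vectors, each with at least two observations.
#' @return list with `t`, `df`, `p` (two-tailed), and `flag` (`""` or
#'   `"degenerate"`).
#' @export
welch_ttest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("welch_ttest needs at least two observations per sample", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = NA_real_, p = 1, flag = "degenerate"))
    }
    stop("both samples are constant with different means; ",
         "Welch statistic is undefined", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, flag = "")
}

#' Trim two length histograms to their common nonzero support
#'
#' KL divergence involves log(p/q) and fails on zero entries, so before
#' comparison both distributions are restricted to the lengths with nonzero
#' count in *both*, and each trimmed vector is renormalised to sum to 1
#' (without renormalisation the result would not be a divergence between
#' probability distributions).
#'
#' @param p1,p2 `length_distribution` objects or raw integer length
#'   vectors.
#' @return list with `p1`, `p2` (named probability vectors over the common
#'   support, each summing to 1) and `support` (integer lengths kept).
#' @export
trim_zero_support <- function(p1, p2) {
  d1 <- as_length_distribution(p1)
  d2 <- as_length_distribution(p2)
  support <- intersect(names(d1$counts), names(d2$counts))
  if (length(support) == 0L) {
    stop("non-overlapping distributions: no common nonzero length support",
         call. = FALSE)
  }
  support <- as.character(sort(as.integer(support)))
  q1 <- d1$counts[support] / sum(d1$counts[support])
  q2 <- d2$counts[support] / sum(d2$counts[support])
  list(p1 = q1, p2 = q2, support = as.integer(support))
}

as_length_distribution <- function(x) {
  if (inherits(x, "length_distribution")) x else length_distribution(x)
}

#' Kullback-Leibler divergence of TMD length distributions (KLDM)
#'
#' Directed divergence sum(p1 * log(p1 / p2)) over the zero-trimmed,
#' renormalised common support (see [trim_zero_support()]). Natural
#' logarithm by default. Asymmetric: `kldm(x, y)` generally differs from
#' `kldm(y, x)`; see [kldm_symmetric()].
#'
#' @param p1,p2 `length_distribution` objects or raw integer length
#'   vectors; `p1` is the base distribution.
#' @param log_base Base of the logarithm; default natural.
#' @return Non-negative divergence value.
#' @export
kldm <- function(p1, p2, log_base = exp(1)) {
  tr <- trim_zero_support(p1, p2)
  sum(tr$p1 * log(tr$p1 / tr$p2, base = log_base))
}

#' Symmetric KLDM
#'
#' Average of the two directed divergences:
#' `(kldm(p1, p2) + kldm(p2, p1)) / 2`.
#'
#' @inheritParams kldm
#' @return Non-negative symmetric divergence.
#' @export
kldm_symmetric <- function(p1, p2, log_base = exp(1)) {
  (kldm(p1, p2, log_base) + kldm(p2, p1, log_base)) / 2
}

#' Root-mean-square TMD-length difference from the plasma membrane
#'
#' For each organelle-associated protein, the difference between its TMD
#' length and the mean plasma-membrane (PM) TMD length of the same species
#' is taken; the default `"rms"` variant returns
#' `sqrt(mean(diff^2))` over all organelle proteins, and the `"sum"`
#' variant returns `sqrt(sum(diff^2))` (both readings of a
#' root-of-squared-differences summary are exposed).
#'
#' @param organelle data.frame with columns `species` and `length`.
#' @param pm data.frame with columns `species` and `length` for
#'   plasma-membrane proteins; every species in `organelle` must appear.
#' @param variant `"rms"` (default) or `"sum"`.
#' @return Non-negative value.
#' @export
rms_pm_difference <- function(organelle, pm, variant = c("rms", "sum")) {
  variant <- match.arg(variant)
  stopifnot(all(c("species", "length") %in% names(organelle)),
            all(c("species", "length") %in% names(pm)))
  missing <- setdiff(unique(organelle$species), unique(pm$species))
  if (length(missing) > 0L) {
    stop("species without plasma-membrane records: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pm_mean <- tapply(pm$length, pm$species, mean)
  diffs <- organelle$length - pm_mean[as.character(organelle$species)]
  if (variant == "rms") sqrt(mean(diffs^2)) else sqrt(sum(diffs^2))
}

#' Compare the TMD-length distributions of two groups
#'
#' Combines the group summaries, Welch t-test, and directed plus symmetric
#' KLDM for two groups of lengths.
#'
#' @param x,y Integer length vectors (each n >= 2).
#' @param labels Character vector of two group labels, used in printing.
#' @param log_base Log base for KLDM.
#' @return Object of class `tmd_comparison`: list with `groups` (per-group
#'   `n`, `mean`, `sd`, `mode`), `t_stat`, `df`, `p_value`, `kldm_xy`,
#'   `kldm_yx`, `kldm_sym`, and `trimmed_support`.
#' @examples
#' viral <- viral_tmd_lengths()
#' pm <- viral$tmd_length[viral$group == "PM"]
#' cme <- viral$tmd_length[viral$group == "CME"]
#' compare_groups(pm, cme, labels = c("PM", "CME"))
#' @export
compare_groups <- function(x, y, labels = c("x", "y"), log_base = exp(1)) {
  x <- check_lengths(x); y <- check_lengths(y)
  tt <- welch_ttest(x, y)
  # distributions with no common length support have no finite divergence;
  # report NA with a flag rather than aborting the whole comparison
  tr <- tryCatch(trim_zero_support(x, y), error = function(e) NULL)
  if (is.null(tr)) {
    kl <- list(xy = NA_real_, yx = NA_real_, sym = NA_real_)
    support <- integer(0)
    flag <- paste(c(tt$flag[nzchar(tt$flag)], "non-overlapping distributions"),
                  collapse = "; ")
  } else {
    kl <- list(xy = kldm(x, y, log_base), yx = kldm(y, x, log_base),
               sym = kldm_symmetric(x, y, log_base))
    support <- tr$support
    flag <- tt$flag
  }
  structure(list(
    groups = stats::setNames(list(group_summary(x), group_summary(y)), labels),
    t_stat = tt$t, df = tt$df, p_value = tt$p, flag = flag,
    kldm_xy = kl$xy, kldm_yx = kl$yx, kldm_sym = kl$sym,
    trimmed_support = support), class = "tmd_comparison")
}

#' @export
print.tmd_comparison <- function(x, ...) {
  cat("TMD length comparison\n")
  for (g in names(x$groups)) {
    s <- x$groups[[g]]
    sd_txt <- if (is.na(s$sd)) "NA" else sprintf("%.2f", s$sd)
    cat(sprintf("  %-12s n = %3d  mean %.2f +/- %s  mode %d\n",
                g, s$n, s$mean, sd_txt, s$mode))
  }
  cat(sprintf("  Welch t = %.3f (df %.1f), two-tailed p = %.4g%s\n",
              x$t_stat, if (is.na(x$df)) NA else x$df, x$p_value,
              if (nzchar(x$flag)) paste0(" [", x$flag, "]") else ""))
  cat(sprintf("  KLDM %s->%s = %.4f, %s->%s = %.4f, symmetric = %.4f\n",
              names(x$groups)[1], names(x$groups)[2], x$kldm_xy,
              names(x$groups)[2], names(x$groups)[1], x$kldm_yx, x$kldm_sym))
  cat("  trimmed support:", paste(x$trimmed_support, collapse = " "), "\n")
  invisible(x)
}
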