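# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

HYDROPHOBIC_ALPHABET <- c("L", "I", "V", "F", "M", "A")
# NOTE: S is excluded from the hydrophilic set although it is a polar
# residue: it scores +0.6 kcal/mol on the GES scale, so planting it in a
# flank would break the invariant that the planted run is the unique
# maximal hydrophobic stretch. All residues below are strictly negative on
# both bundled scales.
HYDROPHILIC_ALPHABET <- c("D", "E", "K", "R", "N", "Q")

.plant <- function(length, flank, hydrophobic_alphabet, hydrophilic_alphabet) {
  length <- as.integer(length)
  flank <- as.integer(flank)
  left <- paste(sample(hydrophilic_alphabet, flank, replace = TRUE), collapse = "")
  run <- paste(sample(hydrophobic_alphabet, length, replace = TRUE), collapse = "")
  right <- paste(sample(hydrophilic_alphabet, flank, replace = TRUE), collapse = "")
  list(sequence = paste0(left, run, right),
       true_start = flank + 1L, true_end = flank + length,
       true_length = as.integer(length))
}

#' Generate one sequence with a planted TMD
#'
#' Builds `hydrophilic flank + hydrophobic run + hydrophilic flank`; the
#' run is the unique maximal stretch of hydrophobic residues, so its
#' coordinates are ground truth for detection. Deterministic for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param length Run length in residues, in `[5, 40]`.
#' @param flank_hydrophilic_len Flank length per side; must be at least
#'   half the 18-residue scan window (>= 9). Default 12.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param hydrophobic_alphabet,hydrophilic_alphabet Disjoint residue sets
#'   to draw the run and the flanks from.
#' @return list with `sequence` and `truth` (`true_start`, `true_end`,
#'   `true_length`, 1-based inclusive).
#' @export
plant_tmd <- function(length, flank_hydrophilic_len = 12L, seed = NULL,
                      hydrophobic_alphabet = HYDROPHOBIC_ALPHABET,
                      hydrophilic_alphabet = HYDROPHILIC_ALPHABET) {
  if (length < 5L || length > 40L) {
    stop("planted TMD length must be in [5, 40]", call. = FALSE)
  }
  if (flank_hydrophilic_len < 9L) {
    stop("flank length must be at least half the scan window (>= 9)",
         call. = FALSE)
  }
  if (length(intersect(hydrophobic_alphabet, hydrophilic_alphabet)) > 0L) {
    stop("hydrophobic and hydrophilic alphabets must be disjoint", call. = FALSE)
  }
  p <- with_seed(seed, .plant(length, flank_hydrophilic_len,
                              hydrophobic_alphabet, hydrophilic_alphabet))
  list(sequence = p$sequence,
       truth = list(true_start = p$true_start, true_end = p$true_end,
                    true_length = p$true_length))
}

#' Generate a group of records with planted TMDs
#'
#' Truth lengths are drawn from a rounded normal distribution (matching the
#' unimodal length distributions observed for organelle protein sets) and
#' clipped to `[8, 34]`; flank lengths vary between 10 and 14 residues and
#' topologies alternate between N_CYTO and C_CYTO so both orientation
#' branches are exercised. Fully deterministic per seed.
#'
#' @param n Number of records.
#' @param length_mean,length_sd Normal parameters for the planted lengths.
#' @param seed Integer seed.
#' @param group Group label written on each record.
#' @param hydrophobic_alphabet,hydrophilic_alphabet Passed to the planter.
#' @return list with `records` (a protein record set) and `truth`
#'   (data.frame: `id`, `true_start`, `true_end`, `true_length`,
#'   `topology`, `group`).
#' @export
generate_group <- function(n, length_mean, length_sd, seed,
                           group = "synthetic",
                           hydrophobic_alphabet = HYDROPHOBIC_ALPHABET,
                           hydrophilic_alphabet = HYDROPHILIC_ALPHABET) {
  if (n < 1L || length_sd < 0 || length_mean < 5) {
    stop("invalid generator parameters: need n >= 1, length_sd >= 0, ",
         "length_mean >= 5", call. = FALSE)
  }
  with_seed(seed, {
    lens <- pmin(pmax(round(stats::rnorm(n, length_mean, length_sd)), 8L), 34L)
    flanks <- sample(10:14, n, replace = TRUE)
    ids <- sprintf("%s_%04d", group, seq_len(n))
    topo <- rep_len(c("N_CYTO", "C_CYTO"), n)
    plants <- lapply(seq_len(n), function(i) {
      .plant(lens[i], flanks[i], hydrophobic_alphabet, hydrophilic_alphabet)
    })
    records <- protein_records(
      id = ids,
      sequence = vapply(plants, `[[`, "", "sequence"),
      group = group, topology = topo)
    truth <- data.frame(
      id = ids,
      true_start = vapply(plants, `[[`, 0L, "true_start"),
      true_end = vapply(plants, `[[`, 0L, "true_end"),
      true_length = vapply(plants, `[[`, 0L, "true_length"),
      topology = topo, group = group, stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Hand-built edge cases for the refinement rules
#'
#' A fixed record set exercising each refinement rule, with the expected
#' refined span for every case:
#'
#' * `interior` — a hydrophilic residue in the middle of the core is
#'   retained (edges are not affected).
#' * `edge_chop` — charged residues at the span edge are chopped.
#' * `buried` — an uncharged hydrophilic residue bracketed by 3+3
#'   hydrophobic residues at the expansion boundary is retained and
#'   expansion continues through it.
#' * `charged_block` — a charged residue blocks expansion even when
#'   hydrophobic residues lie beyond it.
#' * `terminus` — a TMD at the sequence start has its left flank truncated
#'   to 0 residues.
#'
#' @return list with `records` (protein record set, all N_CYTO) and
#'   `expected` (data.frame: `id`, `exp_start`, `exp_end`, `exp_length`).
#' @export
edge_case_suite <- function() {
  d <- function(k) strrep("D", k)
  l <- function(k) strrep("L", k)
  seqs <- c(
    interior = paste0(d(10), l(8), "D", l(9), d(10)),
    edge_chop = paste0(d(10), l(16), d(10)),
    buried = paste0(d(7), l(3), "N", l(3), l(18), d(10)),
    charged_block = paste0(d(10), l(18), "K", l(3), d(8)),
    terminus = paste0(l(18), d(12)))
  records <- protein_records(id = names(seqs), sequence = unname(seqs),
                             group = "edge_case", topology = "N_CYTO")
  expected <- data.frame(
    id = names(seqs),
    exp_start = c(11L, 11L, 8L, 11L, 1L),
    exp_end = c(28L, 26L, 32L, 28L, 18L),
    exp_length = c(18L, 16L, 25L, 18L, 18L),
    stringsAsFactors = FALSE)
  list(records = records, expected = expected)
}

#' Write a simulated dataset to disk
#'
#' Writes `<prefix>.fasta`, `<prefix>_annotations.tsv` (id, group,
#' topology) and `<prefix>_truth.tsv` so a simulation can be re-consumed
#' through the standard file interfaces.
#'
#' @param sim Output of [generate_group()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, paste0(prefix, ".fasta")),
             annotations = file.path(dir, paste0(prefix, "_annotations.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_fasta(sim$records, paths[["fasta"]])
  utils::write.table(sim$records[, c("id", "group", "topology")],
                     paths[["annotations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
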