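TOPOLOGY_LEVELS <- c("N_CYTO", "C_CYTO", "UNKNOWN")

#' Construct a set of protein records
#'
#' A protein record set is a plain data.frame with columns `id`,
#' `sequence`, `group`, and `topology`. Sequences are uppercased and
#' validated against the 20-letter amino-acid alphabet plus X; ambiguous
#' or non-standard residues (B, Z, U, J, O, *) are rejected rather than
#' silently rescored, because edge refinement needs a defined
#' hydrophobicity class for every residue.
#'
#' @param id Character vector of unique record identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @param group Group label per record (organism, organelle, pathway, ...).
#' @param topology `"N_CYTO"` (N terminus cytosolic), `"C_CYTO"`, or
#'   `"UNKNOWN"`.
#' @return data.frame with one row per record.
#' @export
protein_records <- function(id, sequence, group = NA_character_,
                            topology = "UNKNOWN") {
  id <- as.character(id)
  sequence <- toupper(gsub("[[:space:]]", "", as.character(sequence)))
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(sequence)) {
    bad <- setdiff(unique(strsplit(sequence[i], "")[[1L]]), AA_ALPHABET)
    if (length(bad) > 0L) {
      stop("record ", id[i], " contains unsupported residue(s): ",
           paste(bad, collapse = ", "),
           " (allowed: 20 standard residues plus X)", call. = FALSE)
    }
  }
  topology <- match_topology(rep_len(as.character(topology), length(id)))
  data.frame(id = id, sequence = sequence,
             group = rep_len(as.character(group), length(id)),
             topology = topology, stringsAsFactors = FALSE)
}

match_topology <- function(x) {
  bad <- setdiff(unique(x), TOPOLOGY_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown topology value(s): ", paste(bad, collapse = ", "),
         "; allowed values: ", paste(TOPOLOGY_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read protein sequences from a FASTA file
#'
#' Parsing is done with [Biostrings::readAAStringSet()]; a light structural
#' pre-scan produces line-numbered errors for files that are not
#' FASTA-shaped (sequence data before the first header, or no records at
#' all). Sequences are uppercased; record order is preserved; ids are the
#' first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return A protein record set (see [protein_records()]) with `group` NA
#'   and `topology` `"UNKNOWN"`; annotations are attached separately with
#'   [attach_annotations()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    stop("empty dataset: no FASTA records in ", path, call. = FALSE)
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA in ", path, ": line ", first,
         " contains sequence data before any '>' header", call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    stop("empty dataset: no FASTA records in ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  protein_records(id = ids, sequence = as.character(set))
}

#' Write protein records to a FASTA file
#'
#' @param records A protein record set.
#' @param path Output path.
#' @param width Line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::AAStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read a record annotation table
#'
#' The table is a UTF-8 TSV with header columns `id`, `group`, and
#' `topology`; it supplies the membrane topology (which terminus faces the
#' cytosol) that an external topology predictor would otherwise provide.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `id`, `group`, `topology` (validated).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  required <- c("id", "group", "topology")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("annotation table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tab$id <- as.character(tab$id)
  if (anyDuplicated(tab$id)) {
    stop("duplicate id(s) in annotation table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  tab$topology <- match_topology(as.character(tab$topology))
  tab[required]
}

#' Attach group and topology annotations to sequence records
#'
#' @param records A protein record set from [read_fasta()] or
#'   [protein_records()].
#' @param annotations Annotation table from [read_annotations()].
#' @param strict When TRUE (default) every record id must be annotated;
#'   when FALSE, unannotated records keep `group` NA and topology
#'   `"UNKNOWN"`.
#' @return The record set with `group` and `topology` filled in; sequences
#'   and record count are unchanged.
#' @export
attach_annotations <- function(records, annotations, strict = TRUE) {
  idx <- match(records$id, annotations$id)
  if (strict && anyNA(idx)) {
    stop("no annotation for record id(s): ",
         paste(records$id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  hit <- !is.na(idx)
  records$group[hit] <- annotations$group[idx[hit]]
  records$topology[hit] <- annotations$topology[idx[hit]]
  records$topology[!hit] <- "UNKNOWN"
  records
}

#' Bundled viral TMD length table
#'
#' A curated table of single-span TMD lengths reported for viral membrane
#' proteins whose host-cell entry pathway (animal viruses: PM, CME, MPE,
#' CAME) or replication site (plant viruses: ER, Mitochondria, Peroxisome,
#' Chloroplast, Nucleus) is experimentally established. Used as a
#' desk-scale input for the comparison statistics.
#'
#' @return data.frame with columns `virus`, `protein`, `host`
#'   (`"animal"`/`"plant"`), `group`, and `tmd_length`.
#' @export
viral_tmd_lengths <- function() {
  path <- system.file("extdata", "viral_tmd_lengths.tsv",
                      package = "tmdscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}
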