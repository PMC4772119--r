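#' Pairwise sequence identity from a global alignment
#'
#' Needleman-Wunsch global alignment with match score 1, mismatch 0, and a
#' unit penalty per gap column. Identity is the number of identical aligned
#' positions divided by the alignment length (aligned pairs plus gap
#' columns). Optimal alignments are not always unique; among co-optimal
#' alignments identity is strictly increasing in the number of gap columns,
#' so the value is evaluated at the maximum-gap co-optimal alignment. This
#' makes the measure well-defined and symmetric, and errs towards merging
#' during redundancy removal. For score S, gap columns G and sequence
#' lengths nA, nB: identity = 2(S + G) / (nA + nB + G).
#'
#' @param a,b Non-empty amino-acid strings.
#' @param match,mismatch,gap Alignment scoring constants (gap is the
#'   penalty per gap column, applied as -gap).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("LLVIF", "LLVIF")  # 1
#' pairwise_identity("LLLL", "DDDD")    # 0
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("pairwise_identity requires two non-empty sequences", call. = FALSE)
  }
  al <- nw_align(a, b, match = match, mismatch = mismatch, gap = gap)
  2 * (al$score + al$gaps) / (nchar(a) + nchar(b) + al$gaps)
}

# Global alignment DP returning the optimal score and, among co-optimal
# alignments, the maximum number of gap columns.
nw_align <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  M <- matrix(-Inf, n + 1L, m + 1L)  # best score
  G <- matrix(0L, n + 1L, m + 1L)    # max gap columns among optimal
  M[1L, ] <- -gap * (0L:m)
  M[, 1L] <- -gap * (0L:n)
  G[1L, ] <- 0L:m
  G[, 1L] <- 0L:n
  for (i in seq_len(n)) {
    sub <- ifelse(y == x[i], match, mismatch)
    for (j in seq_len(m)) {
      diag <- M[i, j] + sub[j]
      up <- M[i, j + 1L] - gap
      left <- M[i + 1L, j] - gap
      best <- max(diag, up, left)
      g <- -1L
      if (diag >= best) g <- max(g, G[i, j])
      if (up >= best) g <- max(g, G[i, j + 1L] + 1L)
      if (left >= best) g <- max(g, G[i + 1L, j] + 1L)
      M[i + 1L, j + 1L] <- best
      G[i + 1L, j + 1L] <- g
    }
  }
  list(score = M[n + 1L, m + 1L], gaps = G[n + 1L, m + 1L])
}

#' Cluster sequences by single-linkage identity
#'
#' Two records share a cluster iff they are connected by a chain of pairs
#' whose identity exceeds `threshold`. Intended to be run on the TMD region
#' plus flanking residues (the `candidate_sequence` column of a
#' `tmd_table`), mirroring redundancy removal at <30% identity. Each
#' cluster's representative is its longest member, ties broken by the
#' lexicographically smallest id.
#'
#' @param x A `tmd_table` (rows with flags are ignored) or a named
#'   character vector of sequences.
#' @param threshold Identity threshold; pairs with identity strictly
#'   greater than this are linked. Default 0.30.
#' @return Object of class `cluster_set`: list with `clusters` (list of id
#'   vectors, partitioning the input ids), `representatives` (one id per
#'   cluster), and `threshold`.
#' @export
cluster_tmds <- function(x, threshold = 0.30) {
  if (inherits(x, "tmd_table") || (is.data.frame(x) && "candidate_sequence" %in% names(x))) {
    keep <- x$flags == ""
    seqs <- stats::setNames(x$candidate_sequence[keep], x$id[keep])
  } else {
    seqs <- x
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("cluster_tmds needs uniquely named, non-empty sequence ids",
         call. = FALSE)
  }
  if (length(seqs) == 0L) stop("no sequences to cluster", call. = FALSE)
  n <- length(seqs)
  ids <- names(seqs)
  edges <- NULL
  if (n > 1L) {
    pairs <- utils::combn(n, 2L)
    link <- logical(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      link[k] <- pairwise_identity(seqs[[i]], seqs[[j]]) > threshold
    }
    edges <- pairs[, link, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && ncol(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(edges))
  }
  memb <- igraph::components(g)$membership
  # order clusters by first appearance in the input
  first <- tapply(seq_len(n), memb, min)
  ord <- order(first)
  clusters <- lapply(as.integer(names(first))[ord],
                     function(cl) ids[memb == cl])
  reps <- vapply(clusters, function(members) {
    lens <- nchar(seqs[members])
    cand <- members[lens == max(lens)]
    sort(cand)[1L]
  }, "")
  structure(list(clusters = clusters, representatives = reps,
                 threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("%d cluster(s) of %d sequence(s) at identity threshold %.2f\n",
              length(x$clusters), sum(sizes), x$threshold))
  cat("cluster sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Select one representative record per cluster
#'
#' @param clusters A `cluster_set` from [cluster_tmds()].
#' @param records Optional protein record set or `tmd_table` to subset.
#' @return If `records` is supplied, its rows for the representative ids
#'   (ordered by id); otherwise the sorted representative ids.
#' @export
select_representatives <- function(clusters, records = NULL) {
  stopifnot(inherits(clusters, "cluster_set"))
  reps <- sort(clusters$representatives)
  if (is.null(records)) return(reps)
  out <- records[match(reps, records$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write cluster assignments to TSV
#'
#' Columns: `cluster_id`, `member_id`, `is_representative`.
#'
#' @param clusters A `cluster_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  rows <- do.call(rbind, lapply(seq_along(clusters$clusters), function(k) {
    members <- clusters$clusters[[k]]
    data.frame(cluster_id = k, member_id = members,
               is_representative = members == clusters$representatives[k],
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
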