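# Independent oracles used to cross-check the package implementations.
# Each is deliberately written as direct brute force, structurally
# different from the code path it checks.

# Sliding window mean by explicit looping.
oracle_sliding_mean <- function(scores, window) {
  n <- length(scores)
  vapply(seq_len(n - window + 1L), function(i) {
    mean(scores[i:(i + window - 1L)])
  }, 0)
}

# Exhaustive argmax over all windows (first maximum wins).
oracle_best_window <- function(scores, window) {
  n <- length(scores)
  sums <- vapply(seq_len(n - window + 1L), function(i) {
    sum(scores[i:(i + window - 1L)])
  }, 0)
  which(sums >= max(sums) - 1e-9)[1L]
}

# Recursive memoised global alignment: optimal score (match 1, mismatch 0,
# unit gap) and the maximum number of gap columns among optimal alignments.
oracle_align <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  Smemo <- array(NA_real_, c(n + 1L, m + 1L))
  Gmemo <- array(NA_integer_, c(n + 1L, m + 1L))
  rec <- function(i, j) {  # best over suffixes x[i..n], y[j..m]
    if (!is.na(Smemo[i, j])) return(c(Smemo[i, j], Gmemo[i, j]))
    if (i > n && j > m) {
      res <- c(0, 0L)
    } else {
      cand <- list()
      if (i <= n && j <= m) {
        r <- rec(i + 1L, j + 1L)
        cand[[length(cand) + 1L]] <- c(r[1L] + as.numeric(x[i] == y[j]), r[2L])
      }
      if (i <= n) {
        r <- rec(i + 1L, j)
        cand[[length(cand) + 1L]] <- c(r[1L] - 1, r[2L] + 1L)
      }
      if (j <= m) {
        r <- rec(i, j + 1L)
        cand[[length(cand) + 1L]] <- c(r[1L] - 1, r[2L] + 1L)
      }
      scores <- vapply(cand, `[`, 0, 1L)
      best <- max(scores)
      gaps <- max(vapply(cand[scores >= best], `[`, 0, 2L))
      res <- c(best, gaps)
    }
    Smemo[i, j] <<- res[1L]
    Gmemo[i, j] <<- res[2L]
    res
  }
  r <- rec(1L, 1L)
  list(score = r[1L], gaps = as.integer(r[2L]),
       identity = 2 * (r[1L] + r[2L]) / (n + m + r[2L]))
}

# Transitive closure of a boolean adjacency matrix by repeated squaring,
# returning a cluster label per row.
oracle_closure_partition <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  labels <- integer(n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (labels[i] == 0L) {
      next_label <- next_label + 1L
      labels[reach[i, ]] <- next_label
    }
  }
  labels
}

# Partition comparison that ignores label names.
same_partition <- function(labels_a, labels_b) {
  n <- length(labels_a)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if ((labels_a[i] == labels_a[j]) != (labels_b[i] == labels_b[j])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Cluster-set -> per-id labels in a given id order.
cluster_labels <- function(cs, ids) {
  lab <- integer(length(ids))
  for (k in seq_along(cs$clusters)) {
    lab[ids %in% cs$clusters[[k]]] <- k
  }
  lab
}

# Closed-form Welch statistic / Satterthwaite df / two-tailed p.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Direct KL divergence of two probability vectors on an identical support.
oracle_kl <- function(p, q) sum(p * log(p / q))

# Intersect-trim-renormalise two raw length vectors, then directed KL.
oracle_kldm_raw <- function(x, y) {
  tx <- table(x); ty <- table(y)
  support <- intersect(names(tx), names(ty))
  p <- as.numeric(tx[support]); p <- p / sum(p)
  q <- as.numeric(ty[support]); q <- q / sum(q)
  oracle_kl(p, q)
}

# Random amino-acid string from a given alphabet (uses current RNG).
random_seq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                       "I", "K", "L", "M", "N", "P", "Q",
                                       "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
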