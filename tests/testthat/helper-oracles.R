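# Independent brute-force oracles used across the suite. These are kept
# deliberately naive and separate from the package's implementations.

# --- Affine-gap Smith-Waterman oracle (Gotoh), returning the optimal
# score and the set of (n_identical, alignment_length) pairs over ALL
# co-optimal local alignments, found by exhaustive traceback. A gap of
# length L costs open + L * ext.
sw_oracle <- function(a, b, submat, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (vertical)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a (horizontal)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[A[i], B[j]]
      M[i + 1, j + 1] <- max(0, M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
    }
  }
  best <- max(M)
  if (best == 0) {
    return(list(score = 0, alignments = list(c(0L, 0L))))
  }
  results <- new.env()
  results$set <- list()
  # recursive traceback over all co-optimal paths; state in {M, Ix, Iy}
  walk <- function(i, j, state, nid, len) {
    val <- switch(state, M = M[i + 1, j + 1], Ix = Ix[i + 1, j + 1],
                  Iy = Iy[i + 1, j + 1])
    if (state == "M" && val == 0) {
      # this cell can start the alignment...
      key <- paste(nid, len)
      results$set[[key]] <- c(nid, len)
      # ...but co-optimal paths may also extend through it (prefix score
      # dipping to exactly zero), as long as characters remain
      if (i > 0 && j > 0) {
        s <- submat[A[i], B[j]]
        add <- as.integer(A[i] == B[j])
        for (prev in c("M", "Ix", "Iy")) {
          pv <- switch(prev, M = M[i, j], Ix = Ix[i, j], Iy = Iy[i, j])
          if (pv + s == 0) walk(i - 1, j - 1, prev, nid + add, len + 1L)
        }
      }
      return(invisible())
    }
    if (state == "M") {
      s <- submat[A[i], B[j]]
      add <- as.integer(A[i] == B[j])
      for (prev in c("M", "Ix", "Iy")) {
        pv <- switch(prev, M = M[i, j], Ix = Ix[i, j], Iy = Iy[i, j])
        if (pv + s == val) walk(i - 1, j - 1, prev, nid + add, len + 1L)
      }
    } else if (state == "Ix") {
      if (M[i, j + 1] - open - ext == val) walk(i - 1, j, "M", nid, len + 1L)
      if (Ix[i, j + 1] - ext == val) walk(i - 1, j, "Ix", nid, len + 1L)
    } else {
      if (M[i + 1, j] - open - ext == val) walk(i, j - 1, "M", nid, len + 1L)
      if (Iy[i + 1, j] - ext == val) walk(i, j - 1, "Iy", nid, len + 1L)
    }
  }
  ends <- which(M == best, arr.ind = TRUE)
  for (r in seq_len(nrow(ends))) {
    walk(ends[r, 1] - 1L, ends[r, 2] - 1L, "M", 0L, 0L)
  }
  list(score = best, alignments = unname(results$set))
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# --- Connected-components oracle: transitive closure of the adjacency
# matrix by repeated boolean multiplication, then row-pattern grouping.
components_oracle <- function(vertices, edges) {
  n <- length(vertices)
  adj <- diag(TRUE, n)
  rownames(adj) <- colnames(adj) <- vertices
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      adj[edges[r, 1], edges[r, 2]] <- TRUE
      adj[edges[r, 2], edges[r, 1]] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  groups <- split(vertices, apply(adj, 1, paste, collapse = ""))
  unname(lapply(groups, sort))
}

# --- Sliding-window motif oracle via zero-width regex matches.
regex_motif_positions <- function(seq, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# --- Two-sided Fisher exact p by enumerating all tables with the
# observed margins and summing hypergeometric probabilities not larger
# than the observed one (with the conventional 1 + 1e-7 slack).
fisher_oracle <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Shared fixture: the 30-family contraction study, generated once per
# test run (alignment of ~170 proteins is the expensive step).
contraction_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      specs <- contraction_study_specs()
      pr <- generate_proteomes(specs, seed = 1)
      hits <- all_vs_all(pr$proteomes)
      cache <<- list(specs = specs, proteomes = pr$proteomes,
                     truth = pr$truth, hits = hits)
    }
    cache
  }
})

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G",
                                           "H", "I", "K", "L", "M", "N",
                                           "P", "Q", "R", "S", "T", "V",
                                           "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
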