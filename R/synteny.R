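# Synteny-cluster detection between two annotated genomes from
# reciprocal-best-hit (RBH) orthologs.
#
# A synteny cluster is a colinear chain of ortholog anchors: consecutive
# anchors are separated by at most `max_gap` intervening genes on each
# genome, and anchor positions are strictly monotone on both genomes
# (ascending, or descending on genome B for an inverted cluster).

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is retained iff b is a's best hit in the A-vs-B table and
#' a is b's best hit in the B-vs-A table, "best" meaning highest bitscore
#' with ties broken by lowest E-value, then lexicographic subject id. Each
#' gene therefore appears in at most one pair.
#'
#' @param hits_ab,hits_ba `hit_table` data frames for the two search
#'   directions (genome A queries vs B, and B queries vs A).
#' @return A data frame of `gene_a`, `gene_b`, `bitscore`.
#' @export
rbh_orthologs <- function(hits_ab, hits_ba) {
  best_of <- function(hits) {
    if (!nrow(hits)) {
      return(stats::setNames(character(0), character(0)))
    }
    o <- order(hits$query_id, -hits$bitscore, hits$evalue,
               hits$subject_id)
    h <- hits[o, , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
    stats::setNames(h$subject_id, h$query_id)
  }
  best_ab <- best_of(hits_ab)
  best_ba <- best_of(hits_ba)
  mutual <- names(best_ab)[best_ba[best_ab] == names(best_ab)]
  mutual <- mutual[!is.na(mutual)]
  if (!length(mutual)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      bitscore = numeric(0), stringsAsFactors = FALSE))
  }
  key <- paste(mutual, best_ab[mutual], sep = "\r")
  hk <- paste(hits_ab$query_id, hits_ab$subject_id, sep = "\r")
  bits <- vapply(key, function(k) max(hits_ab$bitscore[hk == k]), 0)
  out <- data.frame(gene_a = mutual, gene_b = unname(best_ab[mutual]),
                    bitscore = unname(bits), stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Positional gene order of an annotated genome
#'
#' @param genome An `annotated_genome`.
#' @return A data frame `gene_id`, `contig`, `index` where `index` is the
#'   1-based position of the gene along its contig (by start coordinate).
#' @export
gene_order <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  g <- genome$genes[order(genome$genes$contig, genome$genes$start), ,
                    drop = FALSE]
  g$index <- stats::ave(g$start, g$contig, FUN = seq_along)
  g[c("gene_id", "contig", "index")]
}

# Longest accepted chain among the anchors flagged `free`, or NULL.
# Anchors: data.frame with ai, bi (positional indices). Inverted chains
# need at least max(min_size, 3) anchors: a lone adjacent swapped pair is
# indistinguishable from a local transposition and carries no evidence of
# conserved order.
best_chain <- function(anchors, free, max_gap, min_size) {
  idx <- which(free)
  if (!length(idx)) return(NULL)
  best <- NULL
  for (dir in c(1L, -1L)) {
    need <- if (dir == 1L) min_size else max(min_size, 3L)
    ord <- idx[order(anchors$ai[idx])]
    n <- length(ord)
    len <- rep(1L, n); prev <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        da <- anchors$ai[ord[i]] - anchors$ai[ord[j]]
        db <- dir * (anchors$bi[ord[i]] - anchors$bi[ord[j]])
        if (da >= 1L && da - 1L <= max_gap && db >= 1L &&
            db - 1L <= max_gap && len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    if (!any(len >= need)) next
    ends <- which(len == max(len[len >= need]) & len >= need)
    # reconstruct each candidate, tie-break by leftmost start on genome A
    cands <- lapply(ends, function(e) {
      chain <- integer(0)
      while (!is.na(e)) { chain <- c(ord[e], chain); e <- prev[e] }
      chain
    })
    starts <- vapply(cands, function(ch) anchors$ai[ch[1]], 0)
    pick <- cands[[which.min(starts)]]
    cand <- list(members = pick, dir = dir, length = length(pick),
                 start_a = anchors$ai[pick[1]])
    if (is.null(best) || cand$length > best$length ||
        (cand$length == best$length && cand$start_a < best$start_a)) {
      best <- cand
    }
  }
  best
}

#' Detect synteny clusters between two genomes
#'
#' Finds maximal colinear chains of RBH ortholog anchors on each pair of
#' contigs: within a chain, consecutive anchors are separated by at most
#' `max_gap` intervening genes on both genomes and positions are strictly
#' monotone on both (either orientation). Chains are selected greedily by
#' decreasing length (ties to the leftmost chain on genome A) and each
#' anchor belongs to at most one cluster; chains shorter than
#' `min_cluster_size` are discarded, as are two-anchor inverted chains
#' (an adjacent swapped pair is not evidence of conserved order).
#'
#' @param orthologs Data frame from [rbh_orthologs()].
#' @param gene_order_a,gene_order_b Data frames from [gene_order()] (or
#'   with the same columns) for genomes A and B.
#' @param max_gap Maximum number of intervening non-anchor genes between
#'   consecutive anchors, on each genome (default 2).
#' @param min_cluster_size Minimum anchors per reported cluster
#'   (default 2).
#' @return A data frame of anchors in clusters: `cluster_id`, `gene_a`,
#'   `gene_b`, `contig_a`, `contig_b`, `orientation` (`"+"` or `"-"`),
#'   `index_a`, `index_b`, ordered by cluster and genome-A position; zero
#'   rows if no cluster is found.
#' @export
find_clusters <- function(orthologs, gene_order_a, gene_order_b,
                          max_gap = 2L, min_cluster_size = 2L) {
  empty <- data.frame(cluster_id = character(0), gene_a = character(0),
                      gene_b = character(0), contig_a = character(0),
                      contig_b = character(0), orientation = character(0),
                      index_a = integer(0), index_b = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(orthologs)) return(empty)
  miss_a <- setdiff(orthologs$gene_a, gene_order_a$gene_id)
  miss_b <- setdiff(orthologs$gene_b, gene_order_b$gene_id)
  if (length(miss_a) || length(miss_b)) {
    stop(sprintf("gene(s) missing from the order tables: %s",
                 paste(utils::head(c(miss_a, miss_b), 5), collapse = ", ")))
  }
  pa <- gene_order_a[match(orthologs$gene_a, gene_order_a$gene_id), ]
  pb <- gene_order_b[match(orthologs$gene_b, gene_order_b$gene_id), ]
  anchors <- data.frame(gene_a = orthologs$gene_a,
                        gene_b = orthologs$gene_b,
                        ca = pa$contig, cb = pb$contig,
                        ai = pa$index, bi = pb$index,
                        stringsAsFactors = FALSE)
  out <- list(); cid <- 0L
  groups <- split(anchors, list(anchors$ca, anchors$cb), drop = TRUE)
  # deterministic group order
  groups <- groups[order(names(groups))]
  for (grp in groups) {
    free <- rep(TRUE, nrow(grp))
    repeat {
      ch <- best_chain(grp, free, max_gap, min_cluster_size)
      if (is.null(ch)) break
      cid <- cid + 1L
      sel <- grp[ch$members, , drop = FALSE]
      out[[cid]] <- data.frame(
        cluster_id = sprintf("S%03d", cid),
        gene_a = sel$gene_a, gene_b = sel$gene_b,
        contig_a = sel$ca, contig_b = sel$cb,
        orientation = if (ch$dir == 1L) "+" else "-",
        index_a = sel$ai, index_b = sel$bi,
        stringsAsFactors = FALSE)
      free[ch$members] <- FALSE
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fraction of selected genes lying in synteny clusters
#'
#' @param clusters Cluster table from [find_clusters()].
#' @param selected_genes Non-empty character vector of genome-A gene ids
#'   defining the denominator (e.g. all genes on the ten largest contigs).
#' @param orthologs Optional [rbh_orthologs()] table; if supplied, the
#'   fraction over only those selected genes that have an ortholog is also
#'   reported (the natural denominator is ambiguous, so both are given).
#' @return A list with `fraction`, `n_clustered`, `n_selected`, and, when
#'   `orthologs` is given, `fraction_of_orthologous` and `n_orthologous`.
#' @export
synteny_fraction <- function(clusters, selected_genes, orthologs = NULL) {
  if (!length(selected_genes)) stop("selected_genes must be non-empty")
  clustered <- unique(clusters$gene_a)
  n_sel <- length(unique(selected_genes))
  n_clu <- sum(unique(selected_genes) %in% clustered)
  out <- list(fraction = n_clu / n_sel, n_clustered = n_clu,
              n_selected = n_sel)
  if (!is.null(orthologs)) {
    with_orth <- unique(selected_genes)[unique(selected_genes) %in%
                                          orthologs$gene_a]
    out$n_orthologous <- length(with_orth)
    out$fraction_of_orthologous <- if (length(with_orth))
      sum(with_orth %in% clustered) / length(with_orth) else NA_real_
  }
  out
}

#' The n largest contigs of a genome
#'
#' @param genome An `annotated_genome`.
#' @param n Number of contigs (default 10).
#' @return Character vector of contig names, largest first.
#' @export
largest_contigs <- function(genome, n = 10L) {
  stopifnot(inherits(genome, "annotated_genome"))
  lens <- nchar(genome$contigs)
  names(sort(lens, decreasing = TRUE))[seq_len(min(n, length(lens)))]
}
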