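# Directed pairwise protein similarity hits.
#
# Hits either come from BLAST-style 12-column tabular files or are computed
# internally with Smith-Waterman local alignment (Biostrings) at desk
# scale. Internal E-values use the Karlin-Altschul form
# E = K * m * n * exp(-lambda * S) with the gapped BLOSUM62 constants
# (lambda = 0.267, K = 0.041), m the query length and n the total residue
# count of the subject database.

#' Default alignment scoring scheme
#'
#' BLOSUM62 with gap open 11 / extend 1 and the corresponding gapped
#' Karlin-Altschul constants, i.e. the documented defaults of classic
#' protein-protein BLAST.
#'
#' @param matrix Substitution matrix name (passed to Biostrings data sets).
#' @param gap_open,gap_extend Positive gap penalties.
#' @param lambda,K Karlin-Altschul statistical parameters for the scheme.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11,
                           gap_extend = 1, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

get_substitution_matrix <- function(scoring) {
  if (is.matrix(scoring$matrix)) return(scoring$matrix)
  e <- new.env()
  utils::data(list = scoring$matrix, package = "Biostrings", envir = e)
  get(scoring$matrix, envir = e)
}

hit_columns <- c("query_id", "subject_id", "evalue", "percent_identity",
                 "n_identical", "alignment_length", "bitscore",
                 "query_length", "subject_length", "score")

empty_hit_table <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   evalue = numeric(0), percent_identity = numeric(0),
                   n_identical = integer(0), alignment_length = integer(0),
                   bitscore = numeric(0), query_length = integer(0),
                   subject_length = integer(0), score = numeric(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  df
}

karlin_altschul_evalue <- function(score, m, n, scoring) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment under the scoring scheme (affine gaps: a gap of
#' length L costs `gap_open + L * gap_extend`). Identity is counted over
#' aligned columns; gap columns count toward the alignment length but
#' never toward identity.
#'
#' @param a,b Named length-1 character vectors, or `AAString`/character
#'   scalars with `ids` supplied.
#' @param scoring A [scoring_scheme()].
#' @param ids Optional character(2) with query and subject identifiers.
#' @param db_size Total residue count of the subject database for the
#'   E-value (defaults to the subject length, i.e. a single-sequence
#'   database).
#' @return A one-row `hit_table` data frame with columns query_id,
#'   subject_id, evalue, percent_identity, n_identical, alignment_length,
#'   bitscore, query_length, subject_length and the raw score.
#' @export
align_pair <- function(a, b, scoring = scoring_scheme(), ids = NULL,
                       db_size = NULL) {
  sa <- as_sequence_vector(a)
  sb <- as_sequence_vector(b)
  if (is.null(ids)) ids <- c(names(a) %||% "query", names(b) %||% "subject")
  if (nchar(sa) == 0L || nchar(sb) == 0L) stop("empty sequence")
  check_canonical(sa, ids[1])
  check_canonical(sb, ids[2])
  sub_mat <- get_substitution_matrix(scoring)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "local",
    substitutionMatrix = sub_mat, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend)
  hit_from_alignment(aln, ids[1], ids[2], nchar(sa), nchar(sb),
                     db_size %||% nchar(sb), scoring)
}

hit_from_alignment <- function(aln, qid, sid, qlen, slen, db_size, scoring) {
  s <- Biostrings::score(aln)
  n_id <- Biostrings::nmatch(aln)
  aln_len <- Biostrings::nchar(aln)  # aligned columns, gaps included
  df <- data.frame(
    query_id = qid, subject_id = sid,
    evalue = karlin_altschul_evalue(s, qlen, db_size, scoring),
    percent_identity = 100 * n_id / aln_len,
    n_identical = as.integer(n_id),
    alignment_length = as.integer(aln_len),
    bitscore = (scoring$lambda * s - log(scoring$K)) / log(2),
    query_length = as.integer(qlen), subject_length = as.integer(slen),
    score = s, stringsAsFactors = FALSE)
  class(df) <- c("hit_table", "data.frame")
  df
}

#' All-versus-all similarity search across labelled proteomes
#'
#' Aligns every unordered pair of distinct proteins (within and across
#' taxa) once with [align_pair()]'s engine and reports both directed hits;
#' score and identity are direction-symmetric, but the E-value uses the
#' querying direction's m and the subject taxon's total residue count as
#' the database size. Self-pairs are never retained, and at most one hit
#' is kept per ordered pair.
#'
#' @param proteomes A named list of named character vectors (or
#'   `AAStringSet`s), one per taxon. Identifiers must be unique across
#'   taxa.
#' @param scoring A [scoring_scheme()].
#' @return A `hit_table` data frame with a `taxon_of` attribute (named
#'   character: protein id to taxon) and `provenance = "internal"`.
#' @export
all_vs_all <- function(proteomes, scoring = scoring_scheme()) {
  seqs <- unlist(lapply(proteomes, as_sequence_vector))
  taxon_of <- rep(names(proteomes),
                  vapply(proteomes, length, 0L))
  ids <- unlist(lapply(proteomes, names), use.names = FALSE)
  if (is.null(ids) && length(seqs)) stop("proteins must be named")
  names(seqs) <- ids
  names(taxon_of) <- ids
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate identifier '%s' across proteomes",
                 ids[anyDuplicated(ids)]))
  }
  n <- length(seqs)
  out <- empty_hit_table()
  if (n >= 2L) {
    sub_mat <- get_substitution_matrix(scoring)
    db_res <- vapply(split(nchar(seqs), taxon_of[ids]), sum, 0)
    lens <- nchar(seqs)
    aaset <- Biostrings::AAStringSet(seqs)
    rows <- vector("list", n - 1L)
    for (i in seq_len(n - 1L)) {
      js <- (i + 1L):n
      alns <- Biostrings::pairwiseAlignment(
        aaset[js], aaset[[i]], type = "local",
        substitutionMatrix = sub_mat, gapOpening = scoring$gap_open,
        gapExtension = scoring$gap_extend)
      s <- Biostrings::score(alns)
      n_id <- Biostrings::nmatch(alns)
      aln_len <- Biostrings::nchar(alns)
      pid <- 100 * n_id / aln_len
      bits <- (scoring$lambda * s - log(scoring$K)) / log(2)
      # direction i -> j: query i, database = j's taxon
      e_fwd <- scoring$K * lens[i] * db_res[taxon_of[ids[js]]] *
        exp(-scoring$lambda * s)
      # direction j -> i
      e_rev <- scoring$K * lens[js] * db_res[taxon_of[ids[i]]] *
        exp(-scoring$lambda * s)
      rows[[i]] <- data.frame(
        query_id = c(rep(ids[i], length(js)), ids[js]),
        subject_id = c(ids[js], rep(ids[i], length(js))),
        evalue = c(e_fwd, e_rev),
        percent_identity = c(pid, pid),
        n_identical = as.integer(c(n_id, n_id)),
        alignment_length = as.integer(c(aln_len, aln_len)),
        bitscore = c(bits, bits),
        query_length = as.integer(c(rep(lens[i], length(js)), lens[js])),
        subject_length = as.integer(c(lens[js], rep(lens[i], length(js)))),
        score = c(s, s), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("hit_table", "data.frame")
  }
  attr(out, "provenance") <- "internal"
  attr(out, "taxon_of") <- taxon_of
  out
}

# Best-HSP rule: per ordered (query, subject) pair keep the hit with the
# lowest E-value, ties broken by higher n_identical, then lexicographic
# subject_id.
dedupe_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query_id, hits$subject_id, hits$evalue,
             -hits$n_identical)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits[c("query_id", "subject_id")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Read a BLAST 12-column tabular hit file
#'
#' Parses the classic `-outfmt 6` layout (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore). The identical
#' residue count is reconstructed as `round(pident * length / 100)`;
#' self-pairs are dropped and the best-HSP rule (lowest E-value, then most
#' identities) keeps one hit per ordered pair.
#'
#' @param path Path to the tabular file.
#' @param lengths Sequence lengths for E-value-independent criteria: a
#'   named numeric vector, a two-column data frame (id, length), or a FASTA
#'   file path. Required; rows whose query or subject is missing from it
#'   are an error.
#' @return A `hit_table` data frame with `provenance = "file"`.
#' @export
read_hit_table <- function(path, lengths) {
  if (missing(lengths) || is.null(lengths)) {
    stop("sequence length information is required (named vector, data frame or FASTA path)")
  }
  if (is.character(lengths) && length(lengths) == 1L && file.exists(lengths)) {
    fa <- Biostrings::readAAStringSet(lengths)
    lengths <- stats::setNames(Biostrings::width(fa),
                               sub("\\s.*$", "", names(fa)))
  } else if (is.data.frame(lengths)) {
    lengths <- stats::setNames(as.numeric(lengths[[2]]),
                               as.character(lengths[[1]]))
  }
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  if (!length(raw)) return(empty_hit_table())
  fields <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) != 12L)
  if (length(bad)) {
    stop(sprintf("malformed row(s) at line(s) %s: expected 12 tab-separated columns",
                 paste(bad, collapse = ", ")))
  }
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, c(3, 4, 11, 12), drop = FALSE], 2,
                                as.numeric))
  num <- matrix(num, ncol = 4)
  bad <- which(rowSums(is.na(num)) > 0)
  if (length(bad)) {
    stop(sprintf("malformed numeric field(s) at line(s) %s",
                 paste(bad, collapse = ", ")))
  }
  qid <- m[, 1]; sid <- m[, 2]
  missing_ids <- setdiff(unique(c(qid, sid)), names(lengths))
  if (length(missing_ids)) {
    stop(sprintf("missing length information for: %s",
                 paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  hits <- data.frame(
    query_id = qid, subject_id = sid, evalue = num[, 3],
    percent_identity = num[, 1],
    n_identical = as.integer(round_half_up(num[, 1] * num[, 2] / 100)),
    alignment_length = as.integer(num[, 2]),
    bitscore = num[, 4],
    query_length = as.integer(lengths[qid]),
    subject_length = as.integer(lengths[sid]),
    score = NA_real_, stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  out <- dedupe_hits(hits)
  attr(out, "provenance") <- "file"
  out
}

#' Write a hit table as BLAST-style 12-column TSV
#'
#' Column positions not represented internally (mismatch, gapopen,
#' coordinates) are written as 0.
#'
#' @param hits A `hit_table`.
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  df <- data.frame(hits$query_id, hits$subject_id,
                   sprintf("%.2f", hits$percent_identity),
                   hits$alignment_length, 0L, 0L, 0L, 0L, 0L, 0L,
                   format(hits$evalue, digits = 3),
                   sprintf("%.1f", hits$bitscore))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
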