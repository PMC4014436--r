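# Assembly and gene-model compaction statistics: contig filtering, N50,
# GC content, coding density, exon/intron geometry and coverage-based
# genome-size estimation.

coerce_contigs <- function(contigs) {
  if (is(contigs, "DNAStringSet")) return(contigs)
  if (is.character(contigs)) return(Biostrings::DNAStringSet(contigs))
  stop("contigs must be a DNAStringSet or character vector")
}

#' Filter contigs by minimum length
#'
#' Keeps contigs at least `min_len` bp long (inclusive), preserving order.
#'
#' @param contigs A `DNAStringSet` or named character vector.
#' @param min_len Minimum length in bp (default 500).
#' @return The filtered contigs, same class as the input container.
#' @export
filter_contigs <- function(contigs, min_len = 500) {
  x <- coerce_contigs(contigs)
  keep <- Biostrings::width(x) >= min_len
  if (is.character(contigs)) contigs[keep] else x[keep]
}

#' N50 of a set of contig lengths
#'
#' The largest length L such that contigs of length >= L together contain
#' at least half the total assembly length.
#'
#' @param lengths Positive numeric vector of contig lengths.
#' @return The N50 in bp.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly summary: contig count, total size, N50 and GC
#'
#' GC is computed as `100 * (G + C) / (A + C + G + T)`; ambiguity codes
#' are excluded from both numerator and denominator.
#'
#' @param contigs A `DNAStringSet` or character vector of sequences.
#' @return A list with `n_contigs`, `total_bp`, `n50_bp`, `gc_percent`.
#' @export
assembly_summary <- function(contigs) {
  x <- coerce_contigs(contigs)
  if (length(x) == 0L) stop("assembly_summary requires at least one contig")
  w <- Biostrings::width(x)
  freq <- colSums(Biostrings::letterFrequency(x, c("A", "C", "G", "T")))
  list(n_contigs = length(x),
       total_bp = sum(w),
       n50_bp = n50(w),
       gc_percent = 100 * sum(freq[c("C", "G")]) / sum(freq))
}

#' Coding density in genes per kbp
#'
#' Computed from the assembled size as printed in Mbp (not exact bp), and
#' rounded half away from zero to 3 decimals — the convention of published
#' genome comparison tables.
#'
#' @param n_genes Number of predicted genes (> 0).
#' @param assembled_size_mbp Assembled genome size in Mbp (> 0).
#' @return Genes per kbp, rounded to 3 decimals.
#' @examples
#' coding_density(6035, 12.4)   # 0.487
#' coding_density(9629, 49)     # 0.197
#' @export
coding_density <- function(n_genes, assembled_size_mbp) {
  if (any(n_genes <= 0) || any(assembled_size_mbp <= 0)) {
    stop("n_genes and assembled_size_mbp must be positive")
  }
  round_half_up(n_genes / (assembled_size_mbp * 1000), 3)
}

#' Exon/intron geometry of an annotated genome
#'
#' Introns are the gaps between consecutive exons of a gene (length
#' `next_start - prev_end - 1`). Per-gene means are reported to 1 decimal
#' and mean sizes as integer bp, matching published summary precision; a
#' genome of single-exon genes has an undefined mean intron size, reported
#' as `NA`.
#'
#' @param genome An `annotated_genome` (see [generate_genome()] or
#'   [read_genome()]).
#' @return A list with `mean_exons_per_gene`, `mean_exon_bp`,
#'   `mean_introns_per_gene`, `mean_intron_bp`, and the unrounded values
#'   under `raw`.
#' @export
gene_structure_stats <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  ex <- genome$exons
  if (!nrow(ex)) stop("genome has no exons")
  ex <- ex[order(ex$gene_id, ex$start), , drop = FALSE]
  by_gene <- split(ex, ex$gene_id)
  intron_lens <- numeric(0)
  for (g in by_gene) {
    if (nrow(g) > 1L) {
      if (any(g$start[-1] <= g$end[-nrow(g)])) {
        stop(sprintf("overlapping exons in gene '%s'", g$gene_id[1]))
      }
      intron_lens <- c(intron_lens, g$start[-1] - g$end[-nrow(g)] - 1L)
    }
  }
  n_genes <- length(by_gene)
  exon_lens <- ex$end - ex$start + 1L
  raw <- list(
    mean_exons_per_gene = nrow(ex) / n_genes,
    mean_exon_bp = mean(exon_lens),
    mean_introns_per_gene = length(intron_lens) / n_genes,
    mean_intron_bp = if (length(intron_lens)) mean(intron_lens) else NA_real_
  )
  list(mean_exons_per_gene = round_half_up(raw$mean_exons_per_gene, 1),
       mean_exon_bp = round_half_up(raw$mean_exon_bp),
       mean_introns_per_gene = round_half_up(raw$mean_introns_per_gene, 1),
       mean_intron_bp = if (is.na(raw$mean_intron_bp)) NA_real_ else
         round_half_up(raw$mean_intron_bp),
       raw = raw)
}

#' Estimate genome size from mapped bases and coverage
#'
#' The estimator is `total mapped bases / mean coverage`, i.e. reads times
#' read length over coverage.
#'
#' @param total_mapped_bases Total mapped bases (> 0).
#' @param mean_coverage Mean fold coverage (> 0).
#' @return Estimated genome size in bp.
#' @export
estimate_genome_size <- function(total_mapped_bases, mean_coverage) {
  if (total_mapped_bases <= 0) stop("total_mapped_bases must be positive")
  if (mean_coverage <= 0) stop("mean_coverage must be positive")
  total_mapped_bases / mean_coverage
}

#' Read an annotated genome from FASTA + GFF3
#'
#' Gene models are taken from `gene` and `exon` features (exons linked to
#' genes by their `Parent` attribute).
#'
#' @param fasta_path Contig FASTA file.
#' @param gff_path GFF3 annotation file.
#' @return An `annotated_genome`.
#' @export
read_genome <- function(fasta_path, gff_path) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  is_gene <- gff$type == "gene"
  is_exon <- gff$type == "exon"
  genes <- data.frame(
    gene_id = as.character(gff$ID[is_gene]),
    contig = as.character(GenomicRanges::seqnames(gff[is_gene])),
    strand = as.character(GenomicRanges::strand(gff[is_gene])),
    start = GenomicRanges::start(gff[is_gene]),
    end = GenomicRanges::end(gff[is_gene]),
    stringsAsFactors = FALSE)
  parents <- as.character(S4Vectors::unstrsplit(gff$Parent[is_exon]))
  ex <- data.frame(
    gene_id = parents,
    contig = as.character(GenomicRanges::seqnames(gff[is_exon])),
    start = GenomicRanges::start(gff[is_exon]),
    end = GenomicRanges::end(gff[is_exon]),
    stringsAsFactors = FALSE)
  ex <- ex[order(ex$gene_id, ex$start), , drop = FALSE]
  ex$exon_number <- stats::ave(ex$start, ex$gene_id,
                               FUN = seq_along)
  structure(list(contigs = stats::setNames(as.character(contigs),
                                           names(contigs)),
                 genes = genes,
                 exons = ex[c("gene_id", "contig", "exon_number",
                              "start", "end")]),
            class = "annotated_genome")
}
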