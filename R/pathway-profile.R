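# Presence/absence profiling of reference pathway gene sets.
#
# A reference gene (e.g. a KEGG ortholog or a GreenCut2 plastid protein)
# is called present in a dataset iff its best hit E-value is strictly
# below the dataset's threshold: 1e-10 for protein-vs-proteome searches,
# 1e-5 for protein-vs-genome and protein-vs-transcriptome searches. A
# gene found in none of the three datasets is considered absent from the
# organism.

#' Build a reference gene set
#'
#' @param set_id Label for the set (e.g. a KEGG ko id or `"GreenCut2"`).
#' @param genes Data frame with columns `gene_id` and `pathway_label`
#'   (additional columns such as sequences are carried through).
#' @return A `reference_set` object.
#' @export
reference_set <- function(set_id, genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "pathway_label") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_ids must be unique within a reference set")
  }
  structure(list(set_id = set_id, genes = genes), class = "reference_set")
}

best_evalue_per_gene <- function(hits) {
  if (is.null(hits) || !nrow(hits)) {
    return(stats::setNames(numeric(0), character(0)))
  }
  gid <- if ("gene_id" %in% names(hits)) hits$gene_id else hits$query_id
  vapply(split(hits$evalue, gid), min, 0)
}

#' Presence/absence profile of a reference set across three datasets
#'
#' @param refset A [reference_set()].
#' @param proteome_hits,genome_hits,transcriptome_hits Hit tables (data
#'   frames with an `evalue` column keyed by `gene_id` or `query_id`, e.g.
#'   a `hit_table` whose queries are reference genes), or `NULL` if the
#'   dataset was not searched. A reference gene missing from a table is
#'   simply absent there.
#' @param thresholds Named numeric vector of strict E-value ceilings per
#'   dataset; defaults to `c(proteome = 1e-10, genome = 1e-5,
#'   transcriptome = 1e-5)`.
#' @return A `presence_profile` data frame: per reference gene, the
#'   pathway label, best E-value and presence flag per dataset, and
#'   `overall_present` (the OR of the three flags).
#' @export
map_presence <- function(refset, proteome_hits = NULL, genome_hits = NULL,
                         transcriptome_hits = NULL,
                         thresholds = c(proteome = 1e-10, genome = 1e-5,
                                        transcriptome = 1e-5)) {
  stopifnot(inherits(refset, "reference_set"))
  genes <- refset$genes
  datasets <- list(proteome = proteome_hits, genome = genome_hits,
                   transcriptome = transcriptome_hits)
  out <- data.frame(gene_id = genes$gene_id,
                    pathway_label = genes$pathway_label,
                    stringsAsFactors = FALSE)
  for (d in names(datasets)) {
    best <- best_evalue_per_gene(datasets[[d]])
    ev <- unname(best[out$gene_id])
    out[[paste0("best_evalue_", d)]] <- ev
    out[[paste0("present_in_", d)]] <- !is.na(ev) & ev < thresholds[[d]]
  }
  out$overall_present <- out$present_in_proteome | out$present_in_genome |
    out$present_in_transcriptome
  class(out) <- c("presence_profile", "data.frame")
  out
}

#' Per-pathway retention fractions
#'
#' @param profiles A `presence_profile`.
#' @return A data frame with one row per pathway label plus an `"overall"`
#'   row: `pathway_label`, `n_present`, `n_total`, `fraction`. Genes with
#'   a missing pathway label are excluded with a warning.
#' @export
retention_fraction <- function(profiles) {
  miss <- is.na(profiles$pathway_label)
  if (any(miss)) {
    warning(sprintf("%d gene(s) without a pathway label excluded",
                    sum(miss)))
    profiles <- profiles[!miss, , drop = FALSE]
  }
  by_label <- split(profiles$overall_present, profiles$pathway_label)
  rows <- lapply(names(by_label), function(lab) {
    p <- by_label[[lab]]
    data.frame(pathway_label = lab, n_present = sum(p), n_total = length(p),
               fraction = sum(p) / length(p), stringsAsFactors = FALSE)
  })
  overall <- data.frame(pathway_label = "overall",
                        n_present = sum(profiles$overall_present),
                        n_total = nrow(profiles),
                        fraction = mean(profiles$overall_present),
                        stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), overall)
}

#' Genome/transcriptome congruence of present genes
#'
#' Among reference genes, reports the fractions found in both the genome
#' and the transcriptome, in the genome only, and in the transcriptome
#' only. Because the natural denominator is ambiguous, both are reported:
#' over genes present in at least one dataset (`overall_present`), and
#' over the full reference set.
#'
#' @param profiles A `presence_profile` with genome and transcriptome
#'   flags populated.
#' @return A data frame with rows `both`, `genome_only`,
#'   `transcriptome_only` and columns `n`, `fraction_of_present`,
#'   `fraction_of_all`.
#' @export
cross_dataset_congruence <- function(profiles) {
  g <- profiles$present_in_genome
  t <- profiles$present_in_transcriptome
  n_present <- sum(profiles$overall_present)
  n_all <- nrow(profiles)
  counts <- c(both = sum(g & t), genome_only = sum(g & !t),
              transcriptome_only = sum(!g & t))
  data.frame(
    class = names(counts), n = as.integer(counts),
    fraction_of_present = if (n_present > 0) counts / n_present else
      rep(NA_real_, 3),
    fraction_of_all = if (n_all > 0) counts / n_all else rep(NA_real_, 3),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Test whether gene loss concentrates in a pathway group
#'
#' Builds the 2x2 table of lost/retained versus focus/other pathway
#' membership and applies a two-sided Fisher exact test. Degenerate tables
#' (an all-zero margin) return p = 1 with a warning.
#'
#' @param profiles A `presence_profile`; every gene must carry a pathway
#'   label.
#' @param focus_labels Non-empty character vector of pathway labels making
#'   up the focus group (e.g. photosynthesis-related pathways).
#' @return A list with `table` (2x2 counts: rows lost/retained, columns
#'   focus/other) and `p_value`.
#' @export
loss_concentration_test <- function(profiles, focus_labels) {
  if (!length(focus_labels)) stop("focus_labels must be non-empty")
  if (any(is.na(profiles$pathway_label))) {
    stop("every reference gene must carry a pathway label")
  }
  lost <- !profiles$overall_present
  focus <- profiles$pathway_label %in% focus_labels
  tab <- matrix(c(sum(lost & focus), sum(lost & !focus),
                  sum(!lost & focus), sum(!lost & !focus)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("lost", "retained"),
                                c("focus", "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (all-zero margin); p reported as 1")
    return(list(table = tab, p_value = 1))
  }
  list(table = tab,
       p_value = stats::fisher.test(tab, alternative = "two.sided")$p.value)
}
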