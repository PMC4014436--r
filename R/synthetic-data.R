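# Synthetic three-taxon datasets with a known truth ledger.
#
# The generator emulates the comparison of a focal (parasite-like) proteome
# against two free-living relatives: gene families are simulated as sets of
# sequences derived from a common random ancestor by i.i.d. substitutions,
# so that within-family similarity passes reciprocal-alignment edge
# criteria while between-family similarity stays at the random background.
# Planted family contractions/expansions, chitinase-like motif carriers and
# annotated toy genomes give every downstream stage a ground truth.

#' Specification of one simulated gene family
#'
#' @param family_id Unique label for the family.
#' @param counts Non-negative integer member counts per taxon, in the order
#'   of the `taxa` argument of [generate_proteomes()] (focal first).
#' @param ancestral_length Length of the random ancestral sequence in
#'   residues (at least 50).
#' @param within_divergence Expected fraction of substituted positions
#'   between each member and the ancestor, in `[0, 0.5)`. Two members then
#'   agree at a fraction of positions concentrating near
#'   `(1 - d)^2 + d^2/19`.
#' @param motif_plan Optional motif embedding: a list of per-member plans
#'   (recycled if length 1), each a list of `list(motif=, variant=)`
#'   entries understood by [plant_motifs()]; positions are assigned
#'   automatically, left to right with a 4-residue spacer.
#' @return A `family_spec` object.
#' @export
family_spec <- function(family_id, counts, ancestral_length = 150L,
                        within_divergence = 0.05, motif_plan = NULL) {
  counts <- as.integer(counts)
  stopifnot(length(family_id) == 1L, length(counts) == 3L)
  if (any(is.na(counts)) || any(counts < 0L)) {
    stop("counts must be non-negative integers")
  }
  if (within_divergence < 0 || within_divergence >= 0.5) {
    stop("within_divergence must lie in [0, 0.5)")
  }
  if (ancestral_length < 50L) stop("ancestral_length must be >= 50")
  structure(
    list(family_id = as.character(family_id), counts = counts,
         ancestral_length = as.integer(ancestral_length),
         within_divergence = within_divergence, motif_plan = motif_plan),
    class = "family_spec"
  )
}

# Parse a variant string for a motif: "canonical", or "<label>-><residue>"
# where <label> names a conserved position (catalytic: D1, D2, D3, E).
parse_variant <- function(motif, variant) {
  reg <- motif_registry()[[motif]]
  if (is.null(reg)) stop(sprintf("unknown motif '%s'", motif))
  if (is.null(variant) || identical(variant, "canonical")) return(NULL)
  if (is.null(reg$conserved)) {
    stop(sprintf("motif '%s' has no defined variants", motif))
  }
  m <- regmatches(variant, regexec("^([A-Z][0-9]?)->([A-Z])$", variant))[[1]]
  if (length(m) != 3L || !m[2] %in% reg$labels) {
    stop(sprintf("cannot parse variant '%s' for motif '%s'", variant, motif))
  }
  idx <- reg$conserved[match(m[2], reg$labels)]
  list(index = idx, to = m[3])
}

#' Embed motifs into a protein sequence
#'
#' Overwrites the fixed positions of each requested motif pattern at the
#' requested 1-based position, leaving wildcard positions and the rest of
#' the sequence unchanged. A variant (e.g. `"E->P"` for the catalytic
#' motif) substitutes exactly one conserved position of the planted motif.
#'
#' @inheritParams scan_catalytic
#' @param plan A list of entries `list(motif=, variant=, position=)`;
#'   `variant` may be `"canonical"` (or `NULL`) or a single-substitution
#'   string such as `"E->P"` or `"D1->T"`. Entries must not overlap and
#'   must fit within the sequence.
#' @return The modified sequence as a character scalar.
#' @export
plant_motifs <- function(seq, plan) {
  seq <- as_sequence_vector(seq)
  stopifnot(length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  reg <- motif_registry()
  spans <- matrix(integer(0), ncol = 2)
  for (entry in plan) {
    motif <- entry$motif
    if (is.null(reg[[motif]])) stop(sprintf("unknown motif '%s'", motif))
    form <- reg[[motif]]$forms[[1]]
    pos <- as.integer(entry$position)
    k <- length(form)
    if (pos < 1L || pos + k - 1L > length(chars)) {
      stop(sprintf("motif '%s' at position %d does not fit in a %d-residue sequence",
                   motif, pos, length(chars)))
    }
    if (nrow(spans) &&
        any(pos <= spans[, 2] & (pos + k - 1L) >= spans[, 1])) {
      stop("overlapping motif plan entries")
    }
    spans <- rbind(spans, c(pos, pos + k - 1L))
    fixed <- which(!is.na(form))
    chars[pos + fixed - 1L] <- form[fixed]
    v <- parse_variant(motif, entry$variant)
    if (!is.null(v)) chars[pos + v$index - 1L] <- v$to
  }
  paste(chars, collapse = "")
}

# Automatic non-overlapping positions for a member's motif plan.
auto_positions <- function(plan, seq_length) {
  reg <- motif_registry()
  pos <- 3L
  out <- list()
  for (entry in plan) {
    k <- length(reg[[entry$motif]]$forms[[1]])
    if (pos + k - 1L > seq_length) {
      stop(sprintf("motif plan does not fit: motif '%s' would end at %d in a %d-residue ancestor",
                   entry$motif, pos + k - 1L, seq_length))
    }
    out[[length(out) + 1L]] <- list(motif = entry$motif,
                                    variant = entry$variant %||% "canonical",
                                    position = pos)
    pos <- pos + k + 4L
  }
  out
}

# Definitional representation call from true per-taxon counts
# (focal first). Same rule as classify_components(), applied to the
# planted counts rather than to recovered components.
call_from_counts <- function(counts) {
  focal <- counts[1]
  comp <- counts[-1]
  if (focal == 0L && all(comp >= 1L)) "absent-in-focal"
  else if (focal >= 1L && focal < min(comp)) "contracted"
  else if (focal > max(comp) && all(comp >= 1L)) "expanded"
  else "balanced"
}

#' Generate three synthetic proteomes with a truth ledger
#'
#' Each family derives its members from one random ancestral sequence
#' (uniform over the 20 canonical residues) by i.i.d. substitutions at the
#' family's `within_divergence` rate, substituting uniformly over the 19
#' alternative residues. Families share no ancestry, so between-family
#' identity stays at the ~5% random background. Motif plans are applied
#' after mutation so planted motifs are intact. Deterministic given `seed`;
#' each family uses its own seed stream derived from the master seed by a
#' fixed offset.
#'
#' @param specs A list of [family_spec()] objects (may be empty).
#' @param seed Integer master seed.
#' @param taxa Character vector of three taxon labels, focal taxon first.
#' @return A list with `proteomes` (a named list of three named character
#'   vectors of sequences) and `truth`, a `truth_ledger` list holding
#'   `memberships` (protein_id, taxon, family_id), `families` (family_id,
#'   one count column per taxon, `expected_call`) and `motifs` (protein_id,
#'   motif, variant, position).
#' @export
generate_proteomes <- function(specs, seed,
                               taxa = c("focal", "comparator1", "comparator2")) {
  stopifnot(length(taxa) == 3L, !anyDuplicated(taxa))
  if (!length(specs)) {
    empty <- stats::setNames(
      rep(list(stats::setNames(character(0), character(0))), 3), taxa)
    truth <- structure(list(
      memberships = data.frame(protein_id = character(0),
                               taxon = character(0),
                               family_id = character(0)),
      families = data.frame(family_id = character(0)),
      motifs = data.frame(protein_id = character(0), motif = character(0),
                          variant = character(0), position = integer(0)),
      taxa = taxa
    ), class = "truth_ledger")
    return(list(proteomes = empty, truth = truth))
  }
  ids <- vapply(specs, function(s) s$family_id, "")
  if (anyDuplicated(ids)) stop("duplicate family_id in specs")

  proteomes <- stats::setNames(rep(list(character(0)), 3), taxa)
  memb <- list(); fams <- list(); motifs <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    set.seed((seed + 7919L * i) %% 2147483647L)
    anc <- sample(AA_ALPHABET, sp$ancestral_length, replace = TRUE)
    n_members <- sum(sp$counts)
    plans <- sp$motif_plan
    if (!is.null(plans)) {
      if (length(plans) == 1L) plans <- rep(plans, n_members)
      if (length(plans) != n_members) {
        stop(sprintf("family '%s': motif_plan must have 1 or %d elements",
                     sp$family_id, n_members))
      }
    }
    member_idx <- 0L
    for (t in seq_along(taxa)) {
      for (k in seq_len(sp$counts[t])) {
        member_idx <- member_idx + 1L
        chars <- anc
        mut <- which(stats::runif(length(chars)) < sp$within_divergence)
        for (m in mut) {
          chars[m] <- sample(setdiff(AA_ALPHABET, chars[m]), 1L)
        }
        s <- paste(chars, collapse = "")
        pid <- sprintf("%s_%s_%d", taxa[t], sp$family_id, k)
        if (!is.null(plans) && length(plans[[member_idx]])) {
          placed <- auto_positions(plans[[member_idx]], nchar(s))
          s <- plant_motifs(s, placed)
          for (pl in placed) {
            motifs[[length(motifs) + 1L]] <- data.frame(
              protein_id = pid, motif = pl$motif, variant = pl$variant,
              position = pl$position, stringsAsFactors = FALSE)
          }
        }
        proteomes[[taxa[t]]][pid] <- s
        memb[[length(memb) + 1L]] <- data.frame(
          protein_id = pid, taxon = taxa[t], family_id = sp$family_id,
          stringsAsFactors = FALSE)
      }
    }
    counts <- stats::setNames(as.list(sp$counts), taxa)
    fams[[i]] <- data.frame(family_id = sp$family_id, counts,
                            expected_call = call_from_counts(sp$counts),
                            stringsAsFactors = FALSE)
  }
  truth <- structure(list(
    memberships = do.call(rbind, memb),
    families = do.call(rbind, fams),
    motifs = if (length(motifs)) do.call(rbind, motifs) else
      data.frame(protein_id = character(0), motif = character(0),
                 variant = character(0), position = integer(0)),
    taxa = taxa
  ), class = "truth_ledger")
  list(proteomes = proteomes, truth = truth)
}

#' Specification of a simulated annotated genome
#'
#' Defaults reflect a compact trebouxiophyte-like gene model: about one
#' gene per 2 kb, 2.3 exons per gene, 366 bp exons, 168 bp introns, 62% GC.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length_mean,contig_length_sd,contig_length_min Contig
#'   length distribution in bp (normal, truncated below at the minimum).
#' @param target_gene_density Genes per kbp of assembled sequence.
#' @param exons_per_gene_mean Mean exons per gene (>= 1); exon counts are
#'   drawn as `1 + Poisson(mean - 1)`.
#' @param exon_length_mean,intron_length_mean Mean exon / intron lengths in
#'   bp (Poisson-distributed).
#' @param gc_fraction Target GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(n_contigs = 20L, contig_length_mean = 25000,
                        contig_length_sd = 5000, contig_length_min = 1000,
                        target_gene_density = 0.487,
                        exons_per_gene_mean = 2.3, exon_length_mean = 366,
                        intron_length_mean = 168, gc_fraction = 0.62,
                        seed = 1L) {
  if (target_gene_density <= 0) stop("target_gene_density must be > 0")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]")
  if (exons_per_gene_mean < 1) stop("exons_per_gene_mean must be >= 1")
  stopifnot(n_contigs >= 1L, contig_length_min > 0)
  structure(as.list(environment()), class = "genome_spec")
}

#' Generate an annotated toy genome
#'
#' Draws contig lengths and base composition from the spec, then places
#' non-overlapping gene models (exon chains with implied introns) so that
#' the realized gene density matches the target; genes are distributed
#' across contigs by largest-remainder apportionment of
#' `density * length`. Deterministic given the spec's seed.
#'
#' @param spec A [genome_spec()] object.
#' @return An `annotated_genome`: a list with `contigs` (a named character
#'   vector of sequences), `genes` (data frame: gene_id, contig, strand,
#'   start, end) and `exons` (data frame: gene_id, contig, exon_number,
#'   start, end; 1-based closed coordinates, introns implied between
#'   consecutive exons).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(spec$seed)
  lens <- pmax(round(stats::rnorm(spec$n_contigs, spec$contig_length_mean,
                                  spec$contig_length_sd)),
               spec$contig_length_min)
  lens <- as.integer(lens)
  gc <- spec$gc_fraction
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  contigs <- vapply(seq_along(lens), function(i) {
    paste(sample(names(base_p), lens[i], replace = TRUE, prob = base_p),
          collapse = "")
  }, "")
  names(contigs) <- sprintf("contig_%03d", seq_along(lens))

  # apportion genes to contigs: floor + largest remainder
  quota <- spec$target_gene_density * lens / 1000
  n_total <- round(sum(quota))
  n_i <- floor(quota)
  rem <- n_total - sum(n_i)
  if (rem > 0) {
    frac_order <- order(quota - n_i, decreasing = TRUE)
    n_i[frac_order[seq_len(rem)]] <- n_i[frac_order[seq_len(rem)]] + 1L
  }

  genes <- list(); exons <- list(); gid <- 0L
  for (ci in seq_along(lens)) {
    ng <- n_i[ci]
    if (ng == 0) next
    # draw structures first, then check they fit
    structs <- lapply(seq_len(ng), function(j) {
      ne <- 1L + stats::rpois(1L, spec$exons_per_gene_mean - 1)
      elens <- pmax(stats::rpois(ne, spec$exon_length_mean), 3L)
      ilens <- if (ne > 1L)
        pmax(stats::rpois(ne - 1L, spec$intron_length_mean), 4L)
      else integer(0)
      list(elens = elens, ilens = ilens,
           span = sum(elens) + sum(ilens))
    })
    spans <- vapply(structs, `[[`, 0, "span")
    slack <- lens[ci] - sum(spans) - (ng + 1L)
    if (slack < 0 || any(spans > lens[ci])) {
      stop(sprintf("infeasible gene density: %d genes spanning %d bp cannot fit on a %d bp contig",
                   ng, sum(spans), lens[ci]))
    }
    gap <- slack %/% (ng + 1L)
    pos <- 1L + gap
    for (j in seq_len(ng)) {
      gid <- gid + 1L
      st <- structs[[j]]
      gene_id <- sprintf("gene_%05d", gid)
      estart <- pos
      for (e in seq_along(st$elens)) {
        eend <- estart + st$elens[e] - 1L
        exons[[length(exons) + 1L]] <- data.frame(
          gene_id = gene_id, contig = names(contigs)[ci],
          exon_number = e, start = estart, end = eend,
          stringsAsFactors = FALSE)
        if (e < length(st$elens)) estart <- eend + st$ilens[e] + 1L
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gene_id, contig = names(contigs)[ci],
        strand = sample(c("+", "-"), 1L),
        start = pos, end = pos + st$span - 1L, stringsAsFactors = FALSE)
      pos <- pos + st$span + 1L + gap
    }
  }
  structure(list(
    contigs = contigs,
    genes = if (length(genes)) do.call(rbind, genes) else
      data.frame(gene_id = character(0), contig = character(0),
                 strand = character(0), start = integer(0), end = integer(0)),
    exons = if (length(exons)) do.call(rbind, exons) else
      data.frame(gene_id = character(0), contig = character(0),
                 exon_number = integer(0), start = integer(0),
                 end = integer(0))
  ), class = "annotated_genome")
}

#' Summarise read mapping at a given coverage
#'
#' Closed-form mapped-base summary for genome-size estimation: the read
#' count is `round(genome_size * coverage / read_length)`, total mapped
#' bases are `read_count * read_length`, and the mean coverage is total
#' mapped bases over genome size. No read-level simulation is performed,
#' so the summary is exact arithmetic.
#'
#' @param genome_size True genome size in bp.
#' @param coverage Target fold coverage (> 0).
#' @param read_length Read length in bp.
#' @return A list with `read_count`, `total_mapped_bases` and
#'   `mean_coverage`.
#' @export
simulate_coverage <- function(genome_size, coverage, read_length = 100L) {
  if (genome_size <= 0 || coverage <= 0 || read_length <= 0) {
    stop("genome_size, coverage and read_length must all be positive")
  }
  n_reads <- round(genome_size * coverage / read_length)
  list(read_count = n_reads,
       total_mapped_bases = n_reads * read_length,
       mean_coverage = n_reads * read_length / genome_size)
}

#' Write proteomes as one FASTA file per taxon
#'
#' @param proteomes A named list of named character vectors (as returned in
#'   `generate_proteomes()$proteomes`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_proteomes <- function(proteomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (taxon in names(proteomes)) {
    p <- file.path(dir, paste0(taxon, ".faa"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(proteomes[[taxon]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write an annotated genome as FASTA + GFF3
#'
#' @param genome An `annotated_genome`.
#' @param fasta_path,gff_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  stopifnot(inherits(genome, "annotated_genome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), fasta_path)
  g <- genome$genes
  e <- genome$exons
  strand_of <- stats::setNames(g$strand, g$gene_id)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand, type = "gene", ID = g$gene_id)
  gr_exons <- GenomicRanges::GRanges(
    seqnames = e$contig,
    ranges = IRanges::IRanges(e$start, e$end),
    strand = unname(strand_of[e$gene_id]), type = "exon",
    ID = sprintf("%s.exon%d", e$gene_id, e$exon_number),
    Parent = e$gene_id)
  rtracklayer::export(c(gr_genes, gr_exons), gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

#' Write a truth ledger as JSON
#'
#' @param truth A `truth_ledger`.
#' @param path Output path.
#' @export
write_truth_ledger <- function(truth, path) {
  stopifnot(inherits(truth, "truth_ledger"))
  jsonlite::write_json(unclass(truth), path, dataframe = "rows",
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
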