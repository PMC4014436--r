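# Evolutionary gene network: reciprocal-edge construction, connected
# components as gene families, and contraction/expansion calls for a
# focal taxon against its comparators.
#
# An undirected edge is drawn between two proteins only if BOTH directed
# hits satisfy all four criteria: E-value < 1e-10, percent identity > 20,
# identical residues covering at least 20% of the shorter sequence, and
# alignment length > 20 aa. Connected components of the resulting graph
# approximate gene families; a family with fewer focal members than every
# comparator is called contracted, with more than every comparator
# expanded.

#' Edge criteria for the similarity network
#'
#' @param max_evalue Exclusive E-value ceiling for both directions.
#' @param min_percent_identity Exclusive percent-identity floor.
#' @param min_identical_fraction Inclusive floor on identical residues as
#'   a fraction of the shorter sequence's length.
#' @param min_alignment_length Exclusive floor on aligned columns (aa).
#' @return An `edge_criteria` list.
#' @export
edge_criteria <- function(max_evalue = 1e-10, min_percent_identity = 20,
                          min_identical_fraction = 0.20,
                          min_alignment_length = 20) {
  stopifnot(max_evalue > 0, min_percent_identity > 0,
            min_identical_fraction > 0, min_alignment_length > 0)
  structure(list(max_evalue = max_evalue,
                 min_percent_identity = min_percent_identity,
                 min_identical_fraction = min_identical_fraction,
                 min_alignment_length = min_alignment_length),
            class = "edge_criteria")
}

hit_passes <- function(hit, criteria) {
  hit$evalue < criteria$max_evalue &
    hit$percent_identity > criteria$min_percent_identity &
    hit$n_identical >= criteria$min_identical_fraction *
      pmin(hit$query_length, hit$subject_length) &
    hit$alignment_length > criteria$min_alignment_length
}

#' Reciprocal edge test for one protein pair
#'
#' `TRUE` iff both directed hits of one unordered pair satisfy all four
#' criteria (strict for E-value, identity and length; inclusive for the
#' identical-residue fraction of the shorter sequence).
#'
#' @param fwd,rev One-row `hit_table` rows for the two directions of the
#'   same unordered pair.
#' @param criteria An [edge_criteria()].
#' @return Logical scalar.
#' @export
edge_test <- function(fwd, rev, criteria = edge_criteria()) {
  if (fwd$query_id != rev$subject_id || fwd$subject_id != rev$query_id) {
    stop("fwd and rev must be the two directions of one unordered pair")
  }
  isTRUE(hit_passes(fwd, criteria) && hit_passes(rev, criteria))
}

#' Build the undirected similarity network
#'
#' Vertices are all supplied proteins (isolated ones included); an edge
#' joins an unordered pair iff both directed hits exist and pass
#' [edge_test()].
#'
#' @param hits A deduplicated `hit_table` (both directions present for
#'   internally computed pairs).
#' @param proteins Character vector of all protein ids (the vertex set).
#'   Defaults to the ids occurring in `hits`.
#' @param criteria An [edge_criteria()].
#' @param taxa Optional named character vector mapping protein id to taxon
#'   label, attached as a vertex attribute (defaults to the `taxon_of`
#'   attribute of `hits` if present).
#' @return An igraph undirected graph.
#' @export
build_network <- function(hits, proteins = NULL,
                          criteria = edge_criteria(), taxa = NULL) {
  taxa <- taxa %||% attr(hits, "taxon_of")
  if (is.null(proteins)) {
    proteins <- sort(unique(c(hits$query_id, hits$subject_id,
                              names(taxa))))
  }
  edges <- character(0)
  if (nrow(hits)) {
    pass <- hits[hit_passes(hits, criteria), , drop = FALSE]
    if (nrow(pass)) {
      key_fwd <- paste(pass$query_id, pass$subject_id, sep = "\r")
      key_rev <- paste(pass$subject_id, pass$query_id, sep = "\r")
      reciprocal <- key_rev %in% key_fwd
      p <- pass[reciprocal, , drop = FALSE]
      if (nrow(p)) {
        a <- pmin(p$query_id, p$subject_id)
        b <- pmax(p$query_id, p$subject_id)
        keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
        edges <- rbind(a[keep], b[keep])
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(proteins), name = proteins)
  if (length(edges)) {
    g <- igraph::add_edges(g, match(as.vector(edges), proteins))
  }
  if (!is.null(taxa)) {
    igraph::V(g)$taxon <- unname(taxa[proteins])
  }
  g
}

#' Extract gene-family components from the network
#'
#' Standard connected components, singletons included, ordered by
#' decreasing size and then by the lexicographically smallest member.
#'
#' @param graph An igraph graph from [build_network()].
#' @param taxa Optional named character vector (protein id to taxon);
#'   defaults to the graph's `taxon` vertex attribute.
#' @return A `family_components` object: a list with `components` (data
#'   frame: component_id, size, one `n_<taxon>` count column per taxon)
#'   and `membership` (data frame: protein_id, component_id, taxon).
#' @export
connected_components <- function(graph, taxa = NULL) {
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  if (is.null(taxa)) {
    tx <- igraph::vertex_attr(graph, "taxon")
    if (!is.null(tx)) taxa <- stats::setNames(tx, ids)
  }
  memb_raw <- split(ids, comp$membership)
  # order: decreasing size, then lexicographic smallest member
  sizes <- vapply(memb_raw, length, 0L)
  smallest <- vapply(memb_raw, function(x) min(x), "")
  o <- order(-sizes, smallest)
  memb_raw <- memb_raw[o]
  comp_ids <- sprintf("C%04d", seq_along(memb_raw))
  membership <- data.frame(
    protein_id = unlist(memb_raw, use.names = FALSE),
    component_id = rep(comp_ids, sizes[o]),
    stringsAsFactors = FALSE)
  membership$taxon <- if (!is.null(taxa))
    unname(taxa[membership$protein_id]) else NA_character_
  components <- data.frame(component_id = comp_ids, size = sizes[o],
                           stringsAsFactors = FALSE)
  taxa_levels <- if (!is.null(taxa)) unique(unname(taxa)) else character(0)
  for (t in taxa_levels) {
    counts <- vapply(memb_raw, function(x)
      sum(taxa[x] == t, na.rm = TRUE), 0L)
    components[[paste0("n_", t)]] <- unname(counts)
  }
  rownames(components) <- NULL
  structure(list(components = components, membership = membership,
                 taxa = taxa_levels),
            class = "family_components")
}

#' Classify components as contracted, expanded, balanced or absent
#'
#' A component is contracted iff the focal taxon has at least one member
#' but fewer than every comparator; absent-in-focal iff it has none while
#' every comparator has at least one; expanded iff it has more members
#' than every comparator and every comparator has at least one; balanced
#' otherwise.
#'
#' @param comps A `family_components` object with per-taxon counts.
#' @param focal Focal taxon label.
#' @param comparators Character vector of one or more comparator labels.
#' @return `comps` with a `representation_call` column added to
#'   `$components`.
#' @export
classify_components <- function(comps, focal, comparators) {
  stopifnot(inherits(comps, "family_components"),
            length(focal) == 1L, length(comparators) >= 1L)
  known <- comps$taxa
  unknown <- setdiff(c(focal, comparators), known)
  if (length(unknown)) {
    stop(sprintf("unknown taxon label(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  df <- comps$components
  fc <- df[[paste0("n_", focal)]]
  cc <- as.matrix(df[paste0("n_", comparators)])
  cmin <- apply(cc, 1, min)
  cmax <- apply(cc, 1, max)
  call <- rep("balanced", nrow(df))
  call[fc == 0 & cmin >= 1] <- "absent-in-focal"
  call[fc >= 1 & fc < cmin] <- "contracted"
  call[fc > cmax & cmin >= 1] <- "expanded"
  df$representation_call <- call
  comps$components <- df
  comps$focal <- focal
  comps$comparators <- comparators
  comps
}

#' Summarise classified components by functional category
#'
#' Each component's category is the majority annotation label among its
#' annotated members (ties give `"ambiguous"`, no annotated members
#' `"unknown"`). The summary reports, per category and representation
#' call, the number of components and the focal/comparator gene counts.
#'
#' @param comps A classified `family_components` (see
#'   [classify_components()]).
#' @param annotation_map Named character vector: protein id to category
#'   label; proteins absent from the map are unannotated.
#' @param exclude_categories Optional category blacklist: components whose
#'   category falls in this set are dropped from the summary table (e.g.
#'   to exclude photosynthesis-related products from a contraction count).
#' @return A list with `component_categories` (component_id, category) and
#'   `table` (category, representation_call, n_components, focal_genes,
#'   comparator_genes).
#' @export
summarize_categories <- function(comps, annotation_map,
                                 exclude_categories = character(0)) {
  stopifnot(inherits(comps, "family_components"))
  if (is.null(comps$components$representation_call)) {
    stop("components must be classified first (see classify_components)")
  }
  memb <- split(comps$membership$protein_id,
                comps$membership$component_id)
  category_of <- vapply(memb, function(members) {
    labels <- annotation_map[members]
    labels <- labels[!is.na(labels)]
    if (!length(labels)) return("unknown")
    tab <- sort(table(labels), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) "ambiguous" else names(tab)[1]
  }, "")
  cats <- data.frame(component_id = names(category_of),
                     category = unname(category_of),
                     stringsAsFactors = FALSE)
  df <- merge(comps$components, cats, by = "component_id")
  df <- df[!df$category %in% exclude_categories, , drop = FALSE]
  focal_col <- paste0("n_", comps$focal)
  comp_cols <- paste0("n_", comps$comparators)
  if (!nrow(df)) {
    return(list(component_categories = cats,
                table = data.frame(category = character(0),
                                   representation_call = character(0),
                                   n_components = integer(0),
                                   focal_genes = integer(0),
                                   comparator_genes = integer(0))))
  }
  agg <- do.call(rbind, lapply(
    split(df, list(df$category, df$representation_call), drop = TRUE),
    function(d) data.frame(
      category = d$category[1],
      representation_call = d$representation_call[1],
      n_components = nrow(d),
      focal_genes = sum(d[[focal_col]]),
      comparator_genes = sum(as.matrix(d[comp_cols])),
      stringsAsFactors = FALSE)))
  agg <- agg[order(agg$category, agg$representation_call), , drop = FALSE]
  rownames(agg) <- NULL
  list(component_categories = cats, table = agg)
}
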