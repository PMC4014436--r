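# Canned synthetic study designs.
#
# These fix the conditions of the two standard end-to-end exercises: a
# three-taxon family-contraction study and a chitinase-like expanded
# family carrying planted catalytic/accessory motifs. Keeping them in the
# package makes the ground truth of tests and reproduction scripts one
# definition rather than several copies.

#' Family specs for the three-taxon contraction/expansion study
#'
#' Thirty gene families emulating a focal parasite proteome against two
#' free-living relatives: ten contracted in the focal taxon (fewer focal
#' members than either comparator), fourteen balanced, three expanded and
#' three absent from the focal taxon. Ancestral lengths are 120-160
#' residues and within-family divergence 0.1, comfortably inside the
#' regime where reciprocal-alignment edges recover families exactly.
#' Contracted families are spread over three annotation categories
#' (`transport`, `translation`, `chromatin`) via the `category` attribute
#' attached to each spec.
#'
#' @return A list of [family_spec()] objects, each with a `category`
#'   attribute.
#' @export
contraction_study_specs <- function() {
  specs <- list()
  categories <- rep(c("transport", "translation", "chromatin"),
                    length.out = 10)
  contracted_counts <- list(c(1, 2, 2), c(1, 3, 2), c(1, 2, 3),
                            c(2, 3, 3), c(1, 2, 2), c(1, 3, 3),
                            c(2, 3, 4), c(1, 2, 2), c(1, 4, 2),
                            c(1, 2, 4))
  for (i in 1:10) {
    sp <- family_spec(sprintf("F%02d", i), contracted_counts[[i]],
                      ancestral_length = 120 + 4 * i,
                      within_divergence = 0.1)
    attr(sp, "category") <- categories[i]
    specs[[i]] <- sp
  }
  for (i in 11:24) {
    sp <- family_spec(sprintf("F%02d", i), c(2, 2, 2),
                      ancestral_length = 100 + 4 * i,
                      within_divergence = 0.1)
    attr(sp, "category") <- "metabolism"
    specs[[i]] <- sp
  }
  for (i in 25:27) {
    sp <- family_spec(sprintf("F%02d", i), c(4, 2, 2),
                      ancestral_length = 140,
                      within_divergence = 0.1)
    attr(sp, "category") <- "hydrolase"
    specs[[i]] <- sp
  }
  for (i in 28:30) {
    sp <- family_spec(sprintf("F%02d", i), c(0, 2, 2),
                      ancestral_length = 150,
                      within_divergence = 0.1)
    attr(sp, "category") <- "photosynthesis"
    specs[[i]] <- sp
  }
  specs
}

#' Annotation map implied by the contraction study
#'
#' @param truth The `truth_ledger` from running [generate_proteomes()] on
#'   [contraction_study_specs()].
#' @param specs The spec list the ledger came from.
#' @return Named character vector: protein id to category label.
#' @export
contraction_study_annotation <- function(truth, specs) {
  cat_of <- stats::setNames(
    vapply(specs, function(s) attr(s, "category"), ""),
    vapply(specs, function(s) s$family_id, ""))
  stats::setNames(unname(cat_of[truth$memberships$family_id]),
                  truth$memberships$protein_id)
}

#' Family spec for the chitinase-like expanded family
#'
#' One family with 14 focal members against 2 and 1 members in the
#' comparators (an expanded call), emulating a GH18 chitinase family
#' recently amplified in a parasite. Of the 14 focal members, ten carry
#' the canonical catalytic motif, three carry single-substitution variants
#' (D3 to G, D1 to T, and the catalytic E to P) and one lacks the
#' catalytic motif entirely, so 13 of 14 are catalytic-motif carriers.
#' All members carry the Kx6GG accessory motif and some additionally
#' MxYDx(x)G, always downstream of the catalytic position.
#'
#' @return A single [family_spec()].
#' @export
chitinase_study_spec <- function() {
  catalytic <- function(variant = "canonical")
    list(motif = "catalytic", variant = variant)
  kx <- list(motif = "Kx6GG")
  mx <- list(motif = "MxYDxG")
  focal_plans <- c(
    lapply(1:8, function(i) list(catalytic(), kx)),
    list(list(catalytic(), kx, mx),
         list(catalytic(), kx, mx),
         list(catalytic("D3->G"), kx),
         list(catalytic("D1->T"), kx),
         list(catalytic("E->P"), kx),
         list(kx))
  )
  comparator_plans <- rep(list(list(catalytic(), kx)), 3)
  family_spec("GH18", c(14, 2, 1), ancestral_length = 220,
              within_divergence = 0.08,
              motif_plan = c(focal_plans, comparator_plans))
}
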