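# GH18 chitinase motif scanning.
#
# GH18 chitinases carry a catalytic DxxDxDxE motif ending in the catalytic
# glutamate; chitinases with experimentally confirmed activity in insects
# and bacteria additionally carry one or more of three accessory motifs
# (Kx6GG, MxYDx(x)G, Gx3Wx2DxD). This module detects those motifs,
# tolerating single substitutions at the conserved positions of the
# catalytic motif (which may abolish chitinolytic activity and are
# therefore reported as variants rather than matches).

# Registry of the built-in motif patterns. Each pattern is a character
# vector with NA at wildcard positions; `conserved` indexes the positions
# whose substitution still yields a (variant) match for the catalytic
# motif, with the labels used in variant reports.
motif_registry <- function() {
  list(
    catalytic = list(
      forms = list(c("D", NA, NA, "D", NA, "D", NA, "E")),
      conserved = c(1L, 4L, 6L, 8L),
      labels = c("D1", "D2", "D3", "E")
    ),
    Kx6GG = list(
      forms = list(c("K", NA, NA, NA, NA, NA, NA, "G", "G"))
    ),
    MxYDxG = list(
      # either arity of the internal wildcard run counts
      forms = list(c("M", NA, "Y", "D", NA, "G"),
                   c("M", NA, "Y", "D", NA, NA, "G"))
    ),
    Gx3Wx2DxD = list(
      forms = list(c("G", NA, NA, NA, "W", NA, NA, "D", NA, "D"))
    )
  )
}

motif_names <- function() names(motif_registry())

# Does `chars[pos .. pos+len-1]` match `form` (NA = wildcard)?
window_matches <- function(chars, pos, form) {
  w <- chars[pos:(pos + length(form) - 1L)]
  fixed <- !is.na(form)
  all(w[fixed] == form[fixed])
}

#' Scan a protein for the GH18 catalytic motif
#'
#' Searches for the chitinase catalytic motif `DxxDxDxE` (wildcards free).
#' A window matching the full pattern anywhere yields a `"canonical"` call
#' at the leftmost such window. Failing that, a window in which exactly one
#' of the four conserved positions (the three aspartates and the terminal
#' glutamate) is substituted yields a `"variant"` call, reporting which
#' conserved position changed and to what; single substitutions at these
#' positions (e.g. the catalytic E replaced by P) are known to occur in
#' predicted chitinases and may abolish activity. Otherwise the motif is
#' `"absent"`. Leftmost windows win all ties.
#'
#' @param seq A protein sequence (character, `AAString`, or a length-1
#'   `AAStringSet`).
#' @return A list with elements `status` (one of `"canonical"`,
#'   `"variant"`, `"absent"`), `position` (1-based start of the matched
#'   window, `NA` if absent), and for variants `variant_position` (label
#'   among `D1`, `D2`, `D3`, `E`), `variant_from` and `variant_to`.
#' @examples
#' scan_catalytic("AAADAADADAEAAA")  # canonical at 4
#' scan_catalytic("DAADADAP")        # variant, E -> P
#' @export
scan_catalytic <- function(seq) {
  seq <- as_sequence_vector(seq)
  stopifnot(length(seq) == 1L, nchar(seq) > 0L)
  check_canonical(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  reg <- motif_registry()$catalytic
  form <- reg$forms[[1]]
  k <- length(form)
  n <- length(chars)
  absent <- list(status = "absent", position = NA_integer_)
  if (n < k) return(absent)
  starts <- seq_len(n - k + 1L)
  # canonical match anywhere beats any variant
  for (p in starts) {
    if (window_matches(chars, p, form)) {
      return(list(status = "canonical", position = p))
    }
  }
  for (p in starts) {
    w <- chars[p:(p + k - 1L)]
    mism <- reg$conserved[w[reg$conserved] != form[reg$conserved]]
    if (length(mism) == 1L) {
      i <- mism
      return(list(
        status = "variant", position = p,
        variant_position = reg$labels[match(i, reg$conserved)],
        variant_from = form[i], variant_to = w[i]
      ))
    }
  }
  absent
}

#' Scan a protein for the accessory chitinase motifs
#'
#' Exact-match scan (no variants) for the three accessory motifs found in
#' catalytically active insect and bacterial chitinases: `Kx6GG`,
#' `MxYDx(x)G` (either arity of the internal wildcard run counts) and
#' `Gx3Wx2DxD`. All match positions are reported.
#'
#' @inheritParams scan_catalytic
#' @return A data frame with columns `motif` and `position` (1-based
#'   start), one row per match, ordered by position; zero rows if nothing
#'   matches.
#' @examples
#' scan_accessory("KAAAAAAGG")
#' scan_accessory("MAYDAAG")
#' @export
scan_accessory <- function(seq) {
  seq <- as_sequence_vector(seq)
  stopifnot(length(seq) == 1L, nchar(seq) > 0L)
  check_canonical(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  reg <- motif_registry()
  out <- list()
  for (nm in setdiff(names(reg), "catalytic")) {
    hits <- integer(0)
    for (form in reg[[nm]]$forms) {
      k <- length(form)
      if (n < k) next
      for (p in seq_len(n - k + 1L)) {
        if (window_matches(chars, p, form)) hits <- c(hits, p)
      }
    }
    hits <- sort(unique(hits))
    if (length(hits)) {
      out[[nm]] <- data.frame(motif = nm, position = hits,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(motif = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Average molecular mass of a peptide
#'
#' Sums average-isotopic residue masses and adds one water (18.0153 Da).
#' No signal-peptide cleavage or modification is applied: the mass is that
#' of the full predicted peptide.
#'
#' @inheritParams scan_catalytic
#' @param units `"kDa"` (default; rounded to 2 decimals, the convention of
#'   predicted-protein summary tables) or `"Da"` (unrounded).
#' @return A numeric scalar.
#' @examples
#' peptide_mass("G")   # 0.08 kDa (free glycine, 75.07 Da)
#' peptide_mass("GG")  # 0.13
#' @export
peptide_mass <- function(seq, units = c("kDa", "Da")) {
  units <- match.arg(units)
  seq <- as_sequence_vector(seq)
  stopifnot(length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence has no defined peptide mass")
  check_canonical(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  da <- sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
  if (units == "Da") da else round_half_up(da / 1000, 2)
}

#' Motif report for a set of predicted chitinase proteins
#'
#' Produces one row per protein summarising the catalytic-motif status
#' (canonical / single-substitution variant / absent), presence and
#' position of each accessory motif, the order in which detected motifs
#' occur along the sequence, whether the prediction starts with a
#' methionine, the peptide length and its average mass in kDa.
#'
#' @param proteins A named character vector or `AAStringSet` of protein
#'   sequences.
#' @return A list with `report`, a data frame with columns `protein_id`,
#'   `catalytic_status`, `catalytic_position`, `catalytic_variant` (e.g.
#'   `"E->P"`, `NA` unless a variant), one `<motif>_position` column per
#'   accessory motif (`NA` if absent), `motif_order` (comma-separated
#'   detected motif names by ascending position), `met` (logical),
#'   `length` and `mass_kda`; and `summary`, a list with
#'   `n_catalytic` (canonical + variant carriers) and `n_accessory`
#'   (proteins with at least one accessory motif).
#' @export
build_motif_report <- function(proteins) {
  seqs <- as_sequence_vector(proteins)
  ids <- names(proteins) %||% names(seqs)
  if (is.null(ids) && length(seqs) > 0) {
    stop("proteins must be named")
  }
  acc_names <- setdiff(motif_names(), "catalytic")
  rows <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    cat_res <- scan_catalytic(s)
    acc <- scan_accessory(s)
    # first occurrence per accessory motif
    acc_pos <- vapply(acc_names, function(nm) {
      p <- acc$position[acc$motif == nm]
      if (length(p)) p[1] else NA_integer_
    }, integer(1))
    found <- c(
      if (cat_res$status != "absent")
        stats::setNames(cat_res$position, "catalytic"),
      acc_pos[!is.na(acc_pos)]
    )
    order_str <- if (length(found)) {
      paste(names(sort(found)), collapse = ",")
    } else ""
    data.frame(
      protein_id = ids[i],
      catalytic_status = cat_res$status,
      catalytic_position = cat_res$position,
      catalytic_variant = if (cat_res$status == "variant") {
        paste0(cat_res$variant_from, "->", cat_res$variant_to)
      } else NA_character_,
      as.list(stats::setNames(acc_pos, paste0(acc_names, "_position"))),
      motif_order = order_str,
      met = substr(s, 1, 1) == "M",
      length = nchar(s),
      mass_kda = peptide_mass(s),
      stringsAsFactors = FALSE
    )
  })
  report <- if (length(rows)) do.call(rbind, rows) else data.frame()
  summary <- list(
    n_catalytic = if (length(rows))
      sum(report$catalytic_status != "absent") else 0L,
    n_accessory = if (length(rows))
      sum(rowSums(!is.na(report[paste0(acc_names, "_position")])) > 0)
    else 0L
  )
  list(report = report, summary = summary)
}
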