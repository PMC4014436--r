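# Internal helpers shared across modules.

#' @importFrom methods is
NULL

# The 20 canonical amino acids, alphabetical one-letter codes.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average (isotope-abundance weighted) residue masses in Da, i.e. the
# monomer mass minus one water. Summing residues and adding back one
# water (18.0153 Da) gives the average peptide mass.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.0153

# round() in R rounds half to even; printed genome statistics use the
# conventional half-away-from-zero rule, so provide it explicitly.
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Coerce a protein argument to a plain uppercase character vector of
# sequences, accepting character, AAString or AAStringSet.
as_sequence_vector <- function(x) {
  if (is(x, "AAStringSet") || is(x, "AAString") || is(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x)) {
    stop("sequences must be character, AAString or AAStringSet", call. = FALSE)
  }
  toupper(x)
}

check_canonical <- function(seq, what = "sequence") {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("non-canonical residue '%s' at position %d in %s",
                 chars[bad[1]], bad[1], what), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
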