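# Shared sequence / numeric helpers.

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

# IUPAC code keyed by the sorted base set it stands for.
IUPAC_CODES <- c(
  "A" = "A", "C" = "C", "G" = "G", "U" = "U",
  "AG" = "R", "CU" = "Y", "CG" = "S", "AU" = "W", "GU" = "K", "AC" = "M",
  "CGU" = "B", "AGU" = "D", "ACU" = "H", "ACG" = "V", "ACGU" = "N"
)

# Base sets matched by each IUPAC code (RNA alphabet).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Transliterate DNA-alphabet sequences to RNA
#'
#' Replaces T/t with U/u. Used once on load so all internal sequence logic is
#' over \{A,C,G,U\}.
#'
#' @param x character vector of sequences.
#' @return character vector in the RNA alphabet.
#' @keywords internal
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' Reverse complement in the RNA alphabet
#'
#' @param x character vector of RNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' rna_revcomp("AGG") # "CCU"
rna_revcomp <- function(x) {
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Match a sequence against an IUPAC consensus
#'
#' Position-wise match of equal-length strings; "N" in the query matches
#' nothing unless the consensus position is N (padding bases are treated as
#' unknown, not wildcard).
#'
#' @param x character vector of sequences.
#' @param consensus single IUPAC string, same width as the sequences.
#' @return logical vector.
#' @export
iupac_match <- function(x, consensus) {
  cons <- strsplit(consensus, "", fixed = TRUE)[[1]]
  vapply(strsplit(x, "", fixed = TRUE), function(s) {
    if (length(s) != length(cons)) return(FALSE)
    all(vapply(seq_along(s),
               function(i) s[i] %in% IUPAC_SETS[[cons[i]]],
               logical(1)))
  }, logical(1))
}

.validate_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGU characters (after T->U): %s",
                 what, paste(utils::head(which(bad), 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed without
# touching the caller's RNG state.
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, k))
}

# Split a sequence into consecutive in-frame triplets.
split_codons <- function(sequence) {
  n <- nchar(sequence)
  if (n %% 3L != 0L) {
    stop("sequence length not divisible by 3; refusing to guess the frame",
         call. = FALSE)
  }
  substring(sequence, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
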