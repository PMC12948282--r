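# Reference handling: tRNA and CDS FASTA, gene sets, anticodon->codon maps.

#' Load a mature tRNA reference from FASTA
#'
#' Headers must carry an amino-acid / anticodon token of the form `"AA-NNN"`
#' (e.g. `"Pro-AGG-1"`, or `"tRNA-Val-AAC-2-1"`); the first such token is
#' used. Sequences are transliterated from DNA to RNA on load, the 3'-CCA tail
#' is appended when absent (reported via a message), and species with
#' identical mature sequences are collapsed into one family.
#'
#' @param path FASTA file.
#' @param candidate_position 1-based index of the canonical variable-loop
#'   guanosine probed for m7G (default 46). Positions are plain indices on the
#'   mature sequence; no Sprinzl alignment numbering is attempted.
#' @return A data.frame of class `trna_reference` with columns `id`,
#'   `amino_acid`, `anticodon`, `sequence`, `family_id`, `candidate_position`.
#' @export
load_trna_fasta <- function(path, candidate_position = 46L) {
  if (!file.exists(path)) stop("tRNA FASTA not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  trna_reference(
    id = names(seqs),
    sequence = as.character(seqs),
    candidate_position = candidate_position
  )
}

#' Construct a tRNA reference table
#'
#' In-memory constructor behind [load_trna_fasta()]; also used by the
#' synthetic-data generator.
#'
#' @param id record names carrying `"AA-NNN"` tokens.
#' @param sequence mature sequences (DNA or RNA alphabet).
#' @param candidate_position candidate m7G position (scalar or per-species).
#' @return `trna_reference` data.frame (see [load_trna_fasta()]).
#' @export
trna_reference <- function(id, sequence, candidate_position = 46L) {
  stopifnot(length(id) == length(sequence))
  parsed <- parse_trna_header(id)
  sequence <- toupper(dna_to_rna(sequence))
  .validate_rna(sequence, "tRNA sequence")
  no_cca <- !endsWith(sequence, "CCA")
  if (any(no_cca)) {
    message(sum(no_cca), " tRNA record(s) lacked the 3'-CCA tail; appended.")
    sequence[no_cca] <- paste0(sequence[no_cca], "CCA")
  }
  len <- nchar(sequence)
  if (any(len < 60L | len > 100L)) {
    stop("mature tRNA length outside [60, 100] for: ",
         paste(id[len < 60L | len > 100L], collapse = ", "), call. = FALSE)
  }
  has_ac <- mapply(grepl, parsed$anticodon, sequence, fixed = TRUE)
  if (!all(has_ac)) {
    stop("anticodon not found within the mature sequence for: ",
         paste(id[!has_ac], collapse = ", "), call. = FALSE)
  }
  candidate_position <- as.integer(rep_len(candidate_position, length(id)))
  if (any(candidate_position < 1L | candidate_position > len)) {
    stop("candidate_position outside the mature sequence", call. = FALSE)
  }
  out <- data.frame(
    id = id,
    amino_acid = parsed$amino_acid,
    anticodon = parsed$anticodon,
    sequence = sequence,
    family_id = paste0("fam", match(sequence, unique(sequence))),
    candidate_position = candidate_position,
    stringsAsFactors = FALSE
  )
  class(out) <- c("trna_reference", "data.frame")
  out
}

parse_trna_header <- function(id) {
  m <- regmatches(id, regexpr("[A-Za-z]{3}-[ACGTUacgtu]{3}", id))
  ok <- lengths(regmatches(id, gregexpr("[A-Za-z]{3}-[ACGTUacgtu]{3}", id))) > 0
  if (!all(ok)) {
    stop("malformed tRNA header (no 'AA-NNN' token): ",
         paste(id[!ok], collapse = ", "), call. = FALSE)
  }
  parts <- strsplit(m, "-", fixed = TRUE)
  list(
    amino_acid = vapply(parts, `[[`, character(1), 1L),
    anticodon = toupper(dna_to_rna(vapply(parts, `[[`, character(1), 2L)))
  )
}

#' @export
print.trna_reference <- function(x, ...) {
  cat("tRNA reference:", nrow(x), "species,",
      length(unique(x$family_id)), "families\n")
  print.data.frame(utils::head(x, 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more\n")
  invisible(x)
}

#' Load coding sequences from FASTA
#'
#' @param path FASTA of CDS records; each must begin with AUG and have length
#'   divisible by 3. DNA input is transliterated to RNA.
#' @return data.frame with `gene_id`, `sequence`.
#' @export
load_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("CDS FASTA not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  cds_table(sub("\\s.*$", "", names(seqs)), as.character(seqs))
}

#' Construct a CDS table
#' @param gene_id gene identifiers.
#' @param sequence CDS sequences (frame anchored at position 1, AUG start).
#' @return data.frame with `gene_id`, `sequence`.
#' @export
cds_table <- function(gene_id, sequence) {
  sequence <- toupper(dna_to_rna(sequence))
  .validate_rna(sequence, "CDS sequence")
  if (any(nchar(sequence) %% 3L != 0L)) {
    stop("CDS length not divisible by 3 for: ",
         paste(gene_id[nchar(sequence) %% 3L != 0L], collapse = ", "),
         call. = FALSE)
  }
  if (any(substr(sequence, 1L, 3L) != "AUG")) {
    stop("CDS does not start with AUG for: ",
         paste(gene_id[substr(sequence, 1L, 3L) != "AUG"], collapse = ", "),
         call. = FALSE)
  }
  data.frame(gene_id = gene_id, sequence = sequence, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over [fgsea::gmtPathways()] returning deduplicated,
#' non-empty sets.
#'
#' @param path GMT file (tab-separated: name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0L)) stop("empty gene set in ", path, call. = FALSE)
  sets
}

#' Map an anticodon to its cognate codon(s)
#'
#' With `wobble = FALSE` the single Watson-Crick codon (reverse complement in
#' the RNA alphabet) is returned. With `wobble = TRUE`, position-34 wobble
#' pairings are additionally expanded: anticodon-34 G also reads codons ending
#' in U (G:U) and anticodon-34 U also reads codons ending in G (U:G).
#'
#' @param anticodon 3-mer over \{A,C,G,U\} (T accepted, transliterated).
#' @param wobble expand position-34 G:U / U:G pairings?
#' @return character vector of codons (a codon set).
#' @export
#' @examples
#' anticodon_to_codons("AGG")            # "CCU"
#' anticodon_to_codons("GAA", wobble = TRUE) # "UUC" "UUU"
anticodon_to_codons <- function(anticodon, wobble = FALSE) {
  anticodon <- toupper(dna_to_rna(anticodon))
  if (nchar(anticodon) != 3L || grepl("[^ACGU]", anticodon)) {
    stop("invalid anticodon: ", anticodon, call. = FALSE)
  }
  wc <- rna_revcomp(anticodon)
  codons <- wc
  if (wobble) {
    pos34 <- substr(anticodon, 1L, 1L)
    stem <- substr(wc, 1L, 2L)
    if (pos34 == "G") codons <- c(codons, paste0(stem, "U"))
    if (pos34 == "U") codons <- c(codons, paste0(stem, "G"))
  }
  unique(codons)
}

#' Build a labelled codon set
#' @param codons character vector of codons.
#' @param label set label.
#' @param allow_stop permit stop codons in the set?
#' @return character vector with attribute `label`, class `codon_set`.
#' @export
codon_set <- function(codons, label = "m7G-related", allow_stop = FALSE) {
  codons <- unique(toupper(dna_to_rna(codons)))
  if (length(codons) && any(nchar(codons) != 3L | grepl("[^ACGU]", codons))) {
    stop("invalid codon in set", call. = FALSE)
  }
  if (!allow_stop && any(codons %in% STOP_CODONS)) {
    stop("stop codon in codon set (set allow_stop = TRUE to permit)",
         call. = FALSE)
  }
  structure(codons, label = label, class = c("codon_set", "character"))
}

#' Codons decoded by m7G-modified tRNAs
#'
#' Union of the cognate codons of every tRNA species carrying a called m7G
#' site.
#'
#' @param sites m7G call table (see [call_m7g_sites()]), or any data.frame
#'   with a `trna_id` column.
#' @param trnas `trna_reference`.
#' @param wobble see [anticodon_to_codons()].
#' @return `codon_set` labelled `"m7G-related"`.
#' @export
build_m7g_codon_set <- function(sites, trnas, wobble = FALSE) {
  if (NROW(sites) == 0L) return(codon_set(character(0)))
  unknown <- setdiff(sites$trna_id, trnas$id)
  if (length(unknown)) {
    stop("site references unknown tRNA id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  acs <- trnas$anticodon[match(unique(sites$trna_id), trnas$id)]
  codons <- unique(unlist(lapply(acs, anticodon_to_codons, wobble = wobble)))
  codon_set(codons)
}
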