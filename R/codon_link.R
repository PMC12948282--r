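# Codon-level link between m7G tRNAs and TE change: per-gene frequency of
# codons decoded by m7G-modified tRNAs, and its comparison across TE classes.

#' Fraction of m7G-related codons in a CDS
#'
#' Counts in-frame codons (frame anchored at position 1) belonging to
#' `codon_set`, divided by the number of non-stop codons; the start codon is
#' included in the denominator, stop codons are excluded from both.
#'
#' @param sequence CDS sequence(s) (length divisible by 3, RNA or DNA
#'   alphabet).
#' @param codon_set character vector of target codons (see [codon_set()]).
#' @return numeric vector of frequencies in \[0, 1\] (0 for an empty set or a
#'   CDS with no non-stop codons).
#' @export
m7g_codon_frequency <- function(sequence, codon_set) {
  sequence <- toupper(dna_to_rna(sequence))
  vapply(sequence, function(s) {
    cods <- split_codons(s)
    cods <- cods[!cods %in% STOP_CODONS]
    if (!length(cods) || !length(codon_set)) return(0)
    mean(cods %in% codon_set)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-gene codon frequency table
#'
#' @param cds CDS table (`gene_id`, `sequence`; see [load_cds_fasta()]).
#' @param codon_set target codon set.
#' @param te optional classified `te_table`; adds `te_class` per gene.
#' @return data.frame `gene_id`, `n_codons` (non-stop), `f_m7g`, and
#'   `te_class` when `te` is given.
#' @export
codon_frequency_table <- function(cds, codon_set, te = NULL) {
  n_codons <- vapply(cds$sequence, function(s) {
    cods <- split_codons(s)
    sum(!cods %in% STOP_CODONS)
  }, integer(1), USE.NAMES = FALSE)
  out <- data.frame(gene_id = cds$gene_id, n_codons = n_codons,
                    f_m7g = m7g_codon_frequency(cds$sequence, codon_set),
                    stringsAsFactors = FALSE)
  if (!is.null(te)) {
    out$te_class <- te$te_class[match(out$gene_id, te$gene_id)]
  }
  out
}

#' Compare m7G-codon frequency across TE classes
#'
#' Mann-Whitney U test of `f_m7g` in TE-down genes versus the reference class
#' (by default the pooled up + unchanged genes; `reference = "up"` restricts
#' to up only). The one-sided alternative is down > reference, matching the
#' expectation that translationally repressed genes are enriched for codons
#' decoded by m7G tRNAs; the two-sided p is reported alongside.
#'
#' @param freqs output of [codon_frequency_table()] with `te_class` set.
#' @param reference `"rest"` (up + unchanged) or `"up"`.
#' @param min_genes minimum genes per compared class (default 5).
#' @return list of class `codon_class_comparison`: `u_statistic`,
#'   `p_one_sided`, `p_two_sided`, `effect` (difference of medians,
#'   down - reference), `medians`, `n`.
#' @export
compare_by_te_class <- function(freqs, reference = c("rest", "up"),
                                min_genes = 5L) {
  reference <- match.arg(reference)
  stopifnot("te_class" %in% names(freqs))
  down <- freqs$f_m7g[!is.na(freqs$te_class) & freqs$te_class == "down"]
  ref_classes <- if (reference == "rest") c("up", "unchanged") else "up"
  rest <- freqs$f_m7g[!is.na(freqs$te_class) & freqs$te_class %in% ref_classes]
  n <- c(down = length(down), reference = length(rest))
  if (any(n < min_genes)) {
    warning("a TE class has fewer than ", min_genes,
            " genes; comparison not computed")
    return(structure(list(u_statistic = NA_real_, p_one_sided = NA_real_,
                          p_two_sided = NA_real_, effect = NA_real_,
                          medians = c(down = NA_real_, reference = NA_real_),
                          n = n),
                     class = "codon_class_comparison"))
  }
  one <- stats::wilcox.test(down, rest, alternative = "greater")
  two <- stats::wilcox.test(down, rest, alternative = "two.sided")
  structure(list(
    u_statistic = unname(one$statistic),
    p_one_sided = one$p.value, p_two_sided = two$p.value,
    effect = stats::median(down) - stats::median(rest),
    medians = c(down = stats::median(down), reference = stats::median(rest)),
    n = n), class = "codon_class_comparison")
}

#' @export
print.codon_class_comparison <- function(x, ...) {
  cat("m7G-codon frequency, TE-down vs reference\n")
  cat("  medians:", signif(x$medians[["down"]], 3), "vs",
      signif(x$medians[["reference"]], 3),
      " U:", x$u_statistic, "\n")
  cat("  one-sided p (down > ref):", signif(x$p_one_sided, 4),
      " two-sided p:", signif(x$p_two_sided, 4), "\n")
  invisible(x)
}

#' Per-transcript codon report for genes of interest
#'
#' For each requested gene: its m7G-codon frequency, per-target-codon counts,
#' and the rank of its frequency within the whole supplied transcriptome
#' (rank 1 = highest f; `rank_fraction` = rank / number of genes, so the top
#' decile has `rank_fraction <= 0.1`). Genes absent from the CDS table are
#' returned with NA values.
#'
#' @param cds CDS table for the transcriptome.
#' @param codon_set target codon set.
#' @param genes_of_interest character vector of gene ids.
#' @return data.frame: `gene_id`, `n_codons`, `f_m7g`, `rank`,
#'   `rank_fraction`, then one count column per target codon.
#' @export
transcript_codon_report <- function(cds, codon_set, genes_of_interest) {
  tab <- codon_frequency_table(cds, codon_set)
  rk <- rank(-tab$f_m7g, ties.method = "min")
  idx <- match(genes_of_interest, tab$gene_id)
  out <- data.frame(
    gene_id = genes_of_interest,
    n_codons = tab$n_codons[idx],
    f_m7g = tab$f_m7g[idx],
    rank = rk[idx],
    rank_fraction = rk[idx] / nrow(tab),
    stringsAsFactors = FALSE)
  if (length(codon_set)) {
    counts <- t(vapply(genes_of_interest, function(g) {
      i <- match(g, cds$gene_id)
      if (is.na(i)) return(rep(NA_integer_, length(codon_set)))
      cods <- split_codons(cds$sequence[i])
      as.integer(table(factor(cods, levels = codon_set)))
    }, integer(length(codon_set))))
    colnames(counts) <- as.character(codon_set)
    out <- cbind(out,
                 as.data.frame(counts, row.names = seq_along(genes_of_interest)))
  }
  out
}
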