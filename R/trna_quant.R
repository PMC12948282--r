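# tRNA abundance quantification (CPM) and modified-vs-unmodified comparison.

#' Quantify tRNA abundance per library
#'
#' From pileups, each family's count in a library is the sum over member
#' species of their maximum per-position coverage (robust to 5' truncation by
#' internal RT stops, which biases mean coverage in treated libraries). A
#' pre-made counts table (`trna_id`, `sample_id`, `count`) can be supplied
#' instead. CPM = count / library total x 1e6.
#'
#' @param pileup pileup data.frame, or NULL when `counts` is given.
#' @param counts optional counts data.frame (`trna_id`, `sample_id`, `count`).
#' @param trnas optional `trna_reference`; when given, counts are aggregated
#'   to `family_id`, otherwise each tRNA id is its own family.
#' @param condition when quantifying from pileups, which library condition to
#'   use (default `"control"`, i.e. the untreated libraries).
#' @return list of class `trna_expression`: integer `counts` matrix
#'   (families x samples), numeric `cpm` matrix, and `samples` data.frame
#'   (`sample_id`, `genotype` when available).
#' @export
quantify_trna <- function(pileup = NULL, counts = NULL, trnas = NULL,
                          condition = "control") {
  if (is.null(counts)) {
    stopifnot(!is.null(pileup))
    p <- pileup[pileup$condition == condition, , drop = FALSE]
    counts <- stats::aggregate(coverage ~ trna_id + sample_id, data = p,
                               FUN = max)
    names(counts)[names(counts) == "coverage"] <- "count"
    geno <- if ("genotype" %in% names(pileup)) {
      unique(pileup[, c("sample_id", "genotype")])
    }
  } else {
    geno <- if ("genotype" %in% names(counts)) {
      unique(counts[, c("sample_id", "genotype")])
    }
  }
  fam <- if (is.null(trnas)) counts$trna_id else {
    trnas$family_id[match(counts$trna_id, trnas$id)]
  }
  counts$family_id <- fam
  agg <- stats::aggregate(count ~ family_id + sample_id, data = counts,
                          FUN = sum)
  fams <- sort(unique(agg$family_id))
  samps <- sort(unique(agg$sample_id))
  cm <- matrix(0L, length(fams), length(samps),
               dimnames = list(fams, samps))
  cm[cbind(match(agg$family_id, fams), match(agg$sample_id, samps))] <-
    as.integer(agg$count)
  totals <- colSums(cm)
  if (any(totals == 0)) {
    stop("zero library total for sample(s): ",
         paste(samps[totals == 0], collapse = ", "), call. = FALSE)
  }
  cpm <- sweep(cm, 2, totals, "/") * 1e6
  samples <- data.frame(sample_id = samps, stringsAsFactors = FALSE)
  if (!is.null(geno)) {
    samples$genotype <- geno$genotype[match(samps, geno$sample_id)]
  }
  structure(list(counts = cm, cpm = cpm, samples = samples),
            class = "trna_expression")
}

#' @export
print.trna_expression <- function(x, ...) {
  cat("tRNA expression:", nrow(x$counts), "families x",
      ncol(x$counts), "libraries\n")
  invisible(x)
}

#' Compare expression change of m7G vs non-m7G tRNAs between genotypes
#'
#' Per family, log2FC = log2((mean CPM cKO + 1) / (mean CPM Ctrl + 1)).
#' Families containing a called m7G species form the `m7G` group; their
#' log2FCs are compared to the remaining families with a Mann-Whitney U test
#' (two-sided). When each genotype has >= 3 replicates, per-family two-sample
#' t-tests with BH correction are also reported.
#'
#' @param expr `trna_expression` with a `genotype` column in `$samples`.
#' @param calls `m7g_calls` (or any data.frame with `trna_id`).
#' @param trnas optional `trna_reference` to map called species to families.
#' @param genotypes reference and perturbed genotype labels.
#' @return list of class `trna_group_comparison`: `table` (per-family
#'   `log2fc`, `group`, `p`, `q`), `u_statistic`, `p_value`,
#'   `median_log2fc` (named per group).
#' @export
compare_trna_groups <- function(expr, calls, trnas = NULL,
                                genotypes = c("Ctrl", "cKO")) {
  stopifnot(inherits(expr, "trna_expression"),
            "genotype" %in% names(expr$samples))
  gt <- expr$samples$genotype
  if (!all(genotypes %in% gt)) {
    stop("both genotypes must be present in the expression matrix",
         call. = FALSE)
  }
  ctrl_cols <- expr$samples$sample_id[gt == genotypes[1]]
  cko_cols <- expr$samples$sample_id[gt == genotypes[2]]
  mean_ctrl <- rowMeans(expr$cpm[, ctrl_cols, drop = FALSE])
  mean_cko <- rowMeans(expr$cpm[, cko_cols, drop = FALSE])
  log2fc <- log2((mean_cko + 1) / (mean_ctrl + 1))
  called_fams <- if (is.null(trnas)) unique(calls$trna_id) else {
    unique(trnas$family_id[match(calls$trna_id, trnas$id)])
  }
  group <- ifelse(rownames(expr$cpm) %in% called_fams, "m7G", "non-m7G")
  tab <- data.frame(trna_id = rownames(expr$cpm), log2fc = log2fc,
                    group = group, p = NA_real_, q = NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (length(ctrl_cols) >= 3L && length(cko_cols) >= 3L) {
    lc <- log2(expr$cpm + 1)
    tab$p <- apply(lc, 1, function(v) {
      stats::t.test(v[cko_cols], v[ctrl_cols])$p.value
    })
    tab$q <- stats::p.adjust(tab$p, method = "BH")
  }
  if (min(table(factor(group, levels = c("m7G", "non-m7G")))) < 2L) {
    warning("a group has fewer than 2 members; group test not computed")
    wt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    wt <- stats::wilcox.test(log2fc[group == "m7G"],
                             log2fc[group == "non-m7G"], exact = TRUE)
  }
  med <- tapply(log2fc, group, stats::median)
  structure(list(table = tab, u_statistic = unname(wt$statistic),
                 p_value = wt$p.value, median_log2fc = med),
            class = "trna_group_comparison")
}

#' @export
print.trna_group_comparison <- function(x, ...) {
  cat("tRNA expression change, cKO vs Ctrl\n")
  cat("  median log2FC m7G:", signif(x$median_log2fc[["m7G"]], 3),
      " non-m7G:", signif(x$median_log2fc[["non-m7G"]], 3), "\n")
  cat("  Mann-Whitney U:", x$u_statistic, " p:", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' Write per-tRNA comparison results
#' @param comparison `trna_group_comparison`.
#' @param path TSV path for the per-family table.
#' @export
write_trna_comparison_tsv <- function(comparison, path) {
  utils::write.table(comparison$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
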