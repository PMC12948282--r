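# Translatome analysis: TPM, translation efficiency, TE-change classes,
# preranked gene-set enrichment, signature TE summaries, RNC-qPCR TE, and the
# polysome-to-monosome ratio.

#' Construct an assay count matrix
#'
#' @param counts genes x samples matrix of non-negative integer counts, with
#'   gene ids as row names.
#' @param lengths per-gene transcript lengths in nt (named or in row order).
#' @param genotype per-sample genotype labels (e.g. `"Ctrl"`, `"cKO"`).
#' @param assay `"ribo"` (ribosome-protected fragments) or `"rna"`.
#' @return list of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, genotype,
                         assay = c("ribo", "rna")) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts need gene ids as row names")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts) || anyNA(lengths)) {
    stop("missing length for gene(s): ",
         paste(utils::head(setdiff(rownames(counts), names(lengths)), 5),
               collapse = ", "), call. = FALSE)
  }
  stopifnot(all(lengths > 0), length(genotype) == ncol(counts),
            all(counts >= 0))
  structure(list(counts = counts, lengths = as.numeric(lengths),
                 genotype = as.character(genotype), assay = assay),
            class = "count_matrix")
}

#' Transcripts per million
#'
#' `rate = count / length`; `TPM = rate / sum(rate) x 1e6` per sample, so
#' every column sums to 1e6.
#'
#' @param counts `count_matrix`, or a plain matrix combined with `lengths`.
#' @param lengths per-gene lengths when `counts` is a plain matrix.
#' @return genes x samples TPM matrix.
#' @export
tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  if (is.null(lengths)) stop("gene lengths required", call. = FALSE)
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Translation efficiency per gene and genotype
#'
#' TE is the genotype-mean ribosome-footprint TPM over the genotype-mean
#' RNA-seq TPM, each offset by `pseudocount`; `log2dte` contrasts the two
#' genotypes. A gene is flagged `expressed` when its mean RNA TPM is at least
#' `expressed_min` in both genotypes.
#'
#' @param ribo `count_matrix` with `assay = "ribo"`.
#' @param rna `count_matrix` with `assay = "rna"`.
#' @param pseudocount TPM pseudocount (default 0.5).
#' @param genotypes reference and perturbed genotype labels.
#' @param expressed_min RNA TPM threshold for the expressed flag (default 1).
#' @return data.frame of class `te_table`: `gene_id`, `te_ctrl`, `te_cko`,
#'   `log2dte`, `expressed`.
#' @export
compute_te <- function(ribo, rna, pseudocount = 0.5,
                       genotypes = c("Ctrl", "cKO"), expressed_min = 1) {
  stopifnot(inherits(ribo, "count_matrix"), inherits(rna, "count_matrix"))
  if (ribo$assay != "ribo" || rna$assay != "rna") {
    stop("assay labels are swapped or wrong: got '", ribo$assay, "' and '",
         rna$assay, "'", call. = FALSE)
  }
  genes <- intersect(rownames(ribo$counts), rownames(rna$counts))
  if (!length(genes)) stop("no shared genes between assays", call. = FALSE)
  tpm_ribo <- tpm(ribo)[genes, , drop = FALSE]
  tpm_rna <- tpm(rna)[genes, , drop = FALSE]
  gmean <- function(m, gt, which) {
    rowMeans(m[, gt == which, drop = FALSE])
  }
  for (g in genotypes) {
    if (!any(ribo$genotype == g) || !any(rna$genotype == g)) {
      stop("genotype ", g, " missing from an assay", call. = FALSE)
    }
  }
  ribo_ctrl <- gmean(tpm_ribo, ribo$genotype, genotypes[1])
  ribo_cko <- gmean(tpm_ribo, ribo$genotype, genotypes[2])
  rna_ctrl <- gmean(tpm_rna, rna$genotype, genotypes[1])
  rna_cko <- gmean(tpm_rna, rna$genotype, genotypes[2])
  te_ctrl <- (ribo_ctrl + pseudocount) / (rna_ctrl + pseudocount)
  te_cko <- (ribo_cko + pseudocount) / (rna_cko + pseudocount)
  out <- data.frame(
    gene_id = genes, te_ctrl = te_ctrl, te_cko = te_cko,
    log2dte = log2(te_cko / te_ctrl),
    expressed = rna_ctrl >= expressed_min & rna_cko >= expressed_min,
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("te_table", "data.frame")
  out
}

#' Classify TE changes
#'
#' `down` when `log2dte <= -threshold_log2` and expressed, `up` when
#' `>= +threshold_log2` and expressed, otherwise `unchanged`; non-expressed
#' genes get `NA` (excluded from classes).
#'
#' @param te `te_table`.
#' @param threshold_log2 positive log2 threshold (default 1, i.e. 2-fold).
#' @return the `te_table` with a `te_class` column.
#' @export
classify_te <- function(te, threshold_log2 = 1) {
  if (!is.numeric(threshold_log2) || threshold_log2 <= 0) {
    stop("threshold_log2 must be positive", call. = FALSE)
  }
  cls <- rep(NA_character_, nrow(te))
  cls[te$expressed & te$log2dte <= -threshold_log2] <- "down"
  cls[te$expressed & te$log2dte >= threshold_log2] <- "up"
  cls[te$expressed & abs(te$log2dte) < threshold_log2] <- "unchanged"
  te$te_class <- cls
  te
}

# ---- preranked gene-set enrichment -----------------------------------------

# Running-sum enrichment score on a decreasing ranking. Hits advance by
# |r|^weight / sum(|r|^weight over the set); misses retreat by 1/(N - n).
# ES is the extremum of the running sum (largest absolute deviation).
.es_running <- function(ranked, in_set, weight) {
  n <- sum(in_set)
  N <- length(ranked)
  if (n == 0L) stop("gene set has no overlap with the ranking", call. = FALSE)
  if (n == N) return(list(es = 0, running = rep(0, N)))
  w <- abs(ranked)^weight
  hit <- ifelse(in_set, w, 0)
  denom <- sum(hit)
  if (denom == 0) hit <- as.numeric(in_set) else hit <- hit / denom
  if (denom == 0) hit <- hit / n
  miss <- ifelse(in_set, 0, 1 / (N - n))
  running <- cumsum(hit - miss)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' Preranked gene-set enrichment with a gene-sampling null
#'
#' Genes are ranked by the supplied statistic in decreasing order (GSEA
#' convention: up-shifted sets peak early and score positive ES; down-shifted
#' sets score negative ES). The enrichment score is the extremum of the
#' classic weighted Kolmogorov-Smirnov running sum. The null is built by
#' drawing `n_perm` random gene sets of the same size from the ranked
#' universe; NES divides ES by the mean |null ES| of the same sign, and the
#' empirical p-value is two-sided with a +1 correction. q-values are BH over
#' all sets tested in one call.
#'
#' @param ranking named numeric vector (e.g. `log2dte` per gene).
#' @param sets named list of gene-id vectors (a single character vector is
#'   treated as one set).
#' @param weight_exponent running-sum weight on |statistic| (default 1).
#' @param n_perm number of null gene sets (>= 100; default 1000).
#' @param seed RNG seed for the null draws.
#' @return data.frame of class `enrichment_result`: `set_name`, `size`, `es`,
#'   `nes`, `p`, `q`, `leading_edge` (comma-separated).
#' @export
preranked_enrichment <- function(ranking, sets, weight_exponent = 1,
                                 n_perm = 1000L, seed = 1L) {
  if (!is.list(sets)) sets <- list(set = sets)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  ord <- order(ranking, decreasing = TRUE)
  ranked <- ranking[ord]
  universe <- names(ranked)
  N <- length(ranked)
  seeds <- derive_seeds(seed, length(sets))
  rows <- lapply(seq_along(sets), function(si) {
    set <- unique(sets[[si]])
    set <- set[set %in% universe]
    if (!length(set)) {
      stop("gene set '", names(sets)[si], "' is entirely outside the ranking",
           call. = FALSE)
    }
    in_set <- universe %in% set
    fit <- .es_running(ranked, in_set, weight_exponent)
    es <- fit$es
    n <- length(set)
    null_es <- withr::with_seed(seeds[si], vapply(seq_len(n_perm), function(i) {
      idx <- logical(N)
      idx[sample.int(N, n)] <- TRUE
      .es_running(ranked, idx, weight_exponent)$es
    }, numeric(1)))
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    peak <- which.max(abs(fit$running))
    lead <- if (es >= 0) universe[seq_len(peak)][in_set[seq_len(peak)]] else {
      universe[peak:N][in_set[peak:N]]
    }
    data.frame(set_name = names(sets)[si], size = n, es = es, nes = nes,
               p = p, leading_edge = paste(lead, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set_name", "size", "es", "nes", "p", "q", "leading_edge")]
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Signature TE summary and one-sample test
#'
#' Collects per-gene TE in both genotypes for the signature genes and tests
#' their `log2dte` against zero with a Wilcoxon signed-rank test (two-sided).
#'
#' @param te `te_table` (classified or not).
#' @param signature character vector of signature gene ids (>= 3 must be in
#'   the TE universe).
#' @return list of class `signature_te`: `table` (gene, te_ctrl, te_cko,
#'   log2dte), `median_log2dte`, `statistic`, `p_value`.
#' @export
signature_te_summary <- function(te, signature) {
  sub <- te[te$gene_id %in% unique(signature), , drop = FALSE]
  if (nrow(sub) == 0L) stop("signature has no overlap with the TE table",
                            call. = FALSE)
  if (nrow(sub) < 3L) stop("fewer than 3 signature genes in the TE universe",
                           call. = FALSE)
  wt <- stats::wilcox.test(sub$log2dte, mu = 0, exact = TRUE)
  structure(list(
    table = sub[, c("gene_id", "te_ctrl", "te_cko", "log2dte")],
    median_log2dte = stats::median(sub$log2dte),
    statistic = unname(wt$statistic), p_value = wt$p.value),
    class = "signature_te")
}

#' @export
print.signature_te <- function(x, ...) {
  cat("Signature TE over", nrow(x$table), "genes; median log2dTE",
      signif(x$median_log2dte, 3), " signed-rank p", signif(x$p_value, 4), "\n")
  invisible(x)
}

#' TE from RNC / input qPCR Ct values
#'
#' Relative quantity per well is `RQ = 2^-(Ct_gene - Ct_ref)` against the
#' reference gene of the same fraction and replicate; per gene,
#' `TE = mean(RQ_RNC) / mean(RQ_input)`. The SEM of the ratio is propagated
#' by the delta method: `SEM(TE) = TE * sqrt(cv_RNC^2 + cv_input^2)` with
#' `cv = SEM/mean` per fraction.
#'
#' @param ct data.frame with columns `gene`, `fraction` (`"RNC"`/`"input"`),
#'   `replicate`, `ct`.
#' @param reference_gene the normaliser gene, required in both fractions.
#' @return data.frame `gene`, `te`, `sem`, `n_rnc`, `n_input`.
#' @export
rnc_te <- function(ct, reference_gene) {
  stopifnot(all(c("gene", "fraction", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0 | ct$ct >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  if (!all(c("RNC", "input") %in% ref$fraction)) {
    stop("reference gene missing from a fraction", call. = FALSE)
  }
  refkey <- paste(ref$fraction, ref$replicate)
  genes <- setdiff(unique(ct$gene), reference_gene)
  rows <- lapply(genes, function(g) {
    sub <- ct[ct$gene == g, , drop = FALSE]
    ref_ct <- ref$ct[match(paste(sub$fraction, sub$replicate), refkey)]
    rq <- 2^(-(sub$ct - ref_ct))
    keep <- !is.na(rq)
    rq <- rq[keep]
    frac <- sub$fraction[keep]
    if (!all(c("RNC", "input") %in% frac)) {
      warning("gene ", g, " missing a fraction; skipped")
      return(NULL)
    }
    mstats <- function(v) {
      c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v))
    }
    rn <- mstats(rq[frac == "RNC"])
    ip <- mstats(rq[frac == "input"])
    te <- rn[["mean"]] / ip[["mean"]]
    cv2 <- function(s) {
      if (is.na(s[["sem"]])) 0 else (s[["sem"]] / s[["mean"]])^2
    }
    data.frame(gene = g, te = te,
               sem = te * sqrt(cv2(rn) + cv2(ip)),
               n_rnc = rn[["n"]], n_input = ip[["n"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Polysome-to-monosome ratio from an absorbance trace
#'
#' Subtracts the trace minimum as baseline, then integrates the monosome and
#' polysome windows by the trapezoidal rule (with linear interpolation at the
#' exact window boundaries) and returns polysome area / monosome area.
#'
#' @param trace list with `position` (monotone increasing), `absorbance`, and
#'   `boundaries` (named: `mono_start`, `mono_end`, `poly_start`, `poly_end`).
#' @return the P/M area ratio.
#' @export
polysome_monosome_ratio <- function(trace) {
  b <- trace$boundaries
  need <- c("mono_start", "mono_end", "poly_start", "poly_end")
  stopifnot(all(need %in% names(b)))
  x <- trace$position
  y <- trace$absorbance - min(trace$absorbance)
  if (is.unsorted(x, strictly = TRUE)) {
    stop("trace positions must be strictly increasing", call. = FALSE)
  }
  bo <- unlist(b[need])
  if (is.unsorted(bo) || bo[1] < min(x) || bo[4] > max(x)) {
    stop("window boundaries must be ordered and inside the trace",
         call. = FALSE)
  }
  area <- function(lo, hi) {
    inside <- x > lo & x < hi
    xi <- c(lo, x[inside], hi)
    yi <- c(stats::approx(x, y, lo)$y, y[inside], stats::approx(x, y, hi)$y)
    pracma::trapz(xi, yi)
  }
  mono <- area(b[["mono_start"]], b[["mono_end"]])
  poly <- area(b[["poly_start"]], b[["poly_end"]])
  if (mono <= 0) stop("monosome window has zero area", call. = FALSE)
  poly / mono
}

#' Write a TE table / enrichment results as TSV
#' @param x `te_table` or `enrichment_result`.
#' @param path output TSV.
#' @export
write_result_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
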