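# TRAC-seq scoring: termination pileups, cleavage ratios/scores, m7G site
# calling, motif summary, and between-genotype cleavage comparison.
#
# Termination convention (shared with the read simulator): reverse
# transcription stops one nucleotide 3' of the m7G, so a read whose 5'-most
# aligned reference base is position s marks an RT stop at s-1: term[s-1] is
# incremented. A terminated read also contributes coverage at its stop base
# (s-1)..e, so that term[i] <= coverage[i] holds everywhere and the cleavage
# ratio term/coverage is the fraction of molecules that stopped at i among
# those that reached it.

#' Termination pileups from alignments
#'
#' @param alignments either a data.frame with columns `trna_id`, `start`,
#'   `end` (1-based, inclusive reference coordinates), or a path to a SAM/BAM
#'   file (requires Rsamtools/GenomicAlignments; unmapped and secondary
#'   alignments are skipped and reported).
#' @param trnas `trna_reference`.
#' @param sample_id library identifier stored in the output.
#' @param condition `"treated"` (chemistry on) or `"control"`.
#' @param genotype optional genotype label (e.g. `"Ctrl"`, `"cKO"`).
#' @return long-format pileup data.frame: `trna_id`, `position`, `coverage`,
#'   `term`, `sample_id`, `condition` (and `genotype` when given).
#' @export
pileup_from_alignments <- function(alignments, trnas, sample_id,
                                   condition = c("treated", "control"),
                                   genotype = NULL) {
  condition <- match.arg(condition)
  if (is.character(alignments) && length(alignments) == 1L) {
    alignments <- read_alignments_sam(alignments)
  }
  stopifnot(all(c("trna_id", "start", "end") %in% names(alignments)))
  unknown <- setdiff(unique(alignments$trna_id), trnas$id)
  if (length(unknown)) {
    stop("alignments reference unknown tRNA id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  lens <- stats::setNames(nchar(trnas$sequence), trnas$id)
  out <- lapply(trnas$id, function(tid) {
    L <- lens[[tid]]
    a <- alignments[alignments$trna_id == tid, , drop = FALSE]
    cov <- integer(L)
    term <- integer(L)
    if (nrow(a)) {
      if (any(a$start < 1L | a$end > L | a$start > a$end)) {
        stop("alignment outside reference for ", tid, call. = FALSE)
      }
      from <- pmax(1L, a$start - 1L)                  # stop base included
      inc <- tabulate(from, nbins = L)
      dec <- tabulate(a$end + 1L, nbins = L + 1L)[-1L]
      cov <- cumsum(inc - c(0L, utils::head(dec, -1L)))
      stops <- a$start[a$start > 1L] - 1L
      term <- tabulate(stops, nbins = L)
    }
    data.frame(trna_id = tid, position = seq_len(L),
               coverage = as.integer(cov), term = as.integer(term),
               sample_id = sample_id, condition = condition,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(genotype)) out$genotype <- genotype
  stopifnot(all(out$term <= out$coverage))
  out
}

# SAM/BAM -> alignment table (primary mapped alignments only).
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE)) {
    stop("reading SAM/BAM requires the Rsamtools and GenomicAlignments packages",
         call. = FALSE)
  }
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flags))
  total <- Rsamtools::countBam(path)$records
  if (total > length(ga)) {
    message(total - length(ga), " unmapped/secondary record(s) skipped")
  }
  data.frame(trna_id = as.character(GenomicAlignments::seqnames(ga)),
             start = GenomicAlignments::start(ga),
             end = GenomicAlignments::end(ga),
             stringsAsFactors = FALSE)
}

# Core pseudocounted ratio, vectorised.
.cl_ratio <- function(term, coverage, epsilon) {
  (term + epsilon) / (coverage + 2 * epsilon)
}

#' Cleavage ratio at one position
#'
#' Fraction of molecules terminating at the position among those covering it,
#' with a symmetric pseudocount: `(term + epsilon) / (coverage + 2 epsilon)`.
#'
#' @param profile pileup rows for one tRNA in one library.
#' @param position 1-based position.
#' @param epsilon pseudocount (default 0.5).
#' @return ratio in (0, 1) (in \[0, 1\] when `epsilon = 0`).
#' @export
cleavage_ratio <- function(profile, position, epsilon = 0.5) {
  i <- match(position, profile$position)
  if (is.na(i)) stop("position ", position, " out of range", call. = FALSE)
  .cl_ratio(profile$term[i], profile$coverage[i], epsilon)
}

#' Cleavage score at one position
#'
#' `log2` ratio of treated over control cleavage ratios; positive scores mean
#' more termination under the m7G-selective chemistry.
#'
#' @param treated,control pileup rows for the same tRNA in a treated and a
#'   control library.
#' @inheritParams cleavage_ratio
#' @return log2 cleavage score.
#' @export
cleavage_score <- function(treated, control, position, epsilon = 0.5) {
  if (!identical(unique(treated$trna_id), unique(control$trna_id))) {
    stop("treated and control profiles are for different tRNAs", call. = FALSE)
  }
  log2(cleavage_ratio(treated, position, epsilon) /
         cleavage_ratio(control, position, epsilon))
}

# positions x libraries matrices of term / coverage for one tRNA.
.pileup_matrices <- function(p) {
  samples <- unique(p$sample_id)
  L <- max(p$position)
  term <- cov <- matrix(0, nrow = L, ncol = length(samples),
                        dimnames = list(NULL, samples))
  idx <- cbind(p$position, match(p$sample_id, samples))
  term[idx] <- p$term
  cov[idx] <- p$coverage
  cond <- p$condition[match(samples, p$sample_id)]
  list(term = term, coverage = cov, condition = cond, samples = samples)
}

# Replicate-averaged score per position given a treated/control label vector:
# mean log2 ratio over treated libraries minus mean over control libraries.
.score_stat <- function(lograt, treated_idx) {
  nt <- length(treated_idx)
  rowSums(lograt[, treated_idx, drop = FALSE]) / nt -
    rowSums(lograt[, -treated_idx, drop = FALSE]) / (ncol(lograt) - nt)
}

#' Per-position cleavage profile for one tRNA
#'
#' Pools replicates within condition and reports per-position treated and
#' control ratios plus the log2 cleavage score.
#'
#' @param pileup pileup table covering one genotype.
#' @param trna_id tRNA to profile.
#' @param epsilon pseudocount.
#' @return data.frame `trna_id`, `position`, `ratio_treated`,
#'   `ratio_control`, `score`.
#' @export
cleavage_profile <- function(pileup, trna_id, epsilon = 0.5) {
  p <- pileup[pileup$trna_id == trna_id, , drop = FALSE]
  if (!nrow(p)) stop("no pileup rows for ", trna_id, call. = FALSE)
  agg <- stats::aggregate(cbind(term, coverage) ~ position + condition,
                          data = p, FUN = sum)
  tr <- agg[agg$condition == "treated", ]
  ct <- agg[agg$condition == "control", ]
  pos <- sort(unique(agg$position))
  rt <- .cl_ratio(tr$term[match(pos, tr$position)],
                  tr$coverage[match(pos, tr$position)], epsilon)
  rc <- .cl_ratio(ct$term[match(pos, ct$position)],
                  ct$coverage[match(pos, ct$position)], epsilon)
  data.frame(trna_id = trna_id, position = pos, ratio_treated = rt,
             ratio_control = rc, score = log2(rt / rc),
             stringsAsFactors = FALSE)
}

#' Call m7G sites from treated/control termination pileups
#'
#' Scans a candidate window (default 40-55, anchored on the canonical
#' variable-loop G46) of every tRNA. A position is eligible when the
#' reference base is G (if `require_G`) and mean treated coverage is at least
#' `coverage_min`. The replicate-averaged cleavage score (mean log2 treated
#' ratio minus mean log2 control ratio) is computed per eligible position; the
#' best-scoring position per tRNA (ties broken towards the 5' end) is emitted
#' as a call when its score reaches `score_min` and, if `motif_filter`, its
#' 5-mer context matches `motif`. At most one call per tRNA.
#'
#' Empirical p-values come from treated/control label permutations within each
#' tRNA (all label reassignments when each condition has at most 5 replicates,
#' otherwise `n_perm` random ones), taking the window maximum of the permuted
#' statistic; q-values are Benjamini-Hochberg across tRNAs. They annotate the
#' calls (`significant` flags `qvalue <= fdr`) but do not gate emission.
#'
#' @param trnas `trna_reference`.
#' @param pileup pileup table with at least one treated and one control
#'   library per tRNA (pre-filtered to one genotype, or use `genotype`).
#' @param score_min minimum replicate-averaged log2 score (default 1 = 2-fold).
#' @param coverage_min minimum mean treated coverage at the site (default 50).
#' @param window integer c(lo, hi) candidate window on the mature sequence.
#' @param require_G require a G at the called position (default TRUE).
#' @param motif_filter require the context to match `motif` for emission
#'   (default FALSE; the match is always reported).
#' @param motif IUPAC consensus for the 5-mer context (default `"RGGUY"`).
#' @param fdr BH level used for the `significant` flag.
#' @param n_perm random label permutations when exhaustive enumeration is not
#'   used.
#' @param seed seed for random permutations.
#' @param epsilon pseudocount for ratios.
#' @param genotype optional: restrict `pileup` to this genotype label first.
#' @return data.frame of class `m7g_calls`: `trna_id`, `position`, `score`,
#'   `mean_treated_coverage`, `context`, `motif_match`, `p`, `qvalue`,
#'   `significant`.
#' @export
call_m7g_sites <- function(trnas, pileup, score_min = 1, coverage_min = 50,
                           window = c(40L, 55L), require_G = TRUE,
                           motif_filter = FALSE, motif = "RGGUY",
                           fdr = 0.05, n_perm = 1000L, seed = 1L,
                           epsilon = 0.5, genotype = NULL) {
  if (!is.null(genotype)) {
    if (!"genotype" %in% names(pileup)) {
      stop("pileup has no genotype column", call. = FALSE)
    }
    pileup <- pileup[pileup$genotype == genotype, , drop = FALSE]
  }
  if (!any(pileup$condition == "control")) {
    stop("no control (untreated) library in the pileup", call. = FALSE)
  }
  if (!any(pileup$condition == "treated")) {
    stop("no treated library in the pileup", call. = FALSE)
  }
  seeds <- derive_seeds(seed, nrow(trnas))
  rows <- vector("list", nrow(trnas))
  for (k in seq_len(nrow(trnas))) {
    tid <- trnas$id[k]
    seqk <- trnas$sequence[k]
    L <- nchar(seqk)
    p <- pileup[pileup$trna_id == tid, , drop = FALSE]
    if (!nrow(p)) next
    m <- .pileup_matrices(p)
    tr_idx <- which(m$condition == "treated")
    ct_idx <- which(m$condition == "control")
    if (!length(tr_idx) || !length(ct_idx)) {
      stop("tRNA ", tid, " lacks a treated or control library", call. = FALSE)
    }
    cand <- seq.int(max(1L, window[1]), min(window[2], L))
    base <- substring(seqk, cand, cand)
    mean_cov <- rowMeans(m$coverage[cand, tr_idx, drop = FALSE])
    ok <- mean_cov >= coverage_min
    if (require_G) ok <- ok & base == "G"
    if (!any(ok)) next
    cand <- cand[ok]
    lograt <- log2(.cl_ratio(m$term[cand, , drop = FALSE],
                             m$coverage[cand, , drop = FALSE], epsilon))
    obs <- .score_stat(lograt, tr_idx)
    best <- which.max(obs)                      # ties -> first = smaller pos
    # permutation null of the window-maximum statistic
    n <- ncol(lograt)
    nt <- length(tr_idx)
    if (max(nt, n - nt) <= 5L) {
      perms <- utils::combn(n, nt, simplify = FALSE)
    } else {
      perms <- withr::with_seed(seeds[k], replicate(
        n_perm, sort(sample.int(n, nt)), simplify = FALSE))
    }
    null_max <- vapply(perms, function(ti) max(.score_stat(lograt, ti)),
                       numeric(1))
    pval <- mean(null_max >= max(obs))
    rows[[k]] <- data.frame(
      trna_id = tid, position = cand[best], score = obs[best],
      mean_treated_coverage = mean_cov[ok][best],
      context = .context5(seqk, cand[best]),
      p = pval, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(
    trna_id = character(0), position = integer(0), score = numeric(0),
    mean_treated_coverage = numeric(0), context = character(0),
    p = numeric(0))
  res$qvalue <- stats::p.adjust(res$p, method = "BH")
  res$motif_match <- iupac_match(res$context, motif)
  res$significant <- res$qvalue <= fdr
  res <- res[res$score >= score_min, , drop = FALSE]
  if (motif_filter) res <- res[res$motif_match, , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("trna_id", "position", "score", "mean_treated_coverage",
                 "context", "motif_match", "p", "qvalue", "significant")]
  class(res) <- c("m7g_calls", "data.frame")
  res
}

# 5-mer sequence context centred on pos, N-padded at the ends.
.context5 <- function(sequence, pos) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- (pos - 2L):(pos + 2L)
  ctx <- ifelse(idx >= 1L & idx <= length(chars), chars[pmax(idx, 1L)], "N")
  paste(ctx, collapse = "")
}

#' @export
print.m7g_calls <- function(x, ...) {
  cat("m7G site calls:", nrow(x), "tRNA(s)\n")
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Position weight matrix and consensus of called-site contexts
#'
#' Builds a 4 x 5 column-stochastic PWM over the 5-mer contexts of the calls
#' (pseudocount 0.25 per base; N padding characters are ignored) and an IUPAC
#' consensus listing, per column, every base with frequency >= 0.25.
#'
#' @param calls `m7g_calls` (non-empty).
#' @param trnas unused placeholder kept for interface symmetry; contexts are
#'   taken from the calls.
#' @return list of class `motif_summary` with `pwm`, `consensus`, `n`.
#' @export
summarize_motif <- function(calls, trnas = NULL) {
  if (NROW(calls) == 0L) stop("no calls to summarize", call. = FALSE)
  mat <- do.call(rbind, strsplit(calls$context, "", fixed = TRUE))
  pwm <- sapply(seq_len(ncol(mat)), function(j) {
    counts <- table(factor(mat[, j], levels = RNA_BASES)) + 0.25
    as.numeric(counts / sum(counts))
  })
  rownames(pwm) <- RNA_BASES
  consensus <- paste(vapply(seq_len(ncol(pwm)), function(j) {
    bases <- RNA_BASES[pwm[, j] >= 0.25]
    IUPAC_CODES[[paste(sort(bases), collapse = "")]]
  }, character(1)), collapse = "")
  structure(list(pwm = pwm, consensus = consensus, n = nrow(mat)),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat("Motif over", x$n, "site context(s); consensus:", x$consensus, "\n")
  print(round(x$pwm, 3))
  invisible(x)
}

#' Compare cleavage scores between genotypes
#'
#' Recomputes the replicate-averaged cleavage score at each called position in
#' both genotypes and tests the per-tRNA differences (cKO minus Ctrl) with a
#' paired Wilcoxon signed-rank test.
#'
#' @param calls `m7g_calls` from the control genotype.
#' @param pileup pileup table containing both genotypes (column `genotype`).
#' @param genotypes length-2 character: reference and perturbed genotype
#'   labels (default `c("Ctrl", "cKO")`).
#' @param epsilon pseudocount.
#' @return list of class `cleavage_comparison`: `table` (per-tRNA scores and
#'   `delta`), `statistic` (signed-rank V), `p_value`, `median_delta`.
#' @export
compare_cleavage <- function(calls, pileup, genotypes = c("Ctrl", "cKO"),
                             epsilon = 0.5) {
  stopifnot("genotype" %in% names(pileup))
  score_at <- function(gt, tid, pos) {
    p <- pileup[pileup$genotype == gt & pileup$trna_id == tid, , drop = FALSE]
    m <- .pileup_matrices(p)
    lograt <- log2(.cl_ratio(m$term[pos, , drop = FALSE],
                             m$coverage[pos, , drop = FALSE], epsilon))
    .score_stat(lograt, which(m$condition == "treated"))
  }
  tab <- data.frame(
    trna_id = calls$trna_id, position = calls$position,
    score_ctrl = mapply(function(t, p) score_at(genotypes[1], t, p),
                        calls$trna_id, calls$position),
    score_cko = mapply(function(t, p) score_at(genotypes[2], t, p),
                       calls$trna_id, calls$position),
    stringsAsFactors = FALSE)
  tab$delta <- tab$score_cko - tab$score_ctrl
  if (nrow(tab) < 3L) {
    warning("fewer than 3 paired tRNAs; signed-rank p not computed")
    wt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    wt <- stats::wilcox.test(tab$score_cko, tab$score_ctrl, paired = TRUE,
                             exact = TRUE)
  }
  structure(list(table = tab, statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 median_delta = stats::median(tab$delta)),
            class = "cleavage_comparison")
}

#' @export
print.cleavage_comparison <- function(x, ...) {
  cat("Cleavage score comparison over", nrow(x$table), "m7G tRNAs\n")
  cat("median delta (cKO - Ctrl):", signif(x$median_delta, 4),
      " signed-rank p:", signif(x$p_value, 4), "\n")
  invisible(x)
}

# ---- tabular IO -------------------------------------------------------------

#' Read / write the pileup TSV dialect
#'
#' Columns: `trna_id`, `position` (1-based), `coverage`, `term`, `sample_id`,
#' `condition`, and optionally `genotype`.
#'
#' @param path TSV file.
#' @return pileup data.frame.
#' @export
read_pileup_tsv <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("trna_id", "position", "coverage", "term", "sample_id", "condition")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("pileup TSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(p$term > p$coverage)) {
    stop("pileup invariant violated: term > coverage", call. = FALSE)
  }
  p
}

#' @rdname read_pileup_tsv
#' @param pileup pileup data.frame.
#' @export
write_pileup_tsv <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write m7G calls as TSV and as BED-like intervals
#'
#' The BED output is 0-based half-open (`start = position - 1`,
#' `end = position`), with the score in column 5.
#'
#' @param calls `m7g_calls`.
#' @param path output file.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$trna_id, start = calls$position - 1L,
                    end = calls$position, name = paste0("m7G_", calls$trna_id),
                    score = round(calls$score, 4), strand = "+")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a motif summary as JSON
#' @param motif `motif_summary`.
#' @param path output JSON file.
#' @export
write_motif_json <- function(motif, path) {
  jsonlite::write_json(
    list(consensus = motif$consensus, n = motif$n,
         pwm = as.data.frame(t(motif$pwm))),
    path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
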