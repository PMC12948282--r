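# End-to-end orchestration and clinical liver-volume utilities.

#' Liver regeneration index
#'
#' `(followup - remnant) / tlv` (`denominator = "tlv"`, total liver volume) or
#' `(followup - remnant) / remnant` (`denominator = "remnant"`, remaining
#' liver volume after hepatectomy). A negative index (follow-up volume below
#' the remnant) is returned but flagged with a warning.
#'
#' @param tlv total (pre-resection) liver volume, mL.
#' @param remnant post-resection remnant volume, mL (0 < remnant <= tlv).
#' @param followup volume at follow-up, mL (>= 0).
#' @param denominator which convention to use.
#' @return numeric vector of regeneration indices.
#' @export
#' @examples
#' regeneration_index(1000, 400, 700)                      # 0.30
#' regeneration_index(1000, 400, 700, denominator = "remnant") # 0.75
regeneration_index <- function(tlv, remnant, followup,
                               denominator = c("tlv", "remnant")) {
  denominator <- match.arg(denominator)
  if (any(remnant <= 0) || any(tlv <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(remnant > tlv)) {
    stop("remnant volume exceeds total liver volume", call. = FALSE)
  }
  if (any(followup < 0)) stop("follow-up volume must be >= 0", call. = FALSE)
  idx <- (followup - remnant) / switch(denominator, tlv = tlv,
                                       remnant = remnant)
  if (any(idx < 0)) {
    warning(sum(idx < 0), " record(s) with follow-up volume below the remnant",
            " (negative regeneration index)")
  }
  idx
}

# Every tunable consumed by any pipeline stage; the manifest must echo each.
PIPELINE_PARAMS <- c(
  "seed", "n_trna", "n_modified", "cleavage_eff_treated",
  "cleavage_eff_control", "cleavage_background", "cko_methylation",
  "coverage_per_trna", "cko_trna_log2fc", "modified_abundance_factor",
  "abundance_sdlog", "replicates", "n_genes", "down_fraction", "f_down_mean",
  "f_rest_mean", "f_concentration", "te_effect_slope", "te_effect_center",
  "dispersion", "mean_expression", "expression_sdlog", "te_class_threshold",
  "score_min", "coverage_min", "window", "motif", "fdr", "epsilon",
  "te_pseudocount", "expressed_min", "weight_exponent", "n_perm", "wobble"
)

#' Run the full analysis chain
#'
#' Executes reference -> TRAC-seq scoring -> tRNA quantification ->
#' translatome -> codon link on either a simulated fixture (default) or
#' user-supplied inputs, and returns per-stage results, a manifest echoing
#' every effective parameter, and a summary report asserting the expected
#' qualitative chain: modified tRNAs are down in the knockout, TE-down genes
#' are enriched for m7G-related codons, and the proliferative signature is
#' negatively enriched in the TE ranking.
#'
#' @param config `sim_config`; its seed drives every stochastic stage.
#' @param simulate generate the fixture from `config` (default). With
#'   `simulate = FALSE`, `inputs` must supply the data.
#' @param inputs named list of file paths for non-simulated runs:
#'   `trna_fasta`, `pileup` (TSV), `ribo_counts`, `rna_counts`, `cds_fasta`,
#'   and optionally `gene_sets` (GMT).
#' @param score_min,coverage_min,window,motif,fdr,epsilon site-caller
#'   parameters (see [call_m7g_sites()]).
#' @param te_pseudocount,expressed_min TE parameters (see [compute_te()]).
#' @param weight_exponent,n_perm enrichment parameters.
#' @param wobble wobble expansion for the codon set.
#' @param output_dir optional; when given, per-stage TSV/JSON outputs plus
#'   `manifest.json` and `report.json` are written there (content is a pure
#'   function of the config, so reruns are byte-identical).
#' @return list of class `m7g_pipeline`: stage results (`reference`,
#'   `calls`, `motif`, `cleavage_comparison`, `trna_comparison`, `codon_set`,
#'   `te`, `enrichment`, `signature_te`, `codon_freqs`, `codon_test`),
#'   `manifest`, `report`.
#' @export
run_pipeline <- function(config = sim_config(), simulate = TRUE,
                         inputs = list(),
                         score_min = 1, coverage_min = 50,
                         window = c(40L, 55L), motif = "RGGUY", fdr = 0.05,
                         epsilon = 0.5, te_pseudocount = 0.5,
                         expressed_min = 1, weight_exponent = 1,
                         n_perm = 1000L, wobble = FALSE,
                         output_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (simulate) {
    ref <- stage("reference", gen_trna_reference(config))
    trnas <- ref$trnas
    sim <- stage("tracseq_scoring", gen_tracseq_reads(config, ref))
    pileup <- sim$pileup
  } else {
    need <- c("trna_fasta", "pileup")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      stop("stage 'tracseq_scoring' failed: missing input(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    trnas <- stage("reference", load_trna_fasta(inputs$trna_fasta))
    pileup <- stage("tracseq_scoring", read_pileup_tsv(inputs$pileup))
    ref <- NULL
  }
  calls <- stage("tracseq_scoring", call_m7g_sites(
    trnas, pileup, score_min = score_min, coverage_min = coverage_min,
    window = window, motif = motif, fdr = fdr, epsilon = epsilon,
    seed = config$seed, genotype = if ("genotype" %in% names(pileup)) "Ctrl"))
  motif_sum <- stage("tracseq_scoring",
                     if (nrow(calls)) summarize_motif(calls))
  cleav_cmp <- stage("tracseq_scoring",
                     if ("genotype" %in% names(pileup) && nrow(calls) >= 3L) {
                       compare_cleavage(calls, pileup, epsilon = epsilon)
                     })
  expr <- stage("trna_quant", quantify_trna(pileup, trnas = trnas))
  trna_cmp <- stage("trna_quant", compare_trna_groups(expr, calls,
                                                      trnas = trnas))
  cset <- stage("codon_link", build_m7g_codon_set(calls, trnas,
                                                  wobble = wobble))
  if (simulate) {
    tl <- stage("translatome", gen_translatome(config, cset))
    ribo <- tl$ribo
    rna <- tl$rna
    cds <- tl$cds
    sets <- list(YAP_TAZ_signature = tl$signature)
  } else {
    for (f in c("ribo_counts", "rna_counts")) {
      if (is.null(inputs[[f]])) {
        stop("stage 'translatome' failed: missing input: ", f, call. = FALSE)
      }
    }
    ribo <- stage("translatome", read_counts_tsv(inputs$ribo_counts, "ribo"))
    rna <- stage("translatome", read_counts_tsv(inputs$rna_counts, "rna"))
    cds <- if (!is.null(inputs$cds_fasta)) {
      stage("codon_link", load_cds_fasta(inputs$cds_fasta))
    }
    sets <- if (!is.null(inputs$gene_sets)) {
      stage("translatome", read_gmt(inputs$gene_sets))
    } else stop("stage 'translatome' failed: missing input: gene_sets",
                call. = FALSE)
    tl <- NULL
  }
  te <- stage("translatome", classify_te(
    compute_te(ribo, rna, pseudocount = te_pseudocount,
               expressed_min = expressed_min),
    threshold_log2 = config$te_class_threshold))
  ranking <- stats::setNames(te$log2dte, te$gene_id)
  enr <- stage("translatome", preranked_enrichment(
    ranking, sets, weight_exponent = weight_exponent, n_perm = n_perm,
    seed = config$seed))
  sig_genes <- sets[[1]]
  sig_te <- stage("translatome", signature_te_summary(te, sig_genes))
  freqs <- stage("codon_link",
                 if (!is.null(cds)) codon_frequency_table(cds, cset, te))
  codon_test <- stage("codon_link",
                      if (!is.null(freqs)) compare_by_te_class(freqs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("m7gtrac")),
    simulate = simulate,
    parameters = c(unclass(config),
                   list(score_min = score_min, coverage_min = coverage_min,
                        window = window, motif = motif, fdr = fdr,
                        epsilon = epsilon, te_pseudocount = te_pseudocount,
                        expressed_min = expressed_min,
                        weight_exponent = weight_exponent, n_perm = n_perm,
                        wobble = wobble)),
    input_checksums = if (length(inputs)) {
      as.list(tools::md5sum(unlist(inputs)))
    } else list())
  report <- list(
    n_m7g_trnas_called = nrow(calls),
    motif_consensus = if (!is.null(motif_sum)) motif_sum$consensus,
    median_log2fc = if (!is.null(trna_cmp)) as.list(trna_cmp$median_log2fc),
    assertions = list(
      modified_trnas_down_in_cko =
        !is.null(trna_cmp) && !is.na(trna_cmp$p_value) &&
        trna_cmp$median_log2fc[["m7G"]] < trna_cmp$median_log2fc[["non-m7G"]] &&
        trna_cmp$p_value < 0.05,
      te_down_genes_codon_enriched =
        !is.null(codon_test) && !is.na(codon_test$p_one_sided) &&
        codon_test$effect > 0 && codon_test$p_one_sided < 0.05,
      signature_negatively_enriched =
        enr$nes[1] < 0 && enr$p[1] < 0.05))
  out <- structure(
    list(reference = if (simulate) ref else trnas, calls = calls,
         motif = motif_sum, cleavage_comparison = cleav_cmp,
         trna_expression = expr, trna_comparison = trna_cmp,
         codon_set = cset, te = te, enrichment = enr, signature_te = sig_te,
         codon_freqs = freqs, codon_test = codon_test,
         translatome = tl, manifest = manifest, report = report),
    class = "m7g_pipeline")
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir)
  out
}

write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calls_tsv(run$calls, file.path(dir, "m7g_calls.tsv"))
  write_calls_bed(run$calls, file.path(dir, "m7g_calls.bed"))
  if (!is.null(run$motif)) {
    write_motif_json(run$motif, file.path(dir, "motif.json"))
  }
  if (!is.null(run$cleavage_comparison)) {
    utils::write.table(run$cleavage_comparison$table,
                       file.path(dir, "cleavage_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_trna_comparison_tsv(run$trna_comparison,
                            file.path(dir, "trna_comparison.tsv"))
  write_result_tsv(run$te, file.path(dir, "te_table.tsv"))
  write_result_tsv(run$enrichment, file.path(dir, "enrichment.tsv"))
  if (!is.null(run$codon_freqs)) {
    write_result_tsv(run$codon_freqs, file.path(dir, "codon_frequencies.tsv"))
    jsonlite::write_json(run$codon_test[c("u_statistic", "p_one_sided",
                                          "p_two_sided", "effect")],
                         file.path(dir, "codon_test.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10)
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10)
  invisible(dir)
}

#' @export
print.m7g_pipeline <- function(x, ...) {
  cat("m7G translational-control pipeline run\n")
  cat("  m7G tRNAs called:", x$report$n_m7g_trnas_called,
      " motif:", x$report$motif_consensus %||% "-", "\n")
  a <- x$report$assertions
  cat("  modified tRNAs down in cKO: ", a$modified_trnas_down_in_cko,
      "\n  TE-down genes codon-enriched:", a$te_down_genes_codon_enriched,
      "\n  signature negatively enriched:", a$signature_negatively_enriched,
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
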