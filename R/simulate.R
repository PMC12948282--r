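# Synthetic-data generator with full ground truth: tRNA references with
# planted m7G sites, TRAC-seq termination reads/pileups for two genotypes,
# CDS sets with controlled m7G-codon content, Ribo-seq/RNA-seq counts with
# codon-dependent TE effects, and polysome traces with known area ratios.
#
# Every generator is a pure function of its config: identical inputs give
# identical outputs, and no caller RNG state is disturbed.

# Isoacceptor catalogue used to name synthetic species. The m7G panel size
# (12) mirrors the hepatocyte catalogue; ProAGG and ValAAC are modified and
# GlnCTG is not, matching the experimentally anchored memberships. The other
# panel members are synthetic stand-ins (plausible isoacceptors, not a
# published list).
M7G_PANEL <- c("Pro-AGG", "Val-AAC", "Pro-TGG", "Pro-CGG", "Val-CAC",
               "Val-TAC", "Lys-CTT", "Lys-TTT", "Arg-TCT", "Ala-AGC",
               "Ser-GCT", "Cys-GCA")
NONM7G_PANEL <- c("Gln-CTG", "Met-CAT", "Gln-TTG", "Glu-CTC", "Glu-TTC",
                  "Asp-GTC", "Gly-GCC", "Gly-CCC", "Gly-TCC", "His-GTG",
                  "Asn-GTT", "Ile-AAT", "Ile-TAT", "Leu-AAG", "Leu-CAG",
                  "Leu-TAG", "Leu-CAA", "Phe-GAA", "Ser-AGA", "Ser-CGA",
                  "Thr-AGT", "Thr-CGT", "Thr-TGT", "Trp-CCA", "Tyr-GTA",
                  "Arg-ACG", "Arg-CCG", "Arg-CCT")

#' Simulation configuration
#'
#' Collects and validates every generator parameter. Defaults define the
#' study conditions: a 40-species tRNA pool of which 12 carry an m7G at
#' position 46 inside an RGGUY context, strong treatment-dependent RT
#' termination (0.8 treated vs 0.05 untreated, plus a small
#' methylation-independent background), 2-fold down-regulation of modified
#' species in the knockout, and a 2000-gene translatome in which m7G-codon
#' content drives TE loss in the knockout through
#' `log2dTE = te_effect_slope * (f_m7g - te_effect_center)`.
#'
#' @param seed master seed; all sub-stages derive their own seeds from it.
#' @param n_trna number of tRNA species (>= 10; default 40).
#' @param n_modified size of the planted m7G panel (default 12).
#' @param cleavage_eff_treated,cleavage_eff_control per-molecule termination
#'   probability at a fully methylated site in treated / untreated libraries.
#' @param cleavage_background methylation-independent termination probability
#'   at candidate sites (both conditions, both genotypes).
#' @param cko_methylation residual methylation level of modified species in
#'   the knockout (0 = complete loss; default 0.1).
#' @param coverage_per_trna target mean reads per species per library.
#' @param cko_trna_log2fc planted abundance log2FC of modified species in the
#'   knockout (default -1).
#' @param modified_abundance_factor baseline abundance of modified species
#'   relative to unmodified ones (default 0.35, keeping the m7G pool a minor
#'   share of reads so CPM renormalisation stays mild).
#' @param abundance_sdlog lognormal spread of per-species abundances.
#' @param replicates libraries per genotype x condition (default 3).
#' @param n_genes translatome size (default 2000).
#' @param down_fraction fraction of genes in the high-f_m7g (TE-down) block.
#' @param f_down_mean,f_rest_mean target mean m7G-codon fraction in the two
#'   blocks (0.6 / 0.4).
#' @param f_concentration Beta concentration (a + b) of the f_m7g draws.
#' @param te_effect_slope,te_effect_center linear map from f_m7g to planted
#'   log2dTE (default -2.5 and 0.4).
#' @param dispersion negative-binomial gene-level dispersion (default 0.05).
#' @param mean_expression lognormal median of per-gene mean counts.
#' @param expression_sdlog lognormal spread of per-gene mean counts.
#' @param te_class_threshold |log2dTE| threshold used for planted TE class
#'   labels (matches the analysis default).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_trna = 40L, n_modified = 12L,
                       cleavage_eff_treated = 0.8,
                       cleavage_eff_control = 0.05,
                       cleavage_background = 0.01,
                       cko_methylation = 0.1,
                       coverage_per_trna = 1000L,
                       cko_trna_log2fc = -1,
                       modified_abundance_factor = 0.35,
                       abundance_sdlog = 0.25,
                       replicates = 3L,
                       n_genes = 2000L,
                       down_fraction = 0.25,
                       f_down_mean = 0.6, f_rest_mean = 0.4,
                       f_concentration = 18,
                       te_effect_slope = -2.5, te_effect_center = 0.4,
                       dispersion = 0.05,
                       mean_expression = 200, expression_sdlog = 1,
                       te_class_threshold = 1) {
  cfg <- as.list(environment())
  probs <- c(cleavage_eff_treated, cleavage_eff_control, cleavage_background,
             cko_methylation, down_fraction, f_down_mean, f_rest_mean)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_trna < 10L) stop("n_trna must be >= 10", call. = FALSE)
  if (n_modified < 2L || n_modified > n_trna - 2L) {
    stop("n_modified must leave at least 2 species in each group",
         call. = FALSE)
  }
  if (replicates < 1L || coverage_per_trna < 1L || n_genes < 10L) {
    stop("replicates, coverage_per_trna, n_genes out of range", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' Re-apply the structural modification rule to a reference
#'
#' A species is m7G-eligible iff the base at its candidate position is G and
#' the 5-mer context centred there matches RGGUY. This is the generator's
#' ground-truth definition, usable to re-scan any emitted reference.
#'
#' @param trnas `trna_reference`.
#' @return logical vector, one element per species.
#' @export
motif_eligible <- function(trnas) {
  ctx <- mapply(.context5, trnas$sequence, trnas$candidate_position)
  base <- substring(trnas$sequence, trnas$candidate_position,
                    trnas$candidate_position)
  unname(base == "G" & iupac_match(ctx, "RGGUY"))
}

#' Generate a tRNA reference with planted m7G sites
#'
#' Builds `n_trna` species with realistic mature lengths (70-90 nt body plus
#' CCA), the anticodon embedded at positions 34-36, and - for exactly the
#' panel species - a G at position 46 inside an RGGUY context. The four RGGUY
#' expansions are assigned to the panel in a balanced cycle so the planted
#' motif panel covers both R and both Y bases. Non-panel species receive a
#' non-G base at position 46, so the structural rule ([motif_eligible()])
#' recovers the panel exactly.
#'
#' @param config `sim_config`.
#' @param fasta optional path; when given the reference is also written as
#'   FASTA.
#' @return list of class `sim_reference`: `trnas` (`trna_reference`) and
#'   `ground_truth` data.frame (`trna_id`, `modified`, `position`, `weight`,
#'   `planted_log2fc`).
#' @export
gen_trna_reference <- function(config, fasta = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 2L)
  nm <- config$n_modified
  nu <- config$n_trna - nm
  ids_mod <- paste0(rep_len(M7G_PANEL, nm), "-",
                    (seq_len(nm) - 1L) %/% length(M7G_PANEL) + 1L)
  ids_unm <- paste0(rep_len(NONM7G_PANEL, nu), "-",
                    (seq_len(nu) - 1L) %/% length(NONM7G_PANEL) + 1L)
  ids <- c(ids_mod, ids_unm)
  anticodons <- toupper(dna_to_rna(sub("-[0-9]+$", "",
                                       sub("^[A-Za-z]{3}-", "", ids))))
  modified <- c(rep(TRUE, nm), rep(FALSE, nu))
  expansions <- c("AGGUC", "AGGUU", "GGGUC", "GGGUU")
  seqs <- withr::with_seed(seeds[1], {
    vapply(seq_along(ids), function(i) {
      repeat {
        L <- sample(70:90, 1L)
        s <- sample(RNA_BASES, L, replace = TRUE)
        s[34:36] <- strsplit(anticodons[i], "")[[1]]
        if (modified[i]) {
          ctx <- expansions[(i - 1L) %% 4L + 1L]
          s[44:48] <- strsplit(ctx, "")[[1]]
        } else {
          s[46] <- sample(c("A", "C", "U"), 1L)
        }
        seq <- paste(c(s, "C", "C", "A"), collapse = "")
        # forbid accidental anticodon loss or duplicate bodies
        if (grepl(anticodons[i], seq, fixed = TRUE)) return(seq)
      }
    }, character(1))
  })
  while (anyDuplicated(seqs)) {  # vanishingly unlikely; resample dupes
    dup <- which(duplicated(seqs))
    seqs[dup] <- withr::with_seed(seeds[1] + 1L, vapply(dup, function(i) {
      chartr("ACGU", "CGUA", seqs[i])
    }, character(1)))
  }
  trnas <- trna_reference(ids, seqs, candidate_position = 46L)
  elig <- motif_eligible(trnas)
  stopifnot(identical(elig, modified))   # rule round-trips by construction
  weight <- withr::with_seed(seeds[2], {
    base <- ifelse(modified, config$modified_abundance_factor, 1)
    base * stats::rlnorm(length(ids), 0, config$abundance_sdlog)
  })
  gt <- data.frame(trna_id = ids, modified = modified,
                   position = ifelse(modified, 46L, NA_integer_),
                   weight = weight,
                   planted_log2fc = ifelse(modified, config$cko_trna_log2fc, 0),
                   stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    ss <- Biostrings::BStringSet(stats::setNames(trnas$sequence, trnas$id))
    Biostrings::writeXStringSet(ss, fasta)
  }
  structure(list(trnas = trnas, ground_truth = gt), class = "sim_reference")
}

# termination probability at the planted site for one species/library
.term_prob <- function(config, modified, genotype, condition) {
  if (!modified) return(0)
  meth <- if (genotype == "cKO") config$cko_methylation else 1
  eff <- if (condition == "treated") config$cleavage_eff_treated else {
    config$cleavage_eff_control
  }
  min(1, meth * eff + config$cleavage_background)
}

#' Generate TRAC-seq libraries (pileups and optionally reads)
#'
#' For each genotype x condition x replicate library, per-species read counts
#' are multinomial over genotype-dependent abundances (modified species are
#' scaled by `2^cko_trna_log2fc` in the knockout). Each read of a modified
#' species terminates at the planted site with the library's termination
#' probability (methylation level x chemistry efficiency + background);
#' terminated reads span site..3'-end with their RT stop at the site,
#' read-through reads span the full molecule. Emitted pileups follow the same
#' convention as the scorer, and when reads are materialised the pileups are
#' their exact aggregation.
#'
#' @param config `sim_config`.
#' @param reference `sim_reference` from [gen_trna_reference()].
#' @param return_reads also return per-library read tables (id, sequence)?
#' @param fastq_dir optional directory; when given, one FASTQ per library is
#'   written (Sanger Phred+33, constant quality).
#' @return list of class `sim_tracseq`: `pileup` (all libraries, long
#'   format), `sample_table`, and `reads` (named list or NULL).
#' @export
gen_tracseq_reads <- function(config, reference, return_reads = FALSE,
                              fastq_dir = NULL) {
  stopifnot(inherits(reference, "sim_reference"))
  trnas <- reference$trnas
  gt <- reference$ground_truth
  libs <- expand.grid(replicate = seq_len(config$replicates),
                      condition = c("treated", "control"),
                      genotype = c("Ctrl", "cKO"),
                      stringsAsFactors = FALSE)
  libs$sample_id <- with(libs, paste(genotype, condition, replicate, sep = "_"))
  seeds <- derive_seeds(config$seed + 1L, nrow(libs))
  want_reads <- return_reads || !is.null(fastq_dir)
  pileups <- vector("list", nrow(libs))
  reads <- if (want_reads) stats::setNames(vector("list", nrow(libs)),
                                           libs$sample_id)
  lens <- nchar(trnas$sequence)
  n_total <- config$n_trna * config$coverage_per_trna
  for (li in seq_len(nrow(libs))) {
    gtp <- libs$genotype[li]
    cond <- libs$condition[li]
    w <- gt$weight * 2^(if (gtp == "cKO") gt$planted_log2fc else 0)
    draw <- withr::with_seed(seeds[li], {
      n_i <- as.integer(stats::rmultinom(1, n_total, w / sum(w)))
      k_i <- mapply(function(n, mod) {
        stats::rbinom(1L, n, .term_prob(config, mod, gtp, cond))
      }, n_i, gt$modified)
      list(n = n_i, k = as.integer(k_i))
    })
    rows <- lapply(seq_len(nrow(trnas)), function(i) {
      L <- lens[i]
      n <- draw$n[i]; k <- draw$k[i]
      site <- gt$position[i]
      cov <- rep.int(n - k, L)
      term <- integer(L)
      if (k > 0L) {
        cov[site:L] <- cov[site:L] + k
        term[site] <- k
      }
      data.frame(trna_id = trnas$id[i], position = seq_len(L),
                 coverage = cov, term = term,
                 sample_id = libs$sample_id[li], condition = cond,
                 genotype = gtp, stringsAsFactors = FALSE)
    })
    pileups[[li]] <- do.call(rbind, rows)
    if (want_reads) {
      rd <- lapply(seq_len(nrow(trnas)), function(i) {
        n <- draw$n[i]; k <- draw$k[i]
        if (n == 0L) return(NULL)
        full <- trnas$sequence[i]
        seqs <- rep.int(full, n - k)
        if (k > 0L) {
          seqs <- c(seqs, rep.int(substring(full, gt$position[i] + 1L), k))
        }
        data.frame(id = sprintf("%s:%s:%d", libs$sample_id[li], trnas$id[i],
                                seq_len(n)),
                   sequence = seqs, stringsAsFactors = FALSE)
      })
      reads[[li]] <- do.call(rbind, rd)
    }
  }
  pileup <- do.call(rbind, pileups)
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    for (li in seq_len(nrow(libs))) {
      rd <- reads[[li]]
      ss <- Biostrings::DNAStringSet(chartr("U", "T", rd$sequence))
      names(ss) <- rd$id
      qual <- Biostrings::BStringSet(strrep("I", nchar(rd$sequence)))
      Biostrings::writeXStringSet(
        ss, file.path(fastq_dir, paste0(libs$sample_id[li], ".fastq")),
        format = "fastq", qualities = qual)
    }
  }
  structure(list(pileup = pileup, sample_table = libs,
                 reads = if (return_reads) reads),
            class = "sim_tracseq")
}

#' Exact-match alignment of synthetic reads to the tRNA reference
#'
#' Reads are located by exact substring search against each mature sequence
#' (the synthetic species are unique by construction, so real aligners are
#' unnecessary here). Reads matching zero or multiple species are skipped and
#' reported.
#'
#' @param reads data.frame with `id`, `sequence` (RNA or DNA alphabet), or a
#'   FASTQ path.
#' @param trnas `trna_reference`.
#' @return alignment data.frame (`trna_id`, `start`, `end`) for
#'   [pileup_from_alignments()].
#' @export
align_reads_exact <- function(reads, trnas) {
  if (is.character(reads) && length(reads) == 1L) {
    ss <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- data.frame(id = names(ss), sequence = as.character(ss),
                        stringsAsFactors = FALSE)
  }
  seqs <- toupper(dna_to_rna(reads$sequence))
  uniq <- unique(seqs)
  hit <- lapply(uniq, function(s) {
    pos <- vapply(trnas$sequence, function(ref) {
      regexpr(s, ref, fixed = TRUE)[1]
    }, integer(1), USE.NAMES = FALSE)
    which(pos > 0L)
  })
  nhit <- lengths(hit)
  if (any(nhit != 1L)) {
    message(sum(nhit == 0L), " unmappable and ", sum(nhit > 1L),
            " ambiguous unique read sequence(s) skipped")
  }
  keep <- nhit == 1L
  ref_i <- vapply(hit[keep], `[[`, integer(1), 1L)
  start <- mapply(function(s, ri) regexpr(s, trnas$sequence[ri],
                                          fixed = TRUE)[1],
                  uniq[keep], ref_i)
  map <- match(seqs, uniq[keep])
  ok <- !is.na(map)
  data.frame(trna_id = trnas$id[ref_i][map[ok]],
             start = as.integer(start[map[ok]]),
             end = as.integer(start[map[ok]] + nchar(seqs[ok]) - 1L),
             stringsAsFactors = FALSE)
}

#' Generate a translatome with codon-dependent TE effects
#'
#' Genes are split into a high-f_m7g block (target mean 0.6; contains the
#' six-gene proliferative signature Areg, Birc5, Ctfg, Ccnb1, Cyr61, Foxm1,
#' given fixed codon-rich targets 0.66-0.76) and a background block (target
#' mean 0.4). Each CDS is assembled from an exact count of target codons
#' (`round(f * n_codons)`) shuffled among non-target non-stop codons, so the
#' realised fraction matches its target to within half a codon. The planted
#' TE effect is `te_effect_slope * (f_realised - te_effect_center)`, applied
#' to knockout ribosome-footprint means only; counts are negative-binomial
#' with the configured dispersion.
#'
#' @param config `sim_config`.
#' @param codon_set target codons (typically from [build_m7g_codon_set()] on
#'   the generated reference's modified species).
#' @param dir optional output directory (CDS FASTA, two counts TSVs, GMT of
#'   the signature, ground-truth JSON).
#' @return list of class `sim_translatome`: `cds`, `ribo`, `rna`
#'   (`count_matrix`), `ground_truth`, `signature` (character vector),
#'   `sample_table`.
#' @export
gen_translatome <- function(config, codon_set, dir = NULL) {
  stopifnot(inherits(config, "sim_config"), length(codon_set) >= 1L)
  other_pool <- setdiff(
    apply(expand.grid(RNA_BASES, RNA_BASES, RNA_BASES), 1, paste,
          collapse = ""),
    c(STOP_CODONS, as.character(codon_set)))
  if (length(other_pool) < 2L) {
    stop("codon_set leaves too few background codons", call. = FALSE)
  }
  n <- config$n_genes
  n_down <- max(6L, round(n * config$down_fraction))
  signature <- c("Areg", "Birc5", "Ctfg", "Ccnb1", "Cyr61", "Foxm1")
  gene_id <- c(signature,
               sprintf("gene%04d", seq_len(n - length(signature))))
  down_block <- seq_len(n) <= n_down
  seeds <- derive_seeds(config$seed + 2L, 4L)
  conc <- config$f_concentration
  f_target <- withr::with_seed(seeds[1], {
    f <- numeric(n)
    f[down_block] <- stats::rbeta(n_down, config$f_down_mean * conc,
                                  (1 - config$f_down_mean) * conc)
    f[!down_block] <- stats::rbeta(n - n_down, config$f_rest_mean * conc,
                                   (1 - config$f_rest_mean) * conc)
    f[seq_along(signature)] <- seq(0.66, 0.76,
                                   length.out = length(signature))
    pmin(pmax(f, 0.05), 0.95)
  })
  aug_in <- "AUG" %in% codon_set
  built <- withr::with_seed(seeds[2], {
    n_codons <- sample(150:500, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(g) {
      nc <- n_codons[g]
      m <- round(f_target[g] * nc)
      m_rest <- max(0L, m - as.integer(aug_in))
      m_rest <- min(m_rest, nc - 1L)
      body <- c(sample(as.character(codon_set), m_rest, replace = TRUE),
                sample(other_pool, nc - 1L - m_rest, replace = TRUE))
      paste(c("AUG", sample(body), "UAA"), collapse = "")
    }, character(1))
    list(n_codons = n_codons, seqs = seqs)
  })
  cds <- cds_table(gene_id, built$seqs)
  f_real <- m7g_codon_frequency(cds$sequence, codon_set)
  planted <- config$te_effect_slope * (f_real - config$te_effect_center)
  thr <- config$te_class_threshold
  planted_class <- ifelse(planted <= -thr, "down",
                          ifelse(planted >= thr, "up", "unchanged"))
  lengths_nt <- nchar(cds$sequence)
  reps <- config$replicates
  sample_ids <- paste(rep(c("Ctrl", "cKO"), each = reps),
                      seq_len(reps), sep = "_")
  genotype <- rep(c("Ctrl", "cKO"), each = reps)
  mu <- withr::with_seed(seeds[3], {
    list(expr = stats::rlnorm(n, log(config$mean_expression),
                              config$expression_sdlog),
         te_base = stats::rlnorm(n, 0, 0.25))
  })
  nb_matrix <- function(means_by_geno, seed) {
    withr::with_seed(seed, {
      m <- vapply(seq_along(sample_ids), function(j) {
        mu_j <- means_by_geno[[genotype[j]]]
        if (config$dispersion > 0) {
          stats::rnbinom(n, size = 1 / config$dispersion, mu = mu_j)
        } else {
          stats::rpois(n, mu_j)
        }
      }, numeric(n))
      dimnames(m) <- list(gene_id, sample_ids)
      m
    })
  }
  rna_counts <- nb_matrix(list(Ctrl = mu$expr, cKO = mu$expr),
                          seeds[4])
  ribo_counts <- nb_matrix(
    list(Ctrl = mu$expr * mu$te_base,
         cKO = mu$expr * mu$te_base * 2^planted),
    seeds[4] + 1L)
  ribo <- count_matrix(ribo_counts, lengths_nt, genotype, "ribo")
  rna <- count_matrix(rna_counts, lengths_nt, genotype, "rna")
  gt <- data.frame(gene_id = gene_id, n_codons = built$n_codons,
                   f_target = f_target, f_m7g = f_real,
                   planted_log2dte = planted, te_class = planted_class,
                   down_block = down_block,
                   signature = gene_id %in% signature,
                   stringsAsFactors = FALSE)
  out <- structure(list(cds = cds, ribo = ribo, rna = rna, ground_truth = gt,
                        signature = signature,
                        sample_table = data.frame(sample_id = sample_ids,
                                                  genotype = genotype)),
                   class = "sim_translatome")
  if (!is.null(dir)) write_translatome(out, dir)
  out
}

write_translatome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ss <- Biostrings::BStringSet(stats::setNames(sim$cds$sequence,
                                               sim$cds$gene_id))
  Biostrings::writeXStringSet(ss, file.path(dir, "cds.fasta"))
  for (assay in c("ribo", "rna")) {
    cm <- sim[[assay]]
    tab <- data.frame(gene_id = rownames(cm$counts), length = cm$lengths,
                      cm$counts, check.names = FALSE)
    utils::write.table(tab, file.path(dir, paste0(assay, "_counts.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(paste(c("YAP_TAZ_signature", "proliferative targets",
                     sim$signature), collapse = "\t"),
             file.path(dir, "signature.gmt"))
  jsonlite::write_json(sim$ground_truth,
                       file.path(dir, "translatome_ground_truth.json"),
                       digits = 10)
  invisible(dir)
}

#' Read a counts TSV (gene_id, length, sample columns)
#'
#' Sample genotypes are taken from the column-name prefix before the last
#' underscore (e.g. `Ctrl_1`, `cKO_2`).
#'
#' @param path counts TSV written by the generator or of the same dialect.
#' @param assay `"ribo"` or `"rna"`.
#' @return `count_matrix`.
#' @export
read_counts_tsv <- function(path, assay) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "length") %in% names(tab)))
  samples <- setdiff(names(tab), c("gene_id", "length"))
  m <- as.matrix(tab[, samples, drop = FALSE])
  rownames(m) <- tab$gene_id
  count_matrix(m, tab$length, sub("_[^_]*$", "", samples), assay)
}

#' Generate a polysome absorbance trace with a known area ratio
#'
#' One monosome Gaussian peak and three polysome Gaussian peaks whose
#' amplitudes are scaled so the analytic polysome/monosome area ratio equals
#' `poly_mono_ratio`; window boundaries sit 5 standard deviations from the
#' peak centres, so truncation error is negligible.
#'
#' @param poly_mono_ratio planted P/M area ratio.
#' @param baseline constant absorbance offset (removed by the analyser's
#'   baseline subtraction).
#' @param noise_sd optional Gaussian noise on the absorbance.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @param n_points trace resolution.
#' @return list of class `polysome_trace`: `position`, `absorbance`,
#'   `boundaries`, `planted_ratio`.
#' @export
gen_polysome_trace <- function(poly_mono_ratio = 2, baseline = 0,
                               noise_sd = 0, seed = 1L, n_points = 2001L) {
  x <- seq(0, 10, length.out = n_points)
  gauss <- function(mu, sd, amp) amp * exp(-(x - mu)^2 / (2 * sd^2))
  mono_amp <- 1
  mono_sd <- 0.15
  mono_area <- mono_amp * mono_sd * sqrt(2 * pi)
  poly_sd <- 0.2
  rel <- c(1, 0.8, 0.6)
  poly_scale <- poly_mono_ratio * mono_area /
    (sum(rel) * poly_sd * sqrt(2 * pi))
  y <- gauss(1, 0.3, 0.5) +                       # free-RNP peak, outside windows
    gauss(3, mono_sd, mono_amp) +
    gauss(5, poly_sd, poly_scale * rel[1]) +
    gauss(6, poly_sd, poly_scale * rel[2]) +
    gauss(7, poly_sd, poly_scale * rel[3]) + baseline
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  }
  structure(list(position = x, absorbance = y,
                 boundaries = list(mono_start = 2.25, mono_end = 3.75,
                                   poly_start = 4, poly_end = 8),
                 planted_ratio = poly_mono_ratio),
            class = "polysome_trace")
}
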