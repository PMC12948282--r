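test_that("cleavage ratio follows the pseudocounted closed form", {
  p <- make_profile("Pro-AGG-1", coverage = c(10, 100, 10),
                    term = c(0, 90, 0))
  expect_equal(cleavage_ratio(p, 2, epsilon = 0), 0.9)
  p0 <- make_profile("Pro-AGG-1", coverage = c(0, 0), term = c(0, 0))
  expect_equal(cleavage_ratio(p0, 1, epsilon = 0.5), 0.5)
  expect_error(cleavage_ratio(p, 99), "out of range")
  # random profiles vs independent arithmetic
  withr::with_seed(3, for (i in 1:50) {
    cov <- rpois(5, 80)
    term <- rbinom(5, cov, 0.3)
    pr <- make_profile("x", cov, term)
    pos <- sample(5, 1)
    eps <- runif(1, 0, 2)
    expect_equal(cleavage_ratio(pr, pos, eps),
                 (term[pos] + eps) / (cov[pos] + 2 * eps))
  })
})

test_that("cleavage score is the log2 ratio of ratios and is antisymmetric", {
  tr <- make_profile("t", coverage = 100, term = 90)
  ct <- make_profile("t", coverage = 100, term = 10, condition = "control")
  expect_equal(cleavage_score(tr, ct, 1, epsilon = 0), log2(9))
  expect_equal(cleavage_score(tr, tr, 1), 0)
  expect_equal(cleavage_score(tr, ct, 1), -cleavage_score(ct, tr, 1))
  expect_error(cleavage_score(tr, make_profile("u", 100, 10), 1),
               "different tRNAs")
})

test_that("calls are exactly invariant to uniform depth scaling when epsilon = 0", {
  withr::with_seed(8, {
    cov <- rpois(10, 200) + 50
    term <- rbinom(10, cov, 0.4)
  })
  p1 <- make_profile("t", cov, term)
  p2 <- make_profile("t", cov * 7L, term * 7L)
  for (pos in 1:10) {
    expect_identical(cleavage_ratio(p1, pos, 0), cleavage_ratio(p2, pos, 0))
  }
})

test_that("pileups count RT stops at the base 3' of the alignment start", {
  ref <- tiny_reference(n = 2, n_mod = 1)
  aln <- data.frame(trna_id = ref$id[1], start = 47L, end = 75L)
  p <- pileup_from_alignments(aln, ref, "s1", "treated")
  one <- p[p$trna_id == ref$id[1], ]
  expect_equal(one$term[one$position == 46], 1)
  expect_equal(sum(one$term), 1)
  # the terminated read covers its stop base through its 3' end
  expect_equal(which(one$coverage == 1), 46:75)
  expect_true(all(p$term <= p$coverage))
  # empty alignment set gives all-zero profiles
  p0 <- pileup_from_alignments(aln[0, ], ref, "s1", "treated")
  expect_true(all(p0$coverage == 0) && all(p0$term == 0))
  expect_error(pileup_from_alignments(
    data.frame(trna_id = "nope", start = 1L, end = 10L), ref, "s1", "treated"),
    "unknown")
})

test_that("SAM input and the alignment-table route give identical pileups", {
  ref <- tiny_reference(n = 2, n_mod = 1)
  dna <- chartr("U", "T", ref$sequence)
  sam <- withr::local_tempfile(fileext = ".sam")
  reads <- data.frame(trna_id = c(ref$id[1], ref$id[1], ref$id[2]),
                      start = c(47L, 1L, 5L), end = c(76L, 40L, 44L))
  lines <- c(paste0("@HD\tVN:1.6\tSO:unknown"),
             sprintf("@SQ\tSN:%s\tLN:%d", ref$id, nchar(ref$sequence)),
             vapply(seq_len(nrow(reads)), function(i) {
               w <- reads$end[i] - reads$start[i] + 1L
               seq_i <- substr(dna[match(reads$trna_id[i], ref$id)],
                               reads$start[i], reads$end[i])
               sprintf("r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s", i,
                       reads$trna_id[i], reads$start[i], w, seq_i,
                       strrep("I", w))
             }, character(1)))
  writeLines(lines, sam)
  p_sam <- pileup_from_alignments(sam, ref, "s1", "treated")
  p_df <- pileup_from_alignments(reads, ref, "s1", "treated")
  expect_equal(p_sam, p_df)
})

test_that("planted m7G sites are recovered and unplanted species stay silent", {
  cfg <- sim_config(seed = 2, n_trna = 12, n_modified = 4,
                    coverage_per_trna = 400, replicates = 3)
  ref <- gen_trna_reference(cfg)
  sim <- gen_tracseq_reads(cfg, ref)
  calls <- call_m7g_sites(ref$trnas, sim$pileup, genotype = "Ctrl")
  truth <- ref$ground_truth$trna_id[ref$ground_truth$modified]
  expect_setequal(calls$trna_id, truth)
  expect_true(all(calls$position == 46))
  expect_true(all(calls$motif_match))
  expect_true(all(iupac_match(calls$context, "RGGUY")))
  # no cleavage signal anywhere (zero efficiency, zero background) -> no calls
  cfg0 <- sim_config(seed = 2, n_trna = 12, n_modified = 4,
                     coverage_per_trna = 400, replicates = 3,
                     cleavage_eff_treated = 0, cleavage_eff_control = 0,
                     cleavage_background = 0)
  sim0 <- gen_tracseq_reads(cfg0, ref)
  expect_true(all(sim0$pileup$term == 0))
  expect_equal(nrow(call_m7g_sites(ref$trnas, sim0$pileup,
                                   genotype = "Ctrl")), 0)
  # a missing control condition is a configuration error
  expect_error(call_m7g_sites(
    ref$trnas, sim$pileup[sim$pileup$condition == "treated", ]),
    "control")
})

test_that("motif PWM matches brute-force counting and consensus uses IUPAC codes", {
  single <- data.frame(trna_id = "t", position = 46, score = 2,
                       mean_treated_coverage = 100, context = "AGGUC",
                       motif_match = TRUE, p = 0.1, qvalue = 0.1,
                       significant = FALSE)
  ms <- summarize_motif(single)
  expect_equal(ms$consensus, "AGGUC")
  expect_true(all(abs(colSums(ms$pwm) - 1) < 1e-9))
  expect_error(summarize_motif(single[0, ]), "no calls")
  # random contexts: columns equal brute-force frequency counts
  ctx <- withr::with_seed(4, replicate(20, paste(
    sample(c("A", "C", "G", "U"), 5, replace = TRUE), collapse = "")))
  calls <- single[rep(1, 20), ]
  calls$context <- ctx
  pwm <- summarize_motif(calls)$pwm
  chars <- do.call(rbind, strsplit(ctx, ""))
  for (j in 1:5) {
    for (b in c("A", "C", "G", "U")) {
      expect_equal(unname(pwm[b, j]),
                   (sum(chars[, j] == b) + 0.25) / (20 + 1))
    }
  }
  # balanced RGGUY expansions give the RGGUY consensus back
  calls$context <- rep(c("AGGUC", "AGGUU", "GGGUC", "GGGUU"), 5)
  expect_equal(summarize_motif(calls)$consensus, "RGGUY")
})

test_that("knockout cleavage scores drop at called sites", {
  cfg <- sim_config(seed = 6, n_trna = 14, n_modified = 6,
                    coverage_per_trna = 400, cko_methylation = 0)
  ref <- gen_trna_reference(cfg)
  sim <- gen_tracseq_reads(cfg, ref)
  calls <- call_m7g_sites(ref$trnas, sim$pileup, genotype = "Ctrl")
  cmp <- compare_cleavage(calls, sim$pileup)
  expect_true(all(cmp$table$delta < 0))
  expect_lt(cmp$p_value, 0.05)
  # identical "genotypes": relabel Ctrl as both -> zero deltas
  p2 <- sim$pileup[sim$pileup$genotype == "Ctrl", ]
  p2cko <- p2
  p2cko$genotype <- "cKO"
  both <- rbind(p2, p2cko)
  cmp0 <- suppressWarnings(compare_cleavage(calls, both))
  expect_equal(cmp0$median_delta, 0)
  # fewer than 3 paired tRNAs -> NA with a warning
  expect_warning(c2 <- compare_cleavage(calls[1:2, ], sim$pileup), "fewer")
  expect_true(is.na(c2$p_value))
})

test_that("the paired signed-rank test agrees with exhaustive enumeration", {
  cfg <- sim_config(seed = 6, n_trna = 14, n_modified = 6,
                    coverage_per_trna = 400, cko_methylation = 0)
  ref <- gen_trna_reference(cfg)
  sim <- gen_tracseq_reads(cfg, ref)
  calls <- call_m7g_sites(ref$trnas, sim$pileup, genotype = "Ctrl")
  cmp <- compare_cleavage(calls, sim$pileup)
  orc <- oracle_signed_rank(cmp$table$delta)
  expect_equal(cmp$statistic, orc$statistic)
  expect_equal(cmp$p_value, orc$p_two_sided)
})

test_that("scores negate when treated and control labels are swapped", {
  cfg <- sim_config(seed = 4, n_trna = 10, n_modified = 3,
                    coverage_per_trna = 300)
  ref <- gen_trna_reference(cfg)
  sim <- gen_tracseq_reads(cfg, ref)
  p <- sim$pileup[sim$pileup$genotype == "Ctrl", ]
  swapped <- p
  swapped$condition <- ifelse(p$condition == "treated", "control", "treated")
  for (tid in ref$trnas$id[c(1, 5)]) {
    a <- cleavage_profile(p, tid)
    b <- cleavage_profile(swapped, tid)
    expect_equal(a$score, -b$score)
  }
})
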