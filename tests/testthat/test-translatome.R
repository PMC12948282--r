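test_that("TPM follows the two-pass closed form", {
  cm <- count_matrix(matrix(c(100, 100), 2, 1,
                            dimnames = list(c("g1", "g2"), "s1")),
                     lengths = c(1000, 2000), genotype = "Ctrl", assay = "rna")
  tp <- tpm(cm)
  expect_equal(unname(tp[, 1]), c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)
  single <- count_matrix(matrix(42, 1, 1, dimnames = list("g", "s")),
                         lengths = 500, genotype = "Ctrl", assay = "rna")
  expect_equal(unname(tpm(single)[1, 1]), 1e6)
  # random matrices vs brute-force oracle
  withr::with_seed(11, {
    m <- matrix(rpois(200 * 4, 50), 200, 4,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
    lens <- sample(300:3000, 200)
  })
  expect_equal(tpm(m, lens), oracle_tpm(m, lens), tolerance = 1e-12)
})

test_that("TE is the pseudocounted ratio of genotype-mean TPMs", {
  genes <- c("g1", "g2")
  mk <- function(vals, assay) {
    count_matrix(matrix(vals, 2, 2, dimnames = list(genes, c("a", "b"))),
                 lengths = c(1000, 1000), genotype = c("Ctrl", "cKO"), assay)
  }
  # equal lengths: TPM is proportional to count share
  ribo <- mk(c(100, 50, 100, 50), "ribo")
  rna <- mk(c(50, 100, 50, 100), "rna")
  te <- compute_te(ribo, rna, pseudocount = 0)
  tpm_r <- tpm(ribo)
  tpm_m <- tpm(rna)
  expect_equal(te$te_ctrl, unname(tpm_r[, 1] / tpm_m[, 1]))
  expect_equal(te$log2dte, c(0, 0))   # identical genotype columns
  expect_error(compute_te(rna, ribo), "swapped|wrong")
  # random counts vs a step-by-step oracle
  withr::with_seed(21, {
    rc <- matrix(rpois(100 * 6, 200), 100, 6,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
    mc <- matrix(rpois(100 * 6, 200), 100, 6,
                 dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
    lens <- sample(500:2000, 100)
  })
  gt <- rep(c("Ctrl", "cKO"), each = 3)
  te2 <- compute_te(count_matrix(rc, lens, gt, "ribo"),
                    count_matrix(mc, lens, gt, "rna"), pseudocount = 0.5)
  tr <- oracle_tpm(rc, lens)
  tm <- oracle_tpm(mc, lens)
  for (i in c(1, 50, 100)) {
    tec <- (mean(tr[i, 1:3]) + 0.5) / (mean(tm[i, 1:3]) + 0.5)
    tek <- (mean(tr[i, 4:6]) + 0.5) / (mean(tm[i, 4:6]) + 0.5)
    expect_equal(te2$te_ctrl[i], tec, tolerance = 1e-12)
    expect_equal(te2$log2dte[i], log2(tek / tec), tolerance = 1e-12)
  }
})

test_that("TE is invariant to scaling all counts of one sample", {
  withr::with_seed(31, {
    rc <- matrix(rpois(50 * 4, 100), 50, 4,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
    lens <- sample(500:2000, 50)
  })
  gt <- c("Ctrl", "Ctrl", "cKO", "cKO")
  rc2 <- rc
  rc2[, 2] <- rc2[, 2] * 5L
  te1 <- compute_te(count_matrix(rc, lens, gt, "ribo"),
                    count_matrix(rc, lens, gt, "rna"))
  te2 <- compute_te(count_matrix(rc2, lens, gt, "ribo"),
                    count_matrix(rc2, lens, gt, "rna"))
  expect_equal(te1$log2dte, te2$log2dte, tolerance = 1e-12)
})

test_that("TE classification partitions expressed genes by the log2 threshold", {
  te <- data.frame(gene_id = paste0("g", 1:5),
                   te_ctrl = 1, te_cko = 1,
                   log2dte = c(-1.5, 0.2, 1.7, -0.99, 2),
                   expressed = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  cl <- classify_te(te, threshold_log2 = 1)
  expect_equal(cl$te_class, c("down", "unchanged", "up", "unchanged", NA))
  expect_error(classify_te(te, threshold_log2 = 0), "positive")
  # stable under relabelling of rows
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(classify_te(te[perm, ], 1)$te_class, cl$te_class[perm])
})

test_that("planted TE effects are recovered, tightly in the low-noise limit", {
  cset <- codon_set(c("CCU", "GUU", "AAA", "GCU"))
  lo <- sim_config(seed = 3, n_genes = 600, dispersion = 0.001,
                   replicates = 6)
  tl <- gen_translatome(lo, cset)
  te <- compute_te(tl$ribo, tl$rna)
  planted <- tl$ground_truth$planted_log2dte[match(te$gene_id,
                                                   tl$ground_truth$gene_id)]
  expect_gt(cor(te$log2dte, planted, method = "spearman"), 0.9)
  cl <- classify_te(te, 1)
  agree <- mean(cl$te_class == tl$ground_truth$te_class[match(
    cl$gene_id, tl$ground_truth$gene_id)], na.rm = TRUE)
  expect_gt(agree, 0.95)
  # at the default noise level the association remains strong
  hi <- sim_config(seed = 3, n_genes = 600)
  tl2 <- gen_translatome(hi, cset)
  te2 <- compute_te(tl2$ribo, tl2$rna)
  planted2 <- tl2$ground_truth$planted_log2dte[match(
    te2$gene_id, tl2$ground_truth$gene_id)]
  expect_gt(cor(te2$log2dte, planted2, method = "spearman"), 0.5)
})

test_that("the running-sum ES matches limit cases and the brute-force oracle", {
  r <- setNames(seq(10, 1), paste0("g", 1:10))
  # all members at the top, weight 0: ES reaches exactly 1
  enr <- preranked_enrichment(r, list(top = paste0("g", 1:3)),
                              weight_exponent = 0, n_perm = 100, seed = 1)
  expect_equal(enr$es, 1)
  # set = universe: ES is 0 by convention
  enr0 <- preranked_enrichment(r, list(all = paste0("g", 1:10)),
                               weight_exponent = 0, n_perm = 100, seed = 1)
  expect_equal(enr0$es, 0)
  expect_error(preranked_enrichment(r, list(out = c("x", "y")), n_perm = 100),
               "outside")
  expect_error(preranked_enrichment(r, list(top = "g1"), n_perm = 10),
               "n_perm")
  # exhaustive oracle on random 10-gene universes, 3-gene sets
  withr::with_seed(17, for (i in 1:25) {
    rk <- setNames(rnorm(10), paste0("g", 1:10))
    st <- sample(names(rk), 3)
    w <- sample(c(0, 0.5, 1, 2), 1)
    es_pkg <- preranked_enrichment(rk, list(s = st), weight_exponent = w,
                                   n_perm = 100, seed = 5)$es
    expect_equal(es_pkg, unname(oracle_es(rk, st, w)))
  })
})

test_that("the ES agrees with an independent GSEA implementation", {
  rk <- withr::with_seed(23, setNames(rnorm(200), paste0("g", 1:200)))
  st <- paste0("g", seq(1, 60, by = 3))
  es_pkg <- preranked_enrichment(rk, list(s = st), weight_exponent = 1,
                                 n_perm = 100, seed = 1)$es
  sorted <- sort(rk, decreasing = TRUE)
  es_fgsea <- fgsea::calcGseaStat(unname(sorted),
                                  which(names(sorted) %in% st),
                                  gseaParam = 1)
  expect_equal(es_pkg, es_fgsea, tolerance = 1e-9)
})

test_that("signature TE summaries recover planted repression and pass the enumeration oracle", {
  cset <- codon_set(c("CCU", "GUU", "AAA", "GCU"))
  cfg <- sim_config(seed = 5, n_genes = 600)
  tl <- gen_translatome(cfg, cset)
  te <- compute_te(tl$ribo, tl$rna)
  sig <- signature_te_summary(te, tl$signature)
  expect_lt(sig$median_log2dte, 0)
  expect_lt(sig$p_value, 0.05)
  orc <- oracle_signed_rank(sig$table$log2dte)
  expect_equal(sig$statistic, orc$statistic)
  expect_equal(sig$p_value, orc$p_two_sided)
  # no-effect control: flat slope leaves the signature near zero
  null_cfg <- sim_config(seed = 5, n_genes = 600, te_effect_slope = 0)
  tl0 <- gen_translatome(null_cfg, cset)
  te0 <- compute_te(tl0$ribo, tl0$rna)
  sig0 <- signature_te_summary(te0, tl0$signature)
  expect_lt(abs(sig0$median_log2dte), 0.3)
  expect_error(signature_te_summary(te, c("nope1", "nope2")), "overlap")
})

test_that("RNC/input qPCR TE follows the delta-delta-Ct arithmetic", {
  ct <- expand.grid(gene = c("Yap1", "ref"), fraction = c("RNC", "input"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  ct$ct <- 20
  expect_equal(rnc_te(ct, "ref")$te, 1)
  ct$ct[ct$gene == "Yap1" & ct$fraction == "RNC"] <- 19
  expect_equal(rnc_te(ct, "ref")$te, 2)
  # random table vs step-by-step hand computation
  rct <- withr::with_seed(41, {
    d <- expand.grid(gene = c("g1", "g2", "ref"),
                     fraction = c("RNC", "input"), replicate = 1:4,
                     stringsAsFactors = FALSE)
    d$ct <- runif(nrow(d), 18, 30)
    d
  })
  res <- rnc_te(rct, "ref")
  for (g in c("g1", "g2")) {
    rqs <- sapply(seq_len(nrow(rct)), function(i) {
      if (rct$gene[i] != g) return(NA)
      ref_ct <- rct$ct[rct$gene == "ref" &
                         rct$fraction == rct$fraction[i] &
                         rct$replicate == rct$replicate[i]]
      2^(-(rct$ct[i] - ref_ct))
    })
    rnc_mean <- mean(rqs[rct$gene == g & rct$fraction == "RNC"])
    inp_mean <- mean(rqs[rct$gene == g & rct$fraction == "input"])
    expect_equal(res$te[res$gene == g], rnc_mean / inp_mean)
  }
  # missing fraction is skipped with a warning
  expect_warning(
    r2 <- rnc_te(rct[!(rct$gene == "g2" & rct$fraction == "RNC"), ], "ref"),
    "missing a fraction")
  expect_false("g2" %in% r2$gene)
  expect_error(rnc_te(rct[rct$fraction == "RNC", ], "ref"), "reference")
})

test_that("the polysome/monosome ratio integrates windows correctly", {
  # rectangular peaks of equal then doubled area
  x <- seq(0, 10, by = 0.01)
  rect <- function(lo, hi, h) ifelse(x >= lo & x <= hi, h, 0)
  tr <- list(position = x, absorbance = rect(2.5, 3.5, 1) + rect(5, 6, 1),
             boundaries = list(mono_start = 2, mono_end = 4,
                               poly_start = 4.5, poly_end = 6.5))
  expect_equal(polysome_monosome_ratio(tr), 1, tolerance = 1e-9)
  tr$absorbance <- rect(2.5, 3.5, 1) + rect(5, 6, 2)
  expect_equal(polysome_monosome_ratio(tr), 2, tolerance = 1e-9)
  # random smooth traces vs the independent integration oracle
  withr::with_seed(51, for (i in 1:5) {
    amp <- runif(3, 0.5, 2)
    y <- amp[1] * exp(-(x - 3)^2 / 0.05) + amp[2] * exp(-(x - 5.5)^2 / 0.1) +
      amp[3] * exp(-(x - 7)^2 / 0.1) + 0.05
    tr2 <- list(position = x, absorbance = y,
                boundaries = list(mono_start = 2, mono_end = 4,
                                  poly_start = 4.6, poly_end = 8.2))
    expect_equal(polysome_monosome_ratio(tr2), oracle_window_ratio(tr2),
                 tolerance = 1e-6)
  })
  tr$absorbance <- rect(5, 6, 1)
  expect_error(polysome_monosome_ratio(tr), "zero area")
})

test_that("generated polysome traces recover their planted ratio", {
  for (ratio in c(1, 2)) {
    tr <- gen_polysome_trace(poly_mono_ratio = ratio)
    expect_equal(polysome_monosome_ratio(tr), ratio, tolerance = 0.01)
  }
  # constant baseline offsets cancel in the baseline-subtracted areas
  tr0 <- gen_polysome_trace(poly_mono_ratio = 1.5)
  tr1 <- gen_polysome_trace(poly_mono_ratio = 1.5, baseline = 0.4)
  expect_equal(polysome_monosome_ratio(tr0), polysome_monosome_ratio(tr1),
               tolerance = 1e-9)
})
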