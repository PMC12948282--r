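# m7gtrac

Analysis of N7-methylguanosine (m⁷G) tRNA modification and its downstream
translational consequences, built for the regenerating-liver setting in which
the METTL1/WDR4 methyltransferase writes m⁷G46 on a subset of tRNAs and its
loss represses translation of codon-biased transcripts (notably the Hippo
effectors YAP/TAZ). The package is aimed at computational biologists who work
with TRAC-seq (tRNA reduction and cleavage sequencing), tRNA-seq and
Ribo-seq/RNA-seq data, and who want every stage of the chain to be testable
against planted ground truth.

## What it computes

**Cleavage scoring and site calling.** TRAC-seq chemistry converts m⁷G into a
reverse-transcription stop one base 3′ of the modified guanosine. From
per-position termination pileups the package computes, with pseudocount
ε = 0.5,

    ratio(i)  = (term_i + ε) / (cov_i + 2ε)
    score(i)  = log2( ratio_treated(i) / ratio_control(i) )

replicate-averaged as mean log₂ treated ratio minus mean log₂ control ratio.
Sites are called in a candidate window (default 40–55, anchored on the
canonical variable-loop G46) where the base is G, mean treated coverage ≥ 50
and score ≥ 1, at most one per tRNA; label-permutation q-values and the
RGGUY context match annotate each call.

**Quantification and comparison.** tRNA families are quantified as CPM from
the per-position coverage maximum; per-family log₂FC (knockout vs control)
is contrasted between m⁷G and non-m⁷G groups by a Mann–Whitney test.
Translation efficiency is TE = (mean ribo TPM + 0.5)/(mean RNA TPM + 0.5)
per genotype, with Δlog₂TE classes at |log₂ΔTE| ≥ 1. The codon link tests
whether TE-down genes use more codons decoded by m⁷G tRNAs (one-sided
Mann–Whitney). Preranked gene-set enrichment uses the weighted
Kolmogorov–Smirnov running sum with a gene-sampling null. Utilities cover
polysome/monosome area ratios, RNC/input qPCR TE, and the clinical liver
regeneration index under both denominator conventions (regenerated
volume/TLV and regenerated volume/remnant).

**Synthetic data with ground truth.** `sim_config()` + the `gen_*()`
generators emit a tRNA reference whose modified species are defined by a
structural rule (G46 inside RGGUY), TRAC-seq pileups/FASTQ for
control/knockout × treated/untreated libraries, and a translatome whose TE
effects are driven by each gene's m⁷G-codon fraction. Every planted effect is
returned as machine-readable ground truth.

## Worked example

```r
library(m7gtrac)
run <- run_pipeline(sim_config(seed = 7))
print(run)
#> m7G translational-control pipeline run
#>   m7G tRNAs called: 12  motif: RGGUY
#>   modified tRNAs down in cKO:  TRUE
#>   TE-down genes codon-enriched: TRUE
#>   signature negatively enriched: TRUE

head(run$calls, 3)
#>     trna_id position score mean_treated_coverage context motif_match    p qvalue
#> 1 Pro-AGG-1       46  3.88                   494   AGGUC        TRUE 0.05  0.167
#> 2 Val-AAC-1       46  3.87                   201   AGGUU        TRUE 0.05  0.167
#> 3 Pro-TGG-1       46  3.99                   430   GGGUC        TRUE 0.05  0.167

run$trna_comparison
#>   median log2FC m7G: -0.903  non-m7G: 0.097
#>   Mann-Whitney U: 0  p: 3.58e-10

run$codon_test
#>   medians: 0.645 vs 0.434
#>   one-sided p (down > ref): 1.068e-29

run$enrichment[, c("set_name", "es", "nes", "p")]
#>            set_name    es    nes      p
#> 1 YAP_TAZ_signature -0.86 -1.805 0.004
```

Twelve tRNA species are called m⁷G-positive in the control genotype, all at
position 46 with an RGGUY context. The knockout halves modified-tRNA
abundance (median log₂FC ≈ −0.9) while unmodified species barely move;
TE-down genes carry markedly more m⁷G-related codons (median fraction 0.645
vs 0.434); and the proliferative YAP/TAZ-target signature is negatively
enriched in the TE ranking (NES −1.8) — the full qualitative chain expected
when the methyltransferase is lost.

The clinical utility works on plain volume tables:

```r
v <- read.delim(system.file("extdata", "liver_volumes_synthetic.tsv",
                            package = "m7gtrac"))
regeneration_index(v$tlv, v$remnant, v$followup)[1:3]
#> [1] 0.4106 0.4242 0.3793
```

A command-line wrapper is included at `inst/scripts/run_pipeline.R`
(`Rscript run_pipeline.R --seed 7 --out-dir out/`).

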