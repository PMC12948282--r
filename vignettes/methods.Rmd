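---
title: "Methods: m7G tRNA site calling and codon-dependent translational control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m7G tRNA site calling and codon-dependent translational control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m7gtrac)
```

## The biological question and the model

METTL1/WDR4 writes N7-methylguanosine (m⁷G) at position 46 of a subset of
tRNAs. In TRAC-seq, a chemical reduction/cleavage step converts m⁷G into a
reverse-transcription stop, so treated libraries accumulate read 5′ ends one
base 3′ of the modified guanosine while untreated libraries do not. Losing
the methyltransferase destabilises the modified tRNAs, and transcripts
enriched for the codons those tRNAs decode lose translation efficiency (TE);
in regenerating liver the most consequential targets are the Hippo effectors
YAP/TAZ and their proliferative target programme. `m7gtrac` implements this
chain as testable stages: cleavage scoring and site calling, tRNA abundance
comparison, TE estimation and classification, the codon-frequency statistic,
preranked gene-set enrichment, and a fully ground-truthed simulator.

## Termination and coverage conventions

A read whose 5′-most aligned reference base is *s* marks an RT stop at
*s − 1*: `term[s-1]` is incremented. A terminated read also contributes
coverage at its stop base (positions *s − 1* through its 3′ end). This makes
`term[i] <= coverage[i]` a structural invariant and gives the cleavage ratio
its intended meaning — among molecules that reached position *i*, the
fraction that stopped there — so a fully cleaved site has ratio 1 and an
untouched one ratio ≈ 0. Either off-by-one convention is defensible in the
abstract; generator and scorer share this one, and it is the only choice
under which the ratio is a probability in the full-cleavage limit.

The per-position cleavage ratio uses a symmetric pseudocount ε (default 0.5):
`(term + ε)/(coverage + 2ε)`, which is finite for empty positions and equals
1/2 for a 0/0 position. The cleavage score is the log₂ ratio of treated to
control ratios; the replicate-averaged statistic is the mean log₂ treated
ratio minus the mean log₂ control ratio, which is antisymmetric under label
exchange and, at ε = 0, exactly invariant to uniform depth scaling.

## Site calling

Candidate positions are the window 40–55 (configurable), anchored on the
canonical variable-loop G46; positions must be G (configurable) with mean
treated coverage ≥ 50. The best-scoring eligible position per tRNA is called
when its score is ≥ 1 (2-fold), ties breaking towards the 5′ end, at most
one call per tRNA — one canonical m⁷G per species in this pathway.
Whole-molecule scanning is deliberately avoided: the biology anchors the
site in the variable loop, and a narrow window keeps the permutation null
well-behaved at tRNA scale.

Significance annotation permutes treated/control labels within each tRNA
(all label reassignments when each condition has ≤ 5 replicates — with 3 + 3
libraries that is the full set of 20 — otherwise 1000 random swaps), taking
the window maximum of the permuted statistic to account for position
selection, with Benjamini–Hochberg correction across tRNAs. With 3 + 3
replicates the permutation granularity floors the attainable p at 0.05 and
the BH q above it, so q-values *annotate* calls (a `significant` flag at the
`fdr` parameter) rather than gate them; emission is governed by the
score/coverage/base conditions above. This is stated here because silently
gating on q would empty every call set at realistic replicate counts.

The motif summary builds a 4 × 5 position-weight matrix over the called
5-mer contexts with pseudocount 0.25 per base; the IUPAC consensus lists,
per column, every base at frequency ≥ 0.25, which reports RGGUY when the
panel covers the R/Y degeneracies.

## tRNA quantification

Family counts are the per-position coverage maximum summed over family
members: treated libraries lose coverage 5′ of the stop, so the maximum is
robust where the mean is biased. Abundance is CPM; fold changes use
`log2((mean CPM + 1)/(mean CPM + 1))` and the m⁷G vs non-m⁷G contrast is a
Mann–Whitney test, with per-family t-tests (BH-corrected) when each genotype
has ≥ 3 replicates. CPM is a declared stand-in — the normalisation behind
published per-tRNA expression values is rarely printed — and its
compositional consequence (all log₂FCs shift by the change in total pool
mass) is accounted for in the simulator design below.

## Translatome

TE is the ratio of genotype-mean TPMs with pseudocount 0.5, the field
standard for Ribo-seq and the direct analogue of the RNC-mRNA/input-mRNA
qPCR ratio; Δlog₂TE contrasts knockout against control, and classes use
|Δlog₂TE| ≥ 1 among expressed genes (mean RNA TPM ≥ 1 in both genotypes).
Both thresholds are configurable and echoed in the run manifest because the
underlying cutoffs are convention, not derivation. P-site offsetting and
periodicity QC are out of scope; counts are taken as given.

Preranked enrichment ranks genes by Δlog₂TE in *decreasing* order (the GSEA
convention), so a set concentrated among the most repressed genes attains a
negative enrichment score and a negative NES — the sign readers of standard
GSEA output expect for a TE-down programme. The running sum advances by
|r|^w (w = 1 by default, normalised over the set) on hits and retreats by
1/(N − n) on misses; ES is the extremum. The null draws random same-size
gene sets (1000 by default) from the ranked universe; NES divides ES by the
mean |null ES| of matching sign, and p-values are empirical and two-sided
with a +1 correction, which keeps them conservative (super-uniform) under
the null. Gene-sampling rather than phenotype permutation is forced by the
preranked setting.

The codon statistic is per-gene: the fraction of in-frame non-stop codons
(start codon included, frame anchored at position 1, no frame guessing)
belonging to the m⁷G-related set — the union of Watson–Crick cognate codons
of all called species. Wobble expansion (anticodon-34 G:U / U:G) exists
behind a flag, default off, so sensitivity to the assignment rule is
testable; the default comparison pools up + unchanged genes as the
reference class against TE-down, one-sided in the direction the biology
predicts (down > rest).

## The simulator: what it emulates and what it does not

The generator's defaults are the study conditions. The reference holds 40
species; exactly 12 — the size of the hepatocyte m⁷G catalogue — satisfy the
structural rule "G46 inside an RGGUY context". Membership is defined by the
rule, not a list, so callers are tested against a criterion that can be
re-applied to any emitted FASTA. Pro-AGG and Val-AAC are modified and
Gln-CTG is not (the experimentally anchored memberships); the remaining
panel members are synthetic stand-ins. The four RGGUY expansions are cycled
across the panel so both R and both Y bases are represented by
construction — an i.i.d. draw would leave the consensus under-determined at
those columns in a noticeable fraction of references.

Treated/untreated termination probabilities at a fully methylated site are
0.8 and 0.05, plus a methylation-independent background of 0.01; knockout
tissue retains 10% residual methylation. The background term is what makes
knockout cleavage *scores* fall: with purely methylation-proportional stops
the treated/control ratio would be scale-invariant in the methylation level.
Per-species abundances are lognormal (sdlog 0.25) with modified species at
0.35× the unmodified mean, keeping the m⁷G pool near 13% of reads; this is
deliberate, because CPM renormalisation shifts every log₂FC by the change in
total pool mass, and only a minor-share m⁷G pool keeps the unmodified group
near zero while the modified group sits near the planted −1. Reads span
from the RT stop to the tRNA 3′ end (variable length, like adapter-trimmed
tRNA-seq reads); fixed-length reads anchored at the stop could not provide
read-through coverage at the site, breaking the ratio definition above.

The translatome plants a high-codon block (25% of genes, Beta-distributed
m⁷G-codon fraction with mean 0.6, concentration 18) against a background
block (mean 0.4); the six-gene proliferative signature (Areg, Birc5, Ctfg,
Ccnb1, Cyr61, Foxm1) receives fixed codon-rich targets 0.66–0.76, placing
it in the transcriptome's top decile. Each CDS contains an exact
`round(f·n)` count of target codons shuffled among non-target non-stop
codons, so realised fractions match targets to within half a codon. Planted
effects follow `Δlog₂TE = −2.5 (f − 0.4)` applied to knockout
ribosome-footprint means only; counts are negative-binomial with gene
dispersion 0.05 (a standard RNA-count choice) around lognormal expression
means, 3 + 3 replicates.

Two consequences of these conditions are worth stating plainly. First, with
dispersion 0.05 and 3 replicates the sampling noise of estimated Δlog₂TE is
≈ 0.39 log₂ units while the planted signal spread is ≈ 0.35, so estimated
and planted effects correlate around 0.65 at defaults; near-perfect recovery
(ρ > 0.9, class agreement > 95%) appears only in the low-noise limit
(dispersion 0.001, 6 replicates), and the tests check both regimes rather
than pretending the default regime is noiseless. Second, because the
planted per-gene effects rarely exceed the ±1 class threshold on their own,
the recovered TE-down class is a noise-selected, high-f-enriched subset —
which is exactly the regime in which the codon-frequency contrast is tested.

The simulator does not model sequencing errors, multi-mapping, charged
fractions, tissue heterogeneity, P-site ambiguity, or modification types
other than m⁷G; passing tests demonstrate internal consistency of the chain
under the declared generative model, not robustness to those real-data
complications. Alignment of synthetic reads uses exact substring matching —
adequate only because synthetic species are unique by construction; real
libraries should arrive as SAM/BAM or pileup TSV.

## Numerical and degenerate-input choices

Pseudocounts: ε = 0.5 on cleavage ratios, 1 CPM on tRNA fold changes, 0.5
TPM on TE. Ties in the site caller break towards the 5′ end. Contexts at
molecule ends are N-padded, and N never matches a consensus letter.
Zero-coverage positions give ratio 1/2 and score 0. A zero library total is
an error, as are assay-label swaps, unknown tRNA ids, CDS lengths not
divisible by 3, and an empty monosome window. Sub-seeds for every stochastic
stage derive deterministically from the master seed, all generators restore
the caller's RNG state, and reruns of the same configuration are
byte-identical on disk.

## Problem sizes in the test suite

The suite exercises the full default conditions (40 tRNAs, coverage 1000,
3 + 3 libraries, 2000 genes) for the recovery and determinism checks, a
20-seed sweep for sensitivity/precision and the group-effect bands, reduced
fixtures (10–20 tRNAs, 200–800 genes) for interface and oracle tests, 200
label permutations and 200 random gene sets for the calibration checks, and
exhaustive enumeration oracles (signed-rank at n ≤ 12, Mann–Whitney at
5 vs 5, running-sum ES on 10-gene universes) for the statistics. These sizes
were chosen as the smallest at which each property is informative.

## Known limitations

Positions are plain 1-based indices on the mature sequence; Sprinzl
alignment numbering is not implemented, so "46" is exact only for species
whose variable loop matches the canonical register — acceptable here because
the candidate window is configurable per analysis and per species.
Isodecoder collapsing is by exact mature-sequence identity only. The
permutation null is coarse at small replicate counts (by design, see above).
The enrichment null is gene-sampling, which ignores inter-gene correlation;
its p-values are calibrated for the simulator's independent genes but will
be anti-conservative on strongly co-regulated real modules. The qPCR TE
propagates replicate SEM by the delta method, which assumes small
coefficients of variation.
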