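---
title: "Methods: efficiency-corrected qPCR quantification, sex-bias calling and motif classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: efficiency-corrected qPCR quantification, sex-bias calling and motif classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antennaquant)
```

# The problem

Moths detect mates and hosts through families of chemosensory genes
expressed in their antennae: odorant binding proteins (OBPs) and related
carriers, odorant receptors (ORs) and other receptor families, and
odorant degrading enzymes. Two routine questions for such a repertoire
are (i) which genes are expressed in which tissue and sex, and (ii) which
receptors show sex-biased expression — male-biased ORs are candidate
pheromone receptors. This package provides the quantitative core of such
an analysis: relative qPCR quantification with per-sample efficiency
correction, sex-bias calling, RNAseq detection/concordance summaries, and
rule-based protein classification. It ships the *Epiphyas postvittana*
antennal expression tables (191 non-OR chemosensory genes; 70 ORs) as
typed fixtures.

# The quantification model

qPCR measures, for each reaction, the cycle threshold Ct at which
fluorescence crosses a detection level; each earlier cycle corresponds to
one multiplication of the template by the reaction's amplification
efficiency $E \in (1, 2]$. Because $E$ for the same primer pair differs
between cDNA samples, raw Cts are not comparable across samples. Writing
$E_{\max}$ for the highest efficiency observed for a primer pair across
all samples, every Ct is rescaled to the $E_{\max}$ base by solving

$$E_{\max}^{\,Ct_{corr}} = E_{sample}^{\,Ct_{sample}}
\quad\Longrightarrow\quad
Ct_{corr} = Ct_{sample}\,\frac{\ln E_{sample}}{\ln E_{\max}},$$

the unique solution of the identity (`correct_ct()`). When
$E_{sample} = E_{\max}$ the Ct is returned bit-for-bit unchanged; the
implementation computes the log-ratio first so this identity holds
exactly in floating point.

Each sample's normalization factor (NF) is the arithmetic mean of the
corrected Cts of its three housekeeping genes (actin, α-tubulin, EF-1α
in the reference design); fewer than three contributing genes triggers a
recorded warning, none is an error. Relative expression of a gene in a
sample is then

$$\mathrm{RE} = E_{\max}^{\,\Delta Ct}, \qquad
\Delta Ct = \mathrm{NF} - Ct_{corr}.$$

**Sign convention.** The ΔCt difference is taken as NF − Ct, so that
abundant transcripts (lower Ct than the housekeeping mean) map to values
above 1. The published OR table behaves this way — the co-receptor Orco,
by far the most abundant receptor, is tabled at 2.62 — whereas the
opposite sign would push abundant genes below 1; the package therefore
fixes NF − Ct.

**Replicate structure.** Technical (well) triplicates are combined on
the Ct scale *before* correction by default, the convention of the
window-of-linearity qPCR literature; `tech_rep_mode = "separate"`
corrects each well first and averages corrected Cts (the two agree
exactly on noise-free data, and the choice is exposed because published
protocols rarely state it). Relative expression is computed per
biological replicate and averaged across the three biological replicates
per tissue; per-replicate values are retained alongside the mean. A gene
× tissue combination is reported below limit of detection (BLD) only
when *every* replicate is censored; partially detected genes use the
detected replicates with the count recorded.

**Censoring.** A well is BLD when no Ct is reported within the run
length (45 cycles, the default `max_cycles`, matching the standard
protocol); BLD is carried as `NA` internally and as the literal token
`BLD` in files.

# Sex-bias calling

Per-gene male vs female antennal replicate values are compared with a
Welch two-sample t-test (`welch_test()`, a thin wrapper over
`stats::t.test(var.equal = FALSE)` with explicit degenerate-variance
conventions: zero variance in both groups gives $p = 1$ at equal means
and a flagged $p = 0$ limit otherwise). Direction is `male` when the male
mean is larger and $p < \alpha$, symmetrically `female`; `undetermined`
when a sex has fewer than two detected replicates — such genes are
reported, never silently tested. Defaults: $\alpha = 0.05$, two-sided,
**no multiple-testing correction** — the analysis mirrors per-gene
reporting practice in repertoire studies; users screening many genes
should apply `p.adjust` downstream.

A known limitation, quantified by the test suite: with only three
replicates per sex the Welch test is conservative. Its exact size at
$n_1 = n_2 = 3$ on normal data is ≈ 0.034 rather than the nominal 0.05
(the Welch–Satterthwaite approximation is inexact at such small $n$), and
the full pipeline measured over 10,000 simulated null genes realises
≈ 0.035. Simulation checks that expect the empirical false-call rate to
sit in a tight band around the nominal level will therefore sit at —
and sometimes just beyond — the band's conservative edge; this is a
property of the procedure at $n = 3$, not an implementation artefact.
False-call rates should also be estimated across *independent*
experiments: genes quantified on the same plate set share per-sample
normalization noise, which correlates their test statistics, so the
suite spreads its 2,000 null genes over 40 independent simulated
experiments of 50 genes.

# Efficiency estimation from fluorescence curves

`estimate_efficiency()` implements a window-of-linearity estimator:
subtract a baseline (mean fluorescence of cycles 3–8), slide windows
across the curve, fit $\log_{10} F$ against cycle in each, and keep the
window with the highest $r^2$ among those with $r^2 \ge 0.99$ spanning
at least one log-decade of baseline-subtracted fluorescence; the
efficiency is $10^{\text{slope}}$. Windows containing non-positive
baseline-subtracted values are rejected; a curve with no qualifying
window (flat, or no exponential phase) yields a *censored* estimate, not
an error. Window widths of 5 up to 8 cycles are searched: a five-point
window on a perfect $E = 1.7$ curve spans only $4\log_{10}1.7 = 0.92$
decades, so restricting to width 5 would wrongly censor valid
low-efficiency curves; allowing a few extra cycles keeps the decade
criterion meaningful across the realistic efficiency range. On
noise-free synthetic curves the estimator recovers $E$ to within 0.003
across $E \in [1.7, 2.0]$.

# RNAseq survey and concordance

FPKM detection uses strict `>` at threshold 1 by default (the phrasing
"counts greater than one"); because published tables print rounded
integers, the strict and non-strict counts can straddle the original
figure and both are always reported. On the packaged OR table the
recount is 64 (strict) / 66 (non-strict) against a published figure of
65 — the rounded integers cannot reproduce it exactly, and the package
reports its own recount rather than asserting the published number. The
same applies to the published count of 30 antenna-exclusive receptors:
applying the definition (numeric in an antennal slot, BLD in both body
slots) to the table's censoring pattern yields 15, which is what the
package reports.

Sex ratios are $\log_2\frac{f + c}{m + c}$ with pseudocount $c = 1$
(keeping zero-FPKM receptors finite on the tables' integer scale);
|ratio| below 1 (two-fold) is called unbiased. The concordance report
compares qPCR bias direction with the FPKM ratio direction over a gene
subset; with only tabled mean fold changes available, the qPCR direction
of the nine sex-biased receptors is derived from the antennal means
(`qpcr_direction_from_table()`), and all nine agree with their RNAseq
direction (fraction 1.0).

# Motif classification

OBP subgroups are defined by the cysteine skeleton of the mature
protein: *classic* OBPs carry six conserved cysteines, *minus-C* OBPs
lack skeleton cysteines 2 and 5, *plus-C* OBPs carry extra cysteines and
a conserved proline shortly after the sixth skeleton cysteine. The
describing literature gives motifs, not spacing numerics, so the
skeleton gap ranges (defaults C1–C2 15–45, C2–C3 exactly 3, C3–C4 20–50,
C4–C5 7–14, C5–C6 exactly 8, proline within 12 residues after C6) follow
the canonical insect-OBP spacing and are fully configurable
(`obp_spacing_config()`); classification quality is asserted by
generator round-trip properties, never by spacing-exact fixtures.
Classes are mutually exclusive: classic requires exactly six mature
cysteines, minus-C exactly four matching the merged-gap skeleton, plus-C
a classic skeleton plus at least two extra cysteines and the proline;
everything else (including sequences shorter than the minimal skeleton
span) is `unclassified` with a reason. Skeleton search is an exact
earliest-match scan over ordered cysteine subsets; coordinates are
1-based in the full sequence.

The pheromone-receptor-clade 'PWE' motif is screened as an exact
substring within the C-terminal 60 residues — a deliberate topology-free
proxy for "within the final transmembrane domain", since transmembrane
prediction is out of scope; the window is configurable and a
whole-sequence window reduces to plain substring search. Percent
identity uses Needleman–Wunsch global alignment with affine gaps
(BLOSUM62, open 10, extend 0.5, via `Biostrings::pairwiseAlignment`);
identity is identical columns over alignment columns × 100.

# The synthetic-data generators

The generators define the simulated study conditions and are first-class
tested code:

* `simulation_truth()` / `synth_qpcr()` — three biological replicates
  per group, triplicate wells, three housekeeping genes (programmed at
  expression 1.0: they *define* the NF), per primer × sample
  efficiencies drawn uniformly from [1.7, 2.0] (a plausible assay
  range), Gaussian per-well Ct noise (default sd 0.2 cycles), and
  right-censoring at cycle 45. Cts are generated in corrected-Ct space
  ($Ct_{corr} = \mathrm{NF}_{true} - \log_{E_{\max}}\mathrm{expr}$) and
  mapped back through each sample's own efficiency — the exact inverse
  of the quantification chain, so the noise-free pipeline round trip is
  an identity to machine precision, a property the suite asserts at
  1e-9.
* `synth_amp_curve()` — logistic curves whose early exponential phase
  grows by exactly $E$ per cycle, for estimator validation.
* `synth_fpkm()` — negative-binomial FPKM draws around log-normal
  per-gene base means with multiplicative sex-bias factors, emulating
  unreplicated count tables.
* `synth_obp()`, `synth_pr_clade()`, `synth_protein_family()` —
  proteins with controlled cysteine blueprints, planted or withheld
  C-terminal PWE motifs, and paralog families derived from a common
  ancestor at a substitution rate solved to give a programmed expected
  pairwise identity. These are clearly labelled stand-ins: when real
  receptor sequences are unavailable the motif and identity machinery is
  validated by parameter recovery on them (e.g. a programmed 61%
  four-member family is recovered within a few points), which
  demonstrates the machinery, not the biological sequences.

All generators take explicit seeds, restore the caller's RNG state, and
are byte-reproducible.

# What the simulations do and do not show

The qPCR generator reproduces the replicate structure, efficiency
heterogeneity, Gaussian Ct noise and censoring of a real plate set, but
not pipetting outliers, plate effects, primer-dimer artefacts, genomic
contamination or inter-run drift; passing parameter-recovery tests shows
the arithmetic chain is correct and adequately powered (an 8-fold bias
at sd 0.2 and $n = 3$ is called in >95% of runs), not that real assays
are free of those artefacts. The FPKM generator emulates dispersion and
bias, not read-level effects (mappability, length bias). Synthetic OBPs
have uniform background composition, unlike real proteins; the
classifier round trip shows rule/generator consistency on conformant
inputs, and real borderline sequences (e.g. divergent OBPs that lack
most of the motifs) are expected to come out `unclassified`.

# Numerical choices and problem sizes

Tolerances: formula identities are asserted to 1e-9 relative; the
noise-free round trip to 1e-9; estimator recovery to ±0.05. Test
problem sizes were chosen to give stable statistics at interactive
runtimes: 200 simulated experiments for power, 40 × 50 genes for the
type-I rate, 1,000 blueprints for the classifier round trip, 1,000
random samples for the Welch formula cross-check, and an exact 20-split
permutation oracle at $n = 3 + 3$. Ties in the efficiency window search
are broken toward the wider, earlier window; degenerate inputs
(all-censored genes, empty housekeeping sets, flat curves, empty
concordance subsets) return flagged results or targeted errors as
documented on each function.
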