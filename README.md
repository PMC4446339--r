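# antennaquant

Analysis of the antennal chemosensory gene repertoire of moths from qPCR
and RNAseq summaries, built around the lightbrown apple moth (*Epiphyas
postvittana*) dataset that ships with the package. It is aimed at insect
olfaction groups who profile odorant receptor (OR) and odorant binding
protein (OBP) families in antennal tissue and need a reproducible route
from raw Ct values and published FPKM tables to sex-bias calls and family
classifications.

## What it computes

**Efficiency-corrected ΔCt quantification.** Amplification efficiency *E*
of a primer pair varies between cDNA samples, so each measured Ct is
rescaled to the pair's highest observed efficiency *E*<sub>max</sub> by
solving

&nbsp;&nbsp;&nbsp;&nbsp;*E*<sub>max</sub><sup>Ct<sub>corrected</sub></sup> = *E*<sub>sample</sub><sup>Ct<sub>sample</sub></sup>
&nbsp;&nbsp;⇒&nbsp;&nbsp;Ct<sub>corrected</sub> = Ct<sub>sample</sub> · ln *E*<sub>sample</sub> / ln *E*<sub>max</sub>.

A per-sample normalization factor NF is the mean corrected Ct of three
housekeeping genes (actin, α-tubulin, EF-1α), and relative expression is

&nbsp;&nbsp;&nbsp;&nbsp;RE = *E*<sub>max</sub><sup>ΔCt</sup>, ΔCt = NF − Ct<sub>corrected</sub>,

averaged over biological replicates. Sex bias between male and female
antennae is called with a Welch two-sample t-test (two-sided, α = 0.05).
Amplification efficiencies can be estimated from raw fluorescence curves
with a window-of-linearity estimator (`estimate_efficiency()`).

**RNAseq survey.** FPKM detection at a threshold, pseudocounted log2
female/male ratios, and a concordance report between qPCR bias directions
and RNAseq ratios.

**Motif classification.** OBPs are classified from their cysteine
skeleton (classic six-cysteine, minus-C, plus-C), pheromone-receptor-clade
ORs are screened for the C-terminal 'PWE' motif, and global-alignment
percent identity matrices are computed (BLOSUM62, affine gaps).

**Synthetic data.** Seeded generators produce wells tables, fluorescence
curves, FPKM tables and OBP-like proteins with recorded ground truth, so
every stage is testable by parameter recovery.

## Worked example

```r
library(antennaquant)

# the packaged OR expression table (70 receptors)
t2 <- epos_table2()
qpcr_detection_summary(t2)
#> qPCR detection summary
#>   detected:           67
#>   undetected:        3 (EposOR11, EposOR69, EposOR70)
#>   antenna-exclusive:  15

# simulate a gene at 8x housekeeping level in male antennae, quantify it
fc <- matrix(c(8, 1), 1, 2,
             dimnames = list("gA", c("male_antenna", "female_antenna")))
truth <- simulation_truth(fc, ct_noise_sd = 0.2, seed = 42)
rel <- quantify_experiment(synth_qpcr(truth), truth$housekeeping_ids)
call_sex_bias(rel)
#>   gene_id direction        t       df            p n_male n_female
#> 1      gA      male 37.76385 2.130011 0.0004768007      3        3
```

The detection summary reproduces the published split of the 70 receptors
(67 detected in at least one tissue; three never amplified). The
simulated gene's programmed 8-fold male bias is recovered and called male
at p < 0.001 from three biological replicates per sex.

```r
# full reproduction report over both packaged tables
print(run_report())
```

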