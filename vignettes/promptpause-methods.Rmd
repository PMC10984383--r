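---
title: "Methods: PROMPT expression, promoter pausing and damage-induced repression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PROMPT expression, promoter pausing and damage-induced repression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promptpause)
```

## The scientific setting

Ionizing irradiation induces double-strand breaks and a genome-wide
transcriptional response. Nascent-transcription protocols such as mNET-seq
capture RNA still engaged with immunoprecipitated RNA polymerase II, so the
strand-specific position of each fragment — and in particular its free 3'OH
end — reports where active polymerase sits. Three promoter-linked signals
carry the biology this package quantifies:

* **Gene-body (GB) signal**, the sense coverage from a fixed offset
  downstream of the TSS to the TES, measuring productive transcription
  while excluding paused polymerase;
* **Promoter-proximal region (PPR) signal**, sense coverage in the
  −50/+200 bp window around the TSS where paused polymerase accumulates;
  the **pause index** PI = (PPR density)/(GB density) summarises pausing
  strength per gene;
* **PROMPT signal**, antisense coverage in the 500 bp window immediately
  upstream of the TSS, measuring promoter upstream transcripts.

The coupled signature of damage-induced repression is: GB down, PROMPT up,
PI up. `classify_genes()` joins the three per-gene differential results and
labels genes carrying the full signature `repressed_concordant`; the
accompanying summary reports the contingency percentages among genes
significant on two or three of the axes.

## Coordinates and regions

All internal coordinates are 0-based half-open (BED convention). The TSS is
the 5' boundary base of the gene (`start` on `+`, `end − 1` on `-`), and
every offset is interpreted in transcript orientation. Defaults
(`region_config()`): GB from TSS+200 to the TES; PPR −50/+200; PROMPT
(TSS−500, TSS], abutting the TSS with no gap, counted on the strand
opposite the gene. Published descriptions of the pause-index gene body
disagree between +50 and +200 for its 5' edge; both gene bodies default to
+200 here (a +50 body would overlap the PPR and mix paused signal into the
denominator) and `gb_pi_start` is exposed so either convention can be run —
differential PI is identical in both density and raw-ratio modes because
the per-gene length constants cancel in fold changes.

## Read processing

"Uniquely mapped" is operationalised as a mapping-quality threshold
(default `min_mapq = 50`), the aligner-agnostic proxy. Optional duplicate
collapsing (identical chrom/start/end/strand within a sample) is a
conservative stand-in for PCR-artefact removal and is off by default. Full
fragments are used for all region counting; single-base 3'OH positions
(strand-aware terminal base) feed only the coverage tracks and metagene
profiles. Positions that coincide with the strand-aware 3' end of an
annotated exon are removed before track building, since splicing
intermediates expose the same free 3'OH ends as paused polymerase.

## Counting and normalization

A fragment counts toward a region when it overlaps by at least one base and
matches the region's strand (`bedtools multicov` semantics). Because the
PROMPT region is emitted on the opposite strand of its gene, sense-to-region
counting is antisense-to-gene counting there. Fragments spanning the gene
bodies of two genes are dropped from gene-body counting (`exclude_multigene`),
but kept for promoter windows. Normalization is counts per million retained
fragments per sample; library size is the total of retained fragments, not a
per-region total. Total-count scaling is exact arithmetic but biased when
induction is asymmetric between conditions: a strongly induced class of
regions inflates one condition's totals and shifts every other gene's
apparent fold change. The pipeline therefore defaults to median-of-ratios
size factors estimated on gene bodies (the estimator negative-binomial DE
frameworks use), rescaled so the geometric-mean sample keeps its library
size; `norm_method = "total"` restores plain CPM.

## Differential testing

The exact Mann–Whitney U test (`mwu_exact()`) computes U with midranks and,
for pooled sizes up to 12, the permutation p-value by enumerating all
`choose(n+m, n)` group assignments, ties respected; larger samples use the
tie-corrected normal approximation without continuity correction. A
consequence worth knowing: with 4 vs 4 replicates the smallest attainable
two-sided p is 2/70 ≈ 0.0286, and the test rejects at p < 0.05 only for
complete separation — the realised type-I level is 2/70, not 0.05.

Fold changes are `log2(IR / noIR)` so up-regulation upon damage is
positive. The PROMPT/pause presets first drop features with a zero count in
any sample (no pseudocounts are ever added), then test per-replicate CPM
values; calls use raw p < 0.05 with |log2FC| > 0.1, and the "unchanged"
band |log2FC| < 0.05 is assigned on fold change alone — it is the
background set for the sequence-feature comparisons. The gene preset is a
Welch t-test on log2(CPM+1) with Benjamini–Hochberg adjustment, a
deliberately simple, self-contained stand-in for a negative-binomial count
model; an optional per-batch mean subtraction (replicate i of both
conditions shares batch i) absorbs technical-replicate batch structure.
Significance for integration uses adjusted p for the gene axis and raw p
for the PROMPT and PI axes, mirroring how each axis is called.

## Metagene profiles

Coverage tracks are sparse per-base, per-strand counts of 3'OH positions,
optionally scaled per million. Reference-point profiles bin the
[TSS−flank, TSS+flank) window (defaults flank 500, bin 5, hence 200 bins);
scale-regions profiles bin 1-kb flanks natively and linearly rescale the
body to a fixed bin count. Minus-strand windows are read in decreasing
genomic order so bins always run 5'→3', which makes the strand-mirror
property exact: reflecting all coordinates and flipping strands reproduces
the matrix bit for bit. Each bin stores the mean per-base value, so bin
value × bin width recovers signal mass; unmapped flank bases count as
zeros. Sense and antisense profiles pair the track strand with the region
strand, so the PROMPT peak appears in the antisense profile upstream of the
TSS.

## Sequence features

Two auditable G-quadruplex detectors replace black-box predictors: G4Hunter
scoring (+min(run,4) per G in a G-run, −min(run,4) per C in a C-run, window
mean ≥ 1.2 over 25 nt by default) and the canonical quadparser regex
(G≥3 with 1–7 nt loops, four runs). Predicted windows are merged and
summarised as percent coverage of the 500-nt PROMPT sequence;
groups (up-regulated vs unchanged PROMPTs) are compared by the proportion
of sequences with any predicted structure and a Mann–Whitney test on
coverage. Motif enrichment scans RNA single-strandedly with log2-odds PWM
scores (probabilities floored at 1e-4 before logs; threshold in bits) and
tests per-motif hit counts with a one-sided Fisher exact test. The
published PRC2 RNA-binding motifs are available only as logos, so
`synthetic_prc2_pwms()` provides clearly-labelled synthetic GC-rich and
U-rich stand-ins for simulation and demonstration; real analyses should
supply measured matrices in MEME minimal format.

## The synthetic-data generator

`sim_config()` defines the study conditions the package is validated
under: non-overlapping genes (1.5–6 kb) with a 2-kb buffer on one
synthetic chromosome; per gene and sample, negative-binomial counts in GB,
PPR (sense) and PROMPT (antisense) windows with means
density × length × condition effect; fragments 30–80 nt (the size-selected
small-RNA fraction of mNET-seq) placed uniformly and fully inside their
region, so re-counting them reproduces the internal draws exactly. Three
gene classes are planted: `repressed_prompt` (GB −1, PROMPT +1.5, PPR +1
log2 units in the IR condition — the coupled signature), `upregulated`
(GB +1, PPR +1, PROMPT 0: activation by increased recruitment raises body
and promoter signal proportionally, leaving PI unchanged) and `null` (all
effects exactly 0). Each sample draws from its own RNG stream derived from
the master seed, so adding samples never perturbs existing ones and every
output is byte-reproducible.

Parameter defaults and why:

* `n_genes = 1000`, `baseline_gb_density = 150` fragments/kb/sample: mean
  gene-body counts ≈ 530, deep enough that per-gene fold-change estimates
  are limited by replicate dispersion rather than shot noise, while a full
  run stays around a minute on one core. These problem sizes are what the
  shipped tests and the acceptance script use.
* `nb_dispersion = 0.02` (variance μ + 0.02 μ²): replicate CV ≈ 14%, the
  regime of technical/cell-line replicates, which is what replicate-wise
  batching describes. The choice matters for estimator precision: the
  per-gene log2FC from 4 + 4 replicate means has standard deviation at
  least `sqrt(2)·sqrt(a)/(2·ln 2)` at any depth, so a = 0.02 bounds the
  typical per-gene error near 0.1 log2 units, whereas a = 0.05 would push
  the floor past 0.15 — a level at which planted ±1 effects would still be
  detected but per-gene effect sizes would be materially blurred.
* `pause_enrichment = 10`: expected PI of an unperturbed gene, inside the
  5–50 "moderate" band used for per-gene pause plots.
* `prompt_fraction = 1`: PROMPT density comparable to gene-body density,
  the regime of a promoter/antisense-enriched polymerase fraction (Y1P);
  the 500-bp window then averages ≈ 75 counts per sample.
* `prompt_seq_gc = 0.5` and plant probabilities 0.35/0.19 (G4) and 0.8/0.1
  (motif) per class: neutral base composition with class-linked structural
  enrichment. Random 500-mers at GC 0.5 also contain spontaneous
  G4Hunter/quadparser matches, so realised group proportions sit above the
  plant probabilities; group contrasts, not absolute rates, are the
  meaningful readout.

What the generator does **not** emulate: sequence-level reads (no
alignment errors or mapping ambiguity), splicing isoforms, UV-specific
signal, chromatin context, or correlated gene-gene effects. Passing tests
on this generator therefore validate the statistical machinery and the
region/strand bookkeeping — not robustness to alignment artefacts or to
compositional biases of real libraries. One such bias is visible even
here: strong asymmetric induction shifts library totals, so CPM fold
changes carry a small compositional offset (~0.03 log2 units at the
default effect mix); the generator's effect-recovery checks read raw
counts, where expected depth is equal by construction.

## Numerical choices and degenerate inputs

Ties in the exact test use midranks with a 1e-9 comparison tolerance;
identical groups give p = 1. Genes shorter than the gene-body offset yield
flagged, empty bodies excluded downstream; pause-index genes are dropped
when any sample has a zero PPR or GB count or the body is under 1 kb.
Percentages over empty intersections are NA, never 0/0. PWM cells are
floored, not renormalised, so a consensus hit against a uniform background
scores width × 2 bits minus a negligible flooring correction. Scale-region
bodies shorter than one bin per body bin are skipped with a warning.
Region-order and fragment-order permutations never change any count
(verified property).

## Known limitations

The gene-preset test is not a shrinkage count model; at very low counts its
power profile differs from negative-binomial GLMs, which is why headline
genome-scale gene counts from deep datasets are not expected to be
reproduced at desk scale. The internal-priming artefact filter used
upstream of published datasets is not reproduced (its logic is not public);
duplicate collapsing is the documented stand-in. G4 calls are arithmetic
predictions, not thermodynamic folding. The synthetic PRC2 matrices are
stand-ins and must not be interpreted against real CLIP-derived motifs.
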