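# promptpause

Analysis of strand-specific nascent transcription around gene promoters:
quantification of antisense promoter upstream transcripts (PROMPTs),
promoter-proximal pause-index statistics, and their integration with
gene-body expression changes — the coupled signature by which DNA-damage
signalling represses protein-coding genes.

## The problem and who this is for

DNA double-strand breaks trigger genome-wide transcriptional repression of
protein-coding genes. In nascent-transcription data (mNET-seq and related
protocols), that repression leaves a three-part footprint at each affected
gene:

* **gene body (GB) down** — sense signal from TSS+200 to the TES drops;
* **PROMPT up** — antisense signal in the 500 bp window upstream of the
  TSS rises;
* **pause index (PI) up** — polymerase density in the promoter-proximal
  region (PPR, −50/+200 of the TSS) rises relative to the gene body:

  `PI = (PPR count / |PPR|) / (GB count / |GB|)`

`promptpause` is for computational biologists who need this promoter-level
analysis as tested, reproducible building blocks: strand-aware region
derivation and counting from BED/GTF/SAM inputs, an exact Mann–Whitney U
test (midranks; permutation enumeration for small samples) with the
zero-count filters and thresholds appropriate to lowly-expressed PROMPTs,
differential PI, three-way gene classification with contingency summaries,
strand-resolved metagene profiles from single-nucleotide 3'OH polymerase
positions, G-quadruplex scoring (G4Hunter and quadparser) with
percent-coverage statistics, and PWM motif enrichment between PROMPT
groups (MEME minimal format in, one-sided Fisher exact out).

A negative-binomial synthetic-data generator with planted effect classes
(`sim_config()`, `simulate_genome_and_truth()`, `simulate_fragments()`,
`simulate_prompt_sequences()`) makes the whole pipeline testable end to
end — every statistic the package reports can be checked against planted
ground truth without downloading anything.

## Worked example

Simulate a 200-gene dataset (4+4 replicates, 10% of genes planted with the
repression signature: GB −1, PROMPT +1.5, PPR +1 log2 units) and run the
full pipeline:

```r
library(promptpause)

cfg <- pipeline_config(simulate = sim_config(n_genes = 200,
                                             chrom_length = 2e6,
                                             seed = 7))
res <- run_pipeline(cfg, out_dir = "promptpause_run")
r <- res$report
```

What it prints (this exact run):

```
r$gene_body$down, r$gene_body$up        # 19 down, 21 up-regulated gene bodies
r$prompt$up, r$prompt$unchanged          # 23 PROMPTs up, 40 unchanged
r$pause_index$n_significant_up           # 20 genes with significantly higher PI
r$integration$pct_gb_down                # 94.7  (% of PI+GB-significant genes with GB down)
r$integration$pct_prompt_up              # 100   (% of PI+PROMPT-significant genes with PROMPT up)
r$truth_confusion$sensitivity            # 0.9   (planted repressed genes recovered)
r$truth_confusion$fdr                    # 0
r$sequence_features$motif_enrichment     # synthP7: 60.9% vs 17.5% of PROMPTs, p = 6.3e-4
```

Reading: of the genes whose pause index changed significantly and whose
gene body changed significantly, 94.7% were repressed in the gene body; all
PI-significant genes with a significant PROMPT change had the PROMPT go
*up*; 18 of the 20 planted repressed genes were recovered as
`repressed_concordant` with no false positives; and the GC-rich synthetic
motif planted preferentially into repressed-class PROMPT sequences is
recovered as strongly enriched in up-regulated PROMPTs.

Artifacts land in `promptpause_run/`: region and fragment BEDs, count and
differential TSVs, bedGraph coverage tracks, metagene profiles, the
integration table with per-gene classes, and `report.json`. Reruns with the
same seed are byte-identical.

The methods vignette (`vignettes/promptpause-methods.Rmd`) documents the
model, region conventions, the exact-test behaviour at small sample sizes
(the attainable 4v4 two-sided level is 2/70, not 0.05), the normalization
choice, and what the simulator does and does not emulate.

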