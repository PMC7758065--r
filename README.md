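# echoRNA

Tools for answering a recurring question in tissue transcriptomics: when
transcripts characteristic of a parenchymal cell type turn up in a second,
sorted or affinity-purified cell population — cardiomyocyte myofibrillar
(CMF) mRNAs in cardiac endothelial cells being the motivating case — are
they **ambient/technical contamination**, or does the second population
**intrinsically transcribe** those genes?

No single statistic settles this. echoRNA implements four independent
evidence lines and combines them into a verdict:

1. **Rank correlation** (`contamination_rank_test`). Kendall tau-b between
   the target-population and source-tissue expression profiles over the
   top-300 expressed genes (log2(CPM+1) scale). If shared transcripts were
   sampled from an ambient pool, their relative abundances should mirror
   the source: tau-b = (n_c − n_d) / √((n₀ − n_x)(n₀ − n_y)) should be
   high. Low tau argues against pure contamination.
2. **Marker co-expression dispersion** (`positivity_matrix`,
   `marker_count_distribution`). K marker genes are selected by the
   signature rule — positive (ln(1+CPM) ≥ 1) in >60% of parenchymal cells
   and ≥10-fold enriched — and counted per target cell. Ambient sampling
   makes positive cells positive for *many* markers at once; sporadic
   intrinsic transcription makes most positive cells carry only one or two.
3. **Spliced/unspliced fractions** (`count_splice_states`,
   `median_unspliced`). Ambient mRNA is cytosolic and mature; nascent
   transcription leaves intronic (unspliced) reads. Reads are classified
   against gene models, genes filtered to those with >1% unspliced signal
   in the source population, and the per-group median unspliced/total
   fraction compared between target and source.
4. **TSS chromatin accessibility** (`tss_window_rpkm`,
   `classify_accessibility`). ATAC read density in a ±250 bp TSS window,
   as RPKM = count / (window_kb × library/10⁶); closed < 1.5, open > 3
   (raw-RPKM defaults, scale is an explicit parameter). Chromatin
   abundance scales with cell count, not transcript capture, so open
   marker-gene TSSs in the target population cannot be explained by a few
   percent contamination.

The verdict rule (`build_evidence_report`) is deliberately simple and
fully configurable: *intrinsic* needs ≥3 of 4 lines intrinsic-consistent
including the tau line; *contamination* needs ≥3 contamination-consistent;
otherwise *mixed*, or *indeterminate* with fewer than 3 lines.

Because the original data live in external repositories, the package
ships a first-class, seeded synthetic-data generator (`scenario_truth`,
`simulate_expression`, `simulate_splice_reads`, `simulate_atac_reads`)
that realizes both hypotheses with known ground truth in all three
modalities, so the entire chain is testable offline.

## Worked example

```r
library(echoRNA)
r <- run_simulated_analysis("intrinsic", seed = 1)
print(r$report)
```

```
tau_line         [intrinsic]  tau=-0.469 (max 0.30, n=300)
dispersion_line  [intrinsic]  median markers among positive=1, frac_ge1=0.640
splice_line      [intrinsic]  unspliced median target=0.0394 source=0.0167
chromatin_line   [intrinsic]  open fraction=1.000 (min 0.50)
verdict: intrinsic
```

Reading it: the target population's profile does not mirror the
parenchymal ranks (tau −0.47, far below the 0.30 cutoff); 64% of target
cells are positive for at least one of the 15 selected markers but the
median positive cell carries only 1 of 15 (sporadic, not pool-like); the
target's median unspliced fraction (3.9%) exceeds the parenchyma's (1.7%),
so nascent transcripts are present; and 100% of marker-gene TSSs are open.
All four lines agree: intrinsic transcription.

The same pipeline on a contamination world flips three lines:

```r
print(run_simulated_analysis("contamination", seed = 1)$report)
```

```
tau_line         [intrinsic]  tau=-0.115 (max 0.30, n=300)
dispersion_line  [contamination]  median markers among positive=15, frac_ge1=1.000
splice_line      [contamination]  unspliced median target=0.0030 source=0.0167
chromatin_line   [contamination]  open fraction=0.067 (min 0.50)
verdict: contamination
```

Every positive cell now carries all 15 markers (shared ambient pool), the
target's transcripts are almost fully spliced, and marker TSSs are closed.

## Command line

```sh
Rscript -e 'echoRNA::echo_rna_cli()' run --scenario intrinsic --seed 1 --out-dir out/
Rscript -e 'echoRNA::echo_rna_cli()' simulate --scenario contamination --out-dir sim/
Rscript -e 'echoRNA::echo_rna_cli()' velocity --reads sim/splice_reads.sam --format sam \
    --models sim/splice_models.gtf --out counts.tsv
```

Subcommands: `simulate`, `normalize`, `markers`, `contamination`,
`velocity`, `atac`, `report`, `run`. All tables are plain TSV/MTX/GTF/
BED/SAM/JSON; logs go to standard error.

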