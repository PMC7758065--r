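---
title: "Deciding between ambient contamination and intrinsic transcription: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding between ambient contamination and intrinsic transcription: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Sorted or affinity-purified cell populations routinely contain
transcripts characteristic of their neighboring parenchyma. Two
generative models compete:

* **Ambient contamination.** Lysed parenchymal cells release mRNA; every
  target-cell library captures a fraction of this shared pool. The pool
  is well approximated as proportional to the pooled parenchymal
  expression profile — the standard assumption of ambient-RNA methods.
  Consequences: (i) shared transcripts' relative abundances mirror the
  source profile; (ii) all cells are affected, and a cell that captured
  the pool captured *all* abundant pool genes, not one; (iii) the
  captured RNA is cytosolic and mature (spliced); (iv) target-cell
  chromatin at those genes is closed, and ATAC signal — proportional to
  cell count, not to captured RNA — stays near background.
* **Intrinsic transcription.** Target cells transcribe a sporadic subset
  of the parenchymal genes themselves. Consequences invert on every
  line: rank decoupling from the source profile, one-or-two-gene
  positivity per cell, intronic (unspliced) reads present at comparable
  or higher rates than in the parenchyma, and open TSS chromatin.

echoRNA quantifies each consequence as an *evidence line* and codifies
the verdict. The source argument is enumerative, not quantitative; the
3-of-4 rule here is this package's own codification and every threshold
is a visible parameter.

## Evidence lines and their parameters

### Rank correlation (tau line)

`contamination_rank_test(target, source, n = 300, ranking_reference =
"source")` computes Kendall tau-b over the top-`n` expressed genes,

$$\tau_b = \frac{n_c - n_d}{\sqrt{(n_0-n_x)(n_0-n_y)}},$$

with tie terms $n_x, n_y$ counting pairs tied in either vector (a pair
tied in both counts toward both). Values are correlated on
$\log_2(\mathrm{CPM}+1)$; tau is rank-based, so the transform matters
only through ties, and a raw-scale option is retained. Which profile
defines the top-$n$ universe is ambiguous in general usage, so it is an
explicit parameter; the default is the *source* (whole-tissue) profile,
matching the convention of ranking by total-tissue expression. Top-$n$
ties break lexicographically by gene id for determinism.
`tau_max = 0.3` marks the intrinsic-consistent region: published
endothelial-versus-heart comparisons of this kind report tau in the
0.05–0.3 range, while a profile actually sampled from the source pool
approaches 1 as its own expression vanishes.

A caveat the synthetic world makes visible: with a small ambient
fraction, tau over the top-300 universe is *not* large under
contamination, because the target population's own highly-expressed
genes dominate its ranks. Discrimination therefore never rests on the
tau line alone — it gates the *intrinsic* verdict (a high tau vetoes
it) while the other three lines carry the *contamination* verdict.

### Marker co-expression (dispersion line)

Markers are selected by `select_parenchymal_markers`: positive in more
than `min_frac = 0.60` of parenchymal cells and at least
`min_fold = 10`-fold enriched, ranked by fold, truncated to `n = 15`.
Positivity has a single package-wide definition: $\ln(1+\mathrm{CPM})
\ge 1$, i.e. CPM $\ge e-1$, an *inclusive* bound (`log1p(expm1(1))` is
exactly 1 in double precision, so the boundary is numerically exact).
Fold is pseudocounted, $(\bar{x}_{in}+1)/(\bar{x}_{out}+1)$ on CPM.
`marker_count_distribution` then summarizes, per group, the per-cell
number of positive markers; the line scores intrinsic-consistent when
the median among positive target cells is at most `k_max = 2`. A group
with no positive cell has an undefined median and counts as
intrinsic-consistent: nothing mirrors the ambient pool. The general
`rank_markers` (two-sided Wilcoxon rank-sum on per-cell values, BH
adjustment, normal approximation with continuity correction so ties are
well-defined) replaces package-specific marker callers; the selection
rule, not the test, is what the evidence line consumes.

### Splice state (splice line)

Reads are classified against merged-exon gene models: *unspliced* if any
aligned block overlaps intronic territory by ≥1 bp; *spliced* if all
blocks lie in the exon union and the read is a single fully-exonic block
or every junction gap exactly matches an annotated intron; *ambiguous*
otherwise, and ambiguous reads are excluded from both numerator and
denominator rather than guessed. This is a deliberate simplification of
full velocity-style logic: deterministic, oracle-checkable, and
sufficient for fraction statistics. Strand is ignored by default
(full-length single-cell protocols are unstranded). Genes qualify for
the comparison when their unspliced/total fraction in the *source* group
strictly exceeds `min_frac = 0.01`; medians use R's mean-of-middle rule
and zero-total genes are flagged missing, never zero. The line is
intrinsic-consistent when the target median is at least the source
median.

### Chromatin (chromatin line)

`tss_window_rpkm` counts reads overlapping `[TSS − 250, TSS + 250)` by
≥1 bp (interval intersection, not midpoint — metaprofiles, by contrast,
bin read *starts*) and converts to RPKM with the window in kb and the
declared library size in millions. Classification defaults to raw RPKM
(closed < 1.5, open > 3); because thresholds on a log2 scale are also in
circulation for the same quantity, the scale is a declared parameter and
never silent. The line is intrinsic-consistent when at least
`open_min_frac = 0.5` of marker genes are open. Housekeeping-relative
accessibility divides by the geometric mean of the housekeeping RPKMs
(the natural mean for a ratio scale); a zero housekeeping RPKM is an
error, not a zero. Tissue-enriched gene selection reads "enriched over
brain or lung" conservatively as fold over the *maximum* of the other
tissues, with ε = 0.1 guarding empty denominators and a unit-agnostic
baseline `min_expr = 10` (the sources disagree on CPM vs TPM; both are
per-million scales).

## Coordinates and normalization conventions

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
converts at the boundary, BED is native. The TSS is the gene start on
`+` and the half-open gene end on `-` (the contract's convention; the
1 bp offset from the last transcribed base is immaterial at 250–2000 bp
window scales). Exons are merged across transcripts — the splice logic
is gene-level. CPM normalizes each cell to 10⁶; zero-total cells are
retained as all-zero, flagged, and excluded from per-cell statistics
(thresholds on CPM are undefined for empty cells). Natural log for the
positivity scale, log2 for display-parity scales; per-cell CPM is
computed on all detected genes (whether published matrices used a
pre-filtered gene universe is unknowable downstream; all-genes is the
reproducible default).

## The synthetic world

The generator states one world per scenario and the defaults *are* that
world; none of them was tuned against a test outcome.

* **Expression.** 2,000 genes, 150 parenchyma-exclusive; log-normal
  (σ = 1) base profiles, parenchymal genes elevated 10–100× (log-uniform)
  in the parenchymal profile and exactly zero in the target base
  profile. Cells draw libraries multinomially (depth 10⁵; 200
  parenchymal + 500 target cells in the reference world). Contamination
  replaces a Binomial(depth, f·cell) portion of each target library with
  draws from the pooled empirical parenchymal profile, f = 0.02, with a
  mean-preserving log-normal per-cell ambient fraction (σ = 0.5) —
  ambient load varies between cells in real dissociations, and the
  stated per-cell-correlation property presupposes that variation.
  Intrinsic activates each (cell, parenchymal gene) pair with
  p_on = 0.08, adding a log-normal burst with expected 50 CPM — low but
  comfortably detectable expression, matching the observed regime of
  parenchymal genes in the second population.
* **Splice reads.** Toy genes with 2–4 exons of 150–400 bp and introns
  of 200–1500 bp on a 10 Mb chromosome; exons exceed the 100 bp read
  length so mature reads span at most two exons. Each read is mature
  (uniform on the spliced transcript, junction-split) with probability
  1 − ρ or pre-mRNA (uniform on the gene span) with probability ρ;
  ρ defaults to 0.054 (target) and 0.024 (parenchyma) in the intrinsic
  world — mimicking the reported medians for the motivating contrast —
  and 0.005 (essentially mature ambient RNA) for the target under
  contamination. The recovered fraction is biased low because pre-mRNA
  reads landing fully inside an exon classify as spliced;
  `expected_unspliced_fraction` gives the exact enumeration
  ρ·mean_g P(intron overlap), and tolerances compare against it, not
  against ρ.
* **ATAC reads.** Background uniform on the toy genome; open genes
  receive reads whose center displacement from the TSS is Laplace
  (scale 150 bp). The default enrichment (10⁴ × a 500 bp background
  window per open gene) corresponds to a library almost entirely within
  peaks; on a 10 Mb toy genome this is what reproduces the
  background-vs-peak RPKM contrast that genome-scale libraries (where
  background spreads over 3 Gb) show at the stated absolute thresholds.
  It is a property of the toy genome's size, not a claim about real
  FRiP.

What the generator does **not** emulate: UMI duplication, dropout
curves, doublets, batch effects, Tn5 sequence bias, correlated base
profiles between populations. A green end-to-end test therefore
establishes that the *inference chain* discriminates the two stated
mechanisms at realistic effect sizes — not that it is robust to every
nuisance of real data. One consequence of the independent base profiles
is documented above: absolute tau values are lower than in real tissues,
where shared housekeeping structure raises both scenarios' correlations.

Determinism: every stage seeds from one master seed by fixed offsets
(`derive_seed`), kept below 2³¹; identical configuration gives
byte-identical outputs (report provenance excepted).

## Verdict rule

With lines scored as above: *intrinsic* requires at least 3 of 4
intrinsic-consistent lines **and** an intrinsic-consistent tau line;
*contamination* requires at least 3 contamination-consistent lines;
fewer than 3 available lines is *indeterminate*; anything else is
*mixed*. Lines are unweighted — the source argument treats them as
cumulative, and weighting would demand calibration data the desk-scale
world cannot supply. The asymmetry (tau gates only the intrinsic
verdict) reflects the asymmetric information content established above.

## Known limitations

* The splice classifier discards ambiguous reads; protocols with many
  unannotated junctions would undercount both classes.
* Multi-gene overlapping reads are double-counted (with a logged tally);
  dense genomes would need the configurable drop mode.
* `kendall_tau` is O(n²) in memory and time — intended for
  few-hundred-gene universes, not transcriptome-wide vectors.
* The marker rule assumes the annotation's cell types are trustworthy;
  misannotated doublets would contaminate the parenchymal reference
  itself.
* Absolute accessibility thresholds (1.5/3 RPKM) presuppose
  genome-scale background dilution; small custom genomes need rescaled
  thresholds or the log2 scale option.
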