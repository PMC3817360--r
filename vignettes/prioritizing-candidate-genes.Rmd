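---
title: "Prioritizing candidate genes in QTL regions of divergently selected lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing candidate genes in QTL regions of divergently selected lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divergescan)
```

## The problem

After QTL mapping and fine mapping, a growth QTL in an experimental
population still spans millions of base pairs and hundreds of genes. When
the mapping population descends from two lines divergently selected for the
trait, a further, independent source of information is available: loci that
contribute to the selected trait — and loci hitchhiking with them — should
show large allele-frequency differences (AFD) between the lines, up to
fixation for alternative alleles. `divergescan` operationalizes this idea:
it fuses two measurements of between-line divergence with the QTL mapping
signal into a single per-position score, selects the high-scoring slices of
each QTL, and then ranks the variants inside those slices by annotation
evidence into a short candidate report.

## Evidence tracks

**Pooled-sequencing divergence (AB scores and FSV).** Each line is
sequenced as a DNA pool. At a site, the line's *AB score* is the
proportion of its reads that agree with the reference genome,
`ref / (ref + alt)`; the per-site divergence estimate is
`|AB_high − AB_low|`, which under equal sampling approximates the
between-line AFD. A site with no coverage in a line is *missing*, not
zero — zero would fabricate evidence of no divergence. Because read
proportions at ~12× per pool are noisy, the *flanking-SNP value* (FSV)
smooths them: the FSV at a SNP is the weighted mean of the per-site
divergence of all SNPs within a flanking window on each side (the SNP
itself included), the window being chosen at a scale presumed to be in
strong linkage disequilibrium with the focal SNP. Defaults: window
half-width 40 kb, uniform weights, at least one contributing site; a
linear distance-decay weighting is available
(`fsv_params(weighting = "linear")`). With the window shrunk to zero the
FSV reduces to the per-site divergence.

Sites enter the analysis only if they pass the SNP-detection rule: at
least `min_alt_total = 3` alternate (non-reference) reads summed over
*both* pools (`call_snps()`). Summing over pools at ~24× combined depth
raises sensitivity at sites covered thinly in one line; the threshold of
three guards against sequencing-error artifacts.

**Chip AFD.** With individual genotypes for ~20 birds per line at chip
markers, the per-line alternate allele frequency is the mean allele count
over non-missing individuals, and the track value is
`|p_alt(HIGH) − p_alt(LOW)|`. A marker with no calls in a line is missing.

**QTL support.** The statistical support profile of the QTL scan (here the
intercross analysis's model statistic) is an *input*, not recomputed. The
profile's scale is arbitrary, so it is min–max normalized within each QTL
region: `(s − min)/(max − min)`. A constant profile carries no positional
information and maps to all zeros, which also avoids division by zero.
Min–max keeps all three components commensurable on [0, 1].

## The combined data score

At every sequencing-SNP position the three tracks are fused as

$$\mathrm{CDS} = \frac{\tfrac{1}{2}(\mathrm{FSV} + \mathrm{AFD_{chip}}) + Q}{2}
             = \tfrac14\,\mathrm{FSV} + \tfrac14\,\mathrm{AFD_{chip}} + \tfrac12\,Q$$

so the QTL evidence carries half the weight and the two divergence sources
a quarter each (`cds()` asserts this identity in the tests to 1e-12). The
tracks live on different position grids; `build_cds_track()` evaluates the
CDS at the pooled-SNP positions, taking the chip value from the *nearest*
chip marker (ties toward the lower position) and interpolating the QTL
curve linearly between its flanking points (clamped at the region ends).
Positions where any component is missing are omitted rather than imputed.

## Segment selection

`select_segments()` takes maximal runs of positions with CDS at or above a
threshold, by default also requiring the raw (uninterpolated scale) QTL
support at the position to reach the scan's significance level. The
default threshold is `cds_threshold = 0.8`, with a quantile alternative
(e.g. `"q90"`, the track's own 90th percentile) for profiles whose
absolute level differs. Runs separated by less than `merge_gap_bp` are
merged — the default of 50 kb, about one FSV window, reflects that dips
shorter than the smoothing scale are sampling noise (a single
zero-divergence chip marker, a thinly covered site), not evidence of a
signal boundary. Segments shorter than `min_segment_bp` (default 0) can be
dropped. The significance requirement is a flag
(`require_qtl_significant`) rather than an invariant because regions of
extreme divergence occasionally deserve follow-up even where the QTL scan
is locally non-significant; turning the flag off reproduces that judgment
call explicitly.

`summarize_selection()` reports per-region and total selected sizes in Mbp
(0.1 precision) and the integer percentage of the total QTL extent
covered. Sizes are always recomputed as `end − start`; when a region table
carries its own printed size column it is kept as a report-level value
(`size_printed_mbp`) and used for the QTL totals, since such printed sizes
may reflect sub-0.1-Mbp coordinates that the rounded printed coordinates
cannot reproduce.

## Variant annotation and candidate ranking

`classify_variant()` assigns each gene overlapping or flanking a SNP one
label from a closed vocabulary (`consequence_vocabulary()`), reducing
transcript-level labels by a fixed severity order (stop gain > essential
splice > non-synonymous > splice region > synonymous > UTR > intronic >
up/downstream). Conventions, all configurable via `annotation_params()`:

* up/downstream flank: 5,000 bp on each side of the transcript span;
* essential splice site: the first 2 intronic bases at either intron end;
  splice region: intronic bases 3–8 and the 1–3 exonic bases adjacent to
  an internal junction (co-labelled, e.g. "Synonymous coding, splice
  site");
* coding effects by codon translation under the standard genetic code,
  honoring strand and CDS phase; a stop-lost or phase-broken codon is
  reported as "Coding unknown";
* a gene whose transcripts yield both a stop gain and a non-synonymous
  change reports the combined class;
* a SNP genic in one gene and flanking another yields one row per gene
  (counts are site–gene pairs, not unique SNPs).

`cpg_relation()` reports whether a site falls in a CpG island and, if so,
the island's relation to nearby genes (coding / upstream / downstream,
orientation-aware) — CpG-island variants near growth genes are carried as
potential regulatory candidates even when their coding consequence is
silent, so the report keeps consequence and CpG relation side by side
rather than merging them into one judgment.

`keyword_filter()` retains genes whose free-text annotation terms contain
any of twelve growth-related keywords (growth, development, morphogenesis,
formation, proliferation, differentiation, regeneration, mineralization,
elongation, biosynthetic, biogenesis, organization) as case-insensitive
substrings. Substring matching is deliberate — "biosynthetic" should match
"biosynthetic process"; token matching can be emulated by supplying
pre-tokenized keywords. Adding a keyword can only grow the gene set.

`rank_candidates()` restricts candidates to keyword-passing genes inside
selected segments and orders them by AFD (descending), consequence
severity, then combined substitution score, with genomic position as the
stable tie-break, reporting the top `k = 2` per region.

## Substitution scores

Non-synonymous candidates are scored three ways (`pc_score()`,
`ec_score()`, `pe_score()`):

* **PC (physicochemical)**: Euclidean distance between residue property
  vectors — Kyte–Doolittle hydropathy, residue volume, net charge,
  Grantham polarity, aromaticity — each property z-scored across the 20
  residues, the distance scaled so the most dissimilar of the 190 pairs is
  exactly 1. Symmetric; identity scores 0.
* **EC (evolutionary conservation)**: from an orthologue alignment column,
  `freq(aa_from) × (1 − freq(aa_to))` with gaps excluded from the
  frequencies (a gap is absence of evidence). A perfectly conserved column
  with an unseen target is 1; a target present in every sequence is 0.
* **PE**: the product `PC × EC`, rendered to two decimals in reports. The
  product combination is the component pinned by the reported score pairs;
  the property set and conservation definition are package choices and are
  exposed for replacement.

PE never exceeds `min(PC, EC)`; all three live on [0, 1].

## The synthetic-data generator

`simulate_lines()` evolves two lines from one base population by
Wright–Fisher reproduction with truncation selection up (HIGH) and down
(LOW) on an additive phenotype: `causal_effect × (dosage − 1)` plus
standard normal polygenic noise. No new mutations arise — the design being
emulated is selection on standing variation, and QTL detected by a
line-cross analysis presuppose alternative alleles segregating from the
base. Defaults are the study conditions the pipeline assumes: 40
generations, 30 breeding individuals per line with 10 selected per
generation, causal effect 1 polygenic SD, recombination 3 cM/Mb, 1,500
markers on a 5 Mb segment with the causal locus at its centre, chip
genotypes for 20 individuals per line at 10% of markers, pooled reads at
Poisson mean depth 12 per line with binomial allele sampling
(`sample_pooled_reads()`).

One structural choice deserves emphasis. In the base population the causal
locus sits on a *standing divergent haplotype block*
(`causal_block_bp = 1 Mb`, association `causal_block_ld = 0.95` between a
block marker's allele and its haplotype class): two ancestral haplotype
classes segregate at frequency 0.5 and the causal alleles mark the
classes. Without this, a linkage-equilibrium base would let each line fix
whatever allele happened to ride along, so roughly half the flanking sites
would fix for the *same* allele in both lines and near-causal per-site
divergence would be a coin flip — whereas the scenario this tool targets
is lines driven to fixation for alternative alleles *across* the selected
region. The block models the divergent founder haplotypes (the
experimental lines descend from crosses of partially inbred founder
lines); its 1 Mb width also makes localization meaningful, since the
selectable signal is narrower than the 5 Mb region.

`synth_support_curve()` stands in for the external QTL scan with a
Gaussian peak (width 1 Mb) over the causal position plus optional noise,
its significance threshold set at a quantile (default 0.6) of the curve.
`synth_gene_model()` packs non-overlapping three-exon coding genes on
alternating strands into the region, writes valid CDS (start codon, no
internal stops, terminal stop, length divisible by 3, correct phases) into
a random genome sequence, places CpG islands upstream, downstream of or
overlapping the coding sequence of successive genes, and attaches
growth-keyword annotation terms only to designated genes. Every generated
gene carries a guaranteed lysine codon so that `plant_codon_snp()` can
plant a K→I or K→stop substitution with known truth. The synthetic `qual`
column is a confidence proxy (10 × total alternate reads, capped at 255);
real pipelines would carry their caller's Phred-scaled quality through
unchanged.

What the generator does *not* emulate: sequencing and genotyping error,
variable recombination and mutation landscapes, allelic heterogeneity,
gradual LD decay within the block, overlapping genes and alternative
splicing, and genome-scale annotation volume. Passing recovery tests
therefore show that the pipeline's logic localizes a strong planted signal
under its stated assumptions — not that it would achieve the same
sensitivity on real resequencing data.

## Numerical and degenerate-input conventions

* All coordinates are 1-based inclusive internally (VCF/GFF3 convention);
  BED conversion happens only at the file boundary.
* Mbp coordinates in region tables are expanded as exact `× 1e6` integers;
  sizes are recomputed, never trusted from input.
* Multi-allelic VCF records are an error in strict mode, split per
  alternate allele otherwise; duplicate (chrom, pos, alt) sites are
  rejected.
* Missing values propagate: they are omitted from FSV windows, CDS
  evaluation and selection, never treated as zeros.
* A constant support curve normalizes to zero; a single-point curve
  likewise.
* Nearest-chip ties resolve toward the lower position; segment runs are
  closed intervals from the first to the last qualifying position.
* Severity ties across transcripts resolve by the lexicographically
  smallest amino-acid change, making per-gene labels independent of
  transcript order.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset(sim_config(seed = 1))
res <- run_pipeline(ds)
res
res$segments
res$report
```

With seed 1 this selects one ~1.0 Mbp segment containing the planted
causal locus (20% of the simulated region) and reports two candidate
records in the keyword-annotated host gene, the causal SNP itself ranked
first. The problem sizes used throughout the package's tests — a 5 Mb
region, 1,500 pooled SNPs, 150 chip markers, 20 seeded replicates for the
recovery experiments — were chosen so that a full replicate represents the
assumed study structure faithfully while a complete run remains a
desk-scale computation.

## Limitations

The pooled divergence uses raw read proportions, not a genotype-posterior
model, so the reported AFD column approximates what a Bayesian pooled
caller would estimate; site qualities are consumed as input. The
annotation engine covers SNPs only (no indels), one genetic code, and CpG
islands as the only regulatory annotation. The FSV window and weighting,
the CDS threshold, and the keyword list are all explicit parameters
precisely because reasonable analyses may move them.
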