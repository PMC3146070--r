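---
title: "Quantifying gene-body histone marks from embryo ChIP-seq"
author: "mesmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gene-body histone marks from embryo ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesmark)
```

## The problem

In *C. elegans* embryos, the histone mark H3K36me3 is deposited by two
methyltransferases with very different logic: MET-1 works
cotranscriptionally, while MES-4 maintains the mark on germline-expressed
genes independently of ongoing transcription. In a *met-1* mutant, the
remaining H3K36me3 signal isolates the MES-4-maintained component, which
concentrates on germline- and ubiquitously-expressed gene bodies, is
depleted from the X chromosome, and shows a mild 5' bias within gene
bodies. `mesmark` implements the quantification chain needed to measure
these patterns from mapped single-end reads, together with the
expression-class gene-set logic, staining-proportion statistics and
ChIP-qPCR percent-input arithmetic that accompany such a study.

## The coverage model

The pipeline consumes already-mapped read intervals (BED-style; 0-based
half-open coordinates throughout the internal model, converted only at I/O
boundaries). Four steps build a comparable signal track per sample:

1. **Fragment extension.** Single-end reads tag only fragment ends, so
   each mapped 36 bp read is extended in its strand's 3' direction from
   its 5' end to 200 bp — the expected sheared-fragment length —
   clamped at chromosome boundaries. Extension direction follows the
   classic fragment-extension convention for single-end ChIP.
2. **Pileup.** For every base pair, the number of overlapping extended
   intervals. We compute it with a difference-array cumulative sum, which
   is exact in integer arithmetic; the summed track equals the summed
   interval lengths, giving a conservation invariant the tests exploit.
3. **Median scaling.** Each track is multiplied so that all samples share
   a common genome-wide median read count. At desk-scale depth most bases
   have zero coverage and the plain genome-wide median is 0, which makes
   scaling undefined; the normalization median is therefore taken over
   covered (nonzero) bases, falling back to the plain median when at
   least half the genome is covered (`method = "auto"`; both alternatives
   are exposed). Scaling is a single multiplication, so downstream gene
   scores are exactly linear in the scale factor.
4. **Replicate averaging.** The per-base arithmetic mean of the scaled
   replicates. A small state machine (`raw` → `median_scaled` →
   `replicate_averaged`) enforces that scaling precedes averaging.

## Gene-body scores and chromosome summaries

A gene's score is the mean signal over every base between its
transcription start and end sites — introns included, strand ignored for
the averaging itself (the TSS/TES accessors are strand-aware: TSS is
`start` on "+" and `end − 1` on "−"). Scores are reported alongside their
log10, which is left undefined (NA) for zero-mean genes rather than
imputed; a configurable pseudocount exists but defaults to 0 so that no
signal is invented. Scatter tables pair two samples on the intersection of
their gene universes and count the genes dropped for undefined scores.

The X:autosome summary divides the X mean coverage by the pooled
autosomal mean. Enrichment calling (`classify_enriched()`) is explicitly a
reconstruction, not a published algorithm: a gene is called enriched when
its body mean exceeds a quantile (default 0.95) of per-base signal over
intergenic bases, and the threshold is echoed in the output.

## Metagene profiles

Genes are aligned at the TSS (window 1 kb upstream to 1.5 kb downstream)
or TES (1.5 kb upstream to 1 kb downstream) and signal is averaged per
50 bp bin, reading the track in strand-oriented coordinates (the window
reverses on "−" strand genes). Both windows give exactly 50 bins; bin
`i` covers offsets `[50i, 50(i+1))` with the anchor at 0. Within each
gene the bin mean is taken first; across genes the mean and a 95%
confidence interval are reported. The interval is the normal
approximation mean ± 1.96·SD/√n over genes (a Student-t variant is
available; at typical gene-set sizes the difference is negligible).
The CI is computed across genes, not replicates, matching the per-bin
uncertainty one plots as error bars. Windows are anchored, not clipped:
genes shorter than the downstream span still contribute every bin, and
only bins that would run past a chromosome edge drop a gene (its per-bin
`n` decrements). With a single gene the half-width is 0 by convention.

## Gene sets from tag counts

Expression-breadth sets are built from SAGE-style per-tissue tag counts:
*ubiquitous* = at least 1 tag in germline, muscle, nerve and gut;
*somatic* = at least 8 tags in one or more somatic libraries **and**
strictly zero germline tags ("not expressed (≥ 1 tag)" is read as
excluded whenever germline tags ≥ 1 — the only reading consistent with
"not expressed"); *germline-enriched* = an input list minus an exclusion
list (e.g. spermatogenesis genes); *larval/adult germline-specific* = the
triple intersection of the germline-enriched list, the SAGE
germline-expressed genes and a strictly-maternal class. Raw counts are
thresholded; no library-size normalization is applied. The published
set sizes depend on external expression compendia that the package does
not ship; it ships the set *logic* plus synthetic tag tables.

## The synthetic-data generator

Because no read archive accompanies the original study, the package
includes a deterministic simulator whose defaults define the conditions
every recovery test runs under:

* **Genome.** 5 autosomes plus one X (the *C. elegans* karyotype) of
  100 kb each — a desk-scale coordinate space, not real sequence.
* **Annotation.** 30 genes per chromosome placed in equal non-overlapping
  slots, lengths uniform in 1–3 kb, strands random, classes
  germline/soma/ubiquitous at 0.3/0.4/0.3 on autosomes; on the X the
  germline proportion drops to 0.05 (renormalized), emulating the
  depletion of germline-expressed genes from the X.
* **Reads.** Each of `n_reads` reads is background (uniform over valid
  start positions) with probability `background_fraction`, otherwise it
  comes from a gene sampled ∝ class weight × length × X multiplier, with
  a within-gene position drawn from a linear density `1 + s(1 − 2u)`
  (5' bias; mirrored for 3') via inverse-CDF sampling, oriented by gene
  strand. `bias_strength` s is capped at 1 so the density stays
  nonnegative. Reads are 36 bp on a random strand, clamped at chromosome
  ends, sorted, and carry their source gene as a truth label.
* **Enrichment presets.** `mes4_maintenance`: background 0.2, 5' bias
  0.6, weights germline = ubiquitous = 1, soma = 0, X multiplier 0.1.
  `transcription_coupled`: the same but 3' bias, all classes weighted,
  no X depletion. `pan_h3` and `input`: pure uniform background. The
  original work reports no quantitative effect sizes, so these are the
  package's own choices of what a clean maintenance-marking signal looks
  like; they are deliberately strong enough that class recovery is
  near-perfect at 2×10^5 reads, the regime the acceptance checks run in.
* **Tags.** Poisson counts at mean `depth` (default 10) in the tissues a
  class expresses in, 0 elsewhere. At depth 10 the misclassification
  rates implied by the ≥1 and ≥8 thresholds are bounded by Poisson tails
  (e.g. P(Poisson(10) = 0) = e^−10), which is what makes the
  Jaccard ≥ 0.9 recovery check meaningful rather than automatic.

Each replicate uses an independent RNG stream derived from
`(seed, replicate)`, so replicates are jointly reproducible, and the
generator never touches the caller's global RNG state.

What the simulator does **not** model: sequencing errors, PCR duplicates,
mappability, paired ends, real sequence composition, overlapping or
nested gene models, or depth-dependent dispersion beyond sampling noise.
Passing recovery tests therefore demonstrates that the quantification
chain measures what the model puts in — not that real embryo chromatin
behaves this cleanly.

## Staining and qPCR arithmetic

Staining tables are positive/total embryo counts per genotype and assay.
Percentages are rounded half away from zero — the only rounding
consistent with printed cells such as 3/35 → 9 and 1/40 → 3. Wilson
score intervals and Fisher's exact genotype comparisons are provided as
uncertainty plumbing.

Percent input for ChIP-qPCR is
`100 · b^(−ΔCp) · (df_ChIP/df_input) · (f_input/100)` with
ΔCp = Cp(ChIP) − Cp(input). The bench formula's base is written
"2 × (PCR efficiency)"; we implement that literal reading as the default
and expose the common `1 + efficiency` convention as a switch, since the
two coincide only at efficiency 1. The input-fraction term is a
multiplicative fraction, so ΔCp = 0 at equal dilutions returns exactly
the fraction of extract used as input — the identity the tests pin down.

## Numerical choices and problem sizes

Coordinates are 0-based half-open internally; pileup is exact integer
arithmetic until scaling, after which tracks are double precision.
bedGraph output is run-length compressed with zero runs omitted and
values at 6 decimals (round trips are exact to 5×10⁻⁷). Readers
validate hard: line-numbered parse errors, genome-bounds checks, overlap
rejection — never silent clamping.

The test and acceptance runs use the generator defaults above: coverage
and recovery checks at 10⁴–2×10⁵ reads over 0.1–0.6 Mb genomes, and CI
calibration over 200 independent simulations of 4×10³ uniform reads over
a 90 kb chromosome carrying 30 identical, widely spaced genes (spacing
chosen so no 200 bp fragment can touch two gene windows, keeping
per-gene means independent — the condition under which the across-gene
CI is expected to be calibrated). At 30 genes the normal-approximation
interval is very slightly liberal (~94–95% observed coverage), which is
why the calibration check accepts 95% ± 3%.

## Known limitations

* The normalization median over nonzero bases depends on coverage
  breadth; comparing samples with very different signal-to-background
  ratios shifts what "the median" measures, an ambiguity inherited from
  the verbal definition of median scaling.
* Gene scores use whole gene bodies; transcript isoforms, UTR
  annotation differences and overlapping genes are out of scope.
* `classify_enriched()` is a threshold reconstruction; its calls depend
  on the intergenic background definition and quantile and should be
  treated as descriptive.
* The CI on metagene profiles is across genes; it does not capture
  between-replicate variability.
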