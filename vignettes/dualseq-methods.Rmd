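---
title: "dualseq: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dualseq: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: what each stage assumes, which knobs matter, what the
synthetic generator does and does not emulate, and where a design was
genuinely open and a choice had to be made.

## The analysis in one paragraph

Two mouse cardiac-hypertrophy contrasts are analysed side by side:
pathological pressure overload (sham vs. TAC, called PAH throughout) and
physiological exercise training (sedentary vs. exercise, PHH), each with
three biological replicates.  From filtered alignment intervals the
pipeline derives exon and gene counts, RPKM expression, differentially
expressed genes (DEGs) with two derived gene classes (turned-on,
oppositely regulated), exon inclusion/exclusion variants, pathway
enrichment of the six DEG/AS gene lists, and promoter consensus-motif
enrichment.

## Quantification

Reads are accepted only if uniquely mapped with fewer than two
mismatches; mitochondrial reads are excluded by default (`drop_chrM`,
chromosome name configurable) because the annotation carries no
mitochondrial genes and their large read share would otherwise distort
every library-size normalisation.  The post-filter read total per sample
is the RPKM denominator `M_s`.

A read increments exactly one exon per gene — the exon with the largest
base-pair overlap, ties broken toward the smaller start coordinate.  The
annotation is silent on how a read spanning two exons should be
attributed; the largest-overlap rule makes the gene count equal the sum
of its exon counts by construction, an invariant the tests verify
against a per-base brute-force oracle.  A read overlapping exons of two
*different* genes counts once in each (documented behaviour for
overlapping annotations).  Coordinates are 0-based half-open throughout
(BED convention); GTF input is shifted on read.  Unstranded library
chemistry is assumed, so strand is ignored during assignment.

RPKM is exact arithmetic, `count / (L/10^3 × M_s/10^6)`, with `L` the
merged exon-union ("exon model") length at gene level and the exon
length at exon level.  The log view is `log2(1000 × RPKM + 1)`; the
pseudocount of 1 (configurable) maps zero counts to exactly 0, keeping
the transform monotone and anchored.

Two expressed-gene rules are provided because the phrase "detected at
least once for each biological replicate" admits both readings:
`any_replicate` (default: ≥ 2 RPKM in at least one replicate) and
`group_mean`.

## Differential expression

Per gene, a two-sided **equal-variance Student's t-test** on raw
replicate RPKM values (Welch available via `var_equal = FALSE`), with
`df = n1 + n2 − 2`.  Degenerate inputs are fixed by definition: both
groups constant and equal gives `t = 0, p = 1`; zero pooled variance
with unequal means gives `p = 0`.  A gene is tested only when the larger
group mean reaches the 2-RPKM floor (the criterion's "≥ 2 RPKM" is
ambiguous between one group, both, or any replicate; max-of-means is the
middle reading and configurable).  The fold change is
`(m_trt + c)/(m_ctl + c)` with pseudocount `c = 0.25` RPKM — necessary
because turned-on genes have essentially zero control means — and the
threshold lives on the log-1.5 scale (`|log1.5 FC| ≥ 1` ⇔ 1.5-fold).
P-values are raw by default, matching the analysis the pipeline
reproduces; Benjamini–Hochberg adjustment is a flag (`bh_correction`)
for modern use.

**Turned-on genes** are up-called genes whose mean RPKM is below the
floor in *both* sham and exercise (the stricter of the two published
phrasings, and the more biologically meaningful one: silent in every
non-pathological state) and at least the floor under TAC.
**Opposite genes** are called in both contrasts with opposite signs; the
classifier is symmetric in its arguments.

## Exon-variant calling

The splicing unit is the **exon-versus-rest-of-gene** 2×2 table of
replicate-pooled counts.  This construction was open — the source
analysis names only the tests — and was chosen over exon-versus-library
because dividing by the rest of the gene cancels gene-level differential
expression: what remains significant is a change in exon *usage*.
Replicates are pooled because n = 3 per-exon counts are too sparse to
test individually and a single p per exon is the required output; the
cost of pooling is discussed under limitations.

Exons first pass a 10-RPKM filter (mean over replicates, in *either*
condition — one expressed side suffices to detect a switch).  Then:

* **Fisher exact test**, two-sided, `p < 0.05`.  The p-value sums the
  probabilities of all fixed-margin tables no more probable than the
  observed one, with a relative tie tolerance of 1e-7; the
  implementation is enumeration over the support and is tested
  exhaustively against an independent big-`lchoose` oracle for every
  table with total ≤ 60, and spot-checked against `stats::fisher.test`.
* **Posterior sign-error rate** `e ≤ 0.1`.  The exon proportion is
  modelled independently per condition as Beta–Binomial with a uniform
  prior: `θ_ctl ~ Beta(a+1, c+1)`, `θ_trt ~ Beta(b+1, d+1)`, and
  `e = min(P(θ_trt > θ_ctl), P(θ_trt < θ_ctl))` — the posterior
  probability that the apparent direction is wrong.  The cited
  error-rate construction is not spelled out in the source; this
  sign-error formulation is the package's documented interpretation and
  reduces to 0.5 for perfectly symmetric tables.  The default evaluator
  is adaptive quadrature of each tail *separately* over the control
  posterior's supported quantile range (`qbeta` at 1e-14), which keeps
  tiny error rates free of 1−x cancellation and deterministic; a seeded
  Monte-Carlo evaluator (`method = "mc"`) exists for cross-checking.
* **knownAlt restriction**: only exons carrying at least one
  alternative-splicing label are reported, with the label copied to the
  call.  Direction is *inclusion* when the pooled exon proportion is
  higher in TAC/exercise, *exclusion* otherwise; an exactly tied
  proportion (direction undefined, `e = 0.5`) can never pass the filters.

Type summaries let an exon carrying k labels contribute 1/k to each, so
proportions sum to one.

## Enrichment

Pathway enrichment is the one-sided upper hypergeometric tail
`P(X ≥ k)` with `N` the union of all pathway genes (not the whole
annotation — query genes outside the universe are dropped before `M` is
computed), `n` the pathway size, `M` the query size and `k` their
intersection.  A record is significant only when `p < 0.05` *and*
`k ≥ 5`; the ≥ 5 rule is applied per category record (per contrast and
direction), the stricter of the available readings.  Six categories are
built per run: up/down DEGs and exon-variant genes for each contrast.
The heat matrix holds `−log10 p` for significant cells and 0 elsewhere;
pathway group labels (muscle/metabolism, immunity, and so on) are user
annotation, never computed.

Motif enrichment scans 1 kb strand-aware upstream windows (clipped at
contig ends) for user-supplied IUPAC consensus motifs under two strict
occurrence rules: at most one count per upstream regardless of
multiplicity, and no reverse-complement matching.  Matching is exact
(no mismatch allowance is defined for consensus motifs); a sequence `N`
never satisfies a non-N motif letter.  De-novo motif discovery and
motif-database comparison are external-tool territory and out of scope;
the module's Fisher comparison against an explicit background set is the
transparent occurrence test.  The background must be supplied (the
pipeline default is all tested genes minus the foreground) because no
canonical background is defined.

## The synthetic generator

`simulate_experiment()` emulates the *count structure* of the study —
not its sequences.  Per gene and sample the count is negative-binomial
with dispersion 0.1 (`var = μ + 0.1 μ²`), the dispersion magnitude
typical of small cohorts of outbred animals; the gene's reads are then
split multinomially across exons with weights `exon length × inclusion
proportion`.  This hierarchy is the unique model in which (by
Gamma–Poisson thinning) the per-exon marginals are themselves
negative-binomial with the same dispersion, the gene count equals the
sum of its exon counts exactly, and the exon share of a gene stays
binomial given the gene count — so the exon-usage Fisher test is
calibrated (conservative) under the null.  Had exon counts been drawn
independently, the exon/gene ratio would fluctuate far beyond
hypergeometric noise and the null false-positive rate of the splicing
stage would be enormous.

Per-condition expected totals are normalised to the configured library
size (fixed sequencing depth), minus a 5% decoy budget materialised as
non-unique or two-mismatch reads that the alignment filter must remove.
Reads are 36 bp single-end intervals placed uniformly within their exon.
Defaults are desk-scale — 300 genes, 4 × 3 samples, 2e5 reads per sample
— chosen so a full pipeline run takes seconds; all test and script
problem sizes derive from this configuration.

Spiked truth, all recorded in per-gene/per-exon truth tables:

* 27 regular DEG spikes (14 PAH / 13 PHH, half up, half down),
  fold changes log-uniform on [8, 20];
* 2 turned-on genes (near-zero baseline, induced under TAC to the
  abundance of a strong regular gene);
* 1 opposite gene (×30 in one contrast, silenced in the other);
* 30 spiked exons (16 PAH / 14 PHH, half inclusion, half exclusion),
  inclusion proportion shifted ±0.3 from a 0.5 baseline, always on
  labelled exons of ≥3-exon genes that carry no expression spike;
* a spiked pathway composed predominantly of the spiked PAH DEGs, and a
  20-gene motif-planted promoter foreground.

The spike strengths deserve a note.  With three replicates at
dispersion 0.1, the replicate coefficient of variation has a floor of
√0.1 ≈ 0.32, which caps the per-gene power of the pooled t-test at
roughly 0.95–0.98 *regardless of fold change* (a simulation of 30 000
replicate triplets per design point was used to map this before the
defaults were fixed; at 1.5–3-fold the power is only ~0.5–0.77).  The
spiked effects are therefore deliberately strong, unambiguous
positives — recovery checks are meant to detect implementation defects,
not to flatter borderline power — and recovery *rates* are estimated by
pooling replicate simulated experiments, because a single experiment's
30-odd spikes estimate a ~0.95 rate with ±0.04 of Monte-Carlo noise.
Even so, "every spike recovered" is a conjunction of ~0.95–0.98 events
and occasionally fails for a single unlucky replicate draw; that is a
property of the prescribed test under the prescribed noise, not of the
implementation.

Randomness: one user seed drives everything; internal components
(annotation, counts, pathways, motif foreground) derive fixed distinct
sub-seeds from it so that no two components replay the same stream, and
every emission is byte-identical under the same seed.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: sequence content and alignability (reads
are coordinates, not sequences), junction-spanning reads, isoform
structure beyond exon usage, gene-level correlated dispersion beyond the
NB hierarchy, positional read bias, and library-preparation artefacts.

## Numerical choices

* Fisher tie comparison at relative 1e-7; enumeration over the margin
  support, `dhyper` for the probabilities.
* Sign-error quadrature: `integrate` at `rel.tol = 1e-10` per tail on
  the control posterior's [1e-14, 1−1e-14] quantile range; each tail
  integrated directly rather than via complements.
* Stage-boundary matrices are serialised with 17 significant digits so
  the text round-trips IEEE doubles exactly; rerunning any stage from
  cached upstream TSVs reproduces downstream outputs bit for bit.
* Degenerate inputs are decided, not left to NaN: zero-margin Fisher
  tables give p = 1, single-exon genes and zero-count conditions are
  untestable, empty libraries raise an error, and the t-test limits are
  as above.

## Known limitations

* RPKM is compositional: strong concentrated induction (as in the
  pathological contrast) deflates every other gene's RPKM at fixed
  sequencing depth, which inflates apparent down-regulation.  The
  generator reproduces this real artefact; modern size-factor
  normalisation is deliberately out of scope for fidelity to the
  reproduced analysis.
* Raw p-values with no multiple-testing correction (the reproduced
  criterion) — interpret DEG counts, not genome-wide error rates, unless
  `bh_correction` is on.
* Pooling replicates for the splicing tests discards between-replicate
  variability; the Fisher/sign-error cascade is calibrated under the
  within-gene binomial model but would be anti-conservative against
  genuine per-replicate usage dispersion.
* The t-test at n = 3 with overdispersed counts is underpowered for
  fold changes below ~3–4; that is the method being reproduced, not a
  target for improvement here.
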