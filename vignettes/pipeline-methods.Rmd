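---
title: "Methods: post-processing a de novo two-library transcriptome"
author: "diapauseTx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-processing a de novo two-library transcriptome}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diapauseTx)
```

# The problem

De novo transcriptome assemblies of non-model organisms - here, the
oocyte transcriptome of a mosquito whose offspring enter photoperiodic
diapause - arrive with three linked difficulties. First, the assembly
is redundant: many contigs and unassembled singleton reads
(collectively "ESTs") represent fragments, alleles, isoforms or
mis-assemblies of the same underlying gene. Second, expression is
measured by counting reads from exactly one library per condition
(diapause-inducing, DI, versus non-diapause-inducing, NDI), so no
replicate-aware model is identifiable. Third, sequencing-based calls
need verification on an orthogonal platform (qPCR), which requires a
principled way to score agreement.

This package implements the full post-processing chain - read
cleaning, tiered homology annotation, redundancy reduction with
homology-guided trimming, count-based differential expression under
two normalisations, and qPCR verification with concordance statistics
- together with a synthetic-data module that generates every input
with a ground-truth manifest. All benchmark claims in this vignette
are properties the test suite and the acceptance script themselves
compute.

# Read cleaning

Six steps run in a fixed order; the per-step removal tallies are
order-dependent, so the order is part of the contract:

1. remove reads containing any ambiguous base (`N`);
2. remove exact-duplicate sequences (a recognised artifact of
   pyrosequencing), keeping the first occurrence in input order;
3. remove reads with arithmetic mean Phred quality below 25 (a read
   with mean exactly 25 is kept);
4. remove reads with a contaminant homology hit (ribosomal RNA,
   endosymbiont) at e-value at or below `1e-25`;
5. trim terminal poly-A (3') and poly-T (5') runs;
6. remove reads shorter than 50 bp.

Two parameter choices deserve comment. The duplicate criterion is
exact full-sequence identity: it is conservative, deterministic, and
requires no alignment. The poly-A/T rule is our own (published
tail-trimming tools leave the algorithm unspecified): a terminal run
qualifies when it is at least `min_run = 10` bases long, allowing at
most `mismatch_allowance = 1` interior non-matching base, and the run
must begin and end on a matching base. Both knobs are exposed in
`qc_config()`.

A note on the contaminant cutoff direction: a *significant* homology
match has a *small* e-value, so the screen removes reads with hits at
e-value $\le$ the cutoff. Quality control always satisfies
conservation (`remaining + sum(removed) == input`), preserves input
order, and is idempotent - a second pass removes nothing.

# Tiered homology annotation

Annotation walks an ordered table of reference databases
(`default_tiers()`): conspecific mRNA first, then the close reference
genome's transcripts, genome and peptides, then increasingly distant
insect proteomes, and finally a general protein database. E-value
cutoffs loosen with taxonomic distance (`1e-10` down to `1e-3`).

Within a tier, the best hit is the one with the smallest e-value;
ties are broken by the largest bitscore, and residual ties by subject
id, so the outcome is permutation-invariant. Across tiers we use a
**first-qualifying-tier** rule: an EST is assigned in the
highest-priority tier where it has any hit passing that tier's
cutoff. The alternative - a single global best e-value across all
databases - was rejected because e-values from nucleotide and
translated searches against databases of very different sizes are not
comparable; the cascade keeps the taxonomic stratification
well-defined and deterministic. ESTs qualifying nowhere form the
"no hit" class.

The sequencing-depth diagnostic is a bootstrapped gene-accumulation
curve: the per-read homology outcomes are randomly re-ordered
(default 1,000 permutations) and the cumulative number of distinct
genes at each read rank is averaged. The curve is monotone and its
endpoint always equals the number of distinct genes hit, which the
tests verify across seeds.

# Redundancy reduction and trimming

ESTs assigned to the same reference gene form a group; the pipeline's
central guarantee is **at most one trimmed EST per gene**, each an
exact contiguous substring of its source contig.

Representative selection trades alignment length against percent
identity. For tiers with a positive identity cutoff (85% for the
conspecific and close-reference nucleotide tiers, 70% for the close
reference's peptides): among members at or above the cutoff, take the
longest alignment; if none qualifies, fall back to the highest
identity. For the remaining tiers the cutoff is 0 and selection is by
identity alone, subject to a 50 bp minimum alignment length. The
residual tie-breaks (higher identity, then lexicographic EST id) are
our own - some rule is needed for determinism, and tests compare the
implementation against an exhaustive re-evaluation of the rule on
random groups.

Hits against the genomic tier are used only when the majority
(strictly more than 50%) of the EST's aligned genomic span overlaps
annotated mRNA intervals. The denominator is the aligned span, not
the whole EST, because unaligned tails have no genomic placement;
overlap is computed on the interval union, so overlapping mRNA
annotations are not double-counted. Exactly 50% fails.

The winner is trimmed to the query start/stop coordinates of its
alignment (1-based inclusive). Translated searches can report
reversed query coordinates; we normalise by min/max and keep the
forward strand, since the product is a nucleotide EST resource. The
50 bp floor applies to the *trimmed* product - the stricter of the
two possible readings - and groups whose winner trims below it are
dropped with a logged reason.

# Differential expression

Reads are first mapped to the trimmed ESTs (externally); the mapping
filter keeps alignment rows at $\ge$ 95% identity and then discards
any read that still maps to more than one EST or location. Counts are
tallied per EST and library.

Two normalisation paths feed the same significance machinery:

* **TMM** (trimmed mean of M values), implemented from first
  principles. The reference library is the one whose upper quartile
  of count proportions is closest to the mean upper quartile. For
  each other library, per-gene log ratios $M_g$ and mean log
  abundances $A_g$ are computed on count proportions; genes with a
  zero in either library are excluded; the $M_g$ are trimmed 30% on
  each side and the $A_g$ 5% on each side; the normalisation factor
  is $2^{f}$ with $f$ the precision-weighted mean of the surviving
  $M_g$ (weights = inverse delta-method variances
  $\frac{N-y}{Ny}$ summed over the two libraries); factors are
  rescaled to multiply to 1. Effective library size = raw size
  $\times$ factor. The test suite checks this implementation against
  an independent reference implementation on random matrices.
* **RPKM**: $\mathrm{RPKM}_{g,\ell} = 10^9 \, y_{g\ell} / (L_g
  N_\ell)$ with $L_g$ the trimmed EST length. Because the magnitude
  of an exact-test statistic depends on the totals, the RPKM matrix
  is rescaled by one global constant so its grand sum equals the
  original both-library read total (conservation is exact to
  floating-point), and rounded to integers before testing - the
  binomial test needs integer outcomes, and rounding is the least
  intrusive discretisation.

Significance uses an exact binomial test conditioned on each gene's
total: under the null, the DI count is binomial with success
probability $N_{DI}/(N_{DI}+N_{NDI})$ set by the *effective* library
sizes. The two-sided p-value follows the minimum-likelihood
convention - the sum of all point probabilities not exceeding the
observed one - which matches the classical tag-count test this field
uses; the doubling-the-smaller-tail convention gives different values
and is not used. P-values receive Benjamini-Hochberg adjustment
(delegated to `stats::p.adjust`), and genes with adjusted p below
$\alpha = 0.001$ are called DI-up or NDI-up by the sign of

$$M = \log_2\frac{y_{DI} + 0.1}{N_{DI}} - \log_2\frac{y_{NDI} + 0.1}{N_{NDI}}.$$

The pseudocount 0.1 exists solely so genes observed in only one
library keep a finite fold-change; it never enters the significance
test. The MA-plot abundance axis is the mean of the two log2
normalised abundances (computed with the same pseudocount); the
choice is documented because other conventions exist.

# qPCR verification and concordance

Relative quantification: technical replicates are averaged
arithmetically per biological replicate; the geometric mean of the
three reference-gene Cts (taken over the Ct values themselves, not
over transformed abundances) is subtracted from the target Ct; the
difference maps to relative abundance $2^{-\Delta C_t}$. Fold-change
is the log2 ratio of treatment means of these abundances. Group
differences use a pooled-variance two-sample t-test (the classical
"Student" form; a Welch switch would be a one-line change and is
deliberately not the default), BH-adjusted across the panel.
Replicate variability is compared between treatments by a paired
t-test on per-gene coefficients of variation; CV uses the $n-1$
sample standard deviation.

Concordance scores the sequencing calls against qPCR: a true positive
is a sequencing-DE gene that qPCR finds significant in the same
direction; a sequencing-DE gene that qPCR finds non-significant or
oppositely significant is a false positive; true negatives are
non-significant on both platforms; false negatives are
sequencing-negative genes that qPCR finds significant. Sensitivity
and specificity use the standard epidemiological forms
$\mathrm{TPR} = TP/(TP+FN)$ and $\mathrm{TNR} = TN/(TN+FP)$.
Directional consistency is reported separately: the fraction of each
predicted category whose qPCR mean fold-change has the predicted
sign, regardless of significance.

# The synthetic-data module

The generators produce every input with a manifest, and their
defaults are the study conditions of the test suite:

* **Reference**: random gene sequences (lognormal lengths, floored at
  100 bp) tiled as mRNA features along a synthetic scaffold; a chosen
  number of genes receive a true log2 fold-change of alternating
  sign.
* **Contigs**: each gene spawns $1 + \mathrm{NB}(\mu, k)$ ESTs
  (default mean 8.86 per gene, matching the redundancy scale of a
  real pyrosequencing assembly; the distribution family is a
  parameter because only summary statistics of real redundancy are
  available), with ragged ends, optional non-homologous junk tails,
  and per-base substitution errors. Homology hit rows are
  *constructed* from the known provenance - the pipeline consumes
  tabular hits, so running an aligner would add nothing testable. The
  e-value is a deterministic decreasing function of alignment length
  times identity, floored at `1e-180`; bitscore is monotone in the
  same product. No-hit and chimeric contigs exercise the failure
  classes.
* **Counts**: negative-binomial draws with means proportional to gene
  length x expression x library size; Poisson at dispersion 0, which
  is the default. The exact binomial test models within-library read
  sampling, and with one library per condition biological
  overdispersion is unidentifiable, so the benchmark conditions use
  pure sampling noise; raising the dispersion demonstrates the test's
  anticonservatism under overdispersion. Genes designated
  library-unique are guaranteed a zero in exactly one library (all
  other genes are floored at one read so the designation is exact).
* **QC reads**: clean reads are gene substrings with high qualities;
  defects (ambiguous bases, duplicates, low quality, contaminants,
  poly-A/T tails, sub-50 bp) are injected mutually exclusively at the
  requested rates, so each injected defect is removed by exactly one
  filter and the QC tallies can be checked against the manifest.
* **qPCR**: three reference genes with treatment-independent expected
  Ct; target Ct = reference level $-$ log2(true abundance) + Gaussian
  noise, so the quantification round-trips exactly at zero noise.

What the generators do **not** emulate: flowgram chemistry and
homopolymer error structure, the assembly step itself (contigs are
inputs), real contaminant genomes (contaminants are labelled random
sequences), amplification-efficiency variation in qPCR, and - by
default - biological replicate variance in the count model. Passing
tests therefore demonstrate the correctness and calibration of the
*computational* pipeline under its own model assumptions, not the
biological error structure of a wet-lab dataset.

# Problem sizes and reproducibility

Every generator takes an integer seed and is byte-deterministic given
it. The test suite runs the DE benchmark at 2,000 genes with 20 true
DE genes at $|\log_2 FC| = 2$, base mean count 50 and a 10%
library-size skew, and requires recall $\ge$ 0.8 with false-discovery
proportion $\le$ 0.1 on both normalisation paths; the bundled
"paper-like" fixture uses 400 genes, mean redundancy 8.86 and 4,000
reads so the full workflow completes in seconds. These sizes are the
package's own benchmark choices; the machinery is linear in genes and
reads and runs unchanged at larger scales.

# Known limitations

* With one library per condition the significance machinery measures
  sampling evidence only; it cannot distinguish biological from
  technical effects, which is precisely why the qPCR verification
  stage and its concordance statistics exist.
* The redundancy reducer keeps one representative per gene and so
  discards legitimate isoform and allelic variation by design.
* The genomic-overlap rule evaluates the aligned span only; an EST
  whose alignment is split across distant loci is handled as two hits
  by the upstream search, not merged.
* The accumulation curve treats each read's best hit as fixed; it
  measures sampling saturation, not annotation uncertainty.
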