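---
title: "Methods: regulatory prioritization of noncoding risk variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory prioritization of noncoding risk variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdprio)
```

# The problem and the model

Genome-wide association studies of age-related macular degeneration (AMD)
implicate dozens of loci, but the association signal at a locus is carried
by a block of correlated variants, almost all noncoding. `amdprio`
formalizes a multi-evidence prioritization: a variant is a credible
regulatory candidate when it is accessible in disease-relevant chromatin
(RPE/choroid cell types) *and* several independent lines of evidence link
it to gene regulation. The pipeline's stages, their statistics, and the
fixed thresholds are described below; every threshold is a named key of
`default_config()` and can be overridden explicitly.

## Coordinates

All intervals are 0-based half-open `[start, end)`; a variant position `p`
is inside `[s, e)` iff `s <= p < e`. Readers for 1-based sources convert
at the boundary; chromosome names are compared as exact strings with no
"chr" normalization. Interval overlap and merging are delegated to
IRanges behind this convention.

## Catalog construction

LD expansion retains every variant whose squared Pearson correlation of
dosages with at least one index variant strictly exceeds 0.5, annotated
with its maximal R² and that index's locus. Index variants are included by
rule (R² = 1 to self), which sidesteps the ambiguity of a strict
inequality at 1.0. Index variants absent from the reference panel are
substituted through a caller-supplied table; the package does not
recompute GWAS posterior probabilities, so the choice of substitute stays
with the caller. The union with a credible set is keyed on
(chrom, pos, ref, alt) with the expanded list winning collisions.

Consequence classification maps raw annotation labels onto
{protein-altering, synonymous, noncoding}. Splice-altering labels are
routed to protein-altering — they change the protein product even though
the substitution is not in codon space; this is a judgment call, flagged
here because a "noncoding or synonymous" funnel treats splice variants as
coding. Unknown labels raise an error rather than defaulting to
noncoding. AlphaMissense scores bin at the published strict boundaries
(< 0.34 likely benign, > 0.565 likely pathogenic, ambiguous between).
Printed percentages round halves away from zero to one decimal, matching
the convention of the reported figures.

## Accessibility and enrichment

Cell QC keeps a cell iff all five bounds hold: 200–10,000 RNA transcripts
(inclusive), < 1% mitochondrial, < 5% ribosomal, TSS enrichment > 4,
> 1,000 ATAC fragments. Promoters are 2,000 bp upstream to 100 bp
downstream of the TSS in transcription orientation. Variant accessibility
uses the variant's single reference position (point intersection), not
the ref-allele span — the catalog is SNP-dominated, and indel spans would
need an explicit convention; this is documented rather than hidden.
Enrichment divides accessible-variant counts by the unique bases of the
tissue's merged peak set and normalizes to the mean rate over baseline
tissues, which makes the statistic invariant to splitting a peak into
abutting pieces.

The generic group comparison behind marker/differential feature calling
is a Wilcoxon rank-sum test (mid-ranks, normal approximation, continuity
correction — deterministic under ties), BH-adjusted, gated by a log2 fold
change of group means with pseudocount 1. The pseudocount makes zero-mean
groups well-defined; whether the reference analysis pseudocounted its
means is not stated, so this choice is documented, configurable, and not
claimed to match. The "expressing fraction" gate for marker genes counts
samples with nonzero signal.

## Enhancer connectome

Co-accessibility and peak–gene links use Pearson correlation of
untransformed pseudo-bulk signal with a *signed* cutoff of 0.3 —
anti-correlated pairs never pass. Whether the reference cutoffs were
signed or absolute is not stated; signed is the default here because a
"correlation cutoff" most naturally reads as a one-sided bound, and an
absolute-value variant is a one-line change at the call site. The
co-accessibility window defaults to 250 kb (the linking tool's default;
only the cutoff and resolution are stated upstream).

Loop linking requires the variant (or peak) in one anchor and the gene's
promoter in the *other* anchor of the same loop; a variant and promoter
inside a single anchor are not linked, since the loop is then not the
evidence connecting them. Anchor overlap is any shared base.

ABC scores use activity `A_e = sqrt(ATAC_e * H3K27ac_e)` (the geometric
mean of the two signals over the element), contact `C_eg` read from the
binned map at the element-midpoint and TSS bins (diagonal entry for
same-bin pairs; a power-law fit to the map's own distance decay for bins
outside the stored range), and per-gene normalization over the gene's
candidate elements, so unthresholded scores sum to exactly 1 per gene —
a conservation property the tests assert to 1e-12. Connections are
reported above score 0.025 with the element at least 500 bp from the TSS.
Strategy-overlap fractions use the smaller set as denominator; the
reported overlap range upstream does not define its denominator, so this
choice is explicit and configurable.

## Allele-specific STARR-seq

Amplicon reads are `insert + adapter + barcode`; parsing requires the
exact adapter, a trailing barcode of exactly 10 nt, and an exact-match
insert lookup (no barcode error correction — none is specified upstream,
and at 10 nt the collision risk from correction would be hard to audit).
Unique barcodes per oligo per sample are the analysis unit; PCR
duplicates collapse. QC keeps an oligo iff it has ≥ 5 unique barcodes in
*every* replicate, and a SNP only if both allele oligos survive —
otherwise allelic ratios would be undefined for one arm.

Normalization is median-of-ratios against per-oligo geometric means (the
standard count-model normalization, re-implemented; the even-`n` median
here is the arithmetic midpoint of the two central ratios). Enhancer
calling combines ref+alt counts per SNP and tests replicate-wise
log2(normalized output / mean normalized input) against zero with a
moderated one-sample t-test: residual variances are shrunk toward a
pooled prior via the standard empirical-Bayes moment-matching scheme
(limma's `squeezeVar`), which stabilizes 4-replicate variances. This is a
deliberate substitution for a negative-binomial Wald test: it is
deterministic, matches the effect-size/threshold semantics of the
original analysis, and behaves well at the barcode depths simulated here.
The enhancer definition is two-sided (|log2FC| > log2 1.5 = 0.585) with
output-depleted oligos flagged separately, since the stated definition
uses an absolute fold change while the surrounding narrative describes
output enrichment; `direction = "up"` selects enrichment-only.

Allelic activity is paired by replicate: within an output replicate the
alt/ref ratio cancels the size factor, so the moderated one-sample t is
applied to the per-replicate log-ratios directly. Swapping allele labels
negates estimates exactly. Functional SNPs require the strict conjunction:
in an enhancer, adjusted p < 0.05, and |log2FC| strictly exceeding the
80th percentile of control-SNP |log2FC| (percentile by linear
interpolation with zero-based index `h = q(n-1)`, i.e. R's type-7
quantile — pinned for reproducibility). However many control SNPs survive
QC is however many the threshold uses.

## Predicted variant effects

For each variant and cell type, the log2 fold change of predicted
alt/ref counts is averaged over model folds. The one-sided Poisson test
sets the rate to the fold-averaged reference count and takes the tail in
the direction of the observed change (upper for gains, lower for losses);
the upstream description says "one-sided" without fixing the direction,
and a direction-adaptive tail is the only choice consistent with calling
effects on |log2FC|. Predicted counts are continuous, so the default
rounds to the nearest integer for the tail sum; a continuous variant via
the regularized incomplete gamma is available (`method = "continuous"`).
P-values combine across cell types by Fisher's method (zero p-values
clipped at 1e-300 with a warning) and are BH-corrected across all scored
variants. High effect iff |log2FC| > 0.25 and FDR < 0.01, both strict.

## Integration

The criteria matrix is built over variants accessible in RPE/choroid cell
types. Criteria 1, 2 and 4 are inherited from the variant's containing
peak(s) (union over peaks when a variant sits in two); criterion 3 is
evaluated at the variant position against loop anchors with the partner
anchor required to overlap a gene promoter; criteria 5–8 are direct set
membership. eQTL significance is FDR ≤ 0.05 (inclusive) in either the
macular or non-macular tissue region. Prioritization is `n_criteria >= 3`
(inclusive). Locus reports rank candidates by criteria met, breaking ties
by |allelic log2FC| then rsid, so reports are deterministic; a locus
whose only prioritized candidate is a non-index variant with all index
variants inaccessible is flagged as the "index inaccessible, alternative
candidate" pattern.

# What the synthetic data emulates

The generators are pure functions of their arguments including the seed,
and every planted object is recorded in a truth ledger.

- **Genotypes**: LD blocks built by copying a latent index haplotype and
  flipping alleles at rate `f = (1 - sqrt(r2))/2`, which gives closed-form
  control of the expected dosage R² at allele frequency 0.5. Blocks are
  independent; realized within-block R² is within sampling error of the
  target by a few hundred individuals.
- **Atlas**: peak accessibility and gene expression as affine images of
  Gaussian latents on a positive baseline (`10 + 2z`, clipped at zero with
  negligible probability), so a planted link's generating Pearson
  correlation is exactly `link_corr`; each linked gene also gets a peak
  inside its promoter window carrying the gene's own latent, making
  promoter co-accessibility recoverable. Planted links are placed within
  250 kb of the TSS or generation errors out.
- **Contacts**: off-diagonal background `d^-gamma` in bin distance with a
  fixed diagonal, planted loops as multiplicative focal enrichment of
  their anchor-bin pair; symmetric by construction.
- **STARR-seq**: negative-binomial barcode counts with variance
  `mu + dispersion * mu^2` (Poisson at dispersion 0), oligo-specific
  log-normal abundances, planted enhancer activity `2^1.5` by default,
  and allelic effects split symmetrically between alleles so the planted
  log2(alt/ref) is exact in expectation. Input depth ~3,000 and output
  depth ~300 barcodes per oligo mirror the scale of the assay this
  emulates; replicate-to-replicate correlations of ~0.97–0.99 in such
  assays imply low overdispersion, so module-level recovery checks use
  dispersion 0.01 while pipeline-level checks use a more conservative
  0.05.
- **Predicted counts**: base counts uniform in [200, 2000] with small
  log-normal fold jitter (sd 0.03) and planted |log2FC| = 1 effects in at
  least one cell type.
- **Integration scenario** (`sim_integration`): plants a boolean
  criterion profile per variant and *constructs* the upstream link
  tables, loops and sets to realize it, with variants ≥ 20 kb apart in
  disjoint peaks so recovery by `build_criteria_matrix` is exact by
  construction. This tests the integration bookkeeping, not the
  statistical stages — those are tested on their own noisy generators.

What passing on synthetic data does **not** show: real scATAC/RNA counts
are sparse, overdispersed and compositional rather than Gaussian; real LD
has MAF structure and recombination hotspots; real contact maps have
domain structure beyond a single power law; real STARR libraries have
sequence-dependent abundance biases. Threshold behavior, bookkeeping,
calibration under the stated noise models, and parameter recovery at
realistic depths are what the suite establishes.

# Numerical choices and degenerate inputs

- Percentile convention: R type-7 (`h = q(n-1)`), pinned.
- Pseudocount 1 on count ratios; size factors from all-positive rows only
  (error if none exists).
- Constant profiles cannot be correlated: co-accessibility skips them
  with a warning; R² on a constant dosage vector is an error.
- Zero p-values entering Fisher's method clip at 1e-300 with a warning.
- Genes whose ABC denominator is zero are skipped with a warning rather
  than emitting NaN scores.
- All tie-breaks (locus ranking) are deterministic.

# Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in well under a minute of compute per stage: STARR
recovery at 1,000 test + 350 control SNPs with 4 replicates; variant-effect
recovery at 300 variants x 3 cell types x 5 folds; null calibration over
50 seeds; oracle equivalence on instances of a few hundred elements; the
end-to-end pipeline at 200 integration variants. These sizes are stated
here as the package's own choices; the statistics they exercise do not
change with scale.

# Known limitations

- Real-data formats stop at plain text (BED/BEDPE/TSV/dense matrices);
  bigWig/HDF5/10x inputs are out of scope.
- Pseudo-bulk grouping is taken as given; peak calling, clustering and
  loop calling belong to upstream tools.
- The eight criteria are combined by unweighted counting, as in the
  analysis this package operationalizes; no attempt is made to weight
  evidence types or model their correlation.
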