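---
title: "Methods: four-layer cell line vs tumor comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-layer cell line vs tumor comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoportrait)
```

Cancer cell lines are the workhorse models of tumor biology, but a line
cultured for decades need not resemble the tumors it is meant to stand in
for. `oncoportrait` quantifies that resemblance for breast cancer on four
molecular layers — mRNA expression, DNA copy number, somatic mutation and
(phospho-)protein abundance — and combines the four layer similarities into
one suitability score per cell line. This vignette describes the models and
conventions behind each stage, the tunable parameters and their defaults,
what the synthetic cohort generator does and does not emulate, and the
design choices made where more than one reasonable convention exists.

## Subtype assignment

Breast tumors are conventionally stratified by the hormone receptors ER and
PR and the growth-factor receptor HER2. The marker rule implemented by
`classify_ihc()` is:

| ER/PR | HER2 | label |
|---|---|---|
| ER or PR positive | negative | Luminal A |
| ER or PR positive | positive | Luminal B |
| both negative | positive | HER2-amplified |
| both negative | negative | Basal-like |

Real annotation tables have missing markers, and a naive rule would either
guess or drop those samples. `classify_ihc()` instead evaluates *every*
completion of the unknown markers and returns a label only when all
completions agree (an ER+/HER2− sample with unknown PR is Luminal A
regardless of PR; an ER-unknown triple cannot distinguish Luminal A from
Basal-like and abstains). This makes the classifier total and deterministic,
and the property is exhaustively checkable over the 27 possible status
triples — the test suite does exactly that.

Samples whose markers do not resolve fall back to nearest-centroid
expression prediction (`classify_centroid()`): Pearson correlation against
each column of a user-supplied centroid matrix over the shared genes, the
best-correlated label winning. Centroid estimation itself is out of scope —
centroids are an input, typically an intrinsic-subtype signature. A centroid
labelled normal-like maps to the no-call label, since normal-like calls are
excluded from subtype comparisons by convention. Ties in the correlation
contest are broken by a fixed label order (Luminal A, Luminal B, HER2amp,
Basal-like) so calls never depend on column order.

`concordance()` compares two call vectors and reports the matching fraction
after dropping pairs without a call in a designated list. Applied to the
packaged 68-line annotation table (`table3_cell_lines()`, encoded exactly as
published including its internally inconsistent rows), comparing the
expression-based calls against the final classification over the 56 lines
with an expression call yields 34/56 = 60.71 %. The fixture reproduces the
published table, not the rules — re-deriving marker labels from the marker
columns would change several rows, which is precisely why the table is
packaged verbatim.

## Expression and protein similarity

All similarity layers use Pearson correlation: the data are log-scale
intensities where linear association is the conventional measure, and the
same statistic is used on every layer so the components of the final score
are commensurable. A rank-correlation option exists in
`pairwise_correlation()` but is off by default. Missing entries are handled
pairwise-complete with a minimum of three shared observations per pair —
the weakest assumption that keeps a correlation defined — and pairs below
the minimum are reported missing rather than guessed.

`aggregate_by_cell()` collapses a (cell, tumor) correlation table to one
mean per cell line. Two variants exist because both appear in practice:
averaging over all tumors (the default; used for the combined score) and
averaging only over tumors sharing the cell line's subtype (for
subtype-resolved questions). Cell lines with no usable pair get a missing
mean, never zero.

`mrna_protein_correlation()` relates the two expression layers: a gene may
be probed by several mRNA probe sets and detected as several (phospho-)
protein forms, so the mapping is an explicit (gene, probe, protein-form)
table, each pair is correlated across shared samples, and pair correlations
are averaged per gene.

## Copy-number layer

Copy number arrives as segmented profiles (SEG: 1-based inclusive intervals
with a log2(CN/2) segment mean). Two summaries are computed:

**Fraction of genome altered.** Per sample,
$\mathrm{FGA} = \sum_{|CN_i| > T} L(i) \,/\, \sum L(i)$ with
$L(i) = \mathrm{end} - \mathrm{start} + 1$: the fraction of segmented length
carried by segments whose absolute mean exceeds the threshold. Defaults are
$T = 0.2$ for tumors and $T = 0.3$ for cell lines — cell-line profiles are
systematically more aberrant and noisier, so their cutoff is stricter. The
comparison is strictly greater-than. FGA is monotone non-increasing in $T$
and bounded in $[0,1]$; both properties are tested, and the whole statistic
is pinned against a per-base brute-force oracle on hundreds of random
segment sets.

**Gene-level profiles.** `map_segments_to_genes()` assigns each gene the
overlap-length-weighted mean of the segment means covering it, which is
identical to averaging the per-base segment value across the gene body (the
per-base oracle enforces this equivalence in tests). Genes with no
overlapping segment are missing. Discrete calls use the conventional
$\pm 0.3$ cutoffs (`call_cnv()`).

Because most of the genome is diploid in most samples, correlating full
gene-level profiles would mostly compare flat noise. `cnv_similarity()`
therefore restricts to the most variable genes — by default the top 10 % by
variance with cohorts pooled, so cell lines and tumors see a single shared
gene set. Variance ranking (rather than amplitude) was chosen because it
maximises cross-cohort discriminative signal; the fraction and an explicit
gene-count override are both exposed since the right universe size is
dataset-dependent.

## Mutation layer

`filter_somatic_functional()` keeps records that are flagged somatic, carry
a protein-affecting classification (missense, nonsense, nonstop, splice
site, frameshift and in-frame indels, translation start), and do not sit at
a known germline polymorphism site. Germline removal is file-driven — an
explicit site blacklist — rather than a live database lookup, which keeps
the pipeline deterministic and network-free with the same contract. The
keep-set is a visible, configurable argument because annotation pipelines
disagree at the margins.

Downstream summaries:

- `binarize_mutations()` encodes presence/absence per gene per sample (an
  indicator, not a count); `mutation_frequency()` is its row mean.
- `mutation_rate_per_mb()` divides the filtered record count by the
  sample's merged coverage footprint (BED, 0-based half-open, so bases =
  end − start); merging first means duplicated coverage listings can never
  deflate the rate.
- `mutation_spectrum()` collapses single-base substitutions onto six
  strand-symmetric categories by reverse-complementing any G/T-reference
  record; proportions are pooled counts over all records (not per-sample
  means — pooling is the natural estimator when per-sample counts are
  small). Indels are retained in the table but excluded from spectra.
- `context_profile()` tallies base composition at the ±2 bp flanks, with
  contexts reverse-complemented alongside their records so the profile
  inherits the spectrum's exact strand symmetry.
- `mutation_similarity()` correlates binary columns — for 0/1 vectors the
  Pearson coefficient equals the phi coefficient of the 2×2 table, and the
  tests assert that identity against a closed-form contingency oracle.
  Constant columns (no mutated panel gene, or all mutated) yield a missing
  value; whether to drop all-zero genes beforehand is left to the caller,
  since the defensible default is to keep the declared panel.

## Protein clustering

`hierarchical_cluster()` performs agglomerative clustering of samples, by
default under 1 − Pearson distance with average linkage — the usual choices
when profile shape rather than absolute level should drive the grouping.
These defaults are recorded and exposed, not claimed to reproduce any
particular published dendrogram, since visualisation tools rarely document
their parameters. `stats::hclust` supplies the agglomeration; merge
tie-breaking therefore follows its deterministic internal order, which keeps
runs reproducible (the original motivation for specifying a tie rule at
all). A constant sample under correlation distance is an error naming the
sample rather than a silent NaN. `cut_clusters()` returns the k-cluster
partition; dendrograms export to Newick with branch lengths equal to height
differences.

## The suitability score

For each cell line the four layer means A (expression), B (copy number),
C (mutation), D (protein) combine as the plain sum

$$\mathrm{Score} = A + B + C + D,$$

unweighted and unstandardised. The components live on different effective
scales — expression correlations run much higher than binary mutation
correlations — and summing raw values preserves that imbalance; this is
deliberate, matching the score's published form, and an optional z-scoring
of each component across cell lines exists but is off by default. Under the
default `require_all` policy a cell line missing any layer is unranked
(scores are only comparable when built from the same four components);
`available_mean` rescales the mean of the present components to the
four-component range for exploratory use. Ranking is descending with
lexicographic tie-breaks, so it is a deterministic function of the component
table — the tests permute input order and require bit-identical output.

## The synthetic cohort generator

`simulate_cohort()` produces a matched cohort with known truth so that every
stage, and the end-to-end score, can be validated without external data.
One seed fully determines the output; internally every (section, sample)
pair draws from its own derived seed, so enlarging one cohort arm leaves
every other sample bit-identical — a property the tests assert directly.

What it emulates, per layer:

- **Expression.** Each subtype has a centroid: a shared baseline
  (N(8, 1) log-intensities) with that subtype's 10 marker genes elevated by
  the separation parameter (default 5 expression units = 5 noise SDs).
  Samples are centroid + iid N(0, 1) noise. This gives nearest-centroid
  classification a realistic signal-to-noise regime: accuracy is essentially
  perfect at the default separation and degrades gracefully as it shrinks.
- **Copy number.** Each sample's genome (22 autosomes, lengths proportional
  to the human karyotype) is cut at uniform breakpoints into ~120 segments.
  Recurrent arm-level gains on chromosomes 1 and 8 and losses on 13 and 16
  are modelled as clonal — present in every sample (the probability is a
  parameter) with per-segment magnitudes drawn from U(0.3, 1.2), so the
  event is universal but its regional profile varies per sample. A 10 %
  per-segment focal-alteration background (magnitude U(0.4, 1.0), gain/loss
  sign following the designated chromosomes, random elsewhere) sits on
  N(0, 0.05) baseline jitter. With arm events disabled, the expected FGA
  equals the focal alteration probability exactly, which is how the
  generator/analyzer FGA closure is tested.
- **Mutation.** Functional somatic counts are Poisson with mean rate ×
  covered Mb (default 2 per Mb over a 30 Mb exome-like footprint);
  categories follow the spectrum weights (default C>T-dominated,
  (0.05, 0.15, 0.05, 0.10, 0.20, 0.45)); half the records are emitted on the
  opposite strand with consistent 5-base contexts, so the analyzer's strand
  collapse is genuinely exercised. A 30 % silent and 15 % germline decoy
  load is generated on top — these must be removed by the somatic-functional
  filter for the rate closure to hold, so the closure test also validates
  the filter. Each subtype has six enriched driver genes in the 60-gene
  panel (30 % of mutations hit a driver), giving the binary layer its
  subtype structure.
- **Protein.** Fifty proteins map 1:1 to genes — half signature, half
  background, as antibody panels mix markers and housekeeping targets.
  Protein = mRNA + per-gene Gaussian noise whose SD is calibrated within
  each cohort so the expected mRNA–protein Pearson correlation equals the
  coupling target (default 0.7). The affine form preserves the shared
  abundance baseline, which is what keeps protein profiles of unrelated
  samples positively correlated, as real RPPA data are. A coupling target of
  1 is rejected as infeasible under measurement noise.
- **Cell lines** differ from tumors systematically, not occasionally:
  expression noise ×2.5, a continuous N(0, 0.4) perturbation of every
  segment mean plus a 15 % extra focal-event rate, protein noise ×1.5, and
  mutation rate ×1.5. Culture adaptation affects every line, and modelling
  it as ever-present noise (rather than rare discrete events) gives
  planted-recovery analyses a well-defined signal: a cell line cloned from
  a tumor (`clone_cell = TRUE`) is expected to out-score every cultured
  line on the combined score, and does so stably across seeds.
- **Annotations.** Markers are consistent with the planted subtype; 25 % of
  samples have all markers withheld, exercising the centroid fallback.

What it does **not** emulate: linkage and haplotype structure, subclonal
evolution, batch effects, probe-level measurement artefacts, or realistic
gene lengths and spacing. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline's estimators recover the structure they are
pointed at; they do not certify performance on any particular real dataset.

## Numerical choices and degenerate inputs

- Coordinates: SEG and MAF are 1-based inclusive (length = end − start + 1);
  BED coverage is 0-based half-open (bases = end − start). Chromosome labels
  are normalised on entry ("chr" stripped, X/Y upper-cased); mitochondrial
  records are dropped by default. Whether sex chromosomes enter FGA is up to
  the input — the generator uses autosomes only.
- Missing values are first-class everywhere: empty matrix cells parse as
  missing, never zero; correlations below the observation minimum are
  missing; aggregation means exclude missing pairs and return missing (not
  zero) when nothing remains.
- Empty segment sets, indel-only spectra, constant spectra, zero covered
  bases, and out-of-range cluster counts are errors, not silent NAs.
- Writers emit full-precision numbers, so every reader/writer pair is an
  exact round trip; the file-driven pipeline is byte-reproducible and a run
  manifest (inputs, parameters, package version) is written alongside the
  outputs.

## Problem sizes used in the checks

The packaged checks run at desk scale, chosen to make sampling error small
relative to the tolerances they assert: oracle comparisons use hundreds of
random instances of ≤ 10 segments and ≤ 5 genes; closure checks simulate
200 tumors and compare each estimator to its configured value within three
standard errors; planted-recovery checks run 20 independent cohorts of 160
tumors and 32 cell lines (40 and 8 per subtype) and require mean subtype
accuracy ≥ 0.95 and the planted clone at rank 1 in every run.

## Known limitations

- The score inherits the scale imbalance of its components; rankings are
  dominated by the layers with the widest correlation range (expression and
  copy number). The optional z-scoring addresses this at the cost of
  departing from the score's published form.
- Nearest-centroid prediction is only as good as the supplied centroids;
  no calibration or confidence thresholding is applied to the winning
  correlation.
- The phi coefficient on sparse binary panels is noisy; with small panels
  the mutation component contributes little discrimination, which mirrors
  its behaviour on real gene panels.
- Subtype-matched aggregation and the clustering defaults are conventions,
  exposed as parameters rather than claims about any particular dataset.
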