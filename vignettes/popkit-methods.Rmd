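---
title: "popkit methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popkit methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popkit implements the analysis chain used to build and evaluate harmonized
multi-population genotype resources. This vignette records the models, the
parameter conventions, and the choices made where the design was genuinely
open, so results are interpretable and reproducible.

## The data model

A `genotype_dataset` is a variants-by-samples matrix of alternate-allele
dosages in {0, 1, 2, NA} with variant and sample metadata. Conventions,
fixed once and used everywhere:

* Coordinates are 1-based and fully closed, exactly as in VCF; no internal
  conversion ever happens.
* `NA` is the missing-genotype sentinel. A missing genotype contributes to
  neither AC nor AN; AC/AN are recomputed from the matrix after every
  mutating operation, so stored counts always equal a brute-force recount
  (this is asserted property-style in the tests).
* Multi-allelic records are split into one record per alternate allele,
  with genotypes recoded as copies of that alternate; the variant key is
  the exact string `contig:pos:ref:alt` after splitting. No left-alignment
  or trimming normalization is applied — comparisons match on the literal
  post-split key, and inputs must share a genome build.
* Sex chromosomes are rejected at import: every downstream statistic here
  assumes diploid autosomal genotypes, and silently mixing ploidies is the
  kind of error that should fail loudly. Star and symbolic alleles are
  dropped with a logged count.
* Which FILTER strings count as "pass" is dataset-specific, so filtering on
  FILTER is left to the caller; the `filters` column is carried through
  untouched.

## The simulator: what it emulates, and what it does not

`simulate_genotypes()` draws, per variant, an ancestral frequency
p ~ Uniform(`ancestral_freq_range`, default (0.05, 0.5)) and per population
a frequency from the Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F), so
population frequencies have mean p and variance F·p(1−p). This model was
chosen over coalescent simulation deliberately: it gives closed-form truth
for the quantities the pipeline estimates — pairwise F_ST between two
populations simulated at a common F converges to F, founder kinship to 0,
parent–offspring to 0.25, duplicates to exactly 0.5 — so parameter-recovery
tests have an analytic target. `msprime`-style ancestry simulation would be
more realistic but would replace those targets with approximations.

Pedigrees: a trio consumes two founders as parents and adds a child built
by Mendelian transmission of one random parental haplotype each; a duo adds
a child from one transmitted haplotype plus one fresh population draw; a
duplicate is an exact copy of a founder under a new id, recorded in
`duplicate_of`. Missingness is applied uniformly at `missing_rate` after
pedigree construction, so duplicate copies acquire independent missingness.

Sites are independent by default and placed at 1 kb spacing on a single
synthetic contig, so a 500 kb window holds ~500 variants and windowed
operations are exercised realistically. Because LD pruning then has nothing
to prune, an optional block mode (`ld_block_size`, `ld_copy_error`) copies
each block-head haplotype with a small per-allele error, planting strong
local LD with known block boundaries.

Default geography places the six default populations at large-city
coordinates across five regions; the divergence defaults (F from 0.05 to
0.15) span the range typical of continental human population pairs. These
are simulation defaults, not estimates of any real cohort, and the default
design plants *no* isolation-by-distance relationship: F values are fixed
per population regardless of coordinates.

Not emulated: linkage with realistic decay, recombination maps, selection,
sequencing reads or genotyping error, sex chromosomes, and real imputation.
`simulate_imputed_dosages()` is a noise model — truth plus Gaussian noise
with sd s₀·e^(−coverage)·(1 + c/(MAF+ε)) clipped to [0, 2] — built so that
accuracy is monotone in coverage and MAF with a controllable shape; it
stands in for an imputation engine in evaluation tests and is documented as
such. Consequently, passing tests demonstrate the *statistics* are computed
correctly and calibrated under known truth; they do not certify behaviour
under real LD structure, batch effects or platform artifacts.

## QC conventions

`filter_variants()` has three modes mirroring the stages of a resource
build, with thresholds in `qc_thresholds()`:

* `relatedness_pca`: biallelic SNVs with alternate-allele frequency
  strictly inside (`maf_min`, `maf_max`) = (0.05, 0.95) and per-variant
  missing fraction strictly below `max_missing` = 0.001. "Between" bounds
  are read as open intervals and missingness as strict, matching the
  printed operators of the conventions this follows.
* `phasing_prep`: exact HWE p ≥ 1e-30, missing fraction ≤ 0.1, exact
  excess-heterozygosity p ≥ 0.5 (inclusive bounds, again as printed). An
  upper ExcHet bound of 1.5 is sometimes quoted alongside; it is vacuous
  for a probability and is not a parameter here.
* `monomorphic_only`: drops AC = 0 and AC = AN.

Rules are applied and counted in a fixed order, the report records removals
per rule, and the operation is idempotent. The exact HWE test conditions on
allele counts and sums genotype-configuration probabilities no larger than
the observed one (with a 1+1e-9 relative tolerance when comparing
probabilities, the usual guard against ties lost to floating point);
ExcHet is the one-sided tail P(het ≥ observed). Both are enumerated in
log-space, exact for any cohort size.

LD pruning is a greedy left-to-right scan in position order (ties: ref then
alt lexicographically): a variant is kept iff its squared correlation with
every kept variant within the window is below `ld_r2_max`. The greedy
first-kept-wins rule was chosen because it is deterministic and matches
common practice; the algorithm behind the published threshold is not
specified anywhere, so determinism won. Zero-variance variants cannot
exhibit LD and are retained with a message. Missing genotypes are dropped
pairwise in the correlation.

Per-sample statistics define a *singleton* as a variant with cohort AC = 1
carried as a heterozygote; a single sample carrying AC = 2 as one hom-alt
genotype is counted separately as a *private homozygote* rather than
folded into either singletons or doubleton pairs. Because singleton counts
scale with cohort size, `downsample_singletons()` equalizes populations
(default 4 unrelated samples each, the smallest defensible denominator),
drops monomorphic variants within the subset, and reports per-population
means; populations below the quota are skipped with a warning, not
silently.

## Relatedness

KING-robust was chosen as the single kinship estimator: it needs no allele
frequencies, so it is immune to the structure present by construction in
multi-population cohorts, and its expectations (0.5 / 0.25 / 0) are exact
targets for the simulator. A PC-conditioned moment estimator (PC-Relate
style) is *not* reimplemented: on the synthetic homogeneous-population
checks both estimators answer the same question, and the screening windows
([0.248, 0.252] for parent–offspring, > 0.35 for duplicates, ≤ 0.05 for
unrelated) are applied to KING-robust estimates here. Pairs with a zero
denominator (no heterozygous sites in either sample) get `NA` and are
excluded from classification.

The unrelated partition removes the highest-degree vertex of the
φ̂ > threshold graph iteratively (ties by lexicographic sample id), then
re-admits any removed vertex with no retained neighbour. This is
deterministic, and the final pass guarantees a *maximal* independent set
(verified by exhaustive search on small graphs in the tests); it is a
heuristic, not a maximum independent set, which is NP-hard and not what
production pipelines compute either.

## PCA, projection and ancestry transfer

PCA uses Hardy–Weinberg normalization (g − 2p)/√(2p(1−p)) with p the
training alternate-allele frequency; missing entries become 0 after
centering (mean imputation) and monomorphic variants are an error, not a
warning. Eigenvalues are squared singular values; each component's sign is
fixed by making its largest-magnitude loading positive, so results do not
depend on sample order. Shrinkage correction for projected samples is
deliberately not applied — projection here feeds a classifier trained in
the same projected space, so a uniform contraction largely cancels; the
observed-variant fraction is reported so callers can judge projections with
heavy missingness. Projected scores are rescaled by
(model variants)/(observed variants) per sample to first order compensate
missingness.

Ancestry transfer trains a seeded random forest (500 trees, default up to
20 PCs — the global-PCA convention; both are config) on region labels.
Samples whose winning probability falls below `prob_threshold` (default
0.5) are labelled `"uncertain"` rather than forced, and samples observing
less than 95% of model variants are flagged low-confidence, consistent
with the finding that below ~5% missingness label transfer is typically
reliable — `missingness_sweep()` measures that degradation directly on any
fixture with known labels.

## Divergence, doubletons and geography

F_ST uses the Weir–Cockerham (1984) estimator with the observed-
heterozygosity correction, combined across variants as a ratio of averages
— the default of the standard command-line tool for this statistic; since
published pipelines rarely name the estimator, it is pinned here and a
Hudson option is provided behind a flag for sensitivity analysis. Variants
monomorphic across a pair are skipped; the common-variant threshold
defaults to pooled MAF > 0.05 (config; parameter-recovery tests use 0 to
avoid ascertainment bias against the Balding–Nichols truth). Small
negative estimates are a known property of the estimator near F_ST = 0 and
are clamped to zero only for clustering, never in the reported matrix.
Population clustering is average-linkage on the F_ST matrix treated as a
dissimilarity, with label-sorted input for deterministic tie-breaking.

Doubleton counting excludes single hom-alt carriers from pair counts — a
"shared" doubleton requires two individuals — and tallies them separately.
The default scope is all samples, with an unrelated-only scope available,
since rare-variant sharing is often reported cohort-wide.

Geographic distances use the haversine formula with Earth radius 6371 km.
Waypoint routing sends between-region paths through up to three of five
fixed cities (Istanbul, Cairo, Phnom Penh, Anadyr, Prince Rupert) following
the usual conventions — Cairo for Africa crossings, Istanbul for Europe,
Phnom Penh toward Oceania, Anadyr then Prince Rupert into the Americas
(e.g. the Americas↔Africa route runs Prince Rupert, Anadyr, Cairo). Only
that example route is fixed by convention; the full 21-pair routing table
shipped here is a documented default, entirely config-overridable, with
same-region pairs travelling directly. Reversed pairs traverse the stored
route backwards, so distances are symmetric by construction.

The Mantel test permutes rows and columns of one matrix jointly, seeded,
with one-sided p = (1 + #{r* ≥ r})/(1 + n_perm); its agreement with the
vegan implementation and its type-I error (nominal 5% within [0.03, 0.07]
over 500 null replicates) are asserted in the tests. The Pearson
correlation is computed on raw F_ST by default; an F_ST/(1−F_ST)
linearized option was considered and left out of scope because the raw
statistic is what the association is usually reported on.

## Phasing and imputation evaluation

Switch errors are counted between consecutive truth-heterozygous sites:
the orientation of a site is whether the test's first haplotype carries
the same allele as the truth's first haplotype, and a pair is an error
when orientation flips. A global haplotype swap flips every orientation
and counts nothing. Sites het in truth but homozygous or missing in test
break the chain — the flanking pair is not counted — rather than counting
as errors, since a genotype discordance is a different failure mode than a
phase error; skipped sites are reported per sample. Compound flip+switch
events register as two switches (no flip-aware decomposition): simpler,
deterministic, and unbiased for the calibration checks used here. Indels
and SNVs are reported separately, matched by full position+allele key.

Aggregate r² pools all (truth genotype, imputed dosage) pairs within a MAF
bin and squares their Pearson correlation, the convention behind standard
accuracy-versus-frequency curves; a per-variant-mean alternative is
available behind the `pool` flag. Bins with zero variance on either side
are reported `NA`, never zero-filled — an all-reference bin carries no
information about accuracy.

## Problem sizes and numerical tolerances

The test suite runs the statistical checks at sizes chosen to make
sampling noise negligible relative to the asserted windows while keeping
the whole suite inside a couple of minutes of compute: kinship recovery at
200 founders + 50 parent–offspring pairs + 10 duplicates × 50,000 common
variants (the mean parent–offspring φ̂ is asserted in [0.248, 0.252];
per-pair estimates scatter around 0.25 with sd ≈ 0.003 at this depth, so
min/max land a few thousandths outside — the window is a statement about
the expectation, which is why the acceptance script reports min and max
separately); F_ST recovery at 100 samples/population × 20,000 variants ×
20 seeds for F ∈ {0.01, 0.05, 0.10} within ±20% relative; switch-error
calibration against a planted 0.1 rate within 3 binomial standard errors
over ≈ 2.6 × 10⁵ heterozygous pairs; Mantel size over 500 null replicates
of 999 permutations. Exact-arithmetic checks (doubleton recounts,
allele-count subtraction, MAF-bin margins, the 7/19 Weir–Cockerham
fixture) use `identical`/1e-12 tolerances. Self-consistency of PCA
projection is asserted at 1e-6 relative.

## Known limitations

* No sex chromosomes, CRAM/BAM access, or build liftover.
* The simulator's LD mode is a block-copy caricature; pruning correctness
  is verified by brute force, not against realistic LD decay.
* PC projection is first-order missingness-compensated but not
  shrinkage-corrected; heavy missingness (> 20%) visibly biases scores
  toward the origin and is flagged, not fixed.
* The unrelated set is a deterministic heuristic maximal independent set,
  not a maximum one; counts can differ from other tools by a few samples
  on dense relatedness graphs.
* `run_pipeline()` orchestrates the synthetic demo end to end; on real
  data the individual functions are the interface and the VCF importer
  expects a GT field with splittable multi-allelics.
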