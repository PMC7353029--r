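---
title: "Methods: clonality, saturation and single-biopsy truncal prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality, saturation and single-biopsy truncal prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truncalis)
```

## The model and its assumptions

`truncalis` treats each tumor lesion as a collection of biopsies, and each
biopsy as the *set* of somatic variants called in it. This is the implicit
model of most multi-region analyses: a sample is summarized by presence or
absence of each variant, as if a single dominant clone per sample carried
all of its mutations. The assumption buys a clean combinatorial structure
— every statistic below is a function of the binary variant-by-biopsy
matrix — at the cost of ignoring within-sample subclonal mixtures. Where
that matters (a variant present at low cancer cell fraction in every
biopsy), the presence-based classification will still call it truncal.

Variant identity is the genomic key `(chrom, pos, ref, alt)`; the gene
symbol is annotation only, because annotation pipelines disagree on
symbols more often than on coordinates. Coordinates are 1-based and fully
closed, the MAF convention.

Quality control happens before anything else: biopsies with DNA
concentration below `qc_min_concentration` (default 4 ng/µL) are dropped
with their calls, and a patient must keep at least two biopsies to be
analyzed at all — with one biopsy the truncal/branch/private distinction
is meaningless. Presence is defined by the upstream caller's emission:
`min_alt_reads` defaults to 0 and exists only as an explicit knob, since
re-thresholding calls second-guesses a caller this package does not
model.

## Clonality

With `b` analyzed biopsies and a variant present in `m` of them:

* truncal: `m = b`;
* private: `m = 1`;
* branch: otherwise.

The denominator is each patient's *own* analyzed biopsy count, so a
patient with only two QC-passed cores still yields truncal calls (and an
empty branch class, since with `b = 2` no `1 < m < b` exists). Proportions
are reported per patient and summarized across a cohort as mean ± sample
standard deviation; a patient with zero variants is reported missing, not
as zeros. Binary copy-number events (one row per amplification or
deletion segment) run through the identical classifier; nothing in the
code distinguishes event types.

Mutational load is a column sum of the non-synonymous presence matrix.
"Diversity" — how unevenly load distributes over regions of one lesion —
is not a standardized quantity; this package defines it as the mean ±
standard deviation of `|load_i − load_j|` over all `C(b,2)` biopsy pairs,
the only symmetric pairwise statistic consistent with a mean-and-spread
presentation. The choice is interpretive and recorded here.

## Saturation analysis

For subset size `k`, all `C(b, k)` biopsy subsets are enumerated
(deterministically, in lexicographic order). Per subset: the union count
(`unique`), the intersection count (`ptv`, putative truncal variants) and
the positive predictive value `C / ptv`, where `C` is the truncal count
defined over all `b` biopsies. Averages are taken over subsets.

Numerical conventions:

* Subsets, not permutations: unions and intersections are
  order-invariant, so the number of arrangements is `C(b, k)`.
* `ppv` terms with `ptv = 0` are 0/0 and are *excluded* from the mean
  rather than imputed; the exclusion count is reported. A patient with no
  truncal variants (`C = 0`) makes every term 0/0 and the average is
  reported missing.
* Useful identities, used as test oracles: a variant present in `m`
  biopsies contributes `C(m,k)/C(b,k)` to `avg_ptv(k)` and
  `1 − C(b−m,k)/C(b,k)` to `avg_unique(k)`. Hence `avg_unique` is
  non-decreasing and `avg_ptv` non-increasing in `k`, and
  `avg_unique(1) = avg_ptv(1)`.

The minimum biopsy number for a statistic is found by a paired Wilcoxon
signed-rank test across patients on each step `k → k+1`: the smallest `k`
whose step is non-significant is returned; if every step is significant
the answer is "`≥ b`" — saturation was not reached within the available
cores. Test conventions (the method name alone does not pin these down):
zero differences are dropped; the exact distribution is used below 25
informative pairs without ties, the normal approximation otherwise; a
step with all-zero differences has p = 1. Significance means `p < alpha`
strictly. A consequence worth stating: setting `alpha = 1` does *not*
make every step non-significant, because any informative step has
`p < 1`; `alpha` is a significance level, not a switch. Patients
contribute to the steps their biopsy count supports, and a step with
fewer than two contributing patients stops the search.

The cohort-level Friedman test asks whether load differs systematically
between biopsy *positions* (blocks = patients); it requires a complete
table and at least three patients, and a degenerate all-tied table is
reported as statistic 0, p = 1.

## Single-biopsy truncal prediction

Ground truth is the multi-biopsy classification. The predictor sees one
biopsy at a time and thresholds either AF or CCF:

* `AF = alt / (alt + ref)`;
* `CCF = AF · (ρ·c_t + c_n·(1−ρ)) / (ρ·μ)`, clipped to [0, 1] with the
  number of clipped values reported; ρ is purity, `c_t` local tumor copy
  number, `c_n` normal copy number (2), μ multiplicity of the mutated
  allele. This closed form assumes purity and copy number are *known*
  (user-supplied or, for synthetic data, taken from the generator);
  inferring them is deliberately out of scope, and multiplicity defaults
  to 1 — conservative, since unknowingly multi-copy mutations then get
  overestimated CCFs that clipping absorbs. Patients without purity or
  copy-number annotation simply carry no CCF overlay and are excluded
  from CCF sweeps (and reported), rather than guessed at.

Accuracy for one biopsy is `correct / assessed`, where *assessed* means
the variants present in that biopsy. The alternative reading — all of the
patient's variants, with absent variants scored as implicit branch calls
— was rejected because it rewards a predictor for variants it never
observed; the choice is flagged as interpretive. Per-patient accuracy is
the mean over biopsies; per-group accuracy the mean over the group's
patients (grouping: whole cohort, cancer type, or single patient — the
appropriate level is itself a question the data should answer, so all
three are available). The best threshold is the *smallest* grid value
attaining the maximal accuracy, with an inclusive `≥` comparison; both
conventions are recorded in the sweep output because neither is forced by
the mathematics, and a consumer comparing thresholds across runs needs to
know them.

## Parsimony phylogenies

Trees are built from the binary matrix by exhaustive maximum parsimony:
all rooted binary topologies over the biopsies (the germline, carrying no
somatic variants, is the outgroup and fixes the root state at absent) are
scored by Fitch's algorithm on unordered binary characters, homoplasy
allowed. With at most 8 leaves — the hard bound, beyond which the
`(2n−3)!!` topology count makes exhaustive search pointless and dedicated
software appropriate — the search is exact, so no heuristic tree-space
moves are needed. Ties are broken by the lexicographically smallest
canonical Newick string, making output deterministic.

Edge lengths are mutation counts from a minimum-change assignment
(Sankoff traceback from the fixed germline root). Ambiguities are
resolved *rootward*: when a node can take either state at equal cost, the
state differing from its parent is chosen, so changes happen on the
earliest possible edge. On compatible (perfect-phylogeny) matrices this
puts every truncal variant on the trunk and reproduces score = variant
count; for homoplastic characters the specific placement is a convention,
and the per-edge assignment table in the output makes it auditable. Edge
lengths always sum to the parsimony score (asserted in code).

## Clinical evaluation

The PFS ratio uses each patient as their own control: PFS on the
truncal-directed therapy over PFS on the immediately preceding therapy,
with benefit defined as an unrounded ratio ≥ 1.3 (inclusive). Reported
ratios are rounded half-away-from-zero to 3 significant figures; the
rounding reassembles the value through a decimal string because the naive
binary computation of, e.g., `6.1/4` rounds the printed `1.525` down.
Medians are reported at 2 significant figures, midpoint convention for
even counts. Censoring is not modeled: a patient still progression-free
at last review enters with their observed time, understating the true
ratio — a documented limitation, acceptable for the descriptive use here
(no survival modeling is attempted). Published cohort tables occasionally
disagree with their own running text on such ratios; this package treats
tabulated PFS pairs as the input of record and recomputes everything from
them.

## The synthetic cohort generator

The generator states a fixed world resembling a small multi-region
study; its defaults are chosen once and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| patients × biopsies | 13 × 4 | small prospective multi-region cohort |
| mean depth | 128 | routine whole-exome coverage |
| purity | U(0.5, 0.9) | typical solid-tumor purity after selection |
| truncal / shared / private per patient | 30 / 20 / 75 | private mutations dominate; ~¼ truncal |
| subclonal CCF | U(0.1, 0.6) | clearly separated from the truncal CCF of 1 |
| tumor copy number, multiplicity | 2, 1 | diploid heterozygous baseline |
| false-negative rate | 0 | detection regime is an explicit knob |

Per variant and member biopsy the expected allele frequency is
`ρ·μ·CCF / (ρ·c_t + 2(1−ρ))`; depth is Poisson around the mean, alternate
reads are binomial, and a call is emitted iff at least one alternate read
survives and the call is not suppressed by the false-negative knob.
Generation is bit-reproducible under a fixed seed.

What the generator emulates: the membership structure (truncal clone in
all biopsies, shared subclones in proper subsets of ≥ 2, private
subclones in one), purity dilution and binomial read noise. What it does
not: sequencing error, germline contamination, spatial geometry, caller
artifacts, copy-number variation along the genome. A green end-to-end
test therefore establishes that the *pipeline algebra* is right — that
classification, saturation, sweeps and trees invert the stated generative
process — not that the method is robust to real-data pathologies.

## Degenerate inputs and numerical edges

* Empty panel intersections are legal, flagged, and skipped downstream.
* A patient with no truncal variants: truncal proportion 0; PPV missing.
* Zero-depth calls, `ref == alt` rows and non-numeric counts are
  row-level errors: collected, reported with line numbers, never fatal to
  the file.
* Equality comparisons on subset means use 1e-12 tolerances in tests;
  the statistics themselves are exact rational arithmetic in doubles.
* Configuration files are flat `key: value` text rather than YAML — the
  package deliberately has no parsing dependency.

## Known limitations

Gene symbols are uppercased but not alias-resolved; panel matching can
miss renamed genes. The CCF estimator trusts its purity and copy-number
inputs. The presence model ignores within-sample CCF structure by design.
Exhaustive tree search is exponential and capped at 8 biopsies. None of
the numerical results in this vignette's text go beyond what the test
suite and `scripts/acceptance.R` themselves compute.
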