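---
title: "methylmark: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylmark: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylmark)
```

`methylmark` implements both halves of a methylation-based forensic
tissue-identification workflow: genome-scale discovery of brain-specific
differentially methylated regions from per-position methylation tables, and
read-level diagnostics for targeted bisulfite amplicon sequencing of the
discovered regions. This vignette documents the models, every tunable that
matters, the synthetic-data generator and its limits, and the design
decisions taken where more than one reasonable choice existed.

## The position score

A diagnostic CpG should be fully unmethylated in every brain sample and
fully methylated in every decoy tissue (hypo mode), or the mirror image
(hyper mode). For brain fractions $b_i$ and decoy fractions $d_j$, the
hypo-mode deviations are $b_i$ and $1 - d_j$, and the score is

$$\mathrm{score} = -\Big(w_b\,\overline{L(\mathrm{dev}_b)} +
w_d\,\overline{L(\mathrm{dev}_d)}\Big), \qquad
L(d) = d + A\big[\sigma(k(d-c)) - \sigma(-kc)\big],$$

with $\sigma$ the logistic function. The score is never positive and equals
0 exactly at the ideal contrast; `informativeness = max(hypo, hyper)` gives
one number per position.

The penalty $L$ is anchored at $L(0)=0$, strictly increasing, roughly
linear below the midpoint, and switches in an extra cost of up to $A$ for
*major exceptions* — deviations beyond $c$. The consequence that matters:
one decoy tissue with brain-like methylation at a position costs about
$A/n_d$ on its own, which at the defaults pushes a 24-decoy compendium
position below the qualification floor. Defaults, all configurable through
`scoring_config()`:

| parameter | default | meaning |
|---|---|---|
| `penalty_amplitude` (A) | 4 | extra cost of a major exception |
| `penalty_steepness` (k) | 15 | sharpness of the minor/major switch |
| `penalty_midpoint` (c) | 0.5 | deviation at which the switch centers |
| `weight_brain`, `weight_decoy` | 1, 1 | group weights |
| `score_floor` | −2 | informativeness a CpG must exceed to qualify |
| `min_cpg`, `max_span_bp` | 5, 300 | region membership rule |
| `top_fraction` | 0.5 | share of best member CpGs averaged |
| `cpg_count_bonus` (γ) | 0.5 | weight of the log2 CpG-count bonus |

The specific algebraic form of $L$ and of the region score below are this
package's declared formulation: they satisfy the published constraints on
the scoring scheme (maximum score 0, weighted distance from the ideal,
logistic penalization of major exceptions, ranking by CpG count and the
mean of the best half of member scores), and all of their parameters are
exposed rather than hard-coded.

## Region selection and ranking

Candidate regions are maximal runs of qualifying CpGs whose first-to-last
distance is at most 300 bp with at least 5 members. "Maximal" means the run
can absorb no further qualifying CpG on either side without breaking the
span constraint; overlapping candidates are resolved greedily by region
score, ties by CpG count, then leftmost. The region score is

$$\mathrm{mean}\big(\text{top } \lceil 0.5\,n\rceil \text{ informativeness
values}\big) + \gamma \log_2(n / 5).$$

The additive $\log_2$ bonus keeps region scores on the informativeness
scale while rewarding CpG-dense regions; doubling the CpG count buys
$\gamma$. A region's type (hypo/hyper) is the per-CpG majority mode with
ties going to hypo at both levels — an arbitrary but fixed convention.
Region coordinates are reported 0-based half-open over the first-to-last
member cytosine; published region lengths do not pin down a boundary
convention, so this one is declared. The qualification floor defaults to the
−2 cut that separates the extreme tail (roughly the top 10⁻⁵ of positions in
genome-scale data) from the bulk; it is configurable because the cut is a
reporting threshold first and a region-building rule second.

The implementation is verified against an exhaustive window-enumeration
oracle on random instances of up to 200 CpGs in the test suite.

## Read validation and pattern calling

Filters run in a fixed order so every read carries exactly one rejection
reason:

1. **Primer**: the genome-specific forward primer must match the read start
   exactly, IUPAC degeneracy allowed, zero mismatches.
2. **Merge / coverage**: R2 is reverse-complemented and merged to R1 by the
   best ungapped overlap (≥ 20 bp, ≥ 90% agreement; disagreements resolved
   by base quality, ties to R1). The merged fragment must reach past the
   last CpG.
3. **Identity**: global alignment (match +1, mismatch −1, gap open/extend
   −2/−1) of the merged read against the bisulfite-converted reference, in
   which CpG cytosines are wildcards matching C or T. Identity excludes
   those wildcard columns from numerator and denominator and must exceed
   0.85 strictly.
4. **CpG states**: each CpG must read CG (methylated) or TG (unmethylated)
   on the read strand; anything else — including a gap — invalidates the
   read.

The published filter list gives "CG or CT" for the admissible dinucleotides;
chemically, a converted unmethylated CpG reads TG on the top strand (the C
converts, the G is untouched), so the default implements CG/TG and treats
the literal wording as a slip. `caller_config(strict_literal_ct = TRUE)`
restores the literal behavior for comparison.

Two numerical shortcuts never change results at the operating point: a read
of exactly reference length with ungapped identity ≥ 0.95 skips the
alignment (no gapped alignment of such a read scores better), and the merge
tries the reference-implied offset first, accepting it only on perfect
overlap agreement. Border-zone reads (identity 0.85–0.95) always go through
the full dynamic program.

Pair merging is not described in the published workflow (150-bp paired-end
reads against amplicons up to ~290 bp force it); the overlap merge above is
this package's choice, and quality scores are used only for merge
tie-breaks — there is no quality trimming.

## Sample classification and consensus

A read passes at percent ≤ 0.1 (hypo) or ≥ 0.9 (hyper); a sample is
positive at ≥ 5% passing reads among valid reads, with fewer than 100 valid
reads discarding the sample. All comparisons are inclusive ("5% or more").
Across assays, unanimity among non-discarded assays is required: any
positive/negative split is rejected, and positives confined to a single
assay type (only hypo or only hyper) while the other type tested negative
raise a `possible bisulfite-efficiency artifact` flag, since a conversion
shift can fake only one direction.

The read-level decision tree (`rpart`, depth ≤ 3, stratified 20% held-out
split at a fixed seed) exists to test whether multi-CpG *patterns* carry
information beyond the per-read percent. The comparator is made explicit: a
percent threshold whose direction and cut maximize F1 on the training
split. The tree is flagged as improving only beyond a 0.01 F1 margin. When
per-CpG states are exchangeable — as in the synthetic generator — percent is
sufficient by symmetry and the tree cannot beat the baseline, which the
acceptance tests confirm; this mirrors the published finding that pattern
models added no predictive power. Tree depth 3 pins down "limited depth";
stratification and the fixed seed pin down the unspecified split.

## The synthetic-data generator

The generator is the package's study-condition model, not a tuning knob.

**Amplicon reads.** A tissue is a mixture of molecule archetypes, each a
per-CpG Bernoulli profile. Defaults emulate the bimodal read distributions
of validated brain assays: brain = 90% brain-archetype molecules (per-CpG
methylation probability 0.03 on hypo assays) + 10% decoy-like background;
decoys = background only (0.9); both mirrored for hyper assays. Bisulfite
chemistry: unmethylated C converts with efficiency η = 0.99, methylated C
converts inappropriately at φ = 0.005, substitution error ε = 0.002/base,
constant Phred 35. Non-CpG cytosines are modeled fully unmethylated (the
standard mammalian assumption), so conversion failures surface as retained
non-CpG C's at rate 1 − η — exactly the deviation the identity filter must
tolerate. Primer regions are overwritten by primer realizations because PCR
erases the template there; sequencing error is applied afterwards, so
primer-region errors still cause rejections. Degradation (burned/air-dried
material) is emulated by depth loss (keep 30%), 3′ truncation below full
CpG coverage (20%), and a 3× error multiplier. Mixtures convert weight
fractions to read fractions 1:1 (equal DNA yield per unit mass assumed).

**Compendia.** Per position, one background mean is drawn from
Beta(0.6, 0.6) — the bimodal marginal real methylomes show — and shared
between brain and decoy groups, because tissues agree at the vast majority
of CpGs; per-sample values scatter around it with concentration 30. Planted
regions overwrite the group means (e.g. brain 0.02 / decoy 0.95 for a hypo
region). Sharing the baseline is what makes background contrast rare: with
independent per-group draws (available via `independent_backgrounds =
TRUE`), chance brain-vs-decoy contrast is common and the false-positive
behavior of region finding cannot be tested meaningfully.

What the generator does **not** model: PCR duplicates and chimeras,
realistic Illumina quality profiles, indel sequencing errors, between-CpG
correlation within an archetype, inter-individual methylation variation,
and cross-species off-target amplification. Passing tests therefore show
that the pipeline recovers the structure it assumes, at the stated rates —
not that real forensic samples behave this well.

## Detection sensitivity and its boundary

Resampling detection draws each read from the brain pool with probability
$f$, classifies the resampled sample, and repeats. The expected passing
fraction is $f r_b + (1-f) r_d$, linear in $f$ (the mixture-correlation
test measures Pearson r ≥ 0.99 against the mixing fraction). Because at
most ~90% of brain reads pass (the archetype weight caps it), the 5%
passing threshold translates to a detection boundary near
$f = 0.05 / r_b \approx 0.056$ under the defaults: detection saturates at
$f \ge 0.10$ and is zero at $f = 0$, while $f = 0.05$ sits just below the
boundary and does not detect. The corresponding acceptance test asserts
full detection from 5% brain content and is expected to fail at exactly
that point under the default generator — the thresholds and generator
levels are fixed study conditions, and the boundary algebra above is the
honest description of where they place the limit.

## Problem sizes and numerical conventions

The test suite exercises 10,000 read pairs per assay archetype for the
noiseless round trip, 10⁴-read resampled samples with 50 replicates per
mixing fraction, 100 random instances (≤ 200 CpGs) for the region oracle,
and 150–300-position compendia with 4 brain / 8 decoy samples — sizes at
which every check runs in seconds while keeping Monte-Carlo standard errors
well inside the asserted margins. Genomic records use 0-based half-open
coordinates throughout (the bedGraph convention, minus-strand records
re-keyed to the plus-strand cytosine and coverage-weight averaged);
within-sequence CpG offsets are 1-based, as everywhere in R. Methylation
columns are auto-detected as percent when any value exceeds 1, overridable.
Assay-table coordinate spans that disagree with reported amplicon lengths
(coordinates that include primer annealing sites) produce a validation
warning, not an error; only internally consistent rows are relied on in
tests. Region-rank ties break deterministically (score, then CpG count,
then coordinate), and the degenerate inputs — empty tables, zero valid
reads, all-discarded assay sets, positions with no decoy coverage — each
have a defined, tested behavior rather than an error where the analysis can
continue with a flag.

## Known limitations

* The scoring formulation is a constrained reconstruction, not a published
  equation; rankings could differ in the tail from the original
  implementation even though all stated properties hold.
* Top-strand chemistry only; bottom-strand assays are out of scope.
* The region finder targets desk-scale inputs (streaming over a few
  thousand positions); genome-scale scans would need chunked I/O.
* Decision-tree metrics on synthetic exchangeable patterns cannot surface
  pattern-level signal that real epialleles might carry.
* Discovery requires brain coverage at every retained position; the decoy
  missingness policy (≥ 80% covered) is a declared default, as public
  compendia do not state one.
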