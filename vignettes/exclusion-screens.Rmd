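---
title: "Scoring conjugation-exclusion screens: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring conjugation-exclusion screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conjscreen)
```

# Overview

Conjugative plasmids of the IncC/IncA family exclude the entry of related
elements into their host cell. A transposon screen can reveal the
recipient-encoded factors responsible: mutants of a plasmid-bearing recipient
whose exclusion machinery is disrupted acquire a mobilized reporter plasmid
more often, so insertions in exclusion genes are enriched among
transconjugants. `conjscreen` implements the full computational path of such
a study — simulation of the experiment, screen scoring, mating-assay
statistics, exclusion-group inference and protein-homology analysis — with
every stage testable against analytic or brute-force oracles.

This vignette records the models, the tunable parameters and the design
decisions, in that order of importance.

# The simulated experiment

`generate_reference()` builds a two-replicon host (circular chromosome and
plasmid) with non-overlapping genes drawn uniformly from a length range
(default 300–900 bp, the bulk of bacterial ORF lengths) separated by fixed
200 bp spacers. `simulate_insertion_library()` draws `n_mutants` Tn5
insertions i.i.d. uniformly over all positions and strands — an idealization
of a "high-density, near-random" mini-Tn5 library. Defaults are 10^5 mutants
and sequencing depth 10 reads per mutant, plausible values for a dense
library in a ~4 Mb host; the density of the published screens of this kind is
rarely reported, so these are package choices. The worked analyses and the
acceptance script use a deliberately small instance (50 genes, 10^4 mutants)
that keeps every distributional property of the model while running in
seconds.

Selection is a single Bernoulli thinning: a mutant whose insertion lies in
gene *g* is retained (i.e., acquires the mobilized plasmid and appears in the
output library) with probability `min(1, base_rate * effect(g))`. The effect
multiplier is the only biological dial: `effect > 1` models an exclusion gene
whose disruption lifts a transfer block; everything else, including
intergenic insertions, stays at the base acquisition rate. The model omits,
on purpose, fitness differences between mutants, PCR/sequencing bias, indels
and paired-end structure: the screen statistic below depends on none of them,
and a passing simulation therefore says nothing about those artefacts in
real data — only that the scoring arithmetic and its normalization are
correct.

Junction reads are `tag + genomic sequence` starting at the insertion point
and extending 3'-ward on the insertion's strand; circular replicons wrap,
reads running off a linear replicon are discarded. Substitution errors are
i.i.d. per base. With `error_rate = 0` the pipeline is exactly invertible,
which gives the strongest available end-to-end test: mapping synthesized
reads recovers the library's site set *exactly*, and the suite asserts this.

# Screen scoring

The insertion index of gene *g* in one library is

> II_g = unique insertion sites in g / gene length / total unique sites in the library,

and the screen score is the ratio `R_g = (II_g^out + pc)/(II_g^in + pc)`.
Unique sites rather than read counts: read counts are confounded by
amplification depth, whereas distinct junction positions count mutants.
Normalization by the library-wide total makes `R_g` invariant (in
expectation) to the severe depth difference between input and output
libraries — output libraries are typically ~100× smaller because only a
fraction of mutants conjugate. The pseudocount defaults to half the smallest
nonzero index in either library: small enough not to disturb ranking, large
enough to keep genes with zero output sites finite. The candidate threshold
`R_g > 5` is the field's deliberately arbitrary convention and is exposed as
a flag.

Mapping is unique-best **exact** seed matching (default 25 bp) over both
strands with circular wrap-around; ambiguous seeds (≥2 loci) and unmatched
seeds are discarded and counted. Exact matching keeps the pipeline
deterministic and fast at desk scale; mismatch-tolerant mapping would only
matter at error rates the simulator itself controls.

With the acceptance-scale parameters (one gene holding a fraction *f* ≈ 1–2%
of insertions, effect 20, base rate 0.01) the expected planted-gene ratio is
`0.2 / (0.01(1−f) + 0.2 f)` ≈ 15–17, comfortably above threshold; the
neutral false-positive rate at ratio 5 is far below 1% because a neutral
gene's output site count is approximately Poisson with mean ~2 and would
need to quintuple.

# Mating-assay statistics

Transfer frequency is transconjugant CFUs over donor CFUs. A replicate with
zero transconjugants is censored at the detection limit `1/donor_cfu` — one
colony on the plated volume — rather than dropped, so log-scale analyses
keep their replicate structure; the flag travels with the value. The
exclusion index `EI = T_empty / T_test` is computed from geometric means
over replicates (the natural mean for log-normally distributed frequencies);
per-replicate EIs are available for inspection. An EI derived from a
censored test frequency is reported as a lower bound.

The statistical treatment mirrors standard practice for grouped frequencies:
log10 transform, Bartlett's homogeneity test, one-way fixed-effects ANOVA,
Tukey–Kramer all-pairs comparisons (`q = |m_i − m_j| /
sqrt((MSW/2)(1/n_i + 1/n_j))`, p from the studentized range distribution,
which R evaluates by numerical integration in `ptukey`), and a compact
letter display at α = 0.05. The letter display uses insert-and-absorb
lettering; the implementation guarantees the *sharing relation* — two groups
share a letter iff their adjusted p ≥ α — which the suite verifies
exhaustively on random p-matrices, rather than minimality of the letter set.
Degenerate inputs are pinned down explicitly: zero within-group variance
yields F = 0/p = 1 when means agree and p = 0 otherwise.

# Exclusion groups

`build_exclusion_matrix()` assembles EIs for every (sfx recipient, traN
donor) pair, each column anchored by its own empty-recipient baseline (a
missing baseline is an error naming the column — a partial matrix would
silently bias the grouping). `infer_exclusion_groups()` binarizes at
`EI ≥ 10`: published non-excluding combinations sit near EI 1 and excluding
ones are orders of magnitude higher, so one order of magnitude separates the
regimes with a wide margin on either side; twofold changes are conventionally
treated as minor in this assay. Columns with identical binary profiles form
one group — exact profile equality, not clustering, because desk-scale
matrices are replicate-averaged and essentially noise-free after
binarization. Lower-bound cells count as excluded when the bound itself
reaches the cutoff. The partition is invariant to row/column permutation by
construction, and the synthetic CFU generator (`simulate_mating_table()`,
log-normal replicate noise of 0.1 on the log10 scale, typical of day-to-day
mating variation) reproduces a planted two-group pattern exactly.

# Homology analysis

Hits from an external homolog search are screened at ≥45% identity and ≥85%
query coverage (boundaries retained, filter idempotent). Pairwise identity
is computed from an in-package global Needleman–Wunsch/Gotoh alignment with
BLOSUM62 and affine gaps (open 10, extend 0.5; a gap of length L costs
`open + extend·L`, the same convention as Biostrings, which the test suite
uses as an independent cross-check of the C++ aligner, alongside exhaustive
enumeration of all alignments for short pairs). Percent identity is matches
over aligned columns *excluding terminal-gap columns*, i.e. over the
mutually covered region; published identities of this kind are quoted "over
N residues" without a stated denominator convention, so tests comparing to
printed values carry a ±2 percentage-point tolerance. `X` scores 0 against
everything, including itself. Greedy clustering follows the CD-HIT
convention — longest first (ties by id, making the result independent of
input order), first-fit to a cluster representative at ≥0.90 identity — and
the suite asserts post hoc that every member matches its representative at
the cutoff.

# Numerical and testing choices

* All stochastic operations take an explicit integer seed and are exactly
  reproducible; derived seeds stay below 2^31.
* Binomial oracles use 4–5σ bands, wide enough for a fixed-seed test never
  to flicker yet tight enough to catch an off-by-one in the model.
* The Tukey p-value path is validated three ways: closed-form collapse to
  the two-sample t-test at k = 2, agreement with `TukeyHSD`, and a 10^6-draw
  Monte-Carlo estimate of the studentized range CDF.
* Problem sizes in the suite (50-gene references, 10^4-mutant libraries,
  20-seed false-positive controls, 400-replicate family-wise-error
  simulations) were chosen as the smallest instances at which the tested
  quantities are statistically stable.

# Known limitations

The simulator's uniform-insertion, single-round-selection model cannot
expose biases that arise from insertion-site preference, mutant fitness
differences during outgrowth, or chimeric reads. The aligner's identities
are not bit-identical to MUSCLE-derived pairwise identities (different
objective), hence the stated tolerance. Group inference assumes the EI
matrix is complete and replicate-averaged; noisy single-replicate matrices
should be summarized first. Maximum-likelihood phylogenetics, signal-peptide
prediction and entry-exclusion (traG-side) grouping are out of scope.
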