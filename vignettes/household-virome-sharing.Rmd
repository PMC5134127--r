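---
title: "Tracking virome sharing, persistence and transmission in households"
author: "viroshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking virome sharing, persistence and transmission in households}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viroshare)
```

## The analysis problem

Human-associated viromes are dominated by bacteriophages, and longitudinal
cohorts show that many of these phages persist in the same person for months.
When two unrelated people share a household, how much of their gut and oral
virome do they share, and can presence/absence patterns over time reveal
viruses that moved from one housemate to the other?

`viroshare` implements a complete contig-level analysis for this question, for
a cohort design in which households of two (one member on a short antibiotic
course, the other on placebo) plus unpaired controls are sampled at five time
points (day 0, day 3, day 7, week 8, month 6) at two body sites (feces,
saliva). The unit of comparison is the assembled contig: each specimen's
virome is the set of contigs at least 200 nt long with no ambiguous
characters.

The pipeline has five analysis layers, each exposed as ordinary functions and
orchestrated by `runPipeline()`:

1. **Homology** (`computeHitFlags()`, `allPairsShared()`): every virome is
   indexed, and every contig of every other virome is searched against it.
2. **Beta diversity** (`sorensenMatrix()`, `brayCurtisMatrix()`,
   `pcoaOrdination()`, `householdDistanceComparison()`).
3. **Overlap resampling tests** (`subjectOverlapTest()`,
   `householdOverlapTest()`).
4. **Global-virus tracking** (`clusterGlobalViruses()`,
   `persistenceSummary()`).
5. **Transmission inference** (`householdSharing()`, `callTransmissions()`,
   `directionalitySummary()`).

A seeded cohort simulator (`simulateCohort()`) with planted ground truth
closes the loop: every layer is validated against either an independent
oracle or the simulator's truth table.

## Homology model

The per-virome search is a self-contained seed-and-extend local aligner, so
no external alignment binary is needed. Targets are indexed by exact words
(default 11-mers). Every word shared between a query contig and a target
contig nominates a diagonal, and the best-scoring ungapped segment on each
nominated diagonal is found exactly by a maximum-subarray scan under match
+1 / mismatch −2 scoring. Ungapped extension is the right model here because
the divergence being detected is substitution-dominated; the engine is
validated pairwise against a full Smith–Waterman oracle
(`Biostrings::pairwiseAlignment`, local, identical scoring with a linear gap
cost of 2) on randomized mini-cohorts spanning exact copies, diverged copies
(1–5% and 20–30% substitution), fragments and unrelated sequences.

A query contig *has a homologue* in a target virome when its best alignment
reaches all three of:

* alignment length ≥ `minAlignmentLength` (default 50 nt),
* identity ≥ `minIdentity` (default 0.90),
* Karlin–Altschul E-value ≤ `evalueThreshold` (default 1e-10), with
  E = *K m n* exp(−λS), λ = 1.33, *K* = 0.621 for +1/−2 scoring, *m* the
  query length and *n* the total target length.

Only the E-value bound is anchored in the original comparisons (BLASTN at
E < 1e-10); word size, length and identity floors are engine conventions
chosen to be permissive at the divergence scales of persistent viruses.
A contig counts as shared on a single significant hit; hit multiplicity does
not weight the fraction.

## Distances and ordination

For an unordered virome pair the Sorensen similarity is computed from the
reciprocal hit counts, (n~A→B~ + n~B→A~)/(n~A~ + n~B~), which reduces to the
classic 2C/(S₁+S₂) when hits are reciprocal; it is 0 for disjoint and 1 for
identical viromes. The Bray–Curtis distance used for ordination is exactly
1 − Sorensen. PCoA is classical metric scaling (double-centering of −D²/2,
eigendecomposition, coordinates scaled by the square roots of eigenvalues)
via `stats::cmdscale`. Axes with negative eigenvalues are dropped and
reported rather than corrected (no Lingoes/Cailliez), so ordinations are
always real-valued.

The within- versus between-household comparison pools **all** cross-subject
sample pairs — same and different time points — inside a household against
cross-subject pairs across households, excluding same-subject pairs (the
comparison is between people, not within them). Significance is a two-sided
Mann–Whitney U test: exact when both groups have at most 8 tie-free values,
otherwise the tie-corrected normal approximation.

## The overlap resampling test, and what its p-values mean

Per iteration the test draws a "within" shared percentage from two distinct
random time points of the focal subject (resampling 1,000 contigs per draw,
without replacement when the virome is large enough) and a "between"
percentage from random time points of two distinct randomly chosen subjects.
The empirical p is the fraction of iterations in which between ≥ within;
ties count against significance, and p = 0 is printed as "<1/N". The
household variant replaces within draws by cross-housemate pairs and null
draws by cross-household pairs. One draw-size convention deserves note: the
procedure is documented both as 1,000 and as 10,000 contigs per draw in its
source; `viroshare` defaults to 1,000 (`nContigsPerDraw`), configurable.

**This statistic is not a calibrated permutation p-value.** Because it
compares *N* paired draws, as *N* grows p converges to
P(between ≥ within | cohort) — a property of the cohort, not a uniform
variate. Under an iid null (no subject structure; `nullPoolConfig()`
generates one, with retention equal to acquisition so presence is iid across
samples) the p-values concentrate in a bell around 0.5 instead of spreading
uniformly: with the design's five time points the empirical type-I error at
the 0.05 level is essentially zero. The test is therefore *severely
conservative* under its own study design — small p-values are trustworthy,
but the test has no uniform-null guarantee. (With only two time points per
subject the within statistic degenerates to a single draw and near-uniform
p-values reappear, which confirms the mechanism.) The package implements the
procedure as published; the test suite asserts the properties it actually
has — p centred near 0.5 under the null and a rejection rate never above
nominal — and the strict uniformity check in the acceptance suite documents,
deliberately, that uniformity does not hold.

Despite the conservatism, the test has excellent power in the regime the
analysis targets: with within-subject sharing far above between-subject
sharing, all or nearly all simulated household subjects reach p ≤ 0.05.

## Global viruses, persistence, and the transmission rule

Rather than re-running a read assembler, "global viruses" are built by
single-linkage clustering of contigs pooled across time points (and, at
household scope, across housemates): two contigs are linked when a local
alignment covers at least 50% of the shorter contig at ≥ 98% identity — the
same criteria used to discriminate highly related viruses at assembly time.
Presence/absence per (subject, time point) is all the downstream logic
consumes, which clustering reproduces. Cluster ids are deterministic
(ordered by earliest member time point, then lexicographic member id) and
invariant to contig input order.

Persistence is the span between the earliest and latest day offsets at which
a virus is present (week 8 = day 56 and month 6 = day 182 are calendar
conventions, fixed so interval thresholds are computable); summaries report
the fractions of viruses spanning ≥ 4 days and ≥ 150 days. Missing samples
contribute nothing to spans.

A putative transmission is called for a household virus when (a) the
recipient is absent at every *sampled* time point up to and including the
donor's first presence — a missing recipient specimen in that window is
unknown, not absent, and blocks the call — (b) the recipient's first
presence is strictly later than the donor's, and (c) the recipient is
present at two or more time points. Equal first presences give sharing but
no call (no direction is assignable). Directionality is annotated from the
treatment arms, and the cohort summary reports per-household percentages
(denominator: all of that household's global viruses, so the directional
parts sum to the transmission total and are commensurable with the shared
proportion) with means ± standard errors across households. The ≥ 2
time-point requirement is applied exactly as stated even though it excludes
single-late-appearance patterns; no relaxation is enabled by default.

## What the simulator emulates — and what it does not

`simulateCohort()` generates the full study design: 8 two-person households
(one member amoxicillin or azithromycin, the other placebo) plus 4 controls,
5 time points, both body sites, and the loss of the last household's month-6
specimens. Each subject carries core viruses (some shared with the housemate
as common founders), all present at day 0; a cohort-wide background pool
supplies environmental acquisitions. Presence evolves as a two-state Markov
chain per virus and subject (retain with `retentionProb`, reacquire core
with `reacquisitionProb`, acquire background with
`backgroundAcquisitionProb`). Genomes are uniform-random sequences of
0.5–3 kb that accumulate substitutions (`mutationRate` per base per time
step; substitution-only so identity thresholds stay analytically
predictable) and are emitted re-fragmented into two non-overlapping contigs
per sample, so clustering must genuinely merge fragments. Planted
transmissions copy a donor-exclusive virus into the housemate at a random
interior time point — as a copy of the donor's current genome with one extra
round of divergence — and are floored to two recipient presences so the
caller's rule can in principle recover them; the donor is the placebo member
with probability `transmissionDirectionBias` (default 0.75).

The default dynamics (`defaultSimulationConfig()`: retention 0.78,
reacquisition 0.05, background acquisition 0.04 over a pool of 40, 12 core
viruses of which 5 shared, transmission rate 2.5 per household) were tuned
once, by simulation, so that realized fecal regimes land where the analysis
assumes them — within-subject shared fractions averaging ~60–70% (inside the
20–75% band observed across real subjects), between-subject fractions of a
few percent (inside 1–17%), roughly a quarter of household viruses shared,
and ~10% of them transmitted with a placebo-to-antibiotic majority. Genome
lengths of 0.5–3 kb keep all-pairs alignment desk-scale; they are a
problem-size choice, not a biological claim.

The simulator deliberately does **not** emulate: antibiotic pharmacology
(the treatment arm is a directionality label only, matching the observation
that these antibiotics did not disrupt virome persistence); body-site
differences (feces and saliva get identical dynamics, while real oral
viromes are markedly less persistent); abundance structure, MDA amplification
bias, indels, recombination, or within-host quasispecies diversity. Passing
tests therefore show that the *analysis logic* is correct under a faithful
presence/absence generative model — not that the pipeline is robust to every
artefact of real virome sequencing.

## Numerical and design choices

* **Draws**: sampling is without replacement when a virome has at least
  `nContigsPerDraw` contigs, with replacement otherwise, keeping the
  statistic unbiased for large viromes.
* **Ties**: between ≥ within counts against significance (conservative).
* **Degenerate inputs**: empty viromes are a hard error for homology (the
  caller skips missing specimens); an all-zero distance matrix ordinates to
  all-zero coordinates; clustering of a single contig yields one singleton
  virus.
* **Determinism**: every stochastic routine takes an explicit seed;
  `simulateCohort()` restores the caller's RNG state, identical
  configurations produce byte-identical FASTA, and two pipeline runs under
  one seed produce identical output checksums.
* **Validation scales**: the test suite uses 50 randomized mini-cohorts for
  the alignment-oracle comparison, 200 iid null cohorts (4 subjects each,
  500 iterations per test) for the null-behaviour study, 1,000 viruses for
  the persistence closed form (observed fraction with span ≥ 4 days within
  three binomial standard errors of retention², with reacquisition off),
  and the full 20-subject design for power and transmission recovery
  (recall ≥ 0.95, precision ≥ 0.90 against planted truth at mutation rate
  0.002 with no missing samples and the background pool disabled — the
  background-free setting isolates the caller's behaviour on planted events;
  with the pool enabled, independent double acquisitions can mimic
  transmission patterns and are measured, not forbidden).

## Known limitations

* The overlap test's p-values are conservative by construction (above);
  treat them as evidence summaries, not calibrated error rates.
* Single-linkage clustering can chain distinct viruses through shared
  elements, and re-fragmentation can occasionally split a virus present at
  a single time point into two clusters; both effects perturb denominators
  slightly but not presence patterns.
* Sharing cannot distinguish direct virion transmission from transfer of
  lysogenized host bacteria; the transmission calls are "putative" in
  exactly that sense.
* Homology is nucleotide-level and presence/absence only; no abundance
  weighting, no protein-level annotation, no taxonomy.
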