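---
title: "volatax: methods, parameter choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{volatax: methods, parameter choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(volatax)
```

## The procedure

`volatax` implements chemotaxonomic species identification from aligned
GC-MS headspace peak tables as a cascade of canonical analyses of principal
coordinates (CAP). The underlying assumption is that species differ
primarily in *which* volatile compounds they release — species-specific
markers act like a fingerprint, while a few widely shared compounds (the
aphid alarm pheromone (E)-β-farnesene is the motivating example) partition
whole groups of species by their absence.

One round consists of:

1. **Replicate averaging.** Technical replicates (the protocol assumes
   n ≥ 3 per biological sample; fewer triggers a warning, not an error) are
   collapsed to their arithmetic mean *before* any transformation, because
   replicate means are the intended analysis unit.
2. **Transformation and dissimilarity.** Default: relative abundance
   (columns scaled to sum 1) followed by Bray–Curtis. Presence/absence
   (with a configurable detection threshold, default 0) with Bray–Curtis or
   binary Jaccard is available per round; CAP itself is distance-agnostic.
3. **PCoA.** Gower centering `G = J(-½ D∘D)J`, eigendecomposition, axes
   with eigenvalue ≤ 1e-10·|λ₁| dropped. Negative eigenvalues (possible for
   semimetric dissimilarities) are reported but not corrected — no Lingoes
   or Cailliez adjustment, because the corrections subtly change the
   canonical correlations and the simplest faithful behaviour is preferred.
4. **Canonical analysis.** Eigenanalysis of `Q′HQ` with `Q` the first `m`
   orthonormal PCoA axes and `H` the group hat matrix; eigenvalues are the
   squared canonical correlations δ²ₖ, sample scores their projections.
5. **Model selection.** `m` scans g−1 … min(m_max, retained axes, N−g)
   (m_max default 20) minimising leave-one-out misclassification, ties
   broken toward the smallest `m`. The held-out sample is re-embedded with
   Gower's supplementary-point formula and allocated to the nearest group
   centroid (Euclidean, in canonical space), so the axes it is judged
   against never saw it.
6. **Significance.** Group labels are permuted (default 199 permutations,
   seeded); `p = (1 + #{perm ≥ obs})/(1 + n_perm)` for the trace Σδ² and
   for δ²₁.
7. **Compound vectors and biomarkers.** Each compound's (X, Y) are Pearson
   correlations between its transformed abundances and canonical axes 1–2.
   Correlations (not regression coefficients) are used because the source
   method reports its per-round cutoffs as `|r|` or `X²+Y²`. Significant
   vectors (per-round cutoff and mode, e.g. `X²+Y² > 0.65`) are assigned to
   the a-priori group whose centroid has the largest positive projection
   onto (X, Y) — a formalisation of "the vector points toward the group it
   characterises", which the source applies narratively. Squared lengths
   ≥ 0.49 are essential biomarkers (EBs), [0.29, 0.49) semi-essential
   (SEBs), smaller ones are dropped. The published EB interval tops out at
   0.97; that reads as the empirical maximum of the original dataset, not
   an exclusion, so longer vectors remain EBs with a logged note.

The cascade peels off the groups each round separated. Which groups leave
is *plan-driven* (`groups_to_remove_after`), not automatic: the original
design reads each scatter by eye, and automating that judgement would
over-claim. `suggest_group_removals()` (zero LOO misallocations plus mean
silhouette > 0.5) offers candidates; the plan decides. A round needs at
least three a-priori groups; an outgroup may be added purely to satisfy the
minimum and its biomarkers never enter the key. Host-plant resolution for a
polyphagous species is the same machinery with `grouping_variable =
"host_plant"` on that species' samples.

The dichotomous key unions each taxon's EB/SEB sets over the rounds where
it was separated (inner circle wins when a compound qualifies as both), and
a taxon must end with ≥ 1 EB. The same compound may be an EB for one taxon
and a SEB for another; per-taxon roles are independent.

## Matching unknowns

The source study never states a quantitative matching rule; the one here is
an explicit formalisation. For each taxon, `eb_match_fraction = |EB ∩
profile|/|EB|`, likewise for SEBs (vacuously 1 for an empty SEB set), and
`score = eb + 0.5·seb`. A profile is *identified* as the top-scoring taxon
iff it carries all of that taxon's EBs (`eb_accept = 1`: EBs are
definitional) and leads the runner-up by `margin = 0.25` (avoids coin-flip
identifications); *unidentified* when no taxon's EBs are fully present (the
putative-new-species outcome); otherwise *ambiguous*. Matching is
presence-only — the key is a presence key.

In CAP mode (`identify_unknown()` with a reference dataset), the unknown's
technical replicates enter as *individual samples* of their own a-priori
group. This mirrors the source's final diagnosis round, where the unknown's
three replicates were among the analysed samples, and is also necessary:
with a single averaged sample, leave-one-out could never validate the
unknown's group. The unknown is reported as distinct when every replicate
is re-allocated to it under leave-one-out.

## The synthetic world

The generator's defaults emulate the shape of the motivating dataset:

| parameter | default | why |
|---|---|---|
| species / compounds | 10 / 81 | the emulated study's panel |
| planted EBs / SEBs per species | 2 / 2 | few, strong markers per species |
| shared marker | present in 8/10 species | the alarm-pheromone split: the two lacking species separate first |
| biological samples per species | 6 | the study's opening round analysed 63 replicate-averaged samples over 10 species |
| technical replicates | 3 | protocol minimum |
| marker : background median | 100 : 1 (log-normal) | markers are dominant peaks; ratio stated with the recovery criterion |
| σ (biological / technical) | 0.6 / 0.25 log-units | multiplicative noise dominates GC-MS intensities |
| p_seb | 0.5 | a semi-specific marker present in about half the samples has expected group-structure effect size η² ≈ 0.4, the middle of the SEB band |
| background presence | 0.9 | widely shared volatiles with occasional non-detection |
| dropout | 0.05 | detection-limit losses, applied after the abundance draw |

Planted EBs are disjoint across species by construction (essential
biomarkers are species-distinctive by definition); shared biology lives in
the shared marker and optional host-plant compounds. Every planted EB is
guaranteed observable in at least one replicate of its species even under
unlucky dropout.

`default_recovery_plan()` orders the shared-marker-lacking species into
round 1 and then peels two species per three-group round (one, when four
remain). Its rounds use the presence transform: the source describes every
round's separation as driven by presence/absence, and under
relative-abundance correlations low-abundance background compounds acquire
spuriously long vectors through compositional closure (their relative
abundance anti-correlates with the group-structured marker load). The
package-wide default remains relative + Bray–Curtis.

**Recovery metrics.** `eb_recovery_experiment()` reports recall (planted
EBs recovered as EBs), precision (reported EBs that are planted markers —
EB *or* SEB — of their species), and a strict precision (EB-as-EB only).
With `p_seb = 0.5` a planted SEB's realised vector length straddles the
0.49 boundary across data draws; a planted marker reported as essential is
a correct marker call on that draw, so it does not count against precision,
while background or shared compounds reported as EBs do. The band
thresholds themselves are never adjusted.

**What a green test does and does not establish.** The generator captures
presence-structured markers, multiplicative noise, dropout, and the shared
and host-linked compound structure. It does not simulate retention-time
drift, co-elution, chromatographic batch effects, or correlated compound
families; green recovery tests therefore establish that the pipeline's
inference machinery works on data satisfying its assumptions, not that any
particular real dataset satisfies them. Chance-level SEBs appear at these
sample sizes (null vector lengths are roughly scaled χ²₂ at n ≈ 18
samples), which is why the zero-planted-SEB check asserts sparseness and
background-only membership rather than exact emptiness.

## Numerical conventions

- Eigenvector signs are arbitrary, so each canonical axis is oriented to
  make the first group's centroid coordinate nonnegative (falling back to
  the next group when numerically zero): outputs are deterministic and
  byte-stable under a fixed seed.
- All randomness flows through explicit seeds (`withr::with_seed`), with
  derived per-round seeds kept below 2³¹; the caller's RNG state is never
  perturbed.
- Symmetry is enforced at 1e-12 relative tolerance on distance input;
  Gower-centered rows/columns sum to 0 within 1e-10·scale; eigenvalues
  below 1e-10·|λ₁| are treated as null axes.
- Degenerate inputs fail loudly with classed conditions: all-zero
  compound sets after pruning, all-null eigenvalues, empty groups, plans
  with fewer than three groups, vocabulary-disjoint unknowns.
- Zero-variance compounds get vector (0, 0) with a warning, never an error;
  all-zero columns stay zero under the relative transform, with a warning.
- LOO folds whose reduced ordination supports fewer than `m` axes reduce
  `m` for that fold and log it; a fold that collapses a group allocates to
  the remaining groups (necessarily counting as a misallocation unless the
  labels happen to agree).

## Known limitations

- The sample-to-round accounting of the original study is internally
  inconsistent (its text and figure captions disagree about round sizes),
  so cascades here are plan-driven rather than hard-coded; reproducing the
  original figures is out of scope.
- The per-round significance cutoffs are analyst-chosen in the source
  ("depending on the shape and length of vectors"); `volatax` makes them
  explicit plan parameters with no automatic selection.
- Compound identity across datasets is by aligned compound id/name;
  retention-index re-alignment across instruments is out of scope.
- The matching rule's `margin` interacts with shared EBs: two taxa with
  identical EB sets are reported ambiguous by design.
- At small per-round sample sizes, correlation noise produces occasional
  chance-level SEBs (see above); EB calls are far more robust because the
  0.49 threshold sits several null standard deviations out.
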