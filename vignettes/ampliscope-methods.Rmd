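---
title: "Models and methods behind ampliscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampliscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscope)
```

## The problem

Bulk-trap surveillance of mosquitoes by metabarcoding faces two coupled
questions. First, *selectivity*: traps collect far more non-target arthropod
biomass than mosquitoes, and universal primers waste most sequencing output
on that bycatch. A clade-restricted assay exploits a priming site that is
conserved within the target family but ends, at the primer's 3′ terminus, in
a base that most other taxa lack — a terminal mismatch that blocks polymerase
extension. Second, *quantitation*: once reads are produced, do per-species
read counts track the DNA each specimen contributed, closely enough to use
read proportions as abundance estimates?

`ampliscope` implements both halves as a reusable, fully testable pipeline:
an in-silico PCR engine with a strict 3′-anchor criterion plus coverage,
logo and resolution summaries; and a mock-pool quantitation toolkit
(volume normalization, Best Estimate, regression diagnostics, dropout
analysis) driven by a seeded generative model of pooled amplicon sequencing.

## In-silico PCR

### Matching model

A primer base and a template base are *compatible* when their IUPAC
nucleotide sets intersect; an `N` in the template therefore never counts as
a mismatch. This mirrors common in-silico PCR practice: a degenerate
database base represents uncertainty, not divergence. A window matches when
at most `max_mismatches` positions are incompatible (default 5, the
conventional tolerance for binding-site surveys). Both strands are scanned;
all coordinates are reported as 0-based half-open intervals on the forward
strand, so the upstream flank of a site is simply `start` and the downstream
flank is `length − end`.

The 3′ criterion is evaluated on exactly one base — the primer's 3′-terminal
position — because that is the base whose pairing polymerase extension
absolutely requires. A 3′-incompatible site is still *reported* by
`find_binding_sites()` (flagged `three_prime_match = FALSE`) so that logos
and mismatch histograms can show the diagnostic base doing its work;
exclusion happens in `amplify()` when `require_three_prime = TRUE` (the
default). A 3′ mismatch is one event with two consequences: it counts
against the mismatch budget *and* clears the flag.

### Product enumeration

`amplify()` pairs every forward site with every reverse site in convergent
orientation within `max_amplicon_length` and emits one hit per pair — no
"shortest product" collapsing, because which product dominates a real PCR is
a kinetic question the data model should not prejudge; downstream summaries
deduplicate per accession instead (best site = lowest mismatch count, ties
broken leftmost). The length cap defaults to 2000 nt, a practical ceiling
chosen by this package (amplicons beyond it are irrelevant to short-read
metabarcoding); it is configurable. Products are always reported in
forward-primer orientation, which makes amplification strand-symmetric: a
reverse-complemented reference yields the same product sequences, a property
the test suite asserts.

One subtlety the tests document: a palindromic pattern (its own reverse
complement) legitimately produces a site on *both* strands of the same
window. This falls straight out of the matching model and is not collapsed.

### Verification

The engine is checked against an independently written brute-force
enumerator (explicit double loops, windows reverse-complemented rather than
the primer, its own IUPAC table) on 200 constructed sequences per run:
random backgrounds with planted, mutated site pairs and 10% degenerate
bases, half of them strand-flipped. Output is compared as exact sets of
(orientation, span, product).

## Coverage, logos and resolution

`coverage_table()` reports, per taxonomic group, how many entries carry each
site, both sites, a matching forward 3′ base, and at least one strict
product; fractions are `NA` for empty groups. `build_pcm()` produces the
position count matrices behind binding-site logos with one deduplicated site
per accession; degenerate template bases are tallied in a separate `other`
row rather than spread fractionally over A/C/G/T, keeping every column an
integer partition of the group's sequence count (an invariant the suite
checks).

Species resolution — the fraction of species identifiable from amplicon
sequence alone — has no single canonical formula, so both defensible
conventions are implemented and labelled in the output. `species-unique`
(the default, because the quantity is species-denominated): a species is
resolved iff none of its distinct insert sequences is shared with another
species. `amplicon-lca`: the fraction of distinct inserts produced by
exactly one species. The two bracket the ambiguity about whether
intraspecific variants are counted as records or collapsed.

A note on coarsening: merging two species' labels leaves every *other*
species' resolved status unchanged (their sharing pattern with the merged
pair is unchanged), and that is the invariant the tests assert. The overall
score itself is *not* monotone under merging — if the two merged species
conflicted only with each other, their mutual conflict disappears and the
score rises. The test suite pins both a decreasing and the
counterintuitive direction with concrete cases.

## Exact-identity assignment

Pooled reads are assigned against a library of per-specimen variants.
Two rules follow the validated protocol exactly:

* **1% minor-variant filter** (`filter_minor_variants()`): within one
  specimen's denoised variants, anything representing *strictly fewer* than
  1% of the total is removed (a variant at exactly 1% is kept). This guards
  against trace cross-contamination among specimens processed together.
* **100% identity** (`assign_reads()`): a read is assigned iff it equals a
  library variant character-for-character after uppercasing, full length.
  No substring or near matching — reads are primer-trimmed full amplicons,
  so partial matching would only admit chimeras and errors. Per-species
  counts sum reads across that species' variants.

`build_library()` enforces the library's defining invariant — no variant
sequence under two species — as a hard error, since a violation means the
mock data or the lab process is compromised, not that a tie-break is needed.

## Pool quantitation

`normalize_by_volume()` converts counts to volume-corrected proportions
(`(r_i/v_i)` rescaled to sum 1). Rescaling to proportions, rather than
leaving per-µL rates, makes pools of different depth directly comparable,
and every downstream comparison is proportional. Zero-read design species
stay in the profile at 0: dropout is data, and the Best Estimate
(`best_estimate()`, the per-species mean across replicate pools) counts a
dropout as zero rather than missing so that an intermittently-detected
species is correctly down-weighted.

`fit_regression()` is ordinary least squares with a two-sided Pearson test;
OLS (not orthogonal regression) because slope and intercept of the standard
regression line are the quantities of interest. Bonferroni m defaults to 1
and `pool_fidelity()` sets it to the number of pools tested in the call.
Two degeneracies are worth naming. With *equal* amplifiability the
volume-normalized profile is flat regardless of the design, so the
"slope ≈ 1" expectation is only meaningful when the expected profile varies —
either raw read share against design share (equal-amplifiability case) or
normalized share against a Best Estimate built from heterogeneous
amplifiabilities. A zero-variance regressor is therefore a hard error, not a
`NaN`.

`dropout_probability(N, p) = (1 − p)^N` is the exact marginal zero-count
probability of one multinomial category; the suite confirms it against
10,000-draw Monte Carlo at the depths of interest within three standard
errors.

## The generative model

`synth_reference_set()` emulates the structure that makes a clade-restricted
D2-style assay work, without reproducing any real database:

* target entries carry both priming sites exactly; off-target entries carry
  the conserved reverse site and a forward site whose 3′ base is swapped to
  an incompatible nucleotide, plus 0–2 internal substitutions — so the
  strict policy separates the clades *by the 3′ base alone*, and relaxing it
  admits the off-targets (both directions are asserted);
* two target clades draw insert lengths from Normal(383, 9) and
  Normal(432, 24) nt at GC 0.60 — the observed D2 regimes for culicines and
  anophelines — with off-target inserts at Normal(420, 60) as an
  uninformative default; 3 of the default 17 target species sit in the
  longer clade, mirroring the anopheline share of a representative mock
  assemblage;
* each target species is one specimen with 1–6 intragenomic variants
  (SNPs, occasionally a short tandem duplication or deletion — the
  microsatellite-style indels real rDNA shows), with within-individual
  frequencies; all inserts are globally unique, so the planted resolution
  is 1.0.

`simulate_reads()` generates counts in three steps: raw depth
`N′ = N/(1 − quality_loss)` (default loss 0.20, the typical fraction of
output removed by quality filtering), a binomial discard, then one
multinomial draw over the pool's generating categories. Category
proportions are `volume × amplifiability × degradation` per target species,
renormalized; degradation is a scalar loss of amplifiable template, not
length-dependent fragmentation — the simplest model consistent with the
observation that degraded pools preserve relative profiles. Bycatch enters
as `bycatch_dna_ratio` mass units, one unit defaulting to the pool's total
target mass so the ratio directly sets amplifiable bycatch:target odds
(raw DNA-mass excesses of bycatch are mostly non-amplifying and therefore
not the relevant scale); a configurable `carryover_fraction` of that mass is
reassigned to designated target species, reproducing the enrichment
signature that motivates excluding sympatrically captured specimens from
fidelity regressions. The remainder is spread over named bycatch families,
one dominant by default. Read counts are multinomial given fixed
proportions — no PCR branching-process overdispersion; this is the simplest
model supporting every quantitative property used, and an overdispersion
hook would slot in at the proportion-drawing step.

All randomness flows from one integer seed; pool *i* uses stream
`seed + i`, and every simulated object records its config. Identical seeds
give byte-identical FASTA and count tables.

### What the generator does *not* emulate

No per-base sequencing error or quality profile, no chimera formation, no
GC-dependent polymerase bias, no length-dependent amplification advantage,
no overdispersion beyond multinomial. Passing tests therefore demonstrate
that the *pipeline logic* is correct under a clean generative model — they
do not certify performance on real Illumina data, where denoising quality
and PCR stochasticity add variance the model omits.

## Problem sizes and numerical choices

The shipped test suite runs the oracle comparison on 200 constructed
sequences (≤ 400 nt), the parameter-recovery check on 20 seeds × 4 pools of
17 species at 17,000 reads (R² > 0.95 required against the true
amplifiability profile), species-recovery on 1,000 replicate pools at 3,050
reads, and dropout realism on 200 replicate degraded pools at 3,400 reads —
sizes at which the asserted properties are statistically comfortable.
Degraded pools are modelled with *heterogeneous* degradation (the vulnerable
stock at multiplier 0.02, others 0.3–1) because a uniform multiplier cancels
out of the proportions; heterogeneity is also what real degraded mixtures
show, with the least amplicon-dense taxon differing between fresh and
degraded preparations.

Other fixed choices: sample (n − 1) standard deviations throughout;
per-accession site deduplication by lowest mismatch then leftmost start;
`U` rejected everywhere (DNA only), lowercase uppercased silently; taxonomy
as a flat rank→name table (every grouping used is a rank-equality
predicate, so no taxonomy tree is needed); duplicate FASTA ids and
cross-species shared variants are hard errors.

## Limitations

The engine is O(n·m) per strand per primer in plain R — fine for reference
sets in the tens of thousands of entries, not engineered for
genome-scale scans. Thermodynamic models (melting temperature, ΔG of
terminal mismatches) are out of scope: the 3′ criterion is a binary
compatibility, which matches how such assays are evaluated but understates
partial extension of wobble-paired termini. Compositional statistics
(log-ratio analysis) are deliberately not provided; the fidelity questions
asked here are linear ones about proportions.
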