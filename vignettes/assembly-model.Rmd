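---
title: "The refasm assembly model: tiling paths, alternate loci, and coordinate-stable releases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The refasm assembly model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refasm)
```

## The model and its assumptions

`refasm` implements the clone-based reference-assembly model in which a
genome is not one sequence but a structured collection: a primary haploid
assembly, alternate tiling paths for structurally variant regions, and
patch scaffolds released between major assemblies. The package makes three
structural assumptions throughout:

1. **Assembly is declarative.** An assembled object is fully described by
   its AGP rows; the sequence is a deterministic render of those rows
   (`build_object_sequence()`). Every validator and oracle in the package
   leans on this: the AGP must tile its object exactly (no holes, no
   overlaps, part numbers consecutive from 1), component spans must match
   object spans, and contig-rank objects carry no gap rows.

2. **Overlaps between adjacent components are substitution-only.** Clone
   overlaps in the model disagree at isolated bases (sequencing or clone
   errors), not by indels. This is what the synthetic generator produces and
   what the dovetail detector assumes; it is the reason ungapped overlap
   scoring is exact here (see below). Real clone overlaps can contain small
   indels; handling them would require gapped overlap alignment and
   switch-point rules over alignment columns rather than bases.

3. **Chromosome context is an alignment, not a coordinate.** Alternate loci
   and patches never receive chromosome coordinates. Their `placement` — a
   sorted list of gapless aligned blocks between the scaffold axis and the
   chromosome axis — is the single source of truth for liftover,
   for overlap checks between alternates, and for splicing FIX patches at a
   major release.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_len` (dovetail) | 20 | bp | Shorter matches are too likely by chance at desk scale; also the seed length for overlap detection. |
| `min_identity` (dovetail) | 0.97 | fraction | Accepts a few clone disagreements per 100 bp while rejecting spurious joins; callers working with noisier corpora may lower it (the builder logs both values in the AGP header comment). |
| Alignment scoring (`anchor_align`) | +1 / −1 / −5 / −1 | match, mismatch, gap open, gap extend | Standard affine scoring that keeps a single indel in one gap rather than scattering it; recorded in the placement-file header. |
| Unknown gap render length | 100 | bp of `N` | The AGP convention for `U` gaps; interoperable default. |
| Alternate-locus size advisory | 5 × 10⁶ | bp | Oversized alternates draw a warning-severity finding, never a rejection — there is no hard limit in the model. |
| Release thresholds | 100 fix patches, >1% euchromatin | — | The release decision is `n_fix ≥ 100` **or** `pct > 1` (strict); both are explicit arguments of `release_decision()`. |
| Read aligner | k = 15, identity ≥ 0.9 | — | Deliberately minimal: exact seeds, ungapped evaluation, single best placement, no mapping quality. |

## Numerical and procedural choices

**Dovetail detection.** `find_overlap()` seeds with exact 20-mers from the
right component's prefix, looked up in the left component, and scores each
implied dovetail length by ungapped identity (highest identity wins; ties go
to the longer overlap). If every seed window happens to carry a
substitution, the detector falls back to scanning all dovetail lengths —
cheap at the component sizes this package targets, and it keeps detection
deterministic with no stochastic seeding.

**Switch points.** Within a verified overlap the switch point is the
midpoint of the longest exact-match run; ties go to the leftmost run. The
midpoint maximizes distance from the nearest disagreement, and the leftmost
tie-break makes rebuilds reproducible. The model requires only that *some*
base in the overlap be chosen; any rule satisfying the no-redundancy
invariant (each built base comes from exactly one component) would do.

**Anchored placement.** Components present in both the alternate and the
primary tiling path are anchors: the intersection of their used spans maps
to both objects and forms exact blocks with no alignment at all. Only the
inter-anchor segments are globally aligned (via `Biostrings::pairwiseAlignment`),
then decomposed into gapless blocks and merged with the anchors. Alternates
sharing no anchor with their chromosome are rejected as unplaceable and stay
unlocalized/unplaced — placing them would need mapping data outside this
model.

**Liftover and no-maps.** Positions inside a block map by exact offset;
positions inside an indel return both flanking mapped target positions
rather than silently rounding, so callers choose their own convention.
Positions outside the placement span are a range error, not a no-map.

**Minor releases.** The coordinate-stability contract is enforced, not
assumed: `minor_release()` snapshots every primary sequence and every
existing placement and fails hard if any byte changed. New patches may
overlap primary sequence freely (that is what FIX patches are for) but never
another active patch.

**Major releases.** FIX patches are spliced strictly left-to-right; the
retained old segments become rows of a three-column-per-chromosome remap
table (old span, new span, offset). FIX splicing runs before NOVEL
promotion so that promoted placements — and all surviving alternate-locus
placements — are remapped onto post-splice coordinates; a placement block
that straddles a spliced span is a curation error, not something the code
guesses about. NOVEL patches are assigned to the first alternate-loci unit
where they overlap no existing member, with a fresh unit created when every
existing unit conflicts — mirroring how multiple same-region alternates must
live in different units. "Euchromatic sequence" is operationalized as
non-gap primary-unit bases, and the >1% rule counts the union of FIX-patch
placement spans on the chromosome (each base once, gap bases never).

## What the synthetic generator emulates — and what it does not

`gen_components()` tiles a hidden random truth sequence with clone-like
components (defaults scaled to 1–20 kb against real 10–200 kb clones) whose
overlap copies carry Bernoulli substitution errors at a chosen rate (capped
at 5%). `gen_variant_region()` builds the canonical dual-haplotype fixture:
left and right flank clones anchor both paths, a "deletion path" middle
clone joins the flanks directly, and an "insertion path" middle clone
carries a unique insert (default flanks 5 kb, insert 2 kb — chosen so a
desk-scale run finishes in seconds while leaving the insert far longer than
a read). `simulate_reads()` draws uniform-start, fixed-length reads with
independent substitution errors.

Real data differ in ways that matter: repeats and segmental duplications
(the generator's sequence is i.i.d. random, so spurious seed hits are
vanishingly rare), indel sequencing errors, paired-end structure, coverage
biases, and production aligners with mapping-quality models. Passing the
read-rescue test therefore demonstrates the *direction* of the effect —
carrying an alternate locus can only help allele-specific reads, never hurt
shared-flank reads — not any particular misalignment fraction on real
libraries.

## Degenerate inputs and tie-breaks

* An empty AGP row set, rows naming several objects, or a gap row first in a
  TPF are hard errors; validation findings (holes, overlaps, mismatched
  spans) are data, never exceptions.
* A component fully consumed by its two flanking overlaps is an error — the
  tiling path is redundant and needs curation.
* Orientation tokens `?`/`na`/`0` in input AGP are mapped to `+` with a
  warning rather than rejected.
* `which.max` semantics (leftmost maximum) are relied on for both the
  longest-run and best-candidate tie-breaks, making every choice
  deterministic for a fixed input.
* All generators restore the caller's RNG state; identical seeds give
  byte-identical artifacts end to end, including through the CLI.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run everything at desk scale, as a
design choice keeping a full check under a minute: release-policy scans over
0–150 patches, 50 randomized minor releases and 100 random release histories
on ~2.8 kb toy chromosomes, major-release splice oracles on ~11 kb
chromosomes with 2–4 patches, 100 random tiling paths (2–4 components of
0.3–0.8 kb), 100 random placements for liftover bijectivity, and the
read-rescue experiment at 500 reads per simulated region (20 seeds in the
test suite, 10 in the acceptance script). Every reported quantity is
computed at run time by the same exported functions a user would call.

## Known limitations

* Placements and anchors are forward-strand only; an inverted alternate
  locus is not representable.
* Overlap detection is ungapped, so a true clone overlap containing an indel
  will be rejected (the builder then asks for a gap row).
* `pairwiseAlignment` is unbanded; inter-anchor segments beyond a few tens
  of kb will be slow, though anchors keep typical segments short.
* The issue tracker stores state in a plain data frame — adequate for the
  model, not a multi-user curation database.
* Scheduling policy (quarterly minor releases, announcement lead times) is
  out of scope; only the mechanical release decision is modeled.
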