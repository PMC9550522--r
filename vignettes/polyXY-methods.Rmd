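---
title: "Detecting and classifying two-amino-acid regions with polyXY"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying two-amino-acid regions with polyXY}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyXY)
```

## The model

Protein low complexity regions composed of exactly two amino-acid types
(*polyXY*) sit between homorepeats and general compositionally biased
regions. polyXY detects them with a sliding window of length $w$ (default
6): a window is positive when it contains exactly two distinct residue
types, each at least twice, and only standard amino acids. Positive windows
of the same unordered pair $\{X, Y\}$ that share at least one position are
unioned into maximal regions, so $w$ is also the minimum reportable region
length. Windows of *different* pairs are never merged — doing so would
create regions with more than two residue types, contradicting the polyXY
definition — so regions of different pairs may overlap.

Every region belongs to exactly one of three categories, tested in this
order:

1. **direpeat**: the region is a perfect tandem of the two-residue unit
   `XY`/`YX`, allowing at most one lone X or Y in the whole region, at a
   terminus or between units. Operationally a region is a direpeat iff it
   has no adjacent equal residues (perfect alternation; odd length means a
   lone terminal residue) or exactly one adjacent-equal position with odd
   total length (removing one member of that pair leaves an even perfect
   tandem). The repeat number counts complete units only, so `GLGLGL` and
   `GLGLGLG` both have 3 units; with $w = 6$ no direpeat can have fewer
   than 3.
2. **joined**: exactly two maximal runs, each of length $\ge 2$ (a polyX
   directly followed by a polyY). The observed order is recorded, because
   N- versus C-terminal placement of the two runs can matter biologically.
3. **shuffled**: the remainder. Long shuffled regions may still *contain*
   sub-spans of length $\ge w$ that qualify as joined or direpeat;
   `findEmbeddedPatterns()` reports these by exhaustive sub-span
   enumeration.

The direpeat test precedes the joined test. For pure regions the two
definitions are mutually exclusive (an alternating string has no run of
two), which the test suite confirms by enumeration, but the precedence is
fixed so behaviour is defined for any input.

## Parameters

* `window` (residues, default 6, minimum 4): window length and minimum
  region length. Below 4 no window can contain two residue types twice
  each. Six follows common practice for short repeat detection; larger
  values report only longer regions.
* `mergeGap` (0–2, default 0): when positive, two regions of the *same*
  pair separated by at most this many residues (necessarily outside the
  pair) are merged into one. Merged regions contain a third residue type
  and are therefore always categorized shuffled; when looking for embedded
  patterns inside them, candidate sub-spans are restricted to the region's
  own pair so a gap residue cannot fabricate a pattern.
* `pairFilter`, `categoryFilter`, `minUnits`: post-classification search
  filters. A single-residue pair filter means "any X with this specific
  Y"; `minUnits` applies to direpeats and drops all other categories.

Coordinates are 1-based and inclusive at both ends everywhere — in objects,
TSV output and annotation input. Sequences are upper-cased on ingest;
lower-case soft masking is not honoured. Characters outside the 20 standard
amino acids are accepted in input but disqualify every window touching
them: an ambiguity code is not evidence of composition. Duplicate FASTA ids
are a hard error because per-protein statistics would silently
double-count. Output ordering (protein input order, then start, end, pair)
is fixed so identical inputs yield byte-identical outputs.

## Downstream statistics

`summarizeDataset()` reports regions per protein, the fraction of residues
inside regions (overlapping regions of different pairs count their residues
once per region — the most direct reading, and documented so the number is
auditable), mean region length and category fractions.
`compositionUsage()` compares, per amino acid, the background frequency
with the fraction of regions whose pair contains it; each region counts
once per pair member, so these fractions sum to 2. `positionProfiles()`
maps each region to its midpoint divided by protein length — the midpoint
is symmetric and robust to length differences, where start positions are
not. Order asymmetry of joined regions (`XY` versus `YX` of the same pair)
is tested with a two-sided Mann–Whitney U on the two relative-position
samples; `stats::wilcox.test` supplies the exact small-sample distribution
and the tie-corrected normal approximation for larger samples, and the test
suite cross-checks it against exhaustive enumeration of the null
distribution for $n_1, n_2 \le 8$.

`overlapAnalysis()` quantifies containment: a region overlaps a domain or
predicted disorder interval only when it lies *completely* inside it.
The baseline draws, for each region, `nRandom` same-length regions placed
uniformly at random in the same protein (default 1, matching the simplest
design; more placements reduce baseline variance and the mean is reported).
For a single interval of length $m$ in a protein of length $L$ and a region
of length $k$, the expected random containment is
$\max(0, m - k + 1)/(L - k + 1)$, which the Monte-Carlo estimate converges
to in the tests. Regions on proteins without any annotation record count as
not contained (absence of annotation is informative in a proteome-wide
setting); `annotatedOnly = TRUE` restricts to annotated proteins. All
randomness flows from one documented seed, so reports are bit-reproducible.

## The synthetic generator

`generateFixture()` emulates a proteome with known ground truth: background
residues drawn i.i.d. from a specified composition, planted polyXY of known
pair/category inserted behind guard flanks of two *distinct* non-pair
residues on each side (so a planted span can never extend into its
context), and optional annotation intervals covering the plants. Defaults —
50 proteins of 100–400 residues with a uniform background over the 20
standard amino acids — were chosen once as a small generic proteome;
realistic per-taxon compositions can be supplied but are not built in.
Joined plants constrain both runs to lengths between 2 and $w - 2$, because
a longer run makes its interior windows single-type negative and the
detected region would be trimmed relative to the plant.

The truth table is *defined* as the output of `bruteForceScan()`, a
deliberately naive window-by-window enumerator sharing no code with the
optimized scanner: background sequences can legitimately form polyXY, and
truth-by-oracle guarantees these are part of the truth rather than a source
of flaky tests. What passing fixture tests shows is exact agreement between
two independent implementations of the stated definitions on sequences with
i.i.d. backgrounds; it does not validate biological claims about real
proteomes, whose residue order is far from i.i.d.

## Numerical and design notes

* The scanner core maintains sliding residue counts in C++ (O(L) per
  protein); the reference enumerator recomputes every window from scratch.
  Equivalence over thousands of random sequences (alphabet sizes 2–20,
  lengths 1–500) is asserted in the tests, alongside maximality and purity
  invariants of every reported region.
* Merging across a gap applies transitively left-to-right within one pair.
  Gap residues are provably outside the pair: if a pair residue separated
  two same-pair regions, a bridging window would already have been
  positive.
* "At most one lone residue" is read strictly — one per region, not one per
  location. The permissive reading would blur direpeats into shuffled.
* Unit counting with an internal lone residue counts complete units on both
  sides (`GLGLLGL` has 3), and the lone half unit never counts.
* Degenerate inputs: empty sequences and sequences shorter than the window
  yield empty results, not errors; an all-identical sequence (homorepeat)
  yields no regions; an empty region set summarizes with zero counts and a
  zero mean length.
* Problem sizes used in the bundled checks — 1,000 random sequences for
  detector equivalence, 10,000 two-letter strings for the classifier, 100
  random fixture specs, 20,000 Monte-Carlo placements, a 500-protein
  synthetic proteome in the acceptance script — were chosen to give stable
  agreement statistics at interactive runtimes.

## Limitations

* Only two-type regions are detected; generalized LCRs of three or more
  residue types, DNA/RNA input and translated scanning are out of scope.
* Direpeats with more than one interruption, and periodicities above 2, are
  classified shuffled by design.
* Annotations are consumed as plain interval tables; running disorder
  predictors or domain scanners, and any web retrieval, are outside the
  package.
* Published proteome-scale counts depend on the exact sequence release
  scanned; reproducing them requires the corresponding archived release as
  input.
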