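---
title: "Methods: 5-D pool design, contig-map deconvolution, and the simulated world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 5-D pool design, contig-map deconvolution, and the simulated world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The screening model

A BAC library screening experiment in this package is described by three
objects:

* a **pooling design**: one or more libraries of 384-well plates (wells
  `A1`–`P24`), every plate pooled into a plate pool (PP), plate pools
  arranged in a 2-D matrix whose rows and columns are the row/column
  super-pools (RSP/CSP), and the plate stack split per library into
  sub-pools, each contributing 16 clone row pools (RP) and 24 clone
  column pools (CP). A design with `N` sub-pools therefore has `16N` RPs
  and `24N` CPs. Each clone belongs to exactly one pool of each of the
  five kinds, and all five are recoverable from the clone name
  (`BB092N18` = library BB, plate 92, well N18) plus the matrix — this
  reverse lookup is what makes simulation truth and rate estimation
  possible.
* a **contig map**: clones assembled into contigs with integer left/right
  coordinates in consensus-band units, plus a fingerprint band set per
  clone. Singletons and unassembled (not fingerprinted / failed) clones
  are carried but never participate in solutions.
* per-marker **pool hits**: the positive RSP/CSP/RP/CP identifiers.

The rationale for sub-pooling is the intersection arithmetic: screening
`g` genome equivalents at once yields on average `g` positive matrix rows
and `g` positive columns, hence `g^2` plate intersections of which
`g^2 - g` are false (`expected_intersections()`). Sub-pools of ~1x
coverage keep the RP/CP dimensions near one hit each, collapsing the
candidate count (the worked 4x example: 256 candidates undivided, 64 with
four 1x sub-pools).

# The deconvolution procedure

For a marker, candidate clones `C` are the intersections of candidate
plates (occupied matrix cells at positive row x column pairs) with the
positive RPs and CPs of each sub-pool. By default a sub-pool's RP/CP hits
combine only with candidate plates of its own sub-pool
(`library_filter = TRUE`); the switch exists because the published
worked-example arithmetic combines every sub-pool with *all* candidate
plates, and reproducing those counts requires the unfiltered variant.

Within each contig the candidate subset `C1` (if `|C1| >= 2`) is searched
for linked subsets `C2`: connected components of the relation graph with
edges

* inclusion: `f(a) ⊆ f(b)` or `f(b) ⊆ f(a)`,
* overlap: at least `min_shared` matched bands,
* spanning: `f(c) ⊆ f(a) ∪ f(b)` (evaluated over triples).

Each `C2` gets `Score = 0.8 * NC/MC + 0.2 * (1 - FN/NC)` where `NC = |C2|`,
`MC` is the maximum `NC` over **all** C2 sets of the marker across all
contigs (so the first term rewards the dominant set globally), and `FN`
counts contig members lying inside the C2 span that the pools missed.
Sets are ranked by score; a single top set with positive score is
`unique`, tied tops are `non_unique` (deferred to manual verification),
and a best score `<= 0` or no C2 at all is `no_solution`. Markers with
entirely empty screening results are `no_solution` with a
"screening failure" diagnostic.

## Design choices in the open parts

* **Components, not cliques.** The relations must hold "between each
  other" along a chain of neighbouring clones, not pairwise across the
  whole set (a long tiling of clones shares no single common band).
  Connected components capture exactly the chain scenario; a clique
  requirement would reject valid long tilings.
* **Spanning is skipped when `min_shared = 1`.** If every band of `c` is
  covered by `f(a) ∪ f(b)`, then `c` shares at least one band with `a` or
  `b`, so an overlap edge already exists and components cannot change.
  The cubic spanning pass therefore only runs for `min_shared > 1`, where
  it can genuinely link a clone sharing fewer than `min_shared` bands
  with each neighbour individually.
* **MC across all contigs.** The normalising count is the global top C2
  size for the marker, making scores comparable between contigs.
* **FN interior test.** "Located between the left-most and right-most
  position" is implemented as: clone interval midpoint inside the closed
  span `[min left, max right]` of C2. Midpoints avoid double-counting
  clones that merely poke into the span from outside.
* **Ties.** Scores are compared after rounding to `tie_digits = 6`
  decimals; exact ties produce `non_unique` rather than an arbitrary
  winner. The assigned clone set of a non-unique call is the union of the
  tied top sets (the conservative set a bench scientist would verify).
* **Band matching.** Exact integer matching by default (`tol = 0`), which
  is reproducible and correct for simulated band-site fingerprints. A
  tolerance `tol > 0` matches bands within `|v - w| <= tol`, greedily
  one-to-one in sorted order, for real migration-value data.

# The simulator's stated world

`simulate_screening()` draws clone intervals uniformly on a **circular**
abstract genome (circularity avoids edge-effect coverage loss, matching
the Poisson coverage arithmetic above), with insert lengths normal
(mean 1 unit, sd 0.15, clamped to `[0.2, 2]`). Clones are placed into
384-well plates uniformly at random per library. Fingerprints are the
band-site ids inside the clone interval, with sites on a **regular
lattice** of `band_site_density` sites per unit (default 200): only
*shared* sites matter to the algorithm, so random site placement would add
variance without adding realism, and the lattice guarantees that two
intervals overlapping by more than one lattice spacing share a band.
Contigs are the connected components of the interval-overlap graph —
"perfect" assemblies by construction — with coordinates in band units;
components of size one are singletons, and an optional `p_unassembled`
fraction emulates fingerprinting failures. Observed pool hits are the
true hits (reverse-looked-up from the planted TP clones) minus
per-pool Bernoulli false negatives plus per-pool Bernoulli false
positives, independent across pools, with rates configurable per pool
kind. The defaults emulate the published regime — five libraries of
1.6–1.9x (8.5x total), 55 markers — at a desk-scale genome of 2,000
units; error magnitudes of order 0–0.3 are realistic but default to 0.

The error-injection draws depend only on the truth, so runs with the same
seed and different rates are *coupled*: hits dropped at a lower F- rate
are a subset of those dropped at a higher one. The monotone-degradation
acceptance test relies on this common-random-numbers design rather than
on large-sample averaging.

What the simulator does **not** emulate: restriction-digest chemistry and
gel migration noise (bands are exact integers), assembly errors other
than the explicit `degrade_contigs()` splitting, chimeric clones,
correlated assay failures across the pools of one marker, and non-uniform
clone representation. A green test on simulated data therefore
establishes algorithmic correctness under the stated error model, not
performance on any particular real library.

# Scale of the soundness acceptance world

The soundness criterion (clean pools, perfect contigs, >= 2 TP clones per
marker, 200 markers, recall = precision = 1) fixes the error model but
not the design scale. Soundness is *not* scale-free: at 8.5x total
coverage, false candidates that genuinely overlap inside a contig — the
intrinsic group-testing ambiguity the discrimination score exists to
fight — occur at a rate of order one per marker, so perfect recall is
structurally unattainable there. The criterion is meaningful in the
regime the sub-pooling strategy is designed to create: low per-sub-pool
coverage and candidates sparse on the genome. Chosen once: two libraries
of 1.0x coverage on a 150,000-unit genome (~300,000 clones, 784 plates),
density-200 lattice fingerprints, 200 markers resampled to >= 2 TP
clones. At this scale the probability of any pool-intersection
coincidence across all 200 markers is ~2%, and the run completes in
well under a minute.

# Numerical and degenerate-input conventions

* Map coordinates and band values are integers; intervals are closed.
* `precision` is `NA` when no marker has a solution; presentation
  rounding is 2-decimal half-up (`round_half_up()`), applied only in
  reports, never in comparisons.
* Empty hit sets propagate as empty candidate sets (never errors);
  unknown pool ids, malformed clone names and malformed files raise
  classed parse errors that the CLI maps to exit code 3 (usage/config
  errors map to 2).
* The CLI config file is DCF (`key: value`), parsed by base R
  `read.dcf`; no YAML/TOML parser is a package dependency.
* All randomness funnels through a single mandatory seed per
  configuration; identical configurations are byte-identical in output.

# Known limitations

* The exhaustive search is quadratic (cubic with spanning) in the
  per-contig candidate count; pathological hit patterns on giant contigs
  are the slow case.
* `degrade_contigs()` models over-stringent assembly only as contig
  splitting; it does not create chimeric joins (the opposite failure).
* Real FPC binary project files are out of scope; only the documented
  textual dialect (with inline or sidecar band sets) is read.
* Marker-to-genetic-locus joins (map anchoring downstream of clone
  assignment) are reported, not resolved.
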