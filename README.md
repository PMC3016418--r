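# pooldeconv

Five-dimensional (5-D) BAC clone pool design and contig-map deconvolution
for high-throughput library screening.

## The problem

Anchoring BAC clones and fingerprint contigs on a genetic map requires
screening a BAC library with many markers. Screening every clone is
hopeless for large genomes (a wheat-relative collection holds ~300,000
clones in 789 384-well plates), so clones are screened in pools:

* **PP** — plate pools (all 384 clones of one plate),
* **RSP / CSP** — row and column super-pools of a 2-D matrix of plate
  pools (e.g. 27 x 30: 57 pools screen what 789 plate pools would),
* **RP / CP** — clone row and column pools across the plate stack, split
  per library into *sub-pools* of ~1–2x genome coverage.

A positive marker lights up a few pools of each kind; candidate clones lie
at the intersections. Because multiple genome equivalents are screened at
once, most intersections are false: `g` genome equivalents give on average
`g^2` plate intersections, only `g` of them real (hence the sub-pooling —
at 1x there are no false plate intersections). The fifth dimension
resolves the ambiguity: truly positive (TP) clones share the marker
sequence, so they must overlap and be neighbours in a fingerprint contig.

## The algorithm

For each marker, with candidate set **C** from the pool intersections:

1. in every contig, collect the candidate subset **C1**;
2. for contigs with |C1| >= 2, find linked subsets **C2** — connected
   components of the relation graph whose edges are fingerprint
   *inclusion* (`f(a) ⊆ f(b)`), *overlap* (>= `min_shared` shared bands)
   and *spanning* (`f(c) ⊆ f(a) ∪ f(b)`);
3. count false negatives **FN** — contig members between the left-most
   and right-most position of C2 that are not in C;
4. score every C2 set,

       Score = 0.8 * NC/MC + 0.2 * (1 - FN/NC)

   with NC = |C2| and MC the largest NC over all C2 sets of the marker;
5. the highest score wins: a single best set is a `unique` call, tied top
   scores are `non_unique`, and best score <= 0 (or no C2 at all) is
   `no_solution`.

The package implements the pool design arithmetic, a minimal FPC-style
contig-map dialect with fingerprint band sets, the deconvolution search, a
seeded simulator (clone intervals on an abstract circular genome, lattice
band-site fingerprints, perfect contigs, injectable per-pool F+/F- rates)
and recall/precision evaluation against simulated truth.

## Worked example

```r
library(pooldeconv)

# the published five-library design: 789 plates in a 27 x 30 matrix
design <- build_design(ae_tauschii_libraries(), matrix_shape = c(27, 30))
design
#> 5-D pooling design
#>   libraries: RI, HB, BB, HI, HD
#>   plates: 789  (384-well)
#>   super-pool matrix: 27 x 30 (21 empty cells)
#>   pools: PP 789 | RSP 27 | CSP 30 | RP 80 | CP 120
pool_size(design, "RSP", 1)        # 11520 clones per full row super-pool
pool_size(design, "RP", "RI/A")    # 3384 clones in the RI row sub-pool

# simulate a small noisy screen and deconvolute it
cfg <- sim_config(genome_length = 2000, n_markers = 5, min_tp = 2,
                  p_fp = 0.02, p_fn = 0.05, seed = 101)
sim <- simulate_screening(cfg)
res <- deconvolute(sim$hits, sim$design, sim$map)
res[[1]]
#> marker M0001 -> unique | top: ctg2 (NC=12, FN=12, score=0.800) | 278 candidates (268 in contigs)
compute_metrics(classify_markers(res, sim$truth))
#> markers: 5 | TP: 3 | F+: 1 | no solution: 1
#> recall: 0.60 | precision: 0.75
```

The first marker is resolved uniquely: 278 candidate clones collapse to a
12-clone neighbourhood in one contig (12 interior contig clones were
missed by the pools, costing the FN term its 0.2). With 8.5x total
coverage and injected pool errors, one of five markers picks up a false
clone and one finds no solution — exactly the failure modes the
evaluation module quantifies. With `p_fp = p_fn = 0` and 1x sub-pools the
same pipeline recovers every planted clone set (see the acceptance
tests).

A command-line interface wires the same steps together
(`design | simulate | deconv | evaluate | convert-ace`):

```sh
Rscript exec/pooldeconv simulate --seed 5 --genome-length 2000 \
    --libraries HB:1.0,BB:1.0 --n-markers 12 --min-tp 2 --outdir sim/
Rscript exec/pooldeconv deconv --fpc sim/map.fpc --hits sim/pool_hits.tsv \
    --matrix sim/matrix_design.tsv --outdir res/
Rscript exec/pooldeconv evaluate --summary res/deconv_summary.tsv \
    --truth sim/truth.tsv --out metrics.tsv
```

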