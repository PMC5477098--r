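# mpxdesign

Multiplex PCR (MPCR) primer design for **continuous genomic regions**, for
targeted next-generation sequencing. Given a target sequence with flanks
and (optionally) known variant positions, `mpxdesign` finds a set of
primer pairs whose 300–500-base amplicons tile the whole region with
overlaps, split across *m* ≥ 2 test tubes so that

* every internal primer binding site is covered by the interior of a
  neighboring amplicon from **another** tube (protection against allele
  dropout from 3' variants),
* amplicons sharing a tube never overlap, and
* all primers placed in one tube are pairwise free of stable cross-dimers
  — each tube is a **clique** in the primer compatibility graph.

Candidates pass a nine-rule screen (length 23–30 nt; GC in [0.30, 0.70];
no 4+ homopolymer; nearest-neighbor Tm within 0.5 °C of the optimum and of
the partner primer; hairpin/homodimer/heterodimer ΔG not below
−3 kcal/mol; no known variant under the 3'-terminal three bases; amplicon
length bounds; an optional BLAST/exact-match specificity check discarding
any oligo with more than one potential binding site). Because the clique
formulation is NP-complete, a time-limited **depth-first search** returns
the first feasible tiling, with four candidate-ordering strategies as the
traversal heuristic. Thermodynamics use the unified SantaLucia (1998)
nearest-neighbor parameters with salt correction; dimer/hairpin models are
deliberately simple (ungapped duplexes, single stem-loop) so exact
brute-force oracles can verify every number in the test suite.

## Worked example

```r
library(mpxdesign)

cfg    <- designConfig(mTubes = 3L, flankLen = 240L, timeLimitS = 120)
region <- generateRegion(fixtureSpec(length = 2050, seed = 901), cfg)

sol <- designMultiplex(region, cfg)
show(sol)
#> TilingSolution for 'fixture_s901': solved (0.76 s)
#>   8 pairs across 3 tubes; amplicons [23, 1911)

head(designReport(sol, region, cfg), 4)
#>   tube productIndex    role start end length                sequence   tmC     gc hairpinDG homodimerDG
#> 1    0            0 forward    24  46     23 TGTAACAGCGACCAATTTGTCTG 59.75 0.4348    0.0000     -0.8455
#> 2    0            0 reverse   320 342     23 ACATCAATGGCTACCCTTACGAA 59.80 0.4348    0.0000      0.0000
#> 3    1            1 forward    58  80     23 CTTAGAAGCCCACTCTCTCAGAG 59.62 0.5217   -0.3884     -1.8916
#> 4    1            1 reverse   335 357     23 AGACAAGTCGTCAGGACATCAAT 59.74 0.4348    0.0000      0.0000
```

Eight overlapping amplicons cover the 2,050-base region; products cycle
through tubes 0, 1, 2 so neighbors never share a tube. The report uses
1-based inclusive coordinates; Tm is °C, ΔG columns are kcal/mol (0 means
no qualifying structure). `writeAmpliconBed()` emits the amplicons as
BED6 (0-based half-open; the score column carries the tube index):

```
fixture_s901	23	342	p0	0	+
fixture_s901	57	357	p1	1	+
fixture_s901	343	680	p2	2	+
...
```

`verifySolution(sol, region, cfg)` re-checks a design against every rule
with logic independent of the search. For real targets, read the input
with `readTargetRegion("target.fa", flankLen = 240, "variants.bed")` and
screen specificity with `blastBackend("genomeDB")`; a thin command-line
wrapper lives at `inst/scripts/mpxdesign.R`.

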