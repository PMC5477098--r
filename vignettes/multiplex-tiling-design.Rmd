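---
title: "Designing multiplex PCR amplicon tilings with mpxdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multiplex PCR amplicon tilings with mpxdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpxdesign)
```

## The design problem

Target-amplification assays for desktop sequencers read amplicons of at
most a few hundred bases, so a continuous genomic region longer than one
read — a whole small gene, a long exon, a cluster of exons with short
introns — must be amplified as a set of shorter, overlapping PCR products.
Doing this in a single multiplex reaction fails in two ways: primers that
interact (cross-dimers, hairpins) suppress amplification, and overlapping
products in one tube amplify each other's primer sites. A further clinical
constraint is allele dropout: a variant under a primer's 3' end can
silence one allele. The standard mitigation is to make amplicons overlap
so that every internal primer binding site is itself sequenced as the
interior of the neighboring product — which forces neighboring products
into *different* tubes.

`mpxdesign` automates this design. Given a continuous target with
flanking sequence and a list of known variant positions, it searches for
an ordered set of primer pairs such that

* every amplicon is 300–500 bases long;
* consecutive amplicons overlap, amplicons two apart are disjoint, and the
  union covers the whole inner target;
* the first forward primer lies in the first *n* bases and the last
  reverse primer in the last *n* bases (*n* = `flankLen`, the boundary
  window);
* products are assigned round-robin to *m* ≥ 2 tubes, products sharing a
  tube never overlap, and — the clique condition — **all** primers placed
  in one tube are pairwise compatible: no heterodimer with ΔG below the
  threshold. In graph terms, each tube must be a complete subgraph of the
  primer compatibility graph.

Finding such a subset is a clique-type problem with no known efficient
exact algorithm, so the search is a depth-first backtracking walk that
accepts the *first* feasible tiling and gives up when a wall-clock budget
expires. Any feasible design is experimentally acceptable; optimality is
not pursued.

## Per-primer screening

Candidates are every oligo of 23–30 nt anchored in a window. A candidate
survives when:

* GC fraction lies in [0.30, 0.70] (inclusive — the bounds are "not more
  than 70%, not less than 30%", which admits the endpoints);
* it contains no homopolymer of 4 or more bases;
* its nearest-neighbor melting temperature is within 0.5 °C of the
  configured optimum (`optimumTmC`, default 60 °C);
* hairpin and homodimer free energies are not below −3 kcal/mol;
* no known variant lies on the template under its 3'-terminal three
  bases (applied in template coordinates for both strands, since the
  destabilizing mismatch is positional on the template);
* optionally, a specificity backend reports at most one potential binding
  site: the hit at the candidate's own locus is expected, a second hit
  anywhere disqualifies it. The `blastn -task blastn-short` backend counts
  alignments with E-value below 0.01; the exact-match backend is the
  offline analogue used in tests.

A note on the −3 kcal/mol rule: secondary structures are *unwanted*, so a
structure is disqualifying when it is **more stable** (more negative) than
the threshold. A primer or pair is accepted when every hairpin and dimer
ΔG is ≥ −3 kcal/mol.

## Thermodynamic model

Melting temperatures use the unified DNA/DNA nearest-neighbor parameters
of SantaLucia (1998) — shipped as a plain-text table under `extdata/` so
that tests can re-derive every number independently — with the two-state
formula `Tm = ΔH / (ΔS + R ln(CT/x)) − 273.15`, duplex initiation terms
for the terminal base pairs, a salt-corrected entropy
(`ΔS + 0.368 (N−1) ln[Na+]`, with divalent cations beyond the dNTP pool
folded into an effective monovalent concentration), `x = 4` for a primer
against its template, and `x = 1` plus a symmetry entropy correction for
self-complementary oligos. Defaults: 50 mM monovalent, 1.5 mM Mg²⁺,
0.6 mM dNTP, 50 nM oligo.

Dimer ΔG is evaluated at 37 °C (configurable) as the most stable
*ungapped* antiparallel alignment of the two oligos: every offset is
scanned, every maximal stretch of at least 4 consecutive Watson–Crick
pairs is scored as its stacks plus the two terminal initiation terms, and
the minimum is reported (0 when no such stretch exists). Hairpins are
single-stem, single-loop: stems of ≥ 3 pairs enclosing ≥ 3 unpaired
bases, scored as stem stacks plus a fixed loop penalty (3.5 kcal/mol).
These are deliberately the simplest models admitting an exact brute-force
oracle — no bulges, internal loops, mismatch or dangling-end corrections —
so the test suite can enumerate all alignments and stem-loop placements
and demand exact agreement. Screening decisions near the −3 kcal/mol
threshold would differ under a partition-function model; the threshold
comparisons themselves are strict as configured.

## The search

Product index *n* is global left-to-right order (0-based); tube is
*n* mod *m*. Forward primers are compared by their start (first template
base), reverse primers by their end. At each extension the next forward
must start after the amplicon two back ends, after the previous product
in its own tube ends, after the previous forward start, and before the
previous reverse end (overlap); reverse ends must strictly increase; the
amplicon length, the ≤ 0.5 °C pair-Tm spread, the pair heterodimer and
the incremental per-tube clique checks are applied before recursing. The
search succeeds at the first state whose reverse end falls in the final
boundary window, backtracks at dead ends, and checks a monotonic clock at
every node expansion, returning `timeout` when the budget is spent.

The candidate traversal order is the only tunable heuristic: the four
strategies (`bothNormal`, `fwdReverse`, `revReverse`, `bothReverse`)
reverse the canonical ascending-position order of either role. There is
no randomness anywhere: a fixed (region, configuration, backend) triple
always yields the same solution.

Two readings of the published rule set were genuinely open and are fixed
here as follows. First, the rule set overloads one symbol for both the
boundary-window length and the product index; we keep them separate
(`flankLen` vs `productIndex`), which is the only reading under which the
four positional comparisons are simultaneously satisfiable for
round-robin tubes. Second, whether the two primers of one *pair* must
also be heterodimer-compatible is implied but never stated as a pair
rule; since they share a tube, the clique condition covers them, and
`pairIsValid()` enforces it explicitly.

## Verification

`verifySolution()` is a standalone re-implementation of every rule —
primer/template identity, all per-primer screens, the positional system,
pair constraints, the full pairwise per-tube clique and gap-free coverage
— sharing only the thermodynamic primitives with the search. Every solved
design in the test suite must pass it, and `bruteForceTilings()` (an
exhaustive enumerator, guarded to small candidate sets) provides the
completeness oracle: on small fixtures the search must solve exactly the
instances where the enumeration is non-empty, and its solution must be a
member of the enumerated set.

## Synthetic fixtures

`generateRegion()` builds seeded test regions in which a tiling exists by
construction: oligos are rejection-sampled against the full per-primer
screen (Tm held within ±0.25 °C of the optimum so any two planted primers
also satisfy the ±0.5 °C pair rule, and each new oligo checked for
heterodimer compatibility with all previous ones) and spliced into the
background at positions giving ~400-base amplicons with ~70-base
overlaps. The background is random at a configurable GC fraction, with
planted variants kept off the primer footprints.

In *poison mode* the background is homopolymer blocks, planted oligos
start and end with a run of exactly three identical bases, and a guard
base of the same identity flanks each footprint: any candidate shifted or
extended across a footprint boundary acquires a 4-base homopolymer and
dies. The one unavoidable extra candidate class — the reverse-complement
reading of a planted footprint, which passes every screen whenever the
plant does, by the strand symmetry of the nearest-neighbor table — is
neutralized geometrically: with the inter-product step confined to
263–276 bases, any product anchored at a mirror site is at most 299 or at
least 502 bases long, outside the 300–500 window. The result is a fixture
with exactly one feasible tiling, confirmed by exhaustive enumeration at
generation time; such fixtures pin the search down to a bit-identical
answer under every traversal strategy.

These fixtures emulate what matters to the algorithm — candidate
scarcity, thermodynamic compatibility structure, boundary-window
placement, variant interdiction — but not real genomic sequence: no
repeat structure, no GC-content gradients, no biased variant spectra, and
the offline specificity backend sees only the region itself. Passing
tests therefore demonstrate algorithmic correctness, not performance on a
particular genome.

## Benchmark harness

`runBenchmark()` sweeps a factorial grid of setting batches (short flank
with a base time limit, short flank with twice the limit, long flank with
the base limit) × 4 orderings × tube counts 2–5 — 48 cells — and records
status, wall-clock duration and pair count per region; Fisher's exact
test (two-sided, since no direction is pre-specified) compares success
between groups. Wall-clock limits are parameters, not constants, because
absolute timings are hardware-bound. The package's own evaluation runs
this grid on synthetic fixture panels (2 regions solvable at either
flank, 2 solvable only at the long flank, ~1.3 kb each — sizes chosen so
the full sweep stays interactive on one CPU); on such panels the long
flank dominates the short flank in every cell and adding tubes never
hurts, while doubling the time limit changes nothing — the budget is not
the binding constraint when the initial candidate window is.

## Known limitations

* Dimer and hairpin models are ungapped/single-loop by design; a
  partition-function screen (e.g. primer3's) would shift borderline
  calls.
* Primer–product interactions are not modeled, only primer–primer.
* Variant positions are points; allele identity and frequency are
  ignored.
* The search returns the first feasible tiling, not a minimal-pair or
  maximal-robustness one.
* Specificity against a full genome requires a user-supplied BLAST
  database; the shipped exact-match backend only counts literal
  occurrences in a provided reference.
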