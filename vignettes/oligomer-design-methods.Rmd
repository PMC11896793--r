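---
title: "Designing overlapping oligomer tilings for polymerase chain assembly"
author: "oligotiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing overlapping oligomer tilings for polymerase chain assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligotiler)
```

## The problem

Polymerase chain assembly (PCA) builds a long double-stranded DNA molecule
from a pool of short single-stranded oligomers. Alternating top- and
bottom-strand oligomers tile the target; each consecutive pair shares an
*overlap*, and during thermocycling the overlaps anneal and a polymerase
extends them until the full-length product accumulates. Assembly fails in
characteristic ways: an overlap whose melting temperature (Tm) is far from
the annealing temperature does not prime efficiently; a 3'-terminal thymine
extends less faithfully; a G/C-rich 3' end (an excessive "GC clamp")
stabilizes mispriming; and repeated sequence shared between different
overlaps lets an oligomer anneal at the wrong junction, producing insertions,
deletions or scrambled assemblies.

`oligotiler` turns a target sequence into an ordered, scored, cluster-
annotated oligomer set that a synthesis vendor can take as an order sheet.

## The tiling model

A design for a reference of length $N$ is a sequence of extents
$[s_1, e_1), \dots, [s_n, e_n)$ on the top strand with $s_1 = 0$,
$e_n = N$, $s_{i+1} < e_i$ (gapless, overlapping) and $e_{i+1} > e_i$.
Odd-indexed oligomers carry the top strand, even-indexed ones the reverse
complement of their slice; overlap $i$ is the intersection
$[s_{i+1}, e_i)$ of consecutive extents. Gapless full coverage with the
first and last oligomers at the ends means those terminal oligomers double
as the amplification primers for the assembled product.

## The penalty score

Every oligomer is scored with an unweighted five-component penalty:

$$\mathrm{score} = |T_t - T_c| + 1_T + GC_{\mathrm{clamp}} +
R_{\mathrm{within}} + R_{\mathrm{between}}$$

* $|T_t - T_c|$ — absolute deviation of the *calculated* Tm of the
  oligomer's scoring overlap from the *target* overlap Tm, in degrees C. The
  absolute value matters: without it, overlaps hotter than the target would
  earn negative penalties and a "zero score means faultless" reading would
  be false.
* $1_T$ — indicator that the oligomer's own-strand 3' base is thymine.
* $GC_{\mathrm{clamp}}$ — G/C count above 3 among the five 3'-terminal bases
  of the scoring overlap, oriented in the oligomer's own strand. A raw G/C
  count would make a zero score unreachable (nearly every overlap contains
  G/C), so the standard primer-design allowance of up to three G/C in the
  terminal five is built in and only the excess is penalized.
* $R_{\mathrm{within}}$ — positions of the oligomer covered by a k-mer
  (default $k_w = 8$) whose canonical key occurs at least twice inside the
  oligomer. Counting covered *positions* rather than repeated k-mer types
  makes the penalty scale with the length of the dangerous region.
* $R_{\mathrm{between}}$ — positions of the oligomer's overlap(s) covered by
  k-mers (default $k_b = 10$) shared with non-adjacent overlaps of its
  cluster.

A k-mer and its reverse complement are one *canonical* key throughout,
because mis-annealing happens between complementary strands; a purely
forward-string comparison would miss exactly the events that matter.

Each non-final oligomer is scored on its *downstream* overlap — the one the
greedy construction is choosing when the oligomer is laid down; the final
oligomer, having no successor, is scored on its preceding overlap. A
theoretically faultless oligomer (overlap Tm equal to the target, non-T 3'
base, no clamp excess, no repeats) scores exactly 0.

## Melting temperatures

Tm is computed from nearest-neighbor thermodynamics with the unified
dinucleotide parameter set (shipped as a plain-text table in
`inst/extdata/`, inspectable and swappable), using the two-state formula

$$T_m(^\circ C) = \frac{1000\,\Delta H}{\Delta S + R \ln (C_T/x)} - 273.15
  + 16.6 \log_{10}[\mathrm{Na^+}]$$

with $R = 1.987$ cal mol$^{-1}$K$^{-1}$, $x = 4$ for non-self-complementary
duplexes and $x = 1$ for self-complementary ones. Defaults are
$C_T = 2.5\times10^{-7}$ M total strand and 50 mM monovalent salt — common
oligo-design practice; both are exposed (`oligoConc`, `naConc`) so users can
match any vendor calculator, which typically shifts the absolute scale by a
few degrees without reordering candidates. Magnesium corrections, dangling
ends, mismatches and secondary-structure free energies are out of scope.

## Greedy construction

At each cursor the designer enumerates *every* admissible pair of oligomer
length $L \in [L_{\min}, L_{\max}]$ and next-overlap length
$V \in [V_{\min}, V_{\max}]$, $V < L$, scores each candidate, and commits
one; the next cursor is the chosen overlap's start. Three rules shape the
choice:

1. **GC preference.** Candidates whose overlap GC content lies inside the
   preferred window (default 40–60%) are chosen ahead of out-of-window
   ones. This is a preference, not a constraint: when no candidate
   qualifies, the best non-qualifying one is still returned, so a design is
   always produced (the next-best-fit rule).
2. **Near-tie resolution toward longer oligomers** (`scoreEquiv`, default
   3.5 score units). Candidates within this margin of the minimum total are
   treated as equivalent and the longest oligomer wins, then lower total,
   then Tm closer to target, then smaller overlap start. The rationale:
   penalty differences of a degree or two sit at or below the real accuracy
   of any two-state Tm model, and fewer, longer oligomers mean cheaper
   synthesis and fewer junctions that can fail. The margin was fixed once
   by calibrating assembly-scale behaviour — a 520 bp target at 40–45% GC
   with a 50 nt oligomer cap, overlaps up to 20 bp and a 56 °C target Tm
   should tile into about 20 oligomers, the count published for this class
   of designer under exactly that condition — and is not adjusted per
   design. `scoreEquiv = 0` recovers strict minimum-score selection.
3. **Terminal feasibility.** A candidate is rejected if the remainder it
   leaves cannot be tiled, i.e. if no sequence of admissible strides can
   reach a legal final oligomer (at least `minOverlapLen + 5` nt, at most
   `maxOligoLen`). This reachability test — a linear dynamic program over
   remainder lengths — is what shortens the penultimate step instead of
   stranding an impossible tail.

The Tm tolerance (`tmTolerance`, default ±2.5 °C) never rejects candidates;
it only flags oligomers as error-prone in reports, which is also where the
manual re-design operation (`reoptimize()`) is pointed. `reoptimize()`
keeps a chosen prefix byte-identical and re-runs the construction from a
given ordinal under optionally overridden length/Tm parameters; with no
overrides it reproduces the design exactly (the construction contains no
randomness anywhere).

Greedy per-step selection is deliberate: it matches the candidate-array
formulation of the method and is deterministic and fast. It is *not*
claimed globally optimal over all tilings; a dynamic-programming variant
minimizing the summed penalty would be a natural extension.

## Cluster segregation

After tiling, consecutive oligomers are partitioned into sub-pool clusters:
walking left to right, the current group is extended while no two
non-adjacent overlaps inside it share a canonical $k_b$-mer; at the first
violation a new group opens at the left oligomer of the offending overlap.
Within a cluster no non-adjacent overlap pair shares a repeat, so the
cluster can be pooled and assembled without repeat-driven cross-talk;
conflicts *across* clusters remain visible in the assembly-wide conflict
table and in `crosscheck()` reports, sorted by severity (shared base
pairs). During construction the between-overlap penalty is evaluated
against all committed non-adjacent overlaps (clusters do not exist yet);
after segregation every oligomer is re-scored with the penalty scoped to
its final cluster. Adjacent overlaps are never compared — their sharing is
the designed junction. Whether sub-pools are physically separate reactions
or annotations on one order sheet is the user's call; the package
annotates and reports.

The within-oligomer k-mer (8) is deliberately shorter than the
between-overlap k-mer (10): a 10-mer can only repeat inside an oligomer
carrying at least 20 nt of repetitive content, which a 40–50 nt oligomer
rarely has, while 8-mer seeds already flag self-annealing risk. Both are
configurable (`repeatLenWithin`, `repeatLenBetween`).

## Verification

`reconstruct()` rebuilds the target from the oligomer table alone
(coordinates, strands, own-strand sequences), checking at every junction
that both oligomers spell identical bases over the shared region; a
corrupted design fails with the junction named. `crosscheck()` combines the
reconstruction check with the all-pairs overlap screen. Verification is
advisory by design: repeat conflicts are handled by segregation, not
rejection, and only a reconstruction mismatch fails a run (CLI exit 1).

## Synthetic fixtures and what tests do (and do not) show

`randomSequence()` generates reproducible uniform-composition sequences
whose G+C count is fixed exactly at the target (bases are then permuted
with the seeded generator), optionally with motifs planted verbatim at
fixed positions to provoke repeat handling. These fixtures emulate length,
GC content and planted repeats — *not* codon structure, GC skew gradients,
homopolymer statistics or the long-range repeat families of real genomes.
Tests passing on them demonstrate the algorithmic properties
(reconstruction, determinism, penalty accounting, cluster cleanliness),
not wet-lab assembly success on arbitrary natural sequence.

Problem sizes used by the test suite and acceptance checks, chosen to
exercise every code path at desk scale: thermodynamic oracle agreement on
1,000 random 8–40-mers (tolerance $10^{-9}$ °C against an independent
dimer-by-dimer summation); repeat-count agreement with an exhaustive
$O(n^2)$ oracle on 500 sequences up to 100 nt; byte-exact
design/reconstruct round-trips on 100 seeded references of 200–2,000 nt at
30–70% GC; the 520 bp assembly-scale condition on a 30-seed panel; and a
600 bp GC-balanced run (fixture seed 42) for the overlap GC window.

## Numerical and edge-case choices

* Coordinates are 0-based half-open internally; CSV order sheets are
  1-based inclusive.
* Lowercase input is uppercased; IUPAC ambiguity codes are rejected with
  the offending position named, since the thermodynamics are defined only
  over A/C/G/T.
* A reference no longer than `maxOligoLen` yields a single-oligomer design
  with no overlap; its Tm and clamp components are 0.
* Candidate ties after all tie-break keys cannot occur (the final key,
  overlap start, is unique per candidate), so designs are fully
  deterministic; identical inputs give identical outputs on any platform.
* The final oligomer may be shorter than `minOligoLen` but never shorter
  than `minOverlapLen + 5`.
* Excel export is deliberately replaced by CSV — the format synthesis
  vendors ingest directly and the one that round-trips losslessly
  (`readDesignCsv()` rebuilds the full design, including the reference,
  from the sheet).

## Known limitations

* No secondary-structure screening (hairpins, self-dimers); a fruitful
  extension would be ΔG-based filters.
* The Tm dialect is two-state with a monovalent-salt log correction; no
  Mg²⁺/dNTP correction.
* Repeat detection is exact-match at the configured k; mismatch-tolerant
  (approximate) repeats are not detected.
* Greedy construction can be locally optimal but globally suboptimal on
  adversarial sequences; `reoptimize()` is the manual escape hatch.
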