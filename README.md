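# oligotiler

Oligomer tiling design for polymerase chain assembly (PCA).

Gene-length DNA is routinely built by annealing and extending a pool of
short single-stranded oligomers. The design step decides whether that
assembly works: overlaps must melt near the annealing temperature, 3' ends
must extend cleanly, and repeated sequence shared between different
junctions invites mis-assembly. `oligotiler` is for anyone who needs to
turn a target sequence into a synthesizable oligomer order sheet: it tiles
the target with alternating-strand, overlapping oligomers, scores every
candidate split, and partitions the result into repeat-free sub-pool
clusters.

## The score at the core

Each oligomer is assigned the unweighted penalty

```
score = |T_t − T_c| + 1_T + GC_clamp + R_within + R_between
```

where `T_t` and `T_c` are the target and calculated overlap melting
temperatures (nearest-neighbor thermodynamics, unified SantaLucia
dinucleotide parameters, two-state Tm with `C_T/4` and the
`16.6·log10[Na+]` salt correction), `1_T` indicates a 3'-terminal thymine,
`GC_clamp` counts G/C in excess of 3 among the five 3'-terminal overlap
bases, and `R_within` / `R_between` count base pairs covered by repeated
canonical k-mers inside an oligomer (k = 8) and shared between non-adjacent
overlaps of a cluster (k = 10). A k-mer and its reverse complement are the
same key, so complementary-strand cross-talk is caught. A faultless
oligomer scores exactly 0.

The designer enumerates every admissible (oligomer length, overlap length)
split at each position, prefers overlaps with 40–60% GC, treats candidates
within a small score margin as tied in favour of longer oligomers, and
guards against stranding an untileable tail. If nothing is ideal, the
next-best fit is returned rather than failing. See the methods vignette
(`vignettes/oligomer-design-methods.Rmd`) for the full model.

## Worked example

```r
library(oligotiler)

ref <- randomSequence(520, gcTarget = 40, seed = 13, id = "target520")
d <- designOligomers(ref, DesignParams(maxOligoLen = 50,
                                       maxOverlapLen = 20,
                                       targetTm = 56))
d
#> AssemblyDesign of 'target520' (520 nt)
#>   20 oligomers (10 top / 10 bottom), 19 overlaps, 1 cluster
#>   penalty total : 217.38 (per-oligomer mean 10.87, max 19.40)
#>   overlap Tm    : 36.6-52.0 C (target 56.0), GC 40-60 %
```

A 520 nt target at 40% GC tiles into 20 alternating-strand oligomers in a
single cluster: no two non-adjacent overlaps share a 10-mer, so the whole
set can go into one assembly pool. Every overlap's GC content landed inside
the preferred 40–60% window; overlap Tm runs below the 56 °C target here
because short AT-rich overlaps cannot reach it — the per-oligomer `tmDev`
column quantifies exactly that gap:

```r
head(as.data.frame(designScores(d)), 4)
#>       tmDev threePrimeT gcClamp rWithin rBetween     total
#> 1 13.585108           0       0       0        0 13.585108
#> 2 13.993755           0       0       0        0 13.993755
#> 3  5.468190           0       2       0        0  7.468190
#> 4  8.493924           0       0       0        0  8.493924
```

Oligomer 3 also carries a GC-clamp excess of 2 (five G/C in its overlap's
terminal five bases). Verify and export:

```r
crosscheck(d)
#> VerificationReport
#>   reconstructed length : 520 nt
#>   matches reference    : TRUE
#>   unique junctions     : TRUE
#>   no repeat-sharing overlap pairs

writeDesignCsv(d, "target520.oligos.csv")   # 5'->3' order sheet
d2 <- reoptimize(d, 3, list(maxOverlapLen = 25))  # re-design from oligomer 3
```

The same pipeline is scriptable from a shell via the launcher in
`inst/scripts/oligotiler.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","oligotiler.R",package="oligotiler"))')" \
    design --input target.fa --out-prefix out --target-tm 56
# out.oligos.csv  out.report.txt  out.layout.txt
```

Exit codes: 0 success, 1 verification mismatch, 2 usage/validation error.

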