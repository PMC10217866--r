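# icrscan

Genome-wide detection of **candidate imprinting control regions (ICRs)**
from clustered ZFP57 binding-site composites.

Genomic imprinting — parent-of-origin-specific silencing of one allele —
is governed by ICRs whose CpG methylation is protected by ZFP57, which
binds the methylated hexamer TGC(mC)GC. Inside ICRs, the unmethylated
binding-site word `TGCCGC` (ZFBS) occurs in clusters, and a large share
of characterised ICRs also carry CpG-rich composite elements in which
the ZFBS overlaps an MLL1/MLL2 morpheme ("ZFBS-morph overlaps", ≥ 2
CpGs each). Because composites are rare along chromosomal DNA but
clustered inside ICRs, their local density pinpoints candidate ICRs —
and genes nearby are potential imprinted genes.

`icrscan` is for genomicists who want to run that scan on any assembly
(or a synthetic fixture) and inspect the results on the UCSC genome
browser:

* scan chromosome FASTA for exact occurrences of the ZFBS and of the
  composite elements on both strands (one forward pass over a
  complement-closed word set);
* count composite occurrences in a sliding **850-base** window and
  discard isolated occurrences (any window holding a single element is
  zeroed) — the noise-suppression step;
* chain occurrences at most one window apart into peaks: **robust**
  peaks encompass **≥ 3** elements (the candidate-ICR call), peaks
  covering 2 are **weak** (true or false positives);
* export three UCSC custom tracks (ZFBS hit BED, composite hit BED,
  fixedStep density wiggle) plus the derived peak BED, and annotate
  peaks with genes within a configurable radius (default 10 kb);
* generate seeded synthetic chromosomes with planted clusters and exact
  ground truth (`simulate_genome()`), so every stage is testable
  without assembly downloads.

In symbols: with occurrence starts $x_1 \le \dots \le x_n$ and window
$L = 850$, window counts are $c(w) = \#\{i : x_i \in [w, w+L)\}$ with
$c(w) := 0$ whenever $c(w) = 1$; peaks are maximal runs with
$x_{i+1} - x_i \le L$, kept when their size is ≥ 2 and called robust at
size ≥ 3.

## Worked example

Plant two composite clusters (4 and 2 copies) and one isolated site on a
60 kb synthetic chromosome, scan, and call peaks:

```r
library(icrscan)

sim <- simulate_genome(length = 60000, gc = 0.42,
                       clusters = data.frame(n = c(4, 2), span = c(700, 300)),
                       isolated = 1, seed = 21)
hits <- dedupe_hits(scan_motifs(sim$genome,
                                add_complements(motif_set("TGCCGC"))))
peaks <- call_peaks(hits, window = 850)
tidy(peaks)
#> # A tibble: 2 × 5
#>   chrom  start   end count klass
#>   <chr>  <int> <int> <int> <chr>
#> 1 chrSim 14748 15448     4 robust
#> 2 chrSim 30196 30496     2 weak
glance(peaks)
#> # A tibble: 1 × 6
#>   n_peaks n_robust n_weak max_count window robust_min
#>     <int>    <int>  <int>     <int>  <int>      <int>
#> 1       2        1      1         4    850          3
truth_compare(peaks, sim$truth)$summary
#> # A tibble: 1 × 7
#>   n_planted n_recovered n_missed recovery_pct false_peaks isolated_suppressed
#>       <int>       <int>    <int>        <dbl>       <int> <lgl>
#> 1         2           2        0          100           0 TRUE
```

The 4-copy cluster comes back as a robust peak whose interval is exactly
the hull of its member elements; the 2-copy cluster is a weak peak; the
isolated site is suppressed and produces nothing. `autoplot(d, peaks)`
on a `window_counts()` track draws the browser-style density plot, and
`run_icr_pipeline("genome.fa", out_dir = "out")` (or the CLI wrapper
`inst/cli/icrscan.R` with subcommands `simulate | scan | call | tracks |
annotate | all`) runs everything and writes the track bundle. The
packaged morpheme/composite word lists are synthetic stand-ins
(`inst/extdata/*_synthetic.txt`); point `overlap_file` at a published
list for real analyses.

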