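---
title: "Locating candidate imprinting control regions from clustered ZFP57 binding-site composites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating candidate imprinting control regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icrscan)
```

## The biological problem

Genomic imprinting silences one parental allele of a subset of mammalian
genes. The silencing is governed by imprinting control regions (ICRs):
cis-acting, differentially methylated regions whose methylation is
protected by ZFP57, a KRAB zinc-finger protein that binds the methylated
hexamer TGC(mC)GC. Two sequence observations make ICRs predictable from
DNA alone:

1. ZFP57 binding sites (ZFBS, unmethylated word `TGCCGC`) occur in
   *clusters* inside ICRs, while single occurrences are ubiquitous
   background — the hexamer is short, so chance occurrences are frequent.
2. A large fraction of characterised ICRs/gDMRs contain *composite*
   elements in which the ZFBS overlaps a CpG-rich morpheme of the kind
   recognised by the MLL1/MLL2 CXXC domain. These "ZFBS-morph overlaps"
   carry two or more CpGs, so they are rare along chromosomal DNA, and in
   ICRs they too occur as clusters.

`icrscan` turns these observations into a genome-wide scan: find every
occurrence of the composite elements on both strands, count occurrences
in a sliding window, discard isolated occurrences as noise, and report
each surviving cluster as a candidate ICR. Genes near candidate ICRs are
potential imprinted genes.

## The procedure

For a chromosome sequence $S$ and a complement-closed set of composite
words $W$, the scan reports every exact occurrence (overlapping
occurrences included; windows containing `N` never match). Occurrence
$i$ is summarised by its start $x_i$ (0-based). Two equivalent views of
the density computation are provided:

* **Window counts** (`window_counts()`): for windows $[w, w + L)$ with
  $L = 850$ bases placed every `step` bases,
  $c(w) = \#\{i : x_i \in [w, w+L)\}$, followed by suppression
  $c(w) \leftarrow 0$ whenever $c(w) = 1$. This is the exported wiggle
  track.
* **Cluster chaining** (`call_peaks()`): sort starts and chain
  consecutive occurrences with $x_{i+1} - x_i \le L$ into maximal
  clusters. Singleton clusters are the isolated occurrences and are
  discarded; each surviving cluster becomes a peak spanning the hull of
  its member hits, with `count` equal to its size and class
  `robust` when `count >= 3`, `weak` when `count == 2`. Robust peaks are
  the candidate-ICR calls; two-element peaks can be true or false
  positives.

The two views agree on what "isolated" means up to a one-base boundary
case: two hits whose starts differ by exactly $L$ chain into one cluster
(the chaining rule is $\le L$) but never co-occupy a single window of
width $L$ (co-occupancy requires a gap $< L$). We kept the inclusive
chaining rule because the peak invariant — consecutive member starts at
most one window apart — then holds with equality allowed, and the
property suite tests the equivalence away from the exact boundary.

A related subtlety: enlarging the window can only merge clusters, so the
*cluster* count (peaks plus singletons) is non-increasing in $L$ and
every peak remains inside a larger-window peak with at least its count.
The *peak* count itself is not monotone — two isolated hits (no peak)
can merge into one weak peak under a larger window — which is why the
test suite asserts the containment form of monotonicity.

## Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window` | 850 | bases | the sliding-window width of the original genome-wide scans; clusters of composite elements within this span mark one ICR |
| `wig_step` | 85 | bases | wiggle export resolution (window/10): peak logic is step-free (cluster chaining ≡ step 1), the exported track trades resolution against file size |
| `robust_min` | 3 | elements | empirical threshold separating robust candidate-ICR peaks from two-element peaks |
| `min_overlap` | 1 | bases | any letter-compatible overlap of ZFBS and morpheme counts as a composite; containment counts as overlap of the contained word's length |
| `radius` | 10000 | bases | gene-annotation search radius: "vicinity" is not quantified in the source strategy, 10 kb covers promoter-proximal placement of ICRs relative to their genes |
| `dedupe` | TRUE | — | collapse a word and its reverse complement matching the identical interval to one genomic element before density |

All are configurable through `icr_config()` (arguments > config file >
defaults) and the command-line wrapper `inst/cli/icrscan.R`.

## Motif sets

The ZFBS file holds `TGCCGC`; complements are generated at run time by
`add_complements()`, so a single forward scanning pass covers both
strands (complement-origin motifs report `-` strand hits; the scheme is
provably equivalent to scanning both orientations and the mirror
property is tested). `overlap_motifs()` generates composite words as the
shortest superstrings of a ZFBS word and a morpheme word over every
letter-compatible overlapping placement, excluding merged words with
fewer than two CpGs — the defining property of the composite elements.

The packaged morpheme and overlap word lists under `inst/extdata/` are
**synthetic stand-ins** (so named in their filenames): illustrative
CpG-rich hexamers and the composites generated from them. The published
composite list is not reproduced here; supply it through the
`overlap_file`/`morpheme_file` configuration keys for real analyses.
No correctness test depends on the packaged lists: tests use toy sets
whose expected outputs are computed by independent brute-force oracles.

## Coordinates and file formats

Internally every interval is 0-based half-open. Conversion happens only
in the track writers: BED stays 0-based half-open, fixedStep wiggle
starts are converted to 1-based, both per the UCSC conventions, and both
writers are round-trip tested against their parsers. A genome-wide run
(`run_icr_pipeline()` or the CLI `all` subcommand) emits the three
custom tracks — ZFBS hit BED, composite-element hit BED, density wiggle
— plus the derived peak BED, a per-chromosome summary TSV, and, given
gene models (BED or GFF3; GFF3 keeps `gene` features named by
`Name`, falling back to `ID`), an annotated-peak TSV with signed
hull-to-hull distances (0 when peak and gene overlap, negative when the
gene ends before the peak starts).

## The synthetic-genome generator

`simulate_genome()` is the test stand of the package: an i.i.d.
background with chosen GC fraction, planted motif clusters (`n` copies
spread over at most one window) and isolated sites, all pairwise
separated by more than one window, and *background scrubbing* — chance
occurrences of the motif or its reverse complement outside planted sites
are resampled away. Scrubbing makes the planted truth exact rather than
probabilistic, so end-to-end assertions (100 % cluster recovery with
exact counts, zero false peaks, all isolated sites suppressed) are
deterministic given the seed; the seed is a mandatory argument and there
is no hidden global randomness. What the generator does *not* emulate:
isochore structure, CpG islands, repeats and soft-masking, or the
CpG-depleted dinucleotide composition of real mammalian DNA. Passing
tests therefore certify the machinery (scanning, suppression,
classification, export), not the biological precision/recall of the
strategy on a real assembly, which is beyond a fixture's reach.

```{r}
sim <- simulate_genome(
  length = 60000, gc = 0.42,
  clusters = data.frame(n = c(4, 2), span = c(700, 300)),
  isolated = 1, seed = 21)
hits <- dedupe_hits(scan_motifs(sim$genome,
                                add_complements(motif_set("TGCCGC"))))
peaks <- call_peaks(hits, window = 850)
tidy(peaks)
glance(peaks)
truth_compare(peaks, sim$truth)$summary
```

```{r, fig.width = 7, fig.height = 3}
d <- window_counts(hits, sim$genome$length, window = 850, step = 85)
autoplot(d, peaks = peaks)
```

## Numerical and degenerate-input choices

* Counting uses hit **start** positions: a hit belongs to exactly one
  window per placement. Midpoint counting would differ by at most half a
  motif length and was rejected for simplicity.
* Peak extent is the hull of member hits, not the union of windows, so
  "a peak encompasses k elements" is literally true of the reported
  interval. A cluster chained across more than one window's total span
  stays one peak.
* Lowercase (soft-masked) residues are uppercased and scanned; ambiguity
  codes collapse to `N` and never match (exact-match semantics).
* Empty inputs propagate as empty outputs (no hits → all-zero density,
  no peaks, header-only BED); contract violations (un-complemented set,
  `step > window`, infeasible planting) raise classed errors.
* Test and example problem sizes (chromosomes of 15–120 kb, a 1 Mb
  uniform sequence for the frequency sanity check, 200-case oracle
  sweeps, 20 seeded end-to-end runs) were chosen as the smallest scales
  at which every contract is exercised with comfortable margins.

## Known limitations

Exact matching only — no position-weight matrices or mismatches, by
design: the strategy is defined on literal words. Peaks carry no
significance statistic (none is defined for the method); the
two-element class is reported as-is rather than filtered. The packaged
composite list is a stand-in, see above. Whole-genome inputs are
processed one chromosome at a time in memory; multi-gigabase FASTA files
work but 2bit/indexed access is out of scope.
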