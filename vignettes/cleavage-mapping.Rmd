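---
title: "Mapping endonuclease cleavage sites from read 5' ends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endonuclease cleavage sites from read 5' ends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutmap)
```

## The problem

When a sequence-specific endonuclease cuts double-stranded DNA, library
preparations that tag and enrich the broken ends (SITE-seq and relatives)
produce sequencing reads whose 5' ends pile up precisely at the cleavage
positions. The same logic applies to RNA: an endoribonuclease that cleaves a
tRNA leaves fragments whose 5' bases mark the cut. `cutmap` turns alignment
files from such experiments into cleavage-site calls, and adds two
companion analyses that typically accompany them: degenerate-motif scanning
around the called sites, and a gene-neighborhood enrichment statistic for
asking whether a focal gene (here, a phage homing-endonuclease gene) tends
to sit near tRNA genes across many genomes.

This vignette documents the model behind each stage, the tunable parameters
and their defaults, the numerical conventions, and what the synthetic-data
generator does and does not emulate.

## From alignments to 5'-end tracks

Each replicate's coordinate-sorted BAM is reduced to one integer array per
contig. For every retained record, exactly one count is added at the read's
5'-end reference position: the leftmost aligned base for forward-strand
reads and the rightmost aligned base for reverse-strand reads (0-based;
reference-consumed span, so deletions count and insertions do not). Both
strands accumulate into a single shared array, because a blunt or
near-blunt cut produces ends on both strands at essentially the same
position; per-strand tracks are available via `per_strand = TRUE` for
staggered-cut diagnostics.

Record filters (`filter_config()`): only first mates (R1) — the mate whose
5' end marks the ligated break — with unmapped, secondary, supplementary,
duplicate-flagged, and QC-fail records excluded, and a minimum aligned
length of 40 bases. "Aligned length" is measured in reference space by
default; a query-space mode exists because some pipelines filter on the
number of aligned query bases instead. No MAPQ cutoff is applied by default
(`min_mapping_quality = 0`), since duplicate-marked, primary-only input is
already the norm; the threshold is exposed for aggressive repeat masking.
Unpaired records are treated as R1 so single-end libraries work unchanged.

## Normalization, smoothing, fold change

Counts are scaled to counts per million (CPM) per replicate using the
whole-library total across all contigs, then summed within each condition
(treated vs mock). The aggregate is smoothed with a 5-bp centered moving
average: sharp cut signal survives averaging over a few bases while
single-read shot noise is diluted. Edges are zero-padded with a constant
divisor `w` — the conservative choice, since it shrinks values toward zero
at contig boundaries rather than inflating them; a shrink-window mode
(`edges = "shrink"`) is available where unbiased edge estimates matter.

The per-position log2 fold change is
`log2((treated + pc) / (mock + pc))` on the smoothed tracks, with a
pseudocount `pc = 0.1` CPM. The value is a deliberate order of magnitude
below the 1.0 CPM summit signal threshold, so the pseudocount can never
manufacture threshold-passing signal out of empty positions; it is recorded
with the results and is CLI-overridable.

## Peak calling

Candidate summits are plateau-tolerant local maxima of the smoothed treated
profile: every position whose value is at least that of both neighbors
(missing neighbors at contig boundaries are treated as satisfied). The
plateau tolerance is deliberate. A moving average of width `w` turns an
isolated single-base spike into an exactly flat `w`-position plateau;
collapsing the plateau to one arbitrary end at this stage (for example,
always its leftmost position, two bases from the true cut) would place the
summit outside the raw-count support window below and silently discard
genuine sites. Instead, all plateau positions are carried forward and the
tie is resolved where the information lives: the raw-count support filter
removes plateau positions remote from the actual read pile-up, and the
merge step keeps the strongest smoothed signal, breaking remaining ties to
the leftmost position.

Each candidate must pass three summit criteria (all inclusive, `>=`):

| criterion | default | units |
|---|---|---|
| smoothed treated signal | 1.0 | CPM |
| log2 fold change | 2.0 | log2 units |
| treated/mock ratio (pseudocount-stabilized, smoothed) | 1.2 | — |

The ratio criterion uses the smoothed values with the same pseudocount as
the fold change, keeping all three criteria on one consistent scale (raw
signal at a single base is noisier than the quantity the other two
criteria are computed from).

Reproducibility is enforced at the raw-count level: at least 2 treated
replicates must each show a maximum raw 5'-end count of at least 5 within
±1 bp of the candidate summit. Surviving summits within 3 bp of each other
(transitively chained) are merged, keeping the position with the highest
smoothed treated signal, ties to the leftmost. Final peaks are 3-bp
half-open intervals centered on the summit, clipped at contig boundaries,
with BED scores `round(100 × log2FC)` capped at 1000. `audit_peaks()`
re-checks every emitted peak against all criteria through an independent
post-hoc path, and is called inside the acceptance workflow.

Two conventions are worth stating because the field uses both: all
threshold comparisons are inclusive ("a minimum of 2" admits exactly 2),
while the optional visualization-style export filter
(`peak_table(min_log2fc_export = 2)`) is strict (`log2fc > 2`), matching
how filtered genome-distribution figures are usually produced. Summit
merging is transitive rather than anchored: a chain 100–103–106 merges into
one cluster although its ends are 6 bp apart. An alternative reproducibility
mode (intersecting independently called per-replicate peak sets) was
considered and rejected as the primary definition because the raw-count
rule is the one stated operationally; the raw-count rule is also strictly
cheaper and monotone in its threshold.

## Motif windows and IUPAC scanning

For motif discovery, ±20 bp windows (41 bases) are extracted around each
final summit; windows crossing a contig boundary are skipped and counted.
De novo discovery itself is delegated to MEME (`meme_command()` records the
ZOOPS, ≤5 motifs, width 5–15, both-strands invocation); what the package
implements is the deterministic part: scanning concrete sequences for a
degenerate IUPAC pattern such as `RAWTSGAAC`. A position matches when every
motif position's IUPAC set contains the sequence base; an `N` in the
*sequence* matches only an `N` in the motif — an ambiguous reference base
is missing data, not a wildcard. Minus-strand hits are found by scanning
the reverse complement and reported at plus-strand offsets. Matching is
delegated to `Biostrings::matchPattern(fixed = "subject")`, which
implements exactly this subset semantics; the test suite checks it against
an independent character-by-character oracle.

## Gene-neighborhood tRNA density

For each genome the analysis pairs two rates: the tRNA gene density
(genes per bp) in the *proximal region* — the focal gene body extended by
1000 bp on each side, clipped to the genome — and the genome-wide density.
Two conventions are deliberate:

* a tRNA belongs to the proximal region if it overlaps it by ≥1 bp
  (`overlap = "within"` available). tRNA genes are ~76 bp against a
  ≥2000 bp region, so the choice is nearly inert, but the permissive rule
  avoids discarding genes that straddle the boundary;
* the gene body is included in the region. A tRNA lying between the
  flanks, inside or overlapping the focal gene itself, is unquestionably
  "proximal", and for genomes whose only nearby tRNAs abut the gene the
  flanks-only definition would force paradoxical zero densities
  (`include_gene_body = FALSE` keeps the flanks-only variant for
  sensitivity analysis).

The paired test is the one-sided Wilcoxon signed-rank test (alternative:
proximal > genome-wide). Zero differences are dropped; `W` is the sum of
ranks of positive differences (midranks for ties), so `W` ranges from 0 to
`n(n+1)/2` and attains the maximum exactly when every difference is
positive. p-values come from `stats::wilcox.test`: exact enumeration of
sign assignments for tie-free `n ≤ 25`, otherwise the normal approximation
with tie and continuity corrections; the tests verify both regimes against
an independent brute-force enumeration.

The confidence interval for the median difference is a nonparametric
bootstrap: 10,000 iterations, each independently resampling the two groups
with replacement at their own sizes and recording the difference of
medians, with the 2.5th/97.5th percentiles (linear-interpolation quantile
rule, R type 7) as the interval. Resampling the groups independently —
rather than resampling pairs — is intentional and matches how the interval
accompanying this statistic is customarily computed for the two marginal
density distributions; it ignores pairing and therefore tends to be
conservative for the paired difference. Resampling is performed on sorted
values so the interval depends only on the empirical distributions, not on
input order, and is deterministic given the seed.

## tRF cleavage mapping

For tRNA-fragment sequencing the 5'-base coverage of uniquely aligned
reads is computed per locus position. "Unique" defaults to primary records
whose read name has no secondary alignment anywhere in the file; a
`MAPQ > 0` mode handles aligners that only signal multimapping through
mapping quality. The cleavage call compares two conditions (defense system
present vs absent) through a per-position ratio. Libraries routinely differ
in depth, so each condition is depth-normalized before the ratio: the
pseudocount (default 1 count) is added on the raw-count scale and the
result scaled by the condition's library size,
`(count + pc) / library_size × 1e6`. A raw-count mode (`scale = "raw"`)
exists for matched-depth comparisons. The call is the argmax of the ratio
track (all tied positions reported), only reported when the peak ratio
reaches `min_ratio` (default 2) so that identical coverage never produces
a call.

## The synthetic-data generator

Every stage can be exercised without external data:

* `simulate_genome()` draws i.i.d. bases at a chosen GC fraction (default
  0.35, typical of T-even phage genomes) and can plant concrete,
  non-overlapping resolutions of a degenerate motif at recorded positions.
* `simulate_site_seq()` writes sorted, indexed BAM files per replicate:
  background reads with uniformly placed 5' ends on random strands at a
  Poisson rate per bp, plus — in treated replicates only — Poisson numbers
  of reads whose 5' end lies exactly at each planted cut. Every record is a
  primary, mapped, R1-flagged alignment of constant reference-consumed
  length; reads that would run past the contig end are re-drawn. The
  simulator returns its internal 5'-end tally, and the test suite requires
  `extract_r1_ends()` to reproduce it exactly (writer/reader identity).
* `simulate_neighborhood()` places tRNA genes by a Poisson process at a
  background rate genome-wide and at `background × enrichment` inside the
  focal gene's ±flank region.
* `simulate_trf()` draws a shared Poisson background for both conditions
  and adds a condition-specific spike at the planted cleavage position.

All simulators are bit-reproducible given their seed and restore the
caller's RNG state.

The standard study conditions used throughout the tests and the acceptance
script are: a 50-kb single-contig genome; 12 planted cut sites with
expected treated excess 20 reads per replicate; 3 treated and 3 mock
replicates; background 0.02 ends/bp/replicate; 100-base reads. Sites are
placed evenly with a 1.5-kb margin so that peaks are never edge-clipped
and never merge with each other. The neighborhood cohort uses 296 genomes
(~60 ± 15 kb), background 1e-4 tRNA genes/bp, a 700-bp focal gene, and
76-bp tRNAs; bootstrap calibration uses 200 replications of 10,000
iterations each at group size 50.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing errors and base qualities, adapter
artifacts, duplicate reads (input is modeled as already duplicate-marked),
staggered two-strand cut offsets (available as an option but off by
default), overdispersed (non-Poisson) backgrounds, mappability and GC
biases, base-modification effects on library preparation, and genuinely
clustered cut sites closer than the merge distance. On real libraries,
depth is millions of reads rather than thousands, which makes the CPM
thresholds *more* selective than in the simulations (a single stray read
is worth far less than 1 CPM).

## Degenerate inputs and numerical conventions

* Empty alignment files produce all-zero tracks with a warning;
  CPM-normalizing a zero-library track is an error ("empty replicate").
* Windows crossing contig boundaries are skipped (motif stage) or clipped
  with a warning (peak emission).
* The Wilcoxon test refuses inputs with no nonzero difference;
  `neighborhood_table()` additionally declines the test (with a message)
  when fewer than two nonzero differences exist, while still returning the
  density table.
* Bootstrap and simulators take explicit integer seeds; nothing in the
  package draws from an unseeded stream.
* All intervals are 0-based half-open throughout; BED and bedGraph output
  follow their standard conventions via `rtracklayer`.

## Known limitations

The peak caller is threshold-based by design — it reports no false
discovery rate and fits no background model, so threshold choices must be
justified per experiment. Contigs are treated as linear (no wraparound for
circular genomes; a cut spanning the origin would appear as two
half-signals). The replicate-support rule assumes treated replicates of
broadly comparable depth, since it operates on raw counts. The neighborhood
statistic treats genomes as independent observations; phylogenetic
relatedness between genomes is not modeled and can inflate significance
when many near-identical genomes are included.
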