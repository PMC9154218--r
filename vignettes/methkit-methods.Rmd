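---
title: "methkit: models and methods for per-read modified-base analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methkit: models and methods for per-read modified-base analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methkit)
```

## The problem

Nanopore sequencing reads carry, alongside their base sequence, per-base
modification evidence produced by a modified-base caller: for every
modifiable base the caller emits a probability that the base is modified
(5mC in CpG context being the canonical case, but 5hmC, 6mA from
footprinting assays such as DamID, SMAC-seq and NOMe-seq, and GpC
methylation are handled identically). methkit consolidates the downstream
work: importing those calls from the two families of on-disk
representations, putting them on a single score scale, classifying them,
aggregating them across genomic structures, and drawing the standard
figures (score distributions, segment distributions, locus and region
profiles, repeat-family composites).

## Score model and classification

All importers normalize to one score: the natural-log likelihood ratio

$$\mathrm{LLR} = \ln\frac{P(\text{modified})}{P(\text{unmodified})} =
\ln\frac{p}{1-p}.$$

Probabilities are clamped to $[10^{-6}, 1-10^{-6}]$ before the log so
scores are always finite; megalodon's paired log-probabilities enter as
`mod_log_prob - can_log_prob` (already an LLR) and nanopolish scores are
used as-is. SAM `ML` bytes encode the probability interval
$[b/256, (b+1)/256)$ and are decoded to the interval midpoint
$(b+0.5)/256$.

Classification is a two-sided cutoff rule: `score >= hi` is MOD,
`score <= lo` is UNMOD, the band in between is AMBIG and is excluded from
every methylation fraction (numerator and denominator) while still being
counted and drawn in raw panels. The default cutoffs are $\pm 2$ on the LLR
scale — the widely used nanopolish convention, corresponding to roughly
$p > 0.88$ / $p < 0.12$ — and can be changed per sample at any time with
`adjust_cutoffs()`, which re-derives every stored call's class;
MOD + UNMOD + AMBIG always equals the stored total.

## MM/ML decoding and coordinates

`MM` sub-tags encode modified positions as skip counts over the canonical
base *in the read's original sequencing orientation*; for reverse-strand
alignments the stored SEQ is the reverse complement of what was sequenced,
so decoding walks the reverse complement and maps back to stored
coordinates before lifting through the CIGAR to the reference. Bases in
insertions or soft clips have no reference coordinate and are dropped.
Sub-tags for other canonical bases or modification codes are skipped while
keeping the `ML` byte array in register (multi-code sub-tags interleave
their bytes per position). `?`-flagged and unflagged sub-tags are treated
identically: a skipped canonical base yields *no* call rather than an
implicit unmodified call, which would fabricate scores.

Coordinates are 0-based half-open everywhere internally; BED I/O is native,
bedMethyl output is 0-based, DSS output and the nanopolish input dialect
are converted at the boundary (1-based). For the palindromic CpG motif,
minus-strand calls are collapsed onto the plus-strand C (`pos - 1`) so both
strands aggregate to one site; asymmetric motifs (e.g. GATC 6mA) keep
strands separate.

## Aggregation

`segmeth()` counts calls per (segment, sample) under the half-open overlap
rule and reports `meth_fraction = n_mod / (n_mod + n_unmod)` (NA when no
classified calls). Fractions are per-call, not per-read averages, matching
bedMethyl semantics. `wgmeth_binned()` tiles a chromosome with fixed-size
bins (the last, partial bin is kept and flagged), counts motif occurrences
per bin from the reference, and masks bins with zero motif sites. Because
the field is not settled on whether bin profiles should be normalized by
motif count or by call count, both are exposed: `meth_fraction` (over
classified calls — what the plots show) and `call_density`
(classified calls per motif site).

## Motif space and smoothing

Locus profiles work in *motif space*: the ordered list of motif-site
positions in the window (`find_motif_sites()`, IUPAC-aware, overlapping
matches included) defines a rank for every site, and
`genome_to_motifspace()` is the exact, order-preserving translation. The
smoothed profile at rank $r$ pools the classified calls of all ranks in a
centered window of `smooth_window` sites (default 21, odd only, truncated
at the edges):

$$\hat f(r) = \frac{\sum_{|r'-r| \le w/2} n_\mathrm{mod}(r')}
  {\sum_{|r'-r| \le w/2} n_\mathrm{mod}(r') + n_\mathrm{unmod}(r')}.$$

Pooling calls rather than averaging per-site fractions was a deliberate
choice: at low coverage per-site fractions are noisy 0/1 values and an
average over them weights a 1x site equally with a 30x site. With exactly
one classified call per site the two definitions coincide. A uniform
(boxcar) kernel over motif ranks is used rather than a genomic-distance
kernel because the profile is plotted in motif space, where site density is
constant by construction. NOCALL (site not covered by the read) and AMBIG
(covered, score in the ambiguous band) are distinct states; both are
excluded from fractions, but AMBIG calls are still drawn in the raw panel.

Locus mode is recommended below ~1 Mb (a warning is issued above);
`build_region_data()` covers larger windows by delegating to the binned
aggregator and smoothing over unmasked bins (default window 5 bins).

## Repeat-family composites

`composite_profile()` extracts each element of a repeat family from the
reference (reverse-complementing minus-strand elements), aligns it to the
user-supplied consensus, and lifts calls through the alignment so all
copies share consensus orientation. The alignment is affine-gap
(match +2, mismatch −3, gap open −5, gap extend −2; a length-$k$ gap costs
$5 + 2k$), global in the element and ends-free in the consensus so that
truncated elements — the rule rather than the exception for LINE-type
retrotransposons, which are mostly 5′-truncated — align to the consensus
sub-interval they derive from without overhang penalties. Elements whose
identity (matches / aligned columns) falls below `min_identity` (default
0.6) are excluded as likely misassignments. Gap columns are unmapped, so a
copy with a deletion over a consensus CpG simply contributes nothing
there. Strand-collapsed CpG calls on minus-strand elements are shifted by
one base during lifting, because the collapsed plus-strand C is the
*other*-strand scored base from the element's point of view.

Pooled counts per consensus position sum the lifted classified calls over
all elements; calls landing on consensus columns that are not consensus
motif sites (mutated motifs in individual copies) are pooled but flagged
`at_motif = FALSE` so they can be excluded from motif-axis summaries. The
`max_elements` individual tracks shown are those with the highest
classified-call coverage, tie-broken deterministically by (chrom, start).
When one read spans two tandem copies its calls are assigned by element
interval, i.e. each copy receives the calls falling inside it.

## Synthetic data: what it emulates, and what it does not

The generator (`sim_config()`, `simulate_reference()`, `simulate_reads()`)
produces the full input surface with known truth: a random reference
(default 20 kb, GC 0.5), optionally with planted repeat copies (mutated,
partly 5′-truncated, random strands), and MM/ML-tagged aligned reads
(default depth 20, 3 kb reads, half on the reverse strand). Site
modification states are independent Bernoulli draws at the site's true
probability — background 0.8 with an unmethylated island at 0.1 by
default, and a phased interval at 0.9/0.1 for the two haplotypes in phased
configs, values chosen to resemble a hypermethylated genome with a CpG
island and an imprinted-style allele-specific region. Per-call scores are
drawn from the state-conditional model LLR ~ N(+4, 1.5) for modified and
N(−4, 1.5) for unmodified calls, reproducing the bimodal score shape real
callers produce; at the default ±2 cutoffs about 9% of calls fall in the
ambiguous band symmetrically, so fraction estimates are unbiased.

What the generator does *not* emulate: correlated methylation of
neighbouring CpGs, read-level methylation haplotypes beyond the HP effect,
basecalling errors (substitutions), reference bias, mapping ambiguity, or
caller-specific score artefacts. Passing the parameter-recovery suite
therefore demonstrates that the import → classify → aggregate chain is
correct and unbiased under the stated model; it does not validate any
particular caller's accuracy on real signal data. The indel error mode
(`indel_rate > 0`) exists specifically to exercise CIGAR lifting, not to
model real error processes.

## Numerical and design choices

* **Probability clamping** at $10^{-6}$ bounds scores at about ±13.8,
  well outside any sensible cutoff.
* **KDE**: Scott's rule bandwidth, 512-point grid spanning the data range
  ±3 bandwidths; nearly-constant score sets (zero IQR) fall back to a
  positive bandwidth so the estimate still normalizes. The trapezoidal
  integral over the grid is 1 within $10^{-3}$.
* **Duplicate calls** (same read, sample, site, modification code) resolve
  last-import-wins with a warning.
* **Alignment tie-breaks**: when several alignments attain the optimal
  score the mapping returned is the aligner's canonical traceback; tests
  therefore verify that the returned mapping *attains* the independently
  computed optimal score rather than comparing tracebacks, which are not
  unique.
* **Read stacking** in locus plots is greedy first-fit by alignment start
  (purely aesthetic).
* **Guppy dialect**: guppy's per-read output has shipped in several
  tabular layouts, so the `guppy` dialect is a preset column specification
  (`read_id, chrom, strand, pos, prob_mod`) over the same engine as
  `custom`, and any layout can be described with `column_spec`.
* **Problem sizes** used by the shipped validation suites — 1000-read
  decoder cross-checks, 200-replicate parameter recovery at 1.5 kb / depth
  8, 500 alignment pairs up to 30 bp — were chosen as the smallest sizes
  at which the binomial error bounds are meaningfully tight.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11, ref_length = 8000, depth = 12,
                  read_length = 1500)
simref <- simulate_reference(cfg)
sim <- simulate_reads(cfg, simref, out_dir = tempdir())
st <- import_bam_modcalls(sim$bam, sample = "demo")
st
segmeth(st, data.frame(chrom = "chrS",
                       start = c(0, 2000, 4000),
                       end = c(2000, 4000, 8000),
                       name = c("bg1", "island", "bg2")),
        reference = simref$reference)
```

The recovered `meth_fraction` values track the generator's true
probabilities (0.8 outside the island, 0.1 inside) within binomial error
at the realized coverages.

## Known limitations

* The store is held in memory; whole-genome human-scale call sets are out
  of reach without chunked import (per-chromosome stores are the intended
  workaround).
* Phasing is consumed (HP/PS tags), never computed.
* For asymmetric motifs scanned on the reverse strand, truth tables in the
  simulator cover plus-strand sites only; simulate with
  `frac_reverse = 0` for such motifs.
* Differential methylation is delegated to DSS via its input writer; no
  testing is performed here.
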