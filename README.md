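# methkit

Processing, aggregation and visualization of per-read modified-base calls
from nanopore sequencing.

Nanopore modified-base callers attach per-base modification probabilities to
reads, either as SAM `MM`/`ML` tags in the BAM itself or as tabular per-read
call files (megalodon, nanopolish, guppy, or any "read, position,
probability" table). methkit is the downstream toolkit for people working
with those calls — methylome analysts, chromatin-footprinting users
(6mA/GpC assays), and anyone studying allele-specific or repeat-element
methylation. It imports everything onto one score scale, classifies calls,
aggregates them over genomic structures, exports standard formats, and
draws the standard figures.

## The model in brief

Every call carries a log likelihood ratio

```
LLR = ln( P(modified) / P(unmodified) ) = ln( p / (1 - p) )
```

(ML bytes decode to `p = (b + 0.5)/256`). A two-sided cutoff rule
classifies calls: `LLR >= hi` → MOD, `LLR <= lo` → UNMOD (defaults ±2),
with the in-between band AMBIG and excluded from every methylation
fraction `n_mod / (n_mod + n_unmod)`. On top of that sit:

* **segment aggregation** (`segmeth`) over BED intervals, with per-segment
  counts, motif-site totals and fractions;
* **motif-space locus profiles** (`build_locus_data`): per-read call
  matrices over CpG (or any motif) site ranks, haplotype splitting from
  HP/PS tags, raw score tracks and pooled sliding-window smoothing;
* **motif-normalized bins** (`wgmeth_binned`, `build_region_data`) for
  chromosome-scale profiles;
* **repeat-family composites** (`composite_profile`): each element copy is
  aligned to a consensus (affine gaps, consensus ends free so truncated
  copies align where they belong) and its calls are lifted into consensus
  coordinates and pooled;
* **exports**: bedMethyl (BED9+2) and DSS input tables (`chr pos N X`);
* **plots**: score distributions with cutoff lines, strip/violin/ridge
  segment plots, multi-panel locus figures
  (genes / reads / motif-space translation / raw / smoothed), region and
  composite figures;
* a **synthetic-data generator** (`sim_config`, `simulate_reference`,
  `simulate_reads`) producing references, repeat families and MM/ML-tagged
  BAMs with known per-site truth, so the whole chain is testable offline.

## Worked example

```r
library(methkit)

cfg    <- sim_config(seed = 11, ref_length = 8000, depth = 12,
                     read_length = 1500)
simref <- simulate_reference(cfg)          # 8 kb reference, island at 2-4 kb
sim    <- simulate_reads(cfg, simref, out_dir = tempdir())
st     <- import_bam_modcalls(sim$bam, sample = "demo")
st
#> CallStore: 5870 calls, 1 sample(s), 1 sequence(s)
#>   demo [lo=-2 hi=2]: MOD=2996 UNMOD=2328 AMBIG=546

segmeth(st, data.frame(chrom = "chrS",
                       start = c(0, 2000, 4000),
                       end   = c(2000, 4000, 8000),
                       name  = c("bg1", "island", "bg2")),
        reference = simref$reference)
#>    chrom start   end   name ... n_mod n_unmod n_ambig n_reads n_motif_sites meth_fraction
#> 1:  chrS     0  2000    bg1 ...   684     149      86      22           118    0.82112845
#> 2:  chrS  2000  4000 island ...   172    1683     178      32           131    0.09272237
#> 3:  chrS  4000  8000    bg2 ...  2140     496     282      39           238    0.81183612
```

The generator placed an unmethylated island (true p = 0.1) at 2-4 kb in a
p = 0.8 background; the recovered fractions (0.82 / 0.093 / 0.81) track the
truth within binomial error at the realized coverages. `plot_locus()`,
`plot_region()` and friends render these same structures to figures.

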