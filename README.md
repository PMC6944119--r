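# repscout

Discovery, characterization and insertion dating of **genome-specific
composite repeats** — repetitive elements present in one genome of a
closely related pair and absent from the other.

The motivating system is the cotton (*Gossypium*) D genome, which carries
a composite element the A genome lacks: a tandem-repeat (TR) array of
~133 bp units repeated a variable number of times (2–21, exceptionally
more), adjacent to a stable ~860 bp conserved sequence (CS), the whole
motif harboured inside degraded LTR retrotransposons. Because the motif
marks every D-subgenome chromosome and no A-subgenome chromosome, it is
also a practical subgenome diagnostic for allotetraploid assemblies: a
motif call on an "A" chromosome flags a likely misassigned segment.

The package is aimed at repeat/TE biologists and genome-assembly QC. It
provides, as ordinary R functions returning tibbles:

* **Homology search** — bespoke seed-and-extend local alignment
  (`search_genome()`) with the inclusive **80–80 rule**
  (identity ≥ 0.80 *and* query coverage ≥ 0.80, `passes_80_80()`) and a
  presence/absence screen across two genomes
  (`screen_genome_specific()`).
* **Tandem repeats** — array detection by lag autocorrelation
  (`detect_arrays()`), unit-consensus training
  (`train_unit_consensus()`), self-similarity dot plots.
* **Motif model** — constituent scanning and greedy TR–CS pairing into
  composite motifs (`scan_constituents()`, `pair_constituents()`,
  `call_motifs()`), consensus-accumulation profiling of host elements
  (`consensus_accumulation()`, `plateau_region()`).
* **LTR dating** — paired-LTR detection (`detect_ltr_pairs()`), Kimura
  two-parameter distance
  `d = -1/2 ln[(1 - 2P - Q) sqrt(1 - 2Q)]` (`k2p_distance()`), insertion
  age `T = d / 2r` at `r = 1.3e-8` subs/site/year (`insertion_time()`),
  and 80–80 family clustering (`cluster_families()`).
* **Genome statistics** — χ² test of length-proportional chromosomal
  distribution (`chi_square_uniformity()`, with broom-style `tidy()` /
  `glance()`), 500 kb window density tracks (`window_density()`),
  synteny-block chaining that localizes element loss
  (`find_synteny_blocks()`), and a per-chromosome presence report
  (`subgenome_presence_report()`).
* **Synthetic data** — a fully ground-truthed simulator of a
  D-like/A-like genome pair with planted motifs, solitary constituents
  and aged host elements (`simulate_genome_pair()`,
  `build_motif_element()`, `mutate_k2p()`, `make_tetraploid()`), so the
  whole pipeline is testable offline.
* **Pipeline** — `run_pipeline()` sequences simulate → screen → scan →
  date → stats → report with a checksummed output manifest; a thin CLI
  with the same stages as subcommands lives at `inst/cli/repscout.R`.

Intervals are 0-based half-open internally; GFF3 output is 1-based
inclusive. Standard formats go through Biostrings/rtracklayer.

## Worked example

Simulate a small genome pair, screen for genome specificity, call motifs,
date the host elements and test the chromosomal distribution:

```r
library(repscout)

cfg <- simulation_config(n_chromosomes = 4, chromosome_lengths = 5e5,
                         n_motifs = 10, n_lone_tr = 3, n_lone_cs = 3)
sim <- simulate_genome_pair(cfg, seed = 42)
def <- motif_definition(sim$templates$unit, sim$templates$cs)

screen_genome_specific(
  c(tandem_unit = def$unit_consensus, conserved_seq = def$cs_consensus),
  sim$d_genome, sim$a_genome)
#>           query loci_present_genome loci_absent_genome    class
#> 1   tandem_unit                  21                  0 specific
#> 2 conserved_seq                  13                  0 specific
```

Both constituents repeat across the D-like genome (21 and 13 merged loci)
and never pass the 80–80 screen on the A-like genome — the
presence/absence contrast at sequence level.

```r
calls <- call_motifs(sim$d_genome, def)
table(calls$kind)
#> lone_CS lone_TR   motif
#>       3       3      10

calls[calls$kind == "motif",
      c("chrom", "start", "end", "strand", "unit_count", "gap")]
#>   chrom  start    end strand unit_count   gap
#> 1 chr01  39662  42659 -              16     9
#> 2 chr01 182348 183617 +               3    10
#> 3 chr01 219722 220996 -               3    15
#> # ... 7 more rows
```

All 10 planted motifs are recovered as paired TR+CS instances (with their
unit counts and inter-constituent gaps); the 3 + 3 solitary constituents
stay unpaired. Dating the paired-LTR hosts and testing the distribution:

```r
mot <- calls[calls$kind == "motif", ]
cand <- tibble::tibble(chrom = mot$chrom,
                       start = pmax(0, mot$start - 2500),
                       end = pmin(5e5, mot$end + 2500))
pairs <- detect_ltr_pairs(sim$d_genome, cand,
                          dating_config(ltr_similarity_floor = 0.45))
round(pairs$T_years[pairs$paired] / 1e6, 1)
#> [1] 18.7 18.1 11.7
```

Three hosts still carry a datable LTR pair (the simulator degrades one
LTR on ~2/3 of elements, as observed in the real system); their estimated
insertion ages are in million years.

```r
tr_like <- calls[calls$kind %in% c("motif", "lone_TR"), ]
counts <- chromosomes(sim$d_genome)
counts$observed <- vapply(counts$chrom,
                          function(cc) sum(tr_like$chrom == cc), integer(1))
chi_square_uniformity(counts)
#> Chi-square test of length-proportional distribution
#>   chi2 = 7.867 (df = 3, P > 0.01; p = 0.04885), N = 13 insertions on 4 chromosomes
#>   note: some expected counts < 5; chi-square approximation is rough
```

`autoplot()` methods exist for the uniformity test, consensus histograms,
activity-date histograms and self-similarity matrices; `run_pipeline()`
executes all stages in one call and writes
FASTA/GFF3/TSV/bedGraph/JSON outputs with an MD5 manifest.

## Method notes

See the methods vignette (`vignettes/methods.Rmd`) for the models and
assumptions, the tunable parameters and their defaults, what the
simulator does and does not emulate, and the numerical choices (among
them: why insertion dating re-estimates LTR boundaries by a
rolling-identity changepoint instead of trusting the maximal-scoring
local alignment, which underestimates the divergence of old elements).
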