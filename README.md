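# spaceracq

Analysis and simulation of CRISPR spacer-acquisition amplicon sequencing
for the *E. coli* type I-E system, plus a designer for terminator-based
unit-sized crRNA expression cassettes.

## What problem this solves, and for whom

Spacer acquisition (CRISPR adaptation) is read out by PCR-amplifying the
leader-proximal end of expanded CRISPR arrays and sequencing the
amplicons. Each informative read is
`leader + repeat + new spacer + repeat + pre-existing spacer + tail`.
This package is for researchers analysing such libraries: it extracts new
spacers from reads, maps them onto the circular donor plasmid, classifies
them by PAM and strand, and summarises per-sample acquisition statistics.

The statistics at its core, for mapped spacers of a sample:

- **raw AAG-PAM preference** — fraction of spacers whose protospacer is
  flanked 5' by the AAG PAM (`direct`); during primed adaptation this is
  ~90–94%, versus ~50% for naive adaptation;
- **derived-spacer fraction** — spacers from a correctly recognised AAG
  protospacer but excised **shifted** by k ∈ ±1..±5 nt (so the spacer's
  own PAM is no longer AAG) or inserted **inverted** (so it maps to the
  other strand);
- **reclassified preference** — derived spacers credited to their AAG
  parent protospacer; by the label partition,
  `reclassified − raw = derived fraction` exactly;
- **displaced-strand bias** — fraction of spacers drawn from the strand
  displaced in the R-loop at the priming protospacer (~90% for an intact
  primed system);
- **per-protospacer usage** — counts per donor locus; hotspot landscapes
  are compared between samples by Pearson correlation.

Because no public raw data exists for this assay, the package also ships
a synthetic-read generator whose packaged sample profiles encode the
study conditions (primed profiles `kd263`, `kd390`, `h20a`, `dcas6e` and
a `naive` control); the analysis chain is validated by parameter
recovery: simulate at a profile, run the pipeline blind, and compare the
recovered statistics with the profile's values.

A separate module designs single-guide expression cassettes:
`promoter + 7-nt 5' handle + 33-nt spacer + 29-nt repeat + (T)8`, where
the repeat hairpin plus U-tract acts as an intrinsic transcription
terminator and the mature crRNA species is 7 + 33 + 21 = 61 nt.

## Worked example

```r
library(spaceracq)

plasmid <- make_plasmid(3000, seed = 1)          # circular donor, AAG-flanked priming protospacer
profile <- spaceracq_profile("kd263")            # intact primed system
profile$n_events <- 4000L

sim        <- simulate_sample(plasmid, profile)  # reads + ground truth
calls      <- call_spacers(sim$reads)            # quality filter, repeat scan, 33-nt inserts
classified <- classify_spacers(calls, plasmid)   # exact mapping, PAM/strand/derived classes
report     <- summarize_adaptation(classified, "kd263")
report
```

```
<spacer_calls>
  reads: 4000 | pass quality: 4000 | >=2 repeats: 4000 | calls: 4000
<adaptation_report> kd263
  calls: 4000 (mapped: 4000, ambiguous: 0)
  AAG PAM preference: raw 94.3%, reclassified 98.4%
  derived spacers: 4.1% | displaced-strand bias: 89.4%
```

Reading the numbers: the profile recognises AAG protospacers in 98% of
events and emits ~4% of those as derived spacers, so the pipeline should
recover a raw preference near 0.98 × (1 − 0.0398) ≈ 94%, a reclassified
preference near 98% and a strand bias near 90% — which it does, within
binomial noise at n = 4000. `glance(report)` returns the same numbers as
a one-row tibble, `tidy(report)` the per-locus usage table, and
`autoplot(report)` a strand-split usage track. Two reports are compared
with `usage_correlation(a, b)`.

Designing guides against a genome:

```r
designs <- design_crrnas(genome_string)   # every AAG-flanked 33-nt window, both strands
designs[1, c("start1", "end1", "strand", "mature_len", "stem_len", "terminator_pass")]
write_constructs_fasta(designs, "constructs.fa")
```

Every construct has a 61-nt mature species under the defaults, and
`check_terminator()` verifies the repeat hairpin (6-bp stem in the
*E. coli* repeat) and the U-tract.

A command-line wrapper for shell use is installed at
`system.file("exec", "spaceracq", package = "spaceracq")` with
`simulate`, `call`, `classify`, `report`, `compare` and `design`
subcommands; run it with `Rscript` and `--help` style options as
documented in its header.

## Package layout

- `R/sequence-io.R` — FASTQ/FASTA/BED6 IO, reverse complement, circular
  slicing, Hamming utilities
- `R/simulate.R`, `R/profiles.R` — donor plasmid, acquisition events,
  read rendering, sample profiles (`inst/extdata/profiles/*.yaml`)
- `R/spacer-calling.R` — quality filter, repeat scan, insert extraction
- `R/mapping.R` — exact circular mapping, PAM extraction, derived-spacer
  classification, strand classes
- `R/stats.R` — adaptation reports, usage correlation, EOP/EOT helpers
- `R/designer.R` — PAM-flanked target search, cassette assembly,
  terminator check
- `vignettes/spacer-acquisition.Rmd` — models, assumptions, parameter
  choices and limitations
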