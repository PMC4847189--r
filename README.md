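# satcen

Which satellite DNA family of a genome actually carries the centromere?
Most mammalian centromeres sit on megabase arrays of tandemly repeated
satellite DNA, but cytogenetic colocalisation alone cannot tell which of
several intermingled repeat families is bound by CENP-A, the
centromere-specific histone H3 variant that marks functional centromeric
chromatin. `satcen` implements the sequencing-and-imaging analysis used to
answer that question in the horse system, where three satellite families
(a GC-rich 221-bp-unit family here called *satEC*, plus two pericentromeric
families) compete for the title: mismatch-tolerant read mapping against a
panel of repeat consensus sequences, normalised ChIP/input enrichment
ratios, consensus/logo derivation, tandem-structure analysis, stringent
peak filtering, satellite transcription counting, and quantification of
slot-blot and chromatin-fibre immuno-FISH signals. A seeded simulator
generates every input with known ground truth, so the whole pipeline is
testable without any external data.

It is aimed at people analysing ChIP-seq of highly repetitive loci that are
absent from, or collapsed in, the reference assembly — the situation in
which per-locus peak calling fails and per-family read accounting is the
informative statistic.

## The statistics at the core

**Percent-identity best-hit mapping.** Each read is placed at its
best-scoring position across all panel entries, both strands, every offset
(an exact bit-parallel scan, not a heuristic), and reported when

    identity = matching positions / read length >= 0.80

mirroring a RazerS-style 20 % mismatch allowance. Tandem entries are
scanned on a head-to-tail **dimer** of their monomer so reads spanning the
junction between adjacent monomer copies align end to end; offsets are
reported modulo the monomer length.

**Enrichment.** Per family, counts are normalised by sample depth and
reference length,

    normalized = raw / (total_reads x ref_length) x 1e9
    ratio      = normalized_IP / normalized_input

so `ratio = 1` means a family is equally represented in immunoprecipitated
and input chromatin, and the CENP-A-bound family stands out directly.

**Consensus and logo.** Aligned read bases are accumulated per monomer
position into a 4 x L base-frequency matrix; the consensus is the
per-position majority base and the information content is `2 - H` bits
(Shannon entropy of the column frequencies).

**Structure and imaging.** The repeat unit length is the smallest lag
maximising the sequence's self-match fraction; enriched regions are
classified by the majority family of monomer-sized windows; peaks survive
only if fold enrichment > 5, pile-up > 100, −log10 p > 100 and
−log10 q > 100 (all strict); fibre line profiles are segmented at
median + 3·MAD per channel and classified as pattern I (CENP-A covers the
satellite stretch), II (CENP-A in blocks) or III (no CENP-A).

## Worked example

```r
library(satcen)

cfg <- demo_config(seed = 2)          # ~46 kb toy genome, 60k reads/channel
res <- run_pipeline(cfg, "demo_run", quiet = TRUE)

res$enrichment[, c("entry", "raw_ip", "raw_input", "ratio")]
#>      entry raw_ip raw_input     ratio
#> 1    satEC  39039      6058 6.4442060
#> 2   sat2P1   2237      5936 0.3768531
#> 3 satEC137    706      1791 0.3941932
#> 4     ERE1    686      1717 0.3995341

round(res$gc_percent, 1)
#> [1] 52.9

res$fibre_summary
#>   class count percent percent_exact
#> 1     I    15      60            60
#> 2    II     7      28            28
#> 3   III     3      12            12
```

The simulated CENP-A-bound family (`satEC`, configured to a 6.5-fold
expected enrichment) is recovered at 6.44; the other satellites are
depleted in the IP fraction. The consensus recovered from the mapped IP
reads has the satellite's GC content, and the 25 simulated chromatin
fibres classify to the three binding patterns at 60 % / 28 % / 12 %. All
tables, the run manifest (seed, config snapshot, per-file checksums) and
the FASTQ/FASTA/TSV stage outputs are in `demo_run/`. In this small demo
genome the satellite occupies a third of the sequence, which deflates the
unbound families' ratios below 1; at the default full-size configuration
(1.6 Mb background, satellite under 1 % of the genome, as in a real
genome) an unbound interspersed element recovers a ratio near 1.

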