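---
title: "Methods and design notes for satcen"
author: "satcen authors"
output: html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`satcen` asks which satellite DNA family of a genome is bound by CENP-A,
the histone H3 variant that defines functional centromeric chromatin. The
question cannot be answered by ordinary peak calling because centromeric
satellites are mostly absent from, or collapsed in, reference assemblies;
the informative statistic is instead a per-repeat-family accounting of
ChIP and input reads against a small panel of consensus sequences. This
vignette records the models, the tunable parameters, and the design
decisions that were genuinely open, in enough detail that a maintainer can
revisit any of them.

## Read mapping to a repeat panel

Reads are aligned to each panel entry at every offset, on both strands,
and scored by substitution-only identity: `identity = matches / read
length`. A read is reported at its best placement if identity reaches
`min_identity` (default **0.80**, i.e. a 20 % mismatch allowance, the
convention of RazerS-style percent-identity mappers). `N` never matches.

Two decisions deserve explanation.

* **Tandem entries are mapped against their dimer.** A read sampled from a
  head-to-tail array can straddle the junction between two monomer copies;
  on the monomer alone such reads have no full-length placement, biasing
  counts downward by roughly `read_length / monomer_length`. Concatenating
  the monomer with itself removes the blind spot: every read from an
  infinite tandem array has an exact placement on the dimer (a property
  the test suite asserts). Offsets on the dimer's second copy duplicate
  offsets on the first, so the scan is restricted to offsets
  `[0, monomer_length)` and reported offsets are already canonical
  monomer offsets. Reference lengths used for normalisation are monomer
  lengths — the dimer is a mapping artifice only.
* **The scan is exact, not seeded.** A k-mer-seeded candidate search was
  considered and rejected: with a 20 % mismatch budget over a 100-bp read,
  no practical seed length guarantees a surviving exact seed (pigeonhole
  requires 4-mers, which filter nothing), so any seeding heuristic would
  differ from the exhaustive answer on adversarial reads. Instead the
  all-offset Hamming scan is made fast by bit-parallelism: sequences are
  packed into per-base bit planes and a 64-position block of mismatches is
  one XOR/OR/popcount, with early abandonment once the running mismatch
  count exceeds the current best. The mapper therefore *equals* the
  brute-force oracle by construction, and the suite verifies this on
  mixed read sets.

Ties are resolved deterministically: best identity first; across entries,
the earliest panel entry wins and the read is flagged `ambiguous`; within
an entry, the smallest offset; at the same offset, the plus strand. Each
read contributes to exactly one entry; the ambiguous count is exposed so
users can exclude those reads. An optional `allow_indels` mode scores with
semi-global edit distance for panels where indel divergence matters; the
default is substitution-only because it has an exact, fast oracle and the
satellite families involved diverge mainly by substitution.

## Enrichment

Counts are normalised by sample depth and reference length,
`raw / (total_reads * ref_length) * 1e9`. The `1e9` constant (a
reads-per-billion, RPKM-like scale) is cosmetic — IP/input ratios are
scale-free, which the suite asserts exactly — and merely keeps tabulated
values readable. Ratios with a zero input count are reported as a flagged
`NA`, never as a sentinel number. RNA-seq counting deliberately skips
normalisation: all transcript windows share one length (default 442 bp,
twice a 221-bp satellite monomer, so the satellite's dimer is itself a
valid window) and raw counts are directly comparable.

One honest subtlety found during testing: at the permissive 0.80 identity
floor, reads overhanging a satellite array edge can still be placed on the
dimer (the trailing bases land on dimer sequence and match ~25 % by
chance) while a 442-bp gene window offers no such room, inflating
satellite counts by a few percent. This is inherent to the dimer design,
affects IP and input symmetrically (so enrichment ratios are unbiased),
and vanishes at a strict identity floor — the RNA linearity test uses 0.95
for that reason.

## Synthetic data: what it emulates and what it does not

No sequencing data accession accompanies the study this analysis follows,
so the simulator is a first-class module whose defaults define the study
conditions. It generates a toy genome of head-to-tail tandem arrays
(monomer copies independently mutated at `monomer_divergence`, default
2 %, reflecting highly conserved satellite units), scattered interspersed
elements, transcribed 442-bp gene windows, and random background; reads
are fixed-length (100 bp — the study does not state read length) with
i.i.d. substitution errors (1 %) and constant quality strings.

The IP channel uses a **two-state weight model**: input samples start
positions uniformly; IP samples them with weight `1 + alpha * occupancy`.
No generative model is given in the source study, so `alpha` is a free
parameter with a closed-form consequence: the expected normalised ratio of
family *f* is

    ratio_f = (1 + alpha * o_f) * L_tot / sum_g L_g (1 + alpha * o_g)

which `alpha_for_ratio()` inverts. Two properties of this model matter for
interpretation. First, a family cannot be enriched beyond
`L_tot / L_f` — the default genome therefore keeps the bound satellite at
~0.8 % of a 1.6-Mb background so the whole grid {1, 2, 6.5, 10} is
feasible. Second, enrichment of the bound family necessarily depletes
everything else by the factor `L_tot / (L_tot + alpha * sum L o)`; at that
satellite fraction the factor is ~0.95, which is why an unbound
interspersed element recovers a ratio *near* (not exactly) 1, matching the
qualitative "equally represented" observation. The interspersed element is
kept high-copy (60 copies, as a genome-wide retrotransposon family is)
so its count-based ratio estimate has a ~3 % standard error at 200k reads.
The demo configuration trades this realism for speed (satellite ~30 % of a
46-kb genome), so its unbound families show ratios well below 1.

The simulator does **not** model: indels, quality-score structure, PCR
duplicates, fragment-size distributions, GC-dependent coverage bias, or
chromatin-state heterogeneity beyond the binary bound/unbound flag.
Passing tests therefore demonstrate correct accounting and estimator
behaviour under a clean sampling model, not robustness to every artefact
of real libraries.

Determinism: every channel derives its RNG seed from the configuration
seed plus a fixed small offset, so identical configurations give
byte-identical FASTQ/TSV outputs (asserted via manifest checksums).

## Consensus, period, and classification

The base-frequency matrix assigns read base *i* of a hit at monomer
offset *o* to position `(o + i) mod monomer_length`, reverse-complementing
minus-strand reads first. Information content is the unadjusted `2 - H`
bits (coverage in practice is in the hundreds, so no small-sample
correction is applied by default). Consensus ties break alphabetically and
are flagged; zero-coverage positions emit `N`. GC content excludes `N`
from numerator and denominator.

The repeat period is the smallest lag whose self-match fraction
`mean(s[i] == s[i+p])` is within `tol = 0.02` of the maximum, provided
that maximum exceeds `min_match = 0.7`; random sequence scores ~0.25 at
every lag and returns `NA`. The smallest-lag rule returns the fundamental
period rather than its multiples; 0.7 tolerates the divergence levels at
which window classification (floor 0.8) still works. Head-to-tail testing
finds non-overlapping monomer placements greedily by identity and requires
co-orientation plus adjacency within `max_gap = 5` bp — alternating
orientations (head-to-head) and spacered arrays both fail it.

Regions are classified by tiling into windows the size of the smallest
tandem monomer, assigning each window its best family with the mapper's
scoring, and taking the majority by window count; the published-style
"97 % of regions are the centromeric satellite" figure is reproduced as a
recovery test on 1653-of-1705 synthetic regions. A majority tie is flagged
`mixed` and resolved by mean identity — mosaics of intermingled families
are expected at real pericentromeres. The identity floor for calling a
region (0.80) and majority-by-length rule are this package's decisions;
the source study does not state its criterion.

## Peak filtering and the window domain caller

The four stringent thresholds (fold enrichment > 5, pile-up > 100,
−log10 p > 100, −log10 q > 100) are **strict** exactly as printed;
boundary values fail. The accompanying domain caller is openly invented
plumbing so the synthetic pipeline runs end to end without external peak
software: non-overlapping windows (200 bp) with depth-normalised coverage
ratio ≥ 2 merge into domains; p-values are one-sided binomial tails on
approximate read counts computed in log space (the > 100 regime underflows
double precision otherwise) with Benjamini–Hochberg conversion to q, also
in log space. Users with real MACS output import it via
`read_peak_table()` and bypass the caller entirely. Coverage tracks for
the synthetic path come from the simulator's ground-truth read positions,
since genome alignment is outside this package's scope.

## Fibre and slot-blot quantification

Fibre line profiles are segmented per channel at
`median + 3 * MAD`, with runs shorter than 3 samples dropped and
sub-threshold gaps of ≤ 2 samples bridged; the red (satellite) stretch is
the longest red run and green (CENP-A) blocks are clipped to it. The
median/MAD background rule assumes the signal occupies a minority of the
trace — the simulator keeps the red stretch at ~40 % of the trace
accordingly, and real traces should include comparable flanking
background. The three binding patterns are operationalised from coverage
fraction: **III** ≤ 0.05, **I** ≥ 0.90, **II** between. No numeric rule is
stated in the source imaging work, so these cutoffs are this package's
definitions; they are configurable and echoed in every summary. Slot-blot
ratios are background-subtracted IP/input IDV ratios with background
defaulting to 0 (no subtraction mentioned in the source protocol);
subtracted ratios are scale-invariant only at zero background, and both
behaviours are asserted.

## Problem sizes and runtime

The default configuration maps 200,000 reads per channel against a
four-entry panel (~35 s per channel on one CPU with the bit-parallel
scan); the acceptance script's full grid — four IP samples, one input,
1705 region classifications, consensus recovery and the imaging
quantities — completes in about two minutes, and the test suite in about
ninety seconds. These sizes were chosen to keep binomial standard errors
of the ratio estimates near 1–2 % (so a < 5 % median-error criterion is a
real test of the estimator, not of luck) while remaining desk-scale.

## Known limitations

* Substitution-only scoring will undercount reads from indel-rich repeat
  families unless `allow_indels` (slower, DP-based) is enabled.
* The two-state IP model has a single genome-wide `alpha`; differential
  affinity among bound regions is not representable.
* The domain caller is not a MACS replacement: no local background model,
  no duplicate handling.
* Region classification reports the majority family only; true mosaic
  structure is visible in the per-window assignments but not summarised
  beyond the `mixed` flag.
* The bundled 221-bp monomer is a synthetic stand-in reproducing only the
  published unit length and GC content of the horse centromeric satellite;
  analyses of real data must supply the real Repbase/GenBank consensus
  sequences.
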