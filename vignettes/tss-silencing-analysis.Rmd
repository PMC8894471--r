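---
title: "Methods: TSS calling, promoter annotation, and silencer occupancy analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS calling, promoter annotation, and silencer occupancy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(captss)
```

# Scope

`captss` analyses bacterial transcription start sites (TSSs) and
xenogeneic-silencer occupancy from cappable-seq 5′-end coverage. Cappable-seq
enriches triphosphorylated 5′ ends of primary transcripts, so read 5′ ends
pile up at TSSs; xenogeneic silencers (H-NS in *E. coli*, Rok in
*B. subtilis*) are nucleoid-associated proteins that repress AT-rich,
horizontally acquired DNA, where promoter-like sequences — in particular
−10-element look-alikes — occur frequently and can drive spurious
intragenic transcription. The package covers six analysis stages (TSS
calling, promoter −10 annotation, genomic-context classification,
cross-condition comparison, ChIP occupancy shape, differential activity)
plus a seeded synthetic-data generator so that every stage runs, and is
testable against ground truth, without any external download.

# The TSS calling rule

A position `p` on a strand is called a TSS when, **in every replicate**,

* `depth(p) > fold_threshold × depth(prev(p))` (strict inequality;
  the default threshold 3 means "more than threefold"),
* `depth(p) > 0`, and
* `depth(prev(p)) > 0`,

where `prev(p)` is the previous base **in the direction of transcription**:
`p − 1` on the `+` strand and `p + 1` on the `−` strand. The rule detects
the rising 5′ edge of a coverage peak, which is where the TSS sits;
genome-terminal bases have no previous base and are never called. At least
two replicates are required, and the requirement is all-of-*n*.

## Handling zero-depth positions (`zero_policy`)

Excluding zero-depth positions avoids calling a TSS wherever a single stray
read lands next to an empty base (any count is "more than threefold" zero).
There are two defensible readings of that exclusion, and `call_tss()`
implements both:

* **`"adjacent"`** (default): the immediately previous base must itself be
  nonzero. This is the conservative reading and the package default.
* **`"skip"`**: zero-depth positions are removed from the coverage series
  before the step ratio is computed, so the comparison is against the
  *nearest upstream nonzero* base.

The choice matters only for sparse tracks. On dense coverage (e.g. when
full-read coverage is used) the previous base is almost always nonzero
inside transcribed regions and the two policies agree. On strict 5′-end
spike coverage — the generator's output, and cappable-seq reduced to pure
5′ counts — the base immediately upstream of a genuine TSS is usually
empty, so the `"adjacent"` policy discards nearly every true site (with a
background of 0.2 counts/base the chance that the upstream base is nonzero
in both replicates is about 3%). For such data the `"skip"` policy is the
informative one, and it is what the recovery analyses and the shipped demo
profiles use. Both policies are verified against an independent per-base
brute-force scan in the test suite.

# Promoter −10 annotation

The −10 element is scored as the Hamming mismatch count against the
housekeeping consensus `TATAAT` on the sense strand. For each TSS, every
hexamer whose 3′ base lies `d` bases upstream is evaluated for `d` in the
spacer search range (default 5–9). Conventions:

* **Spacer** = the number of bases strictly *between* the hexamer's 3′ base
  and the +1; the +1 belongs to neither. A "7 bp" spacer means seven
  intervening bases.
* **Discriminator** = exactly those intervening bases (sense strand), so
  its length equals the spacer; its A+T fraction is reported per call.
* **Winner** = the placement with the fewest mismatches. Ties prefer
  `d = 7` (the canonical distance), then the smaller `|d − 7|`, then the
  smaller `d`. The tie-break is deterministic and is exercised against an
  exhaustive enumeration oracle in the tests.
* **`has_element`** = mismatches ≤ 2 with spacer in range. This
  operationalises "correctly positioned downstream of a −10 element"; both
  the mismatch bound and the range are exposed as parameters because any
  such criterion is a judgement call. A mismatch-count score (not a PWM)
  is used because the consensus is unambiguous and the score is exactly
  enumerable; a PWM can be substituted upstream if desired.

Sequence logos are summarised as a position frequency matrix anchored at
the TSS (offsets ...−2, −1, +1; there is no offset 0), with per-column
information content `IC_j = 2 + Σ_b f_bj log2 f_bj` bits. No small-sample
correction is applied by default since TSS sets here number in the
hundreds to thousands; the `3/(2 ln2 · n)` correction is available as a
flag. iNTP usage is the sense-strand +1 base (complemented for `−` strand
TSSs), reported as A/G/C/U.

# Genomic context and cross-condition comparison

"Coding" means the TSS base falls inside any annotated gene on **either**
strand — an antisense start inside a gene is still intragenic transcription
— with a same-strand-only flag available. Silencer-bound means the TSS base
falls inside any bound region (1-based inclusive ends). Cross-condition
Venn partitions match TSSs at **exact** coordinates (strand-aware), the
same convention by which duplicate TSSs are removed when conditions are
pooled; a ±n bp merge exists but is off by default.

# Occupancy shape

ChIP signal is averaged in 10 bp bins; the genome-wide mean of bin values
is subtracted from every bin ("centered" signal, which may be negative).
Two summaries follow:

* **Metagene profile**: each bin (by its center) is assigned to its
  *nearest* gene start codon; distance is signed along that gene's strand
  (negative = upstream). Centered signal is summed per 100 bp distance
  range over ±1 kb. Nearest-codon assignment is a partition, so no bin is
  counted twice; ties go to the lower-coordinate gene. Bin centers rather
  than edges are used to minimise edge bias. Summing centered (rather than
  raw) values follows from background subtraction preceding all downstream
  use; a raw option exists.
* **Percent-of-max curve**: bins are expressed as a percentage of the
  maximum centered bin value and cut into 20 equal levels over [0, 100]
  (negative bins fall into the lowest level); per level the fraction of
  bins whose center base is non-coding is reported. For a promoter-centred
  ("narrow", Rok-like) silencer the top levels are almost entirely
  non-coding; for an island-blanketing ("broad", H-NS-like) silencer they
  are not.

# Differential activity

Gene counts assign each read by its 5′ base to the same-strand gene
containing it; library size is the sample's total read count. TSS counts
pool both conditions' TSS sets, deduplicate, and read the 5′-end coverage
at each TSS base per sample.

The test is an **exact conditional rate test**: conditioning two Poisson
counts on their sum reduces the comparison to a binomial test of `a`
successes in `a + b` trials against `π = M_A / (M_A + M_B)`, with `M` the
pooled condition library sizes and replicates pooled within condition.
Two-sidedness is by minimum likelihood (outcomes no more probable than the
observed one are summed, ties included); `a + b = 0` gives p = 1. Fold
changes are `log2(((a + 0.5)/M_A) / ((b + 0.5)/M_B))` — the 0.5 pseudocount
keeps them finite at zero counts — and FDR control is Benjamini–Hochberg.

Calibration properties worth knowing:

* At small counts the minimum-likelihood binomial test is conservative
  because of discreteness: its exact size at α = 0.05 is ≈ 0.034 at 20
  expected counts per condition, 0.042 at 100, and 0.047 at 500. The
  type-I-error study in the acceptance suite therefore runs at a deep
  coverage of 500 expected counts per condition, where discreteness is
  mild.
* Under genuine overdispersion the Poisson conditional test is
  **anticonservative** — it sees extra-Poisson scatter as signal. This is
  a deliberate, documented trade for a fully specifiable, enumerable test;
  it is *not* a reimplementation of edgeR's negative-binomial exact test,
  and no attempt is made to reproduce published fold-change/p-value
  coordinates. Interpret p-values on overdispersed data accordingly (or
  pre-shrink with an external dispersion model).
* With total-count normalization, repressing a fraction *f* of the library
  in one condition deflates all fold changes by `1/(1 − f + f/φ)` for
  repression factor φ — the usual compositional bias of global-count
  normalization. At the acceptance study's 10% silenced genes and φ = 8 the
  expected median |log2FC| is ≈ 2.9 rather than 3.0.

# The synthetic-data generator

`simulate_genome()` builds a single-contig genome (both study organisms are
single-chromosome): i.i.d. background at 44% GC, AT-rich islands (default
four of 12 kb at 70% AT, embedded one per genome slot), non-overlapping
genes (one per slot; 600–1500 bp), and planted promoters. Each promoter
writes a `TATAAT` hexamer (per-base mismatch rate 0.02), a spacer drawn
from the configured distribution (default {6: 0.15, 7: 0.60, 8: 0.25},
the 7-preferred shape typical of housekeeping promoters), a discriminator
with 75% A+T (AT-rich, as in *B. subtilis*), and a purine-biased +1 base
(A 50%, G 30%). Intergenic promoters are placed 20–150 bp upstream of gene
start codons on the gene's strand — where real gene promoters sit, which
also gives the narrow occupancy mode its start-codon-proximal geometry —
and intragenic promoters only inside island-overlapping gene bodies.

Counts are negative binomial (`var = μ + φμ²`, default φ = 0.1; φ = 0
falls back to Poisson) because sequencing counts are overdispersed and the
differential test's calibration must be probed under realistic dispersion.
Cappable-seq replicates put NB(strength) at each planted TSS over
NB(0.2)/base noise; RNA-seq reads are placed uniformly within genes on the
sense strand. ChIP occupancy is deterministic given the truth: Gaussian
bumps (s.d. = peak_width/2) on intergenic promoter TSSs in narrow mode, a
plateau across each island in broad mode.

The demo pipeline distinguishes a transcript-level repression factor
(default 8, as recovered by the differential test) from a TSS-level
occlusion factor (default 25): silencers block promoter recognition nearly
completely, so silenced TSSs should drop below the caller's detection
limit, whereas transcript abundance retains a measurable residual.

What the generator does **not** emulate: read-level sequences and errors,
PCR duplicates, mappability, operonic co-transcription (each gene is
independent), TSS micro-heterogeneity (one exact +1 per promoter), and
ChIP noise (occupancy tracks are noise-free shapes). Passing recovery
tests therefore demonstrates the pipeline's correctness and calibration on
data with the assumed statistical structure, not performance on real
libraries with alignment artefacts.

# Reproducibility and problem sizes

All randomness flows from one top-level seed through named per-stage
substreams (`stage_seed()`), so any stage can be re-run in isolation and
identical config + seed yields identical outputs. The recovery analyses
run on 500 kb genomes with 300–500 planted promoters; occupancy contrasts
on 200 kb with 180 genes; the type-I study on 10,000 null features; the
differential recovery on 200 genes with 20 silenced — sizes chosen so each
stage's sampling error is small relative to the effect it measures while a
full run stays interactive on a laptop.

# Known limitations

* Single-contig genomes only.
* The caller reports exact +1 positions; closely spaced (< 2 bp) true
  starts on the same strand are resolved as separate records only if each
  independently passes the step rule.
* The `"adjacent"` zero policy is near-blind on sparse 5′-end tracks (see
  above) — choose the policy to match the track type.
* The exact rate test's p-values are anticonservative under overdispersion;
  the package reports them as defined rather than attempting dispersion
  estimation.
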