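---
title: "Calling and analysing mitochondrial heteroplasmy with mitohet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and analysing mitochondrial heteroplasmy with mitohet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The problem and the model

Animal mitochondria carry their genome in hundreds to thousands of copies
per cell. When a mutation arises, or when a mother transmits a mixed pool
of genomes, a site carries two alleles at once within a tissue or an
individual — heteroplasmy. Deep sequencing of the whole circular mtDNA
(amplified as a single long-range PCR product to suppress nuclear mtDNA
pseudogene contamination) turns heteroplasmy detection into a counting
problem: at each of the ~16.8 kb positions, how many reads carry each base?

`mitohet` operates strictly downstream of alignment. Its input is the
per-position, strand-aware base count — parsed from samtools pileup text or
read from a simple TSV — and everything that follows is deterministic
arithmetic on those counts. There is no probabilistic error model: the
caller is a frequency threshold, which matches how deep-coverage mtDNA
surveys are analysed in practice and keeps every call auditable back to two
integers.

For one site, the alternative allele frequency of base $b$ is

$$\mathrm{AAF}(b) = \frac{n_b^{fwd} + n_b^{rev}}
 {\sum_{x \in \{A,C,G,T\}} n_x^{fwd} + n_x^{rev}} \times 100,$$

and the minor allele frequency (MAF) is the AAF of the second most frequent
base — also when more than two alleles are present, in which case the
remaining alleles are reported but ignored for status. Indels are parsed
and counted but excluded from the substitution analysis; reference skips
and ambiguous bases are tracked in separate buckets that never enter the
denominator.

## Thresholds and their meaning

`caller_config()` exposes the tunable parameters:

* `het_threshold` (percent, default **0.5**) — the detection threshold: a
  site with MAF at least 0.5% is called heteroplasmic. Below roughly 0.1%,
  minor alleles become indistinguishable from amplification and sequencing
  error, which motivates the second tier.
* `potential_floor` (percent, default **0.1**) — sites with
  0.1% ≤ MAF < 0.5% are "potentially heteroplasmic": worth follow-up (e.g.
  by pyrosequencing) but not called.
* `min_depth` (reads, default **10**) — below this used depth a site is
  *undetectable* (UN). Survey tables report UN counts without defining
  them; treating UN as a depth floor is this package's documented
  operationalisation, and the default of 10 reads is deliberately
  permissive because whole-mtDNA amplicon coverage is typically in the
  thousands.
* `min_minor_count` (default **2**) and `strand_bias_max` (default off) —
  guards against single-read artefacts and one-strand-only minor alleles.
  They are additions of this implementation; setting `min_minor_count = 0`
  recovers pure threshold behaviour exactly.

Ties at 50/50 break toward the reference base, then alphabetically — a
deterministic, documented choice that only matters in the symmetric case.

Pyrosequencing-based pedigree tables use a much lower heteroplasmy floor
(`het_floor`, default **0.05** percent of the minor allele) than the NGS
threshold. The two scales coexist in the literature; `mitohet` keeps them
as two separate defaults on two separate functions
(`caller_config()` vs `transmission_summary()`) rather than reconciling
them silently.

## The circular reference and annotation

Coordinates are 1-based inclusive throughout, so variant names like
`mt.G8682A` read directly as positions. Features may span the origin
(`end < start`), and all interval arithmetic is modular. Where features
overlap, a position takes a single class by the precedence
**D-loop > tRNA > rRNA > CDS > intergenic**; region lengths computed under
this precedence always partition the genome (their sum equals the genome
length, which the tests assert for every annotation). Overlapping CDSs —
real in vertebrate mtDNA (ATP8/ATP6) — are each annotated, and the report
layer takes the first gene in genome order.

Translation uses NCBI table 2 (vertebrate mitochondrial): AGA/AGG are
stops, ATA is Met, TGA is Trp. Alternative initiation codons are read as
Met only at codon 1. Stop codons are written `X` in amino-acid-change
labels. One consequence worth spelling out: at a GAC (Asp) codon, a G→A
change at the first position yields AAC (Asn) — a `D…N` label. No G→A
substitution can produce an Asp→His change under any reading frame or
strand, since Asp→His requires G→C; the annotator therefore reports `D118N`
at the packaged COX2 landmark site even though an Asp→His label has
circulated for that locus.

### The packaged synthetic stand-in reference

`synthetic_reference()` loads `inst/extdata/synthetic_chicken_mt.fasta`, a
**synthetic** 16,775-bp circular genome. It reproduces the chicken mtDNA
landmarks that the package's worked examples and acceptance checks depend
on — total length, a 1,227-bp D-loop at positions 1..1227, the vertebrate
gene order, primer binding sites placed so the packaged primer sets yield
16,775/232/176/122-bp products, HinfI sites whose presence/absence tracks
the mt.G8682A and mt.G16121A alleles (fragments 196+36 and 145+31), and
ND2/COX2 codons at positions 5694/5718/8682 consistent with the T152S,
S160A and D118N labels. Everything between landmarks is seeded random
sequence: the stand-in is *not* the real chicken reference, and analyses of
real data should load the genuine genome and annotation via
`read_genome_fasta()` and `load_annotation()`.

## Cohort analyses

`cohort_matrix()` stacks per-sample calls into site-by-sample matrices.
Undetectable cells are excluded — never imputed — from polymorphism calls
and concordance; a site is polymorphic only when two *detectable* samples
disagree on the predominant allele. Tissue specificity counts, per
individual, the tissues in which a site is heteroplasmic; maternal-line
concordance reports, per sample pair, the fraction of comparable sites
sharing a predominant allele, which approaches 1 within a maternal line
under maternal inheritance.

The two-sided Fisher exact test is fixed to the point-probability
definition (sum the hypergeometric probabilities of all tables, with the
observed margins, no more probable than the observed one) — the same
convention as `stats::fisher.test` — because two-sided exact tests admit
several definitions and the choice changes borderline p-values. The
chi-square test is the Pearson statistic on 1 df without continuity
correction by default, and refuses tables with a zero expected cell.

## The synthetic-data generator

`simulate_cohort()` is first-class, tested code: it generates base-count
cohorts with known truth so that every stage of the pipeline can be
validated without any sequencing data. Its defaults are the study
conditions the package is built around:

* an 18-sample design (`default_cohort_design()`): one individual sampled
  in ten tissues, six further individuals in skeletal muscle, two
  mixed-tissue homogenates, across three maternal lines;
* 56 haplotype sites distinguishing maternal lines, with lines differing
  pairwise at 42–56 of them — the structure that makes sites polymorphic;
* 4 inherited heteroplasmic sites per individual, shared across its
  tissues with lognormal jitter (sd 0.3) around an individual-level mean,
  emulating the observed allele- and position-specific consistency within
  individuals;
* 10 somatic sites per tissue sample — the tissue-specific majority;
* variant positions drawn with a **34-fold per-base D-loop weight**, chosen
  so that about 73% of variant sites fall in the 1,227-bp D-loop;
* transition probability **κ = 0.84**, matching the observed transition
  bias of heteroplasmic substitutions;
* minor fractions log-uniform on [0.001, 0.40] (observed MAFs reach ~40%),
  negative-binomial coverage with mean 7,800× (the survey's average), and a
  per-base error rate of 10⁻³;
* a germline bottleneck of **N_b = 32** segregating units, the middle of
  the ~30–35 range estimated for vertebrate oogenesis, applied as a single
  binomial draw. A multi-generation Wright–Fisher process would be needed
  for longitudinal pedigrees, but one draw is exactly the quantity the
  single-generation transmission comparison tests.
* pyrosequencing measurement noise of **0.02 percentage points** on
  reported allele ratios. This is the triplicate-averaged scale: because
  the pyrosequencing heteroplasmy floor is 0.05% of the minor allele, any
  noise sd larger than the floor would push every homoplasmic individual
  above it and saturate occurrence counts — so the generator models the
  averaged measurement, not a single noisy read-out.

What the generator deliberately does not emulate: read-level errors and
alignment artefacts (it samples counts, not reads), PCR jackpot/recurrent
artefacts, strand-asymmetric error, contamination from nuclear mtDNA
copies, and age-dependent somatic accumulation. Passing the recovery tests
therefore demonstrates that the *analysis* is correct under the stated
noise model, not that the thresholds are robust to every real-world
artefact — which is why the caller exposes the minor-count and strand-bias
guards for real data.

All randomness flows from a single seed (`sim_config(seed = )`), and a
fixed seed gives byte-identical outputs, which the tests assert.

## In-silico PCR-RFLP

`in_silico_pcr()` finds the forward primer on the top strand and the
reverse-complemented reverse primer downstream, circularly; the product
includes both primers, which reproduces the printed product lengths of the
packaged primer sets, and back-to-back primers yield a full-genome-length
product. Several forward sites with viable products are treated as
ambiguous and error; with one forward site and several reverse sites the
shortest product is taken, matching what dominates a real reaction.

`digest()` scans both strands for the IUPAC recognition pattern and places
one cut per site interval, `cut_offset` bases after the interval's 5'-most
top-strand coordinate. For self-complementary recognition sequences such as
HinfI's GANTC the two strand scans coincide (tested), and fragment lengths
always sum to the product length. HinfI is modelled as G^ANTC
(`cut_offset = 1`). Gel reports flag fragments under a configurable 50-bp
detection floor as unresolved — small fragments run off a 3% agarose gel —
while still counting them in the conservation check.

## Numerical and degenerate-input choices

* Zero-depth sites get MAF 0 and status undetectable; empty inputs
  propagate as empty (not errors) through calling, tabulation and the
  pipeline, with a warning at the pipeline level.
* Reference-mismatch between a variant and the genome sequence is an error,
  as it almost always indicates a coordinate bug.
* Frequencies always sum to 100 (up to floating point) when depth is
  positive; MAF never exceeds 50.
* Fisher enumeration sums probabilities `<= p_obs * (1 + 1e-7)`; the slack
  absorbs floating-point ties, as in `stats::fisher.test`.

## Problem sizes in the tests

The test suite and acceptance script are sized to run in minutes on one
CPU: the parser property uses 1,000 random grammar-valid pileup lines; the
caller convergence check uses coverage 10⁵ with 200 replicates; cohort
recovery uses the default 18-sample design at coverage 10⁴ and error 10⁻³
(about 1,260 simulated sites), requiring at least 95% of truth sites with
fraction ≥ 1% to be called and zero false polymorphic sites within a
maternal line; bottleneck moments use 10⁴ draws. These sizes are the
package's own validation choices; larger experiments simply scale the same
generator up.

## Known limitations

* The frequency-threshold caller has no per-site error model; at MAFs near
  0.1–0.5% its behaviour is governed entirely by the configured guards.
* The packaged reference is a labelled synthetic stand-in; gene content
  between landmarks is random, so coding-region statistics computed on it
  (beyond the engineered landmark codons) are not biological.
* Pedigree analysis covers two generations (F0 mothers, F1 offspring) and
  one site at a time; multi-generation drift is out of scope.
* No structural variants, indel genotyping, or Numt detection — long-range
  PCR is assumed to have handled contamination upstream.
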