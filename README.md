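# mitohet

Detection, annotation and transmission analysis of mitochondrial
heteroplasmy from deep-sequencing base counts.

Mitochondrial DNA is present in hundreds to thousands of copies per cell, so
a site can carry two alleles at once — *heteroplasmy* — at fractions far
below what Sanger sequencing resolves. Deep amplicon sequencing of the whole
circular mitochondrial genome (in chicken, a ~16.8 kb molecule amplified as
a single long-range PCR product from back-to-back primers) makes it possible
to quantify minor alleles down to a fraction of a percent at every position.
`mitohet` implements the downstream analysis of such experiments for
geneticists working on mtDNA variation in birds and other vertebrates: it
consumes per-position base counts (samtools pileup text or a
pileup2base-style table), calls heteroplasmy by a minor-allele-frequency
threshold, annotates each variant on the circular genome, compares samples
across tissues, individuals and maternal lines, predicts PCR-RFLP
genotyping outcomes, and summarises how heteroplasmy is transmitted across
a single germline generation.

## The statistics at the core

For each site, the frequency of every base is computed over both strands:

    AAF(b) = reads(b, forward) + reads(b, reverse)
             ------------------------------------- x 100
             total reads of A, C, G and T (both strands)

The **minor allele frequency (MAF)** is the AAF of the second most frequent
base. A site is called

* **heteroplasmic** when MAF >= 0.5 % (and the minor allele has at least 2
  reads; both guards are configurable),
* **potentially heteroplasmic** when 0.1 % <= MAF < 0.5 %,
* **undetectable** when fewer than `min_depth` used reads cover the site,
* **homoplasmic** otherwise.

Cohort analyses build on the per-sample *predominant allele* (the most
frequent base): a site is **polymorphic** when detectable samples disagree
on it, and **tissue-specific** when it is heteroplasmic in exactly one
tissue of an individual. Contingency comparisons (transition/transversion
composition, D-loop enrichment, F0-vs-F1 heteroplasmy occurrence) use a
two-sided Fisher exact test (point-probability definition) and the Pearson
chi-square statistic. Germline transmission is modelled as one binomial
bottleneck: an offspring's fraction is `k / N_b` with
`k ~ Binomial(N_b, p)`, so offspring variance is `p (1 - p) / N_b`.

## A worked example

Parse one pileup line (10,000x coverage shown truncated to 20 reads), call
the site, annotate it, and predict its PCR-RFLP genotyping pattern on the
packaged reference:

```r
library(mitohet)

line <- "mt\t8682\tG\t10000\t,.,.,.,.,.AaAa,.,.,.\t~~~~~~~~~~~~~~~~~~~~"
bc <- parse_pileup_line(line, sample = "crureus")
call_site(bc)[c("sample", "pos", "ref", "major", "minor", "maf", "status")]
#>    sample  pos ref major minor maf        status
#> 1 crureus 8682   G     G     A  20 heteroplasmic
```

Four of twenty reads carry A, so the MAF is 20 % — far above the 0.5 %
threshold. Annotating the variant places it in the COX2 gene as a
non-synonymous transition (codon 118, Asp to Asn):

```r
ref <- synthetic_reference()   # packaged synthetic stand-in genome
a <- annotate_variant(8682, "G", "A", ref$annotation)
c(a$name, a$feature, a$mutation_type, a$aa_change, a$substitution)
#> "mt.G8682A" "COX2" "NS" "D118N" "transition"
```

In-silico PCR with the packaged primer set and HinfI digestion predict the
gel patterns that genotype this site — the G allele is cut, the A allele is
not, and the 36-bp fragment falls below the 50-bp gel detection floor:

```r
pr <- read_primer_table(mitohet_example("primers.tsv"))
rflp_genotype_report(ref$genome, pr$P8682, 8682, c("G", "A"))
#>   allele product_bp fragments resolved_fragments n_cuts
#> 1      G        232    196+36                196      1
#> 2      A        232       232                232      0
```

A mother with a 30 % minor allele transmits through a bottleneck of ~32
segregating genomes; offspring fractions scatter widely around her value:

```r
set.seed(1)
round(simulate_transmission(0.30, 32, 6), 3)
#> 0.250 0.281 0.312 0.406 0.219 0.406
```

`run_pipeline()` chains the stages over a whole cohort and writes TSV
reports (per-site calls, per-sample threshold tiers, annotated site tables,
polymorphism calls); `inst/scripts/mitohet.R` wraps the same functions as a
command line with `call`, `annotate`, `cohort`, `rflp`, `transmit` and
`simulate` subcommands.

## Package layout

* `R/` — reference model (circular genome, features, vertebrate
  mitochondrial code), pileup parsing, heteroplasmy caller, site annotator,
  cohort analyses, in-silico PCR-RFLP, synthetic-data generator, pipeline.
* `inst/extdata/` — synthetic stand-in reference genome and feature table,
  primer definitions, survey count tables, synthetic pedigree.
* `vignettes/heteroplasmy-pipeline.Rmd` — the methods vignette: model,
  assumptions, parameter choices and limitations.
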