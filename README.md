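# triovar

Somatic single-nucleotide-variant calling that integrates three sequencing
datasets from one cancer patient: normal DNA, tumor DNA and tumor RNA.

## The problem

Tumor/normal DNA comparison is the standard way to find somatic point
mutations, but it loses power exactly where it matters clinically — at low
DNA variant allele frequencies (VAF), where subclonal mutations and impure
tumor samples put the signal below the noise floor. When the tumor
transcriptome has also been sequenced, a mutation on an expressed allele
leaves a second, independent trace in the RNA. `triovar` exploits this: a
site with *weak* DNA evidence (as little as one supporting read) but
*strong* RNA evidence can be **rescued** as a somatic call, while sites
called confidently from DNA alone gain an RNA **confirmation**.

## The method

Every covered position is summarized per sample as a pileup column of read
observations (base, base quality, mapping quality, strand, offset within the
read, pairing, mismatch count). A lenient heuristic detector (depth ≥ 4,
variant reads ≥ 2, base and mapping quality ≥ 10) proposes candidates, which
two decision procedures then filter in parallel:

* **DNA-only method (DOM)** — normal DNA is tested against the reference
  first (germline call), then tumor against normal for somatic evidence:
  depth ≥ 10 in both samples, ≥ 4 alt reads at ≥ 10 % VAF with mean alt base
  quality ≥ 20 in the tumor, ≤ 2 % alt support in the normal.
* **Triple-sample method (TBM)** — the RNA carries the evidential burden
  (≥ 4 alt reads at ≥ 10 % VAF, mean alt base quality ≥ 15) while the tumor
  DNA must contribute at least one alt read (distinguishing true mutations
  from RNA editing) and the normal stays clean.

Both paths apply artifact filters: an accessible-genome blacklist, dbSNP
common/retired position lists, pseudogene and gene-family intervals
(RNA path), strand bias (> 90 % of ≥ 4 alt reads on one strand), positional
bias (≥ 95 % of alt reads in an outer third of their read) and a re-mapping
check on variant-supporting RNA reads. Merged calls are labeled
`RNA_Confirmation` (both methods), `RNA_Rescue` (TBM only) or `DNA_only`,
and every somatic call must finally be supported by ≥ 4 "perfect" reads
(MQ ≥ 10, BQ ≥ 10 incl. 5 flanking bases each side, properly paired, < 4
mismatches, no indel in the alignment) with ≤ 90 % of perfect reads on one
strand. Output is VCF 4.2.

The package also ships a read-level **mutation spike-in simulator** with
truth records, a fully synthetic **triplet pileup generator** (so everything
is testable without any external data), and a **validation classifier**
implementing the deep-resequencing status grid (Somatic Low/Med/High,
Germline/LOH, Not Validated, Ambiguous) with a COSMIC-style database-rescue
rule and precision accounting.

## Worked example

```r
library(triovar)

# a site with 1/6 alt reads in tumor DNA but 8/20 in tumor RNA
obs <- rbind(
  readObservations(base = rep("A", 20), baseQual = 30, mapQual = 40,
                   strand = rep(c("+","-"), 10), sampleRole = "normalDNA"),
  readObservations(base = c(rep("A", 5), "T"), baseQual = 16, mapQual = 40,
                   strand = rep(c("+","-"), 3), sampleRole = "tumorDNA"),
  readObservations(base = c(rep("A", 12), rep("T", 8)), baseQual = 30,
                   mapQual = 40, strand = rep(c("+","-"), 10),
                   sampleRole = "tumorRNA"))
col <- PileupColumn("chr17", 7578210L, "A", obs)

domEvaluate(col)                 # NULL: 17% depth but 1 alt read < 4
tbm <- tbmEvaluate(col); tbm
#> VariantCall chr17:7578210 A>T somatic/TBM label=none filter=PASS
calls <- mergeCalls(list(), list(tbm))
callLabel(calls[[1]])
#> [1] "RNA_Rescue"
formatVafPercent(8, 20)
#> [1] 40
```

The DNA-only method rejects the site (one supporting read cannot meet the
4-read / 10 % tumor thresholds), the triple-sample method accepts it on the
strength of the RNA (8/20 = 40 % VAF), and the merged call is labeled an
RNA rescue — the class of mutation this method exists to recover.

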