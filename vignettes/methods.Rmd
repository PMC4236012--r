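---
title: "Integrated DNA/RNA somatic SNV calling: model, filters and simulation design"
author: "triovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated DNA/RNA somatic SNV calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triovar)
```

## The model

`triovar` is a heuristic, threshold-based somatic SNV caller over
patient-matched triplets (normal DNA, tumor DNA, tumor RNA). It deliberately
avoids genotype-likelihood models: every decision is an explicit,
auditable predicate over per-sample pileup summaries, which makes each
rejected candidate attributable to a named filter. The statistical content
lies in the *design* of the filter chain, not in a probabilistic model; the
cost is that thresholds are hard boundaries, the benefit is exact
reproducibility and per-filter accounting.

A position enters the pipeline as a `PileupColumn`: one read observation per
aligned base, carrying base and mapping quality, strand, the 0-based offset
of the base within its read, the read length, the proper-pair flag, the
read's total mismatch count, an indel-alignment flag and the qualities of up
to five flanking bases on each side. Base qualities are consumed as given —
when columns are built from BAM files the caller is expected to have applied
any alignment-aware base-quality adjustment upstream, as is standard in
pileup-based workflows; no recalibration is performed here.

`summarizeColumn()` aggregates one sample's observations after applying the
quality floors: depth, the alternative allele (the non-reference base with
the highest filtered count), alt depth and fraction, mean alt base quality,
mean mapping quality, the forward-strand fraction of alt reads, and the
fraction of reads supporting any *third* allele. Two conventions matter and
are fixed package-wide:

* N bases never count toward depth or any fraction;
* ties between alternative alleles break alphabetically A<C<G<T, so output
  is deterministic and multi-allelic sites reduce to the top allele.

Internally positions are 0-based; VCF output is 1-based; BED input is
0-based half-open; position-list input (dbSNP/COSMIC-style) is 1-based.
Chromosome names are matched after stripping a leading `chr`.

## The two decision procedures

Candidate detection is lenient by design (depth ≥ 4, variant reads ≥ 2,
base and mapping quality ≥ 10) so that the filter chains, not the detector,
determine the call set.

**DNA-only method.** The normal is tested against the reference first; a
germline variant (normal depth ≥ 10, ≥ 4 alt reads at ≥ 10 % with mean alt
base quality ≥ 20, ≤ 90 % of alt reads on one strand, ≤ 2 % third-allele
support) ends the evaluation — a column never yields both a germline and a
somatic call. Only then is the tumor tested: the same evidence thresholds on
the tumor, plus a clean normal (depth ≥ 10 — enough power to have *seen* a
germline variant — with ≤ 2 % support for the tumor's alt allele). The
normal is summarized *for the tumor's alt allele*, so the 2 % ceiling
guards specifically against germline leakage of the allele being called.

**Triple-sample method.** The candidate allele comes from the RNA, and the
tumor DNA is summarized for that same allele: the RNA alt must be the
DNA-supported alt. Per-sample requirements: normal depth ≥ 10 with ≤ 10 %
alt and ≤ 10 % other; tumor DNA ≥ 1 alt read with mean alt base quality
≥ 15 (one good read is what separates a low-VAF mutation from an RNA-editing
event); tumor RNA depth ≥ 10 with ≥ 4 alt reads at ≥ 10 %, mean alt base
quality ≥ 15, ≤ 2 % other. The RNA path then runs the position/interval
filters (dbSNP common and retired versions, blacklist, pseudogene,
gene-family), positional bias, and optionally the re-mapping check, in a
fixed order so that first-failure attribution in reports is deterministic.

Merged somatic calls are labeled `RNA_Confirmation` (both methods),
`RNA_Rescue` (RNA path only) or `DNA_only`, and finally must show ≥ 4
"perfect" supporting reads. The perfect-read strand re-check differs from
the earlier strand-bias filter on purpose: its denominator is *all* perfect
reads (reference plus alternative) at the site, not alt reads only.

### Resolved design points

Places where the procedure had to be pinned down beyond the published rules,
and the choice made here:

* **Strand-bias guard inside the support tables.** The per-sample support
  profiles carry a 90 % strand ceiling, and the standalone strand-bias rule
  arms only at ≥ 4 alt reads. These are implemented as one check: the
  profile ceiling also carries the ≥ 4-alt-read guard. Without the guard a
  tumor-DNA sample with a single (necessarily 100 %-stranded) alt read
  could never be rescued, which would contradict the ≥ 1-alt-read design of
  the RNA path.
* **dbSNP scope.** The dbSNP position filters act on the RNA path only; a
  flag (`dbsnpOnDom`) extends them to the DNA-only path for users who want
  symmetric behavior.
* **Perfect-read evidence role.** The final support filter counts perfect
  reads in the role that carried the evidence: tumor DNA for `DNA_only`,
  tumor RNA for `RNA_Rescue`, and either for `RNA_Confirmation` (pass if
  either passes), matching each method's proof burden.
* **Thirds of a read.** Positional bias evaluates
  `offsetInRead / readLength` against 1/3 and 2/3 as real numbers —
  independent of read length and deterministic at the boundaries.
* **Overlapping mates.** Mate pairs overlapping a site are counted as two
  observations; no deduplication is attempted.
* **VAF percentages** round halves away from zero (`formatVafPercent`);
  printed ratio tables in the field are not always consistent under any
  single rounding rule, so one convention is fixed and documented.
* **Normal third-allele ceilings differ by path** (2 % DNA-only vs 10 %
  RNA path); both are implemented literally and not reconciled.

## Tunable parameters

All defaults live in `defaultConfig()` and are asserted against a literal
table in the test suite. Quality values are phred-scaled; fractions are
proportions in [0, 1].

| Group | Parameter | Default |
|---|---|---|
| detection | min depth / min variant reads | 4 / 2 |
| detection | min base / mapping quality | 10 / 10 |
| DNA-only germline & tumor | depth / alt reads / VAF / alt BQ | 10 / 4 / 10 % / 20 |
| DNA-only normal (somatic) | max alt / max other | 2 % / 2 % |
| RNA-path normal | depth / max alt / max other | 10 / 10 % / 10 % |
| RNA-path tumor DNA | alt reads / alt BQ | 1 / 15 |
| RNA-path tumor RNA | depth / alt reads / VAF / alt BQ | 10 / 4 / 10 % / 15 |
| strand bias | guard / ceiling | 4 alt reads / 90 % |
| positional bias | failing fraction | 95 % |
| remap check | surviving reads / fraction | 4 / 10 % |
| perfect read | MQ / BQ / flank BQ / mismatches | 10 / 10 / 10 / < 4 |
| read support | perfect reads / strand ceiling | 4 / 90 % |

## The synthetic generator and what passing tests mean

`generateColumn()` builds triplet columns from a `synthColumnSpec`: per-role
depths and true VAFs, normal base/mapping-quality distributions (rounded,
clamped to [0, 60]), a forward-strand probability, an optional positional
bias placing alt reads in an outer third, Poisson mismatch counts and a
proper-pairing rate. The alt count at a column is `round(trueVaf × depth)`
(halves away from zero), so generated columns hit their target VAF to within
half a read — the same guarantee the spike-in simulator makes.

The generator emulates the *decision-relevant structure* of real pileups:
depth, allele mixture, quality scales, strand and positional composition.
It does not emulate machine-specific error profiles, alignment artifacts
around indels, mate-pair correlation or reference bias. Passing the
property suites therefore demonstrates that the decision procedures
implement their stated predicates exactly (10,000 random columns are
checked against `referenceEvaluate()`, an independently coded straight-line
re-implementation that shares no helpers with the production path) and that
the rescue behavior holds under the stated simulation conditions — not that
the thresholds themselves are optimal for any particular instrument or
cohort.

The spike-in simulator (`runSpikein`) mirrors the published experimental
design at the read level: eligible loci are reference-homozygous in all
roles with tumor DNA and RNA depth ≥ 10; the default target-VAF samplers
are DNA uniform on 1–50 % with RNA constant at 25 % (the variable-DNA
experiment), with `vafBelow(0.10)` / `vafUniform(0.01, 0.50)` reproducing
the low-DNA/variable-RNA experiment. Reads are edited in place without
re-mapping — with synthetic reads the mapping is already ideal, and a
re-mapping hook can be layered on when editing real alignments. A target
VAF that rounds to zero edited reads is reported as skipped rather than
silently dropped.

Simulation sizes used by the test suite — 10,000 columns for the oracle
equivalence, 500 columns for the rescue property (depths 30–60 per role, DNA alt counts
drawn to keep the realized VAF strictly below 10 % with at least one alt
read, RNA VAF 10–50 %, clean qualities, balanced strands), 40–60 columns for pipeline round trips — were chosen as
the smallest sizes at which every decision branch is exercised many times
over.

## Numerical and degenerate-input choices

* Boundary semantics are taken literally from the rule texts: strand bias
  fails strictly *above* 90 %; positional bias fails *at or above* 95 %; a
  perfect read has *fewer than* 4 mismatches; validation grid boundaries
  are `< 3 %`, `≥ 8 %`, `< 20 %`, `≥ 20 %`, with "0 %" meaning exactly zero
  alt reads.
* Empty observation sets summarize to depth 0 with zero fractions; a
  mean alt base quality over zero alt reads is `NA` and fails any floor on
  it (the conservative direction).
* The re-mapping check treats a read with no stored sequence as rejected
  (with a warning) rather than assuming it maps uniquely.
* All randomness flows through R's session RNG; every entry point that
  draws (generator, spike-in, locus selection) either takes a seed or
  documents that the caller seeds, and reruns are byte-identical — the
  test suite asserts this at the file level for pileup, truth and VCF
  output.

## Known limitations

* Only SNVs: no indel, LOH or RNA-editing calling, and only the top
  alternative allele per site.
* Position-based (not allele-aware) dbSNP/COSMIC matching: any alternative
  allele at a listed site is filtered or rescued.
* The default re-mapping engine aligns reads against a user-supplied FASTA
  of candidate regions (locus neighborhood plus declared homologs), not the
  whole genome; a whole-genome aligner can be plugged in through the same
  function contract.
* Heuristic thresholds: there is no per-call quality score, so calls
  cannot be re-ranked without re-running with different profiles.
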