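---
title: "Sequence-based microsatellite genotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based microsatellite genotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrseq)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are classically genotyped by
fragment length: the electrophoretic size of a PCR product stands in for the
repeat count. Length is a lossy summary. Two alleles of identical size can
differ by SNPs or indels in the flanking regions or inside the repeat array
("size homoplasy"), and a flanking indel can masquerade as a repeat-count
change. Amplicon sequencing removes the proxy: when a merged read pair spans
the whole amplicon, every allele is observed as a sequence, and length-based
codings can be derived from it rather than measured in place of it.

`ssrseq` implements the full path from multiplexed, dual-tagged amplicon
reads to population-genetic statistics:

1. **readprep** — merge read pairs by best ungapped overlap; quality-trim.
2. **demux** — assign each merged read to a (locus, sample set) by the 10-nt
   tag plus the first 10 primer bases on *both* ends; quarantine reads whose
   two ends disagree (inter-set PCR recombinants).
3. **allele_call** — collapse each individual-by-locus read bin into allele
   contigs, absorb sequencing noise, flag PCR chimeras and stutter, call up
   to `ploidy` alleles with read-depth dosage, apply dataset-level QC.
4. **repeat_annot** — detect perfect tandem repeats, annotate alleles
   against the locus reference, and emit three coded datasets: SSR-length,
   fragment-length, and sequence-identity.
5. **divstats / popgen** — size homoplasy, rare alleles, replicate error,
   and NA / He / Ho / FST / RST with an allele-size permutation test.

A read-level simulator with complete ground truth makes every stage testable
without any external data.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_overlap` | 30 bp | smallest accepted mate overlap |
| `max_mismatch_frac` | 0.1 | mismatch tolerance inside the overlap |
| `q_threshold` | Q30 | terminal base quality kept after trimming |
| `max_mismatch` | 2 | Hamming mismatches allowed per 20-bp demux window |
| `identity` / `max_gap` | 0.99 / 2 | absorption distance limit in clustering |
| `noise_frac` | 1% | abundance below which a neighbour is sequencing noise |
| `min_reads` | 10 | reads required per accepted allele |
| `stutter_frac` | 5% | one-unit neighbour below this fraction is stutter |
| `low_cov_individual_frac` | 10% | locus dropped beyond this missing fraction |
| `missing_locus_frac` | 30% | individual dropped beyond this missing fraction |
| `n_perm` | 10,000 | permutations for the RST test |

The merging rule replaces the statistical overlap test of common merger
tools with a deterministic criterion: accept the overlap (at least
`min_overlap` bases, taken from the assembly settings used for marker
development) with the lowest mismatch fraction, provided it does not exceed
`max_mismatch_frac`; disagreeing bases resolve to the higher-quality call.
The quality trimming is end-trimming only — the simplest rule satisfying a
Q30 threshold; no sliding window.

Because one merged read spans the entire amplicon, de-novo assembly within
an individual-by-locus bin reduces to exact haplotype counting plus noise
absorption. A unique sequence is absorbed into a contig only when it is
within the 99%-identity / max-gap-2 edit distance of the representative
*and* it contributes less than 1% of that allele's reads — the signature of
a sequencing error rather than a second allele. The threshold is evaluated
as `count / (contig + count) < noise_frac`, i.e. the fraction among all
reads of that allele, so 1 error read against 100 clean reads (0.99%) is
absorbed while a 50/50 split never is.

## Chimeras, stutter, dosage

PCR recombinants between the two (or more) alleles of an individual appear
as low-coverage contigs that are exact single-breakpoint joins of two
higher-coverage contigs; `detect_chimeras()` tests precisely that predicate
(`c == a[1:i] + b[(i+1):n]`, either order, count below both parents).
Recombinants between individuals of *different* barcode sets are caught
earlier and more cheaply: with non-combinatorial tagging the two read ends
must carry the same (locus, set) key, so a mismatch is quarantined at demux
(`cross_tag`).

Polymerase stutter (one repeat unit gained or lost) is handled at the
calling stage: a contig whose length differs from an accepted allele by
exactly one repeat unit and whose coverage is below 5% of it is set aside.
Trinucleotide and longer motifs stutter rarely, so the default is
conservative and configurable.

Allele dosage in tetraploids is the composition $d$ of the ploidy
(positive integers, one per allele) maximizing the multinomial likelihood
of the observed read counts with cell probabilities $d_i/P$. Ties go to the
most even composition; exact ties beyond that (equal counts) give the
surplus to the more abundant allele listed first. `estimate_dosage()` is
verified against an exhaustive-composition search.

## The three codings and variable-site accounting

Alleles are coded three ways: by total repeat-region length (SSR-length),
by fragment length, and by exact sequence. A locus with two repeat regions
splits into two sub-loci in the SSR-length scheme only. Codes are dense
integers per (sub-)locus; two alleles share a code if and only if their
coding key is equal.

Annotation projects the reference repeat region through a global
affine-gap alignment (match 1, mismatch −2, gap open 10, extend 1).
Insertions strictly inside the projected region count toward the SSR
length; insertions at a region boundary count only when they are whole
repeats of the motif (a repeat expansion), so flanking indels never
inflate the repeat length.

Variable sites are tallied from the reference-projected pseudo-alignment
of a locus's alleles: substitution columns (`n_snps`), distinct indel
events (`n_indels`), and repeat-count variation booked **once** as a
single term, giving the identity

$$ n_\text{variable} = n_\text{SNP} + n_\text{indel} + [\text{repeat count variable}]. $$

A gap inside the repeat region whose length is a whole number of units *is*
repeat-count variation and is never double-counted as an indel. Published
per-locus tables that list such gaps in their indel column therefore show a
surplus of exactly the number of unit-multiple in-region indels; the
bundled survey tables contain two such rows, and the validation checks the
identity in this accounting.

## Diversity and differentiation

With allele copy counts $x_{ik}$ in population $i$:

* $H_e = n(1-\sum_k p_k^2)/(n-1)$ on the pooled copies (Nei's correction).
* $H_o$: per individual, one minus the fraction of identical
  within-individual copy pairs, $1 - \sum_i d_i(d_i-1)/(P(P-1))$; for a
  diploid this is the heterozygote indicator, for a tetraploid with dosage
  3:1 it is $0.5$ (3 of 6 pairs differ).
* **FST**: a two-level ANOVA (among / within populations) on allele
  indicator variables over copies, components summed over alleles
  (Weir–Cockerham family). Copies within a polyploid individual are
  treated as exchangeable; no within-individual correlation term is
  fitted. Published multi-software estimates may therefore differ
  slightly — exact numerical replication of survey-specific FST tables is
  not attempted, since the estimator variant behind them is not stated.
* **RST**: the same decomposition applied to allele sizes in bp
  (Slatkin-type), defined only for the two size-based codings.
* **Multilocus** values are ratios of summed variance components, never
  means of per-locus ratios; NA sums, He and Ho average over loci.

The RST permutation test permutes size labels among the *distinct alleles*
of a locus — not among copies — so allele-frequency structure is preserved
and only the association between allele identity and size is broken, which
is exactly the stepwise-mutation null ("size carries no differentiation
signal beyond identity"). The one-sided p-value uses the add-one rule,
$p = (1 + \#\{R_{perm} \ge R_{obs}\})/(1 + n_{perm})$, and a seed is
mandatory. With only two distinct alleles every permutation returns the
observed value and $p = 1$. Both the p-value and the permuted mean are
reported, since either may be the quantity of interest when comparing
observed against permuted RST.

## The simulator

`simulate_dataset()` emulates the data-generating process end to end:
random loci with a primitive 3–6 bp motif and a repeat region of at least
21 bp on the reference allele; allele lineages built by stepwise
repeat-count changes plus flanking SNPs and indels; diploid or tetraploid
genotypes drawn per population; and on-wire reads
`tag + primer + insert + revcomp(primer) + revcomp(tag)` cut into 2 × 250
pairs. Noise is injected per read: per-base substitution errors (clean
bases Q37, error bases Q20), one-unit stutter, single-breakpoint chimeras
between the alleles of one individual, and optionally cross-set chimeras.
Per-allele coverage is negative-binomial around dosage × mean with a floor
at 50% of the expectation: the generator represents loci and alleles that
amplified successfully, as dropout-prone loci are excluded by the QC rules
anyway; without the floor, rare deep-coverage troughs would make exact
recovery a lottery rather than a property of the method. One RNG seeded
once drives every draw, so output is byte-reproducible.

What the simulator does **not** model: PCR efficiency and GC bias,
position-dependent Illumina error profiles, multi-breakpoint chimeras,
index hopping beyond the cross-tag mechanism, and null alleles. Passing
the end-to-end tests therefore demonstrates correctness of the algorithms
under the stated noise structure, not robustness to every artifact of real
libraries.

`simulate_coded_locus()` is a lightweight genotype-level generator for
calibrating the estimators: under `null_iam` sizes are assigned to alleles
at random (the permutation null) while allele frequencies may still differ
between populations; under `smm` allele sizes form a tight stepwise ladder
and populations are shifted by four units, a strong stepwise signal.

## Numerical choices and degenerate inputs

* Demultiplexing ties (two candidate keys at equal mismatch count) are
  counted as `ambiguous` and discarded — safety over yield. Mismatches are
  Hamming within the 20-mer; indel tolerance ("partial matches" in the
  heritage tools) is not attempted because it is not reproducible.
* Allele ids are assigned by sorting distinct sequences lexicographically
  within a locus, so catalogs are stable across runs and input orders.
* Alignment identity below 70% marks an allele as a paralog suspect; it is
  excluded from SSR-length coding and reported.
* `nei_He` requires at least 2 copies; `anova_rst` is undefined for a
  size-monomorphic locus; `paired_t_test` distinguishes "all differences
  zero" (t = 0, p = 1) from "constant non-zero shift" (undefined, error).
* Empty read bins, empty catalogs and empty FASTQ inputs all return empty
  but well-formed objects.

## Design choices where the field is ambiguous

* "Rare allele" can mean one *copy* or one *carrier*; `rare_alleles()`
  defaults to one copy (a homozygote's allele, present twice, is not rare)
  and exposes `by = "carrier"` for the other reading.
* The replicate error rate's denominator is the set of
  (individual, locus, replicate-pair) comparisons with both calls present;
  comparisons involving a missing call are excluded and reported.
* A per-locus "mean SSR length" is deliberately not computed: whether such
  a mean should weight distinct repeat counts equally or by their
  frequency across individuals is convention-dependent, and either
  variant is a one-line summary of the coded SSR-length dataset the
  package already emits.

## Validation problem sizes

The shipped test-suite and the acceptance script validate at these sizes,
chosen to exercise every rule while staying comfortably interactive: the
end-to-end recovery study uses 20 loci × 40 diploids at 50× per-allele
coverage (~80,000 read pairs); dosage calling is compared against
exhaustive search on 200 random tetraploid count vectors; the permutation
test's type-I error is measured over 200 null datasets at 1,000
permutations each; published-survey arithmetic runs over all 44 loci of
the bundled tables.

## Known limitations

* Genotype-level replication of published FST/RST tables is out of reach
  without the underlying genotype data and estimator variant; the package
  validates its estimators against closed forms, independent
  variance-component oracles and calibration instead.
* Only ploidy 2 and 4 are supported; higher polyploids raise chimera and
  dosage ambiguities the calling model does not address.
* Clustering absorbs only single-origin noise; two true alleles closer
  than the absorption distance *and* rarer than 1% of each other cannot
  be distinguished (at realistic coverage this does not occur).
* The paralog rule reports and excludes; it does not attempt to split
  multi-copy loci into their paralogous components.
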