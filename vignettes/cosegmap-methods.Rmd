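---
title: "Cosegregation mapping of a recessive locus: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cosegregation mapping of a recessive locus: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegmap)
```

## The mapping model

`cosegmap` localizes a recessive single-locus trait from a small set of
deep-sequenced libraries: an affected father (genotype *m/m*), a carrier
mother (*m/+*), one pooled library of affected offspring and one of
carrier offspring, optionally augmented by unrelated carriers and wild
types. Under Mendelian inheritance, every variant tightly linked to the
causal allele must show a fixed genotype pattern across libraries — the
*cosegregation* pattern — while unlinked variants match it only by chance.
The mapping signal is therefore not a test statistic but an enrichment of
cosegregating variants along the genome, summarized three ways:

* **Run rule** (`detect_runs()`): maximal stretches with at least three
  cosegregating variants, whose ends cosegregate, and with never more than
  two successive mismatches inside. Requiring the terminal variants to
  cosegregate keeps trailing mismatches from inflating interval bounds;
  the bounds are the positions of the terminal cosegregating variants.
* **Sliding windows** (`window_scan()`): the proportion of cosegregating
  variants among *informative* variants (affected parent homozygous,
  carrier parent heterozygous) in 1-Mb windows advancing by 100 kb,
  anchored at position 1. Only full-length windows are emitted, except
  that a scaffold shorter than one window contributes a single
  whole-scaffold window; scaffolds of at most `min_scaffold_len` (default
  100 kb) are skipped. Windows without informative variants have an
  undefined proportion and are excluded from ranking; ties at the top are
  broken by genomic order and all ties are reported.
* **Fixed bins** (`bin_counts()`): counts of cosegregating variants in
  500-kb bins that partition each scaffold, so per-scaffold bin sums equal
  the scaffold's cosegregating total.

Two design questions had no single canonical answer and were resolved as
follows. First, the candidate allele at a cosegregating site may be either
REF or ALT: the reference assembly comes from an individual unrelated to
the cross, so the allele travelling with the causal haplotype can coincide
with the assembly base. The classification is symmetric in the two alleles
(and the test suite asserts invariance under relabelling). Second,
unrelated wild types are required to be homozygous for the *other* allele,
not merely "not homozygous for the candidate": a true wild type cannot
carry a recessive causal allele at a genuinely cosegregating site.

## Filters

Variants enter the analysis only if the site quality exceeds 100 (strict),
the caller's FILTER is PASS, the record lies outside annotated repeats
(overlap judged on the REF footprint, anchor base included for indels),
and **every** analysis library has depth strictly greater than 8, genotype
quality of at least 20, and a called genotype. Depth and genotype quality
are read as per-library thresholds — the stricter interpretation — and the
boundary semantics (`> 100`, `> 8`, `>= 20`) are pinned by tests. Family
mapping uses biallelic SNPs and MNPs; extended mapping adds biallelic
indels. Multiallelic records are dropped rather than decomposed. An MNP's
position is the position of its first base for all interval arithmetic.

## Interval refinement with recombinants

Additional family members genotyped at markers inside a candidate interval
shrink it: an individual is recombinant at a marker when its genotype is
discordant with the genotype its phenotype implies (affected →
homozygous causal, carrier → heterozygous, wild type → homozygous
non-causal). `refine_with_recombinants()` keeps the largest contiguous
block of markers concordant in every individual and trims the interval to
that block's terminal markers wherever a flanking discordant marker
exists. With no recombinant the interval is returned unchanged; if no
marker is universally concordant the function refuses to guess and raises
an error.

## Consequence annotation

Gene models are read from GFF3; the spliced CDS is the concatenation of
CDS segments, reverse-complemented for minus-strand genes, and both the
wild-type and the mutant CDS are translated with the standard nuclear code
(stops TAA/TAG/TGA; no selenocysteine handling). Substitutions are
classified by comparing the two proteins (synonymous, missense,
stop_gain, stop_loss, start_lost); coding indels are frameshift when the
length change is not a multiple of three, otherwise in-frame — and an
in-frame indel exposing a premature stop upon re-translation is promoted
to stop_gain. Splice sites are the two canonical intronic bases at each
junction, and severity dominates: any footprint touching them, including
an MNP straddling a junction, is splice_site. Variants in the 3,000-bp
flanks are located but receive no coding consequence. For a stop-gain
whose first changed base is spliced-CDS position $p$, the mutant protein
length is $\lceil p/3 \rceil - 1$ residues — the identity used to check
the truncation arithmetic (e.g. a substitution at CDS 9,508 of a
3,772-residue protein leaves 3,169 residues).

`candidate_report()` flags genes carrying stop_gain, frameshift or
splice_site changes among the supplied (typically cosegregating) variants
and orders genes by flag, severity of the worst consequence, then
coordinate, so reports are deterministic.

## What the simulator emulates

`simulate_study()` generates the full study design the pipeline assumes:

* Three scaffolds of 2.0, 1.5 and 0.3 Mb (configurable) of uniform random
  sequence, with at least three multi-exon genes per scaffold on both
  strands; the causal gene defaults to an 11,319-nt CDS (3,772 residues
  plus stop) carrying a glutamine codon whose first base is CDS position
  9,508, and it is placed in the scaffold interior so that the linked
  block fits entirely on the scaffold.
* Segregating sites at twice the target pairwise heterozygosity of
  1.25 × 10⁻³ per bp with founder alleles at frequency one half, so two
  random founder haplotypes differ at the configured rate — the
  ~1.25 variants/kb scale typical of such colonies. About 10% of sites
  are indels, 5% MNPs, and 2% of background SNPs receive a second ALT
  allele so the biallelic-only filter has real work.
* A 500-kb haplotype block around the causal site on which the father's
  two haplotypes and the mother's causal-bearing haplotype are identical
  by descent; the unrelated carrier shares only the causal allele itself,
  and unrelated founders are otherwise independent, which is what makes
  extended mapping strictly informative.
* Meioses with Poisson crossover counts per scaffold (rate 1, uniform
  placement, no interference), drawn until each phenotype pool holds 20
  offspring; an offspring's phenotype equals its causal-site genotype.
* Pools emitted as single diploid libraries: per site, depth is
  Poisson(30), ALT reads are binomial in the pooled allele fraction
  perturbed by a read-error rate (default 0.005), and a naive caller
  assigns hom/het/hom by allele-fraction cutoffs 0.1 and 0.9, with a
  phred-scaled binomial likelihood-ratio genotype quality capped at 99.
  True sites get QUAL in (150, 2000] and PASS; an extra 10% of decoy
  sites fail at least one filter (low QUAL, caller filter, low depth or
  low GQ in a family library).
* A repeat track drawn as random non-overlapping segments covering ~40%
  of each scaffold, independent of variant placement, so the repeat
  filter removes a predictable fraction; repeats never overlap the causal
  gene's CDS.

One deliberate departure from neutrality: background variants never
create a premature stop, coding frameshift or splice-disrupting change
(indels and MNPs are kept out of CDS ± 2 bp; coding SNP ALT alleles are
chosen among bases that do not produce a stop codon). In a healthy colony
such alleles are purged by purifying selection, and a second
loss-of-function allele segregating at 50% frequency would be biologically
implausible — this is what lets the candidate report isolate the planted
gene, mirroring the empirical observation that real candidate intervals
contain a single disruptive change.

What the simulator does **not** emulate: read-level artifacts (mapping
error, strand bias, indel realignment), linkage disequilibrium structure
beyond the single IBD block, population demography, and a realistic
variant caller. Passing tests therefore demonstrate the correctness of
the analysis logic under the study design's assumptions, not robustness
to every failure mode of real sequencing data.

## Numerical and degenerate-input choices

* Genotype-quality likelihoods use the configured read-error rate
  directly; at zero error the three genotype models are exact binomials
  (probabilities 0, ½, 1), so clean calls saturate at GQ 99 once depth
  reaches ~34 (≈3 phred per error-free read).
* Zero-depth libraries yield missing genotypes with GQ and DP of 0;
  missing genotypes fail every genotype filter.
* A zero-length interval is a hard error in `variant_density()`;
  degenerate (zero-area) polygons are hard errors in the shape metrics.
* Shape metrics: the fitted ellipse is the one sharing the polygon's
  second central moments (matching ImageJ-style "fitted ellipse"
  semantics), not a Feret-diameter construction; the convex hull comes
  from `grDevices::chull()`. Both metrics are invariant to rotation,
  scaling and translation to within 1e-9 relative tolerance by
  construction, and the tests enforce it.
* The rank-based group shift in `compare_shape_groups()` is the
  Hodges–Lehmann estimator (median of pairwise differences), reported
  descriptively alongside the Wilcoxon rank-sum statistic; no particular
  named test is imposed on shape comparisons.

## Problem sizes used in the tests

Unit tests run on down-scaled studies (two scaffolds of 200 and 120 kb)
chosen so each simulation takes well under a second while exercising every
code path, including repeat filtering, decoys and multiallelic records.
The planted-locus recovery checks run the full default-scale design
(3.8 Mb, 40 pooled offspring, 9 libraries) across 20 independent seeds
with the read-error rate set to zero — the regime in which recovery is
expected to be deterministic; the run-rule equivalence check enumerates
all 2^N cosegregation patterns up to N = 16 against an independent
pairwise-enumeration oracle.

## Known limitations

* Pools are modelled and genotyped as single diploid samples; allele
  frequencies within a pool are observable only through the naive
  caller's three genotype classes, exactly as in the emulated study
  design — no SNP-index/QTL-seq-style continuous allele-frequency signal
  is computed.
* Exonic non-CDS (UTR) positions are reported as `intron`; the simulator
  emits UTR-less models, and for external annotations the distinction is
  not material to candidate flagging.
* No statistical significance is attached to window proportions or run
  lengths; the method is an enrichment scan, and its validation is the
  planted-truth recovery, not a p-value.
* Indel representation is assumed normalized; equivalent left/right
  alignments are not reconciled.
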