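---
title: "Checking HLA allele assignments against SNP genotype posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checking HLA allele assignments against SNP genotype posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacheckr)
```

## The model

An HLA allele is, over the exonic SNP positions of its gene, a string of
nucleotides catalogued in the IPD-IMGT/HLA database.  A diploid
individual carries two alleles, so at every biallelic marker the pair
implies exactly one genotype class: homozygous for the chip's alleleA,
heterozygous, or homozygous for alleleB.  Genotyping or imputation gives
the individual a posterior triplet (p(AA), p(AB), p(BB)) at each marker.

The per-marker discrepancy of a candidate pair is the posterior mass
inconsistent with the genotype the pair implies, `s = 1 − p(implied)`.
Two boundary cases are defined rather than treated as errors:

* **Unknown base** (either allele uncharacterized at the position): the
  marker is *undefined* for that pair — it contributes nothing and is
  not counted as used.  Many database alleles are only sequenced over
  exons 2–3, so this is pervasive in real tables.
* **Off-chip base** (a known base that is neither chip allele): the
  pair is *impossible* at the marker and `s = 1` — no posterior mass
  can support a third nucleotide at a biallelic marker.

The pair's total discrepancy is the plain sum `D = Σ s` over the
markers that are present for the individual and defined for the pair.
A multiplicative combiner (summing `log(1 − s)`) was considered and
rejected: it lets a single confidently mis-imputed marker veto a pair,
which is exactly the failure mode a robustness check must tolerate.

The reported statistic is `Δ = D(attributed) − D_min`, where `D_min` is
the exact minimum of `D` over all `n(n+1)/2` unordered allele pairs of
the table (homozygous included).  Exhaustive enumeration is the
semantics, not an optimization target: the largest real gene has on the
order of a hundred common panel alleles, i.e. ~5,000 pairs over ~120
markers, trivially fast in vectorized form.  All pairs within `1e-9` of
the minimum are reported as ties.

Two consequences of the definition are worth noting.  Pairs containing
poorly characterized alleles are scored over fewer markers, which
biases the minimum toward them; the search therefore excludes alleles
with coverage below `min_coverage` (default 0.5).  The attributed pair
itself always participates in the minimum regardless of coverage, so
`Δ ≥ 0` always holds and `Δ = 0` exactly when the attributed pair is
among the best.  And `D` is never normalized by the number of markers
used: the statistic is a sum, so `Δ` between two pairs scored over the
same markers is a sum of per-marker differences.

## Calibrating the cutoff

The null model asks: what does `Δ` look like when an individual is
given an *arbitrary wrong* pair drawn from the cohort's own pair
distribution?  `calibrate_cutoff()` permutes the allele pairs across
individuals (pairs stay intact, so the multiset of pairs is conserved),
recomputes `Δ` for every individual, pools over `n_shuffles = 10`
permutations, and summarizes the pooled null by its mean μ and standard
deviation σ.  Several permutations pooled with a recorded seed make the
calibration reproducible; in practice single permutations give nearly
identical results.

The default cutoff is the **lower edge** of that null,
`max(0, μ − 2σ)`, flagging any individual whose `Δ` strictly exceeds
it.  The reasoning: correct assignments concentrate near `Δ = 0`, far
below the null bulk, while *any* wrong assignment — whether a typing
error or an imputation failure — is statistically a draw from the same
wrong-pair regime the shuffles sample.  A useful cutoff must therefore
sit between the correct-assignment distribution and the null bulk.  The
upper-tail rule `μ + 2σ` (available as `tail = "upper"`) instead flags
only values extreme *even for random assignments* (about 2.3% of
genuinely normal null draws); with sharply concentrated posteriors the
wrong-assignment null sits at many units of `Δ`, and an upper-tail
cutoff would let essentially all wrong assignments through.  With very
diffuse posteriors the two distributions compress toward each other and
the distinction matters less.  The choice is exposed, recorded in the
calibration object, and the lower edge is floored at 0 so that `Δ = 0`
individuals are never flagged.  On the synthetic default cohort the
lower-edge cutoff lands near 2 — the same order as the integer cutoffs
conventionally published for class I genes.  Integer rounding of the
cutoff is available (`rounding = "integer"`) but off by default.

Flagging is strict (`Δ > cutoff`; a value exactly at the cutoff is
kept), the kept/flagged partition is always exhaustive and disjoint,
and individuals whose `Δ` is uncomputable (no usable markers, or an
attributed allele absent from the database) are kept with their status
recorded — an absent allele is itself a form of implausibility, but it
is reported, not silently dropped.

## Accuracy evaluation

Imputed HLA alleles arrive as per-allele posterior dosages (each allele
imputed as a present/absent binary marker).  `call_from_dosage()`
implements the standard calling rule: an allele contributes one copy
when its dosage exceeds 0.5 (strictly) and two copies above 1.5, and an
individual is "called" only when exactly two copies result.  The
called fraction is reported as a metric, never asserted.

`hla_accuracy()` is per-allele, not per-individual: for each called
individual the two called alleles are compared with the two true
alleles *as multisets* after truncating names to the requested
resolution (one or two fields), so each individual contributes 0, 1 or
2 correct alleles and a homozygous call cannot double-count a single
true copy.  Accuracy is correct alleles over called alleles.
`evaluate_filtering()` reports the conventional triple — base accuracy,
number removed (with the fraction of removed individuals that were in
fact correctly typed), and accuracy on the kept subpopulation — and
`prefilter_typed()` applies the same machinery to gold-standard typed
cohorts before they are used for anything else, reporting
"removed/total" counts.

## The allele table and its file dialects

`parse_nuc_alignment()` reads the compact cDNA alignment dialect
(reference row; `-` identity, `*` unknown, `.` indel placeholder, exon
pipes, multi-block rows).  Indel columns are dropped from the
coordinate frame: the method is defined only over biallelic SNP
markers, so inserted bases carry no marker and deletions simply become
unknown at the deleted reference positions.  The gapless reference
frame after dropping those columns defines 1-based cDNA coordinates.

`project_to_markers()` takes the marker map as the single source of
truth for which positions are used (encoding, e.g., an exon-2/3
restriction in the marker file keeps the core generic) and expresses
every base on the chip strand, complementing at minus-strand markers.
`collapse_resolution()` groups alleles by truncated name and represents
each group by the member with the lexicographically smallest full name
— deterministic, and consistent with the convention that the
first-numbered allele defines the group's protein; the choice is
recorded in the output's resolution metadata.  Reconciling four-field
database names with two-field panel typings has no canonical answer,
and this explicit representative policy is the package's.

Genotype posteriors are read from IMPUTE2 GEN + SAMPLE files.  Triplets
may sum to less than one and are used as-is — renormalizing would
silently convert imputation uncertainty into confidence, so the missing
mass counts as disagreement.  Markers missing for an individual are
skipped for that individual across *all* pairs, keeping each
individual's pair comparison on a common marker set.

## The synthetic generator

`sim_config()` defaults define the study conditions used throughout the
tests: 10 alleles × 20 markers, 300 individuals, no unknown bases,
posterior noise `e = 0.1`, 5% corrupted assignments, and a
geometrically decaying allele-frequency simplex (ratio 0.65, top allele
≈ 0.36) emulating the strong skew of real HLA allele frequencies.
True pairs are drawn by Hardy–Weinberg sampling; posteriors put mass
`1 − e` on the implied genotype and `e/2` on each alternative;
corrupted individuals get a pair drawn uniformly from pairs differing
from the truth at ≥ 3 markers (so detection sensitivity is
well-defined), with the corrupted set returned as ground truth.
Unknown-base masking is applied to the *table* while genotypes are
generated from the complete bases — real individuals carry real
nucleotides even where the database is ignorant.

What the generator does not emulate: MHC linkage disequilibrium (noise
is independent across markers, real imputation error is LD-structured),
population structure, and the sequence similarity of real allele
families (generated alleles are independent random strings, so wrong
pairs are typically far from the truth).  Passing tests therefore
demonstrate the scoring, search, calibration and bookkeeping contracts
— not field performance on real panels, where posterior sharpness and
allele similarity vary by gene.

## Numerical choices and problem sizes

Per-marker `s` is clamped to [0, 1]; ties in the best-pair search use
an absolute tolerance of 1e-9; zero usable markers yields an explicit
degenerate status rather than `D = 0`; the lower-edge cutoff is floored
at 0.  All randomized procedures (generators, shuffles) take integer
seeds and are bit-reproducible given them.  The test suite runs the
oracle-equivalence sweep on 100 random instances of up to 12 alleles ×
15 markers against an independently coded naive enumeration, and the
end-to-end detection check on the default 300-individual cohort; both
finish in seconds on one CPU, and scoring a 100-allele × 120-marker
gene for a cohort of 100 costs well under a minute.

## Known limitations

* Scoring is unphased and per-gene; haplotype-aware or joint multi-gene
  scoring is out of scope, as is calling alleles from `D` itself.
* Only the GEN dialect is ingested (no BGEN/VCF); converters exist
  elsewhere.
* Genes with few exonic markers or heavy paralogy (the DRB1 situation)
  yield overlapping real/null distributions; the calibration object
  exposes μ and σ so users can see when separation fails.
* G-group/P-group nomenclature resolution is not attempted.
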