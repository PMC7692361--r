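---
title: "Detecting Z-to-W transposed regions from sex-stratified sequencing summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Z-to-W transposed regions from sex-stratified sequencing summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Birds carry a ZW sex-chromosome system: females are ZW, males ZZ. The W is
highly degenerated — of the several hundred genes on a typical Z, only a few
dozen intact gametologs survive on the W — and most of the Z is therefore
hemizygous in females. Occasionally, however, a segment of the Z is copied
onto the W by DNA-based transposition. Such a Z-transposed region (ZTR)
restores once-lost genes to the female-specific chromosome, and it leaves a
distinctive footprint in short-read data mapped to the Z reference:

* **Coverage.** Because the young W-borne copy is nearly identical to its Z
  parent, W-derived female reads co-map onto the Z. Female coverage over the
  ZTR is restored to the two-copy (autosome-like) level, while the
  surrounding hemizygous Z stays at half; male coverage is unchanged.
* **Heterozygosity.** The Z and W copies have begun to diverge, so females —
  and only females — show a dense excess of heterozygous calls over the ZTR,
  with allele fractions near 0.5.

Two confounders share part of this signature. A pseudoautosomal region (PAR)
gives two-copy female coverage but no female-specific SNP-density elevation.
A Z-linked duplication elevates coverage in **both** sexes (males, with two
Z's, reach four copies) and produces paralogous sequence variants in both
sexes. `ztrscan` separates the three cases window by window.

## The detection model

Per-site depth tables (samtools-depth dialect, pre-screened at mapping
quality 60) are filtered by dropping sites with depth strictly above three
times the average — a guard against collapsed repeats. Depth is then
summarized in non-overlapping 50 kb windows tiled from coordinate zero; a
trailing partial window is dropped and windows with fewer than 60% of their
sites covered are excluded. Such scans are often described as "sliding"
windows, but one value is produced per fixed 50 kb span (the `bedtools map`
idiom), so non-overlapping tumbling windows are what is implemented. Both the 60%
rule and the 3x depth rule are strict inequalities; equality retains.
Window means are taken over present sites only, mirroring `bedtools map`.

Normalized coverage divides each window's mean depth by the median over a
set of baseline windows, so a two-copy state sits at 1. The baseline is
chosen in preference order: declared autosome-like windows, then PAR
windows, then all retained windows. The choice is recorded in the output.
On a mostly hemizygous chromosome the all-windows fallback centres the
one-copy state at 1 instead, so a declared baseline (autosomes or the
known PARs, which are well-mapped landmarks in these genomes) should be
supplied; the bundled pipeline declares the layout's PAR.

Variant records pass the standard hard filters (fail when FS > 10,
QD < 2, MQ < 50, SOR > 1.5, MQRankSum < -1.5, ReadPosRankSum < -8; a
missing annotation leaves its criterion unapplied) plus a SNP cluster rule:
any SNP within a 10-bp span of another SNP fails (two or more SNPs per
10-bp window; indels are exempt, and the rule inevitably removes a few
percent of genuinely adjacent divergence sites at divergence 0.002/bp).
Heterozygous calls from a single diploid individual have expected
alternate-allele fraction 0.5, so records are retained in the closed
interval [0.3, 0.7]. Indels are hard-filtered with the same numeric
criteria, excluded from SNP density, but retained for pseudo-sequence
construction. SNP density is the count of retained SNPs per 50 kb window.

### Window classification

With per-sex normalized coverage and SNP density in hand, each window is
labelled by signature. Coverage intervals default to [0.8, 1.25] for
"two-copy" and [0.35, 0.65] for "one-copy"; a male coverage of at least 1.5
marks a duplication. A density is *elevated* when it reaches
`max(k * lambda_bg, lambda_bg + 3 * sqrt(lambda_bg))` with `k = 3` and
`lambda_bg` the per-sex background window density — the multiplicative arm
requires a genuinely large excess while the additive arm keeps the
threshold outside the Poisson noise band when the background is small.
`lambda_bg` is the **mean** over the declared baseline windows when a
baseline is given (a declared baseline is candidate-free, so the efficient
estimator applies; a small PAR-only baseline makes the median fragile —
a 10-window median of Poisson counts underestimates the background often
enough to halve the threshold), and the **median** over all retained
windows otherwise (which resists the candidate regions themselves). The
label table:

| label | female cov | male cov | female density | male density |
|---|---|---|---|---|
| ZTR | two-copy | two-copy | elevated | not elevated |
| PAR | two-copy | two-copy | not elevated | not elevated |
| Z_DUP | any | >= 1.5 | elevated | elevated |
| HEMIZYGOUS_Z | one-copy | two-copy | not elevated | — |

These numeric thresholds are package defaults placed so the expected
signatures sit at interval centres (at haploid depth 15 the hemizygous
expectation is 0.5, the diploid 1.0); all are exposed via
`classify_params()`. PAR is recognized by signature only — real PARs happen
to be terminal, but position is not used as evidence.

Runs of identically labelled windows are merged into region calls. A single
interior unclassified or excluded window is bridged so long calls are not
fragmented by window noise; demotion of runs shorter than `min_run = 2`
windows and bridging are iterated to a fixed point, so one spuriously
labelled window inside a long run is first demoted and then absorbed
rather than splitting the call. Runs of hemizygous-looking windows
strictly between two ZTR runs are absorbed into one ZTR envelope and
recorded as candidate W-deletions. ZTR and duplication calls carry one-sided Mann-Whitney rank-sum
p-values of their female (and male) window densities against the baseline
windows; the test enumerates the exact null for `min(n, m) <= 8` and
otherwise uses the tie-corrected normal approximation with continuity
correction. (At n = m = 8 the worst-case disagreement between the two,
over the fully enumerated null, is 0.0109.)

## W pseudo-sequence, deletions and gene fates

Because the transposition is evolutionarily young, every retained female
heterozygous site inside a ZTR is read as Z-W divergence and the alternate
allele is assigned to the W haplotype — alternate-reference logic without
phasing, which also means background polymorphism is *not* separated from
divergence (a known approximation; at the default rates polymorphism is 5%
of the divergence signal). Variants are applied left to right; a variant
whose reference span intersects an already-applied span is skipped and
counted. The reconstruction maintains a Z-to-W coordinate map with an
offset breakpoint at every indel, and the length identity
`|W| = |Z| + sum(len(alt) - len(ref))` holds exactly.

Interior hemizygous runs inside a ZTR envelope become W-deletion calls at
window resolution (no split-read refinement); retained length is envelope
minus total deleted, exactly. Gene fates are then assigned in order of
evidence strength: a gene wholly inside a deletion is `deleted`; any CDS
overlap with a deletion gives `partial_deletion` even if the residual ORF
could be intact (mirroring how partially removed genes are conventionally
reported); otherwise the CDS is lifted onto the W pseudo-sequence,
reverse-complemented as needed and translated. A net indel length in the
CDS that is not a multiple of three is a `frameshift`; an in-frame stop
strictly before the annotated terminal codon is a `premature_stop`
(no tolerance for terminal-exon stops); both can co-occur. Everything else
is `intact`. Direct liftover plus translation replaces homology-based gene
re-prediction, which is justified at the low Z-W divergence of young ZTRs.

## Branch-specific dN/dS by counting

Evolutionary constraint on the surviving W copies is measured with a
counting estimator rather than a maximum-likelihood codon model: the method
is fully self-contained and, at young-ZTR divergences (a few substitutions
per hundred codons), counting and ML agree closely while ML adds numerical
machinery the problem does not need. For a gametolog pair plus outgroup,
each Z/W-differing codon is polarized by parsimony — the copy matching the
outgroup is ancestral, and the substitutions (pathway-averaged, stops
excluded) are assigned to the other copy's branch. Codons at which all
three sequences differ cannot be polarized and are tallied separately, with
a warning above 20%. Sites follow the classic per-codon fractions (each of
the nine single-base changes contributes 1/3 site; stop-creating changes
count as nonsynonymous so S + N = 3L exactly), and proportions are
Jukes-Cantor corrected, `d = -3/4 log(1 - 4/3 p)`, flagged saturated at
p >= 3/4. When dS = 0 the ratio is reported as undefined together with dN
— a branch with zero nonsynonymous changes is a meaningful observation,
not an infinity.

## What the synthetic generator emulates — and what it does not

The generator plants a full study scenario with serialized truth. Site
depth is Poisson with mean `c * D`, where `c` is the planted copy number
(an overdispersion knob switches to gamma-Poisson; the default is 0 because
the downstream inference uses only window means). Z-W divergence sites
(0.002/bp, a young transposition), W
indels (1e-5/bp) and duplication paralog variants (1e-3/bp) are drawn once
per seed as fixed sequence features shared by every sample; background
heterozygosity (1e-4/bp) is drawn per sex. The default haploid depth
D = 15 is a typical single-individual resequencing depth for this kind of
survey. Allele fractions are
Beta(50,50)-binomial around 0.5 at the site's copy-scaled depth, which
keeps about 95% of true heterozygotes inside the [0.3, 0.7] window at
D = 15. A configurable fraction of records (default 5%) is drawn to violate
exactly one hard-filter criterion each, so filter-reason bookkeeping is
testable. The default layout is a 10 Mb chromosome of 200 windows: a
terminal 0.5 Mb PAR, a 1.3 Mb ZTR carrying a 150 kb internal W-deletion
and nine genes (two intact survivors, five wholly inside the deletion, two
straddling its boundaries), a 100 kb Z-linked duplication spanning one
gene, and hemizygous background.

Codon alignments evolve from a stop-free ancestor along outgroup, Z and W
branches radiating from the root; proposals arrive at `3 * L * t` per
branch, stop-creating changes are rejected and nonsynonymous ones accepted
with probability omega. At most one substitution lands per codon, and by
default no codon is hit on more than one branch: the alignment is
homoplasy-free, so parsimony polarization is exact and a fully constrained
branch (omega = 0) provably accumulates zero nonsynonymous counts. This is
a deliberate idealization of the low-divergence regime; `allow_homoplasy =
TRUE` restores independent placement, under which rare convergent outgroup
changes can misassign a substitution — the real failure mode of parsimony
polarization.

The generator does **not** emulate read-level artefacts (no FASTQ/BAM,
mapping biases, GC effects or sequencing error), recombination, TE
insertions, or assembly collapse. Passing the bundled recovery tests
therefore demonstrates that the statistical chain — filters, windows,
normalization, classification, reconstruction, fate calls — is correct
under its stated model, not that the model captures every failure mode of
real resequencing data.

## Numerical and design choices

* Strict boundaries throughout: depth `> 3x` mean fails, coverage `< 60%`
  excludes, allele fractions 0.3 and 0.7 are retained, hard-filter
  thresholds fail only beyond the stated value.
* Cluster rule: two SNPs cluster when both fit in one 10-bp span
  (`|p - q| < 10`).
* Overlapping variants: leftmost wins, deterministically, matching
  left-normalized VCF conventions; skipped variants are counted.
* Variant rederivation (`rederive_variants`, the round-trip inverse used in
  validation) aligns globally with mismatch penalized above short gaps, so
  a deletion + insertion pair is never re-expressed as a substitution run,
  and indels are reported left-normalized; an un-normalized input
  representation inside a repeat run will come back normalized.
* The rank-sum test switches from exact enumeration to the corrected
  normal approximation above `min(n, m) = 8`; identical samples return
  p = 1 with a warning.
* Degenerate inputs: empty depth tables warn and return empty; chromosomes
  shorter than one window warn and emit none; a zero baseline median is an
  error; genes outside the ZTR envelope are skipped with a warning.
* Region-call evidence p-values are only computed against an explicitly
  declared baseline; with no baseline they are `NA` rather than a
  self-referential comparison.

## Problem sizes used in validation

The bundled tests exercise the full 10 Mb / 200-window default layout over
five seeds for region recovery (about 15 s per screen on a single core),
a 2 Mb layout for the fast unit paths, 100 random variant sets for
reconstruction round trips, all 61 x 61 sense-codon pairs against a
brute-force pathway-enumeration oracle, and 20 seeds of 1,000-codon
alignments for omega recovery, where the mean estimate over seeds is
compared against truth (a single 1,000-codon alignment at these branch
lengths carries only ~30 substitutions per branch, so per-seed estimates
have ~25-30% sampling error by ordinary Poisson noise).

## Known limitations

* Polymorphism inside a ZTR is counted as divergence; with population data
  one would subtract the shared-polymorphism fraction.
* W-deletions are window-quantized; deletions below `min_run` windows
  (100 kb at defaults) are invisible, as are any below one window.
* The alternate allele is assigned to W without phasing; reference-allele
  divergence on the W is missed (expected to be half the sites for a
  symmetric mutation process — the pseudo-sequence is a lower bound on
  divergence, as in the alternate-reference approach generally).
* PAR and ZTR are distinguished only by female SNP density, so a ZTR old
  enough for its divergence signal to decay toward background, or one
  still exchanging with the Z, would be labelled PAR.
* Ancient transpositions whose reads no longer co-map are outside the
  method's reach by construction.
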