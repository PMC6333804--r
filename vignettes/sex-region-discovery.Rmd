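---
title: "Detecting sex-determining regions from cohort genotypes and sex-pooled depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-determining regions from cohort genotypes and sex-pooled depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

Many fishes determine sex genetically yet carry no cytogenetically visible
sex chromosomes: the sex-determining locus is a small haplotype difference —
often a male-specific insertion of a few kilobases — embedded in an otherwise
ordinary chromosome. `sexscan` implements two orthogonal genome-wide scans
that expose such a locus in whole-genome resequencing data from a sexed
cohort, plus downstream characterization of the candidate sequences, and a
seeded simulator that makes the whole pipeline testable without any external
data.

## The genotype-pattern filter

In a male-heterogametic (XX–XY) system, a variant inside the recombining
neighborhood of the sex locus that distinguishes the X- and Y-haplotypes is
heterozygous in every male (one X allele, one Y allele) and homozygous in
every female (two X alleles). `classify_variant()` applies exactly this
filter: a site is called `XY` when at most `tolerance_het` males fail to be
heterozygous and at most `tolerance_hom` females fail to be homozygous; `ZW`
is the sex-swapped mirror; the strict setting is zero tolerance on both
sides. Two aspects of "all males het, all females hom" are genuinely
underdetermined and are therefore explicit parameters rather than silent
choices:

* `missing_policy` — a missing genotype cannot *confirm* linkage, so the
  default counts it as a violation; `"ignore"` instead drops the sample from
  that site's tally.
* `require_same_hom_allele` — in an XY system all females share the X
  allele, so the default additionally requires conforming females to be
  homozygous for one identical allele. Because "homozygous" alone is the
  weaker reading, the requirement can be switched off.

"Homozygous" includes both reference and alternate homozygotes, and any
heterozygous combination counts as heterozygous regardless of ALT index: the
filter concerns zygosity pattern, not allele identity.

The filter's power comes from cohort size. Under Hardy–Weinberg at allele
frequency $p$ ($q = 1-p$), an autosomal site passes the strict filter with
probability $(2pq)^{n_m} \cdot (p^2 + q^2)^{n_f}$ (same-allele requirement
relaxed; smaller still with it). At the default cohort of 49 males and 53
females this is at most $2^{-102}$ — effectively zero across any genome —
which `false_positive_rate()` verifies by Monte Carlo. Passing variants are
then chained into clusters wherever consecutive variants lie within
`cluster_max_gap` (default 50 kb, comfortably above the ~15 kb span such
marker sets show in practice while below typical inter-locus distances).

## The pooled-depth differential scan

The second signal needs no genotypes at all. Reads from all males and all
females are pooled separately and per-base depth is tabulated
(`bedtools genomecov -d` dialect). A segment present only on the Y is
hemizygous in males — about half the per-individual depth — and essentially
absent in females; a segment present on the X but missing from the Y shows
the mirror-image signature, about twice the per-individual depth in females
relative to males.

`window_scan()` computes, over half-overlapping windows (defaults 1000 bp
window, 500 bp step), the mean pooled depth per used position divided by
pool size, for each sex, and their absolute difference. Positions with zero
pooled depth in *both* sexes are excluded from the averages — they carry no
signal and would otherwise dilute windows at assembly gaps; windows that are
entirely dark in both sexes are reported but never classified. Terminal
windows are kept, truncated at the chromosome end, so chromosome ends have
no blind spot.

`classify_windows()` labels a window `Y_specific` when the female
per-individual mean is at most `y_female_max_per_ind` (default 0.1, the
"almost complete absence" threshold) and the male mean at least
`y_male_min_per_ind` (default 2.0, requiring real male coverage rather than
noise), and otherwise `X_like` when the male mean is at least 2.0 and the
female:male ratio falls in `x_ratio_band` (default [1.6, 2.4] around the
2-fold signature). Y labels use absolute per-individual thresholds and are
therefore not invariant to rescaling both pools; the ratio-based X label is.
Per-individual normalization divides by pool size only: per-sample coverage
differences within a pool are second-order for pooled means, though a
coverage-weighted variant can be built from the cohort's per-sample
coverages.

Same-class windows are unioned by `merge_regions()` when they overlap or lie
within `merge_max_gap` (default one step), so a half-window dropout does not
split a region but a full unlabeled window does.

## Base-resolution refinement

Window calls are only as sharp as the step. `refine_breakpoints()` narrows
each region inside a search interval padded by one window on each side:

* `Y_specific`: the maximal run of consecutive positions with pooled female
  depth at most `y_female_abs_base` (default 0 — the strictest reading of
  male-specificity) and pooled male depth at least 1.
* `X_like`: the maximal run where the per-base per-individual female:male
  ratio lies in `x_ratio_band` after smoothing with a **centered running
  median** of width `ratio_smooth` (default 51 bp).

Ties are broken leftmost-longest, deterministically. The median rather than
a moving mean is a deliberate numerical choice: the underlying copy-number
signal is piecewise constant, and a running median is edge-preserving — at a
true breakpoint the smoothed ratio switches bands at the breakpoint itself,
whereas any linear smoother blurs the step across half its support and
systematically trims ~`ratio_smooth`/4 bases off each side of a short
segment. With Poisson depth at realistic pool sizes the per-base ratio has a
coefficient of variation of a few percent, which a width-51 median reduces
far below the band half-width, so refinement is simultaneously noise-robust
and boundary-exact.

### Sub-window X segments

A window-level ratio test has a hard geometric limit: a segment of length
$\ell$ inside a window of width $w$ shifts the window's female:male ratio
only to $1/(1 - \ell/2w)$, so reaching the 1.6 band floor requires
$\ell \ge 0.75\,w$ — a few hundred base pairs of X-specific sequence can
never label a 1000 bp window, no matter how clean the data. Such segments
are, however, structurally tied to the Y insertion: they are the X-haplotype
alternative at the same locus, so they adjoin a Y breakpoint. `depth_scan()`
therefore finishes by searching the one-window neighborhood on each side of
every refined Y region for base-resolution runs satisfying the same
smoothed-ratio criterion (requiring at least `ratio_smooth` qualifying
bases), and emits them as `X_like` region calls. Window-commensurate X
segments are still found by the ordinary window route; the neighborhood
search only adds calls where the window statistic is geometrically blind.

## Integration and ranking

`integrate_candidates()` attaches depth regions to each SNP cluster when
they overlap the cluster span padded by `flank` (default 10 kb, absorbing
window-resolution slack), and emits unattached depth regions as depth-only
candidates. Ranking is by evidence count — concordant SNP + Y + X evidence
first — with ties broken by span, then coordinate, a total deterministic
order. Adding evidence can only raise a candidate's rank class.

## Sequence characterization

Candidate genes at such loci are often zinc-finger family members.
`find_zinc_knuckle()` reports every (possibly overlapping) 14-residue window
matching the CCHC zinc-knuckle consensus Cys-X2-Cys-X4-His-X4-Cys, the
metal-binding motif of retroviral nucleocapsid-like RNA-binding proteins.
`classify_copy()` separates functional gene copies from pseudogenized ones
by the two lesion types that matter at desk scale: a premature stop codon in
frame 0 (standard nuclear code), and a frameshift left by a single-base
indel (CDS length not divisible by 3); a copy is functional iff it carries
the motif and neither lesion. Both lesions are monotone-destructive — no
such edit can make a copy functional.

`in_silico_pcr()` predicts amplicons by exact/Hamming primer matching (the
3'-terminal base must always match exactly, since polymerase extension is
intolerant there; no thermodynamics), and `sex_call()` applies the duplex
band logic: a Y-specific forward primer and a common forward primer share
one common reverse primer, so females (X/X) show the common product only and
males (X/Y) additionally show the Y-specific product — one band versus two.

## The simulator

`sim_config()` declares a complete scenario; every generator is a pure
function of it, re-seeded per generator, so outputs are byte-identical under
a fixed seed. The default scenario plants:

* a 9,149 bp male-specific Y insertion and a 425 bp X-specific segment on a
  1 Mb chromosome (`y_start` 500 kb);
* nine fully sex-linked SNPs flanking the insertion, spanning 14,950 bp;
* 10,000 autosomal HWE SNPs with allele frequencies uniform on [0.05, 0.95];
* a cohort of 49 males and 53 females at per-individual coverage
  λ = 15 (per-sample coverages in the sheet drawn from 12.4–19.0×).

The scan reference is deliberately a *hybrid* chromosome carrying the Y
insertion and the X segment side by side. This mirrors how such loci
actually present in a draft assembly built from a heterogametic individual:
the assembler conflates the two haplotypes, so males map at half
per-individual depth across both segments (one Y, one X) while females pile
up at zero on the Y segment and at full depth on the X segment — exactly the
signatures the depth scan keys on. The pure X- and Y-haplotypes (shared
flanks, differing only at the locus; length difference 9,149 − 425 bp) are
also emitted, and serve as PCR templates.

Depth is simulated directly at the per-base pooled level — Poisson draws
around the architecture's expectations, or rounded expectations in
noise-free mode — not via simulated reads. The generator therefore does not
model mappability or GC bias, mismapping plateaus (beyond a constant
`female_leak_rate` into the Y segment), LD decay around the locus,
population structure, or genotype-likelihood uncertainty. Passing recovery
tests consequently demonstrate the correctness of the statistics and the
breakpoint logic under the stated model, not robustness to alignment
artifacts in real resequencing data; on real data the classification
thresholds (`y_female_max_per_ind`, `x_ratio_band`) are the knobs that
absorb those artifacts.

Problem sizes in the shipped tests are a deliberate compromise: module and
property tests run on a 60 kb scenario (3 kb Y, 400 bp X, cohort 8/9), while
the fixture-recovery tests use the full default scenario above; both
complete in seconds.

## Worked run

```{r pipeline}
cfg <- sim_config(seed = 42L, noise_mode = "none")
gen <- simulate_genotypes(cfg)
scan <- scan_sex_linked(gen$variants, gen$cohort, scan_params())
scan$clusters

dep <- simulate_depth(cfg)
ds <- depth_scan(dep$male, dep$female)
ds$regions[, c("region_class", "refined_start", "refined_end",
               "refined_length", "mean_ratio")]

integrate_candidates(scan$clusters, ds$regions)
```

The strict scan recovers the nine planted sex-linked variants in one
cluster; refinement recovers the planted 9,149 bp Y insertion and 425 bp X
segment at base precision; integration ranks the single concordant locus
first with all three evidence flags set.

## Known limitations

* One diploid autosomal baseline: sex-chromosome dosage elsewhere in the
  genome (e.g. an old differentiated X) is not modeled and would need
  adjusted thresholds.
* The depth scan reports no significance measure — it is a detection filter
  with interpretable thresholds, not a test; calibration against the
  genome-wide differential distribution is the user's job.
* The in-silico PCR mismatch model is Hamming with a 3' anchor; primers with
  strong secondary structure or near-duplicate genomic sites need wet-lab
  validation regardless.
* Multi-chromosome inputs are supported by the readers and the CLI loop, but
  each chromosome is scanned independently; no cross-chromosome evidence
  model exists.
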