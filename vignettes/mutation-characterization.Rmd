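---
title: "Characterizing radiation-induced mutations with radmut: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing radiation-induced mutations with radmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmut)
```

radmut implements the desk analysis of a whole-genome resequencing
mutagenesis experiment: a cohort of plants is irradiated, one progeny plant
per line is resequenced, candidate variant calls are filtered and condensed
into classified mutation events, and the event sets are summarized as
rates, spectra and deletion-junction microhomology, alongside a
dose–survival curve fit. This vignette explains the underlying models and
conventions, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design choices made where the
problem was genuinely open.

## Filtering model

Candidate calls carry an allele frequency (AF): the fraction of reads
supporting the mutant allele at the site in one sample. Three rules, in
order, turn candidate calls into retained, zygosity-labelled calls
(`filter_calls()`; thresholds in `filter_config()`):

1. **Shared sites** — a site (chromosome, position, alleles, class, after
   normalization) detected in more than `shared_site_max_samples = 2`
   distinct samples is removed everywhere. Independently arising identical
   mutations in three or more lines are vastly less likely than a
   systematic calling artifact, so such sites are treated as false
   positives.
2. **Low AF** — calls with AF ≤ `af_exclusion_max = 0.25` are removed. A
   true heterozygous variant is expected at AF ≈ 0.5; values at or below
   0.25 are more consistent with mapping artifacts or subclonal/somatic
   signal.
3. **Zygosity** — a call is heterozygous when 0.25 < AF < 0.80 and
   homozygous when AF ≥ 0.80 (`het_hom_boundary = 0.80`, boundary
   inclusive on the homozygous side); in both cases the same site must show
   AF < `other_sample_max = 0.05` in *every* other sample, otherwise the
   call is rejected as cross-sample signal. Other-sample AFs are looked up
   in the unfiltered call set, so low-frequency signal elsewhere still
   disqualifies a call.

Every input call therefore lands in exactly one of five partitions
(retained het/hom, shared-site, low-AF, other-sample-signal), and the
pipeline log asserts that the partition counts sum to the input count.
"More than two samples" is read literally (a site in exactly two samples
survives); the threshold is configurable because designs with many sibling
lines may prefer a stricter rule. The upstream practice of confirming calls
by eye in a genome browser is replaced by these automated rules — nothing
in the package models read-level evidence.

## Event model

Indels are first **left-aligned**: insertions and deletions are shifted to
the leftmost placement that yields the same derived sequence, with shared
flanking bases trimmed (`normalize_calls()`). This makes site identity,
merging and microhomology well defined regardless of how the caller chose
to report an ambiguous indel. Multi-base substitutions read from VCF are
split into per-base substitution calls, and length-changing replacements
into a deletion plus an insertion; the merge step below then reconstitutes
them as one complex event, which is how the seven-category scheme treats
adjacent changes.

Two variants belong to the same **mutation event** when fewer than
`merge_window_bp = 10` reference bases lie between their spans; events are
the transitive closure of this relation, computed per sample and
chromosome. An insertion occupies the zero-length interval between its two
flanking bases, so "intervening bases" is exact for all class pairs. A
cluster of two or more variants is a **complex-type** event and counts as
one mutation everywhere; isolated variants classify by class and length
(SBS, −1, +1, Del ≥2 bp, Ins ≥2 bp), and inversions/translocations are SV
events that never merge with small variants (they are called by different
algorithms on different evidence, and a breakpoint coincidentally near an
SBS is not one repair event). The merge threshold is deliberately "two or
more variants": complex events consisting of exactly two substitutions are
a recognized class, so a two-variant cluster must not be split back into
two SBS events.

Within a complex event, the mutant segment is described as **change
blocks**: runs of at least `spacer_min_match = 2` reference-matching bases
delimit blocks, and a single matching base between two changes is absorbed
into one block (`describe_complex()`). Blocks report their reference and
derived sequence, so applying an event's members and re-deriving its blocks
is a tested round trip.

Mixed-zygosity clusters (members disagreeing) are kept as one event with
the majority zygosity and a `zygosity_mixed` flag rather than dropped;
ties resolve to heterozygous, the more probable state.

## Deletion-junction microhomology

For a deletion of length d ≥ 2, the **apparent microhomology** is defined
as the number of distinct placements of a d-bp deletion that produce the
identical derived sequence, minus one. Shifting the deleted segment one
base rightward is valid exactly when the base entering the junction matches
across it, so the count equals the leftward plus rightward longest common
extension at the junction (`compute_microhomology()`). Two consequences of
this definition are deliberate:

* it is **placement-invariant** — any equivalent reported placement gives
  the same value (tested against a brute-force placement-enumeration
  oracle), and
* it is **uncapped in tandem repeats** — deleting 2 bp from a 5-bp
  mononucleotide run reports 3 bp of microhomology, which can exceed the
  deletion length. The raw ambiguity is reported because any cap would be
  an arbitrary convention; users binning at ≥10 see repeat-mediated
  deletions accumulate there.

A junction is **undefined** (reported and counted, excluded from
distributions) when an `N` base occurs in the deleted segment or within one
deletion length of either flank. A chromosome edge merely truncates the
homology scan rather than invalidating the junction: the placement-count
definition remains exact there, and discarding telomere-proximal deletions
would bias the distribution. Bins are 0 / 1 / 2 / 3–4 / 5–9 / ≥10 bp,
chosen so the characteristic peaks of NHEJ-proficient (2 bp) and
NHEJ-deficient (3–4 bp) material fall in separate bins; the edges are
configurable in spirit — `bin_microhomology()` is a thin wrapper over
`cut()` — but fixed labels keep reports comparable. Only simple Del ≥2 bp
events feed the junction analysis: deletions inside complex events have no
unambiguous junction (the neighbouring changes confound the extension), so
they are excluded by default.

## Rates, spectra and zygosity

Per-plant event counts per category are converted to per-bp rates
(mean ± SE across plants, reported ×10⁻⁸) and per-Gy rates (exact division
by dose, ×10⁻¹⁰) in `summarize_strain()`. The default denominator is the
119,146,348 bp golden path of the five Arabidopsis chromosomes — the
haploid non-redundant assembly, not a diploid length, because that is the
territory in which mutations are callable. Note that published per-bp
tables in this field sometimes coincide numerically with per-plant event
counts; radmut reports both `count_mean` and the per-bp columns so the
denominator is always explicit. Homozygous events count once, not twice:
events are characterized irrespective of zygosity.

Substitution spectra collapse the twelve base changes onto six classes by
strand symmetry. Complex-event members are excluded from the spectrum and
from indel length bins by default (`include_complex = FALSE`): category
tallies count events, and double-counting complex members as SBSs would
break additivity with the per-category rates.

Under selfing, an induced heterozygous mutation segregates 1:2:1 in the
next generation, so among mutations *detected* in one sampled M₂ plant the
homozygous:heterozygous ratio has expectation (1/4)/(1/2) = 0.5.
`zygosity_ratio()` reports the ratio and a two-sided exact binomial test of
the homozygous count against expected fraction 1/3 of detected events.
Per-type mutant-versus-control comparisons use a Welch t-test utility; no
multiple-testing correction is applied, mirroring common practice of
reporting per-type tests at P < 0.05 — users comparing many types should
adjust externally.

## Survival model

Seed survival versus dose follows the single-hit multitarget model
S(D) = 1 − (1 − e^(−D/D₀))ⁿ, with D₀ the mean lethal dose per target and n
the extrapolation number; the shoulder of the curve is summarized by the
quasi-threshold dose Dq = D₀·ln n (0 exactly when n = 1; S(0) = 1 for any
parameters). `fit_single_hit_multitarget()` minimizes unweighted squared
error on the linear fraction scale, because the assay's binomial noise is
roughly homoscedastic on that scale at moderate survivor counts and a log
transform would overweight the low-survival tail. n is continuous and
constrained ≥ 1, standard in target theory. The residual surface is
non-convex, so the fit multi-starts from a log-spaced grid (seven D₀ values
spanning max dose/30 to 3× max dose; n ∈ {1, 2, 4, 8, 16, 32}) and keeps
the lowest residual, breaking ties toward the smaller n (the less-shouldered,
more parsimonious curve). Zero fractions are floored at `1/180` — half a
plant out of three replicates of thirty, the default assay size — before
fitting. Approximate standard errors come from the local curvature, with a
delta-method SE for Dq; they are unavailable on the n = 1 boundary.
Normalization to the unirradiated control is available
(`survival_fractions(, normalize = TRUE)`) but off by default since
absolute fractions are what the assay reports.

## What the synthetic generator emulates — and what it does not

`generate_reference()` draws an i.i.d. genome at a target GC content
(default 0.36, Arabidopsis-like). `spike_mutations()` draws per-plant
category counts Poisson around a strain profile's rates, then places
events:

* substitution classes, indel length bins and the deletion
  microhomology-bin distribution follow the profile weights — the class or
  bin is drawn **once per event** and placements are rejected until they
  realize it (up to 1000 tries, then the event is skipped and counted),
  so the realized distributions match the targets rather than the genome's
  base composition;
* complex events are 2–3 variants separated by 2–8 matching bases
  (substitution-only with the profile's probability, otherwise containing
  short indels);
* zygosity is homozygous with probability 1/3, the Mendelian expectation
  among detected M₂ mutations (`simulate_m2()` exposes the full 1:2:1
  draw);
* events of all samples stay ≥ 100 bp apart, so left-alignment (which can
  shift a deletion by its microhomology length) never pushes two events
  into one merge window.

`emit_candidate_calls()` converts truth to calls with
AF = Binomial(depth_i, p)/depth_i at Poisson per-site depth (p = 0.5 het,
1.0 hom), or exact AFs in `af_mode = "exact"`; it can inject low-AF noise
calls and artifact sites shared across >2 samples — constructed to be
removed by the low-AF and shared-site filters respectively. Long indels are
emitted through the sv_tsv dialect (emulating a dedicated long-indel
caller) and the rest through VCF, exercising both readers.

The built-in profiles (`wt_profile()`, `ku70_profile()`, `lig4_profile()`)
take their per-plant category rates from the published per-type rate table
(`strain_rate_table()`); the control cohort size is set to 10 plants
(the mutant cohorts are 10 and 9), a choice made here since the control
study's cohort is not restated in the table. Spectrum weights give the two
transitions and the A/T→T/A transversion a modest excess; control indel
lengths decrease from 1 bp while mutant deletions peak at 11–30 bp; the
microhomology targets peak at 2 bp (control, 24% with none) versus 3–4 bp
(mutants, 12% and 4% with none); complex events are 87% substitution-only
in the control versus 15% in the mutants. Survival parameters
(D₀ = 800/105/115 Gy, n = 13/6.3/6.9) were calibrated once so each
profile's Dq ≈ 2050/193/222 Gy, matching the reported shoulder ordering;
they are generator conditions, not fitted values.

What the generator does **not** emulate: mapping artifacts with locus
structure (noise is uniform), real genome repeat architecture (an i.i.d.
genome underrepresents long tandem repeats, so ≥10 bp microhomology is
essentially unreachable by rejection sampling and the profiles give it
weight 0), linked/clustered events beyond the built-in complex templates,
translocations (the SV rate is realized as inversions), and read-level
error profiles. Passing tests on synthetic data therefore demonstrate the
correctness of the algorithms under the stated statistical model — not
that a particular biological dataset would be reproduced.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere inside the package; the VCF
  anchor-base convention exists only at the I/O boundary, and deletions at
  position 1 are right-anchored on writing.
* The allele-frequency source field is configurable (`af_field`, default
  INFO key `AF`, with a per-sample FORMAT fallback), since callers differ
  in where they record it.
* Variants overlapping `N` are rejected at normalization (microhomology and
  spectra are undefined on `N`).
* An empty call set flows through the whole pipeline and produces all-zero
  summaries, not errors; a single plant yields SE = 0 with n = 1 visible in
  the output; a zero heterozygous count leaves the zygosity ratio undefined
  while still reporting counts.
* Desk-scale problem sizes: the default pipeline uses a 1 Mb toy genome
  with per-plant event counts equal to the published per-plant rates, and
  the test suite sizes its simulations (hundreds to a couple of thousand
  random cases per property) so a full run completes in about two minutes —
  chosen as comfortable desk-scale sizes that still give the statistical
  assertions (χ² goodness of fit at n ≈ 500 deletions, 3-SE binomial bands
  at n = 10,000, median-error bounds over 100 survival fits) real power.

## Known limitations

* The microhomology convention (summed two-sided extension, uncapped) is
  one of several in the literature; one-sided or capped definitions will
  give smaller values for repeat-adjacent deletions. The brute-force
  placement-count oracle in the tests pins down exactly which convention
  this package implements.
* Cross-sample exclusion applies to all variant classes uniformly, although
  SV callers in practice get their own "unique to a single sample"
  selection; set `shared_site_max_samples` accordingly if that matters.
* The Welch utility and exact binomial test are the only inferential tools
  included; ANOVA-style multi-group comparisons are out of scope.
* Phasing of complex-event members onto haplotypes, breakpoint assembly for
  SVs, and microhomology for insertions or complex events are not
  attempted — the last because neighbouring changes make the junction
  extension ill-defined.
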