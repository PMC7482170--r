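# radmut

Genome-wide characterization of mutations induced by ionizing radiation in
whole-genome resequenced mutant cohorts — built for experiments that compare
DNA double-strand-break repair backgrounds (e.g. wild-type versus
NHEJ-deficient *Ku70* / *Lig4* knockouts in Arabidopsis), but applicable to
any design that produces per-sample candidate variant calls with allele
frequencies plus dose–survival assay tables.

## What it computes

Downstream of read mapping and variant calling (GATK-, Pindel- and
BreakDancer-style outputs are modelled by a VCF subset and a simple
tab-separated SV dialect), the package implements:

* **Candidate-call filtering and zygosity assignment.** Calls with allele
  frequency AF ≤ 0.25 are excluded; sites detected in more than two
  independent samples are excluded as systematic false positives; a retained
  call is heterozygous when 0.25 < AF < 0.80 and homozygous when AF ≥ 0.80,
  requiring AF < 0.05 at the site in every other sample.
* **Mutation-event construction and seven-way classification.** Indels are
  left-aligned to a minimal representation; variants separated by fewer than
  10 intervening reference bases are merged into a single event (transitive
  closure), giving the categories SBS, −1, +1, Del ≥2 bp, Ins ≥2 bp,
  complex-type and SV. Complex events are decomposed into change blocks,
  where runs of ≥ 2 reference-matching bases delimit blocks.
* **Deletion-junction microhomology.** For every Del ≥2 bp, the apparent
  microhomology is the number of distinct equal-length placements of the
  deletion that yield the identical derived sequence, minus one — computed
  as the left + right longest common extension across the junction, binned
  as 0 / 1 / 2 / 3–4 / 5–9 / ≥10 bp.
* **Rates and spectra.** Per-plant event counts per category; per-bp rates
  (mean ± SE, ×10⁻⁸) and per-Gy rates (×10⁻¹⁰); strand-collapsed
  six-class substitution spectra; indel length bins (1 / 2–10 / 11–30 /
  31–100 / >100 bp); homozygous:heterozygous ratio with an exact binomial
  test against the Mendelian M₂ expectation (hom:het = 1:2, i.e. ratio 0.5);
  mutant-versus-control fold changes.
* **Survival-curve fitting.** The single-hit multitarget model
  S(D) = 1 − (1 − e^(−D/D₀))ⁿ is fitted by multi-start least squares
  (D₀ = mean lethal dose per target, n = extrapolation number ≥ 1), and the
  quasi-threshold "shoulder" dose is derived as Dq = D₀·ln n.
* **Synthetic data.** A generator produces reference genomes, ground-truth
  mutation sets per strain profile (category rates, spectra, indel-length
  and microhomology-bin targets, complex-event composition), candidate
  calls with binomial read-support allele frequencies plus injected noise
  and multi-sample artifacts, M₂ segregation, and binomial dose–survival
  tables — so the whole pipeline is testable with no external data.

## Worked example

```r
library(radmut)

res <- run_pipeline(default_config(out_dir = "radmut_out", seed = 3))
subset(res$summaries, type %in% c("SBS", "DelGE2", "Total"),
       c(strain, type, count_mean, rate_per_bp_per_gy_e10))
res$survival[, c("strain", "d0_gy", "n_extrapolation", "dq_gy")]
```

On a 1 Mb toy genome with the built-in wild-type-like (1000 Gy) and two
NHEJ-deficient (100 Gy) strain profiles, a run with seed 3 prints per-Gy
rates (×10⁻¹⁰, toy-genome denominator) in which the control is dominated by
substitutions while the mutants show the deletion excess, e.g.

```
   strain   type count_mean rate_per_bp_per_gy_e10
1      WT    SBS     28.100                  281.0
4      WT DelGE2      6.300                   63.0
8      WT  Total     46.900                  469.0
9  AtKu70    SBS      5.100                  510.0
12 AtKu70 DelGE2      4.500                  450.0
16 AtKu70  Total     12.000                 1200.0
17 AtLig4    SBS      5.111                  511.1
20 AtLig4 DelGE2      5.333                  533.3
24 AtLig4  Total     11.889                 1188.9
```

The per-dose deletion excess of the mutants (Del ≥2 bp rate ≈ SBS rate,
versus a control dominated by substitutions, and more than twice the total
per-Gy rate of the control) falls out directly. The survival fits recover
each profile's generating parameters:

```
  strain  d0_gy n_extrapolation  dq_gy
1     WT 772.45          16.085 2145.8
2 AtKu70  97.93           6.820  188.0
3 AtLig4 116.28           6.589  219.2
```

Exact numbers vary with the seed; the pipeline reruns
byte-identically for a fixed seed, and `radmut_out/` holds the full TSV
reports (`events.tsv`, `strain_summary.tsv`, `sbs_spectrum.tsv`,
`indel_lengths.tsv`, `junctions.tsv`, `mh_distribution.tsv`,
`zygosity.tsv`, `fold_changes.tsv`, `survival_fit.tsv`, `run_log.txt`).

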