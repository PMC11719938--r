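---
title: "Detecting processed pseudogenes and the variant artifacts they cause"
author: "ppsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting processed pseudogenes and the variant artifacts they cause}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A processed pseudogene (PP) is an intronless copy of a gene, created when an
mRNA is reverse-transcribed and the cDNA reintegrates somewhere in the genome.
Because the copy is nearly identical to its parent gene's exons — and because
many PPs are private to individuals or populations and therefore absent from
the reference — short reads that actually come from the PP are routinely
mapped onto the parent gene. Three things happen downstream:

1. **Structural-variant callers report intronic deletions.** Reads spanning
   the PP's exon-exon joins align to the parent with the intron "missing", so
   an SV caller emits one deletion call per intron, with breakpoints at the
   intron boundaries.
2. **Exon coverage is inflated.** PP-derived reads pile onto exons only, so
   the exon/intron mean-depth ratio rises from about 1 to about `(2+c)/2` in
   a carrier with `c` extra copies (1.5 for a heterozygous carrier).
3. **Small-variant calls appear with low allelic balance.** Positions where
   the PP has diverged from its parent are called as variants on the parent.
   Since the alternative reads come from `c` of the `2+c` mapped copies, the
   allelic balance (AB, alternative reads over total reads) sits near
   `c/(2+c)` — roughly 25–33% — instead of the diploid 50%/100%. Calls at
   intron–exon junctions are the worst offenders: junction-spanning PP reads
   disagree with the intron sequence and produce frameshift or splice-loss
   calls that classifiers label pathogenic.

`ppsieve` turns each signature into a computable diagnostic and combines them
into a per-variant verdict over a cohort.

## The pipeline

`read_gene_models()` parses a GTF/GFF3 annotation into merged gene models.
Exons of all transcripts are unioned ("merged projection"): the annotation
does not say which isoform a retrocopy derives from, and the union is the
conservative choice for defining introns — a deletion matching a union-gap is
intronic under every isoform. Coordinates are 0-based half-open internally
(the BED convention) and converted at the VCF (1-based) boundaries.

`detect_pp()` matches each sample's deletion calls against each gene's
introns. A match is **breakpoint-anchored**: both deletion ends must lie
within `tol` (default 10 bp) of the corresponding intron boundary. Mere
overlap does not count — an overlap criterion would fire on ordinary genomic
deletions, while the retrocopy signature is specifically junction-to-junction.
A deletion spanning several introns consequently matches none of them. A gene
reaches a `PP_present` verdict at `min_matched_introns` matched introns
(default 2): a single intron-sized deletion is a perfectly plausible true SV,
whereas two breakpoint-exact intronic deletions in one gene essentially only
occur via a retrocopy. Genes with fewer introns than the threshold are
reported `undetectable` rather than negative. `cohort_pp_matrix()` and
`pp_frequency()` aggregate the calls into the cohort carrier table and
per-gene frequencies; `pp_novel_report()` splits detected genes by presence
in an annotated pseudogene list.

`exon_intron_ratio()` computes the per-gene length-weighted exon and intron
mean depths from a bedGraph depth track and their ratio. Bases absent from
the track count as depth 0 by default (depth trackers emit complete tracks,
so zero-fill is safe); an `"ignore"` policy drops them from the denominator.
A zero intron mean leaves the ratio `NA` and flagged rather than infinite.

`allelic_balance()` / `summarize_ab()` compute per-variant AB as
`ad_alt / (ad_ref + ad_alt)` — the AD sum, not DP, because DP includes
uninformative reads — and summarise distributions as 5%-bin histograms with
their modes. Bins are the 20 equal right-open intervals over [0, 1], the last
closed so AB = 1 is counted; a mode is a bin strictly higher than both
neighbours, and a plateau resolves to its lowest-AB bin. We report histogram
peaks rather than a kernel density because the quantity of interest is "where
do the counts peak", not a smooth estimate. Under this binning a diploid
background peaks in the bins containing 50% (bin centre 52.5%) and 100%
(centre 97.5%), and a PP-shifted group in the bin containing 1/3 (centre
32.5%).

`flag_variants()` evaluates three independent criteria per clinically
labelled variant and flags it `likely_pp_artifact` when all evaluable
criteria hold:

* junction distance ≤ `junction_window` (default 10 bp — the canonical
  splice-region width; "sits on the junction" is a qualitative observation,
  so a small fixed window formalises it);
* carrier/PP-carrier association: a Pearson chi-squared test on the 2×2
  cohort split, significant at `alpha` (default 0.05, no multiple-testing
  correction by default; a `p_adjust` option is available) **and** enriched
  in the PP direction;
* mean carrier AB ≤ `ab_ceiling` (default 0.40, between the PP-shifted
  ~25–33% and the heterozygous 50% mode).

The conjunction of the three criteria is this package's formalisation of a
narrative procedure; each criterion is reported separately in the output so a
user can apply a different rule. A criterion that cannot be computed (no AD
data; a degenerate contingency margin, e.g. when every sample carries the PP;
an intron-less gene) is marked unevaluable and dropped from the conjunction
instead of silently failing the variant. `fp_report()` tabulates flagged
carriers per caller and gene, retaining all-zero rows for callers that flag
nothing, plus the percentage of cohort samples affected.

## The synthetic cohort generator

`simulate_cohort()` emits the *downstream evidence* the pipeline consumes —
SV deletion records, depth tracks, and GT:AD variant records — rather than
reads. Read-level simulation would add a mapper to the loop without
exercising any additional code path of this package, whose inputs are caller
outputs by design.

For each sample and gene the generator draws a PP genotype
(`c ∈ {0, 1, 2}` copies, Hardy–Weinberg at the gene's `pp_allele_freq`, or an
exact quota when `carrier_fraction` is set) and emits:

* one deletion record per intron for carriers, breakpoints jittered uniformly
  within `sv_jitter` (default ±3 bp, inside the detector's 10 bp tolerance —
  callers place breakpoints imprecisely but close), plus `background_dels`
  random decoy deletions per sample;
* a depth track with exon intervals scaled by `(2+c)/2` and introns at the
  base depth (default 30×, the standard WGS operating point), with optional
  Poisson interval noise;
* background small variants (het at AB 0.5, hom at 1.0; Poisson means 1.5 and
  0.5 per gene per sample) and, for carriers, `pp_divergence_variants`
  (default 8) divergence variants shared across carriers like a real PP
  haplotype, the first ones sitting exactly on exon junctions. With the
  default rates a carrier harbours `(8 + 2)/2 = 5×` more variants in the gene
  than a non-carrier — the cohort-scale excess chosen as the study condition.
* AD totals at variant sites follow the mapped-copy model: a fraction
  `read_loss` (default 0.15) of PP-derived reads fails to map back onto the
  parent, so a divergence variant's AB expectation is
  `c(1-l) / (2 + c(1-l))` ≈ 0.30 for a het carrier — inside the 25–30% band
  observed for real artifact variants. `read_loss` is a tuning knob of the
  generator, not a measured quantity.
* one recurrent junction artifact variant per PP gene listed as a clinically
  labelled (`LP`) variant, and a genuine mid-exon `P` variant carried by a
  random `true_clinical_rate` of samples — the positive and negative controls
  for `flag_variants()`.

Every record traces to a truth row (`truth_pp`, `truth_variants`), making the
forward/inverse loop testable: with noise off (`depth_noise = "none"`,
`ad_sampling = "exact"`, `read_loss = 0`) the coverage ratio is exactly
`(2+c)/2` and every AB equals its copy-number expectation; with defaults, the
detector's sensitivity and false-call rate against the truth table are the
package's operating-point check (≥ 0.95 / ≤ 0.01 on a 200-sample cohort).

What the generator does **not** emulate: mapping-quality structure, GC and
mappability bias, segmental duplications and other homology that can mimic
the coverage signature, multi-nucleotide divergence haplotypes, and partial
(isoform-specific) retrocopies. Tests passing on simulated cohorts therefore
demonstrate the pipeline's internal consistency and its behaviour under the
stated generative model, not its accuracy on any real cohort.

## Numerical and design choices

* **Problem sizes.** The shipped tests use cohorts of 15–400 samples over
  panels of 5–50 synthetic genes, and the acceptance script a 300-sample
  null cohort (≈ 3 000 background variants) — large enough that the binomial
  histograms and detection rates are stable at fixed seeds, small enough to
  run in seconds.
* **Chi-squared implementation.** The 2×2 Pearson statistic is computed from
  the margin-product expected counts, with Yates correction off by default
  (the flagging rule is built on the plain chi-squared test); p-values come
  from the 1-df chi-squared distribution. The test suite checks the statistic
  exhaustively against the algebraic identity `n(ad−bc)² / (r₁r₂c₁c₂)` on all
  tables with margins ≤ 20, and the p-value against a fixed-margins
  permutation (hypergeometric) null.
* **Degenerate inputs.** Zero-AD variants are excluded from AB with a
  warning; zero-margin tables refuse the test; genes without introns are
  skipped by the coverage ratio and error on junction distance; deletions
  with neither `END` nor `SVLEN` are skipped with a warning; duplicate
  (sample, gene) PP calls are deduplicated with a warning.
* **Ratio direction.** The coverage ratio is exon mean over intron mean:
  carriers then sit above 1, consistent with extra exon-only reads.
* **Intron subsets.** `detect_pp()` counts any `min_matched_introns` matched
  introns, not necessarily consecutive ones. Requiring consecutive introns
  would encode an assumption about partial retrocopies that the deletion
  evidence cannot distinguish.

## Limitations

The detector cannot locate the PP's integration site (the deletion evidence
lives entirely on the parent gene), cannot call PPs for genes with fewer
introns than the match threshold, and inherits the SV caller's breakpoint
quality through `tol`. The artifact flag is evidence of PP origin, not a
clinical reclassification. On real data, paralogy and reference PPs produce
related but distinct signatures that this package does not model.
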