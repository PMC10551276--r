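---
title: "Methods: somatic mtDNA profiling and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic mtDNA profiling and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosomatic)
```

## Scope and model

`mitosomatic` analyses single-nucleotide variant calls on the human
mitochondrial genome (rCRS, NC_012920.1; 16,569 bp) from matched
normal, tumor and, optionally, serum-EV samples sequenced at deep
coverage. It does not process reads: alignment, primary variant
calling and haplogroup assignment are upstream concerns, and their
outputs (VCF or tabular calls, plus a haplogroup-marker list) are this
package's inputs.

The analysis chain is:

1. **Filtering.** A sample enters somatic calling only if its mean
   coverage strictly exceeds `min_sample_coverage` (default 1000×);
   variant observations with fewer than `min_variant_reads`
   (default 100) supporting reads are discarded. Both boundaries are
   intentionally asymmetric: exactly 1000× is excluded, exactly 100
   reads is kept.
2. **Somatic calling.** A tumor observation is somatic iff no
   observation with the identical (position, ref, alt) key exists in
   the filtered matched normal and its key is not a haplogroup marker
   in the known-variant table. Matching is allele-level, not
   site-level: a different alt at the same normal-side position does
   not suppress the call. The matched normal is mandatory — a missing
   or coverage-excluded normal is an error, not a fallback to
   tumor-only calling.
3. **Annotation.** Each call gets its gene (with the documented
   overlap tie-break), coding/noncoding class, respiratory complex,
   transition/transversion class, MAF, alt fraction and heteroplasmy
   state.
4. **Aggregation.** Cohort statistics (spectrum, frequencies, hotspot
   panel, novelty/pathogenicity, loads) and tumor–EV concordance.

## The gene map and its conventions

The rCRS feature table is embedded as a compiled-in constant: 13
protein genes partitioned into respiratory complexes
(RCI = MT-ND1/2/3/4/4L/5/6, RCIII = MT-CYTB, RCIV = MT-CO1/2/3,
RCV = MT-ATP6/8), 22 tRNAs, RNR1/RNR2, and the control region stored
as two segments (16024–16569, 1–576) under one name so wrap-around
coordinates classify identically. Known overlaps (MT-ATP8/MT-ATP6,
MT-ND4L/MT-ND4, MT-ATP6/MT-CO3, TRNI/TRNQ, TRNC/TRNY) are preserved.

Three conventions are deliberate choices, documented because genuine
alternatives exist:

- **Coding vs noncoding.** "Coding" means protein genes only; rRNA,
  tRNA, control region and intergenic spacers are all "noncoding".
  This matches how mtDNA mutation-profiling studies tabulate their
  spectra (rRNA/tRNA mutations are counted under noncoding even
  though those genes are transcribed).
- **Overlap tie-break.** `locate_position()` reports every feature
  containing a position, but the *primary* feature is the one with the
  smaller start coordinate (e.g. MT-ATP8 at 8527–8572). Published
  catalogs name one gene per mutation without stating a rule; a
  deterministic, auditable tie-break keeps counts reproducible, and
  `all_features` lets callers re-count per gene.
- **Mutation identity.** A mutation is the key (position, ref, alt)
  in heavy-strand `<ref><position><alt>` notation. Spectrum totals
  count distinct keys (a mutation in k patients counts once); loads
  and frequencies count patient-mutation pairs. Both views are
  computed explicitly because cohort reports routinely mix them.

## Codon effects

`coding_effect()` translates with the vertebrate mitochondrial code
(NCBI table 2: AGA/AGG stop, ATA Met, TGA Trp), embedded as the
package's own codon table; the light-strand gene MT-ND6 is handled by
complementing in the reversed frame. Genes ending in a partial stop
codon (completed by transcript polyadenylation) yield `NA` amino
acids for substitutions in the partial codon rather than a fabricated
translation. The test suite cross-checks every codon against
`Biostrings::translate()` with the same code as an independent oracle.

The true rCRS nucleotide sequence is not bundled:
`synthetic_reference()` provides a seeded, clearly-labelled synthetic
stand-in (with an option to pin specific reference bases so named
mutation keys stay consistent), and all sequence-dependent tests run
against it. Real analyses should supply the genuine NC_012920.1 FASTA
via `read_reference_fasta()`; every coordinate-level function is
independent of the sequence.

## MAF, heteroplasmy and rounding

The MAF reported here is mutant reads / wild-type reads × 100 — a
ratio, not a fraction, and unbounded. It is kept verbatim for
comparability with studies that define it this way, but it is a poor
classification variable, so heteroplasmy is classified on the bounded
alt fraction `a/(a+r)` instead. A site with zero wild-type reads has
an undefined ratio; it is retained with an `NA` sentinel (never
infinity) and is homoplasmic by construction.

The homoplasmy threshold (alt fraction ≥ 0.95) is a convention, not a
measured constant: deep-sequencing studies rarely state one, and
published values range roughly 0.90–0.99. It is prominently
configurable in `filter_config()`.

All reported percentages round half-up to integers
(`round_half_up()`), loads to one decimal. Published tables are not
always internally consistent under any single rounding rule (e.g. a
13/23 printed as 56%); the package applies its strict policy uniformly
rather than matching such artifacts.

## The synthetic cohort generator

`simulation_config()` defaults encode the study conditions the
pipeline is designed around: 32 patients split 7 African / 25
European, mean somatic loads 7.5 and 4.6 mutations per patient with a
hard minimum of 3, read depth ~ NegBin(mean 5000, size 10), an 18%
homoplasmic component, transition:transversion odds 4:1, EV samples
for 9/32 patients with per-mutation detection probability 0.38,
~1.2 EV-exclusive mutations per EV patient, and the bundled hotspot
panel injected at its per-mutation frequencies.

Values the study design does not pin down were chosen once as
realistic for deep mtDNA amplicon data and are not tuned:

- germline background: 20 haplogroup variants shared per ancestry
  plus Poisson(10) private variants per patient, all homoplasmic
  (inherited mtDNA variants typically are) and all emitted as
  haplogroup markers in the known-variant table;
- heteroplasmic alt fractions uniform on (0.10, 0.90) and homoplasmic
  on (0.98, 1.0) — deliberately clear of both the 100-read filter and
  the 0.95 threshold, so recovery tests measure the pipeline rather
  than boundary noise;
- somatic positions uniform over the genome (proportional to region
  length) and disjoint from the cohort's germline pool, so a somatic
  draw can never be silently eaten by the haplogroup exclusion.

What the generator does **not** emulate: sequencing error, strand
bias, NUMT contamination, position-specific mutability, linkage
between mutations, and FFPE artifacts. Passing recovery tests
therefore demonstrate the correctness of the filtering/calling/
aggregation logic under clean evidence, not robustness to noisy real
data — the latter is the upstream caller's domain.

Determinism: one seed fixes the whole cohort; `write_cohort()` output
(per-sample VCFs, manifest, known-variant table, reference FASTA,
truth ledger JSON) is byte-identical across runs. The VCF emitter
writes minimal plain-text VCFv4.2 with GT:AD:DP fields; the reader
accepts both GATK-style `AD` (ref first) and VarScan-style `RD`+`AD`
encodings.

## EV concordance conventions

Pooled traceability is the union-based share (a 17-of-45-style
number), not a mean of per-patient fractions; both are reported. EV
mutations matching the patient's normal profile are treated as
germline carry-over — EV cargo contains the patient's constitutive
mtDNA — and are excluded from both the traceable and the exclusive
sets, paralleling the somatic definition. Consequently the traceable
and EV-exclusive sets partition the somatic-relevant EV set, which is
asserted as a property test. The hotspot-panel detection rate is a
detection (sensitivity-like) quantity — the share of panel members
seen in at least one EV — even though such numbers are sometimes
loosely labelled "specificity" in the biomarker literature.

The bundled panel fixture ships the eight named members with their
frequencies; a full eleven-member panel is only partially public, so
the remaining entries are user-configurable and the worked examples
complete the panel with labelled placeholders.

## Problem sizes and numerical checks

The test suite and `scripts/acceptance.R` run at sizes chosen to make
stochastic checks sharp while staying fast: worked-example catalogs
of 168 distinct mutations (the published composition, e.g. RCI
per-gene counts 20/7/2/3/9/29/4 summing to 74), convergence checks at
60–120 patients, frequency-injection checks at 800 patients, and the
main parameter-recovery run at 200 patients (≈1000 somatic calls,
binomial standard errors ≈1.3–1.5 points, comfortably inside the
3-point acceptance band). Monotonicity (filter thresholds, EV
additions), conservation (coding+noncoding = total; complex counts
sum to coding; 4 transitions + 8 transversions partition the 12
ordered substitution classes) and set-algebra invariants are tested
on randomized catalogs under fixed seeds.

Known limitations: no indel support (substitutions only), no
alternative mitochondrial references (RSRS/Yoruba), no statistical
modelling of strand bias or sequencing error, no liftover. The
"present only in cancer" comparison is allele-level by design; a
site-level variant would need only a one-line change in
`call_somatic()` but would alter published-style counts.
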