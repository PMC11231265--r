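---
title: "Modelling an NGS-based BCR::ABL1 kinase-domain mutation assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an NGS-based BCR::ABL1 kinase-domain mutation assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abl1kd)
```

## The assay being modelled

Point mutations in the ABL1 kinase domain (KD) of the BCR::ABL1 fusion
transcript are the principal actionable mechanism of tyrosine-kinase-inhibitor
(TKI) resistance in chronic myeloid leukemia. The assay modelled here enriches
the fusion transcript (so only translocated ABL1 is sequenced), amplifies KD
codons 160–500 (≈1020 coding bases) with 12 overlapping 200–250 bp amplicons
split into two primer pools, sequences the amplicons deeply, and reports
substitution variants at a declared 2% VAF limit of detection together with
the TKIs to which each variant confers poor sensitivity.

`abl1kd` reproduces this workflow in silico: a seeded reference and panel, a
read simulator standing in for the instrument, a transparent pileup caller
standing in for the vendor pipeline, catalogue-based annotation, and the
validation statistics used to qualify such an assay.

## Coordinates and reference

All internal coordinates are KD-local, 0-based and half-open; codon numbers
(160–500) are the external addressing scheme; VCF export converts to 1-based
positions. `codon_to_base_range()` and `base_to_codon()` are exact inverses.

The real transcript sequence is not redistributed. Instead
`build_surrogate_reference()` generates a synthetic 1023-base coding sequence:

* **Catalogue codons** get a deterministic canonical codon: among codons
  encoding the catalogue wild-type residue, the one maximising how many of
  that codon's catalogued mutations are reachable by a *single-base*
  substitution, each mutation weighted by the number of TKIs it affects.
  Weighting matters at codon 315: no threonine codon reaches I, A, M and L in
  one substitution, and the weights make ACT (which reaches T315I, the
  clinically dominant mutation) win over ACG (which reaches only T315A/M).
  Ties break to the alphabetically last codon, which at codon 387 selects TTG
  and keeps L387M reachable. This choice is seed-independent, so any surrogate
  supports the same spike-in vocabulary.
* **All other codons** are drawn uniformly from the 61 sense codons under the
  seed, so the translation never contains a stop.

A user-supplied FASTA (e.g. derived from the real transcript) can replace the
surrogate everywhere; the catalogue's wild-type residues are validated on
load.

## Panel design

The published panel's primer sequences are not public, so
`build_amplicon_panel()` tiles the window algorithmically: 12 amplicons of
215–240 bp at evenly spaced, seed-jittered starts, alternating pools 1/2 so
adjacent amplicons never share a reaction, 20 bp primer regions excluded from
variant calling, and ≥ 20 bases of non-primer overlap between neighbours.
Because the target window is 1023 bases while amplicons must stay inside it, the
first amplicon's forward primer and the last amplicon's reverse primer are
treated as lying in flanking fusion-transcript sequence (`fwd_primer_len = 0`
/ `rev_primer_len = 0`), which is what makes gap-free *non-primer* coverage of
all 1023 bases possible. Note that 12 amplicons of ≈225 bp over 1023 bases
imply ≈2.6× average tiling redundancy — per-position depth is therefore 2–3×
the per-amplicon read count, as in the real design.

## The read simulator

`simulate_sample()` emits full-length amplicon reads (Ion-Torrent-style
single-end amplicon sequencing; no read pairs):

* reads are allocated uniformly over the 12 amplicons;
* each read covering a spiked position carries the alternate allele
  independently with probability `target_vaf/100` (binomial sampling), and the
  realized counts are recorded in a reloadable truth record;
* substitution errors are applied per base at `read_error_rate`
  (default 0.002), uniformly over the three other bases; homopolymer indels
  are deliberately not modelled because the caller handles substitutions only;
* half the reads are reverse-complemented (default `reverse_fraction = 0.5`);
* `off_target_fraction` (default 0.005) of reads are uniform random sequence,
  so the > 99% on-target QC gate is exercised from both sides;
* base qualities are a constant symbol (default Q30); the caller does not use
  quality weighting.

Every generator is deterministic under its seed; dilution series, replicates
and cohorts derive per-sample seeds from the parent seed and the sample index.

**Profiles.** The published protocol targets ≥ 0.5 million reads per library
yet reports ≈ 1900–2000× average depth; for a ≈1 kb target these two figures
are mutually inconsistent, so reads and depth are independent knobs here. The
`"full"` profile uses 500,000 reads with the 100,000-read QC gate; the
`"fast"` profile (24,000 reads ≈ 2000× per amplicon, gate 10,000) gives the
same depth regime at desk scale and is what the examples and test suite use.
Statistical tests that state "depth 2000" size `reads_total` so that the
interrogated site — not the average position — sits near 2000×.

**What the simulator does not emulate:** flow-space signal and homopolymer
artefacts, PCR duplicates and chimeras, reverse-transcription errors and RNA
degradation, library-to-library depth variation, and strand bias. Passing
tests therefore demonstrate the pipeline's statistical behaviour under a
clean substitution-error model, not instrument-specific failure modes. In
particular, the published dilution series observed 3.91/2.78/2.32% where
halving predicts 5.92/2.96/1.48% — an effect attributed to read-number
variation that this simulator intentionally does not reproduce; the packaged
observed series is kept as a fixture instead.

## The caller

`assign_reads()` matches each read's 5′ 20-mer against every amplicon's
terminal 20-mers in both orientations (exact match first, then a ≤ 2-mismatch
scan; ties go to the first minimal anchor). `build_pileup()` counts one base
per covered non-primer position per read; overlap positions accumulate counts
from all covering amplicons; length-discordant reads are skipped and counted.

`call_variants()` emits, for every non-reference base, `VAF = 100·alt/depth`
and passes a call when `vaf ≥ lod_percent` **(inclusive — the assay keeps a
call at exactly its LOD)**, `alt_count ≥ min_alt_reads` (default 10) and
`depth ≥ min_depth` (default 500). The two count guards are artifact-added
safety rails — the published method states only the 2% LOD and the 0.1 M-read
gate — and are sized so they never bind in the assay's depth regime (at
2000×, 2% VAF is 40 reads). Calls are codon-mapped and protein-named under
the standard genetic code; synonymous changes are flagged; two passing calls
in one codon are emitted separately with a multi-hit warning (no phasing).
With the default error rate 0.002, the expected frequency of any *specific*
non-reference base is ≈ 0.067%, some 30-fold below the 2% LOD — which is why
negative samples produce no passing calls (a property the tests check over
hundreds of seeded libraries).

## Annotation and reports

The packaged catalogue transcribes the assay's per-TKI hotspot table: 110
printed tokens (with one duplicated token and occasional stray internal
spaces, which the parser strips) collapsing to 93 unique protein changes;
each change's profile is the union of the TKI rows naming it. The assay's
published description counts "110 hotspot mutations"; the catalogue stores the
93 unique entries and keeps the raw token count as metadata.

Sample classification follows the assay's operational usage: *negative* (no
passing calls), *single*, or *compound* (≥ 2 passing calls — cis/trans
phasing is not attempted, so "compound" may include polyclonal
configurations, and reports label it as such). Variants absent from the
catalogue (e.g. an L298R found only by NGS) are reported with an empty TKI
profile rather than suppressed. Only poor-sensitivity flags are emitted,
never "sensitive to" claims — the catalogue's evidence is asymmetric. One
documented discrepancy: the published four-variant compound example
(F359C + F317L + E255V + G250E) is described in prose as poorly sensitive to
imatinib, nilotinib and dasatinib, although E255V is also in the bosutinib
row of the table; this package follows the table, so its union includes
bosutinib.

## Validation statistics

* **2×2 metrics.** sensitivity = 100·a/(a+c), specificity = 100·d/(b+d),
  PPV = 100·a/(a+b), NPV = 100·d/(c+d), concordance = 100·(a+d)/n; a zero
  denominator yields "undefined" (`NA`), never 0. The packaged 21-sample
  label sheet encodes the published counts a=7, b=1, c=0, d=13. (The
  accompanying narrative — 8 known positives, all concordant, plus one
  NGS-only positive — would give a=8/d=12; the printed 2×2 table and all
  derived percentages use a=7/d=13, so the sheet follows the table.)
* **Rounding.** Values are stored at full precision; `render_percent()`
  offers three conventions because published reports mix them: half-up to
  2 dp (92.857→92.86), truncation to 2 dp (95.238→95.23 for 20/21), and
  half-up integers (87.5→88). Rendering uses a 10⁻⁹ epsilon so decimal
  values sitting just under a half-step in binary round as intended.
* **Dilution.** `expected_dilution_vafs()` halves the initial VAF per 1:1
  step; `dilution_analysis()` reports expected/observed deltas and estimates
  the LOD as the smallest observed VAF among detected steps. The declared
  assay LOD stays a calling parameter, not an output.
* **Reproducibility.** Plain absolute differences between runs, OLS of run 2
  on run 1 (R² computed directly from residuals so an exact fit returns 1),
  and sample-level positive/negative concordance. The packaged replicate
  pairs (78.86/80.25, 4.17/2.31, 60.77/56.14) give absolute differences
  1.39/1.86/4.63; the published report prints 0.69/1.22/2.31 for the same
  pairs, which is not |run1−run2| under any convention we could identify —
  this package computes and reports the plain differences.
* **Cohort summaries.** Positivity, per-variant spectrum shares (denominator:
  total variants), compound share of positives, and the VAF range.

## The packaged cohort spec

`default_cohort_spec()` encodes a 121-sample cohort with the published
spectrum shape: 42 positives (34.71%), 63 variants — 14 T315I (22.22%),
10 F317L (15.87%), 8 L248V (12.70%), six singleton variants — nine compound
samples, VAFs spanning 2.3–93.41%. Four published per-sample examples are
embedded verbatim (T315I+F359V at 17.76/63.43%; G250E+M244V+E255V;
F359C+F317L+E255V+G250E; T315I+G250E). The published examples alone cannot
all coexist with exactly 9 compounds of ≤ 4 variants summing to 63, so the
fifth published pairing (L248V+E459K) is not embedded as-is; both changes
still occur in the cohort, and the five synthetic compound samples have sizes
4,4,4,4,3 with one variant above 20% VAF and the rest between 2 and 20%, as
described for such samples. Unprinted VAFs were drawn once from uniform
ranges under a fixed seed and frozen into the packaged YAML.

Cohort *summaries* are computed from truth-level reports
(`reports_from_truth()`): the spectrum is a property of the designed cohort,
so it is summarised deterministically rather than through read simulation.
The full simulate→call→annotate path is exercised separately; note that a
2.3% VAF sample sits < 1 binomial SD above the 2% LOD at 2000×, so
occasional dropout of the weakest spike under resimulation is expected
behaviour, not a defect.

## Numerical and testing choices

* Child seeds derive as `(48271·seed + 1103·k) mod (2^31 − 19) + 1`, keeping
  every derived seed a valid 32-bit integer.
* The caller is verified against an independent brute-force oracle
  (character-by-character loops) exactly, on read sets of ≤ 50 reads.
* Statistical properties use 4-binomial-SD bands: single-library VAF recovery
  at the spiked site (100 seeds), detection power at 4% truth VAF and a
  zero-false-call floor on negatives (200 seeds each), and the full dilution
  experiment (100 seeds × 4 libraries). Mean observed VAFs are compared
  against the error-adjusted expectation `v(1−e) + (1−v)·e/3` — the raw base
  frequency a pileup measures under the substitution-error model — within
  4 SD of the mean. Libraries for these tests are sized to put the
  interrogated site near 2000× (≈ 8,000 reads given the ≈3× tiling
  redundancy at that site).
* OLS results are cross-checked against closed-form normal equations to
  1e-9.

## Limitations

Indels (including the homopolymer errors typical of the modelled instrument)
are out of scope — every catalogued hotspot is a missense SNV. Quality-aware
calling, strand-bias filters, UMI consensus and realignment are not
implemented. The surrogate reference preserves catalogue wild-type residues
but not the real transcript's composition, so GC/homopolymer-dependent
effects cannot be studied with it. Diagnostic metrics are reported without
confidence intervals, matching the validation design being modelled.
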