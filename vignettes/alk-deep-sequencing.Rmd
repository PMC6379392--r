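---
title: "Calling low-frequency ALK hotspot mutations from ultra-deep sequencing"
author: "alkdeep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling low-frequency ALK hotspot mutations from ultra-deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkdeep)
```

## The problem

Activating point mutations in the *ALK* receptor tyrosine kinase are the
main recurrent targetable lesion of neuroblastoma. They cluster at a handful
of kinase-domain residues — F1174, F1245 and R1275 account for the large
majority, with minor sites at I1170/I1171 and L1240 — and they are often
carried by tumour subclones at variant allele fractions (VAFs) far below the
~15–20% detection limit of capillary sequencing. Since subclonal *ALK*
mutations can expand under therapy and drive relapse, a caller that can
separate a 2–3% allele fraction from sequencing noise has direct clinical
value.

At ≥5000× depth the limiting factor is not counting statistics but the
background substitution noise of PCR and sequencing, typically an apparent
alternate-allele fraction of 0.1–0.5% that varies from site to site and from
sample to sample. `alkdeep` models that background empirically and applies a
simple, stringent classification rule on top of it.

## Target geometry and annotation

The target is the *ALK* tyrosine-kinase domain, five exon intervals on the
minus strand of chr2 (hg19), 477 coding bases in total:

```{r}
alk_target_regions()
```

Because the gene is transcribed from the minus strand, the coding sequence
walks these exons in order of decreasing forward-strand coordinate, and
residue numbers increase as the genomic coordinate decreases. The package
represents this as a single coding-position ladder: every targeted position
gets a coding-sequence coordinate, from which residue number and position
within the codon follow arithmetically. The frame is anchored by the genomic
codon spans of the I1171, F1174, L1240 and F1245 hotspots; a single frame
offset reproduces all four simultaneously, which is a strong internal
consistency check, and it places the R1275 codon in exon 25 by the same
frame walk (flagged as inferred, since no direct anchor exists for it).

```{r}
codon_for_position(c(29445213, 29443697, 29436875, 29436858))
hotspot_codons()[, c("residue", "ref_aa", "codon_start", "codon_end", "inferred")]
```

All counts and substitutions are reported on the forward genomic strand;
annotation reverse-complements the codon before translating. The bundled
reference sequence is *synthetic*: public sources give residue identities,
not nucleotides, so codons are chosen to be consistent with the reference
amino acids at every interrogated residue and to make every reported variant
(F1174L/I/C/S, F1245I/C, L1240V, I1171T, D1160D, R1275Q/L) reachable by a
single-base substitution; filler codons for the remaining residues are
cycled from a fixed stop-free list. A real reference can be supplied as
FASTA via `read_reference_fasta()`.

## The noise model and the 5-SD rule

For every (position, alternate base), `estimate_background()` computes the
mean and unbiased (n−1) SD of the alternate-allele fraction across control
pileups — the study design uses eight germline DNAs from healthy donors.
Mutation-positive control tumours are deliberately excluded from estimation:
their mutated sites would inflate the SD. A sample pileup is then screened
by `call_variants()`:

\[ z = \frac{\mathrm{VAF}_{obs} - \mu_{bg}}{\max(\sigma_{bg}, \sigma_{floor})},
   \qquad \text{call} \iff z > k . \]

Key parameter choices, all configurable:

| parameter | default | units | rationale |
|---|---|---|---|
| `k` | 5 | SDs | the classification rule itself; stringent enough that no multiple-testing correction is applied (the number of tests is reported) |
| `min_depth` | 5000 | reads | assay design floor; shallower positions are "not assessable", distinct from a negative call |
| `min_base_quality` | 30 | phred | assay QC shows read qualities rarely drop below Q30; filtered bases go to `other` and still count toward depth, so VAF denominators equal total coverage (a flag drops them instead) |
| `noise_floor` | 2×10⁻⁴ | fraction | guards sites whose 8-control SD is (near) zero; without it a single stray read at a clean site would be called |
| `clonal_threshold` | 0.20 | fraction | calls strictly below are subclonal |
| `sanger_threshold` | 0.15 | fraction | empirical capillary detection limit; strictly above is flagged detectable |

Per-alternate testing matters: one cohort case carries F1174S at 58.7%
together with an F1174I subclone at 7.7%, and both must surface as separate
calls.

## The synthetic-data generator

Because raw sequencing data cannot be bundled, the generator emulates the
conditions the statistics assume, and its defaults *are* those conditions:

* **Error rates**: per (position, alternate) rates drawn log-normally with
  median 10⁻³ and σ(log₁₀) = 0.3, truncated to [0, 0.05]. This puts the
  noise floor well below the smallest fraction the assay is expected to
  resolve (≈1%) while keeping every site's SD non-zero.
* **Sample jitter**: each sample multiplies all its rates by one shared
  log-normal factor with σ(log₁₀) = 0.1, creating the super-binomial
  between-sample variance that makes the 5-SD rule non-vacuous.
* **Depths**: drawn per position uniformly over 5000–65000×, the per-position
  coverage spread of the assay; fixed depths can be requested.
* **Mixing law**: a spiked alternate's probability is
  background + purity × VAF; purity applies to somatic spikes only (a
  constitutional variant is not diluted by normal cells) and never to the
  background. Counts are exact multinomials drawn by the binomial chain
  rule, vectorised across positions.
* **Dilutions**: a mutant:wild-type mass ratio of 1:d scales the expected
  VAF to VAF₀/(1+d) — the "1:10" label is read as mutant DNA : added
  wild-type DNA, the reading consistent with equal-mass mixing of the
  undiluted aliquot; both readings are expressible through the ratio
  parameter.
* **Reads**: `emit_reads()` decomposes any pileup into aligned single-end
  records (coverage-layer runs cut into chunks of at most the read length)
  such that rebuilding the pileup at quality threshold 0 recovers the counts
  exactly; per-base qualities can be downgraded at a chosen fraction to
  exercise the Q30 filter.

Everything is driven by explicit seeds through `withr::with_seed()`; no
global RNG state leaks.

What the generator does **not** emulate: indels, strand bias, PCR
duplicates, UMI structure, alignment artefacts, context-dependent
(trinucleotide) error spectra, or correlated errors along amplicons. Tests
passing on synthetic data therefore demonstrate the statistical behaviour of
the rule under the stated noise model, not robustness to every artefact of
real libraries.

## Numerical and design choices

* Coordinates are 1-based inclusive throughout; BED export converts to the
  format's 0-based half-open convention, VCF stays 1-based.
* Fisher's exact test is computed in-package as the two-sided sum of
  hypergeometric probabilities not exceeding the observed table's (with the
  conventional 1+10⁻⁷ relative slack), which makes an exhaustive sweep
  against brute-force enumeration cheap; it agrees with `stats::fisher.test`
  to 10⁻⁹ on random tables. The cohort's mutation–11q-deletion association
  is reported with this test (p ≈ 0.010 on the packaged table), as the
  association test used for the original analysis is not recorded.
* Kaplan–Meier and log-rank operations wrap `survival::survfit`/`survdiff`.
  Per-case follow-up times are not published for the cohort, so survival
  operations run on simulated cohorts (`simulate_survival_cohort()`, exponential
  event times with administrative censoring) or user-supplied tables; no
  attempt is made to reproduce the published survival curves numerically.
* The cohort table stores the published per-case Sanger status, and
  Sanger-missed counts use those statuses rather than re-deriving them from
  the 15% threshold — one case sits at 15.1% yet was missed, so the status
  column is authoritative.
* Synonymous deep-seq entries (the cohort's D1160D) are emitted as calls
  with a synonymous flag but excluded from mutation-positive tallies;
  amplification-only cases are tallied separately and join point mutations
  only in the "any ALK event" count (20 of 105).
* A case counts as 11q-deleted or MYCN-amplified if its genomic-profile
  string contains the corresponding token, so combination profiles
  ("NMA + 11q-del") are included in both strata.
* Degenerate inputs fail loudly: fewer than two controls (SD undefined),
  zero-depth frequencies, positions outside the coding frame, reference
  mismatches, over-full probability configurations, gapped SAM records.

## Operating characteristics, and a known limitation

The test-suite problem sizes are chosen to give tight Monte-Carlo error at
interactive runtimes: sensitivity uses 200 replicate noise models at 5000×
(detection of spikes at 2.7–58.7% VAF is essentially certain; the z-score of
a 2.7% spike over a 10⁻³ background is ≈50), the held-out specificity sweep
uses ~10⁶ (position, alternate, sample) trials, and the exhaustive Fisher
sweep covers every 2×2 table with margins ≤ 30.

One limitation deserves emphasis. The rule calls when the observed fraction
exceeds μ̂ + k·σ̂ with μ̂, σ̂ estimated from only eight controls. This is a
prediction interval, and its false-positive rate cannot be pushed below the
t-distribution floor: even with perfectly Gaussian noise,
P(t₇ > k/√(1+1/8)) ≈ 1.1×10⁻³ at k = 5. With realistic skewed counts
(5000× depth puts only ~5 background reads at a median site) and sample-level
rate jitter, the measured held-out false-call rate is ≈2×10⁻³ per
(position, alternate) test — about 3 expected false flags per sample over
the 1431 tests of the full target, which is why hotspot annotation and
recurrence matter for interpretation. Users who need a sub-10⁻³ false-call
rate should raise `k` (under the same conditions, k = 6 measures ≈1.1×10⁻³
and k = 7 ≈5×10⁻⁴) or
increase the number of controls; the package reports the number of tests
performed so calls can also be post-filtered by multiplicity.
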