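---
title: "Mapping RNA oxidation from aniline-cleavage sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping RNA oxidation from aniline-cleavage sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oabseq)
```

## The measurement principle

Aniline cleaves the RNA backbone 3′ of nucleotides whose glycosidic bond has
been weakened — abasic sites most efficiently, 8-oxoguanosine and m⁷G only
after alkaline treatment. Cleavage leaves a 5′-phosphate on the downstream
fragment, and the library protocol ligates adapters exclusively onto
5′-phosphates after a dephosphorylation step has stripped the ends produced
by ordinary fragmentation. A read's 5′ extremity therefore reports a
cleavage event one nucleotide downstream of the lesion; counting read starts
with a backshift of −1 places the signal on the damaged nucleotide itself.

Two fragmentation regimes give two protocols with different chemistry:
alkaline fragmentation (AAS) detects abasic sites, oxo⁸G and m⁷G, while
Mg²⁺/heat fragmentation at neutral pH (OAbSeq) suppresses the
alkaline-dependent species and reads out abasic sites nearly exclusively.
Contrasting the two is what lets the method attribute signal to lesion
classes.

## Counting conventions

`count_five_prime_ends()` retains primary, mapped, forward-strand
alignments of at least `min_read_len` (default 8 nt — shorter fragments
cannot be mapped unambiguously). Multimappers are excluded via the `NH` tag
when the aligner provides one, otherwise by `MAPQ >= mapq_min`; both knobs
are exposed because aligners encode multiplicity differently. The 5′
extremity is the first *aligned* base, so leading soft clips do not shift
the signal. Reads whose backshifted start falls before position 1 stay in
the library total `N` but are assigned to no position.

Coverage at `i` is defined as the number of reads whose aligned span
contains `i` **plus**, when the backshift is −1, the reads whose backshifted
start is `i`: the cleaved nucleotide is not part of the fragment that
reports it, and without this term a fully cleaved position would show a stop
ratio above 1. With backshift 0 the read start already lies inside its own
span and no correction is applied.

All coordinates are 1-based along the reference, matching how sites are
named in the literature (G82, m⁷G1575); bedGraph export converts to 0-based
half-open intervals.

## Scores

For position `i` with start count `n_i`, coverage `cov_i` and library total
`N`:

* stop ratio `= n_i / cov_i` (missing, not zero, where `cov_i = 0`);
* NCleavage `= 1000 · n_i / N`;
* NormGcounts `NGC_i = n_i / B_i` with `B_i` the median start count over
  non-G residues in the ±5-nt window, excluding the focal position;
* random error `= √n_i / √B_i`, relative error `= √(B_i / n_i)`.

Design choices that the score definitions leave open:

* **Focal exclusion.** The focal position is excluded from its own
  background even when it is not a G, so a strong signal cannot inflate the
  very background it is normalized by.
* **Background floor.** `B_i` is floored at 1 count. A window of zeros would
  otherwise divide by zero; the floor caps NGC at `n_i`, which is the
  natural Poisson-limited dynamic range.
* **Sparse windows.** If fewer than 3 non-G residues fall in the window
  (G-rich stretches, sequence ends), the reference-wide non-G median is used
  instead of an unstable 1–2-point median.
* **All bases scored.** NGC is computed at every position, not only at G;
  the site caller restricts by base downstream, so one score table serves
  G-site and A-site analyses.
* **Background unit.** The background is the median of raw 5′-start counts
  (the numerator's unit), not of any normalized quantity.
* **Error formula.** The relative error `√(B/n)` is implemented literally;
  note it *grows* with background. The conventional Poisson relative error
  `1/√n` is reported alongside as `rel_err_poisson`, clearly labelled as an
  alternative, and is not used by the site caller.
* **Non-linearity.** NGC is not linear in the underlying modification
  stoichiometry (the 5′-selective ligation enriches cleaved fragments); no
  linearization is attempted and scores are reported as-is.

`U` and `T` are equivalent wherever base identity is tested.

## Site calling and comparison

A valid oxidation signal satisfies all three criteria: `NGC ≥ 10` (ten
times the local background median), coverage strictly exceeding 1000, and
relative random error strictly below 10%. The comparison operators follow
the literal reading of those phrases and are configurable. Masked positions
(known stoichiometric modifications supplied as BED) are retained in every
table but can never pass, and never enter rankings.

The *noise level* of a base class is defined here as the median NGC over its
unmasked positions — a data-driven quantity, recorded in the output, with
positions at ≥ 3× noise flagged. Condition comparisons pair shared unmasked
positions and report the squared Pearson correlation of log₂ NGC over rows
where both conditions clear a display threshold (default NGC 10); no
pseudocount is needed because retained values are bounded away from zero.
Replicates are aggregated as per-position mean ± sample SD (SD 0 by
convention for a single replicate, flagged `n_rep = 1`). Ranking uses mean
NGC, ties broken deterministically by reference id then position.

## The read simulator

`simulate_library()` emulates the library chemistry per molecule: random
backbone breaks at rate λ per nt create 5′-OH starts that leak into the
library with probability ε despite the phosphate selection; each lesion
cleaves with a protocol- and class-specific probability, creating a
5′-phosphate start at lesion + 1; reads are sampled proportional to
ligation competence and emitted from the reference at fixed read length.
The implementation samples read causes directly from the per-cause weights
(lesion: cleavage probability; leak: λ·ε per nt) — the analytic form of the
same generative model, with an identical read-start distribution. Each read
carries one truth row, and the model's expected per-position counts are
returned alongside.

Default parameters, chosen once as a realistic library:

| parameter | default | rationale |
|---|---|---|
| λ (breaks/nt) | 0.01 | mean fragment ≈ 100 nt, matched to 50-bp reads |
| ε (leak) | 0.01 | small nonspecific background, ~1% of break ends |
| read length | 50 | single-read 50 bp protocol |
| abasic cleavage | 0.90 / 0.90 / 0.90 | efficient β-elimination in all protocols (alkaline / Mg²⁺ / aniline-only) |
| oxo⁸G cleavage | 0.20 / 0.05 / 0 | ~4-fold alkaline-dependent contrast |
| m⁷G cleavage | 0.90 / 0.05 / 0 | detection requires alkaline fragmentation |
| oxo⁸A cleavage | 0.05 / 0.05 / 0 | weakly reactive |
| ring-opened G | 0.50 / 0.50 / 0 | intermediate reactivity |

The cleavage probabilities are tunable assumptions reproducing the
qualitative protocol contrast, not measured rates. What the simulator does
**not** model: ligation sequence bias, PCR duplication, sequencing errors
(an optional uniform substitution rate exists for robustness tests only),
fragment truncation at the *next* random breakpoint (negligible while
1/λ ≫ read length), circular RNAs, and the saturating, non-linear relation
between modification stoichiometry and NGC. Passing tests on simulated data
therefore demonstrate correctness of the counting/scoring/calling machinery
under the stated generative model, not robustness to every artifact of real
libraries.

Because cleavage fragments start at lesion + 1, a lesion within one read
length of the 3′ terminus yields fragments too short to map: such sites are
invisible to the method, and simulation scenarios plant lesions in the
mappable interior.

## Study conditions used by the validation suite

The end-to-end recovery scenario uses a 500-nt reference with 10 abasic
lesions (cleavage 0.9, ε = 0.01) at 10⁵ reads; the caller recovers the
planted set with sensitivity and precision ≥ 0.95. The protocol-contrast
experiment plants one oxo⁸G and one abasic lesion on a 400-nt reference and
compares alkaline (0.20) vs Mg²⁺ (0.05) libraries at 2 × 10⁵ reads with 6
replicate libraries per protocol — the replicate design used for oxo⁸G
oligonucleotide experiments — because the windowed-median background at a
single site is estimated from only ~7 counts per library and the
replicate-mean NGC stabilizes the ratio. The NGC normalization cancels the
library-share denominators, so the expected alkaline/Mg²⁺ ratio at the
oxo⁸G site is exactly the efficiency ratio 0.20/0.05 = 4; the bootstrap CI
(reads resampled within replicates) covers it, and the abasic site stays
near 1. These problem sizes keep the full suite under a minute while
leaving all estimates comfortably inside their tolerances.

## LC-MS quantification and free chlorine

External calibration fits response against standard amount by OLS; the
slope is the relative response factor (rRF) and quantification divides the
signal by the slope *only*, with any fitted intercept reported as a QC
diagnostic — the convention of the nucleoside-quantification literature.
Calibration-range violations warn rather than fail. Two normalization
schemes are provided, both homogeneous of degree 1: division by the total
nucleoside amount of the untreated control, and division by injected amount
× guanosine count. For in vivo material the guanosine denominator comes
from a composition model (80% rRNA of 5475 nt, 15% tRNA of 76 nt, 5% mRNA
of 1700 nt, 25% G each); whether the species fractions are molar or mass
fractions is not fully determined by the published description, so both
weightings are implemented (`g_per_mass(weighting =)`), defaulting to molar
— with a uniform G fraction the two coincide at exactly 0.25, so the choice
only matters for user-supplied species-specific G contents.

The DPD free-chlorine assay is calibrated with KIO₃ standards; the
stoichiometric conversion is 3 mol Cl₂ per mol KIO₃ (molar mass
214.00 g/mol), so

```{r}
free_chlorine_from_kio3(10.06)
```

µmol of Cl₂ equivalents for 10.06 µg KIO₃. `dpd_sample_concentration()`
inverts the absorbance calibration at the sample reading, converts through
the same stoichiometry and scales by dilution and assay volume.

## Known limitations

* Single-read, forward-strand logic only (transcript references); reverse
  alignments are logged and dropped, paired-end input is out of scope.
* No UMI deduplication (the protocol has none).
* NGC is semi-quantitative; converting it to absolute modification
  stoichiometry is explicitly not attempted.
* The simulator validates the pipeline, not the wet-lab protocol; adapter
  trimming and alignment are upstream of this package and consumed as
  SAM/BAM input.
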