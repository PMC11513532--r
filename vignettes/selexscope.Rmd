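---
title: "Models and methods behind selexscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind selexscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selexscope)
```

## The problem

In vivo SELEX selects nucleic-acid aptamers for tissue homing by injecting a
randomised RNA library into an animal, recovering sequences from the target
tissues, re-amplifying them, and repeating. For an ocular selection the
panel is six ocular tissues (conjunctiva, cornea, iris–ciliary body, lens,
retina, RPE-choroid) and four well-perfused control organs (liver, lung,
kidney, spleen). Sequencing selected rounds per tissue yields, for every
library member, a trajectory of counts across cycles and tissues; the
analysis must turn those counts into defensible statements about enrichment,
and the downstream validation assays (qPCR biodistribution of individually
re-synthesised aptamers, circular-dichroism melt curves) need their own
quantitative treatment. `selexscope` covers that chain, plus a simulator
that generates all three data types with ground truth.

## Read preparation

Every library construct is `const5 + N(var_len) + const3` with the constants
fixed (defaults: `GGGGCCACCAACGACATT` / `GTTGATATAAATAGTGCCCATGGATC`,
`var_len = 36`). Extraction anchors both constants in the read and takes the
substring strictly between them. Choices that the construct alone does not
dictate, and the behaviour we adopted:

* **Exact, ungapped anchors by default.** `max_mismatch` (per constant,
  default 0) is exposed because sequencing errors do land in the constants;
  exact matching is the conservative default since every tolerated mismatch
  admits reads whose insert may also be corrupted.
* **Both orientations.** Merged paired-end reads have undefined strand, so
  the forward strand is searched first and the reverse complement second;
  a read and its reverse complement therefore yield the same region.
* **Deterministic tie-breaks.** If a constant occurs more than once, the
  leftmost 5' anchor and the first 3' anchor after it are used.
* **Alphabet.** Input is normalised U→T so RNA- and DNA-spelled records of
  the same molecule count as one sequence. Extracted regions containing `N`
  are rejected (`ambiguous_base`) — at the default depths an ambiguous base
  cannot be attributed to any library member and the read carries no usable
  identity.

Every read receives exactly one status (`ok`, `no_5prime_anchor`,
`no_3prime_anchor`, `wrong_length`, `ambiguous_base`); tallies sum to the
read count, so losses are always accounted for.

## Counting and enrichment

Counts are exact per-(sequence, tissue, cycle) multiset counts; rows are
ordered by descending sequence total with lexicographic tie-break so outputs
are byte-stable. Three analyses sit on top:

* **Threshold summary** — unique sequences whose *total* count (over all
  samples in the table) meets each cutoff in an ascending ladder. This is
  monotone non-increasing by construction and characterises how much of the
  pool is singleton noise versus genuinely amplified material.
* **Candidate filter** — sequences with at least `min_count` (default 10)
  reads within any single qualifying cycle (default cycle 10 or 12). The
  count is summed over all tissues within the cycle: the filter is stated
  per cycle, and the sequenced samples of one cycle derive from one injected
  pool. A `per_tissue = TRUE` mode is exposed for the stricter reading.
* **Abundance and fold change** — a sequence's abundance is its fraction of
  the scope's total counts in a cycle, where the scope is a tissue, the
  ocular or control compartment, or the whole pool; fractions per
  (scope, cycle) sum to 1. Fold changes are ratios of fractions, never raw
  counts, because sequencing depth differs per sample. The special cycle
  selector `"last"` resolves per tissue via `last_cycle_map` (RPE-choroid
  12, others 14) — tissue panels are not always sequenced to the same final
  round, and a global "last cycle" constant would silently mix rounds.

Zero-baseline fold changes raise an error rather than applying a silent
pseudocount; `pseudocount` is an explicit argument for users who want one.
No cross-tissue depth normalisation is applied beyond fraction-of-total: the
bench protocol already equalises RNA input per tissue, and inventing an
additional computational normalisation would be unsupported by the data the
pipeline sees.

## Family clustering

Aptamer families are sets of variable regions sharing at least 80% ungapped
positional identity. Ungapped identity is valid here because all regions are
filtered to one fixed length upstream; a gapped aligner would only add
degrees of freedom the data do not need. The 80% criterion does not by
itself define a clustering algorithm, so we use a greedy, abundance-seeded
single pass: visit sequences in descending count order (ties lexicographic);
each sequence joins the first family whose *seed* it matches at ≥ threshold,
else founds a new family. Consequences worth knowing:

* deterministic and order-invariant under the stated tie-breaks, O(n·k);
* the seed is always the most abundant member of its family;
* membership is identity-to-seed, not complete linkage — two members can be

  below threshold to each other while both within threshold of the seed. A
  `mode = "complete"` option enforces identity to every member instead.

Identity exactly at the threshold joins the family by default
(`inclusive = TRUE`); the strict `>` reading is available. Family pool
fractions are count-weighted (a 90-member family's share of the pool is its
total counts over the pool total), and can be computed over all sequenced
cycles or any subset simply by building the count table from those samples.

Structure-aware alignment, motif discovery and secondary/tertiary structure
prediction are deliberately out of scope — those are external tools, not
computations this package defines.

## qPCR ΔCt analysis

The biodistribution statistic is ΔCt = Ct(aptamer) − Ct(control aptamer)
within a tissue, replicates averaged to a mean Ct per (aptamer, tissue)
before subtraction. One convention issue deserves a flag: under perfect
doubling, a *more abundant* template crosses threshold at a *lower* Ct, so
this ΔCt is negative for aptamers enriched over the control — yet published
figures are often annotated with "higher ΔCt = higher abundance". The
package implements the printed formula verbatim as the default
(`sign = "as_printed"`) and exposes `sign = "abundance_positive"` (the
negation); `simulate_qpcr()`, which encodes the abundance→Ct map explicitly
(`Ct = ct_ref − log2(abundance)`, efficiency configurable), is the
self-consistency arbiter in the tests.

Fold differences use the exact doubling law, `2^|ΔCt|` (1 unit = 2-fold,
4 units = 16-fold); amplification efficiency is fixed at 2.0 by default and
configurable — the package does not estimate efficiency from standard
curves.

For pooled comparisons, replicate-level ΔCt values (replicate i paired with
control replicate i in the same tissue) are pooled across each compartment's
tissues; `compare_groups()` fits `dct ~ aptamer * compartment` by two-way
fixed-effects ANOVA and runs Tukey HSD over the aptamer-by-compartment cell
means (harmonic-mean cell size for unbalanced designs, as `TukeyHSD`
implements). Star tiers follow the conventional mapping (\* p < 0.05 to
\*\*\*\* p < 0.0001). Both pooling representations — tissue-level means and
replicate-level observations — are available, since published summaries do
not always say which was used.

## Melt-curve fitting

CD melt data at a fixed wavelength are fitted with the Boltzmann sigmoid

$$[\theta](T) = [\theta]_{min} + \frac{[\theta]_{max} - [\theta]_{min}}
{1 + \exp((T_m - T)/s)}$$

by bounded Levenberg–Marquardt least squares (`minpack.lm`). Numerical
choices:

* **Initialisation** — asymptotes from the means of the first and last three
  points (robust for either transition direction), `Tm` at the temperature
  of steepest finite-difference slope, `s = 2` °C.
* **Bounds** — `s ∈ (0, 50]` °C and `Tm` within the data range ± 20 °C.
  These prevent asymptote-swapped solutions (the model is invariant under
  swapping the asymptotes and negating `s`) and keep `Tm` identifiable.
* **Convergence** — `ftol = ptol = 1e-12`, up to 500 iterations; the
  `converged` flag is honest and non-convergence is a flagged result, not an
  exception. A warning is emitted when the signal does not clearly span both
  asymptote regions.
* `Tm` is invariant to linear rescaling of the signal, so fitting raw
  millidegrees or molar ellipticity gives the same melting temperature.

Unit helpers: `molar_ellipticity()` implements [θ] = θ/(10·d·c);
`rna_molecular_weight()` computes an approximate MW from monophosphate
residue masses (5'-triphosphate end by default, as in a T7 transcript;
optional 2'F pyrimidine correction) so that a protocol mass concentration
such as 15 µg/mL can be converted to mol/L. `smooth_spectrum()` is
Savitzky–Golay (window 11, order 2 defaults); baseline correction is a
buffer-spectrum subtraction the user performs on their data — no numerical
baseline model is invented. Thermodynamic parameter extraction (ΔH, ΔS) and
two-state model testing are out of scope.

## The simulator

`simulate_selex()` models selection as multiplicative per-cycle fitness:
within tissue *t*, recovery frequencies are
$p^{rec}_{i,t} \propto p^{inj}_i \, w_{i,t}$, and the next cycle's injected
pool is the equal-weight mixture of the six *ocular* recovery distributions
(control recoveries never re-enter, matching the re-injection protocol of
equal aliquots from each ocular tissue). Frequency trajectories are
propagated exactly; stochasticity enters only at sequencing: multinomial
read sampling at the configured depth, then per-base substitution errors.
Reads are emitted as full constructs with constant flanks, and FASTQ
qualities are constant Q30 placeholders (ignored downstream).

Defaults were fixed once as the study conditions: 14 cycles with sequencing
at cycles 10/12/14 and RPE-choroid stopping at 12; uniform initial library;
background fitness 1; substitution error rate 0.001 per base (a realistic
merged-read error scale for modern short-read platforms; no rate is stated
for the original data); substitution-only errors because downstream
filtering is fixed-length, so indels only shift reads into the
`wrong_length` tally. Planted fitness values are free parameters — no
quantitative selection-strength estimates exist to calibrate against — and
a per-sequence amplification-bias multiplier can be emulated by scaling a
sequence's fitness uniformly across tissues (the "PCR overpowering"
scenario).

What the simulator does **not** emulate: pharmacokinetics (circulation,
clearance, saturable uptake), sequence-dependent folding or binding
energetics, animal-to-animal variability, PCR chimeras, or quality-score
structure. Passing tests on simulated data therefore demonstrate that the
pipeline's *computations* are correct under the stated selection model —
not that the model captures every feature of real in vivo data.

`simulate_qpcr()` draws replicate Cts as
`ct_ref − log_eff(abundance/ref) + N(0, noise_sd)`; `simulate_melt()`
evaluates the Boltzmann model on the 22–94 °C, 2 °C protocol grid plus
Gaussian noise. Both are seeded and byte-reproducible.

## Problem sizes and test design

The test suite exercises: exact oracle equivalence (dictionary recounts,
hand-computed identities) on toy inputs; planted-structure recovery through
the full extract→count→filter→cluster chain on a seeded simulation of 10
tissues × 3 sequenced cycles × 10,000 reads; ΔCt↔abundance round trips over
100 seeds; Boltzmann recovery noiseless (<1e-6 relative) and under 2%
amplitude noise (±0.5 °C over 100 seeds); and the ANOVA's type-I error on
2,000 null simulations (95% CI around the empirical family-wise rate must
cover α = 0.05). These sizes keep the suite well under a minute on one CPU
while leaving the statistical checks adequately powered.

## Known limitations

* Anchored extraction discards reads whose constants are corrupted beyond
  the mismatch budget; at high error rates this biases against nothing in
  particular (errors are uniform) but does reduce usable depth.
* Greedy seed clustering can split a true family if its most abundant
  members straddle the threshold; `mode = "complete"` is stricter, not
  looser.
* The ΔCt analysis assumes a common amplification efficiency across
  aptamers and tissues; efficiency estimation from standard curves is not
  implemented.
* The melt fit assumes a single two-state transition; multiphasic melts
  will converge to a compromise `Tm` with a large residual norm — inspect
  `residual_norm` and the fitted curve.
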