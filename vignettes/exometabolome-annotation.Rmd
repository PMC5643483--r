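---
title: "Annotating a bacterial exometabolome from ultrahigh-resolution mass spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating a bacterial exometabolome from ultrahigh-resolution mass spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exometab)
```

## Scope and model of the data

`exometab` annotates the exometabolome — the pool of metabolites a culture
releases into its medium — from FT-ICR-MS peak lists. The data model is
deliberately minimal: a peak is an (m/z, intensity, S/N) triple from a
singly charged ion; a sample is a peak list with strain, substrate, time
point, replicate and ionization-mode metadata; a sterile control grown
alongside each culture provides the blank. Everything downstream operates
on molecular formulas (MF), the canonical currency of ultrahigh-resolution
DOM and exometabolome work: a formula is a CHNOSP element-count map,
written in Hill notation (`C`, then `H`, then the rest alphabetically), and
two detections are "the same compound" exactly when their canonical
strings are equal. Structural isomers are indistinguishable at this level,
so every annotation the package reports is putative; fragmentation evidence
is carried only as a boolean provenance flag plus an elementwise
subformula consistency check (`is_subformula()`, `neutral_loss()`).

## The assignment procedure

For each peak the neutral mass is `M = mz - m_p` (positive mode, [M+H]+) or
`M = mz + m_p` (negative mode, [M-H]-), with the proton mass taken from the
packaged element table. Other adducts (Na in particular) are excluded by
default: protonation/deprotonation is the minimal defensible model for
electrospray DOM spectra, and the element table ships Na so a user can
extend the candidate space deliberately rather than by accident.

`enumerate_candidates()` then searches the full CHNOSP box constrained by
`assignment_config()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `tolerance_ppm` | 0.5 | ppm | standard for 15 T FT-ICR work; the instrument-level value is rarely published, so it is a visible config entry |
| `element_ranges` | C 1–100, H 1–200, N 0–6, O 0–40, S 0–3, P 0–2 | counts | covers every formula in the packaged metabolite table (max N=4, S=2, P=1) with headroom |
| `hc_range` | 0.3–2.5 | ratio | standard DOM plausibility heuristic |
| `oc_max` | 1.2 | ratio | same |
| `dbe_range` | 0–25 | rings+double bonds | same |
| `require_integer_dbe` | TRUE | — | even-electron rule for neutral molecules |

DBE uses the standard CHNOSP convention `1 + C - H/2 + (N+P)/2` (trivalent
N and P, divalent O and S). The search loops over N, S, P and O and bounds
C analytically by the remaining mass; H is then the unique integer within
the tolerance window (the window is orders of magnitude narrower than one
hydrogen mass). Pruning is a performance device only — the test suite holds
it to exact set equivalence with an unpruned brute-force oracle that
enumerates the complete C×H grid for every N,S,P,O combination.

Selection among candidates is deterministic: smallest |mass error|, then
fewest heteroatoms (N+S+P), then lexicographic Hill string. When the
runner-up is within 0.1 ppm of the winner the result is flagged
`ambiguous = TRUE`; ambiguity is surfaced, never hidden, and downstream
counts can exclude or inspect flagged peaks.

Two numerical conventions worth knowing: peak lists are merged at read time
when rows lie within 1e-6 Da (below instrument resolution; intensities sum,
the maximum S/N is kept) so duplicated rows cannot double-count; and the
signed mass error is reported observed-minus-theoretical relative to the
theoretical mass.

## Filtering, calibration, blanks

The peak filter keeps S/N ≥ 5 inside the 92–2,000 Da window, both
boundaries inclusive; it is idempotent and order-preserving. Internal
recalibration fits `mz_corrected = slope * mz + intercept` by least squares
to reference masses matched within 1 ppm; fewer than two matches leaves the
spectrum unchanged and flagged uncalibrated (a warning, not an error — a
single uncalibratable spectrum should not abort a run), and a slope outside
1 ± 1e-3 triggers a sanity warning.

Blank subtraction defaults to the formula level: the blank's assigned
formula set is removed from the sample's by canonical identity. The
instrument-level description of subtracting "mass spectrograms" is
ambiguous; formula-level subtraction is deterministic and tolerance-free,
which matters when counts of distinct formulas are the headline result. A
mass-level variant (`subtract_blank_mz()`, ±0.5 ppm) exists for unassigned
peak lists.

Positive- and negative-mode formula sets are merged by union before
downstream analysis (each retains per-mode provenance in the long
detections table). This was a genuinely open choice; union is the default
because the published per-strain counts aggregate over everything, and
per-mode analyses remain a one-line `dplyr::filter` away.

## Matching, classification, screening

`match_formulas()` is an exact string join against a metabolite database.
The packaged database carries the 43 annotated biosynthetic-pathway
exometabolites of *D. shibae* and *P. inhibens*. All 43 rows are labeled
`pathway_class = "biosynthetic"`: the source material counts all of them as
biosynthetic-pathway metabolites in its per-strain totals while also
mentioning a secondary-metabolite scan that is not resolvable to specific
rows, so the package follows the totals and keeps `"secondary"` (plus
`"degradation"` and `"spontaneous"`) as vocabulary values exercised with
synthetic databases in the tests. Four rows have no stated function; they
are stored as `"unspecified"` and grouped as `"other"`.

The functional grouping (vitamin-related, quorum-sensing,
amino-acid-related, auxin-related, siderophore, defense-antibiotic,
nucleoside, other) is a controlled vocabulary shipped as a TSV; an
unmapped label is a configuration error, not a silent `NA`. Percentages are
of the strain's matched total.

DOM screening is presence/absence by formula membership — FT-ICR-MS
intensities are relative, so no cross-instrument intensity comparison is
attempted. The packaged mesocosm and North Sea sets are synthetic
reconstructions from the database's own presence columns (the underlying
environmental spectra are not deposited), which makes the flag round-trip
an exact self-consistency test but means the packaged sets cannot surprise
you. The per-strain overlap report recomputes the inclusion–exclusion
identity and reports it (`consistent`) rather than enforcing it.

## Growth rates, stimulation, carbon balance

The growth rate of a batch curve is the slope of the least-squares line
through log values over the contiguous window of at least four positive
points that maximizes R², ties resolved toward the longer and then the
earlier window. Two degenerate cases are pinned down: a zero-variance
(constant) window has an undefined R² (0/0) and is scored 0, so plateaus
never outrank genuine log-linear stretches — an entirely flat curve still
returns rate 0 through the tie rules; and windows never span non-positive
values. The estimator is invariant to positive scaling of the curve.

`stimulation()` reports `100 * (mean_t - mean_c) / mean_c` on replicate
rates (or yields) with an equal-variance two-sided Student's t-test; the
0.01 significance threshold is reported, not enforced. Arms with
essentially constant data are handled exactly (p = 1 for equal means).

The carbon mass balance converts cell counts to biomass carbon at 50 fg C
per cell (typical of large, fast-growing heterotrophs) and DCAA
concentrations to carbon either per amino acid (packaged C-count table,
average atomic weight 12.011 — bulk budgets use average, not monoisotopic,
masses) or in bulk at a configurable mean of 4.36 C per residue, the value
consistent with the stationary-phase budgets the package reproduces. The
lysis flag threshold is 5% of biomass carbon: observed lysis regimes sit
near 17–21% and clean cultures below 1%, so 5% separates the regimes with
a wide margin on either side; it is a visible parameter, not a constant.

## What the simulators emulate — and what they do not

`simulate_spectrum()` emulates the structure of one culture × time point ×
mode peak list: true formulas drawn from the database, decoy CHNOS
formulas constructed to pass the same plausibility filters as real
candidates (decoys that fail the filters would make recovery tests
uninformative), mass errors `Normal(0, sigma_ppm)`, lognormal intensities,
uniform S/N with a configurable fraction below the filter threshold, and a
blank sharing an exact number of contaminant formulas with the sample. The
manifest records per peak the true formula, applied error, role and an
eligibility flag (S/N ≥ 5, inside the window, passes the plausibility
filters, not a contaminant) sufficient to recompute every expected
downstream output. Two database formulas are printed in their source as
deprotonated/odd-electron compositions with half-integer DBE
(2,3-dihydroxybenzoate as C7H5O4 and dethiobiotin as C10H17N2O3, where the
neutral molecules are C7H6O4 and C10H18N2O3); the even-electron filter
rejects them by design, they come back explicitly unassigned (no competing
candidate exists within 0.5 ppm of either mass), and the eligibility flag
accounts for them.

`simulate_batch_growth()` integrates the Monod batch model (chosen because
the qualitative pattern to emulate is substrate depletion mirroring growth;
no mechanistic equations are published for these cultures) with fixed-step
RK4 at `dt <= 0.01 / mu_max`, and adds multiplicative lognormal observation
noise. Carbon conservation `x - x0 = Y (s0 - s)` holds along the entire
trajectory and is asserted to integrator tolerance.
`simulate_diatom_experiment()` emulates fluorescence growth curves with a
multiplicative rate stimulation and iid lognormal replicate noise; its
defaults (control rate 0.04 h⁻¹, 3 replicates, 7-day curves observed every
12 h) describe a typical coastal-diatom supplementation assay.

What the generators do **not** emulate: chemical baseline and electronic
noise, isotopologue patterns, multiply charged species, adducts beyond
(de)protonation, ion suppression, chromatographic artifacts, lag phases and
death phases in the diatom curves, or the compositional correlation
structure of real DOM. Passing the recovery tests therefore demonstrates
the correctness of the pipeline's logic under its stated assumptions, not
instrument-level performance on real spectra.

## Problem sizes and determinism

Every generator is fully deterministic under a seed. The test suite and
acceptance script use sizes chosen to exercise each property well while
staying quick on a single core: 20 oracle-equivalence masses in the unit
tests and 200 in the dedicated property check (drawn over 92–800 Da, half
uniform, half near true formula masses where candidate sets are non-empty);
one 68-peak end-to-end run (43 true + 20 decoys + 5 contaminants) at
0.1 ppm error for sensitivity/precision; 1,200-step Monod integrations
observed hourly; and 200 seeded repetitions for the stimulation power
check (1.2× effect, n = 3, CV = 2%, rejection at p < 0.01).

## Known limitations

Formula-level annotation cannot distinguish isomers; matches are putative
by construction. The assignment tolerances and element ranges are
assumptions made visible in the configuration, not published instrument
settings. Degradation-pathway and spontaneous-reaction metabolite classes
are only exercised synthetically, since no flat-file list for them is
packaged. The DOM fixtures are reconstructions, not measured spectra.
Detection-frequency denominators depend on which samples are excluded by
the lysis rule, so frequency tables always report their denominator.
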