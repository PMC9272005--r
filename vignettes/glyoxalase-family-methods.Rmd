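---
title: "Curation and biochemistry of the durum wheat glyoxalase I family: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation and biochemistry of the durum wheat glyoxalase I family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glyoxalaseR)
```

This vignette documents the models behind `glyoxalaseR`, the parameters that
matter, what the synthetic generators do and do not emulate, and the design
choices made where the methodology left room.

## The biological problem

Methylglyoxal (MG) is a cytotoxic α-oxoaldehyde produced as a by-product of
triose-phosphate metabolism; its levels rise under salt and osmotic stress.
The glyoxalase pathway detoxifies MG using glutathione: MG and GSH condense
spontaneously into a hemithioacetal (HA), the true substrate of glyoxalase I
(GLYI), which isomerizes it to S-D-lactoylglutathione. Plant genomes carry
GLYI multigene families in which only a minority of members retain the full
catalytic apparatus; the curation task is to separate putatively active
enzymes from GLYI-like proteins, and the biochemical task is to characterize
the activity (saturation kinetics, GSH inhibition, metal activation) and the
stress response (expression, MG and glutathione pools).

## Catalog model

The family catalog is one row per splice variant: chromosome (1A–7B, the
trailing letter naming the subgenome), gene coordinates (1-based inclusive,
matching the `start–end` style of genome browsers), CDS length (a codon
multiple; protein length = CDS/3 − 1 after removing the stop codon), exon
count, and the length of the N-terminal PF00903 (lactoylglutathione lyase)
domain or `Absent`.

Molecular weight uses the Expasy *average* residue masses plus one water
(18.0153 Da); the theoretical pI solves the Henderson–Hasselbalch charge
balance over the two termini and the D/E/C/Y/H/K/R side chains with the
EMBOSS pKa set, by bisection on pH ∈ [0, 14] to 10⁻⁴. Both tables are
arguments, so other vendors' conventions can be emulated; the MW/pI columns
of the bundled catalog were produced by proprietary software whose tables are
unpublished, so agreement with them is asserted only at the
~110 Da-per-residue plausibility level, never to the printed decimal.
"Multi-splice" means strictly more than one transcript. The mean CDS length
is reported both exact (782.6 bp here) and rounded (783 bp), since summaries
conventionally print the integer.

## Curation pipeline

**Domain filter.** A variant is discarded if it has no PF00903 span or if its
longest span is under `min_domain_len = 100` aa. The observed family shows a
clean gap — discarded fragments of 76–97 aa against retained domains of
≥ 119 aa — and 100 aa splits that gap; the threshold is a parameter, and the
rule deliberately uses the *longest* span so a short N-terminal remnant does
not doom a protein with an intact second domain.

**Alignment.** Conserved-site checking anchors reference positions onto each
candidate with global Needleman–Wunsch alignment under affine gaps (three-state
dynamic programming). Defaults: BLOSUM62, gap open 10, extend 0.5 (a gap of
length L costs `open + (L−1)·extend`). Traceback tie-breaking is
deterministic — diagonal, then gap-in-candidate, then gap-in-reference — so
runs are bit-reproducible. The implementation is validated against a
brute-force enumeration oracle on short sequences and against an independent
aligner at domain scale.

**Reference profiles.** The canonical anchors are the Zn²⁺-dependent human
enzyme (metal tetrad Q34, E100, H127, E173; GSH-binding R38, N104;
dimer-interface G106) and the Ni²⁺-dependent *E. coli* enzyme (tetrad H5,
E56, H74, E122). Because the reference sequences themselves are not
redistributable here, the package constructs *synthetic* scaffolds: fixed
pseudo-random 184 aa (Zn-type) and 133 aa (Ni-type) domains carrying those
residues at those positions, with the Ni-type scaffold derived from the
Zn-type by block indels so that cross-profile alignment recovers the GSH and
dimer homologs the way it does for the real pair. Everything that matters for
the pipeline — the positions, the expected residues, the length contrast
between the metal classes, and alignability — is preserved; tests that
exercise residue-level biology on *real* family sequences are out of reach
without those sequences and are not claimed.

**Activity and metal calls.** A site passes only on exact residue identity
(the binary present/absent convention of family tables; no
conservative-substitution credit). `active` requires all four metal sites,
both GSH sites and the dimer glycine. The first metal site doubles as the
cofactor discriminant: His ⇒ Ni²⁺-type; Gln ⇒ Zn²⁺-type, additionally
requiring domain length ≥ `zn_len_threshold = 140` aa (the Zn-specific
region is not sequence-defined, so the length criterion stands in for it);
a His-type domain in the Zn length range only warns, since length is
advisory for Ni. For two-domain architectures only the N-terminal domain is
checked — the C-terminal domain of two-domain plant GLYI proteins carries a
degenerate metal site and no known function. Proteins without sequence are
"not checkable", a distinct state from inactive.

**Localization consensus.** External predictor labels (vocabulary `Cyt`,
`C`, `M`, `-`; multi-labels split on `/`) are consumed, never recomputed. A
variant supports an organelle if any tool lists it; for the per-gene counts a
variant is counted as organellar only when no tool predicts cytoplasm.
The stricter rule is deliberate: variants with mixed organellar/cytosolic
predictions are set aside as ambiguous rather than counted, which matches how
such tables are read in practice (the raw any-tool support is still reported
per variant for inspection).

## Hemithioacetal equilibrium

With totals `MG_t`, `GSH_t` and dissociation constant `K` (3.0 mM by
default), the HA concentration satisfies
`x² − (MG_t + GSH_t + K)x + MG_t·GSH_t = 0`; the physical root is the
smaller one (the larger always violates `x ≤ min(MG_t, GSH_t)`, which is
asserted, not assumed). The solver uses the product form
`x = 2c/(b + √(b²−4c))` to avoid cancellation when `K` dominates the totals,
and free species come from mass balance so conservation is exact by
construction. The inverse problem — choose totals for a target HA at fixed
free GSH — is closed-form (`MG_free = K·HA/GSH_free`) and round-trips
through the forward solve to 10⁻⁹ relative over HA ∈ [10⁻³, 10] mM,
GSH_free ∈ [0.01, 10] mM. Units are mM end to end; the 30-minute
pre-incubation of assay mixtures is treated as fully equilibrated (no
kinetics of HA formation).

## Enzyme kinetics

Specific activity converts an absorbance slope by Beer–Lambert:
`|slope|/(ε·path) · volume/protein`, with ε = 2.86 mM⁻¹cm⁻¹ at 240 nm for
the GLYI reaction and 13.6 mM⁻¹cm⁻¹ at 412 nm for the TNB-based glutathione
assay. The magnitude of the slope is used; the direction of absorbance change
is a property of each assay, documented rather than inferred.

The primary Michaelis–Menten estimator is untransformed nonlinear least
squares (Levenberg–Marquardt), started from a Hanes linearization, bounded
positive. The four classical linearizations (Lineweaver–Burk, Eadie–Hofstee,
Hanes, Eadie–Scatchard) are provided as diagnostics and agree with each other
and with NLS to 10⁻⁹ on exact data; on noisy data they weight errors
differently and are not averaged into the estimate by default (a pooled mean
across plots is easy to form from the returned values if desired, but the
weighting such pooling implies is unspecified, so the package reports each
estimate separately).

Competitive inhibition (`v = Vmax·S/(Km(1+I/Ki)+S)`) is estimated two ways:
the Dixon construction — per-substrate lines of `1/v` against `I`, whose
common intersection sits at `I = −Ki`; the consensus intersection is the
least-squares common point of all lines, which for exact competitive data is
exact — and a global NLS fit of the competitive model, always reported
alongside. Parallel Dixon lines (no finite intersection) raise a diagnostic
rather than a number. Km is kept in mM internally and displayed in μM where
convention expects it. Metal activation is a straight line of percent
activation against dose over the assayed range (0.125–1.5 mM for Zn²⁺),
intercept fitted, extrapolation flagged.

## Expression quantification

`2^(−ΔΔCt)` with amplification efficiency fixed at 2: technical replicates
are averaged first; ΔCt subtracts the arithmetic mean of the reference-gene
Cts (equivalently, geometric-mean normalization of linear quantities — the
behavior of common qPCR software with two references, here made explicit);
ΔΔCt subtracts the mean ΔCt of the calibrator group. Consequently the
calibrator's *geometric* mean fold is exactly 1; the arithmetic mean exceeds
1 under noise, as for any log-normal quantity, and tests assert the
geometric version. Fold changes are invariant to per-sample plate shifts
because the reference subtraction removes any constant added to all Cts of a
sample. With one reference gene the computation reduces to the classic
single-reference formula exactly. Two calibration schemes are supported:
within-tissue (each tissue's own control, the layout of stress-response
contrasts) and a fixed condition-plus-tissue group (the layout of
shoot-vs-root comparisons).

Group comparison uses fixed-effects ANOVA (one or two factors) and Duncan's
multiple range test, implemented from studentized-range quantiles with the
per-range protection level `1 − (1−α)^(p−1)` and the harmonic mean of group
sizes for unbalanced designs; with two groups the decision coincides with
the pooled-variance t-test at the same α, which is asserted in the tests.
No installed package provides Duncan's test, hence the in-package
implementation.

## Assay quantification

Calibration is unweighted OLS with intercept (forcing through zero is not
assumed), valid over the standard range with extrapolation flagged; MG
content follows the unit chain concentration → dilution → extract amount →
per-gram fresh weight. The glutathione pool follows the subtraction
convention GSH = total − GSSG with GSSG measured as molecules (not GSH
equivalents); the alternative two-equivalents bookkeeping would halve the
reported ratio and is left to the caller's standards rather than a hidden
flag, since the assay's standards define the scale. Pearson correlation uses
the t transform with n − 2 degrees of freedom.

## Synthetic generators

Each generator is a single seeded RNG stream and is bit-reproducible.

- `make_protein_family()` embeds a reference scaffold in uniform-random
  flanking sequence (flanks 5–40 aa, offsets recorded), plants the requested
  active fraction exactly, draws metal type with the family's observed Ni
  share (23/28) and the two-domain architecture with its observed share
  (17/28, the C-terminal copy carrying a degenerate first metal site),
  and makes inactive proteins by 1–7 alanine substitutions at conserved
  sites or by truncating the domain to 60–99 aa. At zero noise the curation
  stage recovers the planted truth with zero errors, and every single-site
  knockout flips the activity call — both are tested exhaustively.
- `make_kinetics()` evaluates the (competitive) rate law on a design and adds
  Gaussian noise σ = fraction × Vmax, truncated at zero. Defaults reproduce
  the study conditions: Vmax 0.519 μmol·min⁻¹·mg⁻¹, Km 0.092 mM, Ki 6.5 mM;
  a 12-point substrate design spanning 0.025–1 mM; the 4 × 5 inhibition grid
  (S ∈ {0.1, 0.25, 0.5, 1} mM, free GSH ∈ {0.2, 1, 5, 10, 15} mM).
- `make_ct_table()` draws per-gene baselines uniformly in 18–30 cycles (a
  realistic qPCR window), lowers target Cts by the planted log2 effect (one
  cycle per doubling), adds a per-sample plate shift (SD 0.5 cycles) that
  the normalization must cancel, and technical noise per replicate.

What the generators do *not* emulate: real codon/amino-acid composition and
homology structure of plant proteomes (flanks are uniform over the 20-letter
alphabet), primer efficiency differences and inter-run calibration drift,
heteroscedastic rate noise at low substrate, and biological covariance
between genes. Passing the synthetic recovery tests therefore demonstrates
correctness of the computations under the stated models, not robustness to
every artifact of bench data.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to exercise every
code path while keeping the full suite in the tens of seconds: synthetic
families of 20–40 proteins, the 12-point and 4 × 5 kinetic designs with 1–3
replicates, 200 Monte-Carlo repetitions for the 2 %-noise unbiasedness
checks, a 10 × 10 grid for equilibrium round-trips, and exhaustive
length-combination coverage up to 6 × 6 against the alignment enumeration
oracle. Bisection tolerance for pI is 10⁻⁴ pH units; equilibrium identities
are asserted to 10⁻⁹ relative; noise-free kinetic recovery to 10⁻⁶
relative. Alignment scores use a large negative sentinel (−10¹²) for
unreachable states and exact tie-breaking on floating-point equality to
10⁻⁹, which is safe because all default penalties are dyadic.

## Known limitations

- The bundled catalog's MW/pI columns cannot be re-derived (their source
  tables are unpublished); only scale plausibility is checked.
- The conserved-site checker is exact-match by design; genuinely active
  enzymes with conservative substitutions at a site would be called
  inactive, matching the table convention it reproduces but not necessarily
  the biochemistry.
- The Zn/Ni discriminant couples one residue with a length threshold; it
  reproduces the family's published partition but is a heuristic, not a
  structural prediction.
- The localization consensus consumes predictor labels as ground input;
  disagreement among tools is surfaced, not resolved.
- The MG–activity correlation and the stress bar-chart magnitudes from the
  underlying study are not reproducible from printed data; the corresponding
  machinery is validated on synthetic data only.
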