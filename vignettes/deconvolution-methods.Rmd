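---
title: "Methods: pseudo-spectrum deconvolution with a 13C internal standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-spectrum deconvolution with a 13C internal standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(msdeconv)
```

## Model and assumptions

An LC-ESI-MS peak table from one chromatogram is modeled as a set of
features (m/z, RT, abundances) produced by a mixture of analytes, each of
which emits several *ion species*: adducts (`[M+H]+`, `[M+Na]+`, ...),
in-source fragments (`[M+H-H2O]+`, ...), homoadducts (`[2M+H]+`), the
natural isotopologues of each of those, and — in labeling experiments — a
uniformly ¹³C-labeled copy of everything, shifted by n × 1.003355 Da for n
carbon atoms. Deconvolution inverts this map: it groups features into
*pseudo spectra*, one per analyte hypothesis, each anchored by at least one
*seed adduct* and named `M{mass}T{rt}` after its implied neutral mass and
the primary peak's retention time.

Core assumptions:

* all species of one analyte coelute: peaks are only compared when their
  RT difference is below ε_rt, and m/z values are equal when within ε_mz;
* isotope chains have strictly decreasing intensity in their direction
  (natural: toward higher mass; mirrored ¹³C patterns: toward lower mass);
  a small multiplicative slack absorbs integration noise;
* the internal standard is incompletely labeled (per-carbon purity just
  below 1), so fully labeled monoisotopic peaks are recognizable by their
  mirrored isotope pattern;
* charge states are 1 or 2, read off the isotope-chain spacing.

A peak may legitimately satisfy several analyte hypotheses — consecutive
small losses make, e.g., a water-loss fragment of one mass a perfectly
valid pseudo-molecular ion of another. The pipeline deliberately keeps all
such memberships and exposes `claim_peaks()` for curation; exports flag
multi-assigned peaks. Within a single hypothesis cluster, when one peak
matches several species (the 17.027 Da ammonia-loss/ammonium ambiguity),
the first species in the configured ion list wins and the annotation is
flagged ambiguous; which interpretation is right depends on instrument
settings, so the resolution is configuration, not code.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `eps_rt` | 5 | s | coelution window; matches sub-minute peak widths of typical gradients |
| `eps_mz` | 0.005 | Da | accuracy of a well-calibrated TOF at small-molecule masses |
| `decomp_tol` | 0.005 | Da | decomposition tolerance inside the pair-vetting and triplet steps; shared with `eps_mz` since both reflect the same mass accuracy |
| `correlation_threshold` | 0.85 | — | EIC shape agreement for automatic pruning; curation tools use a softer 0.75 |
| `max_isotopes` | 4 | — | chain length cap; beyond M+4 natural CHNOPS isotopologues are below typical noise floors |
| `isotope_slack` | 0.05 | — | tolerated relative violation of the decreasing-intensity rule |
| element bounds | C≤39 H≤72 N,O≤20 P≤9 S≤10 | — | standard small-molecule ranges below ~500 Da |

All ion lists are data, not code: TSV/JSON configs with label, delta mass,
charge, multiplicity, seed flag, polarity and an optional loss formula used
for carbon-count reasoning.

## Numerical choices

* **Ion mass convention.** Adduct deltas are built from monoisotopic atom
  masses corrected by the electron mass (proton = 1.007276 Da). This is the
  physically correct convention for ions; the sodium-proton offset then
  comes out at 21.9819 Da, in agreement with values quoted in the
  annotation literature.
* **¹³C increment** fixed at 1.003355 Da, the conventional value in
  isotope-annotation tools; the deviation from the CODATA value is orders
  of magnitude below `eps_mz`. Water-loss offsets are always computed from
  the element table (18.0106 Da), never hard-coded to rounded literature
  figures.
* **Decomposition** is an exact recursive descent over elements in order of
  decreasing mass with branch-and-bound pruning; hydrogen is solved
  arithmetically at the leaves. At metabolite masses this is fast enough
  that exactness beats cleverer money-changing schemes; the test suite
  proves set-equality against a naive lattice enumeration.
* **Filter stack.** Element-ratio ranges (0.1 ≤ H/C ≤ 6, N/C ≤ 4, O/C ≤ 3,
  P/C ≤ 2, S/C ≤ 3) and the multiple-heteroatom probability cutoffs follow
  the published heuristic rules for formula plausibility; the Lewis rule is
  RDBE = C − H/2 + N/2 + 1 ∈ ℕ₀ (even-electron neutral molecules), Senior's
  rule requires an even valence sum sufficient for a connected graph. The
  O ≥ 3.3 P rule encodes that phosphorus in metabolites is phosphate-like.
  Individual filters can be toggled per query; the numeric thresholds are
  fixed in this release.
* **Pair vetting.** A candidate ¹³C partner at distance n × 1.003355/z must
  have n inside the carbon-count range obtained by decomposing the
  annotation's implied neutral mass (multiplicity × M minus the species'
  loss). This is what rejects, e.g., n = 20 for a 147 Da ion.
* **Triplet search (uncommon losses).** S_p, S_f, S_l are full filtered
  decompositions with fixed carbon counts n_p, n_f, n_p − n_f; conservation
  s_p = s_f + s_l is checked by exact elementwise formula addition. A unique
  triplet sets `loss_formula`; multiple triplets annotate the fragment but
  flag it ambiguous. Spectra whose primary ion lacks a ¹³C partner are
  skipped entirely.
* **Snapshot semantics.** Steps 4 and 6 evaluate all spectra against the
  same pre-step assignment state, so the order in which spectra are
  processed cannot starve a later spectrum of candidates. Together with
  sorted iteration everywhere, the pipeline is bitwise deterministic for a
  fixed input and configuration.
* **Correlation.** Pearson on the overlapping RT window, second trace
  interpolated onto the first trace's grid. Unavailable correlations
  (missing trace, < 3 shared points, constant trace) are `NA` — explicitly
  distinct from a low value — and never cause pruning; with no raw data at
  all, pruning is skipped with a warning, because peak tables alone cannot
  support shape comparison.
* **Degenerate inputs.** An empty peak table yields empty results without
  error; a lone peak is an orphan; subtraction of formulas errors on any
  negative count, which is how an impossible loss surfaces.

## The synthetic generator

`simulate_peak_table()` emulates exactly the structure the pipeline keys
on: per compound, configured species with relative yields, natural isotope
patterns from a carbon-only binomial (p(¹³C) = 0.0107), mirrored patterns
from the label purity (default 0.99, a realistic fed-batch ¹³C enrichment),
mixed-label homoadducts, analyte-specific fragments, uniform contaminants,
and Gaussian m/z / RT / multiplicative intensity noise — all deterministic
per seed with a complete peak-level ground-truth map. The default preset
abundances (10⁶ apex for the main ion, internal standard at half) put
isotopologues 1–2 orders above the 500-count emission floor, as in real
high-abundance metabolite spectra.

What it does **not** emulate: heteroatom isotopes (S/N/O fine structure),
chromatographic tailing and saturation, detector heteroscedasticity,
retention-time drift between samples. A green recovery test therefore
establishes that the grouping logic inverts the generative model it was
designed for — it does not establish performance on real chromatograms,
where peak detection quality and coelution density dominate.

The four presets cover the distinct code paths: a glutamate-like compound
(adducts, losses, homoadducts incl. mixed label), a glutamyl-methionine
dipeptide (unique-triplet uncommon loss, the y₁″ residue fragment), a
consecutive-loss coelution scenario (multi-membership and `claim_peaks`),
and an unlabeled compound (undefined isotopomer ratios).

## Quantitation

Ratios are ¹²C/¹³C quotients; a missing or zero ¹³C abundance makes the
ratio *undefined*, which propagates as `NA` and is excluded from group
means with a logged count — never silently coerced to zero. Fold-changes
are ratios of group means computed on ratio-normalized values when the
standard is present in every sample of the contrast, else on
biomass-normalized ¹²C abundances (both modes exist because real
experiments mix both situations). Tests are equal-variance two-sample
Student's t; multiplicity is handled by Benjamini-Hochberg, implemented
directly (and verified against `stats::p.adjust`) so the exported table is
self-contained.

## Design decisions taken where the design was open

* **Seed requirement is spectrum-level**: a cluster qualifies if at least
  one member is explained by a seed species, not every pair. This follows
  the tool behavior of requiring "at least one peak annotated as a
  pseudo-molecular ion or seed adduct" per spectrum.
* **¹³C candidates must head a mirrored chain.** A lone peak with no
  mirrored isotopes is not accepted as a labeled monoisotopic peak. At
  purity 1.0 this disables pair detection by construction; real standards
  are never perfectly pure, and the strict reading avoids spurious pairs.
* **Automatic homoadduct label shifts** are restricted to
  {0} ∪ range(C) ∪ 2·range(C): the mixed and doubly labeled dimers are the
  only physical possibilities.
* **XLSX export is out of scope** — no writer exists in the supported
  dependency stack; CSV/TSV carry identical content.
* **mzML support is deliberately minimal**: MS1 spectra, 64-bit
  little-endian arrays, zlib or none. That covers converter output for EIC
  extraction; everything else (MSn, chromatogram objects, indexed mzML) is
  out of scope, and peak tables remain the primary input.

## Known limitations

* Charge states above 2, radical ions and isotope fine structure are not
  modeled.
* The element-probability thresholds are fixed; genuinely exotic formulas
  (peroxides, polyphosphates) may be filtered out.
* One acceptance check — reproducing published fold-changes from a
  supplementary normalized-area spreadsheet — cannot run here because the
  spreadsheet is not redistributable and the build environment is offline;
  the computation path is tested on synthetic tables instead, and the
  criterion is intentionally left failing as documentation of that gap.
* Reference lists store absolute m/z and RT: they transfer only between
  chromatograms acquired with the same method.
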