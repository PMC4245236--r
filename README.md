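# msdeconv

Deconvolution of LC-ESI-MS metabolomics spectra with ¹³C-labeling support.

## The problem

Electrospray ionization fragments and adducts every analyte: a single
metabolite M shows up in an LC-ESI-MS run as `[M+H]+`, `[M+Na]+`,
`[M+H-H2O]+`, homoadducts like `[2M+H]+`, and the isotopologues of each of
those. Coeluting compounds interleave their peaks. Before any
identification or quantitation can happen, the peak list must be
*deconvolved*: peaks that belong to one analyte are grouped into a **pseudo
spectrum** with a common neutral mass M.

When a uniformly ¹³C-labeled internal standard is spiked into every sample,
each ¹²C monoisotopic peak has a fully labeled partner exactly
n × 1.003355 Da higher, where n is the number of carbon atoms. `msdeconv`
exploits this twice:

* the pair distance **fixes the carbon count** during sum-formula
  generation, often collapsing dozens of candidate formulas to one; and
* the ¹²C/¹³C abundance quotient (**mass isotopomer ratio**) quantifies the
  metabolite while canceling matrix effects, since analyte and standard
  coelute and ionize together.

The package is aimed at metabolomics practitioners post-processing
XCMS-style peak tables from labeling experiments, and implements the whole
chain as a tested library plus CLI: nothing here does peak detection — peak
tables are the input.

## What it does

1. **Isotope chains** — peaks spaced 1.003355/z Da apart (z ∈ {1, 2}) with
   decreasing intensity; in labeled mode a second pass finds *mirrored*
   chains descending from candidate ¹³C monoisotopic peaks.
2. **Pseudo-spectrum assembly** — pairs of monoisotopic ¹²C peaks whose m/z
   distance matches a seed adduct (`[M+H]+`, `[M+Na]+`, `[M+K]+`) against
   any listed species; every spectrum must contain a seed.
3. **¹²C/¹³C pair association** — partner candidates are vetted by
   requiring n to be a chemically possible carbon count for the implied
   neutral mass (by mass decomposition).
4. **Homoadducts** — `[2M+H]+` and mixed-label `[2M+n+H]+` predicted
   directly from M.
5. **Uncommon neutral losses** — for an unassigned ¹²C/¹³C pair below the
   primary ion, the primary mass (n_p carbons), fragment mass (n_f) and
   loss mass (n_p − n_f) are each decomposed; a triplet s_p = s_f + s_l
   annotates the fragment as `[M+H-loss]+`, flagged ambiguous unless the
   triplet is unique.
6. **Correlation pruning** and curation tools: EIC Pearson correlation
   against the primary peak, `claim_peaks()` to resolve multi-membership,
   orphan browsing, `find_correlating_peaks()`.

Mass decomposition uses branch-and-bound search over CHNOPS with a filter
stack: element-count bounds, heteroatom-probability and element-ratio
heuristics, Senior and Lewis (RDBE) rules, an O ≥ 3.3 P rule, plus the two
spectrum-aware constraints (required loss sub-formula, fixed carbon count).

Quantitation: isotopomer ratios, biomass normalization, group fold-changes
`mean(a)/mean(b)`, equal-variance Student's t-tests and Benjamini-Hochberg
adjustment. Identification support: reference lists with dot-product
(cosine) scoring and matching against local MassBank-format record files.

## Worked example

The built-in glutamate scenario plants C₅H₉NO₄ (monoisotopic mass
147.0532 Da) at RT 287.9 s with five ion species, their isotopologues and
the labeled internal standard at half abundance:

```r
library(msdeconv)
preset <- preset_scenario("glutamate")
sim <- simulate_peak_table(preset$compounds, noise_model(seed = 42), preset$cfg)
res <- run_deconvolution(sim$peaks, preset$cfg)
res
#> <deconvolution result> 21 peaks -> 2 pseudo spectra, 9 chains, 6 label pairs, 0 orphans

Filter(function(s) abs(s$M - 147.0532) < 0.01, res$spectra)[[1]]
#> <pseudo spectrum M147.053T287.92> M=147.0532 rt=287.92s status=auto
#>    peak_id            ion_label             role ambiguous
#> 1     P001               [M+H]+      seed_adduct     FALSE
#> 5     P007              [M+Na]+      seed_adduct     FALSE
#> 7     P011           [M+H-H2O]+         fragment     FALSE
#> 9     P015         [M+H-HCOOH]+         fragment     FALSE
#> 11    P019              [2M+H]+       homoadduct     FALSE
#> 13    P004             [M+5+H]+ c13_monoisotopic     FALSE
#> 22    P021            [2M+5+H]+ c13_monoisotopic     FALSE
#> ... (isotopologue rows omitted)
```

Reading: all six ¹²C species were grouped under M = 147.0532; every ¹²C ion
got its ¹³C partner — `[M+5+H]+` is the fully labeled pseudo-molecular ion
(glutamate has 5 carbons), and `[M+4+H-HCOOH]+` shifts by only 4 because the
formic-acid loss removes one carbon. `[2M+5+H]+` is the homoadduct of one
unlabeled and one labeled moiety. The second pseudo spectrum (M129.043) is
the expected coelution ambiguity created by consecutive small losses; it
shares peaks with the glutamate spectrum and would be removed during
curation with `claim_peaks()`.

The label-pair carbon count then makes decomposition unambiguous:

```r
decompose_mass(147.052, tolerance = 0.005, fixed_carbon = 5)
#>   formula     mass       error C H N O P S
#> 1 C5H9NO4 147.0532 0.001157781 5 9 1 4 0 0
```

The same operations are available from the command line:

```sh
exec/msdeconv simulate --preset glutamate --seed 42 --out fixtures/
exec/msdeconv deconvolve --peaks fixtures/peaks.csv --out out/
exec/msdeconv decompose --mass 147.052 --fixed-c 5
```

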