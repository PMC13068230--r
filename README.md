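# isoherd

Multi-isotope analysis of ancient livestock mobility, diet, and birth
seasonality from sequentially sampled tooth enamel.

Herbivore tooth enamel mineralizes incrementally over roughly a year, so a
series of bands milled along a tooth crown preserves a months-resolution
archive of the animal's environment and diet: oxygen isotopes (δ¹⁸O) track
seasonal variation in imbibed water, carbon isotopes (δ¹³C) track the
photosynthetic pathway and water status of the forage, and strontium
isotopes (⁸⁷Sr/⁸⁶Sr) fingerprint the bedrock of the pasture with no
biological fractionation. `isoherd` turns such intra-tooth sequences — plus
the ordinary apparatus of a faunal report (NISP counts, mandibular wear
stages) — into estimates of where, when, and on what herds were raised. It
is written for zooarchaeologists and isotope ecologists; the bundled case
study is an Iron Age II caprine assemblage from the southern Levant.

## The model

The seasonal δ¹⁸O signal along a crown is modelled as a four-parameter
cosine

```
δ¹⁸O(x) = M + A · cos( 2π (x − x₀) / X )
```

where `x` is the distance (mm) from the enamel–root junction, `A` the
amplitude (‰), `X` the period of the annual cycle (mm of crown growth per
year), `x₀` the crown position of the modelled summer maximum, and `M` the
mean level (‰). For fixed `X` the model is linear in
`(A cos φ, A sin φ, M)`, so the fit is a 1-D search over `X` with a
closed-form solve at each candidate period. The modelled winter minimum
falls at `x_min = (x₀ + X/2) mod X`; normalizing by the period gives the
birth-season position `x₀/X` as a fraction of the year, which is compared
across animals with circular statistics (minimal covering arc = cohort
birth-season spread; circular means for inter-period offsets). Fit quality
is tested with a regression ANOVA, `F = ((TSS−RSS)/3)/(RSS/(n−4))` on
`(3, n−4)` degrees of freedom.

Around that core: enamel δ¹³C converts to dietary δ¹³C by subtracting the
bioapatite–diet enrichment (14.1 ± 0.5 ‰) and classifies into pasture types
(closed canopy / open C₃ / water-stressed-or-C₄); ⁸⁷Sr/⁸⁶Sr ratios paired to
the seasonal δ¹⁸O extremes are assigned to bioavailable baseline intervals
of named geological units; and assemblage structure is tested with NISP
frequencies, Pearson chi-square with standardized residuals, and
wear-stage age cohorts.

## Worked example

The increment-level measurements behind the case study are not deposited in
machine-readable form, so the package ships `hazor_sequences()`, a synthetic
reconstruction calibrated to the published per-specimen summary statistics
(see the vignette for exactly what that does and does not preserve). Fitting
the goat mandible "5753":

```r
library(isoherd)

seqs <- hazor_sequences()
fit_cosine(seqs[seqs$specimen_id == "5753", ])
#> cosine_fit <5753>: A=1.41 x0=8.22 X=24.39 M=-0.60 | x0/X=0.34 x_min/X=0.84 p=3.27e-15
```

The amplitude says this goat saw ~2.8 ‰ of seasonal δ¹⁸O swing; `x0/X =
0.34` places its birth about a third of a year before the summer δ¹⁸O peak
position, and the ANOVA p-value says the seasonal model clearly beats a
flat line. Cohort spread across the five fitted late-IRIIA caprines:

```r
fits <- hazor_fits()           # published fit parameters
late <- fits$pos_max_norm[fits$period == "late_IRIIA"]
circular_span(late)
#> [1] 0.54
```

— births staggered over 0.54 of a year, i.e. an extended 5–6 month lambing
season. Assemblage composition over time:

```r
freq <- taxon_frequencies(hazor_nisp(), hazor_grouping())
freq[freq$group == "caprine", c("period", "nisp", "display")]
#>        period nisp display
#>   early_IRIIA  131      81
#>    late_IRIIA  173      63
#>         IRIIB  159      53
```

— the caprine share of identified specimens falls from 81 % to 53 % across
the Iron Age II while cattle and equids rise, the signature of
intensifying agriculture.

The numbered scripts under `analysis/` run the full workflow
(simulation rehearsal, intra-tooth summaries, seasonality, diet and
provenance, assemblage statistics) and write their tables under `results/`.

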