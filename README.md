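# homsms

Annotation and structure inference for online tandem mass spectra of
highly oxygenated organic molecules (HOM) measured as nitrate-adduct
anions by NO₃⁻ chemical-ionization Orbitrap instruments.

HOM — peroxy radicals (RO₂) from monoterpene autoxidation and the ROOR
accretion dimers they form via RO₂ + RO₂ → ROOR + O₂ — are central to
atmospheric new-particle formation, but they are short-lived and
isomer-rich. Collisional activation of their [M·NO₃]⁻ clusters yields
product ions and neutral losses diagnostic of functional groups and
skeleton features. This package is for mass spectrometrists and
atmospheric chemists who want to turn those peak lists into structural
conclusions:

* **Formula core** — exact-mass C/H/N/O arithmetic; anion m/z
  (electron-inclusive); constrained formula enumeration within a 5 ppm
  window (N ≤ 2, RDBE-filtered), ordered by |ppm| then nitrogen count.
* **Spectrum I/O** — MGF and two-column CSV peak lists, base-peak
  normalization, and the inclusive 0.1 % relative-intensity floor
  (precursor and NO₃⁻ peaks are never dropped).
* **Annotation** — precursor assignment, product ions as sub-formulas of
  the precursor composition, and the single-step neutral-loss table
  (loss = precursor − product).
* **Similarity & clustering** — cosine similarity of square-root
  intensity vectors keyed by product-ion formula or loss composition
  (NO₃⁻ and precursor excluded), complete-linkage clustering on
  1 − similarity, Newick export.
* **Structure rules** — a declarative fragmentation-feasibility rule set
  (O₂, HNO₃, HNO₃+OH, H₂O, CO₂, OH, HO₂, CHO₃, CH₃O₂, C₃H₆O channels)
  and an elimination engine over candidate feature records; shipped
  candidate sets for the limonene O₈ (A1–A7, B1–B7) and O₁₀ radicals.
* **Dimers** — RO–OR cleavage with H-exchange (including the acylperoxy
  asymmetry that suppresses the alkyl-side H-gain product) and ranking of
  candidate RO₂ precursor pairs against observed product ions.
* **Simulator** — a seeded forward model of NO₃⁻-CI MS/MS spectra
  (precursor decay and NO₃⁻ growth with collision energy, Dirichlet
  product intensities, ppm-scale mass noise) so the full pipeline is
  testable without instrument data.

## Worked example

Annotate a measured-style spectrum of the limonene O₈ peroxy radical
adduct (precursor m/z 325.0644):

```r
library(homsms)
s <- msms_spectrum("limonene O8 radical", 325.0644, "NO3", nce = 5,
                   data.frame(mz = c(61.9884, 151.0764, 195.0667,
                                     213.0766, 293.0748, 325.0644),
                              intensity = c(500, 30, 60, 120, 400, 1000)))
s <- assign_precursor(normalize_spectrum(s))
ann <- annotate_products(s)
ann$peaks
#>         mz rel_intensity     formula        ppm        role neutral_loss
#> 1  61.9884          0.50        NO3-  0.5413353 reagent_ion         <NA>
#> 2 151.0764          0.03    C9H11O2- -0.3519535     product       CH4NO9
#> 3 195.0667          0.06   C10H11O4-  2.1407540     product        H4NO7
#> 4 213.0766          0.12   C10H13O5- -1.1596512     product        H2NO6
#> 5 293.0748          0.40  C10H15NO9- -1.4659791     product           O2
#> 6 325.0644          1.00 C10H15NO11- -2.0269215   precursor         <NA>
```

Every peak is assigned within 5 ppm; the losses are single-step
differences to the precursor (so the cascade products show combined
compositions such as H2NO6 = O₂ + HNO₃ + OH). Interpreting that cascade
as its mechanistic channels and running the elimination engine over the
fourteen candidate O₈ structures:

```r
eliminate(hom_structures("limonene_o8"),
          c("O2", "H2NO4", "H2O", "CO2", "OH"))
#> <elimination_report>
#>   observed losses: O2, H2NO4, H2O, CO2, HO
#>   surviving: A1, A2, A7, B1, B2
#>   eliminated A3: HO [R-OHelim]
#>   eliminated A4: H2NO4 [R-HNO3-OH]
#>   ...
```

The tertiary radicals (A3/B3) fall to the OH-elimination rule and the
quaternary-α candidates (A/B 4–6, B7) to the combined HNO₃+OH rule,
leaving A/B 1, A/B 2 and A7. Dimer precursor inference works from
observed RO–OR cleavage ions:

```r
pool <- hom_structures("limonene_ro2_pool")
infer_dimer_precursors("C20H30O14",
                       c("C10H14NO10-", "C10H16NO10-", "C10H13O7-"), pool)
#>        a       b score o_asymmetry                                   evidence
#> 1 lim-O8  lim-O8   2.5           0 C10H14NO10-; C10H16NO10-; C10H13O7- (depr…
#> 2 lim-O6 lim-O10   0.0           4
```

Both H-exchange adducts plus the deprotonated carbonyl ion put the
O₈ + O₈ pair first: the O₈ radical is the dominant dimer precursor.

A command-line wrapper (`inst/scripts/hom-msms`) exposes the same
pipeline as subcommands (`simulate`, `annotate`, `losses`, `similarity`,
`cluster`, `infer-structures`, `infer-dimers`).

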