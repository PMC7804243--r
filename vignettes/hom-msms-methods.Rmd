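---
title: "Annotating nitrate-adduct MS/MS spectra of highly oxygenated organic molecules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating nitrate-adduct MS/MS spectra of highly oxygenated organic molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homsms)
```

## The problem

Monoterpene ozonolysis produces peroxy radicals (RO2) that autoxidize,
via intramolecular H-shifts followed by O2 addition, into highly
oxygenated organic molecules (HOM), including ROOR accretion dimers from
RO2 + RO2 reactions. These species drive new-particle formation, but they
are short-lived and isomer-rich, so their structures are hard to pin
down. Nitrate chemical ionization detects them softly as [M·NO3]⁻
clusters; collisional activation of a selected cluster then yields
product ions and neutral losses that are diagnostic of functional groups
(peroxy, hydroperoxide, peroxy acid) and of skeleton features (quaternary
carbons, the gem-dimethyl motif of the pinene skeleton).

`homsms` implements the computational side of that experiment: exact-mass
formula annotation of precursor and product ions, neutral-loss
derivation, spectral similarity and clustering, a rule-based engine that
eliminates candidate isomers whose structure cannot produce an observed
loss, and dimer RO–OR cleavage arithmetic that ranks candidate RO2
precursor pairs. A forward simulator generates NO3⁻-CI-like MS/MS spectra
from candidate structures so the whole pipeline is testable without
instrument data.

## Formula arithmetic and enumeration

All compositions live in the C/H/N/O space: analyte ions are assumed to
contain only carbon, hydrogen and oxygen, plus at most two nitrogens
brought in by the NO3⁻ or HNO3·NO3⁻ reagent ions. Masses are sums of
monoisotopic element masses; anion m/z includes the electron mass by
default. This is the physically correct convention, but printed m/z
values in the literature mix conventions (the two differ by 0.55 mDa,
~1.7 ppm at m/z 325), so all matching in the package is tolerance-based
at the standard 5 ppm window and never exact-decimal.

Candidate enumeration solves for the hydrogen count analytically on a
C/N/O grid, which is exact over the bounded search space; the default
bounds (C 0–25, H 0–45, N 0–2, O 0–20, RDBE −0.5–20) cover C10 monomers,
C20 dimers and their adducts. RDBE is computed as C − H/2 + N/2 + 1;
half-integer values are kept because radical anions and adducts
legitimately produce them, and no nitrogen parity rule is enforced for
the same reason. Ties are ordered by absolute ppm error, then by fewer
nitrogens (and fewer oxygens for product-ion assignment) — a
deterministic proxy for the expert judgement an analyst would apply.

```{r}
mz(parse_formula("C10H15O8.NO3-"))   # O8 radical adduct, reported 325.0644
enumerate_formulas(325.0644)[, c("formula", "mz", "ppm")]
```

## Spectrum processing

Spectra are normalized to the base peak (chosen over all peaks, including
the precursor) and refined with a 0.1 % relative-intensity floor. The
floor comparison is inclusive — a peak exactly at the threshold survives
— and the precursor and NO3⁻ reagent peaks are never dropped, since they
anchor annotation regardless of their intensity. Centroids closer than
1e-5 m/z are merged on input as a duplicate-centroid guard. Product ions
are assigned the best sub-formula of the precursor composition within the
tolerance; unassigned peaks are kept and logged rather than discarded.

Neutral losses are strictly single-step differences (precursor minus
product). Multi-step cascades — e.g. O2 loss followed by a combined
HNO3 + OH loss — are deliberately not reconstructed at this stage; the
composition observed relative to the precursor (H2NO6 in that example) is
what the table stores, and mechanism is left to the rule engine. The
combined-loss composition H2NO4 is treated as a single channel because
whether the HNO3 and OH departures are simultaneous or sequential is not
decidable from the spectrum.

## Similarity and clustering

Spectrum vectors are keyed by assigned formula (product ions) or loss
composition (neutral losses), not by binned m/z, and hold square roots of
relative intensities. The NO3⁻ reagent ion is excluded because its
abundance reflects adduct binding strength rather than analyte structure;
the precursor peak is excluded because it would saturate self-similarity
(this choice is recorded in output metadata and switchable). Pairwise
cosine similarity feeds complete-linkage clustering on the distance
1 − similarity; labels are sorted lexicographically before clustering so
tie merges are deterministic and the result is invariant to input order.
The 0.2 display mask applies to rendered matrices only, never to
clustering. Dendrograms export as Newick via `ape`.

## The fragmentation rule engine

Each rule pairs a neutral-loss composition with a named, pure predicate
over the structure feature record:

```{r}
do.call(rbind, lapply(fragmentation_rules(), function(r)
  data.frame(rule = r$id, loss = r$loss, predicate = r$predicate)))
```

Candidates are feature records, not molecular graphs: the discriminating
logic needs only the radical-site class, the quaternary flag of the
carbon next to the radical, the functional groups present, proximity of
radical and peroxy group, the gem-dimethyl flag, and a count of
H-scrambling sites. The candidate trees for the O8 and O10 limonene
radicals (A/B routes) ship as versioned JSON fixtures, since which
isomers exist is input information, not something the package computes. A
candidate survives elimination iff every observed loss has at least one
feasible rule; "most plausible" is operationalized as "survives all
feasibility checks", with no probabilistic scoring. Elimination is
monotone: more evidence can only shrink the survivor set. Scrambling
variants (H exchange between –OOH and –OO• sites) are generated on
request, off by default, with variant features supplied as fixture data.

```{r}
eliminate(hom_structures("limonene_o8"),
          c("O2", "H2NO4", "H2O", "CO2", "OH"))
```

One design point deserves a note. The HO2-elimination rule's structural
precondition (a non-quaternary carbon next to the peroxy radical) is met
by several O8 candidates, yet O8 spectra show no HO2 loss — which
channels actually appear depends on energetics the feature flags cannot
carry. Feasibility and observation are therefore kept separate: the
elimination engine uses only structural feasibility (absence of an
expected loss never eliminates a candidate), while each fixture may carry
a `channels` list recording the loss channels its family exhibits, which
the forward simulator intersects with the feasible set. The O8 fixtures
list the O2, HNO3+OH, H2O, CO2 and OH channels; the O10 fixtures list O2,
OH, HO2 and CHO3.

## Dimer cleavage and precursor inference

Accretion arithmetic is fixed: dimer = a + b − O2. Collisional cleavage
of the RO–OR peroxide bond gives two alkoxy radicals that exchange a
hydrogen: the donor side loses H (carbonyl product), the acceptor side
gains H (alcohol/acid product), both detected as NO3⁻ adducts. An
acylperoxy side has no abstractable hydrogen on its acyloxy radical and
cannot donate, so with one acylperoxy member only one pathway remains and
the alkyl side's H-gain adduct disappears — the observable contrast
between the symmetric O8+O8 dimer (both C10H14O7·NO3⁻ and C10H16O7·NO3⁻)
and the acylperoxy-O6 + O8 dimer (C10H14O7·NO3⁻ only).

Precursor-pair inference scores every arithmetically valid pool pair by
the predicted cleavage products found among the observed ions. Adduct
matches weigh 1; matches to deprotonated `[M − H]⁻` forms of the neutral
cleavage products weigh 0.5, because such ions can also arise from
secondary fragmentation and are weaker evidence. Ties break toward
oxygen-symmetric pairs, then lexicographically.

## The forward simulator

The simulator is the package's study-condition generator, not a physical
model. For each structure it emits the precursor adduct, the declustered
NO3⁻ ion, and one product per active channel (feasible rules intersected
with the fixture's channel list; plus RO–OR cleavage adducts for dimers).
Intensities follow the qualitative collision-energy behavior of adduct
spectra: the precursor fraction decays as `exp(-k·NCE)` (k = 0.25 for
monomers; k = 0.12 for dimers, which bind NO3⁻ more strongly), 60 % of
the declustered current appears as NO3⁻, and the remainder is
Dirichlet-distributed over product channels. m/z values carry Gaussian
noise of 0.7 ppm SD, keeping ~99 % of draws inside a 2 ppm accuracy
envelope; the default NCE ladder is 2, 5, 10 and the floor 0.1 %. Once
NO3⁻ becomes the base peak its relative intensity saturates at 1, so the
monotone NO3⁻ growth is asserted up to that saturation. Only relative
intensities are modeled; absolute ion counts are instrument settings with
no simulated counterpart.

What passing simulation-based tests shows — and what it does not: the
pipeline inverts its own forward model exactly (noise-free annotation
recovers the generating losses; no structure is eliminated by its own
spectrum across 100+ seeded spectra), and the clustering recovers
engineered co-fragmentation structure (the O8 termination product groups
with the O12/O14 dimers through their shared C10H14O7·NO3⁻ channel before
joining unrelated spectra). Real spectra contain isotopologues,
multi-step fragments, chimeric precursors and electronic noise that the
simulator does not emulate, so these tests validate the software
contract, not instrument performance.

## Numerical choices and problem sizes

Matching tolerance 5 ppm throughout; intensity floor 0.1 % (inclusive);
display mask 0.2 (display only); electron-inclusive anion masses;
deterministic tie-breaks as above. Test simulations use the default
three-step NCE ladder over the shipped fixture sets (roughly a hundred
spectra per run), which keeps the full suite in the seconds range while
still exercising every stage end to end.

## Limitations

No isotope patterns, no elements beyond C/H/N/O, no multiply charged
ions, no vendor raw-file parsing (MGF and CSV only), no kinetics or
quantum-chemical energetics, and no automatic candidate generation — the
candidate trees are curated inputs. Which isomers dominate a real
atmosphere is an experimental question this package does not answer; it
reproduces the inference machinery, not the chemistry.
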