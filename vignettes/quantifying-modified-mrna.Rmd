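---
title: "Quantifying nucleoside-modified mRNA from UV absorbance"
author: "rnaMAC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleoside-modified mRNA from UV absorbance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaMAC)
```

## The problem

RNA concentration is routinely read off the absorbance at 260 nm through
the Beer-Lambert law, $A_{260} = \varepsilon_{260}\,l\,c$. For mRNA
therapeutics this is complicated twice over. First, folding makes the
absorption of an intact mRNA sequence-dependent, which is why accurate
protocols hydrolyze the RNA to mononucleotides before measuring: the
hydrolysate absorbs additively, so its molar absorption coefficient
(MAC) is simply the composition-weighted sum of nucleotide coefficients.
Second, the modified nucleosides used to blunt innate-immune sensing are
intrinsically hypochromic at 260 nm. N1-methylpseudouridine (m1Y)
absorbs roughly 40% less than uridine at 260 nm, 5-methylcytidine (m5C)
about 21% less than cytidine, and both modifications shift the
absorption peak to longer wavelengths. An m1Y-substituted mRNA therefore
absorbs less per mole than its unmodified isosequence, and applying
unmodified coefficients (or the legacy 40 µg/mL-per-absorbance-unit rule
of thumb) under-estimates its concentration by an amount that grows with
the uridine content of the sequence — several percent up to the
mid-teens for typical mRNA compositions.

rnaMAC makes the correction computable: it carries a registry of
photometric constants for standard, modified, and cap nucleosides,
computes the expected MAC~260~ of a hydrolyzed construct from its
composition, and converts absorbance measurements into concentrations
and amounts.

## The model

For a construct with residue counts $n_i$ and cap structure $k$,

$$\mathrm{MAC}_{260} \;=\; \sum_i n_i\,\varepsilon_{260}(i)
\;+\; \varepsilon_{260}^{\mathrm{cap}}(k),$$

with the molar concentration of a stock diluted $d$-fold before
measurement

$$c_{\mathrm{stock}} \;=\; \frac{A_{260}}
{\mathrm{MAC}_{260}\; l}\; d .$$

The additivity assumption is exactly what hydrolysis buys: base
stacking and pairing are gone, so each mononucleotide contributes its
own coefficient. Consequently the model targets *hydrolyzed* samples;
applying it to intact, folded RNA re-introduces a sequence-dependent
(folding) hypochromicity that the calculator deliberately does not
model.

Two derived quantities follow. The *hypochromicity ratio* of a
modification scheme is
$\mathrm{MAC}_{260}^{\mathrm{mod}}/\mathrm{MAC}_{260}^{\mathrm{unmod}}$
for the same sequence and cap, and the *under-estimation percent*,
$100\,(1 - \mathrm{ratio})$, is the error committed by quantifying the
modified construct with the unmodified coefficient. Because counts enter
the sum linearly, the ratio is exactly linear in the substitution
fraction — a property the test suite asserts to machine precision.

```{r}
tbl <- loadNucleosideTable()
sch <- modScheme("U", "m1Y")
round(hypochromicityRatio("UUUU", sch, "none", tbl), 4)
round(underestimationPercent("AUGGCUACGUAA", sch, "none", tbl), 1)
```

## The photometric registry

`loadNucleosideTable()` returns the builtin table: one entry per
nucleoside code with its peak wavelength `lambda_max` (nm), peak
coefficient `eps_max` and 260 nm coefficient `eps_260` (both
M^-1^ cm^-1^), and the average mass of the internal monophosphate
residue (g/mol); plus the cap entries `none`, `cap0` (m^7^GpppN), and
`cap1` (m^7^GpppNm).

```{r}
nucleosides(tbl)[, c("code", "lambda_max", "eps_max", "eps_260",
                     "residue_mass")]
capSpecs(tbl)[, c("code", "eps_260_add", "mass_add")]
```

The standard residues A/C/G/U are anchored on the revised 260 nm
ribonucleotide coefficients of Cavaluzzi & Borer (2004) — 15,020,
7,070, 12,080, and 9,660 M^-1^ cm^-1^ — which are the values modern
composition-based RNA calculators adopt. The modified entries are
placed relative to those anchors using the measured spectroscopic
differences between the nucleoside pairs: m5C sits 20.8% below cytidine
at 260 nm with a +7 nm peak shift, m1Y 39.8% below uridine at 260 nm
(21% below at the peak, which itself shifts +9 nm relative to
pseudouridine), and 5-methyluridine/thymidine 11.4% below uridine at
260 nm. Each entry records its provenance in a `source` field. Two
registry assumptions are worth stating:

* the coefficients describe nucleosides in neutral aqueous buffer
  (pH 7.4); no temperature, pH, or ionic-strength dependence is modelled;
* nucleoside and mononucleotide coefficients at 260 nm are treated as
  interchangeable, a difference well below the accuracy the tool claims.

The cap chromophore contribution (7-methylguanosine, ~7,400
M^-1^ cm^-1^ at neutral pH) is an approximate literature value; it is a
sub-percent term for any construct longer than a few hundred residues.
Cap1 adds a 2'-O-methyl — one CH~2~ of mass and no chromophore — so its
absorption contribution equals Cap0's by construction.

Every value can be overridden per code *and per field* through a config
file of blank-line-separated `key: value` blocks (the same format
`writeNucleosideTable()` emits), so replacing a single coefficient is a
two-line file:

```
code: U
eps_260: 9800
```

Delta operations expose the table's pairwise structure directly:
`deltaEpsilonPercent(tbl, ref, mod, mode)` returns
$100\,(\varepsilon_{\mathrm{mod}}-\varepsilon_{\mathrm{ref}})/\varepsilon_{\mathrm{ref}}$
at 260 nm or at the respective peaks, and `deltaLambdaMax()` the peak
shift in nm (positive = bathochromic).

## Sequences, schemes, and compositions

`readRNASequences()` accepts multi-record FASTA or headerless pasted
text, strips whitespace, digits and GenBank-style numbering,
upper-cases, and converts `T` to `U` with a warning (a strict mode
rejects it) — tolerances chosen because users paste DNA template
sequences and numbered GenBank blocks. Validation failures name the
offending characters and positions.

A modification scheme is a set of `canonical -> modified @ fraction`
rules (at most one per canonical residue), written `"U:m1Y"` or
`"U:m1Y:0.5"` on the command line. Full substitution (fraction 1) is the
standard IVT situation, where the modified triphosphate replaces the
canonical one in the reaction entirely; fractional substitution is a
deliberate generalization for doped transcription mixes. When a
fraction is applied, `applyScheme()` keeps counts real-valued rather
than rounding, so MAC~260~ stays *exactly* linear in the fraction;
`discreteCounts()` rounds half-up only when an integer composition
report is requested.

## Molecular weight

`molecularWeight()` uses the closed formula
$\sum_i n_i m_i + m_{\mathrm{H_2O}} + \mathrm{end}$,
with average (not monoisotopic) residue masses in the free-acid
convention, so results reconcile with vendor oligonucleotide
calculators. The 5'-end term is `+2 HPO3` (+159.96 g/mol) for a
triphosphate — the default, since that is what uncapped T7 transcripts
carry — `0` for a 5'-monophosphate, and `-HPO3` (−79.98) for a
5'-hydroxyl. For capped constructs the cap's `mass_add` (the m^7^G
moiety plus its two bridging phosphates) replaces the end term; the
first transcribed nucleotide belongs to the sequence and is never
double-counted.

## Quantification

`concentrationFromA260()` applies the Beer-Lambert inversion above and
reports the stock in nM and ng/µL (the two are linked by the molecular
weight: ng/µL = nM × MW × 10^-6^); `totals()` multiplies by the stock
volume to get µmol and µg. Every report also carries the legacy
40 µg/mL × A~260~ × dilution estimate for side-by-side comparison.

`fitDilutionSeries()` implements the serial-dilution workflow: replicate
A~260~ readings at several fold-dilutions are averaged per point and
regressed against 1/dilution by ordinary least squares. The slope equals
$\mathrm{MAC}_{260}\, l\, c_{\mathrm{stock}}$, so one fit uses the whole
ladder and damps pipetting/handling error on any single point. The
regression is fitted *with* an intercept: nothing in the physics puts
mass at 1/dilution → 0, so a fitted intercept is a pure diagnostic, and
one beyond ±0.005 AU (about the reproducibility floor of a benchtop
photometer) raises a blank/baseline warning. Fitting through the origin
would silently absorb exactly the handling errors the workflow exists to
expose, which is why the intercept-with-warning design was chosen. A
series with a single dilution point falls back to the direct
single-reading computation on the replicate mean; `pooled = TRUE`
regresses every replicate instead of per-point means (identical slope on
balanced designs).

`fitBeerLambert()` solves the inverse calibration problem — known
concentrations, measured absorbances — returning the OLS slope divided
by the path length as the coefficient estimate together with the Pearson
correlation; a sound calibration exceeds r = 0.9999, and readings above
1.0 AU trigger a linear-range warning.

Defaults: path length 1 cm (microvolume instruments that normalize
internally already report 1 cm equivalents), dilution 1. Human-readable
output rounds to 4 significant figures; machine-readable JSON keeps full
precision.

## Synthetic data and what the tests do (and do not) show

`randomSequence()` draws multinomial sequences at given base fractions
and `simulateSeries()` generates replicate dilution-ladder readings as

$$A = \mathrm{MAC}_{260}\, l\, \frac{c}{d}\,(1 + \mathcal{N}(0,
\mathrm{CV})),$$

with multiplicative (constant-CV) noise, because photometric replicate
error scales with the signal; both are pure functions of their seed, and
the generated truth travels inside the series object. The validation
suite uses 1,000 random sequences of 1–2,000 nt against an independent
per-residue summation oracle, and 200 simulated 6-point × 3-replicate
ladders at 1% CV (default conditions: dilutions 10–320, which keep a
typical stock inside the 0–1 AU linear range), recovering the stock
concentration with sub-1% median error. These sizes make the whole
suite run in about a minute while leaving the Monte-Carlo medians
stable.

What the simulations emulate is *measurement* noise on an ideal
hydrolysate. They do not emulate folding, incomplete hydrolysis,
cytosine deamination during harsh alkaline treatment, buffer absorbance,
or instrument nonlinearity above 1 AU — so passing tests demonstrate the
arithmetic and the regression machinery, not robustness to a misbehaving
wet-lab workflow. Likewise the under-estimation band check (values
spanning roughly 5–15% across uridine fractions 0.15–0.35) is a
qualitative bracket on synthetic compositions, not a reproduction of any
particular construct.

## Numerical choices and degenerate inputs

* Empty sequences are legal compositions with MAC~260~ = 0; asking for a
  concentration or hypochromicity ratio from them raises an explicit
  error rather than returning Inf/NaN.
* Substitution rules whose canonical residue is absent are no-ops (a
  U→m1Y scheme on a U-free sequence gives ratio 1, under-estimation 0).
* Replicate averaging is unweighted; dilution factors must be ≥ 1 and
  absorbances ≥ 0, enforced at object construction.
* Counts are conserved under schemes to machine precision; the
  mass-extinction identity `1000 × MW / MAC260` is enforced by the
  class validity at 10^-9^ relative.
* All simulation tests run under fixed recorded seeds.

## Limitations

* The modified-nucleoside coefficients are placed relative to the
  revised standard anchors via published relative differences; absolute
  re-measurements would slot in through the override config without code
  changes.
* The cap contribution uses an approximate m^7^G coefficient; for short
  RNAs (< ~100 nt) where the cap term matters proportionally more,
  override it with a measured value.
* Single-condition table (neutral pH, aqueous buffer); strongly acidic
  or basic measurement conditions shift pyrimidine spectra and are not
  corrected.
* The calculator predicts properties of the *hydrolyzed* construct;
  A~260~ readings of intact mRNA will under-read against it by the
  folding hypochromicity.
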