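---
title: "Quantifying ISH signal by genotype: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ISH signal by genotype: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ishquant)
```

## The measurement model

Chromogenic in situ hybridisation (ISH) deposits stain in proportion to
local transcript abundance, so on an inverted 8-bit grayscale image the
staining reads as *high* intensity. Each embryo is scored as

$$ s = \bar{I}_{\text{signal ROI}} - \bar{I}_{\text{background ROI}}, $$

the mean inverted pixel intensity of a hand-drawn polygon over the
stained dorsal aorta minus that of an equal-area polygon over unstained
tissue dorsal to the notochord. The subtraction removes the embryo-wide
intensity offset — anything additive and (approximately) uniform across
the two ROIs cancels, including staining-independent background and slow
illumination gradients, which is why the score is comparable across
embryos imaged in one session. The score is kept in floating precision
(only stored images are 8-bit) and may legitimately be negative when the
background region happens to be darker than the signal region; negative
scores are flagged but retained, since truncating them would bias group
means upward.

Because embryos from a heterozygous incross are genotyped *after*
imaging (PCR + restriction digest on DNA extracted from the stained
embryo), quantification is blind to genotype. The package enforces this
at the interface level: `quantify_clutch()` reads only images and ROI
files, and its output table has no genotype column.

### Image-processing conventions

* **Grayscale conversion** uses the unweighted channel mean
  (the ImageJ default conversion), rounded half-to-even. Rec. 601
  luminance weights are available via the `weights` argument of
  `to_grayscale_8bit()`; the choice is irrelevant for gray-rendered
  stains but matters for strongly coloured chromogens.
* **Pixel/polygon convention**: 0-based pixel coordinates, x = column,
  y = row. A pixel belongs to an ROI iff its center (x + 0.5, y + 0.5)
  is inside the polygon under the even-odd rule; ties on edges follow
  the half-open ray-casting convention so abutting polygons tile the
  plane without double-counting. An axis-aligned rectangle with corners
  (0,0)–(5,4) therefore contains exactly 20 pixels.
* **Equal-area tolerance**: the background polygon should be a copy of
  the signal shape, but hand-redrawn polygons are never pixel-identical,
  so `score_embryo()` accepts a relative area mismatch up to 1% by
  default and errors beyond it. `translate_roi()` clones the signal
  polygon at an offset, guaranteeing equal area by construction.

## RFLP genotyping in silico

A mutation that destroys a restriction site converts a two-band digest
into a single band. `digest()` implements complete digestion of a linear
molecule: every occurrence of the (possibly IUPAC-degenerate) recognition
site is located — overlapping occurrences included — and fragment lengths
are differences of consecutive top-strand cut coordinates. Two
conventions matter:

* **Top-strand cut offsets** (HaeII = RGCGC^Y, offset 5; SacII =
  CCGC^GG, offset 4, the standard REBASE notation): gel band sizes
  ignore sticky-end overhangs, so only top-strand coordinates are used.
* **N never matches**: an `N` in the *sequence* matches no pattern code,
  conservatively preventing phantom sites in low-quality sequence.
  Circular molecules are unsupported — amplicons are linear.

`expected_band_patterns()` derives the WT/HET/MUT band sets from an
allele pair (HET is the union of distinct bands of both alleles), and
`call_genotype()` matches observed bands against them with a ±5 bp
per-band tolerance, the resolution of a 2% agarose gel; bands closer
together than the tolerance are merged first, since such doublets
co-migrate. Anything ambiguous returns `"UNKNOWN"` — a value, not an
error — and `UNKNOWN` embryos are excluded from inference but reported
in the accounting table.

## The statistical battery

`ish_fit(score ~ genotype, data)` runs the decision tree used for
score-by-genotype comparisons and returns a classed object with
`print()`, `summary()`, `coef()` and `plot()` methods:

1. **Normality / transform**: Shapiro–Wilk at α = 0.05 stands in for a
   visual Q–Q check (`sqrt_transform_if_needed()`); a square-root
   transform is applied only to non-normal, non-negative samples.
   Negative scores block the transform (and are the reason it cannot be
   unconditional).
2. **Levene's test** on absolute deviations from the group *mean* (the
   SPSS default; median-centering available) decides at α = 0.05
   whether variances are treated as unequal.
3. **Location test**: two groups get a pooled or Welch t-test; three or
   more get the standard or Welch one-way ANOVA, with both ANOVA
   variants always computed and reported.
4. **Post-hoc**: Tukey HSD under equal variances, Games–Howell
   otherwise (unpooled standard errors, per-pair Welch–Satterthwaite
   df, p-values from the studentized range with q = |t|·√2).
5. **Power block** (two groups): Cohen's d from the pooled sd, post-hoc
   power from the noncentral t distribution with noncentrality
   δ = d·√(n/2) and df = 2n − 2, and the smallest per-group n reaching a
   target power (default 90%), found by incrementing n from 2 — exact
   minimality, cheap at these scales, no asymptotic approximation.

Every location test accepts either raw vectors or `(n, mean, sd)`
summaries (`group_summary()`). Summary mode is not a convenience: t, F,
d and power are functions of the summaries alone, and published group
tables rarely come with raw data. Note that statistics recomputed from
*rounded* published summaries reproduce printed values only to the
rounding granularity — e.g. a three-group Welch ANOVA from two-decimal
means and two-digit CVs can shift F by a few percent.

Distribution functions come from base R (`pt` with noncentrality,
`ptukey`, `pf`, `pchisq`); the test suite validates them and our use of
them against Monte-Carlo rejection-rate estimates rather than trusting
either path alone.

### qPCR

`delta_ct()` is mean(target Ct) − mean(housekeeping Ct) per embryo;
expression relative to the housekeeping gene is 2^−ΔCt. Group
comparison defaults to the ΔCt scale, where Ct noise is closest to
normal. Percent change between groups is reported under *both*
conventions — from group-mean ΔCts, 1 − 2^−(ΔCt_B − ΔCt_A), and from
group means of per-embryo levels — because the two differ whenever ΔCt
varies, and published percentages rarely state which was used.

## What the synthetic generator emulates

`generate_clutch()` renders, per embryo: a light field, an elliptical
embryo body, a horizontal "dorsal aorta" stripe whose post-inversion
mean intensity over the signal ROI equals a per-embryo draw from
Normal(µ_g, (CV_g·µ_g)²) truncated at 0, additive Gaussian pixel noise,
and a linear left-right illumination gradient. Genotypes are multinomial
(default Mendelian 1:2:1). Defaults are the study conditions of a
characterised mutant incross: µ = 54/50.1/26.3 intensity units and CV =
0.24/0.22/0.21 for WT/HET/MUT — a mutant that halves the signal, with
the 20–25% biological dispersion typical of ISH staining; noise_sd = 5
and a 10-unit gradient are of the order seen in bright-field
acquisitions. Intensity truth is defined post-inversion so generator
parameters live on the same scale as measured scores. One clutch RNG
(from `seed`) draws genotypes, intensities and per-embryo sub-stream
seeds, making whole datasets byte-reproducible.

The generator emulates what the measurement needs — genotype-conditional
mean staining, biological dispersion, pixel noise, gradients — and *not*
what it does not: no optics (PSF, depth of field), no embryo-to-embryo
morphological variation, no staining texture along the vessel, no
saturated stain. Passing tests therefore demonstrate that the pipeline
recovers known intensities under controlled corruption, not that it
handles every real-world imaging pathology.

Score-level simulation studies use `simulate_scores()` — the same
genotype and intensity model without rendering — which is how the
repeated-clutch batteries (100 clutches for the significance pattern,
2000 for null calibration) stay fast; full rendering is exercised
end-to-end on single clutches (40–60 embryos, 128×196 px), where
measured scores correlate with truth at r > 0.95 under noise_sd = 5.

Allele pairs for RFLP are built by `generate_allele_pair()`: a random
amplicon receives exactly one concrete realisation of the recognition
site at the position that yields the requested fragment lengths; the
mutant destroys it by substituting the least-degenerate site base or by
deleting k bases spanning the site. Both alleles are verified by
digestion, and constructions that acquire spurious sites are redrawn
(bounded retries). qPCR tables centre technical-replicate noise within
each triplicate, so the embryo-level ΔCt follows the requested normal
law exactly — replicate scatter is cosmetic, which is precisely what a
ΔCt-level simulation needs.

## Numerical and design notes

* Digestion conserves length exactly (integer identity), cuts at
  position 0 or L are dropped rather than emitting empty fragments.
* Welch ANOVA flags any zero-variance group (infinite weights) instead
  of returning a misleading statistic; pooled t with zero pooled
  variance returns t = 0 for equal means and a flagged infinite t
  otherwise; the Welch df collapses to n − 1 of the variable group when
  one sd is 0.
* The χ² test applies the Yates continuity correction iff the table is
  2×2 (default on), and errors on zero marginals.
* `ish_fit`'s two-group power block uses the geometric-mean group size
  as the balanced-equivalent n; the sample-size search answers "n per
  group" for a balanced follow-up design.
* The CLI (`inst/cli/ishquant.R`) is a thin argument-parsing shell over
  exported functions; exit codes 0/2/3 distinguish success, config and
  data errors.

## Known limitations

ROIs are inputs, not outputs: there is no automated vessel segmentation,
no ImageJ binary `.roi` import, and no colour deconvolution. Primer
binding is exact-match only (no thermodynamics, no mismatch tolerance),
digestion is complete (no partial-digest ladders), and gel mobility is
not modelled beyond the ±5 bp band tolerance. qPCR quantification
assumes equal amplification efficiencies (no Pfaffl correction, no
standard curves, single reference gene).
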